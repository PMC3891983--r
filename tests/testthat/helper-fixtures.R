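# Shared fixtures and independent oracles.

# a tiny deterministic labeled dataset: 6 deaths, 4 items, 2 causes
tiny_dataset <- function() {
  X <- rbind(c(1, 1, 0, 0),
             c(1, 0, 0, 1),
             c(1, 1, 0, 0),
             c(0, 0, 1, 0),
             c(0, 1, 1, 1),
             c(0, 0, 1, 0))
  items <- va_items(paste0("it", 1:4), is_hce = c(FALSE, FALSE, FALSE, TRUE))
  va_dataset(X, items, gold_cause = rep(c("A", "B"), each = 3))
}

# a generator dataset at a small, fast scale
gen_dataset <- function(n_causes = 5, n_items = 25, signal = 0.9,
                        base = 0.05, n = 600, seed = 11, fr = NULL) {
  prof <- make_cause_profiles(n_causes, n_items, signal = signal,
                              base = base, n_hce = 5, n_text = 5,
                              seed = seed)
  fr <- fr %||% csmf(rep(1 / n_causes, n_causes), prof$causes)
  list(profiles = prof,
       data = simulate_deaths(prof, fr, n, seed = seed + 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- brute-force Bayes oracles -------------------------------------------
# Enumerate every binary profile and its probability under independent
# Bernoulli conditionals, with plain products (no logs) — an independent
# path to the posteriors the classifiers compute.

all_profiles <- function(m) {
  as.matrix(expand.grid(rep(list(0:1), m)))
}

# P(profile | cause) table: 2^m x k, by direct product enumeration
oracle_profile_probs <- function(P) {
  prof <- all_profiles(nrow(P))
  t(apply(prof, 1, function(x)
    apply(P, 2, function(p) prod(ifelse(x == 1, p, 1 - p)))))
}

# joint posterior over causes for each row of X
oracle_joint_posterior <- function(X, P, prior) {
  t(apply(X, 1, function(x) {
    lik <- apply(P, 2, function(p) prod(ifelse(x == 1, p, 1 - p)))
    num <- lik * prior
    num / sum(num)
  }))
}

# one-vs-rest posterior for each cause, against the composite complement
# whose conditionals are the prior-weighted mixture of the other causes
oracle_ovr_posterior <- function(X, P, prior) {
  k <- ncol(P)
  mix <- as.vector(P %*% prior)
  sapply(seq_len(k), function(j) {
    q <- (mix - P[, j] * prior[j]) / (1 - prior[j])
    apply(X, 1, function(x) {
      a <- prior[j] * prod(ifelse(x == 1, P[, j], 1 - P[, j]))
      b <- (1 - prior[j]) * prod(ifelse(x == 1, q, 1 - q))
      a / (a + b)
    })
  })
}

# per-cause recall computed by brute force over the label vectors
oracle_recall <- function(true, pred, causes) {
  vapply(causes, function(cj) {
    hits <- 0; tot <- 0
    for (i in seq_along(true)) {
      if (true[i] == cj) {
        tot <- tot + 1
        if (!is.na(pred[i]) && pred[i] == cj) hits <- hits + 1
      }
    }
    if (tot == 0) NA_real_ else hits / tot
  }, numeric(1))
}
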