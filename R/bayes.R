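# Bayes-theorem symptom classifiers.
#
# Two variants span the design space between InterVA-style expert-prior
# classification and data-driven symptom-pattern classification:
#
# * `interva_assign()` computes, under conditional independence of items
#   given cause, the joint posterior across all causes at once from a
#   (possibly expert-supplied) conditional-probability matrix, optionally
#   on a restricted item set and with an indeterminate threshold.
# * `ssp_assign()` fits the conditionals from training data and computes
#   one-vs-rest posteriors per cause on many random symptom subsets,
#   averaging over the draws; the subsets bound how much conditional
#   dependence any single product term assumes.
#
# All likelihood products are accumulated in the log domain: with ~150
# items a direct product underflows double precision.

#' Fit cause-conditional endorsement probabilities from data
#'
#' `P[i, j] = (endorsements of i among cause-j deaths + smoothing) /
#' (cause-j deaths + 2 * smoothing)`. With positive smoothing no
#' probability is exactly 0 or 1, so no single item can veto a cause.
#'
#' @param train a labeled `va_dataset` with at least one death per cause.
#' @param smoothing additive (beta-binomial) smoothing count.
#' @return a `cause_profiles` object with `provenance = "fitted"`.
#' @export
fit_conditionals <- function(train, smoothing = 1) {
  if (is.null(train$gold_cause)) stop_schema("training data must be labeled")
  causes <- train$causes
  idx <- split(seq_len(n_deaths(train)),
               factor(train$gold_cause, levels = causes))
  if (any(!lengths(idx)))
    stop_schema("cause(s) with zero deaths: ",
                paste(causes[!lengths(idx)], collapse = ", "))
  P <- vapply(idx, function(i)
    (colSums(train$X[i, , drop = FALSE]) + smoothing) /
      (length(i) + 2 * smoothing),
    numeric(n_items(train)))
  P <- matrix(P, nrow = n_items(train),
              dimnames = list(colnames(train$X), causes))
  structure(list(P = P, items = train$items, causes = causes,
                 signal_items = NULL, provenance = "fitted"),
            class = "cause_profiles")
}

# log-likelihood matrix (deaths x causes) of binary profiles under
# independent Bernoulli conditionals
bernoulli_loglik <- function(X, P) {
  logP <- suppressWarnings(log(P))
  log1mP <- suppressWarnings(log1p(-P))
  logP[P == 0] <- -Inf
  log1mP[P == 1] <- -Inf
  L <- X %*% ifelse(is.finite(logP), logP, 0) +
    (1 - X) %*% ifelse(is.finite(log1mP), log1mP, 0)
  # reinstate -Inf where an endorsed item has P = 0 (or non-endorsed P = 1)
  if (any(P == 0) || any(P == 1)) {
    bad <- (X %*% (P == 0)) + ((1 - X) %*% (P == 1))
    L[bad > 0] <- -Inf
  }
  L
}

#' Joint-posterior naive-Bayes assignment (InterVA-style)
#'
#' Computes, for each death, the posterior distribution across all causes
#' at once: `post(j)` proportional to `prior(j)` times the product over
#' the (optionally restricted) items of `P[i,j]` if endorsed and
#' `1 - P[i,j]` otherwise. The death is assigned the argmax cause when its
#' posterior mass reaches `threshold`, and is otherwise indeterminate; a
#' death whose likelihood vanishes for every cause is always
#' indeterminate. The predicted CSMF is the assignment-count composition
#' over determinate deaths.
#'
#' @param test a `va_dataset`.
#' @param conditionals a `cause_profiles` object — expert-supplied (e.g.
#'   via [read_conditionals_csv()]) or fitted with [fit_conditionals()].
#' @param prior prior CSMF over causes (default uniform).
#' @param restricted_items optional character vector of item ids to use
#'   (InterVA uses a restricted sign/symptom set); default all items of
#'   the conditional matrix.
#' @param threshold minimum posterior mass required to assign (default 0:
#'   always assign, so CSMF comparisons need no indeterminate
#'   redistribution rule).
#' @return a `va_assignment` with the posterior matrix attached.
#' @export
interva_assign <- function(test, conditionals, prior = NULL,
                           restricted_items = NULL, threshold = 0) {
  P <- conditionals$P
  if (!is.null(restricted_items)) {
    missing <- setdiff(restricted_items, rownames(P))
    if (length(missing))
      stop_schema("conditionals do not cover item(s): ",
                  paste(missing, collapse = ", "))
    P <- P[restricted_items, , drop = FALSE]
  }
  causes <- conditionals$causes
  prior <- if (is.null(prior)) csmf(rep(1 / length(causes), length(causes)),
                                    causes) else csmf(prior, names(prior) %||% causes)
  X <- align_items(test, rownames(P))
  L <- bernoulli_loglik(X, P)
  lp <- sweep(L, 2, log(as.numeric(prior)), "+")
  m <- apply(lp, 1, max)
  post <- exp(lp - ifelse(is.finite(m), m, 0))
  tot <- rowSums(post)
  indeterminate <- tot == 0 | !is.finite(m)
  post <- post / ifelse(tot > 0, tot, NA_real_)
  best <- max.col(ifelse(is.na(post), -Inf, post), ties.method = "first")
  top <- post[cbind(seq_len(nrow(post)), best)]
  cause <- ifelse(!indeterminate & top >= threshold, causes[best], NA)
  colnames(post) <- causes
  new_va_assignment(cause, causes, posterior = post)
}

# composite "not-j" conditionals: mixture of the other causes' profiles
# weighted by their prior shares
composite_rest <- function(P, prior) {
  pr <- as.numeric(prior)
  mix <- as.vector(P %*% pr)          # marginal endorsement probability
  sweep(mix - sweep(P, 2, pr, "*"), 2, 1 - pr, "/")
}

#' One-vs-rest symptom-pattern assignment with subset resampling (SSP)
#'
#' Fits conditionals from training data, then for each of `n_draws`
#' random subsets of `subset_size` items computes, for every cause j, the
#' two-class posterior P(j | subset pattern) against the composite
#' complement whose conditionals are the prior-weighted mixture of the
#' other causes' profiles. Per-cause posteriors are averaged over draws
#' and each death is assigned its argmax cause. With `n_draws = 1` and
#' the full item set this reduces, for two causes, to the joint
#' naive-Bayes posterior.
#'
#' @param test a `va_dataset`.
#' @param train a labeled `va_dataset`.
#' @param subset_size items per draw (<= size of the item pool).
#' @param n_draws number of random subsets.
#' @param item_pool character vector of item ids to draw from. Default:
#'   the items with at least one significant tariff when a `tariff` fit
#'   is supplied, otherwise all training items.
#' @param tariff optional `tariff_fit`; its significant items define the
#'   default pool (the classifier consumes tariff output as input).
#' @param smoothing passed to [fit_conditionals()].
#' @param prior prior CSMF (default: the training composition).
#' @param seed integer seed for the subset draws.
#' @return a `va_assignment`; `posterior` holds the averaged per-cause
#'   one-vs-rest posteriors (each in `[0, 1]`, no sum constraint).
#' @export
ssp_assign <- function(test, train, subset_size = 16, n_draws = 100,
                       item_pool = NULL, tariff = NULL, smoothing = 1,
                       prior = NULL, seed = NULL) {
  cond <- fit_conditionals(train, smoothing)
  causes <- cond$causes
  if (is.null(item_pool)) {
    item_pool <- if (!is.null(tariff))
      tariff$items[rowSums(tariff$tariffs$significant) > 0]
    else colnames(train$X)
  }
  item_pool <- intersect(item_pool, rownames(cond$P))
  if (subset_size > length(item_pool))
    stop_schema("subset_size exceeds the item pool (", length(item_pool), ")")
  prior <- if (is.null(prior)) empirical_csmf(train$gold_cause, causes)
           else csmf(prior, names(prior) %||% causes)
  pr <- as.numeric(prior)
  P <- cond$P
  Q <- composite_rest(P, prior)
  X <- align_items(test, rownames(P))
  post_sum <- matrix(0, nrow(X), length(causes),
                     dimnames = list(NULL, causes))
  with_seed_(seed, function() {
    for (d in seq_len(n_draws)) {
      S <- sample(item_pool, subset_size)
      La <- bernoulli_loglik(X[, S, drop = FALSE], P[S, , drop = FALSE])
      Lb <- bernoulli_loglik(X[, S, drop = FALSE], Q[S, , drop = FALSE])
      # P(j | S) = 1 / (1 + exp(log[(1-pi_j) P(S|not j)] - log[pi_j P(S|j)]))
      delta <- sweep(Lb, 2, log(1 - pr), "+") - sweep(La, 2, log(pr), "+")
      post_sum <<- post_sum + 1 / (1 + exp(delta))
    }
  })
  post <- post_sum / n_draws
  best <- max.col(post, ties.method = "first")
  new_va_assignment(causes[best], causes, posterior = post)
}
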