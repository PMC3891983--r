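# Synthetic VA data with known cause-conditional endorsement structure.
#
# The generator draws a cause for each death from a CSMF and then item
# indicators as independent Bernoulli draws with probability
# P[item, cause] — the same conditional-independence structure the
# naive-Bayes classifiers assume, which makes their small-instance
# behaviour exactly checkable against enumeration.

#' Build synthetic cause-conditional endorsement profiles
#'
#' Each cause receives a distinct block of "signal" items endorsed with
#' probability `base + signal * (1 - base)`; every other item is endorsed
#' at the background rate `base`. At `signal = 1, base = 0` the causes are
#' perfectly separable; at `signal = 0` every cause has an identical
#' profile and the items carry no information. A chosen number of items is
#' flagged as health-care-experience (HCE) and a trailing block is marked
#' as free-text token indicators, mirroring the composition of a real VA
#' instrument.
#'
#' @param n_causes number of causes (default 34, the adult-module scale).
#' @param n_items total number of items (>= `n_causes`; default 150,
#'   roughly 100 structured plus 50 free-text token items).
#' @param signal signal strength in `[0, 1]`.
#' @param base background endorsement probability.
#' @param n_hce number of items flagged `is_hce` (drawn at random).
#' @param n_text number of trailing items marked `free_text_token`.
#' @param seed integer seed; the same seed reproduces the same profiles.
#' @return a list of class `cause_profiles` with `P` (items x causes
#'   probability matrix), `items` (metadata), `causes`, `signal_items`
#'   (per-cause item-id list) and `provenance = "synthetic-truth"`.
#' @export
make_cause_profiles <- function(n_causes = 34, n_items = 150, signal = 0.8,
                                base = 0.05, n_hce = 30, n_text = 50,
                                seed = NULL) {
  if (n_items < n_causes)
    stop_schema("cannot assign a signal block per cause: n_items < n_causes")
  if (n_hce < 0 || n_hce > n_items) stop_schema("n_hce out of range")
  if (n_text < 0 || n_text > n_items) stop_schema("n_text out of range")
  if (signal < 0 || signal > 1 || base < 0 || base > 1)
    stop_schema("signal and base must lie in [0, 1]")
  with_seed_(seed, function() {
    causes <- sprintf("cause_%02d", seq_len(n_causes))
    n_struct <- n_items - n_text
    ids <- c(sprintf("item_%03d", seq_len(n_struct)),
             if (n_text) sprintf("word_%03d", seq_len(n_text)))
    P <- matrix(base, n_items, n_causes, dimnames = list(ids, causes))
    block <- n_items %/% n_causes
    signal_items <- vector("list", n_causes)
    for (j in seq_len(n_causes)) {
      rows <- ((j - 1) * block + 1):(j * block)
      P[rows, j] <- base + signal * (1 - base)
      signal_items[[j]] <- ids[rows]
    }
    names(signal_items) <- causes
    is_hce <- rep(FALSE, n_items)
    if (n_hce) is_hce[sample.int(n_items, n_hce)] <- TRUE
    items <- va_items(ids, age_module = "adult",
                      source = rep(c("structured", "free_text_token"),
                                   c(n_struct, n_text)),
                      is_hce = is_hce)
    structure(list(P = P, items = items, causes = causes,
                   signal_items = signal_items,
                   provenance = "synthetic-truth"),
              class = "cause_profiles")
  })
}

#' @export
print.cause_profiles <- function(x, ...) {
  cat("cause_profiles (", x$provenance, "): ", nrow(x$P), " items x ",
      ncol(x$P), " causes\n", sep = "")
  invisible(x)
}

#' Read a cause-conditional probability matrix from CSV
#'
#' Accepts an items x causes matrix of endorsement probabilities (first
#' column item ids, remaining columns one per cause), so that a published
#' expert probability base can be dropped in without code changes.
#'
#' @param path CSV path.
#' @param provenance recorded provenance tag.
#' @return a `cause_profiles` object (items default to structured,
#'   non-HCE).
#' @export
read_conditionals_csv <- function(path, provenance = "expert") {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  P <- as.matrix(df[-1])
  rownames(P) <- df[[1]]
  if (any(P < 0 | P > 1)) stop_schema("probabilities must lie in [0, 1]")
  structure(list(P = P, items = va_items(rownames(P)),
                 causes = colnames(P), signal_items = NULL,
                 provenance = provenance),
            class = "cause_profiles")
}

#' Simulate deaths from cause profiles
#'
#' Draws `n` causes i.i.d. from `true_csmf`, then item indicators as
#' independent Bernoulli(P[item, cause]) draws.
#'
#' @param profiles a `cause_profiles` object.
#' @param true_csmf a [csmf()] vector over the profile causes.
#' @param n number of deaths.
#' @param seed integer seed.
#' @return a labeled `va_dataset`.
#' @export
simulate_deaths <- function(profiles, true_csmf, n, seed = NULL) {
  stopifnot(inherits(profiles, "cause_profiles"), n >= 1)
  true_csmf <- csmf(true_csmf, names(true_csmf) %||% profiles$causes)
  if (!identical(names(true_csmf), profiles$causes))
    stop_schema("csmf causes do not match the profiles")
  with_seed_(seed, function() {
    k <- length(profiles$causes)
    ci <- sample.int(k, n, replace = TRUE, prob = as.numeric(true_csmf))
    # deaths x items matrix of Bernoulli draws at the cause-specific rates
    Pt <- t(profiles$P)            # causes x items
    U <- matrix(runif(n * ncol(Pt)), n)
    X <- (U < Pt[ci, , drop = FALSE]) * 1L
    colnames(X) <- rownames(profiles$P)
    va_dataset(X, profiles$items,
               death_id = sprintf("d%06d", seq_len(n)),
               gold_cause = profiles$causes[ci], causes = profiles$causes)
  })
}

#' Write the generator truth (profiles + CSMF) as JSON
#'
#' @param profiles a `cause_profiles` object.
#' @param true_csmf the CSMF the deaths were simulated from.
#' @param path JSON path.
#' @export
write_truth_json <- function(profiles, true_csmf, path) {
  jsonlite::write_json(
    list(causes = profiles$causes, items = rownames(profiles$P),
         P = apply(profiles$P, 2, identity, simplify = FALSE),
         csmf = as.list(setNames(as.numeric(true_csmf), names(true_csmf))),
         provenance = profiles$provenance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
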