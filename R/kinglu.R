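# King-Lu style direct estimation of cause fractions.
#
# Rather than assigning a cause to each death, the method works at the
# population level: for a subset S of items, the distribution of observed
# symptom profiles in the test data, b(profile), is (in expectation) the
# mixture A %*% f of the cause-conditional profile distributions A
# estimated from training data, where f is the test CSMF. Solving
# A f = b under f >= 0, sum(f) = 1 for many random small subsets and
# averaging the solutions estimates the CSMF directly.

# profile distribution of X over item columns S: vector of length 2^|S|
profile_dist <- function(X, S) {
  code <- as.vector(X[, S, drop = FALSE] %*% 2^(seq_along(S) - 1)) + 1L
  tabulate(code, nbins = 2^length(S)) / nrow(X)
}

# constrained least squares: minimize ||A f - b||^2 s.t. sum f = 1, f >= 0
solve_simplex_ls <- function(A, b, ridge = 1e-9) {
  k <- ncol(A)
  D <- 2 * crossprod(A) + ridge * diag(k)
  d <- 2 * crossprod(A, b)
  Amat <- cbind(rep(1, k), diag(k))
  sol <- quadprog::solve.QP(D, d, Amat, bvec = c(1, rep(0, k)), meq = 1)
  pmax(sol$solution, 0)
}

#' Direct estimation of the test CSMF from profile distributions
#'
#' For each of `n_subsets` random item subsets of size `subset_size`, the
#' test profile distribution is regressed on the train cause-conditional
#' profile distributions by constrained least squares on the simplex
#' (nonnegativity and sum-to-one imposed at the solver, not by clipping).
#' The per-subset solutions are combined by (optionally trimmed)
#' element-wise mean and renormalized. No individual-level assignment is
#' produced; individual metrics (CCC, kappa) are undefined for this
#' method.
#'
#' @param train a labeled `va_dataset`.
#' @param test a `va_dataset` on the same items.
#' @param subset_size items per subset; profile tables have `2^subset_size`
#'   cells, so small values (default 8) keep them estimable.
#' @param n_subsets number of random subsets averaged (default 300).
#' @param trim trimming fraction for the element-wise mean (default 0).
#' @param seed integer seed for the subset draws.
#' @param ridge diagonal regularization keeping the quadratic program
#'   positive definite when profile columns collide.
#' @return a [csmf()] vector with attributes `n_used` (subsets solved) and
#'   `n_failed`.
#' @export
estimate_csmf_direct <- function(train, test, subset_size = 8,
                                 n_subsets = 300, trim = 0, seed = NULL,
                                 ridge = 1e-9) {
  if (is.null(train$gold_cause)) stop_schema("training data must be labeled")
  items <- intersect(colnames(train$X), colnames(test$X))
  if (subset_size > length(items))
    stop_schema("subset_size exceeds the shared item set")
  causes <- train$causes
  idx <- split(seq_len(n_deaths(train)),
               factor(train$gold_cause, levels = causes))
  if (any(!lengths(idx)))
    stop_schema("cause(s) with zero deaths: ",
                paste(causes[!lengths(idx)], collapse = ", "))
  sols <- with_seed_(seed, function() {
    out <- matrix(NA_real_, n_subsets, length(causes))
    for (s in seq_len(n_subsets)) {
      S <- sample(items, subset_size)
      b <- profile_dist(test$X, match(S, colnames(test$X)))
      A <- vapply(idx, function(i)
        profile_dist(train$X[i, , drop = FALSE], match(S, colnames(train$X))),
        numeric(2^subset_size))
      f <- tryCatch(solve_simplex_ls(A, b, ridge), error = function(e) NULL)
      if (!is.null(f)) out[s, ] <- f
    }
    out
  })
  ok <- stats::complete.cases(sols)
  if (!any(ok))
    stop_schema("direct estimation failed: the constrained solve was ",
                "degenerate on every item subset")
  est <- apply(sols[ok, , drop = FALSE], 2, mean, trim = trim)
  est <- pmax(est, 0)
  out <- csmf(est / sum(est), causes)
  attr(out, "n_used") <- sum(ok)
  attr(out, "n_failed") <- sum(!ok)
  out
}
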