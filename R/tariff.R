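# The Tariff classifier.
#
# A tariff is a robust standardized score measuring how far an item's
# endorsement rate for one cause sits from its rates across all causes:
# tariff(i, j) = (x[i,j] - median_j' x[i,j']) / IQR_j' x[i,j'], with
# percentiles by linear interpolation and a floor on the IQR. A death's
# score against cause j is the sum of tariffs over its endorsed items,
# restricted to the statistically significant, top-ranked items for that
# cause. Assignment is by rank against a uniform-cause reference pool, so
# that scores are comparable across causes and the training composition
# cannot leak into the prediction.

#' Cause-specific item endorsement rates
#'
#' @param train a labeled `va_dataset`; every cause must have at least one
#'   death.
#' @return items x causes matrix; entry (i, j) is the fraction of cause-j
#'   deaths endorsing item i.
#' @export
endorsement_rates <- function(train) {
  if (is.null(train$gold_cause)) stop_schema("training data must be labeled")
  causes <- train$causes
  idx <- split(seq_len(n_deaths(train)),
               factor(train$gold_cause, levels = causes))
  if (any(!lengths(idx)))
    stop_schema("cause(s) with zero deaths: ",
                paste(causes[!lengths(idx)], collapse = ", "))
  x <- vapply(idx, function(i) colMeans(train$X[i, , drop = FALSE]),
              numeric(n_items(train)))
  matrix(x, nrow = n_items(train),
         dimnames = list(colnames(train$X), causes))
}

# row-wise median and IQR with linear-interpolation percentiles (type 7)
row_med_iqr <- function(x, iqr_floor) {
  q <- apply(x, 1, quantile, probs = c(0.25, 0.5, 0.75), type = 7,
             names = FALSE)
  list(med = q[2, ], iqr = pmax(q[3, ] - q[1, ], iqr_floor))
}

#' Compute tariff scores from endorsement rates
#'
#' @param x items x causes endorsement-rate matrix.
#' @param iqr_floor lower bound applied to the per-item IQR so that items
#'   with no cross-cause spread get tariff 0 rather than 0/0.
#' @return an object of class `tariff_matrix`: list with `T` (items x
#'   causes scores), `significant` (logical mask, initially all `TRUE`)
#'   and `iqr_floor`.
#' @export
compute_tariffs <- function(x, iqr_floor = 0.001) {
  r <- row_med_iqr(x, iqr_floor)
  T <- (x - r$med) / r$iqr
  structure(list(T = T,
                 significant = matrix(TRUE, nrow(T), ncol(T), dimnames = dimnames(T)),
                 iqr_floor = iqr_floor),
            class = "tariff_matrix")
}

#' Bootstrap significance filter for tariffs
#'
#' Recomputes the tariff matrix on bootstrap resamples of the training
#' deaths (resampled within cause, preserving cause counts) and keeps an
#' item-cause tariff only when the two-sided `(1 - alpha)` percentile
#' interval of its bootstrap distribution excludes zero; the rest are
#' zeroed so they contribute nothing to any score.
#'
#' @param tm a `tariff_matrix` from [compute_tariffs()].
#' @param train the labeled training `va_dataset` the rates came from.
#' @param n_boot number of bootstrap resamples (>= 100; `alpha >= 1`
#'   disables filtering).
#' @param alpha two-sided significance level.
#' @param seed integer seed for the resampling.
#' @return the filtered `tariff_matrix` (zeroed entries, updated mask).
#' @export
significance_filter <- function(tm, train, n_boot = 500, alpha = 0.05,
                                seed = NULL) {
  stopifnot(inherits(tm, "tariff_matrix"))
  if (alpha >= 1) return(tm)
  if (n_boot < 100) stop_schema("n_boot must be at least 100")
  causes <- train$causes
  idx <- split(seq_len(n_deaths(train)),
               factor(train$gold_cause, levels = causes))
  ni <- n_items(train)
  boots <- with_seed_(seed, function() {
    out <- array(NA_real_, c(ni, length(causes), n_boot))
    for (b in seq_len(n_boot)) {
      x <- vapply(idx, function(i) {
        r <- i[sample.int(length(i), length(i), replace = TRUE)]
        colMeans(train$X[r, , drop = FALSE])
      }, numeric(ni))
      r <- row_med_iqr(x, tm$iqr_floor)
      out[, , b] <- (x - r$med) / r$iqr
    }
    out
  })
  lo <- apply(boots, c(1, 2), quantile, probs = alpha / 2, type = 7, names = FALSE)
  hi <- apply(boots, c(1, 2), quantile, probs = 1 - alpha / 2, type = 7, names = FALSE)
  keep <- lo > 0 | hi < 0
  tm$significant <- keep
  dimnames(tm$significant) <- dimnames(tm$T)
  tm$T[!keep] <- 0
  tm
}

# per-cause list of the top-|tariff| significant items, at most max_items
select_kept_items <- function(tm, max_items) {
  items <- rownames(tm$T)
  lapply(setNames(colnames(tm$T), colnames(tm$T)), function(j) {
    t_j <- tm$T[, j]
    cand <- which(tm$significant[, j] & t_j != 0)
    cand <- cand[order(abs(t_j[cand]), decreasing = TRUE)]
    items[utils::head(cand, max_items)]
  })
}

#' Fit a Tariff classifier
#'
#' Computes endorsement rates, tariffs, the bootstrap significance filter
#' and the per-cause truncated item lists, and builds the uniform-cause
#' reference pool used at prediction time: `pool_per_cause` training
#' deaths are resampled per cause and scored, giving, for each cause, a
#' reference score distribution under a flat cause composition.
#'
#' @param train a labeled `va_dataset`.
#' @param n_boot,alpha significance-filter settings (see
#'   [significance_filter()]).
#' @param max_items maximum significant items kept per cause (by absolute
#'   tariff).
#' @param pool_per_cause reference-pool deaths resampled per cause.
#' @param iqr_floor see [compute_tariffs()].
#' @param seed integer seed (bootstrap and pool substreams are derived
#'   from it).
#' @return an object of class `tariff_fit`.
#' @export
fit_tariff <- function(train, n_boot = 500, alpha = 0.05, max_items = 40,
                       pool_per_cause = 100, iqr_floor = 0.001, seed = NULL) {
  x <- endorsement_rates(train)
  tm <- compute_tariffs(x, iqr_floor)
  tm <- significance_filter(tm, train, n_boot, alpha,
                            seed = if (!is.null(seed)) child_seed(seed, "boot"))
  kept <- select_kept_items(tm, max_items)
  if (all(!lengths(kept)))
    stop_schema("no significant items survive for any cause")
  Tk <- tm$T
  for (j in colnames(Tk)) Tk[!(rownames(Tk) %in% kept[[j]]), j] <- 0
  causes <- train$causes
  idx <- split(seq_len(n_deaths(train)),
               factor(train$gold_cause, levels = causes))
  pool_idx <- with_seed_(
    if (!is.null(seed)) child_seed(seed, "pool"),
    function() unlist(lapply(idx, function(i)
      i[sample.int(length(i), pool_per_cause, replace = TRUE)])))
  pool_scores <- train$X[pool_idx, , drop = FALSE] %*% Tk
  structure(list(tariffs = tm, scoring = Tk, kept_items = kept,
                 causes = causes, items = rownames(Tk),
                 pool_scores = pool_scores, pool_per_cause = pool_per_cause),
            class = "tariff_fit")
}

#' @export
print.tariff_fit <- function(x, ...) {
  cat("tariff_fit:", length(x$items), "items,", length(x$causes), "causes;",
      sum(x$tariffs$significant), "significant item-cause tariffs\n")
  invisible(x)
}

#' Assign causes to test deaths with a fitted Tariff classifier
#'
#' Each death's score against cause j is the sum of that cause's kept
#' tariffs over the death's endorsed items. The death's score is then
#' ranked within the reference pool's cause-j scores (rank 1 = above the
#' whole pool); the assigned cause is the one with the lowest rank, ties
#' broken toward the lowest cause index and counted in `n_ties`.
#'
#' @param object a `tariff_fit`.
#' @param newdata a `va_dataset` sharing the training items.
#' @param ... unused.
#' @return a `va_assignment`: per-death `cause`, the predicted CSMF from
#'   assignment counts, the score and rank matrices and the tie count.
#' @export
predict.tariff_fit <- function(object, newdata, ...) {
  X <- align_items(newdata, object$items)
  scores <- X %*% object$scoring
  ranks <- matrix(NA_real_, nrow(scores), ncol(scores),
                  dimnames = dimnames(scores))
  npool <- nrow(object$pool_scores)
  for (j in seq_along(object$causes)) {
    sp <- sort(object$pool_scores[, j])
    # rank = 1 + number of pool scores strictly above the death's score
    ranks[, j] <- 1 + npool - findInterval(scores[, j], sp)
  }
  best <- max.col(-ranks, ties.method = "first")
  n_ties <- sum(rowSums(ranks == ranks[cbind(seq_len(nrow(ranks)), best)]) > 1)
  new_va_assignment(object$causes[best], object$causes,
                    scores = scores, ranks = ranks, n_ties = n_ties)
}

# reorder the dataset's item columns to match a fit's item set; items the
# fit never saw are dropped, items absent from the data score as 0
align_items <- function(ds, items) {
  X <- matrix(0L, n_deaths(ds), length(items),
              dimnames = list(NULL, items))
  common <- intersect(items, colnames(ds$X))
  X[, common] <- ds$X[, common]
  X
}

#' Export / import a tariff matrix as CSV
#'
#' Writes the items x causes score matrix as plain CSV (with the
#' significance mask and kept-item lists in a JSON sidecar) so a fitted
#' tariff can be inspected for plausibility or reused outside R.
#'
#' @param tm a `tariff_matrix` or `tariff_fit`.
#' @param path CSV path; the sidecar is `path` with extension `.json`.
#' @return `read_tariff_csv` returns a `tariff_matrix`.
#' @export
write_tariff_csv <- function(tm, path) {
  fit <- inherits(tm, "tariff_fit")
  m <- if (fit) tm$tariffs else tm
  df <- data.frame(item_id = rownames(m$T), m$T, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(significant = apply(m$significant, 2, identity, simplify = FALSE),
         kept_items = if (fit) tm$kept_items,
         iqr_floor = m$iqr_floor),
    sub("\\.[^.]+$", ".json", path), auto_unbox = TRUE)
  invisible(tm)
}

#' @rdname write_tariff_csv
#' @export
read_tariff_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  T <- as.matrix(df[-1])
  rownames(T) <- df[[1]]
  side <- jsonlite::read_json(sub("\\.[^.]+$", ".json", path),
                              simplifyVector = TRUE)
  sig <- as.matrix(as.data.frame(side$significant))
  dimnames(sig) <- dimnames(T)
  structure(list(T = T, significant = sig, iqr_floor = side$iqr_floor),
            class = "tariff_matrix")
}
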