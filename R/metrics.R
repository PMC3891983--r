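# Individual- and population-level evaluation metrics.

#' One-vs-rest confusion counts per cause
#'
#' @param true,pred character vectors of equal length; `pred` may contain
#'   `NA` for indeterminate deaths (counted as misclassifications of their
#'   true cause, never as false positives).
#' @param causes the shared cause list.
#' @return a `data.frame` with per-cause `TP`, `FN`, `FP`, `TN`.
#' @export
confusion <- function(true, pred, causes) {
  if (length(true) != length(pred)) stop_schema("length mismatch")
  if (!all(true %in% causes) || !all(stats::na.omit(pred) %in% causes))
    stop_schema("label outside the cause list")
  n <- length(true)
  tp <- fn <- fp <- integer(length(causes))
  for (j in seq_along(causes)) {
    cj <- causes[j]
    tp[j] <- sum(true == cj & !is.na(pred) & pred == cj)
    fn[j] <- sum(true == cj) - tp[j]
    fp[j] <- sum(true != cj & !is.na(pred) & pred == cj)
  }
  data.frame(cause = causes, TP = tp, FN = fn, FP = fp,
             TN = n - tp - fn - fp, stringsAsFactors = FALSE)
}

#' Per-cause sensitivity and specificity
#'
#' `sens_j = TP_j / (TP_j + FN_j)`, `spec_j = TN_j / (TN_j + FP_j)`.
#' Undefined denominators (a cause absent from the test set) yield `NA`,
#' never 0.
#'
#' @param conf a confusion table from [confusion()].
#' @return the table with `sensitivity` and `specificity` columns added.
#' @export
sensitivity_specificity <- function(conf) {
  conf$sensitivity <- ifelse(conf$TP + conf$FN > 0,
                             conf$TP / (conf$TP + conf$FN), NA_real_)
  conf$specificity <- ifelse(conf$TN + conf$FP > 0,
                             conf$TN / (conf$TN + conf$FP), NA_real_)
  conf
}

#' Chance-corrected concordance
#'
#' Per-cause sensitivity rescaled so that random assignment among the N
#' causes scores 0 and perfect assignment 1:
#' `CCC_j = (TP_j / (TP_j + FN_j) - 1/N) / (1 - 1/N)`.
#' The overall CCC is the unweighted mean over causes with a defined
#' per-cause value.
#'
#' @param conf a confusion table from [confusion()].
#' @return list with `per_cause` (named vector, `NA` where undefined) and
#'   `overall`.
#' @export
chance_corrected_concordance <- function(conf) {
  N <- nrow(conf)
  if (N < 2) stop_schema("CCC needs at least 2 causes")
  sens <- ifelse(conf$TP + conf$FN > 0, conf$TP / (conf$TP + conf$FN),
                 NA_real_)
  ccc <- (sens - 1 / N) / (1 - 1 / N)
  list(per_cause = setNames(ccc, conf$cause),
       overall = mean(ccc, na.rm = TRUE))
}

#' Cohen's kappa for individual cause assignment
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` where `p_o` is observed agreement and
#' `p_e` the chance agreement from the marginal label distributions.
#' Indeterminate (`NA`) predictions count as disagreement and contribute
#' no marginal mass. Degenerate `p_e = 1` yields `NA`.
#'
#' @param true,pred character label vectors of equal length.
#' @return a single numeric value.
#' @export
cohens_kappa <- function(true, pred) {
  if (length(true) != length(pred)) stop_schema("length mismatch")
  n <- length(true)
  labels <- union(unique(true), unique(stats::na.omit(pred)))
  po <- sum(!is.na(pred) & true == pred) / n
  pt <- table(factor(true, labels)) / n
  pp <- table(factor(pred, labels)) / n
  pe <- sum(as.numeric(pt) * as.numeric(pp))
  if (1 - pe < .Machine$double.eps) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' CSMF accuracy
#'
#' `1 - sum_j |true_j - pred_j| / (2 * (1 - min_j true_j))`: 1 when every
#' cause fraction is predicted without error, 0 when the summed absolute
#' error reaches its maximum possible value given the true composition.
#'
#' @param true_csmf,pred_csmf [csmf()] vectors on the same cause list.
#' @return a value in `[0, 1]`.
#' @export
#' @examples
#' v <- csmf(c(a = 0.5, b = 0.3, c = 0.2))
#' csmf_accuracy(v, v)  # 1
csmf_accuracy <- function(true_csmf, pred_csmf) {
  true_csmf <- csmf(true_csmf, names(true_csmf))
  pred_csmf <- csmf(pred_csmf, names(pred_csmf))
  if (!identical(names(true_csmf), names(pred_csmf)))
    stop_schema("cause lists differ")
  mn <- min(true_csmf)
  if (mn >= 1) stop_schema("CSMF accuracy undefined for a single-cause truth")
  1 - sum(abs(true_csmf - pred_csmf)) / (2 * (1 - mn))
}

#' Regression diagnostics of estimated on true CSMF
#'
#' For one cause observed across many splits, regresses the estimated
#' CSMF on the true CSMF by ordinary least squares and reports the slope,
#' intercept and root mean square error of the residuals, plus the mean
#' absolute error. A perfect estimator gives slope 1, intercept 0, RMSE
#' 0; reduced sensitivity pulls the slope below 1 and reduced specificity
#' pushes the intercept above 0.
#'
#' @param true_vals,pred_vals numeric vectors of per-split (true,
#'   estimated) fractions for one cause.
#' @return list with `slope`, `intercept`, `rmse`, `mae`, `n`. When the
#'   true values are constant the regression is undefined (`NA`) but the
#'   absolute error is still returned.
#' @export
csmf_regression <- function(true_vals, pred_vals) {
  ok <- stats::complete.cases(true_vals, pred_vals)
  true_vals <- true_vals[ok]; pred_vals <- pred_vals[ok]
  mae <- mean(abs(pred_vals - true_vals))
  if (length(true_vals) < 3 || var(true_vals) == 0)
    return(list(slope = NA_real_, intercept = NA_real_, rmse = NA_real_,
                mae = mae, n = length(true_vals)))
  fit <- lm(pred_vals ~ true_vals)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       rmse = sqrt(mean(residuals(fit)^2)), mae = mae,
       n = length(true_vals))
}

#' Median and bootstrap uncertainty interval across splits
#'
#' Summarizes a per-split metric by its median and a percentile-bootstrap
#' interval of the median (uncertainty of the summary, not the spread of
#' the split distribution).
#'
#' @param values per-split metric values (`NA` dropped).
#' @param n_boot bootstrap resamples (default 1000).
#' @param level interval coverage (default 0.95).
#' @param seed integer seed.
#' @return list with `median`, `lower`, `upper`, `n`.
#' @export
summarize_splits <- function(values, n_boot = 1000, level = 0.95,
                             seed = NULL) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop_schema("need at least 2 values")
  med <- median(values)
  meds <- with_seed_(seed, function()
    vapply(seq_len(n_boot), function(b)
      median(sample(values, replace = TRUE)), numeric(1)))
  qs <- quantile(meds, c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE, type = 7)
  list(median = med, lower = min(qs[1], med), upper = max(qs[2], med),
       n = length(values))
}
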