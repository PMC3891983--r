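# Orchestration of the full validation protocol: fit every registered
# method on each split's train set, predict on the matched test set (with
# and/or without HCE items), score individual- and population-level
# metrics, summarize across splits, and tabulate head-to-head wins.
#
# All methods see identical splits, so comparisons are paired. Method
# failures on a split are recorded and excluded for that method only,
# never silently dropped, and never abort the run.

#' Define a cause-assignment or CSMF-estimation method plugin
#'
#' A method exposes `fit(train)` returning an arbitrary model object and
#' `predict(model, test)` returning a list with `csmf` (a [csmf()] over
#' the training cause list) and, for individual-level methods, `cause`
#' (one label per test death, `NA` allowed for indeterminate). Methods
#' without individual assignments (direct estimation) set
#' `individual = FALSE` and are scored on population metrics only — CCC
#' and kappa are not computed for them.
#'
#' @param id short unique method identifier.
#' @param fit function of one argument (the training `va_dataset`).
#' @param predict function of two arguments (model, test `va_dataset`).
#' @param individual logical; whether per-death assignments are produced.
#' @return an object of class `va_method`.
#' @export
va_method <- function(id, fit, predict, individual = TRUE) {
  if (!is.character(id) || length(id) != 1 || !nzchar(id))
    stop_schema("method needs a nonempty id")
  if (!is.function(fit) || length(formals(fit)) < 1)
    stop_schema("method '", id, "': fit(train) function missing")
  if (!is.function(predict) || length(formals(predict)) < 2)
    stop_schema("method '", id, "': predict(model, test) function missing")
  structure(list(id = id, fit = fit, predict = predict,
                 individual = isTRUE(individual)),
            class = "va_method")
}

# normalize a plugin prediction into (cause, csmf) and validate it
coerce_prediction <- function(pred, method, test) {
  if (inherits(pred, "va_assignment"))
    pred <- list(cause = pred$cause, csmf = pred$csmf)
  if (inherits(pred, "csmf")) pred <- list(csmf = pred)
  cause <- pred$cause
  if (method$individual) {
    if (is.null(cause) || length(cause) != n_deaths(test))
      stop_schema("method '", method$id,
                  "' did not return one assignment per test death")
    if (!all(stats::na.omit(cause) %in% test$causes))
      stop_schema("method '", method$id, "' assigned a label outside the cause list")
  }
  fr <- pred$csmf
  if (is.null(fr)) {
    if (is.null(cause)) stop_schema("method '", method$id,
                                    "' returned neither assignments nor a CSMF")
    fr <- empirical_csmf(cause[!is.na(cause)], test$causes)
  }
  list(cause = if (method$individual) cause,
       csmf = csmf(as.numeric(fr)[match(test$causes, names(fr))], test$causes))
}

#' Built-in method plugins
#'
#' Thin wrappers turning the package's classifiers into [va_method()]
#' plugins for [run_experiment()]: the Tariff classifier, the
#' joint-posterior naive-Bayes classifier (data-fitted conditionals,
#' optionally on a restricted item fraction, flat prior by default), the
#' one-vs-rest symptom-subset classifier (item pool from the tariff
#' significance mask when `use_tariff_pool`), and direct CSMF estimation
#' (population metrics only).
#'
#' @param n_boot,alpha,max_items,pool_per_cause see [fit_tariff()].
#' @return a `va_method`.
#' @name builtin_methods
#' @export
method_tariff <- function(n_boot = 100, alpha = 0.05, max_items = 40,
                          pool_per_cause = 100) {
  va_method("tariff",
    fit = function(train) fit_tariff(train, n_boot = n_boot, alpha = alpha,
                                     max_items = max_items,
                                     pool_per_cause = pool_per_cause,
                                     seed = sample.int(2^31 - 1, 1)),
    predict = function(model, test) predict(model, test))
}

#' @rdname builtin_methods
#' @param smoothing see [fit_conditionals()].
#' @param item_fraction fraction of items used (first items in dataset
#'   order), emulating a restricted sign/symptom set; 1 = all items.
#' @param threshold indeterminate threshold, see [interva_assign()].
#' @param prior `"uniform"` or `"train"` (training composition).
#' @export
method_interva <- function(smoothing = 1, item_fraction = 1, threshold = 0,
                           prior = c("uniform", "train")) {
  prior <- match.arg(prior)
  va_method("interva",
    fit = function(train) {
      items <- colnames(train$X)
      keep <- items[seq_len(max(1, floor(item_fraction * length(items))))]
      list(cond = fit_conditionals(train, smoothing), items = keep,
           prior = if (prior == "train")
             empirical_csmf(train$gold_cause, train$causes))
    },
    predict = function(model, test)
      interva_assign(test, model$cond, prior = model$prior,
                     restricted_items = model$items, threshold = threshold))
}

#' @rdname builtin_methods
#' @param subset_size,n_draws see [ssp_assign()].
#' @param use_tariff_pool draw symptom subsets from the tariff-significant
#'   items (fits a tariff on the training data first).
#' @param tariff_n_boot bootstrap resamples for that tariff fit.
#' @export
method_ssp <- function(subset_size = 16, n_draws = 100,
                       use_tariff_pool = TRUE, tariff_n_boot = 100,
                       smoothing = 1) {
  va_method("ssp",
    fit = function(train) {
      tf <- if (use_tariff_pool)
        fit_tariff(train, n_boot = tariff_n_boot,
                   seed = sample.int(2^31 - 1, 1))
      list(train = train, tariff = tf)
    },
    predict = function(model, test)
      ssp_assign(test, model$train, subset_size = subset_size,
                 n_draws = n_draws, tariff = model$tariff,
                 smoothing = smoothing, seed = sample.int(2^31 - 1, 1)))
}

#' @rdname builtin_methods
#' @param kl_subset_size,n_subsets see [estimate_csmf_direct()].
#' @export
method_kinglu <- function(kl_subset_size = 8, n_subsets = 300) {
  va_method("kinglu",
    fit = function(train) train,
    predict = function(model, test)
      estimate_csmf_direct(model, test, subset_size = kl_subset_size,
                           n_subsets = n_subsets,
                           seed = sample.int(2^31 - 1, 1)),
    individual = FALSE)
}

#' Run the full validation protocol
#'
#' Generates (or reuses) uncorrelated train/test splits, runs every
#' method on every split under each HCE condition, and collects tidy
#' per-split metrics: overall CCC, Cohen's kappa and CSMF accuracy, plus
#' per-cause sensitivity, specificity, CCC and (true, estimated) CSMF
#' pairs. The `"without"` condition strips HCE-flagged items from both
#' train and test of the same split, so with/without comparisons are
#' paired too. All method randomness flows from `seed` through named
#' substreams, so a rerun with the same configuration is bit-identical.
#'
#' @param ds a labeled `va_dataset`.
#' @param methods list of [va_method()] plugins (unique ids).
#' @param n_splits number of train/test pairs (protocol scale is 500;
#'   desk-scale runs use fewer).
#' @param hce conditions to run: subset of `c("with", "without")`.
#' @param seed root integer seed.
#' @param train_frac,test_size,alpha passed to [generate_splits()].
#' @param splits optional pre-generated `va_splits` (overrides
#'   `n_splits`/`train_frac`/`test_size`/`alpha`).
#' @param verbose print per-split progress.
#' @return an object of class `va_experiment`: list with `metrics` (tidy
#'   per-split data frame: method, split, hce, metric, cause, value),
#'   `csmf` (per-cause true/estimated pairs), `exclusions`, `splits`, and
#'   the configuration.
#' @export
run_experiment <- function(ds, methods, n_splits = 50,
                           hce = c("with", "without"), seed = 1,
                           train_frac = 0.75, test_size = NULL, alpha = 1,
                           splits = NULL, verbose = FALSE) {
  hce <- match.arg(hce, several.ok = TRUE)
  ids <- vapply(methods, function(m) m$id, character(1))
  if (anyDuplicated(ids)) stop_schema("duplicate method ids")
  names(methods) <- ids
  if (is.null(splits))
    splits <- generate_splits(ds, n_splits, train_frac, test_size,
                              seed = child_seed(seed, "splits"), alpha = alpha)
  metric_rows <- csmf_rows <- excl_rows <- list()
  for (sp in splits) {
    pair <- split_data(ds, sp)
    if (verbose) message("split ", sp$split_id)
    for (cond in hce) {
      tr <- if (cond == "without") strip_hce(pair$train) else pair$train
      te <- if (cond == "without") strip_hce(pair$test) else pair$test
      true <- te$gold_cause
      true_fr <- empirical_csmf(true, ds$causes)
      for (m in methods) {
        res <- tryCatch(
          with_seed_(child_seed(seed, "method", m$id, sp$split_id, cond),
                     function() {
                       model <- m$fit(tr)
                       coerce_prediction(m$predict(model, te), m, te)
                     }),
          error = function(e) e)
        if (inherits(res, "error")) {
          excl_rows[[length(excl_rows) + 1]] <- data.frame(
            method = m$id, split = sp$split_id, hce = cond,
            reason = conditionMessage(res), stringsAsFactors = FALSE)
          next
        }
        rows <- data.frame(method = m$id, split = sp$split_id, hce = cond,
                           metric = "csmf_accuracy", cause = NA_character_,
                           value = csmf_accuracy(true_fr, res$csmf),
                           stringsAsFactors = FALSE)
        if (m$individual) {
          conf <- confusion(true, res$cause, ds$causes)
          ss <- sensitivity_specificity(conf)
          cc <- chance_corrected_concordance(conf)
          rows <- rbind(rows, data.frame(
            method = m$id, split = sp$split_id, hce = cond,
            metric = c("ccc", "kappa",
                       rep(c("sensitivity", "specificity", "ccc_cause"),
                           each = length(ds$causes))),
            cause = c(NA, NA, rep(ds$causes, 3)),
            value = c(cc$overall, cohens_kappa(true, res$cause),
                      ss$sensitivity, ss$specificity, cc$per_cause),
            stringsAsFactors = FALSE))
        }
        metric_rows[[length(metric_rows) + 1]] <- rows
        csmf_rows[[length(csmf_rows) + 1]] <- data.frame(
          method = m$id, split = sp$split_id, hce = cond, cause = ds$causes,
          true = as.numeric(true_fr), estimated = as.numeric(res$csmf),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(
    metrics = do.call(rbind, metric_rows),
    csmf = do.call(rbind, csmf_rows),
    exclusions = if (length(excl_rows)) do.call(rbind, excl_rows) else
      data.frame(method = character(), split = integer(), hce = character(),
                 reason = character(), stringsAsFactors = FALSE),
    splits = splits, methods = ids, hce = hce, seed = seed,
    causes = ds$causes),
    class = "va_experiment")
}

#' @export
print.va_experiment <- function(x, ...) {
  cat("va_experiment:", length(x$methods), "methods x", length(x$splits),
      "splits (hce:", paste(x$hce, collapse = ", "), ")\n")
  if (nrow(x$exclusions))
    cat("  excluded method-splits:", nrow(x$exclusions), "\n")
  invisible(x)
}

#' Summarize an experiment across splits
#'
#' Median and bootstrap uncertainty interval of each overall metric per
#' method and HCE condition, mirroring a median-with-95%-UI results
#' table. CCC and kappa are reported as percentages, CSMF accuracy as a
#' fraction.
#'
#' @param object a `va_experiment`.
#' @param n_boot,level see [summarize_splits()].
#' @param percent render CCC and kappa as percentages.
#' @param ... unused.
#' @return a `data.frame` with method, hce, metric, median, lower, upper,
#'   n_splits.
#' @export
summary.va_experiment <- function(object, n_boot = 1000, level = 0.95,
                                  percent = TRUE, ...) {
  df <- object$metrics[is.na(object$metrics$cause), ]
  groups <- unique(df[c("method", "hce", "metric")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    sel <- df$method == groups$method[g] & df$hce == groups$hce[g] &
      df$metric == groups$metric[g]
    s <- summarize_splits(df$value[sel], n_boot, level,
                          seed = child_seed(object$seed, "summary", g))
    scale <- if (percent && groups$metric[g] %in% c("ccc", "kappa")) 100 else 1
    data.frame(groups[g, ], median = s$median * scale,
               lower = s$lower * scale, upper = s$upper * scale,
               n_splits = s$n, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-cause CSMF regression diagnostics across splits
#'
#' @param exp a `va_experiment`.
#' @return a `data.frame` with slope, intercept, RMSE and mean absolute
#'   error of estimated-on-true CSMF per method, HCE condition and cause.
#' @export
csmf_regression_table <- function(exp) {
  df <- exp$csmf
  groups <- unique(df[c("method", "hce", "cause")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    sel <- df$method == groups$method[g] & df$hce == groups$hce[g] &
      df$cause == groups$cause[g]
    r <- csmf_regression(df$true[sel], df$estimated[sel])
    data.frame(groups[g, ], slope = r$slope, intercept = r$intercept,
               rmse = r$rmse, mae = r$mae, n = r$n, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Head-to-head best-method counts across splits
#'
#' For every split (and HCE condition), the method(s) achieving the best
#' value of the chosen metric share one unit of credit equally — exact
#' ties yield fractional counts. Only splits on which every method was
#' scored enter the table, so per-condition counts sum to the number of
#' compared splits.
#'
#' @param exp a `va_experiment`, or a wide `data.frame`/matrix of
#'   per-split values with one column per method.
#' @param metric overall metric to compare (`"csmf_accuracy"`, `"ccc"`,
#'   `"kappa"`).
#' @param higher_better whether larger values win (default `TRUE`).
#' @return a `data.frame` with method, hce (when applicable), credit.
#' @export
head_to_head <- function(exp, metric = "csmf_accuracy",
                         higher_better = TRUE) {
  if (!inherits(exp, "va_experiment")) {
    wide <- as.matrix(exp)
    return(data.frame(method = colnames(wide),
                      credit = h2h_credit(wide, higher_better),
                      stringsAsFactors = FALSE))
  }
  df <- exp$metrics[exp$metrics$metric == metric & is.na(exp$metrics$cause), ]
  out <- do.call(rbind, lapply(unique(df$hce), function(cond) {
    d <- df[df$hce == cond, ]
    wide <- tapply(d$value, list(d$split, d$method), mean)
    wide <- wide[stats::complete.cases(wide), , drop = FALSE]
    data.frame(method = colnames(wide), hce = cond,
               credit = h2h_credit(wide, higher_better),
               n_splits = nrow(wide), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

h2h_credit <- function(wide, higher_better = TRUE) {
  if (!higher_better) wide <- -wide
  credit <- numeric(ncol(wide))
  for (i in seq_len(nrow(wide))) {
    best <- wide[i, ] == max(wide[i, ])
    credit <- credit + best / sum(best)
  }
  setNames(credit, colnames(wide))
}

#' Write experiment outputs as tidy CSV and a JSON summary
#'
#' @param exp a `va_experiment`.
#' @param dir output directory (created if missing): `metrics.csv`,
#'   `csmf.csv`, `head_to_head.csv`, `exclusions.csv`, `summary.json`,
#'   `splits.json`.
#' @export
write_experiment <- function(exp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(exp$metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  write.csv(exp$csmf, file.path(dir, "csmf.csv"), row.names = FALSE)
  write.csv(head_to_head(exp), file.path(dir, "head_to_head.csv"),
            row.names = FALSE)
  write.csv(exp$exclusions, file.path(dir, "exclusions.csv"),
            row.names = FALSE)
  s <- summary(exp)
  jsonlite::write_json(split(s[-(1:2)], paste(s$method, s$hce, sep = ".")),
                       file.path(dir, "summary.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  write_split_manifest(exp$splits, file.path(dir, "splits.json"))
  invisible(exp)
}
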