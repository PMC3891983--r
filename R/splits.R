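# Uncorrelated train/test resampling design.
#
# Each split partitions the deaths of every cause into a train set and a
# test pool (so train and test share no deaths), draws a target cause
# composition from a Dirichlet distribution over the simplex, and builds
# the test set by sampling deaths with replacement within cause from the
# pool to match that composition. Because the target composition is drawn
# independently of the data, the train-set and test-set cause compositions
# are uncorrelated across splits — methods cannot score well merely by
# reproducing the training composition.

#' Draw a target cause composition from a Dirichlet distribution
#'
#' Uses the current RNG state; with the default unit concentration the
#' draw is uniform over the probability simplex.
#'
#' @param n_causes number of causes (>= 2).
#' @param alpha Dirichlet concentration (scalar or per-cause vector).
#' @param causes optional cause names.
#' @return a [csmf()] vector.
#' @export
draw_target_csmf <- function(n_causes, alpha = 1, causes = NULL) {
  if (n_causes < 2) stop_schema("need at least 2 causes")
  g <- rgamma(n_causes, shape = rep_len(alpha, n_causes), rate = 1)
  if (all(g == 0)) g <- rep(1, n_causes)
  csmf(g / sum(g), causes %||% paste0("cause_", seq_len(n_causes)))
}

#' Generate uncorrelated train/test splits
#'
#' For each split: (1) the deaths of every cause are randomly partitioned
#' into a train fraction and a test pool; (2) a target CSMF is drawn from
#' a Dirichlet distribution; (3) the test set is built by drawing
#' per-cause counts from a multinomial at the target composition and
#' sampling that many deaths, with replacement, from the cause's test
#' pool. Train and test never share a death; deaths may repeat within a
#' test set. Causes whose test pool is empty have their target mass
#' renormalized over the causes with available deaths (recorded in the
#' split's `dropped_causes`).
#'
#' @param ds a fully labeled `va_dataset`; every cause must have at least
#'   one death.
#' @param n_splits number of train/test pairs (default 500).
#' @param train_frac fraction of each cause's deaths assigned to train
#'   (default 0.75; must leave a nonempty test pool).
#' @param test_size number of test deaths drawn per split (default: the
#'   pool size).
#' @param seed root seed; split `i` uses the substream
#'   `child_seed(seed, "split", i)`, so regeneration is bit-identical.
#' @param alpha Dirichlet concentration for the target composition.
#' @return an object of class `va_splits`: a list of `va_split` objects
#'   with fields `split_id`, `seed`, `train_id`, `test_id` (death ids, with
#'   repeats), `target_csmf`, `dropped_causes`.
#' @export
generate_splits <- function(ds, n_splits = 500, train_frac = 0.75,
                            test_size = NULL, seed = 1, alpha = 1) {
  if (is.null(ds$gold_cause)) stop_schema("dataset must be labeled")
  causes <- ds$causes
  idx_by_cause <- split(seq_len(n_deaths(ds)),
                        factor(ds$gold_cause, levels = causes))
  if (any(!lengths(idx_by_cause)))
    stop_schema("every cause needs at least one death")
  splits <- vector("list", n_splits)
  for (i in seq_len(n_splits)) {
    s <- child_seed(seed, "split", i)
    splits[[i]] <- with_seed_(s, function() {
      pool <- train <- vector("list", length(causes))
      for (j in seq_along(causes)) {
        idx <- idx_by_cause[[j]]
        n_train <- round(train_frac * length(idx))
        tr <- if (n_train) sample(idx, n_train) else integer()
        train[[j]] <- tr
        pool[[j]] <- setdiff(idx, tr)
      }
      if (!any(lengths(pool)))
        stop_schema("empty test pool for every cause; lower train_frac")
      target <- draw_target_csmf(length(causes), alpha, causes)
      avail <- lengths(pool) > 0
      dropped <- causes[!avail & target > 0]
      prob <- as.numeric(target) * avail
      prob <- prob / sum(prob)
      size <- test_size %||% sum(lengths(pool))
      counts <- as.integer(rmultinom(1, size, prob))
      test_idx <- unlist(lapply(seq_along(causes), function(j) {
        if (!counts[j]) return(integer())
        pool[[j]][sample.int(length(pool[[j]]), counts[j], replace = TRUE)]
      }))
      structure(list(split_id = i, seed = s,
                     train_id = ds$death_id[sort(unlist(train))],
                     test_id = ds$death_id[test_idx],
                     target_csmf = target,
                     dropped_causes = dropped),
                class = "va_split")
    })
  }
  structure(splits, class = "va_splits",
            seed = seed, train_frac = train_frac, alpha = alpha)
}

#' @export
print.va_splits <- function(x, ...) {
  cat("va_splits:", length(x), "train/test pairs (seed",
      attr(x, "seed"), ")\n")
  invisible(x)
}

#' Materialize one split as a train/test dataset pair
#'
#' @param ds the source `va_dataset` the splits were generated from.
#' @param split a `va_split` element of [generate_splits()] output.
#' @return list with `train` and `test` `va_dataset`s. Repeated test
#'   deaths get unique `#k` suffixes; original ids are kept in the
#'   dataset's `"source_id"` attribute.
#' @export
split_data <- function(ds, split) {
  pos_tr <- match(split$train_id, ds$death_id)
  pos_te <- match(split$test_id, ds$death_id)
  if (anyNA(pos_tr) || anyNA(pos_te))
    stop_schema("split refers to death ids absent from the dataset")
  list(train = subset_deaths(ds, pos_tr), test = subset_deaths(ds, pos_te))
}

#' Serialize / restore split manifests
#'
#' A manifest records, per split, the train/test death ids, the seed and
#' the target composition, so any split is reproducible from the manifest
#' plus the source dataset.
#'
#' @param splits a `va_splits` object.
#' @param path JSON path.
#' @return `read_split_manifest` returns a `va_splits` object.
#' @export
write_split_manifest <- function(splits, path) {
  jsonlite::write_json(
    list(seed = attr(splits, "seed"), train_frac = attr(splits, "train_frac"),
         alpha = attr(splits, "alpha"),
         splits = lapply(splits, function(sp) list(
           split_id = sp$split_id, seed = sp$seed,
           train_id = sp$train_id, test_id = sp$test_id,
           causes = names(sp$target_csmf),
           target_csmf = as.numeric(sp$target_csmf),
           dropped_causes = sp$dropped_causes))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(splits)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  splits <- lapply(seq_len(nrow(m$splits)), function(i) {
    row <- m$splits[i, ]
    structure(list(split_id = row$split_id, seed = row$seed,
                   train_id = unlist(row$train_id),
                   test_id = unlist(row$test_id),
                   target_csmf = csmf(unlist(row$target_csmf),
                                      unlist(row$causes)),
                   dropped_causes = unlist(row$dropped_causes) %||% character()),
              class = "va_split")
  })
  structure(splits, class = "va_splits", seed = m$seed,
            train_frac = m$train_frac, alpha = m$alpha)
}
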