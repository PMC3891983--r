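# Data model and I/O for labeled verbal autopsy datasets.
#
# A dataset is one row per death and one binary column per questionnaire
# item (structured items plus dichotomous free-text token indicators), with
# a per-death age module tag and, for training/validation data, a
# gold-standard cause label.

ITEM_SOURCES <- c("structured", "free_text_token")
AGE_MODULES <- c("adult", "child", "neonate")

#' Construct an item-metadata table
#'
#' Each VA item carries an identifier, a human-readable label, the age
#' module it belongs to, whether it is a structured questionnaire item or a
#' free-text token indicator, and whether it reflects household recall of
#' health care experience (HCE). The HCE flag drives [strip_hce()], used to
#' approximate populations with little access to care.
#'
#' @param item_id character vector of unique item identifiers.
#' @param label human-readable labels (defaults to `item_id`).
#' @param age_module one of `"adult"`, `"child"`, `"neonate"` (recycled).
#' @param source `"structured"` or `"free_text_token"` (recycled).
#' @param is_hce logical; whether the item is a health-care-experience item.
#' @return a `data.frame` with one row per item.
#' @export
va_items <- function(item_id, label = item_id, age_module = "adult",
                     source = "structured", is_hce = FALSE) {
  item_id <- as.character(item_id)
  if (anyDuplicated(item_id))
    stop_schema("duplicate item_id: ",
                paste(unique(item_id[duplicated(item_id)]), collapse = ", "))
  n <- length(item_id)
  age_module <- rep_len(as.character(age_module), n)
  source <- rep_len(as.character(source), n)
  is_hce <- rep_len(as.logical(is_hce), n)
  if (!all(age_module %in% AGE_MODULES))
    stop_schema("age_module must be one of: ", paste(AGE_MODULES, collapse = ", "))
  if (!all(source %in% ITEM_SOURCES))
    stop_schema("source must be one of: ", paste(ITEM_SOURCES, collapse = ", "))
  data.frame(item_id = item_id, label = rep_len(as.character(label), n),
             age_module = age_module, source = source, is_hce = is_hce,
             stringsAsFactors = FALSE)
}

#' Construct a verbal autopsy dataset
#'
#' @param X binary matrix, deaths x items; entries must be 0/1. Column
#'   names, if present, must match `items$item_id`.
#' @param items item-metadata `data.frame` from [va_items()].
#' @param death_id unique death identifiers (default: rownames of `X` or
#'   `d1..dn`).
#' @param age_module per-death age module (recycled).
#' @param gold_cause optional per-death gold-standard cause label.
#' @param causes optional cause list (character). Defaults to the sorted
#'   unique gold causes. The order is fixed and shared by every
#'   cause-indexed matrix derived from the dataset.
#' @return an object of class `va_dataset`.
#' @export
va_dataset <- function(X, items, death_id = NULL, age_module = "adult",
                       gold_cause = NULL, causes = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "integer"
  if (!all(X %in% c(0L, 1L)))
    stop_schema("item matrix entries must be 0/1")
  if (ncol(X) != nrow(items))
    stop_schema("item metadata (", nrow(items), " rows) does not match matrix (",
                ncol(X), " columns)")
  if (!is.null(colnames(X)) && !identical(colnames(X), items$item_id))
    stop_schema("column names of X disagree with items$item_id")
  colnames(X) <- items$item_id
  n <- nrow(X)
  death_id <- as.character(death_id %||% rownames(X) %||% paste0("d", seq_len(n)))
  if (length(death_id) != n) stop_schema("death_id length mismatch")
  if (anyDuplicated(death_id)) stop_schema("duplicate death_id")
  rownames(X) <- NULL
  age_module <- rep_len(as.character(age_module), n)
  if (!all(age_module %in% AGE_MODULES))
    stop_schema("unknown age_module value")
  if (!is.null(gold_cause)) {
    gold_cause <- as.character(gold_cause)
    if (length(gold_cause) != n) stop_schema("gold_cause length mismatch")
    causes <- causes %||% sort(unique(gold_cause))
    if (!all(gold_cause %in% causes))
      stop_schema("gold_cause labels absent from cause list: ",
                  paste(setdiff(unique(gold_cause), causes), collapse = ", "))
  }
  structure(list(X = X, items = items, death_id = death_id,
                 age_module = age_module, gold_cause = gold_cause,
                 causes = as.character(causes %||% character())),
            class = "va_dataset")
}

#' @export
print.va_dataset <- function(x, ...) {
  cat("va_dataset:", nrow(x$X), "deaths x", ncol(x$X), "items\n")
  cat("  sources:", paste(names(table(x$items$source)),
                          table(x$items$source), collapse = ", "), "\n")
  cat("  HCE items:", sum(x$items$is_hce), "\n")
  if (!is.null(x$gold_cause))
    cat("  gold-standard causes:", length(x$causes), "\n")
  invisible(x)
}

#' Number of deaths / items in a dataset
#' @param ds a `va_dataset`.
#' @return an integer count.
#' @export
n_deaths <- function(ds) nrow(ds$X)

#' @rdname n_deaths
#' @export
n_items <- function(ds) ncol(ds$X)

# subset deaths by integer positions; ids may repeat (resampling with
# replacement), in which case identifiers are made unique with "#k" suffixes
# and the originals kept in attr "source_id".
subset_deaths <- function(ds, idx) {
  ids <- ds$death_id[idx]
  out <- ds
  out$X <- ds$X[idx, , drop = FALSE]
  out$death_id <- make.unique(ids, sep = "#")
  out$age_module <- ds$age_module[idx]
  if (!is.null(ds$gold_cause)) out$gold_cause <- ds$gold_cause[idx]
  attr(out, "source_id") <- ids
  out
}

subset_items_ <- function(ds, keep) {
  out <- ds
  out$X <- ds$X[, keep, drop = FALSE]
  out$items <- ds$items[keep, , drop = FALSE]
  rownames(out$items) <- NULL
  out
}

#' Drop health-care-experience items from a dataset
#'
#' Removes every item flagged `is_hce` (and, optionally, whole item
#' sources), leaving the death set unchanged. Running an analysis on the
#' stripped dataset approximates performance in populations with limited
#' contact with health services.
#'
#' Idempotent: stripping an already-stripped dataset is a no-op.
#'
#' @param ds a `va_dataset`.
#' @param sources item sources to retain (default: both structured items
#'   and free-text tokens).
#' @return a `va_dataset` with the HCE items removed.
#' @export
strip_hce <- function(ds, sources = ITEM_SOURCES) {
  keep <- !ds$items$is_hce & ds$items$source %in% sources
  if (!any(keep)) warning("strip_hce: no items remain")
  subset_items_(ds, keep)
}

#' Tokenize free-text narratives into dichotomous item indicators
#'
#' Converts one open-text narrative per death into a set of binary items,
#' one per retained word: the indicator is 1 iff the word occurs in that
#' death's narrative after lowercasing, punctuation removal, stop-word and
#' minimum-length filtering. Repeated occurrences still yield 1 (the
#' indicators are dichotomous).
#'
#' @param narratives character vector, one narrative (possibly empty) per
#'   death.
#' @param min_len minimum token length retained (default 3 characters).
#' @param stoplist words to drop.
#' @param age_module age module recorded for the generated items.
#' @param prefix prefix for generated item ids.
#' @return a list with `items` (metadata with `source = "free_text_token"`)
#'   and `X` (deaths x tokens binary matrix).
#' @export
#' @examples
#' tokenize_free_text(c("fever and cough", "cough"), stoplist = "and")
tokenize_free_text <- function(narratives, min_len = 3,
                               stoplist = character(), age_module = "adult",
                               prefix = "word_") {
  toks <- lapply(narratives, function(s) {
    s <- gsub("[^a-z0-9 ]", " ", tolower(s %||% ""))
    w <- strsplit(trimws(s), "\\s+")[[1]]
    unique(w[nchar(w) >= min_len & !(w %in% stoplist) & nzchar(w)])
  })
  vocab <- sort(unique(unlist(toks)))
  X <- matrix(0L, length(narratives), length(vocab),
              dimnames = list(NULL, if (length(vocab)) paste0(prefix, vocab)))
  for (d in seq_along(toks))
    X[d, match(toks[[d]], vocab)] <- 1L
  items <- va_items(item_id = colnames(X) %||% character(), label = vocab,
                    age_module = age_module, source = "free_text_token")
  list(items = items, X = X)
}

#' Merge causes into a shorter joint cause list
#'
#' Relabels gold-standard causes through a many-to-one mapping (for
#' instance onto a joint cause list shared with another method's cause
#' list). The number of causes never increases; deaths and the item matrix
#' are untouched.
#'
#' @param ds a labeled `va_dataset`.
#' @param mapping named character vector, `names(mapping)` are current
#'   cause ids and values the merged ids. Must cover every cause in the
#'   dataset's cause list.
#' @return a `va_dataset` on the merged cause list (order of first
#'   appearance along the original list).
#' @export
map_causes <- function(ds, mapping) {
  if (is.null(ds$gold_cause)) stop_schema("dataset has no gold_cause labels")
  missing <- setdiff(ds$causes, names(mapping))
  if (length(missing))
    stop_schema("mapping does not cover cause(s): ", paste(missing, collapse = ", "))
  out <- ds
  out$gold_cause <- unname(mapping[ds$gold_cause])
  out$causes <- unique(unname(mapping[ds$causes]))
  out
}

#' Construct and validate a CSMF vector
#'
#' A cause-specific mortality fraction (CSMF) vector holds one nonnegative
#' fraction per cause; the entries sum to 1 (tolerance 1e-9) and the cause
#' order is the shared cause-list order.
#'
#' @param x numeric vector of fractions.
#' @param causes cause ids (default `names(x)`).
#' @return a named numeric vector of class `csmf`.
#' @export
csmf <- function(x, causes = names(x)) {
  force(causes)
  x <- as.numeric(x)
  if (is.null(causes)) stop_schema("csmf needs cause names")
  if (length(causes) != length(x)) stop_schema("causes length mismatch")
  if (any(x < 0)) stop_schema("csmf entries must be nonnegative")
  if (abs(sum(x) - 1) > 1e-9) stop_schema("csmf entries must sum to 1")
  structure(setNames(x, causes), class = "csmf")
}

# empirical CSMF of a label vector over a fixed cause list
empirical_csmf <- function(labels, causes) {
  tab <- table(factor(labels, levels = causes))
  csmf(as.numeric(tab) / length(labels), causes)
}

#' Write / read a dataset as delimited text
#'
#' The on-disk dialect is UTF-8 CSV with a header row: reserved columns
#' `death_id`, `age_module` and (when labeled) `gold_cause`, then one 0/1
#' column per item. Item metadata travels in a companion CSV with columns
#' `item_id,label,age_module,source,is_hce`.
#'
#' @param ds a `va_dataset`.
#' @param path CSV path for the death table.
#' @param metadata_path CSV path for item metadata (default: `path` with
#'   `_items` inserted before the extension).
#' @return `write_va_dataset` invisibly returns `ds`; `read_va_dataset`
#'   returns a validated `va_dataset`.
#' @export
write_va_dataset <- function(ds, path,
                             metadata_path = default_meta_path(path)) {
  df <- data.frame(death_id = ds$death_id, age_module = ds$age_module,
                   stringsAsFactors = FALSE)
  if (!is.null(ds$gold_cause)) df$gold_cause <- ds$gold_cause
  df <- cbind(df, as.data.frame(ds$X))
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  write.csv(ds$items, metadata_path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(ds)
}

default_meta_path <- function(path)
  sub("(\\.[^.]+)?$", "_items\\1", path)

#' @rdname write_va_dataset
#' @param missing_code optional sentinel value in item columns to impute as
#'   0 (non-endorsement); any other non-0/1 value is rejected.
#' @param causes optional cause list to validate `gold_cause` against.
#' @export
read_va_dataset <- function(path, metadata_path = default_meta_path(path),
                            missing_code = NULL, causes = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 fileEncoding = "UTF-8")
  meta <- read.csv(metadata_path, check.names = FALSE,
                   stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!"death_id" %in% names(df)) stop_schema("missing death_id column")
  if (anyDuplicated(df$death_id))
    stop_schema("duplicate death_id in ", path)
  reserved <- intersect(c("death_id", "age_module", "gold_cause"), names(df))
  item_cols <- setdiff(names(df), reserved)
  uncovered <- setdiff(item_cols, meta$item_id)
  if (length(uncovered))
    stop_schema("item column(s) without metadata: ",
                paste(uncovered, collapse = ", "))
  meta <- meta[match(item_cols, meta$item_id), , drop = FALSE]
  X <- as.matrix(df[item_cols])
  if (!is.null(missing_code)) X[X == missing_code] <- 0
  X[is.na(X)] <- 0
  if (!all(X %in% c(0, 1)))
    stop_schema("non-binary item value outside the declared missing code")
  items <- va_items(meta$item_id, meta$label, meta$age_module, meta$source,
                    meta$is_hce)
  va_dataset(X, items, death_id = as.character(df$death_id),
             age_module = if ("age_module" %in% names(df)) df$age_module else "adult",
             gold_cause = if ("gold_cause" %in% names(df)) df$gold_cause else NULL,
             causes = causes)
}

#' Write / read a cause list or cause mapping as JSON
#'
#' @param x for `write_cause_list`, a character vector of cause ids or a
#'   named character vector (a cause mapping).
#' @param path JSON file path.
#' @return `read_cause_list` returns the character vector (named when the
#'   file stores a mapping).
#' @export
write_cause_list <- function(x, path) {
  jsonlite::write_json(as.list(x), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(x)
}

#' @rdname write_cause_list
#' @export
read_cause_list <- function(path) {
  x <- jsonlite::read_json(path)
  out <- vapply(x, as.character, character(1))
  if (is.null(names(x)) || all(!nzchar(names(x)))) unname(out) else out
}
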