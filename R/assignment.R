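# Common container for individual-level cause assignments.

new_va_assignment <- function(cause, causes, posterior = NULL, csmf = NULL,
                              ...) {
  cause <- as.character(cause)
  if (!all(stats::na.omit(cause) %in% causes))
    stop_schema("assignment outside the cause list")
  if (is.null(csmf)) {
    det <- !is.na(cause)
    csmf <- if (any(det)) empirical_csmf(cause[det], causes) else NULL
  }
  structure(list(cause = cause, causes = causes, csmf = csmf,
                 posterior = posterior, n_indeterminate = sum(is.na(cause)),
                 ...),
            class = "va_assignment")
}

#' @export
print.va_assignment <- function(x, ...) {
  cat("va_assignment:", length(x$cause), "deaths,", length(x$causes),
      "causes")
  if (x$n_indeterminate) cat(",", x$n_indeterminate, "indeterminate")
  cat("\n")
  invisible(x)
}
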