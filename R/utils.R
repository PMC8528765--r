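`%||%` <- function(x, y) if (is.null(x)) y else x

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Read or write long-format session item data
#'
#' The long format is the package's interchange format: one row per observed
#' item response, with columns `patient_id`, `therapist_id`, `session`,
#' `instrument`, `item`, `value`. Missing responses are simply absent rows.
#'
#' @param path file path of a CSV in the long format.
#' @param x a data frame in the long format.
#' @return `read_session_csv()` returns the data frame; `write_session_csv()`
#'   returns `path` invisibly.
#' @export
read_session_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "therapist_id", "session", "instrument", "item", "value")
  if (!all(need %in% names(x)))
    stop("session CSV must have columns: ", paste(need, collapse = ", "))
  x$session <- as.integer(x$session)
  x$item <- as.integer(x$item)
  x
}

#' @rdname read_session_csv
#' @export
write_session_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
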