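#' Write boxes as a Raven-style selection table
#'
#' Tab-separated, one row per box, with the standard Raven column names
#' (`Begin Time (s)`, `End Time (s)`, `Low Freq (Hz)`, `High Freq (Hz)`);
#' any further columns (call type, series, score, detector, status, ...) are
#' appended verbatim.
#'
#' @param x Annotation or detection tibble.
#' @param path Output path (`.tsv` / `.txt`).
#' @return `path`, invisibly.
#' @export
write_selection_table <- function(x, path) {
  core <- c(t_start = "Begin Time (s)", t_end = "End Time (s)",
            f_low = "Low Freq (Hz)", f_high = "High Freq (Hz)")
  out <- as.data.frame(x)
  idx <- match(names(core), names(out))
  if (anyNA(idx)) stop("table lacks box columns t_start/t_end/f_low/f_high")
  names(out)[idx] <- core
  n_sel <- nrow(out)
  out <- cbind(Selection = seq_len(max(n_sel, 0L)), out)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a Raven-style selection table
#'
#' Inverse of [write_selection_table()]: maps the Raven time/frequency
#' columns back to `t_start`/`t_end`/`f_low`/`f_high` and returns a tibble.
#'
#' @param path Path to a tab-separated selection table.
#' @return A tibble.
#' @export
read_selection_table <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, na.strings = c("NA", ""))
  core <- c("Begin Time (s)" = "t_start", "End Time (s)" = "t_end",
            "Low Freq (Hz)" = "f_low", "High Freq (Hz)" = "f_high")
  idx <- match(names(core), names(raw))
  if (anyNA(idx)) stop("not a selection table: ", path)
  names(raw)[idx] <- core
  raw$Selection <- NULL
  tibble::as_tibble(raw)
}

#' Write annotations as structured JSON
#' @param x Annotation or detection tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations_json <- function(x, path) {
  jsonlite::write_json(x, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read annotations from structured JSON
#' @param path Path written by [write_annotations_json()].
#' @return A tibble.
#' @export
read_annotations_json <- function(path) {
  tibble::as_tibble(jsonlite::fromJSON(path))
}
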