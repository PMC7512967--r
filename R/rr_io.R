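#' Read an RR-interval series from disk
#'
#' Two plain-text dialects are supported. `plain` is one RR value (ms) per
#' line; blank lines and lines starting with `#` are ignored. `table` is a
#' comma- or tab-separated table with a header row containing an `rr_ms`
#' column and optional `subject` and `condition` columns (which must be
#' constant within a file).
#'
#' @param path Path to an existing file.
#' @param format `"auto"` (sniff: a header containing `rr_ms` means table),
#'   `"plain"`, or `"table"`.
#' @return An [rr_series()] with `source` set to `path`.
#' @seealso [write_rr()]
#' @export
read_rr <- function(path, format = c("auto", "plain", "table")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    first <- lines[!grepl("^\\s*(#|$)", lines)][1]
    format <- if (!is.na(first) && grepl("rr_ms", first)) "table" else "plain"
  }
  if (format == "plain") read_rr_plain(lines, path) else read_rr_table(path)
}

read_rr_plain <- function(lines, path) {
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  if (anyNA(vals)) {
    bad <- idx[which(is.na(vals))[1]]
    stop(sprintf("%s: line %d is not numeric: '%s'", path, bad, lines[bad]),
         call. = FALSE)
  }
  if (any(vals <= 0)) {
    bad <- idx[which(vals <= 0)[1]]
    stop(sprintf("%s: line %d has a non-positive RR value", path, bad),
         call. = FALSE)
  }
  rr_series(vals, source = path)
}

read_rr_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (!"rr_ms" %in% names(tab))
    stop(sprintf("%s: table format requires an 'rr_ms' column", path),
         call. = FALSE)
  if (!is.numeric(tab$rr_ms))
    stop(sprintf("%s: 'rr_ms' column contains non-numeric entries", path),
         call. = FALSE)
  one <- function(col) {
    if (!col %in% names(tab)) return(NULL)
    u <- unique(tab[[col]])
    if (length(u) > 1L)
      stop(sprintf("%s: column '%s' is not constant; split the file per series",
                   path, col), call. = FALSE)
    as.character(u)
  }
  rr_series(tab$rr_ms, subject = one("subject"), condition = one("condition"),
            source = path)
}

#' Write an RR-interval series to disk
#'
#' Inverse of [read_rr()]: `read_rr(write_rr(s, path), ...)` reproduces the
#' values bit-exactly for integer-millisecond input and to full double
#' precision otherwise.
#'
#' @param series An [rr_series()] or numeric vector (ms).
#' @param path Output path.
#' @param format `"plain"` (one value per line) or `"table"` (tab-separated
#'   with `rr_ms` and any subject/condition metadata as columns).
#' @return `path`, invisibly.
#' @export
write_rr <- function(series, path, format = c("plain", "table")) {
  format <- match.arg(format)
  vals <- rr_values(series)
  txt <- format(vals, trim = TRUE, scientific = FALSE, digits = 15)
  if (format == "plain") {
    writeLines(c("# RR intervals (ms), one per line", txt), path)
  } else {
    tab <- data.frame(rr_ms = txt, stringsAsFactors = FALSE)
    if (!is.null(attr(series, "subject"))) tab$subject <- attr(series, "subject")
    if (!is.null(attr(series, "condition")))
      tab$condition <- attr(series, "condition")
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
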