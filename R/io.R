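# Tab-separated readers/writers for the pipeline's tables. All files carry a
# one-line header; intensity tables are written long-form-free: metadata
# columns first, one column per ion.

#' Write an intensity table as TSV
#'
#' Sample metadata columns come first, followed by one column per ion.
#' @param x an [ion_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ion_table <- function(x, path) {
  stopifnot(inherits(x, "ion_table"))
  df <- cbind(x$samples, as.data.frame(x$intensity, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an intensity table written by [write_ion_table()]
#'
#' Columns named `ion####` (or listed in `ion_columns`) become the intensity
#' matrix; the rest are sample metadata.
#' @param path TSV file.
#' @param ion_columns optional explicit ion column names.
#' @return an [ion_table()].
#' @export
read_ion_table <- function(path, ion_columns = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (is.null(ion_columns))
    ion_columns <- grep("^ion[0-9]+$", names(df), value = TRUE)
  stopifnot(length(ion_columns) > 0)
  meta <- df[, setdiff(names(df), ion_columns), drop = FALSE]
  ion_table(as.matrix(df[, ion_columns, drop = FALSE]), meta,
            data.frame(ion = ion_columns))
}

#' Write/read a generic TSV table
#' @param x data.frame.
#' @param path file path.
#' @return `path` (write) or a data.frame (read).
#' @export
write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)

#' Read a cytometry event table from TSV
#'
#' Expects columns `dna` and `rna`; an optional `label` column carries
#' ground-truth phases.
#' @param path TSV file.
#' @return data.frame of class `event_table`.
#' @export
read_event_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("dna", "rna") %in% names(d)))
  stopifnot(all(is.finite(d$dna)), all(is.finite(d$rna)),
            all(d$dna >= 0), all(d$rna >= 0))
  class(d) <- c("event_table", "data.frame")
  d
}

#' Read a confluence time series from TSV
#'
#' Expects columns `time_h`, `confluence` and optionally `replicate`.
#' @param path TSV file.
#' @return data.frame of class `confluence_curve`.
#' @export
read_confluence_curve <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time_h", "confluence") %in% names(d)))
  if (is.null(d$replicate)) d$replicate <- 1L
  stopifnot(all(d$confluence >= 0 & d$confluence <= 1))
  class(d) <- c("confluence_curve", "data.frame")
  d
}
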