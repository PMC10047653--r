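#' Read a conditional-independence sample from delimited text
#'
#' Reads a CSV or TSV file (header row required; the delimiter is sniffed
#' from the header, comma or tab) and assembles the selected columns into
#' a \code{\link{ci_sample}}. Columns may be given by name or by integer
#' position; the three selections must be non-empty and disjoint. Rows
#' with missing values in any selected column are rejected with a count
#' and the first offending location in the error message.
#'
#' @param path Path to the file.
#' @param x_cols,y_cols,z_cols Character names or integer positions of
#'   the x, y and z columns.
#' @return A \code{\link{ci_sample}}.
#' @export
read_ci_sample <- function(path, x_cols, y_cols, z_cols) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  resolve <- function(cols, what) {
    if (length(cols) < 1L) stop(sprintf("'%s' selection is empty", what), call. = FALSE)
    if (is.numeric(cols)) {
      if (any(cols < 1 | cols > ncol(df)))
        stop(sprintf("'%s' column positions out of range", what), call. = FALSE)
      return(as.integer(cols))
    }
    idx <- match(cols, names(df))
    if (anyNA(idx))
      stop(sprintf("column(s) not found for %s: %s", what,
                   paste(cols[is.na(idx)], collapse = ", ")), call. = FALSE)
    idx
  }
  ix <- resolve(x_cols, "x"); iy <- resolve(y_cols, "y"); iz <- resolve(z_cols, "z")
  if (anyDuplicated(c(ix, iy, iz)))
    stop("x, y and z column selections must be disjoint", call. = FALSE)
  sel <- df[, c(ix, iy, iz), drop = FALSE]
  non_num <- names(sel)[!vapply(sel, is.numeric, logical(1L))]
  if (length(non_num))
    stop(sprintf("non-numeric values in selected column(s): %s",
                 paste(non_num, collapse = ", ")), call. = FALSE)
  ok <- stats::complete.cases(sel)
  if (!all(ok)) {
    bad_row <- which(!ok)[1L]
    bad_col <- names(sel)[which(is.na(sel[bad_row, ]))[1L]]
    stop(sprintf("%d row(s) with missing values in selected columns (first: row %d, column '%s')",
                 sum(!ok), bad_row, bad_col), call. = FALSE)
  }
  if (nrow(sel) < 2L)
    stop("fewer than 2 complete rows", call. = FALSE)
  ci_sample(df[, ix, drop = FALSE], df[, iy, drop = FALSE], df[, iz, drop = FALSE])
}

#' Write a conditional-independence sample as delimited text
#'
#' Writes the x, y and z blocks side by side with a header row. Column
#' names default to x1..x_dx, y1..y_dy, z1..z_dz. Values are written with
#' 17 significant digits so a read/write round trip reproduces the sample
#' to machine precision.
#'
#' @param sample A \code{\link{ci_sample}}.
#' @param path Output path.
#' @param sep Field separator, \code{","} (default) or \code{"\t"}.
#' @return The column-name list, invisibly:
#'   \code{list(x_cols, y_cols, z_cols)}.
#' @export
write_ci_sample <- function(sample, path, sep = ",") {
  stopifnot(inherits(sample, "ci_sample"))
  if (!sep %in% c(",", "\t")) stop("'sep' must be comma or tab", call. = FALSE)
  nm <- function(prefix, k) paste0(prefix, seq_len(k))
  cols <- list(x_cols = nm("x", ncol(sample$x)),
               y_cols = nm("y", ncol(sample$y)),
               z_cols = nm("z", ncol(sample$z)))
  df <- cbind(as.data.frame(sample$x), as.data.frame(sample$y),
              as.data.frame(sample$z))
  names(df) <- unlist(cols, use.names = FALSE)
  df[] <- lapply(df, function(v) format(v, digits = 17, trim = TRUE,
                                        scientific = FALSE))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(cols)
}
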