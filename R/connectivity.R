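#' Functional connectivity matrices from region-level BOLD time series
#'
#' A `bold_ts` is a plain numeric matrix, time points in rows and regions in
#' columns, with region labels as column names. [compute_fc()] turns it into
#' an `fc_matrix`: a symmetric region-by-region Pearson correlation matrix,
#' optionally Fisher z-transformed by [fisher_z()]. Preprocessing (motion
#' scrubbing, filtering, global-signal regression) is assumed to have
#' happened upstream; these functions operate on already-clean regional
#' averages.
#'
#' @name connectivity
NULL

#' Construct a BOLD time-series object
#'
#' @param values numeric matrix, time x region, no missing values.
#' @param node_labels character vector of region names; defaults to existing
#'   column names or `R001...`.
#' @param tr_seconds optional repetition time in seconds (metadata only).
#' @return a numeric matrix of class `bold_ts` with labelled columns.
#' @export
bold_ts <- function(values, node_labels = NULL, tr_seconds = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("BOLD time series must not contain missing values")
  if (nrow(values) < 3L) stop("need at least 3 timepoints")
  if (ncol(values) < 2L) stop("need at least 2 regions")
  if (is.null(node_labels)) {
    node_labels <- colnames(values)
    if (is.null(node_labels))
      node_labels <- sprintf("R%03d", seq_len(ncol(values)))
  }
  if (length(node_labels) != ncol(values))
    stop("node_labels length must equal the number of columns")
  colnames(values) <- node_labels
  if (!is.null(tr_seconds)) {
    stopifnot(is.numeric(tr_seconds), tr_seconds > 0)
    attr(values, "tr_seconds") <- tr_seconds
  }
  class(values) <- c("bold_ts", class(values))
  values
}

#' Read a delimited BOLD time-series file
#'
#' Expects a header row of region labels and one row per time point.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @inheritParams bold_ts
#' @return a `bold_ts` matrix.
#' @export
read_bold <- function(path, sep = "\t", tr_seconds = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  bold_ts(as.matrix(df), tr_seconds = tr_seconds)
}

#' Write a BOLD time-series matrix as delimited text
#'
#' @param ts a `bold_ts` or plain time x region matrix with column names.
#' @param path output path.
#' @param sep field separator.
#' @export
write_bold <- function(ts, path, sep = "\t") {
  utils::write.table(as.matrix(unclass(ts)), path, sep = sep,
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

new_fc_matrix <- function(values, scale) {
  stopifnot(scale %in% c("pearson_r", "fisher_z"))
  structure(values, scale = scale, class = c("fc_matrix", class(values)))
}

#' Pearson functional connectivity from BOLD time series
#'
#' Entry (i, j) is the Pearson correlation between the BOLD time courses of
#' regions i and j; the diagonal is exactly 1.
#'
#' @param ts time x region matrix (see [bold_ts()]).
#' @return an `fc_matrix` on the `pearson_r` scale, with node labels as
#'   dimnames and a `scale` attribute.
#' @export
compute_fc <- function(ts) {
  ts <- bold_ts(as.matrix(unclass(ts)))
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0]
    stop("zero-variance BOLD signal for region(s): ",
         paste(bad, collapse = ", "))
  }
  r <- stats::cor(ts)
  diag(r) <- 1
  new_fc_matrix(r, "pearson_r")
}

#' Scale of a connectivity matrix
#'
#' @param c an `fc_matrix`.
#' @return `"pearson_r"` or `"fisher_z"`.
#' @export
fc_scale <- function(c) {
  s <- attr(c, "scale")
  if (is.null(s)) stop("not a connectivity matrix: missing scale attribute")
  s
}

#' Fisher z transform of a correlation matrix
#'
#' Applies atanh to every off-diagonal correlation after clipping |r| at
#' 1 - 1e-7, so duplicated regions yield a finite (large) z instead of an
#' infinity that would poison within/between-network means. The diagonal is
#' stored as 0 by convention and excluded from every aggregate downstream.
#'
#' @param c an `fc_matrix` on the `pearson_r` scale.
#' @param clip clipping bound on |r| before atanh.
#' @return an `fc_matrix` on the `fisher_z` scale.
#' @export
fisher_z <- function(c, clip = 1 - 1e-7) {
  if (!inherits(c, "fc_matrix")) c <- as_fc_matrix(c, scale = "pearson_r")
  if (fc_scale(c) != "pearson_r")
    stop("input is already Fisher z-transformed")
  r <- pmin(pmax(unclass(c), -clip), clip)
  z <- atanh(r)
  diag(z) <- 0
  new_fc_matrix(z, "fisher_z")
}

#' Coerce a plain matrix to a connectivity matrix
#'
#' Validates symmetry (to 1e-12) and, for the Pearson scale, that entries
#' lie in [-1, 1] with a unit diagonal.
#'
#' @param values square numeric matrix.
#' @param scale `"pearson_r"` or `"fisher_z"`.
#' @param node_labels optional region names.
#' @return an `fc_matrix`.
#' @export
as_fc_matrix <- function(values, scale = c("pearson_r", "fisher_z"),
                         node_labels = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("connectivity matrix must be square")
  if (max(abs(values - t(values))) > 1e-12)
    stop("connectivity matrix must be symmetric")
  if (scale == "pearson_r") {
    if (any(values < -1 - 1e-12) || any(values > 1 + 1e-12))
      stop("Pearson correlations must lie in [-1, 1]")
    if (any(abs(diag(values) - 1) > 1e-12))
      stop("Pearson connectivity must have a unit diagonal")
  }
  if (is.null(node_labels)) {
    node_labels <- colnames(values)
    if (is.null(node_labels))
      node_labels <- sprintf("R%03d", seq_len(ncol(values)))
  }
  dimnames(values) <- list(node_labels, node_labels)
  new_fc_matrix(values, scale)
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> %d x %d regions, scale = %s\n",
              nrow(x), ncol(x), fc_scale(x)))
  invisible(x)
}

#' Write a connectivity matrix as delimited text
#'
#' Labels appear as the first row and first column.
#'
#' @param c an `fc_matrix`.
#' @param path output path.
#' @param sep field separator.
#' @export
write_fc <- function(c, path, sep = "\t") {
  m <- as.matrix(unclass(c))
  utils::write.table(m, path, sep = sep, row.names = TRUE,
                     col.names = NA, quote = FALSE)
  invisible(path)
}

#' Read a connectivity matrix written by [write_fc()]
#'
#' @param path file path.
#' @param scale scale of the stored matrix.
#' @param sep field separator.
#' @return an `fc_matrix`.
#' @export
read_fc <- function(path, scale = c("pearson_r", "fisher_z"), sep = "\t") {
  scale <- match.arg(scale)
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = sep,
                                   row.names = 1L, check.names = FALSE))
  as_fc_matrix(m, scale = scale)
}
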