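#' Signal matrix: probe-by-sample intensities with a detection mask
#'
#' Wraps a nonnegative numeric matrix (probes in rows, samples in columns)
#' together with a logical detection mask of the same shape and a
#' processing-stage marker. Stages advance only forward through
#' \code{raw -> background_corrected -> quantile_normalized ->
#' control_scaled -> log2}. In a \code{raw} matrix every non-missing cell
#' is considered detected; later stages set \code{detected = FALSE} (value
#' floored at 0) for probes at or below the negative-control background.
#'
#' @param values numeric matrix, probes x samples, with rownames (probe
#'   ids) and colnames (sample ids).
#' @param detected logical matrix of the same shape, or \code{NULL} to
#'   mark all finite cells detected.
#' @param stage processing stage string.
#' @return An object of class \code{"signal_matrix"}: a list with elements
#'   \code{values}, \code{detected}, \code{stage}.
#' @export
signal_matrix <- function(values, detected = NULL,
                          stage = c("raw", "background_corrected",
                                    "quantile_normalized", "control_scaled",
                                    "log2")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("signal_matrix: values must have probe rownames and sample colnames")
  storage.mode(values) <- "double"
  if (any(values[is.finite(values)] < 0))
    stop("signal_matrix: negative intensities are not allowed")
  if (is.null(detected)) detected <- is.finite(values)
  detected <- as.matrix(detected)
  if (!identical(dim(detected), dim(values)))
    stop("signal_matrix: detection mask shape mismatch")
  structure(list(values = values, detected = detected, stage = stage),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("Signal matrix [", x$stage, "]: ", nrow(x$values), " probes x ",
      ncol(x$values), " samples; ",
      round(100 * mean(x$detected), 1), "% detected\n", sep = "")
  invisible(x)
}

#' @export
dim.signal_matrix <- function(x) dim(x$values)

stage_index <- function(stage) {
  match(stage, c("raw", "background_corrected", "quantile_normalized",
                 "control_scaled", "log2"))
}

require_stage <- function(x, stage) {
  if (!inherits(x, "signal_matrix"))
    stop("expected a signal_matrix")
  if (!identical(x$stage, stage))
    stop("signal matrix is at stage '", x$stage, "', expected '", stage, "'")
  invisible(x)
}

advance_stage <- function(x, to) {
  if (stage_index(to) <= stage_index(x$stage))
    stop("stage may only advance forward (", x$stage, " -> ", to, ")")
  x$stage <- to
  x
}

#' Read a raw probe-by-sample intensity matrix
#'
#' Tab-separated, UTF-8: first column \code{probe_id}, header row of
#' sample ids, \code{NA} for missing cells. Every probe id must be listed
#' in the panel; intensities must be nonnegative. Probe and sample order
#' follow the file.
#'
#' @param path file path.
#' @param panel a \code{\link{probe_panel}} naming every admissible probe.
#' @return A \code{\link{signal_matrix}} at stage \code{"raw"}; missing
#'   cells are flagged undetected (\code{NA} kept in \code{values}).
#' @export
read_signal_matrix <- function(path, panel) {
  stopifnot(inherits(panel, "probe_panel"))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("signal matrix file needs probe_id + >=1 sample column")
  ids <- as.character(df[[1]])
  unknown <- setdiff(ids, panel$probe_id)
  if (length(unknown))
    stop("signal matrix contains probes absent from the panel: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (any(m[is.finite(m)] < 0))
    stop("signal matrix contains negative intensities")
  det <- is.finite(m)
  signal_matrix(ifelse(det, m, NA_real_), detected = det, stage = "raw")
}

#' Write a signal matrix as tab-separated text
#'
#' Inverse of \code{\link{read_signal_matrix}} for raw matrices; values are
#' written with full precision (\code{format C17}) so a write/read round
#' trip is bitwise lossless. Undetected cells are written as \code{NA}.
#'
#' @param x a \code{\link{signal_matrix}}.
#' @param path file path.
#' @export
write_signal_matrix <- function(x, path) {
  stopifnot(inherits(x, "signal_matrix"))
  v <- x$values
  chr <- matrix(sprintf("%.17g", v), nrow = nrow(v))
  chr[is.na(v)] <- "NA"
  out <- cbind(probe_id = rownames(v), as.data.frame(chr))
  names(out) <- c("probe_id", colnames(v))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
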