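#' Normalization parameters
#'
#' @param negctrl_trim_fraction fraction of negative-control probes
#'   removed from each tail (ranked by intensity) before taking the mean
#'   that defines the per-array background / detection floor.
#' @param preset_value target value for the per-array internal-control
#'   mean after ratio standardization. \code{NULL} (default) uses the
#'   grand mean of the per-array internal-control means across the batch,
#'   making the batch self-normalizing; supply a fixed constant for
#'   cross-batch comparability.
#' @param log2_offset pseudo-count added before the log2 transform.
#' @return list of class \code{"normalization_params"}.
#' @export
normalization_params <- function(negctrl_trim_fraction = 0.05,
                                 preset_value = NULL,
                                 log2_offset = 1.0) {
  if (negctrl_trim_fraction < 0 || negctrl_trim_fraction >= 0.5)
    stop("negctrl_trim_fraction must lie in [0, 0.5)")
  if (!is.null(preset_value) && preset_value <= 0)
    stop("preset_value must be positive")
  if (log2_offset < 0) stop("log2_offset must be >= 0")
  structure(list(negctrl_trim_fraction = negctrl_trim_fraction,
                 preset_value = preset_value, log2_offset = log2_offset),
            class = "normalization_params")
}

#' Per-array detection floor from negative controls
#'
#' The floor is the mean negative-control intensity after removing
#' \code{ceiling(trim * n)} probes from each tail of the intensities
#' ranked by signal (ties broken by probe order). A miRNA probe is called
#' present only if its signal exceeds this floor strictly.
#'
#' @param array_column named numeric vector of one array's intensities
#'   (names = probe ids), or an unnamed vector of negative-control
#'   intensities only.
#' @param panel a \code{\link{probe_panel}}; ignored when
#'   \code{array_column} is unnamed.
#' @param params \code{\link{normalization_params}}.
#' @return the threshold (a single number).
#' @examples
#' p <- probe_panel(sprintf("n%02d", 1:20), rep("negative_control", 20),
#'                  rep("", 20))
#' negctrl_floor(stats::setNames(1:20, p$probe_id), p)  # 10.5
#' @export
negctrl_floor <- function(array_column, panel = NULL,
                          params = normalization_params()) {
  if (!is.null(names(array_column)) && !is.null(panel)) {
    neg_ids <- panel_probes(panel, "negative_control")
    v <- array_column[names(array_column) %in% neg_ids]
  } else {
    v <- array_column
  }
  v <- v[!is.na(v)]
  n <- length(v)
  if (n == 0)
    stop("no negative-control probes available for background estimation")
  k <- ceiling(params$negctrl_trim_fraction * n)
  if (2 * k >= n) k <- 0  # too few probes to trim: plain mean
  if (k > 0) {
    ord <- order(v)  # ties resolved by probe (row) order
    v <- v[ord][(k + 1):(n - k)]
  }
  mean(v)
}

#' Background correction with negative-control presence calls
#'
#' Per array: probes whose signal strictly exceeds the trimmed-mean
#' negative-control floor are called present and have the floor
#' subtracted; all other probes are set undetected with value 0.
#' Negative-control rows are dropped from the output.
#'
#' @param x a raw \code{\link{signal_matrix}}.
#' @param panel the \code{\link{probe_panel}}.
#' @param params \code{\link{normalization_params}}.
#' @return a \code{signal_matrix} at stage \code{"background_corrected"}
#'   containing target and internal-control probes only.
#' @export
background_correct <- function(x, panel, params = normalization_params()) {
  require_stage(x, "raw")
  neg_ids <- panel_probes(panel, "negative_control")
  if (!length(intersect(neg_ids, rownames(x$values))))
    stop("background correction requested but the matrix has no ",
         "negative-control probes")
  keep <- rownames(x$values)[!rownames(x$values) %in% neg_ids]
  v <- x$values
  out <- v[keep, , drop = FALSE]
  det <- matrix(FALSE, nrow(out), ncol(out), dimnames = dimnames(out))
  for (j in seq_len(ncol(v))) {
    thr <- negctrl_floor(v[neg_ids, j], params = params)
    present <- !is.na(out[, j]) & out[, j] > thr
    out[, j] <- ifelse(present, out[, j] - thr, 0)
    det[, j] <- present
  }
  advance_stage(signal_matrix(out, det, stage = "raw"),
                "background_corrected")
}

#' Cross-array quantile normalization
#'
#' Forces every array to share one value distribution: each array's
#' sorted value vector becomes the across-array mean of sorted vectors;
#' ties within an array receive the mean of the quantile values they
#' span. Undetected cells participate as zeros so per-array vectors stay
#' equal length; the detection mask is unchanged. The operation is
#' idempotent.
#'
#' @param x a \code{signal_matrix} at stage \code{"background_corrected"}.
#' @return a \code{signal_matrix} at stage \code{"quantile_normalized"}.
#' @export
quantile_normalize <- function(x) {
  require_stage(x, "background_corrected")
  if (ncol(x$values) < 2) {
    warning("quantile normalization needs >= 2 arrays; returning input unchanged")
    return(advance_stage(x, "quantile_normalized"))
  }
  v <- limma::normalizeQuantiles(x$values, ties = TRUE)
  dimnames(v) <- dimnames(x$values)
  v[!x$detected] <- 0  # undetected cells stay at the declared floor
  advance_stage(signal_matrix(pmax(v, 0), x$detected, stage = "raw"),
                "quantile_normalized")
}

#' Internal-control ratio standardization
#'
#' Each array is divided by the ratio of its mean internal-control signal
#' to the preset value, so that after scaling every array's
#' internal-control mean equals the preset value.
#'
#' @param x a \code{signal_matrix} at stage \code{"quantile_normalized"}.
#' @param panel the \code{\link{probe_panel}}; all internal-control
#'   probes must be present in the matrix.
#' @param params \code{\link{normalization_params}}; see
#'   \code{preset_value} there.
#' @return a \code{signal_matrix} at stage \code{"control_scaled"}, with
#'   the preset value used stored as attribute \code{"preset_value"}.
#' @export
internal_control_scale <- function(x, panel,
                                   params = normalization_params()) {
  require_stage(x, "quantile_normalized")
  ic_ids <- panel_probes(panel, "internal_control")
  missing_ic <- setdiff(ic_ids, rownames(x$values))
  if (length(missing_ic))
    stop("internal-control probes absent from matrix: ",
         paste(utils::head(missing_ic, 5), collapse = ", "))
  ic_means <- colMeans(x$values[ic_ids, , drop = FALSE])
  bad <- ic_means <= 0
  if (any(bad))
    stop("non-positive internal-control mean on array(s): ",
         paste(names(ic_means)[bad], collapse = ", "))
  preset <- if (is.null(params$preset_value)) mean(ic_means) else
    params$preset_value
  v <- sweep(x$values, 2, ic_means / preset, `/`)
  out <- advance_stage(signal_matrix(v, x$detected, stage = "raw"),
                       "control_scaled")
  attr(out, "preset_value") <- preset
  out
}

#' Log2 transform with a pseudo-count
#'
#' \code{value <- log2(value + offset)}; monotone, detection mask
#' unchanged. With the default offset 1, undetected zeros map to 0.
#'
#' @param x a \code{signal_matrix} at stage \code{"control_scaled"}.
#' @param params \code{\link{normalization_params}}.
#' @return a \code{signal_matrix} at stage \code{"log2"}.
#' @export
log2_transform <- function(x, params = normalization_params()) {
  require_stage(x, "control_scaled")
  v <- log2(x$values + params$log2_offset)
  out <- advance_stage(signal_matrix(v, x$detected, stage = "raw"), "log2")
  attr(out, "preset_value") <- attr(x, "preset_value")
  out
}

#' Run the full normalization chain
#'
#' Background correction with negative-control presence calls, quantile
#' normalization across arrays, internal-control ratio standardization
#' and (optionally) the log2 transform, in that order.
#'
#' @param x a raw \code{\link{signal_matrix}}.
#' @param panel the \code{\link{probe_panel}}.
#' @param params \code{\link{normalization_params}}.
#' @param log2 apply the final log2 transform (default TRUE; the
#'   discriminant stage operates on log2 values by default).
#' @return a normalized \code{signal_matrix}.
#' @examples
#' sim <- simulate_cohort(simulation_config(seed = 1))
#' norm <- normalize_signals(sim$signals, sim$panel)
#' norm
#' @export
normalize_signals <- function(x, panel, params = normalization_params(),
                              log2 = TRUE) {
  x <- background_correct(x, panel, params)
  x <- quantile_normalize(x)
  x <- internal_control_scale(x, panel, params)
  if (log2) x <- log2_transform(x, params)
  x
}
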