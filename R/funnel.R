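#' Configuration of the candidate-miRNA selection funnel
#'
#' @param detection_fraction minimum fraction of pre-operative samples in
#'   which a miRNA must be detected (signal present, value > 0) to pass
#'   stage 1. "Most pre-operative samples" is read as a majority
#'   (\code{>= 0.5}) by default and is exposed as a knob.
#' @param alpha_paired two-sided significance level of the paired
#'   pre/post t-test (stage 2).
#' @param alpha_logrank significance level of the median-split log-rank
#'   test on RFS (stage 3).
#' @param trajectory_margin minimal median log2 change that counts as a
#'   rise or fall in the trajectory stage.
#' @param trajectory_majority fraction of relapsers that must
#'   individually show the canonical three-point pattern (stage 4).
#' @param p_adjust multiplicity correction applied to stage-2 p-values
#'   (\code{"none"}, the default, or \code{"BH"}). Raw per-test
#'   thresholds match the uncorrected funnel counts this pipeline
#'   reproduces.
#' @return list of class \code{"funnel_config"}.
#' @export
funnel_config <- function(detection_fraction = 0.5, alpha_paired = 0.05,
                          alpha_logrank = 0.05, trajectory_margin = 0,
                          trajectory_majority = 0.5,
                          p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (detection_fraction <= 0 || detection_fraction > 1)
    stop("detection_fraction must lie in (0, 1]")
  if (trajectory_majority <= 0 || trajectory_majority > 1)
    stop("trajectory_majority must lie in (0, 1]")
  for (a in c(alpha_paired, alpha_logrank))
    if (a <= 0 || a >= 1) stop("alpha levels must lie in (0, 1)")
  structure(list(detection_fraction = detection_fraction,
                 alpha_paired = alpha_paired,
                 alpha_logrank = alpha_logrank,
                 trajectory_margin = trajectory_margin,
                 trajectory_majority = trajectory_majority,
                 p_adjust = p_adjust),
            class = "funnel_config")
}

# probe rows -> miRNA names for a normalized matrix
mirna_rows <- function(x, panel) {
  nm <- panel$mirna_name[match(rownames(x$values), panel$probe_id)]
  stats::setNames(rownames(x$values), nm)
}

#' Stage 1: keep miRNAs detected in most pre-operative samples
#'
#' A miRNA passes if it is called present (detection mask TRUE and value
#' > 0) in at least \code{detection_fraction} of the pre-operative
#' samples (inclusive: detected in exactly half passes at the default).
#'
#' @param x a normalized \code{\link{signal_matrix}}.
#' @param samples sample sheet with \code{time_point}.
#' @param config a \code{\link{funnel_config}}.
#' @return character vector of surviving probe ids (file order).
#' @export
filter_detected <- function(x, samples, config = funnel_config()) {
  pre <- samples_at(samples, "pre")
  pre <- intersect(colnames(x$values), pre)
  if (!length(pre)) stop("no pre-operative samples in the matrix")
  det <- x$detected[, pre, drop = FALSE] & x$values[, pre, drop = FALSE] > 0
  frac <- rowMeans(det)
  rownames(x$values)[frac >= config$detection_fraction]
}

#' Stage 2: paired pre/post differential test
#'
#' Two-sided paired t-test on the per-patient (pre - post) differences of
#' one miRNA. The direction is the sign of the mean difference:
#' \code{pre_high} when pre-operative expression exceeds postoperative.
#' Zero variance of the differences leaves the p-value undefined; such
#' miRNAs are flagged degenerate and treated as non-significant.
#'
#' @param x normalized \code{signal_matrix}.
#' @param samples sample sheet.
#' @param probe probe id (row of the matrix).
#' @return list with \code{t}, \code{p}, \code{direction}
#'   (\code{"pre_high"}/\code{"pre_low"}), \code{degenerate}.
#' @export
paired_prepost_test <- function(x, samples, probe) {
  d <- paired_differences(x, samples)[probe, ]
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2) stop("paired test needs >= 2 complete pre/post pairs")
  s <- stats::sd(d)
  m <- mean(d)
  if (s == 0) {
    return(list(t = NA_real_, p = if (m == 0) 1 else NA_real_,
                direction = if (m >= 0) "pre_high" else "pre_low",
                degenerate = m != 0))
  }
  t <- m / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1),
       direction = if (m >= 0) "pre_high" else "pre_low",
       degenerate = FALSE)
}

# probes x patients matrix of (pre - post) differences
paired_differences <- function(x, samples) {
  pre <- samples[samples$time_point %in% "pre", ]
  post <- samples[samples$time_point %in% "post", ]
  pats <- intersect(pre$patient_id, post$patient_id)
  pre_id <- pre$sample_id[match(pats, pre$patient_id)]
  post_id <- post$sample_id[match(pats, post$patient_id)]
  d <- x$values[, pre_id, drop = FALSE] - x$values[, post_id, drop = FALSE]
  colnames(d) <- pats
  d
}

# vectorized stage-2 scan over all probes
paired_scan <- function(x, samples) {
  d <- paired_differences(x, samples)
  n <- ncol(d)
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  degenerate <- s == 0 & m != 0
  p[s == 0] <- ifelse(m[s == 0] == 0, 1, NA_real_)
  data.frame(probe_id = rownames(d), t = t, p = p,
             direction = ifelse(m >= 0, "pre_high", "pre_low"),
             degenerate = degenerate, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Stage 3: median-split log-rank test on recurrence-free survival
#'
#' Patients are split at the median of their pre-operative values
#' (values >= median form the high group) and the two groups' RFS curves
#' are compared by a log-rank test. All-identical values cannot be split
#' and are flagged.
#'
#' @param pre_values named numeric vector, one pre-operative value per
#'   patient (names = patient ids).
#' @param cohort the \code{cohort_table}.
#' @return list with \code{p}, \code{high_group_worse} (is the high
#'   group's survival curve lower at the last event time), \code{flag}.
#' @export
median_split_logrank <- function(pre_values, cohort) {
  stopifnot(!is.null(names(pre_values)))
  v <- pre_values[cohort$patient_id]
  if (anyNA(v)) stop("missing pre-operative value for some patients")
  med <- stats::median(v)
  high <- v >= med
  if (all(high) || !any(high))
    return(list(p = NA_real_, high_group_worse = NA, flag = "no_split"))
  lr <- logrank(cohort$rfs_days, cohort$rfs_event, high)
  # compare the two survival curves at the last observed event time
  fit <- survival::survfit(
    survival::Surv(cohort$rfs_days, cohort$rfs_event) ~ high)
  s_end <- vapply(split(seq_along(fit$time),
                        rep(seq_along(fit$strata), fit$strata)),
                  function(i) min(fit$surv[i]), numeric(1))
  names(s_end) <- names(fit$strata)
  worse <- s_end[grepl("TRUE", names(s_end))] <
    s_end[grepl("FALSE", names(s_end))]
  list(p = lr$p, high_group_worse = isTRUE(unname(worse)), flag = NULL)
}

#' Stage 4: three-time-point trajectory classification
#'
#' For a pre-high miRNA the canonical recurrence pattern is a
#' post-operative fall followed by re-elevation at the recurrence time
#' point. The miRNA is kept iff (a) among relapsers
#' \code{median(post) < median(pre) - margin} and \code{median(final) >
#' median(post) + margin}; (b) the fraction of relapsers individually
#' showing fall-then-rise is at least \code{trajectory_majority}; and
#' (c) that fraction exceeds the corresponding fraction among
#' non-relapsers. Pre-low miRNAs use the mirror (rise-then-fall) rule.
#'
#' @param x normalized \code{signal_matrix}.
#' @param samples sample sheet (pre/post/final per patient).
#' @param cohort the \code{cohort_table}.
#' @param probe probe id.
#' @param direction \code{"pre_high"} or \code{"pre_low"} from stage 2.
#' @param config a \code{\link{funnel_config}}.
#' @return logical: keep the miRNA?
#' @export
classify_trajectory <- function(x, samples, cohort, probe,
                                direction = c("pre_high", "pre_low"),
                                config = funnel_config()) {
  direction <- match.arg(direction)
  rel <- cohort$patient_id[cohort$group == "recurrence"]
  if (!length(rel)) {
    warning("no relapsers in cohort; trajectory classification skipped")
    return(NA)
  }
  non <- setdiff(cohort$patient_id, rel)
  tp_val <- function(pats, tp) {
    ids <- samples$sample_id[samples$patient_id %in% pats &
                               samples$time_point %in% tp]
    pat <- samples$patient_id[match(ids, samples$sample_id)]
    stats::setNames(x$values[probe, ids], pat)[pats]
  }
  m <- config$trajectory_margin
  sgn <- if (direction == "pre_high") 1 else -1
  pre <- sgn * tp_val(rel, "pre")
  post <- sgn * tp_val(rel, "post")
  fin <- sgn * tp_val(rel, "final")
  cond_a <- stats::median(post) < stats::median(pre) - m &&
    stats::median(fin) > stats::median(post) + m
  pattern <- function(pre, post, fin) (post < pre - m) & (fin > post + m)
  frac_rel <- mean(pattern(pre, post, fin))
  if (length(non)) {
    frac_non <- mean(pattern(sgn * tp_val(non, "pre"),
                             sgn * tp_val(non, "post"),
                             sgn * tp_val(non, "final")))
  } else frac_non <- 0
  isTRUE(cond_a && frac_rel >= config$trajectory_majority &&
           frac_rel > frac_non)
}

#' Run the full candidate-extraction funnel
#'
#' Executes the four stages in order — detection filter on pre-operative
#' samples, paired pre/post t-test split into pre-high/pre-low pools,
#' per-miRNA median-split log-rank filter on RFS, and three-time-point
#' trajectory classification — and reports the surviving miRNA sets and
#' counts at each stage. Each stage's set is a subset of the previous
#' one; final up-candidates come from the pre-high pool and
#' down-candidates from the pre-low pool.
#'
#' @param x a normalized \code{\link{signal_matrix}}.
#' @param samples sample sheet.
#' @param cohort the \code{cohort_table}.
#' @param panel the \code{\link{probe_panel}} (for miRNA names).
#' @param config a \code{\link{funnel_config}}.
#' @return an object of class \code{"funnel_report"}.
#' @examples
#' sim <- simulate_cohort(simulation_config(seed = 1))
#' norm <- normalize_signals(sim$signals, sim$panel)
#' rep <- run_funnel(norm, sim$samples, sim$cohort, sim$panel)
#' rep
#' @export
run_funnel <- function(x, samples, cohort, panel,
                       config = funnel_config()) {
  cohort <- validate_cohort(as.data.frame(cohort))
  detected <- filter_detected(x, samples, config)

  scan <- paired_scan(x, samples)
  scan <- scan[scan$probe_id %in% detected, ]
  p2 <- if (config$p_adjust == "BH") stats::p.adjust(scan$p, "BH") else scan$p
  sig2 <- !is.na(p2) & p2 < config$alpha_paired & !scan$degenerate
  pre_high <- scan$probe_id[sig2 & scan$direction == "pre_high"]
  pre_low <- scan$probe_id[sig2 & scan$direction == "pre_low"]

  pre_ids <- samples[samples$time_point %in% "pre", ]
  pre_cols <- pre_ids$sample_id[match(cohort$patient_id, pre_ids$patient_id)]
  rfs_keep <- function(probes) {
    ps <- vapply(probes, function(pr) {
      v <- stats::setNames(x$values[pr, pre_cols], cohort$patient_id)
      r <- median_split_logrank(v, cohort)
      if (is.na(r$p)) NA_real_ else r$p
    }, numeric(1))
    list(keep = probes[!is.na(ps) & ps < config$alpha_logrank],
         p = stats::setNames(ps, probes))
  }
  rfs_high <- rfs_keep(pre_high)
  rfs_low <- rfs_keep(pre_low)

  traj_keep <- function(probes, direction) {
    probes[vapply(probes, function(pr)
      isTRUE(classify_trajectory(x, samples, cohort, pr, direction, config)),
      logical(1))]
  }
  final_up <- traj_keep(rfs_high$keep, "pre_high")
  final_down <- traj_keep(rfs_low$keep, "pre_low")

  to_name <- function(ids)
    stats::setNames(panel$mirna_name[match(ids, panel$probe_id)], ids)
  structure(list(
    n_input = nrow(x$values),
    detected_set = detected,
    paired_significant_pre_high = pre_high,
    paired_significant_pre_low = pre_low,
    rfs_significant_pre_high = rfs_high$keep,
    rfs_significant_pre_low = rfs_low$keep,
    final_up = to_name(final_up),
    final_down = to_name(final_down),
    p_paired = stats::setNames(scan$p, scan$probe_id),
    p_logrank = c(rfs_high$p, rfs_low$p),
    config = config
  ), class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Candidate-miRNA selection funnel\n")
  cat("  input probes:            ", x$n_input, "\n")
  cat("  detected (pre-op):       ", length(x$detected_set), "\n")
  cat("  paired-test significant: ",
      length(x$paired_significant_pre_high) +
        length(x$paired_significant_pre_low),
      " (pre-high ", length(x$paired_significant_pre_high),
      " / pre-low ", length(x$paired_significant_pre_low), ")\n", sep = "")
  cat("  RFS log-rank significant: pre-high ",
      length(x$rfs_significant_pre_high), " / pre-low ",
      length(x$rfs_significant_pre_low), "\n", sep = "")
  cat("  final candidates: up {",
      paste(x$final_up, collapse = ", "), "}, down {",
      paste(x$final_down, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Per-stage survivor counts of a funnel report
#'
#' @param report a \code{\link{run_funnel}} result.
#' @return named integer vector of counts at each funnel stage.
#' @export
funnel_counts <- function(report) {
  stopifnot(inherits(report, "funnel_report"))
  c(input = report$n_input,
    detected = length(report$detected_set),
    paired_significant = length(report$paired_significant_pre_high) +
      length(report$paired_significant_pre_low),
    pre_high = length(report$paired_significant_pre_high),
    pre_low = length(report$paired_significant_pre_low),
    rfs_pre_high = length(report$rfs_significant_pre_high),
    rfs_pre_low = length(report$rfs_significant_pre_low),
    final_up = length(report$final_up),
    final_down = length(report$final_down))
}
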