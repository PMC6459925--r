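#' Configuration of the synthetic serum-miRNA cohort
#'
#' Defaults mirror the study design the pipeline targets: 22 patients
#' sampled at three time points (66 arrays), 13 of whom relapse; a
#' 2565-miRNA panel of which 47 are internal-control miRNAs, plus separate
#' negative-control probes; four planted "upregulated" recurrence markers
#' (high pre-operatively in relapsers, dropping after surgery, re-rising
#' at recurrence) and two "downregulated" markers with the mirror pattern;
#' per-array log-normal scale factors and additive background noise so the
#' normalization chain is genuinely exercised; exponential, censored RFS
#' with a median-scale follow-up of 1454 days.
#'
#' @param n_patients number of patients (3 arrays each).
#' @param n_recurrence number of patients who relapse.
#' @param n_target_probes total miRNA probes (internal controls included).
#' @param n_internal_controls internal-control miRNAs within the panel.
#' @param n_negative_controls non-miRNA background probes.
#' @param n_up_markers,n_down_markers planted recurrence markers.
#' @param marker_effect_log2 pre-operative group difference, log2 units.
#' @param dynamics_amplitude_log2 post-operative drop / recurrence
#'   re-elevation magnitude, log2 units.
#' @param trajectory_concordance fraction of relapsers showing the
#'   canonical fall-then-rise pattern.
#' @param array_scale_sd sdlog of the per-array log-normal scale factor.
#' @param background_mean,background_sd additive background intensity
#'   (negative-control level), linear scale.
#' @param rfs_rate exponential hazard (per day) of recurrence for
#'   relapsers; default mean time to recurrence 365 days.
#' @param followup_days administrative follow-up horizon.
#' @param baseline_log2_mean,baseline_log2_sd per-probe baseline log2
#'   intensity distribution for ordinary target probes.
#' @param noise_log2_sd per-measurement log2 noise.
#' @param up_marker_names,down_marker_names miRNA names given to the
#'   planted markers (defaults: the six serum miRNAs the pipeline's
#'   published indices use).
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @return a list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_patients = 22, n_recurrence = 13,
                              n_target_probes = 2565,
                              n_internal_controls = 47,
                              n_negative_controls = 100,
                              n_up_markers = 4, n_down_markers = 2,
                              marker_effect_log2 = 1.5,
                              dynamics_amplitude_log2 = 1.0,
                              trajectory_concordance = 0.9,
                              array_scale_sd = 0.3,
                              background_mean = 30, background_sd = 15,
                              rfs_rate = 1 / 365, followup_days = 1454,
                              baseline_log2_mean = 4.5,
                              baseline_log2_sd = 2.5,
                              noise_log2_sd = 0.5,
                              up_marker_names = c("hsa-miR-1225-3p",
                                                  "hsa-miR-1234-3p",
                                                  "hsa-miR-1260b",
                                                  "hsa-miR-1470"),
                              down_marker_names = c("hsa-miR-6834-3p",
                                                    "hsa-miR-6875-5p"),
                              seed = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_recurrence > cfg$n_patients)
    stop("n_recurrence must not exceed n_patients")
  n_markers <- cfg$n_up_markers + cfg$n_down_markers
  if (n_markers > cfg$n_target_probes - cfg$n_internal_controls)
    stop("marker count exceeds available (non-control) target probes")
  if (cfg$n_internal_controls > cfg$n_target_probes)
    stop("internal controls exceed target probe count")
  sds <- c(cfg$array_scale_sd, cfg$background_sd, cfg$baseline_log2_sd,
           cfg$noise_log2_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (cfg$trajectory_concordance < 0 || cfg$trajectory_concordance > 1)
    stop("trajectory_concordance must lie in [0, 1]")
  if (length(cfg$up_marker_names) < cfg$n_up_markers ||
      length(cfg$down_marker_names) < cfg$n_down_markers)
    stop("not enough marker names for the requested marker counts")
  invisible(cfg)
}

#' Build the probe panel for a simulated array design
#'
#' Planted marker miRNAs get the configured names; internal-control
#' miRNAs are drawn from the target pool (never overlapping the planted
#' markers); negative controls are separate unnamed probes.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return a \code{\link{probe_panel}}.
#' @export
simulate_panel <- function(config) {
  n_t <- config$n_target_probes
  n_ic <- config$n_internal_controls
  up <- config$up_marker_names[seq_len(config$n_up_markers)]
  dn <- config$down_marker_names[seq_len(config$n_down_markers)]
  n_plain <- n_t - n_ic - length(up) - length(dn)
  names_t <- c(up, dn,
               sprintf("hsa-miR-sim-%04d", seq_len(n_plain)),
               sprintf("hsa-miR-ctl-%02d", seq_len(n_ic)))
  cls <- c(rep("target", n_t - n_ic), rep("internal_control", n_ic))
  ids <- c(sprintf("probe_%04d", seq_len(n_t)),
           sprintf("negctl_%03d", seq_len(config$n_negative_controls)))
  probe_panel(ids,
              c(cls, rep("negative_control", config$n_negative_controls)),
              c(names_t, rep("", config$n_negative_controls)))
}

#' Generate the clinical cohort and sample sheet
#'
#' Relapsers draw recurrence-free survival from an exponential
#' distribution truncated at the follow-up horizon (all observed events);
#' non-relapsers are censored near the horizon. Overall survival for
#' relapsers adds an independent exponential post-recurrence survival, so
#' \code{rfs_days <= os_days} by construction. Clinical covariates follow
#' the cohort composition the study reports (age, sex ratio, disease-type
#' and stage mix, lymph-node metastasis rates, CEA / CA19-9 on their
#' clinical scales).
#'
#' @param config a \code{\link{simulation_config}}; if \code{config$seed}
#'   is non-NULL the RNG is seeded.
#' @return list with \code{cohort} (a \code{cohort_table}) and
#'   \code{samples} (sample sheet, 3 rows per patient).
#' @export
generate_cohort <- function(config) {
  validate_simulation_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_patients
  n_rec <- config$n_recurrence
  pid <- sprintf("BTC%02d", seq_len(n))
  relapse <- seq_len(n) <= n_rec

  rfs <- numeric(n)
  if (n_rec > 0) {
    # inverse-CDF draw from Exp(rate) truncated to (0, followup)
    u <- stats::runif(n_rec) * stats::pexp(config$followup_days, config$rfs_rate)
    rfs[relapse] <- pmax(1, round(stats::qexp(u, config$rfs_rate)))
  }
  rfs[!relapse] <- pmax(1, round(config$followup_days *
                                   stats::runif(n - n_rec, 0.85, 1.15)))
  os <- rfs
  os_event <- rep(FALSE, n)
  if (n_rec > 0) {
    post_surv <- pmax(1, round(stats::rexp(n_rec, 1 / 500)))
    horizon <- round(1.5 * config$followup_days)
    os[relapse] <- rfs[relapse] + post_surv
    died <- os[relapse] <= horizon
    os[relapse][!died] <- pmax(horizon, rfs[relapse][!died])
    os_event[relapse] <- died
  }

  lymph_p <- ifelse(relapse, 7 / 13, 3 / 9)
  cohort <- data.frame(
    patient_id = pid,
    group = ifelse(relapse, "recurrence", "nonrecurrence"),
    rfs_days = rfs, rfs_event = relapse,
    os_days = os, os_event = os_event,
    age = pmin(85, pmax(31, round(stats::rnorm(n, 65.4, 11)))),
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(17, 5)),
    disease_type = sample(c("bile_duct", "gallbladder", "ampulla"), n,
                          replace = TRUE, prob = c(15, 5, 2)),
    stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                   prob = c(9, 12, 1, 0.2)),
    differentiation = sample(c("well", "moderate", "poor"), n,
                             replace = TRUE, prob = c(7, 12, 3)),
    lymph_metastasis = stats::runif(n) < lymph_p,
    cea = round(stats::rlnorm(n, log(2.5), 0.8), 2),
    ca19_9 = round(stats::rlnorm(n, log(20), 1.0), 1),
    stringsAsFactors = FALSE
  )
  cohort <- validate_cohort(cohort)
  samples <- data.frame(
    sample_id = paste0(rep(pid, each = 3), "_", c("pre", "post", "final")),
    patient_id = rep(pid, each = 3),
    time_point = rep(c("pre", "post", "final"), n),
    stringsAsFactors = FALSE
  )
  list(cohort = cohort, samples = validate_samples(samples))
}

#' Generate raw probe intensities with planted recurrence markers
#'
#' Signals are generated on the log2 scale (per-probe baselines plus
#' measurement noise plus the planted group/time effects), exponentiated,
#' multiplied by a per-array log-normal scale factor, and given additive
#' Gaussian background — the multiplicative-plus-background structure the
#' normalization chain assumes. Negative-control probes carry background
#' only. Internal controls receive no group or time effect, so
#' internal-control scaling is statistically valid on simulated data.
#'
#' Planted "up" markers add \code{marker_effect_log2} to relapsers at all
#' time points, subtract \code{dynamics_amplitude_log2} post-operatively
#' and restore it at the final (recurrence) time point for a
#' \code{trajectory_concordance} fraction of relapsers; non-relapsers
#' re-elevate at the final time point with probability
#' \code{1 - trajectory_concordance}. "Down" markers are mirror-imaged.
#'
#' @param cohort,samples output of \code{\link{generate_cohort}}.
#' @param panel a \code{\link{simulate_panel}} result.
#' @param config the \code{\link{simulation_config}} used throughout; if
#'   \code{config$seed} is non-NULL the RNG is seeded with
#'   \code{config$seed + 1} (so cohort and signals are independently
#'   reproducible).
#' @return list with \code{signals} (a raw \code{\link{signal_matrix}})
#'   and \code{truth}: planted up/down miRNA name lists, the true
#'   discriminant direction over the planted markers (unit vector,
#'   positive on up markers), and the per-array scale factors.
#' @export
generate_signals <- function(cohort, samples, panel, config) {
  validate_simulation_config(config)
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  n_s <- nrow(samples)
  is_neg <- panel$probe_class == "negative_control"
  is_ic <- panel$probe_class == "internal_control"
  up <- config$up_marker_names[seq_len(config$n_up_markers)]
  dn <- config$down_marker_names[seq_len(config$n_down_markers)]
  is_up <- panel$mirna_name %in% up
  is_dn <- panel$mirna_name %in% dn
  n_p <- nrow(panel)

  baseline <- stats::rnorm(n_p, config$baseline_log2_mean,
                           config$baseline_log2_sd)
  baseline[is_ic] <- stats::rnorm(sum(is_ic), 8, 0.5)
  baseline[is_up | is_dn] <- stats::rnorm(sum(is_up | is_dn), 7, 0.5)

  x <- matrix(stats::rnorm(n_p * n_s, 0, config$noise_log2_sd), n_p, n_s) +
    baseline

  relapse <- cohort$patient_id[cohort$group == "recurrence"]
  concordant <- stats::setNames(
    stats::runif(nrow(cohort)) < config$trajectory_concordance,
    cohort$patient_id)
  # non-relapser spurious re-elevation at the final time point
  spurious <- stats::setNames(
    stats::runif(nrow(cohort)) < (1 - config$trajectory_concordance),
    cohort$patient_id)

  eff <- config$marker_effect_log2
  amp <- config$dynamics_amplitude_log2
  for (j in seq_len(n_s)) {
    pat <- samples$patient_id[j]
    tp <- samples$time_point[j]
    if (pat %in% relapse) {
      shift <- eff
      if (concordant[[pat]] && tp == "post") shift <- eff - amp
      x[is_up, j] <- x[is_up, j] + shift
      x[is_dn, j] <- x[is_dn, j] - shift
    } else if (tp == "final" && spurious[[pat]]) {
      x[is_up, j] <- x[is_up, j] + amp
      x[is_dn, j] <- x[is_dn, j] - amp
    }
  }

  lin <- 2^x
  lin[is_neg, ] <- 0
  scale_f <- stats::rlnorm(n_s, 0, config$array_scale_sd)
  # right-skewed additive background (array backgrounds are nonnegative
  # and heavy-tailed); parameterized by its mean and sd
  m <- config$background_mean; s <- config$background_sd
  if (s > 0 && m > 0) {
    sdlog <- sqrt(log(1 + (s / m)^2))
    meanlog <- log(m) - sdlog^2 / 2
    bg <- matrix(stats::rlnorm(n_p * n_s, meanlog, sdlog), n_p, n_s)
  } else {
    bg <- matrix(m, n_p, n_s)
  }
  values <- sweep(lin + pmax(bg, 0), 2, scale_f, `*`)
  values <- pmax(values, 0)
  dimnames(values) <- list(panel$probe_id, samples$sample_id)

  w <- c(rep(1, length(up)), rep(-1, length(dn)))
  truth <- list(
    planted_up_mirnas = up,
    planted_down_mirnas = dn,
    true_discriminant = stats::setNames(w / sqrt(sum(w^2)), c(up, dn)),
    scale_factors = stats::setNames(scale_f, samples$sample_id)
  )
  list(signals = signal_matrix(values, stage = "raw"), truth = truth)
}

#' Simulate a complete cohort: panel, clinical table, sample sheet,
#' raw signals and ground truth
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with \code{panel}, \code{cohort}, \code{samples},
#'   \code{signals}, \code{truth}.
#' @examples
#' sim <- simulate_cohort(simulation_config(seed = 1))
#' dim(sim$signals)
#' @export
simulate_cohort <- function(config = simulation_config()) {
  panel <- simulate_panel(config)
  cs <- generate_cohort(config)
  sig <- generate_signals(cs$cohort, cs$samples, panel, config)
  c(list(panel = panel), cs, sig)
}

#' Write all simulation artifacts to a directory
#'
#' Writes \code{signals.tsv}, \code{panel.tsv}, \code{cohort.csv},
#' \code{samples.csv} and \code{ground_truth.json}.
#'
#' @param sim a \code{\link{simulate_cohort}} result.
#' @param dir output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_signal_matrix(sim$signals, file.path(dir, "signals.tsv"))
  write_probe_panel(sim$panel, file.path(dir, "panel.tsv"))
  write_cohort(sim$cohort, file.path(dir, "cohort.csv"))
  write_samples(sim$samples, file.path(dir, "samples.csv"))
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
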