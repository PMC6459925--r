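#' End-to-end pipeline configuration
#'
#' Bundles the stage configurations with a single global seed. Per-stage
#' seeds are derived deterministically from the global seed so stages
#' stay reproducible without coupling.
#'
#' @param simulation a \code{\link{simulation_config}} (used when no
#'   external data paths are given).
#' @param normalization a \code{\link{normalization_params}}.
#' @param funnel a \code{\link{funnel_config}}.
#' @param max_size largest miRNA combination evaluated in the
#'   exhaustive discriminant search.
#' @param endpoints survival endpoints to analyse.
#' @param hr_threshold univariate hazard-ratio entry rule for the
#'   multivariate Cox model.
#' @param paths optional named list of input file paths
#'   (\code{signals}, \code{panel}, \code{cohort}, \code{samples});
#'   when given, data are read instead of simulated.
#' @param seed global integer seed.
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            normalization = normalization_params(),
                            funnel = funnel_config(),
                            max_size = 3,
                            endpoints = c("rfs", "os"),
                            hr_threshold = 2.0,
                            paths = NULL,
                            seed = 1L) {
  structure(list(simulation = simulation, normalization = normalization,
                 funnel = funnel, max_size = max_size,
                 endpoints = match.arg(endpoints, several.ok = TRUE),
                 hr_threshold = hr_threshold, paths = paths,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Returns diagnostics (character vector, empty when valid) instead of
#' raising errors, and never mutates the configuration.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return character vector of human-readable diagnostics.
#' @export
validate_config <- function(config) {
  diags <- character()
  note <- function(msg) diags <<- c(diags, msg)
  f <- config$funnel
  if (f$detection_fraction <= 0 || f$detection_fraction > 1)
    note("funnel$detection_fraction must lie in (0, 1]")
  for (nm in c("alpha_paired", "alpha_logrank"))
    if (f[[nm]] <= 0 || f[[nm]] >= 1)
      note(paste0("funnel$", nm, " must lie in (0, 1)"))
  s <- config$simulation
  if (s$n_recurrence > s$n_patients)
    note("simulation$n_recurrence exceeds n_patients")
  if (config$max_size < 1) note("max_size must be >= 1")
  if (config$hr_threshold < 0) note("hr_threshold must be >= 0")
  if (!is.null(config$paths)) {
    need <- c("signals", "panel", "cohort", "samples")
    for (nm in need) {
      if (is.null(config$paths[[nm]]))
        note(paste0("paths$", nm, " missing (required in non-simulation mode)"))
      else if (!file.exists(config$paths[[nm]]))
        note(paste0("paths$", nm, " does not exist: ", config$paths[[nm]]))
    }
  }
  diags
}

# per-stage seed derived from the global seed and the stage name
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 1009L + h) %% 2147483647L
}

#' Run the complete analysis pipeline
#'
#' Simulates (or loads) a cohort, normalizes the raw signals, runs the
#' candidate-selection funnel, fits the exhaustive Fisher-discriminant
#' search over the final candidates, builds the best index, and performs
#' the survival analyses (median/index-split Kaplan-Meier with log-rank,
#' univariate Cox over the index and clinical covariates, multivariate
#' Cox over covariates passing the hazard-ratio entry rule). Reruns with
#' the same configuration and seed are identical.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return an object of class \code{"run_report"} with elements
#'   \code{funnel_counts}, \code{funnel}, \code{per_candidate} (per-miRNA
#'   discriminant table), \code{search} (best-combination table),
#'   \code{index} (the best fitted \code{\link{flda}} model),
#'   \code{survival} (per endpoint: log-rank by index group, univariate
#'   and multivariate Cox tables), \code{provenance}.
#' @examples
#' \donttest{
#' rep <- run_pipeline(pipeline_config(seed = 7))
#' rep$funnel_counts
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  diags <- validate_config(config)
  if (length(diags))
    stop("invalid pipeline configuration:\n  ", paste(diags, collapse = "\n  "))

  if (is.null(config$paths)) {
    sim_cfg <- config$simulation
    sim_cfg$seed <- stage_seed(config$seed, "simulate")
    sim <- simulate_cohort(sim_cfg)
    panel <- sim$panel; cohort <- sim$cohort
    samples <- sim$samples; raw <- sim$signals
    truth <- sim$truth
  } else {
    panel <- read_probe_panel(config$paths$panel)
    cohort <- read_cohort(config$paths$cohort)
    samples <- read_samples(config$paths$samples)
    raw <- read_signal_matrix(config$paths$signals, panel)
    truth <- NULL
  }

  norm <- normalize_signals(raw, panel, config$normalization)
  funnel <- run_funnel(norm, samples, cohort, panel, config$funnel)

  candidates <- c(funnel$final_up, funnel$final_down)
  per_candidate <- NULL; search <- NULL; index <- NULL
  surv_rep <- list()
  if (length(candidates) >= 1) {
    pre <- samples[samples$time_point %in% "pre", ]
    pre_cols <- pre$sample_id[match(cohort$patient_id, pre$patient_id)]
    X <- t(norm$values[names(candidates), pre_cols, drop = FALSE])
    colnames(X) <- unname(candidates)
    rownames(X) <- cohort$patient_id
    y <- cohort$group

    per_candidate <- do.call(rbind, lapply(unname(candidates), function(nm) {
      fit <- fit_flda(X[, nm, drop = FALSE], y)
      data.frame(mirna = nm, accuracy = fit$metrics$accuracy,
                 sensitivity = fit$metrics$sensitivity,
                 specificity = fit$metrics$specificity,
                 auc = fit$metrics$auc, stringsAsFactors = FALSE)
    }))

    search <- exhaustive_search(X, y, unname(candidates),
                                max_size = min(config$max_size,
                                               length(candidates)))
    index <- search$models[[1]]

    high <- apply_index(index, X)$predicted == "recurrence"
    for (ep in config$endpoints) {
      tm <- cohort[[paste0(ep, "_days")]]
      ev <- cohort[[paste0(ep, "_event")]]
      lr <- if (length(unique(high)) == 2) logrank(tm, ev, high) else
        list(chi2 = NA_real_, p = NA_real_, flag = "one_group")
      covs <- data.frame(
        index_high = high,
        age = cohort$age,
        sex = cohort$sex == "M",
        lymph_metastasis = cohort$lymph_metastasis,
        ca19_9_high = cohort$ca19_9 >= 37,
        cea_high = cohort$cea >= 5)
      drop_const <- vapply(covs, function(v) length(unique(v)) > 1,
                           logical(1))
      uv <- cox_fit(covs[, drop_const, drop = FALSE], tm, ev, "univariate")
      sel <- multivariate_select(uv, config$hr_threshold)
      mv <- if (length(sel) >= 1)
        cox_fit(covs[, sel, drop = FALSE], tm, ev, "multivariate") else NULL
      surv_rep[[ep]] <- list(
        km_high = km_fit(tm[high], ev[high]),
        km_low = km_fit(tm[!high], ev[!high]),
        logrank = lr, univariate = uv, selected = sel, multivariate = mv)
    }
  }

  structure(list(
    funnel_counts = funnel_counts(funnel),
    funnel = funnel,
    per_candidate = per_candidate,
    search = if (!is.null(search)) search$best_per_size else NULL,
    search_full = search,
    index = index,
    survival = surv_rep,
    truth = truth,
    provenance = list(package = "miRecur",
                      version = as.character(utils::packageVersion("miRecur")),
                      seed = config$seed, date = "set-by-user")
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("== Recurrence-prediction pipeline report ==\n\nFunnel:\n")
  print(x$funnel_counts)
  if (!is.null(x$per_candidate)) {
    cat("\nPer-candidate discriminant performance:\n")
    print(x$per_candidate, digits = 3, row.names = FALSE)
  }
  if (!is.null(x$search)) {
    cat("\nBest combination per panel size:\n")
    print(x$search, digits = 3, row.names = FALSE)
  }
  if (!is.null(x$index)) { cat("\nSelected index:\n"); print(x$index) }
  for (ep in names(x$survival)) {
    s <- x$survival[[ep]]
    cat(sprintf("\n%s: log-rank chi2 = %.3f, p = %.4g (index-high vs low)\n",
                toupper(ep), s$logrank$chi2, s$logrank$p))
    print(s$univariate)
    if (!is.null(s$multivariate)) print(s$multivariate)
  }
  invisible(x)
}
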