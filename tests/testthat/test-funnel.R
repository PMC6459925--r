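# small normalized-like matrix builder: values given directly at log2 stage
log2_matrix <- function(values, detected = NULL) {
  sm <- signal_matrix(values, detected, stage = "raw")
  sm$stage <- "log2"
  sm
}

test_that("the detection filter keeps miRNAs present in most pre-op samples", {
  samples <- data.frame(sample_id = paste0("s", 1:22),
                        patient_id = paste0("P", 1:22),
                        time_point = "pre")
  v <- rbind(all_det = rep(1, 22),
             none = rep(0, 22),
             half = c(rep(1, 11), rep(0, 11)))
  colnames(v) <- samples$sample_id
  det <- v > 0
  kept <- filter_detected(log2_matrix(v, det), samples)
  expect_true("all_det" %in% kept)
  expect_false("none" %in% kept)
  expect_true("half" %in% kept)   # 11/22 = 0.5 passes (>= convention)
  expect_false("half" %in%
                 filter_detected(log2_matrix(v, det), samples,
                                 funnel_config(detection_fraction = 0.6)))
  nopre <- samples; nopre$time_point <- "post"
  expect_error(filter_detected(log2_matrix(v, det), nopre), "pre-operative")
})

test_that("the paired pre/post test matches the direct t formula", {
  samples <- data.frame(
    sample_id = c("a_pre", "a_post", "b_pre", "b_post", "c_pre", "c_post"),
    patient_id = rep(c("a", "b", "c"), each = 2),
    time_point = rep(c("pre", "post"), 3))
  mk <- function(pre, post) {
    v <- matrix(0, 1, 6, dimnames = list("m1", samples$sample_id))
    v[1, c(1, 3, 5)] <- pre; v[1, c(2, 4, 6)] <- post
    log2_matrix(v)
  }
  # oracle check on a non-degenerate triple
  res <- paired_prepost_test(mk(c(1, 2, 3), c(2, 2.5, 4.5)), samples, "m1")
  ora <- oracle_paired_t(c(1, 2, 3), c(2, 2.5, 4.5))
  expect_equal(res$t, ora$t)
  expect_equal(res$p, ora$p)
  expect_identical(res$direction, "pre_low")
  # cross-check against t.test
  tt <- t.test(c(1, 2, 3), c(2, 2.5, 4.5), paired = TRUE)
  expect_equal(res$p, tt$p.value)

  # constant nonzero differences: degenerate, flagged
  res2 <- paired_prepost_test(mk(c(5, 6, 7), c(3, 4, 5)), samples, "m1")
  expect_true(res2$degenerate)
  expect_true(is.na(res2$p))
  expect_identical(res2$direction, "pre_high")

  # identical pre and post: p = 1 by convention
  res3 <- paired_prepost_test(mk(c(2, 4, 8), c(2, 4, 8)), samples, "m1")
  expect_equal(res3$p, 1)
  expect_false(res3$degenerate)
})

test_that("the median-split log-rank filter follows the >=-median convention", {
  co <- toy_cohort(k_rec = 3, k_non = 3)
  # even n with distinct values: equal group sizes
  v <- stats::setNames(c(1, 2, 3, 4, 5, 6), co$patient_id)
  med <- stats::median(v)
  expect_equal(sum(v >= med), 3L)

  # identical survival in both split groups -> statistic 0, p = 1
  co2 <- validate_cohort(data.frame(
    patient_id = paste0("P", 1:4),
    group = rep(c("recurrence", "nonrecurrence"), 2),
    rfs_days = c(100, 500, 100, 500),
    rfs_event = c(TRUE, FALSE, TRUE, FALSE),
    os_days = c(150, 550, 150, 550), os_event = FALSE))
  # split {P2,P3} vs {P1,P4}: each side one event at 100, one censored at 500
  r <- median_split_logrank(stats::setNames(c(1, 4, 3, 2), co2$patient_id),
                            co2)
  expect_equal(r$p, 1)

  # hand-computed O-E log-rank on a 4-patient table:
  # high group events at day 100; low group censored at day 1000
  co3 <- validate_cohort(data.frame(
    patient_id = paste0("P", 1:4),
    group = rep(c("recurrence", "nonrecurrence"), each = 2),
    rfs_days = c(100, 100, 1000, 1000),
    rfs_event = c(TRUE, TRUE, FALSE, FALSE),
    os_days = c(100, 100, 1000, 1000),
    os_event = c(TRUE, TRUE, FALSE, FALSE)))
  vals <- stats::setNames(c(9, 8, 1, 2), co3$patient_id)
  r3 <- median_split_logrank(vals, co3)
  chi_hand <- oracle_logrank_chi2(co3$rfs_days, co3$rfs_event,
                                  vals >= stats::median(vals))
  expect_equal(r3$p, stats::pchisq(chi_hand, 1, lower.tail = FALSE))
  expect_true(r3$high_group_worse)

  # all values identical: cannot split
  r4 <- median_split_logrank(stats::setNames(rep(1, 4), co3$patient_id), co3)
  expect_identical(r4$flag, "no_split")
})

test_that("trajectory classification keeps canonical patterns only", {
  co <- toy_cohort(k_rec = 4, k_non = 4)
  samples <- data.frame(
    sample_id = paste0(rep(co$patient_id, each = 3), "_",
                       c("pre", "post", "final")),
    patient_id = rep(co$patient_id, each = 3),
    time_point = rep(c("pre", "post", "final"), 8))
  traj <- function(rel_pattern, non_pattern = c(5, 5, 5)) {
    v <- matrix(0, 1, 24, dimnames = list("m1", samples$sample_id))
    for (i in 1:8) {
      pat <- if (i <= 4) rel_pattern else non_pattern
      v[1, (3 * i - 2):(3 * i)] <- pat + stats::rnorm(3, 0, 0.01)
    }
    log2_matrix(v)
  }
  set.seed(8)
  # fall-then-rise in relapsers, flat in non-relapsers: kept as pre_high
  expect_true(classify_trajectory(traj(c(7, 5, 7)), samples, co, "m1",
                                  "pre_high"))
  # flat everywhere: dropped
  expect_false(classify_trajectory(traj(c(5, 5, 5)), samples, co, "m1",
                                   "pre_high"))
  # mirror pattern kept for pre_low
  expect_true(classify_trajectory(traj(c(3, 5, 3)), samples, co, "m1",
                                  "pre_low"))
  # rise-then-fall is wrong for pre_high
  expect_false(classify_trajectory(traj(c(3, 5, 3)), samples, co, "m1",
                                   "pre_high"))
  # no relapsers: NA with warning
  co_non <- co[co$group == "nonrecurrence", ]
  class(co_non) <- "data.frame"
  co_non <- validate_cohort(co_non)
  expect_warning(
    keep <- classify_trajectory(traj(c(7, 5, 7)), samples, co_non, "m1",
                                "pre_high"),
    "no relapsers")
  expect_true(is.na(keep))
})

test_that("the funnel is monotone and recovers planted markers", {
  cfg <- simulation_config(n_patients = 100, n_recurrence = 50,
                           n_target_probes = 250, n_internal_controls = 15,
                           n_negative_controls = 40, seed = 61)
  sim <- simulate_cohort(cfg)
  norm <- normalize_signals(sim$signals, sim$panel)
  rep <- run_funnel(norm, sim$samples, sim$cohort, sim$panel)

  # subset-inclusion invariants of the funnel
  expect_true(all(c(rep$paired_significant_pre_high,
                    rep$paired_significant_pre_low) %in% rep$detected_set))
  expect_true(all(rep$rfs_significant_pre_high %in%
                    rep$paired_significant_pre_high))
  expect_true(all(rep$rfs_significant_pre_low %in%
                    rep$paired_significant_pre_low))
  expect_true(all(names(rep$final_up) %in% rep$rfs_significant_pre_high))
  expect_true(all(names(rep$final_down) %in% rep$rfs_significant_pre_low))

  # planted markers recovered with the correct direction labels
  expect_true(all(sim$truth$planted_up_mirnas %in% rep$final_up))
  expect_true(all(sim$truth$planted_down_mirnas %in% rep$final_down))

  # vanishing alpha empties the candidate sets
  strict <- run_funnel(norm, sim$samples, sim$cohort, sim$panel,
                       funnel_config(alpha_paired = 1e-12))
  expect_equal(length(strict$final_up) + length(strict$final_down), 0L)

  cn <- funnel_counts(rep)
  expect_true(all(diff(cn[c("input", "detected", "paired_significant")]) <= 0))
})

test_that("funnel set inclusions hold across seeds", {
  for (seed in c(3, 14, 159)) {
    cfg <- simulation_config(n_patients = 12, n_recurrence = 6,
                             n_target_probes = 120, n_internal_controls = 10,
                             n_negative_controls = 25, seed = seed)
    sim <- simulate_cohort(cfg)
    norm <- normalize_signals(sim$signals, sim$panel)
    rep <- run_funnel(norm, sim$samples, sim$cohort, sim$panel)
    expect_true(all(c(rep$paired_significant_pre_high,
                      rep$paired_significant_pre_low) %in% rep$detected_set))
    expect_true(all(names(rep$final_up) %in% rep$rfs_significant_pre_high))
    expect_true(all(names(rep$final_down) %in% rep$rfs_significant_pre_low))
  }
})
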