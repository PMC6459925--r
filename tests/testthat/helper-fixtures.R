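# Small fixtures built in code; no stored binary data.

# panel with n_t target probes (first few named after the published
# index members so stored indices can be applied), n_ic internal
# controls and n_neg negative controls
tiny_panel <- function(n_t = 6, n_ic = 2, n_neg = 20) {
  published <- c("hsa-miR-1225-3p", "hsa-miR-1260b", "hsa-miR-6875-5p",
                 "hsa-miR-6834-3p", "hsa-miR-1234-3p", "hsa-miR-1470")
  t_names <- c(published, sprintf("hsa-miR-t%02d", seq_len(max(0, n_t - 6))))
  probe_panel(
    c(sprintf("t%02d", seq_len(n_t)), sprintf("ic%02d", seq_len(n_ic)),
      sprintf("neg%02d", seq_len(n_neg))),
    c(rep("target", n_t), rep("internal_control", n_ic),
      rep("negative_control", n_neg)),
    c(t_names[seq_len(n_t)], sprintf("hsa-miR-ctl-%02d", seq_len(n_ic)),
      rep("", n_neg)))
}

# tie-free fully detected matrix at the background_corrected stage
detected_matrix <- function(values) {
  sm <- signal_matrix(values, stage = "raw")
  sm$stage <- "background_corrected"
  sm
}

# minimal cohort: k_rec relapsers (events spread out), k_non censored
toy_cohort <- function(k_rec = 4, k_non = 4, seed = 42) {
  set.seed(seed)
  n <- k_rec + k_non
  rfs <- c(round(seq(100, 600, length.out = k_rec)),
           rep(1400, k_non) + seq_len(k_non))
  validate_cohort(data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    group = rep(c("recurrence", "nonrecurrence"), c(k_rec, k_non)),
    rfs_days = rfs, rfs_event = rep(c(TRUE, FALSE), c(k_rec, k_non)),
    os_days = rfs + 50, os_event = rep(FALSE, n),
    stringsAsFactors = FALSE))
}

# a hand-written two-sample GEO series-matrix fixture
write_geo_fixture <- function(path, time_points = c("pre-operative",
                                                    "postoperative")) {
  lines <- c(
    '!Series_title\t"serum miRNA test series"',
    paste0('!Sample_title\t"patient 1 A"\t"patient 1 B"'),
    '!Sample_geo_accession\t"GSM0001"\t"GSM0002"',
    sprintf('!Sample_characteristics_ch1\t"patient: P1"\t"patient: P1"'),
    sprintf('!Sample_characteristics_ch1\t"time point: %s"\t"time point: %s"',
            time_points[1], time_points[2]),
    "!series_matrix_table_begin",
    '"ID_REF"\t"GSM0001"\t"GSM0002"',
    '"probe_a"\t10.5\t12.25',
    '"probe_b"\t3\t4',
    "!series_matrix_table_end")
  writeLines(lines, path)
  path
}

# direct-formula paired t (the oracle: t = mean(d) / (sd(d)/sqrt(n)))
oracle_paired_t <- function(pre, post) {
  d <- pre - post
  t <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  list(t = t, p = 2 * stats::pt(-abs(t), df = length(d) - 1))
}

# textbook O-E log-rank chi-square, computed from first principles
oracle_logrank_chi2 <- function(time, event, group) {
  stopifnot(is.logical(group))
  o <- 0; e <- 0; v <- 0
  for (tt in sort(unique(time[event]))) {
    at_risk <- time >= tt
    d <- sum(event & time == tt)
    d1 <- sum(event & time == tt & group)
    n <- sum(at_risk); n1 <- sum(at_risk & group)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}

# exhaustive pair-counting AUC oracle
oracle_auc <- function(scores, y) {
  pos <- scores[y == "recurrence"]; neg <- scores[y == "nonrecurrence"]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}
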