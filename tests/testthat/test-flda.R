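make_classes <- function(n1, n0, mu1, mu0, sd = 1, seed = 1, p = length(mu1)) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n1 * p, rep(mu1, each = n1), sd), n1),
             matrix(rnorm(n0 * p, rep(mu0, each = n0), sd), n0))
  colnames(X) <- paste0("miR-", letters[1:p])
  list(X = X, y = rep(c("recurrence", "nonrecurrence"), c(n1, n0)))
}

test_that("one-dimensional fit puts the cut-off midway between class means", {
  d <- make_classes(40, 40, 2, 0, sd = 1, seed = 2, p = 1)
  fit <- fit_flda(d$X, d$y)
  m1 <- mean(d$X[d$y == "recurrence", 1])
  m0 <- mean(d$X[d$y == "nonrecurrence", 1])
  # unit-norm 1-D direction is +1, so the cut-off is the projected midpoint
  expect_equal(unname(fit$coefficients), 1)
  expect_equal(fit$cutoff,
               (m1 + m0) / 2 + fit$intercept)
  # grand mean anchored at the reference score 0
  expect_equal(sum(fit$coefficients * colMeans(d$X)) + fit$intercept, 0)
})

test_that("a linearly separable training set is classified perfectly", {
  d <- make_classes(10, 12, c(5, 5), c(0, 0), sd = 0.3, seed = 3)
  fit <- fit_flda(d$X, d$y)
  expect_equal(fit$metrics$accuracy, 1)
  expect_equal(fit$metrics$auc, 1)
})

test_that("the fitted direction maximizes the Fisher criterion", {
  # brute-force oracle: criterion over 1e5 random unit directions
  d <- make_classes(60, 50, c(1, 0, 0.5), c(0, 0.4, 0), sd = 1, seed = 4)
  fit <- fit_flda(d$X, d$y)
  rec <- d$y == "recurrence"
  Sw <- (stats::cov(d$X[rec, ]) * (sum(rec) - 1) +
           stats::cov(d$X[!rec, ]) * (sum(!rec) - 1)) / (nrow(d$X) - 2)
  delta <- colMeans(d$X[rec, ]) - colMeans(d$X[!rec, ])
  crit <- function(W) (W %*% delta)^2 / rowSums((W %*% Sw) * W)
  set.seed(5)
  W <- matrix(rnorm(3e5), ncol = 3)
  W <- W / sqrt(rowSums(W^2))
  best <- W[which.max(crit(W)), ]
  cosine <- abs(sum(best * fit$coefficients))
  expect_gte(cosine, 0.999)
  # and no sampled direction beats the analytic one
  expect_gte(max(crit(matrix(fit$coefficients, 1))), max(crit(W)))
})

test_that("fits agree with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  d <- make_classes(30, 25, c(1, 0, 0), c(0, 0.5, 0.2), sd = 1, seed = 6)
  fit <- fit_flda(d$X, d$y)
  ld <- MASS::lda(d$X, grouping = d$y)$scaling[, 1]
  cosine <- abs(sum(fit$coefficients * ld) /
                  sqrt(sum(ld^2)))
  expect_gte(cosine, 0.9999)
})

test_that("predictions are equivariant under affine feature rescaling", {
  d <- make_classes(20, 20, c(1, 0), c(0, 1), sd = 1, seed = 7)
  fit <- fit_flda(d$X, d$y)
  X2 <- d$X
  X2[, 1] <- 100 * X2[, 1] - 7   # rescale + shift one feature
  fit2 <- fit_flda(X2, d$y)
  expect_identical(predict(fit2, X2), predict(fit, d$X))
})

test_that("classifier metrics implement the stated definitions", {
  # perfect separation
  d <- make_classes(5, 5, 10, 0, sd = 0.1, seed = 8, p = 1)
  fit <- fit_flda(d$X, d$y)
  m <- evaluate_classifier(fit, d$X, d$y)
  expect_equal(unlist(m), c(accuracy = 1, sensitivity = 1, specificity = 1))

  # constant score predicts everything 'recurrence' (score >= cutoff with
  # coefficients 0 depends on intercept); check via a hand-built model
  const <- index_model("miR-a", 0, intercept = 1, cutoff = 0)
  y <- rep(c("recurrence", "nonrecurrence"), c(13, 9))
  X <- matrix(rnorm(22), 22, 1, dimnames = list(NULL, "miR-a"))
  m2 <- evaluate_classifier(const, X, y)
  expect_equal(m2$accuracy, 13 / 22)  # majority-class fraction
  expect_error(evaluate_classifier(const, X, rep("recurrence", 22)),
               "both classes")
})

test_that("AUC equals the exhaustive pair-counting oracle", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c("nonrecurrence", "nonrecurrence",
                                        "recurrence", "recurrence")), 1)
  expect_equal(roc_auc(rep(3, 6), rep(c("recurrence", "nonrecurrence"), 3)),
               0.5)
  set.seed(9)
  scores <- sample(round(rnorm(30), 1))  # rounding forces some ties
  y <- sample(rep(c("recurrence", "nonrecurrence"), c(14, 16)))
  expect_equal(roc_auc(scores, y), oracle_auc(scores, y))
  # invariance under strictly increasing transforms
  expect_equal(roc_auc(exp(scores), y), roc_auc(scores, y))
  expect_equal(roc_auc(rank(scores, ties.method = "average"), y),
               roc_auc(scores, y))
  skip_if_not_installed("pROC")
  pr <- pROC::auc(pROC::roc(response = y, predictor = scores,
                            levels = c("nonrecurrence", "recurrence"),
                            direction = "<", quiet = TRUE))
  expect_equal(roc_auc(scores, y), as.numeric(pr))
})

test_that("exhaustive search enumerates, ranks deterministically and is order-invariant", {
  d <- make_classes(15, 15, c(2, 0, 0, 0, 0, 0), rep(0, 6), sd = 1, seed = 10)
  sr <- exhaustive_search(d$X, d$y, colnames(d$X), max_size = 6)
  expect_equal(nrow(sr$results), 63L)   # 2^6 - 1 subsets
  # only the first feature is informative: best size-1 subset is miR-a
  expect_identical(sr$best_per_size$members[sr$best_per_size$size == 1],
                   "miR-a")
  # ranking invariant to candidate order
  sr2 <- exhaustive_search(d$X, d$y, rev(colnames(d$X)), max_size = 6)
  expect_identical(sr$results, sr2$results)
  # training accuracy of the best subset is non-decreasing in max_size
  best_acc <- vapply(1:4, function(k)
    exhaustive_search(d$X, d$y, colnames(d$X)[1:4],
                      max_size = k)$results$accuracy[1], 0)
  expect_true(all(diff(best_acc) >= 0))
  expect_error(exhaustive_search(d$X, d$y,
                                 paste0("c", 1:21), max_size = 2), "20")
})

test_that("stored index formulas apply with the >= cut-off rule", {
  idx <- published_indices()
  zero1 <- stats::setNames(rep(0, 3), idx$index1$members)
  expect_identical(apply_index(idx$index1, zero1)$score, 1.09)
  zero2 <- stats::setNames(rep(0, 3), idx$index2$members)
  expect_identical(apply_index(idx$index2, zero2)$score, 3.14)
  # score exactly at the cut-off predicts recurrence
  at_cut <- index_model("m", 1, intercept = 0, cutoff = 0.5)
  expect_identical(apply_index(at_cut, c(m = 0.5))$predicted, "recurrence")
  expect_identical(apply_index(at_cut, c(m = 0.4999))$predicted,
                   "nonrecurrence")
  # missing member values are an error, never imputed
  expect_error(apply_index(idx$index1, c("hsa-miR-1260b" = 1)), "missing")
})

test_that("covariate dichotomization finds the Youden-optimal cut-off", {
  y <- rep(c("recurrence", "nonrecurrence"), c(6, 6))
  v <- c(rep(1, 6), rep(0, 6))
  r <- dichotomize_covariate(v, y)
  expect_equal(r$metrics$sensitivity + r$metrics$specificity - 1, 1)

  # fixed clinical threshold (37 U/mL): groups split as <=37 / >37
  ca <- c(50, 40, 36, 20, 38, 10, 5, 70)
  yy <- rep(c("recurrence", "nonrecurrence"), each = 4)
  rf <- dichotomize_covariate(ca, yy, method = "fixed", threshold = 37)
  expect_equal(rf$metrics$sensitivity, 2 / 4)  # relapsers 50, 40 are > 37
  expect_equal(rf$metrics$specificity, 2 / 4)  # non-relapsers 10, 5 are <= 37

  # Youden cut-off equals a brute-force scan over all midpoints
  set.seed(12)
  v2 <- round(rlnorm(40, 2, 1), 1)
  y2 <- sample(rep(c("recurrence", "nonrecurrence"), 20))
  r2 <- dichotomize_covariate(v2, y2)
  sv <- sort(unique(v2))
  cuts <- c(sv[1] - 1, (sv[-1] + sv[-length(sv)]) / 2, sv[length(sv)] + 1)
  youden <- vapply(cuts, function(ct) {
    pred <- ifelse(v2 >= ct, "recurrence", "nonrecurrence")
    mean(pred[y2 == "recurrence"] == "recurrence") +
      mean(pred[y2 == "nonrecurrence"] == "nonrecurrence") - 1
  }, 0)
  expect_equal(max(youden),
               r2$metrics$sensitivity + r2$metrics$specificity - 1)
  expect_equal(r2$cutoff, cuts[which.max(youden)])

  expect_true(dichotomize_covariate(rep(2, 8), yy)$degenerate)
})

test_that("singular covariances fall back to ridge or fail loudly", {
  set.seed(13)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("m1", "m2")))
  X[, 2] <- X[, 1]  # perfectly collinear
  y <- rep(c("recurrence", "nonrecurrence"), 10)
  expect_error(fit_flda(X, y, ridge = FALSE), "m1")
  fit <- fit_flda(X, y, ridge = TRUE)
  expect_true(all(is.finite(fit$coefficients)))
})
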