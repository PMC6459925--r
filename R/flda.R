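new_flda <- function(members, coefficients, intercept, cutoff,
                     metrics = NULL, details = NULL) {
  structure(list(members = as.character(members),
                 coefficients = coefficients, intercept = intercept,
                 cutoff = cutoff, metrics = metrics, details = details),
            class = "flda")
}

#' Fit a Fisher linear discriminant recurrence index
#'
#' The recurrence-predictive index is an affine score
#' \eqn{s(x) = \sum_i c_i x_i + b} along the Fisher direction
#' \eqn{w = S_w^{-1}(\mu_{rec} - \mu_{non})}, where \eqn{S_w} is the
#' pooled within-class covariance. The direction is scaled to unit
#' Euclidean norm and oriented so relapsers score higher; the intercept
#' anchors the projected grand mean at \code{reference_score}; the
#' decision cut-off \eqn{\tau} is the midpoint of the projected class
#' means. A patient is predicted to relapse iff \eqn{s(x) \ge \tau}.
#'
#' When the within-class covariance is numerically singular (condition
#' number above 1e12) a ridge \eqn{\lambda I} with
#' \eqn{\lambda = 10^{-6} \cdot tr(S_w)/p} is added; without
#' \code{ridge = TRUE} such fits abort naming the offending members.
#'
#' @param X numeric matrix or data.frame, patients x member miRNAs
#'   (column names = member names), expression on the normalized (by
#'   default log2) scale.
#' @param y group labels: factor/character with values
#'   \code{"recurrence"} / \code{"nonrecurrence"}, or logical
#'   (TRUE = recurrence).
#' @param reference_score score assigned to the projected grand mean.
#' @param ridge allow ridge regularization of a singular within-class
#'   covariance (default TRUE).
#' @return an object of class \code{"flda"}: members, coefficients,
#'   intercept, cutoff, and training metrics (accuracy, sensitivity,
#'   specificity, auc).
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(30, 1), 10), matrix(rnorm(36, 0), 12))
#' colnames(X) <- c("miR-a", "miR-b", "miR-c")
#' y <- rep(c("recurrence", "nonrecurrence"), c(10, 12))
#' fit <- fit_flda(X, y)
#' fit
#' predict(fit, X)
#' @export
fit_flda <- function(X, y, reference_score = 0, ridge = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X needs member miRNA column names")
  y <- as_group(y)
  if (any(table(y) < 2)) stop("need >= 2 patients in each class")
  rec <- y == "recurrence"
  mu1 <- colMeans(X[rec, , drop = FALSE])
  mu0 <- colMeans(X[!rec, , drop = FALSE])
  c1 <- stats::cov(X[rec, , drop = FALSE]) * (sum(rec) - 1)
  c0 <- stats::cov(X[!rec, , drop = FALSE]) * (sum(!rec) - 1)
  Sw <- (c1 + c0) / (nrow(X) - 2)
  p <- ncol(X)
  kappa_ok <- tryCatch(kappa(Sw, exact = TRUE) <= 1e12 && all(diag(Sw) > 0),
                       error = function(e) FALSE)
  if (!kappa_ok) {
    if (!ridge)
      stop("singular within-class covariance for members: ",
           paste(colnames(X), collapse = ", "))
    Sw <- Sw + diag(1e-6 * sum(diag(Sw)) / p, p)
  }
  w <- drop(solve(Sw, mu1 - mu0))
  if (sum(w * (mu1 - mu0)) < 0) w <- -w  # relapsers score higher
  w <- w / sqrt(sum(w^2))
  grand <- colMeans(X)
  b <- reference_score - sum(w * grand)
  tau <- sum(w * (mu1 + mu0) / 2) + b
  model <- new_flda(colnames(X), stats::setNames(w, colnames(X)), b, tau,
                    details = list(mu_rec = mu1, mu_non = mu0,
                                   reference_score = reference_score))
  model$metrics <- c(evaluate_classifier(model, X, y),
                     list(auc = roc_auc(index_scores(model, X), y)))
  model
}

as_group <- function(y) {
  if (is.logical(y)) y <- ifelse(y, "recurrence", "nonrecurrence")
  y <- as.character(y)
  bad <- setdiff(unique(y), c("recurrence", "nonrecurrence"))
  if (length(bad)) stop("unknown group label: ", paste(bad, collapse = ", "))
  y
}

index_scores <- function(model, X) {
  X <- as.matrix(X)
  miss <- setdiff(model$members, colnames(X))
  if (length(miss))
    stop("missing member expression values: ", paste(miss, collapse = ", "))
  Xm <- X[, model$members, drop = FALSE]
  if (anyNA(Xm)) stop("missing member values are not imputed")
  drop(Xm %*% model$coefficients) + model$intercept
}

#' Apply a recurrence-predictive index to expression values
#'
#' Computes \eqn{s(x) = \sum_i c_i x_i + b} and the predicted group;
#' scores at or above the cut-off predict recurrence (\code{>=}
#' convention). Missing member values are an error, never imputed.
#'
#' @param model an \code{\link{flda}} model.
#' @param x named numeric vector (one patient) or a patients x miRNAs
#'   matrix/data.frame containing all member columns.
#' @return list with \code{score} and \code{predicted}
#'   (\code{"recurrence"}/\code{"nonrecurrence"}), vectorized over rows.
#' @examples
#' idx <- published_indices()$index1
#' apply_index(idx, c("hsa-miR-1225-3p" = 0, "hsa-miR-1260b" = 0,
#'                    "hsa-miR-6875-5p" = 0))$score  # the intercept
#' @export
apply_index <- function(model, x) {
  if (is.null(dim(x))) x <- t(as.matrix(x))
  s <- index_scores(model, x)
  list(score = s,
       predicted = ifelse(s >= model$cutoff, "recurrence", "nonrecurrence"))
}

#' @export
predict.flda <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  res <- apply_index(object, newdata)
  if (type == "score") res$score else res$predicted
}

#' @export
coef.flda <- function(object, ...) {
  c(object$coefficients, intercept = object$intercept)
}

#' @export
print.flda <- function(x, digits = 3, ...) {
  co <- x$coefficients
  terms <- paste0(ifelse(co < 0, "- ", "+ "),
                  format(abs(co), digits = digits), " x ", x$members)
  terms[1] <- sub("^\\+ ", "", terms[1])
  cat("Recurrence-predictive index (Fisher linear discriminant)\n")
  cat("  score =", paste(terms, collapse = " "),
      sprintf("%s %s\n", ifelse(x$intercept < 0, "-", "+"),
              format(abs(x$intercept), digits = digits)))
  cat("  cut-off:", format(x$cutoff, digits = digits),
      "(score >= cut-off predicts recurrence)\n")
  if (!is.null(x$metrics))
    cat(sprintf("  training: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%, AUC %.3f\n",
                100 * x$metrics$accuracy, 100 * x$metrics$sensitivity,
                100 * x$metrics$specificity, x$metrics$auc))
  invisible(x)
}

#' @export
summary.flda <- function(object, ...) {
  print(object)
  if (!is.null(object$details)) {
    cat("  class means (projected): recurrence ",
        format(sum(object$coefficients * object$details$mu_rec) +
                 object$intercept, digits = 4),
        ", nonrecurrence ",
        format(sum(object$coefficients * object$details$mu_non) +
                 object$intercept, digits = 4), "\n", sep = "")
  }
  invisible(object)
}

#' Classification metrics of an index on labelled data
#'
#' Sensitivity is the fraction of recurrence patients with score at or
#' above the cut-off, specificity the fraction of nonrecurrence patients
#' below it, accuracy the overall correct fraction.
#'
#' @param model an \code{\link{flda}} model.
#' @param X patients x miRNAs expression (member columns present).
#' @param y group labels (see \code{\link{fit_flda}}).
#' @return list with \code{accuracy}, \code{sensitivity},
#'   \code{specificity}.
#' @export
evaluate_classifier <- function(model, X, y) {
  y <- as_group(y)
  if (length(unique(y)) < 2)
    stop("both classes must be present to evaluate the classifier")
  pred <- apply_index(model, X)$predicted
  rec <- y == "recurrence"
  list(accuracy = mean(pred == y),
       sensitivity = mean(pred[rec] == "recurrence"),
       specificity = mean(pred[!rec] == "nonrecurrence"))
}

#' Area under the ROC curve by rank statistics
#'
#' AUC equals the Mann-Whitney U statistic normalized by
#' \eqn{n_1 n_0}: the probability that a random relapser scores above a
#' random non-relapser, ties counting one half.
#'
#' @param scores numeric scores (higher = more recurrence-like).
#' @param y group labels.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, y) {
  y <- as_group(y)
  n1 <- sum(y == "recurrence"); n0 <- sum(y == "nonrecurrence")
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == "recurrence"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Exhaustive discriminant search over candidate-miRNA subsets
#'
#' Fits and evaluates a Fisher discriminant for every nonempty subset of
#' the candidates up to \code{max_size} members, ranking by training
#' accuracy with ties broken by higher AUC, then fewer members, then
#' lexicographic member names — so the ranking is deterministic and
#' invariant to candidate input order.
#'
#' @param X patients x miRNAs expression matrix.
#' @param y group labels.
#' @param candidates candidate miRNA names (columns of \code{X});
#'   at most 20 (combinatorial guard).
#' @param max_size largest subset size to consider.
#' @return an object of class \code{"flda_search"}: \code{results} (a
#'   data.frame with members, size, accuracy, sensitivity, specificity,
#'   auc, in ranked order), \code{models} (fitted \code{flda} objects,
#'   same order), and \code{best_per_size}.
#' @examples
#' sim <- simulate_cohort(simulation_config(seed = 1))
#' # (see run_pipeline() for the full route from raw signals to search)
#' @export
exhaustive_search <- function(X, y, candidates, max_size = length(candidates)) {
  candidates <- sort(as.character(candidates))
  if (length(candidates) > 20)
    stop("refusing exhaustive search over ", length(candidates),
         " candidates (limit 20)")
  if (max_size > length(candidates))
    stop("max_size exceeds the number of candidates")
  miss <- setdiff(candidates, colnames(X))
  if (length(miss))
    stop("candidates absent from expression matrix: ",
         paste(miss, collapse = ", "))
  subsets <- unlist(lapply(seq_len(max_size), function(k)
    utils::combn(candidates, k, simplify = FALSE)), recursive = FALSE)
  models <- lapply(subsets, function(m)
    fit_flda(X[, m, drop = FALSE], y))
  res <- data.frame(
    members = vapply(subsets, paste, "", collapse = ","),
    size = lengths(subsets),
    accuracy = vapply(models, function(m) m$metrics$accuracy, 0),
    sensitivity = vapply(models, function(m) m$metrics$sensitivity, 0),
    specificity = vapply(models, function(m) m$metrics$specificity, 0),
    auc = vapply(models, function(m) m$metrics$auc, 0),
    stringsAsFactors = FALSE
  )
  ord <- order(-res$accuracy, -res$auc, res$size, res$members)
  res <- res[ord, ]; rownames(res) <- NULL
  models <- models[ord]
  best <- res[!duplicated(res$size), ]
  best <- best[order(best$size), ]; rownames(best) <- NULL
  structure(list(results = res, models = models, best_per_size = best),
            class = "flda_search")
}

#' @export
print.flda_search <- function(x, n = 5, ...) {
  cat("Exhaustive discriminant search:", nrow(x$results),
      "subsets evaluated\n")
  cat("Best combination per panel size:\n")
  print(x$best_per_size, digits = 3)
  invisible(x)
}

#' Dichotomize a clinical covariate as a recurrence classifier
#'
#' Either picks the cut-off maximizing the Youden index
#' (sensitivity + specificity - 1; ties resolved toward the lower
#' cut-off, scanning midpoints between adjacent distinct values) or uses
#' a fixed clinical threshold (e.g. 37 U/mL for CA19-9, 5 ng/mL for
#' CEA). Values at or above the cut-off predict recurrence.
#'
#' @param values numeric covariate (e.g. serum CEA).
#' @param y group labels.
#' @param method \code{"youden"} or \code{"fixed"}.
#' @param threshold the fixed threshold when \code{method = "fixed"}.
#' @return list with \code{cutoff}, \code{metrics} (accuracy,
#'   sensitivity, specificity), \code{auc}, and \code{degenerate}
#'   (TRUE for a constant covariate).
#' @export
dichotomize_covariate <- function(values, y, method = c("youden", "fixed"),
                                  threshold = NULL) {
  method <- match.arg(method)
  y <- as_group(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (length(unique(values)) == 1 && method == "youden")
    return(list(cutoff = values[1], metrics = NULL, auc = 0.5,
                degenerate = TRUE))
  metr <- function(cut) {
    pred <- ifelse(values >= cut, "recurrence", "nonrecurrence")
    rec <- y == "recurrence"
    list(accuracy = mean(pred == y),
         sensitivity = mean(pred[rec] == "recurrence"),
         specificity = mean(pred[!rec] == "nonrecurrence"))
  }
  if (method == "fixed") {
    if (is.null(threshold)) stop("method='fixed' needs a threshold")
    cut <- threshold
  } else {
    v <- sort(unique(values))
    cuts <- c(v[1] - 1, (v[-1] + v[-length(v)]) / 2, v[length(v)] + 1)
    youden <- vapply(cuts, function(ct) {
      m <- metr(ct); m$sensitivity + m$specificity - 1
    }, 0)
    cut <- cuts[which.max(youden)]  # which.max takes the first (lowest) tie
  }
  m <- metr(cut)
  list(cutoff = cut, metrics = m, auc = roc_auc(values, y),
       degenerate = FALSE)
}

#' Construct a recurrence-predictive index from explicit coefficients
#'
#' Builds an \code{\link{flda}}-class index directly from its formula —
#' member miRNAs, coefficients, intercept and decision cut-off — e.g. to
#' encode a published index or to score new samples with a fixed panel.
#'
#' @param members miRNA names (one per coefficient).
#' @param coefficients numeric coefficients \eqn{c_i}.
#' @param intercept intercept \eqn{b}.
#' @param cutoff decision cut-off \eqn{\tau} (score >= cutoff predicts
#'   recurrence).
#' @param metrics optional list of performance metrics to attach.
#' @return an object of class \code{"flda"}.
#' @examples
#' m <- index_model("hsa-miR-1260b", 0.5, intercept = 1, cutoff = 2)
#' apply_index(m, c("hsa-miR-1260b" = 3))
#' @export
index_model <- function(members, coefficients, intercept, cutoff,
                        metrics = NULL) {
  members <- as.character(members)
  if (length(members) < 1 || length(members) != length(coefficients))
    stop("need one coefficient per member miRNA (>= 1)")
  if (!all(is.finite(c(coefficients, intercept, cutoff))))
    stop("coefficients, intercept and cutoff must be finite")
  new_flda(members, stats::setNames(as.numeric(coefficients), members),
           as.numeric(intercept), as.numeric(cutoff), metrics = metrics)
}

#' The published recurrence-predictive index formulas
#'
#' The two three-miRNA serum indices this pipeline was built around,
#' with their printed coefficients, intercepts and ROC cut-offs:
#' index 1 = 0.238 x miR-1225-3p + 0.320 x miR-1260b
#' - 0.473 x miR-6875-5p + 1.09 (cut-off 0.671); index 2 =
#' 0.321 x miR-1260b - 0.216 x miR-6834-3p - 0.421 x miR-6875-5p + 3.14
#' (cut-off 0.646). Scores at or above the cut-off predict recurrence.
#'
#' @return named list of two \code{\link{flda}} models, \code{index1}
#'   and \code{index2}.
#' @examples
#' apply_index(published_indices()$index2,
#'             c("hsa-miR-1260b" = 0, "hsa-miR-6834-3p" = 0,
#'               "hsa-miR-6875-5p" = 0))
#' @export
published_indices <- function() {
  list(
    index1 = new_flda(
      members = c("hsa-miR-1225-3p", "hsa-miR-1260b", "hsa-miR-6875-5p"),
      coefficients = c("hsa-miR-1225-3p" = 0.238, "hsa-miR-1260b" = 0.320,
                       "hsa-miR-6875-5p" = -0.473),
      intercept = 1.09, cutoff = 0.671,
      metrics = list(accuracy = 0.909, sensitivity = 0.846,
                     specificity = 1.000, auc = 0.897)),
    index2 = new_flda(
      members = c("hsa-miR-1260b", "hsa-miR-6834-3p", "hsa-miR-6875-5p"),
      coefficients = c("hsa-miR-1260b" = 0.321, "hsa-miR-6834-3p" = -0.216,
                       "hsa-miR-6875-5p" = -0.421),
      intercept = 3.14, cutoff = 0.646,
      metrics = list(accuracy = 0.909, sensitivity = 0.846,
                     specificity = 1.000, auc = 0.880))
  )
}
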