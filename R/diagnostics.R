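# Diagnostic-accuracy evaluation of consensus rules against gold labels.
# Abnormal is the positive class throughout; prevalence always comes from
# the gold labels. Rates are reported in percent (as screening studies
# print them); AUROCs are on the 0-1 scale.

.as_label_map <- function(x, what) {
  if (is.null(names(x)) || any(names(x) == "")) {
    stop(sprintf("%s must be a named vector (names = item ids)", what),
         call. = FALSE)
  }
  x
}

#' Confusion-matrix summary of binary predictions
#'
#' Counts and rates with abnormal as the positive class. When the gold set
#' lacks one class the corresponding rate (sensitivity or specificity) is
#' `NA`, not zero.
#'
#' @param pred named character vector of predicted labels (names = item
#'   ids).
#' @param gold named character vector of gold labels over the same items.
#' @return an object of class `confusion_summary`: `n`, `tp`, `fp`, `tn`,
#'   `fn`, `percent_correct`, `sensitivity`, `specificity` (rates in
#'   percent).
#' @export
confusion <- function(pred, gold) {
  pred <- .as_label_map(pred, "pred"); gold <- .as_label_map(gold, "gold")
  if (!setequal(names(pred), names(gold))) {
    stop("pred and gold must cover the same items", call. = FALSE)
  }
  p <- .check_labels(pred[names(gold)], "prediction")
  g <- .check_labels(gold, "gold")
  tp <- sum(p == "abnormal" & g == "abnormal")
  fp <- sum(p == "abnormal" & g == "normal")
  tn <- sum(p == "normal" & g == "normal")
  fn <- sum(p == "normal" & g == "abnormal")
  n <- length(g)
  structure(list(
    n = n, tp = tp, fp = fp, tn = tn, fn = fn,
    percent_correct = 100 * (tp + tn) / n,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  ), class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("n = %d: tp %d, fp %d, tn %d, fn %d\n", x$n, x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  correct %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              x$percent_correct, x$sensitivity, x$specificity))
  invisible(x)
}

.roc_pROC <- function(scores, gold) {
  g <- .check_labels(.as_label_map(gold, "gold"), "gold")
  s <- scores[names(g)]
  if (any(is.na(s))) stop("scores missing for some gold items", call. = FALSE)
  if (length(unique(g)) < 2) {
    stop("both classes must be present in gold", call. = FALSE)
  }
  pROC::roc(response = g, predictor = as.numeric(s),
            levels = c("normal", "abnormal"), direction = "<", quiet = TRUE)
}

#' Empirical ROC curve and AUROC with DeLong confidence interval
#'
#' The empirical ROC over all distinct score thresholds, with higher scores
#' indicating abnormal. The AUROC equals the Mann-Whitney concordance
#' probability (ties counted one half); the 95% CI uses DeLong's
#' paired-placement variance estimator.
#'
#' @param scores named numeric vector (names = item ids); higher = more
#'   abnormal.
#' @param gold named character gold labels; both classes must be present.
#' @param conf_level confidence level for the interval. Default 0.95.
#' @return an object of class `roc_result`: data frame `points` (columns
#'   `cutoff`, `fpr`, `sensitivity`, i.e. the (1-specificity, sensitivity)
#'   pairs), `auroc`, `ci_low`, `ci_high`, `method = "empirical"`.
#' @export
auroc <- function(scores, gold, conf_level = 0.95) {
  r <- .roc_pROC(scores, gold)
  # pROC warns that a degenerate CI at AUC = 1 can mislead; the interval is
  # still the DeLong interval, so pass it through quietly
  ci <- as.numeric(suppressWarnings(
    pROC::ci.auc(r, conf.level = conf_level, method = "delong")))
  pts <- data.frame(cutoff = r$thresholds,
                    fpr = 1 - r$specificities,
                    sensitivity = r$sensitivities)
  pts <- pts[order(pts$fpr, pts$sensitivity), ]
  rownames(pts) <- NULL
  structure(list(points = pts, auroc = as.numeric(pROC::auc(r)),
                 ci_low = ci[1], ci_high = ci[3],
                 conf_level = conf_level, method = "empirical",
                 n = length(gold)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("Empirical ROC, n = %d: AUROC %.3f (%d%% CI %.3f-%.3f)\n",
              x$n, x$auroc, round(100 * x$conf_level), x$ci_low, x$ci_high))
  invisible(x)
}

#' Paired DeLong comparison of two correlated AUROCs
#'
#' Both score sets are evaluated on the same items against the same gold
#' labels; the DeLong test accounts for the induced correlation. The
#' statistic is reported as a 1-df chi-square (the squared standardized
#' AUROC difference); the test is symmetric in its arguments.
#'
#' @param scores_a,scores_b named numeric score vectors over the same items.
#' @param gold named character gold labels; both classes present.
#' @return a list of class `auroc_comparison`: `auroc_a`, `auroc_b`,
#'   `chi_square`, `p_value`, `applicable`. Degenerate variance (e.g. both
#'   score sets identical) yields `applicable = FALSE` with `chi_square = 0`,
#'   `p_value = 1` when the curves coincide.
#' @export
compare_auroc <- function(scores_a, scores_b, gold) {
  ra <- .roc_pROC(scores_a, gold)
  rb <- .roc_pROC(scores_b, gold)
  same_auc <- isTRUE(all.equal(as.numeric(pROC::auc(ra)), as.numeric(pROC::auc(rb))))
  tst <- tryCatch(
    pROC::roc.test(ra, rb, method = "delong", paired = TRUE),
    error = function(e) NULL)
  if (is.null(tst) || !is.finite(tst$statistic)) {
    # zero variance of the AUROC difference: identical curves compare equal,
    # anything else is not testable
    return(structure(list(auroc_a = as.numeric(pROC::auc(ra)),
                          auroc_b = as.numeric(pROC::auc(rb)),
                          chi_square = if (same_auc) 0 else NA_real_,
                          p_value = if (same_auc) 1 else NA_real_,
                          applicable = FALSE),
                     class = "auroc_comparison"))
  }
  z <- as.numeric(tst$statistic)
  structure(list(auroc_a = as.numeric(pROC::auc(ra)),
                 auroc_b = as.numeric(pROC::auc(rb)),
                 chi_square = z^2,
                 p_value = stats::pchisq(z^2, df = 1, lower.tail = FALSE),
                 applicable = TRUE),
            class = "auroc_comparison")
}

#' @export
print.auroc_comparison <- function(x, ...) {
  cat(sprintf("Paired DeLong test: AUROC %.3f vs %.3f\n", x$auroc_a, x$auroc_b))
  if (x$applicable) {
    cat(sprintf("  chi-square(1) = %.3f, p = %.3g\n", x$chi_square, x$p_value))
  } else {
    cat("  test not applicable (degenerate variance)\n")
  }
  invisible(x)
}

#' Logistic calibration of a consensus score
#'
#' Univariate maximum-likelihood logistic regression of the gold label on
#' the continuous consensus score. Because the fitted probability is a
#' monotone transform of the score (for positive slope), the ROC of the
#' calibrated probabilities is identical to the ROC of the raw scores; the
#' calibration's role is to express the score as a disease probability and
#' to support cut-point selection on a probability scale. Complete
#' separation is flagged; the raw-score ROC remains valid in that case.
#'
#' @param scores named numeric score vector.
#' @param gold named character gold labels; both classes present.
#' @return a list of class `logistic_calibration`: `intercept`, `slope`,
#'   named vector `probabilities`, logical `separated`, and the underlying
#'   `glm` fit.
#' @export
fit_logistic_calibration <- function(scores, gold) {
  g <- .check_labels(.as_label_map(gold, "gold"), "gold")
  s <- as.numeric(scores[names(g)])
  if (any(is.na(s))) stop("scores missing for some gold items", call. = FALSE)
  if (length(unique(g)) < 2) stop("both classes must be present", call. = FALSE)
  y <- as.integer(g == "abnormal")
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ s, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  # a huge |slope| with separation means the MLE is at infinity
  if (abs(stats::coef(fit)[2]) > 1e3) separated <- TRUE
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 probabilities = stats::setNames(stats::fitted(fit), names(g)),
                 separated = separated,
                 glm_fit = fit),
            class = "logistic_calibration")
}

#' @export
print.logistic_calibration <- function(x, ...) {
  cat(sprintf("Logistic calibration: logit(p) = %.3f + %.3f * score%s\n",
              x$intercept, x$slope,
              if (x$separated) "  [complete separation flagged]" else ""))
  invisible(x)
}

#' Select a diagnostic cut-point on a continuous score
#'
#' Evaluates every candidate cut-off (midpoints between adjacent distinct
#' scores, plus -Inf and +Inf; the rule labels abnormal when
#' `score >= cutoff`) and picks one by criterion:
#' \describe{
#'   \item{`max_correct`}{maximize percent correctly classified; ties go to
#'     higher sensitivity, then to the lower cutoff.}
#'   \item{`min_sensitivity`}{among cut-offs with sensitivity >= `target`,
#'     maximize specificity (ties: higher sensitivity, then lower cutoff).}
#'   \item{`min_specificity`}{among cut-offs with specificity >= `target`,
#'     maximize sensitivity (ties: higher specificity, then higher cutoff).}
#' }
#'
#' @param scores named numeric score vector.
#' @param gold named character gold labels; both classes present.
#' @param criterion one of `"max_correct"`, `"min_sensitivity"`,
#'   `"min_specificity"`.
#' @param target required percent (0-100) for the constrained criteria.
#' @return an object of class `cutpoint_report`: `criterion`, `target`,
#'   `chosen_cutoff`, `summary` (a `confusion_summary` at the cut-off), and
#'   `auroc_at_cutpoint` (the AUROC of the dichotomized classifier,
#'   `(sensitivity + specificity)/2`, on the 0-1 scale).
#' @export
select_cutpoint <- function(scores, gold,
                            criterion = c("max_correct", "min_sensitivity",
                                          "min_specificity"),
                            target = NULL) {
  criterion <- match.arg(criterion)
  g <- .check_labels(.as_label_map(gold, "gold"), "gold")
  s <- as.numeric(scores[names(g)])
  if (any(is.na(s))) stop("scores missing for some gold items", call. = FALSE)
  if (length(unique(g)) < 2) stop("both classes must be present", call. = FALSE)
  if (criterion != "max_correct") {
    if (is.null(target)) stop("target required for constrained criteria", call. = FALSE)
    stopifnot(target >= 0, target <= 100)
  }

  u <- sort(unique(s))
  cutoffs <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  rows <- lapply(cutoffs, function(cut) {
    cs <- confusion(stats::setNames(threshold_label(s, cut), names(g)), g)
    data.frame(cutoff = cut, percent_correct = cs$percent_correct,
               sensitivity = cs$sensitivity, specificity = cs$specificity)
  })
  tab <- do.call(rbind, rows)

  pick <- switch(criterion,
    max_correct = {
      ord <- order(-tab$percent_correct, -tab$sensitivity, tab$cutoff)
      ord[1]
    },
    min_sensitivity = {
      ok <- which(tab$sensitivity >= target)
      if (length(ok) == 0) {
        stop(sprintf("no cutoff achieves sensitivity >= %.1f%% (best achievable: %.1f%%)",
                     target, max(tab$sensitivity)), call. = FALSE)
      }
      ok[order(-tab$specificity[ok], -tab$sensitivity[ok], tab$cutoff[ok])][1]
    },
    min_specificity = {
      ok <- which(tab$specificity >= target)
      if (length(ok) == 0) {
        stop(sprintf("no cutoff achieves specificity >= %.1f%% (best achievable: %.1f%%)",
                     target, max(tab$specificity)), call. = FALSE)
      }
      ok[order(-tab$sensitivity[ok], -tab$specificity[ok], -tab$cutoff[ok])][1]
    })

  cut <- tab$cutoff[pick]
  summ <- confusion(stats::setNames(threshold_label(s, cut), names(g)), g)
  structure(list(criterion = criterion, target = target, chosen_cutoff = cut,
                 summary = summ,
                 auroc_at_cutpoint = (summ$sensitivity + summ$specificity) / 200,
                 candidates = tab),
            class = "cutpoint_report")
}

#' @export
print.cutpoint_report <- function(x, ...) {
  cat(sprintf("Cut-point (%s%s): score >= %.4g -> abnormal\n",
              x$criterion,
              if (!is.null(x$target)) sprintf(", target %.1f%%", x$target) else "",
              x$chosen_cutoff))
  cat(sprintf("  correct %.1f%%, sensitivity %.1f%%, specificity %.1f%%, AUROC %.2f\n",
              x$summary$percent_correct, x$summary$sensitivity,
              x$summary$specificity, x$auroc_at_cutpoint))
  invisible(x)
}

#' Write an evaluation report and ROC points as CSV
#'
#' @param roc a `roc_result`.
#' @param metrics_path CSV of `metric,value,ci_low,ci_high`.
#' @param points_path optional CSV of `cutoff,sensitivity,specificity`
#'   (rates in percent).
#' @param extra optional named list of additional scalar metrics.
#' @export
write_evaluation_csv <- function(roc, metrics_path, points_path = NULL,
                                 extra = NULL) {
  stopifnot(inherits(roc, "roc_result"))
  df <- data.frame(metric = "auroc", value = roc$auroc,
                   ci_low = roc$ci_low, ci_high = roc$ci_high)
  if (!is.null(extra)) {
    df <- rbind(df, data.frame(metric = names(extra),
                               value = as.numeric(unlist(extra)),
                               ci_low = NA_real_, ci_high = NA_real_))
  }
  utils::write.csv(df, metrics_path, row.names = FALSE, quote = FALSE)
  if (!is.null(points_path)) {
    utils::write.csv(
      data.frame(cutoff = roc$points$cutoff,
                 sensitivity = 100 * roc$points$sensitivity,
                 specificity = 100 * (1 - roc$points$fpr)),
      points_path, row.names = FALSE, quote = FALSE)
  }
  invisible(metrics_path)
}

#' Leave-one-item-out jackknife AUROC for the weighted consensus
#'
#' For each item, the Rasch model is refitted on the correctness matrix with
#' that item's grades removed (warm-started from the full-data fit), the
#' refitted abilities are converted to truncated weights, and the held-out
#' item is scored by the weighted sum of its own votes. The AUROC is then
#' computed over the held-out scores. A replicate that fails to converge is
#' flagged and its item scored with the full-data weights.
#'
#' @param records deduplicated `grade_records` (all items).
#' @param truth `truth_labels` covering the items.
#' @param config a [fit_config()].
#' @param low_centile,high_centile weight truncation centiles.
#' @param min_grades workers with fewer grades than this across all items
#'   are dropped before fitting (default 1 = keep all).
#' @param conf_level CI level for the AUROC.
#' @return a `roc_result` with extra fields `n_replicates` and
#'   `n_nonconverged`.
#' @export
jackknife_auroc <- function(records, truth, config = fit_config(),
                            low_centile = 1, high_centile = 99,
                            min_grades = 1L, conf_level = 0.95) {
  stopifnot(is.data.frame(records), is.data.frame(truth))
  items <- sort(unique(records$item_id))
  if (length(items) < 3) stop("need at least 3 items", call. = FALSE)
  if (min_grades > 1) {
    records <- filter_sparse_workers(records, items, min_grades)
  }
  full_mat <- build_correctness_matrix(records, truth)
  full_fit <- fit_rasch(full_mat, config)
  init <- list(D = full_fit$worker_measures, B = full_fit$item_measures)
  full_weights <- truncate_weights(ability_to_weight(full_fit$worker_measures),
                                   low_centile, high_centile)
  gold <- stats::setNames(truth$gold, truth$item_id)[items]

  n_failed <- 0L
  scores <- vapply(items, function(it) {
    sub <- records[records$item_id != it, , drop = FALSE]
    # workers who only graded the held-out item drop out of the refit and
    # are imputed at the neutral weight when scoring
    mat <- build_correctness_matrix(sub, truth)
    fit <- fit_rasch(mat, config, init = init)
    wts <- if (fit$converged) {
      truncate_weights(ability_to_weight(fit$worker_measures),
                       low_centile, high_centile)
    } else {
      n_failed <<- n_failed + 1L
      full_weights
    }
    held <- records[records$item_id == it, , drop = FALSE]
    weighted_score(stats::setNames(held$classification, held$worker_id),
                   wts, impute_missing = TRUE)
  }, numeric(1))

  out <- auroc(stats::setNames(scores, items), gold, conf_level)
  out$n_replicates <- length(items)
  out$n_nonconverged <- n_failed
  out
}
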