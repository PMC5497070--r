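test_that("confusion counts and rates follow the definitions", {
  gold <- named_gold(c(1, 1, 0, 0))
  perfect <- gold
  cs <- confusion(perfect, gold)
  expect_equal(cs$percent_correct, 100)
  expect_equal(cs$sensitivity, 100)
  expect_equal(cs$specificity, 100)
  expect_equal(cs$tp + cs$fp + cs$tn + cs$fn, cs$n)

  # degenerate all-abnormal classifier
  allab <- setNames(rep("abnormal", 4), names(gold))
  cs2 <- confusion(allab, gold)
  expect_equal(cs2$sensitivity, 100)
  expect_equal(cs2$specificity, 0)

  # hand-built integer fixture: tp 453, fn 48, tn 453, fp 146
  g <- named_gold(rep(c(1, 0), c(501, 599)))
  p <- g
  p[1:48] <- "normal"                    # 48 false negatives
  p[501 + 1:146] <- "abnormal"           # 146 false positives
  cs3 <- confusion(p, g)
  expect_equal(c(cs3$tp, cs3$fn, cs3$tn, cs3$fp), c(453, 48, 453, 146))
  expect_equal(cs3$sensitivity, 100 * 453 / 501, tolerance = 1e-10)
  expect_equal(cs3$sensitivity, 90.4, tolerance = 0.01)
  expect_equal(cs3$specificity, 75.6, tolerance = 0.01)

  # a single-class gold set leaves the undefined rate NA, not zero
  g1 <- setNames(rep("abnormal", 3), c("a", "b", "c"))
  cs4 <- confusion(setNames(rep("normal", 3), c("a", "b", "c")), g1)
  expect_true(is.na(cs4$specificity))
  expect_equal(cs4$sensitivity, 0)

  expect_error(confusion(setNames("normal", "x"), setNames("normal", "y")),
               "same items")
})

test_that("empirical AUROC equals the concordant-pair count", {
  g <- named_gold(c(1, 1, 0, 0, 1, 0))
  s <- named_scores(c(3, 2, 2, 1, 5, 0.5))
  r <- auroc(s, g)
  expect_equal(r$auroc, oracle_auroc_pairs(unname(s), unname(g) == "abnormal"))

  # perfect ranking
  gp <- named_gold(c(1, 1, 0, 0))
  expect_equal(auroc(named_scores(c(4, 3, 2, 1)), gp)$auroc, 1.0)
  # all-tied scores
  expect_equal(auroc(named_scores(rep(2, 4)), gp)$auroc, 0.5)

  # randomized fixtures with heavy ties
  set.seed(12)
  for (i in 1:10) {
    n <- sample(5:50, 1)
    g01 <- c(1, 0, rbinom(n - 2, 1, 0.5))
    sc <- sample(0:8, n, replace = TRUE) / 2
    r <- auroc(named_scores(sc), named_gold(g01))
    expect_equal(r$auroc, oracle_auroc_pairs(sc, g01), tolerance = 1e-12)
    expect_true(r$ci_low <= r$auroc && r$auroc <= r$ci_high)
    # ROC points monotone nondecreasing in both coordinates
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$sensitivity) >= -1e-12))
  }
  expect_error(auroc(named_scores(1:3), setNames(rep("normal", 3), names(named_scores(1:3)))),
               "both classes")
})

test_that("paired DeLong comparison is symmetric and null on identical scores", {
  set.seed(3)
  g <- named_gold(rbinom(80, 1, 0.5))
  a <- named_scores(rnorm(80) + 2 * (unname(g) == "abnormal"))
  b <- named_scores(rnorm(80))

  self <- compare_auroc(a, a, g)
  expect_equal(self$chi_square, 0)
  expect_equal(self$p_value, 1)

  ab <- compare_auroc(a, b, g)
  ba <- compare_auroc(b, a, g)
  expect_equal(ab$chi_square, ba$chi_square, tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)

  # near-perfect vs random at n = 200: decisive rejection
  set.seed(41)
  g2_01 <- rbinom(200, 1, 0.5)
  good <- named_scores(g2_01 + rnorm(200, 0, 0.1))
  junk <- named_scores(rnorm(200))
  cmp <- compare_auroc(good, junk, named_gold(g2_01))
  expect_lt(cmp$p_value, 0.001)
  expect_true(cmp$applicable)
})

test_that("logistic calibration recovers slope and leaves the ROC unchanged", {
  set.seed(7)
  n <- 800
  s <- rnorm(n)
  # gold independent of scores: slope ~ 0, intercept ~ logit(prevalence)
  g01 <- rbinom(n, 1, 0.35)
  cal <- fit_logistic_calibration(named_scores(s), named_gold(g01))
  expect_equal(cal$slope, 0, tolerance = 0.15)
  expect_equal(cal$intercept, qlogis(mean(g01)), tolerance = 0.2)

  # scores equal to the true log-odds: slope ~ 1
  set.seed(8)
  lo <- rnorm(n, 0, 1.5)
  g2 <- rbinom(n, 1, plogis(lo))
  cal2 <- fit_logistic_calibration(named_scores(lo), named_gold(g2))
  expect_equal(cal2$slope, 1, tolerance = 0.15)
  expect_false(cal2$separated)

  # monotone invariance: AUROC of probabilities == AUROC of scores
  a1 <- auroc(named_scores(lo), named_gold(g2))$auroc
  a2 <- auroc(cal2$probabilities, named_gold(g2))$auroc
  expect_equal(a1, a2, tolerance = 1e-12)

  # complete separation is flagged but does not crash
  gs <- named_gold(c(1, 1, 1, 0, 0, 0))
  cal3 <- fit_logistic_calibration(named_scores(c(5, 6, 7, 1, 2, 3)), gs)
  expect_true(cal3$separated)
})

test_that("cut-point selection matches the exhaustive sweep on fixtures", {
  set.seed(23)
  for (i in 1:8) {
    n <- sample(8:30, 1)
    g01 <- c(1, 0, rbinom(n - 2, 1, 0.45))
    sc <- round(rnorm(n), 1)
    sweep <- oracle_cutpoint_sweep(sc, g01)
    scores <- named_scores(sc); gold <- named_gold(g01)

    best <- select_cutpoint(scores, gold, "max_correct")
    expect_equal(best$summary$percent_correct, max(sweep$pc))

    target <- 80
    if (any(sweep$se >= target)) {
      rep_se <- select_cutpoint(scores, gold, "min_sensitivity", target)
      expect_gte(rep_se$summary$sensitivity, target)
      expect_equal(rep_se$summary$specificity,
                   max(sweep$sp[sweep$se >= target]))
    } else {
      expect_error(select_cutpoint(scores, gold, "min_sensitivity", target),
                   "best achievable")
    }
    if (any(sweep$sp >= target)) {
      rep_sp <- select_cutpoint(scores, gold, "min_specificity", target)
      expect_gte(rep_sp$summary$specificity, target)
      expect_equal(rep_sp$summary$sensitivity,
                   max(sweep$se[sweep$sp >= target]))
    }
  }
})

test_that("cut-point selection handles separable and vacuous cases", {
  g <- named_gold(c(1, 1, 1, 0, 0))
  s <- named_scores(c(4, 5, 6, 1, 2))
  for (crit in c("max_correct", "min_sensitivity", "min_specificity")) {
    rep <- select_cutpoint(s, g, crit, target = if (crit == "max_correct") NULL else 90)
    expect_equal(rep$summary$percent_correct, 100)
    expect_equal(rep$auroc_at_cutpoint, 1.0)
  }
  # vacuous sensitivity constraint degenerates to the specificity-maximizing
  # extreme cutoff
  rep0 <- select_cutpoint(s, g, "min_sensitivity", target = 0)
  expect_equal(rep0$summary$specificity, 100)

  # never worse than the trivial all-normal / all-abnormal rules
  set.seed(9)
  for (i in 1:5) {
    g01 <- rbinom(12, 1, 0.5); g01[1] <- 1; g01[2] <- 0
    sc <- rnorm(12)
    rep <- select_cutpoint(named_scores(sc), named_gold(g01), "max_correct")
    triv <- 100 * max(mean(g01), 1 - mean(g01))
    expect_gte(rep$summary$percent_correct, triv)
  }
})

test_that("dichotomized-rule AUROC equals (sensitivity + specificity)/2", {
  set.seed(31)
  g01 <- c(1, 0, rbinom(20, 1, 0.5))
  sc <- rnorm(22)
  rep <- select_cutpoint(named_scores(sc), named_gold(g01), "max_correct")
  pred01 <- as.integer(sc >= rep$chosen_cutoff)
  expect_equal(rep$auroc_at_cutpoint, oracle_auroc_pairs(pred01, g01),
               tolerance = 1e-12)
})

test_that("jackknife equals the naive AUROC when weights cannot depend on the data", {
  # identical workers: every refit centers all abilities to zero, so all
  # weights are exactly 1 and the held-out score is the plain vote margin
  votes <- c("abnormal", "normal", "abnormal", "normal")
  r <- rec(rep(c("w1", "w2", "w3"), each = 4), rep(sprintf("i%d", 1:4), 3),
           rep(votes, 3))
  truth <- truth_labels(sprintf("i%d", 1:4),
                        gold = c("abnormal", "normal", "normal", "abnormal"))
  jk <- jackknife_auroc(r, truth)
  tab <- consensus_table(r)
  naive <- auroc(setNames(tab$weighted_score, tab$item_id),
                 setNames(truth$gold, truth$item_id))
  expect_equal(jk$auroc, naive$auroc)
  expect_equal(jk$n_replicates, 4)
})

test_that("evaluation CSV writer emits metrics and ROC points", {
  g <- named_gold(c(1, 1, 0, 0, 1, 0))
  s <- named_scores(c(3, 2, 2, 1, 5, 0.5))
  r <- auroc(s, g)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_evaluation_csv(r, p1, p2, extra = list(percent_correct = 83.3))
  m <- read.csv(p1)
  expect_equal(m$value[m$metric == "auroc"], r$auroc)
  pts <- read.csv(p2)
  expect_true(all(pts$sensitivity >= 0 & pts$sensitivity <= 100))
})
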