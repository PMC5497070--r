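test_that("rasch_probability follows the logistic in B - D", {
  expect_equal(rasch_probability(0.7, 0.7), 0.5)
  expect_equal(rasch_probability(1.3, 1.3), 0.5)
  # closed-form evaluations at the extremes of a realistic ability range
  expect_equal(rasch_probability(0, -3.75), exp(3.75) / (1 + exp(3.75)),
               tolerance = 1e-12)
  expect_equal(rasch_probability(0, -3.75), 0.977, tolerance = 1e-3)
  expect_equal(rasch_probability(-4.74, 0), 0.0087, tolerance = 1e-2)
  # monotone in both arguments, saturating smoothly
  expect_true(rasch_probability(2, 0) > rasch_probability(1, 0))
  expect_true(rasch_probability(0, -1) > rasch_probability(0, 0))
  expect_equal(rasch_probability(800, 0), 1)
  expect_equal(rasch_probability(-800, 0), 0)
})

test_that("JMLE matches the grid-search likelihood maximizer on a complete matrix", {
  X <- make_interior_matrix(4, 6, seed = 21)
  fit <- fit_rasch(matrix_to_cm(X), fit_config(tol = 1e-4))
  expect_true(fit$converged)
  oracle <- oracle_rasch_grid(X)
  expect_lt(max(abs(unname(fit$worker_measures) - oracle$D)), 0.01)
  expect_lt(max(abs(unname(fit$item_measures) - oracle$B)), 0.01)
})

test_that("exchangeable workers get equal measures", {
  # three workers with identical response vectors
  v <- c(1, 0, 1, 1, 0)
  X <- rbind(w1 = v, w2 = v, w3 = v)
  colnames(X) <- sprintf("i%d", 1:5)
  fit <- fit_rasch(matrix_to_cm(X))
  expect_equal(unname(diff(range(fit$worker_measures))), 0, tolerance = 1e-8)
  expect_equal(unname(fit$worker_measures[1]), 0, tolerance = 1e-8)
})

test_that("marginal score is sufficient: same items, same count, same measure", {
  X <- make_interior_matrix(5, 8, seed = 33)
  # force workers 1 and 2 to share the correct count (2 each) on all items
  X[1, ] <- c(1, 1, 0, 0, 0, 0, 0, 1)
  X[2, ] <- c(0, 0, 1, 1, 0, 0, 1, 0)
  cm <- matrix_to_cm(X)
  fit <- fit_rasch(cm, fit_config(tol = 1e-5))
  expect_true(fit$converged)
  expect_equal(unname(fit$worker_measures[1]), unname(fit$worker_measures[2]),
               tolerance = 1e-4)
})

test_that("centering constraint holds in every mode", {
  X <- make_interior_matrix(7, 9, seed = 5)
  cm <- matrix_to_cm(X)
  f1 <- fit_rasch(cm, fit_config(centering = "worker_mean_zero"))
  expect_equal(mean(f1$worker_measures), 0, tolerance = f1$config$tol)
  f2 <- fit_rasch(cm, fit_config(centering = "worker_median_zero"))
  expect_equal(median(f2$worker_measures), 0, tolerance = f2$config$tol)
  f3 <- fit_rasch(cm, fit_config(centering = "item_mean_zero"))
  expect_equal(mean(f3$item_measures), 0, tolerance = f3$config$tol)
  # the modes differ only by a common shift: probabilities agree
  expect_equal(f1$worker_measures + mean(f2$worker_measures - f1$worker_measures),
               f2$worker_measures, tolerance = 1e-3)
})

test_that("the JMLE estimating equation holds at the solution", {
  X <- make_interior_matrix(6, 10, seed = 8)
  cm <- matrix_to_cm(X)
  fit <- fit_rasch(cm, fit_config(tol = 1e-4))
  expect_true(fit$converged)
  P <- rasch_probability(outer(rep(1, 6), fit$item_measures),
                         outer(fit$worker_measures, rep(1, 10)))
  expect_lt(max(abs(rowSums(P) - rowSums(X))), 1e-3)
  expect_lt(max(abs(colSums(P) - colSums(X))), 1e-3)
  expect_lt(fit$max_residual, 1e-4)
})

test_that("an added correct response never makes a worker look less skilled", {
  for (seed in c(3, 14, 27)) {
    X <- make_interior_matrix(5, 7, seed = seed)
    X_miss <- X
    X_miss[2, 4] <- NA     # complete matrix minus one cell
    X_corr <- X
    X_corr[2, 4] <- 1      # ... and with a correct response there
    f0 <- fit_rasch(matrix_to_cm(X_miss), fit_config(tol = 1e-5))
    f1 <- fit_rasch(matrix_to_cm(X_corr), fit_config(tol = 1e-5))
    expect_lte(unname(f1$worker_measures[2]),
               unname(f0$worker_measures[2]) + 1e-4)
  }
})

test_that("extreme marginal scores are adjusted, flagged and finite", {
  X <- make_interior_matrix(5, 6, seed = 77)
  X[1, ] <- 1   # perfect worker
  X[, 2] <- 0   # impossible item (worker 1 too, so rescreening cascades)
  X[1, 2] <- 1
  fit <- fit_rasch(matrix_to_cm(X))
  expect_true(all(is.finite(fit$worker_measures)))
  expect_true(all(is.finite(fit$item_measures)))
  expect_true(fit$worker_extreme[["w01"]])
  expect_true(fit$item_extreme[["i02"]])
  # a perfect worker must come out as the most skilled (lowest measure)
  expect_equal(which.min(fit$worker_measures), c(w01 = 1L))
  expect_true(all(fit$worker_se > 0), all(fit$item_se > 0))
})

test_that("warm-started refits reach the same solution", {
  X <- make_interior_matrix(6, 8, seed = 55)
  cm <- matrix_to_cm(X)
  f0 <- fit_rasch(cm, fit_config(tol = 1e-5))
  f1 <- fit_rasch(cm, fit_config(tol = 1e-5),
                  init = list(D = f0$worker_measures + 0.3,
                              B = f0$item_measures - 0.1))
  expect_equal(f0$worker_measures, f1$worker_measures, tolerance = 1e-3)
})

test_that("non-convergence within max_iter is reported, not hidden", {
  X <- make_interior_matrix(6, 8, seed = 9)
  fit <- fit_rasch(matrix_to_cm(X), fit_config(tol = 1e-9, max_iter = 1))
  expect_false(fit$converged)
  expect_true(is.finite(fit$max_residual))
})

test_that("worker measure quartiles summarize the fitted distribution", {
  fake <- structure(list(worker_measures = c(a = -1, b = 0, c = 1)),
                    class = "rasch_fit")
  q <- worker_measure_quartiles(fake)
  expect_equal(unname(q["median"]), 0)
  fake2 <- structure(list(worker_measures = rep(0.4, 5)), class = "rasch_fit")
  expect_equal(unname(worker_measure_quartiles(fake2)),
               rep(0.4, 3))
  # symmetric simulated abilities: near-zero median after mean centering
  cfg <- sim_config(n_items = 300, n_workers = 150, grades_per_item = 20, seed = 61)
  b <- simulate_crowd(cfg)
  fit <- fit_rasch(build_correctness_matrix(b$records, b$truth))
  expect_lt(abs(worker_measure_quartiles(fit)["median"]), 0.1)
})

test_that("items rank from hardest (lowest measure) to easiest", {
  fake <- structure(list(item_measures = c(easy = 4.9, mid = 0.0, hard = -4.7)),
                    class = "rasch_fit")
  rk <- rank_items_by_difficulty(fake)
  expect_equal(rk$item_id, c("hard", "mid", "easy"))
  expect_equal(rk$measure_logits, c(-4.7, 0, 4.9))
  # ties break by item id
  fake2 <- structure(list(item_measures = c(b = 1, a = 1, c = 1)),
                     class = "rasch_fit")
  expect_equal(rank_items_by_difficulty(fake2)$item_id, c("a", "b", "c"))
})

test_that("fit results CSV has one row per entity", {
  X <- make_interior_matrix(4, 5, seed = 2)
  fit <- fit_rasch(matrix_to_cm(X))
  p <- withr::local_tempfile(fileext = ".csv")
  write_rasch_csv(fit, p)
  df <- read.csv(p)
  expect_equal(nrow(df), 9)
  expect_setequal(unique(df$entity_type), c("worker", "item"))
  expect_true(all(df$se_logits > 0))
})

test_that("preconditions are enforced", {
  X <- make_interior_matrix(4, 5, seed = 2)
  cm <- matrix_to_cm(X)
  cm$workers <- cm$workers[1]
  cm$cells <- cm$cells[cm$cells$worker == 1, ]
  expect_error(fit_rasch(cm), "at least 2")
  expect_error(fit_config(tol = 0), "tol")
  expect_error(fit_config(extreme_score_adjust = 0.6), "extreme_score_adjust")
})
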