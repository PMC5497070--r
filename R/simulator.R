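# Synthetic crowdsourced grading datasets with the statistical structure the
# weighting method assumes: a population of workers with heterogeneous
# ability, items with heterogeneous difficulty, Rasch-distributed
# correctness, and sparse many-workers-per-item assignment.

#' Simulation configuration
#'
#' Defaults mirror the geometry of a 1200-image crowdsourced screening
#' batch: 1200 items, a pool of 300 workers, 10 grades per item, and 42%
#' prevalence of abnormal items. Ability and difficulty spreads default to
#' 1.0 and 1.5 logits.
#'
#' @param n_items number of items.
#' @param n_workers size of the worker pool.
#' @param grades_per_item grades collected per item (must not exceed
#'   `n_workers`; no worker grades an item twice).
#' @param prevalence probability an item's gold label is abnormal, in (0,1).
#' @param ability_sd SD of worker measures `D ~ Normal(0, ability_sd^2)`,
#'   logits.
#' @param difficulty_sd SD of item measures
#'   `B ~ Normal(mean_easiness, difficulty_sd^2)`, logits.
#' @param mean_easiness mean item measure, logits. At the default 0 the
#'   average worker grades the average item correctly with probability
#'   exactly 0.5; positive values emulate a crowd that is better than chance
#'   overall (e.g. 0.6 logits gives ~65% marginal correctness, the regime
#'   typical of real screening crowds).
#' @param assignment `"uniform_random"` (each item graded by a uniform
#'   random subset of workers) or `"heavy_tail"` (worker participation drawn
#'   from a Zipf-like distribution, mimicking marketplaces where a few
#'   workers do most tasks and many do one).
#' @param seed integer seed; mandatory for reproducibility.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_items = 1200L, n_workers = 300L,
                       grades_per_item = 10L, prevalence = 0.42,
                       ability_sd = 1.0, difficulty_sd = 1.5,
                       mean_easiness = 0,
                       assignment = c("uniform_random", "heavy_tail"),
                       seed) {
  assignment <- match.arg(assignment)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (grades_per_item > n_workers) {
    stop("grades_per_item must not exceed n_workers (no worker grades an item twice)",
         call. = FALSE)
  }
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must lie in (0,1)",
                                               call. = FALSE)
  if (ability_sd < 0 || difficulty_sd < 0) stop("SDs must be >= 0", call. = FALSE)
  structure(list(n_items = as.integer(n_items), n_workers = as.integer(n_workers),
                 grades_per_item = as.integer(grades_per_item),
                 prevalence = prevalence, ability_sd = ability_sd,
                 difficulty_sd = difficulty_sd, mean_easiness = mean_easiness,
                 assignment = assignment,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation config from a YAML file
#'
#' @param path YAML file with fields matching [sim_config()] arguments;
#'   `seed` is required.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sim_config, vals)
}

# Ordinal source grades consistent with the gold label, drawn with the
# Messidor composition's conditional frequencies (546:153 within normal,
# 247:254 within abnormal).
.sample_source_grade <- function(gold) {
  g <- integer(length(gold))
  nrm <- gold == "normal"
  g[nrm] <- sample(0:1, sum(nrm), replace = TRUE, prob = c(546, 153))
  g[!nrm] <- sample(2:3, sum(!nrm), replace = TRUE, prob = c(247, 254))
  g
}

#' Simulate a crowdsourced grading dataset
#'
#' Gold labels are Bernoulli(`prevalence`); worker measures `D` and item
#' measures `B` are independent normals. For every (worker, item)
#' assignment, the response is correct with probability
#' [rasch_probability()]`(B_n, D_i)`: a correct response reproduces the gold
#' label, an incorrect one flips it (the error model is symmetric across
#' classes by construction). Fully reproducible for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_truth_bundle`: `records` (a
#'   `grade_records` data frame, one row per grade, with per-worker
#'   `order_index`), `truth` (a `truth_labels` data frame with synthetic
#'   source grades), `true_D` and `true_B` (named numeric vectors), and the
#'   `config`.
#' @export
simulate_crowd <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ni <- config$n_items; nw <- config$n_workers; gpi <- config$grades_per_item
  item_ids <- sprintf("I%04d", seq_len(ni))
  worker_ids <- sprintf("W%03d", seq_len(nw))

  gold <- ifelse(stats::runif(ni) < config$prevalence, "abnormal", "normal")
  D <- stats::setNames(stats::rnorm(nw, 0, config$ability_sd), worker_ids)
  B <- stats::setNames(stats::rnorm(ni, config$mean_easiness, config$difficulty_sd),
                       item_ids)

  part_w <- if (config$assignment == "heavy_tail") {
    # Zipf-like participation: a few workers take most tasks, many take one
    p <- 1 / seq_len(nw)
    sample(p / sum(p))
  } else {
    rep(1 / nw, nw)
  }

  wk <- unlist(lapply(seq_len(ni), function(i) {
    sample.int(nw, gpi, prob = part_w)
  }), use.names = FALSE)
  it <- rep(seq_len(ni), each = gpi)

  p_correct <- stats::plogis(B[it] - D[wk])
  correct <- stats::runif(length(wk)) < p_correct
  vote <- ifelse(correct, gold[it],
                 ifelse(gold[it] == "abnormal", "normal", "abnormal"))

  ord <- stats::ave(seq_along(wk), wk, FUN = seq_along) - 1L
  records <- grade_records(worker_ids[wk], item_ids[it], vote,
                           batch = "sim", order_index = ord)
  truth <- truth_labels(item_ids, source_grade = .sample_source_grade(gold),
                        gold = gold)
  structure(list(records = records, truth = truth,
                 true_D = D, true_B = B, config = config),
            class = "sim_truth_bundle")
}

#' @export
print.sim_truth_bundle <- function(x, ...) {
  cat(sprintf("Simulated crowd: %d grades of %d items by %d workers (%.0f%% abnormal)\n",
              nrow(x$records), x$config$n_items,
              length(unique(x$records$worker_id)),
              100 * mean(x$truth$gold == "abnormal")))
  invisible(x)
}

# One simulate -> split -> fit -> weight -> score -> AUROC pass. Returns the
# test-set scores for the weighted rule, the unweighted vote margin, and the
# oracle (true-ability) weighted rule, plus the gold labels.
.benchmark_once <- function(config, split_fraction = 0.5, min_grades = 10L,
                            config_fit = fit_config(),
                            low_centile = 1, high_centile = 99) {
  bundle <- simulate_crowd(config)
  split <- split_items(bundle$truth$item_id, split_fraction,
                       seed = config$seed + 1L)
  train_rec <- bundle$records[bundle$records$item_id %in% split$train_items, ]
  test_rec <- bundle$records[bundle$records$item_id %in% split$test_items, ]
  train_rec <- filter_sparse_workers(train_rec, split$train_items, min_grades)

  fit <- fit_rasch(build_correctness_matrix(train_rec, bundle$truth), config_fit)
  wts <- truncate_weights(ability_to_weight(fit$worker_measures),
                          low_centile, high_centile)
  oracle_wts <- truncate_weights(ability_to_weight(bundle$true_D),
                                 low_centile, high_centile)

  tab_w <- consensus_table(test_rec, wts, impute_missing = TRUE)
  tab_mv <- consensus_table(test_rec)           # margin = unweighted score
  tab_o <- consensus_table(test_rec, oracle_wts, impute_missing = TRUE)
  gold <- stats::setNames(bundle$truth$gold, bundle$truth$item_id)[tab_w$item_id]

  list(gold = gold,
       weighted = stats::setNames(tab_w$weighted_score, tab_w$item_id),
       mv = stats::setNames(tab_mv$weighted_score, tab_mv$item_id),
       oracle = stats::setNames(tab_o$weighted_score, tab_o$item_id),
       converged = fit$converged)
}

#' Benchmark weighted consensus against majority vote on simulated crowds
#'
#' Per replicate: simulate a crowd, split items 50/50 into train and test,
#' fit the Rasch model on the training correctness matrix, convert abilities
#' to truncated weights, score the test items, and compute the AUROC of (a)
#' the weighted score, (b) the unweighted vote margin (the majority-vote
#' score), and (c) the weighted score using the TRUE simulated abilities (an
#' oracle upper reference). Deterministic given `config$seed`; replicate r
#' uses seed `config$seed + 1000*r`.
#'
#' @param config a [sim_config()].
#' @param n_replicates number of independent replicates (>= 1).
#' @param min_grades training-set sparse-worker threshold (default 10).
#' @param ... further arguments to the internal pipeline
#'   (`split_fraction`, `config_fit`, `low_centile`, `high_centile`).
#' @return a data frame with one row per replicate: `replicate`, `mv_auroc`,
#'   `weighted_auroc`, `oracle_weighted_auroc`, `fit_converged`.
#' @export
benchmark_aggregators <- function(config, n_replicates, min_grades = 10L, ...) {
  stopifnot(inherits(config, "sim_config"), n_replicates >= 1)
  rows <- lapply(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- config$seed + 1000L * r
    res <- .benchmark_once(cfg, min_grades = min_grades, ...)
    data.frame(replicate = r,
               mv_auroc = auroc(res$mv, res$gold)$auroc,
               weighted_auroc = auroc(res$weighted, res$gold)$auroc,
               oracle_weighted_auroc = auroc(res$oracle, res$gold)$auroc,
               fit_converged = res$converged)
  })
  do.call(rbind, rows)
}
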