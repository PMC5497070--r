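# Dichotomous Rasch model, joint maximum-likelihood estimation (JMLE) on a
# sparse worker x item correctness matrix.
#
# Sign convention (matching the grading application): the probability that
# worker i grades item n correctly is
#     P_ni = exp(B_n - D_i) / (1 + exp(B_n - D_i)),
# so a higher B_n means an EASIER item and a LOWER D_i a MORE skilled worker
# (the most skilled worker sits at a negative measure). Both measures are in
# logits. The model is identified only up to a common shift of all B and D,
# fixed by a centering constraint.

#' Rasch response probability
#'
#' Probability that a worker of measure `D_i` grades an item of measure
#' `B_n` correctly: `exp(B_n - D_i) / (1 + exp(B_n - D_i))`. Higher `B_n`
#' (easier item) and lower `D_i` (more skilled worker) both increase the
#' probability. Saturates smoothly at extreme arguments.
#'
#' @param B_n item measure(s), logits.
#' @param D_i worker measure(s), logits.
#' @return probability vector (recycled to the common length).
#' @examples
#' rasch_probability(0, 0)        # 0.5
#' rasch_probability(0, -3.75)    # a highly skilled worker, average item
#' @export
rasch_probability <- function(B_n, D_i) {
  stats::plogis(B_n - D_i)
}

#' Estimation controls for the Rasch fit
#'
#' @param tol convergence tolerance, applied both to the largest measure
#'   update (logits) and to the largest expected-minus-observed marginal
#'   score (score points). Default 0.005.
#' @param max_iter maximum number of alternating sweeps. Default 200.
#' @param extreme_score_adjust fractional-score correction, in (0, 0.5),
#'   applied to perfect and zero marginal scores, which otherwise have no
#'   finite maximum-likelihood measure. Default 0.3 score points.
#' @param centering identifiability constraint: `"worker_mean_zero"`
#'   (default), `"worker_median_zero"`, or `"item_mean_zero"`. The choice
#'   shifts all measures by a constant; it cancels in weight ratios but not
#'   in raw weights, so record it with any saved fit.
#' @return a list of class `fit_config`.
#' @export
fit_config <- function(tol = 0.005, max_iter = 200L,
                       extreme_score_adjust = 0.3,
                       centering = c("worker_mean_zero", "worker_median_zero",
                                     "item_mean_zero")) {
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)
  if (extreme_score_adjust <= 0 || extreme_score_adjust >= 0.5) {
    stop("extreme_score_adjust must lie in (0, 0.5)", call. = FALSE)
  }
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 extreme_score_adjust = extreme_score_adjust,
                 centering = match.arg(centering)),
            class = "fit_config")
}

# Solve sum_j plogis(B_j - theta) = target for a single worker measure
# theta (the expected score is decreasing in theta).
.solve_worker_measure <- function(B_partner, target, tol) {
  theta <- 0
  for (it in 1:100) {
    P <- stats::plogis(B_partner - theta)
    f <- sum(P) - target
    if (abs(f) < tol / 10) break
    I <- max(sum(P * (1 - P)), 1e-12)
    theta <- theta + min(max(f / I, -2), 2)
  }
  list(theta = theta,
       resid = abs(sum(stats::plogis(B_partner - theta)) - target))
}

# Solve sum_i plogis(theta - D_i) = target for a single item measure theta
# (the expected score is increasing in theta).
.solve_item_measure <- function(D_partner, target, tol) {
  theta <- 0
  for (it in 1:100) {
    P <- stats::plogis(theta - D_partner)
    f <- sum(P) - target
    if (abs(f) < tol / 10) break
    I <- max(sum(P * (1 - P)), 1e-12)
    theta <- theta - min(max(f / I, -2), 2)
  }
  list(theta = theta,
       resid = abs(sum(stats::plogis(theta - D_partner)) - target))
}

# Alternating JMLE on the non-extreme core: each sweep solves one facet's
# marginal equations exactly (inner Newton, entities independent given the
# other facet), i.e. coordinate ascent on the concave joint log-likelihood.
.jmle_core <- function(w, n, x, act_w, act_n, config, init, init_ids) {
  wid <- which(act_w); nid <- which(act_n)
  wi <- match(w, wid); nj <- match(n, nid)
  nw <- length(wid); ni <- length(nid)
  m <- tabulate(wi, nw); r <- tabulate(wi[x == 1L], nw)
  k <- tabulate(nj, ni); s <- tabulate(nj[x == 1L], ni)

  D <- log((m - r) / r)
  B <- log(s / (k - s))
  if (!is.null(init)) {
    iD <- init$D[init_ids$w[wid]]; iB <- init$B[init_ids$i[nid]]
    D[!is.na(iD)] <- iD[!is.na(iD)]
    B[!is.na(iB)] <- iB[!is.na(iB)]
  }

  tol <- config$tol
  inner_tol <- tol / 10
  converged <- FALSE
  max_residual <- Inf
  iter <- 0L
  for (iter in seq_len(config$max_iter)) {
    D_old <- D; B_old <- B
    for (inner in 1:25) {
      P <- stats::plogis(B[nj] - D[wi])
      E_w <- as.numeric(rowsum(P, wi, reorder = TRUE))
      if (max(abs(E_w - r)) < inner_tol) break
      I_w <- as.numeric(rowsum(P * (1 - P), wi, reorder = TRUE))
      D <- D + pmin(pmax((E_w - r) / pmax(I_w, 1e-10), -1), 1)
    }
    for (inner in 1:25) {
      P <- stats::plogis(B[nj] - D[wi])
      E_n <- as.numeric(rowsum(P, nj, reorder = TRUE))
      if (max(abs(E_n - s)) < inner_tol) break
      I_n <- as.numeric(rowsum(P * (1 - P), nj, reorder = TRUE))
      B <- B - pmin(pmax((E_n - s) / pmax(I_n, 1e-10), -1), 1)
    }
    shift <- switch(config$centering,
                    worker_mean_zero = mean(D),
                    worker_median_zero = stats::median(D),
                    item_mean_zero = mean(B))
    D <- D - shift; B <- B - shift

    P <- stats::plogis(B[nj] - D[wi])
    max_residual <- max(abs(as.numeric(rowsum(P, wi, reorder = TRUE)) - r),
                        abs(as.numeric(rowsum(P, nj, reorder = TRUE)) - s))
    if (max(abs(D - D_old), abs(B - B_old)) < tol && max_residual < tol) {
      converged <- TRUE
      break
    }
  }
  list(D = D, B = B, iter = iter, converged = converged,
       max_residual = max_residual)
}

#' Fit the dichotomous Rasch model by joint maximum likelihood
#'
#' Alternating per-parameter Newton-Raphson on the marginal-score estimating
#' equations: at the solution every worker's and item's expected marginal
#' score equals its observed marginal. Missing cells contribute nothing to
#' the likelihood (grades are assigned independently of content, so absence
#' is taken as ignorable).
#'
#' Workers and items with perfect or zero marginal scores have no finite
#' maximum-likelihood measure. They are set aside (iteratively, since
#' removing an extreme item can make a worker's remaining score extreme),
#' the non-extreme core is estimated jointly, and each extreme entity's
#' measure is then solved from its own marginal equation -- with the
#' fractional-score adjustment in `config` applied to the extreme marginal --
#' given the fitted measures of its graded partners. Extreme entities are
#' flagged in the result. Should the core be degenerate (fewer than 2
#' non-extreme workers or items), all entities are estimated jointly from
#' adjusted marginals; the reported residual is then honest about the
#' adjustment-induced inconsistency. The fit is deterministic for a fixed
#' matrix and config. JMLE measures carry the well-known finite-length bias
#' when a worker has few grades; no correction is applied.
#'
#' @param matrix a `correctness_matrix` with at least 2 workers and 2 items.
#' @param config a [fit_config()].
#' @param init optional list with numeric vectors `D` and `B` (named by
#'   worker/item id) used as starting values, e.g. to warm-start jackknife
#'   refits.
#' @return an object of class `rasch_fit`: named vectors `worker_measures`
#'   (D, logits), `item_measures` (B, logits), `worker_se`, `item_se`,
#'   counts, extreme-score flags, `n_iterations`, `converged`,
#'   `max_residual`, and `flat_entities` (workers/items whose every observed
#'   cell is shared with a single partner).
#' @export
fit_rasch <- function(matrix, config = fit_config(), init = NULL) {
  stopifnot(inherits(matrix, "correctness_matrix"))
  nw <- length(matrix$workers); ni <- length(matrix$items)
  if (nw < 2 || ni < 2) stop("need at least 2 workers and 2 items", call. = FALSE)
  w <- matrix$cells$worker
  n <- matrix$cells$item
  x <- matrix$cells$correct

  m_w <- tabulate(w, nw)                 # grades per worker
  k_n <- tabulate(n, ni)                 # grades per item
  if (any(m_w == 0) || any(k_n == 0)) {
    stop("every retained worker and item needs at least one observed cell",
         call. = FALSE)
  }
  r_w <- tabulate(w[x == 1L], nw)        # correct per worker
  s_n <- tabulate(n[x == 1L], ni)        # correct per item

  adj <- config$extreme_score_adjust
  tol <- config$tol

  # flat-likelihood diagnostic: an entity observed against a single partner
  # only (its measure rides entirely on that partner's)
  w_partners <- vapply(split(n, w), function(z) length(unique(z)), 1L)
  n_partners <- vapply(split(w, n), function(z) length(unique(z)), 1L)
  flat <- c(matrix$workers[w_partners == 1L & ni > 1],
            matrix$items[n_partners == 1L & nw > 1])

  # --- iterative extreme-score screening -------------------------------
  # Entities whose marginal within the current core is perfect/zero have no
  # finite MLE there; set them aside and re-check, since dropping an extreme
  # item can push a worker's remaining score to an extreme.
  act_w <- rep(TRUE, nw); act_n <- rep(TRUE, ni)
  repeat {
    use <- act_w[w] & act_n[n]
    mw <- tabulate(w[use], nw); rw <- tabulate(w[use & x == 1L], nw)
    kn <- tabulate(n[use], ni); sn <- tabulate(n[use & x == 1L], ni)
    new_w <- act_w & (mw == 0L | rw == 0L | rw == mw)
    new_n <- act_n & (kn == 0L | sn == 0L | sn == kn)
    if (!any(new_w) && !any(new_n)) break
    act_w <- act_w & !new_w
    act_n <- act_n & !new_n
    if (!any(act_w) || !any(act_n)) break
  }
  w_extreme <- !act_w
  n_extreme <- !act_n

  D <- rep(NA_real_, nw); B <- rep(NA_real_, ni)
  converged <- TRUE
  max_residual <- 0
  iter <- 0L

  if (sum(act_w) >= 2 && sum(act_n) >= 2) {
    use <- act_w[w] & act_n[n]
    core <- .jmle_core(w[use], n[use], x[use], act_w, act_n,
                       config, init,
                       init_ids = list(w = matrix$workers, i = matrix$items))
    D[act_w] <- core$D; B[act_n] <- core$B
    converged <- core$converged
    max_residual <- core$max_residual
    iter <- core$iter

    # estimate the set-aside entities from their adjusted marginals, given
    # already-estimated partners; alternate until no entity is left reachable
    repeat {
      progressed <- FALSE
      todo_n <- which(is.na(B))
      for (j in todo_n) {
        sel <- n == j & !is.na(D[w])
        if (!any(sel)) next
        kk <- sum(sel); ss <- sum(x[sel])
        target <- min(max(ss, adj), kk - adj)
        sol <- .solve_item_measure(D[w[sel]], target, tol)
        B[j] <- sol$theta
        max_residual <- max(max_residual, sol$resid)
        converged <- converged && sol$resid < tol
        progressed <- TRUE
      }
      todo_w <- which(is.na(D))
      for (i in todo_w) {
        sel <- w == i & !is.na(B[n])
        if (!any(sel)) next
        mm <- sum(sel); rr <- sum(x[sel])
        target <- min(max(rr, adj), mm - adj)
        sol <- .solve_worker_measure(B[n[sel]], target, tol)
        D[i] <- sol$theta
        max_residual <- max(max_residual, sol$resid)
        converged <- converged && sol$resid < tol
        progressed <- TRUE
      }
      if (!anyNA(c(D, B)) || !progressed) break
    }
    # entities in components with no estimated partner at all: anchor the
    # partner facet at 0 (nothing else identifies them)
    for (j in which(is.na(B))) {
      target <- min(max(s_n[j], adj), k_n[j] - adj)
      B[j] <- .solve_item_measure(rep(0, k_n[j]), target, tol)$theta
    }
    for (i in which(is.na(D))) {
      target <- min(max(r_w[i], adj), m_w[i] - adj)
      D[i] <- .solve_worker_measure(rep(0, m_w[i]), target, tol)$theta
    }
  } else {
    # degenerate core (e.g. every item graded identically by all workers):
    # joint alternation on adjusted marginals; the adjusted worker and item
    # targets need not be mutually consistent, so the residual is reported
    # as-is and convergence may honestly fail
    r_adj <- pmin(pmax(r_w, adj), m_w - adj)
    s_adj <- pmin(pmax(s_n, adj), k_n - adj)
    D <- log((m_w - r_adj) / r_adj)
    B <- log(s_adj / (k_n - s_adj))
    converged <- FALSE
    for (iter in seq_len(config$max_iter)) {
      P <- stats::plogis(B[n] - D[w])
      E_w <- as.numeric(rowsum(P, w, reorder = TRUE))
      I_w <- as.numeric(rowsum(P * (1 - P), w, reorder = TRUE))
      dD <- pmin(pmax((E_w - r_adj) / pmax(I_w, 1e-10), -1), 1)
      D <- D + dD
      P <- stats::plogis(B[n] - D[w])
      E_n <- as.numeric(rowsum(P, n, reorder = TRUE))
      I_n <- as.numeric(rowsum(P * (1 - P), n, reorder = TRUE))
      dB <- pmin(pmax(-(E_n - s_adj) / pmax(I_n, 1e-10), -1), 1)
      B <- B + dB
      P <- stats::plogis(B[n] - D[w])
      max_residual <- max(abs(as.numeric(rowsum(P, w, reorder = TRUE)) - r_adj),
                          abs(as.numeric(rowsum(P, n, reorder = TRUE)) - s_adj))
      if (max(abs(dD), abs(dB)) < tol) {
        converged <- max_residual < tol
        break
      }
    }
  }

  # final identifiability shift over ALL entities (a common shift of both
  # facets leaves every probability, and hence every residual, unchanged)
  shift <- switch(config$centering,
                  worker_mean_zero = mean(D),
                  worker_median_zero = stats::median(D),
                  item_mean_zero = mean(B))
  D <- D - shift
  B <- B - shift

  P <- stats::plogis(B[n] - D[w])
  info_w <- as.numeric(rowsum(P * (1 - P), w, reorder = TRUE))
  info_n <- as.numeric(rowsum(P * (1 - P), n, reorder = TRUE))

  structure(list(
    worker_measures = stats::setNames(D, matrix$workers),
    item_measures = stats::setNames(B, matrix$items),
    worker_se = stats::setNames(1 / sqrt(pmax(info_w, 1e-10)), matrix$workers),
    item_se = stats::setNames(1 / sqrt(pmax(info_n, 1e-10)), matrix$items),
    worker_n = stats::setNames(m_w, matrix$workers),
    item_n = stats::setNames(k_n, matrix$items),
    worker_extreme = stats::setNames(w_extreme, matrix$workers),
    item_extreme = stats::setNames(n_extreme, matrix$items),
    flat_entities = flat,
    n_iterations = iter,
    converged = converged,
    max_residual = max_residual,
    config = config
  ), class = "rasch_fit")
}

#' @export
print.rasch_fit <- function(x, ...) {
  cat(sprintf("Rasch JMLE fit: %d workers, %d items\n",
              length(x$worker_measures), length(x$item_measures)))
  cat(sprintf("  %s after %d iterations (max marginal residual %.2g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations, x$max_residual))
  q <- worker_measure_quartiles(x)
  cat(sprintf("  worker measures: range [%.2f, %.2f], IQR [%.2f, %.2f] logits\n",
              min(x$worker_measures), max(x$worker_measures), q[1], q[3]))
  cat(sprintf("  item measures:   range [%.2f, %.2f] logits\n",
              min(x$item_measures), max(x$item_measures)))
  n_ex <- sum(x$worker_extreme) + sum(x$item_extreme)
  if (n_ex > 0) cat(sprintf("  %d extreme marginal(s) adjusted by %.2g score points\n",
                            n_ex, x$config$extreme_score_adjust))
  invisible(x)
}

#' Quartiles of the fitted worker measures
#'
#' @param fit a converged `rasch_fit`.
#' @return named numeric vector `c(q1, median, q3)` in logits.
#' @export
worker_measure_quartiles <- function(fit) {
  stopifnot(inherits(fit, "rasch_fit"))
  q <- stats::quantile(fit$worker_measures, c(0.25, 0.5, 0.75), names = FALSE)
  stats::setNames(q, c("q1", "median", "q3"))
}

#' Rank items from hardest to easiest
#'
#' Sorts items ascending by fitted measure: the lowest (most negative)
#' measures are the hardest to grade correctly. Ties are broken by item id
#' for determinism.
#'
#' @param fit a converged `rasch_fit`.
#' @return a data frame with columns `item_id` and `measure_logits`, hardest
#'   first.
#' @export
rank_items_by_difficulty <- function(fit) {
  stopifnot(inherits(fit, "rasch_fit"))
  ids <- names(fit$item_measures)
  ord <- order(fit$item_measures, ids)
  data.frame(item_id = ids[ord],
             measure_logits = unname(fit$item_measures[ord]),
             stringsAsFactors = FALSE)
}
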