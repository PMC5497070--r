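# Independent oracles used to check the package's estimators. These are
# deliberately naive (brute force / exhaustive) and share no code with the
# implementation they verify.

# Joint log-likelihood of a complete/dense 0-1 response matrix (workers in
# rows) under P = plogis(B - D).
oracle_loglik <- function(X, D, B) {
  eta <- outer(-D, B, "+")   # eta[i, j] = B_j - D_i
  sum(X * eta - log1p(exp(eta)), na.rm = TRUE)
}

# Brute-force maximizer of the joint Rasch log-likelihood by cyclic
# per-parameter grid search over a coarse-then-refined lattice, followed by
# the same centering used in the fit. X is a dense matrix with NA for
# missing cells.
oracle_rasch_grid <- function(X, centering = "worker_mean_zero",
                              final_step = 5e-4) {
  nw <- nrow(X); ni <- ncol(X)
  D <- rep(0, nw); B <- rep(0, ni)
  step <- 1.6
  offsets <- -4:4
  while (step > final_step) {
    repeat {
      moved <- FALSE
      for (i in seq_len(nw)) {
        cand <- D[i] + offsets * step
        ll <- vapply(cand, function(v) {
          Dt <- D; Dt[i] <- v; oracle_loglik(X, Dt, B)
        }, numeric(1))
        best <- cand[which.max(ll)]
        if (best != D[i]) { D[i] <- best; moved <- TRUE }
      }
      for (j in seq_len(ni)) {
        cand <- B[j] + offsets * step
        ll <- vapply(cand, function(v) {
          Bt <- B; Bt[j] <- v; oracle_loglik(X, D, Bt)
        }, numeric(1))
        best <- cand[which.max(ll)]
        if (best != B[j]) { B[j] <- best; moved <- TRUE }
      }
      if (!moved) break
    }
    step <- step / 4
  }
  shift <- switch(centering,
                  worker_mean_zero = mean(D),
                  worker_median_zero = median(D),
                  item_mean_zero = mean(B))
  list(D = D - shift, B = B - shift)
}

# O(n^2) AUROC: concordant pairs + half ties over all (positive, negative)
# pairs; gold01 is 1 for abnormal.
oracle_auroc_pairs <- function(scores, gold01) {
  pos <- scores[gold01 == 1]; neg <- scores[gold01 == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Exhaustive cut-point sweep: evaluates every midpoint cutoff (plus +-Inf)
# by direct counting, returning the full candidate table.
oracle_cutpoint_sweep <- function(scores, gold01) {
  u <- sort(unique(scores))
  cuts <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  do.call(rbind, lapply(cuts, function(ct) {
    pred <- as.integer(scores >= ct)
    tp <- sum(pred == 1 & gold01 == 1); fp <- sum(pred == 1 & gold01 == 0)
    tn <- sum(pred == 0 & gold01 == 0); fn <- sum(pred == 0 & gold01 == 1)
    data.frame(cutoff = ct,
               pc = 100 * (tp + tn) / length(gold01),
               se = 100 * tp / (tp + fn),
               sp = 100 * tn / (tn + fp))
  }))
}

# Dense 0-1 matrix (no extreme marginals) simulated from known measures;
# resamples until every row and column marginal is interior.
make_interior_matrix <- function(nw, ni, seed) {
  set.seed(seed)
  for (try in 1:500) {
    D <- rnorm(nw, 0, 1); B <- rnorm(ni, 0, 1)
    X <- matrix(rbinom(nw * ni, 1, plogis(outer(-D, B, "+"))), nw, ni)
    rs <- rowSums(X); cs <- colSums(X)
    if (all(rs > 0 & rs < ni) && all(cs > 0 & cs < nw)) {
      dimnames(X) <- list(sprintf("w%02d", 1:nw), sprintf("i%02d", 1:ni))
      return(X)
    }
  }
  stop("could not draw an interior matrix")
}

# correctness_matrix from a dense 0/1 matrix (NA = missing)
matrix_to_cm <- function(X) {
  idx <- which(!is.na(X), arr.ind = TRUE)
  structure(list(workers = rownames(X), items = colnames(X),
                 cells = data.frame(worker = idx[, 1], item = idx[, 2],
                                    correct = X[idx])),
            class = "correctness_matrix")
}
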