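# Turning fitted worker measures into vote weights, and aggregating votes
# into majority-vote and weighted consensus labels.

#' Worker ability measure to vote weight
#'
#' The negative exponentiated worker measure, `exp(-D_i)`: the odds that the
#' worker classifies an item of average difficulty (`B_n = 0`) correctly. An
#' average worker (`D = 0`) has weight 1; skilled workers (negative `D`)
#' weigh more than 1.
#'
#' @param D_i worker measure(s) in logits.
#' @return positive weight(s) on the odds scale.
#' @examples
#' ability_to_weight(0)      # 1
#' ability_to_weight(-3.75)  # a highly skilled worker
#' @export
ability_to_weight <- function(D_i) {
  stopifnot(all(is.finite(D_i)))
  exp(-D_i)
}

#' Truncate vote weights at empirical centiles
#'
#' Winsorizes the odds-scale weights: values below the `low_centile` of the
#' empirical weight distribution are raised to it, values above the
#' `high_centile` lowered to it. Interior weights are untouched, so the
#' ordering of non-clamped workers is preserved. Centiles use the
#' linear-interpolation empirical quantile (R's default, type 7).
#'
#' @param weights named numeric vector of positive weights (worker ids as
#'   names) or the raw output of [ability_to_weight()] on a named measure
#'   vector.
#' @param low_centile,high_centile percent bounds, `0 <= low < high <= 100`.
#'   Defaults 1 and 99.
#' @param source_fit_id optional identifier of the Rasch fit the weights
#'   came from, carried along for provenance.
#' @return an object of class `weight_vector`: a list with named vector
#'   `weights`, `raw_weights`, logical `clamped`, `truncation_bounds`, and
#'   `source_fit_id`.
#' @export
truncate_weights <- function(weights, low_centile = 1, high_centile = 99,
                             source_fit_id = NA_character_) {
  if (length(weights) < 2) stop("need at least 2 workers", call. = FALSE)
  if (is.null(names(weights)) || any(names(weights) == "")) {
    stop("weights must be named by worker id", call. = FALSE)
  }
  if (!(low_centile >= 0 && low_centile < high_centile && high_centile <= 100)) {
    stop("need 0 <= low_centile < high_centile <= 100", call. = FALSE)
  }
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  bounds <- stats::quantile(weights, c(low_centile, high_centile) / 100,
                            names = FALSE, type = 7)
  clamped <- weights < bounds[1] | weights > bounds[2]
  out <- pmin(pmax(weights, bounds[1]), bounds[2])
  structure(list(weights = out, raw_weights = weights, clamped = clamped,
                 truncation_bounds = c(low = bounds[1], high = bounds[2]),
                 source_fit_id = source_fit_id),
            class = "weight_vector")
}

#' Build a weight vector straight from a Rasch fit
#'
#' Convenience wrapper: `exp(-D)` for every fitted worker, then centile
#' truncation.
#'
#' @param fit a `rasch_fit`.
#' @param low_centile,high_centile see [truncate_weights()].
#' @return a `weight_vector`.
#' @export
weights_from_fit <- function(fit, low_centile = 1, high_centile = 99) {
  stopifnot(inherits(fit, "rasch_fit"))
  truncate_weights(ability_to_weight(fit$worker_measures),
                   low_centile, high_centile,
                   source_fit_id = paste0("rasch_fit/", length(fit$worker_measures),
                                          "w_", length(fit$item_measures), "i"))
}

#' @export
as.data.frame.weight_vector <- function(x, ...) {
  data.frame(worker_id = names(x$weights),
             raw_weight = unname(x$raw_weights),
             truncated_weight = unname(x$weights),
             clamped = unname(x$clamped),
             stringsAsFactors = FALSE)
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("Weight vector: %d workers, %d clamped to centile bounds [%.3g, %.3g]\n",
              length(x$weights), sum(x$clamped),
              x$truncation_bounds[1], x$truncation_bounds[2]))
  invisible(x)
}

#' Majority-vote consensus of binary votes
#'
#' Abnormal if half or more of the votes are abnormal, otherwise normal
#' (the tie goes to abnormal — conservative for screening).
#'
#' @param votes character vector of `"normal"`/`"abnormal"` votes.
#' @return `"normal"` or `"abnormal"`.
#' @export
mv_consensus <- function(votes) {
  if (length(votes) == 0) stop("no votes", call. = FALSE)
  votes <- .check_labels(votes, "vote")
  if (sum(votes == "abnormal") >= length(votes) / 2) "abnormal" else "normal"
}

#' Weighted consensus score of one item's votes
#'
#' Recodes each vote as +1 (abnormal) or -1 (normal), multiplies by the
#' voter's weight and sums: `S = sum_i w_i * c_i`. A positive score means
#' the weighted crowd leans abnormal.
#'
#' @param votes named character vector: names are worker ids, values
#'   `"normal"`/`"abnormal"`.
#' @param weights a `weight_vector` (or a named numeric vector of weights).
#' @param impute_missing if `TRUE`, voters absent from `weights` get the
#'   neutral weight 1.0 (an average worker) instead of raising an error; the
#'   number imputed is attached as attribute `n_imputed`.
#' @return the signed weighted score `S`.
#' @export
weighted_score <- function(votes, weights, impute_missing = FALSE) {
  if (length(votes) == 0) stop("no votes", call. = FALSE)
  v <- .check_labels(votes, "vote")
  wtab <- if (inherits(weights, "weight_vector")) weights$weights else weights
  w <- wtab[names(votes)]
  n_imputed <- sum(is.na(w))
  if (n_imputed > 0) {
    if (!impute_missing) {
      stop(sprintf("no weight for voter(s): %s",
                   paste(utils::head(names(votes)[is.na(w)], 5), collapse = ", ")),
           call. = FALSE)
    }
    w[is.na(w)] <- 1.0
  }
  s <- sum(unname(w) * ifelse(v == "abnormal", 1, -1))
  attr(s, "n_imputed") <- n_imputed
  s
}

#' Threshold a weighted score into a binary label
#'
#' @param S weighted consensus score(s).
#' @param cutoff decision cut-off; scores `>= cutoff` are abnormal. Default
#'   0, the natural zero of the signed score.
#' @return `"normal"`/`"abnormal"` labels.
#' @export
threshold_label <- function(S, cutoff = 0) {
  ifelse(S >= cutoff, "abnormal", "normal")
}

#' Per-item consensus table
#'
#' Aggregates a set of grade records item by item: vote counts, the
#' majority-vote label, the weighted score (when weights are given) and its
#' thresholded label.
#'
#' @param records deduplicated `grade_records`.
#' @param weights optional `weight_vector`; when `NULL` all votes get weight
#'   1 and the weighted score reduces to the vote margin.
#' @param cutoff decision cut-off on the weighted score. Default 0.
#' @param impute_missing passed to [weighted_score()].
#' @return a data frame with one row per item: `item_id`, `n_votes`,
#'   `n_abnormal_votes`, `mv_label`, `weighted_score`, `thresholded_label`,
#'   with attribute `n_imputed`.
#' @export
consensus_table <- function(records, weights = NULL, cutoff = 0,
                            impute_missing = FALSE) {
  stopifnot(is.data.frame(records))
  if (anyDuplicated(records[, c("worker_id", "item_id")])) {
    stop("records contain duplicate (worker, item) pairs; run dedupe_grades() first",
         call. = FALSE)
  }
  v <- .check_labels(records$classification)
  sign <- ifelse(v == "abnormal", 1, -1)
  if (is.null(weights)) {
    w <- rep(1, nrow(records))
    n_imputed <- 0L
  } else {
    wtab <- if (inherits(weights, "weight_vector")) weights$weights else weights
    w <- unname(wtab[records$worker_id])
    n_imputed <- sum(is.na(w))
    if (n_imputed > 0 && !impute_missing) {
      stop(sprintf("no weight for %d voting worker(s); set impute_missing = TRUE to assign the neutral weight 1",
                   length(unique(records$worker_id[is.na(w)]))), call. = FALSE)
    }
    w[is.na(w)] <- 1.0
  }
  item <- factor(records$item_id, levels = sort(unique(records$item_id)))
  n_votes <- as.integer(table(item))
  n_abn <- as.integer(rowsum((v == "abnormal") + 0L, item))
  S <- as.numeric(rowsum(w * sign, item))
  out <- data.frame(
    item_id = levels(item),
    n_votes = n_votes,
    n_abnormal_votes = n_abn,
    mv_label = ifelse(n_abn >= n_votes / 2, "abnormal", "normal"),
    weighted_score = S,
    thresholded_label = threshold_label(S, cutoff),
    stringsAsFactors = FALSE
  )
  attr(out, "n_imputed") <- n_imputed
  out
}
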