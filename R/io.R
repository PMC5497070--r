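# Plain-CSV interchange formats. All readers are strict about required
# columns; labels are case-insensitive on the way in and lower-case on the
# way out.

#' Read a grades CSV
#'
#' Expected columns: `worker_id,item_id,classification[,batch,order_index]`
#' with a header row; `classification` in normal/abnormal (case-insensitive).
#'
#' @param path file path.
#' @return a `grade_records` data frame.
#' @export
read_grades_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(worker_id = "character",
                                       item_id = "character"))
  need <- c("worker_id", "item_id", "classification")
  if (!all(need %in% names(df))) {
    stop(sprintf("grades CSV must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  grade_records(df$worker_id, df$item_id, df$classification,
                batch = if ("batch" %in% names(df)) df$batch else NA_character_,
                order_index = if ("order_index" %in% names(df)) df$order_index
                              else NA_integer_)
}

#' Write a grades CSV
#' @param records a `grade_records` data frame.
#' @param path file path.
#' @export
write_grades_csv <- function(records, path) {
  utils::write.csv(
    records[, c("worker_id", "item_id", "classification", "batch", "order_index")],
    path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a truth CSV
#'
#' Expected columns: `item_id,source_grade,gold`; `source_grade` may be blank
#' when `gold` is given directly, and vice versa.
#'
#' @param path file path.
#' @return a `truth_labels` data frame.
#' @export
read_truth_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(item_id = "character"))
  if (!"item_id" %in% names(df)) stop("truth CSV must have an item_id column",
                                      call. = FALSE)
  sg <- if ("source_grade" %in% names(df)) suppressWarnings(as.integer(df$source_grade))
        else rep(NA_integer_, nrow(df))
  gold <- if ("gold" %in% names(df) && !all(is.na(df$gold) | df$gold == ""))
    ifelse(is.na(df$gold) | df$gold == "", dichotomize_safe(sg), tolower(df$gold))
  else NULL
  truth_labels(df$item_id, source_grade = sg, gold = gold)
}

# dichotomize() for possibly-NA vectors used only while merging blank gold
# cells with graded ones in read_truth_csv().
dichotomize_safe <- function(g) {
  out <- rep(NA_character_, length(g))
  ok <- !is.na(g)
  out[ok] <- dichotomize(g[ok])
  out
}

#' Write a truth CSV
#' @param truth a `truth_labels` data frame.
#' @param path file path.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth[, c("item_id", "source_grade", "gold")],
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a train/test split CSV and run manifest
#'
#' The split is written as `item_id,partition` with partition in train/test;
#' the seed (and any extra run parameters) go to a YAML manifest alongside.
#'
#' @param split a `split_assignment`.
#' @param path CSV path.
#' @param manifest optional path of a YAML run manifest; extra fields are
#'   merged in via `...`.
#' @param ... additional named fields recorded in the manifest.
#' @export
write_split_csv <- function(split, path, manifest = NULL, ...) {
  df <- data.frame(
    item_id = c(split$train_items, split$test_items),
    partition = rep(c("train", "test"),
                    c(length(split$train_items), length(split$test_items))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(manifest)) {
    yaml::write_yaml(c(list(seed = split$seed), list(...)), manifest)
  }
  invisible(path)
}

#' Write Rasch fit results as CSV
#'
#' One row per estimated entity:
#' `entity_type,id,measure_logits,se_logits,n_observed,extreme_adjusted`.
#'
#' @param fit a `rasch_fit`.
#' @param path CSV path.
#' @export
write_rasch_csv <- function(fit, path) {
  stopifnot(inherits(fit, "rasch_fit"))
  df <- rbind(
    data.frame(entity_type = "worker", id = names(fit$worker_measures),
               measure_logits = unname(fit$worker_measures),
               se_logits = unname(fit$worker_se),
               n_observed = unname(fit$worker_n),
               extreme_adjusted = unname(fit$worker_extreme)),
    data.frame(entity_type = "item", id = names(fit$item_measures),
               measure_logits = unname(fit$item_measures),
               se_logits = unname(fit$item_se),
               n_observed = unname(fit$item_n),
               extreme_adjusted = unname(fit$item_extreme)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a weight vector as CSV
#'
#' Columns: `worker_id,raw_weight,truncated_weight,clamped`.
#'
#' @param weights a `weight_vector`.
#' @param path CSV path.
#' @export
write_weights_csv <- function(weights, path) {
  stopifnot(inherits(weights, "weight_vector"))
  utils::write.csv(as.data.frame(weights), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-item consensus results as CSV
#'
#' Columns: `item_id,n_votes,n_abnormal_votes,mv_label,weighted_score,`
#' `thresholded_label` (plus `calibrated_probability` when present).
#'
#' @param consensus a data frame from [consensus_table()].
#' @param path CSV path.
#' @export
write_consensus_csv <- function(consensus, path) {
  utils::write.csv(consensus, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
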