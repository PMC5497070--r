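#' @keywords internal
"_PACKAGE"

# Binary labels used at every module boundary. Votes are recoded to +1/-1
# only inside the consensus scoring (see weighted_score()).
.LABELS <- c("normal", "abnormal")

.check_labels <- function(x, what = "classification") {
  x <- stats::setNames(tolower(as.character(x)), names(x))
  bad <- !(x %in% .LABELS)
  if (any(bad)) {
    stop(sprintf("invalid %s value(s): %s (must be 'normal' or 'abnormal')",
                 what, paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  x
}

#' Construct a grade-record table
#'
#' A grade record is one worker's binary classification of one item. Records
#' are stored as a plain data frame with columns `worker_id`, `item_id`,
#' `classification` (`"normal"`/`"abnormal"`), and optional `batch` and
#' `order_index` (submission order within a worker, a stand-in for a
#' timestamp). Duplicate (worker, item) pairs are permitted here and resolved
#' by [dedupe_grades()].
#'
#' @param worker_id character vector of worker identifiers.
#' @param item_id character vector of item identifiers.
#' @param classification binary labels, `"normal"` or `"abnormal"`
#'   (case-insensitive).
#' @param batch optional batch tag (e.g. `"baseline"`, `"color"`,
#'   `"redfree"`).
#' @param order_index optional non-negative integer submission order within
#'   each worker; `NA` allowed.
#' @return a `data.frame` of class `grade_records`.
#' @export
grade_records <- function(worker_id, item_id, classification,
                          batch = NA_character_, order_index = NA_integer_) {
  classification <- .check_labels(classification)
  if (any(!is.na(order_index) & order_index < 0)) {
    stop("order_index must be non-negative", call. = FALSE)
  }
  out <- data.frame(
    worker_id = as.character(worker_id),
    item_id = as.character(item_id),
    classification = classification,
    batch = as.character(batch),
    order_index = as.integer(order_index),
    stringsAsFactors = FALSE
  )
  class(out) <- c("grade_records", "data.frame")
  out
}

#' Construct a truth-label table
#'
#' One row per item: an optional ordinal source grade on the Messidor 0-3
#' retinopathy scale and/or a binary gold label. When a source grade is
#' given, the gold label is derived from it with [dichotomize()]; a gold
#' label supplied alongside a source grade must agree with the
#' dichotomization rule.
#'
#' @param item_id character vector of unique item identifiers.
#' @param source_grade optional integer vector of ordinal grades in 0-3
#'   (`NA` allowed when `gold` is given directly).
#' @param gold optional binary gold labels; derived from `source_grade`
#'   where missing.
#' @return a `data.frame` of class `truth_labels` with columns `item_id`,
#'   `source_grade`, `gold`.
#' @export
truth_labels <- function(item_id, source_grade = NA_integer_, gold = NULL) {
  item_id <- as.character(item_id)
  if (anyDuplicated(item_id)) {
    stop("item_id must be unique in a truth table", call. = FALSE)
  }
  source_grade <- as.integer(rep_len(source_grade, length(item_id)))
  derived <- rep(NA_character_, length(item_id))
  has_grade <- !is.na(source_grade)
  if (any(has_grade)) derived[has_grade] <- dichotomize(source_grade[has_grade])
  if (is.null(gold)) {
    if (any(!has_grade)) {
      stop("gold must be supplied for items without a source_grade",
           call. = FALSE)
    }
    gold <- derived
  } else {
    gold <- .check_labels(rep_len(gold, length(item_id)), "gold")
    disagree <- has_grade & gold != derived
    if (any(disagree)) {
      stop(sprintf("gold label disagrees with dichotomized source_grade for %d item(s)",
                   sum(disagree)), call. = FALSE)
    }
  }
  out <- data.frame(item_id = item_id, source_grade = source_grade,
                    gold = gold, stringsAsFactors = FALSE)
  class(out) <- c("truth_labels", "data.frame")
  out
}

#' Dichotomize an ordinal Messidor-scale grade
#'
#' Collapses the 0-3 ordinal retinopathy scale to a binary screening label:
#' grades 0 and 1 (at most five microaneurysms, no hemorrhages) are
#' `"normal"`, grades 2 and 3 are `"abnormal"`.
#'
#' @param source_grade integer vector with values in 0-3.
#' @return character vector of `"normal"`/`"abnormal"`.
#' @examples
#' dichotomize(0:3)
#' table(dichotomize(rep(0:3, c(546, 153, 247, 254))))
#' @export
dichotomize <- function(source_grade) {
  g <- as.integer(source_grade)
  if (any(is.na(g)) || any(!(g %in% 0:3))) {
    stop("source_grade must be an integer in 0-3", call. = FALSE)
  }
  ifelse(g <= 1L, "normal", "abnormal")
}

#' Remove duplicate grades of the same item by the same worker
#'
#' Keeps, for each (worker, item) pair, the record with the smallest
#' `order_index` (the first submission; later views of the same image are
#' contaminated by prior exposure). Records with missing `order_index` sort
#' after those with one; remaining ties are broken by input order.
#'
#' @param records a `grade_records` data frame.
#' @return the deduplicated `grade_records`, with attribute `n_deleted`
#'   giving the number of records removed.
#' @export
dedupe_grades <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) {
    attr(records, "n_deleted") <- 0L
    return(records)
  }
  oi <- if ("order_index" %in% names(records)) records$order_index else
    rep(NA_integer_, nrow(records))
  oi <- ifelse(is.na(oi), Inf, as.numeric(oi))
  ord <- order(records$worker_id, records$item_id, oi, seq_len(nrow(records)))
  sorted <- records[ord, , drop = FALSE]
  keep <- !duplicated(sorted[, c("worker_id", "item_id")])
  out <- sorted[keep, , drop = FALSE]
  # restore the original relative order of the survivors
  out <- out[order(ord[keep]), , drop = FALSE]
  rownames(out) <- NULL
  n_deleted <- nrow(records) - nrow(out)
  attr(out, "n_deleted") <- n_deleted
  class(out) <- unique(c("grade_records", class(out)))
  out
}

#' Drop grades by workers with too few grades within an item subset
#'
#' Mirrors the stability rule of excluding workers who graded fewer than
#' `min_grades` items within the training set. By default only the
#' sub-threshold worker's records *within* `item_subset` are removed (their
#' grades of other items are retained); `whole_worker = TRUE` removes every
#' record of such workers.
#'
#' @param records a `grade_records` data frame.
#' @param item_subset character vector of item ids defining the counting
#'   window (typically the training items).
#' @param min_grades minimum number of distinct graded items within
#'   `item_subset` a worker must have to be retained (inclusive).
#' @param whole_worker if `TRUE`, remove all records of sub-threshold
#'   workers, not just those within `item_subset`.
#' @return filtered `grade_records`, with attributes `n_deleted` and
#'   `workers_excluded`.
#' @export
filter_sparse_workers <- function(records, item_subset, min_grades = 10L,
                                  whole_worker = FALSE) {
  stopifnot(is.data.frame(records))
  if (length(item_subset) == 0) stop("item_subset must be non-empty", call. = FALSE)
  if (min_grades < 1) stop("min_grades must be >= 1", call. = FALSE)
  item_subset <- as.character(item_subset)
  in_subset <- records$item_id %in% item_subset
  # count DISTINCT graded items, so the rule is insensitive to duplicates
  pairs <- unique(records[in_subset, c("worker_id", "item_id")])
  counts <- table(pairs$worker_id)
  all_workers <- unique(records$worker_id)
  n_in <- as.integer(counts[all_workers])
  n_in[is.na(n_in)] <- 0L
  excluded <- all_workers[n_in < min_grades]
  drop <- if (whole_worker) {
    records$worker_id %in% excluded
  } else {
    records$worker_id %in% excluded & in_subset
  }
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_deleted") <- sum(drop)
  attr(out, "workers_excluded") <- excluded
  class(out) <- unique(c("grade_records", class(out)))
  out
}

#' Build the sparse worker-by-item correctness matrix
#'
#' Scores every deduplicated grade against the gold label: a cell is 1 for a
#' correct classification and 0 for an incorrect one; a (worker, item) pair
#' with no grade is a missing cell. The matrix is stored in triplet form,
#' which is what the Rasch estimator consumes.
#'
#' @param records deduplicated `grade_records`.
#' @param truth a `truth_labels` data frame covering every item in
#'   `records`.
#' @return an object of class `correctness_matrix`: a list with character
#'   vectors `workers` and `items` and a data frame `cells` with columns
#'   `worker` and `item` (integer indices into those vectors) and `correct`
#'   (0/1).
#' @export
build_correctness_matrix <- function(records, truth) {
  stopifnot(is.data.frame(records), is.data.frame(truth))
  if (nrow(records) == 0) stop("no grade records", call. = FALSE)
  if (anyDuplicated(records[, c("worker_id", "item_id")])) {
    stop("records contain duplicate (worker, item) pairs; run dedupe_grades() first",
         call. = FALSE)
  }
  gold <- truth$gold[match(records$item_id, truth$item_id)]
  if (any(is.na(gold))) {
    missing <- unique(records$item_id[is.na(gold)])
    stop(sprintf("no truth label for item(s): %s",
                 paste(utils::head(missing, 5), collapse = ", ")), call. = FALSE)
  }
  workers <- sort(unique(records$worker_id))
  items <- sort(unique(records$item_id))
  cells <- data.frame(
    worker = match(records$worker_id, workers),
    item = match(records$item_id, items),
    correct = as.integer(tolower(records$classification) == gold)
  )
  structure(list(workers = workers, items = items, cells = cells),
            class = "correctness_matrix")
}

#' @export
print.correctness_matrix <- function(x, ...) {
  n <- nrow(x$cells)
  cat(sprintf("Correctness matrix: %d workers x %d items, %d observed cells (%.1f%% dense)\n",
              length(x$workers), length(x$items), n,
              100 * n / (length(x$workers) * length(x$items))))
  cat(sprintf("  proportion correct: %.3f\n", mean(x$cells$correct)))
  invisible(x)
}

#' Dense view of a correctness matrix
#'
#' @param m a `correctness_matrix`.
#' @return a numeric matrix (workers in rows, items in columns) with `NA`
#'   for cells that were never graded.
#' @export
as_dense_matrix <- function(m) {
  stopifnot(inherits(m, "correctness_matrix"))
  out <- matrix(NA_real_, length(m$workers), length(m$items),
                dimnames = list(m$workers, m$items))
  out[cbind(m$cells$worker, m$cells$item)] <- m$cells$correct
  out
}

#' Randomly partition items into training and test sets
#'
#' Reproducible simple-random split, optionally stratified on an ordinal
#' grade so that each stratum's training share stays close to the overall
#' fraction. Stratified allocation uses largest-remainder rounding, keeping
#' every stratum within one item of its proportional share.
#'
#' @param items character vector of item ids (>= 2 distinct).
#' @param fraction training fraction in (0, 1).
#' @param seed integer seed; recorded in the result.
#' @param stratify_by optional vector, parallel to `items`, of stratum
#'   labels (e.g. Messidor grades).
#' @return an object of class `split_assignment`: list with `train_items`,
#'   `test_items`, `seed`.
#' @export
split_items <- function(items, fraction = 0.5, seed, stratify_by = NULL) {
  items <- as.character(items)
  if (length(unique(items)) < 2) stop("need at least 2 items", call. = FALSE)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  items <- unique(items)
  n <- length(items)
  set.seed(as.integer(seed))
  if (is.null(stratify_by)) {
    n_train <- round(fraction * n)
    train <- sample(items, n_train)
  } else {
    if (length(stratify_by) != n) {
      stop("stratify_by must have one value per unique item", call. = FALSE)
    }
    strata <- split(items, stratify_by)
    sizes <- vapply(strata, length, 1L)
    raw <- sizes * fraction
    base <- floor(raw)
    room <- round(fraction * n) - sum(base)
    extra <- rep(0L, length(strata))
    if (room > 0) {
      extra[order(raw - base, decreasing = TRUE)[seq_len(room)]] <- 1L
    }
    train <- unlist(mapply(function(ids, k) sample(ids, k),
                           strata, base + extra, SIMPLIFY = FALSE),
                    use.names = FALSE)
  }
  structure(list(train_items = sort(train),
                 test_items = sort(setdiff(items, train)),
                 seed = as.integer(seed)),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("Item split: %d train / %d test (seed %d)\n",
              length(x$train_items), length(x$test_items), x$seed))
  invisible(x)
}
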