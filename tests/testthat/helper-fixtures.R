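# Small fixture builders shared across test files.

# shorthand grade-record builder
rec <- function(worker, item, label, batch = NA, order = NA) {
  grade_records(worker, item, label, batch = batch, order_index = order)
}

# random grade records with duplicates, for clean-up property tests
random_records <- function(n, n_workers = 6, n_items = 8, seed) {
  set.seed(seed)
  grade_records(
    worker_id = sprintf("w%d", sample(n_workers, n, replace = TRUE)),
    item_id = sprintf("i%d", sample(n_items, n, replace = TRUE)),
    classification = sample(c("normal", "abnormal"), n, replace = TRUE),
    order_index = sample(0:50, n, replace = TRUE)
  )
}

# named score/gold vectors from plain vectors
named_scores <- function(s) setNames(s, sprintf("I%03d", seq_along(s)))
named_gold <- function(g01) {
  setNames(ifelse(g01 == 1, "abnormal", "normal"), sprintf("I%03d", seq_along(g01)))
}
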