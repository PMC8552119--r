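# Independent oracles and small fixtures used across the suite.
# The oracles deliberately avoid the package's own index arithmetic.

random_sequences <- function(n, len_range = c(20L, 80L),
                             alphabet = aa_alphabet()) {
  vapply(seq_len(n), function(i) {
    L <- sample(len_range[1]:len_range[2], 1L)
    paste(sample(alphabet, L, replace = TRUE), collapse = "")
  }, character(1))
}

# Naive double-loop CKSAAP oracle: walks every anchor position, builds the
# pair as a two-character string, and tallies by string name over the
# printed enumeration AA, AC, ..., YY.
oracle_gap_counts <- function(sequence, j) {
  chars <- strsplit(sequence, "")[[1]]
  counts <- stats::setNames(integer(400L), pair_labels())
  L <- length(chars)
  if (L >= j + 2L) {
    pairs <- character(L - j - 1L)
    for (i in seq_len(L - j - 1L)) {
      pairs[i] <- paste0(chars[i], chars[i + j + 1L])
    }
    tab <- table(pairs)
    tab <- tab[names(tab) %in% names(counts)]  # drop non-standard pairs
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

oracle_encode <- function(sequence, k_max, mode = "composition") {
  blocks <- lapply(0:k_max, function(j) {
    counts <- oracle_gap_counts(sequence, j)
    if (mode == "count") return(as.numeric(counts))
    n <- sum(counts)
    if (n == 0) numeric(400L) else counts / n
  })
  unlist(blocks, use.names = FALSE)
}

# Four-way tally oracle for the confusion matrix.
oracle_confusion <- function(labels, predictions) {
  tab <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  for (i in seq_along(labels)) {
    key <- if (labels[i] == "ECM") {
      if (predictions[i] == "ECM") "tp" else "fn"
    } else {
      if (predictions[i] == "ECM") "fp" else "tn"
    }
    tab[key] <- tab[key] + 1L
  }
  tab
}

# Planted-pair dataset shared by the end-to-end tests: strong C-K signal
# at gap 3 in the positives, marginal-matched decoys in the negatives.
planted_spec <- function(seed, gap = 3L, weight = 21) {
  signal_spec(
    planted_pairs = data.frame(a = "C", b = "K", gap = gap, weight = weight,
                               stringsAsFactors = FALSE),
    length_range = c(50L, 300L), seed = seed)
}

# fast model settings for protocol tests on small pools (architecture
# unchanged; larger step size compensates for the few batches per epoch)
fast_model_options <- function(...) {
  utils::modifyList(list(max_epochs = 80L, patience = 15L,
                         learning_rate = 1e-2), list(...))
}
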