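#' CKSAAP encoding configuration
#'
#' The composition of k-spaced amino acid pairs (CKSAAP) encoding tallies,
#' for every gap j = 0..k_max, the 400 ordered residue pairs separated by
#' exactly j intervening residues, and concatenates the per-gap blocks into
#' a vector of length (k_max+1)*400. At j = 0 the block is the classical
#' dipeptide composition.
#'
#' @param k_max Largest gap to encode (j runs 0..k_max). Non-negative.
#' @param mode `"composition"` (each gap block divided by its number of
#'   valid pairs, the default) or `"count"` (raw integer tallies).
#' @param policy An [alphabet_policy()]; pairs touching non-standard
#'   residues are always excluded from the tallies.
#' @return A `cksaap_config` object.
#' @export
cksaap_config <- function(k_max = 8L, mode = c("composition", "count"),
                          policy = alphabet_policy()) {
  k_max <- check_count(k_max, "k_max")
  mode <- match.arg(mode)
  stopifnot(inherits(policy, "alphabet_policy"))
  structure(list(k_max = k_max, mode = mode, policy = policy),
            class = "cksaap_config")
}

#' Count j-spaced residue pairs in one sequence
#'
#' For every position i with i + j + 1 <= L (1-based), the ordered pair
#' (sequence[i], sequence[i + j + 1]) is tallied when both residues are
#' canonical. Pairs touching non-standard residues contribute nothing.
#' Sequences shorter than j + 2 yield the all-zero result.
#'
#' @param sequence Residue string.
#' @param j Gap (number of residues strictly between the pair members).
#' @return List with `counts` (integer vector of length 400 in pair-index
#'   order) and `n_valid` (total number of tallied pairs).
#' @export
count_gap_pairs <- function(sequence, j) {
  j <- check_count(j, "j")
  codes <- residue_codes(sequence)
  L <- length(codes)
  if (L < j + 2L) {
    return(list(counts = integer(400L), n_valid = 0L))
  }
  a <- codes[seq_len(L - j - 1L)]
  b <- codes[seq.int(j + 2L, L)]
  keep <- !is.na(a) & !is.na(b)
  idx <- 20L * (a[keep] - 1L) + b[keep]  # 1-based bin over 400 pairs
  counts <- tabulate(idx, nbins = 400L)
  list(counts = counts, n_valid = sum(counts))
}

#' Feature column labels for a given k_max
#'
#' Gap-major layout: "g0_AA", "g0_AC", ..., "g0_YY", "g1_AA", ...
#'
#' @param k_max Largest encoded gap.
#' @return Character vector of length (k_max+1)*400.
#' @export
cksaap_labels <- function(k_max) {
  k_max <- check_count(k_max, "k_max")
  as.vector(vapply(0:k_max, function(j) paste0("g", j, "_", pair_labels()),
                   character(400L)))
}

#' Encode one sequence as a CKSAAP feature vector
#'
#' Concatenates the gap blocks j = 0..k_max in ascending order. In
#' composition mode each block is divided by its number of valid j-spaced
#' pairs, so a non-degenerate block sums to 1; blocks with no valid pair
#' (sequence shorter than j+2, or all pairs touching non-standard residues)
#' are left all-zero.
#'
#' @param sequence Residue string (non-empty).
#' @param config A [cksaap_config()].
#' @return Named numeric vector of length (k_max+1)*400.
#' @export
#' @examples
#' v <- cksaap_encode("ACDEFGHIK", cksaap_config(k_max = 2))
#' length(v) # 1200
cksaap_encode <- function(sequence, config = cksaap_config()) {
  stopifnot(inherits(config, "cksaap_config"))
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("`sequence` must be a single non-empty string", call. = FALSE)
  }
  blocks <- lapply(0:config$k_max, function(j) {
    gp <- count_gap_pairs(sequence, j)
    if (config$mode == "count") return(as.numeric(gp$counts))
    if (gp$n_valid == 0L) numeric(400L) else gp$counts / gp$n_valid
  })
  out <- unlist(blocks, use.names = FALSE)
  names(out) <- cksaap_labels(config$k_max)
  out
}

#' Encode a record set into a feature matrix
#'
#' One row per record in input order; columns follow [cksaap_labels()].
#' Degenerate (record, gap) blocks — too short for the gap, or with no
#' standard-residue pair — are left all-zero and reported in a single
#' warning.
#'
#' @param records A `protein_records` data frame (non-empty).
#' @param config A [cksaap_config()].
#' @return Numeric matrix with rownames = record ids.
#' @export
encode_dataset <- function(records, config = cksaap_config()) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("no records to encode", call. = FALSE)
  cols <- cksaap_labels(config$k_max)
  mat <- matrix(0, nrow = nrow(records), ncol = length(cols),
                dimnames = list(records$id, cols))
  degenerate <- character()
  for (i in seq_len(nrow(records))) {
    seq_i <- records$sequence[i]
    for (j in 0:config$k_max) {
      gp <- count_gap_pairs(seq_i, j)
      cols_j <- j * 400L + seq_len(400L)
      if (gp$n_valid == 0L) {
        degenerate <- c(degenerate, sprintf("%s:g%d", records$id[i], j))
      } else if (config$mode == "count") {
        mat[i, cols_j] <- gp$counts
      } else {
        mat[i, cols_j] <- gp$counts / gp$n_valid
      }
    }
  }
  if (length(degenerate)) {
    warning("all-zero block for ", length(degenerate), " (record, gap) pair(s): ",
            paste(utils::head(degenerate, 5), collapse = ", "),
            if (length(degenerate) > 5) ", ...", call. = FALSE)
  }
  attr(mat, "k_max") <- config$k_max
  attr(mat, "mode") <- config$mode
  mat
}

#' Write a feature matrix to TSV
#'
#' Header row of (gap, pair) labels plus a leading id column.
#'
#' @param features Matrix from [encode_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  df <- data.frame(id = rownames(features), features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_features()]
#'
#' @param path Path to the TSV.
#' @return Numeric matrix with rownames = record ids; `k_max` attribute
#'   recovered from the column labels.
#' @export
read_features <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          quote = "", colClasses = c("character"))
  mat <- as.matrix(vapply(df[-1], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) mat <- matrix(as.numeric(df[1, -1]), nrow = 1,
                                    dimnames = list(NULL, colnames(df)[-1]))
  rownames(mat) <- df[[1]]
  gaps <- as.integer(sub("^g([0-9]+)_.*$", "\\1", colnames(mat)))
  attr(mat, "k_max") <- max(gaps)
  mat
}
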