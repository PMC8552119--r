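#' Build a protein record set
#'
#' Protein records are held as a data frame with columns `id`, `sequence`
#' and (optionally) `label`, where the label is one of `"ECM"` (the positive
#' class) or `"non-ECM"`.
#'
#' @param id Character vector of unique, non-empty identifiers.
#' @param sequence Character vector of residue strings (uppercased, no
#'   whitespace, terminal '*' stripped).
#' @param label Optional character vector of class labels, or a single label
#'   recycled to all records, or `NA`.
#' @return A `protein_records` data frame.
#' @export
protein_records <- function(id, sequence, label = NA_character_) {
  id <- as.character(id)
  sequence <- clean_sequence(as.character(sequence))
  if (length(id) != length(sequence)) {
    stop("`id` and `sequence` lengths differ", call. = FALSE)
  }
  if (any(!nzchar(id))) stop("record ids must be non-empty", call. = FALSE)
  dup <- unique(id[duplicated(id)])
  if (length(dup)) {
    stop("duplicate record id(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  empty <- id[!nzchar(sequence)]
  if (length(empty)) {
    stop("empty sequence for record(s): ",
         paste(utils::head(empty, 5), collapse = ", "), call. = FALSE)
  }
  label <- check_labels(label, n = length(id))
  out <- data.frame(id = id, sequence = sequence, label = label,
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_records", "data.frame")
  out
}

clean_sequence <- function(x) {
  x <- toupper(gsub("[[:space:]-]", "", x))
  sub("\\*+$", "", x)  # terminal stop symbols are presentation, not residues
}

check_labels <- function(label, n) {
  if (length(label) == 1L) label <- rep(label, n)
  if (length(label) != n) stop("`label` length must be 1 or n", call. = FALSE)
  label <- as.character(label)
  ok <- is.na(label) | label %in% c("ECM", "non-ECM")
  if (!all(ok)) {
    stop("labels must be \"ECM\" or \"non-ECM\" (got: ",
         paste(utils::head(unique(label[!ok]), 3), collapse = ", "), ")",
         call. = FALSE)
  }
  label
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased; whitespace, gap characters and terminal '*'
#' stop symbols are removed. Record ids are the full FASTA header lines.
#'
#' @param path Path to a FASTA file.
#' @param label Optional class label (`"ECM"` or `"non-ECM"`) applied to all
#'   records in the file.
#' @return A `protein_records` data frame in file order.
#' @export
read_fasta <- function(path, label = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    out <- data.frame(id = character(), sequence = character(),
                      label = character(), stringsAsFactors = FALSE)
    class(out) <- c("protein_records", "data.frame")
    return(out)
  }
  protein_records(id = names(set), sequence = as.character(set), label = label)
}

#' Write protein records to a FASTA file
#'
#' Round-trip safe: `read_fasta(write_fasta(x))` reproduces ids and
#' sequences exactly.
#'
#' @param records A `protein_records` data frame.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines (presentation only).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 80L) {
  stopifnot(is.data.frame(records))
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(width))
  invisible(path)
}

#' Read a two-column id/label TSV
#'
#' Labels ride beside sequences in a plain two-column TSV (id, label)
#' rather than being parsed out of FASTA headers.
#'
#' @param path Path to a TSV with columns id and label (no header).
#' @return Data frame with columns `id`, `label`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("id", "label"),
                          colClasses = "character", quote = "")
  df$label <- check_labels(df$label, n = nrow(df))
  df
}

#' Write a two-column id/label TSV
#'
#' @param records A `protein_records` data frame with labels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(records, path) {
  utils::write.table(records[, c("id", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Attach labels from a label table to records
#'
#' @param records A `protein_records` data frame.
#' @param labels Data frame with columns `id`, `label` (e.g. from
#'   [read_labels()]).
#' @return `records` with the `label` column filled in.
#' @export
apply_labels <- function(records, labels) {
  i <- match(records$id, labels$id)
  missing <- records$id[is.na(i)]
  if (length(missing)) {
    stop("no label for record(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  records$label <- labels$label[i]
  records
}

#' Validate records against an alphabet policy
#'
#' Flags residues outside the canonical 20-letter alphabet. Under
#' `"reject_record"` any record containing such a residue is excluded;
#' under `"skip_pairs"` all records pass through unchanged (the encoder
#' skips affected pairs on its own). Reporting, not failing: the flagged
#' positions are returned either way. Idempotent.
#'
#' @param records A `protein_records` data frame.
#' @param policy An [alphabet_policy()].
#' @return List with `records` (accepted records) and `report` (data frame
#'   of columns `id`, `position`, `symbol`, one row per flagged residue).
#' @export
validate_records <- function(records, policy = alphabet_policy()) {
  stopifnot(inherits(policy, "alphabet_policy"))
  flagged <- lapply(seq_len(nrow(records)), function(i) {
    codes <- residue_codes(records$sequence[i])
    pos <- which(is.na(codes))
    if (!length(pos)) return(NULL)
    data.frame(id = records$id[i], position = pos,
               symbol = substring(records$sequence[i], pos, pos),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, c(flagged, list(
    data.frame(id = character(), position = integer(), symbol = character(),
               stringsAsFactors = FALSE))))
  accepted <- records
  if (policy$nonstandard_action == "reject_record" && nrow(report)) {
    accepted <- records[!(records$id %in% unique(report$id)), , drop = FALSE]
    rownames(accepted) <- NULL
  }
  list(records = accepted, report = report)
}
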