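#' Read peptides from a FASTA file
#'
#' Reads a multi-line FASTA file into a peptide tibble. Sequences are
#' uppercased and validated against the 20 natural amino-acid letters; any
#' record containing another character (including `B`, `J`, `O`, `U`, `X`,
#' `Z` or `*`) is rejected with an error naming the record. An optional
#' binary label may travel in the header as a `|label=0` / `|label=1`
#' suffix, or in a separate two-column TSV (id, label) given via `labels`.
#'
#' @param path Path to a FASTA file.
#' @param labels Optional path to a tab-separated file with columns
#'   `id` and `label` (0/1). Header row optional. Labels from this table
#'   override header labels.
#' @return A tibble with columns `id` (character), `sequence` (character)
#'   and `label` (integer, `NA` where no label was supplied).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1|label=1", "ACDEF", ">p2|label=0", "GHIKLMN"), fa)
#' read_fasta(fa)
read_fasta <- function(path, labels = NULL) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) abort(paste0("empty FASTA file: ", path))
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    abort(paste0("malformed FASTA: line ", first,
                 " should start a record with '>' but is: ",
                 substr(lines[first], 1L, 40L)))
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\|.*$", "", sub("\\s.*$", "", headers))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  lab <- rep(NA_integer_, length(ids))
  has <- grepl("\\|label=[01]\\b", headers)
  lab[has] <- as.integer(sub(".*\\|label=([01])\\b.*", "\\1", headers[has]))
  records <- tibble(
    id = ids,
    sequence = unname(toupper(as.character(set))),
    label = lab
  )
  if (!is.null(labels)) {
    lt <- read_labels(labels)
    idx <- match(records$id, lt$id)
    records$label[!is.na(idx)] <- lt$label[idx[!is.na(idx)]]
  }
  validate_peptides(records)
  records
}

#' Read a two-column label table
#'
#' @param path Tab-separated file with columns id and label (0/1); a header
#'   row `id<TAB>label` is recognised and skipped.
#' @return A tibble with columns `id` and `label`.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("id", "label"))
  if (identical(tolower(df$id[1]), "id")) df <- df[-1L, , drop = FALSE]
  lab <- suppressWarnings(as.integer(df$label))
  if (any(is.na(lab)) || !all(lab %in% c(0L, 1L))) {
    abort(paste0("labels must be 0/1 in ", path))
  }
  tibble(id = as.character(df$id), label = lab)
}

#' Write peptides to a FASTA file
#'
#' Inverse of [read_fasta()]: labels, where present, are written back as
#' `|label=` header suffixes so a round-trip preserves the record table.
#'
#' @param records A peptide tibble (columns `id`, `sequence`, optional `label`).
#' @param path Output file path.
#' @param labels_in_header Write `|label=` suffixes for labelled records.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, labels_in_header = TRUE) {
  validate_peptides(records)
  headers <- records$id
  if (labels_in_header && "label" %in% names(records)) {
    has <- !is.na(records$label)
    headers[has] <- paste0(headers[has], "|label=", records$label[has])
  }
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# shared record validation: uppercase 20-letter alphabet, unique non-empty ids
validate_peptides <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("id", "sequence") %in% names(records))) {
    abort("peptide records must be a data frame with columns `id` and `sequence`")
  }
  if (nrow(records) == 0L) return(invisible(records))
  if (any(!nzchar(records$id)) || anyDuplicated(records$id)) {
    abort("record ids must be non-empty and unique")
  }
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"),
               records$sequence) | !nzchar(records$sequence)
  if (any(bad)) {
    abort(paste0("invalid residues (outside the 20 natural amino acids) in ",
                 "record(s): ", paste(records$id[bad], collapse = ", ")))
  }
  invisible(records)
}

#' Keep peptides whose length is inside a window
#'
#' Retains records with `min_len <= nchar(sequence) <= max_len`, preserving
#' order. The defaults remove sequences shorter than 5 or longer than 100
#' residues, the usual working definition of a mature neuropeptide's size
#' range; the boundary lengths 5 and 100 themselves are kept.
#'
#' @param records A peptide tibble.
#' @param min_len,max_len Inclusive length bounds.
#' @return The filtered tibble (possibly empty).
#' @export
filter_by_length <- function(records, min_len = 5L, max_len = 100L) {
  stopifnot(min_len >= 1L, max_len >= min_len)
  len <- nchar(records$sequence)
  records[len >= min_len & len <= max_len, , drop = FALSE]
}

#' Right-pad sequences to a fixed length with 'B'
#'
#' Appends the pad character `B` until each sequence reaches `target_len`,
#' so residue positions stay anchored to the N-terminus. Vectorised.
#'
#' @param sequence Character vector of residue strings.
#' @param target_len Target length (default 100).
#' @return Character vector of padded sequences, each of length `target_len`.
#' @export
#' @examples
#' pad_sequence("ACD", target_len = 10)
pad_sequence <- function(sequence, target_len = 100L) {
  n <- nchar(sequence)
  if (any(n < 1L)) abort("sequences must be non-empty")
  if (any(n > target_len)) {
    abort(paste0("sequence longer than target_len (", target_len, "): ",
                 paste(which(n > target_len), collapse = ", ")))
  }
  paste0(sequence, strrep(PAD_CHAR, target_len - n))
}

#' Stratified train/test split
#'
#' Splits labelled peptides into train and test sets, stratified by label so
#' the class balance of each part matches the whole to within one record;
#' deterministic for a fixed seed.
#'
#' @param records Labelled peptide tibble (no `NA` labels).
#' @param test_fraction Proportion held out (default 0.2, i.e. an 8:2 split).
#' @param seed Integer seed controlling the shuffle.
#' @return An object of class `pepstack_split`: a list with tibbles `train`
#'   and `test` and the `seed`.
#' @export
split_train_test <- function(records, test_fraction = 0.2, seed) {
  if (!"label" %in% names(records) || any(is.na(records$label))) {
    abort("split_train_test() needs a label for every record")
  }
  stopifnot(test_fraction > 0, test_fraction < 1)
  test_idx <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(records)), records$label), function(ix) {
      n_test <- round(length(ix) * test_fraction)
      sample(ix, n_test)
    }), use.names = FALSE)
  })
  out <- list(
    train = records[-sort(test_idx), , drop = FALSE],
    test  = records[sort(test_idx), , drop = FALSE],
    seed  = as.integer(seed)
  )
  class(out) <- "pepstack_split"
  out
}

#' @export
print.pepstack_split <- function(x, ...) {
  cat("<pepstack_split> train:", nrow(x$train), "test:", nrow(x$test),
      "seed:", x$seed, "\n")
  invisible(x)
}

# stratified k-fold assignment, deterministic per seed; every fold gets both
# classes provided each class has >= k members
stratified_folds <- function(labels, k, seed) {
  if (k < 2L) abort("k must be >= 2")
  if (min(table(labels)) < k) {
    abort("k exceeds the size of the smallest class; folds would be single-class")
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      ix <- which(labels == cl)
      fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
  })
  fold
}
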