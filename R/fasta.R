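#' Read a multi-FASTA file into a tibble
#'
#' Headers are split at the first whitespace: the leading token becomes `id`,
#' the remainder (possibly empty) becomes `description`. Sequences are
#' uppercased. Wrapped and unwrapped input are both accepted.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `sequence`, one row per
#'   record, in file order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  header <- names(set)
  id <- sub("\\s.*$", "", header)
  description <- ifelse(grepl("\\s", header), sub("^\\S+\\s+", "", header), "")
  tibble(
    id = id,
    description = description,
    sequence = unname(toupper(as.character(set)))
  )
}

#' Write a tibble of sequence records to multi-FASTA
#'
#' Sequence lines are wrapped at 60 columns. The header is `id` followed by a
#' space and `description` when the description is non-empty.
#'
#' @param records A tibble with columns `id`, `description` (optional) and
#'   `sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) {
    records$description
  } else {
    rep("", nrow(records))
  }
  desc <- ifelse(is.na(desc), "", desc)
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

# Alphabets. Nucleotide: the 4 bases plus the IUPAC ambiguity codes.
# Protein: the 20 residues plus X (unknown) and * (stop).
.NT_ALPHABET <- c("A", "C", "G", "T", names(Biostrings::IUPAC_CODE_MAP))
.AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")

# Error if any sequence contains a character outside `alphabet`, naming the
# offending record and 1-based position.
.check_alphabet <- function(records, alphabet, kind) {
  for (i in seq_len(nrow(records))) {
    chars <- strsplit(records$sequence[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% alphabet)
    if (length(bad)) {
      abort(sprintf(
        "invalid %s character '%s' in record '%s' at position %d",
        kind, chars[bad[1]], records$id[[i]], bad[1]
      ))
    }
  }
  invisible(records)
}

.check_nucleotide <- function(records) {
  .check_alphabet(records, unique(.NT_ALPHABET), "nucleotide")
}

.check_protein <- function(records) {
  .check_alphabet(records, .AA_ALPHABET, "amino-acid")
}

#' Reverse complement of nucleotide sequences
#'
#' Handles the full IUPAC ambiguity alphabet.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTRYKMBDHVSWN", "TGCAYRMKVHDBSWN", toupper(x))
  vapply(
    strsplit(comp, "", fixed = TRUE),
    function(ch) paste(rev(ch), collapse = ""),
    character(1)
  )
}
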