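#' Six-frame translation of genome sequences into theoretical proteins
#'
#' Enumerates every stop-to-stop open reading frame (ORF) product of length
#' `>= min_len` residues in all three forward and all three reverse-complement
#' reading frames of every input record. The resulting table is the theoretical
#' protein search space used for proteogenomic database searching: ORFs are
#' maximal stop-free runs, not gene models, so no start codon is required
#' unless `require_start = TRUE`.
#'
#' Stop codons are excluded from both the reported sequence and the nucleotide
#' interval; trailing incomplete codons are discarded. A codon containing an
#' IUPAC ambiguity code translates to `X` unless all of its disambiguations
#' agree on one residue (so e.g. `GCN` is `A`). `X` never terminates an ORF,
#' but runs consisting solely of `X` are suppressed. Coordinates are 0-based
#' half-open on the forward strand for both strands, so
#' `end - start == 3 * nchar(sequence)` always holds and re-translating
#' `source[start, end)` (reverse-complemented for strand `-`) reproduces the
#' protein.
#'
#' Identifiers are deterministic: `{source_id}|{strand}{frame}|{ordinal}`,
#' where the ordinal numbers ORFs of one (strand, frame) left to right on the
#' forward coordinate axis, starting at 1.
#'
#' @param genome Tibble of nucleotide records with columns `id`, `sequence`
#'   (and optionally `description`), as returned by [read_fasta()].
#' @param min_len Minimum ORF length in residues (default 20, a practical
#'   database-size cutoff comfortably above the shortest identifiable tryptic
#'   peptides).
#' @param codon_table NCBI genetic-code table identifier (default `1`,
#'   standard); pass e.g. `11` for plastid contigs.
#' @param require_start If `TRUE`, each stop-to-stop run is trimmed to begin at
#'   its first methionine and runs without one are dropped (default `FALSE`:
#'   the database is a search space, not a gene model).
#' @return A tibble with columns `id`, `source_id`, `strand` (`"+"`/`"-"`),
#'   `frame` (1-3), `start`, `end` (0-based half-open, forward strand),
#'   `sequence`; ordered by source record, strand (`+` first), frame, then
#'   position.
#' @export
#' @examples
#' genome <- tibble::tibble(id = "ctg1", sequence = "ATGGCCTAA")
#' six_frame_translate(genome, min_len = 1)
six_frame_translate <- function(genome, min_len = 20, codon_table = 1,
                                require_start = FALSE) {
  stopifnot(is.data.frame(genome), min_len >= 1)
  empty <- tibble(
    id = character(), source_id = character(), strand = character(),
    frame = integer(), start = integer(), end = integer(),
    sequence = character()
  )
  if (!nrow(genome)) {
    return(empty)
  }
  genome$sequence <- toupper(genome$sequence)
  .check_nucleotide(genome)
  code <- .genetic_code(codon_table)

  out <- vector("list", nrow(genome) * 6L)
  k <- 0L
  for (i in seq_len(nrow(genome))) {
    fwd <- genome$sequence[[i]]
    L <- nchar(fwd)
    rev <- reverse_complement(fwd)
    for (strand in c("+", "-")) {
      s_str <- if (strand == "+") fwd else rev
      for (f in 1:3) {
        aa <- .translate_frame(s_str, f - 1L, code)
        runs <- .orf_runs(aa, min_len, require_start)
        if (!nrow(runs)) next
        start_local <- (f - 1L) + 3L * (runs$codon_start - 1L)
        end_local <- (f - 1L) + 3L * runs$codon_end
        if (strand == "+") {
          start <- start_local
          end <- end_local
        } else {
          start <- L - end_local
          end <- L - start_local
        }
        k <- k + 1L
        out[[k]] <- tibble(
          source_id = genome$id[[i]], strand = strand, frame = f,
          start = as.integer(start), end = as.integer(end),
          sequence = runs$sequence
        )
      }
    }
  }
  if (k == 0L) {
    return(empty)
  }
  res <- bind_rows(out[seq_len(k)])
  res <- arrange(
    res,
    match(.data$source_id, genome$id), .data$strand, .data$frame, .data$start
  )
  res <- res |>
    group_by(.data$source_id, .data$strand, .data$frame) |>
    mutate(ordinal = row_number()) |>
    ungroup() |>
    mutate(id = paste0(
      .data$source_id, "|", .data$strand, .data$frame, "|", .data$ordinal
    )) |>
    select("id", "source_id", "strand", "frame", "start", "end", "sequence")
  res
}

.genetic_code <- function(codon_table) {
  Biostrings::getGeneticCode(as.character(codon_table))
}

# Translate one reading frame of `s` (offset `off` in 0:2) to a residue
# vector, one element per complete codon; trailing partial codons dropped.
.translate_frame <- function(s, off, code) {
  L <- nchar(s)
  n <- (L - off) %/% 3L
  if (n <= 0L) {
    return(character(0))
  }
  starts <- off + 1L + 3L * (seq_len(n) - 1L)
  codons <- substring(s, starts, starts + 2L)
  aa <- unname(code[codons])
  amb <- which(is.na(aa))
  if (length(amb)) {
    aa[amb] <- vapply(codons[amb], .translate_ambiguous, character(1),
      code = code
    )
  }
  aa
}

# A codon with ambiguity codes gets the consensus residue of all its
# disambiguations, or X when they disagree.
.translate_ambiguous <- function(codon, code) {
  ch <- strsplit(codon, "", fixed = TRUE)[[1]]
  opts <- lapply(ch, function(b) {
    strsplit(Biostrings::IUPAC_CODE_MAP[[b]], "", fixed = TRUE)[[1]]
  })
  combos <- expand.grid(opts, stringsAsFactors = FALSE)
  aas <- unique(unname(code[paste0(combos[[1]], combos[[2]], combos[[3]])]))
  if (length(aas) == 1L && !is.na(aas)) aas else "X"
}

# Stop-to-stop runs of a translated frame, as 1-based codon index intervals.
.orf_runs <- function(aa, min_len, require_start) {
  empty <- tibble(
    codon_start = integer(), codon_end = integer(), sequence = character()
  )
  n <- length(aa)
  if (!n) {
    return(empty)
  }
  stops <- which(aa == "*")
  run_start <- c(1L, stops + 1L)
  run_end <- c(stops - 1L, n)
  keep_s <- integer(0)
  keep_e <- integer(0)
  seqs <- character(0)
  for (j in seq_along(run_start)) {
    s <- run_start[[j]]
    e <- run_end[[j]]
    if (s > e) next
    if (require_start) {
      m <- which(aa[s:e] == "M")
      if (!length(m)) next
      s <- s + m[[1]] - 1L
    }
    if (e - s + 1L < min_len) next
    run <- aa[s:e]
    if (all(run == "X")) next
    keep_s <- c(keep_s, s)
    keep_e <- c(keep_e, e)
    seqs <- c(seqs, paste(run, collapse = ""))
  }
  tibble(codon_start = keep_s, codon_end = keep_e, sequence = seqs)
}

#' Exact-sequence deduplication of protein records
#'
#' Collapses records with byte-identical sequences (I and L are distinct; no
#' equivalence classes) to the first occurrence in input order; every input id
#' is retained in the representative's member list, preserving input order.
#'
#' @param records Tibble of protein records (`id`, `sequence`, optionally
#'   `description`).
#' @return A tibble of representative records with list-column `members`
#'   (character vectors of merged ids, including the representative itself)
#'   and `n_members`; class `dedup_result` so [glance()] summarises it.
#' @export
deduplicate <- function(records) {
  stopifnot(is.data.frame(records))
  if (!nrow(records)) {
    out <- tibble(
      id = character(), description = character(), sequence = character(),
      members = list(), n_members = integer()
    )
    return(structure(out, class = c("dedup_result", class(out)), n_input = 0L))
  }
  reps <- records[!duplicated(records$sequence), , drop = FALSE]
  groups <- split(
    records$id,
    factor(records$sequence, levels = reps$sequence)
  )
  out <- as_tibble(reps)
  if (!"description" %in% names(out)) out$description <- ""
  out$members <- unname(groups)
  out$n_members <- lengths(out$members)
  out <- select(out, "id", "description", "sequence", "members", "n_members")
  structure(
    out,
    class = c("dedup_result", class(out)),
    n_input = nrow(records)
  )
}

#' @exportS3Method generics::glance
glance.dedup_result <- function(x, ...) {
  tibble(
    n_input = attr(x, "n_input"),
    n_representatives = nrow(x),
    n_redundant = attr(x, "n_input") - nrow(x),
    max_multiplicity = if (nrow(x)) max(x$n_members) else NA_integer_
  )
}

#' Subset FASTA records by identifier
#'
#' Keeps exactly the records whose `id` is in `keep_ids`, preserving input
#' order. Requested ids absent from `records` are not an error: they are
#' reported via a message and attached as the `missing_ids` attribute.
#'
#' @param records Tibble of sequence records.
#' @param keep_ids Character vector of ids to retain.
#' @return The retained records, with attribute `missing_ids`.
#' @export
subset_fasta <- function(records, keep_ids) {
  stopifnot(is.data.frame(records))
  keep_ids <- unique(as.character(keep_ids))
  out <- filter(records, .data$id %in% keep_ids)
  missing <- setdiff(keep_ids, records$id)
  if (length(missing)) {
    inform(sprintf(
      "%d requested id(s) not found: %s", length(missing),
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  attr(out, "missing_ids") <- missing
  out
}

#' Map proteins to chromosomes by exact six-frame match
#'
#' Emits one hit for every exact substring occurrence of each protein sequence
#' in any of the six frame translations of any chromosome; a protein may hit
#' several chromosomes or several loci. Coordinates follow the
#' [six_frame_translate()] convention (0-based half-open, forward strand).
#'
#' @param proteins Tibble of amino-acid records.
#' @param chromosomes Tibble of nucleotide records.
#' @param min_len Proteins shorter than this many residues are not searched
#'   (default 20; short sequences match by chance).
#' @param codon_table NCBI genetic-code table identifier.
#' @return A tibble with columns `protein_id`, `chromosome_id`, `strand`,
#'   `frame`, `start`, `end`, ordered by protein, chromosome, strand, frame,
#'   position.
#' @export
map_to_chromosome <- function(proteins, chromosomes, min_len = 20,
                              codon_table = 1) {
  stopifnot(is.data.frame(proteins), is.data.frame(chromosomes), min_len >= 1)
  chromosomes$sequence <- toupper(chromosomes$sequence)
  .check_nucleotide(chromosomes)
  code <- .genetic_code(codon_table)
  qry <- filter(proteins, nchar(.data$sequence) >= min_len)

  out <- list()
  k <- 0L
  for (i in seq_len(nrow(chromosomes))) {
    chrom <- chromosomes$sequence[[i]]
    L <- nchar(chrom)
    rev <- reverse_complement(chrom)
    for (strand in c("+", "-")) {
      s_str <- if (strand == "+") chrom else rev
      for (f in 1:3) {
        frame_aa <- paste(.translate_frame(s_str, f - 1L, code), collapse = "")
        for (j in seq_len(nrow(qry))) {
          pep <- toupper(qry$sequence[[j]])
          hits <- gregexpr(pep, frame_aa, fixed = TRUE)[[1]]
          if (hits[1] == -1L) next
          len <- nchar(pep)
          start_local <- (f - 1L) + 3L * (as.integer(hits) - 1L)
          end_local <- start_local + 3L * len
          if (strand == "+") {
            start <- start_local
            end <- end_local
          } else {
            start <- L - end_local
            end <- L - start_local
          }
          k <- k + 1L
          out[[k]] <- tibble(
            protein_id = qry$id[[j]], chromosome_id = chromosomes$id[[i]],
            strand = strand, frame = f,
            start = as.integer(start), end = as.integer(end)
          )
        }
      }
    }
  }
  if (!k) {
    return(tibble(
      protein_id = character(), chromosome_id = character(),
      strand = character(), frame = integer(),
      start = integer(), end = integer()
    ))
  }
  res <- bind_rows(out)
  arrange(
    res,
    match(.data$protein_id, proteins$id),
    match(.data$chromosome_id, chromosomes$id),
    .data$strand, .data$frame, .data$start
  )
}
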