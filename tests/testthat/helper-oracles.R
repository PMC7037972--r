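# Independent oracles used across the suite. They deliberately take a
# different route from the package code: full-frame translation via
# Biostrings::translate and regex splitting on stop characters, instead of
# the package's codon walker.

# All stop-to-stop ORFs of `seq` (ACGT only) as (strand, frame, start, end,
# sequence) tuples, by translating each frame in full and splitting on '*'.
oracle_sixframe <- function(seq, min_len) {
  L <- nchar(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") {
      seq
    } else {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    }
    for (f in 1:3) {
      n <- (L - (f - 1)) %/% 3
      if (n <= 0) next
      dna <- Biostrings::subseq(Biostrings::DNAString(s), f, f - 1 + 3 * n)
      aa <- as.character(Biostrings::translate(dna, no.init.codon = TRUE))
      m <- gregexpr("[^*]+", aa)[[1]]
      if (m[1] == -1) next
      lens <- attr(m, "match.length")
      for (k in seq_along(m)) {
        if (lens[k] < min_len) next
        cs <- as.integer(m[k])
        start_local <- (f - 1) + 3 * (cs - 1)
        end_local <- start_local + 3 * lens[k]
        rows[[length(rows) + 1L]] <- data.frame(
          strand = strand, frame = f,
          start = if (strand == "+") start_local else L - end_local,
          end = if (strand == "+") end_local else L - start_local,
          sequence = substr(aa, cs, cs + lens[k] - 1)
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      strand = character(), frame = integer(), start = integer(),
      end = integer(), sequence = character()
    )
  }
  out[order(out$strand, out$frame, out$start), , drop = FALSE]
}

# Orf tuple columns of a six_frame_translate() result, for set comparison.
orf_tuples <- function(x) {
  out <- as.data.frame(x[, c("strand", "frame", "start", "end", "sequence")])
  out[order(out$strand, out$frame, out$start), , drop = FALSE]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
    collapse = ""
  )
}

# Re-translate the genomic interval of a theoretical protein with an
# independent translator; must reproduce the reported residue string.
retranslate <- function(source_seq, strand, start, end) {
  nt <- substr(source_seq, start + 1, end)
  dna <- Biostrings::DNAString(nt)
  if (strand == "-") dna <- Biostrings::reverseComplement(dna)
  as.character(Biostrings::translate(dna, no.init.codon = TRUE))
}

# Paired vectors with an exact sample Pearson correlation r (n points).
vectors_with_exact_r <- function(r, n) {
  x <- seq_len(n)
  u <- (x - mean(x)) / sqrt(sum((x - mean(x))^2))
  e <- stats::rnorm(n)
  e <- e - mean(e) - sum(e * u) * u
  e <- e / sqrt(sum(e^2))
  list(x = as.numeric(x), y = r * u + sqrt(1 - r^2) * e)
}
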