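test_that("single-codon examples translate as expected", {
  g <- tibble::tibble(id = "ctg1", sequence = "ATGGCCTAA")
  orfs <- six_frame_translate(g, min_len = 1)
  plus1 <- orfs[orfs$strand == "+" & orfs$frame == 1, ]
  expect_identical(plus1$sequence, "MA")
  expect_identical(plus1$start, 0L)
  expect_identical(plus1$end, 6L)
  expect_identical(plus1$id, "ctg1|+1|1")

  g2 <- tibble::tibble(id = "c", sequence = "TTACAT")
  orfs2 <- six_frame_translate(g2, min_len = 1)
  minus1 <- orfs2[orfs2$strand == "-" & orfs2$frame == 1, ]
  expect_identical(minus1$sequence, "M")
  expect_identical(minus1$start, 3L)
  expect_identical(minus1$end, 6L)
})

test_that("empty genome gives an empty, well-typed result", {
  out <- six_frame_translate(tibble::tibble(id = character(), sequence = character()))
  expect_identical(nrow(out), 0L)
  expect_named(
    out, c("id", "source_id", "strand", "frame", "start", "end", "sequence")
  )
})

test_that("ORF set on a random 10 kb sequence equals the brute-force oracle", {
  withr::local_seed(101)
  seq <- random_dna(10000)
  got <- six_frame_translate(
    tibble::tibble(id = "chr", sequence = seq),
    min_len = 20
  )
  expect_gt(nrow(got), 0)
  expect_equal(
    orf_tuples(got),
    oracle_sixframe(seq, 20),
    ignore_attr = TRUE
  )
})

test_that("every emitted ORF re-translates from its genomic interval", {
  withr::local_seed(7)
  seq <- random_dna(4000)
  got <- six_frame_translate(
    tibble::tibble(id = "chr", sequence = seq),
    min_len = 10
  )
  expect_gt(nrow(got), 10)
  for (i in seq_len(nrow(got))) {
    expect_identical(
      retranslate(seq, got$strand[i], got$start[i], got$end[i]),
      got$sequence[i]
    )
    expect_identical(got$end[i] - got$start[i], 3L * nchar(got$sequence[i]))
  }
})

test_that("min_len is monotone and strand symmetry holds", {
  withr::local_seed(11)
  seq <- random_dna(3000)
  g <- tibble::tibble(id = "s", sequence = seq)
  for (k in c(5, 10, 20)) {
    lo <- six_frame_translate(g, min_len = k)
    hi <- six_frame_translate(g, min_len = k + 1)
    expect_true(all(hi$sequence %in% lo$sequence))
    expect_true(all(nchar(lo$sequence) >= k))
  }
  rc <- tibble::tibble(id = "s", sequence = reverse_complement(seq))
  a <- sort(six_frame_translate(g, min_len = 15)$sequence)
  b <- sort(six_frame_translate(rc, min_len = 15)$sequence)
  expect_identical(a, b)
})

test_that("ambiguity codes translate by consensus and X never terminates", {
  # GCN is alanine in every disambiguation; ATN is ambiguous
  g <- tibble::tibble(id = "a", sequence = "TAAATGGCNATNCCGTAA")
  orfs <- six_frame_translate(g, min_len = 1)
  plus1 <- orfs[orfs$strand == "+" & orfs$frame == 1, ]
  expect_identical(plus1$sequence, "MAXP")

  # a run consisting solely of X is suppressed
  g2 <- tibble::tibble(id = "b", sequence = "TAANNNNNNTAA")
  orfs2 <- six_frame_translate(g2, min_len = 1)
  expect_false(any(orfs2$strand == "+" & orfs2$frame == 1))
})

test_that("require_start trims runs to the first methionine", {
  # frame +1: LLMKV (no stop); with a start requirement the ORF begins at M
  g <- tibble::tibble(id = "s", sequence = "CTGCTGATGAAAGTG")
  free <- six_frame_translate(g, min_len = 1)
  with_start <- six_frame_translate(g, min_len = 1, require_start = TRUE)
  expect_identical(
    free$sequence[free$strand == "+" & free$frame == 1], "LLMKV"
  )
  expect_identical(
    with_start$sequence[with_start$strand == "+" & with_start$frame == 1],
    "MKV"
  )
  expect_identical(
    with_start$start[with_start$strand == "+" & with_start$frame == 1], 6L
  )
})

test_that("planted ORFs are recovered exactly at their recorded coordinates", {
  sg <- sim_genome(
    seed = 5, contig_length = 8000, n_contigs = 2,
    planted = tibble::tibble(
      contig = c(1L, 1L, 2L, 2L),
      strand = c("+", "-", "+", "-"),
      len = c(25L, 40L, 33L, 21L)
    )
  )
  got <- six_frame_translate(sg$genome, min_len = 20)
  found <- dplyr::inner_join(
    sg$manifest, got,
    by = c("source_id", "strand", "frame", "start", "end", "sequence")
  )
  expect_identical(nrow(found), nrow(sg$manifest))
})

test_that("deduplicate collapses exact sequence duplicates, first wins", {
  recs <- tibble::tibble(
    id = c("a", "b", "c"),
    sequence = c("MKV", "MKV", "PWA")
  )
  d <- deduplicate(recs)
  expect_identical(d$id, c("a", "c"))
  expect_identical(d$members[[1]], c("a", "b"))
  expect_identical(d$n_members, c(2L, 1L))

  distinct <- tibble::tibble(id = c("x", "y"), sequence = c("AA", "AB"))
  d2 <- deduplicate(distinct)
  expect_identical(d2$id, distinct$id)
  expect_true(all(d2$n_members == 1L))
})

test_that("deduplicate partitions a constructed 1000-record file and is idempotent", {
  withr::local_seed(13)
  base <- vapply(seq_len(120), function(i) random_protein(30), character(1))
  mult <- c(rep(1L, 60), rep(2L, 30), rep(10L, 20), rep(114L, 5), 106L)
  stopifnot(length(mult) == 116) # remaining 4 bases get multiplicity 1
  mult <- c(mult, rep(1L, 4))
  stopifnot(sum(mult) == 1000)
  seqs <- rep(base, times = mult)
  ord <- sample(1000)
  recs <- tibble::tibble(
    id = sprintf("r%04d", seq_len(1000)),
    sequence = seqs[ord]
  )
  d <- deduplicate(recs)
  expect_identical(nrow(d), 120L)
  expect_identical(sort(unlist(d$members)), sort(recs$id))
  expect_identical(sum(d$n_members), 1000L)
  expect_identical(
    sort(tabulate(factor(recs$sequence))),
    sort(d$n_members)
  )
  again <- deduplicate(d[, c("id", "sequence")])
  expect_identical(again$id, d$id)
  expect_identical(nrow(again), nrow(d))
  expect_true(all(again$n_members == 1L))
})

test_that("subset_fasta keeps order and reports missing ids", {
  withr::local_seed(17)
  recs <- tibble::tibble(
    id = sprintf("p%03d", 1:100),
    sequence = vapply(1:100, function(i) random_protein(12), character(1))
  )
  want <- c(sprintf("p%03d", c(90, 5, 41, 17, 2, 63, 88, 29, 54, 11, 76, 33, 99, 47)),
            "absent1", "absent2", "absent3")
  out <- suppressMessages(subset_fasta(recs, want))
  expect_identical(nrow(out), 14L)
  expect_identical(out$id, recs$id[recs$id %in% want]) # input order preserved
  expect_identical(attr(out, "missing_ids"), c("absent1", "absent2", "absent3"))

  expect_identical(nrow(subset_fasta(recs, character(0))), 0L)
  all_out <- subset_fasta(recs, recs$id)
  expect_equal(all_out, recs, ignore_attr = TRUE)
})

test_that("map_to_chromosome finds exact six-frame matches", {
  chrom <- tibble::tibble(id = "chr1", sequence = "ATGGCCTAA")
  hit <- map_to_chromosome(
    tibble::tibble(id = "p1", sequence = "MA"), chrom,
    min_len = 1
  )
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$strand, "+")
  expect_identical(hit$frame, 1L)
  expect_identical(c(hit$start, hit$end), c(0L, 6L))

  none <- map_to_chromosome(
    tibble::tibble(id = "p2", sequence = "WWWW"), chrom,
    min_len = 1
  )
  expect_identical(nrow(none), 0L)
})

test_that("planted proteins are recovered from synthetic chromosomes", {
  plan <- tibble::tibble(
    contig = rep(1:3, length.out = 50),
    strand = rep(c("+", "-"), length.out = 50),
    len = rep(21:30, length.out = 50)
  )
  sg <- sim_genome(seed = 23, contig_length = 6000, n_contigs = 3, planted = plan)
  proteins <- tibble::tibble(
    id = sprintf("prot%02d", seq_len(nrow(sg$manifest))),
    sequence = sg$manifest$sequence
  )
  hits <- map_to_chromosome(proteins, sg$genome, min_len = 20)

  planted_hits <- dplyr::inner_join(
    dplyr::bind_cols(sg$manifest, protein_id = proteins$id),
    hits,
    by = c(
      "protein_id", source_id = "chromosome_id", "strand", "frame",
      "start", "end"
    )
  )
  expect_identical(nrow(planted_hits), nrow(sg$manifest))

  # every reported hit is verified by an independent re-translation
  for (i in seq_len(nrow(hits))) {
    src <- sg$genome$sequence[sg$genome$id == hits$chromosome_id[i]]
    expect_identical(
      retranslate(src, hits$strand[i], hits$start[i], hits$end[i]),
      proteins$sequence[proteins$id == hits$protein_id[i]]
    )
  }
})
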