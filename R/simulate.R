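# Seeded generators for fully synthetic test inputs: genomes with planted
# ORFs, MGF files with planted diagnostic peaks, emapper-style annotation
# tables, and abundance matrices with planted correlation structure. Every
# generator is deterministic under its seed, and every manifest is sufficient
# to predict the downstream module's output without re-reading the fixture.

# First codon (alphabetically) encoding each residue under `code`.
.reverse_codon_map <- function(code) {
  split(names(code), unname(code)) |>
    lapply(function(cs) sort(cs)[[1]])
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a genome with planted open reading frames
#'
#' Generates random-background contigs and splices in stop-flanked ORF
#' cassettes (`TAA` + codons + `TAA`, reverse-complemented for strand `-`) at
#' recorded positions, so that [six_frame_translate()] must recover each
#' planted ORF exactly. The background itself contains chance ORFs, so
#' recovery is a superset relation; the manifest pins the planted
#' coordinates.
#'
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param contig_length Length of each contig in nucleotides (default
#'   10000).
#' @param n_contigs Number of contigs (default 1).
#' @param planted Tibble describing the ORFs to plant, with columns `contig`
#'   (1-based index), `strand` (`"+"`/`"-"`), and either `aa` (residue
#'   string) or `len` (residue count, sequence drawn at random); an optional
#'   `start` column pins the forward-strand cassette start (0-based), and
#'   overlapping pinned cassettes are an error. `NULL` plants nothing.
#' @param codon_table NCBI genetic-code table identifier.
#' @return A list with `genome` (tibble `id`, `description`, `sequence`) and
#'   `manifest` (tibble `source_id`, `strand`, `frame`, `start`, `end`,
#'   `sequence`, the expected theoretical-protein tuples).
#' @export
sim_genome <- function(seed, contig_length = 10000, n_contigs = 1,
                       planted = NULL, codon_table = 1) {
  code <- .genetic_code(codon_table)
  rev_map <- .reverse_codon_map(code)
  residues <- setdiff(names(rev_map), "*")
  withr::with_seed(seed, {
    contigs <- vapply(
      seq_len(n_contigs),
      function(i) .random_dna(contig_length), character(1)
    )
    manifest <- list()
    if (!is.null(planted) && nrow(planted)) {
      if (!"contig" %in% names(planted)) planted$contig <- 1L
      if (!"aa" %in% names(planted)) planted$aa <- NA_character_
      if (!"start" %in% names(planted)) planted$start <- NA_integer_
      need_len <- is.na(planted$aa)
      if (any(need_len) && !"len" %in% names(planted)) {
        abort("planted rows need either `aa` or `len`")
      }
      planted$aa[need_len] <- vapply(
        planted$len[need_len],
        function(l) paste(sample(residues, l, replace = TRUE), collapse = ""),
        character(1)
      )
      occupied <- lapply(seq_len(n_contigs), function(i) {
        matrix(numeric(0), ncol = 2)
      })
      # pinned cassettes first, then auto-placed ones after a random gap
      ord <- order(!is.na(planted$start), decreasing = TRUE)
      cursor <- rep(0L, n_contigs)
      for (idx in ord) {
        row <- planted[idx, ]
        ci <- row$contig
        aa <- toupper(row$aa)
        codons <- vapply(
          strsplit(aa, "", fixed = TRUE)[[1]],
          function(a) rev_map[[a]], character(1)
        )
        cassette <- paste0("TAA", paste(codons, collapse = ""), "TAA")
        if (row$strand == "-") cassette <- reverse_complement(cassette)
        clen <- nchar(cassette)
        if (!is.na(row$start)) {
          pos <- as.integer(row$start)
          occ <- occupied[[ci]]
          if (nrow(occ) && any(pos < occ[, 2] & pos + clen > occ[, 1])) {
            abort(sprintf(
              "planted ORF at position %d overlaps an earlier plant", pos
            ))
          }
        } else {
          pos <- cursor[ci] + sample(30:90, 1)
          occ <- occupied[[ci]]
          repeat {
            clash <- nrow(occ) && any(pos < occ[, 2] & pos + clen > occ[, 1])
            if (!clash) break
            hit <- which(pos < occ[, 2] & pos + clen > occ[, 1])[1]
            pos <- as.integer(occ[hit, 2]) + sample(30:90, 1)
          }
        }
        if (pos + clen > contig_length) {
          abort("contig too short for the requested plants")
        }
        occupied[[ci]] <- rbind(occupied[[ci]], c(pos, pos + clen))
        cursor[ci] <- max(cursor[ci], pos + clen)
        substr(contigs[ci], pos + 1L, pos + clen) <- cassette

        len <- nchar(aa)
        orf_start <- pos + 3L
        orf_end <- orf_start + 3L * len
        frame <- if (row$strand == "+") {
          (orf_start %% 3L) + 1L
        } else {
          ((contig_length - orf_end) %% 3L) + 1L
        }
        manifest[[length(manifest) + 1L]] <- tibble(
          source_id = sprintf("contig%02d", ci), strand = row$strand,
          frame = frame, start = orf_start, end = orf_end, sequence = aa
        )
      }
    }
    list(
      genome = tibble(
        id = sprintf("contig%02d", seq_len(n_contigs)),
        description = "synthetic contig",
        sequence = contigs
      ),
      manifest = if (length(manifest)) {
        arrange(bind_rows(manifest), .data$source_id, .data$start)
      } else {
        tibble(
          source_id = character(), strand = character(), frame = integer(),
          start = integer(), end = integer(), sequence = character()
        )
      }
    )
  })
}

#' Simulate an MGF file with planted diagnostic-ion peaks
#'
#' Background peaks are drawn uniformly over the m/z range but rejected from
#' a 50 ppm exclusion zone around every registry ion, so only deliberately
#' planted peaks can match. Spiked spectra receive a peak offset from the ion
#' target by `spike_ppm` parts per million (randomly signed); decoy spectra
#' receive one at `decoy_ppm`, beyond the default matching tolerance.
#'
#' @param seed Integer seed.
#' @param n_spectra Number of spectra (default 100).
#' @param ions Ion tibble to plant (default the full
#'   [builtin_ion_registry()]).
#' @param n_spiked,spike_ppm Number of spectra receiving in-tolerance
#'   diagnostic peaks, and their ppm offset (defaults 23 and 2).
#' @param n_decoys,decoy_ppm Number of spectra receiving out-of-tolerance
#'   peaks, and their offset (defaults 5 and 12).
#' @param one_ion_per_spectrum If `TRUE`, each spiked spectrum receives a
#'   single ion (cycling through `ions`) instead of all of them.
#' @param mz_range Background peak m/z range (default 200-1500).
#' @return A list with `spectra` (tibble in [read_mgf()] layout) and
#'   `manifest` (tibble `scan_id`, `ion`, `abs_ppm`, `role`): a scan passes a
#'   tolerance `t` for an ion iff its manifest row has `abs_ppm <= t`.
#' @export
sim_mgf <- function(seed, n_spectra = 100, ions = builtin_ion_registry(),
                    n_spiked = 23, spike_ppm = 2, n_decoys = 5,
                    decoy_ppm = 12, one_ion_per_spectrum = FALSE,
                    mz_range = c(200, 1500)) {
  stopifnot(n_spiked + n_decoys <= n_spectra, nrow(ions) >= 1)
  withr::with_seed(seed, {
    chosen <- sample(n_spectra, n_spiked + n_decoys)
    spiked <- chosen[seq_len(n_spiked)]
    decoys <- setdiff(chosen, spiked)

    excl_lo <- ions$target_mz * (1 - 50e-6)
    excl_hi <- ions$target_mz * (1 + 50e-6)
    draw_background <- function(n) {
      mz <- stats::runif(n, mz_range[1], mz_range[2])
      repeat {
        bad <- rowSums(outer(mz, excl_lo, ">=") & outer(mz, excl_hi, "<=")) > 0
        if (!any(bad)) break
        mz[bad] <- stats::runif(sum(bad), mz_range[1], mz_range[2])
      }
      mz
    }

    rows <- vector("list", n_spectra)
    manifest <- list()
    for (i in seq_len(n_spectra)) {
      n_bg <- sample(30:60, 1)
      mz <- draw_background(n_bg)
      intensity <- round(stats::rlnorm(n_bg, meanlog = 9, sdlog = 1), 2)
      role <- if (i %in% spiked) "spike" else if (i %in% decoys) "decoy" else NA
      if (!is.na(role)) {
        off_ppm <- if (role == "spike") spike_ppm else decoy_ppm
        ion_rows <- if (one_ion_per_spectrum) {
          1L + (match(i, chosen) - 1L) %% nrow(ions)
        } else {
          seq_len(nrow(ions))
        }
        for (k in ion_rows) {
          sign <- sample(c(-1, 1), 1)
          mz <- c(mz, ions$target_mz[[k]] * (1 + sign * off_ppm * 1e-6))
          intensity <- c(intensity, round(stats::rlnorm(1, 11, 0.5), 2))
          manifest[[length(manifest) + 1L]] <- tibble(
            scan_id = sprintf("scan=%04d", i), ion = ions$name[[k]],
            abs_ppm = off_ppm, role = role
          )
        }
      }
      ord <- order(mz)
      rows[[i]] <- tibble(
        scan_id = sprintf("scan=%04d", i),
        title = sprintf("scan=%04d", i),
        precursor_mz = round(stats::runif(1, 400, 1200), 4),
        precursor_charge = sample(2:3, 1),
        rtinseconds = round(i * 1.7, 2),
        peaks = list(tibble(mz = mz[ord], intensity = intensity[ord]))
      )
    }
    list(
      spectra = bind_rows(rows),
      manifest = if (length(manifest)) {
        bind_rows(manifest)
      } else {
        tibble(
          scan_id = character(), ion = character(),
          abs_ppm = numeric(), role = character()
        )
      }
    )
  })
}

#' Simulate an eggNOG-mapper annotation table
#'
#' Writes rows in the requested emapper dialect for the gene-assigned and
#' function-only ids; unassigned ids are queried but receive no row, the
#' convention for queries without a passing ortholog hit.
#'
#' @param seed Integer seed.
#' @param n_gene,n_function,n_unassigned Category counts.
#' @param dialect Output dialect, `"v2"` (default) or `"v1"`.
#' @return A list with `lines` (character vector: comment header plus data
#'   rows, writable with [writeLines()]), `queried_ids` (all ids, shuffled),
#'   and `counts` (tibble `category`, `n`).
#' @export
sim_annotations <- function(seed, n_gene = 50, n_function = 120,
                            n_unassigned = 30, dialect = "v2") {
  d <- .resolve_dialect(dialect)
  total <- n_gene + n_function + n_unassigned
  withr::with_seed(seed, {
    ids <- sprintf("PROT%06d", sample(1e6, total))
    cat_of <- sample(rep(
      c("gene_assigned", "function_only", "unassigned"),
      c(n_gene, n_function, n_unassigned)
    ))
    with_rows <- which(cat_of != "unassigned")
    make_row <- function(i) {
      f <- rep("-", d$ncol)
      f[d$query] <- ids[i]
      f[d$seed_ortholog] <- sprintf("981085.XP_%09d.1", sample(1e9, 1))
      f[d$evalue] <- format(10^stats::runif(1, -120, -10), digits = 3)
      f[d$description] <- sprintf("putative protein %d", sample(1e4, 1))
      if (cat_of[i] == "gene_assigned") {
        f[d$gene] <- sprintf("GENE%04d", sample(1e4, 1))
      }
      paste(f, collapse = "\t")
    }
    lines <- c(
      "# emapper-style synthetic annotation table",
      sprintf("#query\t%s", paste(rep("col", d$ncol - 1), collapse = "\t")),
      vapply(with_rows, make_row, character(1))
    )
    list(
      lines = lines,
      queried_ids = ids,
      counts = tibble(
        category = c("gene_assigned", "function_only", "unassigned"),
        n = as.integer(c(n_gene, n_function, n_unassigned))
      )
    )
  })
}

#' Simulate protein and metabolite abundance matrices with planted
#' correlations
#'
#' All features are drawn about a common positive baseline. For each planted
#' pair `k`, the `k`-th metabolite is constructed from the `k`-th protein's
#' standardized profile plus an orthogonalized residual, so its sample
#' Pearson correlation with that protein equals `planted_r[k]` exactly
#' (`r = 1` means zero residual noise). All other features are independent
#' noise.
#'
#' @param seed Integer seed.
#' @param n_proteins,n_metabolites,n_samples Matrix dimensions (default
#'   100, 100, 6; six samples mirrors a six-plant-material comparison).
#' @param planted_r Numeric vector of target correlations; pair `k` links
#'   protein `k` to metabolite `k`. `NULL` plants nothing (a pure null).
#' @param baseline,scale Affine map from standardized profiles to abundances
#'   (defaults 1000 and 100, keeping values positive).
#' @return A list with `proteins`, `metabolites` (abundance tibbles sharing
#'   sample columns `S1..Sn`) and `manifest` (tibble `protein_id`,
#'   `metabolite_id`, `target_r`).
#' @export
sim_abundance <- function(seed, n_proteins = 100, n_metabolites = 100,
                          n_samples = 6, planted_r = NULL,
                          baseline = 1000, scale = 100) {
  stopifnot(n_samples >= 3, length(planted_r) <= min(n_proteins, n_metabolites))
  withr::with_seed(seed, {
    samples <- sprintf("S%d", seq_len(n_samples))
    std <- function(v) (v - mean(v)) / sqrt(sum((v - mean(v))^2))
    pm <- matrix(stats::rnorm(n_proteins * n_samples), n_proteins)
    mm <- matrix(stats::rnorm(n_metabolites * n_samples), n_metabolites)
    manifest <- tibble(
      protein_id = character(), metabolite_id = character(),
      target_r = numeric()
    )
    for (k in seq_along(planted_r)) {
      r <- planted_r[[k]]
      stopifnot(abs(r) <= 1)
      u <- std(pm[k, ])
      e <- stats::rnorm(n_samples)
      e <- e - mean(e) - sum(e * u) * u # centred, orthogonal to u
      e <- e / sqrt(sum(e^2))
      mm[k, ] <- r * u + sqrt(1 - r^2) * e
      manifest <- bind_rows(manifest, tibble(
        protein_id = sprintf("P%04d", k),
        metabolite_id = sprintf("M%04d", k),
        target_r = r
      ))
    }
    scale_rows <- function(m) {
      t(apply(m, 1, function(v) {
        s <- stats::sd(v)
        baseline + scale * (if (s > 0) (v - mean(v)) / s else v)
      }))
    }
    proteins <- as_tibble(stats::setNames(
      as.data.frame(scale_rows(pm)), samples
    ))
    proteins <- bind_cols(
      tibble(protein_id = sprintf("P%04d", seq_len(n_proteins))), proteins
    )
    metabolites <- as_tibble(stats::setNames(
      as.data.frame(scale_rows(mm)), samples
    ))
    metabolites <- bind_cols(
      tibble(metabolite_id = sprintf("M%04d", seq_len(n_metabolites))),
      metabolites
    )
    list(proteins = proteins, metabolites = metabolites, manifest = manifest)
  })
}
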