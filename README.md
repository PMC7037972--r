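# draftmap

Toolkit for building **draft proteome maps of unannotated organisms** from
genome sequence and shotgun mass-spectrometry data. When no annotated
protein FASTA exists for a species, a proteomics lab can still identify
proteins by (1) translating the genome in all six reading frames into a
theoretical protein search space, (2) reducing the raw MS/MS peak lists to
the spectra that matter, (3) merging ortholog-based functional annotations
back into the identified protein FASTA, and (4) correlating protein
abundances with small-molecule profiles to nominate the enzymes behind
metabolites of interest. draftmap implements these bespoke stages as
composable, pipe-friendly R functions plus a thin command-line interface;
the surrounding database searching (SEQUEST, Percolator, MetaMorpheus, ...)
is vendor/third-party territory and is out of scope.

## What it computes

* **Six-frame databases** — every stop-to-stop open reading frame of length
  ≥ `min_len` in all six frames, with deterministic identifiers
  `{contig}|{strand}{frame}|{ordinal}` and 0-based half-open genome
  coordinates, so `end − start = 3·length(protein)` and every entry
  re-translates exactly from its interval. Plus exact-string deduplication,
  id-based FASTA subsetting, and exact back-mapping of proteins to
  chromosomes across all six frames.
* **D.I.D.A.R. spectral filtering** — keep only MS/MS spectra containing
  diagnostic fragment ions, e.g. the acetyllysine immonium-derived fragment
  or the HexNAc glycan oxonium ions. A peak matches ion *i* when
  |obs − target_i| / target_i × 10⁶ ≤ tol_i (default 5 ppm, denominator =
  theoretical target). Targets come from elemental composition:
  m/z = (Σ monoisotopic masses − z·mₑ)/z, so `C7H12NO⁺` → 126.0913 and
  `C8H14NO5⁺` → 204.0866 (nominal 204). The MGF streamer holds one block in
  memory and copies matching blocks byte for byte.
* **eggNOG annotation merging** — parse `.emapper.annotations` tables
  (v1/v2 dialects), categorize queries into gene-assigned / function-only /
  unassigned (an exact partition), and rewrite FASTA headers to
  `{query}|{gene}|{description}` with the literal placeholder
  `"gene not found"` when no gene name was assigned.
* **Protein–metabolite correlation** — peptide-group → protein roll-up by
  arithmetic mean, then per pair Pearson *r* and Spearman ρ with two-sided
  p-values from t = r·√((n−2)/(1−r²)) on n−2 df, pairwise-complete samples,
  and a disjunctive flag at p ≤ 0.05 (either statistic). Ranked per-metabolite
  top-correlate reports.
* **Fraction pooling** — cyclic concatenation plans (fraction *i* → pool
  *i* mod *n*), e.g. 96 collected fractions → 12 pools of 8 spanning the
  whole gradient.
* **Synthetic fixtures** — seeded generators for genomes with planted ORFs,
  MGF files with planted diagnostic peaks, emapper-style tables, and
  abundance matrices with exactly-planted correlations; all tests run on
  these, no downloads.

## Worked example

```r
library(draftmap)
library(tibble)

# a 10 kb synthetic contig with two planted ORFs (60 aa on +, 45 aa on -)
genome <- sim_genome(seed = 1, contig_length = 10000,
                     planted = tibble(strand = c("+", "-"), len = c(60L, 45L)))
orfs <- six_frame_translate(genome$genome, min_len = 20)
orfs
#> # A tibble: 366 x 7
#>   id            source_id strand frame start   end sequence
#> 1 contig01|+1|1 contig01  +          1    54   234 TCVEHNYGHMAPELRKYSFPWSAFPGDR...
#> 2 contig01|+1|2 contig01  +          1   351   480 VEVYCYLFVLSPFEVVVPCVVWYLEAGA...
#> ...
```

366 candidate proteins (the two planted ORFs plus every chance stop-free
run ≥ 20 residues). Each row's interval re-translates to its sequence
exactly; the planted rows match the generator's manifest coordinates.

```r
compute_ion_mz("C7H12NO")      # acetyllysine diagnostic ion
#> [1] 126.0913

sm   <- sim_mgf(seed = 1, n_spectra = 100, n_spiked = 23, n_decoys = 5)
kept <- filter_spectra(sm$spectra, builtin_ion_registry())
didar_report(kept)
#> D.I.D.A.R. filter report: 23 / 100 spectra matched (mode = any)
#>   acK              23
#>   HexNAc           23
#>   HexNAc-2H2O      23
```

All 23 spectra spiked within 2 ppm are recovered; the 5 decoys planted at
12 ppm (outside the 5 ppm window) are rejected.

```r
ab  <- sim_abundance(seed = 1, n_proteins = 200, n_metabolites = 50,
                     planted_r = c(0.999, -0.97))
res <- correlate_all(ab$proteins, ab$metabolites)
glance(res)
#> # A tibble: 1 x 5
#>   n_pairs n_defined n_flagged flag_rate p_cutoff
#> 1   10000     10000       817    0.0817     0.05

top_correlates(res, "M0001", "positive", k = 1)
#> # A tibble: 1 x 8
#>   protein_id metabolite_id n_used pearson_r  pearson_p spearman_rho spearman_p
#> 1 P0001      M0001              6     0.999 0.00000150            1          0
```

The planted protein–metabolite pair (true r = 0.999 over the 6 samples) is
the top flagged positive correlate of its metabolite. The overall flag rate
(8.2%) exceeds the 5% cutoff because the flag is the disjunction of two
correlated tests — see the methods vignette
(`vignettes/draftmap-methods.Rmd`) for the calibration discussion.

Each result type has `glance()`/`tidy()` summaries and an `autoplot()`
method (per-ion bar charts, r-vs-p scatter, pooling-plan tiles).

## Command line

`exec/draftmap` wraps the same functions:

```sh
draftmap sixframe  --genome genome.fna --out db.faa --min-len 20
draftmap filter    --in run1.mgf --out run1.didar.mgf --ions acK,HexNAc --ppm 5 --report report.tsv
draftmap annotate  --fasta identified.faa --emapper ids.emapper.annotations --out annotated.faa
draftmap correlate --proteins prot.tsv --metabolites metab.tsv --out corr.tsv
draftmap pool      --fractions 96 --pools 12 --out plan.tsv
```

(`dedup`, `subset`, `chrmap`, and per-command options: see the header of
`exec/draftmap`.)

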