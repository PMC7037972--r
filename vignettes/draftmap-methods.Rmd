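---
title: "Methods: six-frame databases, diagnostic-ion filtering, annotation merging, and protein-metabolite correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: six-frame databases, diagnostic-ion filtering, annotation merging, and protein-metabolite correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(draftmap)
library(tibble)
```

draftmap implements the bespoke computational stages of a proteogenomic
"draft map" pipeline for organisms without an annotated proteome: build a
theoretical protein search space directly from genome sequence, reduce raw
MS/MS peak lists to the spectra that carry diagnostic fragment ions of a
modification of interest, merge ortholog-based functional annotations back
into the protein FASTA, and correlate protein abundances with small-molecule
feature abundances across samples. This vignette records the model behind
each stage, the tunable parameters and their defaults, the numerical
conventions, and the design decisions that were genuinely open.

## Six-frame theoretical protein databases

### Model

With no gene models available, the search space is the set of all
stop-to-stop open reading frames: within each of the six reading frames
(three offsets on each strand), every maximal stop-free run of codons is a
candidate protein. This deliberately over-generates — the database is a
search space for spectral matching, not a gene catalogue — and downstream
identification (by an external search engine, out of scope here) decides
which entries are real. For the same reason ORFs are *not* required to begin
with a start codon by default; `require_start = TRUE` trims each run to its
first methionine for users who want the conservative reading.

### Conventions

* **Coordinates** are 0-based half-open on the forward strand for both
  strands, so `end - start = 3 * length(protein)` always holds and any
  interval can be handed to standard genome-arithmetic tooling unchanged.
  Stop codons are excluded from both the sequence and the interval;
  trailing partial codons (< 3 nt) are discarded.
* **Identifiers** are deterministic:
  `{source_id}|{strand}{frame}|{ordinal}`, the ordinal counting ORFs of one
  (strand, frame) left to right on the forward axis. Re-running the
  translation on the same input reproduces identical ids, which matters
  because these ids anchor every downstream merge.
* **Ambiguity codes**: a codon containing an IUPAC ambiguity base
  translates to the consensus residue when all disambiguations agree
  (`GCN` → `A`) and to `X` otherwise. `X` never terminates an ORF — a
  sequencing ambiguity should not split a candidate protein in two — but
  runs consisting solely of `X` are suppressed as uninformative.
* **min_len** defaults to 20 residues. The cutoff used by the original
  MaxQuant-based translation is unpublished; 20 was chosen once as a
  practical bound — it keeps the database size manageable and sits
  comfortably above the shortest peptides a tryptic search can identify
  (~7 residues), so no identifiable protein is lost to the cutoff. It is
  fully configurable.
* **Codon table** defaults to NCBI table 1 (standard); plastid or
  mitochondrial contigs can be translated with the appropriate table id.

Deduplication (`deduplicate()`) compares exact residue strings — isoleucine
and leucine are distinct residues here, a conservative choice since the mass
spectrometer cannot distinguish them but sequence databases can. The first
occurrence in input order is the representative; member lists preserve input
order, so the operation is a pure partition and is idempotent.

Back-mapping (`map_to_chromosome()`) reports one hit per exact substring
occurrence of a protein in any of a chromosome's six frame translations.
Exact matching is the point: a hit certifies that the genomic locus encodes
the protein verbatim. Proteins shorter than `min_len` (default 20) are not
searched, because short exact matches arise by chance. Chromosome pairing
conventions (hits resolvable only to a homologous pair, not an individual
chromosome) are metadata concerns left to the caller.

## Diagnostic-ion spectral filtering

### Model

HCD fragmentation of modified peptides produces characteristic low-mass
fragments: glycopeptides shed oxonium ions (HexNAc at ~204.087, its
double-water-loss fragment at ~168.066) and acetyllysine-containing peptides
produce an immonium-derived fragment at 126.0913. A spectrum containing such
a peak is evidence that the precursor carried the modification, so filtering
a peak-list file down to those spectra concentrates the search space before
any (expensive) database search runs.

The predicate is: a spectrum contains ion *i* iff some peak satisfies
|observed − target_i| / target_i × 10⁶ ≤ tolerance_i and passes the
intensity floor. Three conventions are pinned down explicitly because they
change results at the margins:

* **ppm denominator** is the theoretical target m/z, not the observed peak;
  the two conventions differ at the fifth decimal and matter at boundary
  offsets.
* **tolerance** defaults to 5 ppm per ion, the conventional accuracy of
  high-resolution MS/MS instruments, overridable per ion.
* **intensity floor** defaults to 0 — any detected peak counts. An optional
  relative floor (`min_rel_intensity`, a fraction of the base peak) is
  provided because chemical noise near oxonium masses is common, but it is
  off by default: whether the original filter applied one is unstated, and
  a floor of zero is the more faithful reading of "exhibits a fragment
  ion".
* **combination mode** defaults to `any` (OR over the requested ions),
  since one diagnostic ion suffices as evidence; `all` is available for
  co-occurrence queries.

Ion targets are computed from elemental composition with
`compute_ion_mz()`: the sum of embedded CODATA/IUPAC monoisotopic atomic
masses minus the electron mass per charge, divided by charge. The electron
correction (~0.00055 u) shifts the fourth decimal place at these masses, so
it is not optional. The built-in registry derives all three default targets
from composition rather than hard-coding literature values; published
integer labels ("168 and 204") are nominal masses, and the registry's exact
values (168.0655, 204.0866) are documented as composition-derived.

### File handling

MGF is the contract format (`BEGIN IONS`/`END IONS` blocks, `PEPMASS`
required, `CHARGE`/`RTINSECONDS`/`TITLE` optional). No installed R package
parses MGF, so the reader and writer live in this package; unknown
`KEY=value` headers are preserved verbatim, and the streaming filter
(`filter_mgf()`) copies matching blocks byte for byte while holding only one
block in memory, so arbitrarily large files can be reduced on a laptop.
Unparseable blocks are an error naming the block by ordinal and title; a
permissive mode (`skip_invalid = TRUE`) counts and drops them instead. mzML
input is not implemented; peak lists arrive as MGF here, and conversion is
better served by dedicated tooling.

## Annotation merging

eggNOG-mapper output rows fall into three categories, and the partition is
exact by construction: `gene_assigned` (a preferred gene name was assigned),
`function_only` (an ortholog hit with a functional description but no gene
name), and `unassigned` (no row for the query, or a row without a passing
ortholog hit). Orthology is never re-scored — whatever passed the mapper's
own thresholds is taken as given.

Merged headers use exactly three `|`-delimited fields,
`{query_id}|{gene}|{description}`, with the literal placeholder
`"gene not found"` standing in for the gene when annotation was by function
only (or absent). The three-field form is the unified format that
search-engine FASTA importers expect; the placeholder keeps the field count
fixed. Records with no annotation at all are retained with the placeholder
and an empty description rather than dropped, so the output FASTA always
has the same cardinality and order as the input and sequences are
byte-identical — merging is a header-only transformation.

Because emapper's column layout has changed across releases and the exact
version used by any given table may be unknown, the parser takes a dialect:
`"v2"` (21-column emapper 2.x layout, the default) or `"v1"` (13-column
2019 web-service layout), or an explicit column map. Duplicate annotations
for one query are an error by default; `keep_best = TRUE` keeps the
smallest e-value row, for tables assembled from several runs.

## Protein-metabolite correlation

### Model

Protein abundances are rolled up from peptide-group quantities by the
arithmetic mean per protein and sample (missing values excluded from the
mean; a cell with no observed peptide group stays missing). Each (protein,
metabolite) pair across the shared, identically-ordered sample set then gets
both a Pearson correlation and a Spearman rank correlation, with two-sided
p-values from the t transform, `t = r·sqrt((n−2)/(1−r²))` on n−2 degrees of
freedom — the behaviour of the standard scientific-computing stacks, and for
Pearson exact under bivariate normality. Spearman uses average ranks for
ties (the tie policy changes rho, so it is stated); its t-transform p-value
is the same large-sample approximation used by `cor.test(exact = FALSE)`.

A pair is *flagged* when either p-value is ≤ the cutoff (default 0.05).
This disjunctive, per-pair rule deliberately applies no multiple-testing
correction: the flag list is a screening device for follow-up, not an
inference, and the cutoff is explicitly arbitrary. Benjamini–Hochberg
adjusted columns are available (`bh = TRUE`) for reference but play no part
in flagging. At n = 6 samples the disjunctive null rate exceeds 5% (two
correlated tests are combined, and the rank-based p is discrete at tiny n);
the test suite estimates that null rate by direct simulation rather than
asserting 5%.

Numerical conventions: missing data are handled pairwise-complete per pair;
pairs with fewer than `min_n = 3` complete samples, or a constant vector,
carry undefined (`NA`) statistics and are never flagged. A correlation of
exactly ±1 yields p = 0 (the t statistic is infinite); bounds `r ∈ [−1, 1]`
are enforced against floating-point drift. Abundances are used on the scale
given — zero and negative values are accepted as numbers — and an optional
`log2` flag transforms first (non-positive values become missing), since no
transformation convention is universal for label-free ratios.

`top_correlates()` ranks one metabolite's partners by descending |r| within
the requested correlation sign, ties broken by ascending Pearson p and then
protein id, so the ranking is total and deterministic. Its parameters are
explicit (direction, k) because published "positive correlate" lists rarely
state their p filter.

Complete matrices take a vectorised path (one cross-product per statistic);
matrices with missing values take a per-pair path. Both routes are tested
against each other and against the reference implementations.

## Fraction pooling

Concatenation pooling assigns collected fraction *i* (0-based) to pool
*i mod n_pools*, so each pool contains every n_pools-th fraction and spans
the whole first-dimension gradient — the standard way to keep pooled
fractions orthogonal to the second separation dimension. With 96 fractions
and 12 pools every pool holds exactly 8 fractions. The phrase "every 8th
sample was concatenated to produce 12 fractions" is arithmetically ambiguous
(a stride of 8 would produce 8 pools of 12); the implementation resolves to
the stated *output* count — 12 pools — and exposes `n_pools` explicitly so
either reading is obtainable.

## Synthetic fixtures: what they emulate and what they do not

All tests run on generated inputs; nothing is downloaded. Each generator is
byte-deterministic under its seed and returns a manifest sufficient to
predict the downstream module's output without re-reading the fixture.

* `sim_genome()` plants stop-flanked ORF cassettes into uniform-random
  background contigs (default 10 kb). Default planted ORF lengths of 30–80
  residues are typical small-protein sizes. Background base composition is
  uniform, so chance ORF length statistics differ from real (GC-skewed)
  genomes; recovery tests therefore assert a superset relation pinned to
  the planted coordinates.
* `sim_mgf()` writes 100-spectrum files of 30–60 background peaks drawn
  from 200–1500 m/z with a ≥ 50 ppm exclusion zone around every registry
  ion, plus planted diagnostic peaks at 2 ppm (in tolerance) and decoys at
  12 ppm (out of tolerance at the 5 ppm default). It makes no attempt to
  simulate fragmentation chemistry, isotope envelopes, or chromatography —
  fixtures exercise the matching contract, not a search engine.
* `sim_annotations()` emits emapper-dialect tables with exact category
  counts; unassigned ids are queried but receive no row, which is how
  queries without a passing hit surface in real output.
* `sim_abundance()` draws features about a positive baseline (1000 ± 100
  latent units) over n = 6 samples — six samples mirroring a six-material
  comparison — and constructs each planted pair by Gram–Schmidt so its
  sample Pearson correlation equals the target *exactly* (r = 1 means zero
  residual noise). Real label-free data adds heteroscedastic,
  intensity-dependent noise and missingness that these fixtures do not
  model.

Passing tests therefore demonstrate that the algorithms honour their
contracts (coordinates, recall of planted signal, partition exactness,
distributional calibration of p-values under normality) — not that any
particular biological dataset would yield any particular count.

## Problem sizes and tolerances in the test suite

The suite compares six-frame output against a brute-force
translate-and-split oracle on sequences up to 10 kb; filters 100-spectrum
MGF fixtures; checks categorization on tables up to the 30,988-id published
proportions; and estimates the null Pearson flag rate on a 100 × 100
feature grid (10⁴ pairs, n = 6), asserting it lies within 99% binomial
bounds of the 0.05 cutoff. Correlation statistics are compared to
`stats::cor.test` at 10⁻⁹ relative tolerance (same formulas, independent
code path) and p-values to 10⁻⁶. These sizes run the whole suite in well
under a minute while keeping every estimate's Monte-Carlo error far smaller
than the asserted bounds.

## Known limitations

* ORF enumeration is exhaustive by design; for large genomes the database
  should be filtered (by `min_len`, `require_start`, or downstream
  identification) before use as a search FASTA.
* Exact back-mapping cannot place proteins spanning splice junctions or
  containing sequencing errors; no inexact matching is provided.
* The MGF dialect requires `PEPMASS`; exotic vendor extensions pass through
  unparsed but unharmed.
* Spearman p-values use the t approximation at all n; an exact permutation
  p for tiny n is not currently implemented.
* The correlation module takes abundance matrices as given; it performs no
  normalisation, batch correction, or missing-value imputation.
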