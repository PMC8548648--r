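---
title: "Models and methods behind mybkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mybkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mybkit` characterizes plant MYB transcription-factor gene families:
repeat detection and classification, duplicate-pair discovery with Ka/Ks
estimation and molecular-clock dating, collinearity chaining, promoter
scanning, and expression analysis. This vignette explains each model, the
tunable parameters and their defaults, the numerical conventions, and what
the synthetic-data generator does and does not emulate.

## Coordinates

All in-memory coordinates are 1-based and inclusive, matching GFF3 and the
wider R/Bioconductor ecosystem, so no conversion happens at the I/O
boundary. Amino-acid repeat coordinates and SSR loci follow the same
convention; widths are `end - start + 1`.

## MYB repeat detection

A MYB repeat is ~52–53 residues with stereotypically spaced aromatic
anchors: R2-type repeats carry three tryptophans spaced 20–21 residues
apart; R3-type repeats carry a phenylalanine (occasionally tryptophan) at
the first anchor and two tryptophans spaced 19 residues apart. The detector
replaces a database-dependent HMM/BLAST screen with a self-contained
two-stage rule:

1. **Anchor candidates.** Every residue triple satisfying an anchor rule
   (allowed residues at the stated spacings) proposes a repeat window.
   `X` never matches an anchor.
2. **Profile score.** The window is scored by the column log-odds
   `sum(log(w[residue, col] / 0.05))` against a position-weight profile
   built from the bundled seed alignment with a Laplace pseudocount
   (`(count + 0.05) / (n + 1)` per column). When a 20-residue spacing is
   observed in an R2-type candidate, one designated non-anchor profile
   column is skipped, so both spacing variants score against a consistent
   set of columns.

The seed alignment (`inst/extdata/myb_seed_alignment_synthetic.faa`) is a
*synthetic* alignment: 12 noisy copies per repeat type of a consensus with
the field-typical anchor architecture. It stands in for a curated domain
alignment, which keeps the package self-contained and the tests exact; the
profile file is versioned data and can be replaced by a profile built from
a real seed alignment without code changes.

The score threshold (25, stored in `inst/extdata/myb_profile.yaml`) was
calibrated once on synthetic positives and negatives: over 2,000 random
300-aa proteins the best anchor-matching window scored at most −62, while
planted repeats scored at least 83. Any threshold in between keeps the
per-protein false-positive rate at or below 1% with a wide margin; 25 was
fixed midway on the log-odds scale.

Overlapping candidates are resolved greedily, best score first, ties broken
by the smaller start — a deterministic rule. Classification is a pure
function of the repeat count and the inter-repeat gaps: `n` adjacent
repeats (every gap ≤ `max_linker`, default 40 aa) give 1R/R2R3/3R/4R for
`n` = 1–4; repeats that violate adjacency, or more than four, give
`atypical`; no repeats gives `none`, which is deliberately distinct from
`atypical`.

Conservation profiles report, per alignment column, the modal residue and
its frequency over *all* sequences (gap characters can never be modal but
stay in the denominator); a column is conserved when the modal frequency
reaches the threshold (default 0.80, inclusive). Raising the threshold can
therefore never increase the conserved-column count.

## Protein descriptors

ProtParam conventions throughout: average (not monoisotopic) residue
masses; GRAVY as the mean Kyte–Doolittle hydropathy; aliphatic index
`X_Ala + 2.9·X_Val + 3.9·(X_Ile + X_Leu)` in mole percent; instability
index `(10/L)·Σ DIWV(dipeptide)` with the published dipeptide weight table
shipped as `inst/extdata/diwv.tsv` (for a dipeptide this evaluates to
5 × its DIWV entry); proteins are called unstable above 40. The
isoelectric point uses the Bjellqvist pKa set with position-specific
terminal values, solved by bisection on pH 0–14 to a net charge below
1e-4; the test suite checks it against a brute-force charge scan on a
1e-4 pH grid.

## Duplicate pairs, NG86 and dating

**Screen.** All protein pairs are aligned locally (Smith–Waterman,
BLOSUM62, gap open 11 / extend 1). Identity is counted over aligned
residue columns (gaps excluded); coverage is the aligned fraction of the
*shorter* protein — the stricter symmetric reading of "query coverage".
Pairs pass with identity > 0.75 and coverage > 0.75 (both strict);
cross-genome screens conventionally tighten coverage to 0.80. Note that a
duplicate pair evolved at ω = 0.2 to Ks = 0.5 has an expected amino-acid
identity around 0.80, so such pairs sit near the screen boundary by
construction — the screen, not the estimator, decides them.

**Tandem vs segmental.** A pair is tandem iff both genes share a
chromosome and the gap between their nearest span ends is strictly below
100 kb; everything else — including a gap of exactly 100 kb and all
cross-chromosome pairs — is segmental.

**NG86.** Synonymous sites are counted fractionally per codon; pathway
counting averages the synonymous/nonsynonymous step classification over
all orderings of the differing positions with equal weights. Two
conventions are fixed and used consistently in both the implementation and
the test oracle:

* Changes to stop codons are excluded from *both* site counting (the
  synonymous fraction per position is taken over the non-stop
  alternatives; each codon still contributes three sites) and pathway
  counting (orderings that pass through a stop are dropped; codon pairs
  with no stop-free pathway are skipped and reported in `n_skipped`).
  Excluding stops on one side but not the other leaves a systematic Ka
  deficit, because no evolutionary process can realize substitutions into
  stop codons that sites would nonetheless be charged for.
* Proportions are Jukes–Cantor corrected,
  `K = -3/4 · log(1 - 4p/3)`; `p ≥ 0.75` is reported as saturated (`NA`),
  and ω is `NA` whenever Ks is 0 or saturated.

Divergence time is `T = Ks / (2λ)` in million years with
λ = 6.96 × 10⁻⁹ synonymous substitutions per site per year, the clock rate
conventionally assumed for Solanaceae nuclear genes. Selection is
classified strictly by default — ω < 1 purifying, ω > 1 positive, exactly
1 neutral — because that is the textbook rule the ratio is interpreted
with; `evol_config(neutral_band = c(0.95, 1.05))` widens the neutral call
to a tolerance window when estimation noise warrants it.

**QTL co-localization** uses full containment of the gene span within the
QTL interval ("located within"); `any_overlap = TRUE` relaxes to a single
shared base.

## Codon evolution in the generator

`evolve_duplicate_pair()` evolves one copy of a CDS by uniform
single-nucleotide proposals. Proposals creating stops are rejected;
synonymous proposals are accepted with probability `min(1, 1/ω)` and
nonsynonymous ones with `min(1, ω)`, so the realized
nonsynonymous/synonymous rate ratio per site equals ω for any ω ≥ 0 —
the symmetric generalization needed for ω > 1, where acceptance
probabilities alone cannot exceed 1. Evolution stops when the *observed*
Jukes–Cantor-corrected synonymous divergence between the two current
sequences (tracked incrementally with the NG86 tables) reaches the
target, so the realized Ks matches the target by construction rather than
only in expectation. Targets at or above 1.0 are refused: close to
synonymous saturation the stopping rule becomes unreliable. The test
suite verifies that NG86 run on pairs generated this way recovers the
planted ω (median within 15% over ω ∈ {0.1, 0.5, 1, 2} at Ks ≈ 0.4,
300 codons); the residual downward bias at ω = 2 (~10%) is the familiar
NG86 compression at high nonsynonymous divergence.

## Synteny chaining

Anchors are homolog pairs with ordinal gene ranks per chromosome (by start
coordinate). Consecutive genes of one genome hitting the same partner
(tandem arrays) collapse to their best-scoring anchor first. Within each
chromosome pair, maximal-score chains are found by dynamic programming
over rank-sorted anchors, separately for forward (both ranks strictly
increasing) and reversed (partner rank strictly decreasing) orientations,
with consecutive members at most `max_rank_gap` (default 25) ranks apart
in both genomes and chain score `anchors − gap_penalty · skipped_ranks`
(default penalty 0.05). Chains are extracted best score first; every
anchor belongs to at most one segment; chains below `min_anchors`
(default 5) are dropped. The defaults are conventional collinearity
settings, not estimates.

One boundary effect is inherent to score-maximal chaining with single-use
anchors: a forward chain that spans an interior inversion always absorbs
exactly one anchor of the inverted block (the extra anchor outweighs the
gap saving for any positive gap penalty, and the reversed interior ranks
admit at most one such member). Planted-block recovery is therefore
defined as: a segment of the correct orientation whose anchors all lie in
the block and cover all but at most one of its genes. On noise-free
synthetic genome pairs recovery under this definition is exact, and the
chainer's best-chain score equals an exhaustive subset-enumeration oracle
on small instances.

## SSRs and cis-elements

`find_ssrs()` reports all maximal perfect tandem runs whose period-minimal
motif has length 2–6 and that contain at least six full copies (partial
trailing copies are trimmed, mononucleotide runs excluded by the 2-nt
minimum). Period minimality suppresses sub-period duplicates — an `(AT)₆`
run is AT×6, never ATAT×3 — while genuinely different periods may overlap
and are all reported. `N` breaks runs and never appears inside a locus.
The scanner is run-length based (linear per period) and is checked against
a quadratic brute-force scanner on random sequences. Ties in the summary
(modal motif, longest locus) break to the lexicographically smallest
motif — a deterministic choice.

Upstream regions are the 1,500 bases immediately 5′ of the gene start on
the coding strand (reverse-complemented for minus-strand genes), clipped
and flagged at chromosome edges. Cis-element scanning matches IUPAC
consensus strings exactly on both strands, reporting minus-strand hits at
the forward coordinate of the match start; the bundled dictionary
(`inst/extdata/cis_elements.yaml`) is an editable, consensus-based
catalog in the style of plant promoter-element databases — it is a
reimplementation vehicle, not a copy of any proprietary matrix library.

## Expression

**TMM.** The reference sample is the one whose upper quartile of
library-scaled counts is closest to the mean upper quartile. For each
sample, genes with a zero count in either the sample or the reference are
dropped; the top and bottom 30% by M (log ratio) and 5% by A (average log
expression) are trimmed; the factor is the precision-weighted mean of the
remaining M-values, and factors are renormalized to geometric mean 1.
Weights are `(1-p)/p` per sample on the library-scaled proportion scale
`p = count/library`: these are the usual binomial precision weights but,
unlike count-scale weights, they are exactly invariant when a whole
library is rescaled, which makes the factors scale-invariant to machine
precision (the property the tests assert at 1e-6). Agreement with an
independent TMM implementation is verified at the 1% level.

**FPKM** is `count · 10⁹ / (effective library · length)` with the
effective library being the raw library size times the TMM factor.

**Differential expression** is a per-gene negative-binomial
likelihood-ratio test with effective library sizes as offsets. The
dispersion is a method-of-moments estimate from within-group variances of
normalized counts, shrunk 50% toward the all-gene median — a deliberately
simple, documented stand-in for quasi-likelihood machinery: the moment
estimate is unstable at n = 3 and the median shrinkage stabilizes it
while leaving genuine signal intact. P-values come from the χ²₁ LRT and
are Benjamini–Hochberg adjusted; a gene is significant iff adjusted
p < 0.01 *and* |log2FC| > log2(1.5), the symmetric reading of
"fold change > 1.5" (both directions are reported). The reported log2FC is
`log2((m₂ + 0.5)/(m₁ + 0.5))` on normalized group means; the 0.5
pseudocount keeps all-zero groups finite. Validation is property-based —
null control (mean fraction of adjusted p < 0.01 at or below 0.01 over 50
null simulations) and power (mean recall ≥ 0.8 of planted 4-fold changes
at 3 vs 3 replicates, dispersion 0.1) — rather than numeric equality with
any particular implementation.

**Co-expression** clusters `log2(FPKM + 1)` profiles by average-linkage
hierarchical clustering on `1 − Pearson` distance, cut at `k` clusters or
height `h` (the cluster count is a user choice; no criterion is imposed).
Genes with zero profile variance, for which Pearson correlation is
undefined, are set aside in a dedicated `constant` cluster (id 0) before
clustering.

**qPCR.** `delta_delta_ct()` averages replicate Ct values per gene and
condition, forms ΔCt against the reference gene, subtracts the calibrator
condition's ΔCt, and reports `2^−ΔΔCt`; a two-sided two-sample t-test on
replicate ΔCt values against the calibrator gives the p-value. Shifting
all Ct values by a constant leaves the result unchanged.

## The synthetic-data generator

`simulate_family_genome()` emulates the statistical structure each
downstream stage assumes: chromosomes assembled from random intergenic
spacers and CDS-shaped genes (a strand-aware mix, ~70% plus strand); MYB
proteins of the requested classes with repeats sampled from the bundled
profile (1R is emitted as a single R3-type repeat, 3R/4R reuse R2-type
repeats ahead of the final R3-type one — a simplification, since only two
repeat profiles are bundled); duplicate pairs evolved at chosen ω and Ks
and placed tandem (same chromosome, small gap) or segmental (another
chromosome, or ≥ 150 kb away when only one chromosome exists); SSR
plantings inserted with flanking breaker bases so the planted copy number
is exact (genic plantings go into an intron, keeping the CDS–protein
closure intact); a partner gene order with planted inversions and
translocations for synteny tests; and a negative-binomial count matrix
with planted fold changes.

Determinism: one root seed; every component draws from its own stream
derived by a fixed label (`child_seed()`), so a fixed configuration gives
byte-identical FASTA/GFF3/TSV output and truth tables.

Expression defaults model a three-stage (EG/MG/Br), three-replicate fruit
development design: gene means log-normal (meanlog = log 100,
sdlog = 1.2, a typical RNA-seq abundance spread), sequencing depths
log-uniform over a ±3-fold range (wide enough to make normalization do
real work), NB dispersion 0.1 (a common bulk-RNA-seq scale), planted
changes applied between the first and second stage. Tryptophan is excluded
from simulated flanks and linkers so planted anchors are unambiguous —
real proteins do not offer that courtesy, which is one reason passing
round-trip tests bound but do not guarantee performance on real data.

What the generator does **not** emulate: introns beyond the single
SSR-carrying one, UTRs and alternative isoforms, sequencing reads and
their error models, compound or imperfect SSRs, codon-usage bias,
rate variation across sites, and gene conversion between duplicates.
Results on real genomes depend on upstream annotation quality in ways the
synthetic tests cannot measure.

## Interfaces

The package's functions, this vignette and the test suite are the
interface: inputs are tibbles and named sequence vectors;
`write_genome_package()` emits FASTA/GFF3/TSV for interoperability, and
`scripts/acceptance.R` is a worked, scriptable entry point. No standalone
shell tool is shipped — the intended user drives analyses from R.

## Known limitations

* NG86 is the only Ka/Ks model; maximum-likelihood codon models and
  transition/transversion-aware counting are out of scope, and exact
  numeric replication of published Ka/Ks values from sequences is not
  claimed — only the ratio and dating arithmetic from reported values.
* The repeat profile is synthetic; on real proteomes a profile built from
  a curated seed alignment should replace it (the YAML + FASTA data files
  are the swap point).
* The DE test is a simple NB-LRT; with very small counts or many zeros a
  quasi-likelihood or exact framework is preferable.
* The chainer reports disjoint segments (each anchor used once); deeply
  nested or overlapping duplications are summarized by their best chain
  only.
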