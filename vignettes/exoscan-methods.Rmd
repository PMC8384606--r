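---
title: "Methods: donor introgression scanning and panel phenomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: donor introgression scanning and panel phenomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exoscan)
```

This vignette documents the models and procedures `exoscan` implements,
the assumptions behind them, the tunable parameters, the numerical
decisions taken where the design was genuinely open, and what the
synthetic-data generator does and does not emulate.

## Scope and interface

`exoscan` is an analysis package: the exported functions, chained by
`run_pipeline()`, are the interface, and `scripts/acceptance.R` is the
reproducibility entry point. No shell tool is shipped; users drive the
pipeline from R.

## Genotype preparation

The pipeline's central object is a loci x samples call matrix of
biallelic SNPs (`genotype_matrix`), with calls coded homozygous
reference / heterozygous / homozygous alternate / missing, plus an
undesignated "no-call" state for individuals in which no alternate
allele was observed. Three rules prepare it:

1. **Reference designation** (`apply_reference_call_rule`): a no-call
   with mapping depth >= `min_depth` (default 5x) becomes homozygous
   reference; below that it is missing. The rule only ever touches
   no-calls. Depth must be present wherever the rule needs it; the
   function errors with the offending (sample, locus) pairs otherwise.
2. **Varietal masking** (`mask_varietal_snps`): loci matching a mask
   entry in chromosome, position *and* alternate allele are removed; the
   same position with a different allele is kept. The mask represents an
   external call set of germplasm-vs-reference varietal variation, which
   would otherwise inflate identity-by-state matches to donor taxa.
3. **Locus filtering** (`filter_loci`): keeps loci with missing fraction
   strictly below `max_missing` (default 0.10, denominator = all panel
   samples) and minor allele frequency at least `min_maf` (default
   0.05). MAF is allele-based (hom-alt = 2 alternate alleles, het = 1)
   over non-missing calls, which degenerates correctly on the
   homozygous calls this panel type produces. All-missing loci are
   removed without dividing by zero. The >= 0.05 inclusive boundary is
   deliberate; both thresholds are arguments.

Order of operations: designation, then masking, then filtering.
Introgression scanning runs on designated + masked *per-line* calls,
before the shared-locus MAF filter — per-line donor attribution should
see every SNP a line carries, while the MAF filter serves the
panel-level population-genetic stages (density tracks, Fst).

## Introgression scanning

For one line and one donor variant set (`donor_snpset`: the
reference-relative SNPs of the donor taxon, mask-subtracted):

* homozygous-alternate SNPs are counted in fixed 500-kbp bins, with the
  subset matching the donor set in position and allele counted
  separately (`bin_match_profile`);
* the elite baseline is the arithmetic mean of the per-line bin counts
  across the elite subpopulation (`elite_baseline`);
* a bin is classified donor-derived when the line's count is at least
  `fold` (default 5) times the baseline (`classify_donor_bins`).

Two guards make the fold rule well-defined in SNP-poor regions: the
baseline is floored at `min_baseline` (default 1 SNP/bin, since the rule
is undefined at baseline 0), and a classified bin must hold at least
`min_count` SNPs (default 10). Without the floor, a D-subgenome bin with
an elite mean near 4–5 SNPs could be classified off a handful of noise
SNPs. Classification uses the *total* bin count against the baseline;
the donor-match proportion is reported per segment as supporting
evidence, not applied as a filter (an alternative `use_matching` mode
classifies on matching counts instead).

Maximal runs of donor bins merge into segments (`merge_segments`);
`max_gap_bins` defaults to 0 — observed long contiguous introgressions
should emerge from the data, not from gap bridging. Gap bins, when
allowed, are included in the span but counted. Donor fractions are exact
segment arithmetic over the subgenome length; the panel union
de-duplicates bins across lines and length-weights truncated terminal
bins so chromosome ends are not overcounted. The dilution expectation
for a line n crosses past the primary synthetic is 100 x 0.5^n percent
(`theoretical_contribution`). The same machinery serves alien donors
(rye, *T. ponticum*) on any subgenome via `detect_alien`.

**Recovery evaluation.** `recovery_stats` compares classified bins with
truth segments at bin level. Truth bins are bins at least half covered
by a truth segment, and a one-bin boundary tolerance is applied
symmetrically: crossover breakpoints are continuous while the scan is
bin-quantised, so segment edges are only defined to one bin. Donor
fractions are compared without tolerance.

## Diversity statistics

**Counts and contrasts.** Per-line SNP counts (`per_line_snp_counts`)
count homozygous-alternate calls only — the quantity of interest is
homozygous SNPs per line; heterozygous calls are excluded with a
message. Subgenomes are inferred from the chromosome-name suffix
(…A/…B/…D), with an explicit override mapping for non-standard names.
The contrast statistic is 100 x (exotic − elite)/elite on group means,
reported to 2 decimals, NA when the elite mean is zero.

**Windowed Fst.** The Hudson estimator, aggregated within 500-kbp
windows as a ratio of sums of per-SNP numerators and denominators
(robust to sample-size imbalance across SNPs). One estimator is
implemented; it satisfies both calibration controls (null pseudo-split
and fixed-difference endpoint), and offering a second would double the
surface without changing any conclusion. Two details matter:

* *Inbred haplotype counting.* The panel consists of inbred lines, so
  each line contributes **one** independent haplotype to allele
  frequencies and to the finite-sample correction terms
  p(1−p)/(n−1). Counting two perfectly correlated alleles per line
  undercorrects and biases the null upward by several hundredths —
  enough to swamp a "negligibly small" control.
* *Degenerate windows.* SNPs informative in fewer than two lines per
  group are excluded; windows whose denominator sum is zero (no
  polymorphism) carry NA, never 0. Reported values are clipped to
  [0, 1] with the raw value retained.

`pseudo_split_control` halves the elite group at a given seed and
recomputes windowed Fst: a homogeneous panel should give a genome-wide
mean within noise of zero.

**Evanno ΔK.** For replicate clustering log-likelihoods L(K) at
consecutive K, ΔK(K) = mean over replicates of |L(K+1) − 2L(K) + L(K−1)|
divided by sd of L(K). Replicates are paired by identifier across K;
at least 3 consecutive K and 2 replicates are required, and zero
replicate variance is an error rather than an infinite statistic.

## Phenomics

**Index registry.** Seventeen reflectance indices over bands between
415 and 1722 nm, evaluated exactly as registered. Wavelength lookup is
nearest-neighbour within 1 nm (field spectroradiometers resample to a
1-nm grid) with linear interpolation for coarser grids. A near-zero
denominator (|den| < 1e−9) returns NA with a warning — PSRI's
R531 − R570 term can genuinely vanish. SIPI is implemented as
(R800 − R435)/(R415 + R435), the form this index set uses, although much
of the literature uses (R800 − R445)/(R800 − R680); the latter is
available via `sipi_variant = "literature"`. NDMI likewise follows the
registered 1649/1722 nm form. Normalized-difference indices are
antisymmetric under band swap and pure-ratio indices are scale
invariant; EVI's +1 soil term breaks scale invariance, which the test
suite documents rather than hides.

**Heritability.** Variance components come from the balanced two-way
genotype x environment ANOVA with replicates, by expected mean squares:
σ²ε = MS_error, σ²ge = (MS_GE − MS_error)/r, σ²g = (MS_G − MS_GE)/(re),
each floored at zero, then H² = σ²g/(σ²g + σ²ge/e + σ²ε/(re)).
EMS/method-of-moments was chosen over REML because it is closed-form and
directly testable against hand computation on group means; unbalanced
tables are rejected with an explanatory error instead of being silently
approximated. The replicate count r is a design property of the
measurement (agronomic traits vs paired spectral readings), so it can be
supplied explicitly when it differs from what the table suggests.
Classes: low < 0.30 <= medium < 0.60 <= high.

## The synthetic-data generator

`simulate_panel` emulates the study conditions the pipeline targets:

* **Layout:** 9 chromosomes (3 per subgenome), 55–100 Mbp each — large
  enough for multi-block introgressions, small enough that the full
  default panel (20 elite + 10 exotic lines, ~50,000 loci) simulates and
  scans in seconds.
* **Background:** per-line homozygous SNP densities of 16/25/9 SNPs/Mbp
  on A/B/D, segregating at carrier frequency 0.3 — the D subgenome is
  the bottlenecked, SNP-poor one.
* **Donor blocks:** each exotic line's pedigree is simulated as
  `n_crosses` (2–6) recombination rounds, each drawing 1–2 uniform
  crossovers per chromosome and keeping donor intervals on the
  transmitted haplotype with segment-wise probability 1/2. This
  reproduces both the 0.5^n dilution law and realistic block structure.
  Realized fractions are clipped into `donor_fraction_range` (default
  0.5–43% of the D subgenome) with a warning when the pedigree cannot
  reach the range. Inside its truth segments a line carries *every*
  donor-set SNP (90 SNPs/Mbp, i.e. 10x the elite D density); donor-set
  SNPs never occur outside truth segments.
* **Varietal noise:** scattered panel-monomorphic SNPs (2/Mbp) plus
  clustered varietal haplotype blocks (8 blocks of 2 Mbp at 90 SNPs/Mbp)
  segregating at 8% carrier frequency. The clustered blocks are what
  makes masking load-bearing: panel-monomorphic noise raises exotic bins
  and the elite baseline equally and cancels out of the fold rule,
  whereas a low-frequency varietal haplotype in one exotic line mimics a
  donor block exactly until the mask removes it. The mask VCF covers all
  varietal positions, as an externally derived varietal call set would.
* **Missingness and depth:** i.i.d. missingness (default 5%) expressed
  through the depth field: missing calls get depth 0–4, observed calls
  5 + Poisson(15), so the designation rule is exercised end to end.
  All genotypes are homozygous by default (`het_rate = 0`), matching a
  homozygous-call analysis; heterozygotes exist only as an error-path
  fixture. Alien donors use a higher divergence rate (250 SNPs/Mbp)
  since rye and *T. ponticum* are far more diverged than the D-lineage
  donor and their blocks sit on the denser A/B backgrounds.

`simulate_spectra` builds reflectance from a smooth leaf-like baseline
with Gaussian absorption features at 675/430 nm (chlorophyll), 490 nm
(carotenoid) and 1450/1930 nm (water), so higher pigment truth lowers
the associated bands monotonically. `simulate_traits` draws genotype,
genotype-x-year and error effects from centred normals with the
configured variances — the exact generative model the EMS estimator
assumes.

**What the generator does not emulate:** read-level sequencing error,
linkage disequilibrium beyond block structure, selection, real varietal
haplotype sharing structure, chromosome-scale recombination-rate
variation, or radiative-transfer leaf optics. Passing tests demonstrate
that the implementation computes its statistics correctly under the
stated model, not that the model captures every property of real
capture data.

## Determinism and problem sizes

Every generator is seeded and deterministic: identical seeds give
byte-identical files. Default test and acceptance runs use the 30-line
panel (~50k loci, seconds per scan), 100 spectra, and 150–500 genotypes
for trait recovery — sizes chosen so the full suite exercises every
stage at meaningful statistical resolution while remaining quick to run.

## Known limitations

* The fold rule classifies on total bin counts, so any 5-fold density
  excess — whatever its origin — is called donor-derived; the reported
  match proportion is the interpretive safeguard.
* Segment boundaries are bin-quantised (500 kbp); sub-bin introgressions
  can be missed when they cover less than roughly half a bin.
* EMS heritability requires balance; REML for unbalanced designs is
  deliberately out of scope.
* The Fst implementation assumes inbred material; for outbred diploid
  panels the haploid allele counting would need revisiting.
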