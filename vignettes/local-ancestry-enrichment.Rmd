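---
title: "Methods: local-ancestry summaries, proximity search, and enrichment testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: local-ancestry summaries, proximity search, and enrichment testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixlocus)
```

# Scope

`admixlocus` post-processes haplotype-level local-ancestry calls for
admixed cohorts. It does not run phasing or local-ancestry inference
(LAI); those are upstream tools whose output files it consumes. Its three
analysis stages — per-variant cohort ancestry summaries, genetic-distance
proximity ("bracket") search between SNP sets, and dominant-ancestry
enrichment testing against random-control panels — mirror the workflow
used in admixture-aware pharmacogenomic studies of Caribbean Hispanic
cohorts, where the reference ancestries are Iberian (IBS), Yoruba (YRI)
and Native American (NA).

# The ancestry summary model

At a variant, an LAI tool assigns each haplotype a posterior vector over
the K ancestries. We define a sample's diploid ancestry as the arithmetic
mean of its two haplotype vectors, and the cohort average as the
unweighted mean over included samples. Because every sample is diploid,
averaging over samples and averaging over haplotypes coincide; we fix the
per-sample formulation because it generalizes to designs where samples
must be weighted equally even if haplotype data are partially missing
(such designs are rejected by the reader rather than silently
reweighted: a sample missing one haplotype is a consistency error).

Validity invariants enforced throughout: every posterior vector lies in
the simplex (each entry in [0, 1], sum 1 within tolerance), cM locations
are non-decreasing within a chromosome, and the combined table is ordered
chromosome-major (autosomes numerically, then X) and by cM within a
chromosome.

## File dialect

The on-disk dialect is RFMix-v1-shaped: per chromosome a forward–backward
file (one row per variant, `n_haplotypes x K` probabilities,
haplotype-major), a locations file (one cM per line), a Viterbi file
(hard codes 1..K), and a cohort sample list whose order defines the
haplotype columns (two per sample, `id.0`/`id.1`). Published descriptions
of this family of formats leave details unstated, so this package *fixes*
a dialect and documents it so its simulator and readers agree bit-exactly;
it is not certified against RFMix binaries, and RFMix-v2 `.fb.tsv` /
`.msp.tsv` support is future work. Two pragmatic extensions:

* a headerless `chrN.snp_info` sidecar (rsid, bp position), because the
  combined ancestry table needs variant identifiers and the locations
  file is fixed at one cM per line;
* readers take an optional `cohort` argument naming the file's full
  column order, so a sample subset can be extracted; restriction composes
  (restricting twice equals restricting once to the final subset).

Probabilities are written in fixed notation with six decimals, making
write→read round trips lossless to 1e-6 per probability. Rows whose
probabilities sum outside 1 ± 1e-4 are an error by default — upstream
corruption should surface, not be hidden — with renormalization available
only behind an explicit flag.

# Genetic coordinates

Proximity is measured in centimorgans, the scale on which recombination —
and hence co-inheritance — is uniform. When an input catalog lacks cM, a
monotone piecewise-linear genetic map (3-column text: chrom, bp, cM)
interpolates it; outside the anchor range we extrapolate at the terminal
inter-anchor rate and clamp at 0 cM. Interpolation is exact at anchors
and non-decreasing in position. A fallback uniform 1 cM/Mb map is
provided for demonstrations and simulations and announces itself via
`message()`, since real analyses should use the cM coordinates produced
upstream.

# Bracket search

`bracket_search(A, B, window_cm)` reports every unordered same-chromosome
pair with `|cm_b − cm_a| ≤ window` exactly once. Choices made where the
convention was open:

* **Closed boundary.** A pair exactly at the window edge counts. For a
  co-localization claim this is the conservative reading of "±0.5 cM".
* **Same chromosome only.** cM coordinates are per-chromosome; distance
  across chromosomes is undefined, not infinite.
* **No self-pairs; mirrored duplicates collapse.** When the two sets
  overlap, (x, y) and (y, x) are one pair, and x is never paired with
  itself.
* **Determinism.** Output is sorted by chromosome, then `cm_a`, `cm_b`,
  rsids.

The production implementation sorts each chromosome by cM and sweeps a
two-pointer window, O(n log n + pairs); the O(|A||B|) double loop is kept
as `brute_force_pairs()` and the two are cross-checked on hundreds of
random instances in the test suite.

# Enrichment testing

A locus is *enriched* for an ancestry when its cohort-average proportion
is **strictly greater** than the threshold (default 0.50); loci with no
ancestry above threshold are *unclassified*. With a threshold ≥ 0.5 the
classes are disjoint, so counts partition the loci. The strict inequality
is deliberate: published panels contain loci sitting exactly at 0.50, and
a reproducible rule must decide the boundary one way; strictly-greater is
the choice that treats "half the cohort's alleles" as not yet enriched.
Published tables round proportions to two decimals, so the row-sum sanity
check tolerates 0.02 there (internally computed summaries meet 1e-6).

Random-control panels are drawn by seeded permutation of the universe of
summarized variants after removing the targets, matched by rsid *or* by
(chromosome, position) — exclusion lists in practice carry either. The
draw is uniform (verified empirically in the tests) and reproducible
given the seed.

Target and control class profiles form a 2×C table (ancestries plus
unclassified; all-zero columns dropped). Pearson's chi-square (no
continuity correction) is used when all expected cells exceed 5,
otherwise Fisher's exact test — exact for 2×2 and by the exhaustive
network algorithm for larger tables, falling back to Monte Carlo with a
fixed internal seed only if the exact computation exceeds its workspace.
A table that collapses to a single class carries no evidence of
association and returns p = 1; an all-zero table is a degenerate-input
error.

# The synthetic cohort generator

## What it emulates

A single admixture pulse `g` generations ago: per haplotype and
chromosome of genetic length `L` cM, the number of ancestry breakpoints
is `Poisson(gL/100)` with breakpoints uniform on `[0, L]`, and each
segment's ancestry is drawn iid `Categorical(mix)`. SNPs sit at the
midpoints of a uniform cM grid (midpoints keep every variant strictly
inside `(0, L)` and off the 0 cM edge), with bp positions from the
fallback 1 cM/Mb map so the genetic-map and proximity stages are
exercised consistently. Posteriors put `1 − ε` on the true ancestry and
`ε/(K−1)` elsewhere; `ε < 0.5` keeps the argmax equal to the truth, so
the emitted Viterbi file is exactly the truth-track argmax. All
randomness flows from one master seed through a counter-based splitter,
so every emitted file is a pure function of the parameters.

Defaults state the emulated study cohort: 510 diploid samples, three-way
IBS/YRI/NA admixture with mixing (0.20, 0.25, 0.55), ten generations
since admixture, ε = 0.02, one 100 cM chromosome with 1000 SNPs.

"Risk loci" are injected as *spikes*: inside `[cm_start, cm_end]` the
focal ancestry's segment probability is boosted to `b` (the others
rescaled proportionally), and the interval edges are inserted as
breakpoints so no segment straddles the boundary.

## What it does not emulate

* **No shared drift or pedigree.** Haplotypes are independent, so the
  cohort-average ancestry at a locus concentrates around the mixing
  proportions with sampling standard deviation
  `sqrt(p(1−p)/n_haplotypes)`. Real cohorts descend from a finite
  founding population and share tracts, producing far larger
  locus-to-locus dispersion (in the published random panel the
  dominant-ancestry proportion ranges roughly 0.10–0.94 across loci —
  an effective haplotype count of single digits). A green simulator test
  therefore validates the *computation*, not the demographic realism of
  locus-level variability.
* **No linkage disequilibrium within ancestries, no genotypes or
  sequences**, and no reference panels suitable for actually running an
  LAI tool.

## Estimator notes

`recover_mixing()` is the genome-wide mean of per-variant averages. Its
noise-induced bias is at most `ε·(1 − K·mix_k/(K−1))` per component
(≤ 0.007 at the defaults) — small enough that no deconvolution is
attempted. `mean_tract_length()` averages each haplotype's mean segment
length and then averages over haplotypes: for `N ~ Poisson(λ)` breakpoints
the per-haplotype mean has expectation `L(1−e^{−λ})/λ ≈ 100/g`, whereas
the pooled total-length/total-segments ratio is `L/(λ+1)`, noticeably
biased low for small `λ` (16.7 vs 20 cM at g = 5). Tracts are the
generated inter-breakpoint segments; same-ancestry neighbours are not
merged, matching the Poisson-thinning definition under which the 100/g
rule holds.

# The study replica and its calibration

`run_study()` chains the stages (simulate or ingest → ancestry table →
target lookup → random controls → bracket search → enrichment report)
from a JSON config, writing text-only outputs and a deterministic run
log; reruns with the same config are byte-identical. In simulate mode the
cohort is *written to disk and read back* through the same readers used
for real data, so both modes share one code path and agree exactly.
(JSON is the canonical config format; YAML is accepted when the `yaml`
package is installed. Note that a YAML `NA` must be quoted to remain the
ancestry label rather than a missing value.)

The test suite validates detection power with a fixed experimental world:
50 samples, one 100 cM chromosome, 200 SNPs, mixing (0.35, 0.35, 0.30),
a spike boosting NA to 0.9 over a 5 cM window (10 grid SNPs — the
targets) against 60 random controls. Spiked replicates reject at p < 0.05
essentially always. The matching *null* calibration — unspiked targets
drawn from the same distribution as controls rejecting at the nominal 5%
— is **not** met in this world, and the corresponding test is left
failing rather than adjusted: with 100 independent haplotypes no
component's cohort average strays above 0.50, every locus is
unclassified, the 2×C table collapses to one column, and the test
returns p = 1 (observed type-I rate 0/200). This is a structural
consequence of the independent-haplotype mosaic at cohort scale (see
"What it does not emulate"), compounded by the conservatism of exact
conditional tests on sparse tables, not an implementation defect. The
test calibration that *is* attainable — class counts drawn multinomially
at the empirical class fractions of the published random panel
(25/20/2/13 of 60), 10 targets vs 60 controls — yields an empirical
type-I rate of 0.039 over 1000 replicates, inside the 0.05 ± 0.02 band,
and is asserted in the unit suite.

# Parameters at a glance

| Parameter | Default | Units | Why |
|---|---|---|---|
| `window_cm` | 0.5 | cM | the co-localization window; closed boundary |
| `threshold` | 0.50 | proportion | dominant-ancestry cutoff; strictly greater |
| `n_random` | 60 | SNPs | control panel size matching the study design |
| `mix` | (0.20, 0.25, 0.55) | proportions | IBS/YRI/NA cohort-scale mixing |
| `generations` | 10 | generations | recent admixture; mean tract 10 cM |
| `posterior_noise` | 0.02 | probability | near-hard LAI calls |
| `n_samples` | 510 | individuals | emulated cohort size |
| row-sum tolerance | 1e-4 read / 0.02 tables | — | file rounding vs 2-dp published tables |

# Known limitations

* Proximity requires cM for every record; catalogs lacking a genetic map
  cannot be bracket-searched (the uniform fallback is a demonstration
  device, not a substitute for a real map).
* The exclusion-aware random draw treats the summarized variants as the
  sampling universe; ascertainment of that universe (array content,
  reference-panel coverage) is inherited, not modelled.
* Fisher's exact test on sparse 2×C tables is conservative; reported
  p-values are valid but can understate evidence at these panel sizes.
* No multiple-testing correction across ancestries is applied: one
  omnibus table per comparison, by design.
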