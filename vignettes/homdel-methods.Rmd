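---
title: "Methods: homozygosity, biallelic-deletion burden and regulatory enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homozygosity, biallelic-deletion burden and regulatory enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`homdel` analyzes homozygous (copy-number-zero, CNV0) deletions in
consanguineous families: it measures autozygosity from SNP-array genotypes,
builds consensus CNV calls across multiple calling algorithms, tests
case/control carrier burden, and asks whether the surviving deletions
coincide with regulatory annotation more often than random placement would
predict. This vignette documents the models, the tunable parameters and
their defaults, the numerical conventions, and what the synthetic-data
generator does and does not emulate.

## Coordinates and core containers

All genomic intervals are tibbles (`chrom`, `start`, `end`) in 0-based
half-open coordinates; overlap means at least one shared base, so
book-ended intervals do not touch. Human-readable exports are the place to
convert to 1-based starts. Chromosome names are matched exactly after an
optional "chr"-prefix normalization (`normalize_chrom()`).

Genetic distance drives every homozygosity computation. A `genetic_map` is
a set of (bp, cM) anchors per chromosome; queries interpolate linearly
between anchors and clamp to the terminal cM values outside the anchored
range. Clamping (rather than extrapolating) guarantees that sparse maps can
never produce negative genetic lengths.

Intensity tracks are dense per-bin score vectors (default 25 bp bins, the
resolution of ENCODE-style signal files). bedGraph records not aligned to
the bin grid are resampled by per-bin maximum — the conservative choice for
peak calling, since a bin is kept whenever any covering record reaches the
threshold. Chromatin-state tracks assign exactly one label per 200 bp bin
from a closed alphabet (default: the 15 mnemonic states of the Roadmap
ChromHMM model); bins uncovered by a segmentation take the quiescent state.

## Runs of homozygosity

`call_roh()` implements a sliding-window rule: a window of `window_snps`
consecutive markers (default 100, step 1) qualifies when the homozygous
fraction among its *non-missing* calls is at least `min_hom_frac` (default
0.98). Missing genotypes drop out of both numerator and denominator, so
missingness cannot masquerade as homozygosity; a window with no non-missing
call never qualifies. A marker supports a run when at least one qualifying
window covers it, and maximal stretches of supporting markers become runs
whose boundaries are the outermost supporting markers — the natural union
of qualifying windows, rather than window edges. Runs are retained when the
genetic distance between their first and last marker reaches `min_cM`
(default 5). All three thresholds are inclusive. Chromosomes with fewer
markers than the window are skipped with a warning rather than padded.

Two consequences worth knowing. First, the caller tolerates isolated
heterozygotes (up to 2 per 100-marker window at the defaults), so a single
genotyping error does not split a run. Second, run boundaries extend past a
true autozygous segment for as long as flanking windows stay above the
homozygosity fraction; the expected overhang is a few markers times the
local heterozygosity, so boundary precision is set by marker density. The
test suite verifies exact equivalence with a brute-force
enumerate-all-windows oracle up to 5,000 markers, and segment recovery
(Jaccard > 0.95 against planted truth) on dense error-free panels.

`total_autozygosity()` sums retained runs as a percentage of the autosomal
genetic map, and `classify_families()` calls a family highly homozygous
when any child reaches 2.5% (inclusive).

## Why 5 cM and 2.5%: calibration by simulation

The genetic-length filter is meant to keep autozygosity from recent
consanguinity while discarding the short segments of background relatedness
that any population carries. The package's own simulators justify the
defaults:

- An autozygosity loop through a common ancestor with `m` total meioses
  yields IBD segments whose interior lengths are approximately exponential
  with mean `100/m` cM. For offspring of second cousins (8-meiosis loop,
  mean 12.5 cM) the closed form gives `1 - e^{-0.4}(1 + 0.4) = 93.8%` of
  segment length at or above 5 cM; for descent from a single founder 16
  generations back (32-meiosis loop, mean 3.125 cM) the filter removes
  `47.5%` of segment length. Fractions are length-weighted — this reading
  makes both numbers agree with their closed forms simultaneously.
- Gene-dropping 5,000 first-cousin offspring over a ~3,500 cM map places
  about 95% of them at or above the 2.5% threshold after the 5 cM filter,
  while their mean autozygosity matches the pedigree inbreeding coefficient
  (1/16).

`scripts/acceptance.R` recomputes all three quantities from scratch at
5,000 replicates (a few minutes on one CPU); the test suite checks them at
the same or slightly reduced sizes.

`simulate_founder_ibd()` needs one extra device: unconditioned descent
through a 32-meiosis loop is autozygous with probability `2^-32` per locus,
so a literal two-line gene-drop would return essentially no segments. The
function therefore simulates the exactly equivalent pooled process — each
loop meiosis toggles between transmitting and non-transmitting at Poisson
rate 1/Morgan, autozygosity holding where all are transmitting —
*conditioned on founder descent at the chromosome start*. Because the
crossover process is memoryless, the recorded segment lengths are unbiased
draws from the segment-length distribution; the tests validate them with a
probability-integral transform against the end-truncated exponential.

## The synthetic cohort generator

Gene dropping uses Poisson crossovers at rate 1 per Morgan with no
interference and a single sex-averaged map — the standard gene-dropping
assumptions. The default `synthetic_genome()` has 22 autosomes whose
genetic lengths are scaled from the human autosomal map to ~3,500 cM, with
a uniform 1 cM/Mb recombination rate; a 2-chromosome toy keeps unit tests
fast. Founder haplotypes carry unique labels, autozygosity is label
identity, and `drop_ancestry()` exposes the full mosaic so genotypes can be
read off it.

`sim_genotypes()` draws founder alleles from per-marker frequencies
(default uniform 0.05–0.5 minor-allele frequency), then applies
missingness and a genotype-class error: with probability `error_rate` a
homozygote is observed heterozygous and a heterozygote as a random
homozygote. This is the dominant confusion mode of array genotyping and
makes the heterozygote rate inside true autozygous runs equal the error
rate, which is what the ROH caller's 98% tolerance must absorb.

`sim_caller_calls()` emulates a four-caller setup: per-caller sensitivity,
Gaussian boundary jitter (clipped to positive length), Poisson false calls
per sample placed uniformly on the mappable genome with exponential
lengths and a configurable copy-number-class distribution. `sim_tracks()`
places non-overlapping exponential-length peaks to a target coverage
fraction and renders matched intensity and state tracks.
`sim_case_control_cnvs()` plants a known overlap bias: the biased fraction
of the affected set is placed uniformly *among peak-overlapping
placements* by rejection from the same null sampler the test uses.

What the generator does **not** emulate: linkage disequilibrium among
founder haplotypes, crossover interference, sex-specific maps, and
array-intensity artifacts (wave, batch, GC effects). Passing tests
therefore demonstrate algorithmic correctness and statistical calibration
under the stated model, not robustness to every failure mode of real
array data; the QC module exists precisely because real data need
filtering before these models apply.

## Sample and family QC

`qc_filter()` applies per-platform thresholds: call rate at least 97% for
high-density arrays (95% for the older 5.0/500K designs) and fewer than
200 (respectively 125) CNV calls per sample. Vendor-specific chip metrics
are accepted as precomputed columns rather than recomputed. Sex inference
counts X heterozygosity (male-consistent below 0.05) and Y call presence
(above 0.5); the thresholds are package choices surfaced as arguments,
since genotype-based sex separation is essentially bimodal and insensitive
to the exact cut. Relationship verification counts opposite homozygotes
for declared parent–child pairs (kept below 0.02, accommodating ~1%
genotype error) and identical-genotype fractions for declared sibs (kept
in [0.45, 0.9]; above flags a duplicate/MZ pair). The windows were
calibrated on the synthetic generator and are config-exposed.

## CNV consensus, rarity, and burden

Consensus is geometric: within a sample and copy-number class (classes are
never pooled), each caller's calls are merged and the per-base count of
supporting callers is computed; maximal intervals with depth at least
`min_algorithms` (default 3 of 4) become events. The event's probe support
is the minimum among supporting calls — the cautious summary — and
biallelic-deletion discovery additionally requires 5 probes (25 for de
novo burden scans). Consensus boundaries are the depth-qualified region
itself, not caller-boundary medians.

Rarity compares each event against a control catalog entry of the *same*
copy-number class: common means more than 50% (strict) of the query length
is covered by one entry. The query length is the denominator — the
conservative choice for small query events — and class matching means a
locus seen in controls only as a single-copy loss does not make a
biallelic deletion common. `select_cnv0()` chains the full cascade (drop
known-cause families → CNV0 → support thresholds → rare) and reports
event and carrier counts with a one-sided exact p at every stage, since
readers may reasonably want the burden at any stringency.

De novo flagging is deliberately asymmetric: child events come from the
stringent consensus, but a single caller's call of the same dosage
direction (CN 0/1 loss vs CN 3/4 gain) overlapping by 1 bp in a parent is
enough to call the event inherited. This suppresses false de novo calls
arising from caller boundary jitter or a parent call just missing the
consensus.

`burden_test()` is carrier-based (individuals with at least one event, not
event counts) and computes the one-sided Fisher p as the exact upper
hypergeometric tail by direct summation of `dhyper()` mass. The test suite
cross-checks it against `fisher.test(alternative = "greater")` on 1,000
random tables, keeping implementation and oracle separate.

## The Monte-Carlo coincidence test

The mappable genome is where the array could have detected a CNV: per
autosome, the span between the first and last marker minus inter-marker
gaps over 100 kb and minus exclusion regions. Randomized placements keep
each CNV's length and must lie wholly inside one mappable interval; an
interval is chosen with probability proportional to its number of valid
starts for that length, then a start uniformly — which makes the placement
exactly uniform over all feasible placements (verified by chi-square over
an enumerable toy). Placing wholly within an interval is a deliberate
choice: placements never span low-density gaps, so lengths are preserved
on the mappable genome exactly.

A CNV coincides with a track collection when it intersects any peak of the
collection's union by at least 1 bp. Peaks come from intensity tracks by
fixed thresholding (score at least 20 by default; the score units are
treated as opaque track units, and the threshold is a plain argument so
sweeps over 20–40 reproduce robustness analyses) or from the bins of a
chosen chromatin-state subset.

For observed affected and unaffected sets, each replicate independently
re-places both sets and records the coincidence counts `A_i` and `U_i`.
With the add-one estimator:

- enrichment `p = (1 + #{A_i >= A_obs}) / (n + 1)`,
- depletion `p = (1 + #{U_i <= U_obs}) / (n + 1)`,
- joint `p = (1 + #{A_i >= A_obs and U_i <= U_obs}) / (n + 1)`.

The joint probability is estimated from simultaneous randomization of both
groups within a replicate; groups are independent, as no biological
coupling between case and sibling placements is part of the model. The
add-one form never returns zero, so `1/(n+1)` is the attainable floor. The
counts are discrete, which makes these p-values slightly conservative; the
calibration test therefore applies a randomized tie-broken
probability-integral transform (exactly uniform under the null) when
checking the sampler over 500 simulated cohorts.

The ChromHMM variant runs the same machinery per epigenome against the
bins of a state subset (default the two enhancer states, `EnhG` and `Enh`,
config-exposed), optionally after excluding CNVs that intersect any coding
exon of a coding gene (noncoding-only analysis), and can pool
selected-state bins across the epigenomes of a tissue ("tissue unions").
No multiple-testing correction is applied — tissues overlap and are highly
correlated, so the effective number of tests is undefined; all marginal
and joint p-values are reported as-is and should be read as exploratory.

## Gene neighborhoods and TADs

Neighbor reporting anchors on coding spans: the distance from a CNV to a
gene is the bp gap to the gene's coding region (0 when overlapping), the
nearest coding gene is reported (ties: all), plus any coding gene whose
coding span lies within 150 kb of the nearest gene's coding span, capped
at 1 Mb + 150 kb from the CNV itself. Noncoding genes never enter the
neighbor list, though exon annotation reports them as non-disrupting.
Rather than hard-coding display labels, the report carries the overlap
class and side ("overlap"/"left"/"right") and signed distances, which map
onto table-style intronic/left/right columns at presentation time.

TAD boundary regions are the gaps between consecutive TADs of a profile;
abutting TADs get a 1-bp point boundary so containment stays decidable.
Strict disruption means a deletion contains an entire boundary region;
permissive means a TAD start or end coordinate falls strictly inside the
deletion. A deletion exactly coextensive with a boundary region contains
it without holding any coordinate strictly inside, so permissive is
defined to include strict — keeping the invariant that strict implies
permissive.

## Problem sizes and numerical choices

The default test and acceptance runs use 5,000 gene-dropped offspring for
threshold calibration, up to 5,000-marker panels for oracle equivalence,
10,000 Monte-Carlo replicates (2,000 in the 500-cohort calibration sweep),
and 100 simulated cohorts for the power check of the joint test at a
planted 0.8 overlap bias — sizes chosen so every stochastic check sits
well inside its tolerance on a single CPU. All generators accept a `seed`
and are bit-reproducible; seeded calls restore the caller's RNG state.

Known limitations: the ROH caller is a window heuristic, not an HMM, and
inherits the boundary overhang described above; rarity uses single-entry
(not union) catalog overlap; the enrichment test conditions on the
observed length distribution and mappable genome, so its null does not
model uncertainty in either; and the synthetic generator's omissions (LD,
interference, intensity artifacts) bound what green tests certify about
real cohorts.
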