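---
title: "Dosage genotyping, karyotyping and homoeologous-exchange calling: methods and design notes"
author: "polyhex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosage genotyping, karyotyping and homoeologous-exchange calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `polyhex`, the
parameters that matter, the choices made where the method was genuinely
open, and what the synthetic-data validation does and does not establish.

## The data model

The unit of observation is a diagnostic SNP site at which reads can be
attributed to one of the two parental homoeologs of a segmental
allotetraploid (labelled A = 9311-like and B = Nipponbare-like). For an
individual with `a` copies of homoeolog A and `b` of B at a site (euploid:
`a + b = 4`), the generative model used throughout — both by the simulator
and implicitly by the callers — is

* total site depth `n ~ Poisson(D · (a + b) / 4)`, with `D` the euploid
  mean depth;
* A-attributed reads `~ Binomial(n, p)` with
  `p = f (1 − ε) + (1 − f) ε`, `f = a / (a + b)`,

where `ε` is the probability that a read is attributed to the wrong
homoeolog (sequencing error plus mismapping). The default `ε = 0.005` is a
typical short-read error/mismapping scale; it is configurable everywhere
it appears.

## Site masking

Control samples (reciprocal F1s and a parental mix) have a true 1:1 ratio
at every site, so persistent imbalance there is a property of the site,
not of biology. A site is excluded when any control shows
`max(a, b) ≥ 2 · min(a, b)` with `min > 0`. The boundary is inclusive:
"two-fold biased" is read as the exclusion threshold itself. Two decisions
the rule itself does not determine:

* a site with `(0, c)` is masked only when `c ≥ 4` (`zeroFloor`); at lower
  depth a zero on one side is indistinguishable from sampling noise;
* a site with total control depth below 2 is masked as `low_coverage`
  rather than biased.

The rule is applied per site, not per window; masking is monotone in the
control set.

## Depth painting and karyotype calls

Windows are fixed `[k, k+1)` Mb tiles; a window needs at least 5 kept SNP
sites to be scored (the trailing partial window is kept if it qualifies).
Window state comes from relative depth `r` against rungs at
`(4 + k) / 4`: state −2 when `r ≤ 0.5 + δ`, −1 when `r ≤ 0.75 + δ`,
+2 when `r ≥ 1.5 − δ`, +1 when `r ≥ 1.25 − δ`, else 0, with half-band
`δ = 0.05` absorbing sampling noise around each rung.

**Normalisation.** The global depth that defines `r` is, by default, the
median over windows of the window mean depth. The obvious alternative —
the genome-wide mean per-site depth — is biased by exactly the chromosomes
the painting is meant to find: one +2 chromosome in twelve inflates the
mean by ~4%, which drags the aberrant chromosome's relative depth to
1.44, below the 1.45 band edge, and makes full state recovery impossible.
A per-site median is robust but quantised to integer read counts (a jump
from 20 to 19 is a 5% shift); the median of window means is robust *and*
effectively continuous. `globalStat = "mean"` restores the plain mean.

**From windows to calls.** The original analysis inspected depth paintings
manually; the automated proxy here is: a non-zero state covering ≥ 80% of
scored windows (`modalFrac`) is the whole-chromosome state; otherwise the
chromosome is called 0 and maximal runs of ≥ 3 consecutive windows
(`minRun`) sharing a non-zero state become segmental gain/loss events.
Both thresholds are configurable. A consequence of the run rule and rung
quantisation: a segmental event shorter than `minRun` full windows after
tiling cannot be detected, so the practical resolution is ~3 Mb and called
boundaries are window-aligned (within one window of truth).

## Bin genotyping by G-test

Kept sites are pooled into bins of 10 consecutive SNPs (a trailing
remainder of ≥ 5 sites stands alone, fewer merge backwards), damping
per-site depth noise. Each bin's pooled counts are tested against the five
dosage hypotheses with the likelihood-ratio goodness-of-fit statistic
`G = 2 Σ O ln(O/E)`; the expected A-fraction is `{ε, 1/4, 1/2, 3/4, 1−ε}`
— `ε` replaces the impossible zero expectation of 0:4 and 4:0, without
touching the three heterozygous ratios. Since all five hypotheses have one
degree of freedom, "lowest G" and "highest p" are the same criterion, and
both equal maximum binomial likelihood; ties (which arise only at
symmetric counts) are broken deterministically towards 2:2, then the
smaller departure from balance, then the lower A-dosage. The test suite
verifies exact agreement with exhaustive likelihood maximisation for every
count pair up to depth 60.

## Fragments and HE regions

Runs of equal bin genotype are merged into fragments; fragments spanning
fewer than 5 bins (`minFrag`) are removed. Removal can leave two flanking
fragments with the same genotype; these are re-merged, absorbing the
removed bins, and removal + re-merge repeats until a fixpoint. A single
removal pass is order-dependent (removing a 3-bin island can create a
mergeable pair whose combined span changes what else survives); the
fixpoint is the only order-independent reading, so that is what is
implemented. Every input bin ends up in exactly one surviving fragment or
one removed/inter-fragment gap.

The interval between two adjacent fragments of different genotype — from
the last SNP of the left fragment to the first SNP of the right — is the
HE region: the true exchange point lies inside it, up to the one-bin
uncertainty of a breakpoint-straddling bin. Ground-truth evaluation
therefore tests containment in the region extended by one bin on each
side. For window-scale summaries each HE contributes one event to the
1 Mb window containing its interval midpoint (keeping per-individual
counts integral, rather than overlap-weighting).

Individuals with any non-zero karyotype call or segmental event are
excluded from HE analysis: an aneuploid depth shift also shifts the
allelic ratio and would masquerade as dosage change. The chromosome-scale
HE statistic is the mean HE count per euploid individual.

## Marey-map recombination rates

Genetic maps are first curated: markers at duplicate physical positions
collapse to their median cM, then the longest non-decreasing subsequence
of genetic positions (in physical order) is kept — the minimal removal
achieving monotonicity. The local HR rate is the first derivative of a
tricube-weighted local polynomial (degree 2, span 0.2, both configurable)
of cM on bp, evaluated analytically at window midpoints. The derivative
is taken from the local polynomial coefficients, not finite differences,
which is stable at midpoints and is how Marey-map rate estimation is
conventionally defined. Negative slopes are clipped to zero (curation
makes them rare) and slopes below 1e−9 cM/Mb are zeroed to avoid numeric
dust on flat maps; windows whose midpoint falls outside the marker span
get NA. On dense maps the integrated window rate reproduces the total map
length to within 5%.

## Association statistics

Chromosome-scale and window-scale Pearson correlations use the t-transform
p-value with n − 2 df; at chromosome scale n = 12, which is small, but
this mirrors the scatter-plot analysis the reports emulate. Event-count
comparisons use the Yates-corrected 2×2 chi-square proportion test and
Fisher's exact test. The window report has a fixed row order (SNPs, small
indels, large indels, TIPs, the three TIP classes, shared TEs, the three
shared classes, then base-fraction features) with two-tier stars
(p < 0.05, p < 0.01). Indel size classes are 1–99 bp (small) and ≥ 100 bp
(large): the upstream variant catalogue uses ≥ 100, and this convention
makes the classes partition all lengths ≥ 1. TE presence/absence uses
detected insertion frequencies with strict thresholds (> 0.95 present,
< 0.05 absent); anything between is indeterminate and the insertion is
excluded rather than guessed. No multiple-testing correction is applied,
matching the reports the package reproduces.

## The synthetic-data generator

The generator emulates the statistical structure the callers assume: SNP
positions as a homogeneous Poisson process (default 2 / kbp over 12 × 30
Mb chromosomes); gene/TE tracks with opposing gradients (retrotransposons
enriched around the chromosome midpoint, genes and MITEs distally, DNA
transposons flat), mirroring the organisation of a rice-like genome; a
strictly monotone genetic map whose rate is suppressed pericentromerically;
a TE table mixing shared, parent-specific and intermediate-frequency
insertions; and dosage mosaics from a Poisson number of breakpoints per
chromosome (default mean 3) placed proportionally to a per-Mb intensity
landscape. Aneuploidy probabilities default to 9/240 (gain) and 10/240
(loss) per chromosome — the per-chromosome rates implied by roughly nine
gain and ten loss events in a 20-plant, 12-chromosome cohort.

Choices the observed data do not constrain:

* **Dosage steps are ±1 per breakpoint** (a single reciprocal crossover);
  multi-step transitions arise only from adjacent breakpoints. This is
  the simplest process consistent with the five observable ratios; the
  per-breakpoint step distribution is not itself observable.
* **Aneuploidy applies to one homoeolog chosen uniformly**, shifting depth
  and allelic ratio together, as the two must co-vary in real data.
* Breakpoints are instantaneous (zero-width) in truth; the caller reports
  an uncertainty interval, and evaluation uses containment.

What passing on simulated data does **not** show: the generator draws
independent Poisson/binomial counts per site, so it cannot expose
artefacts from correlated mapping errors along a read, reference bias
hotspots, copy-number variation between the true parents, or
library-specific depth waves. The masking stage exists precisely because
real data contain such sites; on synthetic balanced controls it removes
only the sampling-noise tail (at 20× controls the two-fold rule keeps
roughly 60% of sites, so downstream defaults are exercised under
realistic masking pressure).

## Validation problem sizes

The shipped tests and the acceptance script size their simulations for a
single CPU: exhaustive genotyper validation to depth 60; 10,000 bins per
dosage class at 200 reads/bin; 100 single-breakpoint chromosomes at 20×;
1,000 exchange-free chromosomes of 200 bins; 20 individuals × 12
chromosomes for karyotype recovery (10 Mb chromosomes, 0.5 SNPs/kbp); and
a 20-individual, 12 × 30 Mb, 1 SNP/kbp population with HE intensity
proportional to gene density for the association recovery. These sizes
give the binomial/Poisson margins the assertions need (e.g. ±3 SE checks)
while keeping the whole suite to a few minutes.

## Known limitations

* The karyotyper implements the rung method only; no HMM or changepoint
  segmentation of depth, by design.
* Every genotype transition is one "HE"; gene conversion and crossover
  are not distinguished.
* Fragments under 5 bins are invisible, so HEs closer than ~5 bins merge
  or vanish; HE resolution is bin-scale, not SNP-scale.
* Marker lift-over between assemblies is out of scope: genetic maps must
  already be on the working assembly.
* Aneuploid individuals are excluded from, not modelled in, HE analysis.
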