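# polyhex

Karyotyping and homoeologous-exchange analysis for segmental
allotetraploids from homoeolog-specific read counts.

## The problem

A newly formed allotetraploid carries two related subgenomes (here called
the 9311 and Nipponbare homoeologs, after the rice *indica* × *japonica*
system the package is modelled on; the euploid state is four copies per
chromosome pair, 2n = 48). Because meiosis in such plants is unstable, two
kinds of chromosomal change accumulate within a few selfed generations:

* **aneuploidy** — gain or loss of whole chromosomes (and large segments),
  visible as shifted sequencing depth; and
* **homoeologous exchange (HE)** — reciprocal recombination between the two
  subgenomes, which leaves total depth unchanged but shifts the local
  subgenome dosage away from the balanced 2:2 state.

Given per-site read counts attributed to each parental homoeolog at
diagnostic SNPs, `polyhex` calls both kinds of events per individual and
then asks the population-genetics question behind them: which genomic
features — gene density, transposable-element (TE) classes, TE insertion
polymorphisms (TIPs), local homologous recombination (HR) rate — correlate
with where HEs happen.

## The methods at the core

* **Site masking.** Control samples with a true 1:1 homoeolog ratio
  (reciprocal F1s, a parental mix) flag unreliable sites: any site where a
  control shows a two-fold or greater imbalance (boundary inclusive) is
  excluded.
* **Depth painting.** Mean allelic depth in 1 Mb windows, normalised by the
  individual's global depth, is classified onto the copy-number rungs
  0.5×, 0.75×, 1.25× and 1.5× (states −2, −1, +1, +2); modal-state and
  run-length rules turn window states into whole-chromosome calls and
  segmental events.
* **Dosage genotyping.** Kept sites are pooled into 10-SNP bins and each
  bin's counts (a, b) are tested against the five homoeologous ratios
  9311:Nipponbare ∈ {0:4, 1:3, 2:2, 3:1, 4:0} with the G-test of goodness
  of fit,

  `G = 2 [ a ln(a / n p_h) + b ln(b / n(1 − p_h)) ]`, `n = a + b`,

  with expected 9311 fraction `p_h ∈ {ε, 1/4, 1/2, 3/4, 1 − ε}` (the
  misattribution rate ε replaces the zero expectation of the homozygous
  ratios). The hypothesis with the lowest G — equivalently the maximum
  binomial likelihood — is the bin genotype.
* **HE calling.** Runs of equal genotype become fragments; fragments under
  5 bins are removed with flank re-merging to a fixpoint; the interval
  between adjacent fragments of different genotype is an HE region.
* **Marey map.** Local HR rate (cM/Mb) is the analytic derivative of a
  tricube-weighted local polynomial (span 0.2, degree 2) of genetic on
  physical marker position, evaluated at window midpoints.
* **Association.** Pearson correlations of per-chromosome mean HE counts
  (euploid individuals only) and per-window HE frequency against feature
  densities, with two-tier significance stars, plus proportion and Fisher
  tests for event-count comparisons.

A synthetic-data generator (`SimConfig()`, `simulatePopulation()`) draws
SNP panels, feature tracks, genetic maps, dosage mosaics with known HE
breakpoints, aneuploidies and allelic counts (Poisson depth, binomial
parental split), so every caller can be validated against exported ground
truth.

## Worked example

```r
library(polyhex)

cfg <- SimConfig(nChromosomes = 2, chromLengthBp = 10e6, nIndividuals = 4,
                 meanHePerChrom = 2, seed = 42)
sim  <- simulatePopulation(cfg)          # panel, truth, counts, controls
mask <- controlBiasMask(sim$controls)    # two-fold rule on 3 controls
sum(mask$keep)                           # 23378 of 40499 sites kept

karyo <- callKaryotypes(sim$counts, mask)
subset(karyo$calls, state != 0)          # no aneuploid chromosome in this draw

he <- callHEPopulation(sim$counts, mask, karyo)
he$counts
#>   individual chrom n
#> 1      S2-01  Chr1 3
#> 2      S2-02  Chr1 2
#> 3      S2-03  Chr1 2
#> 4      S2-04  Chr1 2
#> 5      S2-01  Chr2 1
#> 6      S2-02  Chr2 1
#> 7      S2-03  Chr2 2
#> 8      S2-04  Chr2 1
head(he$regions, 3)
#>   individual chrom   start     end leftGenotype rightGenotype
#> 1      S2-01  Chr1 3921262 3922301          2:2           1:3
#> 2      S2-01  Chr1 5889790 5889985          1:3           2:2
#> 3      S2-01  Chr1 6738983 6739972          2:2           1:3
```

The per-individual totals (4, 3, 4, 3) equal the number of breakpoints in
the exported truth for the same individuals. Each HE region is the
uncertainty interval between the last SNP of the left fragment and the
first SNP of the right one, with the dosage genotypes on either side.

Genotyping a single bin:

```r
genotypeBin(c(20, 33, 1), c(20, 7, 39))
#>   genotype        G         p
#> 1      2:2 0.000000 1.0000000
#> 2      3:1 1.297023 0.2547578
#> 3      0:4 1.635065 0.2010039
```

`runPipeline(defaultRunConfig(), "run1")` executes the whole chain
(simulate → mask → karyotype → HE → features → Marey → associate) into a
run directory with a file manifest; reruns with the same configuration and
seed are byte-identical. `inst/scripts/polyhex.R` wraps this as a small
command-line tool.

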