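---
title: "Methods: discriminating GMS inheritance models and mapping the sterility locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discriminating GMS inheritance models and mapping the sterility locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmsmap)
```

## The genetic question

A spontaneous male sterile line in *Brassica rapa*, maintained through a
three-line scheme (sterile line, maintainer whose F1 with the sterile line
is fully sterile, restorer whose F1 is fully fertile), is compatible with
two classical inheritance models:

* **Multi-allelic**: one locus, dominance series $a > b > c$, sterile iff
  the expressed allele is $b$. Sterile genotypes: $b/b$, $b/c$.
* **Two-gene**: dominant sterility gene $Ms$, dominant epistatic restorer
  $Rf$; sterile iff at least one $Ms$ and genotype $rf/rf$.

Both models predict the observed line phenotypes and F1 outcomes under
suitable genotype assignments, and their F2 segregation ratios (1:3 vs
3:13) are too close to separate reliably at realistic family sizes. The
package's central statistic instead scores *qualitative* family outcomes
across three progeny-test designs.

## The likelihood

For a family of $n$ plants whose parentage implies sterile fraction $p$,

$$P(\text{all fertile}) = (1-p)^n,\quad
  P(\text{all sterile}) = p^n,\quad
  P(\text{segregating}) = 1 - p^n - (1-p)^n .$$

A family "segregates" iff it contains at least one sterile and at least one
fertile plant; no count threshold is applied, because the source
observations record only segregating / non-segregating. $p$ comes from
exact enumeration of the cross's gamete outer product. For test B the
family parent is a sterile F2 plant whose genotype is not observed, so the
outcome probability is marginalised over the conditional genotype
distribution given sterility (under the two-gene model, sterile F2 plants
are $1\,MsMs\,rfrf : 2\,Msms\,rfrf$; this conditioning is what makes test B
decisive). The total log-likelihood of a hypothesis sums over the
independent families of all three tests, and hypotheses are ranked by it.

Assumptions: error-free phenotyping; independent families; family sizes
fixed at the design values (60, 20, 60); inbred restorer and maintainer
lines fully homozygous (they were advanced by many selfing generations — a
flag relaxes this and admits the heterozygous-restorer assignment).

Numerical choices: all gamete and genotype probabilities in the study's
crosses are dyadic rationals ($r = 1/2$ gives sixteenths), which binary
doubles represent exactly, so the diagnostic fractions 1/4, 3/16, 1/2 and 1
are reproduced exactly without a rational-arithmetic layer. Zero-probability
observations return a $-10^9$ log-likelihood sentinel instead of $-\infty$
or an error, keeping the hypothesis ranking total. Two-locus genotypes
store linkage phase explicitly; a model parameter `inter_locus_rf`
$\in [0, 0.5]$ lets the two-gene model's loci be linked — at
`inter_locus_rf = 0` the repulsion-phase F2 sterile fraction rises from
3/16 to 1/4, quantifying how linkage would bias a ratio-based test.

## The synthetic-data generator

The simulator exists so that every downstream stage is testable against a
known truth. Its defaults mirror the study conditions:

* 10 chromosomes (A01–A10) with the F2 map's genetic lengths (1,011 cM
  total). Physical lengths use a uniform ~280 kb/cM scale (a ~283 Mb
  genome); the bp→cM map is linear per chromosome. The published table
  gives no per-chromosome physical sizes, so a uniform scale is the neutral
  choice.
* Meiosis without crossover interference: crossover counts per chromosome
  are Poisson(length/100 Morgans) with uniform breakpoints, i.e. Haldane's
  map function at the recombination level. Map *distances* downstream are
  reported with Kosambi's function, as the mapping analysis specifies; the
  resulting mismatch is below 2% for $r < 0.15$ and immaterial at the
  reported tolerances.
* Populations: F2 (selfed F1 of two fully homozygous founders carrying
  alternate alleles at every marker) and BC1. The backcross uses the
  maintainer as recurrent parent; the source material does not name the
  recurrent parent, and biologically the sterile F1 must be the seed
  parent — noted, not enforced.
* GBS-style noise: per-call read depth is Poisson with mean 10 (a typical
  tag depth for a single-end GBS library; the study states only the
  filtering rule, not the mean). A call requires depth strictly greater
  than 5 ("more than five reads"; a switch allows $\ge$). Heterozygotes
  drop out to a random homozygote with probability $2^{1-d}$ at depth $d$ —
  the chance that all sampled reads come from one allele. Markers missing
  in $\ge 20\%$ of the population are excluded (the kept set is strictly
  below the threshold), as are monomorphic markers. Phenotypes are never
  degraded.

What the simulator does **not** emulate: read-level artefacts (alignment
error, allele-specific amplification bias, barcode bleed), non-Poisson
depth overdispersion, segregation distortion, and crossover interference.
Passing tests therefore demonstrate correctness of the inference machinery
under the stated statistical model, not robustness to every pathology of
real GBS data.

## Linkage analysis

* **Two-point estimates.** BC1: $\hat r$ is the recombinant proportion,
  with $LOD = k\log_{10}(2\hat r) + (n-k)\log_{10}(2(1-\hat r))$ and the
  $\hat r = 0$ limit $n \log_{10} 2$. F2: $\hat r$ maximises the 9-class
  multinomial likelihood (phase known from the founders) by bounded 1-D
  optimisation, with the $r = 0$ boundary handled explicitly; a marker ×
  binary-trait column uses the corresponding 3 × 2 likelihood with the
  sterile class equal to the sterile-parent homozygote. The all-pairs scan
  (`pairwise_rf`) evaluates the likelihood on an $r$ grid of step $10^{-3}$
  via count-matrix products — ample for the grouping gates — while the
  per-pair `estimate_rf` is the precise estimator (tested against a
  $10^{-4}$ grid-search oracle to within $10^{-3}$). Missing calls drop
  pairwise; nothing is imputed.
* **Grouping.** Markers join a group when $\hat r < 0.3$ **and**
  $LOD > 7$ (both strict, matching the stated thresholds); groups are
  connected components (single-linkage transitive closure), a documented
  divergence risk relative to other grouping heuristics. Group numbering is
  deterministic (size, then smallest marker id).
* **Ordering.** The source delegated ordering to a general mapping package
  without stating the algorithm; here a greedy chain (seeded at the most
  distant pair, extended by the nearest unplaced marker) is refined by
  2-opt to minimise the sum of adjacent $\hat r$. Exhaustive enumeration
  verifies optimality for groups of ≤ 8 markers in the tests; ordering by
  known physical position is available and is what large noisy simulations
  use.
* **Bins.** Adjacent markers merge while their distance is below 0.5 cM
  and zero recombination events are observed between the candidate and
  *every* current member (the all-members check matters because missing
  data make the adjacent-only rule non-transitive); adjacent bins are
  therefore separated by at least one observed event. The representative
  is drawn uniformly within the bin under a dedicated seeded RNG stream so
  maps are reproducible, and distances are recalculated between
  representatives.
* **Trait placement.** The sterility phenotype enters as a morphological
  marker: recessive-classified in the F2 (sterile = homozygous
  sterile-allele class), codominant-equivalent in the BC1. The trait is
  inserted at the position minimising $\hat r$ to its neighbours,
  interpolated by Kosambi distance; markers with $\hat r = 0$ are reported
  as cosegregating, and a group whose best LOD is below 3 does not receive
  the trait.

## Fine mapping

In a large F2 with a recessive-classified trait, a plant is a recombinant
on one side iff its flanking-marker class is impossible without a crossover
given its phenotype: sterile plants not homozygous for the sterile-parent
allele, or fertile plants that are. Fertile heterozygotes are *not*
evidence. Plants recombinant on both sides are flagged "double" but count
once in the plant tally (the published count is of plants, not events).
The recombinant percentage is $100k/n$ rounded half-to-even to two
decimals. Marker–trait distances come from the marker × trait ML estimate
plus Kosambi; the mapped interval is the sum of the two flanking distances
(additivity assumed, as in the source analysis). The source does not state
how its 0.3 cM figure was derived from 3 recombinants in 1,590
dominant-classified plants, so the package reports ML distances and
recombinant counts separately rather than forcing agreement. Both tallies
("recombinant against either flanking marker" and "within the final
interval") are recoverable from the per-side records.

## Problem sizes and reproducibility

The test suite and acceptance script run entirely on simulated data at the
study's scales: F2 of 88 and 200 for mapping properties, BC1 of 186 with
200 replicates for estimator bias, F2 panels of 1,590 for recombinant
screening (15–50 seeds for recovery medians), 300-tag single-chromosome
runs for bin invariants, and $2\times 10^4$–$2\times 10^5$ draws for
Monte-Carlo checks of closed forms (three-standard-error bands). Every
stochastic routine takes an explicit seed and the same seed reproduces
bit-identical output; the pipeline runner writes a JSON manifest from which
each run can be regenerated.

## Known limitations

* At most two loci; no cytoplasmic (CMS) models; no molecular mechanism.
* No multipoint or hidden-Markov genotype-error correction and no
  imputation — noisy maps therefore inflate, which is precisely the
  motivation for the bin construction.
* Trait placement is two-point, not interval mapping.
* The likelihood treats family sizes as fixed at the design minimums;
  larger real families would only sharpen the discrimination.
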