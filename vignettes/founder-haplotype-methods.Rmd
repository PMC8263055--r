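---
title: "Methods: founder-haplotype detection, dating and autozygosity mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: founder-haplotype detection, dating and autozygosity mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderhap)
```

## The problem

When an allele found in several apparently unrelated patients descends from
a single ancestor, each carrier chromosome still harbours a remnant of that
ancestor's haplotype around the variant. Recombination erodes the remnant by
one meiosis per generation, so its extent in *genetic* distance carries a
clock: old founder alleles sit on short shared haplotypes, recent ones on
long haplotypes. `founderhap` implements the desk half of a founder-variant
work-up from a multi-sample VCF:

1. find the markers at which all homozygous carriers are homozygous for the
   same allele, weighting each by how unlikely that sharing is in the
   population (`scan_shared_homozygosity()`);
2. delineate each carrier's ancestral block and intersect them into the
   shared core (`delineate_blocks()`, `shared_core()`);
3. date the founder event from the one-sided genetic lengths
   (`estimate_generations()`);
4. test whether the number of homozygotes in a large sequencing cohort
   exceeds the Hardy–Weinberg expectation (`homozygote_excess()`), and
   reproduce the frequency/incidence arithmetic such studies report
   (`allele_frequency_percent()`, `incidence_table()`);
5. map shared runs of homozygosity in consanguineous pedigrees
   (`find_shared_roh()`).

A cohort simulator with a recorded truth log (`simulate_cohort()`) backs
every stage with ground truth, because real founder cohorts of this kind
live in access-controlled national sequencing programmes.

## Shared-homozygosity scan

A site enters the scan if its population alternate-allele frequency is
known, its minor allele frequency is at least `maf_min` (default 0.01 — the
conventional ">1% MAF" cut for well-genotyped SNPs), and no more than
`max_missing` (default 20%) of carriers lack a call. A scanned site is
*shared* when every carrier with a call is homozygous and all calls agree on
the allele: mere homozygosity is not enough, since identity by descent
implies identity of the allele itself.

The evidential weight of a shared site is its **information content**, the
reciprocal of the shared allele's population frequency: seven unrelated
individuals all homozygous for a 1.2% allele is striking; for a 95% allele
it is expected. Shared alleles rarer than `informative_af_max` (default 5%)
are flagged `highly_informative` for reporting; nothing is filtered on this
flag.

## Block delineation

Per-carrier blocks are delineated by walking outward from the focal variant
over informative sites, all carriers simultaneously. Three observations
shape the rule:

* For a *homozygous* carrier, a heterozygous call at an informative site is
  direct evidence that the ancestral segment has ended on at least one of
  the two chromosome copies — the observable block is the minimum of the two
  copies' extents — so a het always terminates the walk for that carrier.
* The ancestral allele at a site must be estimated. Within the region where
  all carriers still share, any carrier's homozygous call reveals it; beyond
  that, only the carriers whose blocks are still open carry information. The
  walk therefore takes the modal allele among homozygous calls of the
  *still-active* carriers, and a carrier whose homozygous call contradicts
  it terminates there. A whole-cohort consensus would stop tracking the
  ancestral haplotype as soon as most carriers have dropped out, truncating
  exactly the long blocks that dominate the age estimate.
* Missing calls, sites below the MAF threshold (rare variants can arise on
  a subset of founder haplotypes and be heterozygous within a genuine
  block), and sites where the active homozygous calls tie are transparent:
  they neither extend nor terminate.

Bounds are reported at the last concordant informative marker — a
conservative inner bound that errs short by about half an inter-marker
interval. Because published block lengths do not always state whether they
were measured between outermost concordant markers or up to the discordant
flanks, `boundary = "midpoint"` reports the midpoint convention instead, and
the two can be compared directly; the midpoint core is never shorter. Sides
that run off the loaded region are flagged *censored* — they are lower
bounds, not lengths.

The shared core is the interval intersection of all blocks. It is contained
in every block, and removing a carrier can only widen it (both properties
are asserted in the test suite).

## The recombination clock

Under a star genealogy — every carrier descends independently from the
founder — the one-sided genetic length of retained ancestral haplotype after
$g$ generations is exponential with rate $g$ per Morgan on a single carrier
chromosome. An observed side of a *homozygote* is the minimum of two
independent copies, hence exponential with rate $2g$. With $k$ uncensored
sides, total side length $\sum\ell_i$ in Morgans (censored sides included as
exposure), and $c \in \{1, 2\}$ the ploidy factor, the maximum-likelihood
estimate is

$$\hat g = \frac{k}{c \sum_i \ell_i},$$

with an exact confidence interval from
$2\,c\,g \sum_i \ell_i \sim \chi^2_{2k}$. Both conventions for combining
sides — two observations per homozygote, or one per-individual sum (a
$\mathrm{Gamma}(2, 2g)$ observation) — lead to the same sufficient
statistics and hence the same estimate and interval, so the choice is
immaterial here. Censoring enters as exposure without an event, the standard
treatment for type-I censored exponentials; when every side is censored the
age is unidentifiable and the estimator refuses rather than returning a
degenerate value.

The correlated-genealogy corrections of dedicated haplotype-dating methods
(shared internal branches make carriers' lengths positively dependent) are
deliberately not reproduced: with a handful of carriers the star model is
the transparent default, and `estimate_generations()` is a single function
that alternative models can replace. Years are an exact multiplication by
`years_per_generation` (default 25, the usual human figure).

Defaults: confidence level 0.95, `mode = "homozygote"`. No genetic map is
assumed; a uniform 1 cM/Mb map (the genome-wide human average) is the
self-contained default, and any two-column bp/cM table overrides it —
estimates scale inversely with total genetic length, so the map choice
matters exactly as much as its rates differ from uniform.

## Homozygote excess and count arithmetic

With allele frequency $q$ and cohort size $N$, Hardy–Weinberg equilibrium
(no inbreeding, $F = 0$, no stratification) predicts $Nq^2$ homozygotes.
The tail probability of observing at least the reported number is computed
by exact summation under $\mathrm{Poisson}(Nq^2)$ (default) or
$\mathrm{Binomial}(N, q^2)$; the two agree to well under 5% at the $q^2 \le
10^{-5}$ scales involved, and no normal approximation is ever used. The
frequency source and null are arguments, since published enrichment claims
rarely state either. Stratified denominators (probands only, one ancestry
group) are handled by passing the recalculated counts to
`incidence_table()`.

All printed percentages use half-up rounding at the conventional precision
(3 decimals for allele percentages, 2 for incidences) — verified against
every reproducible published count/percentage pair in the test suite.

## Shared runs of homozygosity

`find_shared_roh()` classifies each site over the chosen individuals as
`hom` (all homozygous; in `strict` homogeneity mode also for the same
allele), `het`, `bad` (strict-mode disagreement between homozygotes — never
part of a run), or transparent (any missing call). Reported regions are
maximal stretches containing at most `max_het` heterozygous interruptions,
trimmed to their outermost homozygous sites, scored by consecutive
homozygous-site count (or span in bp), and ranked densely so tied regions
share a rank. Maximality and exact agreement with an exhaustive window
enumeration are tested on hundreds of random instances. Missing calls are
transparent rather than run-breaking because sparse exome genotypes
otherwise shatter genuine autozygous regions; the cost is that a run's site
count refers to sites with complete calls only.

## The simulator and what it does (not) emulate

`simulate_cohort()` draws a marker panel (positions uniform in the region,
alternate-allele frequencies uniform on `af_range`, default
$[0.01, 0.5]$ — the informative-marker band), one founder haplotype from
those frequencies, and per carrier chromosome a left and right retained
length from $\mathrm{Exponential}(g)$, truncated and flagged censored at the
region edges. Inside the retained segment the carrier copies the founder
haplotype; outside, alleles are independent Hardy–Weinberg draws per site.
Optional per-call genotyping error (uniform flip to another code) and
missingness follow. The focal variant sits at the region centre, hom-alt in
every carrier (het in `carrier` zygosity), with a recorded population
frequency of $10^{-3}$ — a typical rare founder allele, below the MAF cut so
it never participates in its own scan. All randomness derives from one
master seed through fixed per-stage substreams, so a configuration is
byte-reproducible and appending stages cannot perturb earlier draws.

Deliberately absent: background linkage disequilibrium (sites are
independent, so the scan's false-sharing rate off-segment is if anything
*higher* than with real LD structure at these marker densities),
correlated genealogies, demographic history, and read-level artefacts.
Passing tests therefore demonstrate correctness of the algorithms under the
stated generative model, not robustness to cryptic relatedness or
population structure in real cohorts.

## Validation at the study scale

The test suite validates the clock end to end at the scale of a realistic
founder cohort: 200 simulated cohorts of 7 homozygotes, age 311
generations, a 2 Mb region carrying 2000 markers at 1 cM/Mb. The pipeline's
median estimate falls within 15% of the truth and the 95% interval covers
it in about 95% of cohorts; `scripts/acceptance.R` recomputes these numbers
on demand. Pure-estimator calibration (no delineation noise) is checked
separately with direct exponential draws at ages 50, 311 and 1000.

## Known limitations

* The star-genealogy assumption overstates independence; with related
  carriers the interval is anticonservative.
* Block bounds are only as good as marker density; the conservative
  convention biases lengths short (and ages old) by up to one inter-marker
  interval per side.
* The delineation consensus needs at least two carriers to extend beyond
  the all-shared region reliably; a single very long block ends at its
  first heterozygous informative site, which slightly overshoots the true
  breakpoint on average.
* `homozygote_excess()` inherits every caveat of its $q$: a frequency from
  the wrong ancestry stratum shifts $Nq^2$ quadratically.
* Multi-allelic records are dropped by default (`multiallelic = "split"`
  recodes against each alternate allele instead); duplicated positions
  collapse to the first record.
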