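# founderhap

Founder-haplotype detection, recombination-clock dating and autozygosity
mapping from multi-sample genotype data.

## What problem this solves

A rare disease allele observed homozygous in several *unrelated* patients
usually descends from a single founder. Two desk analyses turn that
suspicion into numbers, given a joint-called VCF of the carriers:

* **Ancestral haplotype sharing.** Around the variant, every carrier still
  holds a remnant of the founder's chromosome. Markers at which all
  carriers are homozygous for the same allele outline it; the rarer a
  shared allele is in the population, the stronger the evidence, so each
  shared SNP is weighted by its *information content* `1 / AF`.

* **The recombination clock.** Recombination trims the remnant each
  generation. Under a star genealogy the one-sided retained genetic length
  ℓ (Morgans) of a homozygote's block is Exponential with rate 2*g*, where
  *g* is the founder allele's age in generations. With *k* uncensored sides
  the MLE is

  &nbsp;&nbsp;&nbsp;&nbsp;*ĝ* = *k* / (2 Σᵢ ℓᵢ),

  with an exact CI from 2·2*g*·Σℓᵢ ~ χ²(2*k*). Sides truncated by the edge
  of the analysed region count as censored exposure.

The package also covers the surrounding arithmetic of a founder-variant
study — allele-frequency and incidence percentages, the Hardy–Weinberg
homozygote-excess test (expected *N q²* homozygotes versus observed, exact
Poisson/binomial tails) — and a shared runs-of-homozygosity scan for
autozygosity mapping in consanguineous families. A founder-cohort simulator
with a recorded truth log (`simulate_cohort()`) makes every stage testable
without access-controlled cohort data.

Intended users: statistical/medical geneticists following up a putative
founder allele from national-biobank or cohort sequencing data.

## Worked example

Simulate a cohort of 7 homozygous carriers of a 311-generation-old founder
allele (2 Mb region, 2000 markers, 1 cM/Mb), then run the full analysis:

```r
library(founderhap)

sim    <- simulate_cohort(sim_config(n_carriers = 7, generations = 311,
                                     seed = 42))
G      <- sim$genotypes
sites  <- scan_shared_homozygosity(G)          # per-site sharing report
blocks <- delineate_blocks(G)                  # per-carrier ancestral blocks
core   <- shared_core(blocks)                  # their intersection
age    <- estimate_generations(
            physical_to_genetic(blocks, mode = "homozygote"))

sum(sites$shared)        # 392 of 2000 markers shared homozygous
core$length_kb           # 43.7 kb shared core
print(age)
#> Founder age: 342 generations (95% CI 187-543), ~8555 years
#>   model star-exponential, homozygote mode; k = 14 uncensored sides, total 0.02046 M
```

The true age (311) lies inside the interval; the point estimate carries the
sampling noise of 14 exponential observations, which is why the CI spans
roughly a factor of three. The homozygote-excess test for 7 homozygotes in
a cohort of 74,180 at allele frequency 0.094%:

```r
homozygote_excess(q = 0.00094, N = 74180, observed = 7)
#> Homozygote excess (poisson null): expected 0.06555, observed 7, p = 9.74e-13
```

Seven observed against 0.066 expected — incompatible with the carriers
being independent draws from Hardy–Weinberg, as expected for a recessive
disease cohort enriched by ascertainment.

A thin CLI over the same functions lives in `inst/scripts/founderhap.R`
(`simulate`, `run`, `roh`, `enrich` subcommands), and `run_pipeline()`
writes a complete report bundle (sites/blocks/core TSVs, age JSON,
information-content SVG, log) from one config.

## Layout

* `R/` — marker panel / genotype matrix containers and VCF IO
  (`variants_io`), shared-homozygosity scan and block delineation
  (`haplotype_scan`), exponential-decay age model (`age_model`),
  frequency/incidence/enrichment arithmetic (`enrichment`), shared-ROH
  scanner (`autozygosity`), cohort simulator (`simulate`), pipeline
  orchestration (`pipeline`).
* `tests/testthat/` — unit, property and oracle-equivalence tests,
  including brute-force reference implementations in `helper-oracles.R`.
* `vignettes/founder-haplotype-methods.Rmd` — model assumptions, parameter
  defaults, design choices and limitations.
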