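# parkviable

Demographic and genetic population viability analysis (PVA) for small,
isolated vertebrate populations — built around the motivating case of a red
squirrel (*Sciurus vulgaris*) population of ~100–120 animals confined to an
urban park (72 ha of wooded habitat in two strata of 28 and 44 ha),
isolated by the surrounding urban matrix. The package is for conservation
ecologists who want to ask, with explicit uncertainty: *will this
population persist over ~20 years (about 10 generations), and how much of
its genetic diversity will it keep, with and without immigration?*

## What it computes

**Deterministic demography.** From a life-history scenario (age at first
litter α ∈ {1, 2} yr, juvenile survival S_j, proportion of breeding
females b, adult survival 0.68 ♀ / 0.63 ♂, 35% second litters, litters of
mean 3 / max 6, 1:1 birth sex ratio) the package builds the female life
table (l_x = S_j·S_af^(x−1), m_x = b(1+0.35)·3·0.5 for x ≥ α) and solves
the Euler–Lotka equation

    Σ_x l_x m_x λ^(−x) = 1

by bisection for the asymptotic growth rate λ and generation time T; λ is
verified against the Leslie-matrix dominant eigenvalue to 1e-8.

**Stochastic projection.** An individual-based simulator with
environmental variation (yearly beta draws per vital rate, concordant
across rates by default), demographic stochasticity (Bernoulli fates,
binomial litters, polygynous siring), a probabilistic ceiling at K = 120,
optional Poisson immigration of 1–2-year-olds from a simulated stable
source of 100, and Mendelian tracking of 12 microsatellite loci. It
reports the stochastic growth rate r = mean ln(N_pre-truncation(t+1)/N_t),
the probability of extinction (either sex absent) and the trajectory of
expected heterozygosity He = 1 − Σp² averaged over loci and extant
replicates.

**Genetic summaries.** Allele frequencies, observed and unbiased expected
heterozygosity (Nei 1978), conditional exact Hardy–Weinberg tests
(enumeration with Monte-Carlo fallback), haplotype diversity
Hd = n/(n−1)(1 − Σp²) and nucleotide diversity π with their standard
errors.

**Distance sampling.** Half-normal and hazard-rate
(g(x) = 1 − exp(−(x/σ)^−b)) detection functions with forward-AIC cosine
adjustments, effective strip width, stratified density D = n/(2·L·esw) and
park-wide abundance ΣD_s·A_s with log-normal intervals.

**Synthetic data.** Seed-deterministic generators for genotype tables
matched to target per-locus heterozygosities, haplotype-structured mtDNA
alignments, and line-transect sightings — so the whole pipeline is
testable without field data.

## Worked example

```r
library(parkviable)

s <- life_history_scenario(age_first_litter_f = 1,
                           juvenile_survival = 0.50,
                           prop_females_breeding = 0.50)
deterministic_growth(life_table(s))
#> lambda = 1.180097, generation time = 2.261 yr

sm <- simulate_pva(s, freqs = sceaux_founder_freqs(), seed = 1,
                   replicates = 200)
sm
#> PVA summary: 200 replicates x 20 years (seed 1)
#>   stochastic r = 0.131 (SD 0.315), P(extinction) = 0.000
#>   He: 0.473 initial -> 0.430 (SD 0.033) final (extant reps)
#>   mean N: 120.0 initial -> 102.3 final
```

Under the optimistic scenario the population grows intrinsically
(λ = 1.18), survives 20 years in essentially every stochastic replicate
(r ≈ 0.13 — positive growth held at the ceiling), but still loses about a
tenth of its expected heterozygosity to drift (0.47 → 0.43) when fully
isolated. The published spring census converts to abundance by exact
arithmetic:

```r
abundance(data.frame(stratum = c("eastern", "western"),
                     density = c(2.3, 0.9), area_ha = c(28, 44)))
#> abundance: 104 individuals
```

See the vignette (`vignettes/viability-methods.Rmd`) for the model
details, parameter provenance, and known limitations.

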