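---
title: "Modelling two-locus transmission ratio distortion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling two-locus transmission ratio distortion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trdcross)
```

## The biological setting

The *hms1*–*hms2* system is a two-locus Dobzhansky–Muller hybrid
incompatibility between *Mimulus guttatus* (allele symbol `G`) and
*M. nasutus* (`N`): gametes carrying the `G` allele at *hms1* together
with the `N` allele at *hms2* are largely inviable. Because plants
express thousands of genes in the haploid gametophyte, such an
incompatibility acts on individual pollen grains and embryo sacs — not
on the diploid parent — and therefore distorts transmission ratios at
both loci in predictable, sex-specific ways. Two further mechanisms are
superimposed in this system: drive-like overtransmission of `G` at
*hms1* from heterozygotes (strongest when the parent is homozygous `N`
at *hms2*), and zygotic lethality of *hms1*-GG homozygotes when the
genetic background is *M. nasutus*-like.

`trdcross` expresses all three mechanisms in one gamete-level model and
provides the estimation and testing machinery around it. The two loci
sit on different chromosomes, so independent assortment is assumed
throughout; linked-locus segregation is out of scope.

## Model structure and assumptions

A parent's Mendelian gamete pool is the outer product of its per-locus
segregation margins over the four gamete classes `G;G, G;N, N;G, N;N`
(*hms1* allele first). A `transmission_model()` transforms it in a fixed
order:

1. **drive reweighting** — if the parent is heterozygous at *hms1*, the
   *hms1* margin becomes `(k_drive, 1 − k_drive)`;
2. **gametic selection** — the `G;N` class is multiplied by
   `1 − s_sex`;
3. **renormalisation** — total surviving mass is the predicted
   viability; the pool is rescaled to sum to 1.

Progeny distributions are unions of the two parental surviving pools,
collapsed to the nine unordered two-locus genotypes; a `lethal_rule()`
then removes (a fraction of) matching zygote classes and the
distribution is renormalised again.

The drive-before-selection order is a modelling convention:
overtransmission is treated as acting at gamete formation and the
incompatibility at gamete survival. Progeny data alone cannot
distinguish this order from the reverse (both yield a reweighted,
renormalised pool), so the choice is recorded here rather than claimed
as inference.

## Parameters

| parameter  | meaning                                             | range  | default |
|------------|-----------------------------------------------------|--------|---------|
| `s_male`   | penetrance of `G;N` pollen inviability              | [0, 1] | 0       |
| `s_female` | penetrance of `G;N` ovule inviability               | [0, 1] | 0       |
| `k_drive`  | P(transmit `G` at *hms1*) from a heterozygote       | [0, 1] | 0.5     |
| `lethal`   | zygotic lethality rule (genotype × background)      | —      | none    |

All parameters are probabilities (dimensionless). `k_drive` may be a
named vector keyed by the parent's own *hms2* genotype
(`c(NN = 0.65)`), because the observed overtransmission is conditional
on *hms2*-NN; unnamed backgrounds fall back to 0.5. The null model
(`s = 0`, `k = 0.5`, no lethality) reproduces Mendelian expectations
exactly, which the test suite verifies against an independent
brute-force enumeration of all 16 ordered gamete unions for all 81
parental genotype pairs.

The lethality **background flag** (`"G"`, `"N"`, `"F1"`) is a
cross-level annotation supplied by the analyst, not inferred from the
scored genotypes: the lethality depends on unmapped loci unlinked to
*hms1*, so only the crossing design knows whether progeny carry an
*M. nasutus*-like background (an IL-N self does; a backcross of the same
IL to *M. guttatus* does not).

## Inverting viability into transmission

`predict_transmission_from_viability()` converts an observed pollen
viability into predicted per-locus transmission by attributing sterility
to the incompatible class first: the `G;N` class is killed up to its
Mendelian share; any residual sterility is divided equally among the
remaining classes. The residual is computed from the observed viability
(for a double heterozygote at viability 0.67 it is
1 − 0.67 − 0.25 = 0.08), which yields predicted `G` frequencies of
33.3% at *hms1* and 66.7% at *hms2* — reported rounded to the percent.
When observed sterility is *below* the `G;N` Mendelian share in a double
heterozygote, complete `G;N` inviability is impossible; the function
then attributes all sterility to that class and warns. For parents
heterozygous at only one locus (e.g. `GG;GN`, where the `G;N` share is
0.5), partial attribution is the intended reading and no warning is
emitted.

## Estimation

In a backcross to a homozygous recurrent line the recurrent gamete is
known, so each progeny genotype identifies the gamete transmitted by the
segregating parent; `estimate_gamete_freqs()` is a direct tally.
Cross averages (`average_pools()`) default to the unweighted arithmetic
mean of per-cross frequencies — the convention of published summary
rows, verified arithmetically in the tests — with count weighting
available by flag. Expected selfed-progeny (IL-F2) distributions are
built from the *per-background* pool averages (the IL-G expectation from
the four IL-G crosses, the IL-N expectation from the four IL-N crosses),
which is the construction that reproduces the published expectation
columns; the grand average over both backgrounds does not.

`fit_model_ml()` maximises the joint multinomial log-likelihood over a
chosen parameter subset. The likelihood of these small discrete models
is smooth and unimodal in practice, so the optimiser is a deterministic
coarse grid (default step 0.1 per parameter on [0, 1]) followed by
box-constrained L-BFGS-B refinement from the best grid point; no
gradient machinery or random restarts are needed, and identical data
always give identical estimates. Parameters with no effect on any
supplied cross (e.g. `s_female` when every dam is homozygous) are
detected by likelihood perturbation and rejected as non-identifiable
rather than silently returned at an arbitrary value.

## Goodness of fit

`chi2_gof()` computes the Pearson statistic directly. Classes with
expected frequency zero (created by lethality models) are excluded from
both the statistic and the degrees of freedom — six surviving classes
give df = 5 — and observing a count in such a class is an error, not a
large statistic. No continuity correction is applied; a warning (not an
error) flags expected counts below 5, since several real cells are
small. No multiple-testing correction is applied by default, matching
per-cross reporting; `gof_table(..., bonferroni = TRUE)` adds an
adjusted column. Significance stars follow the thresholds 0.05, 0.01,
0.005, 0.0001. Heterogeneity of transmission across crosses is an R×C
contingency χ² (`stats::chisq.test`, uncorrected), a pragmatic
replacement for factorial ANOVA of transmission ratios, which is out of
scope.

## What the simulator emulates — and what it does not

`simulate_cross()` draws progeny as one multinomial sample from the
model's progeny distribution; `simulate_experiment()` runs a whole
design with one RNG substream per cross, derived from the top-level seed
and a stable hash of the cross label, so adding or removing a cross
never perturbs the others' draws. The bundled design
(`cross_design_il()`) mirrors the real experiment: five segregating IL
genotypes × two backgrounds × two cross directions × two recurrent
parents, minus the four unconstructible IL-N `GG;GN` crosses (36
backcrosses), plus the two IL-F2 selfs (N = 167 and 200) and a species
F2 (default N = 5487). Observed per-cross totals (33–636) are used where
a cross succeeded; unobserved arms default to 136, the mean progeny-class
size of the experiment.
Pollen-viability assays are emulated as binomial draws of 100 grains per
flower on two flowers per plant.

The simulator reproduces the *statistical* structure the analysis
assumes: multinomial sampling, sex-specific gametic selection,
conditional drive, background-dependent lethality, fixed family sizes.
It does not emulate genotyping error or recombinant miscalls (marker
handling is tested separately on constructed tables), segregation of the
genetic background itself, variation in incompatibility penetrance among
individuals, or residual genotype-independent pollen inviability — real
viabilities in compatible genotypes run 10–30% below 1, and a
baseline-viability parameter was deliberately not added, so simulated
viabilities for compatible genotypes are optimistic. Passing tests
therefore demonstrate correctness of the inference machinery under the
model, not robustness to these unmodelled features of real data.

## Numerical choices and degenerate inputs

* Distributions must sum to 1 within 1e-9 at construction; published,
  rounded vectors (which may sum to 0.99–1.08) are accepted by the
  renormalising entry points (`f2_expectation_from_pools`,
  `lethality_renormalize`, `average_pools`) and rescaled by their actual
  mass — which is exactly what reproduces the published
  lethality-renormalised column from its printed source column.
* Reconstructed counts from printed frequencies are `round(f × N)` with
  any shortfall absorbed by the largest class; the repair size is kept
  as an attribute and tests use a correspondingly widened tolerance.
* A fully sterile parent (viability 0) yields no pool and makes crosses
  infeasible (error), mirroring failed greenhouse crosses; all-lethal
  progeny sets are likewise errors, not NaN distributions.
* ML fitting bounds parameters to [1e-6, 1 − 1e-6] during refinement to
  keep boundary likelihoods finite; grid ties resolve to the first
  (lowest-parameter) maximum.
* Internal arithmetic is full precision; rounding to published precision
  (2 decimals for single-locus tables, 3 for two-locus columns) happens
  only in reporting and tests.

## Test problem sizes

The suite exercises: exhaustive 81-pair enumeration checks; law-of-large-
numbers checks at N = 10⁵ progeny (tolerance 0.01); GOF size at the mean
family size N = 136 with 2000 replicates (rejection rate required within
[0.035, 0.065] at α = 0.05); and parameter recovery from six simulated
crosses of 2000 progeny each (s within ±0.05, conditioned k within
±0.03). These sizes make the full suite run in seconds while leaving the
Monte Carlo tolerances comfortably above binomial noise.

## Known limitations

* Two diallelic loci only; the within-species IM62/IM767 analysis reuses
  the same `G`/`N` algebra via a label map rather than a third allele.
* Independent assortment is hard-wired; the package cannot model TRD at
  loci linked to each other.
* Lethality is parameterised by a flag, so designs where the background
  itself segregates (F2s of mixed background) can only be approximated
  by choosing the majority flag.
* Likelihood-ratio confidence intervals beyond the grid, and Bayesian
  inference, are not provided.
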