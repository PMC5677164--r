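# trdcross

Transmission ratio distortion (TRD) — the departure of allele or genotype
transmission from Mendelian 1:1 or 1:2:1 ratios — is a common signature of
hybrid incompatibility and of selfish genetic elements. `trdcross`
implements a complete gamete-level analysis of TRD at a pair of
epistatically interacting loci, built around the *hms1*–*hms2* hybrid
sterility system of the monkeyflowers *Mimulus guttatus* (allele `G`) and
*M. nasutus* (allele `N`): the incompatible gamete class carries `G` at
*hms1* together with `N` at *hms2*, and its loss — along with drive-like
overtransmission of `G` at *hms1* and a background-dependent zygotic
lethality of *hms1*-GG homozygotes — shapes genotype frequencies in F2
and backcross populations.

The package is for geneticists dissecting two-locus TRD in experimental
crosses: it separates gametic from zygotic mechanisms, turns backcross
progeny into direct estimates of transmitted gamete frequencies, and
tests observed genotype counts against a hierarchy of expectations.

## The model

Every cross is described by the union of two sex-specific gamete pools
over the four two-locus gamete classes (`G;G`, `G;N`, `N;G`, `N;N`,
*hms1* allele first; the loci are unlinked, so Mendelian pools factor
into per-locus segregation margins). A `transmission_model` modifies the
Mendelian pools with three mechanisms:

1. **Gametic incompatibility** — the `G;N` class survives with
   probability `1 − s_sex` (`s_male` through pollen, `s_female` through
   ovules);
2. **Drive at *hms1*** — a heterozygote transmits `G` with probability
   `k_drive` instead of ½, optionally conditioned on its own *hms2*
   genotype (the overtransmission is strongest when *hms2* is
   homozygous `N`);
3. **Zygotic lethality** — progeny matching a `lethal_rule` (e.g.
   *hms1*-GG on an *M. nasutus* background) die with a set penetrance.

Order of operations: drive reweighting → gametic selection →
renormalisation; lethality applies to the resulting zygotes. With
`s = 0`, `k = 0.5` and no lethality the model collapses to the Mendelian
expectation exactly.

Progeny genotype frequencies are the outer product of the two surviving
pools collapsed to unordered genotypes; observed counts are compared to
Mendelian, random-union-of-gametes (`p²`, `2p(1−p)`, `(1−p)²`),
backcross-derived, and lethality-renormalised expectations by Pearson
χ² (classes with zero expectation are excluded from statistic and
degrees of freedom). In a backcross to a homozygous line, each progeny
genotype identifies the gamete transmitted by the heterozygous parent,
so gamete-class frequencies are estimated by direct tally; free model
parameters can be recovered from one or more crosses by multinomial
maximum likelihood (grid search plus L-BFGS-B refinement).

## Worked example

```r
library(trdcross)

## a model with strong pollen incompatibility, weaker ovule
## incompatibility, NN-conditioned drive at hms1, and hms1-GG lethality
## on the M. nasutus background
m <- transmission_model(s_male = 0.9, s_female = 0.3,
                        k_drive = c(NN = 0.65),
                        lethal = lethal_rule(hms1 = "GG", background = "N"))

## predicted pollen pool of a doubly heterozygous IL
selected_gamete_pool("GN;GN", "male", m)
#> <viability_prediction> GN;GN via male gametes
#>   viability = 0.775
#> <gamete_pool> sex = male
#>   G;G   G;N   N;G   N;N
#> 0.323 0.032 0.323 0.323
```

77.5% of pollen survives; the incompatible `G;N` class is nearly
eliminated while the other three classes remain equal.

```r
## invert an observed pollen viability (0.67 for a GN;GN plant) into
## predicted transmission, attributing sterility to the G;N class first
round(100 * predict_transmission_from_viability("GN;GN", 0.67)$freq_G)
#> hms1 hms2
#>   33   67
```

A plant at 67% viability should transmit `G` to 33% of progeny at
*hms1* and 67% at *hms2* — the observed backcross values are 37% and
67%.

```r
## estimate transmitted gamete frequencies from a bundled backcross
## (doubly heterozygous IL-G pollen parent, M. guttatus dam, N = 298)
recs <- study_backcross_records()
estimate_gamete_freqs(recs[["sireIL-G_xG"]])
#> <gamete_pool> sex = male, n = 298
#>   G;G   G;N   N;G   N;N
#> 0.319 0.050 0.352 0.279

## and test the four transmitted classes against the Mendelian 1:1:1:1
r <- recs[["sireIL-G_xG"]]
chi2_gof(r$counts[r$counts > 0], rep(0.25, 4),
         expectation_label = "mendelian")
#> <gof_result> vs mendelian: chi2 = 66.6174, d.f. = 3, P = 2.26e-14 ****
```

The `G;N` gamete class is transmitted at 5% instead of 25% — severe
undertransmission through pollen — and the χ² test rejects Mendelian
segregation decisively.

```r
## simulate the IL-N F2 self: hms1-GG progeny never appear
simulate_cross("GN;GN", "GN;GN", m, n = 200, seed = 42,
               background = "N")$counts
#> GG;GG GG;GN GG;NN GN;GG GN;GN GN;NN NN;GG NN;GN NN;NN
#>     0     0     0    50    53    17    20    38    22
```

`simulate_experiment(m, cross_design_il(), seed = 1)` runs the full
reciprocal 36-cross IL design plus the two IL-F2 selfs and a large F2,
with one reproducible substream per cross; `fit_model_ml()` recovers the
generating parameters from such an experiment.

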