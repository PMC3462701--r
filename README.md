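# fluctasym

Fluctuating asymmetry (FA) — small random deviations from perfect
bilateral symmetry — is the standard observable proxy for *developmental
instability*: an organism's inability to buffer its development toward a
symmetric target. `fluctasym` is an R package for ecologists and
evolutionary biologists who score bilateral **meristic** (count) traits —
lateral-line neuromast numbers, lateral plate counts and the like — and
want to compare developmental instability between populations or
habitats, and relate it to genetic diversity measured from multilocus
codominant genotypes.

## What it computes

**Composite standardized relative asymmetry.** For individual *i*, trait
*j*, with left/right counts *L*, *R*:

```
RA_ij  = |L_ij − R_ij| / ((L_ij + R_ij)/2)      relative asymmetry
SRA_ij = RA_ij / mean_i(RA_ij)                  trait-standardized RA
CSRA_i = Σ_j SRA_ij                             composite index
```

RA scales the side difference by trait size (1-vs-2 counts is a large
developmental difference; 101-vs-102 is not); SRA gives each trait unit
mean so traits with different baseline asymmetry weigh equally; CSRA sums
them per individual. Each retained trait has mean SRA exactly 1, and with
complete data the mean CSRA equals the number of retained traits.

Around the index, the package implements the full analysis chain:

* **Screens** that license the FA interpretation: a one-sample *t*-test
  battery per population × trait for directional asymmetry (the flagged
  *fraction* is compared with the nominal α, not the single cells), and an
  antisymmetry screen on excess kurtosis plus Hartigan's dip test of
  unimodality (the dip statistic is computed exactly from its definition).
* **Repeatability** of double counts via the one-way intraclass
  correlation of signed left–right differences.
* **Expected heterozygosity** (Nei's unbiased gene diversity, the FSTAT
  convention) per locus and population, from wide CSV or Genepop input.
* **Inference**: REML mixed models with Satterthwaite denominator df and
  backward elimination (CSRA ~ habitat + sex + heterozygosity, population
  nested in habitat random; Wald Z for the variance component), a type III
  Wilks' Λ MANOVA on per-trait SRA with univariate follow-ups, a one-way
  GLM on heterozygosity with Fisher LSD post hocs, and Spearman
  correlations of population-mean FA against raw and
  *habitat-standardized* heterozygosity — the contrast that separates "FA
  tracks heterozygosity" from "both merely differ by habitat". Small-n
  Spearman p-values are exact (full permutation null via dynamic
  programming).
* **A seeded synthetic-data generator** for bilateral counts
  (habitat-specific developmental noise, optional injected directional
  asymmetry and antisymmetry, recount errors) and Hardy–Weinberg
  genotypes with habitat-dependent allelic diversity, so every stage is
  testable end to end without undeposited raw data.

## Worked example

Simulate the study design — 2 habitats × 4 populations × 20 individuals,
12 traits, 23 loci — with the pond habitat's developmental noise
calibrated to three times the marine level, then run the whole pipeline:

```r
library(fluctasym)
cfg <- pipeline_config(
  simulation = simulation_config(sigma_di = calibrate_di_ratio(3)),
  seed = 1)
res <- run_pipeline(cfg, quiet = TRUE)
print(res)
#> fluctasym pipeline result
#>   individuals: 160  populations: 8
#>   DA screen: 6/96 cells flagged (6.2%)
#>   mean CSRA: 12.00 over 12 retained traits
#>   habitat effect on CSRA: F(1, 158.0) = 346.39, p = 1.14e-41
#>   FA~H correlation: raw rho = -0.762 (p = 0.0368), standardized rho = 0.071 (p = 0.882)
```

Reading the output: about 6% of the 96 population × trait cells flag for
directional asymmetry — chance level at α = 0.05, so the measured
asymmetry is interpretable as FA. The mean composite is 12 (the
normalization identity over 12 retained traits). The mixed model retains
habitat as the sole fixed effect, with least-squares means

```r
res$fa_glmm$ls_means
#>    model  level  estimate        se
#>  fa_glmm marine  5.883003 0.4648072
#>  fa_glmm   pond 18.116997 0.4648072
```

— pond asymmetry is about three times the marine level, recovering the
generator's calibrated ratio. Heterozygosity averages ~0.61 (marine)
vs ~0.33 (pond):

```r
res$diversity$habitat_summary
#>  habitat    mean_h se_across_populations n_populations
#>   marine 0.6076226            0.02195334             4
#>     pond 0.3282469            0.04966660             4
```

and the correlation stage shows the habitat confound: population-mean FA
correlates strongly with raw heterozygosity (rho = −0.762, exact p =
0.037, n = 8) but not with heterozygosity standardized to a common
habitat mean (rho = 0.071, p = 0.88) — the diversity gradient does not
explain FA beyond the habitat contrast.

A thin CLI wrapper with `simulate` / `analyze` / `all` subcommands ships
in `inst/cli/fluctasym.R`.

## Package layout

| Path | Contents |
| --- | --- |
| `R/datasets.R`, `R/data-io.R` | containers, wide-CSV and Genepop I/O, report writer |
| `R/asymmetry.R` | RA / SRA / CSRA index chain |
| `R/screens.R`, `R/dip.R` | DA and antisymmetry screens, repeatability, dip test |
| `R/diversity.R` | Nei gene diversity, habitat standardization |
| `R/inference-*.R`, `R/correlation.R` | mixed models, MANOVA, LSD, Spearman |
| `R/simulate.R`, `R/pipeline.R` | generator and orchestration |
| `vignettes/fluctasym-methods.Rmd` | modelling assumptions and design choices |
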