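---
title: "Methods: composite asymmetry, screens, and the habitat–heterozygosity inference chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite asymmetry, screens, and the habitat-heterozygosity inference chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluctasym)
```

## The scientific problem

Fluctuating asymmetry (FA) — small, random deviations from perfect
bilateral symmetry — is the observable proxy for developmental
instability: an organism's failure to buffer development toward its
symmetric target. `fluctasym` quantifies FA in bilateral *meristic*
(count) traits such as the neuromast numbers of the fish lateral-line
system and lateral plate counts, and carries the analysis through to the
population-level question that motivates such data: do habitats differ in
developmental instability, and is any such difference explained by genetic
diversity (heterozygosity) or not?

Counts are recorded, in principle, without measurement error, which is why
meristic traits are attractive for FA work; the package still estimates
repeatability from double counts to verify that premise.

## The composite index

For individual $i$ and trait $j$ with left and right counts $L_{ij}$,
$R_{ij}$:

$$RA_{ij} = \frac{|L_{ij} - R_{ij}|}{(L_{ij} + R_{ij})/2}, \qquad
  SRA_{ij} = \frac{RA_{ij}}{\overline{RA}_j}, \qquad
  CSRA_i = \sum_j SRA_{ij}.$$

*Relative* asymmetry scales the unsigned side difference by trait size: a
one-count difference is developmentally large for a trait counted in ones
or twos and negligible for one counted in the hundreds
(`relative_asymmetry(1, 2)` $= 0.667$ versus
`relative_asymmetry(101, 102)` $\approx 0.0099$). Dividing by the trait
mean $\overline{RA}_j$ — taken over **all individuals pooled across
populations** — puts traits with different baseline FA–DI relations on a
common scale, so each retained trait has mean SRA exactly 1; the
per-individual sum weights every trait equally (a count-scaled variant of
the standard CFA2-style composite). Two identities follow and are enforced
by tests to numerical precision: per-trait mean SRA $= 1$ (within
$10^{-12}$), and with complete data the mean CSRA equals the number of
retained traits (within $10^{-9}$).

Numerical/degenerate-input choices, all configurable:

* **RA is unsigned.** The composite is an FA index, so $|L-R|$ enters the
  chain; the signed $L-R$ values are kept separately because the
  directional-asymmetry and antisymmetry screens need them. (Computing RA
  signed and absolutizing at the composite stage would be numerically
  identical.)
* **$(0,0)$ pairs**: a structure absent on both sides is read as
  symmetric, so RA $=0$ with a logged warning (`zero_pair = "zero"`);
  `"missing"` drops the cell instead. The default keeps CSRA defined for
  individuals lacking a line entirely, the common biological reading of
  absence.
* **Missing traits in the sum**: the default `"rescale"` policy multiplies
  the observed sum by $n_\mathrm{retained}/n_\mathrm{observed}$ so
  composites stay comparable across individuals; `"complete"` gives `NA`
  unless all retained traits were scored. The choice is declared rather
  than inherited: the source analyses do not state a missing-data policy.
* **Zero-mean traits** carry no asymmetry information and are dropped from
  the composite with a warning.
* A per-population standardization (`pooling = "per_population"`) is
  available for sensitivity analyses but is not the default.

## Screens that license the FA interpretation

Before any FA inference, two alternative asymmetry types must be excluded.

**Directional asymmetry** (one side consistently larger):
`da_screen()` runs a two-sided one-sample *t*-test of the signed
differences against zero in every population × trait cell. No
multiple-testing correction is applied on purpose — the analysis compares
the *flagged fraction* of cells with the nominal level $\alpha$ (a pure-FA
dataset flags $\approx \alpha$ of cells), rather than interpreting single
cells. Zero-variance cells are reported with undefined *t* and never
flagged. Ties and discreteness are accepted as-is; simulation shows the
*t*-battery stays close to nominal on rounded counts (type I
$\approx 0.045$ at $\alpha = 0.05$, $n = 20$).

**Antisymmetry** (asymmetric, but the larger side varies): its signature
is a platykurtic or bimodal signed-difference distribution. The usual
visual inspection is formalized as: flag a cell when excess kurtosis
$< -1$ (an exact two-point antisymmetric mixture has excess kurtosis
$-2$) **or** Hartigan's dip test rejects unimodality at $\alpha$. Both
thresholds are exposed because the visual criterion they replace is
irrecoverably informal. At $n \approx 20$ the kurtosis arm triggers by
chance roughly 10% of the time under a unimodal normal, so the combined
default screen is deliberately sensitive: flags are advisory prompts for
inspection. The dip arm alone is calibrated (false-positive rate
$\le \alpha$). In strict mode the pipeline aborts FA inference when more
than 10% of cells show directional asymmetry; the default is advisory
reporting, since a few percent of chance flags is expected and ignorable.

The dip statistic is computed from its definition — the minimal sup-norm
distance between the ECDF and any unimodal CDF (convex below the mode,
concave above, atom allowed at the mode) — by a band-feasibility test
inside a bisection, exact to $10^{-8}$. Hand-derivable values anchor the
implementation: two equal atoms give $0.25$, $n$ equally spaced points
give $1/(2n)$, a degenerate sample gives $0$. P-values are Monte-Carlo,
against the uniform null (the classical least-favourable unimodal
reference), memoized per sample size with a fixed internal seed so results
are deterministic and the caller's RNG state is untouched.

**Repeatability**: for each trait, the one-way intraclass correlation of
signed differences across the two counting sessions (individuals as
groups; for two sessions $R = (MS_B - MS_W)/(MS_B + MS_W)$), with the
ANOVA *F* p-value. Identical recounts give $R = 1$ exactly.

## Heterozygosity

Expected heterozygosity per locus and population uses Nei's unbiased gene
diversity $\frac{2n}{2n-1}(1 - \sum_k p_k^2)$ (the "gene diversity" of
standard population-genetics software); the uncorrected $1-\sum p_k^2$ is
available by flag for cross-checks. Missing genotypes are excluded
cell-wise (per locus within population), not individual-wise. Population
means are arithmetic means over loci with data; standard errors are
reported both across loci (within population) and across populations
(within habitat), and labelled as such — the two answer different
questions.

`habitat_standardize()` shifts each habitat's population values to the
unweighted grand mean ($x - \bar{x}_\mathrm{habitat} +
\bar{x}_\mathrm{grand}$). It is idempotent, preserves within-habitat
differences exactly, and is the device that asks whether an
across-population correlation survives once the habitat contrast is
removed. The unweighted grand mean is declared for generality; with equal
population counts per habitat the weighting is moot.

## The inference chain

* `fa_glmm()`: CSRA with habitat and sex fixed, population-level
  heterozygosity as a covariate, habitat × sex and habitat ×
  heterozygosity interactions, and population (nested within habitat — the
  population labels are unique, so a random intercept on population *is*
  the nested effect) as a random intercept. REML estimation; type III *F*
  tests with **Satterthwaite** denominator degrees of freedom (the
  convention that produces the familiar fractional denominators such as
  $F_{1,6}$ or $F_{1,156}$ in this design); backward elimination at
  $P < 0.05$, always removing the highest-p *interaction* first and
  touching a main effect only when no remaining interaction contains it.
  The random variance is tested with a Wald $Z$ (two-sided), computed from
  the observed information of the REML criterion — written out directly,
  because the mixed-model fitters do not report a variance-component
  standard error. The Wald test's boundary conservatism is known; a
  singular fit is flagged rather than tested. Habitat least-squares means
  (± SE) come from the fitted model.
* `het_glmm()`: the same machinery with locus-wise $H_E$ as response and
  habitat as the only fixed factor.
* `het_glm_posthoc()`: one-way fixed-effect GLM over loci with population
  as the factor, then all pairwise Fisher LSD tests (unadjusted *t* on the
  pooled error), returned as a symmetric p matrix with unit diagonal.
* `sra_manova()`: type III multivariate tests (Wilks' $\Lambda$, Rao *F*)
  of habitat, sex, habitat × sex and population-within-habitat — all
  fixed, since multivariate models admit no random factor; heterozygosity
  is deliberately excluded (it is population-level and population is in
  the design). The nested factor cannot be expressed as an ordinary factor
  contrast (its block spans the habitat column), so the design matrix is
  built explicitly from within-habitat sum contrasts and the SSCP algebra
  is computed directly; tests verify exact agreement with `car::Manova`
  and `stats::manova` on non-nested designs. A significant multivariate
  habitat effect triggers univariate per-trait habitat *F* tests. Linearly
  dependent response columns are dropped with a warning. The composite
  index, not the MANOVA, is the primary analysis: summed standardized
  indices are known to outperform the multivariate route, which serves
  here as a trait-by-trait corroboration.
* `spearman_pair()`: Spearman's $\rho$ on average ranks, with an **exact**
  permutation p-value for $n \le 10$ — the full $n!$ null distribution of
  $\sum r_x r_{y(\pi)}$ obtained by dynamic programming over subsets
  (ties handled via doubled half-integer ranks), verified against literal
  120-permutation enumeration at $n = 5$ — and the *t* approximation
  above. Two-sided by default. One-sided p-values are computed on request
  and labelled; for near-zero $\rho$ at $n = 8$ the two conventions
  differ markedly, which is worth keeping explicit when comparing against
  published single-sided values.
* `fa_het_correlation_stage()` reports the raw and habitat-standardized
  correlations side by side. When asymmetry and heterozygosity differ
  *only* by habitat, the raw $\rho$ is strongly negative while the
  standardized one is centred on zero — the signature of a
  habitat-confounded association rather than a genuine
  heterozygosity–FA link.

## What the generator emulates — and what it does not

`simulate_counts()` draws a latent trait size $T \sim
N(\mu_j,\, 0.15\,\mu_j)$ truncated positive, then develops the two sides
independently: $L = \max(0, \mathrm{round}(T + \delta_{DA} + a +
\varepsilon_L))$, $R = \max(0, \mathrm{round}(T - a + \varepsilon_R))$
with $\varepsilon \sim N(0, \sigma_{DI}^2)$ per habitat and $a = \pm
\delta_{AS}$ with equal sign probability. Normal-plus-round noise was
chosen over Poisson so the DI variance is tunable independently of the
trait mean — a modelling choice, not an empirical claim; the true noise
distribution of neuromast development is unknown and the generator is
exchangeable behind the same interface.

Closed forms make the generator checkable: the signed side difference has
SD $\sigma_d = \sigma_{DI}\sqrt{2}$, so $E[RA_j] \approx
\sigma_d\sqrt{2/\pi}\,/\,\mu_j$, and the expected composite ratio between
habitats equals the ratio of their $\sigma_{DI}$ values —
`calibrate_di_ratio()` inverts this linear relation. Rounding and zero
truncation attenuate or distort the realized ratio mildly (the closed form
is verified within 10% for $\mu_j \ge 10$; the end-to-end composite ratio
within 20%); those tolerances are documented properties of discretization,
not fitting slack.

Defaults, fixed once: 4 populations per habitat × 20 individuals
(balanced sexes), 12 traits with means 3–30 to exercise per-trait
standardization, $\sigma_{DI} = 0.3$ counts per side in both habitats
(threefold-DI scenarios use `calibrate_di_ratio(3)`, i.e. pond 0.9),
recount error probability 0.02 per side, 23 loci × 8 alleles with
symmetric Dirichlet allele frequencies. The Dirichlet concentrations
(marine 0.25, pond 0.065) are moment-matched so the expected drawn-locus
gene diversity $1 - (a+1)/(ka+1)$ reproduces the study system's habitat
levels ($\approx 0.58$ marine, $\approx 0.30$ pond); genotypes are two
independent allele draws per individual (Hardy–Weinberg, no linkage, no
inbreeding or mutation model).

What passing tests therefore show — and do not: the pipeline recovers
known effects from data with *this* statistical structure (independent
individuals, side-independent Gaussian noise, HWE genotypes,
habitat-exchangeable populations). Real data may violate any of these
(size-dependent noise, within-population family structure, null alleles,
selection on markers); the tests say nothing about such violations, which
is precisely why the screens and repeatability stages exist as data-facing
checks.

## Problem sizes in the test suite

The property tests run at the design size above (160 individuals × 12
traits, 23 loci). Monte-Carlo calibrations use 2000 replicates for the
directional-asymmetry null, 500 for mixed-model type I error, 100 for
threefold-ratio recovery, 200 for the correlation-confounding contrast,
and $n = 5000$ individuals for the closed-form RA check — sizes at which
binomial Monte-Carlo error is comfortably inside the asserted bands.

## Known limitations

* The Wald $Z$ on a variance component is conservative near the boundary;
  singular fits return a flag instead of a test.
* Satterthwaite denominators are an approximation; they are the
  convention matched here, and no attempt is made to reproduce any
  particular software's containment heuristics beyond it.
* The dip p-value is Monte-Carlo against a continuous uniform null;
  for heavily tied integer differences it is mildly conservative.
* The antisymmetry kurtosis threshold is a fixed effect-size cut, not a
  test with controlled size (see above) — by design, since it replaces a
  visual judgement.
* With habitat and heterozygosity strongly confounded (as in the
  motivating design), their separate effects are not jointly identifiable
  at 8 populations; backward elimination can retain either. The
  correlation stage, not the mixed model, is the instrument that
  separates the two explanations.
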