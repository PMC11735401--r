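---
title: "Methods: liability-threshold predictions for polygenic editing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: liability-threshold predictions for polygenic editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the modelling choices behind `polyedit`: the exact
formulas, the defaults and where they come from, the numerical conventions,
and the places where we had to make a judgement call.

## 1. The liability threshold model

Disease liability is a latent standard normal variable; an individual is
affected when liability exceeds `t = Φ⁻¹(1 − K)` for lifetime prevalence
`K` (`threshold_from_prevalence()`). We evaluate thresholds and tail
probabilities with `lower.tail = FALSE` throughout so that small
prevalences keep full relative accuracy; prevalences that fall below
1e-12 are flagged with an `"underflow"` attribute rather than silently
returned.

Editing locus `i` from the undesirable to the protective homozygote
changes an individual's liability by at most `2βᵢ`; averaging over
Hardy–Weinberg genotype frequencies, the population-mean reduction from
editing the top `m` loci is

    δ_m = Σᵢ 2 pᵢ βᵢ,

and the edited-genome prevalence is `K_g = 1 − Φ(t + δ_m)`
(`prevalence_from_shift()`). This closed form holds the residual liability
s.d. at 1 conditional on the edited genotype. The exact conditional s.d.
is `sqrt(1 − var_g)` where `var_g = Σ 2pᵢ(1−pᵢ)βᵢ²` is the variance
explained by the edited loci; for the ≤10 GWS loci the model targets,
`var_g` is well below 1% and the approximation is inside Monte-Carlo error
of an explicit-genotype simulation (the test suite checks this and also
documents that it degrades as `var_g` grows).

Because genomes differ in which undesirable alleles they carried before
editing, the realized gain varies between genomes with standard deviation
`sqrt(var_g)` (`sd_of_gain()`); prediction curves report
`1 − Φ(t + δ ∓ sd)` as a between-genome band, not a sampling confidence
interval.

## 2. From summary statistics to ranked loci

`read_locus_table()` ingests TSV summary statistics with a canonical
schema (`locus_id`, `effect_allele`, `other_allele`, `eaf`, `beta_raw`,
optionally `se`, `n_samples`, `p_value`) and a user column mapping.
Validation names the offending locus and row.

- **Binary traits** report log odds ratios; these are converted to
  liability-scale effects with `β = β_logOR · K(1 − K)/z`, `z = φ(t)`
  (`logor_to_liability()`). For `K = 0.05` the multiplier is 0.4606.
- **Quantitative traits** are analysed in phenotypic standard deviations.
  If the trait's s.d. is not supplied, it is recovered from the GWAS
  standard errors via `sd² ≈ mean(2pᵢ(1−pᵢ) nᵢ seᵢ²)`
  (`estimate_phenotypic_sd()`), which returns exactly 1 for a GWAS run on
  a standardized trait.

`orient_loci()` re-expresses every record in terms of the undesirable
allele (the liability-increasing or biomarker-worsening allele), flipping
frequency and sign as needed, so downstream code never sees a negative
effect. `rank_loci()` orders loci by `pᵢ βᵢ` — the expected per-genome
liability gain from editing that locus — with lexicographic tie-breaking
on `locus_id`, and keeps at most 10 loci by default. Orientation is a pure
reparameterization: the test suite verifies bit-level invariance of the
prediction curves under allele flips.

## 3. Editing direction, G×E, and population shift

`edit_plan()` fixes a trait, a ranked locus set, a maximum number of edits
and a G×E genetic correlation `r_g`. The default direction is
risk/trait-decreasing; the trait-increasing direction
(`trait_shift(..., direction = "increase")`, gain `Σ 2(1−pᵢ)βᵢ`) is
exposed for non-disease traits but unused elsewhere.

If genetic effects correlate only `r_g` between the GWAS environment and
the environment an edited person will live in, the realized mean shift is
`r_g · δ`; `disease_curve()` and `quantitative_curve()` apply `r_g` to the
shift while reporting the raw `δ` alongside. `r_g = 1` recovers the naive
prediction; `r_g = 0` leaves prevalence unchanged.

If a fraction `f` of all conceptions is edited, the population mean moves
by `f · δ` (`population_mean_shift()`), an exact identity used as one of
the acceptance checks.

## 4. Sensitivity analyses

- **Misidentified causal variants** (`apply_misidentification()`): the
  named rank slots are edited but contribute nothing (`β = 0`), modelling
  tag variants mistaken for causal ones. Loci are *not* re-ranked: the
  editor believed the original ranking. With equal per-locus
  contributions, nulling `k` of `m` loci scales the gain by exactly
  `(m − k)/m`.
- **Effect-size shrinkage** (`shrink_effects()`): all effects multiplied
  by a factor in (0, 1], modelling winner's curse or cross-population
  attenuation; quantitative outcomes scale exactly, disease outcomes are
  recomputed through the probit.
- **Off-target load** (`offtarget_fitness()`): each edit independently
  introduces an off-target mutation with probability `q`; the number of
  hits is Poisson with mean `edits · q`, each multiplying fitness by
  `(1 − s)`. The expectation `E[(1−s)^X] = exp(−edits · q · s)` is exact,
  not an approximation.
- **Stabilizing selection** (`stabilizing_fitness()`): Gaussian fitness
  profile `exp(−(Δz − opt)²/(2 V_s))` with the conventional width
  `V_s = 20` (in units of phenotypic variance), penalizing large
  directional trait shifts.

## 5. The inequality simulation

The question: if only some genomes are edited, what happens to the
*distribution* of individual disease risk? We summarize it with the Gini
index (`gini_index()`, the sorted-rank identity
`Σ(2i − n − 1)x₍ᵢ₎ / (n² x̄)`, validated against an O(n²) pairwise oracle;
we implement it directly rather than depend on an external package).

Each unedited individual `j` has liability percentile `ℓⱼ ~ N(0,1)` and
individual lifetime risk `1 − Φ(ℓⱼ)` — uniform on (0, 1), giving the
baseline Gini of exactly 1/3 for any disease. The design decision is how
to assign risks to *edited* individuals. A naive "shift each edited
individual's liability and re-read the percentile risk" construction makes
the mixture Gini monotone in the edited fraction, so the population Gini
would either never exceed or never return below the baseline — it cannot
reproduce the qualitative behaviour the model is meant to exhibit
(inequality first rising under partial adoption, then falling once editing
is widespread). The form that does exhibit it — and the package default
(`form = "guarantee"` in `gini_curve()`) — treats editing as delivering a
*guaranteed* prevalence: every edited individual's risk is the point value
`K′` (the ten-locus edited prevalence), while unedited individuals keep
their heterogeneous percentile risks. Partial adoption then splits the
population into a privileged low-risk class and an unchanged majority:
relative Gini rises well above 1, peaks at an interior fraction, and
crosses below baseline only at high fractions. The alternative
constructions remain available as `form = "percentile"` (shared-percentile
liability shift) and `form = "heritability"` (only the genetic variance
share of liability is shifted, split by `h2`), and
`individual_risks()` defaults to the percentile form as the elementary
building block.

Defaults: `n = 10⁶` simulated individuals, fractions 0–1 in steps of 0.01,
one liability draw per run reused across fractions (so the curve is smooth
in `f` and fully seed-reproducible), edited individuals taken from the
start of the draw. `K′` defaults to the ten-locus edited prevalences of
the five preset diseases; a fold-change interface (`fold =`) is also
provided. A 101-point grid for five diseases at `n = 10⁶` runs in about a
minute on one CPU.

## 6. Synthetic GWAS generator

`simulate_true_loci()` draws true frequencies from a configurable
distribution and true effects with s.d.
`effect_sd · (2p(1−p))^(α/2)`; `α = 0` decouples effect size from
frequency, `α = −1` equalizes expected per-locus variance contributions,
mimicking negative selection. `simulate_gwas_estimates()` adds sampling
noise with the exact standardized-trait standard error
`1/sqrt(2p(1−p) n_gwas)`, computes two-sided p-values, flags genome-wide
significance (`p < 5 × 10⁻⁸`), reports each locus for a random allele
(exercising orientation), and for binary traits converts to the log-OR
scale so the full ingestion path round-trips. Significance selection at
low power produces genuine winner's-curse inflation, which the test suite
demonstrates and debiases with a known shrinkage factor.

Preset traits (five diseases: prevalences 5, 1, 10, 6, 15%; five
biomarkers with typical phenotypic s.d.s and units) are provided via
`trait_presets()`; `make_disease_fixture()` writes a synthetic,
clearly-labelled TSV per trait for examples and tests. All synthetic data
carry a `# SYNTHETIC` header line.

## 7. Numerical and testing conventions

- Upper-tail `pnorm`/`qnorm` everywhere tails matter; no
  `1 − pnorm(...)` subtractions for small probabilities.
- Oracles are independent of the implementation: frozen
  quadrature/bisection constants for thresholds and multipliers,
  explicit-genotype Hardy–Weinberg Monte-Carlo for prevalences (with
  `3 ×` binomial MC standard error as the agreement bound), exhaustive
  `3^m` genotype enumeration for joint probabilities, pairwise-mean Gini.
- Exact identities (population shift, misidentification and shrinkage
  scaling, flip invariance) are tested at tolerance 1e-12 or with
  `expect_identical`.
- Simulation sizes in tests are the package's own choice, balancing MC
  error against runtime; stochastic assertions use fixed seeds and bounds
  derived from the relevant standard errors, not tuned constants.

## 8. Limitations

Everything here is conditional on a deliberately idealized model:
additivity on the liability scale, Hardy–Weinberg and linkage equilibrium,
correctly identified causal variants with exchangeable effects across
environments and ancestries, and editing that is perfect apart from the
explicitly modelled off-target channel. The sensitivity module quantifies
how fast the headline predictions degrade when those assumptions fail;
none of the outputs should be read as forecasts about real interventions.
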