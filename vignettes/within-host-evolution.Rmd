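---
title: "Modelling and measuring within-host evolution of a gut commensal"
author: "gutevolve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring within-host evolution of a gut commensal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutevolve)
```

This vignette describes the model behind the `gutevolve` simulator, the
statistical procedures on the inference side, and the design decisions
taken where the methodology was genuinely open. The setting is an
experimental-evolution design: a barcoded (YFP/CFP) *E. coli* population
inoculated 1:1 into antibiotic-pretreated mice, followed daily by plating,
with short-term competition assays, resistance plating, rRNA-based growth
estimation, and end-point sequencing/typing layered on top.

## The simulator

### State space

Per-cell simulation is impossible at gut loads (~10^8 cells), so the
population is a table of *haplotype classes*: each class is a combination
of fluorescent marker, set of beneficial loci mutated, and set of
resistance alleles (each tagged by its mutational channel, point or IS).
Class-level multinomial resampling has exactly the same marginal law as
resampling individuals, at a cost that depends only on the number of
classes (capped, by default at 512, with an explicit resource error).

### One generation

Each generation applies, in order:

1. **Selection.** Class counts are multiplied by relative fitness and
   renormalized to the population size. Beneficial effects act as
   Malthusian coefficients (`w` multiplies by `exp(s_gen)` per mutated
   locus), so a deterministic single sweep follows the logistic closed
   form `p(t) = p0 e^{σt} / (1 - p0 + p0 e^{σt})` *exactly*, and the
   per-hour log-ratio slope of a competition assay is an unbiased estimate
   of the per-hour advantage. Resistance costs act as per-generation
   Wright–Fisher costs (`w` times `1 - s_d`), which makes the
   deterministic mutation–selection equilibrium exactly `μ_r / s_d`.
   These two conventions differ at second order in `s`; each was chosen to
   make the corresponding observable exact.
2. **Mutation.** Poisson fluxes with expectation `N·x·μ` per source class
   (expected values in deterministic mode). Resistance mutation is split
   between the point and IS channels by `is_fraction`. All channels draw
   against a snapshot of pre-mutation counts — double events within one
   generation are ignored, which is safe because all rates are far below
   one event per class pair per generation.
3. **Resampling.** A multinomial draw returns the population to size `N`
   (skipped in deterministic mode).

Time is converted between units via `gens_per_day = 1440 / gen_time_min`
and `s_gen = s_hour × gen_time_min / 60`. Sampling days map to the
nearest generation; emitted sampling times are the *realized* times of
those generations, so downstream regressions on time are not biased by
grid rounding.

### Antagonistic pleiotropy

The selective effect of each beneficial locus is drawn once per host from
`Normal(s_mean_per_hour, s_sd_per_hour)` and held constant within that
host. A standard deviation large enough to put mass at or below zero
produces mutations beneficial in some hosts and neutral or deleterious in
others, which is the observed signature in immune-compromised animals.
The within-host constancy is a modelling choice: nothing in the data
constrains how `s` might drift as the resident microbiota recovers from
antibiotic pretreatment, so the simplest (constant) form is used.

### Plate sampling

Non-selective plates draw `depth` colonies (default 200; 600 in
competition assays) binomially against the true marker and phenotype
frequencies. Resistant classes at mutation–selection balance sit at
frequencies around 10^-6 and would be invisible at 200 colonies, so
selective plates are simulated with an independent, much larger effective
depth (default 10^7 cells), mirroring the laboratory practice of plating
concentrated material on antibiotic plates.

### Presets

| preset | emulates | key values |
|---|---|---|
| `wt-competition` | gat-mutant vs ancestor assay, immune-competent | 76-min generations, s ~ N(0.068, 0.008) per hour |
| `rag2-competition` | same assay, immune-compromised | 66-min generations, s ~ N(0.03, 0.016) per hour |
| `wt-growth` / `rag2-growth` | true in-gut growth rates | 60·ln2/76 and 60·ln2/66 per hour |
| `fzd-wt` | furazolidone resistance at balance | μ_r = 2.2387e-7, s_d = 0.1, IS fraction 0.457 |
| `paper-replica` | full two-genotype evolution cohort | 4 beneficial loci + resistance locus, 24 days |

The measured anchors are the mean advantages, generation times, and the
equilibrium resistant fraction (log10 −5.65 at cost 0.1). Decompositions
that the measurements do not pin down are documented inferences: the
across-host standard deviations derive from the reported dispersion of
per-host estimates (for the immune-compromised preset, 2 s.e.m. of 0.01
at n = 10 gives an across-host sd of ≈ 0.016); the resistance
`is_fraction` of 0.457 back-derives from the measured transposition
(−5.99) versus total (−5.65) furazolidone frequencies; the `fzd-wt` split
of the equilibrium into μ_r and s_d fixes the cost at 0.1 per generation,
a conventional order for weakly deleterious resistance alleles. In the
`paper-replica` preset the non-gat selective effects and all mutation
supplies are not directly measured; they are chosen once to reproduce the
qualitative dynamics (gat sweeps first and fastest; later targets
interfere clonally; dcuB is beneficial only in the immune-competent
host).

### What the generator does not emulate

No spatial structure in the gut, no migration between hosts, no
horizontal transfer, and no explicit microbiota dynamics — host and
microbiota effects enter only through host-genotype-specific selection
parameters. Passing recovery tests on these synthetic cohorts therefore
shows that the estimators are correct *under the stated generative
model*, not that real gut populations satisfy that model.

## Inference procedures and their design decisions

**Marker divergence.** `ln(YFP/CFP)` is regressed on day over days 1–6
(the first post-gavage samples; including day 0 is a documented
alternative) and the slope tested against zero at α = 0.05. Days with a
zero marker count carry no finite log-ratio; they are excluded with a
warning rather than pseudo-counted (a +0.5 pseudo-count mode exists for
sensitivity analysis), and lines with fewer than four usable days are
*not evaluable* — distinct from non-diverged. The group comparison of
diverged-line counts is a conditional binomial test (given the total
number of diverged lines, their split between groups is binomial under
the null); Fisher's exact test is exposed as an alternative. Both are
exact; the conditional construction was chosen as the default because it
conditions on exactly the statistic that varies between cohorts.

**Type-I control and population size.** On neutral simulated lines at
gut-load population size (10^8), plating noise dominates and the nominal
α holds (the suite checks ≤ 0.10 at α = 0.05 over 200 lines). At small
population sizes genetic drift adds a random-walk component to the
log-ratio that ordinary least squares does not model, and the realized
type-I rate rises above nominal — a caveat for low-load applications.

**Competition fitness.** Unweighted OLS of `ln(mutant/reference)` on
hours with a free intercept; the slope is `s` per hour. Weighting by
counts or forcing the intercept through the inoculum ratio are possible
refinements, but the unweighted free-intercept form is the conventional
reading of "slope of the linear regression" and is exact on noiseless
data for any `s` and starting ratio. Variance comparisons use the
two-sided F test (sample variances, smaller-tail doubling); group
comparisons use one-way ANOVA with Tukey HSD (studentized range), or a
two-way layout with interaction for host × microbiota designs, which
requires a complete factorial and names any empty cell in its error.

**Mutation frequency.** Daily log10 resistant fractions are averaged
within mouse, then across mice (the hierarchical average; pooling all
mouse-days is the documented alternative and would weight mice by their
number of uncensored days). Zero-resistant days are detection-censored,
not zero — a +1 pseudo-count mode exists for sensitivity analysis. The
rank test reports `W` as the rank sum of the first sample; p-values are
exact by a generating-function recursion over midranks for group sizes
≤ 12 (handling ties exactly, which the classical tables do not), with a
tie-corrected normal approximation beyond.

**Division rate.** The calibration is fit as rate-on-fluorescence and
inverted by prediction; fitting fluorescence-on-rate and inverting
algebraically (inverse regression) is the documented alternative. The
linear form matches the near-linearity of rRNA content in growth rate
over moderate rates; a log-linear option can be emulated by transforming
the input. Growth curves are fit on the maximal-R² sliding window
(default five points) within OD 0.02–0.5, isolating exponential phase
without a hand-picked window. Doubling-time standard errors propagate the
calibration prediction error by the delta method.

**Sweep fit.** The reference analysis for such data is a random-intercept
binomial GLMM; `gutevolve` instead fits a fixed-effects binomial GLM with
the initial frequency constrained equal across genotypes and handles
mouse-level dependence with cluster-robust (sandwich) standard errors.
This preserves valid genotype-level inference while avoiding mixed-model
machinery, but the resulting `z` is not numerically comparable to a
GLMM's. Sign convention: with the non-WT genotype as reference, `z > 0`
means the immune-competent host sweeps faster. Complete separation is
flagged rather than silently reported.

**Haplotypes and parallelism.** Variant tables are filtered at an
inclusive 5% frequency cutoff; parallel targets must appear in at least
two populations (pooled across genotypes) and reach 10% in at least one.
Prevalence uncertainty uses the proportion standard error with a
degenerate-case rule of `1/n` when all or no populations are hit — a rule
reverse-engineered from report values such as "100% (±7%)" at n = 14 and
15 (a Wilson interval is the principled alternative; the degenerate rule
reproduces the published arithmetic and is kept as the default for
comparability, and the quoted "±2 s.e.m." values numerically match one
standard error, a discrepancy reproduced rather than corrected).
Host-specificity uses the exact one-sided hypergeometric tail
(conditioning on total hits), with a doubled-tail two-sided variant; for
the classic 7/14-vs-0/15 configuration it gives 0.0022. Population "hit"
status defaults to the 10% threshold (configurable to 5%). Clonal
interference requires two *non-nested* mutated-locus sets each at ≥ 10%:
nested sets are ancestor–descendant, not competitors.

## Numerical choices

- Exact-fit regressions (zero residual variance) are special-cased: a
  zero slope is reported with p = 1, a nonzero exact line with p = 0
  (machine-limited), avoiding 0/0 in the t statistic.
- The binomial sweep fit caps IRLS at 100 iterations and errors with the
  deviance on non-convergence.
- All randomness flows from one root seed through named substreams
  (FNV-1a-mixed), so adding or reordering stages does not perturb other
  stages' draws, and identical configuration plus seed reproduces output
  byte-for-byte.
- The multinomial resampler requires integer population sizes below
  2^31; larger populations must use deterministic mode (the analyses
  here never need stochastic populations above 10^8).

## Problem sizes used in the shipped checks

Recovery checks run at the design's own scale: 20 replicate competition
cohorts of 10 hosts (600 colonies at 0/24/48/72 h) per preset; 6 mice ×
2 days for doubling-time inversion against an 8-condition calibration
(rate noise sd 0.02/h, fluorescence noise sd 10 a.u. — chosen once as
realistic bench-scale noise); 6 mice × 15 daily platings at effective
selective depth 10^7 for the resistance equilibrium, after a 150-
generation burn-in (the equilibrium relaxes on a 1/s_d = 10-generation
timescale); 200 neutral lines for type-I control.

## Known limitations

- Constant `s` within host; no frequency dependence or time variation.
- The class cap makes very-high-diversity regimes (many simultaneous
  targets at high mutation supply) a deliberate error rather than a slow
  crawl.
- The sweep fit's robust errors are asymptotic in the number of mice;
  with very few mice per genotype the `z` is anti-conservative.
- Mutation-rate inversion from equilibrium frequencies is model-dependent
  (requires an assumed cost) and is labelled as such in the output.
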