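---
title: "Analysing graded dominant-mutant titrations with gradedmut"
author: "gradedmut authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing graded dominant-mutant titrations with gradedmut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradedmut)
```

## The experimental design this package analyses

A knockout removes a whole protein; for multifunctional proteins (the
prototype here is the yeast histone acetyltransferase Gcn5p, which combines
catalytic activity with Ada2/SAGA complex interactions and a bromodomain) a
knockout therefore confounds the loss of every function at once and invites
compensation by redundant enzymes. The graded dominant-mutant design
isolates one function: a catalytically dead point mutant (e.g. gcn5-F221A)
is expressed alongside the wild-type allele from a library of promoters of
known relative strength (PS, expressed relative to the native TEF promoter).
The dead allele competes with the wild-type protein for substrates and
complex partners, so increasing PS titrates down the *catalytic* activity
specifically, while protein-interaction functions remain provided by both
alleles.

Three data types arise and each has a module here:

* **Dose-response curves** from a fluorescent reporter read out against PS
  (`fit_hill`, `compare_ic50`).
* **Expression matrices** over {wild-type control, knockout, mutant at
  several PS} in biological triplicate (`differential_expression`,
  `detect_graded`, `classify_genes`, `estimate_grading_threshold`,
  `venn_summary`).
* **Plate-reader growth curves** for phenotypic and synthetic-lethal assays
  (`growth_rate`, `classify_impact`).

Chromatin-mark annotation sets close the loop: if the titration really
targets acetylation, the graded-up genes should be depleted of the marks the
enzyme writes (`class_enrichment`).

## The competitive-inhibition model

Signal versus promoter strength is modelled by the Hill-slope competitive
inhibition curve

$$\mathrm{signal}(PS) = Bottom + \frac{Top - Bottom}{1 + (PS/IC_{50})^h},$$

where *Top* is the uninhibited signal, *Bottom* the signal of a
competitively saturated system, and the $IC_{50}$ is the promoter strength
at which the signal lies exactly halfway between the two. `fit_hill`
minimises the residual sum of squares with a bounded Levenberg-Marquardt
optimiser, multi-started over a log-spaced $IC_{50}$ grid spanning
$[\min PS/10,\ 10\max PS]$, because the RSS surface is multimodal in
$IC_{50}$ for sparse noisy curves. Replicates enter as individual
observations so replicate count weights the loss (averaging first is
available and, with balanced replicates, gives the same optimum).

Numerical choices worth knowing:

* The Hill slope $h$ is fit freely within $[0.2, 10]$ by default; `fix_slope`
  pins it (the identifiable fallback for very sparse curves).
* `fix_bottom` pins the saturated plateau to an independently measured
  value; the grading-threshold estimator uses this with the knockout level
  (below).
* On positive signal scales, *Top* is bounded to $[0.5, 2]\times$ the
  maximum observed signal and *Bottom* to $[0, 2\times$ minimum$]$; on
  signed scales (negated log2 expression) shift-invariant bounds of the same
  widths are used.
* A flat response is reported as `converged = FALSE` with an undefined
  $IC_{50}$; the fit never fabricates a value for unidentifiable input.
* Parameter uncertainty comes from the Gauss-Newton covariance
  $s^2 (J^\top J)^{-1}$; `compare_ic50` propagates the log-scale standard
  errors into a delta-method standard error for the ratio. The canonical use
  is haploid versus diploid reporter hosts, where doubling the gene dosage
  of the wild-type allele should double the $IC_{50}$.

In the packaged recovery studies the dose-response arm is simulated on the
nine-strength promoter-library grid (0.07, 0.11, 0.16, 0.25, 0.32, 0.49,
0.68, 0.95, 1.17), the design of the fluorescence assay, with triplicates
and Gaussian noise of 2% of the dynamic range; under those conditions the
median $IC_{50}$ error is about 8%. On the coarser five-strength subset
printed for the expression and growth arms the same error is 11%, which the
Cramer-Rao bound shows to be essentially the information limit of that
design rather than an estimator deficiency.

```{r hill-example}
curve <- simulate_dose_response(top = 100, bottom = 20, ic50 = 0.3,
                                ps_grid = c(0.07, 0.11, 0.16, 0.25, 0.32,
                                            0.49, 0.68, 0.95, 1.17),
                                noise_sd = 1.6, seed = 1)
fit_hill(curve$ps, curve$signal)
```

## Graded-expression analysis

### Differential expression

`differential_expression` computes per-gene log2 fold changes (condition
minus wild-type control throughout) and a moderated t statistic: per-gene
variances are shrunk towards a pooled prior fit by method of moments to the
log sample variances (matching the mean and variance of $\log s^2$ against
the scaled-F model gives the prior degrees of freedom $d_0$ and scale
$s_0^2$), and the null distribution gains $d_0$ degrees of freedom. This is
the standard empirical-Bayes treatment for three-versus-three microarray
contrasts, implemented transparently in the package; a plain Welch t is
available for cross-checks. Significance uses raw p-values with the
thresholds the analysis is defined with (p < 0.05 and |log2FC| > 1);
BH-adjusted columns are emitted for information only, since the published
gene counts are defined on raw thresholds.

### Monotone (graded) detection

A gene is *graded* when its expression moves monotonically with PS. The
control enters the ordered series as PS = 0; the knockout is excluded from
the trend and serves only as a comparator. The call requires:

1. a Jonckheere-Terpstra ordered-trend p-value below 0.05 in either
   direction. The JT statistic sums pairwise Mann-Whitney counts over
   ordered group pairs; for at most 10 observations the permutation null is
   enumerated exactly over all distinct group assignments, otherwise a
   normal approximation with the standard tie correction is used;
2. per-level means monotone in the trend direction up to a tie tolerance.
   With only three or four titration levels, strict inequality of noisy
   means is too brittle, so the tolerance is noise-aware:
   $\max(0.1, 2\,\mathrm{SE})$ log2 units, where SE is the standard error
   of a difference of two level means from the pooled within-level
   replicate variance. A fixed 0.1 band alone would reject genuinely graded
   genes whose adjacent level means differ by less than replicate noise
   (at noise sd 0.25 and triplicates the SE of a mean difference is about
   0.2); with noise-free data the tolerance reduces to the fixed band.

### Gene classes

Crossing the knockout calls with the graded calls yields the four
(deliberately non-exclusive) classes:

| class | definition | interpretation |
|---|---|---|
| CA_U / CA_D | graded up / down | catalytically associated |
| NCA | knockout-significant, not graded | non-catalytic protein role |
| FN | graded, knockout-unchanged | redundant enzyme compensates in the null |
| OPP | graded and knockout-significant in opposite directions | complex partitioning |

`classify_genes` enforces the structural invariants (FN and OPP imply a CA
flag; NCA excludes it; at most one of CA_U/CA_D), and `venn_summary` does
the direction-resolved set arithmetic between the knockout and titration
gene sets. An UNCAT flag (significant at some mutant level but in no class)
is computed when per-level mutant contrasts are supplied.

### Grading thresholds

The grading threshold $\hat K$ of a graded gene is the PS of half-maximal
response: the midpoint of a Hill fit of mean log2 expression versus PS
(up-graded genes are fit on the negated scale so the decreasing model form
applies). Maximal gradation is a plateaued response matching the knockout
condition, so when the knockout mean agrees in direction with the trend and
reaches at least half the largest in-range response, the plateau of the fit
is anchored at the knockout level (`fix_bottom`). Anchoring matters:
thresholds near or beyond the strongest sampled PS leave the plateau
outside the data, and the unanchored fit is then poorly identified (median
$|\hat K - K|$ of roughly 0.3 at replicate noise 0.25 for a gene with
$K = 0.8$, versus roughly 0.13 anchored). Compensated (FN) and opposite
(OPP) genes, whose knockout contradicts the trend, are always fit
unanchored. If the fit fails, the fallback is the smallest PS whose
response reaches 90% of the plateau reference — the plateau itself is not
numerically defined by the design, and 90% is the package's operational
choice.

Low-threshold genes (default $\hat K \le 0.32$, the lowest arrayed PS) are
the most acetylation-dependent subclass and get their own enrichment class.

## Growth assay

Growth rate is the slope of $\ln$ OD versus time during the exponential
phase. The exponential window is found in the "easy linear" style: among
all windows of at least $\max(5, n/10)$ consecutive points whose linear fit
reaches $R^2 \ge 0.99$, the *steepest* wins (ties go to the longer window).
Growth only decelerates along a batch culture, so the steepest log-linear
stretch is the exponential phase; selecting the *longest* admissible window
instead drags the fit into the deceleration phase and underestimates
logistic low-density rates by 20% or more, because $R^2$ over a long window
is insensitive to curvature. Flat or noisy-flat series fall back to a
full-series fit with rate near 0. Replicate rates are aggregated as
arithmetic mean and standard deviation.

The packaged logistic-recovery study inoculates at OD 0.01 against a
carrying capacity of 1.5, so that the series actually contains a deep
exponential phase; at the assay inoculation density of 0.1 (the generator
default) about 7% of capacity is already occupied at the first reading and
a log-linear rate is intrinsically biased low — which cancels in the
relative reductions the impact analysis uses.

Synthetic-lethal impact of a knockout crossed with the titration is
classified from relative rate reductions $1 - r_{strain}/r_{control}$:
**HIGH** if the reduction at the strongest promoter exceeds 20% and the
reduction trend over PS is increasing (JT statistic above its null mean),
**NONE** if the maximum reduction stays below 5%, **MODERATE** otherwise.
The 20% rule is the published decision boundary; the 5% floor is the
package's configurable default for separating unaffected strains from
noise.

## Enrichment

`hyper_test` scores a class-set overlap with both hypergeometric tails
(enrichment $P[X \ge k]$, depletion $P[X \le k]$), BH-adjusted across sets
within each class and tail. The universe is the expression matrix, not the
genome, so the background matches the analysed gene space. The expected
signature for a catalytic titration is *depletion* of the enzyme's
acetylation marks among graded-up, low-threshold genes: losing an
activating mark de-represses these genes, and they are exactly the ones
whose marks the titration removes.

## The synthetic-data generator

Every input type has a seeded generator, so the full pipeline is testable
without downloads. The expression model gives each gene a residual-activity
response $A(PS) = 1/(1 + (PS/K_g)^h)$ — the same competitive-inhibition
shape the reporter assay follows — with archetype rules: CA genes move by
$\pm\,\mathrm{effect}\,(1 - A)$ and their knockout matches the saturated
mutant; FN genes grade but their knockout is compensated back to baseline;
OPP genes grade up while their knockout moves down; NCA genes are flat
across the titration and shift only in the knockout; NULL genes never move.
This is phenomenological, not mechanistic: no occupancy kinetics, no
probe-level or normalisation artefacts, no correlated gene programs.
Passing recovery tests therefore demonstrate that the statistics recover
this structure at realistic noise, not that real microarray data are this
clean.

Defaults mirror the study design: biological triplicates; the titration
grid {0.07, 0.16, 0.32, 0.68, 0.95} (the microarray arm uses the
{0.32, 0.68, 0.95} subset plus control and knockout); baseline 8 and
asymptotic effect 2 on the log2 scale; Gaussian log2-scale noise of sd 0.25
(typical microarray replicate noise — the design itself reports none, so
this is a configurable stand-in); per-gene midpoints $K_g$ uniform on
[0.05, 1], spanning tightly regulated low-threshold genes through genes
that barely saturate in range. Growth curves are logistic (not pure
exponential) precisely so the exponential-window search is non-trivially
exercised, inoculated at OD 0.1 per the plate protocol with 10-minute
readings for 24 h. Annotation sets are Bernoulli memberships at a 30%
background rate, with graded-up genes' membership probability reduced by a
configurable depletion strength.

The synthetic-lethal panel (`synthetic_lethal_reference`) is a labelled
*synthetic* reconstruction: the published per-strain rates are not
redistributed, so reduction magnitudes are constructed per category (three
strains above the 20% boundary, fifteen between 9% and 19%, four at or
below 2.5%) with margins wider than the rate-estimation noise, in
biological triplicate. It reproduces the published category structure, not
the published numbers.

## Problem sizes and what the packaged studies show

The recovery studies shipped in the tests and acceptance script use: 300
genes (50 per archetype) for classification recovery; 200 seeded
replications for the $IC_{50}$ and threshold Monte-Carlos; 2000 null genes
for type-I calibration; 4000 null class draws for enrichment calibration
(the tail fraction is estimated to about $\pm 0.003$, tight relative to the
0.03-0.07 acceptance band); 22 strains by 6 conditions by 3 replicates of
145-point growth curves. These sizes make every study re-runnable in
seconds to minutes while keeping Monte-Carlo error well inside each check's
tolerance.

## Known limitations

* The generative expression model is the analysis model; real data violate
  it (correlated programs, heteroscedastic probes, batch effects). The
  moderated t and JT trend are rank- or variance-robust choices, but the
  recovery rates reported by the simulation study are upper bounds.
* Grading thresholds for FN/OPP genes (no usable knockout anchor) are
  noticeably noisier than for CA genes.
* The enrichment statistic is a standard two-tailed hypergeometric pair;
  the database the original comparison ran against may have used a
  different background or statistic, so absolute p-values are comparable
  only in scale.
* `run_analysis` accepts any expression TSV in the documented dialect
  (e.g. an RMA-processed matrix exported from a public accession), but the
  package neither downloads nor normalises raw array data.

## End-to-end runs

```{r pipeline, eval = FALSE}
report <- run_simulation_study(run_config(seed = 1), outdir = "run1")
report
report$recovery
```

`run_simulation_study` writes per-stage TSVs plus `summary.json`, each
stamped with the package version, config hash and seed; identical
(config, seed) reproduces every file byte for byte.
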