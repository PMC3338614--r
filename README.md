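# gradedmut

Analysis of **graded dominant-mutant titration experiments**: isolating one
function of a multifunctional protein by titrating a function-dead allele
against the wild-type protein.

## The problem

Knockouts remove a whole protein, so for multifunctional proteins —
epigenetic writers, scaffolding enzymes, signalling hubs — knockout data
confound the loss of every function at once and invite compensation by
redundant enzymes. The graded dominant-mutant design expresses a point
mutant that lacks exactly one function (the prototype is a catalytically
dead allele of the yeast histone acetyltransferase Gcn5p) from a promoter
library of known relative strengths (PS). The dead allele competes with the
wild-type protein, so increasing PS titrates down that one function in a
dose-dependent, measurable way. Contrasting the titration with the knockout
separates catalytic from non-catalytic regulation, gene by gene.

`gradedmut` implements the complete downstream analysis for users of this
design — synthetic biologists and systems/epigenomics groups working with
promoter-library titrations:

* **Competitive-inhibition model** — signal vs PS follows
  `signal(PS) = Bottom + (Top − Bottom) / (1 + (PS/IC50)^h)`;
  `fit_hill()` extracts the IC50 (the PS of half-maximal inhibition) by
  bounded multi-start nonlinear least squares, `compare_ic50()` compares
  fits (e.g. haploid vs diploid hosts, where gene dosage doubles the IC50).
* **Graded expression** — moderated-t differential expression
  (empirical-Bayes variance shrinkage), Jonckheere–Terpstra monotone-trend
  detection across the titration (`detect_graded()`), classification into
  catalytically associated (CA), non-catalytically associated (NCA),
  false-negative (FN) and opposite (OPP) genes (`classify_genes()`), and
  per-gene grading thresholds (`estimate_grading_threshold()`).
* **Growth assay** — exponential-phase growth rates from plate-reader OD
  series (`growth_rate()`) and the >20%-reduction rule classifying the
  graded impact on synthetic-lethal knockouts (`classify_impact()`).
* **Enrichment** — hypergeometric enrichment/depletion of chromatin-mark
  gene sets within each gene class (`class_enrichment()`, GMT I/O).
* **Synthetic data** — seeded generators for every input
  (`simulate_expression()`, `simulate_dose_response()`,
  `simulate_growth_curves()`, `simulate_annotations()`), so the whole
  pipeline is testable without downloads.
* **Pipeline** — `run_simulation_study()` / `run_analysis()` orchestrate
  all stages reproducibly and write stamped TSV/JSON outputs.

## Worked example

Fit a noisy reporter titration on the nine-strength promoter library:

```r
library(gradedmut)
curve <- simulate_dose_response(top = 100, bottom = 20, ic50 = 0.3,
  ps_grid = c(0.07, 0.11, 0.16, 0.25, 0.32, 0.49, 0.68, 0.95, 1.17),
  noise_sd = 1.6, seed = 1)
fit_hill(curve$ps, curve$signal)
#> hill_fit: top=95.48 bottom=23.05 ic50=0.3186 h=1.135 (rss=53.6, n=27)
```

The fitted IC50 of 0.319 recovers the generative value 0.3 to ~6% at 2%
measurement noise; Top/Bottom are the uninhibited and saturated signals.

Run the full simulated study (300 genes, 50 per archetype, triplicates,
noise sd 0.25, the three-level microarray arm plus control and knockout):

```r
rep <- run_simulation_study(run_config(seed = 1))
rep$recovery
#>   archetype n_true n_pred precision recall  accuracy
#> 1     CA_UP     50     50 1.0000000   1.00 0.9766667
#> 2   CA_DOWN     50     48 1.0000000   0.96 0.9766667
#> 3       NCA     50     51 0.9607843   0.98 0.9766667
#> 4        FN     50     52 0.9423077   0.98 0.9766667
#> 5       OPP     50     51 0.9803922   1.00 0.9766667
#> 6      NULL     50     48 0.9791667   0.94 0.9766667
```

Each row compares the classification against the generative ground truth:
e.g. 50 of 50 true CA_UP genes are recovered with no false positives, and
overall archetype accuracy is 97.7% at realistic noise.

Direction-resolved set arithmetic between knockout and titration gene sets
(here fed with externally reported counts):

```r
venn_from_counts(common_up = 84, mutant_only_up = 107,
                 common_down = 69, mutant_only_down = 28,
                 graded_total = 288, ko_total = 282)
#> venn_summary:
#>   up:   common 84, mutant-only 107
#>   down: common 69, mutant-only 28
#>   overlap 153 of 288 graded / 282 knockout (knockout-only 129)
#>   graded up: 191 (66%)
```

Only 153 genes are shared between the two approaches: the knockout misses
136 graded genes (FN + OPP) and adds 129 non-catalytic ones — the
quantitative case for titrating a single function instead of deleting the
protein.

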