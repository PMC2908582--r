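# hypoSig

Biology-driven derivation of hypoxia gene expression signatures and their
prognostic evaluation on tumor cohorts.

Hypoxia — low oxygen tension in poorly vascularized tumor regions — drives a
HIF-mediated transcriptional program associated with aggressive disease.
`hypoSig` derives a hypoxia signature entirely *in vitro*, from paired
expression profiles of tumor cell lines cultured under normoxia and hypoxia,
and then asks whether that signature stratifies patients by outcome. Because
the signature never sees clinical outcomes during its construction, its
prognostic performance can be read directly, without an independent
validation cohort.

## The method

**Derivation** (cell-line stage). For arrays $x_i \in \mathbb{R}^p$ labeled
$y_i = \pm 1$ (hypoxic / normoxic), probesets are selected two ways:

1. *l1-l2 regularization with double optimization* — minimize
   $\tfrac1n\lVert y - X\beta\rVert^2 + \tau\lVert\beta\rVert_1 +
   \mu\lVert\beta\rVert_2^2$ by damped iterative soft-thresholding, re-fit
   the selected support by ridge regression for prediction, and choose
   $\tau$ by leave-one-out error inside $L = n$ outer leave-one-out loops.
   The l2 weight $\mu = \varepsilon \cdot 10^{-3}\sigma_{\max}$ makes
   $\varepsilon$ (default 100) a correlation dial: larger values admit
   groups of correlated probesets together. Each outer loop contributes a
   selected list with a per-feature frequency score; the union is the
   common list, and the outer loops also yield an unbiased leave-one-out
   error for the whole selection procedure.
2. *Differential expression* — per cell line, the hypoxic/normoxic fold
   change; probesets at least 2-fold modulated on average are tested by a
   paired t-test on log2 ratios with Benjamini–Hochberg correction.

The hypoxia signature is the **intersection** of the two lists.

**Evaluation** (tumor stage). Patients are split by k-means (k = 2,
euclidean, 100 random restarts) on the signature's z-scored expression; the
high-expression cluster is the poor-prognosis group. Stability is tested by
reclustering on 300 random same-size gene sets and comparing the
misclassification distances to an exact chance baseline (one-sample
t-test). Prognostic value is quantified by Kaplan–Meier curves, the
log-rank test, and multivariate Cox proportional-hazards regression (Efron
ties, Newton–Raphson) against MYCN status, INSS stage and age — for the
full cohort and for the MYCN-not-amplified subgroup.

Both stages are backed by simulators with known ground truth
(`simulateCellLinePairs()`, `simulateTumorCohort()`), so every claim the
package makes is testable without downloads.

## Worked example

```r
library(hypoSig)

## paired cell-line experiment: 11 lines, 2000 probesets, 50 hypoxia-responsive
sim <- simulateCellLinePairs(seed = 1)
sim$expr
#> ProbesetExperiment: 2000 probesets x 22 samples [linear scale]

res <- runDerivation(sim$expr, sim$design)
res$frequencyTable
#> SelectionFrequencyTable: 55 features over 22 loops, LOO error 0.0%
res$signature
#> GeneSignature 'hypoxia-signature': 46 probesets
sum(sim$truth %in% sigProbesets(res$signature))
#> [1] 46     # 46 of the 50 planted probesets, no false discoveries

## evaluate on a simulated 88-tumor cohort (true hazard ratio 4)
cohort <- simulateTumorCohort(res$signature, seed = 2)
ev <- runEvaluation(cohort$expr, cohort$clinical, res$signature,
                    nPerm = 300, seed = 3)
ev$assignment
#> ClusterAssignment: clusters of 26 and 62 samples (cluster 1 = poor, cluster 2 = good)
ev$stability
#> StabilityResult: 300 permutations, mean distance 0.393, t = -10.88, p = 1.97e-23
ev$survival$full$os$logrank
#> Log-rank: chi2 = 26.438 (1 df), p = 2.72e-07, groups 26/62
ev$survival$full$cox
#> CoxFit (efron ties): n = 88, events = 51, converged
#>                   beta     se     hr lower95 upper95      p
#> nbhypo_poor     1.5870 0.3402 4.8889  2.5098  9.5232 0.0000
#> stage4          0.1519 0.2944 1.1641  0.6536  2.0730 0.6059
#> age_ge1        -0.2143 0.2936 0.8071  0.4540  1.4349 0.4654
#> mycn_amplified -0.1160 0.4123 0.8905  0.3969  1.9979 0.7785
```

Reading the output: the selection loops concur on 55 probesets with a 0%
leave-one-out error; intersecting with the differential-expression list
leaves a 46-probeset signature containing 46 of the 50 planted
hypoxia-responsive probesets and nothing else. On the cohort, the
poor-prognosis cluster (26 patients, high signature expression) has a Cox
hazard ratio of 4.9 (95% CI 2.5–9.5) after adjusting for stage, age and
MYCN — the planted hazard ratio was 4, and the planted covariates carry no
effect, exactly as the fitted model reports. Five-year overall survival is
71.3% in the good-prognosis arm versus 15.1% in the poor one. The stability
t-test shows random gene sets reproduce the reference clustering far more
than chance would allow (distances 0.39 vs a 0.44 baseline), i.e. the
stratification reflects cohort-wide structure, not a quirk of the chosen
probesets.

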