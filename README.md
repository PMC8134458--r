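# morphconn

Gray-matter **morph**ological similarity **conn**ectomes: construction,
graph-theoretic characterization, case-control and longitudinal inference,
and treatment-response prediction — with a synthetic clinical-cohort
generator so the whole pipeline runs and is tested end to end without
imaging data.

## The problem

Structural MRI studies of mood disorders increasingly analyze each subject's
cortex as a network: 90 anatomical regions (AAL parcellation) are nodes, and
an edge weights how similar the gray-matter density distributions of two
regions are. In manic youth, such networks shift away from small-world
toward lattice-like ("regularized") topology — higher clustering and longer
paths — and the shift tracks treatment: it normalizes over weeks of therapy,
correlates with symptom improvement, and the baseline network predicts who
will respond. `morphconn` packages that entire analysis for reuse and for
verification on synthetic cohorts whose ground truth is known.

## The method

**Edges.** For regions $i, j$ with density distributions $p_i, p_j$,

$$\mathrm{KLS}(p_i, p_j) = \exp\{-[\mathrm{KL}(p_i\|p_j) + \mathrm{KL}(p_j\|p_i)]\} \in (0,1],$$

estimated by Gaussian KDE (Silverman bandwidth) on a shared 256-point grid;
KLS = 1 iff the distributions coincide. For Gaussian regions the closed form
`gaussian_kls()` serves as the estimator's oracle.

**Graphs and metrics.** Each 90 x 90 matrix is binarized at sparsities
$S = 0.10, \dots, 0.34$ (step 0.01, strongest edges kept). At each threshold:
clustering coefficient $C_p$, characteristic path length $L_p$ (connected
pairs), global/local efficiency, nodal degree/efficiency/betweenness, and
the small-world parameters $\gamma = C_p/\langle C_p^{rand}\rangle$,
$\lambda = L_p/\langle L_p^{rand}\rangle$, $\sigma = \gamma/\lambda$ against
degree-preserving rewired nulls. Metric curves are summarized by their
trapezoidal AUC over $S$.

**Inference.** Permutation tests (10,000 label reallocations, two-tailed,
add-one corrected) on AUC group differences; a 2-of-3 rule flagging regions
abnormal in at least two nodal centralities at p < 0.05; mixed-effects
group-by-time models (subject random intercept; age, sex covariates);
Pearson correlations of metric change with YMRS change under
Benjamini–Hochberg FDR; ICC(3,1) reliability screening; responder = YMRS
reduction >= 50% from baseline.

**Prediction.** Linear SVM (C = 1) on the 4005 baseline edge features,
stratified 10-fold cross-validation with training-fold-only
standardization, mean balanced accuracy, permutation significance, and a
per-region ranking of mean absolute SVM weights.

## Worked example

```r
library(morphconn)

# a small synthetic cohort: 12 patients, 10 controls, baseline scans only
cfg <- cohort_config(n_patients = 12, n_controls = 10,
                     timepoints = "baseline",
                     normalization_rate = numeric(0), seed = 42)
cohort <- generate_cohort(cfg)
networks <- build_cohort_networks(cohort)
networks[[1]]
#> KLS similarity matrix (S001.baseline): 90 x 90, off-diagonal range [0.0000, 0.9918]

# AUC of each global metric over sparsities 0.10-0.34
aucs <- cohort_global_aucs(networks, threshold_scheme())
group <- cohort$clinical$group[match(sub("\\..*", "", aucs$key),
                                     cohort$clinical$subject_id)]
round(tapply(aucs$Cp, group, mean), 4)
#> control patient
#>  0.1771  0.1819
round(tapply(aucs$Lp, group, mean), 4)
#> control patient
#>  0.8435  0.9071

# permutation test of the baseline clustering-coefficient difference
permutation_test(aucs$Cp[group == "patient"], aucs$Cp[group == "control"],
                 n_perm = 10000, seed = 7)
#> Permutation test: observed diff = 0.004854, p = 9.999e-05 (10000 permutations)

# small-world profile of one control subject (sigma > 1 throughout)
curve <- global_metric_curve(networks[["S013.baseline"]], n_nulls = 100, seed = 1)
round(range(curve$sigma), 2)
#> [1] 1.56 2.60
```

The patients' higher clustering (0.182 vs 0.177) and longer paths (0.907 vs
0.844) are the generator's built-in regularization shift, detected here by
the permutation test (p ~ 1e-4); control networks stay small-world
($\sigma$ between 1.6 and 2.6) across the whole sparsity range.

## Full analysis

Numbered drivers under `analysis/` run the study-scale analysis from one
seed and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # cohort + clinical table
Rscript analysis/02_networks_metrics.R  # KLS networks, metric AUCs, sigma profile
Rscript analysis/03_group_inference.R   # permutation tests, 2-of-3 flags, mixed models, ICC
Rscript analysis/04_prediction.R        # SVM response prediction + weight ranking
```

The methods vignette (`vignettes/morphological-connectomes.Rmd`) documents
the estimator conventions, the generator's design and what it does and does
not emulate.

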