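# liverqmr

Quantitative multiparametric MR analysis for small-animal liver studies:
voxelwise **IVIM** (intravoxel incoherent motion), **diffusion tensor**
(MD/FA) and **R2\*** relaxometry fitting, a six-ROI summarization
protocol, and the cohort statistics (pooled t, Mann–Whitney U, Spearman /
Pearson correlation, interobserver ICC, percent change) used to
characterize hepatic warm ischemia–reperfusion injury. A synthetic
phantom/cohort generator with the published group means and SDs, a
Gaussian-copula dependence structure and Rician noise makes every stage
testable by parameter recovery without any animal data.

It is aimed at readers and reviewers of quantitative liver-MRI studies
who want to reproduce, stress-test or extend this kind of analysis, and
at methods developers who need a fully seeded, inspectable reference
pipeline.

## Models

* IVIM bi-exponential decay over 11 b-values (0–800 s/mm²):

  S(b) = S₀ [ f·e^(−b·D_f) + (1−f)·e^(−b·D_s) ],

  fit voxelwise by full four-parameter nonlinear least squares
  (segmented prefit → damped Gauss–Newton, box constraints, label-swap
  guard D_f ≥ 5 D_s), yielding Dslow, Dfast and the perfusion fraction.
* Diffusion tensor from 1 × b = 0 + 12 directions at b = 500 s/mm² by
  log-linear least squares; MD = tr(D)/3, FA = normalized eigenvalue
  dispersion in [0, 1].
* Monoexponential R2\*: S(TE) = S₀·e^(−TE·R2\*) over 9 echoes
  (TE 2.57–24.25 ms), log-linear by default, with T2\*·R2\* ≡ 1000
  (ms · s⁻¹).
* Cohort statistics: ICC(2,1) with F-based CI, pooled t (raw data or
  printed summaries), Mann–Whitney U with exact enumeration at small n,
  Spearman/Pearson correlations, per-animal percent change.

## Worked example

Recover the model-group operating point from its own forward signal:

```r
library(liverqmr)
p   <- ivim_params(dslow = 1.04e-3, dfast = 22.99e-3, pf = 0.1997, s0 = 100)
fit <- ivim_fit(ivim_signal(p))
fit
#> IVIM bi-exponential fit
#>   dslow = 0.00104 mm^2/s, dfast = 0.02299 mm^2/s, PF = 20.0%, s0 = 100
#>   rss = 1.11e-27, converged = TRUE
```

Run the whole pipeline on a simulated 10 + 10 cohort at SNR 50
(simulate → fit three map types per animal → six-ROI summarization by
two observers → statistics); about two seconds:

```r
res <- run_pipeline(pipeline_config(seed = 42))
gc  <- res$report$group_comparison
gc[gc$variable %in% c("pf", "r2star"), ]
#>  variable mean_control sd_control mean_model sd_model statistic   p_value
#>        pf       0.3124    0.02736     0.2129  0.02367     8.697 7.306e-08
#>    r2star      88.8976   14.48274   117.0106  8.55726    -5.285 5.033e-05

res$report$percent_change
#>  variable direction  mean    sd
#>     dfast  decrease 21.56 5.237
#>        pf  decrease 31.85 7.575
#>    r2star  increase 31.62 9.626
```

The perfusion fraction drops by about a third and R2\* rises by about a
third in the model group — the injury signature the pipeline is built to
detect: ischemia-injured livers lose microcirculatory perfusion (lower
Dfast/PF) and accumulate deoxyhemoglobin (higher R2\*). The
`res$report$icc` table gives interobserver ICC(2,1) per parameter from
the two simulated readers.

A thin command-line wrapper over the same functions lives in
`inst/cli/liverqmr.R` (`simulate`, `fit-ivim`, `fit-dti`, `fit-bold`,
`analyze`, `run`).

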