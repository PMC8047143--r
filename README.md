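# sdbfn — sparse dynamic brain functional networks via hyper-graph manifold regularization

`sdbfn` estimates **sparse dynamic brain functional networks** from
region-of-interest (ROI) fMRI time series and evaluates them as classifiers
of a patient-like group against controls. It is aimed at researchers
studying dynamic functional connectivity who want a self-contained,
seeded, testable implementation of the SHMR estimator family and its
evaluation protocol.

## The method

For a subject's time-series matrix $X \in \mathbb{R}^{Q \times P}$
(Q time points, P regions), sliding windows of width $N$ and step $S$
give $K = \lfloor (Q-N)/S \rfloor + 1$ windowed Pearson correlation
matrices $S_0^{(k)} = X^{(k)\top}X^{(k)}$ (columns standardized per
window). Each window is then sparsified and smoothed by solving

$$\min_W \; \lVert W - S_0 \rVert_F^2 \;+\; \lambda \lVert W \rVert_1
\;+\; \beta\,\mathrm{tr}\!\left(W^\top L^h W\right),$$

where $L^h = I - D_v^{-1/2} H A D_e^{-1} H^\top D_v^{-1/2}$ is the
normalized Laplacian of a k-nearest-neighbor **hyper-graph** over regions
(one hyper-edge per region, containing the region and its $k$ nearest
connectivity profiles). The problem is solved by proximal gradient
descent with soft thresholding and the result symmetrized. Special cases:
$\lambda = 0$ is HMR, $\lambda = \beta = 0$ recovers the Pearson network.
The self-regression baselines SR / MR / SMR
($\min_W \lVert X - XW\rVert_F^2 + \lambda\lVert W\rVert_1 +
\beta\,\mathrm{tr}(W^\top L W)$ with a simple-graph Laplacian and zero
diagonal) are included for comparison.

Downstream, each network window is summarized by Onnela-type weighted
local clustering coefficients, averaged over windows into one feature
vector per subject; features are selected by two-sample t-tests
($p < 0.05$, nested inside the folds) and classified by a linear-kernel
SVM ($C = 1$) under repeated stratified 10×10-fold cross-validation,
reporting ACC / SEN / SPE / AUC with standard deviations.

Because clinical resting-state data cannot ship with the package, a
seeded synthetic-cohort generator produces two-group cohorts with modular
correlation structure, group-specific within-module attenuation, AR(1)
temporal autocorrelation and observation noise, so the entire pipeline is
reproducible end to end. See `vignettes/sdbfn-methods.Rmd` for the full
account of models, conventions and limitations.

## Worked example

```r
library(sdbfn)

spec <- CohortSpec(nPos = 15, nNeg = 15, P = 20, Q = 100,
                   modules = split(1:20, rep(1:4, each = 5)),
                   affectedModules = 1:2, seed = 7)
cohort <- sampleCohort(spec)

cfg <- PipelineConfig(method = "shmr", windowWidth = 40L, windowStep = 10L,
                      kNeighbors = 7L, folds = 5L, reps = 5L, seed = 7L)
run <- runPipeline(cohort, cfg)
run$result
#> Repeated stratified cross-validation result
#>   ACC  90.67% +/- 2.7889
#>   SEN  84.00% +/- 5.9628
#>   SPE  97.33% +/- 3.6515
#>   AUC 0.9707 +/- 0.0112
#>   (5 repetitions; features selected per fold: median 10)

W <- networkMatrices(run$networks[[1]])[[1]]
mean(W[upper.tri(W)] != 0)
#> [1] 0.868
```

Thirty synthetic subjects (15 with within-module correlation attenuated in
2 of 4 modules) are generated, SHMR networks are built per sliding window
($\lambda = 2^{-4}$, $\beta = 2^{-3}$, $k = 7$), and repeated stratified
cross-validation of the clustering-coefficient features separates the
groups at 91% accuracy; the t-test reliably selects the 10 regions of the
two attenuated modules, and the estimated networks keep 87% of
off-diagonal edges at this regularization (the Pearson baseline keeps
100%). Mean sensitivity/specificity and the AUC quantify the same
separation; standard deviations are across the 5 repetitions.

A command-line front end over the same functions is installed at
`inst/cli/sdbfn.R` (subcommands `simulate`, `construct`, `features`,
`classify`, `run`, `sweep`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/sdbfn.R", package="sdbfn"))')" \
  simulate --n-pos 15 --n-neg 15 --seed 7 --out cohort/
```

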