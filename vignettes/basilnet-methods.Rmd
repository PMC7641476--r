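---
title: "Batch screening iterative lasso: model, algorithm and design notes"
author: "basilnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Batch screening iterative lasso: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(basilnet)
```

## The problem

Polygenic prediction from biobank-scale genotype data leads to penalized
regressions with hundreds of thousands of samples and close to a million
variants. A dense double-precision copy of such a genotype matrix does not
fit in memory, while the 2-bit PLINK 1 representation on disk does not fit
the in-memory solvers (glmnet, ncvreg) that practitioners rely on. The
batch screening iterative lasso (BASIL) closes this gap: it computes the
**exact** lasso / elastic-net solution path for the full problem while
only ever holding a small screened submatrix in memory, at the cost of a
single sequential pass over the on-disk data per outer iteration.

## Model

For a response $y$, adjustment covariates $Z$ (age, sex, genotype
principal components, ...) and the variant dosage matrix $X$, the package
solves

$$\hat\alpha(\lambda), \hat\beta(\lambda) = \arg\min_{\alpha,\beta}\;
f(\alpha, \beta) \;+\; \lambda \sum_j c_j\!\left(a\,|\beta_j| +
\tfrac{1-a}{2}\,\beta_j^2\right),$$

where $f$ is the family loss, the intercept and the covariate
coefficients $\alpha$ are never penalized, $c_j \ge 0$ are per-variant
penalty factors, and $a \in (0, 1]$ is the elastic-net mixing weight
(`alpha_mix`; $a = 1$ is the lasso). The families and their scalings are

* **gaussian** — $f = \frac{1}{2n}\lVert y - \eta\rVert^2$;
* **binomial** — $f = \frac{1}{n}$ times the negative Bernoulli
  log-likelihood of $\eta$;
* **cox** — $f = \frac{1}{m}$ times the negative log partial likelihood
  ($m$ = number of observed events), with Breslow handling of tied event
  times and no intercept (the partial likelihood is invariant to one).

The scalings make the penalty sequence comparable across sample sizes:
with them, each family's screening statistic
$s_j = \lVert\nabla_j f\rVert / c_j$ is the per-$n$ absolute inner product
of the variant with a residual-like vector — $y - \eta$ (gaussian),
$y - \hat p$ (binomial), or the partial-likelihood score (cox).

A note on conventions: dosages count the `.bim` A1 allele (bit-pair `00`
decodes to dosage 2), so coefficient signs follow A1. For survival data
the interface takes `event = TRUE` for an observed failure; datasets that
code censoring with $\delta = 0$ meaning failure must be mapped with
`event = (delta == 0)` at ingestion.

## The algorithm

The penalty path is $\lambda_1 > \dots > \lambda_L$, log-equally spaced
from $\lambda_1 = \max_j s_j(\hat\eta^{(0)}) / a$ — the entry penalty, at
which all penalized coefficients are zero — down to
$\lambda_L = \lambda_1 \cdot$ `lambda_min_ratio`. Here $\hat\eta^{(0)}$ is
the covariate-only fit, whose residual seeds the first screening pass.

Each outer iteration has a screen–solve–check structure:

1. **Screening.** Rank all currently inactive variants by $s_j$ at the
   last certified solution and add the top `batch_M` of them to the strong
   set, which always retains every variant that was ever active.
2. **Fitting.** Load the strong-set columns (mean-imputed, training
   samples) into memory and solve the penalized problem there for the next
   `lambdas_per_iteration` pending penalty values, warm-starting each from
   the previous solution.
3. **Checking.** With one sequential pass over the full on-disk genotypes,
   compute $s_j$ for every variant and every candidate solution. A
   candidate at $\lambda$ is certified iff $s_j < \lambda a$ for all
   variants outside the strong set — the stationarity condition that makes
   the zero-padded strong-set solution exact for the full problem. The
   longest certified prefix of the batch is kept; the same pass provides
   the statistics that screen the next iteration, so checking and
   screening share one scan.

If no candidate in a batch passes, the screening batch was too small: the
state falls back to the last certified penalty, `batch_M` grows by
`delta_M`, and the batch is re-screened from the same gradient. Since the
strong set grows strictly, the procedure terminates for any positive
`batch_M` and `delta_M` — in the worst case with the full variant set in
memory, where the certificate holds vacuously. Results cached for failed
penalty values are discarded on fallback.

When a validation set is supplied, each certified solution is scored
($R^2$ for gaussian, AUC for binomial, the negated validation partial
likelihood for cox) and the path stops after `early_stop_patience`
consecutive certified solutions without improvement — mirroring how these
models are actually deployed: the overfitted tail of the path is never
needed.

### The SNP-optimized inner product

Screening and checking reduce to $X^\top R$ for a residual matrix $R$.
Because a dosage vector takes only the values $\{0, 1, 2, \mu\}$ (with
$\mu$ the mean-imputation value), the kernel accumulates three per-column
registers — the sums of $r_i$ over samples with dosage 1, dosage 2, and
missing — and never multiplies: $x^\top r = S_1 + 2 S_2 + \mu S_m$, with
zero dosages skipped entirely. The C++ implementation reads the 2-bit
variant-major bytes in buffered chunks; the result is independent of the
chunk size up to floating-point summation order (verified to $10^{-10}$
relative in the tests).

### The inner solver

The strong-set problems are solved by cyclic coordinate descent with an
active-set strategy (full sweep, then polish the nonzero set, then a
confirming full sweep). The binomial and Cox families wrap an outer
quadratic-approximation loop (IRLS) around weighted Gaussian coordinate
descent, with step-halving whenever the true penalized objective would
increase; the Cox weights are the diagonal curvature of the partial
likelihood. The per-sweep surrogate objective is recorded and tested to be
non-increasing. Any solver with the same
(matrix, response, penalty, warm start) contract could be substituted:
the correctness of the outer loop rests on the certification pass, not on
which solver produced the candidate.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `L` | 100 | path length |
| `lambda_min_ratio` | 0.01 if $p > n$, else $10^{-4}$ | depth of the path |
| `batch_M` | heuristic | screening batch size |
| `delta_M` | `batch_M` | batch growth on total certification failure |
| `lambdas_per_iteration` | 10 | penalties fitted per full-data pass |
| `kkt_tolerance` | $10^{-6}$ | relative slack on the $\lambda a$ threshold |
| `early_stop_patience` | 2 | certified solutions without improvement |
| `alpha_mix` | 1 | elastic-net mixing |
| `max_missing_rate`, `min_maf` | 0.10, 0.001 | variant QC thresholds |

`batch_M` trades iteration count against per-iteration memory and solve
time; any positive value gives the same certified path (asserted in the
tests for `M` from 1 to the full variant count). When unset, it is chosen
as the number of variants whose screening statistic exceeds the
strong-rule threshold $2\lambda_{10} - \lambda_1$ — large enough that the
first iteration plausibly covers ten penalty values — floored at 1000 and
capped at $p$. The pending-penalty list is refilled to
`lambdas_per_iteration` after every iteration; a fixed batch size is the
simplest policy that keeps the per-pass residual matrix small.

`kkt_tolerance` exists because the certificate is checked in floating
point: the fitted strong-set solution satisfies its own stationarity only
to solver precision, and the kernel recomputes inner products in a
different summation order. $10^{-6}$ relative to the threshold is far
above both error sources and far below any meaningful violation. For the
same reason the coordinate update snaps a coefficient to exact zero when
its unpenalized update is within $10^{-8}$ (relative) of the threshold —
without this, the variant that *defines* $\lambda_1$ would oscillate
around zero at machine precision.

**Standardization is off by default.** Hard-call dosages already share
the 0–2 scale; dividing by per-variant standard deviations would shrink
the effective penalty of rare variants and favor them in selection. The
option exists (`standardize = TRUE`, implemented by column scaling with
coefficient back-transformation) for sensitivity analyses.

**Imputation means are training means.** QC statistics and the
mean-imputation value $\mu_j$ are computed on the training samples and
reused for validation, test, and prediction, so no information leaks
across the split. (Computing them on the whole file would be the other
defensible choice; the difference is $O(1/\sqrt{n})$ and does not affect
the certification logic.)

## What the synthetic generator does and does not emulate

`simulate_genotypes()` draws independent
$\text{Binomial}(2, \text{maf}_j)$ dosages with uniform minor-allele
frequencies and i.i.d. missingness, and `simulate_phenotype()` plants a
sparse Gaussian effect vector, calibrating the noise so the genetic signal
explains a target fraction of variance (`heritability`) — on the latent
logistic scale for binary traits, or through exponential event times with
censoring tuned to a target censored fraction for survival. A block
autoregressive mode (`ld_block_size`, `ld_rho`) adds within-block
correlation to exercise the elastic net's grouping behavior.

This emulates the marginal structure of SNP data — discreteness,
frequency spectrum, missingness, sparse polygenic signal — but **not**
realistic linkage disequilibrium, population structure, or
genotype–covariate confounding. Passing tests therefore demonstrate
algorithmic exactness (the screened path equals the full-matrix path) and
statistical sanity (causal variants are recovered when the signal is
strong), not that real-data predictive performance will match any
particular study.

## Numerical choices and degenerate inputs

* Screening ties are broken by ascending variant index, making the whole
  path deterministic; the seed only affects data generation and
  subsampling, never the path computation.
* A variant with all entries missing gets $\mu = 0$ and MAF 0, and is
  removed by any positive MAF threshold.
* Collinear covariates abort with an error naming the offending columns;
  rank-deficient relaxed refits drop aliased columns (coefficients 0)
  with a warning.
* Coordinate-descent convergence is max absolute coefficient change
  $\le 10^{-7}\,\max(1, \mathrm{sd}(z))$ per sweep (10,000 sweeps max;
  non-convergence is flagged per penalty, not fatal). IRLS runs at most
  25 outer iterations with objective-based stopping.
* Test and example paths stop at `lambda_min_ratio = 0.05`: below roughly
  the penalty where the active set approaches the sample count (always in
  the $p > n$ regime), lasso solutions cease to be unique and comparing
  solvers coefficient-wise is meaningless. Validation early stopping ends
  real analyses long before that point.
* Test problem sizes (up to 2000 samples × 5000 variants for the recovery
  study; 400–600 samples for the oracle comparisons) were chosen as the
  smallest instances that exercise multiple screening iterations,
  fallback, and the $p > n$ regime.

## Relaxed lasso and prediction

`relaxed = TRUE` refits each certified active set without penalty
(including the covariates, which must be in the refit for the debiasing
to be meaningful) and tracks its validation metric alongside the
penalized one. `predict()` reconstructs linear predictors from the sparse
stored coefficients, loading only the active variants' columns and
imputing missing genotypes with the stored training means; `"response"`
applies the inverse link (probability, or relative risk $e^\eta$ for
cox).

## Known limitations

* PLINK 2 `.pgen`, dosage (non-hard-call) genotypes, and sample-major
  `.bed` files are not supported.
* Pure ridge ($a = 0$) is excluded: the entry penalty is infinite and the
  screening rationale collapses; use a small positive $a$ instead.
* No cross-validation — the design assumes samples are plentiful enough
  for a fixed train/validation/test split.
* The Cox family reports no baseline hazard, so only relative risks are
  predicted; the validation metric is the partial likelihood, not a
  concordance index.
* The strong-set cache holds every column ever screened, for all samples;
  extremely long paths on wide data can grow it to the size of the active
  universe. Memory-constrained runs should cap the path with
  `lambda_min_ratio` or rely on early stopping.
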