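---
title: "Multi-trait GBLUP with a blended pedigree-genomic kernel: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait GBLUP with a blended pedigree-genomic kernel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kinblend)
```

## The model

For $T$ traits measured on all of $n$ individuals, `kinblend` fits

$$
\mathbf{y} = (\mathbf{I}_T \otimes \mathbf{1}_n)\,\boldsymbol\mu
  + \mathbf{g} + \boldsymbol\varepsilon, \qquad
\mathbf{g} \sim N(\mathbf{0},\, \mathbf{K} \otimes \mathbf{Q}), \qquad
\boldsymbol\varepsilon \sim N(\mathbf{0},\, \mathbf{I}_n \otimes \mathbf{R}),
$$

where $\mathbf{y}$ stacks the pre-corrected trait vectors, $\mathbf{Q}$
and $\mathbf{R}$ are the $T \times T$ among-trait genetic and residual
covariance matrices, and $\mathbf{K}$ is a kinship kernel. The only
fixed effects are per-trait intercepts $\mu_t$; every other systematic
effect is removed beforehand by `preCorrect()`. The Kronecker residual
structure presumes complete multi-trait records, and `mtModelSpec()`
enforces that (missing phenotypes are a hard error, not an imputation
path).

The kernel interpolates between two measures of relatedness,

$$\mathbf{K} = \lambda\,\mathbf{G} + (1 - \lambda)\,\mathbf{A}, \qquad
\lambda \in [0, 1],$$

with $\mathbf{A}$ the pedigree numerator relationship matrix (expected
IBD sharing; `buildA()`, tabular method) and $\mathbf{G}$ a genomic
relationship matrix (realized IBS sharing). Two standard normalizations
of $\mathbf{G} \propto \mathbf{W}\mathbf{W}'$ (with
$W_{ij} = x_{ij} - 2p_j$ the centred 0/1/2 dosages) are provided:
VanRaden's $2\sum_i p_i q_i$ denominator (`buildGVanRaden()`) and
Forni's $\mathrm{trace}(\mathbf{W}\mathbf{W}')/m$ (`buildGForni()`,
which forces $\mathrm{trace}(\mathbf{G_F}) = m$). Allele frequencies
come from the current sample — no base-population frequencies are
assumed to exist.

Because the entries of $\mathbf{A}$ live in $[0, 2]$ while unscaled
$\mathbf{G}$ matrices can carry negative off-diagonals, `minmaxScale()`
optionally maps $\mathbf{G}$ entrywise onto $[0, 2]$ before blending
(scale-then-blend order, fixed). The map is affine in the global
entrywise extrema, diagonal included; its minimum and maximum are
attained exactly by construction. Scaling can perturb positive
semidefiniteness, so `blendKernels()` eigen-checks every interior blend:
a smallest eigenvalue in $(-10^{-6}, 0)$ is repaired by a logged
diagonal jitter, anything lower is an error. The endpoints
$\lambda \in \{0, 1\}$ bypass the repair and return $\mathbf{A}$ or
$\mathbf{G}$ bit-identically, so pedigree-only results never depend on
which $\mathbf{G}$ variant was requested.

## REML estimation

`remlFit()` maximizes the restricted likelihood of the model above.
Writing $\mathbf{K} = \mathbf{U}\mathbf{D}\mathbf{U}'$, rotating the
$n \times T$ data matrix by $\mathbf{U}'$ decouples the likelihood into
$n$ independent $T$-dimensional blocks with covariance
$d_i \mathbf{Q} + \mathbf{R}$. A further simultaneous diagonalization
($\mathbf{T}'\mathbf{R}\mathbf{T} = \mathbf{I}$,
$\mathbf{T}'\mathbf{Q}\mathbf{T} = \boldsymbol\Phi$) reduces every
likelihood evaluation to elementwise operations on an $n \times T$
array, so a single evaluation costs $O(nT + T^3)$ after the one-off
eigendecomposition. The intercepts are profiled out by GLS inside the
likelihood, with the usual $\log|\mathbf{X}'\mathbf{V}^{-1}\mathbf{X}|$
REML correction. The same machinery, evaluated once at the estimates,
yields breeding-value predictions
$\hat{\mathbf{g}}_{\text{target}} =
\mathbf{K}_{\text{target,train}}\,
[\mathbf{V}^{-1}(\mathbf{y}-\mathbf{X}\hat\mu)]\,\hat{\mathbf{Q}}$
(`predictDGV()`); unit tests pin both the likelihood and the predictions
to dense Kronecker-matrix oracles at $10^{-8}$.

Numerical choices, all of which were genuinely open:

* **Parametrization.** $\mathbf{Q} = \mathbf{L}_Q\mathbf{L}_Q'$ with a
  free lower-triangular factor (PSD by construction, boundary estimates
  reachable); $\mathbf{R} = \mathbf{L}_R\mathbf{L}_R'$ with
  log-diagonal factor (kept positive-definite, as the block
  diagonalization requires a Cholesky of $\mathbf{R}$). Degenerate
  blocks during the search return $-\infty$ rather than erroring.
* **Optimizer.** BFGS from three starts that split the phenotypic
  covariance 50/50, 10/90 and 90/10 between $\mathbf{Q}$ and
  $\mathbf{R}$, followed by a restart-from-optimum polish and damped
  Newton steps on the numerical gradient/Hessian. The Newton refinement
  matters for exact invariance properties (e.g. rescaling one trait by
  $c$ must scale $\hat Q_{tt}$ by $c^2$ and leave $h^2$ untouched to
  $10^{-6}$), which BFGS alone localizes too coarsely.
* **Convergence.** Declared when the polish step improves the
  log-likelihood by less than $10^{-8}$ and the gradient norm is below
  $10^{-5}$ *relative to the log-likelihood magnitude* — an absolute
  $10^{-5}$ would sit below the noise floor of finite-difference
  gradients on likelihoods of magnitude $10^3$–$10^4$.
* **Boundary handling.** Estimates with
  $\lambda_{\min}(\hat{\mathbf{Q}}) < 10^{-6}\,\mathrm{trace}(\hat{\mathbf{Q}})$
  are flagged (`details$boundary`), not rejected; a perfectly duplicated
  trait drives the genetic and residual correlations to the $+1$
  boundary and is reported as such.
* **Standard errors.** Inverse numerical Hessian on the unconstrained
  parametrization, delta-method mapped to covariance entries,
  heritabilities and all correlation types; pseudo-inverse fallback at
  boundaries.
* **Identifiability.** With $\mathbf{K}$ numerically proportional to
  $\mathbf{I}$ the genetic and residual components are confounded; the
  fit warns and the single-trait $\mathbf{K}=\mathbf{I}$ case is
  documented as a degenerate ridge.

## Cross-validation and genetic regressions

`runCV()` scores the λ grid by repeated random 60/40 train/test splits
(default 20 replicates). Splits are shared across all (variant, λ) cells
within a replicate, making grid comparisons paired — a deliberate
design choice favouring the statistically stronger paired layout.
Variance components are re-estimated on every training subset; test-set
phenotypes never enter any training computation (a perturbation test in
the suite asserts this). Per cell the report carries predictive
correlations between held-out pre-corrected phenotypes (used as-is, not
re-standardized) and DGV, MSE, and for every ordered trait pair the
realized least-squares regression (with intercept — DGV and phenotype
means differ) of test phenotype of $x$ on DGV of $y$, next to the
REML-implied expectation $b_{xy} = r_G \sigma_x / \sigma_y =
Q_{xy}/Q_{yy}$. Convergence failures mark their cell rather than
aborting the grid.

## The simulator and what it does (not) emulate

`simulateDataset()` produces pedigrees, genotypes and phenotypes with
fully known truth, at the scale of a commercial broiler-type study: a
founder generation followed by discrete generations in which each dam
produces one full-sib family and sires serve several dams (paternal
half-sib structure). Genotypes are gene-dropped at unlinked biallelic
loci (founder MAF uniform on a configurable interval, fair-coin
transmission). Breeding values come in two architectures:

* **infinitesimal** — founders $\sim N(\mathbf{0}, \mathbf{Q})$,
  offspring = mid-parent + Mendelian-sampling deviation with covariance
  $\tfrac12\big(1 - (F_s + F_d)/2\big)\mathbf{Q}$ (the standard
  inbreeding adjustment);
* **pleiotropic_qtl** — a fraction `qtlVarFrac` of genetic variance from
  causal loci *inside* the SNP panel whose per-locus effect vectors have
  correlation `qtlEffectCorr`, plus an infinitesimal remainder. The QTL
  component is rescaled per trait to hit `qtlVarFrac * diag(Qtrue)`
  exactly — a per-trait diagonal rescale preserves the implanted effect
  correlation and matches the target trace, whereas a single scalar
  would miss the per-trait heritabilities.

Setting `qtlEffectCorr` away from the correlation implied by `Qtrue`
implants a mismatch between what markers tag and what the pedigree
transmits: the genomic kernel over-weights realized causal IBS while
marker noise attenuates the polygenic covariance, so correlation
estimates at $\lambda = 1$ shift toward the QTL-level correlation. This
reproduces missing/excessive/spurious marker-based correlations through
IBS-versus-IBD weighting, *not* through explicit marker–QTL linkage
maps — loci are unlinked by design, there is no recombination map, no
selection across generations, and no non-Gaussian residual. Passing
tests therefore demonstrate the estimator's behaviour under family
structure and causal-panel overlap, and say nothing about LD-driven
distortions in real dense-marker data.

Nuisance effects are purely additive categorical shifts (levels assigned
uniformly, effects $N(0, \texttt{nuisanceSd}^2)$), so fixed-effect
residualization can remove them exactly — which is what makes
`preCorrect()` testable for exact recovery. Real phenotype corrections
may involve random effects (e.g. hatch); treating all nuisance factors
as fixed is a documented simplification that avoids a second
mixed-model solver and differs from shrinkage-based correction only in
a shrinkage detail under balanced designs.

All randomness flows from one master seed with fixed per-stage
substreams (pedigree / genotypes / traits), so identical configurations
reproduce bit-identical datasets and each stage is independently
reproducible.

## Scales used by the test suite

The suite validates at sizes chosen to keep Monte-Carlo error
meaningfully small: likelihood and BLUP oracles on $n \le 20$ instances;
gene-dropping IBD checks on a 200-member pedigree at 10{,}000 loci
(entries within 3 Monte-Carlo SEs); parameter recovery on 20 replicates
of a 1500-individual pedigree with $h^2 = (0.2, 0.25, 0.3)$ and
$r_G = (0.5, -0.2, -0.2)$ (3-SE coverage $\ge 90\%$, bias within
Monte-Carlo error); the architecture-mismatch experiment on 20
replicates of 640 individuals with a half-causal 300-SNP panel (sign
test); and a 20-replicate, full-λ-grid cross-validation on 300
individuals. `scripts/acceptance.R` re-runs the pipeline at $n = 600$
and writes every headline quantity as JSON.

## Known limitations

Fixed effects in the kernel model are intercepts only; richer designs
must be handled by pre-correction. Missing phenotypes are unsupported
(no EM step). The A-matrix uses the dense tabular method — fine for
$n \sim 10^3$–$10^4$, not for national evaluations. Min–max scaling is
a pragmatic alignment of ranges, not a base-population adjustment, and
its expectation has no closed form. λ is chosen by grid search and
cross-validation, not estimated; single-step H-matrix constructions and
Bayesian λ estimation are out of scope.
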