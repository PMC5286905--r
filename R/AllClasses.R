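#' @import methods
NULL

.SYM_TOL <- 1e-10

.is_symmetric <- function(m, tol = .SYM_TOL) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    max(abs(m - t(m))) <= tol * max(1, max(abs(m)))
}

.is_pd <- function(m, tol = 1e-12) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol * max(1, abs(ev[1])))
}

#' Pedigree of individuals with sire and dam links
#'
#' Ordered records of (individual, sire, dam). Unknown parents are `NA`.
#' Validity enforces unique ids and that every known parent precedes its
#' offspring, i.e. the records are topologically sorted; [readPedigree()]
#' and [simulatePedigree()] always return sorted pedigrees.
#'
#' @slot id character vector of individual identifiers.
#' @slot sire character vector of sire ids (`NA` = unknown).
#' @slot dam character vector of dam ids (`NA` = unknown).
#'
#' @seealso [buildA()], [inbreeding()], [readPedigree()]
#' @export
setClass("Pedigree",
  representation(id = "character", sire = "character", dam = "character"))

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  if (length(object@sire) != n || length(object@dam) != n)
    return("id, sire and dam must have equal length")
  if (anyDuplicated(object@id))
    return(sprintf("duplicate individual id: %s",
                   object@id[anyDuplicated(object@id)]))
  if (any(object@id == object@sire, na.rm = TRUE) ||
      any(object@id == object@dam, na.rm = TRUE))
    return("an individual cannot be its own parent")
  pos <- seq_len(n)
  names(pos) <- object@id
  for (col in c("sire", "dam")) {
    par <- slot(object, col)
    known <- !is.na(par)
    if (!all(par[known] %in% object@id))
      return(sprintf("%s ids not declared as individuals: %s", col,
                     paste(setdiff(par[known], object@id), collapse = ", ")))
    if (any(pos[par[known]] >= pos[known]))
      return("pedigree is not parent-ordered (a parent follows its offspring)")
  }
  TRUE
})

#' Additively coded SNP genotypes
#'
#' An n x p matrix of 0/1/2 allele-dosage codes (possibly fractional after
#' mean imputation, possibly `NA`), with per-SNP allele frequencies of the
#' counted allele and call rates computed from the non-missing entries.
#'
#' @slot codes numeric matrix, individuals in rows (rownames = ids),
#'   SNPs in columns (colnames = SNP ids).
#' @slot alleleFreq per-SNP frequency of the counted allele,
#'   `colMeans(codes, na.rm = TRUE) / 2`.
#' @slot callRate per-SNP fraction of non-missing entries.
#'
#' @seealso [genotypeMatrix()], [filterSNPs()], [buildGVanRaden()]
#' @export
setClass("GenotypeMatrix",
  representation(codes = "matrix", alleleFreq = "numeric",
                 callRate = "numeric"))

setValidity("GenotypeMatrix", function(object) {
  p <- ncol(object@codes)
  if (is.null(rownames(object@codes)) || is.null(colnames(object@codes)))
    return("codes must carry individual rownames and SNP colnames")
  if (length(object@alleleFreq) != p || length(object@callRate) != p)
    return("alleleFreq and callRate must have one entry per SNP")
  obs <- object@codes[!is.na(object@codes)]
  if (length(obs) && (min(obs) < 0 || max(obs) > 2))
    return("genotype codes must lie in [0, 2]")
  if (any(object@alleleFreq < 0 | object@alleleFreq > 1, na.rm = TRUE))
    return("allele frequencies must lie in [0, 1]")
  if (any(object@callRate < 0 | object@callRate > 1))
    return("call rates must lie in [0, 1]")
  TRUE
})

#' Symmetric relatedness matrix with individual labels
#'
#' Holds any of the relationship matrices used by the blended-kernel
#' model: the pedigree numerator matrix `A`, genomic matrices `G_V`
#' (VanRaden) and `G_F` (Forni), a min-max rescaled `G_scaled`, or the
#' blend `K_blend = lambda * G + (1 - lambda) * A`.
#'
#' @slot values symmetric numeric matrix with matching dimnames.
#' @slot kind one of `"A"`, `"G_V"`, `"G_F"`, `"G_scaled"`, `"K_blend"`.
#' @slot meta list of construction parameters (e.g. `lambda`, scaling
#'   bounds, allele-frequency source, jitter applied).
#'
#' @seealso [buildA()], [buildGVanRaden()], [minmaxScale()], [blendKernels()]
#' @export
setClass("KinshipMatrix",
  representation(values = "matrix", kind = "character", meta = "list"),
  prototype(meta = list()))

setValidity("KinshipMatrix", function(object) {
  v <- object@values
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    return("values must have identical row and column names")
  if (!.is_symmetric(v))
    return("kinship matrix is not symmetric to within 1e-10")
  if (!object@kind %in% c("A", "G_V", "G_F", "G_scaled", "K_blend"))
    return(sprintf("unknown kinship kind '%s'", object@kind))
  if (object@kind == "A") {
    if (any(v < -.SYM_TOL)) return("A must have non-negative entries")
    if (any(v > 2 + 1e-8)) return("A entries cannot exceed 2")
    if (any(diag(v) < 1 - 1e-8)) return("diag(A) must be >= 1")
  }
  TRUE
})

#' Among-trait genetic and residual covariance matrices
#'
#' The T x T genetic covariance `Q` and residual covariance `R` of the
#' Kronecker-structured multi-trait model, plus per-trait intercepts.
#'
#' @slot Q genetic covariance matrix (symmetric, PSD).
#' @slot R residual covariance matrix (symmetric, PSD).
#' @slot mu per-trait intercepts.
#'
#' @seealso [remlFit()], [deriveParameters()]
#' @export
setClass("TraitCovariances",
  representation(Q = "matrix", R = "matrix", mu = "numeric"))

setValidity("TraitCovariances", function(object) {
  if (!.is_symmetric(object@Q, 1e-8) || !.is_symmetric(object@R, 1e-8))
    return("Q and R must be symmetric")
  if (!identical(dim(object@Q), dim(object@R)))
    return("Q and R must have identical dimensions")
  if (length(object@mu) && length(object@mu) != nrow(object@Q))
    return("mu must have one entry per trait")
  evQ <- eigen(object@Q, symmetric = TRUE, only.values = TRUE)$values
  evR <- eigen(object@R, symmetric = TRUE, only.values = TRUE)$values
  scl <- max(1, abs(evQ[1]), abs(evR[1]))
  if (min(evQ) < -1e-8 * scl || min(evR) < -1e-8 * scl)
    return("Q and R must be positive semidefinite")
  TRUE
})

#' Phenotypes paired with a kinship kernel, ready for REML
#'
#' All individuals must have all traits observed, and every phenotyped
#' individual must be present in the kinship matrix (the constructor
#' [mtModelSpec()] aligns the kernel to the phenotype rows).
#'
#' @slot phenotypes n x T numeric matrix, rownames = individual ids,
#'   colnames = trait names.
#' @slot kinship a [KinshipMatrix-class] whose ids equal the phenotype rows.
#'
#' @seealso [mtModelSpec()], [remlFit()], [restrictedLoglik()]
#' @export
setClass("MTModelSpec",
  representation(phenotypes = "matrix", kinship = "KinshipMatrix"))

setValidity("MTModelSpec", function(object) {
  Y <- object@phenotypes
  if (is.null(rownames(Y)) || is.null(colnames(Y)))
    return("phenotypes must carry individual rownames and trait colnames")
  if (anyNA(Y))
    return("all traits must be observed on all individuals (no NA)")
  if (!identical(rownames(Y), rownames(object@kinship@values)))
    return("kinship ids must equal phenotype ids (same order)")
  TRUE
})

#' Fitted multi-trait REML model
#'
#' @slot params estimated [TraitCovariances-class] (Q, R, intercepts).
#' @slot restrictedLoglik maximized restricted log-likelihood.
#' @slot heritability per-trait h2 = Q_tt / (Q_tt + R_tt).
#' @slot geneticCorr,residualCorr,phenotypicCorr T x T correlation matrices.
#' @slot se named list of asymptotic standard errors (numerical Hessian +
#'   delta method): elements `Q`, `R`, `heritability`, `geneticCorr`,
#'   `residualCorr`, `phenotypicCorr`.
#' @slot converged logical convergence flag.
#' @slot nIter iterations used by the best start.
#' @slot spec the training [MTModelSpec-class] (kept for prediction).
#' @slot details list of optimizer diagnostics (per-start log-likelihoods,
#'   gradient norm, boundary flag).
#'
#' @seealso [remlFit()], [predictDGV()]
#' @export
setClass("MTModelFit",
  representation(params = "TraitCovariances", restrictedLoglik = "numeric",
                 heritability = "numeric", geneticCorr = "matrix",
                 residualCorr = "matrix", phenotypicCorr = "matrix",
                 se = "list", converged = "logical", nIter = "numeric",
                 spec = "MTModelSpec", details = "list"))

#' Predicted breeding values for a set of individuals
#'
#' @slot values targets x traits matrix of predicted breeding values
#'   (direct genomic values), rownames = target ids.
#' @slot meta list: training size, kernel kind, blending weight.
#'
#' @seealso [predictDGV()]
#' @export
setClass("DGVPrediction",
  representation(values = "matrix", meta = "list"),
  prototype(meta = list()))

setValidity("DGVPrediction", function(object) {
  if (is.null(rownames(object@values)))
    return("predictions must carry target ids as rownames")
  if (any(!is.finite(object@values)))
    return("predictions must be finite")
  TRUE
})

#' Simulation configuration
#'
#' Defines a multi-generation mating design, an unlinked SNP panel gene
#' dropped through it, and a trait architecture with known genetic (Q)
#' and residual (R) covariance matrices. See [simConfig()] for defaults
#' and the meaning of every field.
#'
#' @slot nFounders,nGenerations,offspringPerMating,nSires,nDams integers
#'   describing the mating design.
#' @slot nSnps,nQtl panel size and number of causal loci.
#' @slot founderMafRange length-2 numeric in (0, 0.5].
#' @slot Qtrue,Rtrue T x T covariance matrices (symmetric, PD).
#' @slot architecture `"infinitesimal"` or `"pleiotropic_qtl"`.
#' @slot qtlEffectCorr T x T correlation of per-QTL effect vectors.
#' @slot qtlVarFrac fraction of genetic variance from the QTL component
#'   (pleiotropic_qtl mode); the remainder is an infinitesimal pedigree
#'   component with covariance proportional to `Qtrue`.
#' @slot nuisanceLevels named integer vector: levels per categorical
#'   nuisance factor (possibly empty).
#' @slot nuisanceSd standard deviation of nuisance level effects.
#' @slot missingRate fraction of genotype entries masked to `NA`.
#' @slot seed master seed; stages use fixed substream offsets.
#'
#' @export
setClass("SimConfig",
  representation(nFounders = "integer", nGenerations = "integer",
                 offspringPerMating = "integer", nSires = "integer",
                 nDams = "integer", nSnps = "integer", nQtl = "integer",
                 founderMafRange = "numeric", Qtrue = "matrix",
                 Rtrue = "matrix", architecture = "character",
                 qtlEffectCorr = "matrix", qtlVarFrac = "numeric",
                 nuisanceLevels = "integer", nuisanceSd = "numeric",
                 missingRate = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  for (f in c("nFounders", "nGenerations", "offspringPerMating",
              "nSires", "nDams", "nSnps", "nQtl"))
    if (length(slot(object, f)) != 1 || is.na(slot(object, f)))
      return(sprintf("%s must be a single integer", f))
  if (object@nFounders < 2) return("need at least 2 founders")
  if (object@nGenerations < 0) return("nGenerations must be >= 0")
  if (object@nGenerations > 0) {
    if (object@nSires < 1 || object@nDams < 1)
      return("mating design needs at least one sire and one dam per generation")
    if (object@offspringPerMating < 1)
      return("offspringPerMating must be >= 1")
    if (object@nSires + object@nDams > object@nFounders)
      return("nSires + nDams cannot exceed the number of candidate parents")
  }
  if (object@nSnps < 1) return("nSnps must be >= 1")
  if (object@nQtl > object@nSnps) return("nQtl cannot exceed nSnps")
  r <- object@founderMafRange
  if (length(r) != 2 || r[1] <= 0 || r[2] > 0.5 || r[1] > r[2])
    return("founderMafRange must lie within (0, 0.5]")
  if (!.is_symmetric(object@Qtrue, 1e-8) || !.is_pd(object@Qtrue))
    return("Qtrue must be symmetric positive-definite")
  if (!.is_symmetric(object@Rtrue, 1e-8) || !.is_pd(object@Rtrue))
    return("Rtrue must be symmetric positive-definite")
  if (!identical(dim(object@Qtrue), dim(object@Rtrue)))
    return("Qtrue and Rtrue must have the same dimension")
  if (!object@architecture %in% c("infinitesimal", "pleiotropic_qtl"))
    return("architecture must be 'infinitesimal' or 'pleiotropic_qtl'")
  if (object@architecture == "pleiotropic_qtl") {
    if (!identical(dim(object@qtlEffectCorr), dim(object@Qtrue)))
      return("qtlEffectCorr must match the trait dimension")
    if (object@nQtl < 1) return("pleiotropic_qtl mode needs nQtl >= 1")
    if (object@qtlVarFrac <= 0 || object@qtlVarFrac > 1)
      return("qtlVarFrac must lie in (0, 1]")
  }
  if (object@missingRate < 0 || object@missingRate >= 1)
    return("missingRate must lie in [0, 1)")
  TRUE
})

#' Simulated dataset with known truth
#'
#' @slot pedigree the simulated [Pedigree-class].
#' @slot genotypes gene-dropped [GenotypeMatrix-class].
#' @slot trueBreedingValues n x T matrix of simulated breeding values.
#' @slot phenotypes n x T raw phenotypes (intercept + nuisance +
#'   breeding value + residual).
#' @slot nuisance data.frame of per-individual factor levels (may have
#'   zero columns).
#' @slot components list with the exact simulated pieces (`residuals`,
#'   `nuisanceEffects`, `intercepts`) so phenotypes are reconstructible.
#' @slot config the generating [SimConfig-class].
#'
#' @export
setClass("SimDataset",
  representation(pedigree = "Pedigree", genotypes = "GenotypeMatrix",
                 trueBreedingValues = "matrix", phenotypes = "matrix",
                 nuisance = "data.frame", components = "list",
                 config = "SimConfig"))

setValidity("SimDataset", function(object) {
  ids <- rownames(object@genotypes@codes)
  if (!all(ids %in% object@pedigree@id))
    return("every genotyped individual must appear in the pedigree")
  if (!identical(rownames(object@phenotypes),
                 rownames(object@trueBreedingValues)))
    return("phenotype and breeding-value rows must align")
  TRUE
})

#' Cross-validation scheme
#'
#' Repeated random train/test partitions shared across all (variant,
#' lambda) cells within a replicate, so comparisons across the grid are
#' paired.
#'
#' @slot nReps number of random partitions.
#' @slot trainFrac fraction assigned to training (train size =
#'   `round(trainFrac * n)`).
#' @slot lambdaGrid blending weights to evaluate.
#' @slot gVariants subset of `"GV_unscaled"`, `"GV_scaled"`,
#'   `"GF_unscaled"`, `"GF_scaled"`.
#' @slot seed integer seed for the partitions.
#'
#' @seealso [cvScheme()], [runCV()]
#' @export
setClass("CVScheme",
  representation(nReps = "integer", trainFrac = "numeric",
                 lambdaGrid = "numeric", gVariants = "character",
                 seed = "integer"))

setValidity("CVScheme", function(object) {
  if (object@nReps < 1) return("nReps must be >= 1")
  if (object@trainFrac <= 0 || object@trainFrac >= 1)
    return("trainFrac must lie strictly between 0 and 1")
  if (any(object@lambdaGrid < 0 | object@lambdaGrid > 1))
    return("lambdaGrid values must lie in [0, 1]")
  ok <- c("GV_unscaled", "GV_scaled", "GF_unscaled", "GF_scaled")
  if (!length(object@gVariants) || !all(object@gVariants %in% ok))
    return(sprintf("gVariants must be a non-empty subset of {%s}",
                   paste(ok, collapse = ", ")))
  TRUE
})

#' Cross-validation report
#'
#' Long-format results: one row per (variant, lambda, rep, trait-or-pair,
#' metric). Metrics are `predCorr` and `mse` per trait, and `realized_b`
#' / `expected_b` per ordered trait pair (`"x~y"` = phenotype of x on DGV
#' of y). Failed cells carry `NA` values and a note.
#'
#' @slot results data.frame with columns variant, lambda, rep, unit,
#'   metric, value, note.
#' @slot scheme the [CVScheme-class] used.
#'
#' @seealso [runCV()], [summarizeReport()]
#' @export
setClass("CVReport",
  representation(results = "data.frame", scheme = "CVScheme"))
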