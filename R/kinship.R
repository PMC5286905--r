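#' Construct a GenotypeMatrix from a dosage matrix
#'
#' Allele frequencies and call rates are computed from the non-missing
#' entries: `p_i = mean(codes[, i], na.rm = TRUE) / 2`.
#'
#' @param codes numeric matrix of additive codes in `[0, 2]` (`NA` =
#'   missing); individual rownames and SNP colnames are required (defaults
#'   are generated when absent).
#' @return a [GenotypeMatrix-class].
#' @export
genotypeMatrix <- function(codes) {
  codes <- as.matrix(codes)
  if (is.null(rownames(codes)))
    rownames(codes) <- paste0("ind", seq_len(nrow(codes)))
  if (is.null(colnames(codes)))
    colnames(codes) <- paste0("snp", seq_len(ncol(codes)))
  storage.mode(codes) <- "double"
  p <- colMeans(codes, na.rm = TRUE) / 2
  cr <- colMeans(!is.na(codes))
  p[cr == 0] <- NA_real_
  new("GenotypeMatrix", codes = codes, alleleFreq = p, callRate = cr)
}

#' Quality-control filter on SNPs
#'
#' Removes SNPs with minor allele frequency below `mafMin` or call rate
#' below `callRateMin`; both thresholds are inclusive on the keep side
#' (a SNP is dropped when `min(p, 1 - p) < mafMin` or
#' `callRate < callRateMin`).
#'
#' @param g a [GenotypeMatrix-class].
#' @param mafMin minimum minor allele frequency (default 0.01).
#' @param callRateMin minimum call rate (default 0.95).
#' @return a filtered [GenotypeMatrix-class]; removal counts are reported
#'   via `message()`.
#' @export
filterSNPs <- function(g, mafMin = 0.01, callRateMin = 0.95) {
  stopifnot(is(g, "GenotypeMatrix"))
  maf <- pmin(g@alleleFreq, 1 - g@alleleFreq)
  dropMaf <- is.na(maf) | maf < mafMin
  dropCall <- g@callRate < callRateMin
  keep <- !(dropMaf | dropCall)
  if (!any(keep))
    stop("all SNPs removed by QC (maf < ", mafMin, " or call rate < ",
         callRateMin, ")")
  message(sum(!keep), " SNP(s) removed (", sum(dropMaf), " low MAF, ",
          sum(dropCall), " low call rate); ", sum(keep), " retained")
  genotypeMatrix(g@codes[, keep, drop = FALSE])
}

#' Mean imputation of missing genotypes
#'
#' Replaces each missing entry by the SNP's mean dosage `2 * p_i`
#' computed from the observed entries; the result is no longer
#' integer-coded.
#'
#' @param g a [GenotypeMatrix-class].
#' @return a [GenotypeMatrix-class] with no missing entries.
#' @export
imputeNaive <- function(g) {
  stopifnot(is(g, "GenotypeMatrix"))
  if (any(g@callRate == 0))
    stop("cannot impute SNP(s) with zero call rate: ",
         paste(utils::head(colnames(g@codes)[g@callRate == 0], 5),
               collapse = ", "))
  codes <- g@codes
  if (anyNA(codes)) {
    miss <- which(is.na(codes), arr.ind = TRUE)
    codes[miss] <- 2 * g@alleleFreq[miss[, "col"]]
  }
  genotypeMatrix(codes)
}

#' Center genotype codes by twice the allele frequency
#'
#' @param g a [GenotypeMatrix-class] with no missing entries.
#' @return plain n x p numeric matrix `W` with `W_ij = codes_ij - 2 p_j`;
#'   column means are zero.
#' @export
centerGenotypes <- function(g) {
  stopifnot(is(g, "GenotypeMatrix"))
  if (anyNA(g@codes))
    stop("genotypes contain missing entries; impute first (imputeNaive)")
  sweep(g@codes, 2, 2 * g@alleleFreq, "-")
}

.new_kinship <- function(values, kind, meta = list()) {
  values <- (values + t(values)) / 2   # enforce exact symmetry
  new("KinshipMatrix", values = values, kind = kind, meta = meta)
}

#' VanRaden genomic relationship matrix
#'
#' `G_V = W W' / (2 * sum(p_i * q_i))` with `W` the centered codes and
#' `q_i = 1 - p_i`; frequencies are taken from the observed sample. The
#' denominator makes `G_V` analogous in scale to the pedigree matrix A.
#'
#' @param g a [GenotypeMatrix-class] with no missing entries (impute
#'   first if needed).
#' @return a [KinshipMatrix-class] of kind `"G_V"`.
#' @export
buildGVanRaden <- function(g) {
  W <- centerGenotypes(g)
  p <- g@alleleFreq
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all SNPs are monomorphic: VanRaden denominator 2*sum(p*q) is zero")
  .new_kinship(tcrossprod(W) / denom, "G_V",
               meta = list(denominator = denom, freqSource = "sample"))
}

#' Forni genomic relationship matrix
#'
#' `G_F = W W' / (trace(W W') / m)` with `m` the number of individuals,
#' so that `trace(G_F) = m` exactly.
#'
#' @inheritParams buildGVanRaden
#' @return a [KinshipMatrix-class] of kind `"G_F"`.
#' @export
buildGForni <- function(g) {
  W <- centerGenotypes(g)
  WW <- tcrossprod(W)
  tr <- sum(diag(WW))
  if (tr <= 0)
    stop("trace(WW') is zero: no polymorphic SNPs")
  m <- nrow(WW)
  .new_kinship(WW / (tr / m), "G_F",
               meta = list(denominator = tr / m, freqSource = "sample"))
}

#' Min-max rescaling of a genomic relationship matrix
#'
#' Entrywise affine map onto `[sMin, sMax]` (defaults `[0, 2]`, the range
#' of the pedigree matrix A):
#' `Gs_ij = (sMax - sMin) * (G_ij - Gmin) / (Gmax - Gmin) + sMin`,
#' where `Gmin`/`Gmax` are the global entrywise extrema including the
#' diagonal. The minimum of the scaled matrix equals `sMin` and the
#' maximum equals `sMax` exactly; symmetry is preserved. Note the map can
#' perturb positive semidefiniteness; [blendKernels()] checks and repairs.
#'
#' @param G a [KinshipMatrix-class].
#' @param sMin,sMax target bounds (`sMax > sMin`).
#' @return a [KinshipMatrix-class] of kind `"G_scaled"`.
#' @export
minmaxScale <- function(G, sMin = 0, sMax = 2) {
  stopifnot(is(G, "KinshipMatrix"), sMax > sMin)
  v <- G@values
  gmin <- min(v); gmax <- max(v)
  if (gmax <= gmin)
    stop("cannot min-max scale a constant matrix (Gmax == Gmin)")
  scaled <- (sMax - sMin) * ((v - gmin) / (gmax - gmin)) + sMin
  new("KinshipMatrix", values = scaled, kind = "G_scaled",
      meta = c(G@meta, list(scaledFrom = G@kind, sMin = sMin, sMax = sMax,
                            Gmin = gmin, Gmax = gmax)))
}

#' Blend genomic and pedigree kinship: K = lambda G + (1 - lambda) A
#'
#' Ids must match in the same order (no silent reordering). `lambda = 0`
#' returns the pedigree values exactly and `lambda = 1` the genomic
#' values exactly. The blend is checked for positive semidefiniteness;
#' a smallest eigenvalue in `(-1e-6, 0)` is repaired by a logged diagonal
#' jitter, anything lower is an error.
#'
#' @param G a [KinshipMatrix-class] (genomic, possibly scaled).
#' @param A a [KinshipMatrix-class] of kind `"A"`.
#' @param lambda blending weight in `[0, 1]`.
#' @return a [KinshipMatrix-class] of kind `"K_blend"` with `lambda`
#'   recorded in `meta`.
#' @export
blendKernels <- function(G, A, lambda) {
  stopifnot(is(G, "KinshipMatrix"), is(A, "KinshipMatrix"),
            length(lambda) == 1, lambda >= 0, lambda <= 1)
  if (!identical(rownames(G@values), rownames(A@values)))
    stop("id mismatch between G and A: align the matrices explicitly ",
         "before blending")
  K <- if (lambda == 0) A@values
       else if (lambda == 1) G@values
       else lambda * G@values + (1 - lambda) * A@values
  meta <- list(lambda = lambda, gKind = G@kind,
               gScaled = G@kind == "G_scaled")
  # endpoints reproduce A or G exactly (bit-identically); the PSD
  # check/repair applies to interior blends only
  if (lambda > 0 && lambda < 1) {
    ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
    evMin <- min(ev)
    if (evMin < -1e-6 * max(1, max(abs(ev))))
      stop(sprintf(paste0("blended kernel is strongly indefinite ",
                          "(min eigenvalue %.3e)"), evMin))
    if (evMin < 0) {
      jitter <- -evMin + 1e-10
      K <- K + diag(jitter, nrow(K))
      meta$jitter <- jitter
      message(sprintf("PSD repair: added diagonal jitter %.3e to blend",
                      jitter))
    }
  }
  new("KinshipMatrix", values = (K + t(K)) / 2, kind = "K_blend",
      meta = meta)
}
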