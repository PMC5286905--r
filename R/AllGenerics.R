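#' Number of individuals in an object
#'
#' @param x a Pedigree, GenotypeMatrix, KinshipMatrix or SimDataset.
#' @return integer count of individuals.
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' Individual identifiers carried by an object
#'
#' @param x a Pedigree, GenotypeMatrix or KinshipMatrix.
#' @return character vector of ids, in the object's canonical order.
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' Matrix of values held by a kinship object
#'
#' @param x a [KinshipMatrix-class].
#' @return the labelled symmetric numeric matrix.
#' @export
setGeneric("kinshipValues", function(x) standardGeneric("kinshipValues"))

#' Kind of relationship matrix
#'
#' @param x a [KinshipMatrix-class].
#' @return one of `"A"`, `"G_V"`, `"G_F"`, `"G_scaled"`, `"K_blend"`.
#' @export
setGeneric("kinshipKind", function(x) standardGeneric("kinshipKind"))

#' Genotype codes, allele frequencies and call rates
#'
#' @param x a [GenotypeMatrix-class].
#' @return `genoCodes`: the numeric dosage matrix; `alleleFreq`: per-SNP
#'   counted-allele frequency; `callRate`: per-SNP non-missing fraction.
#' @export
setGeneric("genoCodes", function(x) standardGeneric("genoCodes"))

#' @rdname genoCodes
#' @export
setGeneric("alleleFreq", function(x) standardGeneric("alleleFreq"))

#' @rdname genoCodes
#' @export
setGeneric("callRate", function(x) standardGeneric("callRate"))

#' Estimated genetic and residual covariance matrices of a fit
#'
#' @param x a [MTModelFit-class] or [TraitCovariances-class].
#' @return `traitCovQ`: the T x T genetic covariance; `traitCovR`: the
#'   T x T residual covariance.
#' @export
setGeneric("traitCovQ", function(x) standardGeneric("traitCovQ"))

#' @rdname traitCovQ
#' @export
setGeneric("traitCovR", function(x) standardGeneric("traitCovR"))

#' Derived genetic parameters of a fitted model
#'
#' @param x a [MTModelFit-class].
#' @return `heritability`: per-trait h2; `geneticCorr`, `residualCorr`,
#'   `phenotypicCorr`: T x T correlation matrices.
#' @export
setGeneric("heritability", function(x) standardGeneric("heritability"))

#' @rdname heritability
#' @export
setGeneric("geneticCorr", function(x) standardGeneric("geneticCorr"))

#' @rdname heritability
#' @export
setGeneric("residualCorr", function(x) standardGeneric("residualCorr"))

#' @rdname heritability
#' @export
setGeneric("phenotypicCorr", function(x) standardGeneric("phenotypicCorr"))
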