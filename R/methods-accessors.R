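#' @rdname nIndividuals
setMethod("nIndividuals", "Pedigree", function(x) length(x@id))
#' @rdname nIndividuals
setMethod("nIndividuals", "GenotypeMatrix", function(x) nrow(x@codes))
#' @rdname nIndividuals
setMethod("nIndividuals", "KinshipMatrix", function(x) nrow(x@values))
#' @rdname nIndividuals
setMethod("nIndividuals", "SimDataset", function(x) nrow(x@phenotypes))

#' @rdname individualIds
setMethod("individualIds", "Pedigree", function(x) x@id)
#' @rdname individualIds
setMethod("individualIds", "GenotypeMatrix", function(x) rownames(x@codes))
#' @rdname individualIds
setMethod("individualIds", "KinshipMatrix", function(x) rownames(x@values))

#' @rdname kinshipValues
setMethod("kinshipValues", "KinshipMatrix", function(x) x@values)
#' @rdname kinshipKind
setMethod("kinshipKind", "KinshipMatrix", function(x) x@kind)

#' @rdname genoCodes
setMethod("genoCodes", "GenotypeMatrix", function(x) x@codes)
#' @rdname genoCodes
setMethod("alleleFreq", "GenotypeMatrix", function(x) x@alleleFreq)
#' @rdname genoCodes
setMethod("callRate", "GenotypeMatrix", function(x) x@callRate)

#' @rdname traitCovQ
setMethod("traitCovQ", "TraitCovariances", function(x) x@Q)
#' @rdname traitCovQ
setMethod("traitCovR", "TraitCovariances", function(x) x@R)
#' @rdname traitCovQ
setMethod("traitCovQ", "MTModelFit", function(x) x@params@Q)
#' @rdname traitCovQ
setMethod("traitCovR", "MTModelFit", function(x) x@params@R)

#' @rdname heritability
setMethod("heritability", "MTModelFit", function(x) x@heritability)
#' @rdname heritability
setMethod("geneticCorr", "MTModelFit", function(x) x@geneticCorr)
#' @rdname heritability
setMethod("residualCorr", "MTModelFit", function(x) x@residualCorr)
#' @rdname heritability
setMethod("phenotypicCorr", "MTModelFit", function(x) x@phenotypicCorr)

setMethod("show", "Pedigree", function(object) {
  n <- length(object@id)
  founders <- sum(is.na(object@sire) & is.na(object@dam))
  cat("Pedigree with", n, "individuals (", founders, "founders )\n")
  k <- min(n, 6L)
  print(data.frame(id = object@id, sire = object@sire,
                   dam = object@dam)[seq_len(k), ], row.names = FALSE)
  if (n > k) cat("... and", n - k, "more records\n")
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@codes), "individuals x",
      ncol(object@codes), "SNPs\n")
  cat(sprintf("  mean MAF %.3f, mean call rate %.3f, missing entries %d\n",
              mean(pmin(object@alleleFreq, 1 - object@alleleFreq)),
              mean(object@callRate), sum(is.na(object@codes))))
})

setMethod("show", "KinshipMatrix", function(object) {
  cat(sprintf("KinshipMatrix (kind %s): %d x %d\n", object@kind,
              nrow(object@values), ncol(object@values)))
  cat(sprintf("  diag mean %.4f, off-diag range [%.4f, %.4f]\n",
              mean(diag(object@values)),
              min(object@values[upper.tri(object@values)]),
              max(object@values[upper.tri(object@values)])))
  if (length(object@meta)) {
    keys <- vapply(object@meta, function(v)
      paste(format(v, digits = 4), collapse = ","), character(1))
    cat("  meta:", paste(names(object@meta), keys, sep = "=",
                         collapse = "; "), "\n")
  }
})

setMethod("show", "TraitCovariances", function(object) {
  cat("TraitCovariances for", nrow(object@Q), "traits\n")
  cat("Genetic covariance Q:\n"); print(round(object@Q, 5))
  cat("Residual covariance R:\n"); print(round(object@R, 5))
  if (length(object@mu)) {
    cat("Intercepts:", paste(round(object@mu, 4), collapse = ", "), "\n")
  }
})

setMethod("show", "MTModelFit", function(object) {
  cat("Multi-trait REML fit (", ncol(object@spec@phenotypes), "traits,",
      nrow(object@spec@phenotypes), "individuals )\n")
  cat(sprintf("  restricted logLik %.4f, converged: %s\n",
              object@restrictedLoglik, object@converged))
  h <- object@heritability
  seh <- object@se$heritability
  for (t in seq_along(h))
    cat(sprintf("  h2[%s] = %.3f (SE %.3f)\n", names(h)[t], h[t],
                if (length(seh)) seh[t] else NA_real_))
  cat("Genetic correlations:\n")
  print(round(object@geneticCorr, 3))
})

#' Matrix of predicted breeding values
#'
#' @param x a [DGVPrediction-class].
#' @return targets x traits numeric matrix.
#' @export
dgvValues <- function(x) {
  stopifnot(is(x, "DGVPrediction"))
  x@values
}

setMethod("show", "DGVPrediction", function(object) {
  cat("DGVPrediction:", nrow(object@values), "individuals x",
      ncol(object@values), "traits",
      if (!is.null(object@meta$lambda))
        sprintf("(kernel lambda %.2f)", object@meta$lambda) else "", "\n")
})

setMethod("show", "SimDataset", function(object) {
  cat("SimDataset:", nrow(object@phenotypes), "phenotyped individuals,",
      ncol(object@phenotypes), "traits,",
      ncol(object@genotypes@codes), "SNPs\n")
  cat("  architecture:", object@config@architecture, "\n")
})

setMethod("show", "CVReport", function(object) {
  r <- object@results
  cat("CVReport:", nrow(r), "rows;",
      length(unique(r$variant)), "variants x",
      length(unique(r$lambda)), "lambdas x",
      length(unique(r$rep)), "reps\n")
  fails <- sum(!is.na(r$note) & r$note != "")
  if (fails) cat("  rows flagged non-converged/failed:", fails, "\n")
})
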