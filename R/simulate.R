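#' Simulation configuration constructor
#'
#' Describes a discrete-generation mating design, an unlinked biallelic
#' SNP panel gene-dropped through the pedigree, and a multi-trait
#' architecture with known genetic covariance `Qtrue` and residual
#' covariance `Rtrue`.
#'
#' Two architectures are available. `"infinitesimal"`: founder breeding
#' values are multivariate normal with covariance `Qtrue`; each offspring
#' is the mid-parent value plus a Mendelian-sampling deviation with
#' covariance `0.5 * (1 - (F_s + F_d) / 2) * Qtrue`. `"pleiotropic_qtl"`:
#' a fraction `qtlVarFrac` of the genetic variance comes from `nQtl`
#' causal loci inside the SNP panel whose per-locus effect vectors are
#' drawn with correlation `qtlEffectCorr` (rescaled per trait so the QTL
#' component's variances match `qtlVarFrac * diag(Qtrue)`); the remaining
#' fraction is an infinitesimal pedigree component with covariance
#' `(1 - qtlVarFrac) * Qtrue`. Setting `qtlEffectCorr` different from the
#' correlation implied by `Qtrue` implants a mismatch between what the
#' markers tag and what the pedigree transmits, which is how missing /
#' excessive / spurious marker-based correlations are emulated.
#'
#' @param nFounders number of base-population individuals.
#' @param nGenerations number of discrete offspring generations.
#' @param offspringPerMating full-sib family size.
#' @param nSires,nDams parents drawn (disjointly) from the previous
#'   generation; each dam is mated to one sire, sires are recycled
#'   round-robin so paternal half-sib groups arise.
#' @param nSnps number of unlinked biallelic SNPs.
#' @param nQtl number of causal loci (`<= nSnps`; pleiotropic_qtl mode).
#' @param founderMafRange interval in `(0, 0.5]` for founder allele
#'   frequencies (drawn uniformly per SNP).
#' @param Qtrue,Rtrue T x T symmetric positive-definite covariance
#'   matrices.
#' @param architecture `"infinitesimal"` (default) or `"pleiotropic_qtl"`.
#' @param qtlEffectCorr T x T correlation matrix for per-QTL effect
#'   vectors (defaults to the correlation implied by `Qtrue`).
#' @param qtlVarFrac fraction of genetic variance due to the QTL
#'   component (default 1).
#' @param nuisanceLevels named integer vector of levels per categorical
#'   nuisance factor (default none).
#' @param nuisanceSd standard deviation of the per-level nuisance shifts.
#' @param missingRate fraction of genotype calls masked to `NA`.
#' @param seed master seed; each stage (pedigree, genotypes, traits)
#'   uses a fixed substream offset so stages are independently
#'   reproducible.
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(nFounders = 60, nGenerations = 2,
                      offspringPerMating = 4, nSires = 10, nDams = 30,
                      nSnps = 500, nQtl = 100,
                      founderMafRange = c(0.05, 0.5),
                      Qtrue = diag(2), Rtrue = diag(2),
                      architecture = c("infinitesimal", "pleiotropic_qtl"),
                      qtlEffectCorr = NULL, qtlVarFrac = 1,
                      nuisanceLevels = integer(0), nuisanceSd = 1,
                      missingRate = 0, seed = 1L) {
  architecture <- match.arg(architecture)
  Qtrue <- as.matrix(Qtrue); Rtrue <- as.matrix(Rtrue)
  if (is.null(qtlEffectCorr)) qtlEffectCorr <- stats::cov2cor(Qtrue)
  if (is.null(names(nuisanceLevels)) && length(nuisanceLevels))
    names(nuisanceLevels) <- paste0("factor", seq_along(nuisanceLevels))
  new("SimConfig", nFounders = as.integer(nFounders),
      nGenerations = as.integer(nGenerations),
      offspringPerMating = as.integer(offspringPerMating),
      nSires = as.integer(nSires), nDams = as.integer(nDams),
      nSnps = as.integer(nSnps), nQtl = as.integer(nQtl),
      founderMafRange = founderMafRange, Qtrue = Qtrue, Rtrue = Rtrue,
      architecture = architecture,
      qtlEffectCorr = as.matrix(qtlEffectCorr),
      qtlVarFrac = qtlVarFrac,
      nuisanceLevels = stats::setNames(as.integer(nuisanceLevels),
                                       names(nuisanceLevels)),
      nuisanceSd = nuisanceSd, missingRate = missingRate,
      seed = as.integer(seed))
}

# substream offsets: keep derived seeds well below 2^31
.stage_seed <- function(config, stage) {
  config@seed + switch(stage, pedigree = 1000L, genotypes = 2000L,
                       traits = 3000L)
}

#' Simulate a multi-generation half-sib / full-sib pedigree
#'
#' Generation 0 holds `nFounders` founders. In each later generation,
#' `nSires` sires and `nDams` dams are drawn (disjointly, so no selfing)
#' from the previous generation; each dam produces one full-sib family of
#' `offspringPerMating` offspring, with sires allocated round-robin to
#' dams so that paternal half-sib groups form. Deterministic given
#' `config@seed`.
#'
#' @param config a [SimConfig-class].
#' @return a parent-ordered [Pedigree-class].
#' @export
simulatePedigree <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  withr::with_seed(.stage_seed(config, "pedigree"), {
    id <- sprintf("F%03d", seq_len(config@nFounders))
    sire <- rep(NA_character_, config@nFounders)
    dam <- rep(NA_character_, config@nFounders)
    prev <- id
    for (g in seq_len(config@nGenerations)) {
      if (config@nSires + config@nDams > length(prev))
        stop("mating design error: generation ", g - 1, " has only ",
             length(prev), " candidates for ", config@nSires, " sires + ",
             config@nDams, " dams")
      parents <- sample(prev, config@nSires + config@nDams)
      sires <- parents[seq_len(config@nSires)]
      dams <- parents[config@nSires + seq_len(config@nDams)]
      mateSire <- rep(sample(sires), length.out = config@nDams)
      kid <- 0L
      gid <- character(0); gsire <- character(0); gdam <- character(0)
      for (m in seq_len(config@nDams)) {
        for (o in seq_len(config@offspringPerMating)) {
          kid <- kid + 1L
          gid <- c(gid, sprintf("G%d_%04d", g, kid))
        }
        gsire <- c(gsire, rep(mateSire[m], config@offspringPerMating))
        gdam <- c(gdam, rep(dams[m], config@offspringPerMating))
      }
      id <- c(id, gid); sire <- c(sire, gsire); dam <- c(dam, gdam)
      prev <- gid
    }
    new("Pedigree", id = id, sire = sire, dam = dam)
  })
}

#' Gene-drop unlinked biallelic genotypes through a pedigree
#'
#' Founder allele frequencies are drawn uniformly from
#' `config@founderMafRange`; founder haplotypes are independent Bernoulli
#' draws, and each non-founder allele is a fair-coin copy of one parental
#' allele per locus (loci unlinked, no recombination map). Optional
#' uniform missingness is applied at `config@missingRate`.
#'
#' @param ped a parent-ordered [Pedigree-class].
#' @param config a [SimConfig-class].
#' @return a [GenotypeMatrix-class]; attribute `"founderFreq"` stores the
#'   generating frequencies.
#' @export
geneDropGenotypes <- function(ped, config) {
  stopifnot(is(ped, "Pedigree"), is(config, "SimConfig"))
  validObject(ped)  # guarantees parent ordering
  n <- length(ped@id); p <- config@nSnps
  pos <- seq_len(n); names(pos) <- ped@id
  si <- ifelse(is.na(ped@sire), 0L, pos[ped@sire])
  di <- ifelse(is.na(ped@dam), 0L, pos[ped@dam])
  withr::with_seed(.stage_seed(config, "genotypes"), {
    freq <- stats::runif(p, config@founderMafRange[1],
                         config@founderMafRange[2])
    H1 <- matrix(0L, n, p); H2 <- matrix(0L, n, p)
    for (i in seq_len(n)) {
      if (si[i] == 0L || di[i] == 0L) {
        H1[i, ] <- stats::rbinom(p, 1L, freq)
        H2[i, ] <- stats::rbinom(p, 1L, freq)
      } else {
        pick1 <- stats::runif(p) < 0.5
        H1[i, ] <- ifelse(pick1, H1[si[i], ], H2[si[i], ])
        pick2 <- stats::runif(p) < 0.5
        H2[i, ] <- ifelse(pick2, H1[di[i], ], H2[di[i], ])
      }
    }
    codes <- H1 + H2
    dimnames(codes) <- list(ped@id, sprintf("snp%05d", seq_len(p)))
    if (config@missingRate > 0) {
      mask <- stats::runif(length(codes)) < config@missingRate
      codes[mask] <- NA_integer_
    }
    g <- genotypeMatrix(codes)
    attr(g@codes, "founderFreq") <- freq
    g
  })
}

.rmvn <- function(n, Sigma) {
  L <- chol(Sigma)
  matrix(stats::rnorm(n * ncol(Sigma)), n) %*% L
}

# infinitesimal breeding values down the pedigree with the standard
# Mendelian-sampling variance 0.5 * (1 - (F_s + F_d)/2) * Sigma
.drop_bv <- function(ped, Sigma, Fcoef) {
  n <- length(ped@id); nt <- nrow(Sigma)
  pos <- seq_len(n); names(pos) <- ped@id
  si <- ifelse(is.na(ped@sire), 0L, pos[ped@sire])
  di <- ifelse(is.na(ped@dam), 0L, pos[ped@dam])
  L <- chol(Sigma)
  bv <- matrix(0, n, nt)
  Z <- matrix(stats::rnorm(n * nt), n)
  for (i in seq_len(n)) {
    if (si[i] == 0L || di[i] == 0L) {
      bv[i, ] <- Z[i, ] %*% L
    } else {
      msVar <- 0.5 * (1 - (Fcoef[si[i]] + Fcoef[di[i]]) / 2)
      bv[i, ] <- (bv[si[i], ] + bv[di[i], ]) / 2 +
        sqrt(msVar) * (Z[i, ] %*% L)
    }
  }
  rownames(bv) <- ped@id
  bv
}

#' Simulate breeding values, nuisance effects and phenotypes
#'
#' See [simConfig()] for the two architectures. Residuals are i.i.d.
#' multivariate normal with covariance `Rtrue`; categorical nuisance
#' effects (additive per-level shifts) are added per assigned level.
#' Deterministic given `config@seed`.
#'
#' @param ped a [Pedigree-class] (from [simulatePedigree()]).
#' @param genotypes a [GenotypeMatrix-class] (from [geneDropGenotypes()]).
#' @param config the generating [SimConfig-class].
#' @return a [SimDataset-class].
#' @export
simulateTraits <- function(ped, genotypes, config) {
  stopifnot(is(ped, "Pedigree"), is(genotypes, "GenotypeMatrix"),
            is(config, "SimConfig"))
  validObject(config)
  n <- length(ped@id)
  nt <- nrow(config@Qtrue)
  traits <- if (!is.null(colnames(config@Qtrue))) colnames(config@Qtrue)
            else paste0("trait", seq_len(nt))
  Fcoef <- inbreeding(ped)
  withr::with_seed(.stage_seed(config, "traits"), {
    if (config@architecture == "infinitesimal") {
      bv <- .drop_bv(ped, config@Qtrue, Fcoef)
    } else {
      frac <- config@qtlVarFrac
      qtlIdx <- sort(sample(config@nSnps, config@nQtl))
      codes <- genotypes@codes[ped@id, qtlIdx, drop = FALSE]
      if (anyNA(codes)) {
        mn <- colMeans(codes, na.rm = TRUE)
        miss <- which(is.na(codes), arr.ind = TRUE)
        codes[miss] <- mn[miss[, "col"]]
      }
      B <- .rmvn(config@nQtl, config@qtlEffectCorr)
      Wq <- sweep(codes, 2, colMeans(codes), "-")
      gq <- Wq %*% B
      sdTarget <- sqrt(frac * diag(config@Qtrue))
      sdNow <- apply(gq, 2, stats::sd)
      if (any(sdNow == 0))
        stop("degenerate QTL component (a trait has zero genetic variance)")
      gq <- sweep(gq, 2, sdTarget / sdNow, "*")
      bv <- gq
      if (frac < 1)
        bv <- bv + .drop_bv(ped, (1 - frac) * config@Qtrue, Fcoef)
      attr(bv, "qtlIdx") <- qtlIdx
    }
    rownames(bv) <- ped@id
    colnames(bv) <- traits
    resid <- .rmvn(n, config@Rtrue)
    dimnames(resid) <- list(ped@id, traits)
    intercepts <- stats::setNames(rep(0, nt), traits)
    nuis <- data.frame(row.names = ped@id)
    nuisEff <- list()
    nuisContrib <- matrix(0, n, nt, dimnames = list(ped@id, traits))
    for (f in seq_along(config@nuisanceLevels)) {
      fname <- names(config@nuisanceLevels)[f]
      nl <- config@nuisanceLevels[f]
      lev <- factor(sample.int(nl, n, replace = TRUE),
                    levels = seq_len(nl),
                    labels = paste0(fname, "_", seq_len(nl)))
      eff <- matrix(stats::rnorm(nl * nt, sd = config@nuisanceSd), nl, nt,
                    dimnames = list(levels(lev), traits))
      nuis[[fname]] <- lev
      nuisEff[[fname]] <- eff
      nuisContrib <- nuisContrib + eff[as.integer(lev), , drop = FALSE]
    }
    pheno <- sweep(bv + resid + nuisContrib, 2, intercepts, "+")
    dimnames(pheno) <- list(ped@id, traits)
    new("SimDataset", pedigree = ped, genotypes = genotypes,
        trueBreedingValues = bv, phenotypes = pheno, nuisance = nuis,
        components = list(residuals = resid, nuisanceEffects = nuisEff,
                          intercepts = intercepts,
                          nuisanceContribution = nuisContrib),
        config = config)
  })
}

#' One-call simulation of a complete dataset
#'
#' Runs [simulatePedigree()], [geneDropGenotypes()] and
#' [simulateTraits()] with the stage substreams of `config@seed`.
#'
#' @param config a [SimConfig-class].
#' @return a [SimDataset-class].
#' @export
simulateDataset <- function(config) {
  ped <- simulatePedigree(config)
  g <- geneDropGenotypes(ped, config)
  simulateTraits(ped, g, config)
}
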