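test_that("pedigree simulation honours the mating design", {
  cfg <- simConfig(nFounders = 2, nGenerations = 1, nSires = 1,
                   nDams = 1, offspringPerMating = 2, seed = 1)
  ped <- simulatePedigree(cfg)
  expect_equal(nIndividuals(ped), 4)
  kids <- !is.na(ped@sire)
  expect_equal(sum(kids), 2)
  # one full-sib group: both offspring share sire and dam
  expect_equal(length(unique(paste(ped@sire[kids], ped@dam[kids]))), 1)

  f <- simulatePedigree(simConfig(nFounders = 7, nGenerations = 0,
                                  seed = 2))
  expect_equal(nIndividuals(f), 7)
  expect_true(all(is.na(f@sire)) && all(is.na(f@dam)))

  cfgBad <- simConfig(nFounders = 10, nGenerations = 2, nSires = 4,
                      nDams = 6, offspringPerMating = 1, seed = 3)
  # generation 1 has only 6 offspring, too few parents for generation 2
  expect_error(simulatePedigree(cfgBad), "mating design")
  expect_error(simConfig(nFounders = 10, nGenerations = 1, nSires = 1,
                         nDams = 0), "sire")
})

test_that("simulation is bit-reproducible given the config seed", {
  cfg <- simConfig(nFounders = 20, nGenerations = 1, nSires = 4,
                   nDams = 12, offspringPerMating = 2, nSnps = 50,
                   nQtl = 5, nuisanceLevels = c(sex = 2, pen = 3),
                   seed = 11)
  d1 <- simulateDataset(cfg)
  d2 <- simulateDataset(cfg)
  expect_identical(d1@pedigree@id, d2@pedigree@id)
  expect_identical(genoCodes(d1@genotypes), genoCodes(d2@genotypes))
  expect_identical(d1@phenotypes, d2@phenotypes)
  expect_identical(d1@trueBreedingValues, d2@trueBreedingValues)
  expect_identical(d1@nuisance, d2@nuisance)
})

test_that("gene dropping is Mendelian-consistent at every locus", {
  cfg <- simConfig(nFounders = 30, nGenerations = 2, nSires = 6,
                   nDams = 20, offspringPerMating = 2, nSnps = 200,
                   nQtl = 1, seed = 12)
  ped <- simulatePedigree(cfg)
  g <- geneDropGenotypes(ped, cfg)
  codes <- genoCodes(g)
  pos <- seq_len(nIndividuals(ped)); names(pos) <- ped@id
  for (i in which(!is.na(ped@sire))) {
    kid <- codes[i, ]
    s <- codes[pos[ped@sire[i]], ]
    d <- codes[pos[ped@dam[i]], ]
    # allele counts a parent can transmit: 0 -> 0, 2 -> 1, 1 -> 0 or 1
    minK <- (s == 2) + (d == 2)
    maxK <- (s >= 1) + (d >= 1)
    expect_true(all(kid >= minK & kid <= maxK))
  }
})

test_that("founder genotype means track the generating frequencies", {
  cfg <- simConfig(nFounders = 400, nGenerations = 0, nSnps = 60,
                   nQtl = 1, seed = 13)
  ds <- simulateDataset(cfg)
  freq <- attr(genoCodes(ds@genotypes), "founderFreq")
  obs <- colMeans(genoCodes(ds@genotypes))
  se <- sqrt(2 * freq * (1 - freq) / 400)
  expect_true(all(abs(obs - 2 * freq) < 4 * se))
})

test_that("full sibs share more alleles IBS than pedigree-unrelated pairs", {
  cfg <- simConfig(nFounders = 80, nGenerations = 1, nSires = 16,
                   nDams = 60, offspringPerMating = 5, nSnps = 150,
                   nQtl = 1, seed = 14)
  ds <- simulateDataset(cfg)
  codes <- genoCodes(ds@genotypes)
  ped <- ds@pedigree
  kids <- which(!is.na(ped@sire))
  fam <- paste(ped@sire[kids], ped@dam[kids])
  ibs <- function(i, j) mean(1 - abs(codes[i, ] - codes[j, ]) / 2)
  sibShare <- c(); unrelShare <- c()
  set.seed(15)
  for (rep in 1:1000) {
    f <- sample(unique(fam), 1)
    members <- kids[fam == f]
    ij <- sample(members, 2)
    sibShare <- c(sibShare, ibs(ij[1], ij[2]))
    founders <- sample(which(is.na(ped@sire)), 2)
    unrelShare <- c(unrelShare, ibs(founders[1], founders[2]))
  }
  expect_gt(mean(sibShare), mean(unrelShare))
})

test_that("founder breeding values realize the target genetic covariance", {
  Q <- mkCov(c(1, 0.8), c(0.6))
  cfg <- simConfig(nFounders = 2500, nGenerations = 0, nSnps = 10,
                   nQtl = 1, Qtrue = Q, Rtrue = diag(2), seed = 16)
  ds <- simulateDataset(cfg)
  S <- cov(ds@trueBreedingValues)
  n <- 2500
  for (i in 1:2) for (j in 1:2) {
    se <- sqrt((Q[i, i] * Q[j, j] + Q[i, j]^2) / n)
    expect_lt(abs(S[i, j] - Q[i, j]), 3 * se)
  }
})

test_that("heritability holds by construction in founder phenotypes", {
  q <- c(0.4, 0.6); r <- c(0.6, 0.4)
  cfg <- simConfig(nFounders = 2500, nGenerations = 0, nSnps = 10,
                   nQtl = 1, Qtrue = diag(q), Rtrue = diag(r), seed = 17)
  ds <- simulateDataset(cfg)
  vr <- diag(cov(ds@trueBreedingValues)) / diag(cov(ds@phenotypes))
  expect_true(all(abs(vr - q / (q + r)) < 3 * sqrt(2 / 2500)))
})

test_that("phenotypes reconstruct exactly from stored components", {
  cfg <- simConfig(nFounders = 30, nGenerations = 1, nSires = 6,
                   nDams = 20, offspringPerMating = 2, nSnps = 40,
                   nQtl = 4, nuisanceLevels = c(sex = 2, hatch = 4),
                   seed = 18)
  ds <- simulateDataset(cfg)
  rebuilt <- sweep(ds@trueBreedingValues + ds@components$residuals +
                     ds@components$nuisanceContribution, 2,
                   ds@components$intercepts, "+")
  expect_equal(ds@phenotypes, rebuilt, tolerance = 1e-12)
  expect_true(all(individualIds(ds@genotypes) %in% ds@pedigree@id))
})

test_that("pleiotropic QTL mode matches target variances and correlation", {
  Q <- mkCov(c(0.5, 0.5), c(0.7))
  cfg <- simConfig(nFounders = 150, nGenerations = 1, nSires = 30,
                   nDams = 100, offspringPerMating = 4, nSnps = 300,
                   nQtl = 120, Qtrue = Q, Rtrue = diag(0.5, 2),
                   architecture = "pleiotropic_qtl",
                   qtlEffectCorr = mkCov(c(1, 1), 0.7), seed = 19)
  ds <- simulateDataset(cfg)
  S <- cov(ds@trueBreedingValues)
  # per-trait variances match by construction (sample-sd rescaling)
  expect_equal(unname(diag(S)), unname(diag(Q)), tolerance = 1e-8)
  expect_equal(cov2cor(S)[1, 2], 0.7, tolerance = 0.2)
})

test_that("vanishing genetic covariance gives uncorrelated phenotypes", {
  cfg <- simConfig(nFounders = 600, nGenerations = 0, nSnps = 10,
                   nQtl = 1, Qtrue = diag(1e-8, 2), Rtrue = diag(2),
                   seed = 20)
  ds <- simulateDataset(cfg)
  expect_lt(abs(cor(ds@phenotypes)[1, 2]), 0.1)
})
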