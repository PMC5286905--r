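test_that("SNP QC applies MAF and call-rate thresholds exactly", {
  # exact MAFs 0.005, 0.20, 0.40 at full call rate; plus one SNP with
  # 6% missing (call rate 0.94 < 0.95)
  n <- 200
  mk <- function(ones) c(rep(1, ones), rep(0, n - ones))
  codes <- cbind(mk(2), mk(80), mk(160), mk(120))
  codes[1:12, 4] <- NA
  colnames(codes) <- paste0("s", 1:4)
  rownames(codes) <- paste0("i", 1:n)
  g <- genotypeMatrix(codes)
  expect_message(kept <- filterSNPs(g), "removed")
  expect_setequal(colnames(genoCodes(kept)), c("s2", "s3"))

  # all pass -> identity
  gOK <- genotypeMatrix(codes[, 2:3])
  expect_message(kept2 <- filterSNPs(gOK), "0 SNP")
  expect_identical(genoCodes(kept2), genoCodes(gOK))

  # all removed -> error
  mono <- genotypeMatrix(matrix(2, 10, 2,
                                dimnames = list(paste0("i", 1:10),
                                                c("a", "b"))))
  expect_error(suppressMessages(filterSNPs(mono)), "all SNPs removed")
})

test_that("naive imputation fills missing entries with the mean dosage", {
  codes <- matrix(c(0, 1, 2, NA, 0, 2, 1, 1), 4, 2,
                  dimnames = list(paste0("i", 1:4), c("a", "b")))
  g <- imputeNaive(genotypeMatrix(codes))
  expect_false(anyNA(genoCodes(g)))
  expect_equal(genoCodes(g)["i4", "a"], 1.0)  # p = 0.5 -> dosage 1

  full <- genotypeMatrix(codes[, 2, drop = FALSE])
  expect_identical(genoCodes(imputeNaive(full)), genoCodes(full))

  allNA <- genotypeMatrix(matrix(NA_real_, 3, 1,
                                 dimnames = list(1:3, "x")))
  expect_error(imputeNaive(allNA), "zero call rate")
})

test_that("centering subtracts twice the allele frequency", {
  g <- genotypeMatrix(matrix(c(0, 1, 2), 3, 1,
                             dimnames = list(1:3, "s")))
  expect_equal(unname(centerGenotypes(g)[, 1]), c(-1, 0, 1))
  mono <- genotypeMatrix(matrix(2, 3, 1, dimnames = list(1:3, "s")))
  expect_equal(unname(centerGenotypes(mono)[, 1]), c(0, 0, 0))
  set.seed(2)
  gr <- genotypeMatrix(matrix(rbinom(300, 2, 0.3), 30, 10,
                              dimnames = list(1:30, paste0("s", 1:10))))
  expect_lt(max(abs(colMeans(centerGenotypes(gr)))), 1e-12)
  gm <- genotypeMatrix(matrix(c(0, 1, NA), 3, 1,
                              dimnames = list(1:3, "s")))
  expect_error(centerGenotypes(gm), "impute")
})

test_that("VanRaden and Forni matrices match hand-computed examples", {
  g <- toyGeno()   # codes (2,2) and (0,0), p = 0.5 each
  GV <- kinshipValues(buildGVanRaden(g))
  expect_equal(unname(GV), matrix(c(2, -2, -2, 2), 2))
  GF <- kinshipValues(buildGForni(g))
  expect_equal(unname(GF), matrix(c(1, -1, -1, 1), 2))

  mono <- genotypeMatrix(matrix(2, 3, 2, dimnames = list(1:3, c("a", "b"))))
  expect_error(buildGVanRaden(mono), "monomorphic")
  expect_error(buildGForni(mono), "trace")
})

test_that("Forni trace identity and proportionality to VanRaden hold", {
  set.seed(5)
  codes <- matrix(rbinom(60 * 40, 2, runif(40, 0.1, 0.5)), 60, 40,
                  byrow = TRUE,
                  dimnames = list(paste0("i", 1:60), paste0("s", 1:40)))
  g <- genotypeMatrix(codes)
  GV <- kinshipValues(buildGVanRaden(g))
  GF <- kinshipValues(buildGForni(g))
  expect_equal(sum(diag(GF)), 60, tolerance = 1e-12)
  ratio <- GV[abs(GF) > 1e-8] / GF[abs(GF) > 1e-8]
  expect_lt(diff(range(ratio)), 1e-10)
})

test_that("duplicate individuals get identical rows and diagonals", {
  set.seed(6)
  codes <- matrix(rbinom(20, 2, 0.4), 2, 10)
  codes <- rbind(codes, codes[2, ])
  dimnames(codes) <- list(c("a", "b", "b_copy"), paste0("s", 1:10))
  GV <- kinshipValues(buildGVanRaden(genotypeMatrix(codes)))
  expect_equal(GV["b", "a"], GV["b_copy", "a"])
  expect_equal(GV["b", "b"], GV["b_copy", "b_copy"])
  expect_equal(GV["b", "b_copy"], GV["b", "b"])
})

test_that("mean VanRaden diagonal is near 1 for unrelated founders", {
  cfg <- simConfig(nFounders = 500, nGenerations = 0, nSnps = 800,
                   nQtl = 1, seed = 7)
  ds <- simulateDataset(cfg)
  GV <- kinshipValues(buildGVanRaden(ds@genotypes))
  expect_equal(mean(diag(GV)), 1, tolerance = 0.05)
})

test_that("min-max scaling maps onto the target bounds exactly", {
  m <- matrix(c(1, -0.5, -0.5, 0.8), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  G <- new("KinshipMatrix", values = m, kind = "G_V")
  sc <- kinshipValues(minmaxScale(G))
  expect_equal(unname(sc), matrix(c(2, 0, 0, 26 / 15), 2),
               tolerance = 1e-12)

  set.seed(8)
  K <- randomKernel(30, 8)
  sc2 <- kinshipValues(minmaxScale(new("KinshipMatrix", values = K,
                                       kind = "G_V")))
  expect_identical(max(sc2), 2)
  expect_identical(min(sc2), 0)
  expect_true(all(sc2 >= 0))                      # no negative entries
  expect_lt(max(abs(sc2 - t(sc2))), 1e-10)        # symmetry preserved

  # fixed point: a matrix already spanning [0, 2]
  fp <- matrix(c(2, 0, 0, 1), 2, 2, dimnames = list(1:2, 1:2))
  G2 <- new("KinshipMatrix", values = fp, kind = "G_V")
  expect_equal(kinshipValues(minmaxScale(G2)), fp)

  const <- new("KinshipMatrix",
               values = matrix(1, 2, 2, dimnames = list(1:2, 1:2)),
               kind = "G_V")
  expect_error(minmaxScale(const), "constant")
})

test_that("blending is exact at the endpoints and monotone in lambda", {
  set.seed(9)
  cfg <- simConfig(nFounders = 12, nGenerations = 1, nSires = 3,
                   nDams = 8, offspringPerMating = 2, nSnps = 100,
                   nQtl = 1, seed = 9)
  ds <- simulateDataset(cfg)
  A <- buildA(ds@pedigree)
  G <- buildGVanRaden(ds@genotypes)
  expect_identical(kinshipValues(blendKernels(G, A, 0)),
                   kinshipValues(A))
  expect_identical(kinshipValues(blendKernels(G, A, 1)),
                   kinshipValues(G))
  K25 <- kinshipValues(blendKernels(G, A, 0.25))
  K75 <- kinshipValues(blendKernels(G, A, 0.75))
  dir <- kinshipValues(G) - kinshipValues(A)
  expect_true(all((K75 - K25) * dir >= -1e-12))
  expect_lt(max(abs(K25 - t(K25))), 1e-10)

  # arithmetic on a hand example
  ab <- list(c("a", "b"), c("a", "b"))
  Am <- new("KinshipMatrix", values = matrix(diag(2), 2, dimnames = ab),
            kind = "A")
  Gm <- new("KinshipMatrix",
            values = matrix(2 * diag(2), 2, dimnames = ab), kind = "G_V")
  expect_equal(unname(kinshipValues(blendKernels(Gm, Am, 0.5))),
               1.5 * diag(2))

  # id mismatch is an error, never a silent reorder
  Gm2 <- Gm
  rownames(Gm2@values) <- colnames(Gm2@values) <- c("b", "a")
  expect_error(blendKernels(Gm2, Am, 0.5), "mismatch")
})

test_that("PSD repair jitters slightly indefinite blends and rejects worse", {
  ids <- c("a", "b")
  # off-diagonal chosen so the 0.999-blend has min eigenvalue ~ -5e-7,
  # inside the repairable window (-1e-6, 0)
  d <- 0.0010015
  near <- matrix(c(1, 1 + d, 1 + d, 1), 2, 2, dimnames = list(ids, ids))
  G <- new("KinshipMatrix", values = near, kind = "G_scaled")
  A <- new("KinshipMatrix",
           values = matrix(diag(2), 2, dimnames = list(ids, ids)),
           kind = "A")
  expect_message(K <- blendKernels(G, A, 0.999), "jitter")
  ev <- eigen(kinshipValues(K), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0)
  expect_true(!is.null(K@meta$jitter))

  bad <- matrix(c(1, 2, 2, 1), 2, 2, dimnames = list(ids, ids))
  Gbad <- new("KinshipMatrix", values = bad, kind = "G_scaled")
  expect_error(blendKernels(Gbad, A, 0.9), "indefinite")
})

test_that("marker-based relatedness tracks pedigree expectation (IBS ~ IBD)", {
  cfg <- simConfig(nFounders = 60, nGenerations = 2, nSires = 12,
                   nDams = 40, offspringPerMating = 3, nSnps = 400,
                   nQtl = 1, seed = 10)
  ds <- simulateDataset(cfg)
  A <- kinshipValues(buildA(ds@pedigree))
  GV <- kinshipValues(buildGVanRaden(ds@genotypes))
  off <- upper.tri(A)
  expect_gt(cor(A[off], GV[off]), 0.3)
})
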