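randomInstance <- function(seed, nMax = 15) {
  set.seed(seed)
  n <- sample(8:nMax, 1)
  nt <- sample(2:3, 1)
  K <- randomKernel(n, seed + 500)
  Y <- matrix(rnorm(n * nt), n,
              dimnames = list(rownames(K), paste0("t", seq_len(nt))))
  Q <- crossprod(matrix(rnorm(nt * nt), nt)) + diag(0.1, nt)
  R <- crossprod(matrix(rnorm(nt * nt), nt)) + diag(0.5, nt)
  list(Y = Y, K = K, Q = Q, R = R,
       spec = mtModelSpec(Y, new("KinshipMatrix", values = K,
                                 kind = "K_blend")))
}

test_that("eigendecomposition likelihood equals the dense formula", {
  for (s in 1:12) {
    inst <- randomInstance(s)
    fast <- restrictedLoglik(inst$spec, inst$Q, inst$R)
    dense <- denseREML(inst$Y, inst$K, inst$Q, inst$R)
    expect_equal(fast, dense, tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to joint permutation of individuals", {
  inst <- randomInstance(99)
  ll <- restrictedLoglik(inst$spec, inst$Q, inst$R)
  set.seed(1)
  perm <- sample(nrow(inst$Y))
  Yp <- inst$Y[perm, , drop = FALSE]
  Kp <- inst$K[perm, perm]
  specP <- mtModelSpec(Yp, new("KinshipMatrix", values = Kp,
                               kind = "K_blend"))
  expect_equal(restrictedLoglik(specP, inst$Q, inst$R), ll,
               tolerance = 1e-9)
})

test_that("with one trait and K = I the likelihood confounds Q and R", {
  set.seed(3)
  n <- 20
  K <- diag(n); ids <- paste0("i", 1:n); dimnames(K) <- list(ids, ids)
  Y <- matrix(rnorm(n), n, dimnames = list(ids, "y"))
  spec <- mtModelSpec(Y, new("KinshipMatrix", values = K, kind = "A"))
  l1 <- restrictedLoglik(spec, matrix(0.3), matrix(0.7))
  l2 <- restrictedLoglik(spec, matrix(0.9), matrix(0.1))
  expect_equal(l1, l2, tolerance = 1e-9)
})

test_that("singular covariance blocks yield -Inf, not an error", {
  inst <- randomInstance(7)
  nt <- ncol(inst$Y)
  expect_message(
    ll <- restrictedLoglik(inst$spec, diag(nt), matrix(0, nt, nt)),
    "-Inf")
  expect_identical(ll, -Inf)
})

test_that("REML recovers known components on simulated data", {
  Q <- mkCov(c(0.4, 0.4), c(0.5)); R <- mkCov(c(0.6, 0.6), c(0))
  cfg <- simConfig(nFounders = 160, nGenerations = 1, nSires = 30,
                   nDams = 120, offspringPerMating = 4, nSnps = 20,
                   nQtl = 1, Qtrue = Q, Rtrue = R, seed = 31)
  ped <- simulatePedigree(cfg)
  ds <- simulateTraits(ped, geneDropGenotypes(ped, cfg), cfg)
  fit <- remlFit(mtModelSpec(ds@phenotypes, buildA(ped)), nStarts = 3)
  expect_true(fit@converged)
  h <- heritability(fit); seh <- fit@se$heritability
  expect_true(all(abs(h - 0.4) < 4 * seh))
  rg <- geneticCorr(fit)[1, 2]
  expect_lt(abs(rg - 0.5), 4 * fit@se$geneticCorr[1, 2])
  # maximization contract: fitted loglik beats every start
  S <- cov(ds@phenotypes)
  for (w in list(c(0.5, 0.5), c(0.1, 0.9), c(0.9, 0.1))) {
    ll0 <- restrictedLoglik(mtModelSpec(ds@phenotypes, buildA(ped)),
                            w[1] * S, w[2] * S)
    expect_gte(fit@restrictedLoglik, ll0 - 1e-6)
  }
  expect_true(all(fit@restrictedLoglik >= fit@details$startLogLik - 1e-6))
})

test_that("duplicating a trait drives its correlations to the boundary", {
  set.seed(33)
  cfg <- simConfig(nFounders = 60, nGenerations = 1, nSires = 12,
                   nDams = 45, offspringPerMating = 3, nSnps = 20,
                   nQtl = 1, Qtrue = matrix(0.5), Rtrue = matrix(0.5),
                   seed = 33)
  ped <- simulatePedigree(cfg)
  ds <- simulateTraits(ped, geneDropGenotypes(ped, cfg), cfg)
  Y <- cbind(y1 = ds@phenotypes[, 1], y2 = ds@phenotypes[, 1])
  fit <- remlFit(mtModelSpec(Y, buildA(ped)), nStarts = 1)
  expect_gt(geneticCorr(fit)[1, 2], 0.99)
  expect_gt(residualCorr(fit)[1, 2], 0.99)
  expect_true(fit@details$boundary ||
                min(eigen(traitCovR(fit))$values) < 1e-4)
})

test_that("rescaling one trait rescales Q and R but not h2 or correlations", {
  Q <- mkCov(c(0.3, 0.5), c(0.4)); R <- mkCov(c(0.7, 0.5), c(0.1))
  cfg <- simConfig(nFounders = 100, nGenerations = 1, nSires = 20,
                   nDams = 75, offspringPerMating = 3, nSnps = 20,
                   nQtl = 1, Qtrue = Q, Rtrue = R, seed = 35)
  ped <- simulatePedigree(cfg)
  ds <- simulateTraits(ped, geneDropGenotypes(ped, cfg), cfg)
  A <- buildA(ped)
  f1 <- remlFit(mtModelSpec(ds@phenotypes, A), nStarts = 1)
  c0 <- 3.7
  Y2 <- ds@phenotypes
  Y2[, 1] <- c0 * Y2[, 1]
  f2 <- remlFit(mtModelSpec(Y2, A), nStarts = 1)
  expect_equal(traitCovQ(f2)[1, 1], c0^2 * traitCovQ(f1)[1, 1],
               tolerance = 1e-5)
  expect_equal(traitCovR(f2)[1, 1], c0^2 * traitCovR(f1)[1, 1],
               tolerance = 1e-5)
  expect_equal(heritability(f2), heritability(f1), tolerance = 1e-6)
  expect_equal(geneticCorr(f2)[1, 2], geneticCorr(f1)[1, 2],
               tolerance = 1e-6)
})

test_that("derived parameters follow their definitions", {
  p <- deriveParameters(matrix(1), matrix(3))
  expect_equal(unname(p$heritability), 0.25)
  p2 <- deriveParameters(mkCov(c(1, 1), 0.5), diag(2))
  expect_equal(p2$geneticCorr[1, 2], 0.5)
  expect_equal(p2$phenotypicCorr[1, 2], 0.5 / 2)
  p3 <- deriveParameters(mkCov(c(1, 1), 0), diag(2))
  expect_equal(p3$phenotypicCorr[1, 2], 0)
  expect_message(p4 <- deriveParameters(diag(c(1, 0)), diag(2)),
                 "zero variance")
  expect_true(is.na(p4$geneticCorr[1, 2]))
})

test_that("DGV predictions match the dense mixed-model conditional mean", {
  for (s in c(51, 52, 53)) {
    set.seed(s)
    n <- 16; ntr <- 12
    K <- randomKernel(n, s)
    ids <- rownames(K)
    nt <- if (s %% 2) 2 else 3
    Y <- matrix(rnorm(n * nt), n,
                dimnames = list(ids, paste0("t", 1:nt)))
    tr <- ids[1:ntr]; te <- ids[(ntr + 1):n]
    Kobj <- new("KinshipMatrix", values = K, kind = "K_blend")
    fit <- remlFit(mtModelSpec(Y[tr, , drop = FALSE], Kobj),
                   nStarts = 1, computeSE = FALSE)
    pred <- dgvValues(predictDGV(fit, Kobj, te))
    dense <- denseCondMean(Y, K, traitCovQ(fit), traitCovR(fit),
                           fit@params@mu, tr, te)
    expect_equal(pred, dense, tolerance = 1e-8)
  }
})

test_that("a target unrelated to all training individuals predicts zero", {
  set.seed(61)
  n <- 10
  K <- randomKernel(n, 61)
  ids <- rownames(K)
  Kfull <- rbind(cbind(K, rep(0, n)), c(rep(0, n), 1))
  rownames(Kfull) <- colnames(Kfull) <- c(ids, "lone")
  Y <- matrix(rnorm(n * 2), n, dimnames = list(ids, c("a", "b")))
  Kobj <- new("KinshipMatrix", values = Kfull, kind = "K_blend")
  fit <- remlFit(mtModelSpec(Y, Kobj), nStarts = 1, computeSE = FALSE)
  pred <- dgvValues(predictDGV(fit, Kobj, "lone"))
  expect_identical(unname(pred), matrix(0, 1, 2))
})

test_that("test-set phenotypes never influence predictions (no leakage)", {
  set.seed(62)
  n <- 20
  K <- randomKernel(n, 62)
  ids <- rownames(K)
  Y <- matrix(rnorm(n * 2), n, dimnames = list(ids, c("a", "b")))
  tr <- ids[1:12]; te <- ids[13:20]
  Kobj <- new("KinshipMatrix", values = K, kind = "K_blend")
  fit <- remlFit(mtModelSpec(Y[tr, ], Kobj), nStarts = 1,
                 computeSE = FALSE)
  p1 <- dgvValues(predictDGV(fit, Kobj, te))
  Y2 <- Y
  Y2[te, ] <- Y2[te, ] + 100          # perturb test phenotypes only
  fit2 <- remlFit(mtModelSpec(Y2[tr, ], Kobj), nStarts = 1,
                  computeSE = FALSE)
  p2 <- dgvValues(predictDGV(fit2, Kobj, te))
  expect_identical(p1, p2)
})
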