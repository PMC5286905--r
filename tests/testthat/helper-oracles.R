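# Independent oracles and small fixture builders shared across tests.
# These deliberately use dense / brute-force formulations so they share
# no code path with the package internals they check.

# covariance matrix from per-trait variances and upper-triangle
# correlations (order 12, 13, 23, ...)
mkCov <- function(v, r, traits = NULL) {
  nt <- length(v)
  s <- sqrt(v)
  m <- diag(v)
  k <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      k <- k + 1
      m[i, j] <- m[j, i] <- r[k] * s[i] * s[j]
    }
  }
  if (!is.null(traits)) dimnames(m) <- list(traits, traits)
  m
}

# dense restricted log-likelihood of y ~ N((I_T (x) 1) mu, Q (x) K + R (x) I)
# (trait-major stacking), with the same (n-1) T log(2 pi) constant the
# package uses
denseREML <- function(Y, K, Q, R) {
  n <- nrow(Y); nt <- ncol(Y)
  V <- kronecker(Q, K) + kronecker(R, diag(n))
  X <- kronecker(diag(nt), rep(1, n))
  y <- as.vector(Y)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  mu <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% mu
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                       t(r) %*% Vi %*% r + (n - 1) * nt * log(2 * pi)))
}

# dense multi-trait conditional mean of breeding values for target
# individuals given training phenotypes
denseCondMean <- function(Y, K, Q, R, mu, trainIds, targetIds) {
  ntr <- length(trainIds); nt <- ncol(Y)
  V <- kronecker(Q, K[trainIds, trainIds]) + kronecker(R, diag(ntr))
  X <- kronecker(diag(nt), rep(1, ntr))
  r <- as.vector(Y[trainIds, , drop = FALSE]) - X %*% mu
  Cg <- kronecker(Q, K[targetIds, trainIds, drop = FALSE])
  out <- matrix(Cg %*% solve(V, r), ncol = nt)
  dimnames(out) <- list(targetIds, colnames(Y))
  out
}

# random positive-definite kinship-like matrix with ids
randomKernel <- function(n, seed) {
  set.seed(seed)
  W <- matrix(rnorm(n * 2 * n), n)
  K <- tcrossprod(W) / (2 * n) + diag(0.4, n)
  ids <- paste0("i", seq_len(n))
  dimnames(K) <- list(ids, ids)
  K
}

# gene-drop founder-unique allele labels down a pedigree at nLoci
# independent loci; returns the two n x nLoci haplotype label matrices
geneDropAlleles <- function(ped, nLoci, seed) {
  n <- length(ped@id)
  pos <- seq_len(n); names(pos) <- ped@id
  si <- ifelse(is.na(ped@sire), 0L, pos[ped@sire])
  di <- ifelse(is.na(ped@dam), 0L, pos[ped@dam])
  set.seed(seed)
  H1 <- matrix(0L, n, nLoci); H2 <- matrix(0L, n, nLoci)
  for (i in seq_len(n)) {
    if (si[i] == 0L || di[i] == 0L) {
      H1[i, ] <- 2L * i - 1L
      H2[i, ] <- 2L * i
    } else {
      H1[i, ] <- ifelse(runif(nLoci) < 0.5, H1[si[i], ], H2[si[i], ])
      H2[i, ] <- ifelse(runif(nLoci) < 0.5, H1[di[i], ], H2[di[i], ])
    }
  }
  rownames(H1) <- rownames(H2) <- ped@id
  list(H1 = H1, H2 = H2)
}

# Monte-Carlo estimate (with its SE) of the additive relationship between
# two individuals from dropped allele labels: A_ij = 2 * P(IBD)
ibdPairEstimate <- function(drops, i, j) {
  if (i == j) {
    s <- drops$H1[i, ] == drops$H2[i, ]   # P(self alleles IBD) = F
    est <- 1 + mean(s)
    se <- sd(s) / sqrt(length(s))
  } else {
    s <- (
      (drops$H1[i, ] == drops$H1[j, ]) + (drops$H1[i, ] == drops$H2[j, ]) +
      (drops$H2[i, ] == drops$H1[j, ]) + (drops$H2[i, ] == drops$H2[j, ])
    ) / 4
    est <- 2 * mean(s)
    se <- 2 * sd(s) / sqrt(length(s))
  }
  c(est = est, se = se)
}

# four-individual textbook pedigree: two founders, two full-sib offspring
fullSibPedigree <- function() {
  pedigree(c("s", "d", "o1", "o2"), c(NA, NA, "s", "s"),
           c(NA, NA, "d", "d"))
}

# toy genotypes behind the hand-computed G examples: two individuals,
# two SNPs, codes (2,2) and (0,0), allele frequencies 0.5
toyGeno <- function() {
  codes <- matrix(c(2, 0, 2, 0), 2, 2,
                  dimnames = list(c("a", "b"), c("s1", "s2")))
  genotypeMatrix(codes)
}

# default tri-variate study structure: phenotypic variance 1 per trait,
# h2 = (0.2, 0.25, 0.3), genetic correlations (0.5, -0.2, -0.2),
# residual correlations (0.48, -0.026, -0.010)
studyCovariances <- function() {
  h2 <- c(0.2, 0.25, 0.3)
  traits <- c("BW", "BM", "HHP")
  list(Q = mkCov(h2, c(0.5, -0.2, -0.2), traits),
       R = mkCov(1 - h2, c(0.48, -0.026, -0.010), traits),
       h2 = setNames(h2, traits), rG = c(0.5, -0.2, -0.2))
}
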