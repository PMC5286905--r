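#' Pair phenotypes with a kinship kernel
#'
#' Aligns the kinship matrix to the phenotype rows (subsetting is fine,
#' a phenotyped individual missing from the kernel is an error) and
#' validates that all traits are observed on all individuals.
#'
#' @param phenotypes n x T numeric matrix (rownames = ids, colnames =
#'   trait names; defaults generated when absent).
#' @param kinship a [KinshipMatrix-class] covering all phenotype ids.
#' @return an [MTModelSpec-class].
#' @export
mtModelSpec <- function(phenotypes, kinship) {
  Y <- as.matrix(phenotypes)
  if (is.null(rownames(Y)))
    stop("phenotypes must carry individual ids as rownames")
  if (is.null(colnames(Y))) colnames(Y) <- paste0("trait", seq_len(ncol(Y)))
  missing <- setdiff(rownames(Y), rownames(kinship@values))
  if (length(missing))
    stop("phenotyped individuals absent from kinship matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  Ksub <- kinship@values[rownames(Y), rownames(Y), drop = FALSE]
  K <- new("KinshipMatrix", values = (Ksub + t(Ksub)) / 2,
           kind = kinship@kind, meta = kinship@meta)
  new("MTModelSpec", phenotypes = Y, kinship = K)
}

# Eigendecomposition of the kernel plus rotated data, computed once per
# spec and reused across likelihood evaluations.
.eigSetup <- function(spec) {
  eg <- eigen(spec@kinship@values, symmetric = TRUE)
  d <- pmax(eg$values, 0)        # floor tiny negative eigenvalues of PSD K
  U <- eg$vectors
  list(d = d, U = U,
       Yr = crossprod(U, spec@phenotypes),
       u = drop(crossprod(U, rep(1, nrow(U)))))
}

# Simultaneous diagonalization of (Q, R): returns Tm with Tm' R Tm = I and
# Tm' Q Tm = diag(phi). Requires R positive-definite.
.simdiag <- function(Q, R) {
  C <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(C)) return(NULL)
  Ci <- backsolve(C, diag(nrow(R)))
  M <- t(Ci) %*% Q %*% Ci
  if (any(!is.finite(M))) return(NULL)
  eg <- tryCatch(eigen((M + t(M)) / 2, symmetric = TRUE),
                 error = function(e) NULL)
  if (is.null(eg)) return(NULL)
  list(Tm = Ci %*% eg$vectors, phi = eg$values,
       logdetR = 2 * sum(log(diag(C))))
}

# Restricted log-likelihood via the rotated per-individual blocks
# V_i = d_i Q + R. Returns -Inf when a block is singular.
.remlLL <- function(setup, Q, R, want = "ll") {
  sd_ <- .simdiag(Q, R)
  if (is.null(sd_)) return(list(ll = -Inf))
  n <- length(setup$d); nt <- ncol(setup$Yr)
  W <- outer(setup$d, sd_$phi) + 1          # n x T weights d_i phi_t + 1
  if (any(W <= 0)) return(list(ll = -Inf))
  Yt <- setup$Yr %*% sd_$Tm
  u <- setup$u
  cw <- colSums(u^2 / W)                    # X'V^-1X = Tm diag(cw) Tm'
  if (any(cw <= 0)) return(list(ll = -Inf))
  b <- colSums(u * Yt / W)
  muTilde <- b / cw                          # = Tm' mu-hat (diagonal GLS)
  Rt <- Yt - outer(u, muTilde)
  quad <- sum(Rt^2 / W)
  logdetV <- sum(log(W)) + n * sd_$logdetR
  logdetXVX <- sum(log(cw)) - sd_$logdetR
  ll <- -0.5 * (logdetV + logdetXVX + quad + (n - 1) * nt * log(2 * pi))
  if (want == "ll") return(list(ll = ll))
  mu <- drop(solve(t(sd_$Tm), muTilde))
  if (want == "mu") return(list(ll = ll, mu = mu))
  # pieces for prediction: V^-1 (y - X mu) in the original basis
  Hrot <- (Rt / W) %*% t(sd_$Tm)
  list(ll = ll, mu = mu, Vinv_resid = setup$U %*% Hrot)
}

#' Restricted log-likelihood of the multi-trait kernel model
#'
#' Evaluates the REML log-likelihood of `y ~ N((I_T (x) 1) mu,
#' K (x) Q + I (x) R)` (trait-major stacking; per-trait intercepts as the
#' only fixed effects, profiled out by GLS). Computation rotates the data
#' by the eigenvectors of K, which decouples the problem into n
#' independent T-dimensional blocks with covariance `d_i Q + R`; the
#' log-determinant correction for the projected fixed effects is
#' included, as is the `(n - 1) T log(2 pi) / 2` constant.
#'
#' @param spec an [MTModelSpec-class].
#' @param Q genetic covariance matrix, or a [TraitCovariances-class]
#'   (in which case `R` is ignored).
#' @param R residual covariance matrix (positive-definite).
#' @return the restricted log-likelihood (scalar); `-Inf` with a message
#'   when a rotated block `d_i Q + R` is singular.
#' @export
restrictedLoglik <- function(spec, Q, R = NULL) {
  stopifnot(is(spec, "MTModelSpec"))
  validObject(spec)
  if (is(Q, "TraitCovariances")) { R <- Q@R; Q <- Q@Q }
  ll <- .remlLL(.eigSetup(spec), Q, R)$ll
  if (!is.finite(ll))
    message("restricted likelihood is -Inf: singular covariance block")
  ll
}

.nPar <- function(nt) nt * (nt + 1) / 2

# theta = (vech of lower-tri Cholesky of Q, raw; vech of Cholesky of R
# with log-diagonal). PSD of Q and PD of R hold by construction.
.thetaToQR <- function(theta, nt) {
  np <- .nPar(nt)
  Lq <- matrix(0, nt, nt); Lq[lower.tri(Lq, diag = TRUE)] <- theta[1:np]
  Lr <- matrix(0, nt, nt)
  Lr[lower.tri(Lr, diag = TRUE)] <- theta[np + 1:np]
  diag(Lr) <- exp(diag(Lr))
  list(Q = tcrossprod(Lq), R = tcrossprod(Lr))
}

.QRtoTheta <- function(Q, R, nt) {
  jit <- 1e-8 * mean(diag(Q) + diag(R))
  Lq <- t(chol(Q + diag(jit, nt)))
  Lr <- t(chol(R + diag(jit, nt)))
  diag(Lr) <- log(diag(Lr))
  c(Lq[lower.tri(Lq, diag = TRUE)], Lr[lower.tri(Lr, diag = TRUE)])
}

#' Derived genetic parameters from covariance matrices
#'
#' Heritabilities `h2_t = Q_tt / (Q_tt + R_tt)`, genetic correlations
#' `r_G = Q_xy / sqrt(Q_xx Q_yy)`, residual correlations from `R`, and
#' phenotypic correlations from `Q + R`. A zero variance makes the
#' affected correlations `NA` (with a message).
#'
#' @param params a [TraitCovariances-class], or a genetic covariance
#'   matrix `Q` (then `R` is required).
#' @param R residual covariance matrix when `params` is a plain matrix.
#' @return list with elements `heritability`, `geneticCorr`,
#'   `residualCorr`, `phenotypicCorr`.
#' @export
deriveParameters <- function(params, R = NULL) {
  if (is(params, "TraitCovariances")) { Q <- params@Q; R <- params@R }
  else Q <- as.matrix(params)
  traits <- colnames(Q)
  if (is.null(traits)) traits <- paste0("trait", seq_len(ncol(Q)))
  dimnames(Q) <- dimnames(R) <- list(traits, traits)
  safeCor <- function(S) {
    v <- diag(S)
    if (any(v <= 0)) {
      message("zero variance for trait(s) ",
              paste(traits[v <= 0], collapse = ", "),
              ": correlations reported as NA")
      bad <- v <= 0
      out <- S / sqrt(outer(pmax(v, 0), pmax(v, 0)))
      out[bad, ] <- NA_real_; out[, bad] <- NA_real_
      diag(out)[!bad] <- 1
      return(out)
    }
    stats::cov2cor(S)
  }
  h2 <- stats::setNames(diag(Q) / (diag(Q) + diag(R)), traits)
  list(heritability = h2, geneticCorr = safeCor(Q),
       residualCorr = safeCor(R), phenotypicCorr = safeCor(Q + R))
}

#' REML estimation of the multi-trait kernel model
#'
#' Maximizes [restrictedLoglik()] over Cholesky-parametrized `Q` and `R`
#' by quasi-Newton (BFGS), from several starting splits of the phenotypic
#' covariance between genetic and residual components (50/50, 10/90,
#' 90/10 by default). After the best start, the optimizer is restarted
#' once from the optimum; convergence is declared when that polish step
#' changes the log-likelihood by less than `1e-8` and the numerical
#' gradient norm is below `1e-5` relative to the log-likelihood
#' magnitude. Standard errors come from the inverse
#' numerical Hessian on the unconstrained parametrization, mapped by the
#' delta method to the covariance entries, heritabilities and
#' correlations.
#'
#' @param spec an [MTModelSpec-class].
#' @param nStarts number of starting values (1-3 use the fixed splits;
#'   more add random perturbations of the first).
#' @param maxit maximum BFGS iterations per start.
#' @param computeSE compute asymptotic standard errors (numerical
#'   Hessian; skip for speed inside cross-validation loops).
#' @param verbose print per-start progress.
#' @return an [MTModelFit-class]. Boundary estimates (smallest eigenvalue
#'   of `Q` below `1e-6 * trace(Q)`) are flagged in `details$boundary`,
#'   not fatal.
#' @export
remlFit <- function(spec, nStarts = 3, maxit = 1000, computeSE = TRUE,
                    verbose = FALSE) {
  stopifnot(is(spec, "MTModelSpec"))
  validObject(spec)
  Y <- spec@phenotypes
  n <- nrow(Y); nt <- ncol(Y)
  if (n <= nt) stop("need more individuals than traits")
  setup <- .eigSetup(spec)
  if (max(setup$d) - min(setup$d) < 1e-10 * max(abs(setup$d), 1))
    warning("kinship matrix is (numerically) proportional to the ",
            "identity: Q and R are not separately identifiable")
  S <- stats::cov(Y)
  shares <- list(c(0.5, 0.5), c(0.1, 0.9), c(0.9, 0.1))
  starts <- lapply(seq_len(nStarts), function(k) {
    if (k <= 3) .QRtoTheta(shares[[k]][1] * S, shares[[k]][2] * S, nt)
    else .QRtoTheta(0.5 * S, 0.5 * S, nt) * exp(stats::rnorm(2 * .nPar(nt),
                                                             sd = 0.2))
  })
  negll <- function(theta) {
    qr_ <- .thetaToQR(theta, nt)
    ll <- .remlLL(setup, qr_$Q, qr_$R)$ll
    if (!is.finite(ll)) 1e10 else -ll
  }
  fits <- lapply(seq_along(starts), function(k) {
    o <- tryCatch(stats::optim(starts[[k]], negll, method = "BFGS",
                               control = list(maxit = maxit,
                                              reltol = 1e-12,
                                              ndeps = rep(1e-5,
                                                          2 * .nPar(nt)))),
                  error = function(e) NULL)
    if (verbose && !is.null(o))
      message(sprintf("start %d: logLik %.6f (%d fn calls)", k,
                      -o$value, o$counts[1]))
    o
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok) || min(vapply(fits[ok], `[[`, 0, "value")) >= 1e10)
    stop("REML failed to converge from any start; check that the kernel ",
         "is PSD and the phenotypes are non-degenerate")
  fits <- fits[ok]
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  # polish step: declare convergence from the change it achieves
  polish <- stats::optim(best$par, negll, method = "BFGS",
                         control = list(maxit = maxit, reltol = 1e-12,
                                        ndeps = rep(1e-5, 2 * .nPar(nt))))
  # Newton refinement localizes the optimum well beyond BFGS precision
  refined <- .newtonRefine(negll, polish$par, polish$value)
  polish$par <- refined$par
  polish$value <- refined$value
  llChange <- best$value - polish$value
  theta <- polish$par
  grad <- pracma::grad(negll, theta)
  gradNorm <- sqrt(sum(grad^2))
  # gradient tolerance is relative to |logLik|: the numerical gradient of
  # a likelihood of magnitude ~1e3 carries noise well above 1e-5 absolute
  converged <- abs(llChange) < 1e-8 &&
    gradNorm < 1e-5 * max(1, abs(polish$value))
  qr_ <- .thetaToQR(theta, nt)
  traits <- colnames(Y)
  Q <- qr_$Q; R <- qr_$R
  dimnames(Q) <- dimnames(R) <- list(traits, traits)
  evQ <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
  boundary <- min(evQ) < 1e-6 * sum(diag(Q))
  final <- .remlLL(setup, Q, R, want = "mu")
  pars <- deriveParameters(Q, R)
  startLL <- -vapply(fits, `[[`, 0, "value")
  se <- list()
  if (computeSE) se <- .remlSE(negll, theta, nt, traits)
  params <- new("TraitCovariances", Q = Q, R = R,
                mu = stats::setNames(final$mu, traits))
  new("MTModelFit", params = params, restrictedLoglik = final$ll,
      heritability = pars$heritability, geneticCorr = pars$geneticCorr,
      residualCorr = pars$residualCorr,
      phenotypicCorr = pars$phenotypicCorr, se = se,
      converged = converged, nIter = as.numeric(polish$counts[1]),
      spec = spec,
      details = list(startLogLik = startLL, gradNorm = gradNorm,
                     llChangePolish = llChange, boundary = boundary,
                     theta = theta))
}

# damped Newton steps on the numerical gradient/Hessian; accepts a step
# only when it does not increase the objective
.newtonRefine <- function(fn, theta, value, maxSteps = 8) {
  for (it in seq_len(maxSteps)) {
    g <- pracma::grad(fn, theta)
    H <- pracma::hessian(fn, theta)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    fac <- 1; accepted <- FALSE
    for (h in 1:6) {
      cand <- theta - fac * step
      v <- fn(cand)
      if (is.finite(v) && v <= value) {
        theta <- cand; value <- v; accepted <- TRUE
        break
      }
      fac <- fac / 2
    }
    if (!accepted || sqrt(sum((fac * step)^2)) < 1e-10) break
  }
  list(par = theta, value = value)
}

# SEs on (vech Q, vech R, h2, rG, rE, rP) by inverse Hessian + delta
.remlSE <- function(negll, theta, nt, traits) {
  H <- pracma::hessian(negll, theta)
  Vtheta <- tryCatch(solve(H), error = function(e) MASS::ginv(H))
  low <- lower.tri(diag(nt), diag = TRUE)
  up <- upper.tri(diag(nt))
  gfun <- function(th) {
    qr_ <- .thetaToQR(th, nt)
    p <- suppressMessages(deriveParameters(qr_$Q, qr_$R))
    c(qr_$Q[low], qr_$R[low], p$heritability, p$geneticCorr[up],
      p$residualCorr[up], p$phenotypicCorr[up])
  }
  J <- pracma::jacobian(gfun, theta)
  seAll <- sqrt(pmax(diag(J %*% Vtheta %*% t(J)), 0))
  np <- .nPar(nt); nc <- nt * (nt - 1) / 2
  fill <- function(v, what) {
    m <- matrix(0, nt, nt, dimnames = list(traits, traits))
    if (what == "low") {
      m[lower.tri(m, diag = TRUE)] <- v
      m[upper.tri(m)] <- t(m)[upper.tri(m)]
    } else {
      m[upper.tri(m)] <- v
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
    }
    m
  }
  i <- 0
  seQ <- fill(seAll[i + 1:np], "low"); i <- i + np
  seR <- fill(seAll[i + 1:np], "low"); i <- i + np
  seH <- stats::setNames(seAll[i + 1:nt], traits); i <- i + nt
  seG <- fill(seAll[i + 1:nc], "up"); i <- i + nc
  seE <- fill(seAll[i + 1:nc], "up"); i <- i + nc
  seP <- fill(seAll[i + 1:nc], "up")
  list(Q = seQ, R = seR, heritability = seH, geneticCorr = seG,
       residualCorr = seE, phenotypicCorr = seP)
}

#' Predicted breeding values (direct genomic values)
#'
#' Multi-trait conditional mean given the training phenotypes:
#' `g_hat(target) = K[target, train] %*% Vinv (y_train - X mu_hat) %*% Q_hat`
#' computed with the eigendecomposition of the training kernel block.
#' Target phenotypes never enter the computation; a target with zero
#' kinship to every training individual gets predictions of exactly 0.
#'
#' @param fit an [MTModelFit-class] (carries the training spec).
#' @param kFull a [KinshipMatrix-class] spanning training and target ids.
#' @param targetIds ids to predict (must be in `kFull`).
#' @return an [DGVPrediction-class]: matrix of predictions (targets x
#'   traits) plus metadata.
#' @export
predictDGV <- function(fit, kFull, targetIds) {
  stopifnot(is(fit, "MTModelFit"), is(kFull, "KinshipMatrix"))
  trainIds <- rownames(fit@spec@phenotypes)
  allIds <- rownames(kFull@values)
  if (!all(trainIds %in% allIds))
    stop("kFull does not span all training individuals")
  if (!all(targetIds %in% allIds))
    stop("kFull does not span all target individuals: ",
         paste(utils::head(setdiff(targetIds, allIds), 5), collapse = ", "))
  Q <- fit@params@Q; R <- fit@params@R
  if (inherits(tryCatch(chol(R), error = function(e) e), "error")) {
    R <- R + diag(1e-8 * mean(diag(R)), nrow(R))
    message("residual covariance at boundary: jittered for prediction")
  }
  trainSpec <- mtModelSpec(fit@spec@phenotypes,
                           new("KinshipMatrix",
                               values = kFull@values[trainIds, trainIds],
                               kind = kFull@kind, meta = kFull@meta))
  setup <- .eigSetup(trainSpec)
  parts <- .remlLL(setup, Q, R, want = "predict")
  if (!is.finite(parts$ll))
    stop("singular covariance at the fitted parameters; cannot predict")
  Kct <- kFull@values[targetIds, trainIds, drop = FALSE]
  pred <- Kct %*% parts$Vinv_resid %*% Q
  dimnames(pred) <- list(targetIds, colnames(fit@spec@phenotypes))
  new("DGVPrediction", values = pred,
      meta = list(nTrain = length(trainIds), kind = kFull@kind,
                  lambda = kFull@meta$lambda))
}
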