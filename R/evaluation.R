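#' Cross-validation scheme constructor
#'
#' @param nReps number of repeated random partitions (default 20).
#' @param trainFrac training fraction (default 0.6; train size is
#'   `round(trainFrac * n)`).
#' @param lambdaGrid blending weights (default `c(0, .2, .4, .6, .8, 1)`).
#' @param gVariants genomic-matrix variants to evaluate: subset of
#'   `"GV_unscaled"`, `"GV_scaled"`, `"GF_unscaled"`, `"GF_scaled"`.
#' @param seed seed for the partitions.
#' @return a [CVScheme-class].
#' @export
cvScheme <- function(nReps = 20, trainFrac = 0.6,
                     lambdaGrid = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                     gVariants = "GV_unscaled", seed = 1L) {
  new("CVScheme", nReps = as.integer(nReps), trainFrac = trainFrac,
      lambdaGrid = lambdaGrid, gVariants = gVariants,
      seed = as.integer(seed))
}

#' Random train/test partitions
#'
#' Each replicate is an independent uniform random partition with
#' `round(trainFrac * n)` training individuals; partitions are shared
#' across all (variant, lambda) cells within a replicate, so grid
#' comparisons are paired. Deterministic given `scheme@seed`.
#'
#' @param ids character vector of individual ids (n >= 10).
#' @param scheme a [CVScheme-class].
#' @return list of `nReps` lists with elements `train` and `test`
#'   (disjoint, union = `ids`).
#' @export
makeSplits <- function(ids, scheme) {
  stopifnot(is(scheme, "CVScheme"))
  n <- length(ids)
  if (n < 10) stop("need at least 10 individuals to split")
  nTrain <- round(scheme@trainFrac * n)
  withr::with_seed(scheme@seed, {
    lapply(seq_len(scheme@nReps), function(r) {
      tr <- sort(sample.int(n, nTrain))
      list(train = ids[tr], test = ids[-tr])
    })
  })
}

#' Expected genetic regressions between traits
#'
#' REML-implied slope of the genetic value of trait x on trait y:
#' `b_xy = r_G(x,y) * sqrt(Q_xx) / sqrt(Q_yy) = Q_xy / Q_yy`, for every
#' ordered pair. A zero genetic variance gives `NA`.
#'
#' @param fit an [MTModelFit-class] (or [TraitCovariances-class]).
#' @return T x T matrix `b` with `b[x, y]` the expected regression of x
#'   on y; diagonal 1.
#' @export
expectedRegressions <- function(fit) {
  Q <- if (is(fit, "MTModelFit")) fit@params@Q else fit@Q
  v <- diag(Q)
  b <- sweep(Q, 2, v, "/")
  b[, v <= 0] <- NA_real_
  b
}

#' Realized regression of phenotype on cross-trait DGV
#'
#' Least-squares slope (with intercept) of a test-set phenotype on the
#' predicted breeding value of another trait.
#'
#' @param pheno numeric vector of phenotypes.
#' @param dgv numeric vector of predicted breeding values (same length,
#'   >= 3 points).
#' @return the OLS slope; `NA` when the DGV variance is zero.
#' @export
realizedRegression <- function(pheno, dgv) {
  stopifnot(length(pheno) == length(dgv), length(pheno) >= 3)
  if (stats::var(dgv) <= 0) return(NA_real_)
  unname(stats::coef(stats::lm(pheno ~ dgv))[2])
}

.gVariantMatrix <- function(variant, gv, gf) {
  base <- if (startsWith(variant, "GV")) gv else gf
  if (endsWith(variant, "_scaled")) minmaxScale(base) else base
}

#' Cross-validated predictive assessment over the lambda grid
#'
#' For every (G variant, lambda, replicate) cell: variance components
#' are re-estimated by REML on the training subset, breeding values are
#' predicted for the test set, and the cell yields the per-trait
#' predictive correlation `cor(test phenotype, DGV)` and mean squared
#' error, plus realized (OLS of test phenotype of x on DGV of y) and
#' expected (REML-implied) regressions for every ordered trait pair.
#' Cells whose fit fails are recorded with `NA` values and a note rather
#' than aborting the grid.
#'
#' @param phenotypes pre-corrected n x T phenotype matrix (rownames =
#'   ids), or a [SimDataset-class] (then its nuisance factors are removed
#'   by [preCorrect()] first).
#' @param ped the [Pedigree-class] (used for A; may contain ancestors
#'   without phenotypes).
#' @param genotypes a [GenotypeMatrix-class] covering the phenotyped ids
#'   (missing entries are mean-imputed).
#' @param scheme a [CVScheme-class].
#' @param nStarts REML starts per cell (default 1 for speed; the fits
#'   start from the phenotypic-covariance split).
#' @param verbose print cell progress.
#' @return a [CVReport-class].
#' @export
runCV <- function(phenotypes, ped = NULL, genotypes = NULL,
                  scheme = cvScheme(), nStarts = 1, verbose = FALSE) {
  if (is(phenotypes, "SimDataset")) {
    ds <- phenotypes
    ped <- ds@pedigree
    genotypes <- ds@genotypes
    df <- cbind(as.data.frame(ds@phenotypes), ds@nuisance)
    phenotypes <- preCorrect(df, colnames(ds@phenotypes),
                             names(ds@nuisance))
  }
  stopifnot(is(ped, "Pedigree"), is(genotypes, "GenotypeMatrix"),
            is(scheme, "CVScheme"))
  ids <- intersect(ped@id, rownames(phenotypes))  # pedigree order
  if (length(ids) < nrow(phenotypes))
    stop("phenotyped individuals missing from the pedigree: ",
         paste(utils::head(setdiff(rownames(phenotypes), ped@id), 5),
               collapse = ", "))
  Y <- phenotypes[ids, , drop = FALSE]
  A <- buildA(ped)
  Asub <- new("KinshipMatrix", values = A@values[ids, ids], kind = "A",
              meta = A@meta)
  g <- genotypes
  if (anyNA(g@codes)) g <- imputeNaive(g)
  g <- genotypeMatrix(g@codes[ids, , drop = FALSE])
  needGV <- any(startsWith(scheme@gVariants, "GV"))
  needGF <- any(startsWith(scheme@gVariants, "GF"))
  gv <- if (needGV) buildGVanRaden(g) else NULL
  gf <- if (needGF) buildGForni(g) else NULL
  splits <- makeSplits(ids, scheme)
  traits <- colnames(Y)
  pairs <- expand.grid(x = traits, y = traits, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$x != pairs$y, ]
  rows <- list()
  addRow <- function(variant, lambda, rep, unit, metric, value,
                     note = "") {
    rows[[length(rows) + 1]] <<- data.frame(
      variant = variant, lambda = lambda, rep = rep, unit = unit,
      metric = metric, value = value, note = note,
      stringsAsFactors = FALSE)
  }
  for (variant in scheme@gVariants) {
    G <- .gVariantMatrix(variant, gv, gf)
    for (lambda in scheme@lambdaGrid) {
      K <- blendKernels(G, Asub, lambda)
      for (r in seq_len(scheme@nReps)) {
        sp <- splits[[r]]
        res <- tryCatch({
          fit <- remlFit(mtModelSpec(Y[sp$train, , drop = FALSE], K),
                         nStarts = nStarts, computeSE = FALSE)
          pred <- dgvValues(predictDGV(fit, K, sp$test))
          eb <- expectedRegressions(fit)
          list(fit = fit, pred = pred, eb = eb)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          for (t in traits)
            addRow(variant, lambda, r, t, "predCorr", NA_real_,
                   conditionMessage(res))
          next
        }
        note <- if (res$fit@converged) "" else "not_converged"
        yTest <- Y[sp$test, , drop = FALSE]
        for (t in traits) {
          pc <- if (stats::sd(res$pred[, t]) > 0)
            stats::cor(yTest[, t], res$pred[, t]) else NA_real_
          addRow(variant, lambda, r, t, "predCorr", pc, note)
          addRow(variant, lambda, r, t, "mse",
                 mean((yTest[, t] - res$pred[, t])^2), note)
        }
        for (k in seq_len(nrow(pairs))) {
          x <- pairs$x[k]; y <- pairs$y[k]
          unit <- paste0(x, "~", y)
          addRow(variant, lambda, r, unit, "realized_b",
                 realizedRegression(yTest[, x], res$pred[, y]), note)
          addRow(variant, lambda, r, unit, "expected_b", res$eb[x, y],
                 note)
        }
        if (verbose)
          message(sprintf("%s lambda=%.1f rep %d done", variant, lambda,
                          r))
      }
    }
  }
  new("CVReport", results = do.call(rbind, rows), scheme = scheme)
}

#' Summaries of a cross-validation report
#'
#' Mean, SD and median of every metric across replicates, per (variant,
#' lambda, trait-or-pair) cell; failed replicates are counted, not
#' averaged.
#'
#' @param report a [CVReport-class].
#' @return long-format data.frame with columns variant, lambda, unit,
#'   metric, mean, sd, median, n, nFailed.
#' @export
summarizeReport <- function(report) {
  stopifnot(is(report, "CVReport"))
  r <- report@results
  key <- interaction(r$variant, r$lambda, r$unit, r$metric, drop = TRUE)
  out <- do.call(rbind, lapply(split(r, key), function(d) {
    v <- d$value[!is.na(d$value)]
    data.frame(variant = d$variant[1], lambda = d$lambda[1],
               unit = d$unit[1], metric = d$metric[1],
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               median = if (length(v)) stats::median(v) else NA_real_,
               n = length(v), nFailed = sum(is.na(d$value)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$variant, out$lambda, out$metric, out$unit), ]
}

#' Boxplots of cross-validated predictive ability
#'
#' One panel per trait, boxes across the lambda grid, colour by variant
#' (requires ggplot2).
#'
#' @param report a [CVReport-class].
#' @param metric `"predCorr"` (default) or `"mse"`.
#' @return a ggplot object.
#' @export
plotCV <- function(report, metric = c("predCorr", "mse")) {
  metric <- match.arg(metric)
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotCV requires the ggplot2 package")
  d <- report@results
  d <- d[d$metric == metric & !is.na(d$value), ]
  ggplot2::ggplot(d, ggplot2::aes(x = factor(lambda), y = value,
                                  fill = variant)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~unit, scales = "free_y") +
    ggplot2::labs(x = expression(lambda), y = metric) +
    ggplot2::theme_bw()
}
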