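#' Pre-correct phenotypes for categorical nuisance factors
#'
#' Residualizes each trait on an intercept plus dummy codes of the named
#' categorical factors by ordinary least squares, removing known
#' non-genetic sources of variation before the kernel model is fitted.
#' Output residuals are centered at zero per trait and orthogonal to
#' every factor dummy; the operation is idempotent. All factors are
#' treated as fixed effects.
#'
#' @param data data.frame holding trait columns and factor columns;
#'   rownames (or an `id` column) identify individuals.
#' @param traits character vector of trait column names.
#' @param factors character vector of factor column names to remove
#'   (may be empty: then traits are only mean-centered).
#' @return n x T matrix of corrected phenotypes (rownames = ids).
#' @export
preCorrect <- function(data, traits, factors = character(0)) {
  stopifnot(is.data.frame(data), all(traits %in% names(data)))
  if (!all(factors %in% names(data)))
    stop("factor column(s) not found: ",
         paste(setdiff(factors, names(data)), collapse = ", "))
  ids <- if ("id" %in% names(data)) as.character(data$id) else
    rownames(data)
  for (f in factors) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2)
      stop("nuisance factor '", f, "' has fewer than 2 levels")
    if (anyNA(data[[f]]))
      stop("missing values in nuisance factor '", f, "'")
  }
  Y <- as.matrix(data[, traits, drop = FALSE])
  if (anyNA(Y)) stop("missing phenotype values are not supported")
  if (!length(factors)) {
    out <- scale(Y, center = TRUE, scale = FALSE)
    attr(out, "scaled:center") <- NULL
    rownames(out) <- ids
    return(out)
  }
  form <- stats::as.formula(paste("~", paste(factors, collapse = " + ")))
  X <- stats::model.matrix(form, data = data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient nuisance design; confounded column(s): ",
         paste(dropped, collapse = ", "))
  }
  out <- qr.resid(qrX, Y)
  dimnames(out) <- list(ids, traits)
  out
}
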