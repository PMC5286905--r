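#' Construct a Pedigree from id/sire/dam vectors
#'
#' Records are topologically sorted so that parents precede offspring.
#' Parents that appear only in the sire/dam columns are auto-created as
#' founder records (with a message). Missing parents may be given as
#' `NA`, `""` or `"0"`.
#'
#' @param id,sire,dam character (or coercible) vectors of equal length.
#' @return a [Pedigree-class].
#' @examples
#' ped <- pedigree(c("s", "d", "o"), c(NA, NA, "s"), c(NA, NA, "d"))
#' @export
pedigree <- function(id, sire, dam) {
  id <- as.character(id); sire <- as.character(sire); dam <- as.character(dam)
  blank <- function(x) replace(x, !is.na(x) & (x == "0" | x == ""), NA)
  sire <- blank(sire); dam <- blank(dam)
  if (anyDuplicated(id))
    stop("duplicate individual id: ", id[anyDuplicated(id)])
  phantom <- setdiff(c(sire, dam), c(id, NA))
  if (length(phantom)) {
    message("auto-creating ", length(phantom),
            " founder record(s) for undeclared parents: ",
            paste(utils::head(phantom, 5), collapse = ", "),
            if (length(phantom) > 5) ", ..." else "")
    id <- c(phantom, id)
    sire <- c(rep(NA_character_, length(phantom)), sire)
    dam <- c(rep(NA_character_, length(phantom)), dam)
  }
  ord <- .topo_sort(id, sire, dam)
  new("Pedigree", id = id[ord], sire = sire[ord], dam = dam[ord])
}

# Kahn's algorithm; names the offending cycle on failure.
.topo_sort <- function(id, sire, dam) {
  n <- length(id)
  pos <- seq_len(n); names(pos) <- id
  si <- ifelse(is.na(sire), NA_integer_, pos[sire])
  di <- ifelse(is.na(dam), NA_integer_, pos[dam])
  if (any(si == pos, na.rm = TRUE) || any(di == pos, na.rm = TRUE)) {
    bad <- id[which(si == pos | di == pos)][1]
    stop("pedigree cycle detected: ", bad, " is its own parent")
  }
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  # stable Kahn: always emit the smallest ready input position, so an
  # already-sorted pedigree keeps its original order
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- min(queue); queue <- queue[queue != v]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    stop("pedigree cycle detected involving: ",
         paste(utils::head(id[setdiff(seq_len(n), out)], 10), collapse = ", "))
  }
  out
}

#' Read a pedigree from a CSV file
#'
#' Expects columns `id,sire,dam` (header required); `"0"` or empty fields
#' denote unknown parents. Output is topologically sorted; undeclared
#' parents become founder records.
#'
#' @param path path to the CSV file.
#' @return a [Pedigree-class].
#' @seealso [writePedigree()]
#' @export
readPedigree <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        strip.white = TRUE)
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df)))
    stop("pedigree file must have columns id,sire,dam; found: ",
         paste(names(df), collapse = ","))
  pedigree(df$id, df$sire, df$dam)
}

#' Write a pedigree to CSV
#'
#' Unknown parents are written as `"0"`.
#'
#' @param ped a [Pedigree-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePedigree <- function(ped, path) {
  df <- data.frame(id = ped@id,
                   sire = ifelse(is.na(ped@sire), "0", ped@sire),
                   dam = ifelse(is.na(ped@dam), "0", ped@dam))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Numerator relationship matrix A from a pedigree
#'
#' Tabular (recursive) method: for individual i with parents s, d,
#' `a_ii = 1 + a_sd / 2` and `a_ij = (a_js + a_jd) / 2` for every prior j;
#' a missing parent contributes 0. Unknown parents are treated as
#' unrelated, non-inbred founders.
#'
#' @param ped a [Pedigree-class] (parent-ordered; constructors guarantee
#'   this).
#' @return a [KinshipMatrix-class] of kind `"A"`.
#' @examples
#' ped <- pedigree(c("s","d","o1","o2"), c(NA,NA,"s","s"), c(NA,NA,"d","d"))
#' kinshipValues(buildA(ped))["o1", "o2"]  # full sibs: 0.5
#' @export
buildA <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  validObject(ped)
  n <- length(ped@id)
  pos <- seq_len(n); names(pos) <- ped@id
  si <- ifelse(is.na(ped@sire), 0L, pos[ped@sire])
  di <- ifelse(is.na(ped@dam), 0L, pos[ped@dam])
  A <- matrix(0, n, n, dimnames = list(ped@id, ped@id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    asd <- if (s > 0L && d > 0L) A[s, d] else 0
    A[i, i] <- 1 + asd / 2
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aj <- (if (s > 0L) A[j, s] else 0) + (if (d > 0L) A[j, d] else 0)
      A[j, i] <- aj / 2
      A[i, j] <- aj / 2
    }
  }
  new("KinshipMatrix", values = A, kind = "A",
      meta = list(source = "pedigree tabular method"))
}

#' Pedigree inbreeding coefficients
#'
#' `F_i = diag(A)_i - 1`; founders (and any individual with an unknown
#' parent) have F = 0.
#'
#' @param ped a [Pedigree-class].
#' @return named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(ped) {
  diag(kinshipValues(buildA(ped))) - 1
}
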