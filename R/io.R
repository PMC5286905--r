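utils::globalVariables(c("lambda", "value", "variant"))

#' Read an additive-coded genotype matrix
#'
#' Tab-delimited, PLINK-raw style: header line `id<TAB>snp1<TAB>...`,
#' then one row per individual with codes in `{0, 1, 2}` or `NA`.
#' Any other token is a parse error reported with its line number.
#'
#' @param path path to the file.
#' @return a [GenotypeMatrix-class].
#' @seealso [writeGenotypes()], [readGenotypesVCF()]
#' @export
readGenotypes <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("genotype file has no data rows: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  snps <- header[-1]
  n <- length(lines) - 1
  codes <- matrix(NA_real_, n, length(snps))
  ids <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(header))
      stop(sprintf("line %d: expected %d fields, found %d", i + 1,
                   length(header), length(f)))
    ids[i] <- f[1]
    v <- f[-1]
    bad <- !v %in% c("0", "1", "2", "NA")
    if (any(bad))
      stop(sprintf("line %d: invalid genotype token '%s' (want 0/1/2/NA)",
                   i + 1, v[which(bad)[1]]))
    codes[i, ] <- suppressWarnings(as.numeric(v))
  }
  dimnames(codes) <- list(ids, snps)
  genotypeMatrix(codes)
}

#' Write genotypes in the additive tab-delimited layout
#'
#' Fractional (imputed) dosages are written with full precision; exact
#' integers are written as integers so files round-trip.
#'
#' @param g a [GenotypeMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(g, path) {
  codes <- g@codes
  fmt <- function(x) {
    out <- ifelse(is.na(x), "NA", format(x, digits = 17, trim = TRUE,
                                         scientific = FALSE))
    ifelse(!is.na(x) & x == round(x), as.character(as.integer(round(x))),
           out)
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c("id", colnames(codes)), collapse = "\t"), con)
  for (i in seq_len(nrow(codes)))
    writeLines(paste(c(rownames(codes)[i], fmt(codes[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' GT fields are converted to alt-allele dosage (0/1/2; missing calls
#' become `NA`). Only biallelic variants are supported.
#'
#' @param path path to an (uncompressed or gzipped) VCF.
#' @return a [GenotypeMatrix-class] (individuals x variants; variant ids
#'   from the ID column, falling back to CHROM:POS).
#' @export
readGenotypesVCF <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
    vapply(a, function(al) {
      if (any(is.na(al)) || any(al == ".")) return(NA_real_)
      sum(al != "0")
    }, numeric(1))
  }
  codes <- t(apply(gt, 1, dose))
  colnames(codes) <- colnames(gt)
  ids <- vcfR::getID(v)
  fallback <- paste0(vcfR::getCHROM(v), ":", vcfR::getPOS(v))
  rownames(codes) <- ifelse(is.na(ids) | ids == ".", fallback, ids)
  genotypeMatrix(t(codes))
}

#' Write a kinship matrix as labelled TSV
#'
#' First line is a comment header `# kind=<kind>` (plus any scalar meta),
#' then a square tab-delimited matrix with row and column labels.
#'
#' @param k a [KinshipMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [readKinship()]
#' @export
writeKinship <- function(k, path) {
  con <- file(path, "w"); on.exit(close(con))
  scal <- k@meta[vapply(k@meta, function(x)
    is.atomic(x) && length(x) == 1, logical(1))]
  hdr <- paste0("# kind=", k@kind,
                if (length(scal))
                  paste0(" ", paste(names(scal), unlist(scal), sep = "=",
                                    collapse = " ")) else "")
  writeLines(hdr, con)
  writeLines(paste(c("id", colnames(k@values)), collapse = "\t"), con)
  for (i in seq_len(nrow(k@values)))
    writeLines(paste(c(rownames(k@values)[i],
                       format(k@values[i, ], digits = 17, trim = TRUE,
                              scientific = TRUE)), collapse = "\t"), con)
  invisible(path)
}

#' Read a kinship matrix written by [writeKinship()]
#'
#' @param path path to the labelled TSV.
#' @return a [KinshipMatrix-class]; values round-trip to full precision.
#' @export
readKinship <- function(path) {
  first <- readLines(path, n = 1)
  kind <- "K_blend"; meta <- list()
  skip <- 0
  if (startsWith(first, "#")) {
    skip <- 1
    toks <- strsplit(sub("^#\\s*", "", first), "\\s+")[[1]]
    kv <- strsplit(toks, "=", fixed = TRUE)
    for (p in kv) {
      if (length(p) == 2) {
        val <- suppressWarnings(as.numeric(p[2]))
        meta[[p[1]]] <- if (is.na(val)) p[2] else val
      }
    }
    if (!is.null(meta$kind)) { kind <- meta$kind; meta$kind <- NULL }
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = skip,
                          check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  colnames(m) <- colnames(df)
  m <- (m + t(m)) / 2
  new("KinshipMatrix", values = m, kind = kind, meta = meta)
}

#' Read / write phenotype tables
#'
#' Tab-delimited with an `id` column, trait columns, and optional
#' nuisance factor columns.
#'
#' @param path file path.
#' @return `readPhenotypes`: a data.frame with rownames set to `id`.
#' @export
readPhenotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("phenotype file must have an 'id' column")
  rownames(df) <- as.character(df$id)
  df
}

#' @rdname readPhenotypes
#' @param data data.frame (an `id` column is added from rownames when
#'   absent).
#' @return `writePhenotypes`: `path`, invisibly.
#' @export
writePhenotypes <- function(data, path) {
  if (!"id" %in% names(data))
    data <- cbind(id = rownames(data), data)
  utils::write.table(data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a simulation configuration from a key-value file
#'
#' Plain text, one `key: value` pair per line; `#` comments allowed.
#' Vectors are comma-separated; matrices (Qtrue, Rtrue, qtlEffectCorr)
#' use `;` between rows, e.g. `Qtrue: 1,0.5; 0.5,1`. Keys are the
#' [simConfig()] argument names.
#'
#' @param path path to the config file.
#' @return a [SimConfig-class].
#' @export
readSimConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  args <- list()
  matKeys <- c("Qtrue", "Rtrue", "qtlEffectCorr")
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$",
                                 ln))[[1]]
    if (length(kv) != 3) stop("malformed config line: ", ln)
    key <- kv[2]; val <- kv[3]
    if (key %in% matKeys) {
      rows <- strsplit(val, ";", fixed = TRUE)[[1]]
      m <- do.call(rbind, lapply(rows, function(r)
        as.numeric(strsplit(r, ",", fixed = TRUE)[[1]])))
      args[[key]] <- m
    } else if (key == "architecture") {
      args[[key]] <- val
    } else if (key == "nuisanceLevels") {
      parts <- strsplit(val, ",", fixed = TRUE)[[1]]
      kvs <- strsplit(trimws(parts), "=", fixed = TRUE)
      nl <- vapply(kvs, function(p) as.integer(p[length(p)]), integer(1))
      names(nl) <- vapply(kvs, function(p)
        if (length(p) == 2) trimws(p[1]) else "", character(1))
      args[[key]] <- nl
    } else {
      args[[key]] <- as.numeric(strsplit(val, ",", fixed = TRUE)[[1]])
    }
  }
  do.call(simConfig, args)
}

#' Write the truth tables of a simulated dataset
#'
#' Writes pedigree CSV, genotype TSV, phenotype TSV (with nuisance
#' columns) and a truth TSV (true breeding values) into a directory.
#'
#' @param ds a [SimDataset-class].
#' @param dir output directory (created if needed).
#' @return named character vector of the file paths, invisibly.
#' @export
writeSimDataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(pedigree = file.path(dir, "pedigree.csv"),
             genotypes = file.path(dir, "genotypes.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             truth = file.path(dir, "true_breeding_values.tsv"))
  writePedigree(ds@pedigree, paths["pedigree"])
  writeGenotypes(ds@genotypes, paths["genotypes"])
  writePhenotypes(cbind(as.data.frame(ds@phenotypes), ds@nuisance),
                  paths["phenotypes"])
  writePhenotypes(as.data.frame(ds@trueBreedingValues), paths["truth"])
  invisible(paths)
}
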