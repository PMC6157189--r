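#' Read genotypes from PLINK binary or VCF
#'
#' Reads biallelic diploid genotypes into a [GenotypeMatrix-class], coded as
#' minor-allele dosages. Sample order follows the fam file / VCF header;
#' each SNP is re-oriented so the stored dosage counts the minor allele.
#'
#' For PLINK, `path` is the fileset prefix (or any of the three file names);
#' the bed file must be SNP-major v1.00. For VCF, genotypes are taken from
#' the GT field and must be diploid; half-missing calls (e.g. `./0`) are a
#' format error. Multiallelic records are rejected by default.
#'
#' @param path file path (PLINK prefix or VCF file, optionally gzipped).
#' @param format `"plink-bed"` or `"vcf"`; guessed from the extension when
#'   missing.
#' @param multiallelic `"error"` (default) or `"drop"`.
#' @return a [GenotypeMatrix-class]; missing calls are `NA` until
#'   [imputeMissing()] is applied.
#' @export
readGenotypes <- function(path, format = c("plink-bed", "vcf"),
                          multiallelic = c("error", "drop")) {
  if (missing(format))
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "plink-bed"
  format <- match.arg(format)
  multiallelic <- match.arg(multiallelic)
  switch(format,
         "plink-bed" = .readPlink(path),
         "vcf" = .readVcf(path, multiallelic))
}

# ---- PLINK binary codec --------------------------------------------------
# bed v1.00, SNP-major: magic 6c 1b 01, then ceiling(n/4) bytes per SNP,
# 2 bits per sample, LSB first: 00 hom A1, 01 missing, 10 het, 11 hom A2.
# Dosage counts A1 (PLINK's A1 is conventionally the minor allele).

.bedLookup <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      m <- matrix(NA_real_, 256, 4)
      code <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
      for (b in 0:255)
        for (s in 0:3)
          m[b + 1, s + 1] <- code[[bitwAnd(bitwShiftR(b, 2L * s), 3L) + 1]]
      tab <<- m
    }
    tab
  }
})

.plinkPrefix <- function(path)
  sub("\\.(bed|bim|fam)$", "", path)

.readPlink <- function(path) {
  prefix <- .plinkPrefix(path)
  files <- paste0(prefix, c(".bed", ".bim", ".fam"))
  miss <- files[!file.exists(files)]
  if (length(miss))
    stop("PLINK fileset incomplete, missing: ", paste(miss, collapse = ", "))
  fam <- read.table(files[3], header = FALSE, stringsAsFactors = FALSE)
  bim <- read.table(files[2], header = FALSE, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  n <- nrow(fam); p <- nrow(bim)
  bytesPerSnp <- ceiling(n / 4)
  raw <- readBin(files[1], "raw", n = 3 + bytesPerSnp * p)
  if (length(raw) < 3 + bytesPerSnp * p)
    stop("bed file truncated: ", files[1])
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK bed v1.00 file: ", files[1])
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bytesPerSnp, ncol = p)
  lk <- .bedLookup()
  dos <- matrix(NA_real_, n, p)
  for (s in 0:3) {
    rows <- seq(s + 1, n, by = 4)
    if (!length(rows)) next
    bytes <- body[seq_along(rows), , drop = FALSE]
    dos[rows, ] <- lk[bytes + 1, s + 1]
  }
  rownames(dos) <- make.unique(as.character(fam[[2]]))
  si <- data.frame(id = bim[[2]], chrom = bim[[1]], pos = bim[[4]],
                   ref = bim[[6]], alt = bim[[5]], stringsAsFactors = FALSE)
  .orientMinor(dos, si)
}

# flip columns whose counted allele is the major one
.orientMinor <- function(dos, si) {
  freq <- colMeans(dos, na.rm = TRUE) / 2
  flip <- which(!is.nan(freq) & freq > 0.5)
  if (length(flip)) {
    dos[, flip] <- 2 - dos[, flip]
    tmp <- si$ref[flip]
    si$ref[flip] <- si$alt[flip]
    si$alt[flip] <- tmp
  }
  GenotypeMatrix(dos, si)
}

#' Write a GenotypeMatrix as a PLINK binary fileset
#'
#' Dosages are written as counts of A1 = the stored (minor) allele. Missing
#' calls are preserved. Intended for fixtures and provenance output.
#'
#' @param g a [GenotypeMatrix-class].
#' @param prefix output path prefix (writes `prefix.bed/.bim/.fam`).
#' @param family optional family id per sample (defaults to the sample id).
#' @return invisibly, the prefix.
#' @export
writePlink <- function(g, prefix, family = NULL) {
  dos <- dosages(g); si <- snpInfo(g)
  n <- nrow(dos); p <- ncol(dos)
  fam <- data.frame(fid = if (is.null(family)) rownames(dos) else family,
                    iid = rownames(dos), pat = 0, mat = 0, sex = 0, phe = -9)
  write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chrom = si$chrom, id = si$id, cm = 0, pos = si$pos,
                    a1 = si$alt, a2 = si$ref)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  # dosage -> 2-bit code: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  codeOf <- function(x) {
    out <- integer(length(x))
    out[is.na(x)] <- 1L
    out[!is.na(x) & x == 1] <- 2L
    out[!is.na(x) & x == 0] <- 3L
    out
  }
  bytesPerSnp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4L * bytesPerSnp - n
  for (j in seq_len(p)) {
    codes <- c(codeOf(dos[, j]), rep(0L, pad))
    dim(codes) <- c(4L, bytesPerSnp)
    byte <- codes[1, ] + bitwShiftL(codes[2, ], 2L) +
      bitwShiftL(codes[3, ], 4L) + bitwShiftL(codes[4, ], 6L)
    writeBin(as.raw(byte), con)
  }
  invisible(prefix)
}

# ---- VCF -----------------------------------------------------------------

.readVcf <- function(path, multiallelic) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    if (multiallelic == "error")
      stop("multiallelic record(s) at ",
           paste(head(paste0(fix[multi, "CHROM"], ":", fix[multi, "POS"]), 3),
                 collapse = ", "),
           "; rerun with multiallelic = \"drop\" to skip them")
    keep <- !multi
    v <- v[keep, ]
    fix <- fix[keep, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)
  p <- nrow(gt); n <- length(samples)
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  dos <- matrix(NA_real_, n, p)
  for (j in seq_len(p)) {
    al <- strsplit(gt[j, ], "[/|]")
    for (i in seq_len(n)) {
      a <- al[[i]]
      if (length(a) == 1 && (is.na(a) || a == "."))
        next                                   # fully missing call
      if (length(a) != 2)
        stop("non-diploid genotype '", gt[j, i], "' at record ", ids[j],
             ", sample ", samples[i])
      if (any(a == ".")) {
        if (all(a == ".")) next
        stop("half-missing genotype '", gt[j, i], "' at record ", ids[j],
             ", sample ", samples[i])
      }
      ai <- suppressWarnings(as.integer(a))
      if (anyNA(ai) || any(ai > 1))
        stop("unsupported allele code '", gt[j, i], "' at record ", ids[j],
             ", sample ", samples[i])
      dos[i, j] <- sum(ai)
    }
  }
  rownames(dos) <- samples
  si <- data.frame(id = ids, chrom = fix[, "CHROM"],
                   pos = as.integer(fix[, "POS"]), ref = fix[, "REF"],
                   alt = fix[, "ALT"], stringsAsFactors = FALSE)
  .orientMinor(dos, si)
}

#' Write a GenotypeMatrix as a minimal VCF 4.2 file
#'
#' Provenance output for filtered SNP sets. Genotypes are written unphased
#' with the alternate allele being the stored minor allele.
#'
#' @param g a [GenotypeMatrix-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeVcfFile <- function(g, path) {
  dos <- dosages(g); si <- snpInfo(g)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(dos)), collapse = "\t")),
             con)
  gtOf <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(dos))) {
    calls <- ifelse(is.na(dos[, j]), "./.", gtOf[dos[, j] + 1])
    writeLines(paste(c(si$chrom[j], si$pos[j], si$id[j], si$ref[j], si$alt[j],
                       ".", "PASS", ".", "GT", calls), collapse = "\t"), con)
  }
  invisible(path)
}

#' Filter variants on MAF and missingness
#'
#' Retains SNPs with minor allele frequency strictly greater than `mafMin`
#' and missingness strictly below `missMax` (defaults: common variants,
#' MAF > 0.05, missing < 1%). SNP order is preserved. An empty result is
#' returned (not an error) with a classed warning so scan drivers can skip
#' cleanly.
#'
#' @param g a [GenotypeMatrix-class].
#' @param mafMin MAF threshold in `[0, 0.5)`; survivors have maf > mafMin.
#' @param missMax missingness threshold; survivors have missRate < missMax.
#' @return the filtered [GenotypeMatrix-class].
#' @export
filterVariants <- function(g, mafMin = 0.05, missMax = 0.01) {
  stopifnot(is(g, "GenotypeMatrix"), mafMin >= 0, mafMin < 0.5,
            missMax >= 0, missMax <= 1)
  si <- snpInfo(g)
  keep <- !is.na(si$maf) & si$maf > mafMin & si$missRate < missMax
  out <- GenotypeMatrix(dosages(g)[, keep, drop = FALSE],
                        as.data.frame(si[keep, , drop = FALSE]))
  if (!any(keep))
    warning(structure(class = c("pedaSPU_empty_filter", "warning",
                                "condition"),
                      list(message = "no SNPs survive the variant filters",
                           call = sys.call())))
  out
}

#' Impute sporadic missing genotypes from the MAF
#'
#' Each missing call is replaced by an independent draw from
#' Binomial(2, maf) of its SNP — the Hardy-Weinberg-consistent,
#' mean-preserving fill-in. Observed genotypes are untouched; the result is
#' deterministic given `seed`.
#'
#' @param g a [GenotypeMatrix-class] (apply [filterVariants()] first so
#'   only lightly missing SNPs remain).
#' @param seed RNG seed.
#' @return a complete [GenotypeMatrix-class] (no `NA` entries).
#' @export
imputeMissing <- function(g, seed = 1L) {
  stopifnot(is(g, "GenotypeMatrix"))
  dos <- dosages(g); si <- snpInfo(g)
  allMiss <- which(colMeans(is.na(dos)) == 1)
  if (length(allMiss))
    stop("SNP(s) with all genotypes missing (MAF undefined): ",
         paste(head(si$id[allMiss], 3), collapse = ", "))
  withSeed(seed, {
    for (j in which(colSums(is.na(dos)) > 0)) {
      miss <- which(is.na(dos[, j]))
      dos[miss, j] <- rbinom(length(miss), 2L, si$maf[j])
    }
  })
  GenotypeMatrix(dos, as.data.frame(si[, c("id", "chrom", "pos", "ref",
                                           "alt")]))
}

#' Read a trait/covariate table
#'
#' Reads a delimited sample table, selects the trait and covariate columns,
#' drops samples with any missing value among them, and returns an aligned
#' trait vector and design matrix (with intercept).
#'
#' @param path delimited text file with a header row.
#' @param traitCol name of the quantitative trait column.
#' @param covarCols character vector of covariate column names (may be
#'   empty for an intercept-only model).
#' @param idCol name of the sample id column.
#' @param sep field separator.
#' @return list with `y` (named trait vector), `X` (design matrix with
#'   intercept), and `dropped` (ids excluded for missingness).
#' @export
readTraitTable <- function(path, traitCol, covarCols = character(0),
                           idCol = "sample", sep = "\t") {
  tab <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  need <- c(idCol, traitCol, covarCols)
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("trait table lacks column(s): ", paste(miss, collapse = ", "))
  keep <- complete.cases(tab[, c(traitCol, covarCols), drop = FALSE])
  dropped <- as.character(tab[[idCol]][!keep])
  tab <- tab[keep, , drop = FALSE]
  ids <- as.character(tab[[idCol]])
  if (anyDuplicated(ids)) stop("duplicated sample ids in trait table")
  X <- cbind(`(Intercept)` = 1,
             as.matrix(tab[, covarCols, drop = FALSE]))
  storage.mode(X) <- "double"
  rownames(X) <- ids
  list(y = setNames(as.numeric(tab[[traitCol]]), ids), X = X,
       dropped = dropped)
}
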