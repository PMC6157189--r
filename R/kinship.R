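#' Estimate the genetic relationship matrix from genotypes
#'
#' The default estimator is the Pearson correlation coefficient between two
#' subjects' dosage profiles over a random subset of SNPs (default 20,000,
#' truncated to the available SNP count), with each SNP centered at its
#' sample mean dosage first. Centering is essential: without it the spread
#' of allele frequencies across SNPs is a mean component shared by every
#' pair of subjects and inflates the correlation of even unrelated pairs
#' well away from 0. After centering, full sibs and parent-offspring pairs
#' sit near 0.5 and unrelated pairs near 0. The diagonal is set to 1
#' (self-correlation) and the result is passed through [makePSD()] so the
#' downstream mixed-model covariance tau * Psi + phi * I is always
#' invertible.
#'
#' @param g a complete [GenotypeMatrix-class] (impute first).
#' @param nSnps number of SNP columns to sample uniformly without
#'   replacement; truncated to `ncol(dosages(g))` with a warning.
#' @param seed RNG seed governing the SNP subsample.
#' @param method `"correlation"` (subject-by-subject Pearson correlation of
#'   mean-centered dosage profiles, the default) or `"grm"` (fully
#'   standardized genotypes, VanRaden-style cross-product divided by the
#'   SNP count).
#' @return a [KinshipMatrix-class].
#' @export
estimateKinship <- function(g, nSnps = 20000L, seed = 1L,
                            method = c("correlation", "grm")) {
  stopifnot(is(g, "GenotypeMatrix"))
  method <- match.arg(method)
  dos <- dosages(g)
  if (anyNA(dos)) stop("genotypes contain missing calls; imputeMissing() first")
  p <- ncol(dos)
  if (nSnps > p) {
    warning("nSnps = ", nSnps, " exceeds available SNPs (", p,
            "); using all ", p)
    nSnps <- p
  }
  idx <- withSeed(seed, sort(sample.int(p, nSnps)))
  x <- dos[, idx, drop = FALSE]
  xc <- scale(x, center = TRUE, scale = FALSE)  # center each SNP column
  sds <- apply(x, 1, sd)                        # raw profile variance
  flat <- which(sds == 0)
  if (length(flat))
    stop("monomorphic genotype profile (zero dosage variance) for subject(s): ",
         paste(head(rownames(dos)[flat], 3), collapse = ", "))
  psi <- if (method == "correlation") {
    cor(t(xc))
  } else {
    zs <- scale(x)                      # standardize each SNP across subjects
    tcrossprod(zs) / ncol(zs)
  }
  diag(psi) <- 1
  psi <- makePSD(psi)
  diag(psi) <- 1
  KinshipMatrix(psi, rownames(dos))
}

#' Clip a symmetric matrix to positive semi-definiteness
#'
#' Eigendecomposes `m`, raises eigenvalues below `floor` to `floor`, and
#' reconstructs. Already-PSD input is returned unchanged.
#'
#' @param m symmetric numeric matrix.
#' @param floor eigenvalue floor (nonnegative).
#' @return symmetric matrix with smallest eigenvalue >= `floor` (up to
#'   round-off).
#' @export
makePSD <- function(m, floor = 1e-8) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), floor >= 0)
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
    stop("matrix is not symmetric")
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= floor) return(m)
  v <- pmax(e$values, floor)
  out <- e$vectors %*% (v * t(e$vectors))
  (out + t(out)) / 2
}

#' Read a kinship matrix from a tab-delimited file
#'
#' Expects a square matrix with sample ids as both the header row and the
#' first column (GEMMA-style interchange format, as written by
#' [writeKinship()]). The matrix is validated for symmetry and unit
#' diagonal.
#'
#' @param path file path.
#' @return a [KinshipMatrix-class].
#' @export
loadKinship <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                    check.names = FALSE)
  m <- as.matrix(tab)
  if (nrow(m) != ncol(m))
    stop("kinship file is not square: ", nrow(m), " x ", ncol(m))
  if (!all(rownames(m) == colnames(m)))
    stop("kinship row and column sample ids disagree")
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
    stop("kinship matrix in ", path, " is asymmetric")
  KinshipMatrix((m + t(m)) / 2, rownames(m))
}

#' @rdname loadKinship
#' @param k a [KinshipMatrix-class].
#' @export
writeKinship <- function(k, path) {
  stopifnot(is(k, "KinshipMatrix"))
  m <- kinshipMatrix(k)
  tab <- data.frame(sample = rownames(m), m, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
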