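#' Construct a GenotypeMatrix
#'
#' Wraps a dosage matrix and its SNP metadata, recomputing `maf` and
#' `missRate` from the dosages so the stored metadata always agrees with the
#' matrix. Rows are samples, columns SNPs.
#'
#' @param dosages numeric matrix of minor-allele dosages with sample ids as
#'   rownames; entries 0/1/2/NA.
#' @param snpInfo data.frame or DataFrame with columns `id`, `chrom`, `pos`,
#'   `ref`, `alt` (maf/missRate are recomputed).
#' @return A [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(dosages, snpInfo) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  si <- S4Vectors::DataFrame(snpInfo)
  si$maf <- unname(.colMaf(dosages))
  si$missRate <- unname(colMeans(is.na(dosages)))
  if (!is.null(si$id)) colnames(dosages) <- si$id
  new("GenotypeMatrix", dosages = dosages, snpInfo = si)
}

# minor-allele frequency per column from non-missing calls
.colMaf <- function(d) {
  f <- colMeans(d, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA_real_
  pmin(f, 1 - f)
}

#' Construct a KinshipMatrix
#'
#' @param psi symmetric numeric matrix with unit diagonal.
#' @param samples sample ids; defaults to `rownames(psi)`.
#' @return A [KinshipMatrix-class] object.
#' @export
KinshipMatrix <- function(psi, samples = rownames(psi)) {
  psi <- as.matrix(psi)
  if (is.null(samples))
    stop("kinship matrix needs sample ids (rownames or `samples`)")
  samples <- as.character(samples)
  dimnames(psi) <- list(samples, samples)
  new("KinshipMatrix", samples = samples, psi = psi)
}

#' @describeIn GenotypeMatrix-class dosage matrix (samples x SNPs)
#' @param x,object a GenotypeMatrix
#' @export
dosages <- function(x) x@dosages

#' @describeIn GenotypeMatrix-class per-SNP metadata DataFrame
#' @export
snpInfo <- function(x) x@snpInfo

#' Sample identifiers of a pedaSPU object
#' @param x a GenotypeMatrix, KinshipMatrix or NullModelFit
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname sampleIds
setMethod("sampleIds", "GenotypeMatrix", function(x) rownames(x@dosages))
#' @rdname sampleIds
setMethod("sampleIds", "KinshipMatrix", function(x) x@samples)
#' @rdname sampleIds
setMethod("sampleIds", "NullModelFit", function(x) x@samples)

#' @describeIn KinshipMatrix-class the relationship matrix itself
#' @param x,object a KinshipMatrix
#' @export
kinshipMatrix <- function(x) x@psi

#' @describeIn ScoreSet-class score vector U
#' @param x,object a ScoreSet
#' @export
scoreVector <- function(x) setNames(x@U, x@snpIds)

#' @describeIn ScoreSet-class null covariance V of U
#' @export
scoreCovariance <- function(x) x@V

#' @describeIn NullModelFit-class variance components c(tau, phi)
#' @param x,object a NullModelFit
#' @export
varianceComponents <- function(x) c(tau = x@tauHat, phi = x@phiHat)

#' @describeIn NullModelFit-class fixed-effect estimates
#' @export
fixedEffects <- function(x) x@alphaHat

#' @describeIn GeneTestResult-class all p-values as a named vector
#' @param x,object a GeneTestResult
#' @export
pValues <- function(x)
  c(setNames(x@spuPvalues, paste0("SPU", names(x@spuPvalues))),
    aSPU = x@aspuPvalue, score = x@scorePvalue)

setMethod("show", "GenotypeMatrix", function(object) {
  d <- object@dosages
  cat(sprintf("GenotypeMatrix: %d samples x %d SNPs\n", nrow(d), ncol(d)))
  if (ncol(d)) {
    si <- object@snpInfo
    cat(sprintf("  chrom: %s\n",
                paste(unique(si$chrom)[seq_len(min(5, length(unique(si$chrom))))],
                      collapse = ", ")))
    cat(sprintf("  MAF range: [%.3f, %.3f]; missing calls: %.3g%%\n",
                min(si$maf, na.rm = TRUE), max(si$maf, na.rm = TRUE),
                100 * mean(is.na(d))))
  }
})

setMethod("show", "KinshipMatrix", function(object) {
  cat(sprintf("KinshipMatrix: %d samples\n", length(object@samples)))
  off <- object@psi[upper.tri(object@psi)]
  if (length(off))
    cat(sprintf("  off-diagonal range: [%.3f, %.3f]\n", min(off), max(off)))
})

setMethod("show", "NullModelFit", function(object) {
  cat(sprintf("NullModelFit (%s): n = %d\n", toupper(object@method),
              length(object@samples)))
  cat(sprintf("  tau = %.4g%s, phi = %.4g, loglik = %.4f\n", object@tauHat,
              if (object@boundary) " (boundary)" else "", object@phiHat,
              object@loglik))
  cat(sprintf("  fixed effects: %s\n",
              paste(sprintf("%s=%.3g", names(object@alphaHat),
                            object@alphaHat), collapse = ", ")))
  if (object@degenerate) cat("  NOTE: degenerate fit (residuals ~ 0)\n")
  if (!object@converged) cat("  WARNING: did not converge\n")
})

setMethod("show", "ScoreSet", function(object) {
  cat(sprintf("ScoreSet: %d SNPs, n = %d samples\n", length(object@snpIds),
              object@nSamples))
  if (length(object@U))
    cat(sprintf("  max |U_j|/sqrt(V_jj) = %.3f\n",
                max(abs(object@U) / sqrt(pmax(diag(object@V), 1e-300)))))
})

setMethod("show", "GeneTestResult", function(object) {
  cat(sprintf("GeneTestResult '%s': %d SNPs, B = %d\n", object@geneId,
              object@nSnps, object@B))
  pv <- pValues(object)
  cat("  ", paste(sprintf("%s=%.3g", names(pv), pv), collapse = " "), "\n")
})
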