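#' @import methods
#' @importFrom stats rnorm rbinom runif pnorm pchisq cor sd var optimize
#'   setNames complete.cases integrate
#' @importFrom utils read.table write.table head
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom S4Vectors DataFrame
NULL

.sym_tol <- 1e-8

#' Genotype dosage matrix with per-SNP metadata
#'
#' Holds an n x p matrix of minor-allele dosages (0, 1, 2 or `NA` for a
#' missing call) for n samples and p biallelic SNPs, together with per-SNP
#' metadata: identifier, chromosome, 1-based position, reference and
#' alternate alleles, minor allele frequency (computed from the non-missing
#' calls) and missingness rate. Dosages always count copies of the minor
#' allele; sites where the alternate allele is the major one are re-oriented
#' on construction by the readers.
#'
#' @slot dosages numeric matrix, samples in rows (rownames are sample ids),
#'   SNPs in columns (colnames are SNP ids); entries in \{0, 1, 2, NA\}.
#' @slot snpInfo [S4Vectors::DataFrame-class] with columns `id`, `chrom`,
#'   `pos`, `ref`, `alt`, `maf`, `missRate`, one row per dosage column.
#'
#' @seealso [GenotypeMatrix()], [readGenotypes()], [filterVariants()],
#'   [imputeMissing()]
#' @export
setClass("GenotypeMatrix",
  representation(dosages = "matrix", snpInfo = "DataFrame"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosages
  si <- object@snpInfo
  msg <- character(0)
  if (is.null(rownames(d)) && nrow(d) > 0)
    msg <- c(msg, "dosage matrix must carry sample ids as rownames")
  if (ncol(d) != nrow(si))
    msg <- c(msg, "snpInfo must have one row per dosage column")
  need <- c("id", "chrom", "pos", "ref", "alt", "maf", "missRate")
  if (!all(need %in% colnames(si)))
    msg <- c(msg, paste("snpInfo lacks columns:",
                        paste(setdiff(need, colnames(si)), collapse = ", ")))
  else {
    if (nrow(si) > 0 && any(si$pos < 1))
      msg <- c(msg, "SNP positions must be >= 1 (1-based)")
    if (nrow(si) > 0 && any(si$maf < 0 | si$maf > 0.5 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "maf must lie in [0, 0.5] after minor-allele orientation")
  }
  ok <- d[!is.na(d)]
  if (length(ok) && !all(ok %in% c(0, 1, 2)))
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  if (length(msg)) msg else TRUE
})

#' Genetic relationship (kinship) matrix
#'
#' Symmetric n x n matrix Psi on the correlation scale: unit diagonal,
#' full sibs / parent-offspring around 0.5, unrelated pairs around 0.
#' Used as the covariance structure of the random intercept in the
#' linear mixed model, Var(b) = tau * Psi.
#'
#' @slot samples character vector of sample ids (row/column order).
#' @slot psi numeric symmetric matrix with unit diagonal.
#'
#' @seealso [KinshipMatrix()], [estimateKinship()], [loadKinship()]
#' @export
setClass("KinshipMatrix",
  representation(samples = "character", psi = "matrix"))

setValidity("KinshipMatrix", function(object) {
  p <- object@psi
  msg <- character(0)
  if (nrow(p) != ncol(p)) msg <- c(msg, "psi must be square")
  if (length(object@samples) != nrow(p))
    msg <- c(msg, "sample ids must match psi dimension")
  if (anyDuplicated(object@samples))
    msg <- c(msg, "duplicated sample ids")
  if (nrow(p) > 0) {
    if (max(abs(p - t(p))) > .sym_tol * max(1, max(abs(p))))
      msg <- c(msg, "psi must be symmetric")
    if (max(abs(diag(p) - 1)) > 1e-6)
      msg <- c(msg, "psi diagonal must equal 1 (self-correlation)")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted covariates-only linear mixed model
#'
#' The null model y = X alpha + b + eps with b ~ N(0, tau * Psi) and
#' eps ~ N(0, phi * I), fitted by ML or REML through an eigendecomposition
#' of Psi. Stores everything score tests need so that a whole genome scan
#' reuses one fit: the GLS fixed effects, variance components, fitted
#' random intercepts, the working residual Sigma^-1 (y - X alpha), and a
#' factorisation sufficient to apply the projector
#' P = Sigma^-1 - Sigma^-1 X (X' Sigma^-1 X)^-1 X' Sigma^-1.
#'
#' @slot samples sample ids, in model row order.
#' @slot alphaHat named fixed-effect estimates.
#' @slot tauHat kinship variance component (>= 0).
#' @slot phiHat residual variance component (> 0).
#' @slot bHat fitted random intercepts.
#' @slot sigmaInvResid Sigma^-1 (y - X alphaHat).
#' @slot eigVectors,eigValues eigendecomposition of Psi.
#' @slot sigInvX Sigma^-1 X.
#' @slot xtSigInvXInv (X' Sigma^-1 X)^-1.
#' @slot loglik maximised (restricted) log-likelihood.
#' @slot method "ml" or "reml".
#' @slot converged,boundary,degenerate fit status flags; `boundary` marks
#'   tauHat on the tau = 0 boundary, `degenerate` a near-perfect fit with
#'   phiHat at its lower bound.
#'
#' @seealso [fitNull()], [computeScores()], [nullResidualCheck()]
#' @export
setClass("NullModelFit",
  representation(samples = "character", alphaHat = "numeric",
    tauHat = "numeric", phiHat = "numeric", bHat = "numeric",
    sigmaInvResid = "numeric", eigVectors = "matrix", eigValues = "numeric",
    sigInvX = "matrix", xtSigInvXInv = "matrix", loglik = "numeric",
    method = "character", converged = "logical", boundary = "logical",
    degenerate = "logical"))

setValidity("NullModelFit", function(object) {
  msg <- character(0)
  n <- length(object@samples)
  if (object@tauHat < 0) msg <- c(msg, "tauHat must be >= 0")
  if (object@phiHat <= 0) msg <- c(msg, "phiHat must be > 0")
  if (length(object@bHat) != n || length(object@sigmaInvResid) != n)
    msg <- c(msg, "bHat and sigmaInvResid must have length n")
  if (length(msg)) msg else TRUE
})

#' Score vector and null covariance for one SNP set
#'
#' The score vector U = G' Sigma^-1 (y - X alphaHat) for the SNP effects at
#' beta = 0 under the fitted null LMM, and its null covariance V = G' P G,
#' which accounts for estimation of the fixed effects. All SPU and score
#' tests for the SNP set are functions of (U, V).
#'
#' @slot snpIds SNP identifiers (length p).
#' @slot U score vector.
#' @slot V p x p symmetric positive semi-definite covariance of U.
#' @slot nSamples number of samples behind the scores.
#'
#' @seealso [computeScores()], [aspuTest()], [multivariateScoreTest()]
#' @export
setClass("ScoreSet",
  representation(snpIds = "character", U = "numeric", V = "matrix",
    nSamples = "integer"))

setValidity("ScoreSet", function(object) {
  msg <- character(0)
  p <- length(object@snpIds)
  if (length(object@U) != p || nrow(object@V) != p || ncol(object@V) != p)
    msg <- c(msg, "U and V dimensions must match snpIds")
  if (p > 0 && max(abs(object@V - t(object@V))) >
        .sym_tol * max(1, max(abs(object@V))))
    msg <- c(msg, "V must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Gene-level test result
#'
#' Monte-Carlo p-values for each SPU(gamma) statistic, the adaptive aSPU
#' combination, and the multivariate score test, for one gene (SNP set).
#'
#' @slot geneId gene identifier.
#' @slot nSnps number of SNPs tested.
#' @slot spuPvalues named p-values, one per gamma ("1".."8", "inf").
#' @slot aspuPvalue adaptive minimum-p combination p-value.
#' @slot scorePvalue multivariate score test p-value.
#' @slot B Monte-Carlo sample size used.
#' @slot seed RNG seed used for the null draws.
#'
#' @seealso [aspuTest()], [runScan()]
#' @export
setClass("GeneTestResult",
  representation(geneId = "character", nSnps = "integer",
    spuPvalues = "numeric", aspuPvalue = "numeric", scorePvalue = "numeric",
    B = "integer", seed = "integer"))

setValidity("GeneTestResult", function(object) {
  msg <- character(0)
  pv <- c(object@spuPvalues, object@aspuPvalue)
  pv <- pv[!is.na(pv)]
  if (length(pv) && (any(pv <= 0) || any(pv > 1)))
    msg <- c(msg, "Monte-Carlo p-values must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})
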