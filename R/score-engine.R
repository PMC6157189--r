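#' Score vector and null covariance for a SNP set
#'
#' Computes U = G' Sigma^-1 (y - X alphaHat) — the score for the SNP
#' effects at beta = 0 under the fitted null LMM — and its null covariance
#' V = G' P G with P = Sigma^-1 - Sigma^-1 X (X' Sigma^-1 X)^-1 X' Sigma^-1,
#' which accounts for estimation of the fixed effects. The variance
#' components are held fixed at their null estimates, the standard practice
#' for mixed-model score tests. No model refit is involved, so a genome
#' scan can call this once per gene off a single [fitNull()].
#'
#' @param fit a [NullModelFit-class].
#' @param g a [GenotypeMatrix-class] restricted to the SNP set (complete,
#'   sample order matching the fit), or a plain dosage matrix with matching
#'   rownames.
#' @return a [ScoreSet-class]. Constant SNP columns yield a ~0 row/column of
#'   V and are flagged with a warning.
#' @export
computeScores <- function(fit, g) {
  stopifnot(is(fit, "NullModelFit"))
  if (is(g, "GenotypeMatrix")) {
    G <- dosages(g)
    ids <- snpInfo(g)$id
  } else {
    G <- as.matrix(g)
    ids <- colnames(G)
    if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(G)))
  }
  if (ncol(G) < 1) stop("empty SNP set")
  if (anyNA(G)) stop("genotypes contain missing calls; imputeMissing() first")
  checkAligned(sampleIds(fit), rownames(G), what = "fit/genotypes")
  U <- as.vector(crossprod(G, fit@sigmaInvResid))
  SG <- .sigmaInvApply(fit, G)
  C <- crossprod(G, fit@sigInvX)                      # p x q
  V <- crossprod(G, SG) - C %*% fit@xtSigInvXInv %*% t(C)
  V <- (V + t(V)) / 2
  flat <- which(diag(V) <= 1e-12 * max(diag(V), 1e-300) |
                  apply(G, 2, function(col) all(col == col[1])))
  if (length(flat))
    warning("near-constant SNP column(s) with ~0 score variance: ",
            paste(head(ids[flat], 3), collapse = ", "))
  new("ScoreSet", snpIds = as.character(ids), U = U, V = V,
      nSamples = nrow(G))
}

#' Multivariate (gene-level) score test
#'
#' The classical comparator: T = U' V^- U with V^- the eigenvalue-truncated
#' pseudoinverse (eigenvalues below 1e-10 of the largest are dropped),
#' referred to a chi-square with degrees of freedom equal to the retained
#' rank.
#'
#' @param s a [ScoreSet-class].
#' @return the p-value.
#' @export
multivariateScoreTest <- function(s) {
  stopifnot(is(s, "ScoreSet"))
  e <- eigen(s@V, symmetric = TRUE)
  keep <- e$values > 1e-10 * max(e$values, 0)
  if (!any(keep))
    undefinedTest("score covariance V has numerical rank 0")
  z <- as.vector(crossprod(e$vectors[, keep, drop = FALSE], s@U))
  stat <- sum(z^2 / e$values[keep])
  pchisq(stat, df = sum(keep), lower.tail = FALSE)
}

#' Genome-wide single-SNP score scan
#'
#' Per-SNP score test z_j = U_j / sqrt(V_jj) with a two-sided normal
#' p-value, vectorised over all SNPs so that one null-model fit serves the
#' whole genome. Monomorphic (zero-variance) SNPs get `NA` with a reason
#' code.
#'
#' @param fit a [NullModelFit-class].
#' @param g a complete [GenotypeMatrix-class].
#' @return data.frame with columns `id`, `chrom`, `pos`, `maf`, `U`, `V`,
#'   `z`, `p`, `reason`.
#' @export
singleSnpScan <- function(fit, g) {
  stopifnot(is(fit, "NullModelFit"), is(g, "GenotypeMatrix"))
  G <- dosages(g)
  if (anyNA(G)) stop("genotypes contain missing calls; imputeMissing() first")
  checkAligned(sampleIds(fit), rownames(G), what = "fit/genotypes")
  si <- snpInfo(g)
  U <- as.vector(crossprod(G, fit@sigmaInvResid))
  SG <- .sigmaInvApply(fit, G)
  C <- crossprod(G, fit@sigInvX)
  Vdiag <- colSums(G * SG) - rowSums((C %*% fit@xtSigInvXInv) * C)
  ok <- Vdiag > 1e-12 * max(Vdiag, 1e-300)
  z <- ifelse(ok, U / sqrt(pmax(Vdiag, 1e-300)), NA_real_)
  p <- 2 * pnorm(-abs(z))
  data.frame(id = si$id, chrom = si$chrom, pos = si$pos, maf = si$maf,
             U = U, V = Vdiag, z = z, p = p,
             reason = ifelse(ok, "", "monomorphic"),
             stringsAsFactors = FALSE)
}
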