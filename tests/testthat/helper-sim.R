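# Shared fixtures, all generated in code at test time.

# unrelated cohort: HWE genotypes, identity kinship
unrelatedCohort <- function(n, p, maf = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(maf)) maf <- runif(p, 0.1, 0.5)
  dos <- sapply(maf, function(f) rbinom(n, 2, f))
  rownames(dos) <- sprintf("S%04d", seq_len(n))
  si <- data.frame(id = sprintf("snp%04d", seq_len(p)), chrom = "1",
                   pos = 1000L * seq_len(p), ref = "A", alt = "B",
                   stringsAsFactors = FALSE)
  # keep the minor-allele orientation invariant of the class
  freq <- colMeans(dos) / 2
  flip <- freq > 0.5
  dos[, flip] <- 2 - dos[, flip]
  list(g = GenotypeMatrix(dos, si),
       psi = KinshipMatrix(diag(n), rownames(dos)))
}

# family study: genotypes + pedigree kinship + covariates + trait
familyStudy <- function(nFam = 100, structure = "sib-pairs", nSnps = 50,
                        tau = 1, phi = 1, alpha = c(0, 0.5, 0.01),
                        beta = NULL, seed = 1) {
  sim <- simulateGenotypes(pedigreeSpec(nFam, structure, nSnps = nSnps,
                                        seed = seed))
  X <- simulateCovariates(sampleIds(sim$genotypes), seed = seed + 1)
  y <- simulateTrait(sim$genotypes, sim$kinship, X, tau = tau, phi = phi,
                     alpha = alpha, beta = beta, seed = seed + 2)
  list(g = sim$genotypes, psi = sim$kinship, X = X, y = y,
       pedigree = sim$pedigree)
}

# explicit-matrix score computation: the brute-force oracle for (U, V)
bruteForceScores <- function(fit, y, X, psiM, G) {
  n <- length(y)
  Sigma <- fit@tauHat * psiM + diag(fit@phiHat, n)
  SigInv <- solve(Sigma)
  P <- SigInv - SigInv %*% X %*%
    solve(t(X) %*% SigInv %*% X) %*% t(X) %*% SigInv
  r <- y - as.vector(X %*% fit@alphaHat)
  list(U = as.vector(t(G) %*% SigInv %*% r), V = t(G) %*% P %*% G)
}

# literal double-loop aSPU: same null sample for outer and inner ranking
doubleLoopAspu <- function(s, gammas, B, seed) {
  p <- length(s@U)
  e <- eigen(s@V, symmetric = TRUE)
  R <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), p)
  set.seed(seed)
  Z <- matrix(rnorm(B * p), B, p) %*% t(R)
  Tobs <- vapply(gammas, function(g) spuStatistic(s@U, g), numeric(1))
  Tb <- sapply(seq_along(gammas), function(k)
    apply(Z, 1, spuStatistic, gamma = gammas[k]))
  pv <- vapply(seq_along(gammas), function(k)
    (sum(abs(Tb[, k]) >= abs(Tobs[k])) + 1) / (B + 1), numeric(1))
  minPobs <- min(pv)
  minP0 <- rep(Inf, B)
  for (b in seq_len(B)) {          # outer loop over null draws
    for (k in seq_along(gammas)) { # plug-in rank against the full sample
      pb <- sum(abs(Tb[, k]) >= abs(Tb[b, k])) / B
      if (pb < minP0[b]) minP0[b] <- pb
    }
  }
  (sum(minP0 <= minPobs) + 1) / (B + 1)
}

# tiny VCF writer for handcrafted records
writeTinyVcf <- function(path, samples, records) {
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"),
             records)
  writeLines(lines, path)
  path
}

vcfRecord <- function(chrom, pos, id, ref, alt, gts)
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
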