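# Score vector U, null covariance V, multivariate and single-SNP tests.

test_that("projector scores match the brute-force explicit-matrix oracle", {
  st <- familyStudy(nFam = 20, nSnps = 12, tau = 1.2, phi = 0.9, seed = 61)
  fit <- fitNull(st$y, st$X, st$psi)
  G <- dosages(st$g)[, 1:6]
  ss <- computeScores(fit, G)
  oracle <- bruteForceScores(fit, st$y, st$X, kinshipMatrix(st$psi), G)
  expect_equal(ss@U, oracle$U, tolerance = 1e-8)
  expect_equal(unname(ss@V), unname(oracle$V), tolerance = 1e-8)
})

test_that("with psi = I, tau = 0 the score test is the OLS score test", {
  co <- unrelatedCohort(n = 150, p = 1, maf = 0.3, seed = 71)
  X <- matrix(1, 150, 1, dimnames = list(sampleIds(co$g), "(Intercept)"))
  y <- simulateTrait(co$g, co$psi, X, tau = 0, phi = 1.3, seed = 72)
  fit <- fitNull(y, X, co$psi)
  expect_equal(unname(varianceComponents(fit)["tau"]), 0)
  ss <- computeScores(fit, co$g)
  phi <- unname(varianceComponents(fit)["phi"])
  Gv <- dosages(co$g)[, 1]
  U0 <- sum(Gv * (y - mean(y))) / phi              # classic score
  V0 <- sum((Gv - mean(Gv))^2) / phi               # classic score variance
  expect_equal(ss@U, U0, tolerance = 1e-8)
  expect_equal(ss@V[1, 1], V0, tolerance = 1e-8)
  # and the chi-square(1) p equals the two-sided normal p
  expect_equal(multivariateScoreTest(ss),
               2 * pnorm(-abs(U0 / sqrt(V0))), tolerance = 1e-10)
})

test_that("score linearity: orthogonal columns give U = 0, duplicates repeat", {
  st <- familyStudy(nFam = 30, nSnps = 10, seed = 81)
  fit <- fitNull(st$y, st$X, st$psi)
  r <- fit@sigmaInvResid
  gcol <- dosages(st$g)[, 1]
  orth <- gcol - r * sum(gcol * r) / sum(r * r)    # project out the residual
  G <- cbind(a = orth, b = dosages(st$g)[, 2], bdup = dosages(st$g)[, 2])
  rownames(G) <- sampleIds(st$g)
  ss <- computeScores(fit, G)
  expect_lt(abs(ss@U[1]), 1e-8 * max(abs(ss@U)))
  expect_equal(ss@U[2], ss@U[3], tolerance = 1e-12)
  expect_equal(ss@V[2, ], ss@V[3, ], tolerance = 1e-12)
  ev <- eigen(ss@V, symmetric = TRUE)$values
  expect_lt(min(ev), 1e-8 * max(ev))               # rank-deficient V
})

test_that("U is mean-zero with covariance V over simulated null traits", {
  sim <- simulateGenotypes(pedigreeSpec(20, "sib-pairs", nSnps = 3,
                                        seed = 91))
  g <- sim$genotypes; psi <- sim$kinship
  X <- simulateCovariates(sampleIds(g), seed = 92)
  nrep <- 2000
  Us <- matrix(NA_real_, nrep, 3)
  Vsum <- 0
  for (r in seq_len(nrep)) {
    y <- simulateTrait(g, psi, X, tau = 1, phi = 1, alpha = c(0, 0.3, 0.01),
                       seed = 10000 + r)
    fit <- fitNull(y, X, psi)
    ss <- computeScores(fit, g)
    Us[r, ] <- ss@U
    Vsum <- Vsum + ss@V
  }
  # per-replicate V varies with the re-estimated variance components; the
  # asymptotic claim is about the average reported covariance
  Vref <- Vsum / nrep
  Vemp <- cov(Us)
  se <- sqrt((outer(diag(Vref), diag(Vref)) + Vref^2) / nrep)
  expect_true(all(abs(Vemp - Vref) <= 4 * se))
  expect_true(all(abs(colMeans(Us)) <= 4 * sqrt(diag(Vref) / nrep)))
})

test_that("U and V depend only on the covariate span", {
  st <- familyStudy(nFam = 40, nSnps = 8, seed = 101)
  fit1 <- fitNull(st$y, st$X, st$psi)
  Tmat <- matrix(c(1, 0, 0, 2, 1, 0, -1, 3, 0.5), 3)  # change of basis
  X2 <- st$X %*% Tmat
  rownames(X2) <- rownames(st$X)
  colnames(X2) <- paste0("c", 1:3)
  fit2 <- fitNull(st$y, X2, st$psi)
  s1 <- computeScores(fit1, st$g)
  s2 <- computeScores(fit2, st$g)
  expect_equal(s1@U, s2@U, tolerance = 1e-8)
  expect_equal(s1@V, s2@V, tolerance = 1e-8)
})

test_that("multivariate score test handles degenerate statistics", {
  ss <- new("ScoreSet", snpIds = c("a", "b"), U = c(0, 0),
            V = diag(2), nSamples = 10L)
  expect_equal(multivariateScoreTest(ss), 1)         # zero statistic
  ssz <- new("ScoreSet", snpIds = "a", U = 0, V = matrix(0, 1, 1),
             nSamples = 10L)
  expect_error(multivariateScoreTest(ssz),
               class = "pedaSPU_undefined_test")
})

test_that("single-SNP scan matches per-SNP tests and flags monomorphs", {
  st <- familyStudy(nFam = 50, nSnps = 6, seed = 111)
  fit <- fitNull(st$y, st$X, st$psi)
  d <- dosages(st$g)
  d <- cbind(d, mono = rep(1, nrow(d)))
  si <- rbind(as.data.frame(snpInfo(st$g)[, 1:5]),
              data.frame(id = "mono", chrom = "1", pos = 999999,
                         ref = "A", alt = "B"))
  g2 <- GenotypeMatrix(d, si)
  tab <- suppressWarnings(singleSnpScan(fit, g2))
  for (j in 1:6) {
    ss <- computeScores(fit, d[, j, drop = FALSE])
    expect_equal(tab$p[j], multivariateScoreTest(ss), tolerance = 1e-10)
  }
  expect_true(is.na(tab$p[7]))
  expect_equal(tab$reason[7], "monomorphic")
})

test_that("null single-SNP p-values are uniform under exchangeability", {
  # tau = 0 cohort; permuting genotype sample labels breaks any association
  co <- unrelatedCohort(n = 300, p = 40, seed = 121)
  X <- matrix(1, 300, 1, dimnames = list(sampleIds(co$g), "(Intercept)"))
  y <- simulateTrait(co$g, co$psi, X, tau = 0, phi = 1, seed = 122)
  fit <- fitNull(y, X, co$psi)
  set.seed(123)
  d <- dosages(co$g)[sample(300), ]
  rownames(d) <- sampleIds(co$g)
  g2 <- GenotypeMatrix(d, as.data.frame(snpInfo(co$g)[, 1:5]))
  tab <- singleSnpScan(fit, g2)
  expect_gt(ks.test(tab$p, "punif")$p.value, 0.01)
})

test_that("a strongly causal SNP tops the single-SNP scan", {
  hits <- replicate(40, {
    seed <- sample.int(1e6, 1)
    co <- unrelatedCohort(n = 200, p = 25, seed = seed)
    X <- matrix(1, 200, 1, dimnames = list(sampleIds(co$g), "(Intercept)"))
    beta <- setNames(1.0, snpInfo(co$g)$id[5])   # ~ all-but-certain signal
    y <- simulateTrait(co$g, co$psi, X, tau = 0, phi = 1, beta = beta,
                       seed = seed + 1)
    fit <- fitNull(y, X, co$psi)
    which.min(singleSnpScan(fit, co$g)$p) == 5
  })
  expect_gte(mean(hits), 0.9)
})
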