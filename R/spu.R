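#' Sum of powered score statistic
#'
#' T_SPU(gamma) = sum_j U_j^gamma for finite gamma (signed for odd gamma),
#' and T_SPU(Inf) = max_j |U_j|. gamma acts as a weight selector: gamma = 1
#' is the burden test, gamma = 2 the sum of squared scores (linear-kernel
#' SKAT), and large gamma approaches the maximum-component test.
#'
#' @param U score vector.
#' @param gamma positive integer or `Inf`.
#' @return the statistic.
#' @export
spuStatistic <- function(U, gamma) {
  stopifnot(length(U) >= 1)
  if (is.infinite(gamma)) max(abs(U)) else sum(U^gamma)
}

# validate a gamma set: positive integers plus optional Inf, no duplicates
checkGammas <- function(gammas) {
  if (length(gammas) == 0) stop("gamma set must be nonempty")
  if (anyDuplicated(gammas)) stop("duplicate gamma values")
  fin <- gammas[is.finite(gammas)]
  if (any(fin < 1) || any(fin != round(fin)))
    stop("finite gammas must be positive integers")
  gammas
}

#' Default gamma set
#'
#' The standard choice \{1, 2, ..., 8, Inf\}: low powers favour dense,
#' same-direction effects; high powers and Inf favour sparse effects.
#' @export
defaultGammas <- function() c(1:8, Inf)

# PSD square-root factor of V by eigendecomposition (tolerates rank
# deficiency, unlike Cholesky); returns NULL if V has numerical rank 0
.psdFactor <- function(V) {
  e <- eigen(V, symmetric = TRUE)
  mx <- max(e$values, 0)
  if (mx <= 0) return(NULL)
  if (min(e$values) < -1e-8 * mx)
    stop("V is not positive semi-definite; repair upstream")
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(V))
}

# SPU statistics for each row of a draw matrix (B x p), one column per gamma
.spuMatrix <- function(Z, gammas) {
  out <- matrix(NA_real_, nrow(Z), length(gammas))
  for (k in seq_along(gammas)) {
    gam <- gammas[k]
    out[, k] <- if (is.infinite(gam)) {
      apply(abs(Z), 1, max)
    } else rowSums(Z^gam)
  }
  out
}

#' Adaptive sum of powered score (aSPU) test
#'
#' Monte-Carlo p-values for every SPU(gamma) and their adaptive minimum-p
#' combination, all from one null sample: B draws U^(b) ~ N(0, V) are
#' generated through a PSD square root of V; each SPU p-value is
#' p_gamma = (#\{b : |T^(b)| >= |T_obs|\} + 1) / (B + 1) (two-sided on the
#' statistic, ties counted — conservative). The aSPU statistic is
#' min_gamma p_gamma; its p-value reuses the same draws by leave-one-out
#' ranking: for each b, p_gamma^(b) ranks |T_gamma^(b)| among the other
#' B - 1 draws, and p_aSPU = (#\{b : min_gamma p^(b) <= min_gamma p\} + 1) /
#' (B + 1). All p-values therefore lie in [1/(B+1), 1] and the whole
#' procedure is deterministic given `seed`.
#'
#' @param s a [ScoreSet-class].
#' @param gammas gamma set (default \{1..8, Inf\}).
#' @param B Monte-Carlo sample size (>= 99).
#' @param seed RNG seed.
#' @param geneId label carried into the result.
#' @return a [GeneTestResult-class].
#' @export
aspuTest <- function(s, gammas = defaultGammas(), B = 1000L, seed = 1L,
                     geneId = "gene") {
  stopifnot(is(s, "ScoreSet"))
  gammas <- checkGammas(gammas)
  B <- as.integer(B)
  if (B < 99L) stop("B must be at least 99")
  p <- length(s@U)
  R <- .psdFactor(s@V)
  if (is.null(R))
    undefinedTest("score covariance V has numerical rank 0")
  Z <- withSeed(seed, matrix(rnorm(B * p), B, p)) %*% t(R)
  Tobs <- vapply(gammas, function(g) spuStatistic(s@U, g), numeric(1))
  Tb <- .spuMatrix(Z, gammas)
  K <- length(gammas)
  pv <- numeric(K)
  minP0 <- rep(Inf, B)
  for (k in seq_len(K)) {
    a <- abs(Tb[, k])
    pv[k] <- (sum(a >= abs(Tobs[k])) + 1) / (B + 1)
    # leave-one-out null p-values: (#{b' != b: a_b' >= a_b} + 1) / B
    p0 <- (B - rank(a, ties.method = "min") + 1) / B
    minP0 <- pmin(minP0, p0)
  }
  aspu <- (sum(minP0 <= min(pv)) + 1) / (B + 1)
  names(pv) <- ifelse(is.infinite(gammas), "inf", as.character(gammas))
  scoreP <- tryCatch(multivariateScoreTest(s),
                     pedaSPU_undefined_test = function(e) NA_real_)
  new("GeneTestResult", geneId = as.character(geneId), nSnps = p,
      spuPvalues = pv, aspuPvalue = aspu, scorePvalue = scoreP,
      B = B, seed = as.integer(seed))
}

#' Tail probability of a positive weighted sum of chi-squares
#'
#' P(sum_k lambda_k chi^2_1 > q) by Imhof's inversion of the characteristic
#' function, evaluated with adaptive quadrature. This is the exact null
#' distribution of the sum of squared scores U'U (linear-kernel SKAT form)
#' with lambda the eigenvalues of V.
#'
#' @param q observed statistic.
#' @param lambda positive weights (non-positive ones are dropped).
#' @return the upper tail probability, clamped to [0, 1].
#' @export
chisqMixturePvalue <- function(q, lambda) {
  lambda <- lambda[lambda > 1e-12 * max(lambda)]
  if (!length(lambda)) stop("no positive weights")
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    out <- sin(theta) / (u * rho)
    # continuous limit at u = 0: theta'(0) = (sum(lambda) - q)/2
    out[u == 0] <- 0.5 * (sum(lambda) - q)
    out
  }
  # truncate where the oscillation-damped tail drops below ~1e-8; the
  # integrand envelope decays like u^-(1 + p/2) once all atan terms saturate
  p <- length(lambda)
  amp <- exp(0.5 * sum(log(lambda)))
  upper <- (2e8 / (max(q, 1e-3) * amp))^(1 / (1 + p / 2))
  upper <- min(max(upper, 1e4), 1e6)
  val <- integrate(integrand, 0, upper, subdivisions = 50000L,
                   rel.tol = 1e-12, abs.tol = 1e-14, stop.on.error = FALSE)
  min(max(0.5 + val$value / pi, 0), 1)
}

#' Check the theoretical equivalences of SPU members
#'
#' On a given score set, compares Monte-Carlo SPU p-values with the
#' analytic forms of the tests they are equivalent to: SPU(1) with the
#' burden test (normal p-value of 1'U / sqrt(1'V1)), SPU(2) with the sum of
#' squared scores / linear-kernel SKAT (chi-square mixture weighted by the
#' eigenvalues of V), and — only when diag(V) is constant, the condition
#' under which the equality holds — SPU(Inf) with the UminP test, whose
#' reference p-value P(max_j |Z_j| >= max_j |U_j|) is estimated by direct
#' multivariate-normal simulation.
#'
#' @param s a [ScoreSet-class].
#' @param B Monte-Carlo sample size for the SPU p-values and the UminP
#'   rectangle-probability simulation.
#' @param seed RNG seed.
#' @return data.frame with one row per equivalence: the Monte-Carlo and
#'   analytic p-values, their absolute difference, the 3-binomial-SE
#'   tolerance, and status `"pass"`, `"fail"` or `"not-applicable"`.
#' @export
equivalenceSuite <- function(s, B = 10000L, seed = 1L) {
  stopifnot(is(s, "ScoreSet"))
  res <- aspuTest(s, gammas = c(1, 2, Inf), B = B, seed = seed)
  U <- s@U; V <- s@V
  burden <- 2 * pnorm(-abs(sum(U) / sqrt(sum(V))))
  skat <- chisqMixturePvalue(sum(U^2), eigen(V, symmetric = TRUE,
                                             only.values = TRUE)$values)
  dv <- diag(V)
  equalVar <- diff(range(dv)) <= 1e-6 * max(dv)
  uminp <- NA_real_
  if (equalVar) {
    R <- .psdFactor(V)
    Z <- withSeed(seed + 1L, matrix(rnorm(B * length(U)), B)) %*% t(R)
    uminp <- (sum(apply(abs(Z), 1, max) >= max(abs(U))) + 1) / (B + 1)
  }
  mc <- unname(res@spuPvalues[c("1", "2", "inf")])
  analytic <- c(burden, skat, uminp)
  tol <- 3 * sqrt(pmax(analytic * (1 - analytic), 1 / (B + 1)) / B)
  status <- ifelse(is.na(analytic), "not-applicable",
                   ifelse(abs(mc - analytic) <= tol, "pass", "fail"))
  data.frame(equivalence = c("SPU(1) = burden",
                             "SPU(2) = SSU/SKAT-linear",
                             "SPU(Inf) = UminP (equal variances)"),
             mcPvalue = mc, analyticPvalue = analytic,
             difference = abs(mc - analytic), tolerance = tol,
             status = status, stringsAsFactors = FALSE)
}
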