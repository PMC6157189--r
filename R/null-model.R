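#' Fit the covariates-only linear mixed model
#'
#' Fits y = X alpha + b + eps with b ~ N(0, tau * Psi), eps ~ N(0, phi * I)
#' by maximum likelihood (default) or REML. For Gaussian traits this direct
#' likelihood maximisation coincides with the PQL fit, so no iterative
#' quasi-likelihood machinery is needed. The fit eigendecomposes Psi once
#' and profiles the likelihood down to a one-dimensional search over the
#' variance ratio lambda = tau / phi: a log-spaced grid (including the
#' lambda = 0 boundary) followed by bounded golden-section refinement.
#'
#' With Psi = I the two components are not separately identifiable; the
#' tie-break keeps lambda at 0 so tauHat = 0 and phiHat equals the OLS
#' residual variance (ML scaling).
#'
#' @param y named trait vector (no missing values; drop incomplete samples
#'   upstream, e.g. via [readTraitTable()]).
#' @param X design matrix with intercept, sample ids as rownames, full
#'   column rank.
#' @param psi a [KinshipMatrix-class] aligned with `y`.
#' @param method `"ml"` or `"reml"`.
#' @return a [NullModelFit-class].
#' @export
fitNull <- function(y, X, psi, method = c("ml", "reml")) {
  method <- match.arg(method)
  stopifnot(is(psi, "KinshipMatrix"), is.matrix(X))
  ids <- names(y)
  if (is.null(ids) || is.null(rownames(X)))
    stop("y and X must carry sample ids (names/rownames)")
  checkAligned(ids, rownames(X), sampleIds(psi), what = "y/X/psi")
  n <- length(y); q <- ncol(X)
  if (n <= q) stop("need more samples than covariates (n > q)")
  if (qr(X)$rank < q) stop("covariate matrix is rank deficient")
  .fitCounter$n <- .fitCounter$n + 1L

  e <- eigen(kinshipMatrix(psi), symmetric = TRUE)
  d <- e$values
  if (min(d) < -1e-6 * max(abs(d)))
    stop("psi is not positive semi-definite; repair it with makePSD()")
  d <- pmax(d, 0)
  Q <- e$vectors
  yt <- as.vector(crossprod(Q, y))
  Xt <- crossprod(Q, X)

  # profile (restricted) log-likelihood at variance ratio lambda = tau/phi
  profile <- function(lambda) {
    v <- lambda * d + 1
    w <- 1 / v
    A <- crossprod(Xt, w * Xt)
    alpha <- solve(A, crossprod(Xt, w * yt))
    r <- yt - as.vector(Xt %*% alpha)
    rss <- sum(w * r * r)
    if (method == "ml") {
      phi <- max(rss / n, 1e-300)
      ll <- -0.5 * (n * log(2 * pi) + n * log(phi) + sum(log(v)) + n)
    } else {
      phi <- max(rss / (n - q), 1e-300)
      ll <- -0.5 * ((n - q) * log(2 * pi) + (n - q) * log(phi) +
                      sum(log(v)) + determinant(A)$modulus[1] + (n - q))
    }
    list(ll = ll, phi = phi, alpha = as.vector(alpha), rss = rss)
  }

  grid <- c(0, 10^seq(-6, 6, by = 0.25))
  lls <- vapply(grid, function(l) profile(l)$ll, numeric(1))
  # flat profile (Psi = I up to round-off): components unidentifiable,
  # rest tau on the boundary instead of chasing numerical noise
  eps <- 1e-6 * max(1, abs(max(lls)))
  best <- if (max(lls) - min(lls) < eps) 1L else which.max(lls)
  lambda <- grid[best]
  converged <- TRUE
  if (best > 1) {
    lo <- grid[max(1, best - 1)]
    hi <- grid[min(length(grid), best + 1)]
    # refine on log10 scale; guard the boundary cell against log(0)
    lo <- max(lo, 1e-10)
    opt <- tryCatch(
      optimize(function(u) profile(10^u)$ll, c(log10(lo), log10(hi)),
               maximum = TRUE, tol = 1e-9),
      error = function(e) NULL)
    if (is.null(opt)) converged <- FALSE
    else if (opt$objective > lls[best]) lambda <- 10^opt$maximum
  }
  fit <- profile(lambda)
  phi <- fit$phi
  tau <- lambda * phi
  boundary <- lambda == 0
  degenerate <- fit$rss <= 1e-10 * max(sum(yt^2), 1)
  alpha <- setNames(fit$alpha,
                    if (is.null(colnames(X))) paste0("x", seq_len(q))
                    else colnames(X))

  v <- lambda * d + 1
  r <- yt - as.vector(Xt %*% fit$alpha)
  sigInvResid <- as.vector(Q %*% (r / v)) / phi          # Sigma^-1 (y - X a)
  bHat <- tau * as.vector(kinshipMatrix(psi) %*% sigInvResid)
  sigInvX <- Q %*% (Xt / v) / phi
  xtSigInvXInv <- solve(crossprod(X, sigInvX))

  new("NullModelFit", samples = ids, alphaHat = alpha, tauHat = tau,
      phiHat = phi, bHat = setNames(bHat, ids),
      sigmaInvResid = setNames(sigInvResid, ids), eigVectors = Q,
      eigValues = d, sigInvX = sigInvX, xtSigInvXInv = xtSigInvXInv,
      loglik = fit$ll, method = method, converged = converged,
      boundary = boundary, degenerate = degenerate)
}

# apply Sigma^-1 = Q diag(1/(tau d + phi)) Q' to a matrix/vector
.sigmaInvApply <- function(fit, M) {
  M <- as.matrix(M)
  Mt <- crossprod(fit@eigVectors, M)
  fit@eigVectors %*% (Mt / (fit@tauHat * fit@eigValues + fit@phiHat))
}

#' Diagnostics on a fitted null model
#'
#' Verifies the working-residual identity
#' Sigma^-1 (y - X alphaHat) = (y - X alphaHat - bHat) / phiHat
#' by explicit dense computation, and the orthogonality
#' X' Sigma^-1 (y - X alphaHat) = 0 that makes the score mean-zero under
#' the null. Report only; nothing is modified.
#'
#' @param fit a converged [NullModelFit-class].
#' @param y,X,psi the data the model was fitted to.
#' @return list with `residIdentity` (max relative discrepancy between the
#'   two residual forms), `xOrthogonality` (max |X' Sigma^-1 r| relative to
#'   the GLS scale), and `ok` at tolerance 1e-8 / 1e-6 respectively.
#' @export
nullResidualCheck <- function(fit, y, X, psi) {
  stopifnot(is(fit, "NullModelFit"))
  checkAligned(sampleIds(fit), names(y), rownames(X), sampleIds(psi),
               what = "fit/y/X/psi")
  Sigma <- fit@tauHat * kinshipMatrix(psi) + diag(fit@phiHat, length(y))
  r <- y - as.vector(X %*% fit@alphaHat)
  lhs <- solve(Sigma, r)
  rhs <- (r - fit@bHat) / fit@phiHat
  scale <- max(abs(lhs), 1e-300)
  residIdentity <- max(abs(lhs - rhs)) / scale
  storedDrift <- max(abs(lhs - fit@sigmaInvResid)) / scale
  denom <- pmax(colSums(abs(X) * abs(fit@sigmaInvResid)), 1e-300)
  xo <- max(abs(as.vector(crossprod(X, fit@sigmaInvResid))) / denom)
  list(residIdentity = residIdentity, storedDrift = storedDrift,
       xOrthogonality = xo,
       ok = residIdentity < 1e-8 && xo < 1e-6)
}
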