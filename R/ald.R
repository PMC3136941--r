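#' Asymmetric Laplace distribution parameters
#'
#' Bundle the three parameters of an asymmetric Laplace distribution (ALD):
#' location \code{theta} (the mode, in bp when modelling tag offsets),
#' asymmetry \code{kappa} (dimensionless, > 0; \code{kappa = 1} gives the
#' symmetric Laplace) and scale \code{sigma} (bp, > 0).
#'
#' The density used throughout is
#' \deqn{f(x) = \frac{\sqrt{2}}{\sigma}\,\frac{\kappa}{1+\kappa^2}
#'   \exp\!\left(-\frac{\sqrt{2}}{\sigma}\,\kappa^{s(x)}\,|x-\theta|\right)}
#' with \eqn{s(x) = 1} for \eqn{x \ge \theta} and \eqn{s(x) = -1} otherwise,
#' so larger \code{kappa} shortens the right tail and lengthens the left.
#'
#' @param theta location (mode), real.
#' @param kappa asymmetry, > 0.
#' @param sigma scale, > 0.
#' @return An object of class \code{ald_params}.
#' @export
ald_params <- function(theta, kappa, sigma) {
  stopifnot(is.finite(theta), is.finite(kappa), is.finite(sigma),
            kappa > 0, sigma > 0)
  structure(list(theta = theta, kappa = kappa, sigma = sigma),
            class = "ald_params")
}

#' @export
print.ald_params <- function(x, ...) {
  cat(sprintf("ALD(theta = %.3f, kappa = %.4f, sigma = %.3f)\n",
              x$theta, x$kappa, x$sigma))
  invisible(x)
}

#' Asymmetric Laplace density
#'
#' @param x numeric vector of positions (bp).
#' @param params an \code{\link{ald_params}} object.
#' @param log if TRUE, return log-density.
#' @return Density values (1/bp), strictly positive with unique mode at
#'   \code{params$theta}.
#' @export
dald <- function(x, params, log = FALSE) {
  stopifnot(inherits(params, "ald_params"))
  if (any(!is.finite(x))) stop("non-finite positions in 'x'")
  z <- x - params$theta
  k <- params$kappa
  rate <- ifelse(z >= 0, k, 1 / k)
  ld <- log(sqrt(2) / params$sigma) + log(k / (1 + k^2)) -
    (sqrt(2) / params$sigma) * rate * abs(z)
  if (log) ld else exp(ld)
}

#' Draw from an asymmetric Laplace distribution
#'
#' Uses the difference-of-exponentials representation
#' \eqn{X = \theta + \frac{\sigma}{\sqrt 2}(E_1/\kappa - \kappa E_2)} with
#' \eqn{E_1, E_2} iid standard exponential.
#'
#' @param n number of draws.
#' @param params an \code{\link{ald_params}} object.
#' @return Numeric vector of length \code{n}.
#' @export
rald <- function(n, params) {
  stopifnot(inherits(params, "ald_params"))
  params$theta + params$sigma / sqrt(2) *
    (stats::rexp(n) / params$kappa - params$kappa * stats::rexp(n))
}

#' Asymmetric Laplace cumulative distribution function
#'
#' @param q numeric vector of quantiles.
#' @param params an \code{\link{ald_params}} object.
#' @return P(X <= q).  The mass left of the mode is
#'   \eqn{\kappa^2/(1+\kappa^2)}.
#' @export
pald <- function(q, params) {
  stopifnot(inherits(params, "ald_params"))
  z <- q - params$theta
  k <- params$kappa
  r <- sqrt(2) / params$sigma
  ifelse(z < 0,
         k^2 / (1 + k^2) * exp(r / k * z),
         1 - 1 / (1 + k^2) * exp(-r * k * z))
}

#' Log-likelihood of a (weighted) sample under an ALD
#'
#' @param x numeric vector of observations.
#' @param params an \code{\link{ald_params}}.
#' @param weights optional nonnegative per-point weights (default 1).
#' @return Weighted sum of log-densities.
#' @export
ald_loglik <- function(x, params, weights = NULL) {
  ld <- dald(x, params, log = TRUE)
  if (is.null(weights)) sum(ld) else sum(weights * ld)
}

# Weighted deviation means about a candidate location t:
#   alpha = sum(w * (x - t)^+) / W,  beta = sum(w * (t - x)^+) / W.
# Computed for every candidate at once via prefix sums over sorted x.
.ald_deviation_means <- function(xs, ws, cand) {
  W <- sum(ws)
  cw <- cumsum(ws)
  cwx <- cumsum(ws * xs)
  idx <- findInterval(cand, xs)          # last sorted index with xs <= cand
  cw_le <- ifelse(idx > 0, cw[pmax(idx, 1L)], 0)
  cwx_le <- ifelse(idx > 0, cwx[pmax(idx, 1L)], 0)
  beta <- (cand * cw_le - cwx_le) / W
  alpha <- ((cwx[length(xs)] - cwx_le) - cand * (W - cw_le)) / W
  list(alpha = pmax(alpha, 0), beta = pmax(beta, 0), W = W)
}

#' Closed-form maximum-likelihood fit of an asymmetric Laplace distribution
#'
#' Two-step estimator: the location estimate is the sample point minimizing
#' \eqn{H(\theta) = \sqrt{\alpha(\theta)} + \sqrt{\beta(\theta)}}, where
#' \eqn{\alpha} and \eqn{\beta} are the (weighted) mean positive and negative
#' deviations about \eqn{\theta}; then
#' \eqn{\hat\kappa = (\beta/\alpha)^{1/4}} and
#' \eqn{\hat\sigma = \sqrt{2}\,(\alpha\beta)^{1/4}(\sqrt\alpha + \sqrt\beta)},
#' both evaluated at \eqn{\hat\theta}.  Candidates with \eqn{\alpha = 0} or
#' \eqn{\beta = 0} (the sample extremes) are excluded: there the profile
#' likelihood degenerates to a one-sided exponential outside the parameter
#' space.  Ties in \eqn{H} are broken toward the smallest candidate, making
#' the fit deterministic.
#'
#' @param x numeric vector of observations, length >= 3.
#' @param weights optional nonnegative weights, same length as \code{x};
#'   uniform weights reproduce the unweighted fit exactly.
#' @return An \code{\link{ald_params}} object.
#' @export
ald_mle <- function(x, weights = NULL) {
  n <- length(x)
  if (n < 3) stop("ALD fit requires at least 3 observations")
  if (any(!is.finite(x))) stop("non-finite observations")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0))
  if (sum(weights > 0) < 3) stop("fewer than 3 observations with positive weight")
  keep <- weights > 0
  x <- x[keep]; weights <- weights[keep]
  o <- order(x)
  xs <- x[o]; ws <- weights[o]
  cand <- unique(xs)
  dm <- .ald_deviation_means(xs, ws, cand)
  ok <- dm$alpha > 0 & dm$beta > 0
  if (!any(ok)) {
    stop("degenerate sample: no interior location candidate ",
         "(all observations identical or too few distinct values)")
  }
  H <- sqrt(dm$alpha[ok]) + sqrt(dm$beta[ok])
  pick <- which(ok)[which.min(H)]   # which.min keeps the smallest candidate on ties
  theta <- cand[pick]
  a <- dm$alpha[pick]; b <- dm$beta[pick]
  kappa <- (b / a)^(1 / 4)
  sigma <- sqrt(2) * (a * b)^(1 / 4) * (sqrt(a) + sqrt(b))
  ald_params(theta, kappa, sigma)
}
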