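#' Fit the normal + exponential convolution model
#'
#' Models an observed spot intensity as the sum of a Normal(mu, sigma^2)
#' background and an Exponential(mean alpha) true signal and estimates
#' (mu, sigma, alpha) by full maximum likelihood, started from
#' moment-based values (the third central moment of the convolution is
#' 2 alpha^3, which identifies the exponential component).
#'
#' @param x numeric vector of raw intensities (finite, non-negative,
#'   at least 50 values for stable estimation).
#' @return named list with \code{mu}, \code{sigma}, \code{alpha} and the
#'   maximized log-likelihood \code{logLik}.
#' @export
normexp_fit <- function(x) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("content error: intensities must be finite and non-negative",
         call. = FALSE)
  if (length(x) < 50)
    stop("need at least 50 intensities for stable normexp estimation",
         call. = FALSE)
  if (stats::sd(x) == 0)
    stop("normexp estimation error: intensities are all identical; ",
         "the background/signal decomposition is not identifiable",
         call. = FALSE)
  m1 <- mean(x)
  m2 <- stats::var(x)
  m3 <- mean((x - m1)^3)
  alpha0 <- if (m3 > 0) (m3 / 2)^(1 / 3) else sqrt(m2) / 10
  sigma0 <- sqrt(max(m2 - alpha0^2, m2 / 100))
  mu0 <- m1 - alpha0

  nll <- function(theta) {
    mu <- theta[1]; sigma <- exp(theta[2]); alpha <- exp(theta[3])
    -sum(dnormexp_log(x, mu, sigma, alpha))
  }
  fit <- stats::nlminb(c(mu0, log(sigma0), log(alpha0)), nll,
                       control = list(iter.max = 300))
  list(mu = fit$par[1], sigma = exp(fit$par[2]), alpha = exp(fit$par[3]),
       logLik = -fit$objective)
}

## log density of Normal(mu, sigma^2) + Exponential(mean alpha).
## With y = (x - mu)/sigma and c = sigma/alpha the density is
##   log f = -log(alpha) - z*c - c^2/2 + log Phi(z),   z = y - c.
## For very negative z the two large terms cancel catastrophically in
## floating point, so there the Mills-ratio asymptotic expansion of
## log Phi(z) is substituted, which collapses -z*c - c^2/2 - z^2/2 to
## the exactly computable -y^2/2.
dnormexp_log <- function(x, mu, sigma, alpha) {
  y <- (x - mu) / sigma
  cc <- sigma / alpha
  z <- y - cc
  out <- numeric(length(x))
  direct <- z > -12
  if (any(direct))
    out[direct] <- -log(alpha) - z[direct] * cc - cc^2 / 2 +
      stats::pnorm(z[direct], log.p = TRUE)
  if (any(!direct)) {
    zz <- z[!direct]
    series <- log1p(-1 / zz^2 + 3 / zz^4 - 15 / zz^6 + 105 / zz^8)
    out[!direct] <- -log(alpha) - y[!direct]^2 / 2 -
      log(-zz * sqrt(2 * pi)) + series
  }
  out
}

#' Normexp background correction
#'
#' Replaces each observed intensity by the conditional expectation of the
#' true signal given the observation under the fitted Normal background +
#' Exponential signal convolution, plus a positive offset that stabilizes
#' low-intensity log-ratios. The correction is strictly positive and
#' monotone increasing in the input.
#'
#' @param x numeric vector of raw intensities.
#' @param offset added to every corrected value (default 10).
#' @param params optional list with \code{mu}, \code{sigma}, \code{alpha};
#'   fitted from \code{x} by \code{\link{normexp_fit}} when omitted.
#' @return numeric vector of corrected intensities, all \code{> offset}
#'   minus numerical tolerance.
#' @export
normexp_correct <- function(x, offset = 10, params = NULL) {
  if (offset < 0) stop("config error: offset must be >= 0", call. = FALSE)
  if (is.null(params)) params <- normexp_fit(x)
  normexp_signal(x, params) + offset
}

## E[signal | observed] under the convolution model; the standard
## truncated-normal form: with musf = x - mu - sigma^2/alpha,
## E = musf + sigma * phi(musf/sigma) / Phi(musf/sigma)
normexp_signal <- function(x, params) {
  musf <- x - params$mu - params$sigma^2 / params$alpha
  z <- musf / params$sigma
  e <- musf + params$sigma *
    exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
  ## guard against underflow for extremely negative z
  pmax(e, .Machine$double.eps)
}
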