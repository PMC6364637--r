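#' Logistic sigmoid
#'
#' Numerically stable logistic function `1 / (1 + exp(-x))`. Stable for
#' arguments at least as large as +/- 700 (no overflow; saturates to 0/1 in
#' double precision).
#'
#' @param x Numeric vector of finite values.
#' @return Values in `[0, 1]` (0/1 only by floating-point saturation).
#' @examples
#' sigm(0)           # 0.5
#' sigm(logit(0.1))  # 0.1
#' @export
sigm <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  # evaluate on the negative half-line only so exp() never overflows;
  # copying x preserves dim/dimnames for matrix input
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' Logit (inverse sigmoid)
#'
#' @param p Numeric vector in (0, 1).
#' @return `log(p / (1 - p))`.
#' @export
logit <- function(p) {
  stopifnot(is.numeric(p), all(p > 0), all(p < 1))
  log(p) - log1p(-p)
}

# clamp inclusion weights away from 0/1 before any logit/log
.clamp_unit <- function(lambda, eps = 1e-12) pmin(pmax(lambda, eps), 1 - eps)

#' LN-CASS prior hyperparameters
#'
#' The LN-CASS prior on a regression coefficient is `beta = tau * lambda * z`
#' with `z ~ N(0, 1)` and `lambda = sigm(eta)`, `eta ~ N(mu_lambda,
#' sigma_lambda^2)`. `tau` is the slab standard deviation; `mu_lambda` sets
#' the prior inclusion probability `a = sigm(mu_lambda)` (the median of the
#' logit-normal); `sigma_lambda` controls how closely the prior approximates
#' a discrete spike-and-slab (larger is closer).
#'
#' Supply at most one of `mu_lambda` and `a`; the other is derived. The
#' defaults are `tau = 5`, `sigma_lambda = 10` and `a = 0.5` (i.e.
#' `mu_lambda = 0`).
#'
#' @param tau Positive slab standard deviation.
#' @param sigma_lambda Positive logit-normal scale.
#' @param mu_lambda Real location of the logit-normal on the logit scale.
#' @param a Prior inclusion probability in (0, 1); alternative to
#'   `mu_lambda`.
#' @return An object of class `lncass_hyper` with fields `tau`,
#'   `mu_lambda`, `sigma_lambda`, `a`.
#' @examples
#' lncass_hyper()                  # tau = 5, sigma_lambda = 10, a = 0.5
#' lncass_hyper(a = 0.1)           # mu_lambda = logit(0.1)
#' @export
lncass_hyper <- function(tau = 5, sigma_lambda = 10, mu_lambda = NULL, a = NULL) {
  stopifnot(is.numeric(tau), length(tau) == 1, is.finite(tau), tau > 0)
  stopifnot(is.numeric(sigma_lambda), length(sigma_lambda) == 1,
            is.finite(sigma_lambda), sigma_lambda > 0)
  if (!is.null(mu_lambda) && !is.null(a)) {
    if (abs(sigm(mu_lambda) - a) > 1e-12)
      stop("supply only one of `mu_lambda` and `a` (given values disagree)")
  }
  if (is.null(mu_lambda) && is.null(a)) {
    mu_lambda <- 0
  } else if (is.null(mu_lambda)) {
    stopifnot(is.numeric(a), length(a) == 1, a > 0, a < 1)
    mu_lambda <- logit(a)
  }
  stopifnot(is.numeric(mu_lambda), length(mu_lambda) == 1, is.finite(mu_lambda))
  structure(
    list(tau = tau, mu_lambda = mu_lambda, sigma_lambda = sigma_lambda,
         a = sigm(mu_lambda)),
    class = "lncass_hyper"
  )
}

#' @export
print.lncass_hyper <- function(x, ...) {
  cat("LN-CASS hyperparameters\n")
  cat(sprintf("  tau (slab sd)        : %g\n", x$tau))
  cat(sprintf("  mu_lambda            : %g\n", x$mu_lambda))
  cat(sprintf("  sigma_lambda         : %g\n", x$sigma_lambda))
  cat(sprintf("  a (prior P(include)) : %g\n", x$a))
  invisible(x)
}

#' Serialize / restore hyperparameters as a flat key-value list
#'
#' @param hyper An `lncass_hyper` object.
#' @return Named list with keys `tau`, `sigma_lambda`, `mu_lambda`.
#' @export
hyper_to_config <- function(hyper) {
  stopifnot(inherits(hyper, "lncass_hyper"))
  list(tau = hyper$tau, sigma_lambda = hyper$sigma_lambda,
       mu_lambda = hyper$mu_lambda)
}

#' @rdname hyper_to_config
#' @param config Named list with `tau`, `sigma_lambda` and exactly one of
#'   `mu_lambda` / `a`.
#' @export
hyper_from_config <- function(config) {
  if (!is.null(config$mu_lambda) && !is.null(config$a))
    stop("config must contain exactly one of `mu_lambda` and `a`")
  lncass_hyper(
    tau = if (is.null(config$tau)) 5 else as.numeric(config$tau),
    sigma_lambda = if (is.null(config$sigma_lambda)) 10 else as.numeric(config$sigma_lambda),
    mu_lambda = if (is.null(config$mu_lambda)) NULL else as.numeric(config$mu_lambda),
    a = if (is.null(config$a)) NULL else as.numeric(config$a)
  )
}

#' Logit-normal density
#'
#' Density at `x` of `sigm(N(mu, sigma^2))`, i.e. the normal density at
#' `logit(x)` divided by `x * (1 - x)`. With `sigma` large this is a
#' U-shaped distribution on (0, 1) that concentrates near the endpoints,
#' which is what makes it a continuous stand-in for a Bernoulli inclusion
#' indicator.
#'
#' @param x Numeric vector strictly inside (0, 1).
#' @param mu Location on the logit scale.
#' @param sigma Positive scale on the logit scale.
#' @return Density values.
#' @export
dlogitnorm <- function(x, mu = 0, sigma = 1) {
  stopifnot(is.numeric(x), sigma > 0)
  if (any(x <= 0 | x >= 1)) stop("dlogitnorm: x must lie strictly in (0, 1)")
  stats::dnorm(logit(x), mean = mu, sd = sigma) / (x * (1 - x))
}

#' Sample from the logit-normal distribution
#'
#' Draws are the sigmoid of normal draws, which is the property that lets
#' LN-CASS models be written entirely in terms of (conditionally) standard
#' normal latents.
#'
#' @param n Number of draws (>= 1).
#' @param mu,sigma Logit-scale location and scale.
#' @param seed Optional integer seed for reproducibility.
#' @return `n` values in (0, 1).
#' @export
rlogitnorm <- function(n, mu = 0, sigma = 1, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1, sigma > 0)
  if (!is.null(seed)) set.seed(seed)
  # guard against floating saturation to exactly 0/1 at large sigma
  .clamp_unit(sigm(stats::rnorm(n, mean = mu, sd = sigma)))
}

#' LN-CASS coefficient map
#'
#' The deterministic map from a standard-normal latent `z` and an inclusion
#' weight `lambda` to a regression coefficient: `beta = tau * lambda * z`.
#' `lambda = 0` excludes the coefficient exactly; `lambda = 1` leaves the
#' full `N(0, tau^2)` slab.
#'
#' @param z Numeric latent(s).
#' @param lambda Inclusion weight(s) in `[0, 1]`.
#' @param hyper `lncass_hyper` object (only `tau` is used).
#' @return `tau * lambda * z`, recycled elementwise.
#' @export
lncass_coefficient <- function(z, lambda, hyper = lncass_hyper()) {
  stopifnot(inherits(hyper, "lncass_hyper"),
            all(lambda >= 0), all(lambda <= 1))
  hyper$tau * lambda * z
}

#' Joint prior draws of (lambda, beta) under the flat LN-CASS prior
#'
#' Simulates `n_draws` independent prior draws of a length-`p` inclusion
#' vector `lambda` (marginally logit-normal) and coefficient vector
#' `beta = tau * lambda * z` with `z` standard normal. Useful for prior
#' predictive checks and for validating the MCMC sampler against direct
#' simulation.
#'
#' @param hyper `lncass_hyper` object.
#' @param p Number of coefficients per draw (>= 1).
#' @param n_draws Number of joint draws (>= 1).
#' @param seed Optional integer seed.
#' @return List with `lambda` and `beta`, each an `n_draws x p` matrix.
#' @export
sample_lncass_prior <- function(hyper = lncass_hyper(), p = 1, n_draws = 1000,
                                seed = NULL) {
  stopifnot(inherits(hyper, "lncass_hyper"), p >= 1, n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  eta <- matrix(stats::rnorm(n_draws * p, hyper$mu_lambda, hyper$sigma_lambda),
                n_draws, p)
  z <- matrix(stats::rnorm(n_draws * p), n_draws, p)
  lambda <- .clamp_unit(sigm(eta))   # guard floating saturation to 0/1
  list(lambda = lambda, beta = hyper$tau * lambda * z)
}
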