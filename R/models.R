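# Shared machinery for LN-CASS model specifications.
#
# A model spec bundles a joint log-density over a flat vector of latents,
# its analytic gradient (used by the HMC sampler and checkable against
# finite differences), and the deterministic map from latents to regression
# coefficients. All stochastic latents are a priori (conditionally) standard
# normal: inclusion weights are represented by their non-centred logits
# eta = mu_lambda + sigma_lambda * u with u ~ N(0, 1), and lambda = sigm(eta).

# sum of standard-normal log densities (constant kept so log-density
# values are comparable across nested variants)
.lp_std_normal <- function(x) -0.5 * sum(x * x) - 0.918938533204672742 * length(x)

# unchecked sigmoid for sampler-hot paths (sigm() validates its input)
.sigm_fast <- function(x) {
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

# stable log(1 + exp(x))
.log1pexp <- function(x) {
  out <- x
  sm <- x < 30
  out[sm] <- log1p(exp(x[sm]))
  out[!sm] <- x[!sm] + exp(-x[!sm])
  out
}

.INTERCEPT_SD <- 10   # vague normal prior on beta0
.NOISE_SD_HN <- 5     # half-normal scale for the gaussian noise sd

.new_model_spec <- function(variant, data, hyper, latent_names, index,
                            lp_grad, coefficient_map, derive,
                            log_likelihood, extra = list()) {
  d <- length(latent_names)
  spec <- c(list(
    variant = variant, family = data$family, data = data, hyper = hyper,
    d = d, latent_names = latent_names, index = index,
    lp_grad = lp_grad,
    log_density = function(theta) lp_grad(theta, want_grad = FALSE)$lp,
    grad = function(theta) lp_grad(theta, want_grad = TRUE)$grad,
    coefficient_map = coefficient_map, derive = derive,
    log_likelihood = log_likelihood,
    init = function() {
      th <- stats::rnorm(d, 0, 0.2)
      names(th) <- latent_names
      th
    }
  ), extra)
  class(spec) <- "lncass_model"
  spec
}

#' @export
print.lncass_model <- function(x, ...) {
  cat(sprintf("<lncass_model> variant = %s, family = %s, %d latent parameters\n",
              x$variant, x$family, x$d))
  invisible(x)
}

# residual-scale gradient of the log-likelihood wrt the linear predictor,
# plus the log-likelihood itself
.lik_parts <- function(family, y, mu, sigma = NULL) {
  if (family == "gaussian") {
    res <- y - mu
    list(ll = -0.918938533204672742 * length(y) - length(y) * log(sigma) -
           0.5 * sum(res * res) / sigma^2,
         r = res / sigma^2)
  } else {
    list(ll = sum(y * mu - .log1pexp(mu)),
         r = y - .sigm_fast(mu))
  }
}

.prior_beta0 <- function(b0) stats::dnorm(b0, 0, .INTERCEPT_SD, log = TRUE)
.prior_sigma <- function(s) {
  # half-normal(0, .NOISE_SD_HN) on sigma = exp(s), with log-Jacobian s
  sigma <- exp(s)
  log(2) + stats::dnorm(sigma, 0, .NOISE_SD_HN, log = TRUE) + s
}

#' Build a flat LN-CASS regression model
#'
#' Linear (gaussian) or logistic (binomial) regression with an independent
#' LN-CASS prior `beta_j = tau * lambda_j * z_j` on every coefficient. The
#' intercept gets a vague `N(0, 10^2)` prior; the gaussian noise sd gets a
#' half-normal(0, 5) prior and is sampled on the log scale.
#'
#' @param data `lncass_dataset`.
#' @param hyper `lncass_hyper`.
#' @param prior_only If `TRUE`, drop the likelihood term (prior sampling).
#' @param fix_lambda Optional scalar or length-p vector freezing every
#'   inclusion weight at a fixed value (the `u` latents are removed); used
#'   for conjugate checks and ridge-like fits.
#' @param fix_sigma Optional fixed gaussian noise sd (removes the noise-sd
#'   latent).
#' @return `lncass_model`.
#' @export
build_flat_model <- function(data, hyper = lncass_hyper(), prior_only = FALSE,
                             fix_lambda = NULL, fix_sigma = NULL) {
  stopifnot(inherits(data, "lncass_dataset"), inherits(hyper, "lncass_hyper"))
  if (!data$family %in% c("gaussian", "binomial"))
    stop("family must be gaussian or binomial")
  X <- data$X; y <- data$y; n <- data$n; p <- data$p
  tau <- hyper$tau; mu_l <- hyper$mu_lambda; sig_l <- hyper$sigma_lambda
  lw <- if (prior_only) 0 else 1
  has_sigma <- data$family == "gaussian" && is.null(fix_sigma)
  free_lambda <- is.null(fix_lambda)
  if (!free_lambda) fix_lambda <- rep_len(as.numeric(fix_lambda), p)

  nm <- "beta0"
  idx <- list(beta0 = 1L)
  off <- 1L
  if (has_sigma) { idx$log_sigma <- off + 1L; nm <- c(nm, "log_sigma_eps"); off <- off + 1L }
  idx$z <- off + seq_len(p); nm <- c(nm, paste0("z.", data$predictor_names)); off <- off + p
  if (free_lambda) { idx$u <- off + seq_len(p); nm <- c(nm, paste0("u.", data$predictor_names)) }

  unpack <- function(theta) {
    lambda <- if (free_lambda) .sigm_fast(mu_l + sig_l * theta[idx$u]) else fix_lambda
    z <- theta[idx$z]
    sigma <- if (data$family != "gaussian") NULL
             else if (has_sigma) exp(theta[idx$log_sigma]) else fix_sigma
    list(beta0 = theta[idx$beta0], z = z, lambda = lambda,
         beta = tau * lambda * z, sigma = sigma)
  }

  lp_grad <- function(theta, want_grad = TRUE) {
    st <- unpack(theta)
    mu <- st$beta0 + drop(X %*% st$beta)
    lik <- .lik_parts(data$family, y, mu, st$sigma)
    lp <- lw * lik$ll + .prior_beta0(st$beta0) +
      .lp_std_normal(theta[idx$z])
    if (free_lambda) lp <- lp + .lp_std_normal(theta[idx$u])
    if (has_sigma) lp <- lp + .prior_sigma(theta[idx$log_sigma])
    if (!want_grad) return(list(lp = lp))
    r <- lw * lik$r
    g <- drop(crossprod(X, r))
    grad <- numeric(length(theta))
    grad[idx$beta0] <- sum(r) - st$beta0 / .INTERCEPT_SD^2
    grad[idx$z] <- g * tau * st$lambda - st$z
    if (free_lambda)
      grad[idx$u] <- g * tau * st$z * st$lambda * (1 - st$lambda) * sig_l - theta[idx$u]
    if (has_sigma) {
      s <- theta[idx$log_sigma]
      grad[idx$log_sigma] <- lw * (-n + sum((y - mu)^2) / st$sigma^2) -
        st$sigma^2 / .NOISE_SD_HN^2 + 1
    }
    list(lp = lp, grad = grad)
  }

  coefficient_map <- function(theta) {
    st <- unpack(theta)
    out <- list(beta0 = unname(st$beta0), beta = unname(st$beta),
                lambda = unname(st$lambda))
    if (data$family == "gaussian") out$sigma_eps <- unname(st$sigma)
    out
  }

  derive <- function(theta_mat) {
    lambda <- if (free_lambda) .sigm_fast(mu_l + sig_l * theta_mat[, idx$u, drop = FALSE])
              else matrix(fix_lambda, nrow(theta_mat), p, byrow = TRUE)
    beta <- tau * lambda * theta_mat[, idx$z, drop = FALSE]
    colnames(beta) <- colnames(lambda) <- data$predictor_names
    out <- list(beta0 = theta_mat[, idx$beta0], beta = beta, lambda = lambda)
    if (data$family == "gaussian")
      out$sigma_eps <- if (has_sigma) exp(theta_mat[, idx$log_sigma])
                       else rep(fix_sigma, nrow(theta_mat))
    out
  }

  log_likelihood <- function(theta) {
    st <- unpack(theta)
    .lik_parts(data$family, y, st$beta0 + drop(X %*% st$beta), st$sigma)$ll
  }

  .new_model_spec("flat", data, hyper, nm, idx, lp_grad, coefficient_map,
                  derive, log_likelihood)
}

#' Build a grouped LN-CASS regression model
#'
#' Hierarchical complexity ladder over pre-specified predictor groups:
#' exclude the whole group first, then include it with one shared
#' coefficient, and only then let members deviate. Coefficients are
#' `beta_gj = tau * lambda_g * (z_g + lambda_gj * w_gj)` where `lambda_g`
#' is the group inclusion weight, `z_g` the shared effect,
#' `lambda_gj` the member inclusion weight and `w_gj` the member deviation;
#' each successive rung multiplies in a fresh logit-normal weight.
#'
#' @param data `lncass_dataset`.
#' @param groups `lncass_groups` consistent with `ncol(X)`.
#' @param hyper `lncass_hyper`.
#' @param prior_only Drop the likelihood term if `TRUE`.
#' @param fix_lambda_group Optional fixed value for every group inclusion
#'   weight (removes those latents).
#' @param fix_lambda_member Optional fixed value for every member inclusion
#'   weight (removes those latents; fixing at 0 also removes the then-inert
#'   deviation latents, leaving the shared-coefficient rung only -- with
#'   singleton groups this is exactly the flat model).
#' @return `lncass_model`.
#' @export
build_grouped_model <- function(data, groups, hyper = lncass_hyper(),
                                prior_only = FALSE, fix_lambda_group = NULL,
                                fix_lambda_member = NULL) {
  stopifnot(inherits(data, "lncass_dataset"), inherits(groups, "lncass_groups"),
            inherits(hyper, "lncass_hyper"))
  if (length(groups$assignment) != data$p)
    stop("group assignment length must equal the number of predictors")
  X <- data$X; y <- data$y; n <- data$n; p <- data$p
  G <- length(groups$groups)
  gi <- match(groups$assignment, groups$groups)   # group index per predictor
  agg <- matrix(0, G, p)                          # G x p member-sum operator
  agg[cbind(gi, seq_len(p))] <- 1
  tau <- hyper$tau; mu_l <- hyper$mu_lambda; sig_l <- hyper$sigma_lambda
  lw <- if (prior_only) 0 else 1
  has_sigma <- data$family == "gaussian"
  free_lg <- is.null(fix_lambda_group)
  if (!free_lg) fix_lambda_group <- rep_len(as.numeric(fix_lambda_group), G)
  free_lm <- is.null(fix_lambda_member)
  if (!free_lm) fix_lambda_member <- rep_len(as.numeric(fix_lambda_member), p)
  has_w <- free_lm || any(fix_lambda_member != 0)

  nm <- "beta0"; idx <- list(beta0 = 1L); off <- 1L
  if (has_sigma) { idx$log_sigma <- off + 1L; nm <- c(nm, "log_sigma_eps"); off <- off + 1L }
  idx$z_group <- off + seq_len(G); nm <- c(nm, paste0("z_group.", groups$groups)); off <- off + G
  if (free_lg) {
    idx$u_group <- off + seq_len(G); nm <- c(nm, paste0("u_group.", groups$groups)); off <- off + G
  }
  if (has_w) {
    idx$w <- off + seq_len(p); nm <- c(nm, paste0("w.", data$predictor_names)); off <- off + p
  }
  if (free_lm) {
    idx$u_member <- off + seq_len(p)
    nm <- c(nm, paste0("u_member.", data$predictor_names))
  }

  unpack <- function(theta) {
    lam_g <- if (free_lg) .sigm_fast(mu_l + sig_l * theta[idx$u_group]) else fix_lambda_group
    lam_j <- if (free_lm) .sigm_fast(mu_l + sig_l * theta[idx$u_member]) else fix_lambda_member
    zg <- theta[idx$z_group]
    w <- if (has_w) theta[idx$w] else numeric(p)
    beta <- tau * lam_g[gi] * (zg[gi] + lam_j * w)
    sigma <- if (has_sigma) exp(theta[idx$log_sigma]) else NULL
    list(beta0 = theta[idx$beta0], zg = zg, w = w, lam_g = lam_g,
         lam_j = lam_j, beta = beta, sigma = sigma)
  }

  lp_grad <- function(theta, want_grad = TRUE) {
    st <- unpack(theta)
    mu <- st$beta0 + drop(X %*% st$beta)
    lik <- .lik_parts(data$family, y, mu, st$sigma)
    lp <- lw * lik$ll + .prior_beta0(st$beta0) +
      .lp_std_normal(theta[idx$z_group])
    if (has_w) lp <- lp + .lp_std_normal(theta[idx$w])
    if (free_lm) lp <- lp + .lp_std_normal(theta[idx$u_member])
    if (free_lg) lp <- lp + .lp_std_normal(theta[idx$u_group])
    if (has_sigma) lp <- lp + .prior_sigma(theta[idx$log_sigma])
    if (!want_grad) return(list(lp = lp))
    r <- lw * lik$r
    g <- drop(crossprod(X, r))
    lgj <- st$lam_g[gi]
    grad <- numeric(length(theta))
    grad[idx$beta0] <- sum(r) - st$beta0 / .INTERCEPT_SD^2
    grad[idx$z_group] <- drop(agg %*% (g * tau * lgj)) - st$zg
    if (free_lg) {
      dlg <- st$lam_g * (1 - st$lam_g) * sig_l
      grad[idx$u_group] <- drop(agg %*%
        (g * tau * (st$zg[gi] + st$lam_j * st$w))) * dlg - theta[idx$u_group]
    }
    if (has_w) grad[idx$w] <- g * tau * lgj * st$lam_j - st$w
    if (free_lm)
      grad[idx$u_member] <- g * tau * lgj * st$w *
        st$lam_j * (1 - st$lam_j) * sig_l - theta[idx$u_member]
    if (has_sigma)
      grad[idx$log_sigma] <- lw * (-n + sum((y - mu)^2) / st$sigma^2) -
        st$sigma^2 / .NOISE_SD_HN^2 + 1
    list(lp = lp, grad = grad)
  }

  coefficient_map <- function(theta) {
    st <- unpack(theta)
    out <- list(beta0 = unname(st$beta0), beta = unname(st$beta),
                lambda = unname(st$lam_g[gi]),          # top layer, per predictor
                lambda_group = unname(st$lam_g),
                lambda_member = unname(st$lam_j))
    if (has_sigma) out$sigma_eps <- unname(st$sigma)
    out
  }

  derive <- function(theta_mat) {
    lam_g <- if (free_lg) .sigm_fast(mu_l + sig_l * theta_mat[, idx$u_group, drop = FALSE])
             else matrix(fix_lambda_group, nrow(theta_mat), G, byrow = TRUE)
    lam_j <- if (free_lm)
      .sigm_fast(mu_l + sig_l * theta_mat[, idx$u_member, drop = FALSE])
    else matrix(fix_lambda_member, nrow(theta_mat), p, byrow = TRUE)
    zg <- theta_mat[, idx$z_group, drop = FALSE]
    w <- if (has_w) theta_mat[, idx$w, drop = FALSE]
         else matrix(0, nrow(theta_mat), p)
    beta <- tau * lam_g[, gi, drop = FALSE] *
      (zg[, gi, drop = FALSE] + lam_j * w)
    colnames(beta) <- data$predictor_names
    lambda <- lam_g[, gi, drop = FALSE]
    colnames(lambda) <- data$predictor_names
    colnames(lam_g) <- groups$groups
    colnames(lam_j) <- data$predictor_names
    out <- list(beta0 = theta_mat[, idx$beta0], beta = beta, lambda = lambda,
                lambda_group = lam_g, lambda_member = lam_j)
    if (has_sigma) out$sigma_eps <- exp(theta_mat[, idx$log_sigma])
    out
  }

  log_likelihood <- function(theta) {
    st <- unpack(theta)
    .lik_parts(data$family, y, st$beta0 + drop(X %*% st$beta), st$sigma)$ll
  }

  .new_model_spec("grouped", data, hyper, nm, idx, lp_grad, coefficient_map,
                  derive, log_likelihood, extra = list(groups = groups))
}
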