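# Hierarchical LN-CASS generalized additive model (logit link).
#
# Each covariate effect is a piecewise-linear function built from an
# identity (linear) column plus hinge columns max(0, x - knot). The
# complexity ladder per covariate is: removed entirely (lambda_i = 0) ->
# purely linear (nonlinearity gate lambda_i^nl = 0) -> free piecewise-linear
# effect, with each rung gated by a fresh logit-normal weight multiplied
# onto the previous one.

#' Piecewise-linear GAM basis for one covariate
#'
#' Column 1 is the identity `x`; columns `1 + k` are hinge functions
#' `max(0, x - knot_k)`.
#'
#' @param x Values in `[0, 1]` (preprocessing is expected to have scaled
#'   covariates to the unit interval).
#' @param config `lncass_gam_config`.
#' @return `length(x) x (1 + n_knots)` matrix.
#' @export
build_gam_basis <- function(x, config = gam_config()) {
  stopifnot(inherits(config, "lncass_gam_config"), is.numeric(x))
  bad <- which(x < 0 | x > 1)
  if (length(bad))
    stop("covariate values outside [0, 1] at index ",
         paste(utils::head(bad, 5), collapse = ", "))
  K <- config$n_knots
  B <- matrix(0, length(x), 1 + K)
  B[, 1] <- x
  for (k in seq_len(K)) B[, 1 + k] <- pmax(0, x - config$knot_positions[k])
  colnames(B) <- c("lin", if (K > 0) paste0("k", seq_len(K)))
  B
}

#' Build the hierarchical LN-CASS GAM (binomial family)
#'
#' Per covariate `i`: inclusion weight `lambda_i`, linear latent `z_i`,
#' nonlinearity gate `lambda_i^nl`, and per-knot latents `w_ik`. The linear
#' coefficient is `tau * lambda_i * z_i`; the knot-k coefficient is
#' `tau * lambda_i * lambda_i^nl * w_ik`. The linear predictor is
#' `beta0 + sum_i f_i(x_i)` with a logit link.
#'
#' @param data `lncass_dataset` with binomial family and columns in `[0,1]`.
#' @param hyper `lncass_hyper`.
#' @param config `lncass_gam_config`.
#' @param prior_only Drop the likelihood term if `TRUE`.
#' @return `lncass_model`.
#' @export
build_hierarchical_gam <- function(data, hyper = lncass_hyper(),
                                   config = gam_config(), prior_only = FALSE) {
  stopifnot(inherits(data, "lncass_dataset"), inherits(hyper, "lncass_hyper"),
            inherits(config, "lncass_gam_config"))
  if (data$family != "binomial")
    stop("the hierarchical GAM supports the binomial (logit-link) family only")
  p <- data$p; n <- data$n; K <- config$n_knots
  y <- data$y
  # full basis: per covariate a block of (1 + K) columns
  B <- do.call(cbind, lapply(seq_len(p), function(i)
    build_gam_basis(data$X[, i], config)))
  lin_col <- (seq_len(p) - 1L) * (1L + K) + 1L
  knot_col <- if (K > 0) t(vapply(seq_len(p), function(i) lin_col[i] + seq_len(K),
                                  integer(K))) else NULL
  if (K == 1) knot_col <- matrix(knot_col, p, 1)
  tau <- hyper$tau; mu_l <- hyper$mu_lambda; sig_l <- hyper$sigma_lambda
  lw <- if (prior_only) 0 else 1
  pn <- data$predictor_names

  nm <- "beta0"; idx <- list(beta0 = 1L); off <- 1L
  idx$z <- off + seq_len(p); nm <- c(nm, paste0("z.", pn)); off <- off + p
  idx$u <- off + seq_len(p); nm <- c(nm, paste0("u.", pn)); off <- off + p
  if (K > 0) {
    idx$u_nl <- off + seq_len(p); nm <- c(nm, paste0("u_nl.", pn)); off <- off + p
    idx$w <- off + seq_len(p * K)    # w[(i-1)*K + k] is covariate i, knot k
    nm <- c(nm, as.vector(t(outer(pn, seq_len(K),
                                  function(a, k) paste0("w.", a, ".k", k)))))
  }

  # coefficient vector in basis-column order from a latent vector
  coef_from <- function(theta) {
    lam <- .sigm_fast(mu_l + sig_l * theta[idx$u])
    z <- theta[idx$z]
    cf <- numeric(p * (1 + K))
    cf[lin_col] <- tau * lam * z
    lamnl <- NULL; wmat <- NULL
    if (K > 0) {
      lamnl <- .sigm_fast(mu_l + sig_l * theta[idx$u_nl])
      wmat <- matrix(theta[idx$w], p, K, byrow = TRUE)
      cf[t(knot_col)] <- t(tau * lam * lamnl * wmat)  # fill by covariate rows
    }
    list(cf = cf, lam = lam, lamnl = lamnl, z = z, wmat = wmat)
  }

  lp_grad <- function(theta, want_grad = TRUE) {
    st <- coef_from(theta)
    mu <- theta[idx$beta0] + drop(B %*% st$cf)
    lik <- .lik_parts("binomial", y, mu)
    lp <- lw * lik$ll + .prior_beta0(theta[idx$beta0]) +
      .lp_std_normal(theta[idx$z]) +
      .lp_std_normal(theta[idx$u])
    if (K > 0)
      lp <- lp + .lp_std_normal(theta[idx$u_nl]) +
        .lp_std_normal(theta[idx$w])
    if (!want_grad) return(list(lp = lp))
    r <- lw * lik$r
    g <- drop(crossprod(B, r))
    glin <- g[lin_col]
    grad <- numeric(length(theta))
    grad[idx$beta0] <- sum(r) - theta[idx$beta0] / .INTERCEPT_SD^2
    grad[idx$z] <- glin * tau * st$lam - st$z
    dlam <- st$lam * (1 - st$lam) * sig_l
    if (K > 0) {
      gknot <- matrix(g[t(knot_col)], p, K, byrow = TRUE)
      gw <- rowSums(gknot * st$wmat)
      grad[idx$u] <- tau * dlam * (glin * st$z + st$lamnl * gw) - theta[idx$u]
      grad[idx$u_nl] <- tau * st$lam * st$lamnl * (1 - st$lamnl) * sig_l * gw -
        theta[idx$u_nl]
      grad[idx$w] <- as.vector(t(gknot * tau * st$lam * st$lamnl)) - theta[idx$w]
    } else {
      grad[idx$u] <- tau * dlam * glin * st$z - theta[idx$u]
    }
    list(lp = lp, grad = grad)
  }

  coefficient_map <- function(theta) {
    st <- coef_from(theta)
    out <- list(beta0 = unname(theta[idx$beta0]), beta = st$cf,
                lambda = unname(st$lam))
    if (K > 0) out$lambda_nl <- unname(st$lamnl)
    out
  }

  derive <- function(theta_mat) {
    nd <- nrow(theta_mat)
    lam <- .sigm_fast(mu_l + sig_l * theta_mat[, idx$u, drop = FALSE])
    z <- theta_mat[, idx$z, drop = FALSE]
    beta <- matrix(0, nd, p * (1 + K))
    beta[, lin_col] <- tau * lam * z
    out <- list(beta0 = theta_mat[, idx$beta0], lambda = lam)
    colnames(out$lambda) <- pn
    if (K > 0) {
      lamnl <- .sigm_fast(mu_l + sig_l * theta_mat[, idx$u_nl, drop = FALSE])
      colnames(lamnl) <- pn
      out$lambda_nl <- lamnl
      for (i in seq_len(p)) {
        wi <- theta_mat[, idx$w[(i - 1L) * K + seq_len(K)], drop = FALSE]
        beta[, knot_col[i, ]] <- tau * lam[, i] * lamnl[, i] * wi
      }
    }
    colnames(beta) <- as.vector(vapply(seq_len(p), function(i)
      paste0(pn[i], ".", c("lin", if (K > 0) paste0("k", seq_len(K)))),
      character(1 + K)))
    out$beta <- beta
    out
  }

  log_likelihood <- function(theta) {
    st <- coef_from(theta)
    .lik_parts("binomial", y, theta[idx$beta0] + drop(B %*% st$cf))$ll
  }

  .new_model_spec("gam", data, hyper, nm, idx, lp_grad, coefficient_map,
                  derive, log_likelihood,
                  extra = list(gam = list(config = config, basis = B,
                                          lin_col = lin_col, knot_col = knot_col)))
}

#' Posterior effect curves from a fitted hierarchical GAM
#'
#' For each covariate, the pointwise posterior mean and central 90% band of
#' its effect function `f_i` evaluated on a grid, computed exactly from the
#' stored basis-coefficient draws (no smoothing).
#'
#' @param samples `lncass_samples` from a GAM model.
#' @param config `lncass_gam_config` used for the fit.
#' @param grid Evaluation points in `[0, 1]`.
#' @return Data frame with columns `predictor`, `x`, `mean`, `lower`,
#'   `upper` (5% and 95% posterior quantiles).
#' @export
extract_effect_curves <- function(samples, config, grid = seq(0, 1, length.out = 50)) {
  stopifnot(inherits(samples, "lncass_samples"))
  model <- samples$model
  if (model$variant != "gam")
    stop("effect curves are defined for GAM fits only")
  K <- config$n_knots
  p <- model$data$p
  beta <- samples$beta                       # (total draws) x p*(1+K)
  if (ncol(beta) != p * (1 + K))
    stop("sample/config shape mismatch: expected ", p * (1 + K),
         " basis coefficients, found ", ncol(beta))
  Bg <- build_gam_basis(grid, config)        # |grid| x (1+K)
  out <- vector("list", p)
  for (i in seq_len(p)) {
    cols <- (i - 1L) * (1L + K) + seq_len(1L + K)
    curves <- beta[, cols, drop = FALSE] %*% t(Bg)   # draws x |grid|
    out[[i]] <- data.frame(
      predictor = model$data$predictor_names[i],
      x = grid,
      mean = colMeans(curves),
      lower = apply(curves, 2, stats::quantile, probs = 0.05, names = FALSE),
      upper = apply(curves, 2, stats::quantile, probs = 0.95, names = FALSE)
    )
  }
  do.call(rbind, out)
}
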