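#' Run MCMC over an LN-CASS model
#'
#' Samples the model's joint posterior with the package's adaptive
#' Hamiltonian Monte Carlo sampler (dual-averaging step-size adaptation,
#' diagonal mass matrix estimated during warmup, jittered trajectory
#' lengths). Chains are seeded deterministically from `seed`, so runs are
#' reproducible. If a chain fails to initialise (non-finite log density),
#' it is re-seeded and retried up to 3 times before erroring.
#'
#' @param model `lncass_model`.
#' @param chains Number of chains (>= 1).
#' @param warmup Warmup (adaptation) iterations per chain, discarded.
#' @param draws Post-warmup draws per chain.
#' @param seed Integer seed.
#' @param control Optional list overriding sampler settings
#'   (`target_accept`, `traj_length`, `max_leapfrog`, ...).
#' @return `lncass_samples`: latent draws (`theta`, an
#'   `chains x draws x d` array), flattened derived draws (`beta`,
#'   `lambda`, and further layers as matrices with one row per draw), and
#'   metadata.
#' @export
run_mcmc <- function(model, chains = 4, warmup = 1000, draws = 1000,
                     seed = 1, control = list()) {
  stopifnot(inherits(model, "lncass_model"), chains >= 1, draws >= 1,
            warmup >= 10)
  d <- model$d
  theta <- array(NA_real_, c(chains, draws, d),
                 dimnames = list(NULL, NULL, model$latent_names))
  diag_info <- vector("list", chains)
  for (ch in seq_len(chains)) {
    res <- NULL
    for (attempt in 0:3) {
      set.seed((seed + 7919L * ch + 104729L * attempt) %% .Machine$integer.max)
      init <- model$init()
      res <- tryCatch(
        .hmc_chain(model$lp_grad, init, warmup, draws, control),
        error = function(e) e
      )
      if (!inherits(res, "error")) break
    }
    if (inherits(res, "error"))
      stop("chain ", ch, " failed after retries: ", conditionMessage(res))
    theta[ch, , ] <- res$draws
    diag_info[[ch]] <- res[c("accept_rate", "n_divergent", "step_size")]
  }
  # flatten chain-by-chain so rows 1..draws are chain 1, etc.
  flat <- do.call(rbind, lapply(seq_len(chains), function(ch) theta[ch, , ]))
  colnames(flat) <- model$latent_names
  derived <- model$derive(flat)
  structure(
    c(list(theta = theta, theta_flat = flat, model = model,
           chains = chains, draws = draws, warmup = warmup, seed = seed,
           variant = model$variant, sampler = diag_info),
      derived),
    class = "lncass_samples"
  )
}

#' @export
print.lncass_samples <- function(x, ...) {
  cat(sprintf("<lncass_samples> %s model: %d chains x %d draws, %d latent parameters\n",
              x$variant, x$chains, x$draws, x$model$d))
  div <- sum(vapply(x$sampler, function(s) s$n_divergent, numeric(1)))
  if (div > 0) cat(sprintf("  %d divergent transitions\n", div))
  invisible(x)
}

#' Split Gelman-Rubin statistic
#'
#' Potential scale reduction computed after splitting each chain in half
#' (so intra-chain drift also inflates the statistic). Values near 1
#' indicate the chains agree.
#'
#' @param x `lncass_samples`, or a `chains x draws x parameters` array
#'   (a `chains x draws` matrix is treated as a single parameter).
#' @return Named vector of R-hat values, one per scalar parameter.
#' @export
gelman_rubin <- function(x) {
  arr <- if (inherits(x, "lncass_samples")) x$theta else x
  if (is.matrix(arr)) arr <- array(arr, c(dim(arr), 1L))
  stopifnot(length(dim(arr)) == 3)
  chains <- dim(arr)[1]; n <- dim(arr)[2]; d <- dim(arr)[3]
  if (chains < 2)
    stop("split R-hat needs at least 2 chains; run more chains")
  if (n < 4) stop("need at least 4 draws per chain")
  half <- floor(n / 2)
  out <- vapply(seq_len(d), function(j) {
    halves <- vector("list", 2 * chains)
    for (ch in seq_len(chains)) {
      halves[[2 * ch - 1]] <- arr[ch, seq_len(half), j]
      halves[[2 * ch]] <- arr[ch, half + seq_len(half), j]
    }
    m <- length(halves)
    means <- vapply(halves, mean, numeric(1))
    vars <- vapply(halves, stats::var, numeric(1))
    W <- mean(vars)
    B <- half * stats::var(means)
    if (W == 0) return(if (B == 0) 1 else Inf)
    sqrt(((half - 1) / half * W + B / half) / W)
  }, numeric(1))
  names(out) <- dimnames(arr)[[3]]
  out
}

#' Posterior summary of an LN-CASS fit
#'
#' Per-coefficient posterior median, mean and central 90% interval
#' (computed on the derived coefficient draws, i.e. the coefficient map is
#' applied per draw before summarising), the per-predictor mean inclusion
#' weight (posterior mean of the top-layer lambda), and split R-hat per
#' latent parameter.
#'
#' @param samples `lncass_samples`.
#' @return `lncass_summary`: a list with `coefficients` (data frame),
#'   `inclusion` (data frame), `rhat` (named vector), `max_rhat`.
#' @export
summarize_posterior <- function(samples) {
  stopifnot(inherits(samples, "lncass_samples"))
  beta <- samples$beta
  coef_tab <- data.frame(
    parameter = colnames(beta),
    median = apply(beta, 2, stats::median),
    mean = colMeans(beta),
    lower90 = apply(beta, 2, stats::quantile, probs = 0.05, names = FALSE),
    upper90 = apply(beta, 2, stats::quantile, probs = 0.95, names = FALSE),
    row.names = NULL
  )
  incl <- data.frame(
    predictor = colnames(samples$lambda),
    inclusion = colMeans(samples$lambda),
    row.names = NULL
  )
  rhat <- if (samples$chains >= 2) gelman_rubin(samples) else
    stats::setNames(rep(NA_real_, samples$model$d), samples$model$latent_names)
  structure(
    list(coefficients = coef_tab, inclusion = incl, rhat = rhat,
         max_rhat = suppressWarnings(max(rhat)),
         beta0 = list(median = stats::median(samples$beta0),
                      mean = mean(samples$beta0)),
         variant = samples$variant),
    class = "lncass_summary"
  )
}

#' @export
print.lncass_summary <- function(x, ...) {
  cat(sprintf("<lncass_summary> %s model\n", x$variant))
  print(utils::head(x$coefficients, 10))
  if (nrow(x$coefficients) > 10) cat("  ...\n")
  cat(sprintf("max split R-hat: %.3f\n", x$max_rhat))
  invisible(x)
}

#' Hard selection of the top-k coefficients
#'
#' Indices of the `k` coefficients largest in absolute posterior median.
#' Ties are broken by lower index, so the selection is stable across runs.
#'
#' @param summary `lncass_summary` (or a numeric vector of medians).
#' @param k Number of predictors to keep, `1 <= k <= p`.
#' @return Integer vector of selected indices (unsorted by magnitude:
#'   returned in magnitude order, largest first).
#' @export
select_top_k <- function(summary, k) {
  med <- if (inherits(summary, "lncass_summary")) summary$coefficients$median
         else as.numeric(summary)
  p <- length(med)
  if (k < 1 || k > p) stop("k must be between 1 and ", p)
  ord <- order(-abs(med), seq_len(p))   # ties -> lower index first
  ord[seq_len(k)]
}

#' Export posterior draws / summaries to CSV
#'
#' The draws table is long format (`chain, draw, parameter, value`) at full
#' double precision, so it round-trips losslessly.
#'
#' @param samples `lncass_samples`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(samples, path) {
  stopifnot(inherits(samples, "lncass_samples"))
  th <- samples$theta
  long <- do.call(rbind, lapply(seq_len(samples$chains), function(ch) {
    m <- th[ch, , ]
    data.frame(chain = ch, draw = seq_len(nrow(m)),
               parameter = rep(colnames(samples$theta_flat), each = nrow(m)),
               value = as.vector(m))
  }))
  utils::write.csv(format(long, digits = 17, scientific = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_draws_csv
#' @param summary `lncass_summary`.
#' @export
write_summary_csv <- function(summary, path) {
  stopifnot(inherits(summary, "lncass_summary"))
  utils::write.csv(summary$coefficients, path, row.names = FALSE)
  invisible(path)
}

#' Read a draws CSV back into a chains x draws x parameters array
#'
#' @param path CSV written by [write_draws_csv()].
#' @return 3-d array (chain, draw, parameter).
#' @export
read_draws_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  params <- unique(long$parameter)
  chains <- max(long$chain); draws <- max(long$draw)
  arr <- array(NA_real_, c(chains, draws, length(params)),
               dimnames = list(NULL, NULL, params))
  for (j in seq_along(params)) {
    sub <- long[long$parameter == params[j], ]
    arr[cbind(sub$chain, sub$draw, j)] <- as.numeric(sub$value)
  }
  arr
}
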