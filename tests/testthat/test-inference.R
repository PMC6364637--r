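test_that("mcmc matches the conjugate normal posterior with inclusion frozen", {
  set.seed(41)
  n <- 40
  X <- matrix(rnorm(n), n, 1)
  y <- 0.5 + 1.2 * X[, 1] + rnorm(n)
  d <- regression_dataset(X, y, family = "gaussian")
  m <- build_flat_model(d, fix_lambda = 1, fix_sigma = 1)
  s <- run_mcmc(m, chains = 2, warmup = 500, draws = 1000, seed = 7)
  # closed-form posterior: prior beta0 ~ N(0, 100), beta ~ N(0, tau^2 = 25)
  A <- cbind(1, X)
  Pn <- diag(c(1 / 100, 1 / 25)) + crossprod(A)
  mu_post <- solve(Pn, crossprod(A, y))
  sd_post <- sqrt(diag(solve(Pn)))
  se <- batch_se(s$beta[, 1])
  expect_lt(abs(mean(s$beta) - mu_post[2]), 3 * se)
  expect_equal(sd(s$beta), sd_post[2], tolerance = 0.05)
  expect_lt(abs(mean(s$beta0) - mu_post[1]), 3 * batch_se(s$beta0))
})

test_that("sampling is deterministic under a fixed seed", {
  d <- tiny_gaussian(n = 20, p = 2, seed = 42, beta = c(1, 0))
  m <- build_flat_model(d)
  s1 <- run_mcmc(m, chains = 2, warmup = 200, draws = 100, seed = 3)
  s2 <- run_mcmc(m, chains = 2, warmup = 200, draws = 100, seed = 3)
  expect_identical(s1$theta, s2$theta)
  expect_identical(summarize_posterior(s1)$coefficients,
                   summarize_posterior(s2)$coefficients)
})

test_that("prior-only sampling recovers the prior inclusion median and quantiles", {
  d <- tiny_gaussian(n = 20, p = 2, seed = 43)
  hy <- lncass_hyper(a = 0.3, sigma_lambda = 5)
  m <- build_flat_model(d, hy, prior_only = TRUE, fix_sigma = 1)
  s <- run_mcmc(m, chains = 2, warmup = 500, draws = 2000, seed = 11)
  expect_lt(abs(median(s$lambda) - sigm(hy$mu_lambda)), 0.05)
  # marginal beta quantiles agree with direct prior simulation
  pr <- sample_lncass_prior(hy, p = 2, n_draws = 4000, seed = 12)
  qs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  expect_equal(quantile(s$beta, qs, names = FALSE),
               quantile(pr$beta, qs, names = FALSE), tolerance = 0.25)
  # exceedance of 1/2 is the normal CDF of the logit location
  expect_equal(mean(s$lambda > 0.5),
               pnorm(hy$mu_lambda / hy$sigma_lambda), tolerance = 0.05)
})

test_that("split R-hat is near 1 for iid chains and large for disjoint chains", {
  set.seed(44)
  draws <- rnorm(1000)
  arr <- array(NA_real_, c(2, 1000, 1))
  arr[1, , 1] <- draws
  arr[2, , 1] <- draws                      # exact copies
  expect_lte(gelman_rubin(arr)[1], 1.001)
  arr[1, , 1] <- rnorm(1000, 0, 1)
  arr[2, , 1] <- rnorm(1000, 10, 1)         # disjoint chains
  expect_gt(gelman_rubin(arr)[1], 2)
  expect_error(gelman_rubin(array(rnorm(100), c(1, 100, 1))), "2 chains")
})

test_that("split R-hat equals an independent textbook implementation", {
  # reference implementation written from the split-R-hat formula
  rhat_ref <- function(chains_mat) {    # draws x m matrix of half-chains
    m <- ncol(chains_mat); n <- nrow(chains_mat)
    W <- mean(apply(chains_mat, 2, var))
    B <- n * var(colMeans(chains_mat))
    sqrt(((n - 1) / n * W + B / n) / W)
  }
  set.seed(45)
  for (i in 1:10) {
    arr <- array(rnorm(4 * 500 * 2, sd = runif(1, 0.5, 3)), c(4, 500, 2))
    got <- gelman_rubin(arr)
    for (j in 1:2) {
      halves <- sapply(1:4, function(ch)
        cbind(arr[ch, 1:250, j], arr[ch, 251:500, j]))
      want <- rhat_ref(matrix(halves, nrow = 250))
      expect_equal(unname(got[j]), want, tolerance = 1e-10)
    }
  }
})

test_that("summaries are computed on per-draw mapped coefficients", {
  d <- tiny_gaussian(n = 25, p = 2, seed = 46, beta = c(2, 0))
  m <- build_flat_model(d)
  s <- run_mcmc(m, chains = 2, warmup = 300, draws = 300, seed = 9)
  su <- summarize_posterior(s)
  # median of mapped draws, not map of median latents
  expect_equal(su$coefficients$median, unname(apply(s$beta, 2, median)))
  hy <- lncass_hyper()
  mapped_median_latents <- hy$tau *
    sigm(hy$sigma_lambda * apply(s$theta_flat[, c("u.x1", "u.x2")], 2, median)) *
    apply(s$theta_flat[, c("z.x1", "z.x2")], 2, median)
  # the two orders of operation genuinely differ on these asymmetric draws
  expect_gt(max(abs(su$coefficients$median - unname(mapped_median_latents))),
            1e-4)
  expect_true(all(su$coefficients$lower90 <= su$coefficients$median))
  expect_true(all(su$coefficients$median <= su$coefficients$upper90))
  expect_true(all(su$inclusion$inclusion > 0 & su$inclusion$inclusion < 1))
})

test_that("degenerate constant draws summarize to a point", {
  d <- tiny_gaussian(n = 20, p = 1, seed = 47)
  m <- build_flat_model(d)
  s <- run_mcmc(m, chains = 2, warmup = 100, draws = 50, seed = 2)
  s$beta[] <- 1.5                          # constant degenerate input
  su <- summarize_posterior(s)
  expect_equal(su$coefficients$median, 1.5)
  expect_equal(su$coefficients$mean, 1.5)
  expect_equal(su$coefficients$lower90, 1.5)
  expect_equal(su$coefficients$upper90, 1.5)
})

test_that("top-k selection orders by |median| with stable index tie-break", {
  med <- c(0.5, -2.0, 0.1)
  expect_equal(select_top_k(med, 1), 2L)
  expect_equal(sort(select_top_k(med, 3)), 1:3)
  tied <- c(-1, 2, 1, -2)
  expect_equal(select_top_k(tied, 2), c(2L, 4L))   # |2| ties: lower index first
  expect_equal(select_top_k(tied, 4), c(2L, 4L, 1L, 3L))
  expect_error(select_top_k(med, 0))
  expect_error(select_top_k(med, 4))
})

test_that("draws and summaries round-trip through CSV at full precision", {
  d <- tiny_gaussian(n = 15, p = 2, seed = 48)
  m <- build_flat_model(d)
  s <- run_mcmc(m, chains = 2, warmup = 100, draws = 40, seed = 4)
  path <- tempfile(fileext = ".csv")
  write_draws_csv(s, path)
  arr <- read_draws_csv(path)
  expect_equal(dim(arr), dim(s$theta))
  expect_equal(max(abs(arr - s$theta)), 0)
  su <- summarize_posterior(s)
  spath <- tempfile(fileext = ".csv")
  write_summary_csv(su, spath)
  back <- utils::read.csv(spath)
  expect_equal(back$median, su$coefficients$median, tolerance = 1e-12)
})

test_that("posterior shrinks truly-zero coefficients below OLS", {
  cfg <- sim_config(n = 80, p = 8, group_sizes = c(4, 4),
                    beta_true = c(3, 3, 3, 3, 0, 0, 0, 0), seed = 49)
  gen <- generate_grouped_regression(cfg)
  s <- run_mcmc(build_flat_model(gen$data), chains = 2, warmup = 500,
                draws = 500, seed = 6)
  su <- summarize_posterior(s)
  zeros <- which(gen$truth$beta_true == 0)
  ols <- ols_fit(gen$data)
  expect_lt(mean(abs(su$coefficients$median[zeros])),
            mean(abs(ols$beta[zeros])))
  # truly-zero predictors get lower inclusion than truly-nonzero ones
  expect_lt(mean(su$inclusion$inclusion[zeros]),
            mean(su$inclusion$inclusion[-zeros]))
})
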