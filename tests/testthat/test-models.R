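test_that("all three model variants match finite-difference gradients", {
  set.seed(21)
  d <- tiny_gaussian(n = 30, p = 4, seed = 21, beta = c(1, 0, -1, 0))
  db <- tiny_binomial(n = 40, p = 4, seed = 22, beta = c(2, 0, 0, -1))
  gr <- group_structure(c("a", "a", "b", "b"))
  models <- list(
    flat_gaussian = build_flat_model(d),
    flat_binomial = build_flat_model(db),
    grouped = build_grouped_model(d, gr),
    gam = build_hierarchical_gam(db, config = gam_config(3))
  )
  for (nmod in names(models)) {
    m <- models[[nmod]]
    for (rep in 1:5) {
      th <- rnorm(m$d, 0, 0.6)
      expect_lt(max_rel_err(m$grad(th), fd_grad(m$log_density, th)), 1e-4,
                label = paste("gradient of", nmod, "draw", rep))
    }
  }
})

test_that("log density is finite at the all-zeros point, including p = 1", {
  set.seed(23)
  X <- matrix(runif(20), 20, 1)
  d <- regression_dataset(X, rep(0, 20), family = "gaussian")
  m <- build_flat_model(d)
  expect_true(is.finite(m$log_density(rep(0, m$d))))
  db <- regression_dataset(X, rep(c(0, 1), 10), family = "binomial")
  expect_true(is.finite(build_flat_model(db)$log_density(rep(0, 2 * 1 + 1))))
})

test_that("likelihood equals the closed-form density sums", {
  d <- tiny_gaussian(n = 25, p = 3, seed = 24, beta = c(1, -2, 0))
  m <- build_flat_model(d)
  set.seed(25)
  th <- rnorm(m$d, 0, 0.5)
  cf <- m$coefficient_map(th)
  mu <- cf$beta0 + drop(d$X %*% cf$beta)
  expect_equal(m$log_likelihood(th),
               sum(dnorm(d$y, mu, cf$sigma_eps, log = TRUE)))
  db <- tiny_binomial(n = 35, p = 3, seed = 26, beta = c(1, 0, -1))
  mb <- build_flat_model(db)
  thb <- rnorm(mb$d, 0, 0.5)
  cfb <- mb$coefficient_map(thb)
  pr <- plogis(cfb$beta0 + drop(db$X %*% cfb$beta))
  expect_equal(mb$log_likelihood(thb),
               sum(dbinom(db$y, 1, pr, log = TRUE)))
})

test_that("grouped coefficients collapse exactly along the complexity ladder", {
  d <- tiny_gaussian(n = 20, p = 6, seed = 27)
  gr <- group_structure(rep(c("g1", "g2"), each = 3))
  # group weight 0 excludes every member
  m0 <- build_grouped_model(d, gr, fix_lambda_group = 0)
  th <- rnorm(m0$d, 0, 1)
  expect_equal(m0$coefficient_map(th)$beta, rep(0, 6))
  # member weights 0 force an identical shared coefficient per group
  ms <- build_grouped_model(d, gr, fix_lambda_member = 0)
  ths <- rnorm(ms$d, 0, 1)
  beta <- ms$coefficient_map(ths)$beta
  expect_equal(beta[1], beta[2])
  expect_equal(beta[2], beta[3])
  expect_equal(beta[4], beta[5])
  hy <- lncass_hyper()
  lamg <- ms$coefficient_map(ths)$lambda_group
  zg <- ths[ms$index$z_group]
  expect_equal(beta[1], hy$tau * lamg[1] * zg[1])
  expect_error(build_grouped_model(d, group_structure(rep("a", 5))), "equal")
})

test_that("grouped model with singleton groups and member rung off is the flat model", {
  d <- tiny_gaussian(n = 25, p = 4, seed = 28, beta = c(1, 1, 0, 0))
  gr <- group_structure(paste0("s", 1:4))
  mg <- build_grouped_model(d, gr, fix_lambda_member = 0)
  mf <- build_flat_model(d)
  expect_equal(mg$d, mf$d)
  set.seed(29)
  for (i in 1:5) {
    th <- rnorm(mf$d)
    expect_equal(mg$log_density(th), mf$log_density(th), tolerance = 1e-12)
    expect_equal(mg$coefficient_map(th)$beta, mf$coefficient_map(th)$beta)
  }
})

test_that("grouping shrinks within-group spread for a truly shared group", {
  # one group with a shared coefficient, one zero group
  cfg <- sim_config(n = 60, p = 6, group_sizes = c(3, 3),
                    beta_true = c(2, 2, 2, 0, 0, 0), seed = 31)
  gen <- generate_grouped_regression(cfg)
  sg <- run_mcmc(build_grouped_model(gen$data, gen$groups),
                 chains = 2, warmup = 400, draws = 400, seed = 5)
  sf <- run_mcmc(build_flat_model(gen$data),
                 chains = 2, warmup = 400, draws = 400, seed = 5)
  spread <- function(s) median(apply(s$beta[, 1:3], 1, sd))
  expect_lt(spread(sg), spread(sf))
})

test_that("gam basis columns are identity plus hinges", {
  cfg <- gam_config(3)              # knots at 1/4, 2/4, 3/4
  expect_equal(cfg$knot_positions, c(0.25, 0.5, 0.75))
  B <- unname(build_gam_basis(c(0, 0.25, 0.6, 1), cfg))
  expect_equal(dim(B), c(4, 4))
  expect_equal(B[, 1], c(0, 0.25, 0.6, 1))      # identity column
  expect_equal(B[1, ], c(0, 0, 0, 0))           # all basis functions vanish at 0
  expect_equal(B[2, 2], 0)                      # hinge is 0 at its own knot
  expect_equal(B[3, 2], 0.35)
  expect_equal(B[4, ], c(1, 0.75, 0.5, 0.25))
  expect_error(build_gam_basis(c(0.5, 1.2), cfg), "index 2")
  # any linear function is representable with zero nonlinear coefficients
  x <- runif(10)
  expect_equal(drop(build_gam_basis(x, cfg) %*% c(3, 0, 0, 0)), 3 * x)
})

test_that("gam config validates knots", {
  expect_error(gam_config(2, c(0.5, 0.2)), "increasing")
  expect_error(gam_config(2, c(0, 0.5)), "interior")
  expect_error(gam_config(1, c(0.3, 0.6)), "length")
  expect_equal(gam_config(0)$knot_positions, numeric(0))
})

test_that("gam ladder limits: removal and exactly-linear effects", {
  db <- tiny_binomial(n = 40, p = 3, seed = 32)
  m <- build_hierarchical_gam(db, config = gam_config(4))
  th <- rnorm(m$d, 0, 1)
  # lambda_i -> 0 (u_i very negative) removes covariate i entirely
  th[m$index$u][1] <- -100
  cf <- m$coefficient_map(th)
  expect_equal(cf$beta[1:5], rep(0, 5))          # all 5 basis coefficients
  # lambda_nl -> 0 with lambda -> 1 leaves a pure linear effect
  th[m$index$u][2] <- 100
  th[m$index$u_nl][2] <- -100
  cf <- m$coefficient_map(th)
  expect_equal(cf$beta[7:10], rep(0, 4))         # knot coefficients vanish
  hy <- lncass_hyper()
  expect_equal(cf$beta[6], hy$tau * th[m$index$z][2])  # slab-scale linear term
  expect_error(build_hierarchical_gam(tiny_gaussian()), "binomial")
})

test_that("gam with zero knots is flat logistic regression", {
  db <- tiny_binomial(n = 30, p = 3, seed = 33, beta = c(1, -1, 0))
  mg <- build_hierarchical_gam(db, config = gam_config(0))
  mf <- build_flat_model(db)
  expect_identical(mg$latent_names, mf$latent_names)
  set.seed(34)
  for (i in 1:5) {
    th <- rnorm(mf$d)
    expect_equal(mg$log_density(th), mf$log_density(th), tolerance = 1e-12)
  }
})

test_that("with inclusion frozen the posterior mode approaches OLS on clean data", {
  set.seed(35)
  n <- 50
  X <- matrix(runif(n * 2), n, 2)
  beta <- c(2, -1)
  y <- 0.5 + drop(X %*% beta)               # noiseless
  d <- regression_dataset(X, y, family = "gaussian")
  m <- build_flat_model(d, fix_lambda = 1, fix_sigma = 0.05)
  opt <- optim(rep(0, m$d), fn = function(t) -m$log_density(t),
               gr = function(t) -m$grad(t), method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  mode_beta <- m$coefficient_map(opt$par)$beta
  ols <- ols_fit(d)
  expect_lt(max(abs(mode_beta - ols$beta)), 0.05)
})

test_that("dataset container validates inputs", {
  X <- matrix(1:6, 3, 2)
  expect_error(regression_dataset(X, c(0, 1, 2), family = "binomial"), "0/1")
  expect_error(regression_dataset(X, c(1, 2)), "equal")
  Xna <- X; Xna[1] <- NA
  expect_error(regression_dataset(Xna, c(1, 2, 3)), "missing")
  d <- regression_dataset(X, c(1, 0, 1), family = "binomial",
                          predictor_names = c("p1", "p2"))
  expect_equal(d$predictor_names, c("p1", "p2"))
})

test_that("group map files are validated against the dataset", {
  d <- tiny_gaussian(n = 10, p = 3, seed = 36)
  path <- tempfile(fileext = ".csv")
  writeLines(c("predictor,group", "x1,a", "x2,a", "x3,b"), path)
  gr <- read_group_map(path, d)
  expect_equal(gr$assignment, c("a", "a", "b"))
  writeLines(c("predictor,group", "x1,a", "bogus,a", "x3,b"), path)
  expect_error(read_group_map(path, d), "bogus")
  writeLines(c("predictor,group", "x1,a", "x3,b"), path)
  expect_error(read_group_map(path, d), "missing")
})
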