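# Seeded generators for the parameter-recovery simulation study and the
# GAM test scene.

#' Unit Latin hypercube design
#'
#' `n x p` design in `[0, 1)` in which every column, divided into `n` equal
#' bins, contains exactly one point, with uniform within-bin positions and
#' independent column permutations.
#'
#' @param n,p Rows and columns (>= 1).
#' @param seed Integer seed.
#' @return `n x p` matrix.
#' @export
latin_hypercube <- function(n, p, seed = 1) {
  stopifnot(n >= 1, p >= 1)
  set.seed(seed)
  lhs::randomLHS(n, p)
}

#' Simulation configuration for the grouped-regression generator
#'
#' @param n Observations.
#' @param p Predictors; must equal `sum(group_sizes)`.
#' @param group_sizes Integer sizes of the predictor groups, in order.
#' @param beta_true Length-`p` true coefficients.
#' @param beta0_true True intercept.
#' @param noise_sd Gaussian noise standard deviation (> 0).
#' @param seed Integer seed.
#' @return `lncass_sim_config`.
#' @export
sim_config <- function(n, p, group_sizes, beta_true, beta0_true = 0,
                       noise_sd = 1, seed = 1) {
  stopifnot(n >= 2, p >= 1, noise_sd > 0, length(beta_true) == p)
  if (sum(group_sizes) != p) stop("group_sizes must sum to p")
  structure(list(n = as.integer(n), p = as.integer(p),
                 group_sizes = as.integer(group_sizes),
                 beta_true = as.numeric(beta_true),
                 beta0_true = as.numeric(beta0_true),
                 noise_sd = as.numeric(noise_sd), seed = as.integer(seed)),
            class = "lncass_sim_config")
}

# group labels g1, g2, ... expanded to predictor level
.group_labels <- function(group_sizes) {
  rep(paste0("g", seq_along(group_sizes)), times = group_sizes)
}

#' Generate a grouped sparse linear-regression dataset
#'
#' `X` from a unit Latin hypercube; `y = beta0 + X beta_true + eps` with
#' i.i.d. zero-mean Gaussian noise. The truth record classifies each group
#' as `zero` (all members zero), `shared` (all members equal and non-zero)
#' or `heterogeneous`.
#'
#' @param config `lncass_sim_config`.
#' @return List with `data` (`lncass_dataset`), `groups`
#'   (`lncass_groups`) and `truth` (list: `beta_true`, `beta0_true`,
#'   `noise_sd`, `group_type`).
#' @export
generate_grouped_regression <- function(config) {
  stopifnot(inherits(config, "lncass_sim_config"))
  X <- latin_hypercube(config$n, config$p, seed = config$seed)
  set.seed(config$seed + 1L)
  eps <- stats::rnorm(config$n, 0, config$noise_sd)
  y <- config$beta0_true + drop(X %*% config$beta_true) + eps
  labels <- .group_labels(config$group_sizes)
  groups <- group_structure(labels)
  group_type <- vapply(groups$index, function(ii) {
    b <- config$beta_true[ii]
    if (all(b == 0)) "zero"
    else if (length(unique(b)) == 1) "shared"
    else "heterogeneous"
  }, character(1))
  names(group_type) <- groups$groups
  data <- regression_dataset(X, y, family = "gaussian",
                             predictor_names = paste0("x", seq_len(config$p)))
  list(data = data, groups = groups,
       truth = list(beta_true = config$beta_true,
                    beta0_true = config$beta0_true,
                    noise_sd = config$noise_sd, group_type = group_type))
}

#' Default simulation-study scenarios
#'
#' Three grouped settings at `n = 100` with `p = 20, 70, 120`. Each
#' contains several all-zero groups, one shared-coefficient group and one
#' heterogeneous group whose members take similar but unequal values. The
#' coefficient tables are package fixtures defined in one place
#' (`.scenario_table`) and are deliberately easy to edit.
#'
#' @param seed Base seed; scenario `i` uses `seed + i`.
#' @return List of three `lncass_sim_config` objects.
#' @export
default_scenarios <- function(seed = 100) {
  lapply(seq_along(.scenario_table), function(i) {
    sc <- .scenario_table[[i]]
    sim_config(n = 100, p = sum(sc$group_sizes), group_sizes = sc$group_sizes,
               beta_true = sc$beta_true, beta0_true = sc$beta0_true,
               noise_sd = sc$noise_sd, seed = seed + i)
  })
}

#' Generate the GAM test scene
#'
#' Ten covariates uniform on `[0, 1]`; the linear predictor is a centred
#' quadratic effect of covariate 1 plus a linear effect of covariate 2 and
#' exactly zero contribution from covariates 3-10; Bernoulli response with
#' logit link.
#'
#' @param n Observations (>= 50).
#' @param seed Integer seed.
#' @return List with `data` (binomial `lncass_dataset`), `truth`
#'   (list of the 10 true effect functions), and `linear_predictor`.
#' @export
generate_gam_scene <- function(n, seed = 1) {
  stopifnot(n >= 50)
  set.seed(seed)
  p <- 10
  X <- matrix(stats::runif(n * p), n, p)
  f1 <- function(x) 12 * (x - 0.5)^2 - 1          # centred quadratic, range [-1, 2]
  f2 <- function(x) 4 * (x - 0.5)                 # centred linear, range [-2, 2]
  zero_fn <- function(x) 0 * x
  truth <- c(list(f1, f2), rep(list(zero_fn), p - 2))
  lp <- f1(X[, 1]) + f2(X[, 2])
  y <- stats::rbinom(n, 1, sigm(lp))
  data <- regression_dataset(X, y, family = "binomial",
                             predictor_names = paste0("x", seq_len(p)))
  list(data = data, truth = truth, linear_predictor = lp)
}
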