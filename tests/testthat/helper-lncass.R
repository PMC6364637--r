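# Shared test utilities: independent oracles and small fixture builders.

# central finite differences -- the independent gradient oracle
fd_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- x; e[i] <- x[i] + h; up <- f(e)
    e[i] <- x[i] - h; (up - f(e)) / (2 * h)
  }, numeric(1))
}

max_rel_err <- function(a, b, floor = 1e-6) max(abs(a - b) / pmax(abs(b), floor))

# total mass of the logit-normal pdf by adaptive quadrature. Integrating on
# the log(x) scale resolves the boundary layer near 0 (where most of the
# mass sits when sigma is large) in double precision; the mass near 1 is
# integrated through the exact reflection pdf(1 - x; mu) = pdf(x; -mu),
# because doubles cannot represent x within ~1e-16 of 1.
quad_logitnorm_mass <- function(mu, sigma) {
  lower_half <- function(mu) {
    stats::integrate(function(u) dlogitnorm(exp(u), mu, sigma) * exp(u),
                     -700, log(0.5), rel.tol = 1e-9,
                     subdivisions = 2000L)$value
  }
  lower_half(mu) + lower_half(-mu)
}

# brute-force pairwise-concordance AUC (enumeration oracle)
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (sp in pos) for (sn in neg)
    tot <- tot + (sp > sn) + 0.5 * (sp == sn)
  tot / (length(pos) * length(neg))
}

# small gaussian fixture dataset
tiny_gaussian <- function(n = 30, p = 4, seed = 1, beta = NULL, noise = 1) {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p)
  if (is.null(beta)) beta <- rep(0, p)
  y <- drop(X %*% beta) + rnorm(n, 0, noise)
  regression_dataset(X, y, family = "gaussian")
}

tiny_binomial <- function(n = 60, p = 3, seed = 1, beta = rep(0, p)) {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p)
  y <- rbinom(n, 1, plogis(drop(X %*% beta)))
  regression_dataset(X, y, family = "binomial")
}

# batch-means Monte Carlo standard error of a chain mean
batch_se <- function(x, n_batches = 20) {
  bm <- colMeans(matrix(x[seq_len(n_batches * (length(x) %/% n_batches))],
                        ncol = n_batches))
  stats::sd(bm) / sqrt(n_batches)
}
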