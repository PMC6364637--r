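# Adaptive Hamiltonian Monte Carlo.
#
# One chain = warmup + sampling. Warmup runs in two phases: phase A adapts
# the step size by dual averaging under a unit mass matrix; a diagonal mass
# matrix is then estimated from the second half of phase A, and phase B
# re-adapts the step size under that metric. Trajectory lengths are
# jittered uniformly around a nominal physical length to avoid resonance.
# Non-finite Hamiltonians (divergences) are rejected and counted.

.hmc_defaults <- function() {
  list(target_accept = 0.9, traj_length = 1.6, jitter = c(0.3, 1),
       max_leapfrog = 128, gamma = 0.05, t0 = 10, kappa = 0.75,
       init_attempts = 3)
}

.find_init_step <- function(lp_grad, theta, inv_mass) {
  d <- length(theta)
  eps <- 0.1
  s0 <- lp_grad(theta)
  mom <- stats::rnorm(d) / sqrt(inv_mass)
  h0 <- s0$lp - 0.5 * sum(inv_mass * mom^2)
  step_once <- function(eps) {
    m <- mom + 0.5 * eps * s0$grad
    th <- theta + eps * inv_mass * m
    s1 <- lp_grad(th)
    if (!all(is.finite(s1$grad)) || !is.finite(s1$lp)) return(-Inf)
    m <- m + 0.5 * eps * s1$grad
    s1$lp - 0.5 * sum(inv_mass * m^2) - h0
  }
  dh <- step_once(eps)
  if (!is.finite(dh)) dh <- -Inf
  dir <- if (dh > log(0.8)) 1 else -1
  for (i in 1:50) {
    eps2 <- eps * 2^dir
    dh <- step_once(eps2)
    if (dir == 1 && !(is.finite(dh) && dh > log(0.8))) break
    if (dir == -1 && (is.finite(dh) && dh > log(0.8))) { eps <- eps2; break }
    eps <- eps2
  }
  eps
}

.leapfrog <- function(lp_grad, theta, mom, eps, L, inv_mass, grad0) {
  g <- grad0
  mom <- mom + 0.5 * eps * g
  for (l in seq_len(L)) {
    theta <- theta + eps * inv_mass * mom
    s <- lp_grad(theta)
    if (!is.finite(s$lp) || !all(is.finite(s$grad)))
      return(list(ok = FALSE))
    g <- s$grad
    if (l < L) mom <- mom + eps * g
  }
  mom <- mom + 0.5 * eps * g
  list(ok = TRUE, theta = theta, mom = mom, lp = s$lp, grad = g)
}

# single chain; RNG state of the caller is used (seed it before calling)
.hmc_chain <- function(lp_grad, init, n_warmup, n_draws, control = list()) {
  ctl <- utils::modifyList(.hmc_defaults(), control)
  d <- length(init)
  theta <- init
  s <- lp_grad(theta)
  if (!is.finite(s$lp)) stop("non-finite log density at the initial point")
  inv_mass <- rep(1, d)
  draws <- matrix(NA_real_, n_draws, d)
  n_divergent <- 0L
  accept_sum <- 0

  phaseA <- floor(n_warmup / 2)
  phases <- list(seq_len(phaseA), seq_len(n_warmup - phaseA) + phaseA)
  win_buf <- matrix(NA_real_, max(1, ceiling(phaseA / 2)), d)

  eps <- .find_init_step(lp_grad, theta, inv_mass)
  for (phase in 1:2) {
    # dual averaging state (restarted per phase)
    mu_da <- log(10 * eps); log_eps_bar <- 0; h_bar <- 0
    iters <- phases[[phase]]
    wrow <- 0L
    for (it in seq_along(iters)) {
      mom <- stats::rnorm(d) / sqrt(inv_mass)
      h0 <- s$lp - 0.5 * sum(inv_mass * mom^2)
      L <- max(1L, min(ctl$max_leapfrog,
                       round(stats::runif(1, ctl$jitter[1], ctl$jitter[2]) *
                             ctl$traj_length / eps)))
      prop <- .leapfrog(lp_grad, theta, mom, eps, L, inv_mass, s$grad)
      if (prop$ok) {
        h1 <- prop$lp - 0.5 * sum(inv_mass * prop$mom^2)
        a <- min(1, exp(h1 - h0))
        if (stats::runif(1) < a) {
          theta <- prop$theta
          s <- list(lp = prop$lp, grad = prop$grad)
        }
      } else {
        a <- 0
        n_divergent <- n_divergent + 1L
      }
      # dual averaging update
      m_da <- it
      h_bar <- (1 - 1 / (m_da + ctl$t0)) * h_bar +
        (ctl$target_accept - a) / (m_da + ctl$t0)
      log_eps <- mu_da - sqrt(m_da) / ctl$gamma * h_bar
      w <- m_da^(-ctl$kappa)
      log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
      eps <- exp(log_eps)
      if (phase == 1 && it > phaseA / 2) {
        wrow <- wrow + 1L
        if (wrow <= nrow(win_buf)) win_buf[wrow, ] <- theta
      }
    }
    eps <- exp(log_eps_bar)
    if (phase == 1 && wrow >= 10) {
      v <- apply(win_buf[seq_len(min(wrow, nrow(win_buf))), , drop = FALSE], 2,
                 stats::var)
      # regularize towards unit like a short adaptation window would
      v <- pmax(v * wrow / (wrow + 5) + 1e-3 * 5 / (wrow + 5), 1e-8)
      inv_mass <- v
      eps <- .find_init_step(lp_grad, theta, inv_mass)
    }
  }

  for (it in seq_len(n_draws)) {
    mom <- stats::rnorm(d) / sqrt(inv_mass)
    h0 <- s$lp - 0.5 * sum(inv_mass * mom^2)
    L <- max(1L, min(ctl$max_leapfrog,
                     round(stats::runif(1, ctl$jitter[1], ctl$jitter[2]) *
                           ctl$traj_length / eps)))
    prop <- .leapfrog(lp_grad, theta, mom, eps, L, inv_mass, s$grad)
    if (prop$ok) {
      h1 <- prop$lp - 0.5 * sum(inv_mass * prop$mom^2)
      a <- min(1, exp(h1 - h0))
      if (stats::runif(1) < a) {
        theta <- prop$theta
        s <- list(lp = prop$lp, grad = prop$grad)
      }
      accept_sum <- accept_sum + a
    } else {
      n_divergent <- n_divergent + 1L
    }
    draws[it, ] <- theta
  }
  list(draws = draws, accept_rate = accept_sum / n_draws,
       n_divergent = n_divergent, step_size = eps)
}
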