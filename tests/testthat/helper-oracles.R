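# Independent oracles used across the suite. These deliberately avoid the
# package's internal code paths.

# scalar inhibitor-dilution steady state, written out longhand
oracle_cn <- function(eps, rho, r, ki, kp, n) {
  if (is.finite(n)) {
    n * (eps + r) / (ki - kp) * ((rho * kp / r)^(1 / n) - 1)
  } else {
    (eps + r) / (ki - kp) * log(rho * kp / r)
  }
}

# undamped cobweb iteration of the copy-number / growth feedback loop;
# returns the trajectory of growth rates
oracle_cobweb <- function(params, a, b, n_iter = 200, r_floor = 1e-6) {
  r <- b
  out <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    np <- oracle_cn(params$epsilon, params$rho, max(r, r_floor),
                    params$k_i, params$k_p, params$n_steps)
    r <- max(b * (1 - a * max(np, 0)), r_floor)
    out[i] <- r
  }
  out
}

# exhaustive occupancy oracle: enumerate every set of R occupied sites among
# N_a + N_c specific and N_NS nonspecific distinct sites (tiny systems only)
oracle_occupancy_bruteforce <- function(delta_eps, R, N_NS, N_a, N_c) {
  n_sites <- N_a + N_c + N_NS
  stopifnot(choose(n_sites, R) < 2e5)
  sets <- utils::combn(n_sites, R)
  # sites 1..(N_a+N_c) are specific; site 1..N_a active
  num <- 0; den <- 0
  for (j in seq_len(ncol(sets))) {
    occ <- sets[, j]
    m_spec <- sum(occ <= N_a + N_c)
    w <- exp(-m_spec * delta_eps)
    den <- den + w
    num <- num + w * sum(occ <= N_a) / N_a
  }
  num / den
}

# random valid replication parameter draw (stable domain)
draw_stable_params <- function(n_steps = 1) {
  repeat {
    r <- stats::runif(1, 0.004, 0.02)
    rho <- stats::runif(1, 0.3, 1)
    ki <- stats::runif(1, 0.5, 2)
    kp <- stats::runif(1, 0.02, 0.9) * ki
    if (rho * kp / r > 1.05 && kp < ki * 0.98)
      return(rep_params(r = r, rho = rho, k_i = ki, k_p = kp,
                        n_steps = n_steps))
  }
}
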