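# Independent fixed-step RK4 integrator used as a cross-check oracle.
# Deliberately re-states the model equations inline rather than calling any
# package RHS or solver code.
rk4_dimer <- function(model = c("primed", "cold_start"), params, dt = 1,
                      record_every = 60) {
  model <- match.arg(model)
  f <- if (model == "primed") {
    function(y, lam) {
      flux <- params$lambda_D * y[1] * y[2]
      c(lam - params$beta_N * y[1] - flux,
        -params$beta_V * y[2] - flux,
        flux)
    }
  } else {
    function(y, lam) {
      flux <- params$lambda_D * y[1]^2
      c(lam - params$beta_N * y[1] - flux, flux)
    }
  }
  y <- if (model == "primed") c(0, params$V0, 0) else c(0, 0)
  bounds <- unique(c(0, params$t_on, params$t_off, params$t_end))
  rec_t <- seq(0, params$t_end, by = record_every)
  rec <- matrix(NA_real_, length(rec_t), length(y))
  rec[1, ] <- y
  for (k in seq_len(length(bounds) - 1)) {
    a <- bounds[k]; b <- bounds[k + 1]
    lam <- if (a >= params$t_on && b <= params$t_off) params$lambda_N_on else 0
    nstep <- round((b - a) / dt)
    t <- a
    for (s in seq_len(nstep)) {
      k1 <- f(y, lam)
      k2 <- f(y + dt / 2 * k1, lam)
      k3 <- f(y + dt / 2 * k2, lam)
      k4 <- f(y + dt * k3, lam)
      y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- a + s * dt
      i <- match(t, rec_t)
      if (!is.na(i)) rec[i, ] <- y
    }
  }
  states <- if (model == "primed") {
    data.frame(N = rec[, 1], V = rec[, 2], D = rec[, 3])
  } else {
    data.frame(N = rec[, 1], V = 0, D = rec[, 2])
  }
  list(times = rec_t, states = states)
}

# Minimal hand-built trajectory object for metric unit tests.
toy_trajectory <- function(times, D, N = 0 * D, V = 0 * D,
                           model = "primed", params = default_parameters()) {
  structure(list(model = model, params = params, times = times,
                 states = data.frame(N = N, V = V, D = D),
                 rel_tol = 1e-8, abs_tol = 1e-15),
            class = "dimer_trajectory")
}
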