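test_that("with no dimerization the integrator matches the closed forms", {
  p <- update_parameters(default_parameters(), lambda_D = 0)
  traj <- integrate_model("primed", p)
  n_ref <- monomer_closed_form(traj$times, p)
  v_ref <- vg1_decay_closed_form(traj$times, p)
  expect_lt(max(abs(traj$states$N - n_ref)) / max(n_ref), 1e-6)
  expect_lt(max(abs(traj$states$V - v_ref) / v_ref), 1e-6)
  expect_equal(traj$states$D, rep(0, length(traj$times)))
})

test_that("conservation ledgers close to solver tolerance for both models", {
  p <- default_parameters()
  primed <- integrate_model("primed", p)
  ml <- mass_ledger(primed)
  expect_lt(max(abs(ml$r_N)), 1e-6 * p$V0)
  expect_lt(max(abs(ml$r_V)), 1e-6 * p$V0)
  expect_equal(ml$r_N[1], 0)
  expect_equal(ml$r_V[1], 0)
  cold <- integrate_model("cold_start", p)
  mlc <- mass_ledger(cold)
  expect_lt(max(abs(mlc$r_N)), 1e-6 * p$V0)
  expect_null(mlc$r_V)
})

test_that("trajectory invariants hold at defaults for both models", {
  p <- default_parameters()
  for (model in model_kinds()) {
    traj <- integrate_model(model, p)
    expect_true(all(diff(traj$times) > 0))
    expect_true(all(traj$states$N >= -traj$abs_tol))
    expect_true(all(diff(traj$states$D) >= -traj$abs_tol))
    # no Nodal before the production window opens
    pre <- traj$times < p$t_on
    expect_true(all(abs(traj$states$N[pre]) <= traj$abs_tol))
    expect_true(all(diff(traj$cum_production) >= -traj$abs_tol))
    expect_true(all(diff(traj$cum_deg_N) >= -traj$abs_tol))
    # dimers cannot outnumber produced Nodal, nor (primed) the Vg1 pool
    expect_true(all(traj$states$D <= traj$cum_production + 1e-6 * p$V0))
    if (model == "primed") {
      expect_true(all(traj$states$D <= p$V0))
    }
  }
})

test_that("solutions are stable under grid refinement and tighter tolerance", {
  p <- default_parameters()
  coarse <- integrate_model("primed", p, grid = seq(0, p$t_end, by = 300))
  fine <- integrate_model("primed", p, grid = seq(0, p$t_end, by = 60))
  shared <- match(coarse$times, fine$times)
  expect_equal(coarse$states$D, fine$states$D[shared], tolerance = 1e-7)

  d1 <- integrate_model("cold_start", p, rel_tol = 1e-8)
  d2 <- integrate_model("cold_start", p, rel_tol = 5e-9)
  dend1 <- d1$states$D[length(d1$times)]
  dend2 <- d2$states$D[length(d2$times)]
  expect_lt(abs(dend1 - dend2) / dend2, 10 * 1e-8)
})

test_that("cold-start monomer attains quasi-steady state late in the window", {
  p <- default_parameters()
  traj <- integrate_model("cold_start", p)
  nstar <- cold_start_qss_monomer(p)
  last_q <- traj$times >= p$t_off - (p$t_off - p$t_on) / 4 &
    traj$times <= p$t_off
  expect_true(all(abs(traj$states$N[last_q] - nstar) / nstar < 0.05))
})

test_that("degenerate inputs give the expected null trajectories", {
  p <- default_parameters()
  # no Vg1 pool: the primed scheme cannot form a single heterodimer
  t_v0 <- integrate_model("primed", update_parameters(p, V0 = 0))
  expect_true(all(t_v0$states$D == 0))
  expect_true(all(t_v0$states$V == 0))
  # no dimerization: no dimers in either model
  p_ld0 <- update_parameters(p, lambda_D = 0)
  expect_true(all(integrate_model("primed", p_ld0)$states$D == 0))
  expect_true(all(integrate_model("cold_start", p_ld0)$states$D == 0))
  # no synthesis: Nodal and dimer identically zero
  p_ln0 <- update_parameters(p, lambda_N_on = 0)
  for (model in model_kinds()) {
    tr <- integrate_model(model, p_ln0)
    expect_true(all(tr$states$N == 0))
    expect_true(all(tr$states$D == 0))
  }
})

test_that("invalid grids and tolerances are rejected", {
  p <- default_parameters()
  expect_error(integrate_model("primed", p, grid = c(0, 10, 5)),
               "increasing")
  expect_error(integrate_model("primed", p, grid = c(-10, 0, 10)),
               "within")
  expect_error(integrate_model("primed", p, grid = c(0, p$t_end + 1)),
               "within")
  expect_error(integrate_model("primed", p, rel_tol = 0), "> 0")
  expect_error(mass_ledger(structure(list(model = "primed"),
                                     class = "dimer_trajectory")),
               "ledger")
})

test_that("the adaptive integrator agrees with an independent RK4 oracle", {
  p <- default_parameters()
  for (model in model_kinds()) {
    ref <- rk4_dimer(model, p, dt = 1, record_every = 60)
    # tolerances tightened below the default reporting floor so the
    # comparison probes the solution, not the solver's atol cushion
    traj <- integrate_model(model, p, grid = ref$times,
                            rel_tol = 1e-10, abs_tol = 1e-20)
    scale <- max(ref$states$D)
    expect_lt(max(abs(traj$states$D - ref$states$D)) / scale, 1e-6)
    expect_lt(max(abs(traj$states$N - ref$states$N)) / max(ref$states$N),
              1e-5)
  }
})
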