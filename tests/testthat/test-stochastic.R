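default_omega <- function() 1e5 / (100e-9 * AVOGADRO)

test_that("pure Vg1 death process halves the pool at one half-life", {
  # all rates zero except beta_V: binomial thinning with survival 1/2
  p <- kinetic_parameters(lambda_N_on = 0, beta_N = 0, beta_V = 1.16e-4,
                          lambda_D = 0, V0 = nM_to_M(100),
                          t_on = 1, t_off = log(2) / 1.16e-4,
                          t_end = log(2) / 1.16e-4)
  omega <- 100 / (100e-9 * AVOGADRO)  # 100 nM <-> 100 molecules
  sc <- stochastic_config(omega = omega, seed = 99, n_replicates = 400,
                          record_times = c(0, p$t_end))
  ens <- ssa_ensemble("primed", p, sc)
  expect_equal(ens$mean$V[1], 100)
  # survivors ~ Binomial(100, 1/2): sd = 5 counts, SE over 400 reps = 0.25;
  # with 100 molecules <-> 100 nM, counts and nM coincide numerically
  expect_lt(abs(ens$mean$V[2] - 50), 4 * 0.25)
})

test_that("zero-rate system stays identically at zero", {
  p <- kinetic_parameters(0, 0, 0, 0, 0, t_on = 1, t_off = 2, t_end = 10)
  sc <- stochastic_config(seed = 5, record_times = 0:10)
  tr <- ssa_run("cold_start", p, sc)
  expect_true(all(unlist(tr$counts) == 0))
  ens <- ssa_ensemble("cold_start", p,
                      stochastic_config(seed = 5, n_replicates = 3,
                                        record_times = 0:10))
  expect_true(all(unlist(ens$mean) == 0))
  expect_true(all(unlist(ens$se) == 0))
})

test_that("SSA realizations respect count invariants", {
  p <- default_parameters()
  sc <- stochastic_config(omega = default_omega() / 100, seed = 31,
                          record_times = seq(0, hpf_to_s(10), by = 600))
  for (model in model_kinds()) {
    tr <- ssa_run(model, p, sc)
    cts <- as.matrix(tr$counts)
    expect_true(all(cts >= 0))
    expect_true(all(cts == round(cts)))
    expect_true(all(diff(tr$counts$n_D) >= 0))
    if (model == "primed") {
      n_v0 <- round(p$V0 * sc$omega * AVOGADRO)
      expect_true(all(tr$counts$n_D <= n_v0))
      # every dimer consumed one V: V + D never exceeds the initial pool
      expect_true(all(tr$counts$n_V + tr$counts$n_D <= n_v0))
    } else {
      expect_true(all(tr$counts$n_V == 0))
    }
  }
})

test_that("identical seeds reproduce SSA runs bit-for-bit; seeds matter", {
  p <- default_parameters()
  sc <- stochastic_config(omega = default_omega() / 10, seed = 123,
                          record_times = seq(0, hpf_to_s(10), by = 1800))
  a <- ssa_run("primed", p, sc)
  b <- ssa_run("primed", p, sc)
  expect_identical(a$counts, b$counts)
  sc2 <- sc; sc2$seed <- 124L
  c2 <- ssa_run("primed", p, sc2)
  expect_false(identical(a$counts, c2$counts))
  e1 <- ssa_ensemble("cold_start", p,
                     stochastic_config(omega = default_omega(), seed = 7,
                                       n_replicates = 5,
                                       record_times = seq(0, hpf_to_s(10),
                                                          by = 3600)))
  e2 <- ssa_ensemble("cold_start", p,
                     stochastic_config(omega = default_omega(), seed = 7,
                                       n_replicates = 5,
                                       record_times = seq(0, hpf_to_s(10),
                                                          by = 3600)))
  expect_identical(e1$mean, e2$mean)
})

test_that("ensemble means track the deterministic trajectories", {
  p <- default_parameters()
  rt <- seq(0, hpf_to_s(10), length.out = 26)
  sc <- stochastic_config(omega = default_omega(), seed = 2026,
                          n_replicates = 120, record_times = rt)
  for (model in model_kinds()) {
    ens <- ssa_ensemble(model, p, sc)
    det <- integrate_model(model, p, grid = rt)
    dd <- M_to_nM(det$states$D)
    ok <- abs(ens$mean$D - dd) <= pmax(3 * ens$se$D, 1e-9)
    expect_gte(mean(ok), 0.95)
  }
})

test_that("relative dimer fluctuations shrink roughly as sqrt(volume)", {
  p <- default_parameters()
  rt <- c(0, hpf_to_s(10))
  sds <- vapply(c(1, 4), function(f) {
    sc <- stochastic_config(omega = default_omega() / 50 * f, seed = 17,
                            n_replicates = 150, record_times = rt)
    ens <- ssa_ensemble("primed", p, sc)
    ens$se$D[2] * sqrt(150)  # per-replicate sd in nM
  }, numeric(1))
  # quadrupling the volume should halve concentration-scale fluctuations
  expect_equal(sds[1] / sds[2], 2, tolerance = 0.35)
})

test_that("noisy synthetic datasets honor the lognormal noise contract", {
  p <- default_parameters()
  ot <- default_obs_times(p, dt = 600)
  # degenerate noise reproduces the deterministic dimer exactly
  ds0 <- generate_noisy_trajectories(p, sigma = 0, n_reps = 3,
                                     obs_times = ot, seed = 1)
  det <- integrate_model("primed", p, grid = sort(unique(c(0, p$t_on,
                                                           p$t_off, ot))))
  dd <- M_to_nM(det$states$D[match(ot, det$times)])
  for (r in 1:3) expect_equal(ds0$observed[r, ], dd)
  # lognormal noise: the per-time median matches the noiseless curve
  ds <- generate_noisy_trajectories(p, sigma = 0.1, n_reps = 50,
                                    obs_times = ot, seed = 8)
  med <- apply(ds$observed, 2, stats::median)
  pos <- ds$noiseless > 0
  expect_true(all(abs(med[pos] / ds$noiseless[pos] - 1) < 0.06))
  expect_true(all(ds$observed[, pos] > 0))
  # determinism and validation
  ds2 <- generate_noisy_trajectories(p, sigma = 0.1, n_reps = 50,
                                     obs_times = ot, seed = 8)
  expect_identical(ds$observed, ds2$observed)
  expect_error(generate_noisy_trajectories(p, sigma = -1, n_reps = 1,
                                           obs_times = ot, seed = 1), "sigma")
  expect_error(generate_noisy_trajectories(p, sigma = 0, n_reps = 1,
                                           obs_times = c(0, p$t_end + 60),
                                           seed = 1), "within")
})

test_that("stochastic configuration is validated", {
  expect_error(stochastic_config(omega = 0), "> 0")
  expect_error(stochastic_config(n_replicates = 0), ">= 1")
  expect_error(stochastic_config(record_times = c(3, 2, 1)), "increasing")
  p <- default_parameters()
  sc <- stochastic_config(record_times = c(0, p$t_end + 1))
  expect_error(ssa_run("primed", p, sc), "within")
  expect_error(ssa_ensemble("primed", p,
                            stochastic_config(n_replicates = 1)), ">= 2")
})
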