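#' Configuration for stochastic simulation
#'
#' Fixes the reaction volume, random seed, replicate count, and output grid
#' for the stochastic twin of the dimerization networks. Counts and
#' concentrations convert through `n = c * omega * N_A`.
#'
#' The default volume maps the 100 nM maternal Vg1 pool to 1e5 molecules
#' (`omega = 1e5 / (100e-9 * N_A)` L, about 1.66e-12 L), which keeps
#' fluctuations visible while ensemble means track the deterministic
#' trajectories.
#'
#' @param omega Reaction volume (L), `> 0`.
#' @param seed Integer random seed.
#' @param n_replicates Number of realizations, `>= 1`.
#' @param record_times Strictly increasing output grid (s), starting at
#'   `>= 0`.
#' @return An object of class `stochastic_config`.
#' @export
stochastic_config <- function(omega = 1e5 / (100e-9 * AVOGADRO),
                              seed = 1L, n_replicates = 1L,
                              record_times = seq(0, hpf_to_s(10),
                                                 length.out = 51)) {
  if (!is.numeric(omega) || length(omega) != 1 || omega <= 0) {
    stop("omega must be a single volume > 0", call. = FALSE)
  }
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 1) {
    stop("n_replicates must be >= 1", call. = FALSE)
  }
  record_times <- as.numeric(record_times)
  if (length(record_times) < 1 || any(diff(record_times) <= 0) ||
      record_times[1] < 0) {
    stop("record_times must be strictly increasing and non-negative",
         call. = FALSE)
  }
  structure(list(omega = omega, seed = as.integer(seed),
                 n_replicates = n_replicates, record_times = record_times),
            class = "stochastic_config")
}

#' Single exact stochastic realization
#'
#' Runs the direct-method Gillespie algorithm for the selected reaction
#' network at integer molecule counts in volume `config$omega`. The
#' time-varying production propensity is handled by restricting each
#' simulation segment to intervals where the synthesis rate is constant, so
#' the direct method remains exact. Deterministic given `config$seed`.
#'
#' The cold-start homodimerization event consumes one Nodal monomer per
#' dimer formed (propensity `lambda_D * nN * (nN - 1) / (omega * N_A)`), so
#' that the large-volume mean field reproduces the model's equations as
#' written.
#'
#' @param model `"primed"` or `"cold_start"`.
#' @param params A [kinetic_parameters] object.
#' @param config A [stochastic_config] object.
#' @return An object of class `count_trajectory`: list with `times` (s),
#'   `counts` (data.frame of integer columns `n_N`, `n_V`, `n_D`),
#'   `config`, `params`, `model`.
#' @export
ssa_run <- function(model, params, config) {
  model <- match_model_kind(model)
  stopifnot(inherits(params, "kinetic_parameters"),
            inherits(config, "stochastic_config"))
  if (max(config$record_times) > params$t_end) {
    stop("record_times must lie within [0, t_end]", call. = FALSE)
  }
  omega_na <- config$omega * AVOGADRO
  n_V0 <- as.integer(round(params$V0 * omega_na))
  set.seed(config$seed)
  m <- ssa_run_cpp(primed = (model == "primed"),
                   lambda_on = params$lambda_N_on,
                   beta_N = params$beta_N, beta_V = params$beta_V,
                   lambda_D = params$lambda_D, omega_na = omega_na,
                   n_V0 = n_V0, t_on = params$t_on, t_off = params$t_off,
                   record_times = config$record_times)
  structure(list(times = config$record_times,
                 counts = data.frame(n_N = m[, 1], n_V = m[, 2],
                                     n_D = m[, 3]),
                 config = config, params = params, model = model),
            class = "count_trajectory")
}

#' Ensemble of stochastic realizations
#'
#' Runs `config$n_replicates` independent realizations (replicate seeds
#' derived deterministically from `config$seed`) and returns per-time mean
#' and standard error of the concentration-converted counts.
#'
#' @inheritParams ssa_run
#' @return List with `times` (s), `mean` and `se` (data.frames with columns
#'   `N`, `V`, `D` in nM), `n_replicates`, and `counts_D` (replicates x
#'   times matrix of raw dimer counts).
#' @export
ssa_ensemble <- function(model, params, config) {
  model <- match_model_kind(model)
  stopifnot(inherits(config, "stochastic_config"))
  if (config$n_replicates < 2) {
    stop("ssa_ensemble requires n_replicates >= 2", call. = FALSE)
  }
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, config$n_replicates)
  omega_na <- config$omega * AVOGADRO
  nt <- length(config$record_times)
  acc <- list(N = matrix(0L, config$n_replicates, nt),
              V = matrix(0L, config$n_replicates, nt),
              D = matrix(0L, config$n_replicates, nt))
  for (i in seq_len(config$n_replicates)) {
    cfg_i <- config
    cfg_i$seed <- seeds[i]
    cfg_i$n_replicates <- 1L
    tr <- ssa_run(model, params, cfg_i)
    acc$N[i, ] <- tr$counts$n_N
    acc$V[i, ] <- tr$counts$n_V
    acc$D[i, ] <- tr$counts$n_D
  }
  to_nM <- function(m) M_to_nM(m / omega_na)
  mean_df <- data.frame(N = colMeans(to_nM(acc$N)),
                        V = colMeans(to_nM(acc$V)),
                        D = colMeans(to_nM(acc$D)))
  se <- function(m) apply(to_nM(m), 2, stats::sd) / sqrt(nrow(m))
  se_df <- data.frame(N = se(acc$N), V = se(acc$V), D = se(acc$D))
  list(times = config$record_times, mean = mean_df, se = se_df,
       n_replicates = config$n_replicates, counts_D = acc$D)
}

#' Generate synthetic noisy dimer observations
#'
#' Produces the synthetic datasets used for parameter recovery: the
#' deterministic dimer trajectory of the chosen model, observed through
#' multiplicative lognormal noise, `obs(t) = D(t) * exp(eps)` with
#' `eps ~ Normal(0, sigma^2)` i.i.d. per replicate and time point.
#' Where the noiseless dimer is exactly zero the observation is zero.
#' Reproducible from `seed`.
#'
#' @param params True [kinetic_parameters] used to generate the data.
#' @param sigma Lognormal noise scale (`>= 0`; 0 gives noiseless data).
#' @param n_reps Number of replicate trajectories (`>= 1`).
#' @param obs_times Observation times (s) within `[0, t_end]`.
#' @param seed Integer seed.
#' @param model `"primed"` (default) or `"cold_start"`.
#' @return An object of class `synthetic_dataset`: list with `times` (s),
#'   `observed` (n_reps x times matrix, nM), `noiseless` (nM),
#'   `sigma`, `true_params`, `seed`, `model`.
#' @export
generate_noisy_trajectories <- function(params, sigma, n_reps, obs_times,
                                        seed, model = "primed") {
  model <- match_model_kind(model)
  stopifnot(inherits(params, "kinetic_parameters"))
  if (!is.numeric(sigma) || sigma < 0) {
    stop("sigma must be >= 0", call. = FALSE)
  }
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  obs_times <- as.numeric(obs_times)
  if (any(obs_times < 0) || any(obs_times > params$t_end)) {
    stop("obs_times must lie within [0, t_end]", call. = FALSE)
  }
  if (any(diff(obs_times) <= 0)) {
    stop("obs_times must be strictly increasing", call. = FALSE)
  }
  d <- noiseless_dimer(model, params, obs_times)
  set.seed(seed)
  eps <- matrix(stats::rnorm(n_reps * length(obs_times), 0, sigma),
                nrow = n_reps)
  observed <- sweep(exp(eps), 2, d, `*`)
  structure(list(times = obs_times, observed = observed, noiseless = d,
                 sigma = sigma, true_params = params, seed = as.integer(seed),
                 model = model),
            class = "synthetic_dataset")
}

#' Default observation design for synthetic datasets
#'
#' Observations every 60 s from one reporting interval after production
#' onset to the simulation end — the same reporting cadence as the
#' deterministic simulator's default output grid. Time-lapse imaging of a
#' fluorescent dimer reporter at one frame per minute is a realistic
#' acquisition rate for this developmental window.
#'
#' @param params A [kinetic_parameters] object.
#' @param dt Observation spacing (s), default 60.
#' @return Numeric vector of observation times (s).
#' @export
default_obs_times <- function(params, dt = 60) {
  stopifnot(inherits(params, "kinetic_parameters"))
  seq(params$t_on + dt, params$t_end, by = dt)
}

# Deterministic dimer trajectory (nM) evaluated at obs_times.
noiseless_dimer <- function(model, params, obs_times) {
  grid <- sort(unique(c(0, params$t_on, params$t_off, obs_times)))
  grid <- grid[grid <= params$t_end]
  traj <- integrate_model(model, params, grid = grid)
  M_to_nM(traj$states$D[match(obs_times, traj$times)])
}
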