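#' Closed-form Nodal monomer solution in the no-dimerization limit
#'
#' With `lambda_D = 0` the Nodal equation decouples to
#' `dN/dt = lambda_N(t) - beta_N * N`, a linear ODE with piecewise-constant
#' forcing whose solution is elementary:
#' * `N(t) = 0` for `t <= t_on`;
#' * `N(t) = (lambda_N/beta_N) (1 - exp(-beta_N (t - t_on)))` inside the
#'   window;
#' * exponential decay `N(t_off) exp(-beta_N (t - t_off))` afterwards.
#'
#' Used as an independent oracle for the numerical integrator.
#'
#' @param t Time (s), vectorized; must be non-negative.
#' @param params A [kinetic_parameters] object (interpreted with
#'   `lambda_D = 0`).
#' @return Nodal monomer concentration (M).
#' @export
monomer_closed_form <- function(t, params) {
  stopifnot(inherits(params, "kinetic_parameters"))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("t must be finite and >= 0", call. = FALSE)
  }
  lam <- params$lambda_N_on
  bN <- params$beta_N
  rise <- function(dt) {
    if (bN > 0) (lam / bN) * (1 - exp(-bN * dt)) else lam * dt
  }
  n_off <- rise(params$t_off - params$t_on)
  ifelse(t <= params$t_on, 0,
         ifelse(t <= params$t_off,
                rise(t - params$t_on),
                n_off * exp(-bN * (t - params$t_off))))
}

#' Closed-form Vg1 decay in the no-dimerization limit
#'
#' With no heterodimerization sink (`lambda_D * N * V = 0`) the maternal
#' Vg1 pool decays exponentially: `V(t) = V0 exp(-beta_V t)`.
#'
#' @inheritParams monomer_closed_form
#' @return Vg1 monomer concentration (M).
#' @export
vg1_decay_closed_form <- function(t, params) {
  stopifnot(inherits(params, "kinetic_parameters"))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("t must be finite and >= 0", call. = FALSE)
  }
  params$V0 * exp(-params$beta_V * t)
}

#' Quasi-steady-state Nodal monomer of the cold-start model
#'
#' During the production window the cold-start monomer settles where
#' synthesis balances degradation plus the homodimerization sink:
#' `lambda_D N^2 + beta_N N - lambda_N = 0`. Returns the non-negative root
#' \deqn{N^* = \frac{-\beta_N + \sqrt{\beta_N^2 + 4 \lambda_D \lambda_N}}
#'   {2 \lambda_D}.}
#' For `lambda_N = 0` the root is 0.
#'
#' @param params A [kinetic_parameters] object with `lambda_D > 0`.
#' @return Quasi-steady-state monomer concentration (M).
#' @examples
#' M_to_nM(cold_start_qss_monomer(default_parameters()))  # ~0.393 nM
#' @export
cold_start_qss_monomer <- function(params) {
  stopifnot(inherits(params, "kinetic_parameters"))
  if (params$lambda_D <= 0) {
    stop("cold_start_qss_monomer requires lambda_D > 0", call. = FALSE)
  }
  if (params$lambda_N_on == 0) return(0)
  disc <- params$beta_N^2 + 4 * params$lambda_D * params$lambda_N_on
  (-params$beta_N + sqrt(disc)) / (2 * params$lambda_D)
}
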