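#' Model selection
#'
#' The two kinetic schemes compared by the package:
#' * `"primed"` — a maternal Vg1 monomer pool is present before Nodal
#'   production begins; the signaling dimer is the Vg1-Nodal heterodimer
#'   (flux `lambda_D * N * V`).
#' * `"cold_start"` — no Vg1; Nodal monomers must accumulate and
#'   homodimerize (flux `lambda_D * N^2`).
#'
#' @param model Character string naming the model.
#' @return The matched model kind.
#' @export
model_kinds <- function() c("primed", "cold_start")

match_model_kind <- function(model) {
  match.arg(model, model_kinds())
}

#' Windowed Nodal synthesis rate
#'
#' Nodal monomer production is piecewise constant: zero before zygotic
#' transcription starts (`t_on`, 4 hpf by default), `lambda_N_on` during
#' the mesendodermal patterning window, zero after `t_off` (6 hpf by
#' default). The value at exactly `t_on` or `t_off` is defined as 0; a value
#' on a measure-zero set cannot affect the integral, and a fixed convention
#' keeps the function deterministic.
#'
#' @param t Time (s), vectorized; must be non-negative.
#' @param params A [kinetic_parameters] object.
#' @return Synthesis rate (M s^-1), same length as `t`.
#' @examples
#' p <- default_parameters()
#' production_rate(hpf_to_s(c(3, 5, 7)), p)  # 0, 2e-13, 0
#' @export
production_rate <- function(t, params) {
  stopifnot(inherits(params, "kinetic_parameters"))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("t must be finite and >= 0", call. = FALSE)
  }
  ifelse(t > params$t_on & t < params$t_off, params$lambda_N_on, 0)
}

#' Right-hand side of the primed (heterodimer) model
#'
#' Mass-action dynamics of Nodal monomer N, Vg1 monomer V, and Vg1-Nodal
#' heterodimer D:
#' \deqn{dN/dt = \lambda_N(t) - \beta_N N - \lambda_D N V}
#' \deqn{dV/dt = -\beta_V V - \lambda_D N V}
#' \deqn{dD/dt = \lambda_D N V}
#' There is no dimer degradation and no Vg1 synthesis: Vg1 is maternally
#' deposited and enters only through the initial condition.
#'
#' @param t Time (s).
#' @param state Named numeric vector or list with components `N`, `V`, `D`
#'   (M); all must be non-negative.
#' @param params A [kinetic_parameters] object.
#' @return Named numeric vector `c(N = dN/dt, V = dV/dt, D = dD/dt)` in
#'   M s^-1.
#' @export
rhs_primed <- function(t, state, params) {
  s <- check_state(state, c("N", "V", "D"))
  lam <- production_rate(t, params)
  dim_flux <- params$lambda_D * s[["N"]] * s[["V"]]
  c(N = lam - params$beta_N * s[["N"]] - dim_flux,
    V = -params$beta_V * s[["V"]] - dim_flux,
    D = dim_flux)
}

#' Right-hand side of the cold-start (homodimer) model
#'
#' Mass-action dynamics of Nodal monomer N and Nodal-Nodal homodimer D:
#' \deqn{dN/dt = \lambda_N(t) - \beta_N N - \lambda_D N^2}
#' \deqn{dD/dt = \lambda_D N^2}
#' The homodimerization sink removes one unit of N per unit of D formed,
#' exactly as the model equations are written; see the package vignette for
#' discussion of this stoichiometric convention.
#'
#' @inheritParams rhs_primed
#' @param state Named numeric vector or list with components `N`, `D` (M).
#' @return Named numeric vector `c(N = dN/dt, D = dD/dt)` in M s^-1.
#' @export
rhs_cold_start <- function(t, state, params) {
  s <- check_state(state, c("N", "D"))
  lam <- production_rate(t, params)
  dim_flux <- params$lambda_D * s[["N"]]^2
  c(N = lam - params$beta_N * s[["N"]] - dim_flux,
    D = dim_flux)
}

check_state <- function(state, fields) {
  s <- unlist(state)
  if (!all(fields %in% names(s))) {
    stop("state must have components ", paste(fields, collapse = ", "),
         call. = FALSE)
  }
  s <- s[fields]
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("state concentrations must be finite and >= 0", call. = FALSE)
  }
  s
}
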