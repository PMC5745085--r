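#' Kinetic parameters for the dimerization models
#'
#' Bundle of rate constants, the maternal Vg1 pool, and the zygotic
#' production window that together define both the primed (Vg1-Nodal
#' heterodimer) and cold-start (Nodal homodimer) kinetic schemes.
#'
#' All fields are stored in SI units (M, s). Use the `*_nM` / `*_hpf`
#' arguments of [kinetic_parameters()] convenience wrappers, or convert with
#' [nM_to_M()] and [hpf_to_s()].
#'
#' @param lambda_N_on Nodal synthesis rate during the production window
#'   (M s^-1). Outside the window synthesis is zero.
#' @param beta_N First-order Nodal monomer degradation rate (s^-1).
#' @param beta_V First-order Vg1 monomer degradation rate (s^-1).
#' @param lambda_D Bimolecular dimerization rate (M^-1 s^-1). Applies to
#'   Nodal-Vg1 heterodimerization (primed) and Nodal-Nodal homodimerization
#'   (cold-start) alike.
#' @param V0 Initial maternal Vg1 monomer concentration (M).
#' @param t_on Production window start (s); zygotic transcription onset.
#' @param t_off Production window end (s).
#' @param t_end Simulation end time (s).
#' @return An object of class `kinetic_parameters` (a named list).
#' @seealso [default_parameters()] for the published parameterization.
#' @examples
#' p <- default_parameters()
#' p$beta_N                 # 1.16e-4 per second
#' M_to_nM(p$V0)            # 100 nM maternal Vg1
#' @export
kinetic_parameters <- function(lambda_N_on, beta_N, beta_V, lambda_D, V0,
                               t_on = hpf_to_s(4), t_off = hpf_to_s(6),
                               t_end = hpf_to_s(10)) {
  p <- list(lambda_N_on = as.numeric(lambda_N_on),
            beta_N = as.numeric(beta_N),
            beta_V = as.numeric(beta_V),
            lambda_D = as.numeric(lambda_D),
            V0 = as.numeric(V0),
            t_on = as.numeric(t_on),
            t_off = as.numeric(t_off),
            t_end = as.numeric(t_end))
  validate_kinetic_parameters(p)
  structure(p, class = "kinetic_parameters")
}

validate_kinetic_parameters <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("all kinetic parameters must be finite numeric scalars: ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  }
  rates <- c("lambda_N_on", "beta_N", "beta_V", "lambda_D", "V0")
  bad <- rates[vapply(rates, function(nm) p[[nm]] < 0, logical(1))]
  if (length(bad)) {
    stop("rates and V0 must be >= 0; negative: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!(0 <= p$t_on && p$t_on < p$t_off && p$t_off <= p$t_end)) {
    stop("require 0 <= t_on < t_off <= t_end (got t_on = ", p$t_on,
         ", t_off = ", p$t_off, ", t_end = ", p$t_end, " s)", call. = FALSE)
  }
  invisible(p)
}

#' Published default parameterization
#'
#' The rate constants and initial condition used for the primed vs
#' cold-start comparison: Nodal synthesis 2e-13 M/s between 4 and 6 hpf,
#' Nodal and Vg1 degradation 1.16e-4 /s (half-life ~1.66 h), dimerization
#' rate 1e6 /M/s, and a 100 nM maternal Vg1 pool. The simulation horizon
#' defaults to 10 hpf, covering the post-window decay.
#'
#' @param t_end Simulation end time (s); default 10 hpf.
#' @return A [kinetic_parameters] object.
#' @export
default_parameters <- function(t_end = hpf_to_s(10)) {
  kinetic_parameters(lambda_N_on = 2e-13,
                     beta_N = 1.16e-4,
                     beta_V = 1.16e-4,
                     lambda_D = 1e6,
                     V0 = nM_to_M(100),
                     t_on = hpf_to_s(4),
                     t_off = hpf_to_s(6),
                     t_end = t_end)
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("Kinetic parameters (SI units internally):\n")
  cat(sprintf("  lambda_N_on: %.4g M/s during (%g, %g) hpf\n",
              x$lambda_N_on, s_to_hpf(x$t_on), s_to_hpf(x$t_off)))
  cat(sprintf("  beta_N: %.4g /s   beta_V: %.4g /s\n", x$beta_N, x$beta_V))
  cat(sprintf("  lambda_D: %.4g /M/s\n", x$lambda_D))
  cat(sprintf("  V0: %.4g nM\n", M_to_nM(x$V0)))
  cat(sprintf("  t_end: %g hpf\n", s_to_hpf(x$t_end)))
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, revalidated.
#'
#' @param params A [kinetic_parameters] object.
#' @param ... Named fields to replace (SI units).
#' @return A new `kinetic_parameters` object.
#' @export
update_parameters <- function(params, ...) {
  stopifnot(inherits(params, "kinetic_parameters"))
  repl <- list(...)
  unknown <- setdiff(names(repl), names(params))
  if (length(unknown)) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p <- unclass(params)
  p[names(repl)] <- lapply(repl, as.numeric)
  do.call(kinetic_parameters, p)
}

#' Serialize parameters to a flat I/O-unit list
#'
#' The on-disk representation uses the mixed units of the published
#' parameter table: rates in SI, concentrations in nM, times in hpf. Keys:
#' `lambda_N_on_M_per_s`, `beta_N_per_s`, `beta_V_per_s`,
#' `lambda_D_per_M_per_s`, `V0_nM`, `t_on_hpf`, `t_off_hpf`, `t_end_hpf`.
#'
#' @param params A [kinetic_parameters] object.
#' @return A named list suitable for JSON/YAML serialization.
#' @export
params_to_io_list <- function(params) {
  stopifnot(inherits(params, "kinetic_parameters"))
  list(lambda_N_on_M_per_s = params$lambda_N_on,
       beta_N_per_s = params$beta_N,
       beta_V_per_s = params$beta_V,
       lambda_D_per_M_per_s = params$lambda_D,
       V0_nM = M_to_nM(params$V0),
       t_on_hpf = s_to_hpf(params$t_on),
       t_off_hpf = s_to_hpf(params$t_off),
       t_end_hpf = s_to_hpf(params$t_end))
}

#' @rdname params_to_io_list
#' @param x A named list with the I/O-unit keys (unknown keys rejected).
#' @export
params_from_io_list <- function(x) {
  keys <- c("lambda_N_on_M_per_s", "beta_N_per_s", "beta_V_per_s",
            "lambda_D_per_M_per_s", "V0_nM", "t_on_hpf", "t_off_hpf",
            "t_end_hpf")
  unknown <- setdiff(names(x), keys)
  if (length(unknown)) {
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(keys, names(x))
  if (length(missing)) {
    stop("missing parameter key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  kinetic_parameters(lambda_N_on = x$lambda_N_on_M_per_s,
                     beta_N = x$beta_N_per_s,
                     beta_V = x$beta_V_per_s,
                     lambda_D = x$lambda_D_per_M_per_s,
                     V0 = nM_to_M(x$V0_nM),
                     t_on = hpf_to_s(x$t_on_hpf),
                     t_off = hpf_to_s(x$t_off_hpf),
                     t_end = hpf_to_s(x$t_end_hpf))
}
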