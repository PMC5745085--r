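#' Unit conversion helpers
#'
#' All internal computation is in SI units (molar concentrations, seconds).
#' User-facing I/O uses nanomolar (nM) and hours post-fertilization (hpf).
#' Conversions are exact: 1 nM = 1e-9 M, 1 hpf = 3600 s.
#'
#' @param x Numeric vector to convert.
#' @return Numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
hpf_to_s <- function(x) x * 3600

#' @rdname units
#' @export
s_to_hpf <- function(x) x / 3600

#' @rdname units
#' @export
nM_to_M <- function(x) x * 1e-9

#' @rdname units
#' @export
M_to_nM <- function(x) x * 1e9

# Avogadro's constant (CODATA exact value), used for count<->concentration
# conversion in the stochastic module.
AVOGADRO <- 6.02214076e23
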