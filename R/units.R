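# Speed of light in cm per femtosecond; the single constant every unit
# conversion in the package goes through.
.c_cm_per_fs <- 2.99792458e-5

#' Convert spectroscopic wavenumbers to rates
#'
#' Spectroscopic couplings and site energies are quoted in wavenumbers
#' (cm^-1); the equations of motion use rates in fs^-1 (energies divided by
#' hbar). Under the angular convention a wavenumber `x` maps to the angular
#' frequency `2 * pi * c * x`; under the linear convention to `c * x`.
#' The angular convention is the default because the coupling rate multiplies
#' amplitudes directly in the equation of motion.
#'
#' @param x Numeric vector of wavenumbers in cm^-1; must be non-negative.
#' @param convention `"angular"` (factor `2*pi*c`, default) or `"linear"`
#'   (factor `c`).
#' @return Rates in fs^-1, same length as `x`.
#' @examples
#' wavenumber_to_rate(530)            # ~0.0998 fs^-1
#' rate_to_wavenumber(wavenumber_to_rate(530))
#' @export
wavenumber_to_rate <- function(x, convention = c("angular", "linear")) {
  convention <- match.arg(convention)
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("wavenumber must be finite numeric", call. = FALSE)
  }
  if (any(x < 0)) stop("wavenumber must be non-negative", call. = FALSE)
  x * unit_factor(convention)
}

#' Convert rates to spectroscopic wavenumbers
#'
#' Exact inverse of [wavenumber_to_rate()].
#'
#' @param x Numeric vector of rates in fs^-1; must be non-negative.
#' @inheritParams wavenumber_to_rate
#' @return Wavenumbers in cm^-1.
#' @export
rate_to_wavenumber <- function(x, convention = c("angular", "linear")) {
  convention <- match.arg(convention)
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("rate must be finite numeric", call. = FALSE)
  }
  if (any(x < 0)) stop("rate must be non-negative", call. = FALSE)
  x / unit_factor(convention)
}

unit_factor <- function(convention) {
  switch(convention,
    angular = 2 * pi * .c_cm_per_fs,
    linear  = .c_cm_per_fs,
    stop("unknown unit convention: ", convention, call. = FALSE)
  )
}
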