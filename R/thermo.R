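#' Thermodynamic context
#'
#' Bundles the absolute temperature and the Boltzmann constant, and derives
#' the inverse temperature `beta = 1 / (kB * T)`. All energies in the package
#' are in kJ/mol, so `kB` defaults to 0.00831446 kJ/(mol K) and `beta` is in
#' mol/kJ.
#'
#' @param temperature Absolute temperature in Kelvin. Must be > 0.
#' @param kB Boltzmann constant in kJ/(mol K).
#' @return An object of class `thermo_context` with fields `temperature`,
#'   `kB` and `beta`.
#' @examples
#' th <- thermo_context(300)
#' th$beta # about 0.4009 mol/kJ
#' @export
thermo_context <- function(temperature = 300, kB = 0.00831446) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature), temperature > 0,
            is.numeric(kB), length(kB) == 1L, kB > 0)
  structure(
    list(temperature = temperature, kB = kB, beta = 1 / (kB * temperature)),
    class = "thermo_context"
  )
}

#' @export
print.thermo_context <- function(x, ...) {
  cat(sprintf("<thermo_context> T = %g K, kB = %g kJ/(mol K), beta = %g mol/kJ\n",
              x$temperature, x$kB, x$beta))
  invisible(x)
}

is_thermo <- function(x) inherits(x, "thermo_context")
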