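#' Physical constants (CODATA 2018)
#'
#' Exact CODATA 2018 values of the constants used throughout the package:
#' elementary charge `e` (C), vacuum permittivity `epsilon0` (F/m), Boltzmann
#' constant `kB` (J/K) and the Avogadro constant `avogadro` (1/mol).
#'
#' @return Named list of constants in SI units.
#' @examples
#' physical_constants()$kB
#' @export
physical_constants <- function() {
  list(
    e        = 1.602176634e-19,  # C, exact
    epsilon0 = 8.8541878128e-12, # F/m
    kB       = 1.380649e-23,     # J/K, exact
    avogadro = 6.02214076e23     # 1/mol, exact
  )
}

# internal shorthand
.const <- physical_constants()

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    .stopf("'%s' must be a single positive finite number", name)
  invisible(x)
}
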