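#' Smoluchowski mobility/zeta conversions
#'
#' In the thin-double-layer (Smoluchowski) limit the electrophoretic mobility
#' and zeta potential are proportional: mu_e = epsilon zeta / eta, with
#' epsilon = eps_rel * epsilon0 the absolute permittivity of the suspending
#' medium. `zeta_from_mobility()` returns zeta in mV;
#' `mobility_from_zeta()` is the exact inverse and returns m^2/(V s). The
#' default medium is the electrophoresis buffer (1 mM KNO3: eps_rel = 100,
#' eta = 1e-3 Pa s), deliberately distinct from pure water. Note the measured
#' zeta is a bare (weakly screened) surface potential; under physiological
#' ionic strength the effective electrostatics are screened far below it.
#'
#' @param mobility Electrophoretic mobility in m^2/(V s); vectorized.
#' @param zeta_mV Zeta potential in mV; vectorized.
#' @param medium A [solvent_medium()] with viscosity.
#' @return mV, or m^2/(V s) respectively.
#' @examples
#' zeta_from_mobility(3.9e-8)  # ~44 mV
#' @export
zeta_from_mobility <- function(mobility, medium = zeta_medium()) {
  medium <- .as_medium(medium)
  if (is.na(medium$viscosity)) .stopf("medium viscosity is required")
  1e3 * mobility * medium$viscosity /
    (medium$relative_permittivity * .const$epsilon0)
}

#' @rdname zeta_from_mobility
#' @export
mobility_from_zeta <- function(zeta_mV, medium = zeta_medium()) {
  medium <- .as_medium(medium)
  if (is.na(medium$viscosity)) .stopf("medium viscosity is required")
  zeta_mV * 1e-3 * medium$relative_permittivity * .const$epsilon0 /
    medium$viscosity
}

#' Electrophoresis measurement medium default
#'
#' The dilute KNO3 suspension buffer used for zeta measurements:
#' eps_rel = 100, eta = 1e-3 Pa s at 298.15 K.
#' @return A [solvent_medium()].
#' @export
zeta_medium <- function() solvent_medium(100, 298.15, 1e-3)

#' Summarize replicate zeta measurements
#'
#' Mean, sample standard deviation and a neutrality call for a set of
#' replicate zeta potentials; a preparation is called neutral when the
#' absolute mean lies within `neutrality_band` mV of zero.
#'
#' @param values_mV Numeric vector of replicate zeta potentials in mV.
#' @param neutrality_band Half-width of the neutrality band in mV (default 5).
#' @return Object of class `zeta_summary` with `mean`, `sd`, `n`, `neutral`.
#' @examples
#' summarize_replicates(c(-2, 3, 3, -3, -4))  # neutral
#' @export
summarize_replicates <- function(values_mV, neutrality_band = 5) {
  if (length(values_mV) < 1L) .stopf("no replicate values supplied")
  m <- mean(values_mV)
  s <- if (length(values_mV) >= 2L) stats::sd(values_mV) else NA_real_
  structure(list(mean = m, sd = s, n = length(values_mV),
                 neutral = abs(m) <= neutrality_band),
            class = "zeta_summary")
}

#' @export
print.zeta_summary <- function(x, ...) {
  cat(sprintf("Zeta: %.1f +/- %.1f mV (n = %d)%s\n", x$mean,
              ifelse(is.na(x$sd), 0, x$sd), x$n,
              if (x$neutral) " [neutral]" else ""))
  invisible(x)
}
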