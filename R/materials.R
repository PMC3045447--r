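#' X-ray optical constants for phantom materials
#'
#' The complex refractive index of a material at hard X-ray energies is
#' `n = 1 - delta - i*beta`: `delta` (the refractive decrement) drives the
#' phase shift accumulated along a ray and `beta` the absorption. For soft
#' tissue in the 10-30 keV range `delta/beta` is of order one thousand, which
#' is why propagation-based imaging sees air/tissue interfaces that
#' absorption contrast cannot.
#'
#' Reference constants are tabulated at 18 keV and scaled as
#' `delta ~ 1/E^2` (Thomson scattering, far from edges) and `beta ~ 1/E^4`
#' (photoelectric regime) for other energies in the supported 8-72.5 keV
#' band of a bending-magnet imaging beamline.
#'
#' @param energy_keV beam energy in keV, in `[8, 72.5]`.
#' @return A `material_table` data frame with columns `material`, `delta`,
#'   `beta` (rows: `air`, `soft_tissue`, `bone`) and attribute `energy_keV`.
#' @examples
#' tab <- build_material_table(18)
#' with(tab, delta / beta)   # soft tissue ratio ~ 1000
#' @export
build_material_table <- function(energy_keV) {
  if (!is.numeric(energy_keV) || length(energy_keV) != 1 || is.na(energy_keV)) {
    stop("energy_keV must be a single number")
  }
  if (energy_keV < 8 || energy_keV > 72.5) {
    stop("energy ", energy_keV, " keV outside the supported 8-72.5 keV range")
  }
  ref <- material_constants_18keV()
  se <- (18 / energy_keV)^2
  tab <- data.frame(
    material = ref$material,
    delta = ref$delta * se,
    beta = ref$beta * se * se,
    stringsAsFactors = FALSE
  )
  attr(tab, "energy_keV") <- energy_keV
  class(tab) <- c("material_table", "data.frame")
  validate_material_table(tab)
  tab
}

# Reference delta/beta at 18 keV (lambda = 0.6888 A).
#
# soft tissue: water-equivalent.
#   delta = r_e * lambda^2 * n_e / (2 pi) with n_e(water) = 3.34e29 m^-3
#         = 7.11e-7
#   beta  = mu * lambda / (4 pi) with mu(water, 18 keV) ~ 1.06 cm^-1
#         (NIST XCOM mass attenuation, log-interpolated 15-20 keV)
#         = 5.79e-10          -> delta/beta ~ 1.2e3
# bone: cortical bone, rho = 1.92 g/cm^3, n_e ~ 1.78 x water
#   delta = 1.26e-6;  mu ~ 10.4 cm^-1 -> beta = 5.70e-9
# air: sea level, rho = 1.205e-3 g/cm^3, n_e ~ 1.08e-3 x water
#   delta = 7.70e-10; mu ~ 1.23e-3 cm^-1 -> beta = 6.74e-13
material_constants_18keV <- function() {
  data.frame(
    material = c("air", "soft_tissue", "bone"),
    delta = c(7.70e-10, 7.11e-7, 1.26e-6),
    beta = c(6.74e-13, 5.79e-10, 5.70e-9),
    stringsAsFactors = FALSE
  )
}

validate_material_table <- function(tab) {
  stopifnot(all(tab$delta >= 0), all(tab$beta >= 0))
  d <- function(m) tab$delta[tab$material == m]
  b <- function(m) tab$beta[tab$material == m]
  if (!(d("air") < d("soft_tissue") && d("soft_tissue") < d("bone"))) {
    stop("delta ordering air < soft_tissue < bone violated")
  }
  if (!(b("air") < b("soft_tissue") && b("soft_tissue") < b("bone"))) {
    stop("beta ordering air < soft_tissue < bone violated")
  }
  if (d("soft_tissue") / b("soft_tissue") <= 100) {
    stop("soft tissue delta/beta must exceed 100 at hard X-ray energies")
  }
  invisible(tab)
}

#' @export
print.material_table <- function(x, ...) {
  cat(sprintf("<material_table at %.4g keV>\n", attr(x, "energy_keV")))
  print.data.frame(cbind(x, ratio = x$delta / x$beta), row.names = FALSE,
                   digits = 4)
  invisible(x)
}

# delta/beta lookup for a label volume (0 air, 1 soft tissue, 2 bone)
material_lookup <- function(tab) {
  list(
    delta = c(tab$delta[tab$material == "air"],
              tab$delta[tab$material == "soft_tissue"],
              tab$delta[tab$material == "bone"]),
    beta = c(tab$beta[tab$material == "air"],
             tab$beta[tab$material == "soft_tissue"],
             tab$beta[tab$material == "bone"])
  )
}
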