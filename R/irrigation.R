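#' Soil layer description for irrigation scheduling
#'
#' @param theta_fc Volumetric water content at field capacity (cm^3 cm^-3).
#' @param theta_i Current volumetric water content (cm^3 cm^-3).
#' @param dz Layer thickness (m).
#' @return A `soil_layer` list.
#' @export
soil_layer <- function(theta_fc, theta_i, dz) {
  if (!(dz > 0)) abort("layer thickness `dz` must be > 0.", class = "forageQG_domain_error")
  if (theta_fc < 0 || theta_fc > 1 || theta_i < 0) {
    abort("volumetric water contents must lie in [0, 1].", class = "forageQG_domain_error")
  }
  if (theta_i > theta_fc) {
    abort("current water content exceeds field capacity.", class = "forageQG_domain_error")
  }
  structure(list(theta_fc = theta_fc, theta_i = theta_i, dz = dz),
            class = "soil_layer")
}

#' Net irrigation depth from soil water deficit
#'
#' The depth of water needed to refill the profile to field capacity:
#' the soil-water deficit summed over layers,
#' `d_n = sum_i (theta_FC,i - theta_i) * dz_i`. The single-layer case is the
#' usual drip-irrigation configuration; any layer count is accepted.
#'
#' @param layers A `soil_layer` or a list of them.
#' @return Net irrigation depth in metres (>= 0).
#' @examples
#' net_irrigation_depth(soil_layer(0.32, 0.22, 0.30)) # 0.03 m
#' @export
net_irrigation_depth <- function(layers) {
  if (inherits(layers, "soil_layer")) layers <- list(layers)
  stopifnot(length(layers) >= 1)
  sum(vapply(layers, function(l) {
    if (!inherits(l, "soil_layer")) l <- do.call(soil_layer, l)
    (l$theta_fc - l$theta_i) * l$dz
  }, numeric(1)))
}

#' Gross irrigation depth under an application efficiency and deficit level
#'
#' Converts a net depth to the gross depth actually applied, allowing for
#' conveyance/application losses (default efficiency 0.9, i.e. 10% loss) and
#' for deficit-irrigation treatments that deliver only a fraction of the
#' full requirement (e.g. 0.5 for a 50% drought-stress treatment, 1.0 for
#' the well-watered control).
#'
#' @param d_n Net irrigation depth (m), `>= 0`.
#' @param efficiency Application efficiency in (0, 1]; default 0.9.
#' @param treatment_fraction Fraction of the gross depth applied, in (0, 1].
#' @return Gross depth applied (m): `treatment_fraction * d_n / efficiency`.
#' @examples
#' gross_irrigation_depth(0.09)                            # 0.10 control
#' gross_irrigation_depth(0.09, treatment_fraction = 0.5)  # 0.05 stress
#' @export
gross_irrigation_depth <- function(d_n, efficiency = 0.9, treatment_fraction = 1.0) {
  if (d_n < 0) abort("`d_n` must be >= 0.", class = "forageQG_domain_error")
  if (!(efficiency > 0 && efficiency <= 1)) {
    abort("`efficiency` must be in (0, 1].", class = "forageQG_domain_error")
  }
  if (!(treatment_fraction > 0 && treatment_fraction <= 1)) {
    abort("`treatment_fraction` must be in (0, 1].", class = "forageQG_domain_error")
  }
  treatment_fraction * d_n / efficiency
}
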