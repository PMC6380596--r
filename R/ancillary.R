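# Ancillary layers: crop suitability, potential yields, rural population
# density and irrigated area, with controllable spatial structure.

# Per-system multipliers applied to potential yields: irrigated crops
# out-yield high-input rainfed, which out-yields low-input/subsistence.
SYSTEM_YIELD_MULT <- c(
  irrigated = 1.5, rainfed_high = 1.2, rainfed_low = 0.8, subsistence = 0.6
)
# Suitable-area fractions of pixel area by system (<= 1 keeps the
# suitable-area <= pixel-area invariant).
SYSTEM_SUIT_FRAC <- c(
  irrigated = 0.9, rainfed_high = 1.0, rainfed_low = 1.0, subsistence = 1.0
)

#' Generate ancillary layers for a landscape
#'
#' Produces the layers the cross-entropy priors are built from: a
#' crop- and system-specific suitable-area surface, potential yields
#' positively associated with suitability, a smooth rural population
#' density surface and an irrigated-area layer bounded by cropland.
#' Each crop receives its own spatially autocorrelated suitability field,
#' so different crops have distinct spatial optima; `suitability_sharpness`
#' controls the contrast (0 gives spatially uniform suitability).
#'
#' @param landscape A [generate_landscape()] result.
#' @param crops A `crop_set`.
#' @param suitability_sharpness Nonnegative contrast exponent; 0 makes
#'   every crop's suitability uniform.
#' @param seed RNG seed (mandatory).
#' @param spatial_corr_length Correlation length (pixels) of the
#'   suitability and population fields.
#' @param irrigated_frac Mean fraction of cropland that is irrigated.
#' @param suitability_floor Minimum of the normalized suitability in
#'   `[0, 1)`.  A positive floor guarantees every reporting unit enough
#'   suitable area to host any allocation target its own cropland can
#'   generate, keeping the suitability-constrained baseline feasible.
#' @return An `ancillary` object: list with `suitable_area` and
#'   `potential_yield` (arrays `n_pixels x n_crops x 4`),
#'   `rural_pop_density` and `irrigated_area` (vectors of length
#'   `n_pixels`).
#' @export
generate_ancillary <- function(landscape, crops, suitability_sharpness = 5,
                               seed, spatial_corr_length = 3,
                               irrigated_frac = 0.25,
                               suitability_floor = 0.25) {
  stopifnot(inherits(landscape, "landscape"), inherits(crops, "crop_set"))
  if (suitability_sharpness < 0) stopf("`suitability_sharpness` must be >= 0")
  if (suitability_floor < 0 || suitability_floor >= 1) {
    stopf("`suitability_floor` must be in [0, 1)")
  }
  J <- n_crops(crops)
  L <- length(production_systems())
  N <- n_pixels(landscape)
  with_seed(seed, {
    suit_norm <- matrix(0, N, J)  # in (0, 1], per-crop normalized
    for (j in seq_len(J)) {
      z <- smooth_noise_field(landscape$n_rows, landscape$n_cols,
                              spatial_corr_length)
      e <- exp(suitability_sharpness * as.vector(z))
      suit_norm[, j] <- suitability_floor +
        (1 - suitability_floor) * e / max(e)
    }
    suitable_area <- array(0, dim = c(N, J, L),
                           dimnames = list(NULL, crops$table$name,
                                           production_systems()))
    potential_yield <- suitable_area
    base_yield <- stats::rlnorm(J, meanlog = log(2), sdlog = 0.3)
    for (l in seq_len(L)) {
      suitable_area[, , l] <-
        landscape$pixel_area * SYSTEM_SUIT_FRAC[l] * suit_norm
      potential_yield[, , l] <-
        sweep(0.5 + suit_norm, 2, base_yield * SYSTEM_YIELD_MULT[l], `*`)
    }
    zp <- smooth_noise_field(landscape$n_rows, landscape$n_cols,
                             spatial_corr_length)
    rural_pop_density <- 50 * exp(0.8 * as.vector(zp))  # persons / km^2
    zi <- smooth_noise_field(landscape$n_rows, landscape$n_cols,
                             spatial_corr_length)
    irr_frac <- stats::pnorm(as.vector(zi))
    irr_frac <- irr_frac * irrigated_frac / mean(irr_frac)
    irrigated_area <- as.vector(landscape$cropland) * pmin(1, irr_frac)

    structure(
      list(
        suitable_area = suitable_area,
        potential_yield = potential_yield,
        rural_pop_density = rural_pop_density,
        irrigated_area = irrigated_area
      ),
      class = "ancillary"
    )
  })
}
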