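# Allocation results and the simple (cropland-proportional) allocator.

new_allocation <- function(physical_area, harvested_area, production, yield,
                           method, scenario = NULL, adjustments = NULL,
                           residuals = NULL) {
  structure(
    list(
      physical_area = physical_area, harvested_area = harvested_area,
      production = production, yield = yield,
      method = method, scenario = scenario,
      adjustments = adjustments, residuals = residuals
    ),
    class = "allocation"
  )
}

#' @export
print.allocation <- function(x, ...) {
  cat(sprintf(
    "<allocation> method=%s%s: %d pixels x %d crops; total harvested %.1f ha, production %.1f mt\n",
    x$method,
    if (!is.null(x$scenario)) paste0(" scenario=", x$scenario) else "",
    nrow(x$harvested_area), ncol(x$harvested_area),
    sum(x$harvested_area), sum(x$production)))
  invisible(x)
}

# Pixel raster (matrix n_rows x n_cols) for one crop/variable.
allocation_raster <- function(result, landscape,
                              variable = c("harvested", "production", "yield"),
                              crop) {
  variable <- match.arg(variable)
  m <- switch(variable, harvested = result$harvested_area,
              production = result$production, yield = result$yield)
  matrix(m[, crop], landscape$n_rows, landscape$n_cols)
}

#' Convert a ground-truth allocation into an allocation result
#'
#' Derives the harvested-area, production and yield surfaces implied by a
#' `true_allocation`, so the truth can enter [compare_allocations()] like
#' any model output.
#'
#' @param truth A `true_allocation`.
#' @param landscape,ancillary,crops The synthetic world.
#' @return An `allocation` with `method = "truth"`.
#' @export
truth_to_allocation <- function(truth, landscape, ancillary, crops) {
  out <- pixel_outputs(truth$physical_area, ancillary, crops)
  yld <- ifelse(out$harvested > 0, out$production / out$harvested, 0)
  new_allocation(truth$physical_area, out$harvested, out$production, yld,
                 method = "truth")
}

#' Simple cropland-proportional allocation
#'
#' Spreads each reporting unit's harvested area per crop over the unit's
#' pixels in proportion to their cropland share, and assigns every pixel
#' the unit-level average yield.  Production is the product of the two.
#' No production-system split is made: all physical area is placed in a
#' single composite system (the first system slot), with a cropping
#' intensity of 1.  Crops are allocated independently; no per-pixel
#' capacity cap is enforced, so summed crop area may exceed a pixel's
#' cropland under multi-cropping.
#'
#' @param sru_table SRU statistics (any mix of reporting levels).
#' @param landscape The pixel grid.
#' @param crops The crop catalogue.
#' @return An `allocation` with `method = "simple"`.
#' @export
allocate_simple <- function(sru_table, landscape, crops) {
  stopifnot(inherits(landscape, "landscape"), inherits(crops, "crop_set"))
  J <- n_crops(crops)
  L <- length(production_systems())
  N <- n_pixels(landscape)
  if (any(!sru_table$crop_id %in% seq_len(J))) {
    stopf("SRU table references crop ids absent from the crop set")
  }
  phys <- array(0, dim = c(N, J, L),
                dimnames = list(NULL, crops$table$name, production_systems()))
  harv <- matrix(0, N, J)
  prod <- matrix(0, N, J)
  yld <- matrix(0, N, J)
  cl <- as.vector(landscape$cropland)
  for (r in seq_len(nrow(sru_table))) {
    H <- sru_table$harvested_area[r]
    if (H <= 0) next
    j <- sru_table$crop_id[r]
    p <- pixels_of_unit(landscape, sru_table$admin_level[r],
                        sru_table$sru_id[r])
    tot <- sum(cl[p])
    if (length(p) == 0L || tot <= 0) {
      stopf("allocation infeasible: SRU %s (level %d) has positive area for crop %d but no cropland",
            sru_table$sru_id[r], sru_table$admin_level[r], j)
    }
    share <- cl[p] / tot
    h <- H * share
    harv[p, j] <- harv[p, j] + h
    y <- sru_table$yield[r]
    yld[p, j] <- y
    prod[p, j] <- prod[p, j] + h * y
    phys[p, j, 1L] <- phys[p, j, 1L] + h  # composite system, CI = 1
  }
  new_allocation(phys, harv, prod, yld, method = "simple")
}
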