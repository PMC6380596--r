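# Spatial concordance scoring: pixel-level similarity index, crop-level
# and area-weighted country-level aggregates, Moran's I diagnostics.

#' Pixel-level spatial similarity index
#'
#' `1 - |a - b| / max(a, b)` for nonnegative pixel pairs: 1 when the two
#' values are identical, 0 when one is zero and the other positive.
#' Pixels where both values are zero carry no information and are
#' signalled with `NA` (they are excluded from crop-level averaging).
#' The index is symmetric and invariant to a common positive rescaling.
#'
#' @param a,b Nonnegative numeric vectors (recycled to a common length).
#' @return Numeric vector of similarities in `[0, 1]`, `NA` where both
#'   inputs are zero.
#' @examples
#' ssi_pixel(5, 5)  # 1
#' ssi_pixel(7, 0)  # 0
#' ssi_pixel(2, 8)  # 0.25
#' @export
ssi_pixel <- function(a, b) {
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE)) {
    stopf("similarity inputs must be nonnegative")
  }
  m <- pmax(a, b)
  out <- 1 - abs(a - b) / m
  out[m == 0] <- NA_real_
  out
}

#' Crop-level mean similarity
#'
#' Arithmetic mean of the pixel similarities over the compared pixels
#' (those with a non-`NA` index, optionally restricted by a mask).
#'
#' @param ssi_raster Numeric matrix (or vector) of pixel similarities,
#'   `NA` marking excluded pixels.
#' @param mask Optional logical matrix/vector restricting the average.
#' @return The mean similarity, or `NA` when no pixel is compared.
#' @export
ssi_crop <- function(ssi_raster, mask = NULL) {
  v <- as.vector(ssi_raster)
  if (!is.null(mask)) v <- v[as.vector(mask)]
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(NA_real_)
  mean(v)
}

#' Area-weighted country-level similarity
#'
#' Weighted mean of crop-level similarities, the weight of each crop
#' being its harvested area in the designated baseline estimates.
#'
#' @param ssi_crop_values Crop-level similarities (`NA`s dropped together
#'   with their weights).
#' @param crop_harvested_areas Nonnegative weights, same length.
#' @return The weighted mean similarity.
#' @export
ssi_country <- function(ssi_crop_values, crop_harvested_areas) {
  stopifnot(length(ssi_crop_values) == length(crop_harvested_areas))
  if (any(crop_harvested_areas < 0)) stopf("weights must be nonnegative")
  keep <- !is.na(ssi_crop_values)
  w <- crop_harvested_areas[keep]
  if (sum(w) <= 0) stopf("country-level similarity undefined: all-zero weights")
  sum(ssi_crop_values[keep] * w) / sum(w)
}

#' Moran's I spatial autocorrelation
#'
#' Global Moran's I over the masked pixels of a raster, with contiguity
#' neighbourhoods (queen by default) and row-standardized weights.
#' Pixels without any in-mask neighbour are dropped.
#'
#' @param raster Numeric matrix.
#' @param mask Logical matrix of pixels to include (`NULL` = all).
#' @param contiguity `"queen"` (8 neighbours) or `"rook"` (4).
#' @return Moran's I (scalar).  Errors when fewer than 2 usable pixels
#'   remain or the masked values have zero variance.
#' @export
morans_i <- function(raster, mask = NULL, contiguity = c("queen", "rook")) {
  contiguity <- match.arg(contiguity)
  stopifnot(is.matrix(raster))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(raster), ncol(raster))
  offs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (contiguity == "queen") {
    offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  }
  m <- mask * 1
  deg <- Reduce(`+`, lapply(offs, function(o) shift_matrix(m, o[1], o[2])))
  use <- mask & deg > 0
  n <- sum(use)
  if (n < 2L) stopf("Moran's I undefined: fewer than 2 usable pixels")
  mu <- mean(raster[use])
  z <- (raster - mu) * (use * 1)
  s2 <- sum(z[use]^2)
  if (s2 <= 0) stopf("Moran's I undefined: zero variance")
  nbsum <- Reduce(`+`, lapply(offs, function(o) {
    shift_matrix(z, o[1], o[2])
  }))
  # row-standardized weights: each pixel's neighbour values averaged
  num <- sum(z[use] * nbsum[use] / deg[use])
  num / s2
}

#' Root-mean-squared-error regression diagnostic
#'
#' RMSE of an OLS regression of scenario values on baseline values over
#' the compared pixels.  Provided only as an optional diagnostic: unlike
#' the bounded similarity index it is highly sensitive to outliers and
#' its dissimilarity is unbounded, so it is not used in any aggregate
#' reported by this package.
#'
#' @param a Scenario values; regressed on `b`.
#' @param b Baseline values.
#' @return List with `rmse`, `intercept`, `slope`.
#' @export
rmse_similarity <- function(a, b) {
  keep <- !(a == 0 & b == 0)
  fit <- stats::lm(a[keep] ~ b[keep])
  list(rmse = sqrt(mean(stats::residuals(fit)^2)),
       intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]))
}

COMPARE_VARIABLES <- c("harvested", "production", "yield")

#' Compare two allocations
#'
#' The full concordance pipeline: per crop and variable (harvested area,
#' production, yield), both surfaces are focally smoothed over the
#' country mask, the pixel similarity index is computed wherever at
#' least one smoothed surface is non-zero, averaged per crop, and
#' area-weighted to a country-level score using the baseline's crop
#' harvested-area totals.  Presence shares and Moran's I (computed on
#' the unsmoothed surfaces of both allocations) are reported alongside.
#'
#' @param result_a Scenario allocation.
#' @param result_b Baseline allocation (supplies the country-level
#'   weights).
#' @param landscape,crops The world being compared on.
#' @param kernel Focal kernel; the default is a 1-pixel radius, 0.33-sd
#'   Gaussian.  Use `gaussian_kernel(0, 1)` to skip smoothing.
#' @return A `similarity_report`: list with `ssi_raster` (nested list
#'   `[[variable]][[crop]]` of matrices), `n_compared` and `ssi_crop`
#'   (crop x variable matrices), `ssi_country` (per variable),
#'   `weights`, `morans_i` (list of crop x variable matrices for `a`
#'   and `b`), and `presence` (per-crop shares for both allocations).
#' @export
compare_allocations <- function(result_a, result_b, landscape, crops,
                                kernel = gaussian_kernel(1, 0.33)) {
  stopifnot(inherits(result_a, "allocation"), inherits(result_b, "allocation"))
  J <- n_crops(crops)
  vars <- COMPARE_VARIABLES
  mask <- landscape$country_mask
  thr <- PRESENCE_THRESHOLD
  ssi_raster <- stats::setNames(vector("list", length(vars)), vars)
  n_compared <- matrix(0L, J, length(vars),
                       dimnames = list(crops$table$name, vars))
  ssi_crop_m <- matrix(NA_real_, J, length(vars),
                       dimnames = list(crops$table$name, vars))
  mi_a <- ssi_crop_m
  mi_b <- ssi_crop_m
  for (v in seq_along(vars)) {
    ssi_raster[[v]] <- vector("list", J)
    for (j in seq_len(J)) {
      ra <- allocation_raster(result_a, landscape, vars[v], j)
      rb <- allocation_raster(result_b, landscape, vars[v], j)
      sa <- focal_smooth(ra, kernel, mask)
      sb <- focal_smooth(rb, kernel, mask)
      compared <- mask & (sa > thr | sb > thr)
      ssi <- matrix(NA_real_, landscape$n_rows, landscape$n_cols)
      ssi[compared] <- ssi_pixel(sa[compared], sb[compared])
      ssi_raster[[v]][[j]] <- ssi
      n_compared[j, v] <- sum(compared)
      ssi_crop_m[j, v] <- ssi_crop(ssi)
      mi_a[j, v] <- tryCatch(morans_i(ra, mask), error = function(e) NA_real_)
      mi_b[j, v] <- tryCatch(morans_i(rb, mask), error = function(e) NA_real_)
    }
    names(ssi_raster[[v]]) <- crops$table$name
  }
  weights <- colSums(result_b$harvested_area)
  ssi_country_v <- vapply(seq_along(vars), function(v) {
    ssi_country(ssi_crop_m[, v], weights)
  }, numeric(1))
  names(ssi_country_v) <- vars
  presence <- data.frame(
    crop_id = seq_len(J), crop = crops$table$name,
    share_a = vapply(seq_len(J), function(j) {
      presence_share(result_a, landscape, j)
    }, numeric(1)),
    share_b = vapply(seq_len(J), function(j) {
      presence_share(result_b, landscape, j)
    }, numeric(1))
  )
  structure(
    list(ssi_raster = ssi_raster, n_compared = n_compared,
         ssi_crop = ssi_crop_m, ssi_country = ssi_country_v,
         weights = weights, morans_i = list(a = mi_a, b = mi_b),
         presence = presence,
         scenario_a = result_a$scenario %||% result_a$method,
         scenario_b = result_b$scenario %||% result_b$method),
    class = "similarity_report"
  )
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("<similarity_report> %s vs %s\n", x$scenario_a, x$scenario_b))
  cat("country-level SSI (area-weighted):\n")
  print(round(x$ssi_country, 4))
  cat("crop-level SSI:\n")
  print(round(x$ssi_crop, 4))
  invisible(x)
}
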