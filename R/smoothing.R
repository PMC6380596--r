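#' Gaussian focal-weight kernel
#'
#' Builds a truncated, normalized Gaussian kernel on a square window of
#' `(2*radius+1)^2` pixels.  The weight at offset `(dx, dy)` is
#' proportional to `exp(-(dx^2 + dy^2) / (2 * sd^2))`.  The default used
#' for similarity scoring is a 1-pixel radius with a 0.33-pixel standard
#' deviation: with the radius set to three standard deviations, 99.7% of
#' the mass of the untruncated Gaussian falls inside the window, so
#' truncation barely distorts the kernel shape.
#'
#' @param radius Integer window radius in pixels, `>= 0`.  `radius = 0`
#'   gives the identity kernel.
#' @param sd Gaussian standard deviation in pixels, `> 0`.
#' @return A `kernel_spec`: list with `radius`, `sd` and `weights`
#'   (a `(2*radius+1)` square matrix summing to 1).
#' @examples
#' k <- gaussian_kernel(1, 0.33)
#' sum(k$weights)     # 1
#' k$weights[2, 2]    # ~0.96, centre-dominated
#' @export
gaussian_kernel <- function(radius = 1, sd = 0.33) {
  if (length(radius) != 1L || radius < 0 || radius != as.integer(radius)) {
    stopf("`radius` must be a single nonnegative integer")
  }
  if (length(sd) != 1L || !is.finite(sd) || sd <= 0) {
    stopf("`sd` must be a single positive number")
  }
  radius <- as.integer(radius)
  off <- seq.int(-radius, radius)
  d2 <- outer(off^2, off^2, `+`)
  w <- exp(-d2 / (2 * sd^2))
  w <- w / sum(w)
  structure(list(radius = radius, sd = sd, weights = w),
            class = "kernel_spec")
}

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_matrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr  # source rows
  cs <- seq_len(nc) - dc
  rok <- rs >= 1L & rs <= nr
  cok <- cs >= 1L & cs <= nc
  if (any(rok) && any(cok)) {
    out[which(rok), which(cok)] <- m[rs[rok], cs[cok], drop = FALSE]
  }
  out
}

#' Focal (neighbourhood) smoothing of a raster
#'
#' Replaces each valid pixel by the kernel-weighted mean of the valid
#' pixels in its window, with the kernel weights renormalized over the
#' valid in-window subset.  Invalid pixels pass through untouched, as
#' does any valid pixel whose window contains no valid neighbours (a
#' degenerate renormalization).  Renormalizing instead of zero-padding
#' avoids artificial attenuation along country borders.
#'
#' @param raster Numeric matrix.
#' @param kernel A `kernel_spec` from [gaussian_kernel()].
#' @param valid_mask Logical matrix of the same shape; `NULL` means all
#'   pixels valid.
#' @return A numeric matrix of the same shape.
#' @export
focal_smooth <- function(raster, kernel, valid_mask = NULL) {
  stopifnot(is.matrix(raster))
  if (!inherits(kernel, "kernel_spec")) stopf("`kernel` must be a kernel_spec")
  if (is.null(valid_mask)) {
    valid_mask <- matrix(TRUE, nrow(raster), ncol(raster))
  }
  stopifnot(is.matrix(valid_mask), all(dim(valid_mask) == dim(raster)))
  r <- kernel$radius
  if (r == 0L) return(raster)
  vm <- valid_mask * 1
  vx <- raster * vm
  num <- matrix(0, nrow(raster), ncol(raster))
  den <- num
  for (dr in -r:r) {
    for (dc in -r:r) {
      w <- kernel$weights[dr + r + 1L, dc + r + 1L]
      num <- num + w * shift_matrix(vx, dr, dc)
      den <- den + w * shift_matrix(vm, dr, dc)
    }
  }
  out <- raster
  ok <- valid_mask & den > 0
  out[ok] <- num[ok] / den[ok]
  out
}
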