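# Synthetic landscape generation: nested contiguous administrative units
# grown by seeded region-growing, plus spatially autocorrelated fields.

# Smoothed standard-normal noise field: white noise convolved with a
# Gaussian kernel (renormalized edges), then re-standardized.
smooth_noise_field <- function(n_rows, n_cols, corr_length) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (corr_length > 0) {
    sd <- corr_length
    k <- gaussian_kernel(max(1L, as.integer(ceiling(2 * sd))), sd)
    z <- focal_smooth(z, k)
  }
  s <- stats::sd(as.vector(z))
  if (s > 0) z <- (z - mean(z)) / s
  z
}

# Partition the pixel set `cells` (linear indices into an n_rows x n_cols
# grid) into `n_units` contiguous regions by multi-source random growth.
# Each unassigned cell attaches to the region of a uniformly chosen
# already-assigned 4-neighbour, so regions stay connected.
grow_regions <- function(cells, n_units, n_rows, n_cols) {
  n <- length(cells)
  if (n < n_units) {
    stopf("grid region of %d pixels cannot host %d units", n, n_units)
  }
  # size-safe sampling (sample() treats a length-1 vector as 1:x)
  resample <- function(x, size = length(x)) x[sample.int(length(x), size)]
  member <- rep(NA_integer_, n_rows * n_cols)
  inset <- logical(n_rows * n_cols)
  inset[cells] <- TRUE
  seeds <- resample(cells, n_units)
  member[seeds] <- seq_len(n_units)
  # 4-neighbour offsets in linear (column-major) indexing
  up <- -1L; down <- 1L; left <- -n_rows; right <- n_rows
  row_of <- function(idx) (idx - 1L) %% n_rows + 1L
  unassigned <- setdiff(cells, seeds)
  while (length(unassigned) > 0L) {
    assigned_now <- integer(0)
    # randomized sweep order keeps boundaries irregular but seeded
    for (idx in resample(unassigned)) {
      r <- row_of(idx)
      nb <- c(if (r > 1L) idx + up, if (r < n_rows) idx + down,
              idx + left, idx + right)
      nb <- nb[nb >= 1L & nb <= n_rows * n_cols]
      nb <- nb[inset[nb] & !is.na(member[nb])]
      if (length(nb) > 0L) {
        member[idx] <- member[resample(nb, 1L)]
        assigned_now <- c(assigned_now, idx)
      }
    }
    if (length(assigned_now) == 0L) {
      stopf("region growing stalled: pixel set is not connected")
    }
    unassigned <- setdiff(unassigned, assigned_now)
  }
  member[cells]
}

#' Generate a synthetic landscape
#'
#' Builds a rectangular pixel grid carrying a spatially autocorrelated
#' cropland field and a nested administrative partition: one country
#' (level 0) split into `n_adm1` contiguous level-1 units, each split
#' into `n_adm2_per_adm1` contiguous level-2 units.  Level-2 codes are
#' globally unique and nest deterministically in their level-1 parent.
#' The cropland surface is thresholded smoothed noise rescaled so the
#' grid-mean cropland fraction matches `mean_cropland_frac`.
#'
#' @param n_rows,n_cols Grid dimensions in pixels (each `>= 2`).
#' @param n_adm1 Number of level-1 units (`>= 1`).
#' @param n_adm2_per_adm1 Number of level-2 units per level-1 unit (`>= 1`).
#' @param spatial_corr_length Gaussian correlation length of the cropland
#'   field, in pixels.
#' @param seed RNG seed (mandatory; identical seeds give bit-identical
#'   landscapes).
#' @param mean_cropland_frac Target mean cropland fraction of pixel area.
#' @param pixel_area Hectares per pixel (uniform across the grid).
#' @return A `landscape`: list with `n_rows`, `n_cols`, `pixel_area`,
#'   `cropland` (matrix, ha), `admin` (list of integer matrices for
#'   levels `"0"`, `"1"`, `"2"`), `country_mask` (logical matrix) and
#'   `units` (data.frame `level`, `code`, `parent`).
#' @export
generate_landscape <- function(n_rows, n_cols, n_adm1, n_adm2_per_adm1,
                               spatial_corr_length = 3, seed,
                               mean_cropland_frac = 0.45,
                               pixel_area = 100) {
  if (n_rows < 2 || n_cols < 2) stopf("grid dimensions must be >= 2")
  if (n_adm1 < 1 || n_adm2_per_adm1 < 1) stopf("unit counts must be >= 1")
  if (n_rows * n_cols < n_adm1 * n_adm2_per_adm1) {
    stopf("grid of %d pixels too small for %d level-2 units",
          n_rows * n_cols, n_adm1 * n_adm2_per_adm1)
  }
  if (mean_cropland_frac <= 0 || mean_cropland_frac > 1) {
    stopf("`mean_cropland_frac` must be in (0, 1]")
  }
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  n_adm1 <- as.integer(n_adm1)
  n_adm2_per_adm1 <- as.integer(n_adm2_per_adm1)
  with_seed(seed, {
    N <- n_rows * n_cols
    all_cells <- seq_len(N)
    adm1 <- grow_regions(all_cells, n_adm1, n_rows, n_cols)
    adm2 <- rep(NA_integer_, N)
    for (a1 in seq_len(n_adm1)) {
      cells <- all_cells[adm1 == a1]
      sub <- grow_regions(cells, n_adm2_per_adm1, n_rows, n_cols)
      adm2[cells] <- (a1 - 1L) * n_adm2_per_adm1 + sub
    }
    z <- smooth_noise_field(n_rows, n_cols, spatial_corr_length)
    f0 <- stats::pnorm(as.vector(z))
    # rescale (with clipping at full-pixel cropland) to hit the mean target
    target <- mean_cropland_frac
    g <- function(cc) mean(pmin(1, cc * f0)) - target
    cc <- if (g(1) >= 0) {
      stats::uniroot(g, c(1e-12, 1), tol = 1e-12)$root
    } else if (g(1e6) <= 0) 1e6 else {
      stats::uniroot(g, c(1, 1e6), tol = 1e-12)$root
    }
    cropland <- matrix(pixel_area * pmin(1, cc * f0), n_rows, n_cols)

    units <- rbind(
      data.frame(level = 0L, code = 1L, parent = NA_integer_),
      data.frame(level = 1L, code = seq_len(n_adm1), parent = 1L),
      data.frame(level = 2L,
                 code = seq_len(n_adm1 * n_adm2_per_adm1),
                 parent = rep(seq_len(n_adm1), each = n_adm2_per_adm1))
    )
    structure(
      list(
        n_rows = n_rows, n_cols = n_cols, pixel_area = pixel_area,
        cropland = cropland,
        admin = list(
          "0" = matrix(1L, n_rows, n_cols),
          "1" = matrix(adm1, n_rows, n_cols),
          "2" = matrix(adm2, n_rows, n_cols)
        ),
        country_mask = matrix(TRUE, n_rows, n_cols),
        units = units
      ),
      class = "landscape"
    )
  })
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf(
    "<landscape> %d x %d pixels (%.0f ha each), %d ADM1 / %d ADM2 units, mean cropland fraction %.3f\n",
    x$n_rows, x$n_cols, x$pixel_area,
    sum(x$units$level == 1L), sum(x$units$level == 2L),
    mean(x$cropland) / x$pixel_area))
  invisible(x)
}

n_pixels <- function(landscape) landscape$n_rows * landscape$n_cols

# Linear pixel indices of administrative unit `code` at `level`.
pixels_of_unit <- function(landscape, level, code) {
  which(as.vector(landscape$admin[[as.character(level)]]) == code &
          as.vector(landscape$country_mask))
}

# Ancestor code of `code` (at `from` level) at the coarser `to` level.
ancestor_code <- function(landscape, code, from, to) {
  stopifnot(to <= from)
  cur <- code
  lev <- from
  while (lev > to) {
    u <- landscape$units
    row <- u[u$level == lev & u$code == cur, , drop = FALSE]
    if (nrow(row) != 1L) stopf("unknown admin unit %s at level %d", cur, lev)
    cur <- row$parent
    lev <- lev - 1L
  }
  cur
}

# Admin codes present at a level (in-country pixels only).
unit_codes <- function(landscape, level) {
  sort(unique(as.vector(
    landscape$admin[[as.character(level)]]
  )[as.vector(landscape$country_mask)]))
}
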