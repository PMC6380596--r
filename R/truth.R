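# Ground-truth allocations and their aggregation to statistical
# reporting units (SRUs).  The truth is package plumbing: it manufactures
# SRU tables whose pixel-level origin is known, so allocator recovery can
# be scored.

# Rainfed split of the non-irrigated harvested share, by system.
RAINFED_SHARES <- c(rainfed_high = 0.35, rainfed_low = 0.45,
                    subsistence = 0.20)

#' Generate a known ground-truth allocation
#'
#' Draws a pixel-level physical cropping area per (pixel, crop, system)
#' proportional to `cropland x (suitability fraction)^concentration`,
#' subject exactly to the per-pixel cropland capacity.  `concentration`
#' near 0 spreads each crop in proportion to cropland alone (the simple
#' method's geometry); large values concentrate area on the most suitable
#' pixels.
#'
#' @param landscape,ancillary,crops The synthetic world.
#' @param concentration Suitability exponent, `>= 0`.
#' @param cropland_use Fraction of total cropland demanded across all
#'   crops and systems (must be `<= 1` for feasibility).
#' @param seed RNG seed for the crop demand mix.
#' @return A `true_allocation`: list with `physical_area`
#'   (array `n_pixels x n_crops x 4`, ha).
#' @export
generate_true_allocation <- function(landscape, ancillary, crops,
                                     concentration = 2, cropland_use = 0.7,
                                     seed) {
  stopifnot(inherits(landscape, "landscape"), inherits(ancillary, "ancillary"),
            inherits(crops, "crop_set"))
  if (concentration < 0) stopf("`concentration` must be >= 0")
  cl <- as.vector(landscape$cropland)
  total_cropland <- sum(cl)
  demand_total <- cropland_use * total_cropland
  if (demand_total > total_cropland) {
    stopf("demanded area %.1f ha exceeds total cropland %.1f ha",
          demand_total, total_cropland)
  }
  J <- n_crops(crops)
  L <- length(production_systems())
  N <- n_pixels(landscape)
  with_seed(seed, {
    wj <- stats::rgamma(J, shape = 2)
    wj <- wj / sum(wj)
    irr_share <- sum(ancillary$irrigated_area) / total_cropland
    sys_share <- c(irrigated = irr_share, (1 - irr_share) * RAINFED_SHARES)
    demand <- demand_total * outer(wj, sys_share)  # J x L

    w <- array(0, dim = c(N, J, L))
    suit_frac <- ancillary$suitable_area / landscape$pixel_area
    for (l in seq_len(L)) {
      w[, , l] <- cl * suit_frac[, , l]^concentration
    }
    A <- array(0, dim = c(N, J, L),
               dimnames = dimnames(ancillary$suitable_area))
    wm <- matrix(w, N, J * L)
    dvec <- as.vector(demand)  # column-major (j, l) pairs, matching wm
    Am <- sweep(wm, 2, ifelse(colSums(wm) > 0, colSums(wm), 1), `/`)
    Am <- sweep(Am, 2, dvec, `*`)
    # iterative capacity squeeze: saturated pixels frozen at capacity,
    # each column's shortfall redistributed over free pixels
    sat <- rep(FALSE, N)
    for (it in seq_len(300)) {
      load <- rowSums(Am)
      over <- load > cl * (1 + 1e-14)
      if (any(over)) {
        f <- ifelse(load > 0, pmin(1, cl / load), 1)
        Am <- Am * f
        sat <- sat | over
      }
      short <- dvec - colSums(Am)
      if (all(short <= 1e-10 * pmax(dvec, 1)) && !any(over)) break
      for (k in which(short > 1e-12 * pmax(dvec, 1))) {
        wf <- wm[, k] * (!sat)
        sw <- sum(wf)
        if (sw > 0) Am[, k] <- Am[, k] + short[k] * wf / sw
      }
    }
    # final hard clip (guards last redistribution round)
    load <- rowSums(Am)
    over <- load > cl
    if (any(over)) {
      f <- ifelse(load > 0, pmin(1, cl / load), 1)
      Am <- Am * f
    }
    A[] <- Am
    structure(list(physical_area = A), class = "true_allocation")
  })
}

# Internal: per-pixel harvested area and production implied by a
# physical-area array, cropping intensities and ancillary yields.
pixel_outputs <- function(phys, ancillary, crops) {
  N <- dim(phys)[1]; J <- dim(phys)[2]; L <- dim(phys)[3]
  harv <- matrix(0, N, J)
  prod <- matrix(0, N, J)
  for (j in seq_len(J)) {
    for (l in seq_len(L)) {
      h <- phys[, j, l] * crops$ci[j, l]
      harv[, j] <- harv[, j] + h
      prod[, j] <- prod[, j] + h * ancillary$potential_yield[, j, l]
    }
  }
  list(harvested = harv, production = prod)
}

#' Aggregate a ground-truth allocation to SRU statistics
#'
#' Sums the truth's physical area per (unit, crop) at the requested
#' administrative level, converting to harvested area via cropping
#' intensities and to production via the per-system potential yields.
#'
#' @param truth A `true_allocation`.
#' @param landscape,ancillary,crops The synthetic world.
#' @param level Administrative level of the output rows (0, 1 or 2).
#' @return An SRU table: data.frame with columns `sru_id`, `admin_level`,
#'   `crop_id`, `harvested_area` (ha), `production` (mt), `yield`
#'   (mt/ha; 0 where harvested area is 0), one row per (unit, crop),
#'   sorted by (`sru_id`, `crop_id`).
#' @export
aggregate_to_sru <- function(truth, landscape, ancillary, crops, level) {
  stopifnot(inherits(truth, "true_allocation"), level %in% 0:2)
  out <- pixel_outputs(truth$physical_area, ancillary, crops)
  codes <- unit_codes(landscape, level)
  J <- n_crops(crops)
  rows <- vector("list", length(codes))
  for (u in seq_along(codes)) {
    p <- pixels_of_unit(landscape, level, codes[u])
    H <- colSums(out$harvested[p, , drop = FALSE])
    P <- colSums(out$production[p, , drop = FALSE])
    rows[[u]] <- data.frame(
      sru_id = codes[u], admin_level = as.integer(level),
      crop_id = seq_len(J),
      harvested_area = H, production = P,
      yield = ifelse(H > 0, P / H, 0)
    )
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$sru_id, tab$crop_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Coarsen an SRU table to a higher administrative level
#'
#' Re-aggregates statistics to `to_level`: areas and production are
#' summed within the ancestor unit and yields recomputed, conserving
#' country totals exactly.  Refinement (a `to_level` finer than a source
#' row) is not supported.
#'
#' @param sru_table An SRU table (see [aggregate_to_sru()]).
#' @param landscape The landscape supplying the admin hierarchy.
#' @param to_level Target level; must be coarser than or equal to every
#'   row's level (coarser = smaller number).
#' @return An SRU table at `to_level`, sorted by (`sru_id`, `crop_id`).
#' @export
degrade_statistics <- function(sru_table, landscape, to_level) {
  stopifnot(to_level %in% 0:2)
  if (any(sru_table$admin_level < to_level)) {
    stopf("cannot refine statistics: rows at level %d requested at level %d",
          min(sru_table$admin_level), to_level)
  }
  anc <- mapply(function(code, lev) {
    ancestor_code(landscape, code, lev, to_level)
  }, sru_table$sru_id, sru_table$admin_level)
  key <- interaction(anc, sru_table$crop_id, drop = TRUE)
  H <- tapply(sru_table$harvested_area, key, sum)
  P <- tapply(sru_table$production, key, sum)
  ids <- do.call(rbind, strsplit(names(H), ".", fixed = TRUE))
  tab <- data.frame(
    sru_id = as.integer(ids[, 1]), admin_level = as.integer(to_level),
    crop_id = as.integer(ids[, 2]),
    harvested_area = as.numeric(H), production = as.numeric(P)
  )
  tab$yield <- ifelse(tab$harvested_area > 0,
                      tab$production / tab$harvested_area, 0)
  tab <- tab[order(tab$sru_id, tab$crop_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
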