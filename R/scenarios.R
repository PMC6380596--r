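# Robustness scenarios: the baseline cross-entropy run plus eight
# methodological variants, each a single switch away from the baseline.

SCENARIO_IDS <- c("baseline", "allocation_method", "crop_choice",
                  "remainder_allocation", "crop_suitability",
                  "market_access", "crop_price", "adm0_only", "adm1_only")

#' Specify a robustness scenario
#'
#' @param scenario_id One of `"baseline"`, `"allocation_method"` (simple
#'   cropland-proportional allocation), `"crop_choice"` (merge crops into
#'   aggregates, requires `crop_merge_map`), `"remainder_allocation"`
#'   (passive residual assignment of the rest-of-crops aggregate),
#'   `"crop_suitability"`, `"market_access"`, `"crop_price"` (each drops
#'   the corresponding prior/constraint ingredient), `"adm0_only"`,
#'   `"adm1_only"` (coarsened reporting level).
#' @param crop_merge_map For `crop_choice` only: named list mapping each
#'   aggregate name to the vector of crop ids it absorbs.
#' @param rest_crop For `remainder_allocation`: the crop id of the
#'   rest-of-crops aggregate; defaults to the single crop flagged
#'   `is_aggregate` in the crop set.
#' @param notes Free-form annotation carried into provenance.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(scenario_id, crop_merge_map = NULL,
                          rest_crop = NULL, notes = "") {
  if (length(scenario_id) != 1L || !scenario_id %in% SCENARIO_IDS) {
    stopf("`scenario_id` must be one of: %s",
          paste(SCENARIO_IDS, collapse = ", "))
  }
  if (scenario_id == "crop_choice" && is.null(crop_merge_map)) {
    stopf("`crop_choice` requires a `crop_merge_map`")
  }
  if (scenario_id != "crop_choice" && !is.null(crop_merge_map)) {
    stopf("`crop_merge_map` is only meaningful for the crop_choice scenario")
  }
  structure(list(scenario_id = scenario_id, crop_merge_map = crop_merge_map,
                 rest_crop = rest_crop, notes = notes),
            class = "scenario_spec")
}

#' Merge crops into aggregates
#'
#' Sums harvested areas and production per merged group (yield
#' recomputed as their ratio); the merged price and per-system cropping
#' intensities are harvested-area-weighted means over the members.
#' Crops not covered by the map pass through unchanged.
#'
#' @param crops A `crop_set`.
#' @param sru_table SRU statistics for those crops.
#' @param crop_merge_map Named list: aggregate name -> member crop ids.
#'   A crop appearing in two aggregates is an error.
#' @return List with `crops` (the merged `crop_set`) and `sru_table`
#'   (statistics re-keyed to the merged crop ids).
#' @export
merge_crops <- function(crops, sru_table, crop_merge_map) {
  all_members <- unlist(crop_merge_map, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    stopf("crop %d is mapped to two aggregates",
          all_members[duplicated(all_members)][1])
  }
  if (any(!all_members %in% crops$table$crop_id)) {
    stopf("merge map references unknown crop ids")
  }
  J <- n_crops(crops)
  # new id per old crop: singletons keep their own name
  group_of <- as.character(crops$table$name)
  for (gname in names(crop_merge_map)) {
    group_of[crop_merge_map[[gname]]] <- gname
  }
  new_names <- unique(group_of)
  # total harvested area per old crop, for weighting
  H_old <- vapply(seq_len(J), function(j) {
    sum(sru_table$harvested_area[sru_table$crop_id == j])
  }, numeric(1))
  price <- numeric(length(new_names))
  is_agg <- logical(length(new_names))
  ci <- matrix(0, length(new_names), length(production_systems()),
               dimnames = list(new_names, production_systems()))
  for (gi in seq_along(new_names)) {
    members <- which(group_of == new_names[gi])
    w <- H_old[members]
    w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(members),
                                             length(members))
    price[gi] <- sum(w * crops$table$price[members])
    is_agg[gi] <- length(members) > 1L || any(crops$table$is_aggregate[members])
    ci[gi, ] <- colSums(crops$ci[members, , drop = FALSE] * w)
  }
  crops2 <- make_crops(new_names, price = price, is_aggregate = is_agg,
                       cropping_intensity = ci)
  new_id_of_old <- match(group_of, new_names)
  tab <- sru_table
  tab$crop_id <- new_id_of_old[tab$crop_id]
  key <- interaction(tab$sru_id, tab$admin_level, tab$crop_id, drop = TRUE)
  H <- tapply(tab$harvested_area, key, sum)
  P <- tapply(tab$production, key, sum)
  ids <- do.call(rbind, strsplit(names(H), ".", fixed = TRUE))
  out <- data.frame(
    sru_id = as.integer(ids[, 1]), admin_level = as.integer(ids[, 2]),
    crop_id = as.integer(ids[, 3]),
    harvested_area = as.numeric(H), production = as.numeric(P)
  )
  out$yield <- ifelse(out$harvested_area > 0,
                      out$production / out$harvested_area, 0)
  out <- out[order(out$sru_id, out$crop_id), , drop = FALSE]
  rownames(out) <- NULL
  list(crops = crops2, sru_table = out)
}

# Area-weighted merge of ancillary layers onto a merged crop set.
merge_ancillary <- function(ancillary, crops, crops2, group_of, weights) {
  L <- length(production_systems())
  N <- dim(ancillary$suitable_area)[1]
  J2 <- n_crops(crops2)
  sa <- array(0, dim = c(N, J2, L),
              dimnames = list(NULL, crops2$table$name, production_systems()))
  py <- sa
  for (gi in seq_len(J2)) {
    members <- which(group_of == crops2$table$name[gi])
    w <- weights[members]
    w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(members),
                                             length(members))
    for (l in seq_len(L)) {
      sa[, gi, l] <- matrix(ancillary$suitable_area[, members, l],
                            ncol = length(members)) %*% w
      py[, gi, l] <- matrix(ancillary$potential_yield[, members, l],
                            ncol = length(members)) %*% w
    }
  }
  structure(list(suitable_area = sa, potential_yield = py,
                 rural_pop_density = ancillary$rural_pop_density,
                 irrigated_area = ancillary$irrigated_area),
            class = "ancillary")
}

#' Run one robustness scenario
#'
#' Dispatches to the appropriate allocator with the appropriate toggles:
#' the baseline is the cross-entropy method with all prior ingredients
#' and constraints on and the statistics at their reported level; each
#' scenario changes exactly one thing (see [scenario_spec()]).
#'
#' @param spec A `scenario_spec`.
#' @param landscape,ancillary,crops,sru_table The world and statistics.
#' @param config Baseline [entropy_config()]; scenario toggles are
#'   applied on top of it.
#' @return An `allocation` tagged with the scenario id.
#' @export
run_scenario <- function(spec, landscape, ancillary, crops, sru_table,
                         config = entropy_config()) {
  stopifnot(inherits(spec, "scenario_spec"))
  id <- spec$scenario_id
  run_entropy <- function(tab, cr = crops, anc = ancillary, cfg = config) {
    pri <- build_priors(landscape, anc, cr, cfg)
    allocate_cross_entropy(pri, tab, landscape, anc, cr, cfg)
  }
  res <- tryCatch(
    switch(
      id,
      baseline = run_entropy(sru_table),
      allocation_method = allocate_simple(sru_table, landscape, crops),
      crop_choice = {
        merged <- merge_crops(crops, sru_table, spec$crop_merge_map)
        group_of <- as.character(crops$table$name)
        for (g in names(spec$crop_merge_map)) {
          group_of[spec$crop_merge_map[[g]]] <- g
        }
        H_old <- vapply(seq_len(n_crops(crops)), function(j) {
          sum(sru_table$harvested_area[sru_table$crop_id == j])
        }, numeric(1))
        anc2 <- merge_ancillary(ancillary, crops, merged$crops, group_of,
                                H_old)
        run_entropy(merged$sru_table, merged$crops, anc2)
      },
      remainder_allocation = run_remainder(spec, landscape, ancillary,
                                           crops, sru_table, config),
      crop_suitability = {
        cfg <- config; cfg$use_suitability_constraint <- FALSE
        run_entropy(sru_table, cfg = cfg)
      },
      market_access = {
        cfg <- config; cfg$use_market_access <- FALSE
        run_entropy(sru_table, cfg = cfg)
      },
      crop_price = {
        cfg <- config; cfg$use_prices <- FALSE
        run_entropy(sru_table, cfg = cfg)
      },
      adm0_only = run_entropy(degrade_statistics(sru_table, landscape, 0L)),
      adm1_only = run_entropy(degrade_statistics(sru_table, landscape, 1L))
    ),
    error = function(e) {
      stopf("scenario %s: %s", id, conditionMessage(e))
    })
  res$scenario <- id
  res
}

# Passive remainder: allocate the named crops by cross-entropy, then set
# the rest-of-crops physical area to each pixel's residual cropland
# (clipped at zero).  Production of the rest crop is distributed over
# the residual so unit production totals are conserved; its harvested
# area is the residual times its cropping intensity and is NOT forced to
# match the statistics -- that is the point of passive assignment.
run_remainder <- function(spec, landscape, ancillary, crops, sru_table,
                          config) {
  rest <- spec$rest_crop %||% {
    cand <- which(crops$table$is_aggregate)
    if (length(cand) != 1L) {
      stopf("remainder_allocation needs `rest_crop` (found %d aggregate crops)",
            length(cand))
    }
    cand
  }
  active_tab <- sru_table[sru_table$crop_id != rest, , drop = FALSE]
  pri <- build_priors(landscape, ancillary, crops, config)
  res <- allocate_cross_entropy(pri, active_tab, landscape, ancillary,
                                crops, config)
  cl <- as.vector(landscape$cropland)
  named_phys <- rowSums(res$physical_area[, -rest, , drop = FALSE],
                        dims = 1)
  resid <- pmax(0, cl - named_phys)
  rest_l <- match("rainfed_low", production_systems())
  ci_rest <- crops$ci[rest, rest_l]
  if (ci_rest <= 0) ci_rest <- 1
  rest_rows <- sru_table[sru_table$crop_id == rest, , drop = FALSE]
  for (r in seq_len(nrow(rest_rows))) {
    p <- pixels_of_unit(landscape, rest_rows$admin_level[r],
                        rest_rows$sru_id[r])
    res$physical_area[p, rest, rest_l] <- resid[p]
    h <- resid[p] * ci_rest
    res$harvested_area[p, rest] <- h
    P <- rest_rows$production[r]
    tot <- sum(resid[p])
    if (tot > 0 && P > 0) {
      res$production[p, rest] <- P * resid[p] / tot
    }
    res$yield[p, rest] <- ifelse(h > 0, res$production[p, rest] / h, 0)
  }
  res
}

#' Presence share of a crop
#'
#' Percentage of cropland pixels where the allocated harvested area of
#' `crop` exceeds the presence threshold.  The share can exceed 100%
#' only when a cropland adjustment placed capacity on non-cropland
#' pixels (see [adjust_cropland()]).
#'
#' @param result An `allocation`.
#' @param landscape The pixel grid.
#' @param crop Crop id.
#' @return A percentage (scalar).
#' @export
presence_share <- function(result, landscape, crop) {
  cl <- as.vector(landscape$cropland)
  mask <- as.vector(landscape$country_mask)
  n_cropland <- sum(cl > PRESENCE_THRESHOLD & mask)
  if (n_cropland == 0L) {
    stopf("presence share undefined: landscape has no cropland pixels")
  }
  n_present <- sum(result$harvested_area[, crop] > PRESENCE_THRESHOLD & mask)
  100 * n_present / n_cropland
}
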