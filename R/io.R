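# Plain-text readers and writers.  All tabular formats are UTF-8 CSV
# with a mandatory header and '.' decimal; numerics are written with 17
# significant digits so write -> read round-trips within float
# representation.  Config and manifests are JSON.

fmt_num <- function(x) {
  formatC(x, digits = 17, format = "g")
}

write_csv_precise <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  out <- df
  out[num] <- lapply(df[num], fmt_num)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

require_columns <- function(df, cols, what, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stopf("%s file '%s' is missing column(s): %s", what, path,
          paste(missing, collapse = ", "))
  }
}

#' Write / read a landscape as CSV
#'
#' One row per pixel with columns `row`, `col`, `pixel_area`, `cropland`,
#' `adm0`, `adm1`, `adm2`, `country`.  The nested unit table is rebuilt
#' on read from the pixel-level admin codes.
#'
#' @param landscape A `landscape`.
#' @param path File path.
#' @return `write_landscape` returns `path` invisibly; `read_landscape`
#'   returns a `landscape`.
#' @export
write_landscape <- function(landscape, path) {
  N <- n_pixels(landscape)
  idx <- seq_len(N)
  df <- data.frame(
    row = (idx - 1L) %% landscape$n_rows + 1L,
    col = (idx - 1L) %/% landscape$n_rows + 1L,
    pixel_area = rep(landscape$pixel_area, N),
    cropland = as.vector(landscape$cropland),
    adm0 = as.vector(landscape$admin[["0"]]),
    adm1 = as.vector(landscape$admin[["1"]]),
    adm2 = as.vector(landscape$admin[["2"]]),
    country = as.integer(as.vector(landscape$country_mask))
  )
  write_csv_precise(df, path)
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  df <- utils::read.csv(path)
  require_columns(df, c("row", "col", "pixel_area", "cropland",
                        "adm0", "adm1", "adm2", "country"),
                  "landscape", path)
  if (anyNA(df)) stopf("landscape file '%s' contains missing values", path)
  n_rows <- max(df$row); n_cols <- max(df$col)
  if (nrow(df) != n_rows * n_cols) {
    stopf("landscape file '%s' is truncated: %d rows for a %d x %d grid",
          path, nrow(df), n_rows, n_cols)
  }
  ord <- order(df$col, df$row)
  df <- df[ord, ]
  mk <- function(v, mode = "double") {
    matrix(as.vector(v, mode = mode), n_rows, n_cols)
  }
  adm1 <- mk(df$adm1, "integer"); adm2 <- mk(df$adm2, "integer")
  pairs <- unique(data.frame(code = as.vector(adm2),
                             parent = as.vector(adm1)))
  if (anyDuplicated(pairs$code)) {
    stopf("landscape file '%s' violates nesting: an ADM2 unit spans two ADM1 units",
          path)
  }
  units <- rbind(
    data.frame(level = 0L, code = sort(unique(as.vector(df$adm0))),
               parent = NA_integer_),
    data.frame(level = 1L, code = sort(unique(as.vector(adm1))),
               parent = unique(df$adm0)[1]),
    data.frame(level = 2L, code = pairs$code[order(pairs$code)],
               parent = pairs$parent[order(pairs$code)])
  )
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         pixel_area = df$pixel_area[1],
         cropland = mk(df$cropland),
         admin = list("0" = mk(df$adm0, "integer"), "1" = adm1, "2" = adm2),
         country_mask = mk(df$country, "integer") > 0L,
         units = units),
    class = "landscape"
  )
}

SRU_HEADER <- c("sru_id", "admin_level", "crop", "harvested_area_ha",
                "production_mt", "yield_mt_ha")

#' Write / read SRU statistics as CSV
#'
#' File header: `sru_id, admin_level, crop, harvested_area_ha,
#' production_mt, yield_mt_ha`; `crop` holds the integer crop id.
#'
#' @param sru_table An SRU table (internal column names).
#' @param path File path.
#' @return `read_sru_table` returns an SRU table with internal column
#'   names (`harvested_area`, `production`, `yield`).
#' @export
write_sru_table <- function(sru_table, path) {
  df <- data.frame(
    sru_id = sru_table$sru_id, admin_level = sru_table$admin_level,
    crop = sru_table$crop_id,
    harvested_area_ha = sru_table$harvested_area,
    production_mt = sru_table$production,
    yield_mt_ha = sru_table$yield
  )
  write_csv_precise(df, path)
  invisible(path)
}

#' @rdname write_sru_table
#' @export
read_sru_table <- function(path) {
  df <- utils::read.csv(path)
  require_columns(df, SRU_HEADER, "SRU", path)
  if (anyNA(df)) stopf("SRU file '%s' contains missing values", path)
  data.frame(
    sru_id = as.integer(df$sru_id),
    admin_level = as.integer(df$admin_level),
    crop_id = as.integer(df$crop),
    harvested_area = as.numeric(df$harvested_area_ha),
    production = as.numeric(df$production_mt),
    yield = as.numeric(df$yield_mt_ha)
  )
}

#' Write / read a crop catalogue as CSV
#' @param crops A `crop_set`.
#' @param path File path.
#' @export
write_crops <- function(crops, path) {
  ci <- crops$ci
  colnames(ci) <- paste0("ci_", production_systems())
  write_csv_precise(cbind(crops$table, as.data.frame(ci)), path)
  invisible(path)
}

#' @rdname write_crops
#' @export
read_crops <- function(path) {
  df <- utils::read.csv(path)
  require_columns(df, c("crop_id", "name", "price", "is_aggregate",
                        paste0("ci_", production_systems())), "crops", path)
  ci <- as.matrix(df[, paste0("ci_", production_systems())])
  make_crops(df$name, price = df$price,
             is_aggregate = as.logical(df$is_aggregate),
             cropping_intensity = unname(ci))
}

#' Write / read ancillary layers as CSV
#'
#' Two files: a long crop file (`pixel, crop, system, suitable_area_ha,
#' potential_yield_mt_ha`) and a pixel file (`pixel,
#' rural_pop_density, irrigated_area_ha`).
#'
#' @param ancillary An `ancillary`.
#' @param crop_path,pixel_path File paths.
#' @param crops Crop catalogue (names the crop column on write).
#' @export
write_ancillary <- function(ancillary, crop_path, pixel_path, crops) {
  dm <- dim(ancillary$suitable_area)
  N <- dm[1]; J <- dm[2]; L <- dm[3]
  long <- data.frame(
    pixel = rep(seq_len(N), times = J * L),
    crop = rep(rep(seq_len(J), each = N), times = L),
    system = rep(production_systems(), each = N * J),
    suitable_area_ha = as.vector(ancillary$suitable_area),
    potential_yield_mt_ha = as.vector(ancillary$potential_yield)
  )
  write_csv_precise(long, crop_path)
  write_csv_precise(data.frame(
    pixel = seq_len(N),
    rural_pop_density = ancillary$rural_pop_density,
    irrigated_area_ha = ancillary$irrigated_area
  ), pixel_path)
  invisible(crop_path)
}

#' @rdname write_ancillary
#' @export
read_ancillary <- function(crop_path, pixel_path) {
  long <- utils::read.csv(crop_path)
  require_columns(long, c("pixel", "crop", "system", "suitable_area_ha",
                          "potential_yield_mt_ha"), "ancillary", crop_path)
  px <- utils::read.csv(pixel_path)
  require_columns(px, c("pixel", "rural_pop_density", "irrigated_area_ha"),
                  "ancillary", pixel_path)
  N <- max(long$pixel); J <- max(long$crop)
  L <- length(production_systems())
  sysid <- match(long$system, production_systems())
  if (anyNA(sysid)) stopf("ancillary file '%s' has unknown system labels",
                          crop_path)
  sa <- array(0, dim = c(N, J, L),
              dimnames = list(NULL, NULL, production_systems()))
  py <- sa
  idx <- cbind(long$pixel, long$crop, sysid)
  sa[idx] <- long$suitable_area_ha
  py[idx] <- long$potential_yield_mt_ha
  px <- px[order(px$pixel), ]
  structure(list(suitable_area = sa, potential_yield = py,
                 rural_pop_density = px$rural_pop_density,
                 irrigated_area = px$irrigated_area_ha),
            class = "ancillary")
}

#' Write an allocation result as CSV
#'
#' Writes `<prefix>_pixels.csv` (pixel, crop, harvested_area_ha,
#' production_mt, yield_mt_ha) and `<prefix>_audit.csv`, a per-(SRU,
#' crop) conservation audit of pixel sums against the statistics.
#'
#' @param result An `allocation`.
#' @param prefix Path prefix.
#' @param sru_table Optional statistics for the audit.
#' @param landscape Required with `sru_table`.
#' @return Vector of paths written, invisibly.
#' @export
write_allocation <- function(result, prefix, sru_table = NULL,
                             landscape = NULL) {
  N <- nrow(result$harvested_area); J <- ncol(result$harvested_area)
  keep <- which(result$harvested_area > 0 | result$production > 0,
                arr.ind = TRUE)
  df <- data.frame(
    pixel = keep[, 1], crop = keep[, 2],
    harvested_area_ha = result$harvested_area[keep],
    production_mt = result$production[keep],
    yield_mt_ha = result$yield[keep]
  )
  df <- df[order(df$crop, df$pixel), ]
  p1 <- paste0(prefix, "_pixels.csv")
  write_csv_precise(df, p1)
  paths <- p1
  if (!is.null(sru_table)) {
    stopifnot(!is.null(landscape))
    aud <- sru_table[, c("sru_id", "admin_level", "crop_id")]
    aud$table_area <- sru_table$harvested_area
    aud$allocated_area <- vapply(seq_len(nrow(aud)), function(r) {
      p <- pixels_of_unit(landscape, aud$admin_level[r], aud$sru_id[r])
      sum(result$harvested_area[p, aud$crop_id[r]])
    }, numeric(1))
    aud$residual <- aud$allocated_area - aud$table_area
    p2 <- paste0(prefix, "_audit.csv")
    write_csv_precise(aud, p2)
    paths <- c(paths, p2)
  }
  invisible(paths)
}

#' Validate a landscape / ancillary / statistics triple
#'
#' Enforces the structural invariants of the input types and itemizes
#' every violation: negative or over-capacity cropland, suitable area
#' exceeding pixel area, broken admin nesting, statistics rows whose
#' yield disagrees with production/area beyond tolerance, duplicated
#' (unit, crop) rows, and unit ids absent from the landscape.
#'
#' @param landscape,ancillary,sru_table The inputs (ancillary may be
#'   `NULL`).
#' @param tol Relative tolerance of the yield identity.
#' @return A data.frame (`component`, `id`, `message`); zero rows means
#'   a clean bill of health.
#' @export
validate_inputs <- function(landscape, ancillary = NULL, sru_table = NULL,
                            tol = 1e-9) {
  issues <- list()
  add <- function(component, id, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      component = component, id = as.character(id), message = message)
  }
  cl <- as.vector(landscape$cropland)
  if (any(cl < 0)) add("landscape", "cropland", "negative cropland")
  if (any(cl > landscape$pixel_area * (1 + 1e-12))) {
    add("landscape", "cropland", "cropland exceeds pixel area")
  }
  pairs <- unique(cbind(as.vector(landscape$admin[["2"]]),
                        as.vector(landscape$admin[["1"]])))
  dup <- pairs[duplicated(pairs[, 1]), 1]
  for (d in dup) add("landscape", d, "ADM2 unit spans multiple ADM1 units")
  if (!is.null(ancillary)) {
    if (any(ancillary$suitable_area < 0) || any(ancillary$irrigated_area < 0) ||
        any(ancillary$rural_pop_density < 0) ||
        any(ancillary$potential_yield < 0)) {
      add("ancillary", "", "negative ancillary values")
    }
    if (any(ancillary$suitable_area > landscape$pixel_area * (1 + 1e-12))) {
      add("ancillary", "suitable_area", "suitable area exceeds pixel area")
    }
  }
  if (!is.null(sru_table)) {
    key <- paste(sru_table$sru_id, sru_table$admin_level, sru_table$crop_id)
    for (k in key[duplicated(key)]) {
      add("sru_table", k, "duplicated (unit, crop) row")
    }
    bad <- which(sru_table$harvested_area > 0 & abs(
      sru_table$yield * sru_table$harvested_area - sru_table$production
    ) > tol * pmax(sru_table$production, 1e-300))
    for (r in bad) {
      add("sru_table", paste(sru_table$sru_id[r], sru_table$crop_id[r]),
          sprintf("yield %.6g inconsistent with production/area %.6g (repair: recompute yield)",
                  sru_table$yield[r],
                  sru_table$production[r] / sru_table$harvested_area[r]))
    }
    for (r in seq_len(nrow(sru_table))) {
      lev <- sru_table$admin_level[r]
      codes <- unit_codes(landscape, lev)
      if (!sru_table$sru_id[r] %in% codes) {
        add("sru_table", sru_table$sru_id[r],
            sprintf("unit id absent from landscape level %d (orphan unit)",
                    lev))
      }
    }
  }
  if (length(issues) == 0L) {
    return(data.frame(component = character(), id = character(),
                      message = character()))
  }
  do.call(rbind, issues)
}

#' Repair an SRU table's yield column
#'
#' Recomputes `yield` as `production / harvested_area` (0 where the area
#' is 0), the repair option for yield-identity violations flagged by
#' [validate_inputs()].
#' @param sru_table An SRU table.
#' @return The repaired table.
#' @export
repair_sru_table <- function(sru_table) {
  sru_table$yield <- ifelse(sru_table$harvested_area > 0,
                            sru_table$production / sru_table$harvested_area, 0)
  sru_table
}

#' Write / read an entropy configuration as JSON
#' @param config An [entropy_config()].
#' @param path File path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  entropy_config(
    use_suitability_constraint = x$use_suitability_constraint,
    use_market_access = x$use_market_access,
    use_prices = x$use_prices,
    cropland_slack = x$cropland_slack,
    solver_tol = x$solver_tol,
    max_iter = x$max_iter,
    rainfed_shares = unlist(x$rainfed_shares),
    degenerate_prior = x$degenerate_prior
  )
}

#' Write a run manifest
#'
#' Records output files with their MD5 digests, the configuration
#' snapshot, the seed registry and optional summaries, as JSON.
#'
#' @param path Manifest path.
#' @param files Character vector of output files.
#' @param config Configuration list (or `NULL`).
#' @param seeds Named list of seeds used.
#' @param summaries Optional list of run summaries.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, files, config = NULL, seeds = list(),
                           summaries = list()) {
  man <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = data.frame(path = files,
                       md5 = unname(tools::md5sum(files))),
    config = if (!is.null(config)) unclass(config),
    seeds = seeds,
    summaries = summaries
  )
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(man)
}

#' Verify a run manifest
#'
#' Checks that every file listed in a manifest exists and matches its
#' recorded digest.
#' @param path Manifest path.
#' @return `TRUE` when everything matches, else a character vector of
#'   problems.
#' @export
verify_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  probs <- character()
  for (r in seq_len(nrow(man$files))) {
    f <- man$files$path[r]
    if (!file.exists(f)) {
      probs <- c(probs, sprintf("missing file: %s", f))
    } else if (unname(tools::md5sum(f)) != man$files$md5[r]) {
      probs <- c(probs, sprintf("digest mismatch: %s", f))
    }
  }
  if (length(probs) == 0L) TRUE else probs
}
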