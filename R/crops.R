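#' Define a set of crops
#'
#' Builds the crop catalogue used throughout the pipeline: one row per
#' crop with its producer price and aggregate flag, plus a cropping
#' intensity (harvested-to-physical area ratio) per production system.
#'
#' @param name Character vector of crop names (unique).
#' @param price Producer price, international dollars per metric ton;
#'   recycled.  Must be positive.
#' @param is_aggregate Logical; `TRUE` marks composite categories such as
#'   a rest-of-crops aggregate.  Recycled.
#' @param cropping_intensity Either a single number, a vector of length
#'   `length(name)` (per crop, shared across systems), or a matrix
#'   `n_crops x 4` (crops by production systems).  Defaults to 1
#'   (no multi-cropping).
#' @return An object of class `crop_set`: list with `table` (data.frame
#'   `crop_id`, `name`, `price`, `is_aggregate`) and `ci` (matrix
#'   crops x systems of cropping intensities).
#' @export
make_crops <- function(name, price = 1, is_aggregate = FALSE,
                       cropping_intensity = 1) {
  if (anyDuplicated(name)) stopf("crop names must be unique")
  n <- length(name)
  if (n < 1L) stopf("at least one crop is required")
  price <- rep_len(as.numeric(price), n)
  if (any(!is.finite(price)) || any(price <= 0)) {
    stopf("all crop prices must be positive and finite")
  }
  is_aggregate <- rep_len(as.logical(is_aggregate), n)
  sys <- production_systems()
  ci <- cropping_intensity
  if (is.matrix(ci)) {
    if (!all(dim(ci) == c(n, length(sys)))) {
      stopf("cropping_intensity matrix must be %d x %d", n, length(sys))
    }
  } else {
    ci <- matrix(rep_len(as.numeric(ci), n), nrow = n, ncol = length(sys))
  }
  if (any(!is.finite(ci)) || any(ci < 0)) {
    stopf("cropping intensities must be nonnegative and finite")
  }
  dimnames(ci) <- list(name, sys)
  structure(
    list(
      table = data.frame(
        crop_id = seq_len(n), name = name, price = price,
        is_aggregate = is_aggregate, stringsAsFactors = FALSE
      ),
      ci = ci
    ),
    class = "crop_set"
  )
}

#' A small default crop catalogue
#'
#' Convenience constructor: `n_named` named crops plus one rest-of-crops
#' aggregate, with prices drawn (seeded) on a realistic scale
#' (100-600 I$/mt) and unit cropping intensities.
#'
#' @param n_named Number of named (non-aggregate) crops.
#' @param seed Seed for price draws.
#' @param rest Include a rest-of-crops aggregate? Default `TRUE`.
#' @return A `crop_set`.
#' @export
default_crops <- function(n_named = 3, seed = 1, rest = TRUE) {
  stopifnot(n_named >= 1)
  nm <- paste0("crop", seq_len(n_named))
  if (rest) nm <- c(nm, "rest_of_crops")
  prices <- with_seed(seed, stats::runif(length(nm), 100, 600))
  make_crops(nm, price = prices,
             is_aggregate = c(rep(FALSE, n_named), rep(TRUE, as.integer(rest))))
}

n_crops <- function(crops) nrow(crops$table)

#' @export
print.crop_set <- function(x, ...) {
  cat("<crop_set> ", n_crops(x), " crops (",
      sum(x$table$is_aggregate), " aggregate)\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}
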