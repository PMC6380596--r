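# scenario driver, crop merging, presence shares

test_that("merge_crops arithmetic and error cases", {
  crops <- make_crops(c("a", "b", "c"), price = c(100, 300, 50))
  tab <- data.frame(
    sru_id = 1L, admin_level = 0L, crop_id = 1:3,
    harvested_area = c(10, 30, 5), production = c(20, 90, 5),
    yield = c(2, 3, 1))
  m <- merge_crops(crops, tab, list(ab = c(1L, 2L)))
  agg <- m$crops$table[m$crops$table$name == "ab", ]
  expect_equal(agg$price, 250)  # (10*100 + 30*300) / 40
  expect_true(agg$is_aggregate)
  row <- m$sru_table[m$sru_table$crop_id == agg$crop_id, ]
  expect_equal(row$harvested_area, 40)
  expect_equal(row$production, 110)
  expect_equal(row$yield, 110 / 40)
  # untouched crop passes through
  cid <- m$crops$table$crop_id[m$crops$table$name == "c"]
  expect_equal(m$sru_table$harvested_area[m$sru_table$crop_id == cid], 5)
  # identity map leaves statistics unchanged
  ident <- merge_crops(crops, tab, list())
  expect_equal(ident$sru_table$harvested_area, tab$harvested_area)
  expect_equal(ident$crops$table$price, crops$table$price)
  # a crop in two aggregates is an error
  expect_error(merge_crops(crops, tab, list(x = c(1L, 2L), y = c(2L, 3L))),
               "two aggregates")
})

test_that("no-op scenarios reproduce the baseline bitwise", {
  ls <- generate_landscape(10, 10, 2, 2, 3, seed = 21)
  crops <- make_crops(c("crop1", "crop2", "rest_of_crops"),
                      price = 1,  # unit prices: crop_price toggle is a no-op
                      is_aggregate = c(FALSE, FALSE, TRUE))
  anc <- generate_ancillary(ls, crops, seed = 22)
  truth <- generate_true_allocation(ls, anc, crops, seed = 23)
  tab1 <- aggregate_to_sru(truth, ls, anc, crops, 1)  # reported at ADM1
  base <- run_scenario(scenario_spec("baseline"), ls, anc, crops, tab1)
  price <- run_scenario(scenario_spec("crop_price"), ls, anc, crops, tab1)
  expect_identical(base$harvested_area, price$harvested_area)
  expect_identical(base$physical_area, price$physical_area)
  adm1 <- run_scenario(scenario_spec("adm1_only"), ls, anc, crops, tab1)
  expect_identical(base$harvested_area, adm1$harvested_area)
  expect_identical(base$production, adm1$production)
})

test_that("remainder scenario assigns residual cropland to the rest crop", {
  w <- small_world(seed = 31)
  res <- run_scenario(scenario_spec("remainder_allocation"), w$landscape,
                      w$ancillary, w$crops, w$sru)
  rest <- which(w$crops$table$is_aggregate)
  named_phys <- rowSums(res$physical_area[, -rest, , drop = FALSE], dims = 1)
  cl <- as.vector(w$landscape$cropland)
  rest_phys <- rowSums(res$physical_area[, rest, , drop = FALSE], dims = 1)
  expect_equal(rest_phys, pmax(0, cl - named_phys), tolerance = 1e-9)
  # production of the rest crop is conserved per unit even though its
  # harvested area is passive
  resid <- conservation_residuals(res, w$sru[w$sru$crop_id == rest, ],
                                  w$landscape, "production")
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("scenario errors carry the scenario id", {
  w <- small_world(seed = 33)
  expect_error(
    run_scenario(scenario_spec("crop_choice", crop_merge_map = list(x = 99L)),
                 w$landscape, w$ancillary, w$crops, w$sru),
    "crop_choice")
  expect_error(scenario_spec("nope"), "scenario_id")
  expect_error(scenario_spec("crop_choice"), "crop_merge_map")
  expect_error(scenario_spec("baseline", crop_merge_map = list(a = 1L)),
               "only meaningful")
})

test_that("presence shares count cropland pixels", {
  ls <- manual_landscape(matrix(c(10, 10, 10, 10), 2, 2), pixel_area = 20)
  crops <- make_crops("maize")
  harv <- matrix(c(5, 3, 1, 0), 4, 1)  # present in 3 of 4 cropland pixels
  res <- structure(list(
    physical_area = array(0, c(4, 1, 4)), harvested_area = harv,
    production = harv * 2, yield = matrix(2, 4, 1), method = "manual"),
    class = "allocation")
  expect_equal(presence_share(res, ls, 1), 75)
  res$harvested_area[] <- 0
  expect_equal(presence_share(res, ls, 1), 0)
  ls0 <- manual_landscape(matrix(0, 2, 2), pixel_area = 20)
  expect_error(presence_share(res, ls0, 1), "no cropland")
})

test_that("over-demand triggers the adjustment flag and >100% presence", {
  # one unit: two cropland pixels (40 ha each) plus two empty pixels with
  # spare land; required area 1.2x the unit's cropland
  ls <- manual_landscape(matrix(c(40, 40, 0, 0), 1, 4), pixel_area = 50)
  crops <- make_crops("maize")
  anc <- manual_ancillary(ls, 1)
  tab <- data.frame(sru_id = 1L, admin_level = 2L, crop_id = 1L,
                    harvested_area = 96, production = 192, yield = 2)
  pri <- build_priors(ls, anc, crops)
  res <- allocate_cross_entropy(pri, tab, ls, anc, crops)
  expect_true(res$adjustments$adjusted)
  expect_equal(res$adjustments$factor, 1.2)
  share <- presence_share(res, ls, 1)
  expect_gt(share, 100)
  expect_lt(max(abs(conservation_residuals(res, tab, ls, "harvested"))),
            1e-6)
})

test_that("country production totals are conserved by every scenario", {
  w <- small_world(seed = 41, n_rows = 10, n_cols = 10)
  tab0 <- degrade_statistics(w$sru, w$landscape, 0)
  ids <- c("baseline", "allocation_method", "remainder_allocation",
           "crop_suitability", "market_access", "crop_price",
           "adm0_only", "adm1_only")
  for (id in ids) {
    res <- run_scenario(scenario_spec(id), w$landscape, w$ancillary,
                        w$crops, w$sru)
    for (j in w$crops$table$crop_id) {
      expect_equal(sum(res$production[, j]),
                   tab0$production[tab0$crop_id == j],
                   tolerance = 1e-6,
                   label = sprintf("%s crop %d production", id, j))
    }
  }
  # crop_choice conserves per merged group
  named <- which(!w$crops$table$is_aggregate)
  spec <- scenario_spec("crop_choice",
                        crop_merge_map = list(grp = named[1:2]))
  res <- run_scenario(spec, w$landscape, w$ancillary, w$crops, w$sru)
  expect_equal(sum(res$production[, 1]),
               sum(tab0$production[tab0$crop_id %in% named[1:2]]),
               tolerance = 1e-6)
})
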