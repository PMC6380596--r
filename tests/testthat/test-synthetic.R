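# ancillary layers, ground truth, SRU aggregation and degradation

test_that("ancillary: distinct suitability per crop, limits and bounds", {
  ls <- generate_landscape(12, 12, 2, 2, 3, seed = 1)
  crops <- default_crops(2, seed = 2, rest = FALSE)
  anc <- generate_ancillary(ls, crops, suitability_sharpness = 5, seed = 3)
  s1 <- anc$suitable_area[, 1, 2]
  s2 <- anc$suitable_area[, 2, 2]
  expect_lt(stats::cor(s1, s2), 1)
  expect_true(all(anc$suitable_area <= ls$pixel_area + 1e-9))
  expect_true(all(anc$suitable_area >= 0))
  # sharpness 0: spatially uniform per crop
  anc0 <- generate_ancillary(ls, crops, suitability_sharpness = 0, seed = 3)
  for (j in 1:2) {
    expect_equal(max(anc0$suitable_area[, j, 1]),
                 min(anc0$suitable_area[, j, 1]))
  }
  # yields positively associated with suitability within crop
  expect_gt(stats::cor(anc$potential_yield[, 1, 2], s1), 0.9)
  # determinism
  expect_identical(anc, generate_ancillary(ls, crops, 5, seed = 3))
})

test_that("true allocation respects capacity for any seed and scales with concentration", {
  ls <- generate_landscape(12, 12, 2, 2, 3, seed = 1)
  crops <- default_crops(2, seed = 2)
  anc <- generate_ancillary(ls, crops, seed = 3)
  cl <- as.vector(ls$cropland)
  for (seed in 1:5) {
    tr <- generate_true_allocation(ls, anc, crops, concentration = 2,
                                   seed = seed)
    load <- rowSums(tr$physical_area, dims = 1)
    expect_true(all(load <= cl + 1e-8))
    expect_true(all(tr$physical_area >= 0))
  }
  # concentration -> 0: each (crop, system) surface proportional to cropland
  tr0 <- generate_true_allocation(ls, anc, crops, concentration = 0, seed = 4)
  for (j in 1:2) {
    a <- tr0$physical_area[, j, 2]
    keep <- cl > 0
    ratio <- a[keep] / cl[keep]
    expect_lt(diff(range(ratio)), 1e-9 * max(ratio))
  }
  # large concentration puts more mass on the most suitable half
  tr5 <- generate_true_allocation(ls, anc, crops, concentration = 6, seed = 4)
  trl <- generate_true_allocation(ls, anc, crops, concentration = 0.5,
                                  seed = 4)
  j <- 1
  top <- anc$suitable_area[, j, 2] >= stats::median(anc$suitable_area[, j, 2])
  expect_gt(sum(tr5$physical_area[top, j, 2]) / sum(tr5$physical_area[, j, 2]),
            sum(trl$physical_area[top, j, 2]) / sum(trl$physical_area[, j, 2]))
  # infeasible demand errors
  expect_error(
    generate_true_allocation(ls, anc, crops, cropland_use = 1.4, seed = 1),
    "exceeds total cropland")
})

test_that("aggregate_to_sru sums nested units and keeps the yield identity", {
  # toy: 1 x 4 strip, two ADM2 units under one ADM1
  cl <- matrix(c(50, 50, 50, 50), 1, 4)
  adm2 <- matrix(c(1L, 1L, 2L, 2L), 1, 4)
  ls <- manual_landscape(cl, adm1 = matrix(1L, 1, 4), adm2 = adm2,
                         pixel_area = 100)
  crops <- make_crops("maize", price = 150)
  anc <- manual_ancillary(ls, 1, yield = 2)
  phys <- array(0, dim = c(4, 1, 4))
  phys[, 1, 2] <- c(4, 6, 12, 18)  # 10 ha in unit 1, 30 ha in unit 2
  truth <- structure(list(physical_area = phys), class = "true_allocation")
  t2 <- aggregate_to_sru(truth, ls, anc, crops, 2)
  expect_equal(t2$harvested_area, c(10, 30))
  expect_equal(t2$production, c(20, 60))
  t1 <- aggregate_to_sru(truth, ls, anc, crops, 1)
  expect_equal(nrow(t1), 1)
  expect_equal(t1$harvested_area, 40)
  t0 <- aggregate_to_sru(truth, ls, anc, crops, 0)
  expect_equal(nrow(t0), 1)  # one row per crop for the whole country
  expect_equal(t0$harvested_area, 40)
  expect_equal(t0$yield * t0$harvested_area, t0$production)
})

test_that("aggregation is conservative across levels on generated worlds", {
  w <- small_world(seed = 11)
  for (lev in c(2, 1)) {
    tabl <- aggregate_to_sru(w$truth, w$landscape, w$ancillary, w$crops, lev)
    tab0 <- aggregate_to_sru(w$truth, w$landscape, w$ancillary, w$crops, 0)
    for (j in w$crops$table$crop_id) {
      expect_equal(sum(tabl$harvested_area[tabl$crop_id == j]),
                   tab0$harvested_area[tab0$crop_id == j],
                   tolerance = 1e-9)
      expect_equal(sum(tabl$production[tabl$crop_id == j]),
                   tab0$production[tab0$crop_id == j],
                   tolerance = 1e-9)
    }
  }
})

test_that("degrade_statistics re-aggregates, conserves and refuses to refine", {
  w <- small_world(seed = 5)
  tab2 <- w$sru
  tab0 <- degrade_statistics(tab2, w$landscape, 0)
  for (j in w$crops$table$crop_id) {
    expect_equal(sum(tab2$harvested_area[tab2$crop_id == j]),
                 tab0$harvested_area[tab0$crop_id == j], tolerance = 1e-12)
  }
  tab1 <- degrade_statistics(tab2, w$landscape, 1)
  units <- w$landscape$units
  for (r in seq_len(nrow(tab1))) {
    members <- units$code[units$level == 2 & units$parent == tab1$sru_id[r]]
    expect_equal(
      sum(tab2$harvested_area[tab2$sru_id %in% members &
                                tab2$crop_id == tab1$crop_id[r]]),
      tab1$harvested_area[r], tolerance = 1e-12)
  }
  # already at ADM0: identity
  expect_identical(degrade_statistics(tab0, w$landscape, 0), tab0)
  # refinement unsupported
  expect_error(degrade_statistics(tab0, w$landscape, 2), "refine")
  # yield identity on all outputs
  keep <- tab1$harvested_area > 0
  expect_equal(tab1$yield[keep] * tab1$harvested_area[keep],
               tab1$production[keep], tolerance = 1e-9)
})
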