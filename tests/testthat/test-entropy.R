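# priors, cropland adjustment and the cross-entropy solver

test_that("priors: price elimination, symmetry and monotonicity", {
  ls <- generate_landscape(8, 8, 2, 1, 2, seed = 1)
  crops <- default_crops(2, seed = 2, rest = FALSE)
  anc <- generate_ancillary(ls, crops, seed = 3)
  cfg_np <- entropy_config(use_prices = FALSE)
  p1 <- build_priors(ls, anc, crops, cfg_np)
  crops2 <- crops
  crops2$table$price <- crops$table$price * 37.5
  p2 <- build_priors(ls, anc, crops2, cfg_np)
  expect_identical(p1, p2)  # prices eliminated entirely

  # uniform suitability and yield, no market access: uniform prior over
  # the pixels carrying suitable area
  support <- as.vector(ls$cropland) > 0
  anc_u <- manual_ancillary(ls, 1, support = support)
  cu <- make_crops("maize")
  pu <- build_priors(ls, anc_u, cu, entropy_config(use_market_access = FALSE))
  got <- pu[support, 1, 1]
  expect_equal(max(got) - min(got), 0)
  expect_true(all(pu[!support, 1, 1] == 0))
  expect_equal(sum(pu[, 1, 1]), 1, tolerance = 1e-12)

  # doubling one pixel's suitable area strictly increases its share
  anc_d <- anc
  before <- build_priors(ls, anc, crops)[5, 1, 2]
  anc_d$suitable_area[5, 1, 2] <- min(ls$pixel_area,
                                      2 * anc_d$suitable_area[5, 1, 2])
  after <- build_priors(ls, anc_d, crops)[5, 1, 2]
  expect_gt(after, before)

  # every (crop, system) slice with support is normalized
  p <- build_priors(ls, anc, crops)
  expect_true(all(abs(apply(p, c(2, 3), sum) - 1) < 1e-9))
})

test_that("cropland adjustment: minimal scaling, spare land, slack error", {
  crops <- make_crops("maize")
  # fully cropped unit (no spare land): uniform x1.2 scaling
  ls_full <- manual_landscape(matrix(25, 2, 2), pixel_area = 25)
  tab <- data.frame(sru_id = 1L, admin_level = 2L, crop_id = 1L,
                    harvested_area = 120, production = 240, yield = 2)
  adj <- adjust_cropland(ls_full, tab, crops, slack = 2)
  expect_true(adj$flags$adjusted)
  expect_equal(adj$flags$factor, 1.2)
  expect_equal(adj$capacity, rep(30, 4))  # all capacities x 1.2
  # under-used unit: untouched, flag false
  tab80 <- tab; tab80$harvested_area <- 80; tab80$production <- 160
  adj80 <- adjust_cropland(ls_full, tab80, crops, slack = 2)
  expect_false(adj80$flags$adjusted)
  expect_equal(adj80$capacity, rep(25, 4))
  # zero requirement: untouched
  tab0 <- tab; tab0$harvested_area <- 0; tab0$production <- 0
  expect_false(adjust_cropland(ls_full, tab0, crops, 2)$flags$adjusted)
  # spare land absorbs the deficit: non-cropland pixels gain capacity
  ls_sp <- manual_landscape(matrix(c(50, 50, 0, 0), 1, 4), pixel_area = 50)
  adj_sp <- adjust_cropland(ls_sp, tab, crops, slack = 2)
  expect_true(adj_sp$flags$adjusted)
  expect_equal(adj_sp$capacity[1:2], c(50, 50))
  expect_equal(sum(adj_sp$capacity), 120)
  expect_true(all(adj_sp$capacity[3:4] > 0))
  # beyond slack: hard error
  tab_big <- tab; tab_big$harvested_area <- 500; tab_big$production <- 1000
  expect_error(adjust_cropland(ls_full, tab_big, crops, slack = 2),
               "infeasible")
})

test_that("solver returns the prior when it is feasible (objective 0)", {
  set.seed(1)
  n <- 5; K <- 3
  pi <- matrix(stats::runif(n * K), n, K)
  pi <- sweep(pi, 2, colSums(pi), `/`)
  targets <- c(4, 7, 2)
  # generous caps: prior allocation itself is feasible
  upper <- matrix(Inf, n, K)
  cap <- rep(sum(targets), n)
  sol <- solve_kl_allocation(pi, targets, upper, cap)
  expect_equal(sol$A, sweep(pi, 2, targets, `*`), tolerance = 1e-9)
  s <- sweep(sol$A, 2, targets, `/`)
  expect_equal(sum(s * log(s / pi)), 0, tolerance = 1e-9)
})

test_that("binding capacity on one of two pixels gives shares (0.3, 0.7)", {
  # uniform prior, one crop; pixel 1 capacity = 0.3 of the target:
  # KL projection caps pixel 1 and pushes the rest to pixel 2
  pi <- matrix(c(0.5, 0.5), 2, 1)
  targets <- 10
  sol <- solve_kl_allocation(pi, targets, matrix(Inf, 2, 1), c(3, 100))
  expect_equal(as.vector(sol$A) / targets, c(0.3, 0.7), tolerance = 1e-8)
})

test_that("solver matches an independent generic convex solver", {
  skip_if_not(requireNamespace("stats", quietly = TRUE))
  for (seed in 1:20) {
    inst <- random_kl_instance(seed)
    sol <- solve_kl_allocation(inst$pi, inst$targets, inst$upper, inst$cap,
                               tol = 1e-11)
    orc <- oracle_kl_solve(inst$pi, inst$targets, inst$upper, inst$cap)
    s_mine <- sweep(sol$A, 2, inst$targets, `/`)
    obj_mine <- sum(s_mine[s_mine > 0] *
                      log(s_mine[s_mine > 0] / inst$pi[s_mine > 0]))
    expect_equal(obj_mine, orc$objective, tolerance = 1e-6)
    expect_lt(max(abs(s_mine - orc$shares)), 1e-6)
  }
})

test_that("relaxing constraints never increases the optimum", {
  for (seed in 21:25) {
    inst <- random_kl_instance(seed)
    # tighten: scale caps down toward the uniform load
    capt <- pmax(inst$cap * 0.75, sum(inst$targets) / nrow(inst$pi) * 1.05)
    obj <- function(cap, upper) {
      sol <- solve_kl_allocation(inst$pi, inst$targets, upper, cap,
                                 tol = 1e-11)
      s <- sweep(sol$A, 2, inst$targets, `/`)
      sum(s[s > 0] * log(s[s > 0] / inst$pi[s > 0]))
    }
    o_tight <- obj(capt, inst$upper)
    o_loose <- obj(inst$cap, inst$upper)
    o_free <- obj(rep(sum(inst$targets), nrow(inst$pi)),
                  matrix(Inf, nrow(inst$pi), ncol(inst$pi)))
    expect_lte(o_loose, o_tight + 1e-9)
    expect_lte(o_free, o_loose + 1e-9)
  }
})

test_that("full entropy allocation conserves unit totals and constraints", {
  w <- small_world(seed = 9)
  cfg <- entropy_config()
  pri <- build_priors(w$landscape, w$ancillary, w$crops, cfg)
  res <- allocate_cross_entropy(pri, w$sru, w$landscape, w$ancillary,
                                w$crops, cfg)
  expect_false(any(res$adjustments$adjusted))
  expect_lt(max(abs(conservation_residuals(res, w$sru, w$landscape,
                                           "harvested"))), 1e-6)
  expect_lt(max(abs(conservation_residuals(res, w$sru, w$landscape,
                                           "production"))), 1e-6)
  # capacity and suitability respected
  load <- rowSums(res$physical_area, dims = 1)
  cl <- as.vector(w$landscape$cropland)
  expect_true(all(load <= cl * (1 + 1e-6) + 1e-6))
  expect_true(all(res$physical_area <=
                    w$ancillary$suitable_area * (1 + 1e-6) + 1e-6))
  irr <- match("irrigated", production_systems())
  expect_true(all(res$physical_area[, , irr] <=
                    w$ancillary$irrigated_area * (1 + 1e-6) + 1e-6))
  # production = harvested x yield identity
  pos <- res$harvested_area > 0
  expect_equal(res$production[pos],
               (res$harvested_area * res$yield)[pos], tolerance = 1e-9)
})

test_that("degenerate priors error or fall back as configured", {
  ls <- manual_landscape(matrix(c(30, 10), 1, 2), pixel_area = 100)
  crops <- make_crops("maize")
  anc <- manual_ancillary(ls, 1, support = c(FALSE, FALSE))
  tab <- data.frame(sru_id = 1L, admin_level = 2L, crop_id = 1L,
                    harvested_area = 20, production = 40, yield = 2)
  pri <- build_priors(ls, anc, crops)  # all-zero slices
  expect_error(
    allocate_cross_entropy(pri, tab, ls, anc, crops,
                           entropy_config(use_suitability_constraint = FALSE)),
    "degenerate prior")
  cfg_fb <- entropy_config(use_suitability_constraint = FALSE,
                           degenerate_prior = "cropland")
  res <- allocate_cross_entropy(pri, tab, ls, anc, crops, cfg_fb)
  expect_equal(sum(res$harvested_area), 20, tolerance = 1e-6)
})
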