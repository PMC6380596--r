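# Cross-entropy allocation: informed priors updated by minimizing
# KL divergence to the prior subject to reporting-unit totals, per-pixel
# cropland capacity, an irrigated-area cap and (optionally) suitability
# caps.

#' Cross-entropy allocator configuration
#'
#' @param use_suitability_constraint Cap allocated area per (pixel, crop,
#'   system) at the suitable area? (Turning this off is the
#'   crop-suitability robustness scenario.)
#' @param use_market_access Weight priors by a market-access measure
#'   derived from rural population density? (Off = market-access
#'   scenario.)
#' @param use_prices Multiply priors by crop prices? (Off is equivalent
#'   to setting all prices to 1 I$/mt: the crop-price scenario.)
#' @param cropland_slack Maximum factor (`>= 1`) by which a reporting
#'   unit's cropland may be expanded to restore feasibility.
#' @param solver_tol Relative convergence tolerance of the dual solver.
#' @param max_iter Outer iteration cap of the dual solver.
#' @param rainfed_shares Split of the non-irrigated harvested share over
#'   the three rainfed systems (sums to 1).
#' @param degenerate_prior `"error"` to fail on an all-zero prior for a
#'   (crop, system) with positive area, `"cropland"` to fall back to a
#'   cropland-proportional prior.
#' @return An `entropy_config` list.
#' @export
entropy_config <- function(use_suitability_constraint = TRUE,
                           use_market_access = TRUE,
                           use_prices = TRUE,
                           cropland_slack = 2,
                           solver_tol = 1e-9,
                           max_iter = 2000,
                           rainfed_shares = c(rainfed_high = 0.35,
                                              rainfed_low = 0.45,
                                              subsistence = 0.20),
                           degenerate_prior = c("error", "cropland")) {
  if (solver_tol <= 0) stopf("`solver_tol` must be > 0")
  if (cropland_slack < 1) stopf("`cropland_slack` must be >= 1")
  if (length(rainfed_shares) != 3) stopf("`rainfed_shares` needs 3 entries")
  rainfed_shares <- rainfed_shares / sum(rainfed_shares)
  names(rainfed_shares) <- setdiff(production_systems(), "irrigated")
  structure(
    list(use_suitability_constraint = use_suitability_constraint,
         use_market_access = use_market_access,
         use_prices = use_prices,
         cropland_slack = cropland_slack,
         solver_tol = solver_tol,
         max_iter = as.integer(max_iter),
         rainfed_shares = rainfed_shares,
         degenerate_prior = match.arg(degenerate_prior)),
    class = "entropy_config"
  )
}

#' Build prior pixel shares for the cross-entropy allocation
#'
#' The prior share of pixel *i* in crop *j* / system *l* is proportional
#' to `suitable_area(i,j,l) * revenue(i,j,l) * access(i,l)`, normalized
#' over pixels per (crop, system).  `revenue` is potential yield times
#' price when `use_prices` is on, potential yield alone otherwise.  The
#' access weight is a bounded, monotone increasing transform of rural
#' population density, `d / (d + median(d))`; for the subsistence system
#' it is inverted (subsistence production tracks the rural population
#' itself rather than market proximity).
#'
#' @param landscape,ancillary,crops The world the priors describe.
#' @param config An [entropy_config()].
#' @return A `prior_shares` array `n_pixels x n_crops x 4`; each
#'   (crop, system) slice sums to 1 (or to 0 when no pixel has support).
#' @export
build_priors <- function(landscape, ancillary, crops,
                         config = entropy_config()) {
  stopifnot(inherits(landscape, "landscape"), inherits(ancillary, "ancillary"))
  J <- n_crops(crops)
  L <- length(production_systems())
  N <- n_pixels(landscape)
  if (config$use_market_access) {
    d <- ancillary$rural_pop_density
    a <- d / (d + stats::median(d))
  } else {
    a <- rep(1, N)
  }
  pi <- array(0, dim = c(N, J, L),
              dimnames = dimnames(ancillary$suitable_area))
  subsist <- match("subsistence", production_systems())
  for (j in seq_len(J)) {
    pr <- if (config$use_prices) crops$table$price[j] else 1
    for (l in seq_len(L)) {
      acc <- if (config$use_market_access && l == subsist) 1 - a else a
      raw <- ancillary$suitable_area[, j, l] *
        (pr * ancillary$potential_yield[, j, l]) * acc
      s <- sum(raw)
      pi[, j, l] <- if (s > 0) raw / s else 0
    }
  }
  structure(pi, class = c("prior_shares", class(pi)))
}

# Irrigated share of a unit's harvested area: its irrigated fraction of
# cropland, capped so that no crop's irrigated physical target can
# exceed the unit's total irrigated area (the per-pixel irrigation caps
# would otherwise be jointly infeasible for over-subscribed units).
unit_irr_share <- function(cl_p, irr_p, Hj, ci_irr) {
  tot <- sum(cl_p)
  s <- if (tot > 0) min(1, sum(irr_p) / tot) else 0
  pos <- Hj > 0
  if (any(pos) && s > 0) {
    s <- min(s, ci_irr[pos] * sum(irr_p) / Hj[pos])
  }
  s
}

# Physical-area targets per (crop, system) for one SRU: harvested area is
# split into an irrigated share (the unit's irrigated fraction of
# cropland) and fixed rainfed shares, then converted to physical area by
# dividing out the per-system cropping intensity.
sru_system_targets <- function(H_by_crop, irr_share, crops, config) {
  J <- length(H_by_crop)
  L <- length(production_systems())
  share <- c(irrigated = irr_share, (1 - irr_share) * config$rainfed_shares)
  T <- matrix(0, J, L, dimnames = list(NULL, production_systems()))
  for (l in seq_len(L)) {
    ci <- crops$ci[, l]
    T[, l] <- ifelse(ci > 0, H_by_crop * share[l] / ci, 0)
  }
  T
}

#' Adjust cropland capacity for feasibility
#'
#' Where a reporting unit's required physical area exceeds its cropland,
#' capacity is raised by the minimal amount that restores feasibility:
#' the deficit is first assigned to spare (non-cropland) land within the
#' unit in proportion to each pixel's spare area; if the unit has no
#' spare land the remaining deficit is spread by uniform scaling of the
#' pixel capacities.  A unit whose pixels are fully cropped therefore
#' gets exactly the minimal uniform scaling, while a unit with spare land
#' acquires capacity on non-cropland pixels -- which is how presence
#' shares above 100% of cropland pixels arise.  If the required expansion
#' factor exceeds `slack`, a hard infeasibility error is thrown.
#'
#' @param landscape The pixel grid.
#' @param sru_table SRU statistics.
#' @param crops Crop catalogue (cropping intensities enter the physical
#'   requirement).
#' @param slack Maximum expansion factor (`>= 1`).
#' @param ancillary Optional; supplies per-unit irrigated shares for the
#'   system split.  Without it the split assumes no irrigation.
#' @param config An [entropy_config()].
#' @return List with `capacity` (vector of adjusted per-pixel capacities,
#'   ha) and `flags` (data.frame `sru_id`, `admin_level`, `adjusted`,
#'   `factor`).
#' @export
adjust_cropland <- function(landscape, sru_table, crops, slack = 2,
                            ancillary = NULL, config = entropy_config()) {
  if (slack < 1) stopf("`slack` must be >= 1")
  cl <- as.vector(landscape$cropland)
  pa <- landscape$pixel_area
  capacity <- cl
  groups <- unique(sru_table[, c("sru_id", "admin_level")])
  flags <- data.frame(sru_id = groups$sru_id,
                      admin_level = groups$admin_level,
                      adjusted = FALSE, factor = 1)
  for (g in seq_len(nrow(groups))) {
    rows <- sru_table$sru_id == groups$sru_id[g] &
      sru_table$admin_level == groups$admin_level[g]
    p <- pixels_of_unit(landscape, groups$admin_level[g], groups$sru_id[g])
    if (length(p) == 0L) {
      stopf("SRU %s (level %d) has no pixels in the landscape",
            groups$sru_id[g], groups$admin_level[g])
    }
    H <- sru_table$harvested_area[rows]
    jj <- sru_table$crop_id[rows]
    Hj <- numeric(n_crops(crops)); Hj[jj] <- H
    irr_share <- if (is.null(ancillary)) 0 else {
      unit_irr_share(cl[p], ancillary$irrigated_area[p], Hj,
                     crops$ci[, match("irrigated", production_systems())])
    }
    required <- sum(sru_system_targets(Hj, irr_share, crops, config))
    avail <- sum(cl[p])
    if (required <= avail || required <= 0) next
    factor <- required / avail
    if (!is.finite(factor) || factor > slack) {
      stopf("SRU %s (level %d) infeasible: requires %.1f ha physical area vs %.1f ha cropland (factor %.2f > slack %.2f)",
            groups$sru_id[g], groups$admin_level[g], required, avail,
            if (is.finite(factor)) factor else Inf, slack)
    }
    deficit <- required - avail
    spare <- pmax(0, pa - cl[p])
    spare_tot <- sum(spare)
    # assign the deficit onto spare land proportionally (capped at spare);
    # any remainder is spread by uniform scaling of the capacities
    add <- if (spare_tot >= deficit && spare_tot > 0) {
      deficit * spare / spare_tot
    } else spare
    newcap <- cl[p] + add
    if (required - sum(newcap) > 1e-12 * required) {
      newcap <- newcap * (required / sum(newcap))
    }
    capacity[p] <- newcap
    flags$adjusted[g] <- TRUE
    flags$factor[g] <- factor
  }
  list(capacity = capacity, flags = flags)
}

#' Low-level KL-divergence allocation solver
#'
#' Solves, for one reporting unit, the cross-entropy program: minimize
#' `sum_k sum_i s_ik log(s_ik / pi_ik)` over shares `s_ik = A_ik / T_k`
#' subject to `sum_i A_ik = T_k` (unit totals), `A_ik <= upper_ik`
#' (suitability / irrigation caps) and `sum_k A_ik <= cap_i` (pixel
#' capacity).  Deterministic block-coordinate ascent on the dual:
#' exact capped waterfilling for the per-column scales alternated with
#' bisection on the per-pixel capacity multipliers.
#'
#' @param pi `n x K` prior shares; columns sum to 1.
#' @param targets Length-`K` positive physical-area targets (ha).
#' @param upper `n x K` upper bounds on allocated area (`Inf` allowed).
#' @param cap Length-`n` per-pixel capacities (ha).
#' @param tol Relative tolerance on unit totals and capacity violation.
#' @param max_iter Outer iteration cap.
#' @return List with `A` (the `n x K` allocated areas), the dual
#'   variables `lambda` and `beta`, `iterations`, and the final
#'   `mass_residual` and `capacity_violation`.
#' @export
solve_kl_allocation <- function(pi, targets, upper, cap,
                                tol = 1e-9, max_iter = 2000) {
  n <- nrow(pi); K <- ncol(pi)
  stopifnot(length(targets) == K, length(cap) == n,
            all(dim(upper) == dim(pi)))
  eff_upper <- upper
  eff_upper[pi <= 0] <- 0  # KL keeps zero-prior pixels at zero
  feas <- colSums(eff_upper) - targets
  if (any(feas < -1e-9 * pmax(targets, 1))) {
    k <- which.min(feas)
    stopf("infeasible: column %d upper bounds sum to %.6g < target %.6g",
          k, colSums(eff_upper)[k], targets[k])
  }
  if (sum(cap) < sum(targets) * (1 - 1e-9)) {
    stopf("infeasible: total capacity %.6g < total target %.6g",
          sum(cap), sum(targets))
  }
  lam <- rep(0, n)
  base <- sweep(pi, 2, targets, `*`)  # pi_ik * T_k
  A <- base
  # exact column scale b solving sum_i min(U_i, b * c_i) = T by sorted
  # breakpoint scan (capped waterfilling)
  col_scale <- function(cvec, U, T) {
    pos <- cvec > 0
    cp <- cvec[pos]; Up <- U[pos]
    if (length(cp) == 0L) return(Inf)
    r <- Up / cp  # breakpoint where entry i caps
    ord <- order(r)
    r <- r[ord]; Up <- Up[ord]; cp <- cp[ord]
    cumU <- cumsum(Up); cumc <- cumsum(cp)
    total_c <- cumc[length(cp)]
    # mass at breakpoint m (m entries capped); guard Inf * 0 at the tail
    rem <- total_c - cumc
    mass_br <- cumU + ifelse(rem > 0, r * rem, 0)
    mass_br <- cummax(mass_br)
    m <- findInterval(T, mass_br) # entries 1..m capped at the solution
    if (m >= length(cp)) return(if (is.finite(r[length(r)]))
      r[length(r)] else 1e300)  # everything capped; mass = sum(U) ~ T
    freec <- total_c - if (m > 0) cumc[m] else 0
    capU <- if (m > 0) cumU[m] else 0
    (T - capU) / freec
  }
  beta <- rep(1, K)
  converged <- FALSE
  mass_resid <- cap_viol <- Inf
  for (iter in seq_len(max_iter)) {
    E <- exp(-outer(lam, targets))  # n x K
    for (k in seq_len(K)) {
      beta[k] <- col_scale(base[, k] * E[, k], eff_upper[, k], targets[k])
      A[, k] <- pmin(eff_upper[, k], beta[k] * base[, k] * E[, k])
    }
    # capacity step: raise lambda_i on violating pixels, relax where
    # slack remains; vectorized bisection over the affected pixel set
    load <- rowSums(A)
    act <- which(load > cap * (1 + tol) + 1e-300 |
                   (lam > 0 & load < cap * (1 - tol)))
    if (length(act) > 0L) {
      sb <- sweep(base[act, , drop = FALSE], 2, beta, `*`)
      ub <- eff_upper[act, , drop = FALSE]
      hload <- function(l) {  # per-pixel load at multipliers l
        rowSums(pmin(ub, sb * exp(-outer(l, targets))))
      }
      at_zero <- hload(rep(0, length(act))) <= cap[act]
      lam[act[at_zero]] <- 0
      live <- which(!at_zero)
      if (length(live) > 0L) {
        ia <- act[live]
        sb <- sb[live, , drop = FALSE]; ub <- ub[live, , drop = FALSE]
        hl <- function(l) rowSums(pmin(ub, sb * exp(-outer(l, targets))))
        lo <- rep(0, length(live))
        hi <- pmax(lam[ia], 1e-12)
        for (e in 1:60) {
          bad <- hl(hi) > cap[ia]
          if (!any(bad)) break
          hi[bad] <- hi[bad] * 8
        }
        for (it in 1:90) {
          mid <- (lo + hi) / 2
          over <- hl(mid) > cap[ia]
          lo[over] <- mid[over]
          hi[!over] <- mid[!over]
        }
        lam[ia] <- (lo + hi) / 2
      }
    }
    E <- exp(-outer(lam, targets))
    A <- pmin(eff_upper, sweep(base * E, 2, beta, `*`))
    mass_resid <- max(abs(colSums(A) - targets) / pmax(targets, 1e-300))
    cap_viol <- max(c(0, (rowSums(A) - cap) / pmax(cap, 1e-300)))
    if (mass_resid < tol && cap_viol < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stopf("cross-entropy solver did not converge in %d iterations (mass residual %.3g, capacity violation %.3g)",
          max_iter, mass_resid, cap_viol)
  }
  # exact column mass restoration on unconstrained entries is already
  # within tol; report residuals for the caller's audit trail
  list(A = A, lambda = lam, beta = beta, iterations = iter,
       mass_residual = mass_resid, capacity_violation = cap_viol)
}

# Objective value sum s log(s / pi), with 0 log 0 = 0.
kl_objective <- function(A, pi, targets) {
  s <- sweep(A, 2, targets, `/`)
  pos <- s > 0
  sum(s[pos] * log(s[pos] / pi[pos]))
}

#' Cross-entropy allocation of SRU statistics to pixels
#'
#' For each reporting unit, minimizes the KL divergence of the pixel
#' shares from the prior, per (crop, system), subject to: unit totals
#' (physical-area targets derived from harvested area via the system
#' split and cropping intensities), per-pixel cropland capacity (after
#' any feasibility adjustment), an irrigated-area cap on the irrigated
#' system, and -- when `use_suitability_constraint` is on -- per-pixel
#' suitable-area caps.  Allocated physical area is then converted back:
#' harvested area via cropping intensities, production via per-system
#' potential yields rescaled so each unit/crop production total matches
#' the statistics, yield as their ratio.
#'
#' @param priors A `prior_shares` array from [build_priors()].
#' @param sru_table SRU statistics.
#' @param landscape,ancillary,crops The world being allocated.
#' @param config An [entropy_config()].
#' @return An `allocation` with `method = "entropy"`, carrying the
#'   cropland-adjustment flags and per-unit solver residuals.
#' @export
allocate_cross_entropy <- function(priors, sru_table, landscape, ancillary,
                                   crops, config = entropy_config()) {
  stopifnot(inherits(landscape, "landscape"), inherits(ancillary, "ancillary"))
  J <- n_crops(crops)
  L <- length(production_systems())
  N <- n_pixels(landscape)
  adj <- adjust_cropland(landscape, sru_table, crops,
                         slack = config$cropland_slack,
                         ancillary = ancillary, config = config)
  cl <- as.vector(landscape$cropland)
  irr_l <- match("irrigated", production_systems())
  phys <- array(0, dim = c(N, J, L),
                dimnames = list(NULL, crops$table$name, production_systems()))
  groups <- unique(sru_table[, c("sru_id", "admin_level")])
  resids <- data.frame(sru_id = groups$sru_id,
                       admin_level = groups$admin_level,
                       iterations = 0L, mass_residual = 0,
                       capacity_violation = 0, objective = 0)
  for (g in seq_len(nrow(groups))) {
    rows <- which(sru_table$sru_id == groups$sru_id[g] &
                    sru_table$admin_level == groups$admin_level[g])
    p <- pixels_of_unit(landscape, groups$admin_level[g], groups$sru_id[g])
    Hj <- numeric(J)
    Hj[sru_table$crop_id[rows]] <- sru_table$harvested_area[rows]
    irr_share <- unit_irr_share(cl[p], ancillary$irrigated_area[p], Hj,
                                crops$ci[, irr_l])
    Tmat <- sru_system_targets(Hj, irr_share, crops, config)  # J x L
    active <- which(Tmat > 0, arr.ind = TRUE)
    if (nrow(active) == 0L) next
    K <- nrow(active)
    pi_sub <- matrix(0, length(p), K)
    up <- matrix(Inf, length(p), K)
    for (k in seq_len(K)) {
      j <- active[k, 1]; l <- active[k, 2]
      pr <- priors[p, j, l]
      s <- sum(pr)
      if (s <= 0) {
        if (config$degenerate_prior == "cropland" && sum(cl[p]) > 0) {
          pr <- cl[p]; s <- sum(pr)
        } else {
          stopf("degenerate prior: all-zero prior for crop %d / system %s in SRU %s",
                j, production_systems()[l], groups$sru_id[g])
        }
      }
      pi_sub[, k] <- pr / s
      if (config$use_suitability_constraint) {
        up[, k] <- ancillary$suitable_area[p, j, l]
      }
      if (l == irr_l) {
        up[, k] <- pmin(up[, k], ancillary$irrigated_area[p])
      }
    }
    sol <- tryCatch(
      solve_kl_allocation(pi_sub, Tmat[active], up, adj$capacity[p],
                          tol = config$solver_tol,
                          max_iter = config$max_iter),
      error = function(e) {
        stopf("SRU %s (level %d): %s", groups$sru_id[g],
              groups$admin_level[g], conditionMessage(e))
      })
    for (k in seq_len(K)) {
      phys[p, active[k, 1], active[k, 2]] <- sol$A[, k]
    }
    resids$iterations[g] <- sol$iterations
    resids$mass_residual[g] <- sol$mass_residual
    resids$capacity_violation[g] <- sol$capacity_violation
    resids$objective[g] <- kl_objective(sol$A, pi_sub, Tmat[active])
  }
  # convert physical area back to harvested / production / yield,
  # rescaling per-system yields so unit production totals match
  harv <- matrix(0, N, J)
  prod_raw <- matrix(0, N, J)
  for (j in seq_len(J)) {
    for (l in seq_len(L)) {
      h <- phys[, j, l] * crops$ci[j, l]
      harv[, j] <- harv[, j] + h
      prod_raw[, j] <- prod_raw[, j] + h * ancillary$potential_yield[, j, l]
    }
  }
  prod <- matrix(0, N, J)
  for (g in seq_len(nrow(groups))) {
    rows <- which(sru_table$sru_id == groups$sru_id[g] &
                    sru_table$admin_level == groups$admin_level[g])
    p <- pixels_of_unit(landscape, groups$admin_level[g], groups$sru_id[g])
    for (r in rows) {
      j <- sru_table$crop_id[r]
      P <- sru_table$production[r]
      raw <- sum(prod_raw[p, j])
      if (raw > 0 && P > 0) {
        prod[p, j] <- prod_raw[p, j] * (P / raw)
      }
    }
  }
  yld <- ifelse(harv > 0, prod / harv, 0)
  new_allocation(phys, harv, prod, yld, method = "entropy",
                 adjustments = adj$flags, residuals = resids)
}
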