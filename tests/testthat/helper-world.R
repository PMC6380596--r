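# Shared fixture builders: everything generated in code, no stored data.

# Hand-built landscape from explicit matrices (for arithmetic toys).
manual_landscape <- function(cropland, adm1 = NULL, adm2 = NULL,
                             pixel_area = max(cropland)) {
  stopifnot(is.matrix(cropland))
  nr <- nrow(cropland); nc <- ncol(cropland)
  if (is.null(adm1)) adm1 <- matrix(1L, nr, nc)
  if (is.null(adm2)) adm2 <- adm1
  pairs <- unique(data.frame(code = as.vector(adm2),
                             parent = as.vector(adm1)))
  units <- rbind(
    data.frame(level = 0L, code = 1L, parent = NA_integer_),
    data.frame(level = 1L, code = sort(unique(as.vector(adm1))), parent = 1L),
    data.frame(level = 2L, code = pairs$code[order(pairs$code)],
               parent = pairs$parent[order(pairs$code)])
  )
  structure(
    list(n_rows = nr, n_cols = nc, pixel_area = pixel_area,
         cropland = cropland,
         admin = list("0" = matrix(1L, nr, nc), "1" = adm1, "2" = adm2),
         country_mask = matrix(TRUE, nr, nc), units = units),
    class = "landscape")
}

# Uniform hand-built ancillary (suitability = pixel_area on given support).
manual_ancillary <- function(landscape, n_crops_ = 1,
                             support = NULL, yield = 2) {
  N <- landscape$n_rows * landscape$n_cols
  L <- length(production_systems())
  if (is.null(support)) support <- rep(TRUE, N)
  sa <- array(0, dim = c(N, n_crops_, L))
  py <- array(yield, dim = c(N, n_crops_, L))
  for (j in seq_len(n_crops_)) for (l in seq_len(L)) {
    sa[, j, l] <- landscape$pixel_area * as.numeric(support)
  }
  structure(list(suitable_area = sa, potential_yield = py,
                 rural_pop_density = rep(10, N),
                 irrigated_area = 0.2 * as.vector(landscape$cropland)),
            class = "ancillary")
}

# A fully generated small world: landscape + crops + ancillary + truth +
# SRU table at `level`.
small_world <- function(seed = 1, n_rows = 12, n_cols = 12, n_adm1 = 2,
                        n_adm2 = 2, n_crops_ = 2, level = 2,
                        rest = TRUE, ...) {
  ls <- generate_landscape(n_rows, n_cols, n_adm1, n_adm2, 3, seed = seed)
  crops <- default_crops(n_crops_, seed = seed + 1, rest = rest)
  anc <- generate_ancillary(ls, crops, seed = seed + 2)
  truth <- generate_true_allocation(ls, anc, crops, seed = seed + 3, ...)
  tab <- aggregate_to_sru(truth, ls, anc, crops, level)
  list(landscape = ls, crops = crops, ancillary = anc, truth = truth,
       sru = tab)
}

# Per-(SRU, crop) relative conservation residuals of an allocation.
conservation_residuals <- function(result, sru_table, landscape,
                                   what = "harvested") {
  m <- if (what == "harvested") result$harvested_area else result$production
  ref <- if (what == "harvested") sru_table$harvested_area else
    sru_table$production
  vapply(seq_len(nrow(sru_table)), function(r) {
    p <- pixels_of_unit_t(landscape, sru_table$admin_level[r],
                          sru_table$sru_id[r])
    (sum(m[p, sru_table$crop_id[r]]) - ref[r]) / max(ref[r], 1e-12)
  }, numeric(1))
}

# test-side duplicate of the internal pixel lookup (kept independent)
pixels_of_unit_t <- function(landscape, level, code) {
  which(as.vector(landscape$admin[[as.character(level)]]) == code &
          as.vector(landscape$country_mask))
}

# Independent generic convex solver for the KL allocation program
# (stats::constrOptim, adaptive-barrier BFGS on the equality-eliminated
# problem).  Instances must be strictly feasible at uniform shares.
oracle_kl_solve <- function(pi, targets, upper, cap) {
  n <- nrow(pi); K <- ncol(pi)
  stopifnot(n >= 2)
  nf <- n - 1L  # free pixels per column; last row eliminated
  idx <- function(i, k) (k - 1L) * nf + i
  nv <- nf * K
  shares_of <- function(x) {
    s <- matrix(0, n, K)
    s[seq_len(nf), ] <- matrix(x, nf, K)
    s[n, ] <- 1 - colSums(s[seq_len(nf), , drop = FALSE])
    s
  }
  f <- function(x) {
    s <- shares_of(x)
    if (any(s < 0)) {
      # steep finite wall: keeps BFGS line searches on the simplex,
      # where the true entropic objective self-barriers
      return(1e8 * (1 + sum(pmax(0, -s))))
    }
    pos <- s > 0
    sum(s[pos] * log(s[pos] / pi[pos]))
  }
  gr <- function(x) {
    s <- pmax(shares_of(x), 1e-12)
    g <- log(s[seq_len(nf), , drop = FALSE] / pi[seq_len(nf), , drop = FALSE])
    g <- sweep(g, 2, log(s[n, ] / pi[n, ]), `-`)
    as.vector(g)
  }
  ui <- NULL; ci <- NULL
  # a tiny margin keeps the adaptive barrier's iterates strictly interior
  # (log of an exactly-zero slack would otherwise abort the inner BFGS);
  # it displaces the optimum by O(1e-8), far below the 1e-6 tolerance
  margin <- 1e-8
  add <- function(row, rhs) {
    ui <<- rbind(ui, row); ci <<- c(ci, rhs + margin)
  }
  # s_ik >= 0 for free rows
  for (v in seq_len(nv)) {
    row <- numeric(nv); row[v] <- 1; add(row, 0)
  }
  # last-row nonnegativity: 1 - sum_i x_ik >= 0
  for (k in seq_len(K)) {
    row <- numeric(nv); row[idx(seq_len(nf), k)] <- -1; add(row, -1)
  }
  # upper bounds s_ik <= U_ik / T_k
  for (k in seq_len(K)) {
    ub <- upper[, k] / targets[k]
    for (i in seq_len(nf)) {
      if (is.finite(ub[i])) {
        row <- numeric(nv); row[idx(i, k)] <- -1; add(row, -ub[i])
      }
    }
    if (is.finite(ub[n])) {
      # 1 - sum x >= ... <=> sum x >= 1 - ub
      row <- numeric(nv); row[idx(seq_len(nf), k)] <- 1; add(row, 1 - ub[n])
    }
  }
  # capacity sum_k T_k s_ik <= C_i
  for (i in seq_len(nf)) {
    row <- numeric(nv); row[idx(i, seq_len(K))] <- -targets; add(row, -cap[i])
  }
  row <- numeric(nv); row[] <- rep(targets, each = nf)
  add(row, sum(targets) - cap[n])  # last pixel capacity
  x0 <- rep(1 / n, nv)
  fit <- stats::constrOptim(x0, f, gr, ui = ui, ci = ci, mu = 1e-5,
                            method = "BFGS",
                            outer.iterations = 150, outer.eps = 1e-11,
                            control = list(maxit = 300, reltol = 1e-11))
  s <- matrix(0, n, K)
  s[seq_len(nf), ] <- matrix(fit$par, nf, K)
  s[n, ] <- 1 - colSums(s[seq_len(nf), , drop = FALSE])
  list(shares = s, objective = fit$value)
}

# Random strictly feasible instance for the oracle comparison.
random_kl_instance <- function(seed, n = NULL, K = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(2:6, 1)
  if (is.null(K)) K <- 4L  # 2 crops x 2 systems
  pi <- matrix(stats::runif(n * K, 0.2, 1), n, K)
  pi <- sweep(pi, 2, colSums(pi), `/`)
  targets <- stats::runif(K, 5, 20)
  # uniform shares strictly interior: caps above uniform usage
  upper <- matrix(stats::runif(n * K, 1.3, 3) / n, n, K)
  upper <- sweep(upper, 2, targets, `*`)
  upper[stats::runif(n * K) < 0.3] <- Inf
  cap <- stats::runif(n, 1.2, 2.5) * sum(targets) / n
  list(pi = pi, targets = targets, upper = upper, cap = cap)
}
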