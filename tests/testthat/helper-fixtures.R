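# Shared fixtures and independent (naive) oracles.

# tiny well-formed dataset: two cells, one facility, explicit impedance
tiny_dataset <- function() {
  cells <- demand_cells(data.frame(
    cell_id = c("c1", "c2"), x = c(0, 1000), y = 0,
    older_pop = c(1000, 500), district_id = "D1"))
  fac <- facilities(data.frame(
    facility_id = "f1", x = 0, y = 0, beds = 100,
    tier = "level_3", district_id = "D1"))
  imp <- structure(matrix(c(0.5, 0.75), 2, 1,
                          dimnames = list(cells$cell_id, fac$facility_id)),
                   class = c("impedance_matrix", "matrix"),
                   floor_hours = 1 / 60)
  list(cells = cells, facilities = fac, impedance = imp)
}

# random micro dataset (<= 5 cells x <= 3 facilities) with explicit impedance
random_micro <- function(n_cells, n_fac) {
  cells <- demand_cells(data.frame(
    cell_id = sprintf("c%d", seq_len(n_cells)),
    x = runif(n_cells, 0, 10000), y = runif(n_cells, 0, 10000),
    older_pop = sample(0:2000, n_cells),
    district_id = sample(c("A", "B"), n_cells, replace = TRUE)))
  fac <- facilities(data.frame(
    facility_id = sprintf("f%d", seq_len(n_fac)),
    x = runif(n_fac, 0, 10000), y = runif(n_fac, 0, 10000),
    beds = sample(c(20, 150, 600), n_fac, replace = TRUE),
    tier = sample(c("ungraded", "level_2", "level_3", "level_4", "level_5"),
                  n_fac, replace = TRUE),
    district_id = "A"))
  imp <- structure(matrix(runif(n_cells * n_fac, 0.05, 3), n_cells, n_fac,
                          dimnames = list(cells$cell_id, fac$facility_id)),
                   class = c("impedance_matrix", "matrix"),
                   floor_hours = 1 / 60)
  list(cells = cells, facilities = fac, impedance = imp)
}

# naive scalar-loop recomputation of all three potential models, written
# directly from the formulas, independent of the vectorized path
brute_force_accessibility <- function(cells, fac, imp,
                                      params = model_params(),
                                      model = c("basic", "weibull",
                                                "improved")) {
  model <- match.arg(model)
  b <- params$beta
  n <- nrow(cells)
  m <- nrow(fac)
  S <- matrix(1, n, m)
  if (model == "improved") {
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        d <- if (fac$beds[j] >= params$bed_threshold) params$d_large
             else params$d_small
        Dj <- params$tier_limits[[fac$tier[j]]]
        s <- 1 - (imp[i, j] / (d + Dj))^b
        S[i, j] <- min(max(s, 0), 1)
      }
    }
  }
  A <- numeric(n)
  if (model == "basic") {
    for (i in seq_len(n)) {
      for (j in seq_len(m)) A[i] <- A[i] + fac$beds[j] / imp[i, j]^b
    }
    return(A)
  }
  V <- numeric(m)
  for (j in seq_len(m)) {
    for (k in seq_len(n)) {
      V[j] <- V[j] + S[k, j] * cells$older_pop[k] / imp[k, j]^b
    }
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (V[j] > 0) {
        A[i] <- A[i] + S[i, j] * fac$beds[j] / (imp[i, j]^b * V[j])
      }
    }
  }
  if (model == "improved") A <- A * params$scale_per
  A
}

# O(n^2) pairwise (weighted mean-absolute-difference) Gini on grouped data
pairwise_gini <- function(units) {
  x <- units$beds / units$older_pop      # per-capita supply
  w <- units$older_pop
  x[w == 0] <- 0
  mu <- sum(units$beds) / sum(w)
  num <- 0
  for (i in seq_along(x)) {
    for (j in seq_along(x)) num <- num + w[i] * w[j] * abs(x[i] - x[j])
  }
  num / (2 * sum(w)^2 * mu)
}

# a small synthetic city used by several test files
small_city <- function(seed = 11) {
  generate_city(city_spec(seed = seed, extent_km = 6, grid_m = 500,
                          n_districts = 4, total_older_pop = 5e4,
                          n_facilities = 25))
}
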