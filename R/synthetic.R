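#' Specification of a synthetic city
#'
#' Parameters of the deterministic synthetic-city generator. Defaults
#' emulate a Shanghai-like monocentric metropolis: an 80 km square at
#' 500 m grid resolution, 16 districts, 5,536,600 residents aged 60+,
#' 658 facilities with log-normal bed counts (median 150 beds, mean
#' around 210), about 60% of facilities graded, and facility placement
#' biased towards population.
#'
#' @param seed Integer seed; the only source of randomness.
#' @param extent_km Side of the square study area, km.
#' @param grid_m Demand-cell size, metres (default 500).
#' @param n_districts Number of districts (k-means tessellation of cell
#'   centroids).
#' @param total_older_pop Total 60+ population, conserved exactly across
#'   cells (largest-remainder rounding).
#' @param center_concentration Exponential decay rate of population with
#'   distance from the centre(s); 0 gives a uniform city.
#' @param n_facilities Number of facilities.
#' @param beds_meanlog,beds_sdlog Log-normal parameters for bed counts
#'   (rounded, floored at 1).
#' @param tier_probs Named probabilities over quality tiers (sum 1).
#' @param facility_placement_bias In `[0, 1]`: 0 places facilities
#'   uniformly over cells, 1 proportionally to cell population.
#' @param centers Optional data frame `x`, `y`, `weight` (metres) of
#'   population centres; default a single centre at the midpoint.
#' @return Object of class `city_spec`.
#' @export
city_spec <- function(seed = 1L,
                      extent_km = 80,
                      grid_m = 500,
                      n_districts = 16L,
                      total_older_pop = 5536600,
                      center_concentration = 2,
                      n_facilities = 658L,
                      beds_meanlog = log(150),
                      beds_sdlog = 0.8,
                      tier_probs = c(ungraded = 0.40, level_2 = 0.15,
                                     level_3 = 0.25, level_4 = 0.15,
                                     level_5 = 0.05),
                      facility_placement_bias = 0.7,
                      centers = NULL) {
  stopifnot(extent_km > 0, grid_m > 0, n_districts >= 1,
            total_older_pop > 0, center_concentration >= 0,
            n_facilities >= 1,
            facility_placement_bias >= 0, facility_placement_bias <= 1)
  if (abs(sum(tier_probs) - 1) > 1e-8) {
    stop("tier_probs must sum to 1", call. = FALSE)
  }
  bad <- setdiff(names(tier_probs), TIER_LEVELS)
  if (length(bad)) stop("unknown tiers in tier_probs: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  n_side <- max(1L, round(extent_km * 1000 / grid_m))
  if (n_districts > n_side^2) {
    stop("more districts than demand cells: infeasible", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), extent_km = extent_km,
                 grid_m = grid_m, n_districts = as.integer(n_districts),
                 total_older_pop = total_older_pop,
                 center_concentration = center_concentration,
                 n_facilities = as.integer(n_facilities),
                 beds_meanlog = beds_meanlog, beds_sdlog = beds_sdlog,
                 tier_probs = tier_probs,
                 facility_placement_bias = facility_placement_bias,
                 centers = centers),
            class = "city_spec")
}

# run code under a local RNG stream, leaving the global state untouched
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a synthetic city
#'
#' Builds a reproducible demand surface, district partition and facility
#' registry from a [city_spec()]. Cell populations follow an exponential
#' decay from the population centre(s) and are rounded to integers by the
#' largest-remainder method, so they sum exactly to `total_older_pop`.
#' Districts partition the grid by k-means on cell centroids. Facilities
#' are placed in cells sampled with probability interpolating between
#' uniform and population-proportional, jittered within the cell.
#' The same seed always yields identical output.
#'
#' @param spec A [city_spec()].
#' @return List with `cells` ([demand_cells()]), `facilities`
#'   ([facilities()]) and `districts` (data frame of district centroids
#'   and cell counts; the cell-to-district mapping lives on `cells`).
#' @examples
#' city <- generate_city(city_spec(seed = 7, extent_km = 5,
#'                                 n_districts = 4, total_older_pop = 1e4,
#'                                 n_facilities = 12))
#' nrow(city$cells)
#' @export
generate_city <- function(spec) {
  stopifnot(inherits(spec, "city_spec"))
  with_local_seed(spec$seed, {
    ext <- spec$extent_km * 1000
    n_side <- max(1L, round(ext / spec$grid_m))
    cc <- (seq_len(n_side) - 0.5) * (ext / n_side)
    g <- expand.grid(x = cc, y = cc)
    centers <- spec$centers %||% data.frame(x = ext / 2, y = ext / 2,
                                            weight = 1)
    w <- rep(0, nrow(g))
    for (i in seq_len(nrow(centers))) {
      r <- sqrt((g$x - centers$x[i])^2 + (g$y - centers$y[i])^2)
      w <- w + centers$weight[i] *
        exp(-spec$center_concentration * r / (ext / 2))
    }
    pop <- largest_remainder(spec$total_older_pop * w / sum(w))

    km <- stats::kmeans(cbind(g$x, g$y), centers = spec$n_districts,
                        iter.max = 50, nstart = 3)
    district <- sprintf("D%02d", km$cluster)

    cells <- demand_cells(data.frame(
      cell_id = sprintf("c%05d", seq_len(nrow(g))),
      x = g$x, y = g$y, older_pop = pop, district_id = district))

    p_cell <- spec$facility_placement_bias * pop / sum(pop) +
      (1 - spec$facility_placement_bias) / nrow(g)
    host <- sample.int(nrow(g), spec$n_facilities, replace = TRUE,
                       prob = p_cell)
    jit <- spec$grid_m * 0.4
    fac <- facilities(data.frame(
      facility_id = sprintf("f%04d", seq_len(spec$n_facilities)),
      x = g$x[host] + runif(spec$n_facilities, -jit, jit),
      y = g$y[host] + runif(spec$n_facilities, -jit, jit),
      beds = pmax(1, round(rlnorm(spec$n_facilities, spec$beds_meanlog,
                                  spec$beds_sdlog))),
      tier = sample(names(spec$tier_probs), spec$n_facilities,
                    replace = TRUE, prob = spec$tier_probs),
      district_id = district[host]))

    districts <- data.frame(district_id = sprintf("D%02d",
                                                  seq_len(spec$n_districts)),
                            center_x = km$centers[, 1],
                            center_y = km$centers[, 2],
                            n_cells = as.vector(km$size))
    list(cells = cells, facilities = fac, districts = districts)
  })
}

# round nonnegative reals to integers preserving the exact total
largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- round(sum(x)) - sum(fl)
  if (rem > 0) {
    frac <- x - fl
    top <- order(frac, decreasing = TRUE)[seq_len(rem)]
    fl[top] <- fl[top] + 1
  }
  fl
}

#' District-level facility table of the Shanghai case (2022)
#'
#' The published per-district counts for Shanghai's 16 districts: beds,
#' aged-care institutions and graded institutions, as shipped in
#' `extdata/shanghai_table1.csv`. Column sums: 136,719 beds over 658
#' institutions.
#'
#' @return Data frame `district_id`, `beds`, `institutions`, `graded`.
#' @examples
#' sum(table1_fixture()$institutions)  # 658
#' @export
table1_fixture <- function() {
  utils::read.csv(system.file("extdata", "shanghai_table1.csv",
                              package = "careaccess", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Synthetic stand-in for Shanghai's district 60+ populations
#'
#' Only the five largest district 60+ populations of the 2022 Shanghai
#' case are published; the full set lives in the Shanghai Statistical
#' Yearbook 2022, which is not shipped. This table keeps the five
#' published values exactly and fills the remaining eleven districts by
#' an equal split of the remaining citywide 60+ total (5,536,600). The
#' `source` column flags each row. Use for demonstrations; equity
#' statistics computed from it are stand-ins, not the case study's.
#'
#' @return Data frame `district_id`, `older_pop`, `source`.
#' @export
shanghai_pop60_synthetic <- function() {
  utils::read.csv(system.file("extdata", "shanghai_pop60_synthetic.csv",
                              package = "careaccess", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
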