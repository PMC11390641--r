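#' Bed-scale service radius
#'
#' Facilities at or above the bed threshold (default 500 beds) serve a
#' 2 h radius; smaller ones serve 1 h. The boundary case (exactly the
#' threshold) takes the large radius.
#'
#' @param beds Integer vector of bed counts (>= 1).
#' @param params [model_params()].
#' @return Numeric vector of service radii `d` in hours.
#' @examples
#' service_radius(c(100, 500, 600))  # 1, 2, 2
#' @export
service_radius <- function(beds, params = model_params()) {
  stopifnot(all(beds >= 1))
  ifelse(beds >= params$bed_threshold, params$d_large, params$d_small)
}

#' Quality-tier travel limit
#'
#' Travel-time allowance tied to the national quality grading: 15 min for
#' institutions below Level 3 (ungraded and Level 2), 0.5 h for Level 3,
#' 1 h for Level 4 and 2 h for Level 5.
#'
#' @param tier Character vector of tiers (`ungraded`, `level_2`, ...,
#'   `level_5`).
#' @param params [model_params()].
#' @return Numeric vector of limits `D_j` in hours.
#' @examples
#' tier_travel_limit(c("ungraded", "level_3", "level_5"))  # 0.25 0.5 2
#' @export
tier_travel_limit <- function(tier, params = model_params()) {
  bad <- setdiff(unique(tier), names(params$tier_limits))
  if (length(bad)) {
    stop("unknown tier label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(names(params$tier_limits), collapse = ", "), ")",
         call. = FALSE)
  }
  unname(params$tier_limits[tier])
}

#' Influence coefficient of a facility on a demand point
#'
#' `S = 1 - (D / (d + D_j))^beta`, clamped to `[0, 1]`: the facility's pull
#' decays with travel time relative to its combined scale radius and tier
#' limit, reaching zero at (and beyond) `D = d + D_j` — a soft catchment
#' boundary.
#'
#' @param D_ij Travel time in hours (nonnegative; recycled).
#' @param d Service radius in hours (see [service_radius()]).
#' @param D_j Tier travel limit in hours (see [tier_travel_limit()]).
#' @param beta Friction exponent.
#' @return Values in `[0, 1]`; nonincreasing in `D_ij`, nondecreasing in
#'   `d` and `D_j`.
#' @examples
#' influence_coefficient(0.5, d = 1, D_j = 0.5)  # 2/3
#' influence_coefficient(1.5, d = 1, D_j = 0.5)  # 0 (catchment edge)
#' @export
influence_coefficient <- function(D_ij, d, D_j, beta = 1) {
  stopifnot(all(D_ij >= 0), all(d > 0), all(D_j > 0), beta > 0)
  pmin(pmax(1 - (D_ij / (d + D_j))^beta, 0), 1)
}

# cells x facilities matrix of S_ij for a dataset
influence_matrix <- function(impedance, facilities, params) {
  d <- service_radius(facilities$beds, params)
  Dj <- tier_travel_limit(facilities$tier, params)
  reach <- rep(d + Dj, each = nrow(impedance))
  s <- 1 - (unclass(impedance) / reach)^params$beta
  matrix(pmin(pmax(s, 0), 1), nrow(impedance), ncol(impedance),
         dimnames = dimnames(impedance))
}

#' Demand potential (competition term) per facility
#'
#' `V_j = sum_k S_kj * P_k / D_kj^beta`: the population-weighted demand a
#' facility can reach, used to normalise its bed supply across competing
#' demand points. The `"weibull"` variant sets `S == 1` (pure
#' population-size competition); the `"improved"` variant attenuates
#' demand by the influence coefficient, so facilities out of reach of all
#' population have `V_j = 0`.
#'
#' @param cells Demand cells.
#' @param facilities Facility registry.
#' @param impedance Impedance matrix in hours (cells x facilities).
#' @param params [model_params()].
#' @param variant `"improved"` (default) or `"weibull"`.
#' @return Named numeric vector `V_j` over facilities.
#' @export
demand_potential <- function(cells, facilities, impedance,
                             params = model_params(),
                             variant = c("improved", "weibull")) {
  variant <- match.arg(variant)
  check_dataset(cells, facilities, impedance)
  w <- cells$older_pop / unclass(impedance)^params$beta
  if (variant == "improved") {
    w <- influence_matrix(impedance, facilities, params) * w
  }
  v <- colSums(w)
  names(v) <- facilities$facility_id
  v
}

check_dataset <- function(cells, facilities, impedance) {
  v <- dataset_violations(cells, facilities, impedance)
  if (nrow(v)) stop(format_violations(v), call. = FALSE)
  invisible(TRUE)
}

new_surface <- function(cells, A, model, params, unused = character()) {
  structure(data.frame(cell_id = cells$cell_id, accessibility = unname(A)),
            class = c("accessibility_surface", "data.frame"),
            model = model, params = params, unused_facilities = unused)
}

#' Basic potential-model accessibility
#'
#' The classic gravity form `A_i = sum_j M_j / D_ij^beta`: every
#' facility's beds, discounted by travel impedance, with no competition
#' adjustment and no catchment. Units are raw potential (bed-hours^-beta),
#' not per-capita.
#'
#' @inheritParams demand_potential
#' @return An `accessibility_surface`: data frame `cell_id`,
#'   `accessibility` with the model and parameters as attributes.
#' @export
accessibility_basic <- function(cells, facilities, impedance,
                                params = model_params()) {
  check_dataset(cells, facilities, impedance)
  A <- as.vector(unclass(impedance)^(-params$beta) %*% facilities$beds)
  new_surface(cells, A, "basic", params)
}

#' Competition-adjusted (population-size) potential accessibility
#'
#' `A_i = sum_j M_j / (D_ij^beta * V_j)` with
#' `V_j = sum_k P_k / D_kj^beta`: each facility's beds are shared across
#' the demand it can reach, so accessibility is a per-capita supply rate.
#' Facilities with `V_j = 0` contribute nothing.
#'
#' @inheritParams demand_potential
#' @return An `accessibility_surface` (beds per older adult, unscaled).
#' @export
accessibility_weibull <- function(cells, facilities, impedance,
                                  params = model_params()) {
  check_dataset(cells, facilities, impedance)
  V <- demand_potential(cells, facilities, impedance, params, "weibull")
  keep <- V > 0
  D <- unclass(impedance)
  contrib <- sweep(D[, keep, drop = FALSE]^(-params$beta), 2,
                   facilities$beds[keep] / V[keep], `*`)
  A <- rowSums(contrib)
  new_surface(cells, A, "weibull", params,
              unused = facilities$facility_id[!keep])
}

#' Improved potential-model accessibility (beds per 1,000 older adults)
#'
#' The headline model:
#' `A_i = scale_per * sum_j S_ij * M_j / (D_ij^beta * V_j)` with
#' `V_j = sum_k S_kj * P_k / D_kj^beta`. The influence coefficient `S`
#' (bed-scale service radius + quality-tier travel limit, see
#' [influence_coefficient()]) attenuates both the supply a demand point
#' sees and the demand a facility serves; `V_j` normalises beds across
#' competing demand, making `A_i` a per-capita rate, reported per
#' `scale_per` (default 1,000) older adults. Facilities whose catchment
#' contains no population (`V_j = 0`) are excluded and reported in the
#' `unused_facilities` attribute.
#'
#' Within reach of any demand, total supply is conserved:
#' `sum_i P_i * A_i / scale_per == sum_j M_j` over facilities with
#' `V_j > 0` (exact algebraic identity of the competition normalisation).
#'
#' @inheritParams demand_potential
#' @return An `accessibility_surface` in beds per `scale_per` older
#'   adults.
#' @examples
#' cs <- demand_cells(data.frame(cell_id = "c", x = 0, y = 0,
#'                               older_pop = 1000, district_id = "D"))
#' fs <- facilities(data.frame(facility_id = "f", x = 1, y = 0, beds = 100,
#'                             tier = "level_3", district_id = "D"))
#' D <- structure(matrix(0.5, 1, 1, dimnames = list("c", "f")),
#'                class = c("impedance_matrix", "matrix"))
#' accessibility_improved(cs, fs, D)$accessibility  # 100 beds / 1000
#' @export
accessibility_improved <- function(cells, facilities, impedance,
                                   params = model_params()) {
  check_dataset(cells, facilities, impedance)
  S <- influence_matrix(impedance, facilities, params)
  D <- unclass(impedance)
  V <- colSums(S * (cells$older_pop / D^params$beta))
  keep <- V > 0
  contrib <- S[, keep, drop = FALSE] / D[, keep, drop = FALSE]^params$beta
  contrib <- sweep(contrib, 2, facilities$beds[keep] / V[keep], `*`)
  A <- params$scale_per * rowSums(contrib)
  new_surface(cells, A, "improved", params,
              unused = facilities$facility_id[!keep])
}

#' Population-weighted district accessibility
#'
#' Aggregates a cell-level surface to districts as the older-population-
#' weighted mean, the per-district supply ratio behind "beds per 1,000
#' older adults by district" comparisons.
#'
#' @param surface An `accessibility_surface`.
#' @param cells The demand cells the surface was computed on.
#' @return Data frame `district_id`, `older_pop`, `accessibility`;
#'   districts with zero population get `NA` accessibility.
#' @export
surface_to_district <- function(surface, cells) {
  stopifnot(inherits(surface, "accessibility_surface"))
  i <- match(cells$cell_id, surface$cell_id)
  if (anyNA(i)) stop("surface does not cover every cell", call. = FALSE)
  A <- surface$accessibility[i]
  sp <- split(seq_len(nrow(cells)), cells$district_id)
  out <- data.frame(
    district_id = names(sp),
    older_pop = vapply(sp, function(k) sum(cells$older_pop[k]), 0),
    accessibility = vapply(sp, function(k) {
      p <- cells$older_pop[k]
      if (sum(p) == 0) NA_real_ else stats::weighted.mean(A[k], p)
    }, 0),
    row.names = NULL)
  out
}

#' @export
print.accessibility_surface <- function(x, ...) {
  p <- attr(x, "params")
  cat("Accessibility surface (", attr(x, "model"), " model, beta = ",
      p$beta, "): ", nrow(x), " cells\n", sep = "")
  cat("  A in [", signif(min(x$accessibility), 4), ", ",
      signif(max(x$accessibility), 4), "]",
      if (identical(attr(x, "model"), "improved"))
        paste0(" beds per ", p$scale_per, " older adults"), "\n", sep = "")
  un <- attr(x, "unused_facilities")
  if (length(un)) {
    cat("  unused capacity: ", length(un),
        " facility(ies) with no reachable demand\n", sep = "")
  }
  invisible(x)
}
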