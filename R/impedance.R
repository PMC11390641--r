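#' Impedance specification: how travel times are derived
#'
#' Travel impedance stands in for road-network travel time. Distances are
#' straight-line (planar euclidean or great-circle haversine), inflated by
#' a detour factor and divided by a travel speed; a precomputed matrix can
#' be supplied instead (`method = "external"`).
#'
#' @param method `"euclidean"` (planar metres), `"haversine"` (lon/lat) or
#'   `"external"` (load a precomputed matrix with [load_impedance()]).
#' @param speed_kmh Travel speed in km/h used to convert distance to time.
#' @param detour_factor Multiplicative inflation of straight-line distance
#'   approximating network detours; must be >= 1.
#' @param floor_hours Minimum travel time in hours (keeps `1 / D^beta`
#'   finite for co-located points).
#' @return An object of class `impedance_spec`.
#' @examples
#' impedance_spec("euclidean", speed_kmh = 30)
#' @export
impedance_spec <- function(method = c("euclidean", "haversine", "external"),
                           speed_kmh = 30, detour_factor = 1.3,
                           floor_hours = 1 / 60) {
  method <- match.arg(method)
  stopifnot(is.numeric(speed_kmh), speed_kmh > 0,
            is.numeric(detour_factor), detour_factor >= 1,
            is.numeric(floor_hours), floor_hours > 0)
  structure(list(method = method, speed_kmh = speed_kmh,
                 detour_factor = detour_factor, floor_hours = floor_hours),
            class = "impedance_spec")
}

# mean Earth radius (m) so 1 degree of latitude is ~111.19 km
EARTH_RADIUS_M <- 6371008.8

#' Cell-to-facility distance matrix
#'
#' @param cells Demand cells ([demand_cells()]).
#' @param facilities Facility registry ([facilities()]).
#' @param method `"euclidean"` for planar metre coordinates, `"haversine"`
#'   for geographic lon/lat. Both inputs must carry the matching
#'   coordinate kind; mixing kinds is an error.
#' @return Matrix of kilometres, rows named by `cell_id`, columns by
#'   `facility_id`. Entries are nonnegative and zero only for coincident
#'   points.
#' @examples
#' cs <- demand_cells(data.frame(cell_id = "c", x = 0, y = 0,
#'                               older_pop = 1, district_id = "D"))
#' fs <- facilities(data.frame(facility_id = "f", x = 3000, y = 4000,
#'                             beds = 10, tier = "level_3", district_id = "D"))
#' distance_matrix(cs, fs)  # 5 km
#' @export
distance_matrix <- function(cells, facilities,
                            method = c("euclidean", "haversine")) {
  method <- match.arg(method)
  want <- if (method == "euclidean") "planar" else "geographic"
  kinds <- c(coord_kind(cells), coord_kind(facilities))
  if (any(kinds != want)) {
    stop("method '", method, "' needs ", want, " coordinates, but inputs are ",
         paste(unique(kinds), collapse = " and "), call. = FALSE)
  }
  if (method == "euclidean") {
    dx <- outer(cells$x, facilities$x, "-")
    dy <- outer(cells$y, facilities$y, "-")
    km <- sqrt(dx^2 + dy^2) / 1000
  } else {
    km <- matrix(0, nrow(cells), nrow(facilities))
    for (j in seq_len(nrow(facilities))) {
      km[, j] <- geosphere::distHaversine(
        cbind(cells$x, cells$y),
        c(facilities$x[j], facilities$y[j]),
        r = EARTH_RADIUS_M) / 1000
    }
  }
  dimnames(km) <- list(cells$cell_id, facilities$facility_id)
  km
}

#' Convert a distance matrix to a travel-time impedance matrix
#'
#' `hours = max(km * detour_factor / speed_kmh, floor_hours)`; linear in
#' distance above the floor.
#'
#' @param km_matrix Nonnegative matrix of kilometres (see
#'   [distance_matrix()]).
#' @param spec An [impedance_spec()].
#' @return Impedance matrix (class `impedance_matrix`) in hours, every
#'   entry `>= spec$floor_hours`.
#' @examples
#' time_from_distance(matrix(5), impedance_spec())  # 5 * 1.3 / 30 h
#' @export
time_from_distance <- function(km_matrix, spec = impedance_spec()) {
  stopifnot(inherits(spec, "impedance_spec"))
  if (any(km_matrix < 0)) stop("distances must be nonnegative", call. = FALSE)
  hours <- pmax(km_matrix * spec$detour_factor / spec$speed_kmh,
                spec$floor_hours)
  structure(hours, class = c("impedance_matrix", class(hours)),
            floor_hours = spec$floor_hours)
}

#' Build an impedance matrix straight from coordinates
#'
#' Convenience wrapper: [distance_matrix()] then [time_from_distance()].
#'
#' @inheritParams distance_matrix
#' @param spec An [impedance_spec()] with method `"euclidean"` or
#'   `"haversine"`.
#' @return An `impedance_matrix` in hours.
#' @export
impedance_from_coords <- function(cells, facilities,
                                  spec = impedance_spec()) {
  if (spec$method == "external") {
    stop("spec method is 'external'; use load_impedance()", call. = FALSE)
  }
  time_from_distance(distance_matrix(cells, facilities, spec$method), spec)
}

#' Load a precomputed impedance matrix
#'
#' Reads a long-format CSV `cell_id,facility_id,hours` covering every
#' cell-facility pair. Entries below the floor are raised to it with one
#' warning giving the count.
#'
#' @param path CSV path.
#' @inheritParams distance_matrix
#' @param floor_hours Minimum travel time in hours.
#' @return An `impedance_matrix` (hours) with rows/columns ordered as in
#'   `cells` / `facilities`.
#' @export
load_impedance <- function(path, cells, facilities, floor_hours = 1 / 60) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "facility_id", "hours")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("impedance file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(df$hours)) {
    stop("impedance 'hours' column is not numeric", call. = FALSE)
  }
  unknown_c <- setdiff(df$cell_id, cells$cell_id)
  unknown_f <- setdiff(df$facility_id, facilities$facility_id)
  if (length(unknown_c) || length(unknown_f)) {
    stop("impedance file references unknown ids: ",
         paste(c(unknown_c, unknown_f), collapse = ", "), call. = FALSE)
  }
  m <- matrix(NA_real_, nrow(cells), nrow(facilities),
              dimnames = list(cells$cell_id, facilities$facility_id))
  m[cbind(match(df$cell_id, cells$cell_id),
          match(df$facility_id, facilities$facility_id))] <- df$hours
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("impedance file is missing pair(s), e.g. cell '",
         rownames(m)[idx[1]], "' x facility '", colnames(m)[idx[2]], "'",
         call. = FALSE)
  }
  n_low <- sum(m < floor_hours)
  if (n_low > 0) {
    warning(n_low, " impedance entr", if (n_low == 1) "y" else "ies",
            " below the floor of ", signif(floor_hours, 4),
            " h were raised to it", call. = FALSE)
    m <- pmax(m, floor_hours)
  }
  structure(m, class = c("impedance_matrix", class(m)),
            floor_hours = floor_hours)
}

#' Write an impedance matrix as long-format CSV
#'
#' Round-trips with [load_impedance()] on the same id ordering.
#'
#' @param impedance An `impedance_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_impedance <- function(impedance, path) {
  df <- data.frame(
    cell_id = rep(rownames(impedance), times = ncol(impedance)),
    facility_id = rep(colnames(impedance), each = nrow(impedance)),
    hours = as.vector(impedance))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.impedance_matrix <- function(x, ...) {
  cat("Impedance matrix: ", nrow(x), " cells x ", ncol(x),
      " facilities, hours in [", signif(min(x), 4), ", ", signif(max(x), 4),
      "], floor ", signif(attr(x, "floor_hours") %||% min(x), 4), " h\n",
      sep = "")
  invisible(x)
}
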