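#' Weighted Gaussian kernel density on a regular grid
#'
#' Smooths a weighted facility point pattern into a density surface
#' (weight per square kilometre). Each point contributes an isotropic
#' Gaussian kernel integrating to its weight, so the grid-cell-weighted
#' sum of the surface recovers the total weight (up to edge truncation).
#' Weight 1 per point gives facility density; bed counts give bed
#' density.
#'
#' @param points Data frame with planar metre columns `x`, `y`.
#' @param weights Per-point weights (recycled; default 1).
#' @param bandwidth_km Kernel standard deviation in km; default is
#'   Silverman's rule on the mean per-axis spread.
#' @param grid Optional list `nx`, `ny`, `xmin`, `xmax`, `ymin`, `ymax`
#'   (metres). Default: 96 x 96 cells over the bounding box padded by
#'   four bandwidths.
#' @return Object of class `density_grid`: `x`, `y` (cell-centre
#'   coordinates, metres), `z` (`nx` x `ny` density, per km^2),
#'   `bandwidth_km`, `total_weight`, `cell_area_km2`.
#' @examples
#' kd <- kernel_density(data.frame(x = 0, y = 0), bandwidth_km = 2)
#' sum(kd$z) * kd$cell_area_km2  # ~1
#' @export
kernel_density <- function(points, weights = 1, bandwidth_km = NULL,
                           grid = NULL) {
  if (nrow(points) < 1) stop("need at least one point", call. = FALSE)
  w <- rep_len(weights, nrow(points))
  stopifnot(all(is.finite(w)), all(w >= 0))
  px <- points$x / 1000
  py <- points$y / 1000
  if (is.null(bandwidth_km)) bandwidth_km <- silverman_bw(px, py)
  stopifnot(bandwidth_km > 0)
  h <- bandwidth_km
  if (is.null(grid)) {
    pad <- 4 * h * 1000
    grid <- list(nx = 96, ny = 96,
                 xmin = min(points$x) - pad, xmax = max(points$x) + pad,
                 ymin = min(points$y) - pad, ymax = max(points$y) + pad)
  }
  gx <- seq(grid$xmin, grid$xmax, length.out = grid$nx + 1)
  gy <- seq(grid$ymin, grid$ymax, length.out = grid$ny + 1)
  cx <- (gx[-1] + gx[-length(gx)]) / 2 / 1000   # cell centres, km
  cy <- (gy[-1] + gy[-length(gy)]) / 2 / 1000
  # separable Gaussian: z = Gx diag(w) Gy' / (2 pi h^2)
  Gx <- exp(-outer(cx, px, "-")^2 / (2 * h^2))
  Gy <- exp(-outer(cy, py, "-")^2 / (2 * h^2))
  z <- (Gx %*% (w * t(Gy))) / (2 * pi * h^2)
  structure(list(x = cx * 1000, y = cy * 1000, z = z,
                 bandwidth_km = h, total_weight = sum(w),
                 cell_area_km2 = diff(cx[1:2]) * diff(cy[1:2])),
            class = "density_grid")
}

# Silverman's rule of thumb, averaged over the two axes (km)
silverman_bw <- function(px, py) {
  n <- length(px)
  s <- mean(c(stats::sd(px), stats::sd(py)), na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(1)
  1.06 * s * n^(-1 / 5)
}

#' @export
print.density_grid <- function(x, ...) {
  mass <- sum(x$z) * x$cell_area_km2
  cat("Density grid ", length(x$x), " x ", length(x$y),
      ", bandwidth ", signif(x$bandwidth_km, 3), " km\n",
      "  grid mass ", signif(mass, 5), " of total weight ",
      signif(x$total_weight, 5), "\n", sep = "")
  invisible(x)
}

#' Per-district descriptive summary of facilities
#'
#' Tabulates institutions, beds, facility-scale statistics and (when a
#' population is supplied) beds per 1,000 older adults, per district.
#' Accepts either a raw facility registry (one row per institution) or an
#' already-aggregated table with columns `district_id`, `beds`,
#' `institutions` — e.g. a published district table — in which case the
#' per-facility median is unavailable and mean beds is `beds /
#' institutions`.
#'
#' @param facilities A [facilities()] registry, or an aggregated district
#'   table (`district_id`, `beds`, `institutions`).
#' @param cells Optional demand cells; district older population is the
#'   within-district sum.
#' @param district_pop Optional data frame `district_id`, `older_pop`
#'   (used when `cells` is absent).
#' @return Data frame with one row per district: `district_id`,
#'   `n_institutions`, `n_beds`, `share_institutions_pct`, `mean_beds`,
#'   `median_beds`, and, when population is known, `older_pop` and
#'   `beds_per_1000` (`NA` where older_pop is zero).
#' @examples
#' district_summary(table1_fixture())
#' @export
district_summary <- function(facilities, cells = NULL, district_pop = NULL) {
  if (all(c("district_id", "beds", "institutions") %in% names(facilities)) &&
      !"facility_id" %in% names(facilities)) {
    out <- data.frame(district_id = as.character(facilities$district_id),
                      n_institutions = facilities$institutions,
                      n_beds = facilities$beds)
    out$mean_beds <- out$n_beds / out$n_institutions
    out$median_beds <- NA_real_
  } else {
    sp <- split(facilities$beds, facilities$district_id)
    out <- data.frame(district_id = names(sp),
                      n_institutions = lengths(sp),
                      n_beds = vapply(sp, sum, 0),
                      mean_beds = vapply(sp, mean, 0),
                      median_beds = vapply(sp, stats::median, 0),
                      row.names = NULL)
  }
  out$share_institutions_pct <-
    100 * out$n_institutions / sum(out$n_institutions)
  pop <- NULL
  if (!is.null(cells)) {
    sp <- split(cells$older_pop, cells$district_id)
    pop <- data.frame(district_id = names(sp),
                      older_pop = vapply(sp, sum, 0), row.names = NULL)
  } else if (!is.null(district_pop)) {
    pop <- data.frame(district_id = as.character(district_pop$district_id),
                      older_pop = district_pop$older_pop)
  }
  if (!is.null(pop)) {
    out <- merge(out, pop, by = "district_id", all.x = TRUE)
    out$beds_per_1000 <- ifelse(!is.na(out$older_pop) & out$older_pop > 0,
                                1000 * out$n_beds / out$older_pop, NA_real_)
  }
  out[order(-out$n_institutions), , drop = FALSE]
}
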