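#' Lorenz curve of bed supply against older-population demand
#'
#' Units (typically administrative districts) are sorted ascending by
#' per-capita supply (beds per older adult, ties broken by `unit_id`,
#' zero-demand units first), then cumulative demand and supply shares are
#' accumulated from the origin. Plotted as cumulative supply share
#' against cumulative demand share, the curve lies on the diagonal for a
#' perfectly proportional allocation and sags below it as supply
#' concentrates.
#'
#' @param units Data frame with columns `unit_id`, `older_pop` (demand)
#'   and `beds` (supply); all values nonnegative, totals positive.
#' @return Object of class `lorenz_result`: list with `unit_ids` (sorted),
#'   `cum_pop` and `cum_supply` (length `n + 1`, from 0 to 1), `n_units`.
#' @examples
#' lorenz_curve(data.frame(unit_id = c("a", "b"),
#'                         older_pop = c(1, 1), beds = c(0, 1)))
#' @export
lorenz_curve <- function(units) {
  need <- c("unit_id", "older_pop", "beds")
  miss <- setdiff(need, names(units))
  if (length(miss)) {
    stop("units table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(units) < 1) stop("need at least one unit", call. = FALSE)
  if (any(units$older_pop < 0) || any(units$beds < 0)) {
    stop("demand and supply must be nonnegative", call. = FALSE)
  }
  tot_p <- sum(units$older_pop)
  tot_s <- sum(units$beds)
  if (tot_p <= 0) stop("total demand must be positive", call. = FALSE)
  if (tot_s <= 0) stop("total supply must be positive", call. = FALSE)
  # per-capita supply; zero-demand units sort first (zero-width segments)
  key <- ifelse(units$older_pop == 0, -Inf, units$beds / units$older_pop)
  ord <- order(key, as.character(units$unit_id))
  u <- units[ord, ]
  structure(list(unit_ids = as.character(u$unit_id),
                 cum_pop = c(0, cumsum(u$older_pop) / tot_p),
                 cum_supply = c(0, cumsum(u$beds) / tot_s),
                 n_units = nrow(u)),
            class = "lorenz_result")
}

#' Gini coefficient from a Lorenz curve
#'
#' Trapezoidal form over the grouped Lorenz polyline:
#' `G = 1 - sum_k (P_k - P_{k-1}) * (T_k + T_{k-1})`, i.e. one minus twice
#' the area under the curve. 0 means supply exactly proportional to
#' demand; 1 means total concentration.
#'
#' @param x A `lorenz_result` (see [lorenz_curve()]) or a units data
#'   frame accepted by [lorenz_curve()].
#' @return `G` in `[0, 1]`.
#' @examples
#' gini(data.frame(unit_id = c("a", "b"), older_pop = c(1, 1),
#'                 beds = c(0, 1)))  # 0.5
#' @export
gini <- function(x) {
  if (!inherits(x, "lorenz_result")) x <- lorenz_curve(x)
  P <- x$cum_pop
  T_ <- x$cum_supply
  g <- 1 - sum(diff(P) * (T_[-1] + T_[-length(T_)]))
  # guard floating-point dust at the ends of [0, 1]
  min(max(g, 0), 1)
}

#' Equity band for a Gini coefficient
#'
#' Conventional bands: below 0.2 "absolute average" (equitable), 0.2-0.3
#' "relatively average", 0.3-0.4 "relatively reasonable", 0.4-0.5 "large
#' gap", 0.5 and above "wide gap". Edges are half-open on the right.
#'
#' @param G Gini coefficient(s) in `[0, 1]`.
#' @return Character vector of band labels.
#' @examples
#' classify_gini(c(0.19, 0.5))
#' @export
classify_gini <- function(G) {
  if (any(!is.finite(G)) || any(G < 0) || any(G > 1)) {
    stop("Gini coefficient must lie in [0, 1]", call. = FALSE)
  }
  cut(G, breaks = c(-Inf, 0.2, 0.3, 0.4, 0.5, Inf), right = FALSE,
      labels = c("absolute-average", "relatively-average",
                 "relatively-reasonable", "large-gap", "wide-gap")) |>
    as.character()
}

#' One-call equity summary
#'
#' Lorenz curve, Gini coefficient and equity band for a units table.
#'
#' @inheritParams lorenz_curve
#' @return A `lorenz_result` with `gini` and `band` fields filled in.
#' @export
equity_summary <- function(units) {
  lz <- lorenz_curve(units)
  lz$gini <- gini(lz)
  lz$band <- classify_gini(lz$gini)
  lz
}

#' @export
print.lorenz_result <- function(x, ...) {
  cat("Lorenz curve over ", x$n_units, " units\n", sep = "")
  if (!is.null(x$gini)) {
    cat("  Gini G = ", format(round(x$gini, 4)), " (", x$band, ")\n", sep = "")
  }
  inner <- seq_len(min(5, x$n_units)) + 1
  cat("  first points (cum_pop, cum_supply): ",
      paste(sprintf("(%.3f, %.3f)", x$cum_pop[inner], x$cum_supply[inner]),
            collapse = " "), "\n", sep = "")
  invisible(x)
}
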