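#' Model parameters for the potential accessibility models
#'
#' Bundles every tunable of the accessibility models into one validated
#' object. Defaults reproduce the improved-model configuration for urban
#' aged care: friction coefficient `beta = 1`, a two-level service radius
#' keyed on a 500-bed threshold (1 h below, 2 h at or above), quality-tier
#' travel limits of 15 min for facilities below Level 3 (including
#' ungraded ones), 0.5 h for Level 3, 1 h for Level 4 and 2 h for Level 5,
#' and results scaled to beds per 1,000 older adults.
#'
#' @param beta Travel friction exponent. Values between 1 and 2 are usual
#'   for care and health facilities; a warning is issued outside that range.
#' @param bed_threshold Bed count at which the large service radius applies.
#'   Facilities with exactly `bed_threshold` beds take the large radius.
#' @param d_small,d_large Service radii in hours for facilities below /
#'   at-or-above the bed threshold. Must satisfy `d_small <= d_large`.
#' @param tier_limits Named numeric vector of travel limits (hours) per
#'   quality tier; names must cover `ungraded`, `level_2`, `level_3`,
#'   `level_4`, `level_5`.
#' @param impedance_floor Minimum travel time in hours; all impedances are
#'   floored here so divisions by `D^beta` are defined for co-located
#'   demand and supply. Default one minute.
#' @param scale_per Population unit for reporting the improved model
#'   (default 1000: "beds per 1,000 older adults").
#'
#' @return An object of class `care_params` (a named list).
#' @examples
#' p <- model_params()
#' p$tier_limits[["level_5"]]
#' @export
model_params <- function(beta = 1,
                         bed_threshold = 500L,
                         d_small = 1,
                         d_large = 2,
                         tier_limits = c(ungraded = 0.25, level_2 = 0.25,
                                         level_3 = 0.5, level_4 = 1,
                                         level_5 = 2),
                         impedance_floor = 1 / 60,
                         scale_per = 1000) {
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta), beta > 0)
  if (beta < 1 || beta > 2) {
    warning("beta = ", beta, " is outside the usual [1, 2] range", call. = FALSE)
  }
  stopifnot(length(bed_threshold) == 1L, bed_threshold >= 1)
  if (!is.numeric(d_small) || !is.numeric(d_large) || d_small <= 0 ||
      d_large <= 0) {
    stop("service radii d_small and d_large must be positive hours",
         call. = FALSE)
  }
  if (d_small > d_large) stop("d_small must not exceed d_large", call. = FALSE)
  missing_tiers <- setdiff(TIER_LEVELS, names(tier_limits))
  if (length(missing_tiers)) {
    stop("tier_limits missing entries for: ",
         paste(missing_tiers, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(tier_limits)) || any(tier_limits <= 0)) {
    stop("all tier travel limits must be positive hours", call. = FALSE)
  }
  stopifnot(is.numeric(impedance_floor), impedance_floor > 0,
            is.numeric(scale_per), scale_per > 0)
  structure(list(beta = beta,
                 bed_threshold = as.integer(bed_threshold),
                 d_small = d_small,
                 d_large = d_large,
                 tier_limits = tier_limits[TIER_LEVELS],
                 impedance_floor = impedance_floor,
                 scale_per = scale_per),
            class = "care_params")
}

#' @export
print.care_params <- function(x, ...) {
  cat("Potential-model parameters\n")
  cat("  beta (friction):        ", x$beta, "\n")
  cat("  service radius (h):     ", x$d_small, "below /", x$d_large,
      "at or above", x$bed_threshold, "beds\n")
  cat("  tier limits (h):        ",
      paste(names(x$tier_limits), x$tier_limits, sep = "=", collapse = ", "),
      "\n")
  cat("  impedance floor (h):    ", format(x$impedance_floor, digits = 4), "\n")
  cat("  reporting scale:         beds per", x$scale_per, "older adults\n")
  invisible(x)
}
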