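#' Demand cells: gridded counts of older adults
#'
#' Validates and tags a data frame of demand grid cells. Each row is one
#' cell of a demand surface (typically 500 m x 500 m) carrying the count
#' of residents aged 60+ at its centroid.
#'
#' @param df Data frame with columns `cell_id`, `x`, `y`, `older_pop`,
#'   `district_id`.
#' @param coords Coordinate kind: `"planar"` (metres, projected CRS) or
#'   `"geographic"` (lon/lat degrees). Distance computations check this tag.
#' @return `df` with class `demand_cells` and a `coords` attribute.
#' @examples
#' demand_cells(data.frame(cell_id = "c1", x = 0, y = 0,
#'                         older_pop = 100, district_id = "D1"))
#' @export
demand_cells <- function(df, coords = c("planar", "geographic")) {
  coords <- match.arg(coords)
  need <- c("cell_id", "x", "y", "older_pop", "district_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("demand table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[need]
  df$cell_id <- as.character(df$cell_id)
  df$district_id <- as.character(df$district_id)
  bad <- dataset_violations(cells = df)
  if (nrow(bad)) stop(format_violations(bad), call. = FALSE)
  structure(df, class = c("demand_cells", "data.frame"), coords = coords)
}

#' Facility registry: aged-care institutions
#'
#' Validates and tags a data frame of facilities. Each row is one
#' institution with its location, bed capacity, national quality tier and
#' administrative district.
#'
#' @param df Data frame with columns `facility_id`, `x`, `y`, `beds`,
#'   `tier`, `district_id`. `tier` must be one of `ungraded`, `level_2`,
#'   `level_3`, `level_4`, `level_5`.
#' @inheritParams demand_cells
#' @return `df` with class `facilities` and a `coords` attribute.
#' @examples
#' facilities(data.frame(facility_id = "f1", x = 0, y = 0, beds = 120,
#'                       tier = "level_3", district_id = "D1"))
#' @export
facilities <- function(df, coords = c("planar", "geographic")) {
  coords <- match.arg(coords)
  need <- c("facility_id", "x", "y", "beds", "tier", "district_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("facility table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[need]
  df$facility_id <- as.character(df$facility_id)
  df$tier <- as.character(df$tier)
  df$district_id <- as.character(df$district_id)
  bad <- dataset_violations(facilities = df)
  if (nrow(bad)) stop(format_violations(bad), call. = FALSE)
  structure(df, class = c("facilities", "data.frame"), coords = coords)
}

coord_kind <- function(x) attr(x, "coords") %||% "planar"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a demand/facility/impedance dataset
#'
#' Reports (rather than raises) every invariant violation found in a
#' dataset: duplicate identifiers, negative populations, non-positive bed
#' counts, unknown quality tiers, non-finite coordinates, impedance
#' dimension mismatches and non-positive travel times. An empty report
#' means every downstream operation will accept the dataset.
#'
#' @param cells Demand cell table (see [demand_cells()]), or a bare data
#'   frame with the same columns.
#' @param facilities Facility table (see [facilities()]), or a bare data
#'   frame with the same columns.
#' @param impedance Optional impedance matrix (cells x facilities, hours).
#' @return Data frame with columns `scope`, `id`, `message`; zero rows iff
#'   all invariants hold. Side-effect free and idempotent.
#' @examples
#' cs <- data.frame(cell_id = c("a", "b"), x = 0:1, y = 0,
#'                  older_pop = c(10, 20), district_id = "D1")
#' fs <- data.frame(facility_id = "f", x = 0, y = 0, beds = 10,
#'                  tier = "level_3", district_id = "D1")
#' validate_inputs(cs, fs)   # zero rows
#' @export
validate_inputs <- function(cells = NULL, facilities = NULL,
                            impedance = NULL) {
  dataset_violations(cells, facilities, impedance)
}

dataset_violations <- function(cells = NULL, facilities = NULL,
                               impedance = NULL) {
  out <- list()
  add <- function(scope, id, message) {
    out[[length(out) + 1L]] <<- data.frame(scope = scope, id = id,
                                           message = message)
  }
  if (!is.null(cells)) {
    dup <- unique(cells$cell_id[duplicated(cells$cell_id)])
    for (d in dup) add("cell", d, "duplicate cell_id")
    neg <- cells$cell_id[!is.finite(cells$older_pop) | cells$older_pop < 0]
    for (d in neg) add("cell", d, "older_pop must be a nonnegative number")
    badxy <- cells$cell_id[!is.finite(cells$x) | !is.finite(cells$y)]
    for (d in badxy) add("cell", d, "non-finite coordinates")
  }
  if (!is.null(facilities)) {
    dup <- unique(facilities$facility_id[duplicated(facilities$facility_id)])
    for (d in dup) add("facility", d, "duplicate facility_id")
    bad <- facilities$facility_id[!is.finite(facilities$beds) |
                                    facilities$beds < 1]
    for (d in bad) add("facility", d, "beds must be >= 1")
    badt <- facilities$facility_id[!facilities$tier %in% TIER_LEVELS]
    for (d in badt) {
      add("facility", d, paste0("unknown tier (allowed: ",
                                paste(TIER_LEVELS, collapse = ", "), ")"))
    }
    badxy <- facilities$facility_id[!is.finite(facilities$x) |
                                      !is.finite(facilities$y)]
    for (d in badxy) add("facility", d, "non-finite coordinates")
  }
  if (!is.null(impedance)) {
    if (!is.null(cells)) {
      m1 <- setdiff(cells$cell_id, rownames(impedance))
      for (d in m1) add("impedance", d, "cell missing from impedance rows")
      m2 <- setdiff(rownames(impedance), cells$cell_id)
      for (d in m2) add("impedance", d, "impedance row has no matching cell")
    }
    if (!is.null(facilities)) {
      m3 <- setdiff(facilities$facility_id, colnames(impedance))
      for (d in m3) add("impedance", d, "facility missing from impedance columns")
      m4 <- setdiff(colnames(impedance), facilities$facility_id)
      for (d in m4) {
        add("impedance", d, "impedance column has no matching facility")
      }
    }
    if (any(!is.finite(impedance)) || any(impedance <= 0)) {
      add("impedance", "<entries>",
          "all travel times must be finite and strictly positive")
    }
  }
  if (!length(out)) {
    return(data.frame(scope = character(), id = character(),
                      message = character()))
  }
  do.call(rbind, out)
}

format_violations <- function(v) {
  paste0("invalid dataset:\n",
         paste0("  [", v$scope, " ", v$id, "] ", v$message, collapse = "\n"))
}

#' @export
print.demand_cells <- function(x, ...) {
  cat("Demand surface: ", nrow(x), " cells, ",
      length(unique(x$district_id)), " district(s), total older_pop ",
      format(sum(x$older_pop), big.mark = ","), " (", coord_kind(x),
      " coordinates)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' @export
print.facilities <- function(x, ...) {
  cat("Facility registry: ", nrow(x), " institutions, ",
      format(sum(x$beds), big.mark = ","), " beds (", coord_kind(x),
      " coordinates)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}
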