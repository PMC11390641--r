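#' Read a facility registry from CSV or GeoJSON
#'
#' CSV needs header `facility_id,x,y,beds,tier,district_id`; GeoJSON
#' needs Point features with those fields (minus x/y) as properties.
#' Schema violations are reported with the offending column / feature.
#'
#' @param path File path; format chosen by extension (`.csv` vs
#'   `.geojson`/`.json`).
#' @param coords Coordinate kind of the file, `"planar"` or
#'   `"geographic"`. GeoJSON is geographic by convention.
#' @return A [facilities()] table.
#' @export
read_facilities <- function(path, coords = NULL) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    feats <- read_geojson_points(path,
                                 c("facility_id", "beds", "tier",
                                   "district_id"))
    facilities(feats, coords = coords %||% "geographic")
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    check_columns(df, c("facility_id", "x", "y", "beds", "tier",
                        "district_id"), path)
    facilities(df, coords = coords %||% "planar")
  }
}

#' Read a demand surface from CSV or an ESRI ASCII grid
#'
#' CSV needs header `cell_id,x,y,older_pop,district_id`. An ASCII grid
#' (`.asc`) of older-population counts is converted to cell centroids
#' with `cell_id = "row_col"` (row 1 at the top); NoData cells are
#' dropped, zero-population cells kept. District membership comes from
#' `district_map` (data frame `cell_id,district_id`), from polygon
#' features in `districts_geojson` (property `district_id`), or defaults
#' to a single district `"all"`.
#'
#' @param path File path (`.csv` or `.asc`).
#' @param coords Coordinate kind (CSV only; grids are planar metres).
#' @param district_map Optional `cell_id,district_id` data frame.
#' @param districts_geojson Optional path to a polygon GeoJSON.
#' @return A [demand_cells()] table; grid-derived tables carry a `grid`
#'   attribute (the ASCII-grid header) so surfaces can be written back on
#'   the same grid.
#' @export
read_demand <- function(path, coords = NULL, district_map = NULL,
                        districts_geojson = NULL) {
  if (grepl("\\.asc$", path, ignore.case = TRUE)) {
    g <- read_ascii_grid(path)
    idx <- which(!is.na(g$z), arr.ind = TRUE)   # row 1 = top row
    x <- g$xll + (idx[, 2] - 0.5) * g$cellsize
    y <- g$yll + (g$nrows - idx[, 1] + 0.5) * g$cellsize
    df <- data.frame(cell_id = paste0(idx[, 1], "_", idx[, 2]),
                     x = x, y = y, older_pop = g$z[idx],
                     district_id = "all")
    if (!is.null(district_map)) {
      i <- match(df$cell_id, as.character(district_map$cell_id))
      if (anyNA(i)) {
        stop("district_map is missing cell(s), e.g. '",
             df$cell_id[which(is.na(i))[1]], "'", call. = FALSE)
      }
      df$district_id <- as.character(district_map$district_id)[i]
    } else if (!is.null(districts_geojson)) {
      polys <- read_geojson_polygons(districts_geojson)
      df$district_id <- assign_districts(df$x, df$y, polys)
    }
    out <- demand_cells(df, coords = "planar")
    attr(out, "grid") <- g[c("ncols", "nrows", "xll", "yll", "cellsize")]
    out
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    check_columns(df, c("cell_id", "x", "y", "older_pop", "district_id"),
                  path)
    demand_cells(df, coords = coords %||% "planar")
  }
}

check_columns <- function(df, need, path) {
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("'", path, "' is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write demand cells / facilities to CSV or GeoJSON
#'
#' Round-trips with the corresponding reader: `read(write(x))` equals
#' `x` field-for-field.
#'
#' @param x A [demand_cells()] or [facilities()] table.
#' @param path Output path; `.geojson` writes Point features, anything
#'   else CSV.
#' @return `path`, invisibly.
#' @export
write_points <- function(x, path) {
  df <- as.data.frame(x)
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    props <- setdiff(names(df), c("x", "y"))
    feats <- lapply(seq_len(nrow(df)), function(i) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(df$x[i], df$y[i])),
           properties = as.list(df[i, props, drop = FALSE]))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

read_geojson_points <- function(path, prop_names) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("'", path, "' is not a FeatureCollection",
                                 call. = FALSE)
  rows <- lapply(seq_along(gj$features), function(i) {
    f <- gj$features[[i]]
    if (!identical(f$geometry$type, "Point")) {
      stop("feature ", i, " in '", path, "' is not a Point", call. = FALSE)
    }
    miss <- setdiff(prop_names, names(f$properties))
    if (length(miss)) {
      stop("feature ", i, " in '", path, "' is missing propert",
           if (length(miss) == 1) "y: " else "ies: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    c(list(x = f$geometry$coordinates[[1]], y = f$geometry$coordinates[[2]]),
      f$properties[prop_names])
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}

# polygon features with a district_id property; outer ring + holes,
# even-odd rule
read_geojson_polygons <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(gj$features, function(f) {
    ty <- f$geometry$type
    rings <- switch(ty,
      Polygon = f$geometry$coordinates,
      MultiPolygon = unlist(f$geometry$coordinates, recursive = FALSE),
      stop("unsupported geometry type '", ty, "' in district file",
           call. = FALSE))
    rings <- lapply(rings, function(r) {
      m <- do.call(rbind, lapply(r, function(p) c(p[[1]], p[[2]])))
      m
    })
    list(district_id = as.character(f$properties$district_id), rings = rings)
  })
}

# ray casting, even-odd over all rings
point_in_rings <- function(px, py, rings) {
  inside <- FALSE
  for (r in rings) {
    n <- nrow(r)
    j <- n
    for (i in seq_len(n)) {
      if (((r[i, 2] > py) != (r[j, 2] > py)) &&
          (px < (r[j, 1] - r[i, 1]) * (py - r[i, 2]) /
             (r[j, 2] - r[i, 2]) + r[i, 1])) {
        inside <- !inside
      }
      j <- i
    }
  }
  inside
}

assign_districts <- function(x, y, polys) {
  out <- rep(NA_character_, length(x))
  for (p in polys) {
    hit <- vapply(seq_along(x), function(i) {
      is.na(out[i]) && point_in_rings(x[i], y[i], p$rings)
    }, TRUE)
    out[hit] <- p$district_id
  }
  out[is.na(out)] <- "unassigned"
  out
}

#' Read / write an ESRI ASCII grid
#'
#' Minimal ASCII-grid (`.asc`) support: header
#' `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` followed by
#' rows top-down. The geotransform is preserved exactly on round-trip.
#'
#' @param path File path.
#' @return For the reader: list `ncols`, `nrows`, `xll`, `yll`,
#'   `cellsize`, `nodata`, `z` (matrix, row 1 = top, `NA` for NoData).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("'", path, "' grid header is missing: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  nodata <- hdr$nodata_value %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("'", path, "' has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows, call. = FALSE)
  }
  z <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  z[z == nodata] <- NA
  list(ncols = hdr$ncols, nrows = hdr$nrows, xll = hdr$xllcorner,
       yll = hdr$yllcorner, cellsize = hdr$cellsize, nodata = nodata, z = z)
}

#' @rdname read_ascii_grid
#' @param grid A list as returned by `read_ascii_grid()` (field `z` plus
#'   the header fields).
#' @export
write_ascii_grid <- function(grid, path) {
  z <- grid$z
  z[is.na(z)] <- grid$nodata %||% -9999
  hdr <- c(paste("ncols", grid$ncols), paste("nrows", grid$nrows),
           paste("xllcorner", format(grid$xll, scientific = FALSE)),
           paste("yllcorner", format(grid$yll, scientific = FALSE)),
           paste("cellsize", format(grid$cellsize, scientific = FALSE)),
           paste("NODATA_value", grid$nodata %||% -9999))
  body <- apply(z, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write an accessibility surface
#'
#' CSV (`cell_id,accessibility`) always works; `format = "asc"` writes
#' the surface back onto the source grid and needs cells read from an
#' ASCII grid (or an explicit `grid` header list).
#'
#' @param surface An `accessibility_surface`.
#' @param path Output path.
#' @param format `"csv"` or `"asc"`.
#' @param cells The demand cells the surface was computed on (for
#'   `"asc"`, must carry the `grid` attribute from [read_demand()]).
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path, format = c("csv", "asc"),
                          cells = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(surface), path, row.names = FALSE,
                     quote = FALSE)
    return(invisible(path))
  }
  g <- attr(cells, "grid")
  if (is.null(g)) {
    stop("'asc' output needs cells carrying a grid attribute ",
         "(demand read from an ASCII grid)", call. = FALSE)
  }
  z <- matrix(NA_real_, g$nrows, g$ncols)
  rc <- do.call(rbind, strsplit(cells$cell_id, "_"))
  i <- match(cells$cell_id, surface$cell_id)
  z[cbind(as.integer(rc[, 1]), as.integer(rc[, 2]))] <-
    surface$accessibility[i]
  write_ascii_grid(c(g, list(z = z, nodata = -9999)), path)
}

#' Write a machine-readable run report
#'
#' Every pipeline run can record its full configuration: package
#' version, resolved model parameters, validation violations, unused
#' facilities and any extra metadata — the reproducibility contract for
#' a run.
#'
#' @param path Output JSON path.
#' @param params [model_params()] used.
#' @param violations Validation report (see [validate_inputs()]).
#' @param unused_facilities Facility ids with no reachable demand.
#' @param seed Seed used, if any.
#' @param extra Named list of additional fields.
#' @return The report list, invisibly.
#' @export
write_report <- function(path, params = model_params(), violations = NULL,
                         unused_facilities = character(), seed = NULL,
                         extra = list()) {
  p <- unclass(params)
  p$tier_limits <- as.list(p$tier_limits)   # keep names in JSON
  rep <- c(list(
    package = "careaccess",
    version = as.character(utils::packageVersion("careaccess")),
    seed = seed,
    params = p,
    n_violations = if (is.null(violations)) 0L else nrow(violations),
    violations = violations,
    unused_facilities = unused_facilities), extra)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(rep)
}
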