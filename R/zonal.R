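#' Field boundary polygon
#'
#' @param field_id Field identifier.
#' @param crop Crop label.
#' @param coords Two-column matrix of polygon vertices (x, y) in scene
#'   coordinates (meters), >= 3 vertices, not closed (first vertex is not
#'   repeated).
#' @return An object of class `field_boundary`.
#' @export
field_boundary <- function(field_id, crop, coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L || nrow(coords) < 3L)
    stop("`coords` must be a matrix with >= 3 rows and 2 columns")
  if (anyNA(coords)) stop("`coords` must not contain NA")
  if (nrow(coords) > 3L &&
      isTRUE(all.equal(coords[1, ], coords[nrow(coords), ], check.attributes = FALSE)))
    coords <- coords[-nrow(coords), , drop = FALSE]
  structure(list(field_id = as.character(field_id), crop = as.character(crop),
                 coords = unname(coords)),
            class = "field_boundary")
}

#' Point-in-polygon test (even-odd rule)
#'
#' Vectorized ray-casting test used for pixel-center zonal membership.
#' Points exactly on an edge follow the half-open convention implied by the
#' strict `>` / `<` comparisons: left/bottom edges are inside, right/top
#' edges outside, so abutting polygons never double-count a pixel center.
#'
#' @param x,y Point coordinates (vectors of equal length).
#' @param coords Polygon vertex matrix as in [field_boundary()].
#' @return Logical vector, `TRUE` where the point is inside.
#' @export
point_in_polygon <- function(x, y, coords) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- coords[i, 1]; yi <- coords[i, 2]
    xj <- coords[j, 1]; yj <- coords[j, 2]
    straddles <- (yi > y) != (yj > y)
    xint <- (xj - xi) * (y - yi) / (yj - yi) + xi
    inside <- xor(inside, straddles & (x < xint))
    j <- i
  }
  inside
}

#' Per-field daily zonal statistics from a raster stack
#'
#' For every field polygon, date and variable, computes the mean over the
#' pixels whose centers fall inside the polygon, excluding nodata (`NA`)
#' pixels from both the numerator and the count. Records with zero valid
#' pixels are emitted with `n_pixels = 0` and `mean = NA` so that downstream
#' filtering (see [drop_empty()]) is explicit rather than silent; a boundary
#' containing no pixel center at all additionally raises a warning.
#'
#' @param scene A `synthetic_scene`, or any list with elements `grid`
#'   ([grid_spec()]) and `layers` (per variable, a list with `dates` and a
#'   pixels x days `values` matrix in the [pixel_centers()] ordering).
#' @param boundaries List of [field_boundary()] objects; defaults to the
#'   scene's own fields.
#' @param variables Optional character vector restricting which layers are
#'   summarized.
#' @return Data frame with columns `field_id`, `crop`, `date`, `variable`,
#'   `mean`, `n_pixels`.
#' @export
zonal_daily_stats <- function(scene, boundaries = NULL, variables = NULL) {
  grid <- scene$grid
  layers <- scene$layers
  stopifnot(inherits(grid, "grid_spec"), is.list(layers))
  if (is.null(boundaries)) boundaries <- scene$fields
  if (is.null(boundaries) || length(boundaries) == 0L)
    stop("no field boundaries supplied")
  if (inherits(boundaries, "field_boundary")) boundaries <- list(boundaries)
  if (!is.null(variables)) {
    missing_v <- setdiff(variables, names(layers))
    if (length(missing_v))
      stop("variables not in stack: ", paste(missing_v, collapse = ", "))
    layers <- layers[variables]
  }
  ctr <- pixel_centers(grid)
  out <- vector("list", length(boundaries) * length(layers))
  z <- 0L
  for (b in boundaries) {
    stopifnot(inherits(b, "field_boundary"))
    inside <- point_in_polygon(ctr$x, ctr$y, b$coords)
    if (!any(inside))
      warning(sprintf("field '%s' contains no pixel centers (outside grid?)",
                      b$field_id))
    for (v in names(layers)) {
      l <- layers[[v]]
      vals <- l$values[inside, , drop = FALSE]
      n <- colSums(!is.na(vals))
      m <- suppressWarnings(colMeans(vals, na.rm = TRUE))
      m[n == 0L] <- NA_real_
      z <- z + 1L
      out[[z]] <- data.frame(field_id = b$field_id, crop = b$crop,
                             date = l$dates, variable = v,
                             mean = unname(m), n_pixels = unname(n))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tabulate crop-class pixel counts and areas
#'
#' Counts pixels per crop class in a categorical class map and converts
#' counts to hectares, optionally restricted to a region polygon first (the
#' class map is clipped by pixel-center membership before counting, e.g. a
#' chia-viability region or a hydrologic unit).
#'
#' @param class_map Character matrix of per-pixel crop labels (`NA` =
#'   unclassified background).
#' @param pixel_area_ha Area of one pixel in hectares (> 0).
#' @param grid Optional [grid_spec()]; required when `region` is given.
#' @param region Optional region polygon: a [field_boundary()] or a vertex
#'   matrix.
#' @return Data frame with columns `crop`, `pixel_count`, `area_ha`, sorted
#'   by crop; zero rows for an all-`NA` or empty map.
#' @export
tabulate_class_areas <- function(class_map, pixel_area_ha, grid = NULL,
                                 region = NULL) {
  if (!is.matrix(class_map)) stop("`class_map` must be a matrix")
  if (!is.numeric(pixel_area_ha) || pixel_area_ha <= 0)
    stop("`pixel_area_ha` must be > 0")
  labels <- as.vector(class_map)
  if (!is.null(region)) {
    if (is.null(grid)) stop("`grid` is required when `region` is given")
    stopifnot(inherits(grid, "grid_spec"),
              grid$nrow == nrow(class_map), grid$ncol == ncol(class_map))
    coords <- if (inherits(region, "field_boundary")) region$coords else as.matrix(region)
    ctr <- pixel_centers(grid)
    labels <- labels[point_in_polygon(ctr$x, ctr$y, coords)]
  }
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0L)
    return(data.frame(crop = character(), pixel_count = integer(),
                      area_ha = numeric()))
  tab <- table(labels)
  data.frame(crop = names(tab),
             pixel_count = as.integer(tab),
             area_ha = as.integer(tab) * pixel_area_ha,
             row.names = NULL)
}

#' Drop empty or invalid zonal records
#'
#' Removes records with zero valid pixels or a non-finite mean (the
#' "no data" files of a raw satellite extraction).
#'
#' @param records Data frame as returned by [zonal_daily_stats()].
#' @param verbose Report the number of removed records (default `TRUE`).
#' @return The filtered data frame.
#' @export
drop_empty <- function(records, verbose = TRUE) {
  stopifnot(is.data.frame(records),
            all(c("mean", "n_pixels") %in% names(records)))
  keep <- records$n_pixels >= 1L & is.finite(records$mean)
  if (all(keep)) return(records)
  if (verbose) message(sum(!keep), " empty record(s) removed")
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
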