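#' Regular raster grid specification
#'
#' Defines the pixel grid shared by all layers of a scene. The default pixel
#' side of 70 m matches the resolution of current thermal ET products
#' (0.49 ha per pixel). Scene coordinates are meters, with the origin at the
#' lower-left corner; pixel (row r, col c) has its center at
#' `((c - 0.5) * pixel_m, (r - 0.5) * pixel_m)`.
#'
#' @param nrow,ncol Grid dimensions in pixels (positive integers).
#' @param pixel_m Pixel side length in meters.
#' @return An object of class `grid_spec` with an added `pixel_area_ha`
#'   field.
#' @export
grid_spec <- function(nrow, ncol, pixel_m = 70) {
  nrow <- as.integer(nrow); ncol <- as.integer(ncol)
  if (is.na(nrow) || is.na(ncol) || nrow < 1L || ncol < 1L)
    stop("grid dimensions must be positive integers")
  if (pixel_m <= 0) stop("`pixel_m` must be > 0")
  structure(list(nrow = nrow, ncol = ncol, pixel_m = pixel_m,
                 pixel_area_ha = pixel_m^2 / 1e4),
            class = "grid_spec")
}

#' Pixel-center coordinates of a grid
#'
#' Pixels are ordered column-major (matching `matrix(values, nrow, ncol)`),
#' i.e. pixel index `i` maps to row `((i - 1) %% nrow) + 1` and column
#' `((i - 1) %/% nrow) + 1`.
#'
#' @param grid A [grid_spec()].
#' @return Data frame with columns `x`, `y` (meters), `row`, `col`.
#' @export
pixel_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  row <- rep(seq_len(grid$nrow), times = grid$ncol)
  col <- rep(seq_len(grid$ncol), each = grid$nrow)
  data.frame(x = (col - 0.5) * grid$pixel_m,
             y = (row - 0.5) * grid$pixel_m,
             row = row, col = col)
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so simulations that embed seeded generators
# remain reproducible end to end.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic satellite scene for one site-season
#'
#' Builds daily raster layers over a pixel grid for a set of crops, each
#' occupying one rectangular field, with known ground-truth flux curves.
#' Per pixel and day, ET is the crop's curve value plus independent Gaussian
#' noise truncated at zero; canopy fraction, WUE and reflectances receive
#' proportionally scaled noise (so `pixel_noise_sd = 0` yields exact curve
#' values everywhere). GPP is generated as `wue_pixel * et_pixel` (with ET in
#' mm d^-1 = kg m^-2 d^-1) so that the GPP/ET quotient is consistent with
#' the WUE layer by construction. For each layer a seed-determined subset of
#' days is dropped entirely, emulating revisit gaps; the scene-wide drop
#' probability is the mean of the profiles' `missing_day_rate` (a missing
#' overpass affects every field at once).
#'
#' Fields are laid out as vertical strips with a one-pixel margin, and the
#' class map labels exactly the pixels inside each field polygon. Background
#' pixels carry a constant bare-soil ET (`background_et`), canopy 0.05 and
#' WUE 0.5.
#'
#' @param profiles A [crop_profile()] or list of them (one field each).
#' @param grid A [grid_spec()]. Must be large enough for one >= 1-pixel-wide
#'   strip per profile with margins (`ncol >= 3 * n_profiles`, `nrow >= 3`).
#' @param dates Either a `Date` vector of candidate days or `c(start, end)`
#'   to expand daily. Must cover every profile's season.
#' @param seed Integer seed; the same seed reproduces the scene bit for bit.
#' @param variables Which layers to simulate, a subset of
#'   `c("et", "canopy", "wue", "gpp", "red", "nir")`.
#' @param background_et Bare-soil ET outside fields, mm d^-1.
#' @return An object of class `synthetic_scene`: a list with `grid`,
#'   `fields` (list of [field_boundary()]), `class_map` (character matrix),
#'   `layers` (per variable: `dates` and a pixels x days `values` matrix),
#'   `temperature` (data frame `date`, `tair_c`), `dates`, and `truth`
#'   (profiles and seed).
#' @examples
#' chia <- crop_profile("chia", "2022-06-01", "2022-09-30",
#'                      pixel_noise_sd = 0, missing_day_rate = 0)
#' sc <- generate_site_season(chia, grid_spec(8, 8),
#'                            c("2022-06-01", "2022-09-30"), seed = 1)
#' sc
#' @export
generate_site_season <- function(profiles, grid, dates, seed,
                                 variables = c("et", "canopy", "wue",
                                               "gpp", "red", "nir"),
                                 background_et = 1.0) {
  if (inherits(profiles, "crop_profile")) profiles <- list(profiles)
  if (length(profiles) == 0L) stop("`profiles` must not be empty")
  ok <- vapply(profiles, inherits, logical(1), what = "crop_profile")
  if (!all(ok)) stop("all elements of `profiles` must be crop_profile objects")
  stopifnot(inherits(grid, "grid_spec"))
  if (missing(seed) || is.null(seed)) stop("`seed` is required")
  variables <- match.arg(variables, several.ok = TRUE)

  dates <- as.Date(dates)
  if (length(dates) == 2L && dates[1] < dates[2])
    dates <- seq(dates[1], dates[2], by = "day")
  dates <- sort(unique(dates))
  starts <- as.Date(vapply(profiles, function(p) as.character(p$season_start), ""))
  ends <- as.Date(vapply(profiles, function(p) as.character(p$season_end), ""))
  if (min(dates) > min(starts) || max(dates) < max(ends))
    stop("`dates` must cover every profile's season")

  k <- length(profiles)
  strip_w <- grid$ncol %/% k
  if (strip_w < 3L || grid$nrow < 3L)
    stop("grid too small: need ncol >= 3 * n_profiles and nrow >= 3")

  npix <- grid$nrow * grid$ncol
  nd <- length(dates)
  pm <- grid$pixel_m
  class_map <- matrix(NA_character_, grid$nrow, grid$ncol)
  fields <- vector("list", k)
  field_pix <- vector("list", k)
  for (j in seq_len(k)) {
    cmin <- (j - 1L) * strip_w + 2L
    cmax <- j * strip_w - 1L
    rmin <- 2L; rmax <- grid$nrow - 1L
    class_map[rmin:rmax, cmin:cmax] <- profiles[[j]]$name
    # polygon hugging the outer edge of the field's pixels, in meters
    coords <- cbind(x = c(cmin - 1L, cmax, cmax, cmin - 1L) * pm,
                    y = c(rmin - 1L, rmin - 1L, rmax, rmax) * pm)
    fields[[j]] <- field_boundary(paste0("F", j), profiles[[j]]$name, coords)
    idx <- outer(rmin:rmax, (cmin:cmax - 1L) * grid$nrow, `+`)
    field_pix[[j]] <- as.integer(idx)
  }

  miss_rate <- mean(vapply(profiles, `[[`, numeric(1), "missing_day_rate"))

  layers <- with_seed(seed, {
    # truth matrices, pixels x days
    et_true <- matrix(background_et, npix, nd)
    fc_true <- matrix(0.05, npix, nd)
    wue_true <- matrix(0.5, npix, nd)
    sd_px <- rep(0, npix)
    for (j in seq_len(k)) {
      p <- profiles[[j]]
      et_true[field_pix[[j]], ] <- rep(et_curve(p, dates), each = length(field_pix[[j]]))
      fc_true[field_pix[[j]], ] <- rep(canopy_curve(p, dates), each = length(field_pix[[j]]))
      wue_true[field_pix[[j]], ] <- p$wue_base
      sd_px[field_pix[[j]]] <- p$pixel_noise_sd
    }
    noisy <- function(truth, scale, lo = -Inf, hi = Inf) {
      sd_mat <- sd_px * scale
      x <- truth + matrix(stats::rnorm(npix * nd), npix, nd) * sd_mat
      pmin(pmax(x, lo), hi)
    }
    out <- list()
    if ("et" %in% variables) out$et <- noisy(et_true, 1, lo = 0)
    if ("canopy" %in% variables) out$canopy <- noisy(fc_true, 0.02, lo = 0, hi = 1)
    if ("wue" %in% variables) out$wue <- noisy(wue_true, 0.05, lo = 0)
    if ("gpp" %in% variables) {
      et_px <- if (!is.null(out$et)) out$et else et_true
      wue_px <- if (!is.null(out$wue)) out$wue else wue_true
      out$gpp <- wue_px * et_px
    }
    if ("red" %in% variables) out$red <- noisy(0.30 - 0.22 * fc_true, 0.01, lo = 0.01, hi = 0.99)
    if ("nir" %in% variables) out$nir <- noisy(0.20 + 0.40 * fc_true, 0.01, lo = 0.01, hi = 0.99)
    # seed-determined revisit gaps, independent per layer
    out <- lapply(out, function(vals) {
      keep <- stats::runif(nd) >= miss_rate
      if (!any(keep)) keep[1] <- TRUE
      list(dates = dates[keep], values = vals[, keep, drop = FALSE])
    })
    doy <- as.integer(format(dates, "%j"))
    out_t <- data.frame(
      date = dates,
      tair_c = 18 + 8 * sin(2 * pi * (doy - 110) / 365) + stats::rnorm(nd, 0, 1.5))
    list(layers = out, temperature = out_t)
  })

  structure(list(grid = grid, fields = fields, class_map = class_map,
                 layers = layers$layers, temperature = layers$temperature,
                 dates = dates,
                 truth = list(profiles = profiles, seed = seed)),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d pixels (%g m), %d fields, %d candidate days\n",
              x$grid$nrow, x$grid$ncol, x$grid$pixel_m,
              length(x$fields), length(x$dates)))
  for (v in names(x$layers))
    cat(sprintf("  layer %-6s %d days\n", v, length(x$layers[[v]]$dates)))
  crops <- vapply(x$fields, `[[`, character(1), "crop")
  cat("  crops:", paste(crops, collapse = ", "), "\n")
  invisible(x)
}

#' Flatten a scene's layers to a long data frame
#'
#' One row per pixel x day x variable, suitable for CSV export.
#'
#' @param x A `synthetic_scene`.
#' @param row.names,optional Ignored (S3 signature).
#' @param ... Ignored.
#' @return Data frame with columns `variable`, `date`, `pixel`, `value`.
#' @export
as.data.frame.synthetic_scene <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  out <- lapply(names(x$layers), function(v) {
    l <- x$layers[[v]]
    data.frame(variable = v,
               date = rep(l$dates, each = nrow(l$values)),
               pixel = rep(seq_len(nrow(l$values)), times = length(l$dates)),
               value = as.vector(l$values))
  })
  do.call(rbind, out)
}
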