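#' Spectral band roster
#'
#' Canonical band names for the five-band multispectral stacks handled by the
#' package (blue, green, red, red edge, near infrared), together with the
#' factory-supplied reflectance calibration coefficients of the camera panel.
#'
#' @return Named numeric vector of panel reflectances, one per band.
#' @export
panel_reflectances <- function() {
  c(blue = 0.542, green = 0.542, red = 0.539, rededge = 0.533, nir = 0.537)
}

sg_bands <- function() c("blue", "green", "red", "rededge", "nir")

#' Spectral index definitions
#'
#' The four vegetation indices used for stay-green scoring. Normalized
#' difference forms; OSAVI carries a soil-adjustment constant `L` in the
#' denominator and the conventional `(1 + L)` scaling in the numerator.
#'
#' * NDVI  = (NIR - R) / (NIR + R)
#' * GNDVI = (NIR - G) / (NIR + G)
#' * NDRE  = (NIR - RE) / (NIR + RE)
#' * OSAVI = (1 + L) (NIR - R) / (NIR + R + L)
#'
#' @param osavi_L Soil-adjustment constant for OSAVI (default 0.16).
#' @return Named list of index definitions; each has `name`, `bands`
#'   (band roles used) and `fun(bands)` mapping a named list/vector of band
#'   reflectances to the index value. Pixels with a zero denominator map to
#'   `NA`.
#' @export
si_definitions <- function(osavi_L = 0.16) {
  nd <- function(a, b) {
    den <- a + b
    out <- (a - b) / den
    out[den == 0] <- NA_real_
    out
  }
  list(
    ndvi = list(name = "ndvi", bands = c("nir", "red"),
                fun = function(b) nd(b$nir, b$red)),
    gndvi = list(name = "gndvi", bands = c("nir", "green"),
                 fun = function(b) nd(b$nir, b$green)),
    ndre = list(name = "ndre", bands = c("nir", "rededge"),
                fun = function(b) nd(b$nir, b$rededge)),
    osavi = list(name = "osavi", bands = c("nir", "red"),
                 fun = function(b) {
                   den <- b$nir + b$red + osavi_L
                   out <- (1 + osavi_L) * (b$nir - b$red) / den
                   out[den == 0] <- NA_real_
                   out
                 })
  )
}

resolve_index <- function(index, osavi_L = 0.16) {
  if (is.list(index) && !is.null(index$fun)) return(index)
  defs <- si_definitions(osavi_L)
  sg_assert(is.character(index) && length(index) == 1L &&
              tolower(index) %in% names(defs),
            paste0("unknown spectral index: ", paste(index, collapse = ",")),
            "sg_invalid_definition")
  defs[[tolower(index)]]
}

#' Construct a five-band raster stack
#'
#' @param bands Named list of equally sized numeric matrices; names must
#'   cover `blue, green, red, rededge, nir`.
#' @param date Flight date (`Date` or coercible).
#' @param panel_region Rectangle `c(r0, c0, r1, c1)` (0-based, half-open)
#'   covering the calibration panel, or `NULL` if absent.
#' @return Object of class `sg_bandstack`.
#' @export
band_stack <- function(bands, date, panel_region = NULL) {
  sg_assert(is.list(bands) && all(sg_bands() %in% names(bands)),
            "bands must be a named list containing blue/green/red/rededge/nir")
  bands <- bands[sg_bands()]
  dims <- dim(bands[[1]])
  for (b in bands) {
    sg_assert(is.matrix(b) && identical(dim(b), dims),
              "all five bands must be matrices of identical dimensions")
  }
  if (!is.null(panel_region)) {
    panel_region <- as_rect(panel_region)
    sg_assert(rect_in_bounds(panel_region, dims),
              "panel_region outside raster bounds")
  }
  structure(list(bands = bands, date = as.Date(date),
                 panel_region = panel_region),
            class = "sg_bandstack")
}

#' @export
print.sg_bandstack <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf("<sg_bandstack> %d x %d px, 5 bands, date %s\n",
              d[1], d[2], format(x$date)))
  invisible(x)
}

#' Panel-based reflectance calibration
#'
#' Converts a raw digital-number raster to reflectance using the calibration
#' panel: the gain is the known panel reflectance divided by the mean digital
#' number over the panel region, and the whole raster is scaled by it.
#'
#' @param raw Numeric matrix of raw digital numbers.
#' @param panel_region Rectangle `c(r0, c0, r1, c1)` (0-based, half-open).
#' @param panel_reflectance Known reflectance of the panel for this band.
#' @return Reflectance raster (matrix); the gain is attached as
#'   `attr(, "gain")`.
#' @export
calibrate_reflectance <- function(raw, panel_region, panel_reflectance) {
  sg_assert(is.matrix(raw) && is.numeric(raw), "raw must be a numeric matrix")
  panel_region <- as_rect(panel_region)
  sg_assert(rect_in_bounds(panel_region, dim(raw)),
            "panel_region outside raster bounds")
  sg_assert(is.numeric(panel_reflectance) && length(panel_reflectance) == 1L &&
              is.finite(panel_reflectance) && panel_reflectance > 0,
            "panel_reflectance must be a positive number")
  dn <- mean(raw[rect_rows(panel_region), rect_cols(panel_region)],
             na.rm = TRUE)
  if (!is.finite(dn) || dn <= 0) {
    sg_stop("mean panel digital number is not positive; cannot calibrate",
            "sg_calibration_error")
  }
  gain <- panel_reflectance / dn
  out <- raw * gain
  attr(out, "gain") <- gain
  out
}

#' Calibrate all bands of a stack against the panel
#'
#' @param stack An `sg_bandstack` of raw digital numbers with a panel region.
#' @param panel Named vector of panel reflectances per band
#'   (default [panel_reflectances()]).
#' @return An `sg_bandstack` of reflectances.
#' @export
calibrate_stack <- function(stack, panel = panel_reflectances()) {
  sg_assert(inherits(stack, "sg_bandstack"), "stack must be an sg_bandstack")
  sg_assert(!is.null(stack$panel_region),
            "stack has no panel_region; cannot calibrate",
            "sg_calibration_error")
  bands <- lapply(sg_bands(), function(b) {
    out <- calibrate_reflectance(stack$bands[[b]], stack$panel_region,
                                 panel[[b]])
    attr(out, "gain") <- NULL
    out
  })
  names(bands) <- sg_bands()
  band_stack(bands, stack$date, stack$panel_region)
}

#' Compute a spectral index raster
#'
#' Applies an index definition pixel-wise to a reflectance stack. Pixels with
#' a zero denominator become `NA`.
#'
#' @param stack An `sg_bandstack` of reflectances.
#' @param index Index name (`"ndvi"`, `"gndvi"`, `"ndre"`, `"osavi"`) or a
#'   definition from [si_definitions()].
#' @param osavi_L OSAVI soil constant, used when `index` is a name.
#' @return Numeric matrix of index values.
#' @export
compute_index <- function(stack, index, osavi_L = 0.16) {
  sg_assert(inherits(stack, "sg_bandstack"), "stack must be an sg_bandstack")
  defn <- resolve_index(index, osavi_L)
  missing_bands <- setdiff(defn$bands, names(stack$bands))
  if (length(missing_bands)) {
    sg_stop(paste0("index ", defn$name, " needs missing band(s): ",
                   paste(missing_bands, collapse = ",")),
            "sg_invalid_definition")
  }
  out <- defn$fun(stack$bands)
  dim(out) <- dim(stack$bands[[1]])
  out
}

# index of a single named spectrum (vector of 5 band reflectances)
si_value <- function(spectrum, index, osavi_L = 0.16) {
  defn <- resolve_index(index, osavi_L)
  as.numeric(defn$fun(as.list(spectrum)))
}

#' Build the canopy mask from the anthesis-flight NDVI
#'
#' Pixels at or above the NDVI threshold on the first (anthesis) flight are
#' canopy; the mask is built once and reused for every later date. Missing
#' NDVI pixels are excluded.
#'
#' @param ndvi NDVI raster from the first flight.
#' @param threshold NDVI segmentation threshold (default 0.6).
#' @param source_date Flight date the raster came from (optional, recorded).
#' @return Object of class `sg_mask` wrapping a logical matrix.
#' @export
build_mask <- function(ndvi, threshold = 0.6, source_date = NULL) {
  sg_assert(is.matrix(ndvi) && is.numeric(ndvi), "ndvi must be a numeric matrix")
  m <- !is.na(ndvi) & ndvi >= threshold
  structure(list(mask = m, threshold = threshold,
                 source_date = if (is.null(source_date)) NULL
                               else as.Date(source_date)),
            class = "sg_mask")
}

#' Per-plot mean of an index raster under the canopy mask
#'
#' Pixel membership is pixel-center-in-rectangle with 0-based half-open plot
#' rectangles. A plot whose intersection with the mask is empty yields `NA`
#' (never zero); a warning reports how many plots were empty.
#'
#' @param index_raster Numeric index raster.
#' @param mask An `sg_mask` (or logical matrix) of the same dimensions.
#' @param plots An `sg_plotmap` (see [make_plot_grid()]).
#' @return Named numeric vector of per-plot means.
#' @export
extract_plot_values <- function(index_raster, mask, plots) {
  sg_assert(is.matrix(index_raster), "index_raster must be a matrix")
  m <- if (inherits(mask, "sg_mask")) mask$mask else mask
  sg_assert(is.logical(m) && identical(dim(m), dim(index_raster)),
            "mask must be logical and match the raster dimensions")
  sg_assert(inherits(plots, "sg_plotmap"), "plots must be an sg_plotmap")
  out <- rep(NA_real_, nrow(plots$plots))
  names(out) <- plots$plots$plot_id
  for (i in seq_len(nrow(plots$plots))) {
    rect <- unlist(plots$plots[i, c("r0", "c0", "r1", "c1")])
    if (!rect_in_bounds(rect, dim(index_raster))) {
      sg_stop(sprintf("plot %s extends outside the raster",
                      plots$plots$plot_id[i]), "sg_invalid_plot")
    }
    vals <- index_raster[rect_rows(rect), rect_cols(rect)]
    keep <- m[rect_rows(rect), rect_cols(rect)] & !is.na(vals)
    if (any(keep)) out[i] <- mean(vals[keep])
  }
  if (anyNA(out)) {
    warning(sprintf("%d plot(s) had no masked pixels; values set to NA",
                    sum(is.na(out))))
  }
  out
}

#' Assemble per-date plot means into an index trajectory
#'
#' @param values List with one element per flight date; each element is a
#'   plot x index numeric matrix (rownames = plot ids, colnames = index
#'   names), as produced by [extract_plot_values()] per index.
#' @param dates Vector of flight dates, same length as `values`.
#' @param anthesis_flight Which flight is the anthesis reference: an index
#'   into the date-sorted sequence (default 1, the earliest flight).
#' @return Object of class `sg_traj`: a `plot x date x index` array plus the
#'   anthesis values per plot and index.
#' @export
assemble_trajectories <- function(values, dates, anthesis_flight = 1L) {
  sg_assert(is.list(values) && length(values) == length(dates) &&
              length(dates) >= 1L,
            "values must be a list with one plot x index matrix per date")
  dates <- as.Date(dates)
  if (anyDuplicated(dates)) {
    sg_stop("duplicate flight dates", "sg_invalid_input")
  }
  ord <- order(dates)
  dates <- dates[ord]
  values <- values[ord]
  plot_ids <- rownames(values[[1]])
  idx_names <- colnames(values[[1]])
  for (v in values) {
    sg_assert(identical(rownames(v), plot_ids) &&
                identical(colnames(v), idx_names),
              "all per-date matrices must share plot and index names")
  }
  arr <- array(NA_real_,
               dim = c(length(plot_ids), length(dates), length(idx_names)),
               dimnames = list(plot_ids, format(dates), idx_names))
  for (j in seq_along(values)) arr[, j, ] <- values[[j]]
  sg_assert(anthesis_flight >= 1L && anthesis_flight <= length(dates),
            "anthesis_flight out of range")
  anth <- matrix(arr[, anthesis_flight, ], length(plot_ids),
                 length(idx_names), dimnames = list(plot_ids, idx_names))
  structure(list(values = arr, dates = dates,
                 anthesis_date = dates[anthesis_flight],
                 anthesis = anth),
            class = "sg_traj")
}

#' @export
print.sg_traj <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<sg_traj> %d plots x %d dates x %d indices (%s .. %s)\n",
              d[1], d[2], d[3], format(min(x$dates)), format(max(x$dates))))
  invisible(x)
}

#' Full imaging pipeline: raw stacks to spectral-index trajectories
#'
#' Calibrates every stack against the panel, builds the canopy mask from the
#' NDVI of the anthesis flight, computes each index per pixel, averages over
#' plot-by-mask intersections and assembles the dated trajectory.
#'
#' @param stacks List of raw `sg_bandstack` objects (one per flight).
#' @param plots An `sg_plotmap`.
#' @param panel Named panel reflectances (default [panel_reflectances()]).
#' @param indices Character vector of index names.
#' @param threshold NDVI mask threshold (default 0.6).
#' @param anthesis_flight Index of the anthesis flight in date order.
#' @return An `sg_traj`.
#' @export
extract_si_trajectories <- function(stacks, plots,
                                    panel = panel_reflectances(),
                                    indices = c("ndvi", "gndvi", "ndre",
                                                "osavi"),
                                    threshold = 0.6, anthesis_flight = 1L) {
  sg_assert(length(stacks) >= 1L, "need at least one band stack")
  dates <- as.Date(vapply(stacks, function(s) format(s$date), ""))
  ord <- order(dates)
  stacks <- stacks[ord]
  refl <- lapply(stacks, calibrate_stack, panel = panel)
  mask <- build_mask(compute_index(refl[[anthesis_flight]], "ndvi"),
                     threshold = threshold,
                     source_date = refl[[anthesis_flight]]$date)
  values <- lapply(refl, function(st) {
    vapply(indices, function(ix) {
      extract_plot_values(compute_index(st, ix), mask, plots)
    }, numeric(nrow(plots$plots)))
  })
  assemble_trajectories(values, dates[ord], anthesis_flight)
}
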