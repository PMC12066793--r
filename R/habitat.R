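#' Threat specification for habitat degradation
#'
#' One stressor acting on habitat: a source raster (or the name of a land
#' class, whose pixels become sources with the given intensity), a relative
#' weight, a maximum impact distance, and a distance-decay kernel. Linear
#' decay is `1 - d/d_max`; exponential decay is `exp(-2.99 d/d_max)`, the two
#' conventional kernels of the habitat-quality model family; both vanish
#' beyond `d_max`.
#'
#' @param name threat label; if `source` is `NULL` it must name a land class
#'   (see [land_classes()]) from which source pixels are taken.
#' @param weight relative weight `W_r >= 0`; weights are normalized to sum to
#'   one across threats.
#' @param max_dist maximum impact distance `d_max` in metres (`> 0`).
#' @param decay `"exponential"` or `"linear"`.
#' @param intensity threat intensity `r_y` in `[0, 1]` at source pixels.
#' @param source optional [raster_grid] of per-pixel intensities; overrides
#'   the land-class lookup.
#' @return an object of class `threat_spec`.
#' @export
threat_spec <- function(name, weight = 1, max_dist = 5000,
                        decay = c("exponential", "linear"),
                        intensity = 1, source = NULL) {
  decay <- match.arg(decay)
  if (weight < 0) stop("`weight` must be >= 0", call. = FALSE)
  if (max_dist <= 0) stop("`max_dist` must be > 0", call. = FALSE)
  if (intensity < 0 || intensity > 1)
    stop("`intensity` must be in [0, 1]", call. = FALSE)
  structure(list(name = name, weight = weight, max_dist = max_dist,
                 decay = decay, intensity = intensity, source = source),
            class = "threat_spec")
}

#' Default threat set for the synthetic county
#'
#' Construction, cropland and unused (bare) land act as stressors, the usual
#' choice for arid-county habitat assessments: construction carries the
#' largest weight and reach.
#' @return list of [threat_spec()]s.
#' @export
default_threats <- function() {
  list(
    threat_spec("construction", weight = 1.0, max_dist = 8000,
                decay = "exponential"),
    threat_spec("cropland", weight = 0.6, max_dist = 4000, decay = "linear"),
    threat_spec("unused", weight = 0.3, max_dist = 3000, decay = "linear")
  )
}

#' Habitat suitability and sensitivity parameters
#'
#' @param suitability named vector in `[0, 1]`, habitat suitability `H_j` per
#'   land class.
#' @param sensitivity matrix in `[0, 1]`, rows = land classes, columns =
#'   threat names: sensitivity `S_jr` of habitat `j` to stressor `r`.
#' @param k half-saturation constant (`> 0`): degradation level at which
#'   quality falls to half the suitability.
#' @param z scaling exponent (`> 0`).
#' @return an object of class `habitat_params`.
#' @export
habitat_params <- function(suitability = default_suitability(),
                           sensitivity = default_sensitivity(),
                           k = 0.5, z = 2.5) {
  if (k <= 0) stop("half-saturation `k` must be > 0", call. = FALSE)
  if (z <= 0) stop("exponent `z` must be > 0", call. = FALSE)
  if (any(suitability < 0 | suitability > 1))
    stop("suitability values must be in [0, 1]", call. = FALSE)
  if (any(sensitivity < 0 | sensitivity > 1))
    stop("sensitivity values must be in [0, 1]", call. = FALSE)
  structure(list(suitability = suitability, sensitivity = sensitivity,
                 k = k, z = z), class = "habitat_params")
}

#' @rdname habitat_params
#' @export
default_suitability <- function() {
  c(cropland = 0.4, forest = 1.0, grassland = 0.8, water = 0.9,
    construction = 0.0, unused = 0.1)
}

#' @rdname habitat_params
#' @export
default_sensitivity <- function() {
  m <- rbind(
    cropland     = c(0.5, 0.3, 0.1),
    forest       = c(0.9, 0.7, 0.4),
    grassland    = c(0.7, 0.6, 0.4),
    water        = c(0.8, 0.6, 0.2),
    construction = c(0.0, 0.0, 0.0),
    unused       = c(0.2, 0.1, 0.0)
  )
  colnames(m) <- c("construction", "cropland", "unused")
  m
}

# distance-decay kernel matrix for FFT convolution, cell units
decay_kernel <- function(nr, nc, max_dist_cells, decay) {
  di <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dj <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  d <- sqrt(outer(di^2, dj^2, `+`))
  k <- switch(decay,
              linear = pmax(1 - d / max_dist_cells, 0),
              exponential = exp(-2.99 * d / max_dist_cells) *
                (d <= max_dist_cells))
  dim(k) <- dim(d)
  k
}

# circular FFT convolution of a source field with a kernel; grids are small
# relative to kernel support so wrap-around is suppressed by zero padding
kernel_convolve <- function(src, max_dist_cells, decay) {
  nr <- nrow(src); nc <- ncol(src)
  pad <- ceiling(max_dist_cells)
  NR <- nr + pad; NC <- nc + pad
  big <- matrix(0, NR, NC)
  big[seq_len(nr), seq_len(nc)] <- src
  kern <- decay_kernel(NR, NC, max_dist_cells, decay)
  out <- Re(stats::fft(stats::fft(big) * stats::fft(kern), inverse = TRUE)) /
    (NR * NC)
  out[seq_len(nr), seq_len(nc)]
}

#' Habitat degradation from distance-decayed threats
#'
#' Degradation of each habitat pixel is the weighted sum over stressors of
#' the mean distance-decayed impact of that stressor's source pixels, scaled
#' by pixel accessibility and by the sensitivity of the pixel's land class to
#' the stressor. Threat weights are normalized to sum to one.
#'
#' @param land categorical [raster_grid] of land-class codes (see
#'   [land_classes()]).
#' @param threats list of [threat_spec()]s.
#' @param params a [habitat_params()]; every land class present must have a
#'   sensitivity row.
#' @param accessibility optional [raster_grid] in `[0, 1]` (default 1
#'   everywhere).
#' @param normalize_sources divide each stressor's summed impact by its
#'   source-pixel count (the convention of the cited model family); `FALSE`
#'   uses the raw sum.
#' @return degradation [raster_grid] (`>= 0`, nodata where `land` is nodata).
#' @export
habitat_degradation <- function(land, threats, params = habitat_params(),
                                accessibility = NULL,
                                normalize_sources = TRUE) {
  stopifnot(is_raster_grid(land))
  lv <- land$values
  classes_present <- land_classes()[sort(unique(lv[!is.na(lv)]))]
  missing_rows <- setdiff(classes_present, rownames(params$sensitivity))
  if (length(missing_rows))
    stop("no sensitivity row for land class(es): ",
         paste(missing_rows, collapse = ", "), call. = FALSE)
  w <- vapply(threats, `[[`, numeric(1), "weight")
  if (sum(w) <= 0) stop("threat weights sum to zero", call. = FALSE)
  w <- w / sum(w)
  beta <- if (is.null(accessibility)) 1 else {
    stop_if_misaligned(list(land, accessibility))
    accessibility$values
  }
  D <- matrix(0, nrow(lv), ncol(lv))
  for (i in seq_along(threats)) {
    th <- threats[[i]]
    if (is.null(th$source)) {
      code <- match(th$name, land_classes())
      if (is.na(code))
        stop("threat '", th$name, "' is not a land class and has no source ",
             "raster", call. = FALSE)
      src <- (!is.na(lv) & lv == code) * th$intensity
    } else {
      stop_if_misaligned(list(land, th$source))
      src <- th$source$values
      src[is.na(src)] <- 0
    }
    n_src <- sum(src > 0)
    if (n_src == 0) next
    impact <- kernel_convolve(src, th$max_dist / land$cell_size, th$decay)
    impact[impact < 0] <- 0                      # FFT round-off
    if (normalize_sources) impact <- impact / n_src
    srow <- params$sensitivity[, th$name]
    sens <- matrix(0, nrow(lv), ncol(lv))
    ok <- !is.na(lv)
    sens[ok] <- srow[land_classes()[lv[ok]]]
    D <- D + w[i] * impact * beta * sens
  }
  D[is.na(lv)] <- NA_real_
  raster_grid(D, land$xll, land$yll, land$cell_size)
}

#' Habitat quality from degradation
#'
#' Quality of pixel `x` with land class `j` is
#' `Q = H_j * (1 - D^z / (D^z + k^z))`: equal to the suitability `H_j` at
#' zero degradation, half of it at the half-saturation point `D = k`, and
#' monotone non-increasing in `D`.
#'
#' @param degradation degradation [raster_grid] (`>= 0`), e.g. from
#'   [habitat_degradation()].
#' @param land categorical land-class [raster_grid].
#' @param params a [habitat_params()].
#' @return quality [raster_grid] in `[0, 1]`.
#' @export
habitat_quality <- function(degradation, land, params = habitat_params()) {
  stopifnot(is_raster_grid(degradation), is_raster_grid(land))
  stop_if_misaligned(list(degradation, land))
  if (params$k <= 0) stop("half-saturation `k` must be > 0", call. = FALSE)
  D <- degradation$values
  if (any(D[!is.na(D)] < 0))
    stop("degradation must be non-negative", call. = FALSE)
  lv <- land$values
  H <- matrix(NA_real_, nrow(lv), ncol(lv))
  ok <- !is.na(lv)
  H[ok] <- params$suitability[land_classes()[lv[ok]]]
  q <- H * (1 - D^params$z / (D^params$z + params$k^params$z))
  q[is.na(D)] <- NA_real_
  raster_grid(q, land$xll, land$yll, land$cell_size)
}
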