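#' RUSLE factor bundle for soil conservation
#'
#' @param R rainfall erosivity raster, MJ·mm/(hm²·h·a).
#' @param K soil erodibility raster, t·hm²·h/(hm²·MJ·mm).
#' @param LS topographic (slope length and steepness) factor raster.
#' @param C vegetation management factor raster in `[0, 1]`.
#' @param P conservation-practice factor raster in `[0, 1]`.
#' @return an object of class `rusle_factors`.
#' @export
rusle_factors <- function(R, K, LS, C, P) {
  gs <- list(R = R, K = K, LS = LS, C = C, P = P)
  stopifnot(all(vapply(gs, is_raster_grid, logical(1))))
  stop_if_misaligned(gs, "RUSLE factor rasters")
  for (nm in names(gs)) {
    v <- gs[[nm]]$values
    if (any(v[!is.na(v)] < 0))
      stop("negative values in factor ", nm, call. = FALSE)
  }
  for (nm in c("C", "P"))
    if (any(gs[[nm]]$values[!is.na(gs[[nm]]$values)] > 1))
      stop(nm, " factor must be <= 1", call. = FALSE)
  structure(gs, class = "rusle_factors")
}

#' Soil conservation as retained potential erosion
#'
#' `SC = R * K * LS * (1 - C * P)` per pixel, in t·hm⁻²·yr⁻¹: the share of
#' potential erosion `R*K*LS` retained by vegetation cover and conservation
#' practice. Regional reporting uses t/km² (1 km² = 100 hm², so the
#' per-unit-area mean in t/km² is 100 times the mean in t/hm²).
#'
#' @param factors a [rusle_factors()].
#' @return soil-conservation [raster_grid], t/hm²/yr.
#' @export
soil_conservation <- function(factors) {
  stopifnot(inherits(factors, "rusle_factors"))
  rg_map(function(R, K, LS, C, P) R * K * LS * (1 - C * P),
         factors$R, factors$K, factors$LS, factors$C, factors$P)
}

#' Convenience estimators for RUSLE inputs
#'
#' `erosivity_from_precip()` is a simple annual-precipitation power law
#' `R = a * P^b`; `erodibility_from_texture()` is the EPIC texture/organic
#' matter nomograph; `ls_factor()` combines a slope-length term
#' `(lambda/22.13)^m` (exponent piecewise in slope) with the
#' standard quadratic steepness polynomial. These are pragmatic defaults for
#' synthetic data, not calibrated formulations; supply measured `R`, `K`, `LS`
#' rasters where available.
#'
#' @param pre annual precipitation [raster_grid], mm.
#' @param a,b power-law coefficients.
#' @return [raster_grid] of the estimated factor.
#' @export
erosivity_from_precip <- function(pre, a = 0.3, b = 1.5) {
  stopifnot(is_raster_grid(pre))
  rg_map(function(p) a * pmax(p, 0)^b, pre)
}

#' @rdname erosivity_from_precip
#' @param sand,silt,clay,om texture [raster_grid]s in percent.
#' @export
erodibility_from_texture <- function(sand, silt, clay, om) {
  rg_map(function(SAN, SIL, CLA, OM) {
    sn <- 1 - SAN / 100
    k <- (0.2 + 0.3 * exp(-0.0256 * SAN * (1 - SIL / 100))) *
      (SIL / pmax(CLA + SIL, 1e-9))^0.3 *
      (1 - 0.25 * OM / (OM + exp(3.72 - 2.95 * OM))) *
      (1 - 0.7 * sn / (sn + exp(-5.51 + 22.9 * sn)))
    pmax(k, 0)
  }, sand, silt, clay, om)
}

#' @rdname erosivity_from_precip
#' @param dem elevation [raster_grid], metres (used for cell size only).
#' @param slope slope [raster_grid] in degrees; computed from `dem` if `NULL`.
#' @param slope_length slope length `lambda` in metres (default: cell size).
#' @export
ls_factor <- function(dem, slope = NULL, slope_length = NULL) {
  stopifnot(is_raster_grid(dem))
  if (is.null(slope))
    slope <- raster_grid(slope_from_dem(dem$values, dem$cell_size),
                         dem$xll, dem$yll, dem$cell_size)
  lambda <- if (is.null(slope_length)) dem$cell_size else slope_length
  rg_map(function(sl) {
    sinth <- sin(sl * pi / 180)
    m <- ifelse(sl < 0.57, 0.2,
                ifelse(sl < 1.72, 0.3, ifelse(sl < 2.86, 0.4, 0.5)))
    (lambda / 22.13)^m * (65.41 * sinth^2 + 4.56 * sinth + 0.065)
  }, slope)
}

#' Per-land-class cover and practice factors
#'
#' Lookup of the RUSLE `C` and `P` factors by land class, optionally
#' modulating `C` downward with fractional vegetation cover
#' (`C * (1 - fvc_weight * FVC)`).
#'
#' @param land categorical land-class [raster_grid].
#' @param table data frame with columns `class`, `c_factor`, `p_factor` (see
#'   [default_landclass_table()]).
#' @param fvc optional fractional-vegetation-cover [raster_grid] in `[0, 1]`.
#' @param fvc_weight modulation strength in `[0, 1]` (used when `fvc` given).
#' @return list of `C` and `P` [raster_grid]s.
#' @export
cover_practice_factors <- function(land, table = default_landclass_table(),
                                   fvc = NULL, fvc_weight = 0) {
  stopifnot(is_raster_grid(land))
  lv <- land$values
  look <- function(col) {
    out <- matrix(NA_real_, nrow(lv), ncol(lv))
    ok <- !is.na(lv)
    idx <- match(land_classes()[lv[ok]], table$class)
    if (anyNA(idx))
      stop("land class missing from factor table", call. = FALSE)
    out[ok] <- table[[col]][idx]
    raster_grid(out, land$xll, land$yll, land$cell_size)
  }
  C <- look("c_factor"); P <- look("p_factor")
  if (!is.null(fvc) && fvc_weight > 0)
    C <- rg_map(function(c0, f) pmin(pmax(c0 * (1 - fvc_weight * f), 0), 1),
                C, fvc)
  list(C = C, P = P)
}
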