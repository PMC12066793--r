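#' Plant-available water content from soil texture
#'
#' Pedotransfer polynomial in sand, silt, clay and organic-matter
#' percentages, evaluated in percent and divided by 100. The default preset
#' `"plausible"` uses quadratic coefficients 0.003 (sand), 0.055/0.006
#' (silt), which keep the output positive for ordinary soils; preset
#' `"printed"` uses the 0.03/0.55/0.06 variant found in some transcriptions,
#' which goes negative for common textures and is clipped to 0 with a
#' warning. Output is clipped to `[0, 1]`.
#'
#' @param sand,silt,clay,om soil percentages in `[0, 100]`; scalars, vectors
#'   or [raster_grid]s.
#' @param preset `"plausible"` (default) or `"printed"`.
#' @return plant-available water content as a fraction in `[0, 1]`, same
#'   shape as the inputs.
#' @export
plant_available_water <- function(sand, silt, clay, om,
                                  preset = c("plausible", "printed")) {
  preset <- match.arg(preset)
  as_vals <- function(x) if (is_raster_grid(x)) x$values else x
  SAN <- as_vals(sand); SIL <- as_vals(silt); CLA <- as_vals(clay)
  OM <- as_vals(om)
  rng_ok <- function(x) all(x[!is.na(x)] >= 0 & x[!is.na(x)] <= 100)
  if (!all(vapply(list(SAN, SIL, CLA, OM), rng_ok, logical(1))))
    stop("soil percentages must lie in [0, 100]", call. = FALSE)
  co <- if (preset == "plausible") c(san2 = 0.003, sil = 0.055, sil2 = 0.006)
        else c(san2 = 0.03, sil = 0.55, sil2 = 0.06)
  pct <- 54.509 - 0.132 * SAN - co["san2"] * SAN^2 -
    co["sil"] * SIL - co["sil2"] * SIL^2 -
    0.738 * CLA + 0.007 * CLA^2 - 2.688 * OM + 0.501 * OM^2
  frac <- pct / 100
  out_of_range <- !is.na(frac) & (frac < 0 | frac > 1)
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " cell(s) outside [0, 1] clipped (pedotransfer polynomial ",
            "out of range)")
    frac <- pmin(pmax(frac, 0), 1)
  }
  if (is_raster_grid(sand))
    raster_grid(frac, sand$xll, sand$yll, sand$cell_size)
  else unname(frac)
}

#' Annual water yield (Budyko-type evapotranspiration partition)
#'
#' Per pixel: available water capacity `AWC = min(MSD, RD) * PAWC`; the
#' seasonality parameter `w = Z * AWC / P`; the dryness ratio
#' `R = k * ET0 / P`; the evapotranspiration fraction
#' `AET/P = (1 + wR) / (1 + wR + 1/R)`; and yield `Y = (1 - AET/P) * P`, mm,
#' bounded by `0 <= Y <= P`. Pixels with `P = 0` yield 0.
#'
#' @param p precipitation [raster_grid], mm.
#' @param et0 reference evapotranspiration [raster_grid], mm.
#' @param k_coef evapotranspiration coefficient: [raster_grid], scalar, or
#'   per-land-class values already mapped onto a raster.
#' @param root_depth rooting depth, mm ([raster_grid] or scalar).
#' @param msd maximum soil depth, mm (scalar or [raster_grid]).
#' @param pawc plant-available water content fraction ([raster_grid] or
#'   scalar), e.g. from [plant_available_water()].
#' @param z Zhang seasonality factor (`> 0`), default 3.6.
#' @return water-yield [raster_grid], mm.
#' @export
water_yield <- function(p, et0, k_coef = 1, root_depth = 1000, msd = 2000,
                        pawc = 0.15, z = 3.6) {
  stopifnot(is_raster_grid(p), is_raster_grid(et0))
  if (z <= 0) stop("Zhang factor `z` must be > 0", call. = FALSE)
  chk <- function(x, nm) {
    v <- if (is_raster_grid(x)) x$values else x
    if (any(v[!is.na(v)] < 0)) stop(nm, " must be non-negative",
                                    call. = FALSE)
    x
  }
  chk(p, "precipitation"); chk(et0, "ET0"); chk(k_coef, "k_coef")
  chk(root_depth, "root_depth"); chk(msd, "msd"); chk(pawc, "pawc")
  rg_map(function(P, E, K, RD, MSD, PAWC) {
    awc <- pmin(MSD, RD) * PAWC
    y <- P * 0
    pos <- !is.na(P) & P > 0
    w <- z * awc / P
    r <- K * E / P
    aet_frac <- ifelse(r <= 0, 0, (1 + w * r) / (1 + w * r + 1 / r))
    y[pos] <- ((1 - aet_frac) * P)[pos]
    pmin(pmax(y, 0), pmax(P, 0))
  }, p, et0, k_coef, root_depth, msd, pawc)
}
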