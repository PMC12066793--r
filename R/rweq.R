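#' Fractional vegetation cover from NDVI (dimidiate pixel model)
#'
#' `F_c = (NDVI - NDVI_soil) / (NDVI_veg - NDVI_soil)` with the bare-soil and
#' full-vegetation endmembers taken as the `q_low` and `q_high` NDVI
#' percentiles over valid pixels, clipped to `[0, 1]`.
#'
#' @param ndvi NDVI [raster_grid] in `[-1, 1]`.
#' @param q_low,q_high endmember percentiles in `[0, 1]`, defaults 0.05 and
#'   0.95.
#' @return fractional-cover [raster_grid] in `[0, 1]`.
#' @export
fractional_vegetation_cover <- function(ndvi, q_low = 0.05, q_high = 0.95) {
  stopifnot(is_raster_grid(ndvi))
  if (q_low >= q_high)
    stop("`q_low` must be below `q_high`", call. = FALSE)
  v <- ndvi$values[!is.na(ndvi$values)]
  qs <- stats::quantile(v, c(q_low, q_high), names = FALSE)
  if (qs[2] - qs[1] <= .Machine$double.eps)
    stop("degenerate NDVI field: endmember percentiles coincide",
         call. = FALSE)
  rg_map(function(x) pmin(pmax((x - qs[1]) / (qs[2] - qs[1]), 0), 1), ndvi)
}

#' Wind-erosion climate factor
#'
#' `WF = [sum over erosive records of WS2 * (WS2 - WSt)^2] * Nd * rho /
#' (N * g) * SW * SD`, where the sum runs over wind-speed records exceeding
#' the threshold `WSt`, `N` is the number of observations, `Nd` the number of
#' test days, `rho` the air density and `g` gravitational acceleration
#' (m/s²); `SW` and `SD` are the soil-moisture and snow-cover factors.
#'
#' @param records wind speeds at 2 m (m/s): a vector (one site) or a matrix
#'   with observations in rows and grid cells in columns.
#' @param threshold threshold wind speed `WSt`, m/s.
#' @param n_days number of test days `Nd`.
#' @param rho air density, kg/m³.
#' @param g gravitational acceleration, m/s².
#' @param sw,sd_factor soil-moisture and snow factors in `(0, 1]`; scalars or
#'   per-cell vectors.
#' @param n_obs number of observations `N`; defaults to the number of
#'   records (rows).
#' @return `WF` as a scalar (vector input) or per-cell vector (matrix input);
#'   always `>= 0`.
#' @export
wind_climate_factor <- function(records, threshold, n_days, rho = 1.2,
                                g = 9.8, sw = 1, sd_factor = 1,
                                n_obs = NULL) {
  if (is.null(dim(records))) records <- matrix(records, ncol = 1)
  if (is.null(n_obs)) n_obs <- nrow(records)
  if (n_obs <= 0) stop("number of observations must be positive",
                       call. = FALSE)
  if (n_days <= 0) stop("`n_days` must be positive", call. = FALSE)
  if (any(records[!is.na(records)] < 0))
    stop("wind speeds must be non-negative", call. = FALSE)
  erosive <- records > threshold
  contrib <- records * (records - threshold)^2 * erosive
  s <- colSums(contrib, na.rm = TRUE)
  s[colSums(!is.na(records)) == 0] <- NA_real_
  wf <- s * n_days * rho / (n_obs * g) * sw * sd_factor
  if (length(wf) == 1) wf[[1]] else wf
}

#' Soil erodible fraction and crust factor
#'
#' `EF` follows the standard wind-erosion-equation regression
#' `(29.09 + 0.31 Sa + 0.17 Si + 0.33 Sa/Ci - 2.59 OM - 0.95 CaCO3) / 100`
#' (preset `"standard"`, the default). Preset `"printed"` reproduces an
#' alternative transcription of the coefficients,
#' `(29.09 + 0.31 Sa + 0.17 Si + 0.33 Si*Ci/100 - 2.95 OM + 0.95 CaCO3)/100`,
#' which avoids the sand/clay ratio and so tolerates `Ci = 0`.
#' `SCF = 1 / (1 + 0.0066 Ci^2 + 0.021 OM^2)`.
#'
#' @param sand,silt,clay,om,caco3 soil fractions in percent (`[0, 100]`);
#'   scalars, vectors or [raster_grid]s (all of one kind).
#' @param preset coefficient preset, `"standard"` or `"printed"`.
#' @return list with elements `EF` and `SCF` (same shape as the inputs).
#' @export
soil_erodible_factors <- function(sand, silt, clay, om, caco3 = 0,
                                  preset = c("standard", "printed")) {
  preset <- match.arg(preset)
  as_vals <- function(x) if (is_raster_grid(x)) x$values else x
  Sa <- as_vals(sand); Si <- as_vals(silt); Ci <- as_vals(clay)
  OM <- as_vals(om); Ca <- as_vals(caco3)
  rng_ok <- function(x) all(x[!is.na(x)] >= 0 & x[!is.na(x)] <= 100)
  if (!all(vapply(list(Sa, Si, Ci, OM, Ca), rng_ok, logical(1))))
    stop("soil percentages must lie in [0, 100]", call. = FALSE)
  if (preset == "standard") {
    if (any(Ci[!is.na(Ci)] == 0))
      stop("clay = 0 is undefined for the ratio-form EF; use ",
           "preset = \"printed\"", call. = FALSE)
    ef <- (29.09 + 0.31 * Sa + 0.17 * Si + 0.33 * Sa / Ci -
             2.59 * OM - 0.95 * Ca) / 100
  } else {
    ef <- (29.09 + 0.31 * Sa + 0.17 * Si + 0.33 * Si * Ci / 100 -
             2.95 * OM + 0.95 * Ca) / 100
  }
  scf <- 1 / (1 + 0.0066 * Ci^2 + 0.021 * OM^2)
  wrap <- function(v, tpl) {
    if (is_raster_grid(tpl))
      raster_grid(v, tpl$xll, tpl$yll, tpl$cell_size)
    else v
  }
  list(EF = wrap(ef, sand), SCF = wrap(scf, sand))
}

#' Windbreak and sand fixation (potential minus actual wind erosion)
#'
#' The transport-capacity model: `Q_max = 109.8 * FP` with factor product
#' `FP = WF * EF * SCF * K' * COG`; critical field length
#' `s = 150.71 * FP^-0.3711`; transported soil loss at plot length `x`
#' `SL = (2x / s^2) * Q_max * exp(-(x/s)^2)` (kg/m²). The potential loss
#' `SL_q` recomputes `SL` with the vegetation factor reset to the bare-soil
#' value, and the sand-fixation service is `SR = SL_q - SL`, non-negative
#' whenever `COG <= bare_cog`. A zero factor product leaves the critical
#' length undefined; such cells return `SL = 0` with a warning.
#'
#' @param wf climate factor `WF` (scalar, vector or [raster_grid]).
#' @param ef,scf,kprime,cog erodible-fraction, crust, surface-roughness and
#'   vegetation factors (same shapes as `wf`; `kprime`, `cog` in `(0, 1]`).
#' @param x plot length in metres (`> 0`).
#' @param bare_cog vegetation factor under bare soil, default 1.
#' @return list with `SL_q`, `SL`, `SR` (kg/m², same shape as inputs).
#' @export
sand_fixation <- function(wf, ef, scf, kprime, cog, x = 50, bare_cog = 1) {
  if (x <= 0) stop("plot length `x` must be positive", call. = FALSE)
  as_vals <- function(v) if (is_raster_grid(v)) v$values else v
  WF <- as_vals(wf); EF <- as_vals(ef); SCF <- as_vals(scf)
  KP <- as_vals(kprime); CG <- as_vals(cog)
  neg <- function(v) any(v[!is.na(v)] < 0)
  if (neg(WF) || neg(EF) || neg(SCF) || neg(KP) || neg(CG))
    stop("factors must be non-negative", call. = FALSE)
  sl_of <- function(fp) {
    out <- fp * 0
    pos <- !is.na(fp) & fp > 0
    qmax <- 109.8 * fp[pos]
    s <- 150.71 * fp[pos]^(-0.3711)
    out[pos] <- (2 * x / s^2) * qmax * exp(-(x / s)^2)
    out
  }
  fp_act <- WF * EF * SCF * KP * CG
  fp_bare <- WF * EF * SCF * KP * bare_cog
  if (any(!is.na(fp_act) & fp_act == 0))
    warning("zero factor product: critical field length undefined, SL set ",
            "to 0 there")
  sl <- sl_of(fp_act)
  sl_q <- sl_of(fp_bare)
  sr <- sl_q - sl
  wrap <- function(v, tpl) {
    if (is_raster_grid(tpl)) raster_grid(v, tpl$xll, tpl$yll, tpl$cell_size)
    else v
  }
  list(SL_q = wrap(sl_q, wf), SL = wrap(sl, wf), SR = wrap(sr, wf))
}
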