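#' Configuration for the synthetic county generator
#'
#' Describes a small arid county on a regular grid with a north-mountain /
#' south-plain elevation gradient, spatially autocorrelated climate fields and
#' a categorical land-use mosaic, evolving over `n_years` annual steps. The
#' generator emulates the statistical structure the downstream trade-off
#' analysis assumes (co-registered drivers, spatial autocorrelation, slowly
#' varying climate, urban expansion); it makes no attempt to reproduce any
#' real geography.
#'
#' @param n_rows,n_cols grid dimensions in pixels.
#' @param cell_size cell edge length in metres.
#' @param n_years number of annual steps (at least 4).
#' @param seed integer seed; together with the configuration it fixes every
#'   generated value bitwise.
#' @param corr_length spatial autocorrelation length of the Gaussian random
#'   fields, in pixels (squared-exponential kernel).
#' @param elev_range `c(min, max)` elevation in metres.
#' @param lapse_rate temperature lapse rate in degrees C per metre.
#' @param tem_base air temperature at zero elevation, degrees C.
#' @param precip_base annual precipitation at the lowest elevation, mm.
#' @param precip_elev_gradient precipitation increase per metre of elevation,
#'   mm/m (orographic enhancement).
#' @param land_class_props named proportions over the six land classes
#'   `cropland, forest, grassland, water, construction, unused`; must sum to 1.
#' @param persistence lag-1 temporal correlation of the climate/NDVI anomaly
#'   fields (AR(1) coefficient in `[0, 1]`).
#' @param construction_expansion fraction of cropland pixels converted to
#'   construction per step, chosen nearest to existing construction.
#' @param noise_sd named list of anomaly standard deviations:
#'   `pre` (mm), `tem` (deg C), `ndvi` (unitless), `sw` (unitless).
#' @param mask_fraction fraction of the grid masked as outside the county
#'   (nodata), carved from a smooth field so the boundary is coherent.
#' @param wind_shape,wind_scale Weibull shape and scale (m/s) of the 2-m
#'   wind-speed records.
#' @param wind_n_obs number of wind-speed observations per year per pixel.
#' @param wind_threshold threshold wind speed at 2 m, m/s.
#' @param wind_days number of test days entering the climate factor.
#'
#' @return an object of class `county_config`.
#' @export
county_config <- function(n_rows = 64, n_cols = 64, cell_size = 1000,
                          n_years = 20, seed = 1, corr_length = 8,
                          elev_range = c(1050, 4000),
                          lapse_rate = 0.0065, tem_base = 22,
                          precip_base = 40, precip_elev_gradient = 0.012,
                          land_class_props = c(cropland = 0.20, forest = 0.08,
                                               grassland = 0.32, water = 0.05,
                                               construction = 0.05,
                                               unused = 0.30),
                          persistence = 0.9,
                          construction_expansion = 0.01,
                          noise_sd = list(pre = 5, tem = 0.8, ndvi = 0.04,
                                          sw = 0.05),
                          mask_fraction = 0.05,
                          wind_shape = 2, wind_scale = 4.5,
                          wind_n_obs = 60, wind_threshold = 5,
                          wind_days = 30) {
  if (n_rows <= 0 || n_cols <= 0)
    stop("grid dimensions must be positive", call. = FALSE)
  if (n_years < 4)
    stop("`n_years` must be at least 4", call. = FALSE)
  if (corr_length < 1)
    stop("`corr_length` must be at least 1 pixel", call. = FALSE)
  if (length(elev_range) != 2 || elev_range[1] >= elev_range[2])
    stop("`elev_range` must be c(min, max) with min < max", call. = FALSE)
  if (!all(land_classes() %in% names(land_class_props)))
    stop("`land_class_props` must be named over: ",
         paste(land_classes(), collapse = ", "), call. = FALSE)
  land_class_props <- land_class_props[land_classes()]
  if (abs(sum(land_class_props) - 1) > 1e-9)
    stop("`land_class_props` must sum to 1", call. = FALSE)
  if (any(land_class_props < 0))
    stop("`land_class_props` must be non-negative", call. = FALSE)
  if (persistence < 0 || persistence > 1)
    stop("`persistence` must be in [0, 1]", call. = FALSE)
  cfg <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              cell_size = cell_size, n_years = as.integer(n_years),
              seed = as.integer(seed), corr_length = corr_length,
              elev_range = elev_range, lapse_rate = lapse_rate,
              tem_base = tem_base, precip_base = precip_base,
              precip_elev_gradient = precip_elev_gradient,
              land_class_props = land_class_props,
              persistence = persistence,
              construction_expansion = construction_expansion,
              noise_sd = noise_sd, mask_fraction = mask_fraction,
              wind_shape = wind_shape, wind_scale = wind_scale,
              wind_n_obs = as.integer(wind_n_obs),
              wind_threshold = wind_threshold,
              wind_days = wind_days)
  class(cfg) <- "county_config"
  cfg
}

#' @export
print.county_config <- function(x, ...) {
  cat(sprintf("<county_config> %d x %d cells (%.6g m), %d years, seed %d\n",
              x$n_rows, x$n_cols, x$cell_size, x$n_years, x$seed))
  cat(sprintf("  elevation %g-%g m, corr length %g px, persistence %g\n",
              x$elev_range[1], x$elev_range[2], x$corr_length, x$persistence))
  invisible(x)
}

#' Land-class coding shared across the package
#'
#' Integer codes 1..6 in the fixed order cropland, forest, grassland, water,
#' construction, unused.
#' @return character vector of class names in code order.
#' @export
land_classes <- function() {
  c("cropland", "forest", "grassland", "water", "construction", "unused")
}

# ---- seeded random-field machinery -----------------------------------------

# Deterministic substream seed below 2^31 for (config seed, field id, year).
substream <- function(seed, field_id, year = -1L) {
  ((as.double(seed) * 48271 + field_id * 8191 + (year + 2) * 131071) %%
     2147483629) + 1
}

FIELD_IDS <- c(dem = 1L, mask = 2L, landlat = 3L, soil = 4L, sand = 5L,
               clay = 6L, om = 7L, caco3 = 8L, pop = 9L, gdp = 10L,
               windpat = 11L, pre = 12L, tem = 13L, ndvi = 14L, sw = 15L,
               et0 = 16L, wind = 17L)

#' Seeded Gaussian random field
#'
#' Stationary zero-mean, unit-variance Gaussian field on a grid, built by
#' FFT-filtering white noise with a squared-exponential kernel of the given
#' correlation length (circulant embedding on the torus). Uses the current
#' RNG state; callers seed a substream first.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param corr_length kernel length scale in pixels.
#' @return a numeric matrix.
#' @keywords internal
gaussian_field <- function(n_rows, n_cols, corr_length) {
  eps <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (corr_length <= 0) return(eps)
  di <- pmin(0:(n_rows - 1), n_rows - 0:(n_rows - 1))
  dj <- pmin(0:(n_cols - 1), n_cols - 0:(n_cols - 1))
  d2 <- outer(di^2, dj^2, `+`)
  kern <- exp(-d2 / (2 * corr_length^2))
  spec <- Re(stats::fft(kern))
  spec[spec < 0] <- 0
  f <- Re(stats::fft(stats::fft(eps) * sqrt(spec), inverse = TRUE)) /
    (n_rows * n_cols)
  s <- stats::sd(as.vector(f))
  if (s > 0) f <- (f - mean(f)) / s
  f
}

seeded_field <- function(cfg, field, year = -1L, corr_length = cfg$corr_length) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(substream(cfg$seed, FIELD_IDS[[field]], year))
  gaussian_field(cfg$n_rows, cfg$n_cols, corr_length)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

# AR(1) anomaly field for year t with unit marginal variance:
# a_0 = e_0;  a_t = rho a_{t-1} + sqrt(1-rho^2) e_t.
anomaly_field <- function(cfg, field, year) {
  a <- seeded_field(cfg, field, 0L)
  if (year == 0L) return(a)
  rho <- cfg$persistence
  for (t in seq_len(year)) {
    e <- seeded_field(cfg, field, t)
    a <- rho * a + sqrt(max(0, 1 - rho^2)) * e
  }
  a
}

# ---- static county structure -----------------------------------------------

county_static <- function(cfg) {
  nr <- cfg$n_rows; nc <- cfg$n_cols
  rowfrac <- matrix((seq_len(nr) - 0.5) / nr, nr, nc)   # 0 = north edge

  # DEM: smooth north-high/south-low profile plus a correlated field
  relief <- diff(cfg$elev_range)
  profile <- stats::plogis(6 * (0.55 - rowfrac))
  dem <- cfg$elev_range[1] + relief * profile +
    0.08 * relief * seeded_field(cfg, "dem")
  dem <- pmin(pmax(dem, cfg$elev_range[1]), cfg$elev_range[2])

  # county boundary: mask the lowest quantile of a smooth field
  mask <- matrix(FALSE, nr, nc)
  if (cfg$mask_fraction > 0) {
    mf <- seeded_field(cfg, "mask", corr_length = 2 * cfg$corr_length)
    mask <- mf < stats::quantile(mf, cfg$mask_fraction)
  }
  dem[mask] <- NA_real_

  slope <- slope_from_dem(dem, cfg$cell_size)

  # land-use mosaic: latent correlated field biased by elevation, classes
  # assigned by exact quantile thresholds (ties broken by raster order)
  latent <- 0.8 * seeded_field(cfg, "landlat") +
    0.6 * scale_field(dem)
  land0 <- mosaic_from_latent(latent, cfg$land_class_props, mask)

  soil_lat <- seeded_field(cfg, "soil", corr_length = 1.5 * cfg$corr_length)
  soil <- classify_quantiles(soil_lat, c(0.25, 0.20, 0.25, 0.15, 0.15), mask)
  landform <- classify_quantiles(scale_field(dem), c(0.35, 0.25, 0.25, 0.15),
                                 mask)

  # static soil texture (percent), sand+silt+clay = 100 exactly
  sand <- 35 + 25 * stats::plogis(seeded_field(cfg, "sand"))
  clay <- (100 - sand) * (0.25 + 0.20 * stats::plogis(seeded_field(cfg, "clay")))
  silt <- 100 - sand - clay
  om <- 0.3 + 1.7 * stats::plogis(seeded_field(cfg, "om"))
  caco3 <- 2 + 8 * stats::plogis(seeded_field(cfg, "caco3"))

  pop_pat <- seeded_field(cfg, "pop")
  gdp_pat <- seeded_field(cfg, "gdp")
  wind_pat <- seeded_field(cfg, "windpat")

  list(dem = dem, slope = slope, mask = mask, land0 = land0, soil = soil,
       landform = landform, sand = sand, silt = silt, clay = clay, om = om,
       caco3 = caco3, pop_pat = pop_pat, gdp_pat = gdp_pat,
       wind_pat = wind_pat)
}

scale_field <- function(m) {
  v <- m[!is.na(m)]
  out <- (m - mean(v)) / max(stats::sd(v), .Machine$double.eps)
  out[is.na(m)] <- 0
  out
}

slope_from_dem <- function(dem, cell_size) {
  nr <- nrow(dem); nc <- ncol(dem)
  filled <- dem
  if (anyNA(filled)) filled[is.na(filled)] <- mean(dem, na.rm = TRUE)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  if (nc > 2) gx[, 2:(nc - 1)] <-
      (filled[, 3:nc] - filled[, 1:(nc - 2)]) / (2 * cell_size)
  if (nr > 2) gy[2:(nr - 1), ] <-
      (filled[3:nr, ] - filled[1:(nr - 2), ]) / (2 * cell_size)
  sl <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  sl[is.na(dem)] <- NA_real_
  sl
}

# exact-count quantile mosaic; ties broken by raster (column-major) order
mosaic_from_latent <- function(latent, props, mask) {
  out <- matrix(NA_real_, nrow(latent), ncol(latent))
  idx <- which(!mask)
  n <- length(idx)
  counts <- diff(c(0, round(cumsum(props) * n)))
  ord <- idx[order(latent[idx], seq_along(idx), method = "radix")]
  codes <- rep(seq_along(props), counts)
  out[ord] <- codes
  out
}

classify_quantiles <- function(latent, props, mask) {
  mosaic_from_latent(latent, props / sum(props), mask)
}

# flip a fraction of cropland pixels nearest existing construction
expand_construction <- function(land, fraction) {
  codes <- match(c("cropland", "construction"), land_classes())
  crop <- which(land == codes[1]); constr <- which(land == codes[2])
  n_flip <- floor(length(crop) * fraction)
  if (n_flip == 0 || !length(constr)) return(land)
  nr <- nrow(land)
  rc <- function(i) cbind((i - 1) %% nr + 1, (i - 1) %/% nr + 1)
  pc <- rc(crop); qc <- rc(constr)
  d2 <- outer(pc[, 1], qc[, 1], `-`)^2 + outer(pc[, 2], qc[, 2], `-`)^2
  nearest <- apply(d2, 1, min)
  flip <- crop[order(nearest, seq_along(crop), method = "radix")][
    seq_len(n_flip)]
  land[flip] <- codes[2]
  land
}

# ---- per-year stack --------------------------------------------------------

#' Generate one year of co-registered driver rasters
#'
#' Builds the complete driver stack for `year_index`: the ten analysis drivers
#' (Dem, Slope, NDVI, Pre, Tem, Soil, Landforms, Land, Pop, GDP) plus the
#' auxiliary fields the service models need (soil texture fractions, organic
#' matter, calcium carbonate, soil-moisture and snow factors, reference
#' evapotranspiration, and per-pixel 2-m wind-speed records). All rasters
#' share shape, transform and nodata mask; the result is bitwise-deterministic
#' given the configuration.
#'
#' @param config a [county_config].
#' @param year_index year to generate, `0`-based, `< config$n_years`.
#' @return an object of class `driver_stack`: list with `year`, `rasters`
#'   (named list of [raster_grid]), `wind` (list with `records` matrix of
#'   `wind_n_obs` rows by grid cells, `threshold`, `n_days`) and `config`.
#' @export
generate_driver_stack <- function(config, year_index) {
  stopifnot(inherits(config, "county_config"))
  if (year_index < 0 || year_index >= config$n_years)
    stop(sprintf("`year_index` must be in [0, %d)", config$n_years),
         call. = FALSE)
  st <- county_static(config)
  build_year_stack(config, st, year_index,
                   land = evolve_land(config, st, year_index))
}

evolve_land <- function(cfg, st, year_index) {
  land <- st$land0
  if (year_index > 0 && cfg$construction_expansion > 0)
    for (t in seq_len(year_index))
      land <- expand_construction(land, cfg$construction_expansion)
  land
}

build_year_stack <- function(cfg, st, year, land) {
  mask <- st$mask
  rg <- function(m, categorical = FALSE) {
    m <- matrix(m, cfg$n_rows, cfg$n_cols)   # guard against dropped dims
    m[mask] <- NA_real_
    raster_grid(m, xll = 0, yll = 0, cell_size = cfg$cell_size,
                categorical = categorical)
  }
  dem0 <- st$dem; dem0[is.na(dem0)] <- cfg$elev_range[1]
  rel_dem <- dem0 - cfg$elev_range[1]

  pre <- pmax(0, cfg$precip_base + cfg$precip_elev_gradient * rel_dem +
                cfg$noise_sd$pre * anomaly_field(cfg, "pre", year))
  tem <- cfg$tem_base - cfg$lapse_rate * dem0 +
    cfg$noise_sd$tem * anomaly_field(cfg, "tem", year)

  affinity <- c(cropland = 0.45, forest = 0.60, grassland = 0.35,
                water = 0.05, construction = 0.12, unused = 0.08)
  aff <- matrix(affinity[land], nrow(land), ncol(land))
  aff[is.na(aff)] <- 0
  ndvi <- aff * (0.6 + 0.006 * (pre - cfg$precip_base)) +
    cfg$noise_sd$ndvi * anomaly_field(cfg, "ndvi", year)
  ndvi <- pmin(pmax(ndvi, -1), 1)

  sw <- pmin(pmax(0.8 - 0.004 * (pre - cfg$precip_base) +
                    cfg$noise_sd$sw * anomaly_field(cfg, "sw", year),
                  0.05), 1)
  sd_fac <- pmin(pmax(1 - 1e-4 * pmax(dem0 - 2500, 0), 0.6), 1)
  et0 <- pmax(0, 900 + 45 * tem + 20 * anomaly_field(cfg, "et0", year))

  constr_code <- match("construction", land_classes())
  near_constr <- proximity_boost(land == constr_code & !is.na(land))
  pop <- exp(1.0 + 1.1 * st$pop_pat) * (1 + 3 * near_constr) *
    1.015^year
  gdp <- pop * (2 + 1.5 * stats::plogis(st$gdp_pat)) * 1.015^year

  # 2-m wind-speed records: per-pixel Weibull draws, scale spatially modulated
  old <- get_rng_state()
  set.seed(substream(cfg$seed, FIELD_IDS[["wind"]], year))
  scale_px <- cfg$wind_scale * (1 + 0.15 * st$wind_pat)
  scale_px <- pmax(scale_px, 0.5)
  ncell <- cfg$n_rows * cfg$n_cols
  rec <- matrix(stats::rweibull(cfg$wind_n_obs * ncell,
                                shape = cfg$wind_shape,
                                scale = rep(as.vector(scale_px),
                                            each = cfg$wind_n_obs)),
                nrow = cfg$wind_n_obs, ncol = ncell)
  rec[, as.vector(mask)] <- NA_real_
  restore_rng_state(old)

  rasters <- list(
    Dem = rg(st$dem), Slope = rg(st$slope), NDVI = rg(ndvi),
    Pre = rg(pre), Tem = rg(tem),
    Soil = rg(st$soil, categorical = TRUE),
    Landforms = rg(st$landform, categorical = TRUE),
    Land = rg(land, categorical = TRUE),
    Pop = rg(pop), GDP = rg(gdp),
    sand = rg(st$sand), silt = rg(st$silt), clay = rg(st$clay),
    om = rg(st$om), caco3 = rg(st$caco3),
    SW = rg(sw), SD = rg(sd_fac), ET0 = rg(et0)
  )
  structure(list(year = year, rasters = rasters,
                 wind = list(records = rec, threshold = cfg$wind_threshold,
                             n_days = cfg$wind_days),
                 config = cfg),
            class = "driver_stack")
}

proximity_boost <- function(is_source) {
  src <- which(is_source)
  out <- matrix(0, nrow(is_source), ncol(is_source))
  if (!length(src)) return(out)
  nr <- nrow(is_source)
  all_i <- (seq_along(is_source) - 1) %% nr + 1
  all_j <- (seq_along(is_source) - 1) %/% nr + 1
  si <- all_i[src]; sj <- all_j[src]
  d2 <- outer(all_i, si, `-`)^2 + outer(all_j, sj, `-`)^2
  dmin <- sqrt(apply(d2, 1, min))
  matrix(exp(-dmin / 3), nrow(is_source), ncol(is_source))
}

#' @export
print.driver_stack <- function(x, ...) {
  cat(sprintf("<driver_stack> year %d: %d rasters, %d x %d cells\n",
              x$year, length(x$rasters), nrow(x$rasters$Dem$values),
              ncol(x$rasters$Dem$values)))
  cat("  layers:", paste(names(x$rasters), collapse = ", "), "\n")
  invisible(x)
}

#' Generate the full annual series of driver stacks
#'
#' Elevation, soil and landform rasters are fixed; climate, NDVI and the
#' soil-moisture factor evolve as AR(1) anomalies with the configured
#' persistence, and land use evolves by stepwise construction expansion.
#'
#' @param config a [county_config].
#' @return list of `n_years` [generate_driver_stack()] results, years
#'   `0 .. n_years-1`.
#' @export
generate_annual_series <- function(config) {
  stopifnot(inherits(config, "county_config"))
  st <- county_static(config)
  land <- st$land0
  out <- vector("list", config$n_years)
  for (y in seq_len(config$n_years) - 1L) {
    if (y > 0 && config$construction_expansion > 0)
      land <- expand_construction(land, config$construction_expansion)
    out[[y + 1]] <- build_year_stack(config, st, y, land)
  }
  out
}

# ---- fixture I/O -----------------------------------------------------------

#' Write a driver-stack series to a fixture directory
#'
#' Writes one ASCII-grid raster per layer per year, the per-year wind-speed
#' record tables, the default parameter tables (habitat suitability and
#' sensitivity, threat definitions, per-land-class factors) as CSV, and a
#' JSON manifest listing every file with its MD5 checksum plus the seed and a
#' hash of the generating configuration.
#'
#' @param stacks list of `driver_stack` objects (from
#'   [generate_annual_series()]).
#' @param directory output directory, created if needed.
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
write_fixture_set <- function(stacks, directory) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  if (file.access(directory, mode = 2) != 0)
    stop("directory not writable: ", directory, call. = FALSE)
  files <- character(0)
  for (s in stacks) {
    tag <- sprintf("year%02d", s$year)
    for (nm in names(s$rasters)) {
      f <- file.path(directory, sprintf("%s_%s.asc", tag, nm))
      write_asc(s$rasters[[nm]], f)
      files <- c(files, f)
    }
    wf <- file.path(directory, sprintf("%s_wind.txt", tag))
    rec <- s$wind$records
    rec[is.na(rec)] <- -9999
    con <- file(wf, "wb")
    writeLines(apply(rec, 1, function(r)
      paste(sprintf("%.7g", r), collapse = " ")), con, sep = "\n")
    close(con)
    files <- c(files, wf)
  }
  prm <- default_es_params()
  pfiles <- write_param_tables(prm, directory)
  files <- c(files, pfiles)

  cfg <- stacks[[1]]$config
  manifest <- list(
    seed = cfg$seed,
    n_years = length(stacks),
    config = cfg[setdiff(names(cfg), character(0))],
    config_hash = hash_object(unclass(cfg)),
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a fixture directory written by [write_fixture_set()]
#'
#' @param directory fixture directory containing `manifest.json`.
#' @return list of `driver_stack` objects.
#' @export
read_fixture_set <- function(directory) {
  mf <- file.path(directory, "manifest.json")
  if (!file.exists(mf))
    stop("no manifest.json in ", directory, call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  cfg <- manifest$config
  n_years <- manifest$n_years
  categorical <- c("Soil", "Landforms", "Land")
  lapply(seq_len(n_years) - 1L, function(y) {
    tag <- sprintf("year%02d", y)
    layer_files <- list.files(directory,
                              pattern = sprintf("^%s_.*\\.asc$", tag),
                              full.names = TRUE)
    nms <- sub("\\.asc$", "", sub(sprintf("^%s_", tag), "",
                                  basename(layer_files)))
    rasters <- stats::setNames(
      lapply(seq_along(layer_files), function(i)
        read_asc(layer_files[i], categorical = nms[i] %in% categorical)),
      nms)
    wf <- file.path(directory, sprintf("%s_wind.txt", tag))
    rec <- NULL
    if (file.exists(wf)) {
      rec <- as.matrix(utils::read.table(wf))
      dimnames(rec) <- NULL
      rec[rec == -9999] <- NA_real_
    }
    structure(list(year = y, rasters = rasters,
                   wind = list(records = rec,
                               threshold = cfg$wind_threshold,
                               n_days = cfg$wind_days),
                   config = cfg),
              class = "driver_stack")
  })
}

hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  writeLines(deparse(x, control = c("exact")), con, sep = "\n")
  close(con)
  unname(tools::md5sum(f))
}
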