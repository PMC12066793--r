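#' Default per-land-class factor table
#'
#' One row per land class: RUSLE cover (`c_factor`) and practice
#' (`p_factor`) factors, the Budyko evapotranspiration coefficient
#' (`k_coef`), rooting depth (`root_depth_mm`), and the wind-erosion surface
#' roughness factor (`kprime`). Values are conventional magnitudes for an
#' arid agro-pastoral county.
#'
#' @return data frame with columns `class`, `c_factor`, `p_factor`,
#'   `k_coef`, `root_depth_mm`, `kprime`.
#' @export
default_landclass_table <- function() {
  data.frame(
    class = land_classes(),
    c_factor = c(0.22, 0.006, 0.05, 0.0, 0.0, 0.45),
    p_factor = c(0.35, 1.0, 1.0, 0.0, 0.0, 1.0),
    k_coef = c(0.65, 1.0, 0.65, 1.1, 0.3, 0.2),
    root_depth_mm = c(600, 3000, 1200, 10, 10, 200),
    kprime = c(0.75, 0.4, 0.6, 0.3, 0.5, 0.9),
    stringsAsFactors = FALSE
  )
}

#' Bundle of parameters for service quantification
#'
#' @param habitat a [habitat_params()].
#' @param threats list of [threat_spec()]s.
#' @param landclass per-land-class factor table
#'   ([default_landclass_table()]).
#' @param ef_preset,pawc_preset coefficient presets for
#'   [soil_erodible_factors()] and [plant_available_water()].
#' @param zhang_z Zhang seasonality factor.
#' @param msd_mm maximum soil depth, mm.
#' @param plot_length_m wind-erosion plot length `x`, metres.
#' @param bare_cog bare-soil vegetation factor for potential wind erosion.
#' @param erosivity_a,erosivity_b precipitation power-law coefficients for
#'   the rainfall-erosivity convenience estimator.
#' @param cog_coef exponential response of the vegetation factor to
#'   fractional cover: `COG = exp(-cog_coef * 100 * FVC)`.
#' @return an object of class `es_params`.
#' @export
es_params <- function(habitat = habitat_params(),
                      threats = default_threats(),
                      landclass = default_landclass_table(),
                      ef_preset = "standard", pawc_preset = "plausible",
                      zhang_z = 3.6, msd_mm = 2000, plot_length_m = 50,
                      bare_cog = 1, erosivity_a = 0.3, erosivity_b = 1.5,
                      cog_coef = 0.0438) {
  structure(list(habitat = habitat, threats = threats, landclass = landclass,
                 ef_preset = ef_preset, pawc_preset = pawc_preset,
                 zhang_z = zhang_z, msd_mm = msd_mm,
                 plot_length_m = plot_length_m, bare_cog = bare_cog,
                 erosivity_a = erosivity_a, erosivity_b = erosivity_b,
                 cog_coef = cog_coef),
            class = "es_params")
}

#' @rdname es_params
#' @export
default_es_params <- function() es_params()

# lookup of a per-class column onto the land raster
class_lookup <- function(land, table, col) {
  lv <- land$values
  out <- matrix(NA_real_, nrow(lv), ncol(lv))
  ok <- !is.na(lv)
  out[ok] <- table[[col]][match(land_classes()[lv[ok]], table$class)]
  raster_grid(out, land$xll, land$yll, land$cell_size)
}

#' Quantify the four ecosystem services for one year
#'
#' Computes aligned rasters of water yield (WY, mm), soil conservation (SC,
#' t/hm²/yr), windbreak and sand fixation (WS, t/hm²/yr) and habitat quality
#' (HQ, unitless) from a driver stack, plus the regional summaries used for
#' reporting: mean WY depth (mm), SC per unit area (t/km², i.e. 100 times
#' the t/hm² mean), total WS (t, summed over cell areas) and mean HQ.
#'
#' @param stack a `driver_stack` (see [generate_driver_stack()]).
#' @param params an [es_params()].
#' @return an object of class `es_layers`: list with `year`, `services`
#'   (named list of WY/SC/WS/HQ [raster_grid]s) and `summary` (data frame
#'   `year, service, statistic, value, units`).
#' @export
quantify_all <- function(stack, params = es_params()) {
  stopifnot(inherits(stack, "driver_stack"))
  r <- stack$rasters
  need <- c("Dem", "Slope", "NDVI", "Pre", "Tem", "Land", "sand", "silt",
            "clay", "om", "caco3", "SW", "SD", "ET0")
  miss <- setdiff(need, names(r))
  if (length(miss))
    stop("driver stack is missing layer(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  land <- r$Land

  # --- habitat quality
  degr <- habitat_degradation(land, params$threats, params$habitat)
  hq <- habitat_quality(degr, land, params$habitat)

  # --- soil conservation (RUSLE)
  fvc <- fractional_vegetation_cover(r$NDVI)
  cp <- cover_practice_factors(land, params$landclass)
  rf <- rusle_factors(
    R = erosivity_from_precip(r$Pre, params$erosivity_a, params$erosivity_b),
    K = erodibility_from_texture(r$sand, r$silt, r$clay, r$om),
    LS = ls_factor(r$Dem, r$Slope),
    C = cp$C, P = cp$P
  )
  sc <- soil_conservation(rf)

  # --- windbreak and sand fixation (RWEQ)
  wf_cells <- wind_climate_factor(stack$wind$records,
                                  threshold = stack$wind$threshold,
                                  n_days = stack$wind$n_days,
                                  sw = as.vector(r$SW$values),
                                  sd_factor = as.vector(r$SD$values))
  wf <- raster_grid(matrix(wf_cells, nrow(land$values), ncol(land$values)),
                    land$xll, land$yll, land$cell_size)
  ers <- soil_erodible_factors(r$sand, r$silt, r$clay, r$om, r$caco3,
                               preset = params$ef_preset)
  kprime <- class_lookup(land, params$landclass, "kprime")
  cog <- rg_map(function(f) pmax(exp(-params$cog_coef * 100 * f), 1e-6), fvc)
  sf <- sand_fixation(wf, ers$EF, ers$SCF, kprime, cog,
                      x = params$plot_length_m, bare_cog = params$bare_cog)
  ws <- rg_map(function(v) v * 10, sf$SR)        # kg/m2 -> t/hm2

  # --- water yield (Budyko)
  pawc <- plant_available_water(r$sand, r$silt, r$clay, r$om,
                                preset = params$pawc_preset)
  wy <- water_yield(r$Pre, r$ET0,
                    k_coef = class_lookup(land, params$landclass, "k_coef"),
                    root_depth = class_lookup(land, params$landclass,
                                              "root_depth_mm"),
                    msd = params$msd_mm, pawc = pawc, z = params$zhang_z)

  services <- list(WY = wy, SC = sc, WS = ws, HQ = hq)
  # harmonize masks: a pixel is valid only where all four services are
  mask <- Reduce(`|`, lapply(services, nodata_mask))
  services <- lapply(services, function(g) {
    g$values[mask] <- NA_real_
    g
  })

  cell_hm2 <- (land$cell_size / 100)^2           # 1 hm2 = 100 m x 100 m
  msk_mean <- function(g) mean(g$values, na.rm = TRUE)
  summary <- data.frame(
    year = stack$year,
    service = c("WY", "SC", "WS", "HQ"),
    statistic = c("mean_depth", "per_unit_area", "total", "mean"),
    value = c(msk_mean(services$WY),
              msk_mean(services$SC) * 100,
              sum(services$WS$values, na.rm = TRUE) * cell_hm2,
              msk_mean(services$HQ)),
    units = c("mm", "t/km2", "t", "index"),
    stringsAsFactors = FALSE
  )
  structure(list(year = stack$year, services = services, summary = summary),
            class = "es_layers")
}

#' @export
print.es_layers <- function(x, ...) {
  cat(sprintf("<es_layers> year %d\n", x$year))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write the parameter tables of an [es_params()] bundle as CSV
#'
#' @param params an [es_params()].
#' @param directory output directory.
#' @return written file paths, invisibly.
#' @export
write_param_tables <- function(params, directory) {
  su <- params$habitat$suitability
  sens <- params$habitat$sensitivity
  hab <- data.frame(class = names(su), suitability = unname(su),
                    stringsAsFactors = FALSE)
  hab <- cbind(hab, as.data.frame(sens[hab$class, , drop = FALSE],
                                  row.names = NULL))
  names(hab)[-(1:2)] <- paste0("sens_", colnames(sens))
  thr <- do.call(rbind, lapply(params$threats, function(t)
    data.frame(threat = t$name, weight = t$weight, max_dist = t$max_dist,
               decay = t$decay, intensity = t$intensity,
               stringsAsFactors = FALSE)))
  files <- c(
    habitat = file.path(directory, "habitat_params.csv"),
    threats = file.path(directory, "threats.csv"),
    landclass = file.path(directory, "landclass_factors.csv")
  )
  utils::write.csv(hab, files["habitat"], row.names = FALSE)
  utils::write.csv(thr, files["threats"], row.names = FALSE)
  utils::write.csv(params$landclass, files["landclass"], row.names = FALSE)
  invisible(unname(files))
}
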