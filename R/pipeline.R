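#' Pipeline configuration
#'
#' Exactly one input source: a synthetic-county configuration (`county`) or
#' a fixture directory written by [write_fixture_set()] (`fixture_dir`).
#' Stages can be toggled; later stages require the earlier ones' outputs.
#'
#' @param county a [county_config()], or `NULL` when reading fixtures.
#' @param fixture_dir directory with a generated fixture set, or `NULL`.
#' @param out_dir output directory.
#' @param stages character subset of
#'   `c("simulate", "quantify", "tradeoffs", "drivers")`.
#' @param pairs list of service pairs; default all six pairs of
#'   WY, SC, WS, HQ.
#' @param mode correlation mode for the pairwise maps (see [tradeoff_map()]).
#' @param alpha significance level.
#' @param std_domain standardization domain for [rmsd_map()].
#' @param es an [es_params()].
#' @param boost a [boost_params()].
#' @param attribution_year year index explained by the driver stage;
#'   default the most recent.
#' @param seed master seed; overrides the county config seed and seeds the
#'   model fits.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(county = county_config(), fixture_dir = NULL,
                            out_dir = tempfile("estrade_run_"),
                            stages = c("simulate", "quantify", "tradeoffs",
                                       "drivers"),
                            pairs = NULL, mode = "temporal", alpha = 0.05,
                            std_domain = "year", es = es_params(),
                            boost = boost_params(),
                            attribution_year = NULL, seed = NULL) {
  if (!is.null(fixture_dir) && !is.null(county) &&
      !missing(county) && !missing(fixture_dir))
    stop("supply exactly one input source: `county` or `fixture_dir`",
         call. = FALSE)
  if (!is.null(fixture_dir)) county <- NULL
  if (is.null(county) && is.null(fixture_dir))
    stop("supply a county configuration or a fixture directory",
         call. = FALSE)
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(pairs)) {
    svc <- c("WY", "SC", "WS", "HQ")
    pairs <- utils::combn(svc, 2, simplify = FALSE)
  }
  if (!is.null(seed)) {
    if (!is.null(county)) county$seed <- as.integer(seed)
    boost$seed <- as.integer(seed)
  }
  structure(list(county = county, fixture_dir = fixture_dir,
                 out_dir = out_dir, stages = stages, pairs = pairs,
                 mode = mode, alpha = alpha, std_domain = std_domain,
                 es = es, boost = boost,
                 attribution_year = attribution_year,
                 seed = seed %||% (county$seed %||% NA_integer_)),
            class = "pipeline_config")
}

log_line <- function(log_con, ...) {
  msg <- sprintf(...)
  cat(msg, "\n", sep = "", file = log_con, append = TRUE)
  invisible(msg)
}

#' Run the full trade-off pipeline
#'
#' Executes the enabled stages in order — simulate (or read fixtures),
#' quantify, tradeoffs, drivers — writing every stage's outputs under
#' `out_dir` together with a plain-text log (stage timings, parameter
#' echoes) and a JSON manifest with the configuration hash and an MD5
#' checksum of every output file. A rerun with an identical configuration
#' reproduces identical checksums.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_file <- file.path(out_dir, "run.log")
  unlink(log_file)
  files <- character(0)
  stage_times <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    stage_times[[stage]] <<- proc.time()[["elapsed"]] - t0
    log_line(log_file, "[%s] completed in %.2f s", stage,
             stage_times[[stage]])
    res
  }
  log_line(log_file, "estrade pipeline run; seed = %s; stages = %s",
           as.character(config$seed), paste(config$stages, collapse = ","))

  # --- stage: simulate (or load fixtures)
  stacks <- NULL
  if ("simulate" %in% config$stages) {
    stacks <- tick("simulate", {
      if (!is.null(config$fixture_dir)) read_fixture_set(config$fixture_dir)
      else generate_annual_series(config$county)
    })
    sim_dir <- file.path(out_dir, "drivers_in")
    mf <- write_fixture_set(stacks, sim_dir)
    files <- c(files, file.path(sim_dir,
                                vapply(mf$files, `[[`, "", "name")),
               file.path(sim_dir, "manifest.json"))
  } else if (!is.null(config$fixture_dir)) {
    stacks <- read_fixture_set(config$fixture_dir)
  }

  # --- stage: quantify
  es_list <- NULL
  if ("quantify" %in% config$stages) {
    if (is.null(stacks))
      stop("stage 'quantify' needs driver stacks: enable 'simulate' or ",
           "set `fixture_dir`", call. = FALSE)
    es_list <- tick("quantify", lapply(stacks, quantify_all,
                                       params = config$es))
    es_dir <- file.path(out_dir, "services")
    dir.create(es_dir, showWarnings = FALSE)
    for (e in es_list)
      for (nm in names(e$services)) {
        f <- file.path(es_dir, sprintf("year%02d_%s.asc", e$year, nm))
        write_asc(e$services[[nm]], f)
        files <- c(files, f)
      }
    summ <- do.call(rbind, lapply(es_list, `[[`, "summary"))
    f <- file.path(es_dir, "service_summaries.csv")
    utils::write.csv(summ, f, row.names = FALSE)
    files <- c(files, f)
  }

  # --- stage: tradeoffs
  intensity <- list()
  tmaps <- list()
  if ("tradeoffs" %in% config$stages) {
    if (is.null(es_list))
      stop("stage 'tradeoffs' needs quantified services: enable 'quantify'",
           call. = FALSE)
    to_dir <- file.path(out_dir, "tradeoffs")
    dir.create(to_dir, showWarnings = FALSE)
    pair_rows <- list()
    tick("tradeoffs", {
      for (pr in config$pairs) {
        tag <- paste(pr, collapse = "-")
        tm <- tradeoff_map(es_list, pr, mode = config$mode,
                           alpha = config$alpha)
        tmaps[[tag]] <- tm
        if (inherits(tm, "tradeoff_maps")) {
          for (layer in c("r", "p", "category")) {
            f <- file.path(to_dir, sprintf("%s_%s.asc", tag, layer))
            write_asc(tm[[layer]], f)
            files <- c(files, f)
          }
          pair_rows[[tag]] <- data.frame(
            pair = tag, mode = tm$mode, n = tm$n, g = tm$g,
            frac_tradeoff = tm$fractions["tradeoff"],
            frac_synergy = tm$fractions["synergy"],
            frac_nonsignificant = tm$fractions["nonsignificant"],
            stringsAsFactors = FALSE)
        } else {
          pair_rows[[tag]] <- tm
        }
        im <- rmsd_map(es_list, pr, year = config$attribution_year,
                       domain = config$std_domain)
        intensity[[tag]] <- im
        f <- file.path(to_dir, sprintf("%s_rmsd.asc", tag))
        write_asc(im$rmsd, f)
        files <- c(files, f)
      }
    })
    f <- file.path(to_dir, "pair_summary.csv")
    utils::write.csv(do.call(rbind, c(pair_rows,
                                      list(make.row.names = FALSE))),
                     f, row.names = FALSE)
    files <- c(files, f)
  }

  # --- stage: drivers
  driver_out <- list()
  if ("drivers" %in% config$stages) {
    if (!length(intensity))
      stop("stage 'drivers' needs intensity maps: enable 'tradeoffs'",
           call. = FALSE)
    dr_dir <- file.path(out_dir, "drivers")
    dir.create(dr_dir, showWarnings = FALSE)
    years <- vapply(stacks, `[[`, numeric(1), "year")
    yr <- config$attribution_year %||% years[length(years)]
    stack_yr <- stacks[[match(yr, years)]]
    tick("drivers", {
      for (tag in names(intensity)) {
        tab <- build_feature_table(stack_yr, intensity[[tag]])
        model <- fit_tradeoff_model(tab, config$boost)
        att <- shapley_attributions(model, tab)
        rk <- rank_drivers(att)
        f <- file.path(dr_dir, sprintf("%s_ranking.csv", tag))
        utils::write.csv(rk, f, row.names = FALSE)
        files <- c(files, f)
        thr <- lapply(DRIVER_NAMES, function(feat)
          tryCatch(unclass(detect_thresholds(att, tab, feat)),
                   error = function(e) list(feature = feat,
                                            error = conditionMessage(e))))
        meta <- list(pair = tag, year = yr,
                     hyperparams = unclass(config$boost),
                     metrics = as.list(model$metrics),
                     max_local_accuracy_residual =
                       att$max_local_accuracy_residual,
                     ranking = rk, thresholds = thr)
        f <- file.path(dr_dir, sprintf("%s_attribution.json", tag))
        jsonlite::write_json(meta, f, auto_unbox = TRUE, digits = 10,
                             pretty = TRUE)
        files <- c(files, f)
        driver_out[[tag]] <- list(model = model, ranking = rk)
      }
    })
  }

  files <- c(files, log_file)
  manifest <- list(
    seed = config$seed,
    stages = config$stages,
    config_hash = hash_object(list(
      county = if (!is.null(config$county)) unclass(config$county),
      pairs = config$pairs, mode = config$mode, alpha = config$alpha,
      std_domain = config$std_domain, boost = unclass(config$boost))),
    stage_seconds = stage_times,
    # the log carries wall-clock timings, so it is listed without a checksum
    files = lapply(sort(unique(files)), function(f)
      list(name = sub(paste0("^", out_dir, "/?"), "", f),
           md5 = if (grepl("\\.log$", f)) NA else
             unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
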