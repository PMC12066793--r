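DRIVER_NAMES <- c("Dem", "Slope", "NDVI", "Pre", "Tem", "Soil", "Landforms",
                  "Land", "Pop", "GDP")
CATEGORICAL_DRIVERS <- c("Soil", "Landforms", "Land")

#' Assemble the driver/response feature table for one trade-off pair
#'
#' One row per pixel valid in every driver layer and in the intensity map;
#' columns are the ten drivers (categorical drivers as integer codes) plus
#' the response `intensity`. Sampling is reproducible given the seed.
#'
#' @param stack a `driver_stack` for the year being explained.
#' @param intensity an `intensity_map` (from [rmsd_map()]) or a
#'   [raster_grid] of the response.
#' @param sampling `"all"` or `"random"`.
#' @param n number of rows when `sampling = "random"`.
#' @param seed seed for the random sample.
#' @return data frame of class `feature_table` with attributes `pair`,
#'   `year`, `seed` and `categorical`.
#' @export
build_feature_table <- function(stack, intensity,
                                sampling = c("all", "random"),
                                n = NULL, seed = 1) {
  sampling <- match.arg(sampling)
  resp_grid <- if (inherits(intensity, "intensity_map")) intensity$rmsd
               else intensity
  stopifnot(is_raster_grid(resp_grid))
  cols <- lapply(stack$rasters[DRIVER_NAMES], function(g)
    as.vector(g$values))
  resp <- as.vector(resp_grid$values)
  ok <- Reduce(`&`, lapply(c(cols, list(resp)), function(v) !is.na(v)))
  if (!any(ok))
    stop("no pixel is valid in every driver layer and the intensity map",
         call. = FALSE)
  tab <- as.data.frame(lapply(cols, `[`, ok))
  tab$intensity <- resp[ok]
  if (sampling == "random") {
    if (is.null(n)) stop("`n` is required for random sampling",
                         call. = FALSE)
    old <- get_rng_state()
    set.seed(seed)
    keep <- sort(sample.int(nrow(tab), min(n, nrow(tab))))
    restore_rng_state(old)
    tab <- tab[keep, , drop = FALSE]
    rownames(tab) <- NULL
  }
  attr(tab, "pair") <- if (inherits(intensity, "intensity_map"))
    paste(intensity$pair, collapse = "-") else NA_character_
  attr(tab, "year") <- if (inherits(intensity, "intensity_map"))
    intensity$year else stack$year
  attr(tab, "seed") <- seed
  attr(tab, "categorical") <- CATEGORICAL_DRIVERS
  class(tab) <- c("feature_table", class(tab))
  tab
}

#' Hyperparameters for the boosted trade-off model
#'
#' Defaults: 500 boosting rounds, depth 6, learning rate 0.05, L2 penalty
#' `lambda = 1`, split penalty `gamma = 0`, no subsampling, single thread
#' (for bitwise reproducibility).
#'
#' @param nrounds,max_depth,eta,lambda,gamma,subsample,alpha standard
#'   gradient-boosting hyperparameters (`alpha` is the L1 leaf penalty).
#' @param nthread training threads; keep 1 for deterministic fits.
#' @param valid_fraction held-out fraction for the logged fit quality.
#' @param seed seed for the train/validation shuffle.
#' @return list of class `boost_params`.
#' @export
boost_params <- function(nrounds = 500, max_depth = 6, eta = 0.05,
                         lambda = 1, gamma = 0, alpha = 0, subsample = 1,
                         nthread = 1, valid_fraction = 0.2, seed = 1) {
  structure(list(nrounds = nrounds, max_depth = max_depth, eta = eta,
                 lambda = lambda, gamma = gamma, alpha = alpha,
                 subsample = subsample, nthread = nthread,
                 valid_fraction = valid_fraction, seed = seed),
            class = "boost_params")
}

#' Fit the gradient-boosted trade-off intensity model
#'
#' Squared-error gradient boosting with second-order (Newton) leaf updates
#' and L1/L2 leaf regularization — an additive ensemble of regression trees
#' whose prediction is the sum of the per-tree outputs. Fit quality (RMSE
#' and R²) is evaluated on a seeded held-out split and stored with the
#' model; training itself uses all rows.
#'
#' @param table a `feature_table` (or data frame with an `intensity`
#'   column).
#' @param hyperparams a [boost_params()].
#' @param min_rows minimum accepted number of rows.
#' @return an object of class `tradeoff_model` with elements `booster`,
#'   `features`, `hyperparams`, `metrics`, `pair`, `year`.
#' @export
fit_tradeoff_model <- function(table, hyperparams = boost_params(),
                               min_rows = 50) {
  if (!"intensity" %in% names(table))
    stop("`table` must contain an `intensity` response column",
         call. = FALSE)
  if (nrow(table) < min_rows)
    stop(sprintf("need at least %d rows, got %d", min_rows, nrow(table)),
         call. = FALSE)
  y <- table$intensity
  if (any(!is.finite(y))) stop("response must be finite", call. = FALSE)
  feats <- setdiff(names(table), "intensity")
  X <- as.matrix(table[, feats, drop = FALSE])
  storage.mode(X) <- "double"

  old <- get_rng_state()
  set.seed(hyperparams$seed)
  n <- nrow(X)
  n_valid <- max(1, floor(hyperparams$valid_fraction * n))
  idx_valid <- sample.int(n, n_valid)
  restore_rng_state(old)

  params <- list(objective = "reg:squarederror",
                 max_depth = hyperparams$max_depth, eta = hyperparams$eta,
                 lambda = hyperparams$lambda, gamma = hyperparams$gamma,
                 alpha = hyperparams$alpha,
                 subsample = hyperparams$subsample,
                 nthread = hyperparams$nthread,
                 seed = hyperparams$seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = hyperparams$nthread)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = hyperparams$nrounds, verbose = 0)
  pred_valid <- stats::predict(booster, X[idx_valid, , drop = FALSE])
  resid <- y[idx_valid] - pred_valid
  ss_tot <- sum((y[idx_valid] - mean(y[idx_valid]))^2)
  metrics <- c(rmse = sqrt(mean(resid^2)),
               r_squared = if (ss_tot > 0) 1 - sum(resid^2) / ss_tot
                           else NA_real_,
               n_train = n, n_valid = n_valid)
  structure(list(booster = booster, features = feats,
                 hyperparams = hyperparams, metrics = metrics,
                 pair = attr(table, "pair"), year = attr(table, "year")),
            class = "tradeoff_model")
}

#' @export
print.tradeoff_model <- function(x, ...) {
  cat(sprintf("<tradeoff_model> %s (year %s): %d features\n",
              x$pair %||% "response", as.character(x$year %||% "?"),
              length(x$features)))
  cat(sprintf(
    "  %d rounds, depth %d, eta %g | held-out RMSE %.4g, R^2 %.3f\n",
    x$hyperparams$nrounds, x$hyperparams$max_depth, x$hyperparams$eta,
    x$metrics["rmse"], x$metrics["r_squared"]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' @export
predict.tradeoff_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  storage.mode(X) <- "double"
  stats::predict(object$booster, X)
}

#' Shapley additive attributions of the fitted model
#'
#' Per-row, per-feature additive contributions (tree-structured Shapley
#' values) satisfying local accuracy: every prediction equals the base value
#' plus the row's contributions, to within numerical tolerance. The base
#' value is the ensemble's expected prediction over the training background.
#'
#' @param model a [fit_tradeoff_model()] result.
#' @param table data frame with the model's feature columns.
#' @return an object of class `attribution`: list with `contributions`
#'   (matrix rows x features), `base_value`, `predictions`,
#'   `max_local_accuracy_residual`, `features`, `table`.
#' @export
shapley_attributions <- function(model, table) {
  miss <- setdiff(model$features, names(table))
  if (length(miss))
    stop("table is missing model feature column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  X <- as.matrix(table[, model$features, drop = FALSE])
  storage.mode(X) <- "double"
  contrib <- stats::predict(model$booster, X, predcontrib = TRUE)
  base_col <- ncol(contrib)
  base_value <- contrib[1, base_col]
  contributions <- contrib[, -base_col, drop = FALSE]
  colnames(contributions) <- model$features
  predictions <- stats::predict(model$booster, X)
  resid <- max(abs(base_value + rowSums(contributions) - predictions))
  structure(list(contributions = contributions, base_value = base_value,
                 predictions = predictions,
                 max_local_accuracy_residual = resid,
                 features = model$features,
                 table = table[, model$features, drop = FALSE]),
            class = "attribution")
}

#' @export
print.attribution <- function(x, ...) {
  cat(sprintf(
    "<attribution> %d rows x %d features; base value %.5g\n",
    nrow(x$contributions), ncol(x$contributions), x$base_value))
  cat(sprintf("  max local-accuracy residual: %.3g\n",
              x$max_local_accuracy_residual))
  invisible(x)
}

#' Rank drivers by mean absolute contribution
#'
#' Importance is the mean absolute Shapley contribution. The direction tag
#' ("promote" or "inhibit") is the sign of the mean signed contribution
#' among rows where the feature exceeds its median — the reading of a
#' beeswarm summary plot made operational.
#'
#' @param attr an [shapley_attributions()] result.
#' @return data frame `feature, importance, direction`, descending by
#'   importance.
#' @export
rank_drivers <- function(attr) {
  stopifnot(inherits(attr, "attribution"))
  imp <- colMeans(abs(attr$contributions))
  direction <- vapply(attr$features, function(f) {
    x <- attr$table[[f]]
    high <- x > stats::median(x)
    if (!any(high)) high <- x >= stats::median(x)
    m <- mean(attr$contributions[high, f])
    if (is.na(m) || m == 0) "neutral" else if (m > 0) "promote" else "inhibit"
  }, character(1))
  out <- data.frame(feature = attr$features, importance = unname(imp),
                    direction = unname(direction),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract promoting/suppressing thresholds from attribution curves
#'
#' For a continuous feature: bin the feature by quantiles, average the
#' contributions per bin, smooth with a centred moving average, and report
#' the locations where the smoothed curve changes sign and keeps the new
#' sign for at least `min_persistence` bins. Crossings are interpolated
#' linearly between bin centres; flanking intervals are labelled promoting
#' (positive contribution to trade-off intensity) or suppressing. For a
#' categorical feature the per-category mean contribution and its sign are
#' reported instead.
#'
#' @param attr an [shapley_attributions()] result.
#' @param table the feature table the attributions were computed on.
#' @param feature feature name.
#' @param bins number of quantile bins (>= 10).
#' @param smooth_window moving-average window (odd; 1 disables smoothing).
#' @param min_persistence bins a new sign must persist to count.
#' @return an object of class `threshold_report`: for continuous features a
#'   list with `feature`, `crossings` (increasing numeric), `intervals`
#'   (data frame `from, to, effect`), and the binned curve; for categorical
#'   features a per-category summary data frame.
#' @export
detect_thresholds <- function(attr, table, feature, bins = 50,
                              smooth_window = 3, min_persistence = 2) {
  stopifnot(inherits(attr, "attribution"))
  if (!feature %in% attr$features)
    stop("unknown feature: ", feature, call. = FALSE)
  x <- table[[feature]]
  phi <- attr$contributions[, feature]
  if (feature %in% (attr(table, "categorical") %||% CATEGORICAL_DRIVERS)) {
    agg <- tapply(phi, x, mean)
    out <- data.frame(category = as.numeric(names(agg)),
                      mean_contribution = as.numeric(agg),
                      effect = ifelse(agg > 0, "promoting", "suppressing"),
                      stringsAsFactors = FALSE)
    return(structure(list(feature = feature, type = "categorical",
                          categories = out), class = "threshold_report"))
  }
  if (bins < 10) stop("`bins` must be at least 10", call. = FALSE)
  if (length(unique(x)) < bins)
    stop("too few distinct values in ", feature, " for ", bins,
         " quantile bins", call. = FALSE)
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        names = FALSE)
  qs[1] <- qs[1] - .Machine$double.eps * max(1, abs(qs[1]))
  bin_id <- cut(x, breaks = unique(qs), include.lowest = TRUE,
                labels = FALSE)
  centres <- tapply(x, bin_id, mean)
  curve <- tapply(phi, bin_id, mean)
  if (smooth_window > 1) {
    k <- smooth_window %/% 2
    sm <- curve
    for (i in seq_along(curve)) {
      lo <- max(1, i - k); hi <- min(length(curve), i + k)
      sm[i] <- mean(curve[lo:hi])
    }
    curve <- sm
  }
  sgn <- sign(curve)
  sgn[sgn == 0] <- 1
  crossings <- numeric(0)
  run_start <- 1
  i <- 2
  while (i <= length(sgn)) {
    if (sgn[i] != sgn[i - 1]) {
      run_len <- 1
      j <- i + 1
      while (j <= length(sgn) && sgn[j] == sgn[i]) {
        run_len <- run_len + 1; j <- j + 1
      }
      if (run_len >= min_persistence || j > length(sgn)) {
        # linear interpolation of the zero between bin centres i-1 and i
        x0 <- centres[i - 1]; x1 <- centres[i]
        y0 <- curve[i - 1]; y1 <- curve[i]
        crossings <- c(crossings, x0 - y0 * (x1 - x0) / (y1 - y0))
        i <- i + 1
      } else {
        sgn[i:(j - 1)] <- sgn[i - 1]          # transient blip: ignore
        i <- j
      }
    } else i <- i + 1
  }
  edges <- c(min(x), crossings, max(x))
  seg_sign <- sgn[c(1, findInterval(crossings, centres) + 1)]
  intervals <- data.frame(
    from = edges[-length(edges)], to = edges[-1],
    effect = ifelse(seg_sign > 0, "promoting", "suppressing"),
    stringsAsFactors = FALSE
  )
  structure(list(feature = feature, type = "continuous",
                 crossings = unname(crossings), intervals = intervals,
                 bin_centres = as.numeric(centres),
                 bin_means = as.numeric(curve)),
            class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf("<threshold_report> %s (%s)\n", x$feature, x$type))
  if (x$type == "categorical") {
    print(x$categories, row.names = FALSE)
  } else if (!length(x$crossings)) {
    cat(sprintf("  no sign change; %s over the whole range\n",
                x$intervals$effect[1]))
  } else {
    cat("  crossings at:", paste(sprintf("%.4g", x$crossings),
                                 collapse = ", "), "\n")
    print(x$intervals, row.names = FALSE)
  }
  invisible(x)
}
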