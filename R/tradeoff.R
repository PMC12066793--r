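#' Min-max standardization over a declared domain
#'
#' `(v - min) / (max - min)` with the endpoints taken over the declared
#' standardization domain (by default the data themselves).
#'
#' @param v numeric vector.
#' @param domain_min,domain_max domain endpoints; `domain_max` must exceed
#'   `domain_min`.
#' @return standardized vector in `[0, 1]` (values inside the domain).
#' @export
minmax_standardize <- function(v, domain_min = min(v, na.rm = TRUE),
                               domain_max = max(v, na.rm = TRUE)) {
  if (!is.finite(domain_min) || !is.finite(domain_max) ||
      domain_max <= domain_min)
    stop("degenerate standardization domain (max must exceed min)",
         call. = FALSE)
  (v - domain_min) / (domain_max - domain_min)
}

#' Partial correlation by recursive elimination of controls
#'
#' Order-0 is the Pearson correlation; order-1 removes one control via
#' `r12.3 = (r12 - r13 r23) / sqrt((1 - r13^2)(1 - r23^2))`; higher orders
#' apply the same recursion, eliminating one control at a time. The result
#' is invariant under affine rescaling of any input.
#'
#' @param a,b numeric vectors of equal length.
#' @param controls list of control vectors (possibly empty).
#' @return partial correlation in `[-1, 1]`; `NA` with a warning if any
#'   input has zero variance.
#' @export
partial_correlation <- function(a, b, controls = list()) {
  if (is.numeric(controls)) controls <- list(controls)
  n <- length(a)
  vars <- c(list(a, b), controls)
  if (any(lengths(vars) != n))
    stop("all inputs must have equal length", call. = FALSE)
  g <- length(controls)
  if (n - 2 - g < 1)
    stop(sprintf(
      "insufficient observations: need n - 2 - g >= 1 (n = %d, g = %d)",
      n, g), call. = FALSE)
  if (any(vapply(vars, stats::sd, numeric(1)) == 0)) {
    warning("zero-variance input: partial correlation undefined")
    return(NA_real_)
  }
  X <- do.call(cbind, vars)
  pcor_recursive(stats::cor(X), 1L, 2L, seq_len(g) + 2L)
}

# first-order elimination applied recursively on a correlation matrix
pcor_recursive <- function(R, i, j, ctrl) {
  if (!length(ctrl)) return(R[i, j])
  k <- ctrl[length(ctrl)]
  rest <- ctrl[-length(ctrl)]
  rij <- pcor_recursive(R, i, j, rest)
  rik <- pcor_recursive(R, i, k, rest)
  rjk <- pcor_recursive(R, j, k, rest)
  denom <- sqrt((1 - rik^2) * (1 - rjk^2))
  if (denom <= 0) return(NA_real_)
  max(min((rij - rik * rjk) / denom, 1), -1)
}

#' Two-sided p-value for a (partial) correlation coefficient
#'
#' `t = r * sqrt((n - 2 - g) / (1 - r^2))` referred to the t distribution
#' with `n - 2 - g` degrees of freedom.
#'
#' @param r correlation coefficient(s), `|r| <= 1` (vectorized).
#' @param n number of observations.
#' @param g number of controlled variables.
#' @return two-sided p-value(s) in `[0, 1]`.
#' @export
correlation_pvalue <- function(r, n, g = 0) {
  df <- n - 2 - g
  if (df < 1)
    stop("insufficient degrees of freedom: need n - 2 - g >= 1",
         call. = FALSE)
  if (any(abs(r[!is.na(r)]) > 1))
    stop("|r| must not exceed 1", call. = FALSE)
  p <- rep(NA_real_, length(r))
  degen <- !is.na(r) & abs(r) == 1
  if (any(degen)) {
    warning("|r| = 1: degenerate p-value 0")
    p[degen] <- 0
  }
  ok <- !is.na(r) & !degen
  t <- r[ok] * sqrt(df / (1 - r[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(t), df)
  if (length(r) == 1) p[[1]] else p
}

#' Classify a pairwise relationship as synergy, trade-off or non-significant
#'
#' Synergy: `r > 0` and `p < alpha`; trade-off: `r < 0` and `p < alpha`;
#' otherwise non-significant. Integer codes: 1 synergy, -1 trade-off,
#' 0 non-significant.
#'
#' @param r correlation coefficient(s).
#' @param p p-value(s) in `[0, 1]`.
#' @param alpha significance level, default 0.05.
#' @return integer vector of category codes (`NA` where `r` or `p` is `NA`).
#' @export
classify_relationship <- function(r, p, alpha = 0.05) {
  if (any(p[!is.na(p)] < 0 | p[!is.na(p)] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- integer(length(r))
  out[is.na(r) | is.na(p)] <- NA_integer_
  sig <- !is.na(r) & !is.na(p) & p < alpha
  out[sig & r > 0] <- 1L
  out[sig & r < 0] <- -1L
  out
}

#' @rdname classify_relationship
#' @details `significance_stars()` reproduces the reporting convention used
#'   in some trade-off studies (`*` for p > 0.1, `**` for 0.05 < p <= 0.1,
#'   `***` for p <= 0.05); it is a formatting helper only — classification
#'   always uses raw p against `alpha`.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p > 0.1, "*", ifelse(p > 0.05, "**", "***")))
}

#' Root-mean-square deviation of standardized service values
#'
#' `RMSD = sqrt(sum((v - mean(v))^2) / (n - 1))` over the `n` standardized
#' service values of one unit; permutation-invariant and 0 when all services
#' agree. For two services in `[0, 1]` the maximum is `sqrt(0.5)`.
#'
#' @param std_values numeric vector of standardized values (length >= 2).
#' @return non-negative scalar.
#' @export
rmsd <- function(std_values) {
  n <- length(std_values)
  if (n < 2) stop("RMSD needs at least two services", call. = FALSE)
  sqrt(sum((std_values - mean(std_values))^2) / (n - 1))
}

# ---- pixel-wise machinery --------------------------------------------------

service_matrix <- function(es_list, service) {
  do.call(cbind, lapply(es_list, function(e)
    as.vector(e$services[[service]]$values)))
}

rowwise_cor <- function(A, B) {
  Ac <- A - rowMeans(A); Bc <- B - rowMeans(B)
  num <- rowSums(Ac * Bc)
  den <- sqrt(rowSums(Ac^2) * rowSums(Bc^2))
  out <- num / den
  out[den == 0] <- NA_real_
  pmin(pmax(out, -1), 1)
}

# second-order partial correlation of (1,2) given (3,4), all elementwise
rowwise_pcor2 <- function(r12, r13, r23, r14, r24, r34) {
  p1 <- function(rij, rik, rjk) {
    den <- sqrt((1 - rik^2) * (1 - rjk^2))
    out <- (rij - rik * rjk) / den
    out[den <= 0] <- NA_real_
    pmin(pmax(out, -1), 1)
  }
  r12.3 <- p1(r12, r13, r23)
  r14.3 <- p1(r14, r13, r34)
  r24.3 <- p1(r24, r23, r34)
  p1(r12.3, r14.3, r24.3)
}

#' Map pairwise trade-offs and synergies
#'
#' Two analysis modes. `"temporal"` correlates the two services across years
#' separately at every pixel, controlling for the remaining services
#' (second-order partial correlation when all four are present), and returns
#' rasters of r, p and category plus the fraction of valid pixels per
#' category. `"spatial"` correlates the two services across valid pixels
#' within each year (again controlling for the others) and returns one row
#' per year.
#'
#' @param es_list list of `es_layers` (one per year, from [quantify_all()]).
#' @param pair character vector of two service names from
#'   `c("WY", "SC", "WS", "HQ")`.
#' @param mode `"temporal"` or `"spatial"`.
#' @param alpha significance level for the category rule.
#' @param controls service names to control for; default all remaining
#'   services.
#' @return `"temporal"`: an object of class `tradeoff_maps` (rasters `r`,
#'   `p`, `category` + `fractions`); `"spatial"`: a data frame of class
#'   `pair_relation` with columns `pair, year, mode, n, g, r, p, category`.
#' @export
tradeoff_map <- function(es_list, pair, mode = c("temporal", "spatial"),
                         alpha = 0.05, controls = NULL) {
  mode <- match.arg(mode)
  services <- names(es_list[[1]]$services)
  if (length(pair) != 2 || !all(pair %in% services))
    stop("`pair` must name two of: ", paste(services, collapse = ", "),
         call. = FALSE)
  if (is.null(controls)) controls <- setdiff(services, pair)
  g <- length(controls)
  n_years <- length(es_list)
  template <- es_list[[1]]$services[[pair[1]]]

  if (mode == "temporal") {
    if (n_years - 2 - g < 1)
      stop(sprintf(paste0(
        "temporal mode needs n_years - 2 - g >= 1 degrees of freedom ",
        "(n_years = %d, g = %d)"), n_years, g), call. = FALSE)
    M <- lapply(c(pair, controls), service_matrix, es_list = es_list)
    r <- if (g == 0) {
      rowwise_cor(M[[1]], M[[2]])
    } else if (g == 1) {
      r12 <- rowwise_cor(M[[1]], M[[2]])
      r13 <- rowwise_cor(M[[1]], M[[3]])
      r23 <- rowwise_cor(M[[2]], M[[3]])
      den <- sqrt((1 - r13^2) * (1 - r23^2))
      out <- (r12 - r13 * r23) / den
      out[den <= 0] <- NA_real_
      pmin(pmax(out, -1), 1)
    } else if (g == 2) {
      rowwise_pcor2(rowwise_cor(M[[1]], M[[2]]),
                    rowwise_cor(M[[1]], M[[3]]),
                    rowwise_cor(M[[2]], M[[3]]),
                    rowwise_cor(M[[1]], M[[4]]),
                    rowwise_cor(M[[2]], M[[4]]),
                    rowwise_cor(M[[3]], M[[4]]))
    } else stop("temporal mode supports at most two controls", call. = FALSE)
    valid <- Reduce(`&`, lapply(M, function(m) rowSums(is.na(m)) == 0))
    r[!valid] <- NA_real_
    p <- rep(NA_real_, length(r))
    suppressWarnings(p[!is.na(r)] <-
                       correlation_pvalue(r[!is.na(r)], n_years, g))
    cat_codes <- classify_relationship(r, p, alpha)
    shape <- dim(template$values)
    as_grid <- function(v, categorical = FALSE)
      raster_grid(matrix(v, shape[1], shape[2]), template$xll, template$yll,
                  template$cell_size, categorical = categorical)
    n_valid <- sum(!is.na(cat_codes))
    fractions <- c(
      tradeoff = sum(cat_codes == -1L, na.rm = TRUE) / n_valid,
      synergy = sum(cat_codes == 1L, na.rm = TRUE) / n_valid,
      nonsignificant = sum(cat_codes == 0L, na.rm = TRUE) / n_valid
    )
    structure(list(pair = pair, mode = mode, alpha = alpha, g = g,
                   n = n_years, r = as_grid(r), p = as_grid(p),
                   category = as_grid(as.numeric(cat_codes),
                                      categorical = TRUE),
                   fractions = fractions),
              class = "tradeoff_maps")
  } else {
    rows <- lapply(es_list, function(e) {
      vals <- lapply(c(pair, controls), function(s)
        as.vector(e$services[[s]]$values))
      ok <- Reduce(`&`, lapply(vals, function(v) !is.na(v)))
      vals <- lapply(vals, `[`, ok)
      r <- partial_correlation(vals[[1]], vals[[2]], vals[-(1:2)])
      p <- if (is.na(r)) NA_real_ else
        suppressWarnings(correlation_pvalue(r, sum(ok), g))
      data.frame(pair = paste(pair, collapse = "-"), year = e$year,
                 mode = mode, n = sum(ok), g = g, r = r, p = p,
                 category = c("tradeoff", "nonsignificant", "synergy")[
                   classify_relationship(r, p, alpha) + 2L],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("pair_relation", class(out))
    out
  }
}

#' @export
print.tradeoff_maps <- function(x, ...) {
  cat(sprintf(
    "<tradeoff_maps> %s, %s mode, n = %d, order g = %d, alpha = %g\n",
    paste(x$pair, collapse = "-"), x$mode, x$n, x$g, x$alpha))
  cat(sprintf("  pixels: %.1f%% tradeoff, %.1f%% synergy, %.1f%% n.s.\n",
              100 * x$fractions["tradeoff"], 100 * x$fractions["synergy"],
              100 * x$fractions["nonsignificant"]))
  invisible(x)
}

#' Map trade-off intensity as pixel-wise RMSD
#'
#' Each service is min-max standardized over the declared domain (by default
#' its own valid pixels within the chosen year; `"all_years"` standardizes
#' over the pooled years), then the per-pixel [rmsd()] of the services'
#' standardized values is mapped. For a pair this equals
#' `|v1 - v2| / sqrt(2)`. Passing more than two services gives the
#' multi-service overall intensity.
#'
#' @param es_list list of `es_layers`.
#' @param pair two (or more) service names.
#' @param year year index (matching `es_layers$year`); default the last.
#' @param domain standardization domain: `"year"` or `"all_years"`.
#' @return an object of class `intensity_map`: list with the RMSD
#'   [raster_grid] (`$rmsd`), the pair, year and domain descriptor.
#' @export
rmsd_map <- function(es_list, pair, year = NULL,
                     domain = c("year", "all_years")) {
  domain <- match.arg(domain)
  years <- vapply(es_list, `[[`, numeric(1), "year")
  if (is.null(year)) year <- years[length(years)]
  e <- es_list[[match(year, years)]]
  if (length(pair) < 2) stop("need at least two services", call. = FALSE)
  std <- lapply(pair, function(s) {
    v <- as.vector(e$services[[s]]$values)
    dom <- if (domain == "year") v else
      unlist(lapply(es_list, function(ee)
        as.vector(ee$services[[s]]$values)))
    minmax_standardize(v, min(dom, na.rm = TRUE), max(dom, na.rm = TRUE))
  })
  S <- do.call(cbind, std)
  n <- ncol(S)
  mu <- rowMeans(S)
  out <- sqrt(rowSums((S - mu)^2) / (n - 1))
  tpl <- e$services[[pair[1]]]
  grid <- raster_grid(matrix(out, nrow(tpl$values), ncol(tpl$values)),
                      tpl$xll, tpl$yll, tpl$cell_size)
  structure(list(pair = pair, year = year, domain = domain, rmsd = grid),
            class = "intensity_map")
}

#' @export
print.intensity_map <- function(x, ...) {
  v <- x$rmsd$values[!is.na(x$rmsd$values)]
  cat(sprintf("<intensity_map> %s, year %d (domain: %s)\n",
              paste(x$pair, collapse = "-"), x$year, x$domain))
  cat(sprintf("  RMSD: mean %.4f, max %.4f (theoretical max %.5f for 2 ",
              mean(v), max(v), sqrt(0.5)))
  cat("services)\n")
  invisible(x)
}
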