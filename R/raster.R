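#' Gridded raster field with affine georeferencing
#'
#' `raster_grid` is the elementary spatial container of the package: a numeric
#' matrix of cell values on a regular north-up grid, together with the lower-left
#' corner coordinates and the (square) cell size in metres. Row 1 is the
#' northern edge; values are stored row-major from north to south. Missing
#' (`NA`) cells are the nodata mask. Every multi-raster operation in the
#' package requires its inputs to share shape, transform and mask.
#'
#' @param values numeric matrix of cell values; `NA` marks nodata.
#' @param xll,yll coordinates of the lower-left corner of the grid (metres).
#' @param cell_size cell edge length in metres; must be positive.
#' @param categorical logical; `TRUE` for integer-coded class rasters
#'   (land use, soil type, landform type). Categorical rasters are resampled
#'   by nearest neighbour only and written as integers.
#'
#' @return an object of class `raster_grid`.
#' @examples
#' g <- raster_grid(matrix(runif(12), 3, 4), cell_size = 100)
#' dim(g)
#' @export
raster_grid <- function(values, xll = 0, yll = 0, cell_size = 1000,
                        categorical = FALSE) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number", call. = FALSE)
  structure(
    list(values = values, xll = as.numeric(xll), yll = as.numeric(yll),
         cell_size = as.numeric(cell_size), categorical = isTRUE(categorical)),
    class = "raster_grid"
  )
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<raster_grid> %d x %d cells, %.6g m resolution%s\n",
              d[1], d[2], x$cell_size,
              if (x$categorical) " (categorical)" else ""))
  cat(sprintf("  origin (xll, yll): (%.6g, %.6g); nodata: %d cells\n",
              x$xll, x$yll, sum(is.na(x$values))))
  if (length(v))
    cat(sprintf("  values: min %.6g, mean %.6g, max %.6g\n",
                min(v), mean(v), max(v)))
  invisible(x)
}

#' @export
summary.raster_grid <- function(object, ...) {
  v <- object$values[!is.na(object$values)]
  c(n_valid = length(v), n_nodata = sum(is.na(object$values)),
    min = if (length(v)) min(v) else NA_real_,
    mean = if (length(v)) mean(v) else NA_real_,
    max = if (length(v)) max(v) else NA_real_)
}

#' @export
plot.raster_grid <- function(x, main = NULL, ...) {
  # image() draws column-major bottom-up; flip rows so north stays on top
  z <- t(x$values[nrow(x$values):1, , drop = FALSE])
  xs <- x$xll + (seq_len(nrow(z)) - 0.5) * x$cell_size
  ys <- x$yll + (seq_len(ncol(z)) - 0.5) * x$cell_size
  graphics::image(xs, ys, z, asp = 1, xlab = "x (m)", ylab = "y (m)",
                  main = main, ...)
  invisible(x)
}

nodata_mask <- function(g) is.na(g$values)

#' @rdname raster_grid
#' @param x object to test.
#' @export
is_raster_grid <- function(x) inherits(x, "raster_grid")

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

stop_if_misaligned <- function(rasters, what = "rasters") {
  ref <- rasters[[1]]
  ok <- vapply(rasters, same_grid, logical(1), b = ref)
  if (!all(ok))
    stop(sprintf("%s do not share shape and transform", what), call. = FALSE)
  invisible(NULL)
}

# Elementwise combination of aligned rasters; mask is the union of input masks.
rg_map <- function(f, ..., template = NULL, categorical = FALSE) {
  gs <- Filter(is_raster_grid, list(...))
  if (!length(gs)) stop("rg_map() needs at least one raster_grid input")
  stop_if_misaligned(gs)
  ref <- if (is.null(template)) gs[[1]] else template
  args <- lapply(list(...), function(a) if (is_raster_grid(a)) a$values else a)
  out <- do.call(f, args)
  dim(out) <- dim(ref$values)       # elementwise ops may drop matrix dims
  mask <- Reduce(`|`, lapply(gs, nodata_mask))
  out[mask] <- NA_real_
  raster_grid(out, ref$xll, ref$yll, ref$cell_size, categorical = categorical)
}

#' Read and write Arc/Info ASCII grid rasters
#'
#' The package interchanges rasters in the ESRI ASCII grid format (`.asc`):
#' a six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by whitespace-separated cell values, north row
#' first. The format is plain text, supported by all common GIS software.
#'
#' @param grid a [raster_grid].
#' @param path file path ending in `.asc`.
#' @param digits significant digits written for continuous rasters;
#'   categorical rasters are written as integers.
#' @return `write_asc()` returns `path` invisibly; `read_asc()` returns a
#'   [raster_grid].
#' @export
write_asc <- function(grid, path, digits = 7) {
  stopifnot(is_raster_grid(grid))
  v <- grid$values
  nodata <- -9999
  if (any(v[!is.na(v)] == nodata))
    nodata <- floor(min(v, na.rm = TRUE)) - 1
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$xll),
    sprintf("yllcorner %.10g", grid$yll),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %g", nodata)
  )
  body <- v
  body[is.na(body)] <- nodata
  fmt <- if (grid$categorical) "%d" else paste0("%.", digits, "g")
  lines <- apply(body, 1L, function(row) {
    if (grid$categorical) row <- as.integer(round(row))
    paste(sprintf(fmt, row), collapse = " ")
  })
  con <- file(path, "wb")  # binary mode: LF endings, byte-stable checksums
  on.exit(close(con))
  writeLines(c(hdr, lines), con, sep = "\n")
  invisible(path)
}

#' @rdname write_asc
#' @param categorical logical passed to [raster_grid()] on read.
#' @export
read_asc <- function(path, categorical = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "[[:space:]]+")
  key <- tolower(vapply(kv, `[`, "", 1L))
  val <- as.numeric(vapply(kv, `[`, "", 2L))
  names(val) <- key
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% key))
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  vals <- scan(path, what = double(), skip = 6L, quiet = TRUE)
  nr <- as.integer(val["nrows"]); nc <- as.integer(val["ncols"])
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d cells in %s, found %d", nr * nc, path,
                 length(vals)), call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == val["nodata_value"]] <- NA_real_
  raster_grid(m, val["xllcorner"], val["yllcorner"], val["cellsize"],
              categorical = categorical)
}

#' Resample rasters onto a common reference grid
#'
#' Aligns a list of rasters to the grid of `reference`. Rasters already on the
#' reference grid are returned unchanged (bitwise). Continuous rasters may be
#' resampled bilinearly; categorical rasters must use nearest-neighbour.
#' Output cells whose source support falls outside the source extent, or whose
#' contributing source cells are nodata, are nodata.
#'
#' @param rasters a [raster_grid] or list of them.
#' @param reference [raster_grid] defining the target grid.
#' @param resampling `"nearest"` or `"bilinear"`.
#' @return a list of aligned [raster_grid]s (a single raster if a single
#'   raster was supplied).
#' @export
align_rasters <- function(rasters, reference,
                          resampling = c("nearest", "bilinear")) {
  resampling <- match.arg(resampling)
  single <- is_raster_grid(rasters)
  if (single) rasters <- list(rasters)
  out <- lapply(rasters, align_one, reference = reference,
                resampling = resampling)
  if (single) out[[1]] else out
}

align_one <- function(r, reference, resampling) {
  if (!is_raster_grid(r)) stop("inputs must be raster_grid objects")
  if (same_grid(r, reference)) return(r)
  if (r$categorical && resampling == "bilinear")
    stop("bilinear resampling is not valid for a categorical raster; ",
         "use resampling = \"nearest\"", call. = FALSE)
  nr <- nrow(reference$values); nc <- ncol(reference$values)
  # target cell-centre coordinates
  cx <- reference$xll + (seq_len(nc) - 0.5) * reference$cell_size
  cy_top <- reference$yll + (nr - seq_len(nr) + 0.5) * reference$cell_size
  # fractional (row, col) position in the source grid, 1-based cell centres
  src_nr <- nrow(r$values); src_nc <- ncol(r$values)
  fc <- (rep(cx, each = nr) - r$xll) / r$cell_size + 0.5
  fr <- (r$yll + src_nr * r$cell_size - rep(cy_top, nc)) / r$cell_size + 0.5
  inside <- fr >= 0.5 & fr <= src_nr + 0.5 & fc >= 0.5 & fc <= src_nc + 0.5
  if (!any(inside))
    stop("raster extent does not overlap the reference grid", call. = FALSE)
  out <- rep(NA_real_, nr * nc)
  if (resampling == "nearest") {
    ri <- pmin(pmax(round(fr), 1L), src_nr)
    ci <- pmin(pmax(round(fc), 1L), src_nc)
    out[inside] <- r$values[cbind(ri, ci)][inside]
  } else {
    i0 <- pmin(pmax(floor(fr), 1), src_nr); i1 <- pmin(i0 + 1, src_nr)
    j0 <- pmin(pmax(floor(fc), 1), src_nc); j1 <- pmin(j0 + 1, src_nc)
    wr <- pmin(pmax(fr - i0, 0), 1); wc <- pmin(pmax(fc - j0, 0), 1)
    v00 <- r$values[cbind(i0, j0)]; v01 <- r$values[cbind(i0, j1)]
    v10 <- r$values[cbind(i1, j0)]; v11 <- r$values[cbind(i1, j1)]
    est <- (1 - wr) * ((1 - wc) * v00 + wc * v01) +
      wr * ((1 - wc) * v10 + wc * v11)
    out[inside] <- est[inside]
  }
  m <- matrix(out, nrow = nr, ncol = nc)
  raster_grid(m, reference$xll, reference$yll, reference$cell_size,
              categorical = r$categorical)
}

#' Moran's I spatial autocorrelation of a raster
#'
#' Global Moran's I with rook (4-neighbour) contiguity weights, used as a
#' diagnostic that generated fields carry the intended spatial structure.
#' Nodata cells are excluded; only neighbour pairs with both cells valid
#' contribute.
#'
#' @param grid a [raster_grid].
#' @return Moran's I (scalar).
#' @export
morans_i <- function(grid) {
  stopifnot(is_raster_grid(grid))
  v <- grid$values
  ok <- !is.na(v)
  z <- v - mean(v[ok])
  z[!ok] <- 0
  pair_sum <- function(a, b, oka, okb) sum(a * b * oka * okb)
  num <- 0; w <- 0
  # horizontal and vertical neighbour pairs, each counted in both directions
  nr <- nrow(v); nc <- ncol(v)
  if (nc > 1) {
    a <- z[, -nc, drop = FALSE]; b <- z[, -1, drop = FALSE]
    oa <- ok[, -nc, drop = FALSE]; ob <- ok[, -1, drop = FALSE]
    num <- num + 2 * pair_sum(a, b, oa, ob); w <- w + 2 * sum(oa & ob)
  }
  if (nr > 1) {
    a <- z[-nr, , drop = FALSE]; b <- z[-1, , drop = FALSE]
    oa <- ok[-nr, , drop = FALSE]; ob <- ok[-1, , drop = FALSE]
    num <- num + 2 * pair_sum(a, b, oa, ob); w <- w + 2 * sum(oa & ob)
  }
  n <- sum(ok)
  denom <- sum(z[ok]^2)
  if (denom == 0 || w == 0) return(NA_real_)
  (n / w) * (num / denom)
}
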