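## Species climate-range summaries: occurrence thinning, value extraction
## from regular lon/lat grids, range percentiles, and order-statistic
## maximum height.

#' Plain-text climate grids
#'
#' Regular lon/lat grids in the common 6-line-header plain-text layout
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`,
#' then one matrix row per line, northernmost row first).
#'
#' @param file path to a grid file.
#' @return `read_grid`: object of class `climate_grid` (list with `values`
#'   matrix, `xll`, `yll`, `cellsize`, `nodata`).
#' @export
read_grid <- function(file) {
  hdr <- readLines(file, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  val <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  m <- as.matrix(utils::read.table(file, skip = 6))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == val[["nrows"]], ncol(m) == val[["ncols"]])
  m[m == val[["nodata_value"]]] <- NA
  structure(list(values = m, xll = val[["xllcorner"]], yll = val[["yllcorner"]],
                 cellsize = val[["cellsize"]], nodata = val[["nodata_value"]]),
            class = "climate_grid")
}

#' @rdname read_grid
#' @param grid a `climate_grid`.
#' @export
write_grid <- function(grid, file) {
  m <- grid$values
  m[is.na(m)] <- grid$nodata
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           paste("xllcorner", format(grid$xll, digits = 12)),
           paste("yllcorner", format(grid$yll, digits = 12)),
           paste("cellsize", format(grid$cellsize, digits = 12)),
           paste("NODATA_value", grid$nodata))
  writeLines(c(hdr, apply(m, 1, paste, collapse = " ")), file)
  invisible(file)
}

#' Build a climate grid from a value function
#'
#' Evaluates `f(lon, lat)` at every cell center; convenient for synthetic
#' layers with closed-form truth.
#'
#' @param f vectorized function of (lon, lat).
#' @param xll,yll lower-left corner (degrees).
#' @param cellsize cell size (degrees).
#' @param ncols,nrows grid dimensions.
#' @param nodata sentinel value (default -9999).
#' @return a `climate_grid`.
#' @export
grid_from_function <- function(f, xll, yll, cellsize, ncols, nrows,
                               nodata = -9999) {
  lon <- xll + (seq_len(ncols) - 0.5) * cellsize
  lat <- yll + (nrows - seq_len(nrows) + 0.5) * cellsize  # top row first
  vals <- outer(lat, lon, f2 <- function(la, lo) f(lo, la))
  structure(list(values = vals, xll = xll, yll = yll, cellsize = cellsize,
                 nodata = nodata), class = "climate_grid")
}

#' Nearest-cell extraction of grid values at points
#'
#' @param grid a `climate_grid`.
#' @param lon,lat coordinate vectors (degrees).
#' @return numeric vector; NA for points outside the grid or on nodata cells.
#' @export
extract_at_points <- function(grid, lon, lat) {
  stopifnot(length(lon) == length(lat))
  m <- grid$values
  col <- floor((lon - grid$xll) / grid$cellsize) + 1L
  row_from_bottom <- floor((lat - grid$yll) / grid$cellsize) + 1L
  row <- nrow(m) - row_from_bottom + 1L
  ok <- col >= 1 & col <= ncol(m) & row >= 1 & row <= nrow(m) &
    !is.na(col) & !is.na(row)
  out <- rep(NA_real_, length(lon))
  out[ok] <- m[cbind(row[ok], col[ok])]
  out
}

#' Spatially thin occurrence points
#'
#' Greedy pass over a seed-shuffled point order, keeping each point only if
#' it lies at least `min_dist_km` (great-circle, Earth radius 6371 km) from
#' every point kept so far; if more than `max_n` survive, a seeded random
#' subsample of `max_n` is kept. Deterministic given `seed`, and idempotent:
#' thinning its own output changes nothing beyond order.
#'
#' @param lon,lat coordinate vectors (degrees).
#' @param max_n maximum number of points to keep (default 15000).
#' @param min_dist_km minimum pairwise spacing in km (default 10).
#' @param seed integer RNG seed.
#' @return integer vector of kept indices into the input.
#' @export
thin_occurrences <- function(lon, lat, max_n = 15000, min_dist_km = 10, seed) {
  stopifnot(length(lon) == length(lat),
            all(lon >= -180 & lon <= 180), all(lat >= -90 & lat <= 90))
  n <- length(lon)
  if (n == 0) return(integer())
  set.seed(as.integer(seed))
  ord <- sample.int(n)
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0L) { kept <- i; next }
    d <- geosphere::distHaversine(cbind(lon[i], lat[i]),
                                  cbind(lon[kept], lat[kept]), r = 6371)
    if (all(d >= min_dist_km)) kept <- c(kept, i)
  }
  if (length(kept) > max_n) kept <- sort(sample(kept, max_n))
  sort(kept)
}

#' Range percentile of extracted climate values
#'
#' Linear-interpolation percentile (the R default convention) over
#' non-missing values; used for the 5th percentile of the aridity index and
#' of minimum daily temperature across a species' range.
#'
#' @param values numeric vector, possibly with NAs.
#' @param q probability in (0, 1), default 0.05.
#' @return the percentile value.
#' @export
range_percentile <- function(values, q = 0.05) {
  stopifnot(q > 0, q < 1)
  v <- values[!is.na(values)]
  if (length(v) == 0) stop("no non-missing values to summarize")
  stats::quantile(v, q, names = FALSE, type = 7)
}

#' Maximum height from a record set
#'
#' Prefers an allometric-model asymptotic height when available; otherwise
#' drops outlier-flagged records and, if at least `min_records` remain,
#' returns the height of the `rank`-th tallest individual (an order statistic
#' robust to extreme-measurement error). Species with too few records are
#' excluded with a recorded reason.
#'
#' @param heights numeric vector of individual heights (m).
#' @param outlier_flag logical vector (TRUE = drop), optional.
#' @param model_hmax optional allometric-model maximum height (m).
#' @param rank order statistic rank from the top (default 10).
#' @param min_records minimum records required (default 100).
#' @return list with `hmax` (or NA), `source`
#'   ("model" / "order_statistic" / "excluded"), `reason`, `n_used`.
#' @export
max_height_estimate <- function(heights = numeric(), outlier_flag = NULL,
                                model_hmax = NA, rank = 10, min_records = 100) {
  if (!is.na(model_hmax))
    return(list(hmax = model_hmax, source = "model", reason = NA_character_,
                n_used = length(heights)))
  if (!is.null(outlier_flag)) heights <- heights[!outlier_flag]
  heights <- heights[!is.na(heights)]
  if (length(heights) < min_records)
    return(list(hmax = NA_real_, source = "excluded",
                reason = sprintf("fewer than %d records", min_records),
                n_used = length(heights)))
  list(hmax = sort(heights, decreasing = TRUE)[rank],
       source = "order_statistic", reason = NA_character_,
       n_used = length(heights))
}

#' Climate summary of one species' occurrences
#'
#' Thins the occurrences, extracts each supplied grid at the kept points and
#' reports means for MAP/MAT-type layers and a low percentile for extreme
#' layers (aridity index, minimum temperature).
#'
#' @param lon,lat occurrence coordinates.
#' @param grids named list of `climate_grid`s; names ending in `_p05` (or
#'   listed in `percentile_layers`) are summarized by [range_percentile()],
#'   the rest by the mean.
#' @param percentile_layers names of layers to summarize by percentile.
#' @param q percentile (default 0.05).
#' @param max_n,min_dist_km,seed thinning parameters (see
#'   [thin_occurrences()]).
#' @return one-row data.frame: one column per layer plus `n_points_used`.
#' @export
species_climate_summary <- function(lon, lat, grids,
                                    percentile_layers = c("ai", "tmin"),
                                    q = 0.05, max_n = 15000, min_dist_km = 10,
                                    seed = 1) {
  keep <- thin_occurrences(lon, lat, max_n, min_dist_km, seed)
  out <- list(n_points_used = length(keep))
  for (nm in names(grids)) {
    v <- extract_at_points(grids[[nm]], lon[keep], lat[keep])
    out[[if (nm %in% percentile_layers) paste0(nm, "_p05") else
      paste0(nm, "_mean")]] <-
      if (nm %in% percentile_layers) range_percentile(v, q) else mean(v, na.rm = TRUE)
  }
  as.data.frame(out)
}
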