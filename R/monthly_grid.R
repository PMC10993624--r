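#' Monthly gridded stack
#'
#' The shared container for all gridded monthly variables (NDVI, SPEI-k,
#' precipitation, ...): a `rows x cols x time` numeric array at a strictly
#' monthly time step, with pixel-centre georeferencing. Missing observations
#' are `NA` and are excluded from every downstream statistic.
#'
#' @param values numeric array `[row, col, time]`; row 1 / col 1 is the
#'   north-west cell.
#' @param start_year,start_month calendar date of the first time slice.
#' @param geotransform list with `xll`, `yll` (lower-left corner, degrees)
#'   and `cellsize` (degrees).
#' @param variable variable name (used in file naming).
#' @param units free-text unit string.
#'
#' @return An object of class `monthly_grid`.
#' @export
monthly_grid <- function(values, start_year, start_month = 1L,
                         geotransform = list(xll = 0, yll = 0, cellsize = 0.05),
                         variable = "var", units = "") {
  values <- as.array(values)
  stopifnot(length(dim(values)) == 3L,
            start_month %in% 1:12,
            all(c("xll", "yll", "cellsize") %in% names(geotransform)),
            geotransform$cellsize > 0)
  g <- structure(list(
    values = values,
    start_year = as.integer(start_year),
    start_month = as.integer(start_month),
    geotransform = geotransform,
    variable = variable,
    units = units
  ), class = "monthly_grid")
  g
}

#' @export
print.monthly_grid <- function(x, ...) {
  d <- dim(x$values)
  ti <- time_index(x)
  cat(sprintf("<monthly_grid> %s [%s]\n", x$variable,
              if (nzchar(x$units)) x$units else "unitless"))
  cat(sprintf("  %d x %d cells, %d months (%04d-%02d .. %04d-%02d)\n",
              d[1], d[2], d[3], ti$year[1], ti$month[1],
              ti$year[d[3]], ti$month[d[3]]))
  cat(sprintf("  cellsize %g deg, origin (%g, %g), %.1f%% missing\n",
              x$geotransform$cellsize, x$geotransform$xll, x$geotransform$yll,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Calendar index of a monthly grid
#'
#' @param g a `monthly_grid`.
#' @return data.frame with columns `year` and `month`, one row per time slice.
#' @export
time_index <- function(g) {
  nt <- dim(g$values)[3]
  m0 <- (g$start_year * 12L + (g$start_month - 1L)) + seq_len(nt) - 1L
  data.frame(year = m0 %/% 12L, month = m0 %% 12L + 1L)
}

n_times <- function(g) dim(g$values)[3]
grid_shape <- function(g) dim(g$values)[1:2]

#' Crop a monthly grid to a calendar span
#'
#' @param g a `monthly_grid`.
#' @param from,to `c(year, month)` vectors, inclusive.
#' @return a `monthly_grid` restricted to `[from, to]`.
#' @export
crop_time <- function(g, from, to) {
  ti <- time_index(g)
  key <- ti$year * 12L + ti$month
  k0 <- from[1] * 12 + from[2]; k1 <- to[1] * 12 + to[2]
  sel <- which(key >= k0 & key <= k1)
  if (length(sel) == 0L) stop("time crop leaves no months")
  monthly_grid(g$values[, , sel, drop = FALSE],
               ti$year[sel[1]], ti$month[sel[1]],
               g$geotransform, g$variable, g$units)
}

same_geometry <- function(a, b, tol = 1e-9) {
  all(grid_shape(a) == grid_shape(b)) &&
    abs(a$geotransform$xll - b$geotransform$xll) < tol &&
    abs(a$geotransform$yll - b$geotransform$yll) < tol &&
    abs(a$geotransform$cellsize - b$geotransform$cellsize) < tol
}

same_time_index <- function(a, b) {
  n_times(a) == n_times(b) &&
    a$start_year == b$start_year && a$start_month == b$start_month
}

stop_if_not_coregistered <- function(...) {
  gs <- list(...)
  ref <- gs[[1]]
  for (g in gs[-1]) {
    if (!same_geometry(ref, g))
      stop("grids are not co-registered: geometry mismatch between '",
           ref$variable, "' and '", g$variable, "'")
    if (!same_time_index(ref, g))
      stop("grids are not co-registered: time index mismatch between '",
           ref$variable, "' and '", g$variable, "'")
  }
  invisible(TRUE)
}

#' SPEI stack across accumulation scales 1-12
#'
#' Bundles twelve co-registered [monthly_grid]s of SPEI, one per accumulation
#' scale (months of trailing water balance entering the standardised index).
#'
#' @param grids list of exactly 12 `monthly_grid`s, in scale order 1..12.
#' @return An object of class `spei_stack`; `x$scales[[k]]` is SPEI-k.
#' @export
spei_stack <- function(grids) {
  stopifnot(is.list(grids), length(grids) == 12L)
  for (k in 2:12) stop_if_not_coregistered(grids[[1]], grids[[k]])
  structure(list(scales = grids), class = "spei_stack")
}

#' @export
print.spei_stack <- function(x, ...) {
  cat("<spei_stack> scales 1..12\n")
  print(x$scales[[1]])
  invisible(x)
}

#' Per-pixel phenology map
#'
#' @param greenup,peak integer matrices of calendar months (1-12); `NA` marks
#'   pixels with no usable phenology, which are excluded downstream.
#' @return An object of class `pheno_map`.
#' @export
pheno_map <- function(greenup, peak) {
  greenup <- as.matrix(greenup); peak <- as.matrix(peak)
  stopifnot(all(dim(greenup) == dim(peak)))
  bad <- function(m) any(!is.na(m) & (m < 1 | m > 12 | m != round(m)))
  if (bad(greenup) || bad(peak))
    stop("phenology months must be integers in 1..12 or NA")
  valid <- !is.na(greenup) & !is.na(peak)
  structure(list(greenup = greenup, peak = peak, valid = valid),
            class = "pheno_map")
}

#' Land-cover class codes
#'
#' Fixed coding shared by the whole package; majority-vote ties during
#' resampling are broken towards the lowest code.
#' @export
landcover_classes <- function() {
  c(shrubs = 1L, herbaceous = 2L, cropland = 3L, forest = 4L, other = 5L)
}

#' Categorical land-cover map
#'
#' @param class_code integer matrix of codes from [landcover_classes()].
#' @return An object of class `landcover_map`.
#' @export
landcover_map <- function(class_code) {
  class_code <- as.matrix(class_code)
  codes <- landcover_classes()
  if (any(!is.na(class_code) & !(class_code %in% codes)))
    stop("unknown land-cover code; allowed: ",
         paste(sprintf("%s=%d", names(codes), codes), collapse = ", "))
  structure(list(class_code = class_code), class = "landcover_map")
}

#' @export
print.landcover_map <- function(x, ...) {
  codes <- landcover_classes()
  tab <- table(factor(x$class_code, levels = codes, labels = names(codes)))
  cat("<landcover_map>", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}
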