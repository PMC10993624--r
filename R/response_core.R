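#' Moving-window specification
#'
#' @param width_years odd window width in years (default 5).
#' @param min_samples minimum valid (anomaly, SPEI) pairs for a window
#'   correlation (default 10).
#' @return object of class `window_spec`.
#' @export
window_spec <- function(width_years = 5L, min_samples = 10L) {
  width_years <- as.integer(width_years)
  if (width_years %% 2L != 1L || width_years < 1L)
    stop("width_years must be a positive odd integer")
  structure(list(width_years = width_years, min_samples = as.integer(min_samples)),
            class = "window_spec")
}

# Masked column-wise Pearson correlation between X and Y (both T x P with
# NAs); returns list(r, n) of length-P vectors. Zero-variance columns -> NA.
masked_pearson <- function(X, Y, min_n) {
  ok <- !is.na(X) & !is.na(Y)
  X0 <- ifelse(ok, X, 0); Y0 <- ifelse(ok, Y, 0)
  n <- colSums(ok)
  sx <- colSums(X0); sy <- colSums(Y0)
  sxx <- colSums(X0 * X0); syy <- colSums(Y0 * Y0); sxy <- colSums(X0 * Y0)
  vx <- n * sxx - sx^2; vy <- n * syy - sy^2
  r <- (n * sxy - sx * sy) / sqrt(pmax(vx, 0) * pmax(vy, 0))
  scale2 <- pmax(vx, vy)                     # zero-variance guard, scale-aware
  r[n < min_n | vx <= 1e-12 * pmax(scale2, 1) | vy <= 1e-12 * pmax(scale2, 1)] <- NA
  r[!is.finite(r)] <- NA
  list(r = r, n = n)
}

#' Moving-window NDVI-SPEI correlations over scales 1-12
#'
#' For every pixel, window centre year and SPEI accumulation scale, pools
#' all growing-season months of the window's season-years and computes the
#' Pearson correlation between NDVI anomalies and SPEI-k. The moving window
#' slides by one year; a record of `Y` years yields centre years
#' `start+w/2 .. end-w/2` (1984-2014 for 1982-2016 with a 5-year window).
#'
#' @param anom a [monthly_grid] of detrended NDVI anomalies.
#' @param spei a [spei_stack].
#' @param gs a `growing_season` object (see
#'   [growing_season_from_phenology()]).
#' @param w a [window_spec].
#' @return object of class `r_cube`: list with `r` and `n` arrays of
#'   dimension `[row, col, centre, scale]`, and `center_years`.
#' @export
windowed_correlations <- function(anom, spei, gs, w = window_spec()) {
  stopifnot(inherits(anom, "monthly_grid"), inherits(spei, "spei_stack"),
            inherits(gs, "growing_season"), inherits(w, "window_spec"))
  stop_if_not_coregistered(anom, spei$scales[[1]])
  shp <- grid_shape(anom)
  if (!all(dim(gs$start) == shp))
    stop("growing-season map shape differs from the grids")

  ti <- time_index(anom)
  nt <- nrow(ti); np <- prod(shp)
  half <- w$width_years %/% 2L
  years <- sort(unique(ti$year))
  centers <- years[(1 + half):(length(years) - half)]
  if (length(centers) == 0L) stop("record shorter than the window width")

  mem <- season_membership(anom, gs)
  A <- matrix(aperm(anom$values, c(3, 1, 2)), nt, np)
  A[!mem$inseason] <- NA
  S <- lapply(spei$scales, function(g)
    matrix(aperm(g$values, c(3, 1, 2)), nt, np))

  r <- array(NA_real_, c(shp, length(centers), 12L))
  nn <- array(0L, c(shp, length(centers), 12L))
  for (ci in seq_along(centers)) {
    cy <- centers[ci]
    inwin <- !is.na(mem$seasonyear) &
      mem$seasonyear >= cy - half & mem$seasonyear <= cy + half
    Aw <- A; Aw[!inwin] <- NA
    for (k in 1:12) {
      mp <- masked_pearson(Aw, S[[k]], w$min_samples)
      r[, , ci, k] <- mp$r
      nn[, , ci, k] <- mp$n
    }
  }
  structure(list(r = r, n = nn, center_years = centers),
            class = "r_cube")
}

#' First peak or plateau across SPEI scales
#'
#' Scans the correlation profile over accumulation scales k = 1..12 and
#' stops at the first scale whose successor does not exceed it by more than
#' `plateau_tol`: either a local maximum (next value lower or equal) or the
#' first entry of a plateau (next value higher by at most `plateau_tol`).
#' A strictly increasing profile stops at the last scale. Missing scales
#' are skipped; ties between equal peaks resolve to the smallest scale.
#'
#' @param r_by_scale numeric vector of length 12 (NAs allowed).
#' @param plateau_tol absolute tolerance in r units defining a plateau
#'   (default 0.01).
#' @return list `(sensitivity, ced)`; both NA when all scales are missing.
#' @export
first_peak_or_plateau <- function(r_by_scale, plateau_tol = 0.01) {
  idx <- which(!is.na(r_by_scale))
  m <- length(idx)
  if (m == 0L) return(list(sensitivity = NA_real_, ced = NA_integer_))
  v <- r_by_scale[idx]
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      if (v[i + 1L] - v[i] <= plateau_tol)
        return(list(sensitivity = v[i], ced = idx[i]))
    }
  }
  list(sensitivity = v[m], ced = idx[m])
}

#' Per-pixel, per-window sensitivity and CED surface
#'
#' Applies the first-peak-or-plateau rule to every pixel-window profile of
#' the correlation cube. The sensitivity is the correlation value at the
#' selected scale; the CED (cumulative effect duration) is that scale in
#' months.
#'
#' @param rc an `r_cube` from [windowed_correlations()].
#' @param plateau_tol passed to [first_peak_or_plateau()].
#' @return object of class `response_surface`: arrays `sensitivity`, `ced`,
#'   `valid` of dimension `[row, col, centre]`, plus `center_years`.
#' @export
response_surface <- function(rc, plateau_tol = 0.01) {
  stopifnot(inherits(rc, "r_cube"))
  d <- dim(rc$r)
  sens <- array(NA_real_, d[1:3])
  ced <- array(NA_integer_, d[1:3])
  # vectorised scan over the scale margin: flatten pixel-window profiles
  prof <- matrix(rc$r, ncol = 12L)          # (row*col*centre) x 12
  res_s <- rep(NA_real_, nrow(prof))
  res_c <- rep(NA_integer_, nrow(prof))
  navail <- rowSums(!is.na(prof))
  todo <- which(navail > 0L)
  for (i in todo) {
    fp <- first_peak_or_plateau(prof[i, ], plateau_tol)
    res_s[i] <- fp$sensitivity
    res_c[i] <- fp$ced
  }
  sens[] <- res_s; ced[] <- res_c
  structure(list(sensitivity = sens, ced = ced, valid = !is.na(sens),
                 center_years = rc$center_years),
            class = "response_surface")
}

#' Water-constrained pixel mask
#'
#' A pixel is water constrained when its record-average sensitivity over
#' valid window centres is strictly positive: vegetation growth co-varies
#' positively with water availability there. Pixels with no valid window
#' are excluded (not constrained, `n_valid = 0`).
#'
#' @param rs a `response_surface`.
#' @return object of class `water_constraint_mask`: matrices `constrained`
#'   (logical), `mean_r` and `n_valid`.
#' @export
water_constrained_mask <- function(rs) {
  stopifnot(inherits(rs, "response_surface"))
  n_valid <- apply(rs$valid, c(1, 2), sum)
  mean_r <- apply(rs$sensitivity, c(1, 2), function(x)
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
  constrained <- !is.na(mean_r) & mean_r > 0
  structure(list(constrained = constrained, mean_r = mean_r, n_valid = n_valid),
            class = "water_constraint_mask")
}
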