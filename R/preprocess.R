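#' Monthly NDVI anomalies
#'
#' Removes the mean seasonal cycle: each value becomes the raw NDVI minus
#' the full-record climatological mean of that pixel and calendar month,
#' so anomalies are mean-zero per (pixel, calendar month) by construction.
#' Pixels with fewer than `min_years` observations of a calendar month get
#' missing anomalies for that month.
#'
#' @param ndvi a [monthly_grid] of raw NDVI.
#' @param min_years minimum number of years a calendar month must be
#'   observed for its climatology (default 2).
#' @return a [monthly_grid] of anomalies (variable suffixed `_anom`).
#' @export
compute_anomalies <- function(ndvi, min_years = 2L) {
  stopifnot(inherits(ndvi, "monthly_grid"))
  v <- ndvi$values
  months <- time_index(ndvi)$month
  out <- array(NA_real_, dim(v))
  for (m in 1:12) {
    sel <- which(months == m)
    if (length(sel) == 0L) next
    slab <- v[, , sel, drop = FALSE]
    n <- apply(!is.na(slab), c(1, 2), sum)
    clim <- apply(slab, c(1, 2), function(x) mean(x, na.rm = TRUE))
    clim[n < min_years] <- NA
    out[, , sel] <- sweep(slab, c(1, 2), clim, `-`)
  }
  monthly_grid(out, ndvi$start_year, ndvi$start_month, ndvi$geotransform,
               paste0(ndvi$variable, "_anom"), ndvi$units)
}

#' Remove the linear trend from each pixel's anomaly series
#'
#' Fits one ordinary-least-squares line per pixel against the continuous
#' month index over the whole record and subtracts it, so that long-term
#' greening/browning does not masquerade as a water response. Pixels with
#' fewer than `min_months` non-missing values are passed through unchanged
#' and flagged.
#'
#' @param anom a [monthly_grid] of anomalies.
#' @param min_months minimum non-missing months per pixel (default 24).
#' @return a [monthly_grid]; attribute `detrended` is a logical matrix of
#'   per-pixel success flags.
#' @export
detrend_linear <- function(anom, min_months = 24L) {
  stopifnot(inherits(anom, "monthly_grid"))
  d <- dim(anom$values)
  nt <- d[3]; np <- d[1] * d[2]
  Y <- matrix(aperm(anom$values, c(3, 1, 2)), nrow = nt, ncol = np)
  t0 <- seq_len(nt)
  ok <- !is.na(Y)
  n <- colSums(ok)
  Tm <- matrix(t0, nt, np)
  Tm[!ok] <- 0
  Y0 <- Y; Y0[!ok] <- 0
  st <- colSums(Tm); sy <- colSums(Y0)
  stt <- colSums(Tm^2); sty <- colSums(Tm * Y0)
  denom <- n * stt - st^2
  slope <- ifelse(denom > 0, (n * sty - st * sy) / denom, NA)
  icpt <- ifelse(n > 0, (sy - slope * st) / n, NA)
  flags <- n >= min_months & !is.na(slope)
  fit <- outer(t0, slope) + matrix(icpt, nt, np, byrow = TRUE)
  res <- Y - fit
  res[, !flags] <- Y[, !flags]           # pass-through where the fit failed
  out <- aperm(array(res, c(nt, d[1], d[2])), c(2, 3, 1))
  g <- monthly_grid(out, anom$start_year, anom$start_month, anom$geotransform,
                    anom$variable, anom$units)
  attr(g, "detrended") <- matrix(flags, d[1], d[2])
  g
}

#' Growing-season window from phenology
#'
#' The growing season of a pixel starts one month before green-up, runs
#' forward through the seasonal peak, and ends one month after it, on the
#' circular calendar (it may wrap across December). Both anchors are always
#' contained and the window is calendar-contiguous with length >= 3 months;
#' when green-up and peak are so far apart that the nominal window exceeds
#' a year, the season saturates to all 12 months.
#'
#' @param pheno a [pheno_map].
#' @return An object of class `growing_season` with integer matrices
#'   `start`, `end` (calendar months), `length`, and logical `valid`.
#' @export
growing_season_from_phenology <- function(pheno) {
  stopifnot(inherits(pheno, "pheno_map"))
  wrap <- function(m) (m - 1L) %% 12L + 1L
  start <- wrap(pheno$greenup - 1L)
  len <- pmin((pheno$peak - pheno$greenup) %% 12L + 3L, 12L)
  end <- wrap(start + len - 1L)
  start[!pheno$valid] <- NA; end[!pheno$valid] <- NA; len[!pheno$valid] <- NA
  structure(list(start = start, end = end, length = len, valid = pheno$valid),
            class = "growing_season")
}

#' Calendar months of one growing season
#'
#' @param start,end calendar months (1-12), season runs circularly from
#'   `start` to `end` inclusive.
#' @return integer vector of months in season order.
#' @export
season_months <- function(start, end) {
  if (is.na(start) || is.na(end)) return(integer(0))
  if (start <= end) start:end else c(start:12L, 1L:end)
}

# For every (time, pixel): TRUE when the month lies in the pixel's growing
# season, and the "season year" the month belongs to (the calendar year in
# which that season started). Returns T x P matrices; P = rows*cols in
# column-major pixel order.
season_membership <- function(g, gs) {
  ti <- time_index(g)
  nt <- nrow(ti)
  np <- length(gs$start)
  months <- ti$month; years <- ti$year
  inseason <- matrix(FALSE, nt, np)
  seasonyear <- matrix(NA_integer_, nt, np)
  st <- as.vector(gs$start); en <- as.vector(gs$end)
  for (p in seq_len(np)) {
    if (is.na(st[p])) next
    if (st[p] <= en[p]) {
      sel <- months >= st[p] & months <= en[p]
      inseason[sel, p] <- TRUE
      seasonyear[sel, p] <- years[sel]
    } else {                       # wraps December -> January
      head_part <- months >= st[p]
      tail_part <- months <= en[p]
      inseason[head_part | tail_part, p] <- TRUE
      seasonyear[head_part, p] <- years[head_part]
      seasonyear[tail_part, p] <- years[tail_part] - 1L
    }
  }
  list(inseason = inseason, seasonyear = seasonyear)
}
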