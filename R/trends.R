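#' Mann-Kendall trend test with Sen slope
#'
#' Nonparametric monotonic-trend test on an (implicitly unit-spaced) series.
#' The S statistic counts concordant minus discordant pairs; its variance is
#' tie-corrected. For n <= 10 without ties the two-sided p-value comes from
#' the exact permutation null (via the inversion-number distribution);
#' otherwise from the normal approximation with continuity correction.
#' The accompanying magnitude estimate is the Sen slope, the median of all
#' pairwise slopes.
#'
#' @param x numeric series (NAs dropped; time spacing of remaining points
#'   preserved via their original indices).
#' @param alpha significance level for the `significant` flag (default
#'   0.05; per-pixel, no multiplicity correction).
#' @param t optional time vector (defaults to `seq_along(x)`).
#' @return list with `S`, `var_s`, `tau` (tie-corrected tau-b), `p_value`,
#'   `sen_slope` (units of x per unit t), `n`, `significant`.
#' @export
mann_kendall <- function(x, alpha = 0.05, t = seq_along(x)) {
  keep <- !is.na(x)
  x <- x[keep]; t <- t[keep]
  n <- length(x)
  out <- list(S = NA_integer_, var_s = NA_real_, tau = NA_real_,
              p_value = NA_real_, sen_slope = NA_real_, n = n,
              significant = FALSE)
  if (n < 2L) return(out)

  dx <- outer(x, x, `-`)      # dx[j, i] = x[j] - x[i]
  dt <- outer(t, t, `-`)
  up <- upper.tri(dx)         # pairs i < j, entry [i, j]
  sgn <- sign(t(dx)[up])      # x[j] - x[i] for i < j
  S <- sum(sgn)
  slopes <- (t(dx)[up]) / (t(dt)[up])
  sen <- stats::median(slopes)

  ties <- table(x)
  ties <- ties[ties > 1L]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  N <- n * (n - 1) / 2
  Tx <- sum(ties * (ties - 1) / 2)
  tau <- if (N - Tx > 0) S / sqrt((N - Tx) * N) else 0

  p <- if (n <= 10L && length(ties) == 0L) {
    mk_exact_p(S, n)
  } else if (var_s <= 0) {
    1
  } else {
    z <- (S - sign(S)) / sqrt(var_s)     # continuity correction
    if (S == 0) 1 else 2 * stats::pnorm(-abs(z))
  }
  p <- min(1, p)

  list(S = as.integer(S), var_s = var_s, tau = tau, p_value = p,
       sen_slope = sen, n = n, significant = is.finite(p) && p < alpha)
}

# Exact two-sided p-value of MK S for n distinct observations: the null
# distribution of the number of inversions d (S = N - 2d) has generating
# function prod_{i=1}^{n} (1 + q + ... + q^{i-1}).
mk_exact_p <- function(S, n) {
  counts <- mk_exact_counts(n)
  N <- n * (n - 1) / 2
  s_vals <- N - 2 * (seq_along(counts) - 1)   # S for d = 0, 1, ..., N
  sum(counts[abs(s_vals) >= abs(S)]) / sum(counts)
}

mk_exact_counts <- function(n) {
  poly <- 1
  if (n < 2L) return(poly)
  for (i in 2:n) {                     # multiply by (1 + q + ... + q^(i-1))
    newp <- numeric(length(poly) + i - 1)
    for (s in 0:(i - 1))
      newp[seq_along(poly) + s] <- newp[seq_along(poly) + s] + poly
    poly <- newp
  }
  poly
}

#' Per-pixel trend field of a response surface
#'
#' Runs the Mann-Kendall test and Sen slope on each water-constrained
#' pixel's sensitivity (or CED) series over window centre years. Pixels
#' outside the mask, or with fewer than `min_points` valid windows, are
#' missing in every output layer.
#'
#' @param rs a `response_surface`.
#' @param which `"sensitivity"` or `"ced"`.
#' @param mask a `water_constraint_mask`.
#' @param alpha per-pixel significance level (default 0.05, uncorrected).
#' @param min_points minimum valid points per series (default 8).
#' @return object of class `trend_field`: matrices `S`, `tau`, `p_value`,
#'   `sen_slope`, `significant`, `valid`.
#' @export
trend_map <- function(rs, which = c("sensitivity", "ced"), mask,
                      alpha = 0.05, min_points = 8L) {
  which <- match.arg(which)
  stopifnot(inherits(rs, "response_surface"),
            inherits(mask, "water_constraint_mask"))
  vals <- rs[[which]]
  d <- dim(vals)
  mk_na <- matrix(NA_real_, d[1], d[2])
  out <- list(S = mk_na, tau = mk_na, p_value = mk_na, sen_slope = mk_na,
              significant = matrix(FALSE, d[1], d[2]),
              valid = matrix(FALSE, d[1], d[2]),
              alpha = alpha, which = which)
  yrs <- rs$center_years
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (!isTRUE(mask$constrained[i, j])) next
    series <- vals[i, j, ]
    if (sum(!is.na(series)) < min_points) next
    mk <- mann_kendall(series, alpha = alpha, t = yrs)
    out$S[i, j] <- mk$S; out$tau[i, j] <- mk$tau
    out$p_value[i, j] <- mk$p_value; out$sen_slope[i, j] <- mk$sen_slope
    out$significant[i, j] <- mk$significant
    out$valid[i, j] <- TRUE
  }
  structure(out, class = "trend_field")
}

#' Stratified trend summary
#'
#' Fractions of significantly increasing / decreasing pixels per stratum
#' (land-cover class or rainfall zone) among the valid, water-constrained
#' pixels covered by the trend field.
#'
#' @param trend a `trend_field`.
#' @param strata a [landcover_map], or an integer/factor matrix of stratum
#'   codes (e.g. from [rainfall_zones()]).
#' @return data.frame with one row per stratum: `stratum`, `n`,
#'   `n_increasing`, `n_decreasing`, `fraction_increasing`,
#'   `fraction_decreasing` (fractions NA for empty strata).
#' @export
stratify <- function(trend, strata) {
  stopifnot(inherits(trend, "trend_field"))
  if (inherits(strata, "landcover_map")) {
    codes <- landcover_classes()
    lab <- matrix(names(codes)[match(strata$class_code, codes)],
                  nrow(strata$class_code), ncol(strata$class_code))
    levels <- names(codes)
  } else {
    lab <- as.matrix(strata)
    levels <- sort(unique(as.vector(lab[!is.na(lab)])))
  }
  if (!all(dim(lab) == dim(trend$valid)))
    stop("stratum map shape differs from the trend field")
  valid <- trend$valid
  inc <- valid & trend$significant & trend$tau > 0
  dec <- valid & trend$significant & trend$tau < 0
  rows <- lapply(levels, function(lv) {
    sel <- !is.na(lab) & lab == lv & valid
    n <- sum(sel)
    data.frame(stratum = as.character(lv), n = n,
               n_increasing = sum(inc & sel), n_decreasing = sum(dec & sel),
               fraction_increasing = if (n > 0) sum(inc & sel) / n else NA_real_,
               fraction_decreasing = if (n > 0) sum(dec & sel) / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rainfall zones from mean annual precipitation
#'
#' Bins per-pixel mean annual precipitation at the classic dryland isohyets
#' 150, 300, 600, 1000 and 1200 mm.
#'
#' @param precip a [monthly_grid] of precipitation (mm/month).
#' @param breaks isohyets in mm/yr.
#' @return character matrix of zone labels (e.g. `"150-300"`).
#' @export
rainfall_zones <- function(precip, breaks = c(150, 300, 600, 1000, 1200)) {
  stopifnot(inherits(precip, "monthly_grid"))
  annual <- 12 * apply(precip$values, c(1, 2), function(x)
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
  brks <- c(0, breaks, Inf)
  labs <- paste(brks[-length(brks)], brks[-1], sep = "-")
  labs[length(labs)] <- paste0(">", breaks[length(breaks)])
  z <- matrix(labs[findInterval(annual, brks, rightmost.closed = TRUE)],
              nrow(annual), ncol(annual))
  z[is.na(annual)] <- NA
  z
}

#' Domain-average response series and its trend
#'
#' Unweighted mean of the response over valid, water-constrained pixels for
#' each window centre year, with the Mann-Kendall test and Sen slope of
#' that annual series.
#'
#' @param rs a `response_surface`.
#' @param mask a `water_constraint_mask`.
#' @param which `"sensitivity"` or `"ced"`.
#' @param alpha significance level.
#' @return list with `center_years`, `mean` (annual series), `n_pixels`
#'   per year, and `trend` (a [mann_kendall()] result).
#' @export
domain_mean_series <- function(rs, mask, which = c("sensitivity", "ced"),
                               alpha = 0.05) {
  which <- match.arg(which)
  stopifnot(inherits(rs, "response_surface"),
            inherits(mask, "water_constraint_mask"))
  vals <- rs[[which]]
  ny <- dim(vals)[3]
  cons <- mask$constrained
  mean_y <- rep(NA_real_, ny); n_y <- integer(ny)
  for (y in seq_len(ny)) {
    slab <- vals[, , y]
    sel <- cons & !is.na(slab)
    n_y[y] <- sum(sel)
    if (n_y[y] > 0) mean_y[y] <- mean(slab[sel])
  }
  list(center_years = rs$center_years, mean = mean_y, n_pixels = n_y,
       trend = mann_kendall(mean_y, alpha = alpha, t = rs$center_years))
}
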