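#' Scenario configuration for the synthetic generator
#'
#' Defines one fully seeded synthetic study: a coupled NDVI / water-balance
#' simulation on a regular grid in which growing-season NDVI anomalies are
#' linearly coupled to SPEI at a pixel-specific accumulation scale `k*`,
#' with coupling strength `beta0` drifting by `beta1` per year, Gaussian
#' noise `sigma`, a north-south phenology gradient and (optionally) one
#' climate driver whose trend field covaries with the planted coupling
#' trend. The generated truth is kept alongside the data and is never
#' consumed by the analysis pipeline under test.
#'
#' `sigma` defaults to the value that makes the theoretical pixel
#' correlation `beta0 / sqrt(beta0^2 + sigma^2)` equal `target_r`.
#'
#' @param nrow,ncol grid size (default 40 x 40).
#' @param start_year first calendar year (default 1982).
#' @param n_years record length in years (default 35).
#' @param k_star_range range of true accumulation scales, interpolated
#'   north (short) to south (long) across rows (default 2..6 months).
#' @param beta0 baseline coupling strength (default 0.7).
#' @param beta1 coupling trend per year, scalar or `nrow x ncol` matrix
#'   (default 0).
#' @param target_r theoretical NDVI-SPEI correlation at `beta0` used to set
#'   the noise level (default 0.7).
#' @param sigma NDVI noise SD; overrides `target_r` when given.
#' @param ndvi_trend long-term NDVI drift per month (re-greening surrogate,
#'   default 1e-4; removed by detrending in the pipeline).
#' @param ar_phi month-to-month AR(1) coefficient of water-balance
#'   anomalies (default 0.2).
#' @param smooth_sigma spatial correlation length of noise fields, in cells
#'   (default 1.5).
#' @param causal_driver `NULL`, or one of `"precipitation_mean"`,
#'   `"temperature_mean"`, `"radiation_mean"` and their `"_sd"` variants:
#'   the driver feature whose per-pixel trend is constructed to covary with
#'   the planted coupling trend field.
#' @param geotransform georeferencing of the generated grids.
#' @param seed mandatory RNG seed; every stochastic field derives from it.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(nrow = 40L, ncol = 40L, start_year = 1982L,
                            n_years = 35L, k_star_range = c(2L, 6L),
                            beta0 = 0.7, beta1 = 0, target_r = 0.7,
                            sigma = NULL, ndvi_trend = 1e-4, ar_phi = 0.2,
                            wb_noise_sd = 15, smooth_sigma = 1.5,
                            causal_driver = NULL,
                            geotransform = list(xll = -5, yll = 10, cellsize = 0.05),
                            seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (is.null(sigma)) sigma <- beta0 * sqrt(1 / target_r^2 - 1)
  stopifnot(sigma >= 0, wb_noise_sd >= 0, n_years >= 5, nrow >= 1, ncol >= 1)
  b1 <- if (is.matrix(beta1)) beta1 else matrix(beta1, nrow, ncol)
  stopifnot(all(dim(b1) == c(nrow, ncol)))
  if (!is.null(causal_driver)) {
    allowed <- as.vector(outer(c("precipitation", "temperature", "radiation"),
                               c("mean", "sd"), paste, sep = "_"))
    if (!causal_driver %in% allowed)
      stop("causal_driver must be one of: ", paste(allowed, collapse = ", "))
  }
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 start_year = as.integer(start_year),
                 n_years = as.integer(n_years),
                 k_star_range = as.integer(k_star_range),
                 beta0 = beta0, beta1 = b1, sigma = sigma,
                 ndvi_trend = ndvi_trend, ar_phi = ar_phi,
                 wb_noise_sd = wb_noise_sd,
                 smooth_sigma = smooth_sigma, causal_driver = causal_driver,
                 geotransform = geotransform, seed = as.integer(seed)),
            class = "scenario_config")
}

# Separable Gaussian smoothing with edge renormalisation.
gauss_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  smooth1 <- function(n) {
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- pmax(1L, i - half):pmin(n, i + half)
      w <- k[j - i + half + 1L]
      K[i, j] <- w / sum(w)
    }
    K
  }
  smooth1(nrow(mat)) %*% mat %*% t(smooth1(ncol(mat)))
}

# Fixed sub-seed offsets keep independently callable stages reproducible.
stage_seed <- function(cfg, stage)
  (cfg$seed + 1000003L * match(stage, c("wb", "ndvi", "drivers", "landcover"))) %% .Machine$integer.max

#' True per-pixel parameters of a scenario
#'
#' @param cfg a [scenario_config].
#' @return object of class `synthetic_truth`: `k_star` (matrix of true
#'   accumulation scales), `beta0`, `beta1` (matrix, per year), `sigma`,
#'   `r_theory` (matrix, theoretical correlation at mid-record),
#'   `causal_driver`.
#' @export
synthetic_truth <- function(cfg) {
  ks <- round(seq(cfg$k_star_range[1], cfg$k_star_range[2],
                  length.out = cfg$nrow))
  k_star <- matrix(rep(as.integer(ks), cfg$ncol), cfg$nrow, cfg$ncol)
  structure(list(k_star = k_star, beta0 = cfg$beta0, beta1 = cfg$beta1,
                 sigma = cfg$sigma,
                 r_theory = cfg$beta0 / sqrt(cfg$beta0^2 + cfg$sigma^2),
                 causal_driver = cfg$causal_driver),
            class = "synthetic_truth")
}

#' Theoretical sensitivity of a scenario at given years
#'
#' The noise-free correlation implied by the generator at each pixel and
#' year: `beta(y) / sqrt(beta(y)^2 + sigma^2)` with
#' `beta(y) = beta0 + beta1 * (y - mid-record year)`.
#'
#' @param cfg a [scenario_config]; `truth` its [synthetic_truth()].
#' @param years calendar years (e.g. window centre years).
#' @return array `[row, col, year]` of theoretical correlations.
#' @export
theoretical_sensitivity <- function(cfg, truth, years) {
  mid <- cfg$start_year + (cfg$n_years - 1) / 2
  out <- array(NA_real_, c(cfg$nrow, cfg$ncol, length(years)))
  for (yi in seq_along(years)) {
    b <- truth$beta0 + truth$beta1 * (years[yi] - mid)
    out[, , yi] <- b / sqrt(b^2 + truth$sigma^2)
  }
  out
}

#' North-south phenology gradient
#'
#' Green-up around July in the north shifting to May in the south, with the
#' seasonal peak stretching from September to October: seasons lengthen
#' from north to south as in monsoonal drylands.
#'
#' @param cfg a [scenario_config].
#' @return a [pheno_map].
#' @export
simulate_phenology <- function(cfg) {
  gu <- round(seq(7, 5, length.out = cfg$nrow))
  pk <- round(seq(9, 10, length.out = cfg$nrow))
  pheno_map(matrix(rep(gu, cfg$ncol), cfg$nrow, cfg$ncol),
            matrix(rep(pk, cfg$ncol), cfg$nrow, cfg$ncol))
}

#' Synthetic land-cover layout
#'
#' Contiguous patches drawn by cutting a spatially smoothed Gaussian field
#' at quantiles matching typical Sahelian class shares (shrubs 30%,
#' herbaceous 29%, cropland 22%, forest 16%, other 2%... remainder folded
#' into `other`).
#'
#' @param cfg a [scenario_config].
#' @param shares class shares in code order (shrubs, herbaceous, cropland,
#'   forest, other); normalised to 1.
#' @return a [landcover_map].
#' @export
simulate_landcover <- function(cfg, shares = c(0.30, 0.29, 0.22, 0.16, 0.03)) {
  set.seed(stage_seed(cfg, "landcover"))
  shares <- shares / sum(shares)
  f <- gauss_smooth(matrix(stats::rnorm(cfg$nrow * cfg$ncol), cfg$nrow, cfg$ncol),
                    cfg$smooth_sigma)
  q <- stats::quantile(f, cumsum(shares)[-length(shares)], names = FALSE)
  landcover_map(matrix(findInterval(f, q) + 1L, cfg$nrow, cfg$ncol))
}

#' Simulate the monthly water balance
#'
#' Precipitation-minus-potential-evapotranspiration surrogate: a seasonal
#' cycle (wet season centred on August, amplitude growing southwards) plus
#' a spatially correlated AR(1) anomaly field, in mm/month. One spin-up
#' year before `start_year` is included so that all SPEI scales up to 12
#' months are defined from the first analysis month.
#'
#' @param cfg a [scenario_config].
#' @return a [monthly_grid] `wb` starting in January of `start_year - 1`.
#' @export
simulate_water_balance <- function(cfg) {
  set.seed(stage_seed(cfg, "wb"))
  ny <- cfg$n_years + 1L
  nt <- 12L * ny
  months <- rep(1:12, ny)
  amp <- seq(20, 60, length.out = cfg$nrow)
  seas <- outer(amp, rep(1, cfg$ncol)) # row gradient
  vals <- array(NA_real_, c(cfg$nrow, cfg$ncol, nt))
  a <- matrix(0, cfg$nrow, cfg$ncol)
  sd_innov <- cfg$wb_noise_sd
  for (t in seq_len(nt)) {
    innov <- if (sd_innov > 0)
      gauss_smooth(matrix(stats::rnorm(cfg$nrow * cfg$ncol, sd = sd_innov),
                          cfg$nrow, cfg$ncol), cfg$smooth_sigma)
    else matrix(0, cfg$nrow, cfg$ncol)
    a <- cfg$ar_phi * a + innov
    vals[, , t] <- 45 + seas * cos(2 * pi * (months[t] - 8) / 12) + a
  }
  monthly_grid(vals, cfg$start_year - 1L, 1L, cfg$geotransform, "wb", "mm/month")
}

#' SPEI surrogate from a water-balance grid
#'
#' The k-month trailing sum of the water balance, standardised to zero mean
#' and unit SD per pixel and calendar month over the record. This keeps the
#' standardised-anomaly property the analysis consumes while skipping the
#' distribution fitting of operational SPEI products. The first `k - 1`
#' months are missing.
#'
#' @param wb a [monthly_grid] of water balance (mm/month).
#' @param k accumulation scale in months (1-12).
#' @return a [monthly_grid] of SPEI-k (dimensionless).
#' @export
spei_from_balance <- function(wb, k) {
  stopifnot(inherits(wb, "monthly_grid"), k >= 1, k <= 12)
  d <- dim(wb$values)
  nt <- d[3]; np <- d[1] * d[2]
  M <- matrix(aperm(wb$values, c(3, 1, 2)), nt, np)
  CS <- apply(M, 2, cumsum)
  S <- matrix(NA_real_, nt, np)
  if (k == 1L) S <- M else {
    S[k, ] <- CS[k, ]
    if (nt > k) S[(k + 1):nt, ] <- CS[(k + 1):nt, , drop = FALSE] -
        CS[1:(nt - k), , drop = FALSE]
  }
  months <- time_index(wb)$month
  for (m in 1:12) {
    sel <- which(months == m)
    block <- S[sel, , drop = FALSE]
    mu <- colMeans(block, na.rm = TRUE)
    sdv <- apply(block, 2, stats::sd, na.rm = TRUE)
    sdv[sdv < .Machine$double.eps] <- NA
    S[sel, ] <- sweep(sweep(block, 2, mu, `-`), 2, sdv, `/`)
  }
  vals <- aperm(array(S, c(nt, d[1], d[2])), c(2, 3, 1))
  monthly_grid(vals, wb$start_year, wb$start_month, wb$geotransform,
               paste0("spei", k), "")
}

#' Build the 12-scale SPEI stack from a water balance
#'
#' @param wb a [monthly_grid] from [simulate_water_balance()].
#' @param from optional `c(year, month)` to crop the stack to (defaults to
#'   one year after the start of `wb`, past the spin-up).
#' @return a [spei_stack].
#' @export
build_spei_stack <- function(wb, from = NULL) {
  if (is.null(from)) from <- c(wb$start_year + 1L, 1L)
  ti <- time_index(wb)
  to <- c(ti$year[nrow(ti)], ti$month[nrow(ti)])
  spei_stack(lapply(1:12, function(k)
    crop_time(spei_from_balance(wb, k), from, to)))
}

#' Simulate NDVI coupled to SPEI at the true scale
#'
#' Monthly NDVI = seasonal climatology + linear drift + anomaly, where the
#' growing-season anomaly is `beta(year) * SPEI-k*` plus Gaussian noise and
#' off-season months carry noise only. `beta` follows the planted linear
#' trajectory per pixel; the drift emulates re-greening and is removed by
#' the pipeline's detrending.
#'
#' @param spei a [spei_stack] on the analysis time axis.
#' @param truth a `synthetic_truth`.
#' @param cfg the [scenario_config].
#' @return a [monthly_grid] of NDVI.
#' @export
simulate_ndvi <- function(spei, truth, cfg) {
  set.seed(stage_seed(cfg, "ndvi"))
  ref <- spei$scales[[1]]
  ti <- time_index(ref)
  nt <- nrow(ti); np <- cfg$nrow * cfg$ncol
  gs <- growing_season_from_phenology(simulate_phenology(cfg))
  mem <- season_membership(ref, gs)

  Sk <- matrix(NA_real_, nt, np)       # SPEI at each pixel's true scale
  kvec <- as.vector(truth$k_star)
  for (k in sort(unique(kvec))) {
    cols <- which(kvec == k)
    Sk[, cols] <- matrix(aperm(spei$scales[[k]]$values, c(3, 1, 2)),
                         nt, np)[, cols]
  }

  mid <- cfg$start_year + (cfg$n_years - 1) / 2
  B <- matrix(0, nt, np)
  sy <- mem$seasonyear
  for (p in seq_len(np)) {
    yrs <- sy[, p]
    B[, p] <- ifelse(is.na(yrs), 0,
                     truth$beta0 + as.vector(truth$beta1)[p] * (yrs - mid))
  }
  anom <- matrix(stats::rnorm(nt * np, sd = cfg$sigma), nt, np)
  coupled <- mem$inseason & !is.na(Sk)
  anom[coupled] <- anom[coupled] + (B * Sk)[coupled]

  clim <- 0.25 + 0.12 * cos(2 * pi * (ti$month - 9) / 12)
  vals <- matrix(clim, nt, np) + outer(seq_len(nt), rep(cfg$ndvi_trend, np)) + anom
  monthly_grid(aperm(array(vals, c(nt, cfg$nrow, cfg$ncol)), c(2, 3, 1)),
               ref$start_year, ref$start_month, cfg$geotransform, "ndvi", "")
}

#' Simulate climate driver grids and the global CO2 series
#'
#' Precipitation, temperature and radiation receive seasonal cycles,
#' spatially correlated noise and per-pixel linear trend fields; CO2 is a
#' single global series with a monotone rise whose growth rate varies by
#' calendar month. When `cfg$causal_driver` is set, that driver's trend
#' field (for `_mean` features) or its time-growing noise amplitude (for
#' `_sd` features) is constructed to covary linearly with the planted
#' coupling-trend field `beta1` across pixels; all other trend fields are
#' independent of it.
#'
#' @param cfg a [scenario_config]; `truth` a `synthetic_truth`.
#' @param time_axis a [monthly_grid] providing the analysis time axis.
#' @return list with [monthly_grid]s `precipitation`, `temperature`,
#'   `radiation`, and numeric vector `co2` (ppm per month).
#' @export
simulate_drivers <- function(cfg, truth, time_axis) {
  set.seed(stage_seed(cfg, "drivers"))
  ti <- time_index(time_axis)
  nt <- nrow(ti); nr <- cfg$nrow; nc <- cfg$ncol
  tt <- (seq_len(nt) - (nt + 1) / 2) / 12      # years around mid-record

  z <- as.vector(truth$beta1)
  z <- if (stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) else z * 0
  zmat <- matrix(z, nr, nc)

  make_driver <- function(name, base, amp, noise_sd, trend_sd, causal_effect) {
    seas <- base + amp * cos(2 * pi * (ti$month - 8) / 12)
    trend <- gauss_smooth(matrix(stats::rnorm(nr * nc, sd = trend_sd), nr, nc),
                          cfg$smooth_sigma)
    sd_grow <- matrix(0, nr, nc)
    if (!is.null(cfg$causal_driver)) {
      if (cfg$causal_driver == paste0(name, "_mean"))
        trend <- trend + causal_effect * zmat
      if (cfg$causal_driver == paste0(name, "_sd"))
        sd_grow <- 0.04 * zmat               # relative SD growth per year
    }
    vals <- array(NA_real_, c(nr, nc, nt))
    for (t in seq_len(nt)) {
      sdfac <- pmax(0.2, 1 + sd_grow * tt[t])
      eps <- gauss_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                          cfg$smooth_sigma) * noise_sd * sdfac
      vals[, , t] <- seas[t] + trend * tt[t] + eps
    }
    monthly_grid(vals, time_axis$start_year, time_axis$start_month,
                 cfg$geotransform, name, "")
  }

  drivers <- list(
    precipitation = make_driver("precipitation", 60, 50, 8, 0.10, 0.5),
    temperature = make_driver("temperature", 300, 4, 0.6, 0.010, 0.05),
    radiation = make_driver("radiation", 2e7, 3e6, 5e5, 1e4, 5e4)
  )
  yrs <- ti$year - ti$year[1] + (ti$month - 1) / 12
  co2 <- 340 + (1.8 + 0.15 * sin(2 * pi * (ti$month - 4) / 12)) * yrs +
    2 * cos(2 * pi * (ti$month - 5) / 12)
  c(drivers, list(co2 = co2))
}

#' Generate one complete synthetic scenario
#'
#' One-stop generator producing every input the analysis pipeline needs
#' plus the ground truth. Presets: `"recovery"` (stationary coupling at
#' r ~ 0.7), `"trend"` (coupling declining at 0.025 per year, a
#' clear-signal scenario for trend detection), `"null"` (no coupling at
#' all) and `"attribution"` (spatially varying negative coupling trend with
#' a designated causal climate driver).
#'
#' @param scenario preset name.
#' @param seed RNG seed.
#' @param ... overrides passed to [scenario_config()].
#' @return object of class `vw_scenario`: `ndvi`, `spei`, `wb`, `pheno`,
#'   `landcover`, `drivers`, `co2`, `truth`, `cfg`.
#' @export
simulate_scenario <- function(scenario = c("recovery", "trend", "null",
                                           "attribution"),
                              seed, ...) {
  scenario <- match.arg(scenario)
  if (missing(seed)) stop("a seed is mandatory")
  dots <- list(...)
  preset <- switch(scenario,
    recovery = list(),
    trend = list(beta1 = -0.025),
    null = list(beta0 = 0, sigma = 0.3),
    attribution = list(beta1 = NULL, causal_driver = "temperature_mean"))
  args <- utils::modifyList(preset, dots)
  args$seed <- seed
  if (scenario == "attribution" && is.null(args$beta1)) {
    # smooth negative coupling-trend field, set after nrow/ncol are known
    tmp <- do.call(scenario_config, utils::modifyList(args, list(beta1 = 0)))
    set.seed((seed + 7L) %% .Machine$integer.max)
    f <- gauss_smooth(matrix(stats::rnorm(tmp$nrow * tmp$ncol),
                             tmp$nrow, tmp$ncol), tmp$smooth_sigma * 2)
    f <- (f - mean(f)) / stats::sd(f)
    args$beta1 <- -0.016 + 0.006 * f      # mostly negative, spatially varying
  }
  cfg <- do.call(scenario_config, args)
  truth <- synthetic_truth(cfg)
  wb <- simulate_water_balance(cfg)
  spei <- build_spei_stack(wb)
  ndvi <- simulate_ndvi(spei, truth, cfg)
  drv <- simulate_drivers(cfg, truth, ndvi)
  structure(list(ndvi = ndvi, spei = spei, wb = wb,
                 pheno = simulate_phenology(cfg),
                 landcover = simulate_landcover(cfg),
                 drivers = drv[c("precipitation", "temperature", "radiation")],
                 co2 = drv$co2, truth = truth, cfg = cfg),
            class = "vw_scenario")
}
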