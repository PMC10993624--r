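test_that("self- and anti-correlated series give r of +1 and -1 at their scale", {
  set.seed(3)
  base <- rnorm(120)
  stk <- stack_from_series(function(k) base * k, nrow = 2, ncol = 2, nt = 120,
                           start_year = 2000)
  anom <- make_grid(2, 2, 120, 2000, fill = function(r, c, t) base[t])
  gs <- growing_season_from_phenology(flat_pheno(2, 2, 6, 9))
  rc <- windowed_correlations(anom, stk, gs, window_spec())
  expect_true(all(abs(rc$r[, , , 3] - 1) < 1e-12, na.rm = TRUE))

  anti <- make_grid(2, 2, 120, 2000, fill = function(r, c, t) -base[t])
  rc2 <- windowed_correlations(anti, stk, gs, window_spec())
  expect_true(all(abs(rc2$r[, , , 1] + 1) < 1e-12, na.rm = TRUE))
})

test_that("windows pool growing-season months of the window's season-years", {
  # anomaly equals SPEI-1 only inside one 5-year window; elsewhere noise
  set.seed(9)
  nt <- 120
  s <- rnorm(nt)
  stk <- stack_from_series(function(k) if (k == 1) s else rnorm(nt),
                           nrow = 1, ncol = 1, nt = nt, start_year = 2000)
  months <- time_index(stk$scales[[1]])$month
  years <- time_index(stk$scales[[1]])$year
  a <- rnorm(nt)
  sel <- years %in% 2002:2006
  a[sel] <- s[sel]
  anom <- make_grid(1, 1, nt, 2000, fill = function(r, c, t) a[t])
  gs <- growing_season_from_phenology(flat_pheno(1, 1, 6, 9))
  rc <- windowed_correlations(anom, stk, gs, window_spec())
  ci <- which(rc$center_years == 2004)
  expect_equal(rc$r[1, 1, ci, 1], 1, tolerance = 1e-12)
})

test_that("correlations are invariant to permuting pooled window samples", {
  set.seed(21)
  nt <- 120
  s <- rnorm(nt)
  stk <- stack_from_series(function(k) s + rnorm(nt, sd = 0.5),
                           nrow = 1, ncol = 1, nt = nt, start_year = 2000)
  a0 <- s + rnorm(nt, sd = 0.5)
  anom <- make_grid(1, 1, nt, 2000, fill = function(r, c, t) a0[t])
  gs <- growing_season_from_phenology(flat_pheno(1, 1, 6, 9))
  rc <- windowed_correlations(anom, stk, gs, window_spec())

  # permute whole years (jointly in both variables): same pooled samples
  yr_perm <- c(2, 1, 4, 3, 5, 7, 6, 9, 8, 10)
  perm_t <- as.vector(vapply(yr_perm, function(y) (y - 1) * 12 + 1:12,
                             numeric(12)))
  stk_p <- spei_stack(lapply(stk$scales, function(g)
    monthly_grid(g$values[, , perm_t, drop = FALSE], 2000, 1,
                 g$geotransform, g$variable)))
  anom_p <- monthly_grid(anom$values[, , perm_t, drop = FALSE], 2000, 1,
                         anom$geotransform, "x")
  rc_p <- windowed_correlations(anom_p, stk_p, gs, window_spec())
  # windows fully inside the swapped pairs keep identical pooled samples
  ci <- which(rc$center_years == 2004)      # years 2002-2006, pairs (3,4) swapped
  expect_equal(rc_p$r[1, 1, ci, ], rc$r[1, 1, ci, ], tolerance = 1e-12)
})

test_that("zero-variance and under-sampled windows are missing, not NaN", {
  nt <- 120
  stk <- stack_from_series(function(k) rep(0.5, nt), nrow = 1, ncol = 1,
                           nt = nt, start_year = 2000)
  set.seed(2)
  anom <- make_grid(1, 1, nt, 2000, fill = function(r, c, t) rnorm(length(t)))
  gs <- growing_season_from_phenology(flat_pheno(1, 1, 6, 9))
  rc <- windowed_correlations(anom, stk, gs, window_spec())
  expect_true(all(is.na(rc$r)))
  expect_false(any(is.nan(rc$r)))

  # raising min_samples above the pooled count invalidates every window
  stk2 <- stack_from_series(function(k) rnorm(nt), nrow = 1, ncol = 1,
                            nt = nt, start_year = 2000)
  rc2 <- windowed_correlations(anom, stk2, gs,
                               window_spec(min_samples = 1000L))
  expect_true(all(is.na(rc2$r)))
})

test_that("first peak or plateau follows the scan rule", {
  r <- c(0.2, 0.5, 0.4, 0.3, 0.2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
  expect_equal(first_peak_or_plateau(r), list(sensitivity = 0.5, ced = 2L))

  r2 <- c(0.6, 0.5, 0.4, 0.3, 0.2, 0.1, 0, 0, 0, 0, 0, 0)
  expect_equal(first_peak_or_plateau(r2), list(sensitivity = 0.6, ced = 1L))

  increasing <- seq(0.1, 0.9, length.out = 12)
  expect_equal(first_peak_or_plateau(increasing)$ced, 12L)

  plateau <- c(0.2, 0.4, 0.405, 0.41, 0.9, rep(0.9, 7))
  expect_equal(first_peak_or_plateau(plateau)$ced, 2L)

  with_na <- c(NA, 0.2, NA, 0.5, 0.3, rep(NA, 7))
  expect_equal(first_peak_or_plateau(with_na), list(sensitivity = 0.5, ced = 4L))

  expect_true(is.na(first_peak_or_plateau(rep(NA_real_, 12))$ced))
})

test_that("scan agrees with the brute-force oracle on random profiles", {
  set.seed(4242)
  vals <- seq(0, 0.9, by = 0.1)
  for (i in 1:3000) {
    v <- sample(vals, 12, replace = TRUE)
    if (i %% 5 == 0) v[sample(12, 3)] <- NA
    got <- first_peak_or_plateau(v)
    want <- peak_oracle(v)
    expect_identical(got$ced, want$ced)
    expect_identical(got$sensitivity, want$sensitivity)
  }
})

test_that("the response surface is internally consistent with its r-cube", {
  set.seed(77)
  scn <- simulate_scenario("recovery", seed = 31, nrow = 6, ncol = 6,
                           n_years = 10)
  res <- run_response_pipeline(scn$ndvi, scn$spei, scn$pheno)
  rc <- res$r_cube; rs <- res$surface
  d <- dim(rs$sensitivity)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (y in seq_len(d[3])) {
    if (!rs$valid[i, j, y]) next
    expect_identical(rs$sensitivity[i, j, y], rc$r[i, j, y, rs$ced[i, j, y]])
  }
  expect_true(all(abs(rs$sensitivity[rs$valid]) <= 1))
  expect_true(all(rs$ced[rs$valid] %in% 1:12))
})

test_that("white-noise anomalies give near-zero mean correlation", {
  set.seed(55)
  nt <- 120
  stk <- stack_from_series(function(k) rnorm(nt), nrow = 10, ncol = 10,
                           nt = nt, start_year = 2000)
  anom <- make_grid(10, 10, nt, 2000, fill = function(r, c, t) rnorm(length(t)))
  gs <- growing_season_from_phenology(flat_pheno(10, 10, 6, 9))
  rc <- windowed_correlations(anom, stk, gs, window_spec())
  rbar <- mean(rc$r, na.rm = TRUE)
  n_eff <- sum(!is.na(rc$r))
  se <- sd(rc$r, na.rm = TRUE) / sqrt(n_eff / 12)   # scales share samples
  expect_lt(abs(rbar), 3 * se + 0.02)
})

test_that("the water-constrained mask uses a strict positive mean", {
  d <- c(1, 1, 10)
  mk_rs <- function(series) {
    s <- array(series, d)
    structure(list(sensitivity = s, ced = array(1L, d),
                   valid = !is.na(s), center_years = 2001:2010),
              class = "response_surface")
  }
  expect_true(water_constrained_mask(mk_rs(rep(0.3, 10)))$constrained[1, 1])
  expect_false(water_constrained_mask(mk_rs(rep(-0.2, 10)))$constrained[1, 1])
  alt <- water_constrained_mask(mk_rs(rep(c(0.1, -0.1), 5)))
  expect_equal(alt$mean_r[1, 1], 0)
  expect_false(alt$constrained[1, 1])       # strict inequality
  none <- water_constrained_mask(mk_rs(rep(NA_real_, 10)))
  expect_false(none$constrained[1, 1])
  expect_equal(none$n_valid[1, 1], 0)
})
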