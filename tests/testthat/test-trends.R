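test_that("Mann-Kendall matches base R Kendall inference on small samples", {
  set.seed(42)
  for (n in c(6, 8, 10)) {
    for (rep in 1:10) {
      x <- rnorm(n)
      mk <- mann_kendall(x)
      ct <- cor.test(seq_len(n), x, method = "kendall")
      expect_equal(mk$tau, unname(ct$estimate), tolerance = 1e-12)
      expect_equal(mk$p_value, ct$p.value, tolerance = 1e-12)
    }
  }
})

test_that("Mann-Kendall handles canonical series", {
  up <- mann_kendall(1:10)
  expect_equal(up$S, 45L)
  expect_equal(up$tau, 1)
  expect_lt(up$p_value, 0.001)

  const <- mann_kendall(rep(3, 12))
  expect_equal(const$S, 0L)
  expect_equal(const$p_value, 1)
  expect_equal(const$sen_slope, 0)
  expect_equal(const$tau, 0)

  down <- mann_kendall(10:1)
  expect_equal(down$S, -45L)
  expect_equal(down$tau, -1)
})

test_that("exact p-values equal the exhaustive permutation null for n = 8", {
  P <- all_permutations(1:8)
  expect_equal(nrow(P), factorial(8))
  Svals <- apply(P, 1, mk_s_statistic)
  for (s in unique(abs(Svals))) {
    expect_equal(vegwater:::mk_exact_p(s, 8), mean(abs(Svals) >= s),
                 tolerance = 1e-12)
  }
})

test_that("Sen slope and tau agree in sign and ties are tolerated", {
  set.seed(11)
  for (rep in 1:50) {
    x <- sample(0:3, 15, replace = TRUE)       # heavy ties, integer data
    mk <- mann_kendall(x)
    expect_gte(mk$p_value, 0)
    expect_lte(mk$p_value, 1)
    if (mk$tau != 0 && mk$sen_slope != 0)
      expect_equal(sign(mk$tau), sign(mk$sen_slope))
  }
})

make_surface <- function(series_fun, nrowg = 2, ncolg = 2,
                         years = 1984:2014) {
  d <- c(nrowg, ncolg, length(years))
  s <- array(NA_real_, d)
  for (i in seq_len(nrowg)) for (j in seq_len(ncolg))
    s[i, j, ] <- series_fun(i, j, years)
  structure(list(sensitivity = s,
                 ced = array(2L, d), valid = !is.na(s),
                 center_years = years),
            class = "response_surface")
}

test_that("trend_map finds a planted decline and respects the mask", {
  rs <- make_surface(function(i, j, yrs) 0.5 - 0.01 * (yrs - 1984))
  mask <- water_constrained_mask(rs)
  mask$constrained[2, 2] <- FALSE             # exclude one pixel
  tf <- trend_map(rs, "sensitivity", mask)
  expect_true(tf$significant[1, 1])
  expect_lt(tf$tau[1, 1], 0)
  expect_equal(tf$sen_slope[1, 1], -0.01, tolerance = 1e-10)
  expect_false(tf$valid[2, 2])
  expect_true(is.na(tf$p_value[2, 2]))
})

test_that("per-pixel false-positive rate on white noise is near alpha", {
  set.seed(606)
  n <- 500
  sig <- logical(n)
  for (i in seq_len(n)) {
    mk <- mann_kendall(rnorm(31), alpha = 0.05)
    sig[i] <- mk$significant
  }
  band <- qbinom(c(0.005, 0.995), n, 0.05) / n
  expect_gte(mean(sig), band[1])
  expect_lte(mean(sig), band[2])
})

test_that("stratified summaries count and partition correctly", {
  rs <- make_surface(function(i, j, yrs) {
    if (i == 1) 0.5 - 0.01 * (yrs - 1984) else 0.3 + 0 * yrs
  }, nrowg = 2, ncolg = 5)
  mask <- water_constrained_mask(rs)
  tf <- trend_map(rs, "sensitivity", mask)
  strata <- matrix(c(rep("a", 5), rep("b", 5)), 2, 5, byrow = TRUE)
  sm <- stratify(tf, strata)
  expect_equal(sm$n, c(5, 5))
  expect_equal(sm$fraction_decreasing[sm$stratum == "a"], 1)
  expect_equal(sm$fraction_decreasing[sm$stratum == "b"], 0)
  expect_equal(sum(sm$n), sum(tf$valid))

  # land-cover stratification with an empty class is flagged, not dropped
  lc <- landcover_map(matrix(c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 4L, 4L), 2, 5))
  sm2 <- stratify(tf, lc)
  expect_equal(sum(sm2$n), 10)
  expect_true(is.na(sm2$fraction_increasing[sm2$stratum == "other"]))
  expect_equal(sm2$n[sm2$stratum == "other"], 0)
})

test_that("planted land-cover effect shows up in the right stratum", {
  set.seed(31)
  years <- 1984:2014
  lc_codes <- matrix(sample(1:4, 100, replace = TRUE), 10, 10)
  rs <- make_surface(function(i, j, yrs) {
    base <- rnorm(length(yrs), 0.3, 0.03)
    if (lc_codes[i, j] == 4L) base + 0.012 * (yrs - 1984) else base
  }, nrowg = 10, ncolg = 10, years = years)
  mask <- water_constrained_mask(rs)
  tf <- trend_map(rs, "sensitivity", mask)
  sm <- stratify(tf, landcover_map(lc_codes))
  fi <- sm$fraction_increasing
  names(fi) <- sm$stratum
  expect_gt(fi["forest"], max(fi[c("shrubs", "herbaceous", "cropland")]))
})

test_that("rainfall zones bin mean annual precipitation at the isohyets", {
  # constant monthly precipitation of 20, 40 and 90 mm -> 240, 480, 1080 mm/yr
  g <- make_grid(1, 3, 24, 2000,
                 fill = function(r, c, t) c(20, 40, 90)[c])
  z <- rainfall_zones(g)
  expect_equal(as.vector(z), c("150-300", "300-600", "1000-1200"))
})

test_that("domain mean series reduces to the pixel series for uniform fields", {
  rs <- make_surface(function(i, j, yrs) 0.4 - 0.003 * (yrs - 1984))
  mask <- water_constrained_mask(rs)
  dm <- domain_mean_series(rs, mask)
  expect_equal(dm$mean, 0.4 - 0.003 * (dm$center_years - 1984),
               tolerance = 1e-12)
  expect_equal(dm$trend$sen_slope, -0.003, tolerance = 1e-10)
  expect_true(dm$trend$significant)

  # single-pixel domain equals that pixel
  rs1 <- make_surface(function(i, j, yrs) 0.3 + 0.1 * sin(yrs / 3),
                      nrowg = 1, ncolg = 1)
  dm1 <- domain_mean_series(rs1, water_constrained_mask(rs1))
  expect_equal(dm1$mean, as.vector(rs1$sensitivity[1, 1, ]))
})
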