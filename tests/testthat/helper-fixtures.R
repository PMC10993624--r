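# Small in-code fixtures shared across tests.

# A monthly grid with given dimensions filled from a function of (r, c, t)
# or from supplied values.
make_grid <- function(nrow = 3, ncol = 3, nt = 24, start_year = 2000,
                      fill = function(r, c, t) 0, variable = "x") {
  v <- array(NA_real_, c(nrow, ncol, nt))
  for (r in seq_len(nrow)) for (c in seq_len(ncol))
    v[r, c, ] <- fill(r, c, seq_len(nt))
  monthly_grid(v, start_year, 1L,
               list(xll = 0, yll = 0, cellsize = 0.05), variable)
}

# Uniform phenology map (same green-up / peak everywhere).
flat_pheno <- function(nrow = 3, ncol = 3, greenup = 6, peak = 9) {
  pheno_map(matrix(greenup, nrow, ncol), matrix(peak, nrow, ncol))
}

# SPEI-like stack where scale k carries the series in `series_for(k)`,
# identical at every pixel.
stack_from_series <- function(series_for, nrow = 3, ncol = 3, nt = 24,
                              start_year = 2000) {
  spei_stack(lapply(1:12, function(k) {
    s <- series_for(k)
    make_grid(nrow, ncol, nt, start_year, fill = function(r, c, t) s,
              variable = paste0("spei", k))
  }))
}

# Independent brute-force oracle for the first-peak-or-plateau scan:
# enumerate classic local maxima (boundary-adjusted) and plateau starts
# (next value higher by at most tol), and take the earliest index.
peak_oracle <- function(v, tol = 0.01) {
  idx <- which(!is.na(v))
  if (length(idx) == 0L) return(list(sensitivity = NA_real_, ced = NA_integer_))
  x <- v[idx]; m <- length(x)
  is_max <- vapply(seq_len(m), function(i)
    (i == 1L || x[i] >= x[i - 1L]) && (i == m || x[i] >= x[i + 1L]), logical(1))
  is_plateau <- c(vapply(seq_len(m - 1L), function(i)
    x[i + 1L] > x[i] && x[i + 1L] - x[i] <= tol, logical(1)), FALSE)
  cand <- which(is_max | is_plateau)
  i <- if (length(cand) > 0L) min(cand) else m
  list(sensitivity = x[i], ced = idx[i])
}

# Exhaustive Mann-Kendall S over all permutations of 1..n (small n only).
all_permutations <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1, 1))
  do.call(rbind, lapply(seq_along(v), function(i)
    cbind(v[i], all_permutations(v[-i]))))
}

mk_s_statistic <- function(x) {
  d <- outer(x, x, `-`)
  sum(sign(t(d)[upper.tri(d)]))
}

# A synthetic attribution feature table with one causal feature (by column
# index into the 8 driver features).
planted_table <- function(n = 300, causal = 3, seed = 1, noise = 0.2) {
  set.seed(seed)
  X <- as.data.frame(matrix(rnorm(n * 8), n, 8))
  names(X) <- paste0(vegwater:::driver_feature_names(), "_trend")
  X$response <- sin(2 * X[[causal]]) + rnorm(n, sd = noise)
  X
}
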