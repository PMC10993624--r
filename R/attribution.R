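#' Sen slope (median of pairwise slopes)
#'
#' @param x numeric series; `t` time vector.
#' @return slope in units of x per unit t (NA if fewer than 2 points).
#' @export
sen_slope <- function(x, t = seq_along(x)) {
  keep <- !is.na(x)
  x <- x[keep]; t <- t[keep]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  dx <- outer(x, x, `-`); dt <- outer(t, t, `-`)
  up <- upper.tri(dx)
  stats::median(t(dx)[up] / t(dt)[up])
}

driver_feature_names <- function()
  as.vector(t(outer(c("precipitation", "temperature", "radiation", "co2"),
                    c("mean", "sd"), paste, sep = "_")))

# Growing-season mean and SD of a T x P value matrix for one season-year.
gs_year_stats <- function(V, sel) {
  ok <- sel & !is.na(V)
  n <- colSums(ok)
  V0 <- ifelse(ok, V, 0)
  m <- colSums(V0) / n
  ss <- colSums(V0 * V0) - n * m^2
  s <- sqrt(pmax(ss, 0) / pmax(n - 1, 1))
  m[n < 2] <- NA; s[n < 2] <- NA
  list(mean = m, sd = s)
}

#' Climate-driver feature table for attribution
#'
#' For every retained pixel, builds eight features: the Sen-slope trend of
#' the window-averaged growing-season mean and growing-season standard
#' deviation of monthly precipitation, temperature, radiation and CO2.
#' Per season-year the growing-season mean/SD of each monthly driver is
#' computed, averaged inside the same moving window as the vegetation
#' response, and the trend of each per-centre-year feature series is taken.
#' The response is the per-pixel Sen slope of the vegetation response
#' (sensitivity or CED). Rows are restricted to water-constrained pixels
#' whose response trend is significant.
#'
#' @param drivers named list of co-registered [monthly_grid]s:
#'   `precipitation` (mm/month), `temperature` (K), `radiation` (J/m2).
#' @param co2 numeric vector of global monthly CO2 (ppm), one value per
#'   time step of the driver grids (broadcast to all pixels).
#' @param gs a `growing_season` object.
#' @param w the [window_spec] used for the response.
#' @param trend a `trend_field` for the chosen response.
#' @param mask a `water_constraint_mask`.
#' @param center_years window centre years of the response surface.
#' @param significant_only keep only pixels with a significant response
#'   trend (default TRUE, mirroring the attribution protocol).
#' @return data.frame: `row`, `col`, 8 feature columns
#'   (`<driver>_<mean|sd>_trend`), and `response` (response units per year).
#' @export
build_features <- function(drivers, co2, gs, w, trend, mask, center_years,
                           significant_only = TRUE) {
  stopifnot(is.list(drivers),
            all(c("precipitation", "temperature", "radiation") %in% names(drivers)),
            inherits(trend, "trend_field"),
            inherits(mask, "water_constraint_mask"))
  ref <- drivers$precipitation
  for (g in drivers) stop_if_not_coregistered(ref, g)
  nt <- n_times(ref)
  if (length(co2) != nt)
    stop("co2 series length (", length(co2), ") != number of months (", nt, ")")
  shp <- grid_shape(ref)
  np <- prod(shp)
  half <- w$width_years %/% 2L

  mem <- season_membership(ref, gs)
  mats <- lapply(drivers[c("precipitation", "temperature", "radiation")],
                 function(g) matrix(aperm(g$values, c(3, 1, 2)), nt, np))
  mats$co2 <- matrix(co2, nt, np)

  # per season-year growing-season stats, then window means per centre year
  years <- sort(unique(as.vector(mem$seasonyear)))
  years <- years[!is.na(years)]
  stats_by_year <- lapply(mats, function(V) {
    res <- list(mean = matrix(NA_real_, length(years), np),
                sd = matrix(NA_real_, length(years), np))
    for (yi in seq_along(years)) {
      sel <- !is.na(mem$seasonyear) & mem$seasonyear == years[yi]
      st <- gs_year_stats(V, sel)
      res$mean[yi, ] <- st$mean
      res$sd[yi, ] <- st$sd
    }
    res
  })

  feature_series <- function(per_year) {     # centre-year window averages
    out <- matrix(NA_real_, length(center_years), np)
    for (ci in seq_along(center_years)) {
      yi <- which(years >= center_years[ci] - half &
                    years <= center_years[ci] + half)
      if (length(yi) == 0L) next
      block <- per_year[yi, , drop = FALSE]
      out[ci, ] <- colMeans(block, na.rm = TRUE)
    }
    out
  }

  keep <- mask$constrained & trend$valid
  if (significant_only) keep <- keep & trend$significant
  idx <- which(keep)
  if (length(idx) == 0L) stop("no pixels satisfy the attribution row filter")

  feat <- matrix(NA_real_, length(idx), 8L,
                 dimnames = list(NULL, paste0(driver_feature_names(), "_trend")))
  colidx <- 1L
  for (dn in c("precipitation", "temperature", "radiation", "co2")) {
    for (stat in c("mean", "sd")) {
      series <- feature_series(stats_by_year[[dn]][[stat]])
      feat[, colidx] <- vapply(idx, function(p)
        sen_slope(series[, p], center_years), numeric(1))
      colidx <- colidx + 1L
    }
  }
  rc <- arrayInd(idx, shp)
  out <- data.frame(row = rc[, 1], col = rc[, 2], feat,
                    response = trend$sen_slope[idx], check.names = FALSE)
  out <- out[stats::complete.cases(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Out-of-bag aggregate predictions of a kept-inbag forest for arbitrary X.
oob_predict <- function(rf, X) {
  ind <- stats::predict(rf, X, predict.all = TRUE)$individual
  oob <- rf$inbag == 0
  rowSums(ind * oob) / rowSums(oob)
}

#' Random-forest attribution of response trends to climate drivers
#'
#' Trains a regression forest of the response trend on the eight driver
#' trend features using every row (attribution, not prediction), then
#' reports permutation importance (mean R-squared reduction over repeated
#' shuffles of one feature at a time) and partial-dependence curves over
#' the central 95% of each feature. Importance is scored on out-of-bag
#' predictions by default, which keeps a forest that interpolates its
#' training data from crediting uninformative features; set
#' `importance_mode = "insample"` to score on the training predictions.
#'
#' @param ft feature table from [build_features()] (or any data.frame with
#'   feature columns and a `response` column).
#' @param seed RNG seed controlling tree growth and shuffles.
#' @param n_trees number of trees (default 500).
#' @param mtry features tried per split (default `max(1, floor(p/3))`).
#' @param permutation_repeats shuffles per feature (default 10).
#' @param importance_mode `"oob"` (default) or `"insample"`.
#' @param pd_points grid size of each partial-dependence curve (default 20;
#'   0 skips the curves, e.g. in repeated-fit harnesses).
#' @param min_rows minimum rows required (default 50).
#' @return object of class `attribution_report`: `importance` (ranked
#'   data.frame with mean and SD per feature), `partial_dependence`
#'   (data.frame `feature`, `value`, `prediction`), `r2_train`, `r2_oob`,
#'   `n`, and the fitted forest.
#' @export
fit_rf_attribution <- function(ft, seed = 1L, n_trees = 500L, mtry = NULL,
                               permutation_repeats = 10L,
                               importance_mode = c("oob", "insample"),
                               pd_points = 20L, min_rows = 50L) {
  importance_mode <- match.arg(importance_mode)
  stopifnot("response" %in% names(ft))
  feat_cols <- setdiff(names(ft), c("row", "col", "lat", "lon", "response"))
  X <- as.data.frame(ft[, feat_cols, drop = FALSE])
  y <- ft$response
  n <- nrow(X); p <- ncol(X)
  if (n < min_rows) stop("attribution needs at least ", min_rows, " rows, got ", n)
  if (stats::var(y) < .Machine$double.eps)
    stop("response is constant: no attributable variance")
  if (is.null(mtry)) mtry <- max(1L, floor(p / 3))

  set.seed(seed)
  rf <- randomForest::randomForest(x = X, y = y, ntree = n_trees, mtry = mtry,
                                   keep.inbag = TRUE, keep.forest = TRUE)
  r2 <- function(pred) 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  r2_train <- r2(stats::predict(rf, X))
  r2_oob <- r2(rf$predicted)
  base_r2 <- if (importance_mode == "oob") r2_oob else r2_train
  predictor <- if (importance_mode == "oob") {
    function(Xp) oob_predict(rf, Xp)
  } else {
    function(Xp) stats::predict(rf, Xp)
  }

  imp <- matrix(NA_real_, permutation_repeats, p,
                dimnames = list(NULL, feat_cols))
  for (rep_i in seq_len(permutation_repeats)) {
    for (j in seq_len(p)) {
      Xp <- X
      Xp[[j]] <- X[[j]][sample.int(n)]
      imp[rep_i, j] <- base_r2 - r2(predictor(Xp))
    }
  }
  importance <- data.frame(feature = feat_cols,
                           importance = colMeans(imp),
                           sd = apply(imp, 2, stats::sd),
                           stringsAsFactors = FALSE)
  importance <- importance[order(-importance$importance), ]
  importance$rank <- seq_len(p)
  rownames(importance) <- NULL

  pd <- if (pd_points < 2L) NULL else do.call(rbind, lapply(feat_cols, function(fc) {
    qs <- stats::quantile(X[[fc]], c(0.025, 0.975), names = FALSE)
    grid <- seq(qs[1], qs[2], length.out = pd_points)
    pred <- vapply(grid, function(v) {
      Xg <- X; Xg[[fc]] <- v
      mean(stats::predict(rf, Xg))
    }, numeric(1))
    data.frame(feature = fc, value = grid, prediction = pred,
               stringsAsFactors = FALSE)
  }))

  structure(list(importance = importance, partial_dependence = pd,
                 r2_train = r2_train, r2_oob = r2_oob, n = n,
                 importance_mode = importance_mode,
                 seed = seed, n_trees = n_trees, mtry = mtry,
                 permutation_repeats = permutation_repeats, forest = rf),
            class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat(sprintf("<attribution_report> n=%d, trees=%d, training R2=%.3f, OOB R2=%.3f\n",
              x$n, x$n_trees, x$r2_train, x$r2_oob))
  print(x$importance[, c("rank", "feature", "importance", "sd")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write an attribution report to disk
#'
#' CSV of ranked importances, one partial-dependence CSV per feature and a
#' JSON summary of the fit.
#'
#' @param att an `attribution_report`.
#' @param dir output directory (created if absent).
#' @return character vector of written paths, invisibly.
#' @export
write_attribution_report <- function(att, dir) {
  stopifnot(inherits(att, "attribution_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "importance.csv")
  utils::write.csv(att$importance, paths[1], row.names = FALSE)
  for (fc in unique(att$partial_dependence$feature)) {
    p <- file.path(dir, paste0("pd_", fc, ".csv"))
    utils::write.csv(att$partial_dependence[att$partial_dependence$feature == fc,
                                            c("value", "prediction")],
                     p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "fit.json")
  jsonlite::write_json(list(n = att$n, r2_train = att$r2_train,
                            r2_oob = att$r2_oob, n_trees = att$n_trees,
                            mtry = att$mtry, seed = att$seed,
                            importance_mode = att$importance_mode),
                       p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
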