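#' Run the full vegetation-water response pipeline
#'
#' Convenience wrapper chaining anomaly computation, linear detrending,
#' growing-season construction, moving-window correlation over SPEI scales
#' 1-12, the first-peak-or-plateau response surface and the
#' water-constrained mask.
#'
#' @param ndvi raw NDVI [monthly_grid].
#' @param spei a [spei_stack].
#' @param pheno a [pheno_map].
#' @param w a [window_spec].
#' @param plateau_tol plateau tolerance in r units (default 0.01).
#' @return list with `anomalies`, `gs`, `r_cube`, `surface`
#'   (`response_surface`), and `mask` (`water_constraint_mask`).
#' @export
run_response_pipeline <- function(ndvi, spei, pheno, w = window_spec(),
                                  plateau_tol = 0.01) {
  anom <- detrend_linear(compute_anomalies(ndvi))
  gs <- growing_season_from_phenology(pheno)
  rc <- windowed_correlations(anom, spei, gs, w)
  rs <- response_surface(rc, plateau_tol = plateau_tol)
  mask <- water_constrained_mask(rs)
  list(anomalies = anom, gs = gs, r_cube = rc, surface = rs, mask = mask)
}
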