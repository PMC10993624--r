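#' Block-aggregate a matrix to a coarser grid
#'
#' Continuous fields are averaged over `factor x factor` blocks; a target
#' cell with less than `min_frac` valid contributing area becomes missing.
#'
#' @param mat numeric matrix; dimensions must be multiples of `factor`.
#' @param factor integer aggregation factor (>= 1).
#' @param min_frac minimum valid fraction per block (default 0.5).
#' @return aggregated matrix.
#' @export
block_average <- function(mat, factor, min_frac = 0.5) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L, nrow(mat) %% factor == 0L, ncol(mat) %% factor == 0L)
  if (factor == 1L) return(mat)
  nr <- nrow(mat) %/% factor; nc <- ncol(mat) %/% factor
  # fold each factor x factor block into the 1st and 3rd array margins
  a <- array(mat, c(factor, nr, factor, nc))
  ok <- !is.na(a)
  s <- apply(ifelse(ok, a, 0), c(2, 4), sum)
  n <- apply(ok, c(2, 4), sum)
  out <- s / n
  out[n / factor^2 < min_frac] <- NA
  out
}

#' Block-majority resampling for categorical maps
#'
#' Each target cell takes the modal class of its `factor x factor` block;
#' ties are broken deterministically towards the lowest class code. Blocks
#' with less than `min_frac` valid area become missing.
#'
#' @inheritParams block_average
#' @return aggregated integer matrix of class codes.
#' @export
block_majority <- function(mat, factor, min_frac = 0.5) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L, nrow(mat) %% factor == 0L, ncol(mat) %% factor == 0L)
  if (factor == 1L) return(mat)
  nr <- nrow(mat) %/% factor; nc <- ncol(mat) %/% factor
  out <- matrix(NA_integer_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    blk <- mat[((i - 1L) * factor + 1L):(i * factor),
               ((j - 1L) * factor + 1L):(j * factor)]
    v <- blk[!is.na(blk)]
    if (length(v) / factor^2 < min_frac) next
    tab <- table(v)
    win <- as.integer(names(tab)[tab == max(tab)])
    out[i, j] <- min(win)   # lowest code wins ties
  }
  out
}

#' Align grids and maps onto a target geometry
#'
#' Resamples every input onto the geometry of `target` (typically the SPEI
#' grid): continuous grids by block averaging, categorical maps by majority
#' vote, and crops all monthly grids to the common time span. Only
#' integer-factor, same-origin coarsening within one CRS is supported.
#'
#' @param grids named list of [monthly_grid], [pheno_map] or
#'   [landcover_map] objects.
#' @param target a [monthly_grid] defining the output geometry.
#' @param min_frac minimum valid contributing fraction per output cell.
#' @return named list of aligned objects (monthly grids also time-cropped
#'   to the intersection of all input spans).
#' @export
align_grids <- function(grids, target, min_frac = 0.5) {
  stopifnot(inherits(target, "monthly_grid"))
  tg <- target$geotransform
  tshape <- grid_shape(target)

  factor_for <- function(geo, shape) {
    f <- tg$cellsize / geo$cellsize
    if (abs(f - round(f)) > 1e-6 || f < 1 - 1e-9)
      stop("cell size ", geo$cellsize, " is not an integer refinement of the ",
           "target cell size ", tg$cellsize)
    f <- as.integer(round(f))
    if (abs(geo$xll - tg$xll) > 1e-6 * tg$cellsize ||
        abs(geo$yll - tg$yll) > 1e-6 * tg$cellsize)
      stop("grid origin differs from target origin; only same-origin ",
           "alignment is supported")
    if (!all(shape == tshape * f))
      stop("spatial extent differs from the target extent")
    f
  }

  out <- vector("list", length(grids))
  names(out) <- names(grids)
  mg <- vapply(grids, inherits, logical(1), what = "monthly_grid")

  # common monthly span across target and all monthly inputs
  spans <- lapply(c(list(target), grids[mg]), function(g) {
    ti <- time_index(g)
    c(ti$year[1] * 12L + ti$month[1],
      ti$year[nrow(ti)] * 12L + ti$month[nrow(ti)])
  })
  lo <- max(vapply(spans, `[`, numeric(1), 1))
  hi <- min(vapply(spans, `[`, numeric(1), 2))
  if (lo > hi) stop("monthly grids have no overlapping time span")
  from <- c((lo - 1L) %/% 12L, (lo - 1L) %% 12L + 1L)
  from[1] <- (lo - from[2]) %/% 12L
  to <- c(0L, (hi - 1L) %% 12L + 1L)
  to[1] <- (hi - to[2]) %/% 12L

  for (i in seq_along(grids)) {
    g <- grids[[i]]
    if (inherits(g, "monthly_grid")) {
      f <- factor_for(g$geotransform, grid_shape(g))
      gc <- crop_time(g, from, to)
      if (f > 1L) {
        nt <- n_times(gc)
        v <- array(NA_real_, c(tshape, nt))
        for (t in seq_len(nt))
          v[, , t] <- block_average(gc$values[, , t], f, min_frac)
        gc <- monthly_grid(v, gc$start_year, gc$start_month, tg,
                           g$variable, g$units)
      }
      out[[i]] <- gc
    } else if (inherits(g, "pheno_map")) {
      # calendar months are categorical: only identity pass-through supported
      if (!all(dim(g$greenup) == tshape))
        stop("phenology map must already be on the target geometry")
      out[[i]] <- g
    } else if (inherits(g, "landcover_map")) {
      shape <- dim(g$class_code)
      if (all(shape == tshape)) { out[[i]] <- g; next }
      f <- as.integer(round(shape[1] / tshape[1]))
      if (!all(shape == tshape * f))
        stop("land-cover extent is not an integer refinement of the target")
      out[[i]] <- landcover_map(block_majority(g$class_code, f, min_frac))
    } else stop("unsupported object of class ", class(g)[1])
  }
  out
}
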