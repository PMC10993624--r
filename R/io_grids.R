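#' @name grid_io
#' @title Grid input/output in the ESRI ASCII raster format
#'
#' @description
#' All gridded data is exchanged as ESRI ASCII grids (`.asc`): a six-line
#' header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by `nrows` lines of values, north row first.
#' A monthly stack is a directory of per-month files named
#' `<variable>_YYYYMM.asc`; single-band maps (phenology, land cover) are
#' single files. The format is plain text and readable by standard GIS
#' software.
NULL

NODATA <- -9999

write_asc <- function(mat, path, geotransform, digits = 10) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(mat)),
    paste("nrows", nrow(mat)),
    paste("xllcorner", format(geotransform$xll, digits = 15)),
    paste("yllcorner", format(geotransform$yll, digits = 15)),
    paste("cellsize", format(geotransform$cellsize, digits = 15)),
    paste("NODATA_value", NODATA)
  ), con)
  m <- mat
  m[is.na(m)] <- NODATA
  utils::write.table(format(m, digits = digits, trim = TRUE, scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

read_asc <- function(path) {
  hdr <- utils::read.table(path, nrows = 6, col.names = c("key", "value"),
                           colClasses = c("character", "numeric"))
  keys <- tolower(hdr$key)
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% keys))
    stop("not an ESRI ASCII grid (missing header keys): ", path)
  h <- stats::setNames(hdr$value, keys)
  vals <- scan(path, what = numeric(), skip = 6, quiet = TRUE)
  if (length(vals) != h["ncols"] * h["nrows"])
    stop("grid body has ", length(vals), " values, header promises ",
         h["ncols"] * h["nrows"], ": ", path)
  mat <- matrix(vals, nrow = h["nrows"], ncol = h["ncols"], byrow = TRUE)
  mat[mat == h["nodata_value"]] <- NA
  list(values = mat,
       geotransform = list(xll = unname(h["xllcorner"]),
                           yll = unname(h["yllcorner"]),
                           cellsize = unname(h["cellsize"])))
}

stack_file_name <- function(variable, year, month)
  sprintf("%s_%04d%02d.asc", variable, year, month)

#' Write a monthly stack as a directory of ASCII grids
#'
#' One `.asc` file per month, named `<variable>_YYYYMM.asc`.
#'
#' @param g a [monthly_grid].
#' @param path directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_monthly_stack <- function(g, path) {
  stopifnot(inherits(g, "monthly_grid"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ti <- time_index(g)
  for (t in seq_len(n_times(g)))
    write_asc(g$values[, , t],
              file.path(path, stack_file_name(g$variable, ti$year[t], ti$month[t])),
              g$geotransform, digits = 17)
  invisible(path)
}

#' Read a monthly stack from a directory of ASCII grids
#'
#' Collects `<variable>_YYYYMM.asc` files, orders them by date and checks
#' that they form a contiguous monthly sequence on a single geometry.
#'
#' @param path directory containing the per-month files.
#' @param variable variable name encoded in the file names.
#' @param units unit string to attach.
#' @return a [monthly_grid].
#' @export
read_monthly_stack <- function(path, variable, units = "") {
  files <- list.files(path, pattern = paste0("^", variable, "_\\d{6}\\.asc$"),
                      full.names = TRUE)
  if (length(files) == 0L)
    stop("no '", variable, "_YYYYMM.asc' files under ", path)
  ym <- sub(paste0("^", variable, "_(\\d{6})\\.asc$"), "\\1", basename(files))
  year <- as.integer(substr(ym, 1, 4)); month <- as.integer(substr(ym, 5, 6))
  if (any(month < 1 | month > 12))
    stop("file name encodes an invalid month: ",
         basename(files[which(month < 1 | month > 12)[1]]))
  ord <- order(year * 12L + month)
  files <- files[ord]; year <- year[ord]; month <- month[ord]
  key <- year * 12L + month
  if (anyDuplicated(key))
    stop("duplicate month in stack: ",
         sprintf("%04d-%02d", year[duplicated(key)][1], month[duplicated(key)][1]))
  gap <- which(diff(key) != 1L)
  if (length(gap) > 0L) {
    miss <- key[gap[1]] + 1L
    mm <- (miss - 1L) %% 12L + 1L
    stop(sprintf("monthly stack has a gap: %04d-%02d is missing",
                 (miss - mm) %/% 12L, mm))
  }
  first <- read_asc(files[1])
  vals <- array(NA_real_, c(dim(first$values), length(files)))
  vals[, , 1] <- first$values
  for (t in seq_along(files)[-1]) {
    g <- read_asc(files[t])
    if (!all(dim(g$values) == dim(first$values)) ||
        !isTRUE(all.equal(g$geotransform, first$geotransform)))
      stop("geometry of ", basename(files[t]), " differs from ", basename(files[1]))
    vals[, , t] <- g$values
  }
  monthly_grid(vals, year[1], month[1], first$geotransform, variable, units)
}

#' Write / read single-band maps
#'
#' Phenology maps are stored as two ASCII grids (`greenup.asc`, `peak.asc`);
#' land-cover maps as one grid of integer class codes.
#'
#' @param pm a [pheno_map]; `lc` a [landcover_map].
#' @param path directory (phenology) or file path (land cover).
#' @param geotransform georeferencing to stamp on the files.
#' @return the written path / the reconstructed object.
#' @name map_io
NULL

#' @rdname map_io
#' @export
write_pheno_map <- function(pm, path, geotransform) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_asc(pm$greenup, file.path(path, "greenup.asc"), geotransform)
  write_asc(pm$peak, file.path(path, "peak.asc"), geotransform)
  invisible(path)
}

#' @rdname map_io
#' @export
read_pheno_map <- function(path) {
  gu <- read_asc(file.path(path, "greenup.asc"))
  pk <- read_asc(file.path(path, "peak.asc"))
  pheno_map(gu$values, pk$values)
}

#' @rdname map_io
#' @export
write_landcover_map <- function(lc, path, geotransform) {
  write_asc(lc$class_code, path, geotransform)
  invisible(path)
}

#' @rdname map_io
#' @export
read_landcover_map <- function(path) {
  landcover_map(read_asc(path)$values)
}
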