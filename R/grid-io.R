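#' Lightweight in-memory raster grid
#'
#' `eco_grid` is the raster container used throughout the package: a plain
#' numeric matrix with geographic registration. Row 1 is the *northern* edge
#' of the extent (the usual raster convention), columns run west to east, and
#' all cells are square in decimal degrees. Missing / nodata cells are stored
#' as `NA` internally; the `nodata` sentinel is only used on disk.
#'
#' A longitude/latitude point is assigned to the cell containing it under
#' half-open intervals: `[west, east)` in longitude and `(south, north]` in
#' latitude, so every point maps to at most one cell.
#'
#' @param values numeric matrix (row 1 = northern edge); `NA` marks nodata.
#' @param xll,yll coordinates of the lower-left corner of the extent
#'   (decimal degrees).
#' @param cellsize cell edge length in decimal degrees; must be `> 0`.
#' @param nodata sentinel written to file for `NA` cells.
#' @param crs CRS tag carried along (informational; no reprojection is done).
#' @return An object of class `eco_grid`.
#' @examples
#' g <- eco_grid(matrix(1:6, 2, 3), xll = 0, yll = 0, cellsize = 0.5)
#' dim(g)
#' @export
eco_grid <- function(values, xll = 0, yll = 0, cellsize = 1,
                     nodata = -9999, crs = "EPSG:4326") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("`cellsize` must be a single positive number", call. = FALSE)
  structure(
    list(values = values, xll = as.numeric(xll), yll = as.numeric(yll),
         cellsize = as.numeric(cellsize), nodata = as.numeric(nodata),
         crs = crs),
    class = "eco_grid"
  )
}

#' @export
dim.eco_grid <- function(x) dim(x$values)

#' @export
print.eco_grid <- function(x, ...) {
  d <- dim(x$values)
  nv <- sum(!is.na(x$values))
  cat(sprintf("<eco_grid> %d x %d cells, cellsize %g deg, origin (%g, %g), %s\n",
              d[1], d[2], x$cellsize, x$xll, x$yll, x$crs))
  cat(sprintf("  valid cells: %d / %d", nv, prod(d)))
  if (nv > 0)
    cat(sprintf("; range [%g, %g]", min(x$values, na.rm = TRUE),
                max(x$values, na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

is_eco_grid <- function(x) inherits(x, "eco_grid")

#' Number of non-nodata cells
#' @param grid an [eco_grid].
#' @return Integer count of valid cells.
#' @export
n_valid <- function(grid) {
  stopifnot(is_eco_grid(grid))
  sum(!is.na(grid$values))
}

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Map longitude/latitude points to grid cells
#'
#' Uses half-open intervals `[west, east)` x `(south, north]` so each point
#' belongs to exactly one cell. Points outside the extent get `NA`.
#'
#' @param grid an [eco_grid].
#' @param lon,lat numeric vectors of equal length.
#' @return A tibble with columns `row`, `col` (`NA` when outside the grid).
#' @export
cell_from_lonlat <- function(grid, lon, lat) {
  stopifnot(is_eco_grid(grid), length(lon) == length(lat))
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cellsize
  col <- floor((lon - grid$xll) / cs) + 1L
  # latitude: cell counted from the bottom, top edge inclusive
  d <- (lat - grid$yll) / cs
  from_bottom <- ceiling(d)
  row <- nr - as.integer(from_bottom) + 1L
  bad <- col < 1L | col > nc | row < 1L | row > nr |
    !is.finite(lon) | !is.finite(lat)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

parse_ascii_header <- function(lines, path) {
  hdr <- list()
  i <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L || is.na(suppressWarnings(as.numeric(parts[2]))))
      break
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
    if (i >= 6L) break
  }
  required <- c("ncols", "nrows", "cellsize")
  missing <- setdiff(required, names(hdr))
  if (length(missing) > 0)
    stop(sprintf("ESRI ASCII header of '%s' is missing field(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  if (!any(c("xllcorner", "xllcenter") %in% names(hdr)))
    stop(sprintf("ESRI ASCII header of '%s' is missing field: xllcorner", path),
         call. = FALSE)
  if (!any(c("yllcorner", "yllcenter") %in% names(hdr)))
    stop(sprintf("ESRI ASCII header of '%s' is missing field: yllcorner", path),
         call. = FALSE)
  if (hdr$cellsize <= 0)
    stop(sprintf("ESRI ASCII header of '%s' has non-positive field: cellsize",
                 path), call. = FALSE)
  hdr$n_header_lines <- i
  hdr
}

#' Read a raster grid from disk
#'
#' Reads an ESRI ASCII grid (`ncols`/`nrows`/`xllcorner`/`yllcorner`/
#' `cellsize`/`NODATA_value` header followed by row-major values, northern
#' row first). `xllcenter`/`yllcenter` headers are converted to the corner
#' convention. Cells equal to the nodata sentinel become `NA`.
#'
#' @param path file to read.
#' @param format only `"esri_ascii"` is supported.
#' @return An [eco_grid].
#' @export
read_grid <- function(path, format = c("esri_ascii")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("raster file '%s' does not exist", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- parse_ascii_header(lines[seq_len(min(6L, length(lines)))], path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  cs <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  body <- lines[-seq_len(hdr$n_header_lines)]
  vals <- suppressWarnings(as.numeric(scan(text = paste(body, collapse = " "),
                                           what = "", quiet = TRUE)))
  if (anyNA(vals))
    stop(sprintf("non-numeric cell value in '%s'", path), call. = FALSE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop(sprintf(
      "'%s': expected %d values (ncols x nrows) but found %d",
      path, hdr$ncols * hdr$nrows, length(vals)), call. = FALSE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  eco_grid(m, xll = xll, yll = yll, cellsize = cs, nodata = nodata)
}

#' Write a raster grid to disk
#'
#' Writes an ESRI ASCII grid re-readable by [read_grid()] with identical
#' mask and transform. Values are written with `digits` significant digits
#' (default 6); `NA` cells are written as the grid's nodata sentinel.
#'
#' @param grid an [eco_grid].
#' @param path output file; its parent directory must exist.
#' @param format only `"esri_ascii"` is supported.
#' @param digits significant digits for cell values.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, format = c("esri_ascii"), digits = 6) {
  format <- match.arg(format)
  stopifnot(is_eco_grid(grid))
  if (!dir.exists(dirname(path)))
    stop(sprintf("cannot write '%s': directory does not exist", path),
         call. = FALSE)
  m <- grid$values
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", grid$xll),
    sprintf("yllcorner %.10g", grid$yll),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", grid$nodata)
  )
  fmt <- paste0("%.", digits, "g")
  chr <- matrix(sprintf(fmt, m), nrow = nrow(m))
  chr[is.na(m)] <- sprintf("%.10g", grid$nodata)
  rows <- apply(chr, 1L, paste, collapse = " ")
  ok <- tryCatch({
    writeLines(c(hdr, rows), path)
    TRUE
  }, error = function(e) {
    stop(sprintf("failed to write '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(path)
}

#' Bundle aligned raster layers into a stack
#'
#' A `grid_stack` is an ordered, named list of [eco_grid] layers sharing
#' shape and transform (e.g. the Bio1...Bio19 bioclimatic variables).
#'
#' @param grids a named list of [eco_grid] objects; names are the layer
#'   codes (e.g. `"Bio1"`). Order is preserved.
#' @return An object of class `grid_stack`.
#' @export
stack_layers <- function(grids) {
  if (length(grids) < 1L) stop("a stack needs at least one layer", call. = FALSE)
  codes <- names(grids)
  if (is.null(codes) || any(!nzchar(codes)))
    stop("all layers must be named with a layer code", call. = FALSE)
  if (anyDuplicated(codes))
    stop(sprintf("duplicate layer code(s): %s",
                 paste(unique(codes[duplicated(codes)]), collapse = ", ")),
         call. = FALSE)
  for (g in grids)
    if (!is_eco_grid(g)) stop("all layers must be eco_grid objects", call. = FALSE)
  ref <- grids[[1L]]
  for (i in seq_along(grids)) {
    if (!same_geometry(ref, grids[[i]]))
      stop(sprintf("layer '%s' is not aligned with layer '%s' (shape/transform mismatch)",
                   codes[i], codes[1L]), call. = FALSE)
  }
  structure(grids, class = "grid_stack")
}

#' @export
`[.grid_stack` <- function(x, i) stack_layers(unclass(x)[i])

#' @export
print.grid_stack <- function(x, ...) {
  d <- dim(x[[1L]]$values)
  cat(sprintf("<grid_stack> %d layer(s) of %d x %d cells: %s\n",
              length(x), d[1], d[2], paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Joint validity mask of a stack
#'
#' @param stack a `grid_stack`.
#' @return A logical-valued [eco_grid]: 1 exactly where *every* layer is
#'   non-nodata, 0 elsewhere (no `NA` cells in the mask itself).
#' @export
valid_mask <- function(stack) {
  stopifnot(inherits(stack, "grid_stack"))
  ref <- stack[[1L]]
  ok <- !is.na(ref$values)
  for (g in unclass(stack)[-1L]) ok <- ok & !is.na(g$values)
  eco_grid(ok + 0, xll = ref$xll, yll = ref$yll,
           cellsize = ref$cellsize, nodata = ref$nodata, crs = ref$crs)
}

#' Extract layer values at cells
#'
#' @param stack a `grid_stack`.
#' @param cells a data frame with integer columns `row`, `col`.
#' @return A tibble with one column per layer code.
#' @export
extract_cells <- function(stack, cells) {
  stopifnot(inherits(stack, "grid_stack"))
  idx <- cbind(cells$row, cells$col)
  out <- lapply(stack, function(g) g$values[idx])
  tibble::as_tibble(stats::setNames(out, names(stack)))
}

grid_to_tibble <- function(grid) {
  m <- grid$values
  nr <- nrow(m); nc <- ncol(m); cs <- grid$cellsize
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    lon = grid$xll + (rep(seq_len(nc), each = nr) - 0.5) * cs,
    lat = grid$yll + (nr - rep(seq_len(nr), times = nc) + 0.5) * cs,
    value = as.vector(m)
  )
}

#' Plot a raster grid with ggplot2
#'
#' @param object an [eco_grid].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot eco_grid
#' @export
autoplot.eco_grid <- function(object, ...) {
  df <- grid_to_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "value") +
    ggplot2::theme_minimal()
}
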