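#' Load presence-only occurrence records from CSV
#'
#' Expects a header with at least `species`, `lon`, `lat` (extra columns are
#' ignored; `source_id` is kept when present). Rows with unparseable or
#' out-of-range coordinates (|lon| > 180, |lat| > 90) are dropped and counted
#' in the load report attached as the `"load_report"` attribute.
#'
#' @param path CSV file, UTF-8, `.` decimal separator.
#' @return A tibble with columns `species`, `lon`, `lat`, `source_id`, and a
#'   `load_report` attribute (list with `n_rows`, `n_kept`, `n_dropped`).
#' @export
load_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("species", "lon", "lat")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop(sprintf("occurrence CSV '%s' is missing column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  n_rows <- nrow(df)
  lon <- suppressWarnings(as.numeric(df$lon))
  lat <- suppressWarnings(as.numeric(df$lat))
  keep <- is.finite(lon) & is.finite(lat) &
    lon >= -180 & lon <= 180 & lat >= -90 & lat <= 90
  out <- tibble::tibble(
    species = df$species[keep],
    lon = lon[keep],
    lat = lat[keep],
    source_id = if ("source_id" %in% names(df)) df$source_id[keep]
                else as.character(which(keep))
  )
  attr(out, "load_report") <- list(
    path = path, n_rows = n_rows, n_kept = sum(keep),
    n_dropped = n_rows - sum(keep)
  )
  out
}

#' Spatially rarefy occurrences to one record per grid cell
#'
#' Collapses multiple records falling in the same cell of the reference grid
#' to a single record (the first in input order), which curbs sampling bias
#' and spatial autocorrelation in presence-only modelling. Records falling
#' outside the grid or on nodata cells are dropped.
#'
#' @param occ occurrence tibble (`species`, `lon`, `lat`, ...).
#' @param grid reference [eco_grid] defining the cell tessellation (and the
#'   validity mask: `NA` cells are unusable).
#' @return The rarefied occurrence tibble with extra columns `row`, `col`,
#'   plus a `rarefy_report` attribute (`n_input`, `n_out_of_grid`,
#'   `n_nodata`, `n_duplicates`, `n_kept`).
#' @export
rarefy_occurrences <- function(occ, grid) {
  stopifnot(is_eco_grid(grid))
  if (nrow(occ) == 0L) {
    out <- dplyr::mutate(occ, row = integer(0), col = integer(0))
    attr(out, "rarefy_report") <- list(n_input = 0L, n_out_of_grid = 0L,
                                       n_nodata = 0L, n_duplicates = 0L,
                                       n_kept = 0L)
    return(out)
  }
  cells <- cell_from_lonlat(grid, occ$lon, occ$lat)
  inside <- !is.na(cells$row)
  valid <- inside
  valid[inside] <- !is.na(grid$values[cbind(cells$row[inside],
                                            cells$col[inside])])
  occ2 <- occ[valid, , drop = FALSE]
  occ2$row <- cells$row[valid]
  occ2$col <- cells$col[valid]
  key <- paste(occ2$row, occ2$col)
  first <- !duplicated(key)
  out <- tibble::as_tibble(occ2[first, , drop = FALSE])
  attr(out, "rarefy_report") <- list(
    n_input = nrow(occ),
    n_out_of_grid = sum(!inside),
    n_nodata = sum(inside) - sum(valid),
    n_duplicates = sum(valid) - sum(first),
    n_kept = nrow(out)
  )
  out
}

#' Split occurrences into calibration and validation sets
#'
#' Seeded random split; `round(train_frac * n)` records go to the training
#' (calibration) set and the remainder to the test (validation) set.
#'
#' @param occ occurrence tibble.
#' @param train_frac fraction for calibration, in (0, 1); default 0.75.
#' @param seed integer seed; the same seed reproduces the same split.
#' @return A list with tibbles `train` and `test` (disjoint, union = input).
#' @export
partition_occurrences <- function(occ, train_frac = 0.75, seed = 1L) {
  n <- nrow(occ)
  if (n < 2L) stop("need at least 2 records to split", call. = FALSE)
  if (!(train_frac > 0 && train_frac < 1))
    stop("`train_frac` must be in (0, 1)", call. = FALSE)
  n_train <- round(train_frac * n)
  n_train <- max(1L, min(n - 1L, n_train))
  idx <- withr::with_seed(as.integer(seed), sample.int(n, n_train))
  list(train = occ[sort(idx), , drop = FALSE],
       test = occ[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Sample background cells uniformly from the valid area
#'
#' Background cells act as the availability sample (pseudo-absences) in
#' presence-only modelling. Cells are drawn uniformly without replacement
#' from the valid cells of `mask`; if fewer valid cells than `n` exist, all
#' are returned.
#'
#' @param mask an [eco_grid] whose non-`NA`, non-zero cells are sampleable
#'   (e.g. the output of [valid_mask()]).
#' @param n number of background cells requested (default 10000).
#' @param seed integer seed.
#' @param exclude optional data frame with `row`, `col` of cells never to
#'   sample (e.g. presence cells).
#' @return A tibble with columns `row`, `col`.
#' @export
sample_background <- function(mask, n = 10000L, seed = 1L, exclude = NULL) {
  stopifnot(is_eco_grid(mask), n >= 1L)
  ok <- !is.na(mask$values) & mask$values != 0
  if (!is.null(exclude) && nrow(exclude) > 0) {
    ok[cbind(exclude$row, exclude$col)] <- FALSE
  }
  avail <- which(ok)
  if (length(avail) == 0L)
    stop("no valid cells available for background sampling", call. = FALSE)
  k <- min(n, length(avail))
  picked <- withr::with_seed(as.integer(seed),
                             sample(avail, k, replace = FALSE))
  picked <- sort(picked)
  nr <- nrow(mask$values)
  tibble::tibble(row = as.integer((picked - 1L) %% nr + 1L),
                 col = as.integer((picked - 1L) %/% nr + 1L))
}
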