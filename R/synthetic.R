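#' Simulate a stack of correlated, climate-like raster layers
#'
#' Generates smooth Gaussian random fields (white noise convolved with a
#' separable Gaussian kernel), standardises them, and mixes them with the
#' Cholesky factor of `corr_target` so that the empirical inter-layer
#' correlation over cells approaches the target. Each layer is then given a
#' climate-flavoured location/scale so values look like temperatures or
#' precipitation rather than z-scores. Deterministic per seed.
#'
#' @param shape `c(rows, cols)` of the grid.
#' @param n_layers number of layers; codes are `Bio1`, `Bio2`, ...
#' @param corr_target symmetric positive semi-definite target correlation
#'   matrix (`n_layers` x `n_layers`); default identity.
#' @param smoothing Gaussian kernel lengthscale in cells (default 8).
#' @param seed integer seed.
#' @param xll,yll,cellsize georeferencing of the synthetic extent.
#' @return A `grid_stack`.
#' @export
simulate_bioclim_stack <- function(shape, n_layers,
                                   corr_target = diag(n_layers),
                                   smoothing = 8, seed = 1L,
                                   xll = 0, yll = 0,
                                   cellsize = 2.5 / 60) {
  stopifnot(length(shape) == 2L, n_layers >= 1L, smoothing > 0)
  corr_target <- as.matrix(corr_target)
  if (!isTRUE(all.equal(corr_target, t(corr_target), tolerance = 1e-8)))
    stop("`corr_target` must be symmetric", call. = FALSE)
  U <- tryCatch(chol(corr_target),
                error = function(e)
                  stop("`corr_target` is not positive semi-definite",
                       call. = FALSE))
  nr <- shape[1L]; nc <- shape[2L]
  fields <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_layers), function(i) {
      smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), smoothing)
    })
  })
  # standardise, then mix columns to the target correlation
  Fm <- vapply(fields, function(m) {
    v <- as.vector(m)
    (v - mean(v)) / stats::sd(v)
  }, numeric(nr * nc))
  mixed <- Fm %*% U
  # climate-flavoured units: odd layers temperature-like, even precipitation-like
  grids <- lapply(seq_len(n_layers), function(i) {
    v <- mixed[, i]
    v <- if (i %% 2L == 1L) 12 + 8 * v else pmax(0, 900 + 400 * v)
    eco_grid(matrix(v, nr, nc), xll = xll, yll = yll, cellsize = cellsize)
  })
  names(grids) <- paste0("Bio", seq_len(n_layers))
  stack_layers(grids)
}

# separable Gaussian smoothing with edge renormalisation
smooth_field <- function(m, lengthscale) {
  half <- max(1L, ceiling(3 * lengthscale))
  k <- stats::dnorm(seq(-half, half), sd = lengthscale)
  k <- k / sum(k)
  num <- conv_axis(conv_axis(m, k, by_row = FALSE), k, by_row = TRUE)
  den <- conv_axis(conv_axis(matrix(1, nrow(m), ncol(m)), k,
                             by_row = FALSE), k, by_row = TRUE)
  num / den
}

conv_axis <- function(m, k, by_row) {
  half <- (length(k) - 1L) %/% 2L
  if (by_row) m <- t(m)
  n <- nrow(m)
  padded <- rbind(matrix(0, half, ncol(m)), m, matrix(0, half, ncol(m)))
  out <- matrix(0, n, ncol(m))
  for (i in seq_along(k))
    out <- out + k[i] * padded[i:(i + n - 1L), , drop = FALSE]
  if (by_row) t(out) else out
}

#' Construct a virtual species with known Gibbs suitability
#'
#' The true niche is a Gibbs (maximum-entropy) model that is linear in the
#' min-max-scaled layers: raw density proportional to
#' `exp(sum_v lambda_v * scaled_v)` over valid cells, and the true
#' suitability is its cloglog transform with the entropy computed over all
#' valid cells. This gives the generator the same functional form the
#' fitted model assumes, so parameter/structure recovery is well defined.
#'
#' @param stack a `grid_stack`.
#' @param true_lambda named numeric vector (layer code -> weight); codes
#'   must exist in the stack. Layers not named get weight 0.
#' @return A `virtual_niche`: list with `true_lambda`, `raw` (eco_grid of
#'   normalised Gibbs density), `suitability` (cloglog eco_grid),
#'   `entropy`.
#' @export
make_virtual_niche <- function(stack, true_lambda) {
  stopifnot(inherits(stack, "grid_stack"))
  missing <- setdiff(names(true_lambda), names(stack))
  if (length(missing) > 0)
    stop(sprintf("true_lambda names not in stack: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  mask <- valid_mask(stack)
  ok <- mask$values != 0
  idx <- which(ok, arr.ind = TRUE)
  eta <- numeric(nrow(idx))
  for (v in names(true_lambda)) {
    x <- stack[[v]]$values[idx]
    r <- range(x)
    s <- if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else rep(0, length(x))
    eta <- eta + true_lambda[[v]] * s
  }
  lse <- logsumexp(eta)
  q <- exp(eta - lse)
  H <- -sum(ifelse(q > 0, q * log(q), 0))
  cc <- 1 - exp(-exp(H) * q)
  ref <- stack[[1L]]
  as_grid <- function(v) {
    m <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
    m[idx] <- v
    eco_grid(m, xll = ref$xll, yll = ref$yll, cellsize = ref$cellsize,
             nodata = ref$nodata, crs = ref$crs)
  }
  structure(list(true_lambda = true_lambda, raw = as_grid(q),
                 suitability = as_grid(cc), entropy = H),
            class = "virtual_niche")
}

#' Sample presence records from a virtual niche
#'
#' Cells are drawn with probability proportional to the true Gibbs density;
#' each record is placed uniformly at random inside its cell. A fraction
#' `dup_rate` of the records is then re-drawn *into already-sampled cells*,
#' producing the within-cell duplicates that spatial rarefaction is meant
#' to remove.
#'
#' @param niche a `virtual_niche`.
#' @param n number of records.
#' @param dup_rate fraction of records that duplicate an occupied cell.
#' @param seed integer seed.
#' @param species species label for the records.
#' @return An occurrence tibble (`species`, `lon`, `lat`, `source_id`).
#' @export
sample_presences <- function(niche, n, dup_rate = 0, seed = 1L,
                             species = "virtual") {
  stopifnot(inherits(niche, "virtual_niche"), n >= 1L,
            dup_rate >= 0, dup_rate < 1)
  g <- niche$raw
  ok <- !is.na(g$values)
  cells <- which(ok)
  pr <- g$values[cells]
  nr <- nrow(g$values)
  withr::with_seed(as.integer(seed), {
    n_base <- n - round(n * dup_rate)
    n_base <- max(1L, n_base)
    draw <- sample(cells, n_base, replace = TRUE, prob = pr)
    if (n > n_base)
      draw <- c(draw, sample(draw, n - n_base, replace = TRUE))
    row <- (draw - 1L) %% nr + 1L
    col <- (draw - 1L) %/% nr + 1L
    cs <- g$cellsize
    u <- stats::runif(length(draw)); v <- stats::runif(length(draw))
    tibble::tibble(
      species = species,
      lon = g$xll + (col - 1L + u) * cs,
      lat = g$yll + (nr - row + v) * cs,
      source_id = sprintf("sim-%05d", seq_along(draw))
    )
  })
}

#' Perturb layers into a future-scenario stack
#'
#' Applies an affine transform `x -> shift + scale * x` to the named
#' layers, leaving the others (and all masks) untouched — a stand-in for
#' future climate layer sets.
#'
#' @param stack a `grid_stack`.
#' @param deltas named list code -> `c(shift, scale)` (or a single shift;
#'   scale defaults to 1).
#' @return A new `grid_stack`.
#' @export
perturb_scenario <- function(stack, deltas) {
  stopifnot(inherits(stack, "grid_stack"))
  missing <- setdiff(names(deltas), names(stack))
  if (length(missing) > 0)
    stop(sprintf("deltas name layers not in stack: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  out <- unclass(stack)
  for (v in names(deltas)) {
    d <- deltas[[v]]
    shift <- d[1L]; scale <- if (length(d) > 1L) d[2L] else 1
    out[[v]]$values <- shift + scale * out[[v]]$values
  }
  stack_layers(out)
}

#' Partition a grid into contiguous random zones
#'
#' Seeded Voronoi growth: `k` seed cells are drawn among the valid cells
#' and every valid cell joins its nearest seed (row/col Euclidean distance,
#' ties to the lower zone id). Stands in for administrative divisions or
#' continents in zonal accounting.
#'
#' @param mask an [eco_grid] whose non-`NA`, non-zero cells are the valid
#'   area (e.g. from [valid_mask()]).
#' @param k number of zones.
#' @param seed integer seed.
#' @param cell_area_km2 per-cell area used for the zone table totals.
#' @return A `zone_set`: list with `raster` (integer eco_grid, 0 outside)
#'   and `table` (tibble `zone_id`, `name`, `total_area_km2`).
#' @export
make_zones <- function(mask, k, seed = 1L, cell_area_km2 = 4.5) {
  stopifnot(is_eco_grid(mask), k >= 1L)
  ok <- !is.na(mask$values) & mask$values != 0
  valid <- which(ok, arr.ind = TRUE)
  if (k > nrow(valid))
    stop("more zones requested than valid cells", call. = FALSE)
  seeds <- withr::with_seed(as.integer(seed),
                            valid[sample.int(nrow(valid), k), , drop = FALSE])
  d2 <- outer(valid[, 1L], seeds[, 1L], "-")^2 +
    outer(valid[, 2L], seeds[, 2L], "-")^2
  assign <- max.col(-d2, ties.method = "first")
  z <- matrix(0, nrow(mask$values), ncol(mask$values))
  z[valid] <- assign
  counts <- tabulate(assign, nbins = k)
  structure(
    list(raster = eco_grid(z, xll = mask$xll, yll = mask$yll,
                           cellsize = mask$cellsize, nodata = mask$nodata,
                           crs = mask$crs),
         table = tibble::tibble(zone_id = seq_len(k),
                                name = paste0("zone_", seq_len(k)),
                                total_area_km2 = counts * cell_area_km2)),
    class = "zone_set")
}

#' @export
print.zone_set <- function(x, ...) {
  cat(sprintf("<zone_set> %d zone(s), total area %g km^2\n",
              nrow(x$table), sum(x$table$total_area_km2)))
  invisible(x)
}
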