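#' Build a MaxEnt feature set from background cells
#'
#' Constructs the feature expansion of the environmental layers used by the
#' maximum-entropy model. Every feature is scaled so that it evaluates into
#' \[0, 1\] on the training background:
#' \describe{
#'   \item{L (linear)}{min-max scaled variable.}
#'   \item{Q (quadratic)}{the variable's square, min-max scaled.}
#'   \item{P (product)}{pairwise products of variables, min-max scaled.}
#'   \item{H (hinge)}{forward hinge `max(0, (x - k) / (max - k))` and
#'     reverse hinge `max(0, (k - x) / (k - min))`, knots `k` at background
#'     quantiles.}
#'   \item{T (threshold)}{step indicator `x > k`, knots at background
#'     quantiles.}
#' }
#' Per-variable background ranges are stored as clamp ranges: when the model
#' is projected onto new layers, inputs are clipped to these ranges so the
#' model never extrapolates beyond its training support.
#'
#' @param stack a `grid_stack` of environmental layers.
#' @param background data frame with `row`, `col` of background cells.
#' @param classes subset of `c("L","Q","P","H","T")`.
#' @param hinge_knots number of interior quantile knots per variable for
#'   hinge and threshold features (default 10).
#' @return A `feature_set`: list with `defs` (tibble: name, kind, var1,
#'   var2, knot, direction, lo, hi), `clamp` (per-variable min/max), `codes`.
#' @export
build_features <- function(stack, background,
                           classes = c("L", "Q", "H"),
                           hinge_knots = 10L) {
  stopifnot(inherits(stack, "grid_stack"))
  classes <- match.arg(classes, c("L", "Q", "P", "H", "T"),
                       several.ok = TRUE)
  if (any(c("H", "T") %in% classes) && hinge_knots < 2L)
    stop("`hinge_knots` must be >= 2 when hinge/threshold features are requested",
         call. = FALSE)
  bg <- extract_cells(stack, background)
  if (anyNA(bg))
    stop("background contains nodata cells", call. = FALSE)
  codes <- names(stack)
  clamp <- tibble::tibble(
    code = codes,
    min = vapply(bg, min, numeric(1)),
    max = vapply(bg, max, numeric(1))
  )
  defs <- list()
  add <- function(name, kind, var1, var2 = NA_character_,
                  knot = NA_real_, direction = NA_character_,
                  lo = NA_real_, hi = NA_real_) {
    defs[[length(defs) + 1L]] <<- tibble::tibble(
      name = name, kind = kind, var1 = var1, var2 = var2,
      knot = knot, direction = direction, lo = lo, hi = hi)
  }
  for (v in codes) {
    x <- bg[[v]]
    lo <- min(x); hi <- max(x)
    if (hi == lo) {
      warning(sprintf("layer '%s' is constant on the background; its features are dropped",
                      v), call. = FALSE)
      next
    }
    if ("L" %in% classes) add(v, "linear", v, lo = lo, hi = hi)
    if ("Q" %in% classes) {
      x2 <- x^2
      add(paste0(v, "^2"), "quadratic", v, lo = min(x2), hi = max(x2))
    }
    if ("H" %in% classes) {
      ks <- stats::quantile(x, probs = seq_len(hinge_knots) /
                              (hinge_knots + 1), names = FALSE, type = 7)
      for (k in unique(ks)) {
        if (k < hi) add(sprintf("h(%s>%.6g)", v, k), "hinge", v,
                        knot = k, direction = "fwd", lo = lo, hi = hi)
        if (k > lo) add(sprintf("h(%s<%.6g)", v, k), "hinge", v,
                        knot = k, direction = "rev", lo = lo, hi = hi)
      }
    }
    if ("T" %in% classes) {
      ks <- stats::quantile(x, probs = seq_len(hinge_knots) /
                              (hinge_knots + 1), names = FALSE, type = 7)
      for (k in unique(ks))
        if (k > lo && k < hi)
          add(sprintf("t(%s>%.6g)", v, k), "threshold", v, knot = k,
              lo = lo, hi = hi)
    }
  }
  if ("P" %in% classes && length(codes) >= 2L) {
    cmb <- utils::combn(codes, 2L)
    for (m in seq_len(ncol(cmb))) {
      u <- cmb[1L, m]; w <- cmb[2L, m]
      pr <- bg[[u]] * bg[[w]]
      if (max(pr) > min(pr))
        add(paste0(u, "*", w), "product", u, var2 = w,
            lo = min(pr), hi = max(pr))
    }
  }
  if (length(defs) == 0L)
    stop("no usable features could be built (all layers constant?)",
         call. = FALSE)
  structure(list(defs = dplyr::bind_rows(defs), clamp = clamp,
                 codes = codes, hinge_knots = hinge_knots),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d features over %d variable(s) (%s)\n",
              nrow(x$defs), length(x$codes),
              paste(sort(unique(x$defs$kind)), collapse = ", ")))
  invisible(x)
}

#' Evaluate a feature set on raw variable values
#'
#' @param fs a `feature_set`.
#' @param values data frame of raw layer values (one column per variable
#'   code, one row per cell), e.g. from [extract_cells()].
#' @param clamp clip each variable to its training-background range before
#'   evaluating (the projection default); features are additionally clipped
#'   to \[0, 1\].
#' @return Numeric matrix, rows = cells, columns = features (named).
#' @export
feature_matrix <- function(fs, values, clamp = TRUE) {
  stopifnot(inherits(fs, "feature_set"))
  need <- unique(c(fs$defs$var1, fs$defs$var2))
  need <- need[!is.na(need)]
  missing <- setdiff(need, names(values))
  if (length(missing) > 0)
    stop(sprintf("missing variable(s) in values: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  vals <- as.data.frame(values)
  if (clamp) {
    for (i in seq_len(nrow(fs$clamp))) {
      v <- fs$clamp$code[i]
      if (v %in% names(vals))
        vals[[v]] <- pmin(pmax(vals[[v]], fs$clamp$min[i]), fs$clamp$max[i])
    }
  }
  d <- fs$defs
  n <- nrow(vals)
  out <- matrix(0, nrow = n, ncol = nrow(d),
                dimnames = list(NULL, d$name))
  for (j in seq_len(nrow(d))) {
    x <- vals[[d$var1[j]]]
    f <- switch(d$kind[j],
      linear = (x - d$lo[j]) / (d$hi[j] - d$lo[j]),
      quadratic = (x^2 - d$lo[j]) / (d$hi[j] - d$lo[j]),
      product = {
        pr <- x * vals[[d$var2[j]]]
        (pr - d$lo[j]) / (d$hi[j] - d$lo[j])
      },
      hinge = if (d$direction[j] == "fwd")
        pmax(0, (x - d$knot[j]) / (d$hi[j] - d$knot[j]))
      else
        pmax(0, (d$knot[j] - x) / (d$knot[j] - d$lo[j])),
      threshold = as.numeric(x > d$knot[j])
    )
    out[, j] <- pmin(pmax(f, 0), 1)
  }
  out
}

#' Default automatic feature classes by presence count
#'
#' Mirrors the usual MaxEnt default of growing the feature expansion with
#' sample size: `< 10` presences use linear only; `10-79` add quadratic and
#' hinge; `>= 80` add product and threshold.
#'
#' @param n_presence number of presence records.
#' @return Character vector of feature class codes.
#' @export
auto_feature_classes <- function(n_presence) {
  if (n_presence < 10) "L"
  else if (n_presence < 80) c("L", "Q", "H")
  else c("L", "Q", "H", "P", "T")
}

# per-class base regularisation; below 10 presences everything is held at 1
default_beta <- function(kind, n_presence) {
  if (n_presence < 10) return(rep(1, length(kind)))
  vapply(kind, function(k)
    switch(k, hinge = 0.5, linear = , quadratic = , product = ,
           threshold = 1.0),
    numeric(1))
}
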