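#' Pairwise correlation of stack layers over a cell sample
#'
#' Computes the correlation matrix of the layer values at the sampled cells,
#' by default Spearman's rank correlation (robust to the skewed, non-linear
#' distributions typical of bioclimatic variables). Layers that are constant
#' on the sample get correlation 0 against every other layer and are flagged.
#'
#' @param stack a `grid_stack`.
#' @param sample data frame with `row`, `col` of sample cells (typically the
#'   background sample).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A `corr_matrix` object: list with `codes`, symmetric matrix `r`
#'   (unit diagonal), `method`, and `constant` (codes flagged constant).
#' @export
pairwise_correlation <- function(stack, sample,
                                 method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(inherits(stack, "grid_stack"))
  if (length(stack) < 2L)
    stop("need at least 2 layers to correlate", call. = FALSE)
  if (is.null(sample) || nrow(sample) < 3L)
    stop("need at least 3 sample cells for a robust correlation", call. = FALSE)
  vals <- as.matrix(extract_cells(stack, sample))
  if (anyNA(vals))
    stop("sample contains nodata cells; sample from the valid mask",
         call. = FALSE)
  sds <- apply(vals, 2L, stats::sd)
  constant <- names(stack)[sds == 0]
  r <- suppressWarnings(stats::cor(vals, method = method))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  r <- (r + t(r)) / 2
  structure(list(codes = names(stack), r = r, method = method,
                 constant = constant),
            class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat(sprintf("<corr_matrix> %d layers, method = %s\n", length(x$codes),
              x$method))
  print(round(x$r, 3))
  invisible(x)
}

#' Turn a correlation matrix into a tidy tibble
#' @param x a `corr_matrix`.
#' @param ... unused.
#' @return Tibble with one row per unordered layer pair (`a`, `b`, `r`).
#' @method tidy corr_matrix
#' @export
tidy.corr_matrix <- function(x, ...) {
  cmb <- utils::combn(seq_along(x$codes), 2L)
  tibble::tibble(a = x$codes[cmb[1L, ]], b = x$codes[cmb[2L, ]],
                 r = x$r[t(cmb)])
}

#' Greedy pruning of collinear layers
#'
#' Repeatedly finds the pair with the largest |r| at or above the threshold
#' and drops its lower-priority member, until every retained pair has
#' |r| below the threshold (strict: |r| < threshold is retained). Ties in
#' priority are broken by the larger mean |r| against the remaining layers,
#' then by later input order. Deterministic.
#'
#' @param corr a `corr_matrix` from [pairwise_correlation()].
#' @param threshold retain pairs with `|r| < threshold`; default 0.75.
#' @param priority optional named numeric vector code -> score (higher kept);
#'   e.g. univariate model gain. Missing codes / `NULL` fall back to input
#'   order (earlier layers preferred).
#' @return Character vector of retained codes (input order), with attribute
#'   `"dropped"`: a tibble of dropped codes and the partner that eliminated
#'   each.
#' @export
prune_collinear <- function(corr, threshold = 0.75, priority = NULL) {
  stopifnot(inherits(corr, "corr_matrix"))
  if (!(threshold > 0 && threshold <= 1))
    stop("`threshold` must be in (0, 1]", call. = FALSE)
  codes <- corr$codes
  p <- length(codes)
  prio <- rep(-seq_len(p), length.out = p)  # fallback: earlier input wins
  names(prio) <- codes
  if (!is.null(priority)) {
    hit <- intersect(names(priority), codes)
    prio[hit] <- priority[hit]
  }
  keep <- rep(TRUE, p)
  dropped <- list()
  r <- abs(corr$r); diag(r) <- 0
  repeat {
    sub <- r
    sub[!keep, ] <- 0; sub[, !keep] <- 0
    if (max(sub) < threshold) break
    ij <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
    i <- ij[1L]; j <- ij[2L]
    loser <- pick_loser(i, j, prio, r, keep)
    keep[loser] <- FALSE
    dropped[[length(dropped) + 1L]] <- tibble::tibble(
      code = codes[loser],
      eliminated_by = codes[if (loser == i) j else i],
      abs_r = r[i, j]
    )
  }
  out <- codes[keep]
  attr(out, "dropped") <- if (length(dropped)) dplyr::bind_rows(dropped)
  else tibble::tibble(code = character(), eliminated_by = character(),
                      abs_r = numeric())
  out
}

pick_loser <- function(i, j, prio, r, keep) {
  if (prio[i] != prio[j]) return(if (prio[i] < prio[j]) i else j)
  others <- keep
  others[c(i, j)] <- FALSE
  mi <- if (any(others)) mean(r[i, others]) else 0
  mj <- if (any(others)) mean(r[j, others]) else 0
  if (mi != mj) return(if (mi > mj) i else j)
  max(i, j)  # later input order loses
}

#' Univariate model gain as a pruning priority
#'
#' Fits a single-variable maximum-entropy model (linear + quadratic
#' features) per layer and returns the unpenalised training gain, the
#' conventional priority score for deciding which member of a collinear
#' pair to keep.
#'
#' @param stack a `grid_stack`.
#' @param presences data frame with `row`, `col` of presence cells.
#' @param background data frame with `row`, `col` of background cells.
#' @param reg_multiplier regularisation multiplier passed to the fits.
#' @return Named numeric vector code -> gain.
#' @export
univariate_gain <- function(stack, presences, background,
                            reg_multiplier = 1.0) {
  gains <- vapply(names(stack), function(code) {
    sub <- stack_layers(stack[code])
    fs <- build_features(sub, background, classes = c("L", "Q"))
    m <- fit_maxent(feature_matrix(fs, extract_cells(sub, presences)),
                    feature_matrix(fs, extract_cells(sub, background)),
                    feature_set = fs, reg_multiplier = reg_multiplier)
    m$gain
  }, numeric(1))
  gains
}
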