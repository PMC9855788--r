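#' Fit an L1-regularised maximum-entropy (Gibbs) model
#'
#' Minimises the penalised negative log-likelihood of the presences against
#' the background availability sample,
#' \deqn{J(\lambda) = -\overline{\lambda f}_{pres}
#'   + \log \sum_{bg} e^{\lambda f(x)} - \log n_{bg}
#'   + \sum_j \beta_j |\lambda_j|,}
#' with per-feature regularisation
#' \eqn{\beta_j = m \cdot \beta_{class} \cdot sd_j(bg) / \sqrt{n_{pres}}}
#' (`m` = `reg_multiplier`). The optimiser is cyclic coordinate descent
#' with a soft-thresholded Newton step per coordinate and backtracking, so
#' the objective is non-increasing and every accepted update's gain
#' increment can be credited to its feature (the bookkeeping behind
#' [percent_contribution()]).
#'
#' @param presence_features numeric feature matrix of the presences
#'   (rows = presences, columns = features), values in \[0, 1\].
#' @param background_features feature matrix of the background cells,
#'   same columns.
#' @param feature_set optional `feature_set` (used for per-class
#'   regularisation and variable bookkeeping); when `NULL` all features are
#'   treated as linear-class.
#' @param reg_multiplier multiplier on the default regularisation (1 =
#'   default; smaller fits tighter).
#' @param tol relative objective-change convergence tolerance per sweep.
#' @param max_iter maximum number of full coordinate sweeps.
#' @return A `maxent_model`: list with `lambda`, `beta`, `logZ` (normaliser
#'   relative to the background mean, i.e. `logsumexp(eta) - log(n_bg)`),
#'   `entropy` (Shannon entropy of the fitted raw distribution), `gain`
#'   (unpenalised training gain), `contrib` (per-feature credited gain),
#'   `feature_set`, `background_features`, and `meta`.
#' @export
fit_maxent <- function(presence_features, background_features,
                       feature_set = NULL, reg_multiplier = 1.0,
                       tol = 1e-6, max_iter = 5000L) {
  Fp <- as.matrix(presence_features)
  Fb <- as.matrix(background_features)
  if (nrow(Fp) < 1L) stop("need at least one presence", call. = FALSE)
  if (nrow(Fb) < 2L) stop("need at least two background rows", call. = FALSE)
  if (ncol(Fp) != ncol(Fb))
    stop("presence and background feature matrices differ in columns",
         call. = FALSE)
  if (!all(is.finite(Fp)) || !all(is.finite(Fb)))
    stop("non-finite feature values", call. = FALSE)
  p <- ncol(Fb)
  n_p <- nrow(Fp); n_b <- nrow(Fb)
  kinds <- if (!is.null(feature_set)) feature_set$defs$kind
           else rep("linear", p)
  sd_bg <- apply(Fb, 2L, stats::sd)
  beta <- reg_multiplier * default_beta(kinds, n_p) * sd_bg / sqrt(n_p)
  beta <- pmax(beta, 1e-8)  # keep the problem strictly penalised

  fbar <- colMeans(Fp)
  lambda <- numeric(p)
  eta <- numeric(n_b)
  lse <- logsumexp(eta)
  lin <- 0; pen <- 0
  J <- -lin + lse - log(n_b) + pen
  contrib <- numeric(p)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    J_start <- J
    for (j in seq_len(p)) {
      mx <- max(eta)
      w <- exp(eta - mx); q <- w / sum(w)
      fj <- Fb[, j]
      Ef <- sum(q * fj)
      Vf <- max(sum(q * fj^2) - Ef^2, 1e-12)
      g <- -fbar[j] + Ef
      lam_new <- soft_threshold(Vf * lambda[j] - g, beta[j]) / Vf
      delta <- lam_new - lambda[j]
      if (abs(delta) < 1e-15) next
      # backtracking on the exact objective
      repeat {
        cand_lam <- lambda[j] + delta
        cand_eta <- eta + delta * fj
        cand_lse <- logsumexp(cand_eta)
        cand_J <- -(lin + delta * fbar[j]) + cand_lse - log(n_b) +
          (pen - beta[j] * abs(lambda[j]) + beta[j] * abs(cand_lam))
        if (cand_J <= J + 1e-12 || abs(delta) < 1e-15) break
        delta <- delta / 2
      }
      if (cand_J < J) {
        contrib[j] <- contrib[j] + (J - cand_J)
        lin <- lin + delta * fbar[j]
        pen <- pen - beta[j] * abs(lambda[j]) + beta[j] * abs(cand_lam)
        lambda[j] <- cand_lam
        eta <- cand_eta
        lse <- cand_lse
        J <- cand_J
      }
    }
    if (abs(J_start - J) < tol * max(1, abs(J_start))) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf("coordinate descent did not converge in %d sweeps", it),
            call. = FALSE)
  q <- exp(eta - lse)
  logZ <- lse - log(n_b)
  H <- -sum(ifelse(q > 0, q * log(q), 0))
  gain <- sum(lambda * fbar) - logZ
  names(lambda) <- names(beta) <- names(contrib) <- colnames(Fb)
  structure(
    list(lambda = lambda, beta = beta, logZ = logZ, entropy = H,
         gain = gain, objective = J, contrib = contrib,
         feature_set = feature_set,
         background_features = Fb,
         meta = list(n_presence = n_p, n_background = n_b,
                     reg_multiplier = reg_multiplier, tol = tol,
                     iterations = it, converged = converged)),
    class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  nz <- sum(x$lambda != 0)
  cat(sprintf("<maxent_model> %d features (%d active), %d presences vs %d background\n",
              length(x$lambda), nz, x$meta$n_presence, x$meta$n_background))
  cat(sprintf("  gain %.4f, entropy %.4f, converged: %s (%d sweeps)\n",
              x$gain, x$entropy, x$meta$converged, x$meta$iterations))
  invisible(x)
}

#' Raw (Gibbs) probabilities over the training background
#'
#' The raw output is only defined on the cells the model was normalised
#' over; passing anything else is an error.
#'
#' @param model a fitted `maxent_model`.
#' @param cells feature matrix of exactly the training background (defaults
#'   to the stored one).
#' @return Numeric vector of probabilities summing to 1.
#' @export
predict_raw <- function(model, cells = NULL) {
  stopifnot(inherits(model, "maxent_model"))
  if (is.null(cells)) cells <- model$background_features
  cells <- as.matrix(cells)
  if (!isTRUE(all.equal(unname(cells), unname(model$background_features),
                        tolerance = 1e-12)))
    stop("raw output is only defined over the training background cells",
         call. = FALSE)
  eta <- drop(cells %*% model$lambda)
  exp(eta - logsumexp(eta))
}

#' Project a fitted model as a cloglog suitability grid
#'
#' Evaluates the model over every cell of the stack (with inputs clamped to
#' the training background ranges) and maps the Gibbs density to the
#' cloglog suitability scale
#' \eqn{c(x) = 1 - \exp(-e^{H} \tilde q(x))}, where `H` is the entropy of
#' the fitted raw distribution and
#' \eqn{\tilde q(x) = e^{\lambda f(x) - \log Z} / n_{bg}}. A featureless
#' (uniform) model yields `1 - exp(-1)` everywhere.
#'
#' @param model a fitted `maxent_model` carrying its `feature_set`.
#' @param stack a `grid_stack` providing every model variable.
#' @return An [eco_grid] of suitability in \[0, 1\], `NA` where any input
#'   layer is nodata.
#' @export
predict_cloglog <- function(model, stack) {
  stopifnot(inherits(model, "maxent_model"))
  if (is.null(model$feature_set))
    stop("model has no feature_set; fit via train_maxent() or pass one to fit_maxent()",
         call. = FALSE)
  fs <- model$feature_set
  missing <- setdiff(fs$codes, names(stack))
  if (length(missing) > 0)
    stop(sprintf("stack is missing model variable(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  sub <- stack[fs$codes]
  mask <- valid_mask(sub)
  ok <- mask$values != 0
  cells <- which(ok, arr.ind = TRUE)
  vals <- extract_cells(sub, tibble::tibble(row = cells[, 1L],
                                            col = cells[, 2L]))
  feats <- feature_matrix(fs, vals, clamp = TRUE)
  eta <- drop(feats %*% model$lambda)
  q_tilde <- exp(eta - model$logZ) / model$meta$n_background
  cc <- 1 - exp(-exp(model$entropy) * q_tilde)
  out <- matrix(NA_real_, nrow = nrow(mask$values), ncol = ncol(mask$values))
  out[cells] <- pmin(pmax(cc, 0), 1)
  ref <- sub[[1L]]
  eco_grid(out, xll = ref$xll, yll = ref$yll, cellsize = ref$cellsize,
           nodata = ref$nodata, crs = ref$crs)
}

#' Fit a maximum-entropy niche model from cells and layers
#'
#' Convenience wrapper tying together [build_features()], [extract_cells()]
#' and [fit_maxent()]: the usual entry point when working from occurrence
#' and background cell tables.
#'
#' @param stack a `grid_stack`.
#' @param presences,background data frames with `row`, `col` cell indices.
#' @param classes feature classes; `NULL` (default) picks
#'   [auto_feature_classes()] by presence count.
#' @param hinge_knots quantile knots per variable for hinge/threshold
#'   features.
#' @param reg_multiplier,tol,max_iter passed to [fit_maxent()].
#' @return A fitted `maxent_model` (with its `feature_set` attached).
#' @export
train_maxent <- function(stack, presences, background, classes = NULL,
                         hinge_knots = 10L, reg_multiplier = 1.0,
                         tol = 1e-6, max_iter = 5000L) {
  if (is.null(classes)) classes <- auto_feature_classes(nrow(presences))
  fs <- build_features(stack, background, classes = classes,
                       hinge_knots = hinge_knots)
  Fp <- feature_matrix(fs, extract_cells(stack, presences))
  Fb <- feature_matrix(fs, extract_cells(stack, background))
  model <- fit_maxent(Fp, Fb, feature_set = fs,
                      reg_multiplier = reg_multiplier, tol = tol,
                      max_iter = max_iter)
  model$presence_features <- Fp
  model
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

soft_threshold <- function(a, b) sign(a) * max(abs(a) - b, 0)
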