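#' Percent contribution of each variable
#'
#' During fitting every accepted coordinate update's increase in penalised
#' gain is credited to the updated feature; contributions are rolled up to
#' the feature's variable(s) (product features split equally between their
#' two variables), negatives floored at zero, and the vector normalised to
#' sum to 100.
#'
#' @param model a fitted `maxent_model` with a `feature_set`.
#' @return Named numeric vector (variable code -> percent), summing to 100
#'   when any variable contributed.
#' @export
percent_contribution <- function(model) {
  stopifnot(inherits(model, "maxent_model"))
  if (is.null(model$feature_set))
    stop("model has no feature_set; variable roll-up is undefined",
         call. = FALSE)
  d <- model$feature_set$defs
  codes <- model$feature_set$codes
  acc <- stats::setNames(numeric(length(codes)), codes)
  for (j in seq_len(nrow(d))) {
    cj <- model$contrib[j]
    if (d$kind[j] == "product") {
      acc[d$var1[j]] <- acc[d$var1[j]] + cj / 2
      acc[d$var2[j]] <- acc[d$var2[j]] + cj / 2
    } else {
      acc[d$var1[j]] <- acc[d$var1[j]] + cj
    }
  }
  acc <- pmax(acc, 0)
  s <- sum(acc)
  if (s > 0) acc <- 100 * acc / s
  acc
}

#' Permutation importance of each variable
#'
#' For each variable the raw values are permuted jointly across the
#' presence and background rows, features are rebuilt, and the drop in
#' training AUC (presences vs background, scored by the linear predictor)
#' is recorded. Drops are floored at zero and normalised to sum to 100.
#'
#' @param model a fitted `maxent_model` with a `feature_set`.
#' @param stack the `grid_stack` the model was trained on.
#' @param presences,background data frames with `row`, `col` of the
#'   training cells.
#' @param seed integer seed for the permutations.
#' @return Named numeric vector (variable code -> percent).
#' @export
permutation_importance <- function(model, stack, presences, background,
                                   seed = 1L) {
  stopifnot(inherits(model, "maxent_model"))
  fs <- model$feature_set
  if (is.null(fs)) stop("model has no feature_set", call. = FALSE)
  sub <- stack[fs$codes]
  vp <- extract_cells(sub, presences)
  vb <- extract_cells(sub, background)
  all_vals <- dplyr::bind_rows(vp, vb)
  n_p <- nrow(vp)
  score <- function(vals) {
    feats <- feature_matrix(fs, vals, clamp = TRUE)
    drop(feats %*% model$lambda)
  }
  s0 <- score(all_vals)
  auc0 <- roc_auc(s0[seq_len(n_p)], s0[-seq_len(n_p)])
  drops <- withr::with_seed(as.integer(seed), {
    vapply(fs$codes, function(v) {
      perm <- all_vals
      perm[[v]] <- sample(perm[[v]])
      s <- score(perm)
      auc0 - roc_auc(s[seq_len(n_p)], s[-seq_len(n_p)])
    }, numeric(1))
  })
  drops <- pmax(drops, 0)
  s <- sum(drops)
  if (s > 0) drops <- 100 * drops / s
  drops
}

#' Jackknife of variable gains
#'
#' For each variable `v`, fits a model with only `v` (`gain_only`) and a
#' model with every variable except `v` (`gain_without`), reporting the
#' unpenalised training gain of each. Separates variables that carry
#' information on their own from variables whose information is redundant.
#'
#' @param stack a `grid_stack`.
#' @param presences,background data frames with `row`, `col` cells.
#' @param variables variable codes to jackknife (default: all layers).
#' @param classes,hinge_knots,reg_multiplier fit configuration (see
#'   [train_maxent()]).
#' @return A tibble with columns `code`, `gain_only`, `gain_without`,
#'   `error` (NA unless a sub-fit failed), plus attribute `"full_gain"`.
#' @export
jackknife_gains <- function(stack, presences, background,
                            variables = names(stack), classes = NULL,
                            hinge_knots = 10L, reg_multiplier = 1.0) {
  if (length(variables) < 2L)
    stop("jackknife needs at least 2 variables", call. = FALSE)
  if (is.null(classes)) classes <- auto_feature_classes(nrow(presences))
  fit_gain <- function(codes) {
    tryCatch({
      m <- train_maxent(stack[codes], presences, background,
                        classes = classes, hinge_knots = hinge_knots,
                        reg_multiplier = reg_multiplier)
      list(gain = m$gain, error = NA_character_)
    }, error = function(e) list(gain = NA_real_,
                                error = conditionMessage(e)))
  }
  full <- fit_gain(variables)
  rows <- purrr::map(variables, function(v) {
    only <- fit_gain(v)
    without <- fit_gain(setdiff(variables, v))
    tibble::tibble(code = v, gain_only = only$gain,
                   gain_without = without$gain,
                   error = dplyr::coalesce(only$error, without$error))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "full_gain") <- full$gain
  out
}
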