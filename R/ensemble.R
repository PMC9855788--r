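#' Replicated MaxEnt runs with re-splits and a mean suitability grid
#'
#' Each replicate `r` re-partitions the rarefied occurrences with seed
#' `seed + r`, fits a model on the calibration cells, projects the cloglog
#' suitability grid, and evaluates it on both the calibration and the
#' holdout presences against the background. The ensemble suitability is
#' the cellwise mean of the replicate grids; binarisation happens *after*
#' averaging, downstream.
#'
#' @param occ rarefied occurrence tibble with `row`, `col` columns (from
#'   [rarefy_occurrences()]).
#' @param stack a `grid_stack` of the selected layers.
#' @param background data frame with `row`, `col` of background cells.
#' @param n_replicates number of replicated re-splits (the full-study
#'   convention is 100; desk-scale runs use fewer).
#' @param seed master seed; replicate `r` uses `seed + r`.
#' @param train_frac calibration fraction (default 0.75).
#' @param classes,hinge_knots,reg_multiplier fit configuration (see
#'   [train_maxent()]).
#' @return A list: `mean_suitability` ([eco_grid]), `reports` (tibble, one
#'   row per replicate with train/test metrics at the replicate's MTSS
#'   threshold), `models` (list of fitted models, only if `keep_models`).
#' @param keep_models keep the per-replicate model objects (memory-heavy).
#' @export
ensemble_replicates <- function(occ, stack, background, n_replicates = 10L,
                                seed = 1L, train_frac = 0.75,
                                classes = NULL, hinge_knots = 10L,
                                reg_multiplier = 1.0, keep_models = FALSE) {
  stopifnot(n_replicates >= 1L)
  acc <- NULL
  reports <- vector("list", n_replicates)
  models <- if (keep_models) vector("list", n_replicates) else NULL
  for (r in seq_len(n_replicates)) {
    res <- tryCatch({
      parts <- partition_occurrences(occ, train_frac = train_frac,
                                     seed = seed + r)
      model <- train_maxent(stack, parts$train[, c("row", "col")],
                            background, classes = classes,
                            hinge_knots = hinge_knots,
                            reg_multiplier = reg_multiplier)
      grid <- predict_cloglog(model, stack)
      bg_scores <- grid$values[cbind(background$row, background$col)]
      tr_scores <- grid$values[cbind(parts$train$row, parts$train$col)]
      te_scores <- grid$values[cbind(parts$test$row, parts$test$col)]
      ev_tr <- evaluate_scores(tr_scores, bg_scores)
      list(model = model, grid = grid,
           report = dplyr::mutate(ev_tr, replicate = r,
                                  auc_test = roc_auc(te_scores, bg_scores),
                                  .before = 1L))
    }, error = function(e)
      stop(sprintf("replicate %d failed: %s", r, conditionMessage(e)),
           call. = FALSE))
    acc <- if (is.null(acc)) res$grid$values
           else acc + res$grid$values
    reports[[r]] <- res$report
    if (keep_models) models[[r]] <- res$model
  }
  ref <- stack[[1L]]
  mean_grid <- eco_grid(acc / n_replicates, xll = ref$xll, yll = ref$yll,
                        cellsize = ref$cellsize, nodata = ref$nodata,
                        crs = ref$crs)
  out <- list(mean_suitability = mean_grid,
              reports = dplyr::bind_rows(reports))
  if (keep_models) out$models <- models
  out
}
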