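toy_model <- function(etas) {
  # minimal model whose linear predictor over background is `etas`
  structure(list(
    lambda = c(f1 = 1),
    background_features = matrix(etas, ncol = 1,
                                 dimnames = list(NULL, "f1"))),
    class = "maxent_model")
}

test_that("feature construction scales into [0,1] with the stated forms", {
  st <- toy_stack(6, 6, seed = 2)
  bg <- expand.grid(row = 1:6, col = 1:6)
  fs <- build_features(st, bg, classes = "L")
  expect_equal(nrow(fs$defs), 2L)  # one linear feature per variable
  fm <- feature_matrix(fs, extract_cells(st, bg))
  expect_true(all(fm >= 0 & fm <= 1))

  # midpoint scaling: background range [0,10], x = 5 -> 0.5
  defs <- tibble::tibble(name = "lin", kind = "linear", var1 = "X",
                         var2 = NA, knot = NA_real_, direction = NA,
                         lo = 0, hi = 10)
  clamp <- tibble::tibble(code = "X", min = 0, max = 10)
  fs2 <- manual_feature_set(defs, clamp)
  expect_equal(unname(feature_matrix(fs2, data.frame(X = 5))[1, 1]), 0.5)
  # clamping: projection value outside the training range is clipped
  expect_equal(unname(feature_matrix(fs2, data.frame(X = 99))[1, 1]), 1)
  expect_equal(unname(feature_matrix(fs2, data.frame(X = 99),
                                     clamp = FALSE)[1, 1]), 1)

  # forward hinge with knot 4 on range [0,10]: x = 7 -> (7-4)/(10-4) = 0.5
  defs_h <- tibble::tibble(name = "h", kind = "hinge", var1 = "X",
                           var2 = NA, knot = 4, direction = "fwd",
                           lo = 0, hi = 10)
  fs3 <- manual_feature_set(defs_h, clamp)
  expect_equal(unname(feature_matrix(fs3, data.frame(X = 7))[1, 1]), 0.5)
  expect_equal(unname(feature_matrix(fs3, data.frame(X = 3))[1, 1]), 0)

  # constant layer drops its features with a warning
  st2 <- stack_layers(list(A = gradient_grid(4, 4),
                           K = eco_grid(matrix(1, 4, 4))))
  expect_warning(fsk <- build_features(st2, expand.grid(row = 1:4, col = 1:4),
                                       classes = "L"),
                 "constant")
  expect_equal(nrow(fsk$defs), 1L)
})

test_that("fitted weights match a brute-force grid search of the objective", {
  # 1 feature, 20 background cells, presences concentrated high
  withr::with_seed(3, {
    fb <- matrix(runif(20), 20, 1, dimnames = list(NULL, "f"))
    fp <- matrix(runif(8, 0.6, 1), 8, 1, dimnames = list(NULL, "f"))
  })
  for (rm in c(0.5, 1)) {
    m <- fit_maxent(fp, fb, reg_multiplier = rm, tol = 1e-10)
    beta <- rm * sd(fb) / sqrt(nrow(fp))
    grid <- seq(-10, 10, by = 1e-3)
    J <- vapply(grid, function(l) maxent_objective(l, fp, fb, beta),
                numeric(1))
    expect_equal(unname(m$lambda), grid[which.min(J)], tolerance = 2e-3)
    expect_gt(m$lambda[1], 0)  # presences sit at high feature values
  }

  # 2 features: coarse grid then fine local grid as the oracle
  withr::with_seed(4, {
    fb2 <- cbind(f1 = runif(20), f2 = runif(20))
    fp2 <- cbind(f1 = runif(10, 0.5, 1), f2 = runif(10, 0, 0.5))
  })
  m2 <- fit_maxent(fp2, fb2, reg_multiplier = 1, tol = 1e-10)
  beta2 <- apply(fb2, 2, sd) / sqrt(nrow(fp2))
  coarse <- expand.grid(l1 = seq(-8, 8, 0.1), l2 = seq(-8, 8, 0.1))
  Jc <- apply(coarse, 1, function(l) maxent_objective(l, fp2, fb2, beta2))
  c0 <- as.numeric(coarse[which.min(Jc), ])
  fine <- expand.grid(l1 = seq(c0[1] - 0.15, c0[1] + 0.15, 1e-3),
                      l2 = seq(c0[2] - 0.15, c0[2] + 0.15, 1e-3))
  Jf <- apply(fine, 1, function(l) maxent_objective(l, fp2, fb2, beta2))
  expect_equal(unname(m2$lambda), as.numeric(fine[which.min(Jf), ]),
               tolerance = 2e-3)
})

test_that("no-signal and heavy-regularisation limits give a uniform model", {
  withr::with_seed(5, {
    fb <- matrix(runif(50), 50, 1, dimnames = list(NULL, "f"))
  })
  # presences drawn from the background itself + heavy penalty
  fp <- fb[sample(50, 20), , drop = FALSE]
  m <- fit_maxent(fp, fb, reg_multiplier = 50)
  expect_equal(unname(m$lambda), 0, tolerance = 1e-8)
  q <- predict_raw(m)
  expect_equal(q, rep(1 / 50, 50), tolerance = 1e-8)
  expect_equal(m$entropy, log(50), tolerance = 1e-8)
  # penalised gain is never negative: J(lambda_hat) <= J(0)
  expect_gte(m$gain, -1e-10)
})

test_that("raw prediction is the normalised Gibbs density", {
  m <- toy_model(c(0, log(2), log(4)))
  q <- predict_raw(m)
  expect_equal(q, c(1, 2, 4) / 7)
  expect_equal(sum(q), 1)
  # raw is only defined over the training background
  expect_error(predict_raw(m, matrix(c(0, 1), 2, 1)), "training background")
})

test_that("cloglog projection has the uniform closed form and monotonicity", {
  st <- toy_stack(8, 8, seed = 6)
  bg <- expand.grid(row = 1:8, col = 1:8)
  pres <- bg[sample(64, 20), ]
  # heavy regularisation -> uniform model -> cloglog = 1 - exp(-1)
  m <- train_maxent(st, pres, bg, classes = "L", reg_multiplier = 100)
  g <- predict_cloglog(m, st)
  expect_equal(as.vector(g$values), rep(1 - exp(-1), 64), tolerance = 1e-6)

  # informative model: cloglog increases with the linear predictor
  pres2 <- expand.grid(row = 1:8, col = 7:8)
  m2 <- train_maxent(st, pres2, bg, classes = "L", reg_multiplier = 0.2)
  g2 <- predict_cloglog(m2, st)
  expect_true(all(g2$values >= 0 & g2$values <= 1))
  fm <- feature_matrix(m2$feature_set, extract_cells(st, bg))
  eta <- drop(fm %*% m2$lambda)
  cc <- g2$values[cbind(bg$row, bg$col)]
  expect_gt(cor(eta, cc, method = "spearman"), 0.999)

  # nodata propagates, missing layer errors
  st3 <- st; st3$Bio1$values[1, 1] <- NA
  st3 <- stack_layers(unclass(st3))
  g3 <- predict_cloglog(m2, st3)
  expect_true(is.na(g3$values[1, 1]))
  expect_error(predict_cloglog(m2, st3["Bio2"]), "Bio1")
})

test_that("raw probabilities sum to one across random refits", {
  for (s in 1:5) {
    withr::with_seed(s, {
      fb <- cbind(a = runif(30), b = runif(30))
      fp <- cbind(a = runif(10), b = runif(10)^2)
    })
    m <- fit_maxent(fp, fb, reg_multiplier = 0.5)
    expect_equal(sum(predict_raw(m)), 1, tolerance = 1e-12)
    expect_gte(m$gain, -1e-10)  # penalised gain non-negative
  }
})

test_that("percent contribution credits the informative variable", {
  st <- toy_stack(10, 10, seed = 8)
  bg <- expand.grid(row = 1:10, col = 1:10)
  pres <- expand.grid(row = 1:10, col = 9:10)  # driven by the Bio1 gradient
  m <- train_maxent(st, pres, bg, classes = c("L", "Q"),
                    reg_multiplier = 0.5)
  pc <- percent_contribution(m)
  expect_equal(sum(pc), 100, tolerance = 1e-6)
  expect_gt(pc[["Bio1"]], 90)

  # single-variable model -> 100%
  m1 <- train_maxent(st["Bio1"], pres, bg, classes = "L")
  expect_equal(unname(percent_contribution(m1)), 100)
})

test_that("permutation importance is zero for inactive variables and sums to 100", {
  st <- toy_stack(10, 10, seed = 9)
  bg <- expand.grid(row = 1:10, col = 1:10)
  pres <- expand.grid(row = 1:10, col = 9:10)
  m <- train_maxent(st, pres, bg, classes = "L", reg_multiplier = 0.5)
  pi <- permutation_importance(m, st, pres, bg, seed = 1)
  expect_equal(sum(pi), 100, tolerance = 1e-6)
  if (m$lambda[["Bio2"]] == 0) expect_equal(pi[["Bio2"]], 0)
  expect_gt(pi[["Bio1"]], 50)
})

test_that("jackknife separates informative from uninformative variables", {
  st <- toy_stack(12, 12, seed = 10)
  bg <- expand.grid(row = 1:12, col = 1:12)
  pres <- expand.grid(row = 1:12, col = 11:12)
  jk <- jackknife_gains(st, pres, bg, classes = "L", reg_multiplier = 0.5)
  full <- attr(jk, "full_gain")
  expect_gt(jk$gain_only[jk$code == "Bio1"],
            jk$gain_only[jk$code == "Bio2"] + 0.2)
  expect_lt(abs(jk$gain_only[jk$code == "Bio2"]), 0.2)
  # nested models: leaving one variable out cannot beat the full model
  expect_true(all(jk$gain_without <= full + 1e-6))
})

test_that("replicate ensembles average cellwise and are stable", {
  st <- toy_stack(12, 12, seed = 12)
  mask <- valid_mask(st)
  niche <- make_virtual_niche(st, c(Bio1 = 6))
  occ <- sample_presences(niche, 120, dup_rate = 0, seed = 1)
  rar <- rarefy_occurrences(occ, mask)
  bg <- sample_background(mask, 120, seed = 2)

  e1 <- ensemble_replicates(rar, st, bg, n_replicates = 1, seed = 3,
                            classes = "L")
  parts <- partition_occurrences(rar, 0.75, seed = 3 + 1)
  m <- train_maxent(st, parts$train[, c("row", "col")], bg, classes = "L")
  g <- predict_cloglog(m, st)
  expect_equal(e1$mean_suitability$values, g$values)

  e3 <- ensemble_replicates(rar, st, bg, n_replicates = 5, seed = 3,
                            classes = "L", keep_models = TRUE)
  grids <- lapply(e3$models, predict_cloglog, stack = st)
  lo <- Reduce(pmin, lapply(grids, `[[`, "values"))
  hi <- Reduce(pmax, lapply(grids, `[[`, "values"))
  expect_true(all(e3$mean_suitability$values >= lo - 1e-12))
  expect_true(all(e3$mean_suitability$values <= hi + 1e-12))
  expect_equal(nrow(e3$reports), 5L)
  expect_lt(sd(e3$reports$auc), 0.05)
})
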