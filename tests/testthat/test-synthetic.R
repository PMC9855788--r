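test_that("simulated stacks hit the target correlation structure", {
  # independent layers: small off-diagonal correlations (the grid holds
  # ~2500 independent patches at this lengthscale, so |r| < 0.1 is ~5 sigma)
  st <- simulate_bioclim_stack(c(300, 300), 3, smoothing = 3, seed = 1)
  cells <- expand.grid(row = 1:300, col = 1:300)
  r <- pairwise_correlation(st, cells, method = "pearson")$r
  expect_true(all(abs(r[upper.tri(r)]) < 0.1))

  # engineered strong correlation lands near the target
  ct <- diag(3); ct[1, 2] <- ct[2, 1] <- 0.95
  st2 <- simulate_bioclim_stack(c(200, 200), 3, corr_target = ct,
                                smoothing = 5, seed = 2)
  cells2 <- expand.grid(row = 1:200, col = 1:200)
  r2 <- pairwise_correlation(st2, cells2, method = "pearson")$r
  expect_equal(r2[1, 2], 0.95, tolerance = 0.05)

  # seeded determinism is bit-exact
  st3 <- simulate_bioclim_stack(c(50, 50), 2, smoothing = 4, seed = 9)
  st4 <- simulate_bioclim_stack(c(50, 50), 2, smoothing = 4, seed = 9)
  expect_identical(st3$Bio1$values, st4$Bio1$values)
  expect_identical(st3$Bio2$values, st4$Bio2$values)

  # invalid correlation target is rejected
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(simulate_bioclim_stack(c(10, 10), 2, corr_target = bad),
               "positive semi-definite")
})

test_that("the virtual niche has the Gibbs closed forms", {
  st <- toy_stack(10, 10, seed = 3)
  # zero weights: uniform suitability 1 - exp(-1)
  n0 <- make_virtual_niche(st, c(Bio1 = 0))
  expect_equal(as.vector(n0$suitability$values), rep(1 - exp(-1), 100))
  expect_equal(sum(n0$raw$values), 1, tolerance = 1e-12)

  # single positive weight on a west-east gradient: monotone suitability
  n1 <- make_virtual_niche(st, c(Bio1 = 5))
  expect_true(all(diff(n1$suitability$values[1, ]) > 0))
  expect_equal(sum(n1$raw$values), 1, tolerance = 1e-12)

  # doubling a moderate weight sharpens the niche: the raw density
  # concentrates (variance grows monotonically) and, below the cloglog
  # saturation regime, so does the suitability variance
  n_lo <- make_virtual_niche(st, c(Bio1 = 2))
  n_hi <- make_virtual_niche(st, c(Bio1 = 4))
  expect_gt(var(as.vector(n_hi$suitability$values)),
            var(as.vector(n_lo$suitability$values)))
  expect_gt(var(as.vector(n_hi$raw$values)),
            var(as.vector(n_lo$raw$values)))
  n2 <- make_virtual_niche(st, c(Bio1 = 10))
  expect_gt(var(as.vector(n2$raw$values)),
            var(as.vector(n1$raw$values)))

  expect_error(make_virtual_niche(st, c(Nope = 1)), "Nope")
})

test_that("presence sampling follows the raw density and duplicates cells", {
  # 2-cell grid with raw odds 9:1
  g <- eco_grid(matrix(c(9, 1), 1, 2))
  niche <- make_virtual_niche(stack_layers(list(Bio1 = g)), c(Bio1 = log(9)))
  # confirm the engineered raw split before sampling from it
  expect_equal(as.vector(niche$raw$values), c(0.9, 0.1), tolerance = 1e-12)
  occ <- sample_presences(niche, 10000, dup_rate = 0, seed = 4)
  cells <- cell_from_lonlat(niche$raw, occ$lon, occ$lat)
  frac1 <- mean(cells$col == 1)
  expect_equal(frac1, 0.9, tolerance = 0.02)  # binomial(10000, 0.9)

  # duplication inflates per-cell multiplicity that rarefaction removes
  st <- simulate_bioclim_stack(c(60, 60), 2, smoothing = 4, seed = 5)
  flat <- make_virtual_niche(st, c(Bio1 = 0.5))
  occ2 <- sample_presences(flat, 100, dup_rate = 0.5, seed = 6)
  rar <- rarefy_occurrences(occ2, valid_mask(st))
  removed <- 1 - nrow(rar) / nrow(occ2)
  expect_gt(removed, 0.35)  # ~half the records were forced duplicates

  expect_identical(sample_presences(flat, 50, seed = 7),
                   sample_presences(flat, 50, seed = 7))
})

test_that("scenario perturbation is an affine map that preserves masks", {
  st <- toy_stack(5, 5, seed = 8)
  st$Bio1$values[2, 2] <- NA
  st <- stack_layers(unclass(st))
  # zero deltas: identical stack
  same <- perturb_scenario(st, list(Bio1 = c(0, 1)))
  expect_equal(same$Bio1$values, st$Bio1$values)
  # shift + scale applied to the named layer only
  warm <- perturb_scenario(st, list(Bio1 = c(2, 1.1)))
  expect_equal(warm$Bio1$values, 2 + 1.1 * st$Bio1$values)
  expect_identical(warm$Bio2$values, st$Bio2$values)
  expect_identical(is.na(warm$Bio1$values), is.na(st$Bio1$values))
  expect_error(perturb_scenario(st, list(Bio9 = 1)), "Bio9")
})

test_that("a favourable uniform shift increases suitable area at a fixed threshold", {
  # species prefers high values of a west-east gradient layer
  grad <- gradient_grid(15, 15)
  noise <- withr::with_seed(31, eco_grid(matrix(rnorm(225, 10, 2), 15, 15)))
  st <- stack_layers(list(Bio1 = grad, Bio2 = noise))
  niche <- make_virtual_niche(st, c(Bio1 = 8))
  occ <- sample_presences(niche, 150, dup_rate = 0, seed = 32)
  rar <- rarefy_occurrences(occ, valid_mask(st))
  bg <- sample_background(valid_mask(st), 225, seed = 33)
  m <- train_maxent(st, rar[, c("row", "col")], bg, classes = "L",
                    reg_multiplier = 0.5)
  g0 <- predict_cloglog(m, st)
  t0 <- mtss_threshold(g0$values[cbind(rar$row, rar$col)],
                       g0$values[cbind(bg$row, bg$col)])
  area0 <- suitable_area(binarize(g0, t0))
  # shifting the favoured layer up makes more cells resemble presences
  g1 <- predict_cloglog(m, perturb_scenario(st, list(Bio1 = c(3, 1))))
  area1 <- suitable_area(binarize(g1, t0))
  expect_gt(area1, area0)
})

test_that("random zones partition the valid area deterministically", {
  mask <- eco_grid(matrix(1, 20, 20))
  mask$values[1:5, 1:5] <- NA
  zs <- make_zones(mask, 4, seed = 10)
  # zones cover exactly the valid cells
  expect_equal(sum(zs$raster$values != 0), n_valid(mask))
  expect_equal(sum(zs$table$total_area_km2), n_valid(mask) * 4.5)
  expect_setequal(unique(as.vector(zs$raster$values[!is.na(mask$values)])),
                  1:4)
  # k = 1: everything in one zone
  z1 <- make_zones(mask, 1, seed = 2)
  expect_equal(sum(z1$raster$values == 1), n_valid(mask))
  # determinism and the infeasible case
  expect_identical(make_zones(mask, 4, seed = 10)$raster$values,
                   zs$raster$values)
  expect_error(make_zones(mask, 10000, seed = 1), "more zones")
})

test_that("packaged reference tables are intact and well-shaped", {
  fx <- reference_tables()
  expect_named(fx, c("table1", "table2", "table3", "table5"))
  # shapes
  expect_equal(nrow(fx$table5), 17L)
  expect_equal(ncol(fx$table5), 11L)  # ad + total + current + 8 projections
  expect_equal(nrow(fx$table1), 6L)
  # spot values
  expect_equal(fx$table2$after_rarefying[fx$table2$parameter == "auc"], 0.776)
  expect_equal(fx$table1$model_contribution_pct[fx$table1$code == "Bio2"],
               0.40)
  # checksums freeze the shipped transcriptions
  files <- c(table1 = "table1_variable_contributions.csv",
             table2 = "table2_evaluation_scores.csv",
             table3 = "table3_continent_change.csv",
             table5 = "table5_korea_ad_areas.csv")
  sums <- vapply(files, function(f)
    unname(tools::md5sum(system.file("extdata", f, package = "maxentsdm"))),
    character(1))
  expect_equal(unname(sums), c("856d91a3e9c3b33e6ceb7ff14a251d48",
                               "3791a0c2df67a246540028234171104c",
                               "5cfd9748fad76c24c493a0c6821c0a29",
                               "6b60de43a5f561077dfeda539e769076"))
})
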