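# Small in-code fixtures shared across the suite.

# grid whose values are a simple west-east gradient
gradient_grid <- function(nr = 5, nc = 5, xll = 0, yll = 0, cellsize = 1) {
  eco_grid(matrix(rep(seq_len(nc), each = nr), nr, nc),
           xll = xll, yll = yll, cellsize = cellsize)
}

# two aligned layers: a gradient and a seeded noise layer
toy_stack <- function(nr = 6, nc = 6, seed = 1) {
  g1 <- gradient_grid(nr, nc)
  g2 <- g1
  g2$values <- matrix(withr::with_seed(seed, stats::rnorm(nr * nc, 10, 3)),
                      nr, nc)
  stack_layers(list(Bio1 = g1, Bio2 = g2))
}

# a tiny feature_set with hand-chosen scaling/knots, bypassing quantiles
manual_feature_set <- function(defs, clamp) {
  structure(list(defs = defs, clamp = clamp,
                 codes = unique(defs$var1), hinge_knots = 2L),
            class = "feature_set")
}

# exhaustive pairwise AUC oracle
auc_oracle <- function(pres, bg) {
  wins <- 0
  for (p in pres) for (b in bg)
    wins <- wins + (p > b) + 0.5 * (p == b)
  wins / (length(pres) * length(bg))
}

# enumeration oracles for threshold metrics
confusion_oracle <- function(pres, bg, t) {
  list(TP = sum(pres >= t), FN = sum(pres < t),
       TN = sum(bg < t), FP = sum(bg >= t))
}
tss_oracle <- function(cc) cc$TP / (cc$TP + cc$FN) + cc$TN / (cc$TN + cc$FP) - 1
kappa_oracle <- function(cc) {
  N <- cc$TP + cc$FN + cc$TN + cc$FP
  po <- (cc$TP + cc$TN) / N
  pe <- ((cc$TP + cc$FN) * (cc$TP + cc$FP) +
           (cc$TN + cc$FP) * (cc$TN + cc$FN)) / N^2
  (po - pe) / (1 - pe)
}
mtss_oracle <- function(pres, bg) {
  cand <- sort(unique(c(0, pres, bg)))
  ss <- sapply(cand, function(t)
    mean(pres >= t) + mean(bg < t))
  cand[which(ss == max(ss))[1]]
}

# penalised objective used by the brute-force fit oracle
maxent_objective <- function(lambda, Fp, Fb, beta) {
  eta <- drop(Fb %*% lambda)
  m <- max(eta)
  lse <- m + log(sum(exp(eta - m)))
  -sum(lambda * colMeans(Fp)) + lse - log(nrow(Fb)) + sum(beta * abs(lambda))
}
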