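test_that("NorCont rows are exactly invariant to total-lipid scale", {
  p <- milk_preset("organic")
  params <- quiet_params()
  s1 <- simulate_spectrum(p, params, lipid_scale = 1, reference = FALSE)
  s2 <- simulate_spectrum(p, params, lipid_scale = 2, reference = FALSE)
  bm <- bucket_matrix(list(s1, s2), c("a", "b"))
  nc <- normalize_norcont(bm)
  expect_equal(nc$normalization, "NorCont")
  expect_equal(nc$values[1, ], nc$values[2, ], tolerance = 1e-12)
  # a row whose methyl sum is already 3 is unchanged
  tl <- sum(bm$values[1, methyl_bucket_indices(bm$centers)])
  bm3 <- bm; bm3$values <- bm$values * (3 / tl)
  nc3 <- normalize_norcont(bm3)
  expect_equal(nc3$values[1, ], bm3$values[1, ], tolerance = 1e-12)
})

test_that("NorCont shrinks the fat-content separation that dominates UNor", {
  # mixed 1.5%/3% fat subgroups within one class: the lipid-scale split
  # dominates between-sample distances in UNor and vanishes in NorCont
  spec <- cohort_spec(n_per_class = 4, seed = 21,
                      lipid_scale = list(organic = 1, conventional = c(1, 2)))
  coh <- simulate_cohort(spec, acquisition_params(n_points = 8192L))
  bm <- bucket_matrix(coh$spectra, coh$classes, coh$sample_ids)
  conv <- bm$values[bm$classes == "conventional", ]
  d_unor <- stats::dist(conv)
  nc <- normalize_norcont(bm)
  d_nor <- stats::dist(nc$values[nc$classes == "conventional", ])
  # subgroup split: samples 1,3 have scale 1 and 2,4 scale 2
  between_unor <- mean(as.matrix(d_unor)[c(2, 4), c(1, 3)])
  between_nor <- mean(as.matrix(d_nor)[c(2, 4), c(1, 3)])
  rel_unor <- between_unor / mean(d_unor)
  rel_nor <- between_nor / mean(d_nor)
  expect_lt(between_nor / between_unor, 0.05)
  expect_lt(rel_nor, rel_unor)
})

test_that("NorCont reports the sample with a vanishing methyl sum", {
  x <- matrix(1, 2, 631)
  x[2, ] <- 0
  sp <- nmr_spectrum(seq(0, 7, length.out = 4096), rep(0, 4096))
  bm <- structure(list(values = x, centers = seq(0.035, 6.335, by = 0.01),
                       edges = seq(0.03, 6.34, by = 0.01),
                       classes = factor(c("a", "b")),
                       sample_ids = c("ok", "bad"), normalization = "UNor"),
                  class = "bucket_matrix")
  expect_error(normalize_norcont(bm), "bad")
})

test_that("Pareto scaling centers columns and divides by sqrt(sd)", {
  m <- cbind(a = c(0, 2), b = c(5, 5), c = c(1, 3))
  s <- pareto_scale(m)
  expect_equal(unname(s[, "a"]), c(-0.840896, 0.840896), tolerance = 1e-6)
  expect_equal(unname(s[, "b"]), c(0, 0))      # constant column -> zeros
  expect_equal(unname(colMeans(s)), c(0, 0, 0))
  expect_error(pareto_scale(m[1, , drop = FALSE]), "2 samples")
})

test_that("PCA agrees with an independent eigen-decomposition", {
  set.seed(10)
  x <- matrix(rnorm(15 * 6), 15, 6) %*% diag(c(5, 3, 2, 1, 0.5, 0.2))
  pc <- pca_fit(x, 4)
  ev <- eigen(stats::cov(x), symmetric = TRUE)
  for (a in 1:4) {
    expect_equal(abs(sum(pc$loadings[, a] * ev$vectors[, a])), 1,
                 tolerance = 1e-8)
  }
  expect_equal(pc$explained_variance_pct,
               100 * ev$values[1:4] / sum(ev$values), tolerance = 1e-8)
  ctr <- sweep(x, 2, colMeans(x))
  expect_equal(unname(pc$scores), unname(ctr %*% pc$loadings),
               tolerance = 1e-8)
  # rank-1 data loads a single component
  r1 <- tcrossprod(rnorm(10), rnorm(5))
  expect_gt(pca_fit(r1, 2)$explained_variance_pct[1], 99.999)
})

test_that("NIPALS PLS-DA satisfies its algebraic identities", {
  sep <- separable_matrix(10, 40, delta = 3, seed = 2)
  fit <- plsda_fit(sep$x, sep$classes, 3)
  # unit-norm weights, orthogonal scores
  expect_equal(unname(colSums(fit$weights^2)), rep(1, 3), tolerance = 1e-10)
  g <- crossprod(fit$scores)
  expect_lt(max(abs(g[upper.tri(g)])) / max(diag(g)), 1e-8)
  # first weight is the dominant left singular vector of X'Y
  xc <- sweep(sep$x, 2, colMeans(sep$x))
  y <- cbind(sep$classes == "a", sep$classes == "b") + 0
  yc <- sweep(y, 2, colMeans(y))
  w1 <- svd(crossprod(xc, yc))$u[, 1]
  expect_equal(abs(sum(fit$weights[, 1] * w1)), 1, tolerance = 1e-8)
  # R2Y is cumulative and bounded
  expect_true(all(diff(fit$R2Y) >= -1e-12))
  expect_true(all(fit$R2Y <= 1 + 1e-12))
  # separable classes are perfectly re-predicted in training
  expect_equal(as.character(predict(fit, sep$x)$class),
               as.character(sep$classes))
})

test_that("PLS-DA matches the reference NIPALS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(3)
  x <- matrix(rnorm(20 * 12), 20, 12)
  cls <- factor(rep(c("a", "b"), each = 10))
  fit <- plsda_fit(x, cls, 2)
  y <- cbind(a = as.numeric(cls == "a"), b = as.numeric(cls == "b"))
  ref <- mixOmics::pls(x, y, ncomp = 2, scale = FALSE, mode = "regression")
  for (a in 1:2) {
    expect_equal(abs(stats::cor(fit$scores[, a], ref$variates$X[, a])), 1,
                 tolerance = 1e-6)
  }
})

test_that("an exact linear relation yields R2Y ~ 1 with one component", {
  set.seed(4)
  x <- matrix(rnorm(16 * 5), 16, 5) * 0.01
  cls <- factor(rep(c("hi", "lo"), 8))
  x[, 3] <- as.numeric(cls == "hi")          # one column encodes the class
  fit <- plsda_fit(x, cls, 1)
  expect_gte(fit$R2Y[1], 0.999)
})

test_that("cross-validation scores prediction honestly", {
  sep <- separable_matrix(8, 30, delta = 4, seed = 5)
  cv <- plsda_cv(sep$x, sep$classes, n_segments = 4, seed = 6)
  expect_gt(cv$Q2, 0.5)
  expect_equal(cv$pct_correct, 100)
  expect_equal(cv$fisher_p, fisher_enum(matrix(c(8, 0, 0, 8), 2, 2)),
               tolerance = 1e-10)
  # null labels: no predictive power
  set.seed(7)
  q2s <- replicate(5, {
    xr <- matrix(rnorm(20 * 15), 20, 15)
    plsda_cv(xr, factor(rep(c("a", "b"), 10)), n_segments = 5)$Q2
  })
  expect_lte(mean(q2s), 0)
  # leave-one-out as the segment-count boundary
  loo <- plsda_cv(sep$x, sep$classes, segments = seq_along(sep$classes))
  expect_equal(loo$n_segments, 16L)
  expect_equal(loo$pct_correct, 100)
  # a fold swallowing an entire class is refused
  segs <- ifelse(sep$classes == "a", 1L, 2L)
  expect_error(plsda_cv(sep$x, sep$classes, segments = segs),
               "entire class")
})

test_that("VIP satisfies its normalization and ranks planted variables first", {
  sep <- separable_matrix(10, 40, delta = 3, seed = 8)
  fit <- plsda_fit(sep$x, sep$classes, 2)
  v <- milknmr::vip(fit)
  expect_equal(mean(v^2), 1, tolerance = 1e-8)
  # the informative variables (1:3) carry the top VIP scores
  expect_true(all(sort(order(-v)[1:3]) == 1:3))
  # single informative variable: it takes the maximum
  one <- separable_matrix(10, 25, delta = 0, seed = 9)
  x <- one$x
  x[one$classes == "b", 7] <- x[one$classes == "b", 7] + 4
  v1 <- milknmr::vip(plsda_fit(x, one$classes, 2))
  expect_equal(which.max(v1), 7L)
})

test_that("permutation validation separates signal from label noise", {
  sep <- separable_matrix(8, 25, delta = 3, seed = 10)
  perm <- permutation_test(sep$x, sep$classes, n_permutations = 30,
                           n_segments = 4, seed = 11)
  expect_lt(perm$q2_intercept, 0)
  expect_true(all(perm$perm_cor >= 0 & perm$perm_cor <= 1))
  expect_true(perm$valid)
  expect_true(all(perm$perm_Q2 < perm$Q2))
  expect_error(permutation_test(sep$x, sep$classes, n_permutations = 5),
               ">= 20")
  # the reported default follows the conventional 100 iterations
  expect_equal(formals(permutation_test)$n_permutations, 100)
})

test_that("exchangeable labels rarely pass the validity flag", {
  set.seed(12)
  flags <- replicate(8, {
    x <- matrix(rnorm(16 * 12), 16, 12)
    cls <- factor(rep(c("a", "b"), each = 8))
    permutation_test(x, cls, n_permutations = 20, n_segments = 4)$valid
  })
  expect_lte(mean(flags), 0.25)
})

test_that("Fisher's exact test equals exhaustive hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2, 2)), 1.0)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, 2)), 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(14, 0, 0, 16), 2, 2)),
               1 / choose(30, 14), tolerance = 1e-12)
  # sweep of margins: every admissible observed table, margins <= 12
  for (r1 in c(2, 5, 9, 12)) {
    for (r2 in c(3, 7, 12)) {
      for (c1 in unique(pmin(c(2, 6, 10), r1 + r2 - 1))) {
        a_min <- max(0, c1 - r2); a_max <- min(r1, c1)
        for (a in a_min:a_max) {
          tab <- matrix(c(a, c1 - a, r1 - a, r2 - c1 + a), 2, 2)
          expect_equal(fisher_exact_2x2(tab), fisher_enum(tab),
                       tolerance = 1e-9)
        }
      }
    }
  }
  expect_error(fisher_exact_2x2(matrix(c(1.5, 1, 1, 1), 2, 2)), "integer")
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2, 2)), "integer")
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 1, 1), 2, 2)), "margins")
})

test_that("Hotelling screening flags gross outliers only", {
  set.seed(13)
  scores <- matrix(rnorm(30 * 2), 30, 2)
  scores[7, ] <- c(10, -12)                   # planted ~10 sigma sample
  flags <- hotelling_outliers(scores)
  expect_true(flags[7])
  expect_lte(sum(flags), 3)
  # sign flips of a score axis change nothing
  flipped <- scores %*% diag(c(-1, 1))
  expect_equal(unclass(hotelling_outliers(flipped)), unclass(flags),
               ignore_attr = TRUE)
  # identical scores: nothing to flag
  same <- matrix(1, 10, 2)
  expect_false(any(hotelling_outliers(same)))
  expect_error(hotelling_outliers(scores[1:2, ]), "3 samples")
})

test_that("marker t-tests match the closed-form pooled statistic", {
  tt <- marker_ttest(c(1, 2, 3), c(4, 5, 6), pooled = TRUE)
  expect_equal(unname(tt["t"]), -3.67423, tolerance = 1e-5)
  expect_equal(unname(tt["p"]), 0.021312, tolerance = 1e-4)
  ident <- marker_ttest(rep(2, 3), rep(2, 4))
  expect_equal(unname(ident), c(0, 1))
  expect_error(marker_ttest(1, c(1, 2)), "at least 2")
})

test_that("planted class differences are detected with realistic cohorts", {
  coh <- simulate_cohort(cohort_spec(n_per_class = 8, seed = 14))
  comp <- do.call(rbind, lapply(coh$spectra, function(sp) {
    suppressWarnings(composition_report(extract_integral_set(sp)))
  }))
  org <- coh$classes == "organic"
  tt <- marker_ttest(comp$cla_ct[org], comp$cla_ct[!org])
  expect_lt(unname(tt["p"]), 0.05)
  expect_gt(mean(comp$cla_ct[org]), mean(comp$cla_ct[!org]))
})
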