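test_that("leaf dissection index matches analytic values and is scale invariant", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(leaf_dissection_index(sq), 4 / pi, tolerance = 1e-12)
  circ <- ellipse_poly(n = 4096)
  expect_equal(leaf_dissection_index(circ), 1, tolerance = 0.01)
  set.seed(7)
  th <- sort(runif(40, 0, 2 * pi))
  poly <- cbind(cos(th) * (1 + 0.2 * sin(3 * th)), sin(th) * (1 + 0.2 * sin(3 * th)))
  expect_equal(leaf_dissection_index(poly * 10), leaf_dissection_index(poly),
               tolerance = 1e-9)
  expect_gte(leaf_dissection_index(poly), 1 - 1e-6)  # isoperimetric bound
  expect_error(leaf_dissection_index(rbind(c(0, 0), c(1, 1), c(2, 2))), "zero area")
})

test_that("LDI >= 1 for random simple polygons (isoperimetric inequality)", {
  set.seed(42)
  for (r in 1:25) {
    th <- sort(runif(30, 0, 2 * pi))
    rad <- 1 + 0.6 * runif(30)
    poly <- cbind(rad * cos(th), rad * sin(th))  # star-shaped, hence simple
    expect_gte(leaf_dissection_index(poly), 1 - 1e-6)
  }
})

test_that("EFA of a near-circular ellipse concentrates in the first harmonic", {
  # an ellipse is the first-harmonic object in the small-eccentricity limit;
  # at b/a = 0.998 the chord-length parameterization residue is < 1e-3
  e <- elliptic_fourier_descriptors(ellipse_poly(a = 2, b = 1.996), 20)
  expect_lt(max(abs(e$coeffs[-1, ])), 1e-3)
  expect_equal(unname(e$coeffs[1, 4]), 0.998, tolerance = 1e-3)
})

test_that("normalized EFA has A1=1, B1=0, C1=0 and 77 features at 20 harmonics", {
  set.seed(3)
  th <- seq(0, 2 * pi, length.out = 301)[-301]
  leaf <- cbind(cos(th) * (1 + 0.25 * sin(6 * th)), 0.7 * sin(th) * (1 + 0.25 * sin(6 * th)))
  e <- elliptic_fourier_descriptors(leaf, 20)
  expect_equal(unname(e$coeffs[1, 1:3]), c(1, 0, 0), tolerance = 1e-9)
  expect_length(e$features, 77)
  expect_identical(names(e$features)[1:6], c("D1", "A2", "B2", "C2", "D2", "A3"))
})

test_that("EFA features are invariant to rotation, scale and start point", {
  set.seed(4)
  th <- seq(0, 2 * pi, length.out = 513)[-513]
  leaf <- cbind(cos(th) * (1 + 0.3 * sin(5 * th)), 0.6 * sin(th) * (1 + 0.3 * sin(5 * th)))
  f0 <- elliptic_fourier_descriptors(leaf, 20)$features
  for (case in list(c(37, 3, 101), c(180, 1, 0), c(292, 0.25, 400))) {
    a <- case[1] * pi / 180
    R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
    xy <- (leaf %*% t(R)) * case[2]
    if (case[3] > 0) xy <- xy[c((case[3] + 1):nrow(xy), 1:case[3]), ]
    f1 <- elliptic_fourier_descriptors(xy, 20)$features
    expect_lt(max(abs(f0 - f1)), 1e-6)
  }
  expect_error(elliptic_fourier_descriptors(matrix(0, 4, 2)), "degenerate")
})

test_that("leaf straightening is near-identity for straight leaves and undoes bending", {
  straight <- simulate_leaves(n = 1, elongation = 1.8, dissection_amplitude = 0.1,
                              lobe_count = 6, bend_curvature = 0,
                              resolution = 80, seed = 2)
  st <- straighten_leaf(straight$annotations[[1]])
  expect_gte(mask_iou(st$mask, straight$truth_masks[[1]]$mask), 0.98)
  bent <- simulate_leaves(n = 3, elongation = 1.8, dissection_amplitude = 0.15,
                          lobe_count = 7, bend_curvature = 0.002,
                          resolution = 80, seed = 5)
  for (i in 1:3) {
    st <- straighten_leaf(bent$annotations[[i]])
    truth <- bent$truth_masks[[i]]
    expect_gte(mask_iou(st$mask, truth$mask), 0.90)
    # area preserved within 5%
    expect_lt(abs(sum(st$mask) / sum(truth$mask) - 1), 0.05)
  }
  ann <- bent$annotations[[1]]
  ann$midvein <- rbind(c(0, 0), c(0, 0))
  expect_error(straighten_leaf(ann), "zero arc length")
})

test_that("shape PCA is centered, ordered, and reconstructs planar data", {
  set.seed(9)
  # data on a 2-D plane embedded in 20-D
  B <- matrix(rnorm(40), 20, 2)
  X <- matrix(rnorm(60), 30, 2) %*% t(B)
  p <- shape_feature_pca(X, n_pc = 10)
  expect_lt(sum(p$explained[3:10]), 1e-9)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_true(all(diff(p$cum_explained) >= -1e-12))
  expect_lt(max(abs(colMeans(p$scores))), 1e-9)
  # full reconstruction of the centered data
  pfull <- shape_feature_pca(X, n_pc = 2)
  rec <- pfull$scores %*% t(pfull$loadings)
  expect_lt(max(abs(rec - sweep(X, 2, colMeans(X)))), 1e-8)
  expect_error(shape_feature_pca(matrix(rnorm(90), 30, 3), n_pc = 5), "rank")
})

test_that("permutation shape test separates distant clouds and respects row order", {
  set.seed(11)
  X <- rbind(matrix(rnorm(20, 0, 0.01), 10), matrix(rnorm(20, 5, 0.01), 10))
  lab <- rep(c("A", "B"), each = 10)
  r <- permutation_shape_test(X, lab, "A", "B", n_perm = 199, seed = 1)
  expect_equal(r$p_value, 1 / 200)
  ord <- sample(20)
  r2 <- permutation_shape_test(X[ord, ], lab[ord], "A", "B", n_perm = 199, seed = 1)
  expect_equal(r2$p_value, r$p_value)
  expect_error(permutation_shape_test(X, lab, "A", "Z", n_perm = 19, seed = 1),
               "absent")
})

test_that("NPMANOVA pseudo-F equals classical one-way ANOVA F on 1-D data", {
  set.seed(13)
  x <- c(rnorm(8, 0), rnorm(7, 1), rnorm(9, 3))
  g <- rep(c("a", "b", "c"), c(8, 7, 9))
  F_aov <- summary(aov(x ~ g))[[1]]$`F value`[1]
  r <- npmanova(as.matrix(dist(x)), g, n_perm = 19, seed = 1)
  expect_equal(r$pseudo_F, F_aov, tolerance = 1e-9)
})

test_that("NPMANOVA agrees with vegan::adonis2 and is flat on identical groups", {
  skip_if_not_installed("vegan")
  set.seed(14)
  X <- matrix(rnorm(60), 20, 3)
  g <- rep(c("a", "b"), each = 10)
  r <- npmanova(as.matrix(dist(X)), g, n_perm = 49, seed = 1)
  va <- vegan::adonis2(dist(X) ~ g, permutations = 49)
  expect_equal(r$pseudo_F, va$F[1], tolerance = 1e-9)
  # duplicated rows: no among-group signal
  Y <- rbind(X[1:10, ], X[1:10, ])
  r2 <- npmanova(as.matrix(dist(Y)), g, n_perm = 49, seed = 1)
  expect_lt(r2$pseudo_F, 1 + 1e-9)
  expect_gt(r2$p_value, 0.5)
  expect_error(npmanova(as.matrix(dist(X)), rep(c("a", "b"), c(19, 1))),
               "at least 2")
})

test_that("Welch test matches its contract and swaps cleanly", {
  r <- welch_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$t, 0)
  expect_equal(r$p_value, 1)
  r2 <- welch_test(c(1, 2, 3, 4), c(10, 11, 12, 13))
  expect_lt(r2$p_value, 1e-4)
  r3 <- welch_test(c(10, 11, 12, 13), c(1, 2, 3, 4))
  expect_equal(r3$t, -r2$t)
  expect_equal(r3$p_value, r2$p_value)
  expect_error(welch_test(1, c(1, 2)), "n >= 2")
})

test_that("Bonferroni adjustment multiplies and truncates to 1", {
  expect_equal(bonferroni_adjust(0.004, m = 28), 0.112)
  expect_equal(bonferroni_adjust(0.2, m = 28), 1.0)
  expect_equal(bonferroni_adjust(c(0.1, 0.5)), c(0.2, 1.0))
  expect_equal(bonferroni_adjust(0.3, m = 1), 0.3)
  expect_error(bonferroni_adjust(1.2, m = 1), "0, 1")
})

test_that("permutation p values live in [1/(B+1), 1]", {
  set.seed(15)
  for (r in 1:5) {
    X <- matrix(rnorm(32), 16, 2)
    lab <- rep(c("A", "B"), each = 8)
    p1 <- permutation_shape_test(X, lab, "A", "B", n_perm = 39, seed = r)$p_value
    p2 <- npmanova(as.matrix(dist(X)), lab, n_perm = 39, seed = r)$p_value
    expect_gte(p1, 1 / 40); expect_lte(p1, 1)
    expect_gte(p2, 1 / 40); expect_lte(p2, 1)
  }
})

test_that("Welch on LDI separates taxa simulated with distinct dissection", {
  # n = 30 leaves per taxon, amplitude difference worth >= 2 within-taxon SDs
  reject <- 0
  for (rep in 1:20) {
    a <- simulate_leaves(n = 30, elongation = 1.5, dissection_amplitude = 0.08,
                         lobe_count = 6, resolution = 60, render_masks = FALSE,
                         seed = 100 + rep)
    b <- simulate_leaves(n = 30, elongation = 1.5, dissection_amplitude = 0.2,
                         lobe_count = 6, resolution = 60, render_masks = FALSE,
                         seed = 200 + rep)
    ldiA <- vapply(a$annotations, function(x) leaf_dissection_index(x$outline), 1)
    ldiB <- vapply(b$annotations, function(x) leaf_dissection_index(x$outline), 1)
    expect_gt(abs(mean(ldiB) - mean(ldiA)), 2 * min(sd(ldiA), sd(ldiB)))
    if (welch_test(ldiA, ldiB)$p_value < 0.01) reject <- reject + 1
  }
  expect_gte(reject / 20, 0.95)
})

test_that("LDI of rendered synthetic leaves increases with dissection amplitude", {
  means <- vapply(c(0, 0.2, 0.4), function(a) {
    s <- simulate_leaves(n = 8, elongation = 1.2, dissection_amplitude = a,
                         lobe_count = 6, resolution = 60, jitter_sd = 0.02,
                         seed = 31)
    mean(vapply(seq_along(s$annotations), function(i)
      leaf_dissection_index(mask_contour(s$truth_masks[[i]]$mask)), 1))
  }, 1)
  expect_true(all(diff(means) > 0))
  # amplitude 0 renders a (stretched) smooth oval: LDI close to the analytic
  s0 <- simulate_leaves(n = 1, elongation = 1, dissection_amplitude = 0,
                        lobe_count = 6, resolution = 128, jitter_sd = 0, seed = 1)
  expect_equal(leaf_dissection_index(mask_contour(s0$truth_masks[[1]]$mask)),
               1, tolerance = 0.02)
})
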