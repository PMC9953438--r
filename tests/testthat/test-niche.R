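test_that("environment PCA standardizes, decorrelates and averages depth triplets", {
  set.seed(1)
  base <- matrix(rnorm(400), 20, 20)
  st <- env_stack(list(a = base, b = 2 * base + 3, c = matrix(rnorm(400), 20, 20)),
                  extent = c(0, 20, 0, 20), res = 1)
  # two perfectly correlated layers dominate PC1
  p2 <- env_pca_rasters(env_stack(list(a = base, b = 2 * base + 3),
                                  extent = c(0, 20, 0, 20), res = 1),
                        n_components = 2)
  expl <- attr(p2, "explained")
  expect_equal(expl[1], 1, tolerance = 1e-9)
  expect_lt(expl[2], 1e-9)
  # PC layers are mutually uncorrelated over cells (full-rank stack)
  st3 <- env_stack(list(a = base, c = matrix(rnorm(400), 20, 20),
                        d = matrix(rnorm(400), 20, 20)),
                   extent = c(0, 20, 0, 20), res = 1)
  p3 <- env_pca_rasters(st3, n_components = 3)
  v <- sapply(p3$layers, c)
  cc <- cor(v)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  # depth triplets averaged before the PCA
  st2 <- env_stack(list(ph_d1 = matrix(1, 4, 4), ph_d2 = matrix(2, 4, 4),
                        ph_d3 = matrix(3, 4, 4), x = matrix(rnorm(16), 4, 4),
                        y = matrix(rnorm(16), 4, 4)),
                   extent = c(0, 4, 0, 4), res = 1)
  expect_warning(
    pd <- env_pca_rasters(st2, n_components = 2,
                          average_groups = list(ph = c("ph_d1", "ph_d2", "ph_d3"))),
    "constant")  # the averaged layer (constant 2) is dropped with a warning
  expect_length(pd$layers, 2)
  # constant-layer averaging itself is exact
  avg <- (st2$layers$ph_d1 + st2$layers$ph_d2 + st2$layers$ph_d3) / 3
  expect_true(all(avg == 2))
})

test_that("the Gaussian envelope peaks at the occurrence centroid", {
  L <- simulate_landscape(taxa_niches = list(A = list(center = 0, width = 0.6)),
                          scenario = "sympatric", n_occ_per_taxon = 40, seed = 2)
  pcs <- env_pca_rasters(L$stack, n_components = 3)
  s <- fit_suitability(L$occ, pcs)
  expect_true(all(s$suitability >= 0 & s$suitability <= 1, na.rm = TRUE))
  # suitability decreases with environmental distance from the occupied centroid
  rc <- cell_of(pcs, L$occ$lon, L$occ$lat)
  occ_mean <- mean(s$suitability[rc], na.rm = TRUE)
  expect_gt(occ_mean, mean(s$suitability, na.rm = TRUE))
  # duplicated occurrence rows do not change the fit
  occ2 <- occurrence_set(rbind(as.data.frame(L$occ), as.data.frame(L$occ)))
  s2 <- fit_suitability(occ2, pcs)
  expect_equal(s2$suitability, s$suitability)
})

test_that("single-cell occurrences raise NICHE_UNDEFINED", {
  L <- simulate_landscape(taxa_niches = list(A = list(center = 0, width = 1),
                                             B = list(center = 0, width = 1)),
                          scenario = "point_endemic", seed = 5)
  pcs <- env_pca_rasters(L$stack, n_components = 3)
  oB <- L$occ[L$occ$taxon == "B", ]
  expect_error(fit_suitability(oB, pcs), "NICHE_UNDEFINED",
               class = "niche_undefined")
  # and the tests propagate it as n/a rather than failing
  oA <- L$occ[L$occ$taxon == "A", ]
  r <- niche_equivalency_test(oA, oB, pcs, n_reps = 9, seed = 1)
  expect_equal(r$status, "niche_undefined")
  expect_true(is.na(r$p_D))
})

test_that("niche overlap statistics match analytic cases and D <= I", {
  m1 <- matrix(c(1, 0), 1, 2)
  m2 <- matrix(c(0.5, 0.5), 1, 2)
  ov <- niche_overlap(m1, m2)
  expect_equal(ov$D, 0.5)
  expect_equal(ov$I, 1 - 0.5 * ((1 - sqrt(0.5))^2 + 0.5), tolerance = 1e-12)
  # identical maps
  ov2 <- niche_overlap(m2, m2)
  expect_equal(ov2$D, 1); expect_equal(ov2$I, 1)
  # disjoint supports
  ov3 <- niche_overlap(matrix(c(1, 0), 1, 2), matrix(c(0, 1), 1, 2))
  expect_equal(ov3$D, 0); expect_equal(ov3$I, 0)
  # scaling invariance
  ov4 <- niche_overlap(m1 * 7, m2 * 0.3)
  expect_equal(ov4$D, ov$D); expect_equal(ov4$I, ov$I)
  expect_error(niche_overlap(matrix(0, 1, 2), m2), "all-zero")
})

test_that("0 <= D <= I <= 1 on random suitability map pairs", {
  set.seed(6)
  for (r in 1:200) {
    a <- matrix(runif(64), 8, 8)
    b <- matrix(runif(64)^2, 8, 8)
    ov <- niche_overlap(a, b)
    expect_gte(ov$D, 0); expect_lte(ov$D, ov$I + 1e-12); expect_lte(ov$I, 1)
  }
})

test_that("identical occurrence sets give D = 1 and p = 1", {
  L <- simulate_landscape(taxa_niches = list(A = list(center = 0, width = 1)),
                          scenario = "sympatric", n_occ_per_taxon = 25, seed = 7)
  pcs <- env_pca_rasters(L$stack, n_components = 3)
  oA <- L$occ
  oB <- L$occ
  oB$taxon <- "B"
  r <- niche_equivalency_test(oA, oB, pcs, n_reps = 49, seed = 1)
  expect_equal(r$D_obs, 1)
  expect_equal(r$p_D, 1)
  expect_equal(r$p_I, 1)
})

test_that("strongly separated niches are flagged non-equivalent at the floor p", {
  hit <- 0
  for (seed in 1:5) {
    L <- simulate_landscape(taxa_niches = list(A = list(center = -1.2, width = 0.3),
                                               B = list(center = 1.2, width = 0.3)),
                            scenario = "allopatric", n_occ_per_taxon = 30,
                            seed = seed)
    pcs <- env_pca_rasters(L$stack, n_components = 3)
    r <- niche_equivalency_test(L$occ[L$occ$taxon == "A", ],
                                L$occ[L$occ$taxon == "B", ], pcs,
                                n_reps = 99, seed = seed)
    if (r$p_D == 1 / 100) hit <- hit + 1
  }
  expect_gte(hit, 4)
})

test_that("pairwise niche table shows the n/a pattern for point endemics", {
  L <- simulate_landscape(taxa_niches = list(A = list(center = 0, width = 1),
                                             B = list(center = 0.5, width = 1),
                                             C = list(center = 0, width = 1)),
                          scenario = "point_endemic", n_occ_per_taxon = 15,
                          seed = 9)
  pcs <- env_pca_rasters(L$stack, n_components = 3)
  tab <- pairwise_niche_tests(L$occ, pcs, n_reps = 9, seed = 1)
  expect_true(all(is.na(tab$p_D["C", c("A", "B")])))
  expect_true(all(is.na(tab$p_I[c("A", "B"), "C"])))
  expect_false(is.na(tab$p_D["A", "B"]))
  expect_equal(tab$m, 1)
})
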