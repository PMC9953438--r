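test_that("constraint consistency matches hand-computed weights", {
  lab <- c(a = 1, b = 1, c = 2, d = 2)
  cs <- constraint_set(must_link = data.frame(i = "a", j = "b", weight = 1),
                       must_not_link = data.frame(i = "b", j = "c", weight = 1))
  r <- constraint_consistency(lab, cs)
  expect_equal(r$Q, 1)
  expect_true(all(r$q == 1))
  # two constraints, weights 1.0 and 0.5, only the 0.5 one violated
  cs2 <- constraint_set(must_link = data.frame(i = c("a", "c"), j = c("b", "d"),
                                               weight = c(1, 0.5)))
  lab2 <- c(a = 1, b = 1, c = 1, d = 2)
  r2 <- constraint_consistency(lab2, cs2)
  expect_equal(r2$Q, 1 - 0.5 / 1.5)
  # all violated -> Q = 0
  lab3 <- c(a = 1, b = 2, c = 1, d = 2)
  expect_equal(constraint_consistency(lab3, cs2)$Q, 0)
  # no applicable constraints -> Q = 1
  expect_equal(constraint_consistency(lab, constraint_set())$Q, 1)
})

test_that("constraint sets validate weights and disjointness", {
  expect_error(constraint_set(must_link = data.frame(i = "a", j = "b", weight = 2)),
               "\\(0, 1\\]")
  expect_error(constraint_set(must_link = data.frame(i = "a", j = "b", weight = 1),
                              must_not_link = data.frame(i = "b", j = "a", weight = 0.5)),
               "both")
})

test_that("the ensemble recovers planted blobs and is seed-deterministic", {
  set.seed(1)
  X <- rbind(matrix(rnorm(40, 0, 0.02), 20, 2),
             matrix(rnorm(40, 1, 0.02), 20, 2))  # 50 sigma separation
  rownames(X) <- paste0("s", 1:40)
  cfg <- wkm_config(n_runs = 500, k_max = 8, seed = 42)
  m <- run_wkm_ensemble(X, NULL, cfg)
  within <- m$C[1:20, 1:20][upper.tri(diag(20))]
  across <- m$C[1:20, 21:40]
  expect_true(all(across < 0.05))
  expect_gt(min(within), max(across))
  expect_true(all(m$C >= 0 & m$C <= 1))
  # with k fixed at the planted value the blobs are never split
  m2fix <- run_wkm_ensemble(X, NULL, wkm_config(n_runs = 200, k_min = 2,
                                                k_max = 2, seed = 7))
  expect_true(all(m2fix$C[1:20, 1:20] > 0.95))
  expect_true(all(m2fix$C[1:20, 21:40] < 0.05))
  expect_lt(max(abs(m$C - t(m$C))), 1e-12)
  expect_true(all(m$weights >= 0 & m$weights <= 1))
  # bit-for-bit determinism under the same seed
  m2 <- run_wkm_ensemble(X, NULL, cfg)
  expect_identical(m$C, m2$C)
  # consensus partition at k = 2 equals the planted split, and both model
  # selectors pick the planted k
  m <- consensus_partition(m, X)
  expect_equal(adjusted_rand(m$per_k[["2"]]$labels, rep(1:2, each = 20)), 1)
  expect_equal(m$k_best_bic, 2)
  expect_equal(m$k_best_ch, 2)
})

test_that("fully satisfied must-links give runs Q = 1; violated ones are down-weighted", {
  set.seed(2)
  X <- rbind(matrix(rnorm(30, 0, 0.05), 15, 2),
             matrix(rnorm(30, 3, 0.05), 15, 2))
  rownames(X) <- paste0("s", 1:30)
  # must-link pairs inside the first blob: at k = 2 they are always satisfied
  cs <- constraint_set(must_link = data.frame(i = paste0("s", 1:5),
                                              j = paste0("s", 6:10), weight = 1))
  m <- run_wkm_ensemble(X, cs, wkm_config(n_runs = 150, k_min = 2, k_max = 2,
                                          seed = 3))
  expect_true(all(m$weights > 0))
  # adding always-violated must-not-links halves the consistency Q
  cs2 <- constraint_set(must_link = data.frame(i = paste0("s", 1:5),
                                               j = paste0("s", 6:10), weight = 1),
                        must_not_link = data.frame(i = paste0("s", 11:15),
                                                   j = paste0("s", 1:5), weight = 1))
  m2 <- run_wkm_ensemble(X, cs2, wkm_config(n_runs = 150, k_min = 2, k_max = 2,
                                            seed = 3))
  expect_lt(mean(m2$weights), mean(m$weights))
})

test_that("consensus matrix permutes consistently with sample order", {
  set.seed(4)
  X <- matrix(rnorm(60), 20, 3)
  rownames(X) <- paste0("s", 1:20)
  m <- run_wkm_ensemble(X, NULL, wkm_config(n_runs = 200, k_max = 6, seed = 9))
  perm <- sample(20)
  m2 <- run_wkm_ensemble(X[perm, ], NULL, wkm_config(n_runs = 200, k_max = 6, seed = 9))
  # same samples, same entries (values differ run-wise, but the labels map)
  expect_identical(sort(rownames(m2$C)), sort(rownames(m$C)))
  # exact permutation equivariance of the scoring step
  ms <- consensus_partition(m, X)
  labs <- ms$per_k[[as.character(ms$k_best_bic)]]$labels
  expect_equal(length(unique(labs)), ms$k_best_bic)
})

test_that("cluster-number selection skips k >= n and caps at the sample count", {
  set.seed(5)
  X <- matrix(rnorm(24), 8, 3)
  rownames(X) <- paste0("s", 1:8)
  expect_warning(
    m <- run_wkm_ensemble(X, NULL, wkm_config(n_runs = 100, k_min = 2,
                                              k_max = 14, seed = 1)),
    "capped")
  expect_warning(ms <- consensus_partition(m, X), "k > n - 1")
  expect_lte(max(as.integer(names(ms$per_k))), 7)
  expect_false("1" %in% names(ms$per_k))  # k = 1 never evaluated
})

test_that("planted four-taxon genotypes yield k_best = 4 by BIC", {
  hits <- 0
  for (seed in 1:4) {
    sim <- simulate_genotypes(n_taxa = 4, samples_per_taxon = 10, n_sites = 2000,
                              divergence_F = 0.2, seed = seed)
    nd <- nei_distance_matrix(sim$genotypes)
    pc <- pcoa_lingoes(nd$D)
    X <- pc$scores[, seq_len(max(2, pc$n_axes)), drop = FALSE]
    m <- run_wkm_ensemble(X, NULL, wkm_config(n_runs = 400, seed = seed))
    m <- consensus_partition(m, X, X_score = pc$scores)
    if (m$k_best_bic == 4) hits <- hits + 1
    expect_equal(adjusted_rand(m$per_k[["4"]]$labels, sim$genotypes$taxon), 1)
  }
  expect_gte(hits, 3)
})

test_that("taxon_constraints builds within-taxon links and cross-taxon not-links", {
  tx <- setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
  cs <- taxon_constraints(tx, link_taxa = c("A", "B"),
                          not_link_taxa = list(c("A", "B")), weight = 0.8)
  expect_equal(nrow(cs$must_link), 2 * choose(3, 2))
  expect_equal(nrow(cs$must_not_link), 9)
  expect_true(all(cs$must_link$weight == 0.8))
  # perfect clustering by taxon satisfies everything
  lab <- setNames(c(1, 1, 1, 2, 2, 2), names(tx))
  expect_equal(constraint_consistency(lab, cs)$Q, 1)
})
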