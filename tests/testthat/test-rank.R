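# The published pairwise tables and the k = 6 consensus membership are kept
# as text fixtures; parsing them reconstructs the four-axis evidence pattern
# that the rank engine is then evaluated on.

fixture_evidence <- function(alpha = 0.01) {
  cl <- utils::read.csv(extdata("consensus_clusters_k6.csv"))
  clusters <- setNames(cl$cluster, cl$taxon)
  morpho <- list(
    p_ldi = read_pairwise_pvalues(extdata("morphology_pairwise_p.csv"),
                                  triangle = "upper"),
    p_perm = read_pairwise_pvalues(extdata("morphology_pairwise_p.csv"),
                                   triangle = "lower", part = 1),
    p_npmanova = read_pairwise_pvalues(extdata("morphology_pairwise_p.csv"),
                                       triangle = "lower", part = 2))
  niche_D <- read_pairwise_pvalues(extdata("niche_equivalency_pairwise_p.csv"),
                                   triangle = "upper")
  niche_I <- read_pairwise_pvalues(extdata("niche_equivalency_pairwise_p.csv"),
                                   triangle = "lower")
  symp <- read_pairwise_pvalues(extdata("sympatry_pairwise_p.csv"),
                                triangle = "upper")
  build_evidence_matrix(clusters, symp, niche_D, niche_I, morpho, alpha = alpha)
}

test_that("published tables parse to the printed significance counts", {
  ldi <- read_pairwise_pvalues(extdata("morphology_pairwise_p.csv"),
                               triangle = "upper")
  expect_equal(count_nonsignificant_pairs(ldi, 0.01)$n_nonsig, 3)
  nD <- read_pairwise_pvalues(extdata("niche_equivalency_pairwise_p.csv"),
                              triangle = "upper")
  cn <- count_nonsignificant_pairs(nD, 0.01)
  expect_equal(cn$n_nonsig, 2)
  expect_equal(cn$n_testable, 21)
  sy <- read_pairwise_pvalues(extdata("sympatry_pairwise_p.csv"),
                              triangle = "upper")
  cs <- count_nonsignificant_pairs(sy, 0.01)
  expect_equal(cs$n_nonsig, 2)
  expect_equal(cs$n_testable, 21)
})

test_that("evidence matrix flags match the fixture pattern", {
  ev <- fixture_evidence()
  row <- function(a, b) ev[ev$taxon1 == min(a, b) & ev$taxon2 == max(a, b), ]
  # taxa merged by the BIC-optimal clustering are GEN non-significant
  expect_equal(row("ircutianum", "cantabricum")$GEN, "nonsig")
  expect_equal(row("delarbrei", "meridionale")$GEN, "nonsig")
  expect_equal(row("ircutianum", "leucolepis")$GEN, "sig")
  # the point endemic is not testable on the geographic/ecological axes
  mer <- ev[ev$taxon1 == "meridionale" | ev$taxon2 == "meridionale", ]
  expect_true(all(mer$GEO == "na"))
  expect_true(all(mer$EcoD == "na"))
  # morphology is always testable
  expect_true(all(ev$ML %in% c("sig", "nonsig")))
  # all-p-equal-one tables give an all-green matrix
  ones <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  diag(ones) <- NA
  evg <- build_evidence_matrix(c(a = 1, b = 1), ones, ones, ones,
                               list(p_ldi = ones, p_perm = ones, p_npmanova = ones))
  expect_true(all(unlist(evg[, 3:9]) == "nonsig"))
  expect_error(build_evidence_matrix(c(a = 1, z = 2), ones, ones, ones,
                                     list(p_ldi = ones, p_perm = ones,
                                          p_npmanova = ones)),
               "taxon set")
})

test_that("the rank engine reproduces the documented pairwise outcomes", {
  ev <- fixture_evidence()
  overrides <- list(
    "delarbrei|meridionale" = "edaphic_distinct",
    "ircutianum|leucolepis" = "hybrid_swarms")
  dec <- rank_decisions(ev, overrides)
  pick <- function(a, b) dec[dec$taxon1 == min(a, b) & dec$taxon2 == max(a, b), ]
  # (a) genetically independent allopatric lineages with eco/morph support
  for (sp in c("crassifolium", "ruscinonense", "pseudosylvaticum")) {
    others <- setdiff(unique(c(dec$taxon1, dec$taxon2)),
                      c(sp, "delarbrei", "meridionale", "ircutianum",
                        "cantabricum", "leucolepis"))
    for (o in others) expect_equal(pick(sp, o)$recommendation, "distinct_species")
  }
  # (b) the edaphically distinct allopatric sisters: subspecies
  expect_equal(pick("delarbrei", "meridionale")$recommendation, "subspecies")
  expect_equal(pick("delarbrei", "meridionale")$rule, "allopatric_subspecies")
  # (c) hybrid swarms force conservative subspecific ranking
  expect_equal(pick("ircutianum", "leucolepis")$recommendation, "subspecies")
  expect_equal(pick("ircutianum", "leucolepis")$rule, "hybrid_swarm_conservatism")
  # cantabricum nests under ircutianum without any override
  expect_equal(pick("ircutianum", "cantabricum")$recommendation, "subspecies")
  # a fully corroborated pair is a species pair
  expect_equal(pick("crassifolium", "leucolepis")$recommendation, "distinct_species")
  expect_error(rank_decisions(ev, list("a|b" = "not_a_key")), "unknown override")
})

test_that("decisions are a pure function of evidence plus overrides", {
  ev <- fixture_evidence()
  ov <- list("ircutianum|leucolepis" = "hybrid_swarms")
  d1 <- rank_decisions(ev, ov)
  d2 <- rank_decisions(ev, ov)
  expect_identical(d1, d2)
  # overrides change outcomes only for their pair
  d3 <- rank_decisions(ev, list())
  changed <- d1$recommendation != d3$recommendation
  expect_true(all(paste(d1$taxon1, d1$taxon2, sep = "|")[changed] ==
                    "ircutianum|leucolepis"))
})

test_that("the species arrangement groups subspecies into their species", {
  ev <- fixture_evidence()
  dec <- rank_decisions(ev, list(
    "delarbrei|meridionale" = "edaphic_distinct",
    "ircutianum|leucolepis" = "hybrid_swarms"))
  arr <- species_arrangement(dec)
  sizes <- sort(lengths(arr))
  # five species: three monotypic, one with two and one with three subspecies
  expect_equal(unname(sizes), c(1, 1, 1, 2, 3))
  grp <- function(t) which(vapply(arr, function(g) t %in% g, TRUE))
  expect_equal(grp("delarbrei"), grp("meridionale"))
  expect_equal(grp("ircutianum"), grp("leucolepis"))
  expect_equal(grp("ircutianum"), grp("cantabricum"))
  expect_false(grp("crassifolium") == grp("ircutianum"))
})

test_that("rule list is total over flag combinations", {
  taxa <- c("a", "b")
  flags <- c("sig", "nonsig", "na")
  ones <- matrix(1, 2, 2, dimnames = list(taxa, taxa))
  combos <- expand.grid(GEN = c("sig", "nonsig"), GEO = flags, Eco = flags,
                        M = flags, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(combos))) {
    ev <- data.frame(taxon1 = "a", taxon2 = "b", GEN = combos$GEN[r],
                     GEO = combos$GEO[r], EcoD = combos$Eco[r],
                     EcoI = combos$Eco[r], ML = combos$M[r], MP = combos$M[r],
                     MN = combos$M[r], stringsAsFactors = FALSE)
    class(ev) <- c("evidence_matrix", "data.frame")
    d <- rank_decisions(ev)
    expect_true(d$recommendation %in% c("distinct_species", "subspecies",
                                        "conspecific"))
  }
})
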