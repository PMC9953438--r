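# Four-axis evidence integration ('Wettstein tesseract'): genetic,
# geographic, ecological and morphological differentiation flags per taxon
# pair, turned into explicit rank recommendations by an ordered rule list.

.FLAGS <- c("sig", "nonsig", "na")

#' Build the per-pair evidence matrix
#'
#' Axis flags per unordered taxon pair:
#' * `GEN`: significant iff the two taxa occupy different consensus clusters
#'   at the BIC-optimal k,
#' * `GEO`: sympatry test significant (=> allopatry),
#' * `EcoD`, `EcoI`: niche-equivalency tests on Schoener's D / Warren's I,
#' * `ML`, `MP`, `MN`: Welch-on-LDI, permutation shape test, NPMANOVA.
#' All test axes are thresholded at `alpha` on Bonferroni-corrected p values;
#' `NA` entries (un-modellable point endemics) become `"na"` (not testable).
#'
#' @param clusters named integer vector, taxon -> consensus cluster (see
#'   [taxon_clusters()]).
#' @param sympatry_p symmetric matrix of corrected sympatry p values.
#' @param niche_p_D,niche_p_I corrected niche-equivalency p values.
#' @param morpho a `pairwise_test_table` (or list with `p_ldi`, `p_perm`,
#'   `p_npmanova`).
#' @param alpha significance level (default 0.01).
#' @return object of class `evidence_matrix`: data frame with one row per
#'   pair and flag columns `GEN`, `GEO`, `EcoD`, `EcoI`, `ML`, `MP`, `MN`.
#' @export
build_evidence_matrix <- function(clusters, sympatry_p, niche_p_D, niche_p_I,
                                  morpho, alpha = 0.01) {
  taxa <- sort(names(clusters))
  for (m in list(sympatry_p, niche_p_D, niche_p_I,
                 morpho$p_ldi, morpho$p_perm, morpho$p_npmanova)) {
    if (!all(taxa %in% rownames(m)))
      stop("tables do not cover the same taxon set")
  }
  flag <- function(p) {
    if (is.na(p)) "na" else if (p < alpha) "sig" else "nonsig"
  }
  rows <- list()
  for (i in seq_len(length(taxa) - 1)) {
    for (j in (i + 1):length(taxa)) {
      A <- taxa[i]; B <- taxa[j]
      rows[[length(rows) + 1]] <- data.frame(
        taxon1 = A, taxon2 = B,
        GEN = if (clusters[A] != clusters[B]) "sig" else "nonsig",
        GEO = flag(sympatry_p[A, B]),
        EcoD = flag(niche_p_D[A, B]),
        EcoI = flag(niche_p_I[A, B]),
        ML = flag(morpho$p_ldi[A, B]),
        MP = flag(morpho$p_perm[A, B]),
        MN = flag(morpho$p_npmanova[A, B]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  class(out) <- c("evidence_matrix", "data.frame")
  out
}

.pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

.KNOWN_OVERRIDES <- c("hybrid_swarms", "edaphic_distinct")

#' Rank recommendations from the evidence matrix
#'
#' Ordered, total rule list (first match wins). Overrides are explicit named
#' inputs - field knowledge the tests cannot see - given as a named list
#' `list("taxonA|taxonB" = c("hybrid_swarms"))`; known keys are
#' `"hybrid_swarms"` (documented introgressive hybrid swarms in contact
#' zones) and `"edaphic_distinct"` (substrate niches distinct below the
#' raster's grain).
#'
#' 1. `hybrid_swarm_conservatism`: genetically distinct, but declared hybrid
#'    swarms blur the taxon limits -> subspecies (conservative ranking).
#' 2. `species_corroborated`: genetically distinct and corroborated by any
#'    ecological or morphological axis -> distinct species.
#' 3. `allopatric_subspecies`: not genetically distinct, allopatric (or an
#'    untestable point endemic), and any ecological/morphological axis or an
#'    edaphic override differentiates -> subspecies of one species.
#' 4. `conspecific_uniform`: every testable axis non-significant ->
#'    conspecific.
#' 5. `species_genetic_only`: genetically distinct without corroboration ->
#'    distinct species.
#' 6. `conspecific_fallback`: everything else -> conspecific.
#'
#' @param evidence an `evidence_matrix`.
#' @param overrides named list of override keyword vectors per pair key.
#' @return data frame (class `rank_decisions`) with one row per pair:
#'   `recommendation` (distinct_species / subspecies / conspecific),
#'   `rule` and `rationale`.
#' @export
rank_decisions <- function(evidence, overrides = list()) {
  for (k in names(overrides)) {
    bad <- setdiff(overrides[[k]], .KNOWN_OVERRIDES)
    if (length(bad)) stop("unknown override key(s): ", paste(bad, collapse = ", "))
  }
  out <- evidence[, c("taxon1", "taxon2")]
  out$recommendation <- out$rule <- out$rationale <- NA_character_
  for (r in seq_len(nrow(evidence))) {
    e <- evidence[r, ]
    ov <- overrides[[.pair_key(e$taxon1, e$taxon2)]]
    eco_sig <- e$EcoD == "sig" || e$EcoI == "sig"
    morph_sig <- e$ML == "sig" || e$MP == "sig" || e$MN == "sig"
    testable <- unlist(e[, c("GEN", "GEO", "EcoD", "EcoI", "ML", "MP", "MN")])
    all_green <- all(testable[testable != "na"] == "nonsig")
    d <- if (e$GEN == "sig" && "hybrid_swarms" %in% ov) {
      list("subspecies", "hybrid_swarm_conservatism",
           "genetically distinct, but documented hybrid swarms blur the limits; kept at subspecific rank for conservative reasons")
    } else if (e$GEN == "sig" && (eco_sig || morph_sig)) {
      list("distinct_species", "species_corroborated",
           "independent genetic lineage corroborated by ecological and/or morphological differentiation")
    } else if (e$GEN == "nonsig" && e$GEO %in% c("sig", "na") &&
               (eco_sig || morph_sig || "edaphic_distinct" %in% ov)) {
      list("subspecies", "allopatric_subspecies",
           "insufficient genetic differentiation; allopatric distribution with ecological/morphological (or declared edaphic) differences supports subspecific rank")
    } else if (all_green && is.null(ov)) {
      list("conspecific", "conspecific_uniform",
           "no testable axis differentiates the pair")
    } else if (e$GEN == "sig") {
      list("distinct_species", "species_genetic_only",
           "genetically distinct without corroborating axes")
    } else {
      list("conspecific", "conspecific_fallback",
           "no genetic differentiation and no allopatry signal")
    }
    out$recommendation[r] <- d[[1]]
    out$rule[r] <- d[[2]]
    out$rationale[r] <- d[[3]]
  }
  class(out) <- c("rank_decisions", "data.frame")
  out
}

#' Group taxa into species according to the pairwise decisions
#'
#' Connects taxa linked by `subspecies` or `conspecific` recommendations and
#' returns the connected components: each component is one species, its
#' members (if > 1) subspecies.
#'
#' @param decisions a `rank_decisions` data frame.
#' @return list of character vectors (one per species).
#' @export
species_arrangement <- function(decisions) {
  taxa <- sort(unique(c(decisions$taxon1, decisions$taxon2)))
  parent <- stats::setNames(taxa, taxa)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (r in seq_len(nrow(decisions))) {
    if (decisions$recommendation[r] %in% c("subspecies", "conspecific")) {
      a <- find(decisions$taxon1[r]); b <- find(decisions$taxon2[r])
      if (a != b) parent[a] <- b
    }
  }
  split(taxa, vapply(taxa, find, ""))
}

#' Parse a published pairwise p-value table fixture
#'
#' Reads a CSV holding printed pairwise p values verbatim (entries like
#' `"<0.01"`, `"0.21"`, `"1.0"`, `"0"`, `"n/a"`, or `"a/b"` for two tests
#' sharing one triangle) and returns numeric matrices. `"<x"` is parsed as
#' `x / 2` (any value below the printed bound), `"n/a"` as `NA`.
#'
#' @param path CSV with first column = taxon, remaining columns = taxa.
#' @param triangle `"upper"`, `"lower"` or `"both"`: which triangle holds the
#'   values of interest.
#' @param part for `"a/b"` entries, take part 1 or 2 (default 1).
#' @return symmetric numeric matrix (diagonal `NA`).
#' @export
read_pairwise_pvalues <- function(path, triangle = c("both", "upper", "lower"),
                                  part = 1) {
  triangle <- match.arg(triangle)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  taxa <- raw[[1]]
  M <- as.matrix(raw[, -1, drop = FALSE])
  rownames(M) <- taxa
  parse1 <- function(s) {
    s <- trimws(s)
    if (is.na(s) || s == "" || s == "n/a") return(NA_real_)
    if (grepl("/", s, fixed = TRUE) && !grepl("^n/a$", s)) {
      s <- strsplit(s, "/", fixed = TRUE)[[1]][part]
      s <- trimws(s)
    }
    if (startsWith(s, "<")) return(as.numeric(substring(s, 2)) / 2)
    as.numeric(s)
  }
  P <- matrix(NA_real_, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  for (i in seq_along(taxa)) for (j in seq_along(taxa)) {
    if (i == j) next
    use <- switch(triangle,
                  both = TRUE, upper = j > i, lower = j < i)
    if (use) P[i, j] <- parse1(M[i, j])
  }
  # symmetrize from the populated triangle(s)
  for (i in seq_along(taxa)) for (j in seq_along(taxa)) {
    if (i < j) {
      v <- c(P[i, j], P[j, i])
      v <- v[!is.na(v)]
      if (length(v)) P[i, j] <- P[j, i] <- v[1]
    }
  }
  P
}

#' Count non-significant pairs in a pairwise p-value matrix
#'
#' @param P symmetric p-value matrix (`NA` = not testable).
#' @param alpha significance level (default 0.01).
#' @return list with `n_nonsig`, `n_sig`, `n_testable`.
#' @export
count_nonsignificant_pairs <- function(P, alpha = 0.01) {
  v <- P[upper.tri(P)]
  list(n_nonsig = sum(!is.na(v) & v >= alpha),
       n_sig = sum(!is.na(v) & v < alpha),
       n_testable = sum(!is.na(v)))
}
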