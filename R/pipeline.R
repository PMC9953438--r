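# End-to-end orchestration: genotypes -> distances -> consensus clustering;
# leaves -> morphometric tests; landscape -> niche and sympatry tests;
# everything -> evidence matrix -> rank recommendations.

#' Build and validate a pipeline configuration
#'
#' Defaults are the published analysis settings: 20 EFA harmonics, 15 shape
#' PCs, 5000/100 permutations for the shape tests, 0.60/0.80 WKM
#' feature/sample fractions, k in 2-14, 200 niche-equivalency replicates, 400
#' sympatry simulations, range threshold 0.25 and alpha 0.01. Unknown keys
#' are rejected.
#'
#' @param ... key = value overrides of the defaults.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    n_harmonics = 20, n_pc = 15,
    n_perm_shape = 5000, n_perm_npmanova = 100,
    wkm_runs = 5000, feature_fraction = 0.60, sample_fraction = 0.80,
    k_min = 2, k_max = 14,
    niche_reps = 200, sympatry_sims = 400, range_threshold = 0.25,
    alpha = 0.01, d_cap = 10, min_shared_sites = 50,
    suitability_model = "envelope", seed = 1, out_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) stop("unknown configuration key(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the integrative delimitation pipeline
#'
#' Executes the stages in dependency order on in-memory inputs: Nei
#' distances, PCoA and WKM consensus clustering from `genotypes`; LDI/EFA
#' morphometrics and the three pairwise tests from `leaves`; niche-equivalency
#' and sympatry tables from `landscape`; then the evidence matrix and rank
#' recommendations. Any subset of inputs may be supplied; only the dependent
#' stages run. When `cfg$out_dir` is set, per-stage CSV outputs and a
#' Markdown report are written there.
#'
#' @param genotypes a [genotype_matrix()] (optional).
#' @param leaves list with `annotations` (list of [leaf_annotation()]) and
#'   `taxon` (label per leaf), or `NULL`.
#' @param landscape list with `stack` ([env_stack()]) and `occ`
#'   (`occurrence_set`), or `NULL`.
#' @param constraints optional [constraint_set()] for the clustering.
#' @param overrides rank-decision overrides (see [rank_decisions()]).
#' @param cfg a [pipeline_config()].
#' @return list with the per-stage results (`nei`, `pcoa`, `consensus`,
#'   `clusters`, `morpho`, `niche`, `sympatry`, `evidence`, `decisions`).
#' @export
run_pipeline <- function(genotypes = NULL, leaves = NULL, landscape = NULL,
                         constraints = NULL, overrides = list(),
                         cfg = pipeline_config()) {
  if (is.null(genotypes) && is.null(leaves) && is.null(landscape))
    stop("no inputs: supply at least one of genotypes, leaves, landscape")
  out <- list(cfg = cfg)
  if (!is.null(genotypes)) {
    out$nei <- nei_distance_matrix(genotypes, d_cap = cfg$d_cap,
                                   min_shared = cfg$min_shared_sites)
    out$pcoa <- pcoa_lingoes(out$nei$D, variance_target = 0.5)
    X <- out$pcoa$scores[, seq_len(out$pcoa$n_axes), drop = FALSE]
    if (ncol(X) < 2) X <- out$pcoa$scores[, 1:2, drop = FALSE]
    wcfg <- wkm_config(n_runs = cfg$wkm_runs,
                       feature_fraction = cfg$feature_fraction,
                       sample_fraction = cfg$sample_fraction,
                       k_min = cfg$k_min, k_max = cfg$k_max, seed = cfg$seed)
    out$consensus <- consensus_partition(
      run_wkm_ensemble(X, constraints, wcfg), X, X_score = out$pcoa$scores)
    out$clusters <- taxon_clusters(out$consensus, genotypes$taxon)
  }
  if (!is.null(leaves)) {
    ann <- leaves$annotations
    taxon <- leaves$taxon
    feats <- matrix(NA_real_, length(ann), 4 * cfg$n_harmonics - 3)
    ldi <- numeric(length(ann))
    for (i in seq_along(ann)) {
      st <- straighten_leaf(ann[[i]])
      contour <- mask_contour(st$mask)
      ldi[i] <- leaf_dissection_index(contour)
      feats[i, ] <- elliptic_fourier_descriptors(
        contour, n_harmonics = cfg$n_harmonics)$features
    }
    pca <- shape_feature_pca(feats, n_pc = min(cfg$n_pc, length(ann) - 1,
                                               ncol(feats)))
    out$morpho <- pairwise_morphology_tests(
      ldi, pca$scores, taxon, n_perm_shape = cfg$n_perm_shape,
      n_perm_npmanova = cfg$n_perm_npmanova, seed = cfg$seed)
    out$morpho_leafwise <- data.frame(specimen = vapply(ann, `[[`, "", "specimen_id"),
                                      taxon = taxon, ldi = ldi)
  }
  if (!is.null(landscape)) {
    pcs <- env_pca_rasters(landscape$stack,
                           n_components = min(3, length(landscape$stack$layers)))
    out$niche <- pairwise_niche_tests(landscape$occ, pcs,
                                      n_reps = cfg$niche_reps, seed = cfg$seed,
                                      model = cfg$suitability_model)
    out$sympatry <- pairwise_sympatry_tests(landscape$occ, pcs,
                                            n_sim = cfg$sympatry_sims,
                                            threshold = cfg$range_threshold,
                                            seed = cfg$seed,
                                            model = cfg$suitability_model)
  }
  have_all <- !is.null(out$clusters) && !is.null(out$morpho) &&
    !is.null(out$niche) && !is.null(out$sympatry)
  if (have_all) {
    out$evidence <- build_evidence_matrix(out$clusters, out$sympatry$p,
                                          out$niche$p_D, out$niche$p_I,
                                          out$morpho, alpha = cfg$alpha)
    out$decisions <- rank_decisions(out$evidence, overrides = overrides)
    out$arrangement <- species_arrangement(out$decisions)
  }
  if (!is.null(cfg$out_dir)) .write_pipeline_outputs(out, cfg$out_dir)
  out
}

.write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # echo the resolved configuration so a run is reproducible from its outputs
  jsonlite::write_json(unclass(out$cfg), file.path(dir, "run_config.json"),
                       auto_unbox = TRUE, null = "null")
  wcsv <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = TRUE)
  if (!is.null(out$nei)) wcsv(out$nei$D, "nei_distances.csv")
  if (!is.null(out$pcoa)) wcsv(out$pcoa$scores, "pcoa_scores.csv")
  if (!is.null(out$consensus)) {
    wcsv(out$consensus$C, "consensus_matrix.csv")
    utils::write.csv(out$consensus$score_table,
                     file.path(dir, "cluster_scores.csv"), row.names = FALSE)
  }
  if (!is.null(out$morpho)) {
    wcsv(out$morpho$p_ldi, "pairwise_p_ldi.csv")
    wcsv(out$morpho$p_perm, "pairwise_p_perm.csv")
    wcsv(out$morpho$p_npmanova, "pairwise_p_npmanova.csv")
  }
  if (!is.null(out$niche)) {
    wcsv(out$niche$p_D, "pairwise_p_niche_D.csv")
    wcsv(out$niche$p_I, "pairwise_p_niche_I.csv")
  }
  if (!is.null(out$sympatry)) wcsv(out$sympatry$p, "pairwise_p_sympatry.csv")
  if (!is.null(out$decisions)) {
    utils::write.csv(out$decisions, file.path(dir, "rank_decisions.csv"),
                     row.names = FALSE)
    md <- c("# Rank recommendations", "",
            vapply(seq_len(nrow(out$decisions)), function(r) {
              d <- out$decisions[r, ]
              sprintf("- **%s vs %s**: %s (`%s`) - %s", d$taxon1, d$taxon2,
                      d$recommendation, d$rule, d$rationale)
            }, ""))
    writeLines(md, file.path(dir, "report.md"))
  }
  invisible(dir)
}
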