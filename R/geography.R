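# ---- connected components ---------------------------------------------------

# 8-connected component labelling of a logical matrix via frontier BFS.
# Returns an integer matrix (0 = background).
.label_components8 <- function(mask) {
  d <- dim(mask)
  lab <- matrix(0L, d[1], d[2])
  todo <- which(mask)
  nexts <- c(-1L, 1L, -d[1], d[1], -d[1] - 1L, -d[1] + 1L, d[1] - 1L, d[1] + 1L)
  row_of <- function(i) ((i - 1L) %% d[1]) + 1L
  comp <- 0L
  for (s in todo) {
    if (lab[s] != 0L) next
    comp <- comp + 1L
    lab[s] <- comp
    frontier <- s
    while (length(frontier)) {
      cand <- rep(frontier, each = 8L) + nexts
      rows <- row_of(cand)
      src_rows <- rep(row_of(frontier), each = 8L)
      ok <- cand >= 1L & cand <= length(lab) & abs(rows - src_rows) <= 1L
      cand <- unique(cand[ok])
      cand <- cand[mask[cand] & lab[cand] == 0L]
      lab[cand] <- comp
      frontier <- cand
    }
  }
  lab
}

# ---- occupied range ---------------------------------------------------------

#' Occupied-range approximation from a suitability map
#'
#' Binarizes the suitability surface at `threshold`, labels 8-connected
#' components and keeps only components containing at least one occurrence
#' cell - removing predicted but unsampled regions separated from the
#' collections by low-suitability areas. Occurrence cells below the threshold
#' are always retained (each becomes its own component): an occupied cell is
#' by definition part of the realized range.
#'
#' @param suit a `suitability_map` from [fit_suitability()].
#' @param occ `occurrence_set` of the same taxon.
#' @param threshold binarization threshold (default 0.25).
#' @return object of class `range_mask`: `mask` (logical matrix),
#'   `threshold`, `n_components` before/after pruning.
#' @export
occupied_range <- function(suit, occ, threshold = 0.25) {
  st <- list(layers = list(suit$suitability), extent = suit$extent,
             res = suit$res)
  rc <- cell_of(st, occ$lon, occ$lat)
  if (anyNA(rc)) stop("occurrences outside the raster extent")
  m <- !is.na(suit$suitability) & suit$suitability >= threshold
  if (!any(m)) warning("no cell reaches the threshold")
  lab <- .label_components8(m)
  n_before <- max(lab)
  occ_lin <- unique((rc[, "col"] - 1) * nrow(m) + rc[, "row"])
  keep_comp <- unique(lab[occ_lin])
  keep_comp <- keep_comp[keep_comp != 0L]
  mask <- matrix(lab %in% keep_comp, nrow(m), ncol(m))
  mask[occ_lin] <- TRUE  # sub-threshold occurrence cells stay occupied
  structure(list(mask = mask, threshold = threshold,
                 n_components = c(before = n_before,
                                  after = length(keep_comp) +
                                    sum(!(occ_lin %in% which(m)))),
                 extent = suit$extent, res = suit$res),
            class = "range_mask")
}

#' Range overlap fraction
#'
#' `|A intersect B| / min(|A|, |B|)` so that a restricted taxon nested inside
#' a widespread one scores 1; 0 when either mask is empty. `method =
#' "jaccard"` uses `|A intersect B| / |A union B|` instead.
#'
#' @param maskA,maskB `range_mask` objects (or logical matrices) on one grid.
#' @param method `"min"` (default) or `"jaccard"`.
#' @return overlap fraction in `[0, 1]`.
#' @export
range_overlap <- function(maskA, maskB, method = c("min", "jaccard")) {
  method <- match.arg(method)
  a <- if (inherits(maskA, "range_mask")) maskA$mask else maskA
  b <- if (inherits(maskB, "range_mask")) maskB$mask else maskB
  if (!identical(dim(a), dim(b))) stop("masks are not aligned")
  na <- sum(a); nb <- sum(b)
  if (na == 0 || nb == 0) return(0)
  inter <- sum(a & b)
  if (method == "min") inter / min(na, nb) else inter / sum(a | b)
}

#' Permutation test of sympatry
#'
#' Observed statistic: the range overlap of the two taxa's pruned occupied
#' ranges. Null model: taxon labels are permuted over the pooled occurrence
#' points (preserving the two sample sizes), both ranges are rebuilt and the
#' overlap recomputed; `p = (1 + #{overlap* <= overlap_obs}) / (n_sim + 1)`.
#' A small p indicates less overlap than expected from one pooled
#' distribution, i.e. a deviation from sympatry. The pair is ordered
#' canonically by taxon label first, so the result does not depend on
#' argument order.
#'
#' @param occA,occB `occurrence_set`s of the two taxa.
#' @param stack an [env_stack()] of (PC) layers.
#' @param n_sim permutation replicates (default 400).
#' @param threshold range threshold (default 0.25).
#' @param seed RNG seed.
#' @param model suitability model type.
#' @return list with `overlap_obs`, `p`, `status`.
#' @export
sympatry_test <- function(occA, occB, stack, n_sim = 400, threshold = 0.25,
                          seed = 1, model = "envelope") {
  if (nrow(occA) && nrow(occB) && occA$taxon[1] > occB$taxon[1]) {
    tmp <- occA; occA <- occB; occB <- tmp
  }
  set.seed(seed)
  if (model == "envelope") {
    prep <- .prep_env(stack)
    linA <- .occ_lin(prep, occA$lon, occA$lat)
    linB <- .occ_lin(prep, occB$lon, occB$lat)
    build_lin <- function(lin) {
      s <- .envelope_suit(prep, lin)
      if (is.null(s)) return(NULL)
      .range_mask_fast(prep, s, lin, threshold)
    }
    mA <- build_lin(linA); mB <- build_lin(linB)
    if (is.null(mA) || is.null(mB)) {
      return(list(overlap_obs = NA_real_, p = NA_real_, status = "niche_undefined"))
    }
    obs <- range_overlap(mA, mB)
    pool <- c(linA, linB)
    nA <- length(linA)
    one_sim <- function() {
      idx <- sample.int(length(pool), nA)
      a <- build_lin(pool[idx]); b <- build_lin(pool[-idx])
      if (is.null(a) || is.null(b)) return(NULL)
      range_overlap(a, b)
    }
  } else {
    build <- function(o) {
      s <- fit_suitability(o, stack, model = model)
      occupied_range(s, o, threshold = threshold)
    }
    obs <- tryCatch(range_overlap(build(occA), build(occB)),
                    niche_undefined = function(e) NULL)
    if (is.null(obs)) {
      return(list(overlap_obs = NA_real_, p = NA_real_, status = "niche_undefined"))
    }
    pool_df <- rbind(as.data.frame(occA), as.data.frame(occB))
    nA <- nrow(occA)
    one_sim <- function() {
      idx <- sample.int(nrow(pool_df), nA)
      tryCatch({
        oA <- occurrence_set(pool_df[idx, , drop = FALSE], dedup = FALSE)
        oB <- occurrence_set(pool_df[-idx, , drop = FALSE], dedup = FALSE)
        range_overlap(build(oA), build(oB))
      }, niche_undefined = function(e) NULL)
    }
  }
  le <- 0L; used <- 0L
  for (b in seq_len(n_sim)) {
    ov <- one_sim()
    if (is.null(ov)) next
    used <- used + 1L
    if (ov <= obs) le <- le + 1L
  }
  list(overlap_obs = obs, p = (1 + le) / (used + 1), status = "ok")
}

# threshold + 8-connected pruning on the fast-path representation
.range_mask_fast <- function(prep, suit_valid, occ_lin, threshold) {
  m <- matrix(FALSE, prep$dim[1], prep$dim[2])
  m[prep$lin_valid] <- suit_valid >= threshold
  lab <- .label_components8(m)
  keep <- unique(lab[unique(occ_lin)])
  keep <- keep[keep != 0L]
  mask <- matrix(lab %in% keep, prep$dim[1], prep$dim[2])
  mask[occ_lin] <- TRUE
  mask
}

#' Pairwise sympatry test table
#'
#' Runs [sympatry_test()] for all taxon pairs, Bonferroni-corrected over the
#' testable pairs; single-cell taxa give `NA` ("n/a").
#'
#' @param occ `occurrence_set` over several taxa.
#' @param stack an [env_stack()].
#' @param n_sim,threshold,seed,model passed through.
#' @return list with corrected `p` matrix and `overlap` matrix.
#' @export
pairwise_sympatry_tests <- function(occ, stack, n_sim = 400, threshold = 0.25,
                                    seed = 1, model = "envelope") {
  taxa <- sort(unique(occ$taxon))
  k <- length(taxa)
  p <- matrix(NA_real_, k, k, dimnames = list(taxa, taxa))
  ov <- p
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      r <- sympatry_test(occ[occ$taxon == taxa[i], ], occ[occ$taxon == taxa[j], ],
                         stack, n_sim = n_sim, threshold = threshold,
                         seed = seed + i * k + j, model = model)
      p[i, j] <- p[j, i] <- r$p
      ov[i, j] <- ov[j, i] <- r$overlap_obs
    }
  }
  m <- sum(!is.na(p[upper.tri(p)]))
  p <- .adjust_sym(p, max(m, 1))
  list(taxa = taxa, p = p, overlap = ov, m = m)
}
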