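# Per-SNP classification of (diploid parent, diploid parent, tetraploid
# child) triplets into the five SNiPloid categories. Categories 3 and 4
# cannot be separated on unphased data and are reported jointly as CAT34.

.SNP_CATS <- c("CAT1", "CAT2", "CAT34", "CAT5", "UNCLASSIFIED")

#' Classify SNPs of one parent-parent-child individual triplet
#'
#' Vectorized over sites. Only sites where both parents are homozygous
#' (fixed for a single allele each) are classifiable. With parental alleles
#' `a` (parent 1) and `b` (parent 2):
#' * child carries any allele outside `{a, b}` -> `CAT34` (derived SNP unique
#'   to the child; flagged separately when `a != b`),
#' * `a != b`, child fixed for `a` -> `CAT1`; fixed for `b` -> `CAT2`,
#' * `a != b`, child carries both and only `a` and `b` -> `CAT5` (homeo-SNP),
#' * `a == b` and child fixed for it -> `UNCLASSIFIED` (no SNP),
#' * missing genotype or heterozygous parent -> `UNCLASSIFIED`.
#'
#' @param p1_dosage,p2_dosage,child_dosage dosage matrices `sites x alleles`
#'   (rows of `NA` = missing).
#' @param ploidies integer vector `c(p1, p2, child)` (defaults 2, 2, 4);
#'   checked against the dosage row sums.
#' @return list with factor `category` (one per site, levels CAT1, CAT2,
#'   CAT34, CAT5, UNCLASSIFIED) and logical `novel_with_diverged_parents`
#'   (diagnostic flag for CAT34 calls where the parents disagree).
#' @export
categorize_snps <- function(p1_dosage, p2_dosage, child_dosage,
                            ploidies = c(2L, 2L, 4L)) {
  p1 <- as.matrix(p1_dosage); p2 <- as.matrix(p2_dosage)
  ch <- as.matrix(child_dosage)
  L <- nrow(p1)
  for (m in list(p1, p2, ch)) if (nrow(m) != L) stop("dosage matrices differ in length")
  sums <- cbind(rowSums(p1), rowSums(p2), rowSums(ch))
  for (k in 1:3) {
    bad <- which(!is.na(sums[, k]) & sums[, k] != ploidies[k])
    if (length(bad))
      stop(sprintf("dosage/ploidy mismatch for triplet member %d at site %d", k, bad[1]))
  }
  cat <- rep("UNCLASSIFIED", L)
  novel <- rep(FALSE, L)
  complete <- !is.na(sums[, 1]) & !is.na(sums[, 2]) & !is.na(sums[, 3])
  # fixed allele index per parent (NA when heterozygous)
  fixed_idx <- function(m, pl) {
    hit <- !is.na(m) & m == pl
    idx <- max.col(hit, ties.method = "first")
    idx[rowSums(hit) != 1] <- NA
    idx
  }
  a <- fixed_idx(p1, ploidies[1])
  b <- fixed_idx(p2, ploidies[2])
  usable <- complete & !is.na(a) & !is.na(b)
  if (any(usable)) {
    iu <- which(usable)
    has <- ch[iu, , drop = FALSE] > 0
    n_all <- ncol(ch)
    pos <- matrix(seq_len(n_all), length(iu), n_all, byrow = TRUE)
    outside <- rowSums(has & pos != a[iu] & pos != b[iu]) > 0
    has_a <- has[cbind(seq_along(iu), a[iu])]
    has_b <- has[cbind(seq_along(iu), b[iu])]
    same <- a[iu] == b[iu]
    cat[iu[outside]] <- "CAT34"
    novel[iu] <- outside & !same
    diff_in <- !outside & !same
    cat[iu[diff_in & has_a & !has_b]] <- "CAT1"
    cat[iu[diff_in & !has_a & has_b]] <- "CAT2"
    cat[iu[diff_in & has_a & has_b]] <- "CAT5"
    # same & !outside & child fixed for a: no SNP -> stays UNCLASSIFIED
  }
  list(category = factor(cat, levels = .SNP_CATS),
       novel_with_diverged_parents = novel)
}

#' SNP-category profile of a parent-parent-child taxon triplet
#'
#' Classifies every (parent-1 individual, parent-2 individual, child
#' individual) combination at every site, aggregates counts per child
#' individual, and reports per-child category proportions over classified
#' sites plus their arithmetic means across child individuals.
#'
#' @param g a [genotype_matrix()].
#' @param parent1_samples,parent2_samples,child_samples disjoint, non-empty
#'   sample id vectors.
#' @return object of class `triplet_profile`: per-child count and proportion
#'   matrices, mean proportions, `n_classified` per child.
#' @export
triplet_profile <- function(g, parent1_samples, parent2_samples,
                            child_samples) {
  sets <- list(parent1_samples, parent2_samples, child_samples)
  if (any(lengths(sets) == 0)) stop("each sample set must be non-empty")
  if (length(unique(unlist(sets))) != sum(lengths(sets)))
    stop("sample sets must be disjoint")
  idx <- lapply(sets, function(s) {
    i <- match(s, g$sample_ids)
    if (anyNA(i)) stop("unknown sample(s): ", paste(s[is.na(i)], collapse = ", "))
    i
  })
  cats4 <- setdiff(.SNP_CATS, "UNCLASSIFIED")
  counts <- matrix(0, length(child_samples), 4,
                   dimnames = list(child_samples, cats4))
  n_class <- stats::setNames(numeric(length(child_samples)), child_samples)
  for (ci in seq_along(idx[[3]])) {
    c_dos <- matrix(g$dosage[idx[[3]][ci], , ], ncol = dim(g$dosage)[3])
    c_pl <- g$ploidy[idx[[3]][ci]]
    for (i1 in idx[[1]]) {
      p1_dos <- matrix(g$dosage[i1, , ], ncol = dim(g$dosage)[3])
      for (i2 in idx[[2]]) {
        p2_dos <- matrix(g$dosage[i2, , ], ncol = dim(g$dosage)[3])
        res <- categorize_snps(p1_dos, p2_dos, c_dos,
                               c(g$ploidy[i1], g$ploidy[i2], c_pl))
        tab <- table(res$category)[cats4]
        counts[ci, ] <- counts[ci, ] + as.numeric(tab)
        n_class[ci] <- n_class[ci] + sum(tab)
      }
    }
  }
  prop <- counts / ifelse(n_class > 0, n_class, NA)
  structure(list(parent1 = parent1_samples, parent2 = parent2_samples,
                 child = child_samples, counts = counts, proportions = prop,
                 mean_proportions = colMeans(prop, na.rm = TRUE),
                 n_classified = n_class),
            class = "triplet_profile")
}

#' @export
print.triplet_profile <- function(x, ...) {
  mp <- x$mean_proportions
  cat(sprintf("triplet_profile: %d child individual(s); mean proportions CAT1 %.3f, CAT2 %.3f, CAT34 %.3f, CAT5 %.3f\n",
              length(x$child), mp["CAT1"], mp["CAT2"], mp["CAT34"], mp["CAT5"]))
  invisible(x)
}

#' Scan candidate diploid parent pairs for a polyploid child taxon
#'
#' Evaluates every unordered pair of candidate parent taxa against the child
#' taxon and ranks the pairs by mean homeo-SNP (category 5) proportion, the
#' signature of recent allopolyploid origin.
#'
#' @param g a [genotype_matrix()].
#' @param candidate_parent_taxa character vector of at least two diploid taxa.
#' @param child_taxon the polyploid taxon (must not be among the candidates).
#' @return data frame (class `parent_scan`) with one row per pair, sorted by
#'   `cat5` descending; attribute `profiles` holds the full
#'   [triplet_profile()] objects.
#' @export
parent_scan <- function(g, candidate_parent_taxa, child_taxon) {
  if (length(candidate_parent_taxa) < 2) stop("need at least 2 candidate parent taxa")
  if (child_taxon %in% candidate_parent_taxa)
    stop("child taxon must not be among the candidate parents")
  child_samples <- taxon_samples(g, child_taxon)
  pairs <- utils::combn(sort(candidate_parent_taxa), 2)
  profs <- list()
  rows <- list()
  for (p in seq_len(ncol(pairs))) {
    t1 <- pairs[1, p]; t2 <- pairs[2, p]
    pr <- triplet_profile(g, taxon_samples(g, t1), taxon_samples(g, t2),
                          child_samples)
    profs[[paste(t1, t2, sep = "|")]] <- pr
    mp <- pr$mean_proportions
    rows[[p]] <- data.frame(parent1 = t1, parent2 = t2,
                            cat1 = mp["CAT1"], cat2 = mp["CAT2"],
                            cat34 = mp["CAT34"], cat5 = mp["CAT5"],
                            mean_n_classified = mean(pr$n_classified))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(-out$cat5), ]
  attr(out, "profiles") <- profs
  attr(out, "child_taxon") <- child_taxon
  class(out) <- c("parent_scan", "data.frame")
  out
}
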