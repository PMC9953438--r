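#' Genotype matrix for mixed-ploidy samples
#'
#' Container for allele-dosage genotypes of diploid and tetraploid samples at
#' (possibly multiallelic) SNP sites. Dosages are stored as a 3-d array
#' `[sample, site, allele]`; a missing call sets all allele slots of that
#' sample/site to `NA`. At a non-missing site the dosage vector sums to the
#' sample's ploidy.
#'
#' @param dosage numeric array `[n_samples, n_sites, max_alleles]`; allele 1
#'   is the reference allele.
#' @param sample_ids character vector of sample labels.
#' @param taxon named character vector mapping each sample to its taxon.
#' @param ploidy named integer vector (2 or 4) per sample.
#' @param sites data frame with columns `chrom`, `pos`, `ref`, `alt` (comma
#'   separated alternate alleles, possibly `""`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, sample_ids, taxon, ploidy, sites) {
  stopifnot(is.array(dosage), length(dim(dosage)) == 3)
  n <- length(sample_ids)
  if (dim(dosage)[1] != n) stop("dosage rows must match sample_ids")
  if (dim(dosage)[2] != nrow(sites)) stop("dosage columns must match sites")
  taxon <- taxon[sample_ids]
  ploidy <- as.integer(ploidy[sample_ids])
  names(ploidy) <- sample_ids
  if (anyNA(taxon)) stop("taxon map is missing samples: ",
                         paste(sample_ids[is.na(taxon)], collapse = ", "))
  if (anyNA(ploidy)) stop("ploidy map is missing samples: ",
                          paste(sample_ids[is.na(ploidy)], collapse = ", "))
  if (!all(ploidy %in% c(2L, 4L))) stop("ploidy must be 2 or 4")
  dup <- duplicated(sites[, c("chrom", "pos")])
  if (any(dup)) stop("duplicated site positions: ",
                     paste(sites$chrom[dup], sites$pos[dup], sep = ":", collapse = ", "))
  n_alleles <- 1L + ifelse(nzchar(sites$alt),
                           vapply(strsplit(sites$alt, ","), length, 1L), 0L)
  # dosage sums must equal ploidy wherever not missing
  tot <- apply(dosage, c(1, 2), sum)
  bad <- which(!is.na(tot) & abs(tot - matrix(ploidy, n, nrow(sites))) > 0)
  if (length(bad)) {
    i <- ((bad[1] - 1) %% n) + 1
    j <- ((bad[1] - 1) %/% n) + 1
    stop(sprintf("dosage of sample '%s' at %s:%d does not sum to its ploidy (%d)",
                 sample_ids[i], sites$chrom[j], sites$pos[j], ploidy[i]))
  }
  structure(list(sample_ids = sample_ids, taxon = taxon, ploidy = ploidy,
                 sites = sites, n_alleles = n_alleles, dosage = dosage),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosage[, , 1]))
  cat(sprintf("genotype_matrix: %d samples x %d sites (%d taxa; ploidy %s; %.1f%% missing)\n",
              length(x$sample_ids), nrow(x$sites), length(unique(x$taxon)),
              paste(sort(unique(x$ploidy)), collapse = "/"), 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$sample_ids), nrow(x$sites))

#' Per-site allele frequencies of one sample
#'
#' At each non-missing site the frequency vector is `dosage / ploidy` and sums
#' to one; missing sites stay `NA`. SNP-level frequencies make diploid and
#' tetraploid samples directly comparable in downstream distances.
#'
#' @param g a [genotype_matrix()].
#' @param sample sample label.
#' @return numeric matrix `sites x alleles` of frequencies (rows of `NA` where
#'   the call is missing).
#' @export
sample_allele_frequencies <- function(g, sample) {
  i <- match(sample, g$sample_ids)
  if (is.na(i)) stop("unknown sample: ", sample)
  m <- g$dosage[i, , , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, ncol = dim(g$dosage)[3])
  m / g$ploidy[i]
}

# frequency array [sample, site, allele] for internal vectorised use
.freq_array <- function(g) {
  g$dosage / array(g$ploidy, dim = dim(g$dosage))
}

#' Samples belonging to a taxon
#' @param g a [genotype_matrix()].
#' @param taxon taxon label.
#' @return character vector of sample ids.
#' @export
taxon_samples <- function(g, taxon) {
  g$sample_ids[g$taxon == taxon]
}
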