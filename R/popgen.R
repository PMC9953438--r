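#' SNP-based Nei (1972) standard genetic distances
#'
#' Computes pairwise Nei standard distances directly from per-sample SNP
#' allele frequencies (dosage / ploidy), which makes diploid and tetraploid
#' samples directly comparable. For a sample pair, over the pairwise-complete
#' sites: `J_x = mean_l sum_i x_li^2`, `J_y` likewise,
#' `J_xy = mean_l sum_i x_li * y_li`, identity `I = J_xy / sqrt(J_x * J_y)`
#' and `D = -ln(I)`, capped at `d_cap` (disjoint allele sets give `I = 0`).
#' Missing genotypes are handled by pairwise-complete deletion; pairs sharing
#' fewer than `min_shared` sites are flagged, and pairs sharing none get `NA`.
#'
#' @param g a [genotype_matrix()].
#' @param d_cap upper bound replacing the divergent `-ln(0)` (default 10).
#' @param min_shared minimum pairwise-complete sites before a pair is flagged
#'   unreliable (default 50).
#' @param pool_by_taxon average allele frequencies within taxa first and
#'   return taxon-level distances (default `FALSE`: per-sample distances).
#' @return object of class `nei_dist`: list with `labels`, `D` (symmetric,
#'   zero diagonal), `n_shared` (pairwise-complete site counts), `flagged`
#'   (logical matrix), `d_cap`.
#' @export
nei_distance_matrix <- function(g, d_cap = 10.0, min_shared = 50,
                                pool_by_taxon = FALSE) {
  fr <- .freq_array(g)                    # [sample, site, allele]
  labels <- g$sample_ids
  if (pool_by_taxon) {
    taxa <- unique(g$taxon)
    L <- dim(fr)[2]; A <- dim(fr)[3]
    pooled <- array(NA_real_, c(length(taxa), L, A))
    for (t in seq_along(taxa)) {
      rows <- which(g$taxon == taxa[t])
      sub <- fr[rows, , , drop = FALSE]
      pooled[t, , ] <- apply(sub, c(2, 3), function(v) {
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      })
    }
    fr <- pooled
    labels <- taxa
  }
  n <- dim(fr)[1]
  if (n < 2) stop("need at least 2 samples")
  A <- dim(fr)[3]
  ok <- matrix(!is.na(fr[, , 1]), nrow = n)  # sample x site
  # per-site sum of squared frequencies, with NA propagated
  sq <- apply(fr^2, c(1, 2), sum)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  nsh <- matrix(0L, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- ok[i, ] & ok[j, ]
      nsh[i, j] <- nsh[j, i] <- sum(shared)
      if (!any(shared)) {
        D[i, j] <- D[j, i] <- NA_real_
        next
      }
      Jx <- mean(sq[i, shared])
      Jy <- mean(sq[j, shared])
      xi <- matrix(fr[i, shared, ], ncol = A)
      yj <- matrix(fr[j, shared, ], ncol = A)
      Jxy <- mean(rowSums(xi * yj))
      I <- Jxy / sqrt(Jx * Jy)
      d <- if (I <= exp(-d_cap)) d_cap else -log(min(I, 1))
      D[i, j] <- D[j, i] <- d
    }
  }
  flagged <- nsh < min_shared
  diag(flagged) <- FALSE
  structure(list(labels = labels, D = D, n_shared = nsh, flagged = flagged,
                 d_cap = d_cap),
            class = "nei_dist")
}

#' @export
print.nei_dist <- function(x, ...) {
  cat(sprintf("nei_dist: %d samples, mean D = %.4f (cap %.1f), %d flagged pair(s)\n",
              length(x$labels), mean(x$D[upper.tri(x$D)], na.rm = TRUE),
              x$d_cap, sum(x$flagged[upper.tri(x$flagged)])))
  invisible(x)
}

#' Principal coordinate analysis with Lingoes correction
#'
#' Classical metric scaling of a distance matrix. The Gower matrix
#' `-1/2 * J D^2 J` is eigendecomposed; if the smallest eigenvalue is below
#' `-1e-8`, the Lingoes (1971) additive correction is applied: `2 * c1` with
#' `c1 = |lambda_min|` is added to all squared off-diagonal distances and the
#' decomposition repeated, which shifts every non-trivial eigenvalue up by
#' `c1` and removes the negative part. Scores are `eigenvector * sqrt(lambda)`
#' for positive eigenvalues, so pairwise score distances reproduce the
#' (corrected) input distances.
#'
#' @param D symmetric distance matrix (no `NA`).
#' @param variance_target share of (positive) eigenvalue mass used to choose
#'   `n_axes` (default 0.5).
#' @return object of class `pcoa_result`: `scores`, `eigenvalues`,
#'   `lingoes_constant`, `n_axes` (smallest axis count reaching the target),
#'   `labels`.
#' @export
pcoa_lingoes <- function(D, variance_target = 0.5) {
  D <- as.matrix(D)
  if (anyNA(D)) stop("distance matrix contains NA")
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix must be symmetric")
  n <- nrow(D)
  J <- diag(n) - 1 / n
  decomp <- function(D2) {
    B <- -0.5 * J %*% D2 %*% J
    eigen((B + t(B)) / 2, symmetric = TRUE)
  }
  e <- decomp(D^2)
  c1 <- 0
  if (min(e$values) < -1e-8) {
    c1 <- abs(min(e$values))
    D2 <- D^2 + 2 * c1
    diag(D2) <- 0
    e <- decomp(D2)
  }
  pos <- which(e$values > 1e-9 * max(abs(e$values), 1))
  scores <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), length(pos))
  rownames(scores) <- rownames(D)
  colnames(scores) <- paste0("PCo", seq_along(pos))
  share <- cumsum(e$values[pos]) / sum(e$values[pos])
  n_axes <- which(share >= variance_target)[1]
  structure(list(scores = scores, eigenvalues = e$values,
                 lingoes_constant = c1, n_axes = n_axes,
                 explained = e$values[pos] / sum(e$values[pos]),
                 labels = rownames(D)),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("pcoa_result: %d positive axes, Lingoes c = %.4g, %d axes reach the variance target\n",
              ncol(x$scores), x$lingoes_constant, x$n_axes))
  invisible(x)
}
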