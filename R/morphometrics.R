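# ---- polygon and mask geometry helpers -------------------------------------

#' Signed polygon area (shoelace)
#' @param xy `n x 2` matrix of vertices.
#' @return signed area (positive for counter-clockwise tracing).
#' @keywords internal
polygon_area_signed <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1)
  sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]) / 2
}

.polygon_perimeter <- function(xy) {
  d <- rbind(diff(xy), xy[1, ] - xy[nrow(xy), ])
  sum(sqrt(rowSums(d^2)))
}

#' Rasterize a polygon to a binary mask
#'
#' Cells whose centres fall inside the polygon are set to 1. Uses
#' `mgcv::in.out` for point-in-polygon.
#'
#' @param xy polygon vertices (`n x 2`).
#' @param resolution pixels per unit of the polygon's coordinates (default 1:
#'   coordinates already in pixels).
#' @param pad margin in pixels around the bounding box.
#' @return list with `mask` (matrix, row = y), `origin` (xy of pixel (1,1)
#'   centre) and `resolution`.
#' @export
rasterize_polygon <- function(xy, resolution = 1, pad = 2) {
  xy <- xy * resolution
  xr <- range(xy[, 1]); yr <- range(xy[, 2])
  x0 <- floor(xr[1]) - pad; y0 <- floor(yr[1]) - pad
  nx <- ceiling(xr[2]) + pad - x0 + 1
  ny <- ceiling(yr[2]) + pad - y0 + 1
  cx <- x0 + seq_len(nx) - 1
  cy <- y0 + seq_len(ny) - 1
  gr <- cbind(rep(cx, times = ny), rep(cy, each = nx))
  inside <- mgcv::in.out(rbind(xy, xy[1, ]), gr)
  mask <- matrix(0L, nrow = ny, ncol = nx)
  mask[cbind(rep(seq_len(ny), each = nx), rep(seq_len(nx), times = ny))] <-
    as.integer(inside)
  list(mask = mask, origin = c(x0, y0), resolution = resolution)
}

#' Extract the boundary contour of a binary mask
#'
#' Marching-squares contour at level 0.5 (sub-pixel, base
#' `grDevices::contourLines`), optionally smoothed with a circular moving
#' average to suppress pixel staircase. The longest contour is returned.
#'
#' @param mask binary matrix (row = y).
#' @param smooth odd moving-average window in vertices (0 = none; default 5).
#' @return `n x 2` matrix of (x, y) contour coordinates in pixel units.
#' @export
mask_contour <- function(mask, smooth = 5) {
  m <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  # contourLines treats x as the first index; build so that x = columns
  cl <- grDevices::contourLines(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                                z = t(m), levels = 0.5)
  if (!length(cl)) stop("mask has no foreground")
  lens <- vapply(cl, function(s) length(s$x), 1L)
  s <- cl[[which.max(lens)]]
  xy <- cbind(s$x, s$y) - 1  # undo padding
  if (nrow(xy) > 1 && all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
  if (smooth >= 3) xy <- .smooth_closed(xy, smooth)
  xy
}

.smooth_closed <- function(xy, w) {
  n <- nrow(xy)
  if (n <= w) return(xy)
  pad <- rbind(xy[(n - w + 1):n, , drop = FALSE], xy, xy[1:w, , drop = FALSE])
  k <- rep(1 / w, w)
  sm <- apply(pad, 2, function(col) stats::filter(col, k, sides = 2))
  sm[(w + 1):(w + n), , drop = FALSE]
}

# ---- leaf straightening -----------------------------------------------------

#' Straighten a leaf along its mid-vein
#'
#' Re-renders the leaf in a frame whose x-axis is arc length along the
#' mid-vein and whose y-axis is the signed perpendicular offset from it, so
#' that a bent leaf becomes straight while area is approximately preserved.
#' The mid-vein is resampled at 1-px arc-length steps; every outline vertex is
#' mapped to (arc length of the nearest vein point, signed offset) and the
#' transformed polygon is re-rasterized.
#'
#' @param annotation a [leaf_annotation()].
#' @param resolution pixels per input pixel in the output rendering (default 1).
#' @return list as returned by [rasterize_polygon()], plus the transformed
#'   `outline` polygon.
#' @export
straighten_leaf <- function(annotation, resolution = 1) {
  stopifnot(inherits(annotation, "leaf_annotation"))
  mv <- annotation$midvein
  seglen <- sqrt(rowSums(diff(mv)^2))
  L <- sum(seglen)
  if (L <= 0) stop("midvein has zero arc length")
  # resample midvein at ~1 px steps
  s_in <- c(0, cumsum(seglen))
  s_out <- seq(0, L, by = min(1, L / 32))
  vx <- stats::approx(s_in, mv[, 1], xout = s_out)$y
  vy <- stats::approx(s_in, mv[, 2], xout = s_out)$y
  # tangents (central differences)
  n <- length(s_out)
  tx <- c(vx[2] - vx[1], (vx[-(1:2)] - vx[1:(n - 2)]) / 2, vx[n] - vx[n - 1])
  ty <- c(vy[2] - vy[1], (vy[-(1:2)] - vy[1:(n - 2)]) / 2, vy[n] - vy[n - 1])
  nt <- sqrt(tx^2 + ty^2)
  tx <- tx / nt; ty <- ty / nt
  p <- annotation$outline
  # nearest vein sample per outline vertex
  d2 <- outer(p[, 1], vx, "-")^2 + outer(p[, 2], vy, "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  dx <- p[, 1] - vx[nearest]
  dy <- p[, 2] - vy[nearest]
  off <- dx * (-ty[nearest]) + dy * tx[nearest]  # signed perpendicular offset
  along <- dx * tx[nearest] + dy * ty[nearest]   # residual along-tangent part
  new_xy <- cbind(s_out[nearest] + along, off)
  r <- rasterize_polygon(new_xy, resolution = resolution)
  r$outline <- new_xy
  r
}

# ---- leaf dissection index --------------------------------------------------

#' Leaf dissection index
#'
#' `P^2 / (4 * pi * A)` with perimeter `P` and enclosed area `A`: 1 for a
#' circle, growing with elongation and incision of the outline.
#' Scale-invariant.
#'
#' @param outline polygon vertices (`n x 2`) or a binary mask matrix (the
#'   contour is then extracted with [mask_contour()]).
#' @return dissection index (dimensionless, >= 1 up to discretization error).
#' @export
leaf_dissection_index <- function(outline) {
  if (is.matrix(outline) && ncol(outline) != 2) outline <- mask_contour(outline)
  A <- abs(pracma::polyarea(outline[, 1], outline[, 2]))
  if (A <= 0) stop("outline encloses zero area")
  .polygon_perimeter(outline)^2 / (4 * pi * A)
}

# ---- elliptic Fourier analysis ----------------------------------------------

#' Elliptic Fourier descriptors of a closed contour
#'
#' Kuhl-Giardina elliptic Fourier coefficients with chord-length
#' parameterization. Normalization (default) removes scale, rotation and
#' start-point so that `A1 = 1`, `B1 = 0`, `C1 = 0`; contour orientation is
#' canonicalized to counter-clockwise and the residual half-turn ambiguity of
#' the first-harmonic phase is resolved by the sign of the first substantial
#' even-harmonic coefficient, making the descriptors reproducible across
#' rotated, rescaled and start-shifted copies of the same contour.
#'
#' @param outline closed polygon (`n x 2`, at least 3 distinct vertices).
#' @param n_harmonics number of harmonics (default 20).
#' @param normalize apply the invariance normalization (default `TRUE`).
#' @return list with `coeffs` (`n_harmonics x 4` matrix of (A, B, C, D)) and,
#'   when normalized, `features`: the coefficients excluding the constant
#'   A1, B1, C1 in fixed order (D1, A2..D2, ..., An..Dn).
#' @export
elliptic_fourier_descriptors <- function(outline, n_harmonics = 20,
                                         normalize = TRUE) {
  xy <- as.matrix(outline)
  if (nrow(xy) > 1 && all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
  if (nrow(xy) < 3) stop("contour needs at least 3 vertices")
  dxy <- rbind(diff(xy), xy[1, ] - xy[nrow(xy), ])
  dt <- sqrt(rowSums(dxy^2))
  keep <- dt > 0
  dxy <- dxy[keep, , drop = FALSE]
  dt <- dt[keep]
  if (sum(dt) <= 0 || length(dt) < 3) stop("degenerate (zero-length) contour")
  if (polygon_area_signed(xy) < 0) {  # canonical ccw orientation
    xy <- xy[nrow(xy):1, , drop = FALSE]
    dxy <- rbind(diff(xy), xy[1, ] - xy[nrow(xy), ])
    dt <- sqrt(rowSums(dxy^2))
    keep <- dt > 0
    dxy <- dxy[keep, , drop = FALSE]
    dt <- dt[keep]
  }
  t1 <- cumsum(dt)
  TT <- t1[length(t1)]
  t0 <- c(0, t1[-length(t1)])
  co <- matrix(0, n_harmonics, 4)
  for (n in seq_len(n_harmonics)) {
    w <- 2 * pi * n / TT
    cc <- cos(w * t1) - cos(w * t0)
    ss <- sin(w * t1) - sin(w * t0)
    f <- TT / (2 * n^2 * pi^2)
    co[n, 1] <- f * sum(dxy[, 1] / dt * cc)
    co[n, 2] <- f * sum(dxy[, 1] / dt * ss)
    co[n, 3] <- f * sum(dxy[, 2] / dt * cc)
    co[n, 4] <- f * sum(dxy[, 2] / dt * ss)
  }
  colnames(co) <- c("A", "B", "C", "D")
  if (!normalize) return(list(coeffs = co))
  co <- .efa_normalize(co)
  list(coeffs = co, features = efa_feature_vector(co))
}

.efa_normalize <- function(co) {
  a1 <- co[1, 1]; b1 <- co[1, 2]; c1 <- co[1, 3]; d1 <- co[1, 4]
  th <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1), a1^2 + c1^2 - b1^2 - d1^2)
  out <- co
  for (n in seq_len(nrow(co))) {
    S <- matrix(c(cos(n * th), -sin(n * th), sin(n * th), cos(n * th)),
                2, 2, byrow = TRUE)
    out[n, ] <- c(t(matrix(co[n, ], 2, 2, byrow = TRUE) %*% S))
  }
  psi <- atan2(out[1, 3], out[1, 1])
  E <- sqrt(out[1, 1]^2 + out[1, 3]^2)
  R <- matrix(c(cos(psi), sin(psi), -sin(psi), cos(psi)), 2, 2, byrow = TRUE)
  for (n in seq_len(nrow(co))) {
    out[n, ] <- c(t(R %*% matrix(out[n, ], 2, 2, byrow = TRUE))) / E
  }
  # the first-harmonic phase is determined modulo pi; the two solutions differ
  # by the sign of all even harmonics. Pick the representative whose first
  # substantial even-harmonic coefficient is positive.
  feats <- efa_feature_vector(out)
  affected <- c(FALSE, rep(seq(2, nrow(out)) %% 2 == 0, each = 4))
  cand <- which(affected & abs(feats) > 1e-7)
  if (length(cand) && feats[cand[1]] < 0) {
    ev <- seq(2, nrow(out), by = 2)
    out[ev, ] <- -out[ev, ]
  }
  out
}

#' Feature vector from normalized EFA coefficients
#'
#' Drops the constant A1, B1, C1 and returns the remaining coefficients in
#' fixed order (D1, then A2..D2, ..., An..Dn); 77 features for 20 harmonics.
#'
#' @param coeffs normalized coefficient matrix from
#'   [elliptic_fourier_descriptors()].
#' @return numeric vector of length `4 * n_harmonics - 3`.
#' @export
efa_feature_vector <- function(coeffs) {
  v <- c(coeffs[1, 4], t(coeffs[-1, , drop = FALSE]))
  names(v) <- c("D1", paste0(rep(c("A", "B", "C", "D"), nrow(coeffs) - 1),
                             rep(seq(2, nrow(coeffs)), each = 4)))
  v
}

# ---- shape feature PCA ------------------------------------------------------

#' PCA of EFA shape features
#'
#' Centered (not re-standardized) principal component analysis of the
#' normalized descriptors; normalized EFA coefficients are already
#' commensurate, so no per-feature rescaling is applied.
#'
#' @param features leaves x features matrix.
#' @param n_pc number of principal components to retain (default 15).
#' @param variance_target if not `NULL`, retain the smallest number of PCs
#'   explaining at least this share of total variance instead of `n_pc`.
#' @return list of class `shape_pc_space` with `scores`, `loadings`,
#'   `explained`, `cum_explained`, `n_pc`, `center`.
#' @export
shape_feature_pca <- function(features, n_pc = 15, variance_target = NULL) {
  X <- as.matrix(features)
  if (nrow(X) < n_pc + 1) stop("need at least n_pc + 1 leaves")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  if (!is.null(variance_target)) {
    n_pc <- which(cumsum(expl) >= variance_target)[1]
  }
  if (n_pc > ncol(pc$x)) stop("n_pc exceeds the rank of the feature matrix")
  structure(list(scores = pc$x[, seq_len(n_pc), drop = FALSE],
                 loadings = pc$rotation[, seq_len(n_pc), drop = FALSE],
                 explained = expl, cum_explained = cumsum(expl),
                 n_pc = n_pc, center = pc$center),
            class = "shape_pc_space")
}

# ---- pairwise tests ---------------------------------------------------------

#' Permutation test of shape difference in PC space
#'
#' Test statistic: the mean Euclidean distance over all cross-taxon leaf
#' pairs in PC space (alternative: mean cross-group minus mean within-group
#' distance). The null distribution comes from label permutations restricted
#' to the two taxa's leaves; `p = (1 + #{T* >= T_obs}) / (n_perm + 1)`.
#'
#' @param scores leaves x PCs score matrix.
#' @param labels taxon label per leaf.
#' @param taxonA,taxonB the two taxa to compare.
#' @param n_perm number of permutations (default 5000).
#' @param seed RNG seed.
#' @param statistic `"cross"` (mean cross-group distance, default) or
#'   `"cross_minus_within"`.
#' @return list with `statistic`, `p_value`, `n_perm`.
#' @export
permutation_shape_test <- function(scores, labels, taxonA, taxonB,
                                   n_perm = 5000, seed = 1,
                                   statistic = c("cross", "cross_minus_within")) {
  statistic <- match.arg(statistic)
  if (!taxonA %in% labels) stop("taxon absent from labels: ", taxonA)
  if (!taxonB %in% labels) stop("taxon absent from labels: ", taxonB)
  sel <- labels %in% c(taxonA, taxonB)
  X <- as.matrix(scores)[sel, , drop = FALSE]
  lab <- labels[sel]
  nA <- sum(lab == taxonA)
  nB <- sum(lab == taxonB)
  if (nA < 2 || nB < 2) stop("both taxa need at least 2 leaves")
  D <- as.matrix(stats::dist(X))
  stat_fun <- function(isA) {
    cross <- mean(D[isA, !isA])
    if (statistic == "cross") return(cross)
    within <- (sum(D[isA, isA]) + sum(D[!isA, !isA])) /
      (nA * (nA - 1) + nB * (nB - 1))
    cross - within
  }
  obs <- stat_fun(lab == taxonA)
  set.seed(seed)
  n <- nA + nB
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    isA <- logical(n)
    isA[sample.int(n, nA)] <- TRUE
    if (stat_fun(isA) >= obs) exceed <- exceed + 1L
  }
  list(statistic = obs, p_value = (1 + exceed) / (n_perm + 1), n_perm = n_perm)
}

#' Non-parametric multivariate analysis of variance (Anderson pseudo-F)
#'
#' Distance-based one-way NPMANOVA. With
#' `SS_total = (1/N) * sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) * sum_{i<j in g} d_ij^2` and
#' `SS_among = SS_total - SS_within`, the statistic is
#' `F = (SS_among / (a - 1)) / (SS_within / (N - a))`. Significance by label
#' permutation.
#'
#' @param d distance matrix (square symmetric) or `dist`.
#' @param labels group label per object (>= 2 groups, >= 2 objects each).
#' @param n_perm number of permutations (default 100).
#' @param seed RNG seed.
#' @return list with `pseudo_F`, `p_value`, `df` and the SS decomposition.
#' @export
npmanova <- function(d, labels, n_perm = 100, seed = 1) {
  D <- as.matrix(d)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-9) stop("d must be square symmetric")
  labels <- as.character(labels)
  N <- nrow(D)
  groups <- unique(labels)
  a <- length(groups)
  if (a < 2) stop("need at least 2 groups")
  if (any(table(labels) < 2)) stop("each group needs at least 2 objects")
  D2 <- D^2
  ss_total <- sum(D2[upper.tri(D2)]) / N
  fstat <- function(lab) {
    ss_w <- 0
    for (gr in unique(lab)) {
      idx <- which(lab == gr)
      ss_w <- ss_w + sum(D2[idx, idx][upper.tri(diag(length(idx)))]) / length(idx)
    }
    ((ss_total - ss_w) / (a - 1)) / (ss_w / (N - a))
  }
  F_obs <- fstat(labels)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (fstat(labels[sample.int(N)]) >= F_obs) exceed <- exceed + 1L
  }
  list(pseudo_F = F_obs, p_value = (1 + exceed) / (n_perm + 1),
       df = c(among = a - 1, within = N - a), ss_total = ss_total,
       n_perm = n_perm)
}

#' Welch's two-sample t test
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of freedom
#' (delegates to [stats::t.test()]).
#'
#' @param x,y numeric samples (each n >= 2).
#' @return list with `t`, `df`, `p_value`.
#' @export
welch_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("both samples need n >= 2")
  if (stats::var(x) + stats::var(y) <= 0) {
    return(list(t = 0, df = length(x) + length(y) - 2, p_value = 1))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Bonferroni adjustment truncated to 1
#'
#' `p_adj = min(1, m * p)`.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param m number of tests in the family (defaults to `length(p_values)`).
#' @return adjusted p values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  if (m < sum(!is.na(p_values))) stop("m must be at least the number of tests")
  pmin(1, m * p_values)
}

#' All pairwise morphology tests for a set of taxa
#'
#' Runs, for every unordered taxon pair, Welch's test on leaf dissection
#' indices and the two shape tests (permutation test and NPMANOVA) on PC
#' scores, then Bonferroni-corrects each family over the number of pairs.
#'
#' @param ldi numeric vector of per-leaf dissection indices.
#' @param scores PC score matrix (same leaves, same order).
#' @param labels taxon per leaf.
#' @param n_perm_shape,n_perm_npmanova permutation counts (defaults 5000, 100).
#' @param seed RNG seed.
#' @return object of class `pairwise_test_table`: list of symmetric matrices
#'   `p_ldi`, `p_perm`, `p_npmanova` of corrected p values (diagonal `NA`).
#' @export
pairwise_morphology_tests <- function(ldi, scores, labels,
                                      n_perm_shape = 5000,
                                      n_perm_npmanova = 100, seed = 1) {
  taxa <- sort(unique(labels))
  k <- length(taxa)
  m <- k * (k - 1) / 2
  mk <- function() matrix(NA_real_, k, k, dimnames = list(taxa, taxa))
  p_ldi <- mk(); p_perm <- mk(); p_np <- mk()
  D_full <- as.matrix(stats::dist(scores))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      A <- taxa[i]; B <- taxa[j]
      sel <- labels %in% c(A, B)
      p_ldi[i, j] <- p_ldi[j, i] <-
        welch_test(ldi[labels == A], ldi[labels == B])$p_value
      p_perm[i, j] <- p_perm[j, i] <-
        permutation_shape_test(scores, labels, A, B, n_perm = n_perm_shape,
                               seed = seed)$p_value
      p_np[i, j] <- p_np[j, i] <-
        npmanova(D_full[sel, sel], labels[sel], n_perm = n_perm_npmanova,
                 seed = seed)$p_value
    }
  }
  structure(list(taxa = taxa, p_ldi = .adjust_sym(p_ldi, m),
                 p_perm = .adjust_sym(p_perm, m),
                 p_npmanova = .adjust_sym(p_np, m), m = m),
            class = "pairwise_test_table")
}

# Bonferroni-correct a symmetric pairwise p-value matrix over its upper
# triangle (family size m), mirroring the result.
.adjust_sym <- function(p, m) {
  ut <- upper.tri(p)
  p[ut] <- bonferroni_adjust(p[ut], m = max(m, sum(!is.na(p[ut]))))
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  p
}
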