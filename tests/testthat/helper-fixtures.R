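# shared helpers for the test suite

# intersection-over-union of two binary masks after centering their
# foreground bounding boxes on a common canvas
mask_iou <- function(m1, m2) {
  crop <- function(m) {
    r <- range(which(rowSums(m) > 0))
    c <- range(which(colSums(m) > 0))
    m[r[1]:r[2], c[1]:c[2], drop = FALSE]
  }
  a <- crop(m1); b <- crop(m2)
  nr <- max(nrow(a), nrow(b)); nc <- max(ncol(a), ncol(b))
  pa <- matrix(0, nr, nc); pb <- matrix(0, nr, nc)
  pa[seq_len(nrow(a)) + (nr - nrow(a)) %/% 2,
     seq_len(ncol(a)) + (nc - ncol(a)) %/% 2] <- a
  pb[seq_len(nrow(b)) + (nr - nrow(b)) %/% 2,
     seq_len(ncol(b)) + (nc - ncol(b)) %/% 2] <- b
  sum(pa & pb) / sum(pa | pb)
}

# closed circle / ellipse polygon
ellipse_poly <- function(a = 1, b = 1, n = 512) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(a * cos(th), b * sin(th))
}

# tiny two-taxon genotype matrix built by hand (biallelic + one triallelic)
tiny_genotypes <- function() {
  ids <- c("d1", "d2", "t1")
  sites <- data.frame(chrom = "c1", pos = 1:3, ref = "A",
                      alt = c("T", "T", "T,G"), stringsAsFactors = FALSE)
  dosage <- array(NA_real_, c(3, 3, 3))
  dosage[1, , ] <- rbind(c(1, 1, 0), c(2, 0, 0), c(0, 2, 0))
  dosage[2, , ] <- rbind(c(0, 2, 0), c(2, 0, 0), c(2, 0, 0))
  dosage[3, , ] <- rbind(c(3, 1, 0), c(4, 0, 0), c(2, 1, 1))
  genotype_matrix(dosage, ids,
                  taxon = c(d1 = "A", d2 = "B", t1 = "C"),
                  ploidy = c(d1 = 2, d2 = 2, t1 = 4), sites)
}

# brute-force Nei (1972) distance between two samples, straight from the
# definition (independent oracle for nei_distance_matrix)
nei_brute <- function(g, s1, s2, d_cap = 10) {
  f1 <- sample_allele_frequencies(g, s1)
  f2 <- sample_allele_frequencies(g, s2)
  shared <- !is.na(f1[, 1]) & !is.na(f2[, 1])
  jx <- jy <- jxy <- numeric(0)
  for (l in which(shared)) {
    jx <- c(jx, sum(f1[l, ]^2))
    jy <- c(jy, sum(f2[l, ]^2))
    jxy <- c(jxy, sum(f1[l, ] * f2[l, ]))
  }
  I <- mean(jxy) / sqrt(mean(jx) * mean(jy))
  if (I <= exp(-d_cap)) d_cap else -log(min(I, 1))
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  exp_idx <- si * sj / choose(n, 2)
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

extdata <- function(f) system.file("extdata", "leucanthemum", f,
                                   package = "polyrank")
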