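# Generators producing inputs with the statistical structure the analysis
# assumes: taxon-structured mixed-ploidy SNP matrices (Balding-Nichols-style
# Beta drift around shared ancestral frequencies, with allo-/autotetraploid
# derivation from the diploid pools), parametric leaf silhouettes, and
# gradient landscapes with Gaussian niches. Every generator is deterministic
# under its seed and returns a `truth` record sufficient to regenerate the
# dataset.

#' Simulate taxon-structured mixed-ploidy genotypes
#'
#' Per site, an ancestral allele frequency `p0 ~ Uniform(0.05, 0.95)` is
#' drawn; each diploid taxon drifts to
#' `p ~ Beta(p0 (1 - F) / F, (1 - p0)(1 - F) / F)` (differentiation parameter
#' `F` in (0, 1)). Diploid dosages are `Binomial(2, p_taxon)`; an
#' allotetraploid taxon combines one binomial draw from each parent taxon's
#' frequency (`Binomial(2, p1) + Binomial(2, p2)`), an autotetraploid draws
#' `Binomial(4, p_taxon)`. Calls are set missing at `missing_rate`. All sites
#' are biallelic (`ref` A, `alt` T).
#'
#' @param n_taxa number of diploid taxa.
#' @param samples_per_taxon samples per taxon (recycled).
#' @param n_sites number of SNP sites.
#' @param divergence_F differentiation parameter in (0, 1).
#' @param polyploid_specs list of lists `list(taxon =, type = "allo"|"auto",
#'   parents = c(t1, t2), n_samples =)`; parents must be diploid taxa (for
#'   `"auto"` a single parent).
#' @param missing_rate per-call missing probability (default 0).
#' @param seed RNG seed.
#' @return list with `genotypes` (a [genotype_matrix()]) and `truth`.
#' @export
simulate_genotypes <- function(n_taxa = 4, samples_per_taxon = 10,
                               n_sites = 1000, divergence_F = 0.2,
                               polyploid_specs = NULL, missing_rate = 0,
                               seed = 1) {
  stopifnot(divergence_F > 0, divergence_F < 1)
  set.seed(seed)
  dip_taxa <- paste0("T", seq_len(n_taxa))
  for (sp in polyploid_specs) {
    if (!all(sp$parents %in% dip_taxa))
      stop("polyploid parent not among the diploid taxa: ",
           paste(setdiff(sp$parents, dip_taxa), collapse = ", "))
  }
  p0 <- stats::runif(n_sites, 0.05, 0.95)
  FF <- divergence_F
  pt <- vapply(dip_taxa, function(tx)
    stats::rbeta(n_sites, p0 * (1 - FF) / FF, (1 - p0) * (1 - FF) / FF),
    numeric(n_sites))
  spt <- rep(samples_per_taxon, length.out = n_taxa)
  ids <- character(0); taxon <- character(0); ploidy <- integer(0)
  alt_dos <- list()
  for (t in seq_len(n_taxa)) {
    for (s in seq_len(spt[t])) {
      ids <- c(ids, sprintf("%s_%02d", dip_taxa[t], s))
      taxon <- c(taxon, dip_taxa[t]); ploidy <- c(ploidy, 2L)
      alt_dos[[length(alt_dos) + 1]] <- stats::rbinom(n_sites, 2, pt[, t])
    }
  }
  parents_of <- list()
  for (sp in polyploid_specs) {
    ns <- if (is.null(sp$n_samples)) samples_per_taxon[1] else sp$n_samples
    parents_of[[sp$taxon]] <- sp$parents
    for (s in seq_len(ns)) {
      ids <- c(ids, sprintf("%s_%02d", sp$taxon, s))
      taxon <- c(taxon, sp$taxon); ploidy <- c(ploidy, 4L)
      dos <- if (identical(sp$type, "auto")) {
        stats::rbinom(n_sites, 4, pt[, sp$parents[1]])
      } else {
        stats::rbinom(n_sites, 2, pt[, sp$parents[1]]) +
          stats::rbinom(n_sites, 2, pt[, sp$parents[2]])
      }
      alt_dos[[length(alt_dos) + 1]] <- dos
    }
  }
  n <- length(ids)
  dosage <- array(NA_real_, c(n, n_sites, 2))
  for (i in seq_len(n)) {
    a <- alt_dos[[i]]
    if (missing_rate > 0) a[stats::runif(n_sites) < missing_rate] <- NA
    dosage[i, , 1] <- ploidy[i] - a
    dosage[i, , 2] <- a
  }
  sites <- data.frame(chrom = "sim1", pos = seq_len(n_sites),
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  g <- genotype_matrix(dosage, ids, stats::setNames(taxon, ids),
                       stats::setNames(ploidy, ids), sites)
  list(genotypes = g,
       truth = list(taxon = stats::setNames(taxon, ids),
                    parents_of = parents_of, divergence_F = divergence_F,
                    p0 = p0, taxon_freqs = pt, missing_rate = missing_rate,
                    seed = seed))
}

#' Simulate leaf annotations with known shape parameters
#'
#' Outlines follow `r(theta) = R (1 + a sin(m theta))` scaled by `elongation`
#' along the x axis (dissection amplitude `a` in [0, 1), `m` lobes); the
#' mid-vein runs along the major axis. Optional smooth bending (constant
#' curvature) is applied to outline and vein together while the unbent
#' ground-truth mask is retained. Per-leaf variability jitters `a` and the
#' elongation multiplicatively.
#'
#' @param n number of leaves.
#' @param elongation major/minor axis ratio (>= 1).
#' @param dissection_amplitude mean lobe amplitude `a` (must stay < 1).
#' @param lobe_count number of lobes `m`.
#' @param bend_curvature curvature of the applied bend (1/px; 0 = straight).
#' @param resolution leaf radius in pixels (default 100).
#' @param jitter_sd relative s.d. of per-leaf parameter jitter (default 0.05).
#' @param render_masks rasterize the unbent ground-truth masks (default
#'   `TRUE`; disable when only annotations are needed).
#' @param taxon taxon label stored with the annotations.
#' @param seed RNG seed.
#' @return list with `annotations` (list of [leaf_annotation()]),
#'   `truth_masks` (unbent masks from [rasterize_polygon()]) and `truth`
#'   (per-leaf parameters).
#' @export
simulate_leaves <- function(n = 10, elongation = 1.5,
                            dissection_amplitude = 0.1, lobe_count = 6,
                            bend_curvature = 0, resolution = 100,
                            jitter_sd = 0.05, render_masks = TRUE,
                            taxon = "sim", seed = 1) {
  if (dissection_amplitude >= 1) stop("dissection amplitude must be < 1 (self-intersection)")
  set.seed(seed)
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  ann <- list(); masks <- list()
  pars <- data.frame(a = numeric(n), elong = numeric(n), kappa = numeric(n))
  for (i in seq_len(n)) {
    a <- min(0.95, dissection_amplitude * exp(stats::rnorm(1, 0, jitter_sd)))
    el <- max(1, elongation * exp(stats::rnorm(1, 0, jitter_sd)))
    R <- resolution
    r <- R * (1 + a * sin(lobe_count * th))
    outline <- cbind(el * r * cos(th), r * sin(th))
    span <- diff(range(outline[, 1]))
    vein_x <- seq(min(outline[, 1]) + 0.03 * span,
                  max(outline[, 1]) - 0.03 * span, length.out = 64)
    midvein <- cbind(vein_x, 0)
    if (render_masks) masks[[i]] <- rasterize_polygon(outline)
    kappa <- bend_curvature
    if (kappa != 0) {
      bend <- function(p) {
        rr <- 1 / kappa
        cbind((rr - p[, 2]) * sin(kappa * p[, 1]),
              rr - (rr - p[, 2]) * cos(kappa * p[, 1]))
      }
      outline <- bend(outline)
      midvein <- bend(midvein)
    }
    ann[[i]] <- leaf_annotation(outline, midvein,
                                specimen_id = sprintf("%s_%03d", taxon, i))
    pars[i, ] <- c(a, el, kappa)
  }
  list(annotations = ann, truth_masks = masks,
       truth = list(taxon = taxon, params = pars, elongation = elongation,
                    dissection_amplitude = dissection_amplitude,
                    lobe_count = lobe_count, bend_curvature = bend_curvature,
                    resolution = resolution, seed = seed))
}

#' Simulate an environmental landscape with taxon niches and occurrences
#'
#' Environmental layers are smooth linear gradients in random directions plus
#' spatially correlated noise, standardized per layer. Each taxon has a
#' Gaussian niche in environment space (`suitability =
#' exp(-0.5 sum ((e - center) / width)^2)`); occurrences are sampled with
#' probability proportional to suitability, restricted to scenario regions:
#' `"sympatric"` (all taxa everywhere), `"allopatric"` (disjoint
#' longitudinal bands), `"parapatric"` (overlapping bands), `"point_endemic"`
#' (last taxon confined to its single most suitable cell).
#'
#' @param grid_shape `c(nrow, ncol)` cells (default `c(40, 40)`).
#' @param n_env number of environmental layers (default 3).
#' @param taxa_niches named list per taxon: `list(center =, width =)` in
#'   (standardized) environment space; `center` is recycled to `n_env`.
#' @param n_occ_per_taxon occurrences per taxon (recycled).
#' @param scenario one of `"sympatric"`, `"allopatric"`, `"parapatric"`,
#'   `"point_endemic"`.
#' @param extent geographic extent (default 10 x 10 degrees at lon 0-10,
#'   lat 40-50).
#' @param noise_sd relative weight of the correlated noise field (default 0.3).
#' @param seed RNG seed.
#' @return list with `stack` ([env_stack()]), `occ` (`occurrence_set`) and
#'   `truth` (niches, regions, per-taxon suitability surfaces).
#' @export
simulate_landscape <- function(grid_shape = c(40, 40), n_env = 3,
                               taxa_niches = list(A = list(center = 0, width = 1),
                                                  B = list(center = 0, width = 1)),
                               n_occ_per_taxon = 30,
                               scenario = c("sympatric", "allopatric",
                                            "parapatric", "point_endemic"),
                               extent = c(0, 10, 40, 50), noise_sd = 0.3,
                               seed = 1) {
  scenario <- match.arg(scenario)
  set.seed(seed)
  nr <- grid_shape[1]; nc <- grid_shape[2]
  res <- (extent[2] - extent[1]) / nc
  if (abs((extent[4] - extent[3]) / nr - res) > 1e-9)
    stop("extent and grid shape imply unequal x/y resolution")
  rowc <- matrix(rep(seq_len(nr), nc), nr)
  colc <- matrix(rep(seq_len(nc), each = nr), nr)
  layers <- list()
  for (e in seq_len(n_env)) {
    ang <- stats::runif(1, 0, 2 * pi)
    grad <- cos(ang) * colc / nc + sin(ang) * rowc / nr
    noise <- matrix(stats::rnorm(nr * nc), nr)
    for (it in 1:3) {  # cheap smoothing: 4-neighbour averaging passes
      noise <- (noise +
                  noise[c(1, seq_len(nr - 1)), ] + noise[c(seq_len(nr - 1) + 1, nr), ] +
                  noise[, c(1, seq_len(nc - 1))] + noise[, c(seq_len(nc - 1) + 1, nc)]) / 5
    }
    l <- grad + noise_sd * noise / stats::sd(noise)
    layers[[paste0("env", e)]] <- (l - mean(l)) / stats::sd(l)
  }
  stack <- env_stack(layers, extent, res)
  taxa <- names(taxa_niches)
  nt <- length(taxa)
  nocc <- rep(n_occ_per_taxon, length.out = nt)
  # scenario regions (logical matrices)
  regions <- stats::setNames(vector("list", nt), taxa)
  for (t in seq_len(nt)) {
    reg <- matrix(TRUE, nr, nc)
    if (scenario == "allopatric") {
      lo <- floor((t - 1) * nc / nt) + 1
      hi <- floor(t * nc / nt)
      reg <- colc >= lo & colc <= hi
    } else if (scenario == "parapatric") {
      w <- ceiling(nc / nt * 1.5)
      lo <- max(1, floor((t - 1) * nc / nt) - floor(w / 4))
      reg <- colc >= lo & colc <= min(nc, lo + w)
    }
    regions[[t]] <- reg
  }
  suits <- list()
  occ_rows <- list()
  for (t in seq_len(nt)) {
    ni <- taxa_niches[[t]]
    cen <- rep(ni$center, length.out = n_env)
    wid <- rep(ni$width, length.out = n_env)
    z <- matrix(0, nr, nc)
    for (e in seq_len(n_env)) z <- z + ((layers[[e]] - cen[e]) / wid[e])^2
    suit <- exp(-0.5 * z)
    suits[[taxa[t]]] <- suit
    w <- suit * regions[[t]]
    if (scenario == "point_endemic" && t == nt) {
      best <- which.max(suit)
      w[] <- 0
      w[best] <- 1
    }
    if (sum(w > 0) == 0) stop("no cell available for taxon ", taxa[t])
    cells <- sample.int(nr * nc, nocc[t], replace = TRUE, prob = c(w))
    rws <- ((cells - 1) %% nr) + 1
    cls <- ((cells - 1) %/% nr) + 1
    lon <- extent[1] + (cls - 1 + stats::runif(nocc[t], 0.05, 0.95)) * res
    lat <- extent[4] - (rws - 1 + stats::runif(nocc[t], 0.05, 0.95)) * res
    occ_rows[[t]] <- data.frame(taxon = taxa[t], lon = lon, lat = lat)
  }
  occ <- occurrence_set(do.call(rbind, occ_rows))
  list(stack = stack, occ = occ,
       truth = list(taxa_niches = taxa_niches, scenario = scenario,
                    regions = regions, suitability = suits, seed = seed))
}
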