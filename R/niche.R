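# ---- environment PCA --------------------------------------------------------

#' Principal-component rasters of an environmental stack
#'
#' Standardizes each layer over its non-nodata cells (mean 0, sd 1), runs a
#' PCA across cells and returns the first `n_components` component scores as
#' new raster layers. Layers listed together in `average_groups` (e.g. the
#' same soil variable at several depth levels) are averaged into one layer
#' first; groups named like `<var>_d1`, `<var>_d2`, ... can be auto-detected
#' via `depth_suffixes`. Constant layers are dropped with a warning.
#'
#' @param stack an [env_stack()].
#' @param n_components number of PC layers to return (default 3).
#' @param average_groups optional named list mapping a new layer name to the
#'   layer names to average.
#' @param depth_suffixes character vector of suffixes identifying depth
#'   triplets to auto-average (default none).
#' @return an [env_stack()] of PC layers, with attribute `explained`
#'   (variance ratios) and `loadings`.
#' @export
env_pca_rasters <- function(stack, n_components = 3, average_groups = NULL,
                            depth_suffixes = NULL) {
  layers <- stack$layers
  if (!is.null(depth_suffixes) && is.null(average_groups)) {
    pat <- paste0("(", paste(depth_suffixes, collapse = "|"), ")$")
    base <- sub(pat, "", names(layers))
    grp <- split(names(layers), base)
    average_groups <- grp[vapply(grp, length, 1L) > 1]
  }
  if (!is.null(average_groups)) {
    for (nm in names(average_groups)) {
      mem <- average_groups[[nm]]
      avg <- Reduce(`+`, layers[mem]) / length(mem)
      layers[mem] <- NULL
      layers[[nm]] <- avg
    }
  }
  valid <- !is.na(layers[[1]])
  vals <- vapply(layers, function(l) l[valid], numeric(sum(valid)))
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant layer(s): ",
            paste(names(layers)[sds == 0], collapse = ", "))
    vals <- vals[, sds > 0, drop = FALSE]
  }
  if (ncol(vals) < n_components) stop("need at least n_components non-constant layers")
  pc <- stats::prcomp(vals, center = TRUE, scale. = TRUE)
  out <- list()
  for (c_i in seq_len(n_components)) {
    l <- layers[[1]]
    l[] <- NA
    l[valid] <- pc$x[, c_i]
    out[[paste0("PC", c_i)]] <- l
  }
  st <- env_stack(out, stack$extent, stack$res)
  attr(st, "explained") <- pc$sdev^2 / sum(pc$sdev^2)
  attr(st, "loadings") <- pc$rotation
  st
}

# ---- grid/coordinate helpers ------------------------------------------------

#' Grid cell index of lon/lat points
#' @param stack an [env_stack()].
#' @param lon,lat coordinates in degrees.
#' @return matrix with columns `row`, `col` (`NA` outside the extent).
#' @export
cell_of <- function(stack, lon, lat) {
  ex <- stack$extent; res <- stack$res
  col <- floor((lon - ex[1]) / res) + 1
  row <- floor((ex[4] - lat) / res) + 1
  d <- dim(stack$layers[[1]])
  bad <- col < 1 | col > d[2] | row < 1 | row > d[1]
  col[bad] <- NA; row[bad] <- NA
  cbind(row = row, col = col)
}

# env values at cells: matrix cells x layers
.env_at_cells <- function(stack, rc) {
  d <- dim(stack$layers[[1]])
  lin <- (rc[, "col"] - 1) * d[1] + rc[, "row"]
  vapply(stack$layers, function(l) l[lin], numeric(nrow(rc)))
}

#' NICHE_UNDEFINED condition
#'
#' Signalled when a taxon's occurrences fall into fewer than two distinct
#' raster cells, making niche modelling impossible (the point-endemic case).
#' @param taxon taxon label for the message.
#' @keywords internal
niche_undefined <- function(taxon = "") {
  stop(structure(class = c("niche_undefined", "error", "condition"),
                 list(message = paste0("NICHE_UNDEFINED: occurrences of '", taxon,
                                       "' occupy fewer than 2 raster cells"),
                      call = NULL)))
}

# ---- suitability models -----------------------------------------------------

#' Fit a suitability model for one taxon
#'
#' The built-in default is a multivariate Gaussian envelope: the Mahalanobis
#' distance of every cell's environment to the centroid of the occupied
#' cells' environments, mapped to `[0, 1]` through the chi-squared survival
#' function. Alternatives: a presence-background logistic regression
#' (quadratic terms; background drawn uniformly within `bg_range_km` of the
#' occurrences) and `"grid"`, an adapter accepting an externally produced
#' suitability grid (e.g. MaxEnt output read via [read_esri_ascii()]).
#'
#' @param occ an `occurrence_set` for a single taxon.
#' @param stack an [env_stack()] of (PC) layers.
#' @param model `"envelope"` (default), `"logistic"` or `"grid"`.
#' @param background_n number of background points (logistic model; default
#'   1000).
#' @param bg_range_km radius around occurrences from which background points
#'   are drawn (default 20).
#' @param grid external suitability matrix for `model = "grid"`.
#' @param seed RNG seed for background sampling.
#' @return object of class `suitability_map`: `suitability` (matrix in
#'   `[0, 1]`), `stack` geometry, `model` metadata.
#' @export
fit_suitability <- function(occ, stack, model = c("envelope", "logistic", "grid"),
                            background_n = 1000, bg_range_km = 20, grid = NULL,
                            seed = 1) {
  model <- match.arg(model)
  taxon <- if (nrow(occ)) occ$taxon[1] else ""
  rc <- cell_of(stack, occ$lon, occ$lat)
  if (anyNA(rc)) stop("occurrences outside the raster extent")
  urc <- unique(rc)
  if (nrow(urc) < 2) niche_undefined(taxon)
  d <- dim(stack$layers[[1]])
  valid <- !is.na(stack$layers[[1]])
  E_all <- vapply(stack$layers, function(l) l[valid], numeric(sum(valid)))
  suit_vec <- rep(NA_real_, sum(valid))
  if (model == "grid") {
    if (is.null(grid)) stop("model = 'grid' needs a suitability grid")
    suit <- grid
    suit[!valid] <- NA
  } else if (model == "envelope") {
    E_occ <- .env_at_cells(stack, urc)
    if (anyNA(E_occ)) stop("occurrence cell has nodata environment")
    mu <- colMeans(E_occ)
    S <- stats::cov(E_occ)
    S <- S + diag(ncol(S)) * (1e-6 * mean(diag(S)) + 1e-12)
    md2 <- stats::mahalanobis(E_all, mu, S)
    suit_vec <- stats::pchisq(md2, df = ncol(E_all), lower.tail = FALSE)
    suit <- stack$layers[[1]]
    suit[] <- NA
    suit[valid] <- suit_vec
  } else {
    set.seed(seed)
    bg <- .background_cells(stack, rc, n = background_n, range_km = bg_range_km)
    pres_E <- .env_at_cells(stack, rc)
    bg_E <- .env_at_cells(stack, bg)
    df <- as.data.frame(rbind(pres_E, bg_E))
    names(df) <- paste0("V", seq_len(ncol(df)))
    df$y <- rep(c(1, 0), c(nrow(pres_E), nrow(bg_E)))
    form <- stats::as.formula(paste("y ~",
      paste(c(names(df)[-ncol(df)],
              paste0("I(", names(df)[-ncol(df)], "^2)")), collapse = " + ")))
    fit <- suppressWarnings(stats::glm(form, family = stats::binomial(), data = df))
    newd <- as.data.frame(E_all)
    names(newd) <- paste0("V", seq_len(ncol(newd)))
    p <- stats::predict(fit, newdata = newd, type = "response")
    suit_vec <- p / max(p)
    suit <- stack$layers[[1]]
    suit[] <- NA
    suit[valid] <- suit_vec
  }
  structure(list(suitability = suit, extent = stack$extent, res = stack$res,
                 model = list(type = model, taxon = taxon,
                              n_occurrences = nrow(occ),
                              n_cells = nrow(urc))),
            class = "suitability_map")
}

# cells within range_km of any occurrence cell (latitude-corrected great
# circle approximation on the cell-centre grid)
.background_cells <- function(stack, rc, n, range_km) {
  d <- dim(stack$layers[[1]])
  rows <- rep(seq_len(d[1]), times = d[2])
  cols <- rep(seq_len(d[2]), each = d[1])
  lat <- stack$extent[4] - (rows - 0.5) * stack$res
  lon <- stack$extent[1] + (cols - 0.5) * stack$res
  occ_lat <- stack$extent[4] - (rc[, "row"] - 0.5) * stack$res
  occ_lon <- stack$extent[1] + (rc[, "col"] - 0.5) * stack$res
  km_deg <- 111.195
  keep <- rep(FALSE, length(rows))
  for (o in seq_len(nrow(rc))) {
    dy <- (lat - occ_lat[o]) * km_deg
    dx <- (lon - occ_lon[o]) * km_deg * cos(occ_lat[o] * pi / 180)
    keep <- keep | (dx^2 + dy^2 <= range_km^2)
  }
  valid <- !is.na(stack$layers[[1]])
  keep <- keep & valid[cbind(rows, cols)]
  idx <- which(keep)
  pick <- idx[sample.int(length(idx), min(n, length(idx)))]
  cbind(row = rows[pick], col = cols[pick])
}

# ---- fast internal envelope path -------------------------------------------
# Precomputed environment for repeated envelope fits (permutation tests):
# valid-cell matrix, dimensions, and per-point cell indices resolved once.
.prep_env <- function(stack) {
  valid <- !is.na(stack$layers[[1]])
  E <- vapply(stack$layers, function(l) l[valid], numeric(sum(valid)))
  lin_valid <- which(valid)
  lin_to_row <- integer(length(valid))
  lin_to_row[lin_valid] <- seq_along(lin_valid)
  list(valid = valid, E = E, lin_valid = lin_valid, lin_to_row = lin_to_row,
       dim = dim(stack$layers[[1]]), extent = stack$extent, res = stack$res)
}

# linear cell index per occurrence point
.occ_lin <- function(prep, lon, lat) {
  col <- floor((lon - prep$extent[1]) / prep$res) + 1
  row <- floor((prep$extent[4] - lat) / prep$res) + 1
  if (any(col < 1 | col > prep$dim[2] | row < 1 | row > prep$dim[1]))
    stop("occurrences outside the raster extent")
  (col - 1) * prep$dim[1] + row
}

# Gaussian-envelope suitability over the valid cells, from unique occupied
# cells; NULL when fewer than two distinct cells (the NICHE_UNDEFINED case)
.envelope_suit <- function(prep, occ_lin) {
  u <- unique(occ_lin)
  if (length(u) < 2) return(NULL)
  Eo <- prep$E[prep$lin_to_row[u], , drop = FALSE]
  mu <- colMeans(Eo)
  S <- stats::cov(Eo)
  S <- S + diag(ncol(S)) * (1e-6 * mean(diag(S)) + 1e-12)
  md2 <- stats::mahalanobis(prep$E, mu, S)
  stats::pchisq(md2, df = ncol(prep$E), lower.tail = FALSE)
}

.overlap_DI <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  c(D = 1 - 0.5 * sum(abs(p - q)), I = 1 - 0.5 * sum((sqrt(p) - sqrt(q))^2))
}

# ---- overlap statistics -----------------------------------------------------

#' Niche overlap: Schoener's D and Warren's I
#'
#' Both maps are normalized to probability surfaces over the shared
#' non-nodata cells; `D = 1 - 0.5 * sum|p - q|` and
#' `I = 1 - 0.5 * sum (sqrt(p) - sqrt(q))^2`. Both lie in `[0, 1]` with
#' `D <= I`, and both are invariant to rescaling either map by a positive
#' constant.
#'
#' @param map1,map2 `suitability_map` objects (or bare matrices) on the same
#'   grid.
#' @return list with `D` and `I`.
#' @export
niche_overlap <- function(map1, map2) {
  m1 <- if (inherits(map1, "suitability_map")) map1$suitability else map1
  m2 <- if (inherits(map2, "suitability_map")) map2$suitability else map2
  if (!identical(dim(m1), dim(m2))) stop("maps are not aligned")
  ok <- !is.na(m1) & !is.na(m2)
  p <- m1[ok]; q <- m2[ok]
  if (sum(p) <= 0 || sum(q) <= 0) stop("all-zero suitability map")
  p <- p / sum(p); q <- q / sum(q)
  D <- 1 - 0.5 * sum(abs(p - q))
  I <- 1 - 0.5 * sum((sqrt(p) - sqrt(q))^2)
  list(D = D, I = I)
}

#' Niche equivalency permutation test
#'
#' Tests whether the two taxa's suitability models could have been drawn from
#' their pooled occurrences: per replicate the pooled occurrences are
#' re-split at random (preserving the two sample sizes), both models are
#' refitted and `D*`, `I*` recomputed. One-tailed:
#' `p = (1 + #{stat* <= stat_obs}) / (n_reps + 1)` - equivalency is rejected
#' when the observed overlap is lower than expected under the pooled null.
#' A single-cell taxon propagates as `NA` ("n/a") with status
#' `"niche_undefined"`.
#'
#' @param occA,occB `occurrence_set`s of the two taxa.
#' @param stack an [env_stack()] of (PC) layers.
#' @param n_reps permutation replicates (default 200).
#' @param seed RNG seed.
#' @param model suitability model type passed to [fit_suitability()].
#' @return list with `D_obs`, `I_obs`, `p_D`, `p_I`, `status`.
#' @export
niche_equivalency_test <- function(occA, occB, stack, n_reps = 200, seed = 1,
                                   model = "envelope") {
  res_na <- list(D_obs = NA_real_, I_obs = NA_real_, p_D = NA_real_,
                 p_I = NA_real_, status = "niche_undefined")
  set.seed(seed)
  if (model == "envelope") {
    # fast path: the envelope depends only on the occupied cells' environment
    prep <- .prep_env(stack)
    linA <- .occ_lin(prep, occA$lon, occA$lat)
    linB <- .occ_lin(prep, occB$lon, occB$lat)
    sA <- .envelope_suit(prep, linA)
    sB <- .envelope_suit(prep, linB)
    if (is.null(sA) || is.null(sB)) return(res_na)
    obs <- as.list(.overlap_DI(sA, sB))
    pool <- c(linA, linB)
    nA <- length(linA)
    fit_pair <- function(idx) {
      rA <- .envelope_suit(prep, pool[idx])
      rB <- .envelope_suit(prep, pool[-idx])
      if (is.null(rA) || is.null(rB)) return(NULL)
      as.list(.overlap_DI(rA, rB))
    }
  } else {
    obs <- tryCatch({
      mA <- fit_suitability(occA, stack, model = model)
      mB <- fit_suitability(occB, stack, model = model)
      niche_overlap(mA, mB)
    }, niche_undefined = function(e) NULL)
    if (is.null(obs)) return(res_na)
    pool_df <- rbind(as.data.frame(occA), as.data.frame(occB))
    nA <- nrow(occA)
    fit_pair <- function(idx) {
      tryCatch({
        oA <- occurrence_set(pool_df[idx, , drop = FALSE], dedup = FALSE)
        oB <- occurrence_set(pool_df[-idx, , drop = FALSE], dedup = FALSE)
        niche_overlap(fit_suitability(oA, stack, model = model),
                      fit_suitability(oB, stack, model = model))
      }, niche_undefined = function(e) NULL)
    }
    pool <- seq_len(nrow(pool_df))
  }
  leD <- 0L; leI <- 0L; used <- 0L
  for (b in seq_len(n_reps)) {
    ov <- fit_pair(sample.int(length(pool), nA))
    if (is.null(ov)) next
    used <- used + 1L
    if (ov$D <= obs$D) leD <- leD + 1L
    if (ov$I <= obs$I) leI <- leI + 1L
  }
  list(D_obs = obs$D, I_obs = obs$I,
       p_D = (1 + leD) / (used + 1), p_I = (1 + leI) / (used + 1),
       status = "ok")
}

#' Pairwise niche-equivalency test table
#'
#' Runs [niche_equivalency_test()] for every taxon pair and
#' Bonferroni-corrects over the testable pairs; single-cell taxa yield `NA`
#' rows/columns ("n/a").
#'
#' @param occ an `occurrence_set` covering several taxa.
#' @param stack an [env_stack()].
#' @param n_reps,seed,model passed through.
#' @return list with symmetric matrices `p_D`, `p_I` (corrected), `D`, `I`.
#' @export
pairwise_niche_tests <- function(occ, stack, n_reps = 200, seed = 1,
                                 model = "envelope") {
  taxa <- sort(unique(occ$taxon))
  k <- length(taxa)
  mk <- function() matrix(NA_real_, k, k, dimnames = list(taxa, taxa))
  pD <- mk(); pI <- mk(); Dm <- mk(); Im <- mk()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      oA <- occ[occ$taxon == taxa[i], ]
      oB <- occ[occ$taxon == taxa[j], ]
      r <- niche_equivalency_test(oA, oB, stack, n_reps = n_reps,
                                  seed = seed + i * k + j, model = model)
      pD[i, j] <- pD[j, i] <- r$p_D
      pI[i, j] <- pI[j, i] <- r$p_I
      Dm[i, j] <- Dm[j, i] <- r$D_obs
      Im[i, j] <- Im[j, i] <- r$I_obs
    }
  }
  m <- sum(!is.na(pD[upper.tri(pD)]))
  pD <- .adjust_sym(pD, max(m, 1))
  pI <- .adjust_sym(pI, max(m, 1))
  list(taxa = taxa, p_D = pD, p_I = pI, D = Dm, I = Im, m = m)
}
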