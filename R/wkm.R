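# ---- configuration and constraints -----------------------------------------

#' Configuration for the weighted k-means ensemble
#'
#' Defaults follow the published analysis set-up: 5000 k-means runs, random
#' feature fraction 0.60, random sample fraction 0.80, and the number of
#' clusters drawn uniformly from 2 to 14 (inclusive) per run.
#'
#' @param n_runs number of base k-means runs.
#' @param feature_fraction fraction of features drawn per run, in (0, 1].
#' @param sample_fraction fraction of samples drawn per run, in (0, 1].
#' @param k_min,k_max bounds of the per-run cluster number.
#' @param seed RNG seed for the whole ensemble.
#' @return list of class `wkm_config`.
#' @export
wkm_config <- function(n_runs = 5000, feature_fraction = 0.60,
                       sample_fraction = 0.80, k_min = 2, k_max = 14,
                       seed = 1) {
  stopifnot(feature_fraction > 0, feature_fraction <= 1,
            sample_fraction > 0, sample_fraction <= 1,
            k_min >= 2, k_max >= k_min, n_runs >= 1)
  structure(list(n_runs = as.integer(n_runs),
                 feature_fraction = feature_fraction,
                 sample_fraction = sample_fraction,
                 k_min = as.integer(k_min), k_max = as.integer(k_max),
                 seed = as.integer(seed)),
            class = "wkm_config")
}

#' Fuzzy pairwise clustering constraints
#'
#' Must-link and must-not-link constraints with weights in (0, 1]. A pair may
#' not appear in both sets.
#'
#' @param must_link,must_not_link data frames with columns `i`, `j` (sample
#'   names or indices) and `weight`, or `NULL`.
#' @return list of class `constraint_set`.
#' @export
constraint_set <- function(must_link = NULL, must_not_link = NULL) {
  norm <- function(df) {
    if (is.null(df) || nrow(df) == 0)
      return(data.frame(i = character(0), j = character(0), weight = numeric(0)))
    df <- as.data.frame(df)
    names(df)[1:2] <- c("i", "j")
    if (is.null(df$weight)) df$weight <- 1
    if (any(df$weight <= 0 | df$weight > 1)) stop("constraint weights must lie in (0, 1]")
    df$i <- as.character(df$i); df$j <- as.character(df$j)
    df
  }
  ml <- norm(must_link); mnl <- norm(must_not_link)
  key <- function(df) paste(pmin(df$i, df$j), pmax(df$i, df$j))
  if (length(intersect(key(ml), key(mnl))))
    stop("a pair appears in both must_link and must_not_link")
  structure(list(must_link = ml, must_not_link = mnl), class = "constraint_set")
}

#' Must-link constraints within taxa (and optional must-not-links)
#'
#' Convenience builder mirroring the usual a-priori set-up: all within-taxon
#' sample pairs of the named taxa are must-links; `not_link_taxa` adds
#' must-not-links between all cross-taxon pairs of the given taxon pair list.
#'
#' @param taxon named character vector (sample -> taxon).
#' @param link_taxa taxa whose samples are pairwise must-linked.
#' @param not_link_taxa list of 2-element taxon vectors to must-not-link.
#' @param weight constraint weight (default 1).
#' @return a [constraint_set()].
#' @export
taxon_constraints <- function(taxon, link_taxa = unique(taxon),
                              not_link_taxa = NULL, weight = 1) {
  ml <- do.call(rbind, lapply(link_taxa, function(tx) {
    s <- names(taxon)[taxon == tx]
    if (length(s) < 2) return(NULL)
    cb <- utils::combn(s, 2)
    data.frame(i = cb[1, ], j = cb[2, ], weight = weight)
  }))
  mnl <- do.call(rbind, lapply(not_link_taxa, function(pair) {
    s1 <- names(taxon)[taxon == pair[1]]
    s2 <- names(taxon)[taxon == pair[2]]
    expand.grid(i = s1, j = s2, stringsAsFactors = FALSE) |>
      transform(weight = weight)
  }))
  constraint_set(ml, mnl)
}

#' Constraint consistency of one clustering
#'
#' Clustering-level consistency
#' `Q = 1 - sum(weights of violated constraints) / sum(weights of applicable
#' constraints)` and per-cluster consistencies `q_c` computed over the
#' constraints touching cluster `c`. Constraints whose samples are not both
#' present in `labels` are not applicable. `Q = 1` with no applicable
#' constraints.
#'
#' @param labels named cluster assignment (names = sample ids).
#' @param constraints a [constraint_set()].
#' @return list with `Q` and named vector `q` (one entry per cluster).
#' @export
constraint_consistency <- function(labels, constraints) {
  cl <- sort(unique(labels))
  q <- stats::setNames(rep(1, length(cl)), cl)
  app_w <- 0; vio_w <- 0
  q_app <- stats::setNames(rep(0, length(cl)), as.character(cl))
  q_vio <- q_app
  check <- function(df, must) {
    for (r in seq_len(nrow(df))) {
      li <- labels[df$i[r]]; lj <- labels[df$j[r]]
      if (is.na(li) || is.na(lj)) next
      w <- df$weight[r]
      violated <- if (must) li != lj else li == lj
      app_w <<- app_w + w
      touched <- unique(as.character(c(li, lj)))
      q_app[touched] <<- q_app[touched] + w
      if (violated) {
        vio_w <<- vio_w + w
        q_vio[touched] <<- q_vio[touched] + w
      }
    }
  }
  check(constraints$must_link, TRUE)
  check(constraints$must_not_link, FALSE)
  Q <- if (app_w > 0) 1 - vio_w / app_w else 1
  has <- q_app > 0
  q[has] <- 1 - q_vio[has] / q_app[has]
  list(Q = Q, q = q)
}

# ---- k-means machinery ------------------------------------------------------

# k-means++ seeding (Arthur & Vassilvitskii) on the rows of X
.kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- numeric(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((X - matrix(X[centers[1], ], n, ncol(X), byrow = TRUE))^2)
  for (c in seq_len(k - 1)) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[c + 1] <- sample.int(n, 1, prob = prob)
    d2 <- pmin(d2, rowSums((X - matrix(X[centers[c + 1], ], n, ncol(X),
                                       byrow = TRUE))^2))
  }
  X[centers, , drop = FALSE]
}

.run_kmeans <- function(X, k) {
  cen <- .kmeanspp_centers(X, k)
  cen <- cen + matrix(stats::rnorm(length(cen), sd = 1e-9), nrow(cen))  # avoid duplicate centers
  km <- suppressWarnings(stats::kmeans(X, centers = cen, iter.max = 300))
  km$cluster
}

# mean silhouette width; 0 for singleton clusters, and 0 overall if only one
# cluster survives
.mean_silhouette <- function(X, labels) {
  if (length(unique(labels)) < 2) return(0)
  sil <- cluster::silhouette(labels, stats::dist(X))
  mean(sil[, "sil_width"])
}

# ---- ensemble ---------------------------------------------------------------

#' Run the weighted ensemble of random-(k) k-means
#'
#' Each run draws a random feature subset (`ceiling(frac_f * d)`), a random
#' sample subset (`ceiling(frac_s * n)`) and a random `k`, fits k-means
#' (k-means++ seeding, up to 300 iterations), and is weighted by
#' `w = ((s + 1) / 2) * Q * geometric-mean(q_c)` where `s` is the mean
#' silhouette and `Q`, `q_c` the clustering-/cluster-level constraint
#' consistencies. Weighted co-assignments are accumulated into the consensus
#' co-association matrix `C_ij = M_ij / N_ij` over co-sampled pairs.
#'
#' @param X samples x features matrix (e.g. PCo scores); row names are sample
#'   ids.
#' @param constraints a [constraint_set()] or `NULL`.
#' @param cfg a [wkm_config()].
#' @return object of class `consensus_model` with `C`, `co_sample_counts`,
#'   `weights` (per run), `cfg`.
#' @export
run_wkm_ensemble <- function(X, constraints = NULL, cfg = wkm_config()) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (d < 2) stop("need at least 2 features")
  if (is.null(rownames(X))) rownames(X) <- paste0("S", seq_len(n))
  ids <- rownames(X)
  if (is.null(constraints)) constraints <- constraint_set()
  m_sub <- ceiling(cfg$sample_fraction * n)
  d_sub <- ceiling(cfg$feature_fraction * d)
  if (n < cfg$k_max) warning("fewer samples than k_max; large k values will be capped")
  k_hi <- max(cfg$k_min, min(cfg$k_max, m_sub - 1))  # keep silhouette defined
  M <- matrix(0, n, n); N <- matrix(0, n, n)
  w_all <- numeric(cfg$n_runs)
  set.seed(cfg$seed)
  for (r in seq_len(cfg$n_runs)) {
    rows <- sample.int(n, m_sub)
    cols <- sample.int(d, d_sub)
    k <- if (k_hi > cfg$k_min) sample(cfg$k_min:k_hi, 1) else cfg$k_min
    Xs <- X[rows, cols, drop = FALSE]
    lab <- .run_kmeans(Xs, k)
    names(lab) <- ids[rows]
    s <- .mean_silhouette(Xs, lab)
    cc <- constraint_consistency(lab, constraints)
    gq <- exp(mean(log(pmax(cc$q, 1e-300))))
    w <- ((s + 1) / 2) * cc$Q * gq
    w_all[r] <- w
    same <- outer(lab, lab, "==")
    M[rows, rows] <- M[rows, rows] + w * same
    N[rows, rows] <- N[rows, rows] + w
  }
  off <- upper.tri(N)
  if (any(N[off] == 0))
    stop("some sample pairs were never co-sampled; increase n_runs")
  C <- M / N
  diag(C) <- 1
  dimnames(C) <- list(ids, ids)
  structure(list(C = C, co_sample_counts = N, weights = w_all, cfg = cfg,
                 per_k = NULL, k_best_bic = NULL, k_best_ch = NULL),
            class = "consensus_model")
}

#' Consensus partition and cluster-number selection
#'
#' Cuts an average-linkage hierarchical clustering of the consensus
#' dissimilarity `1 - C` at each `k` in `[k_min, k_max]` and scores every
#' partition on a feature matrix:
#' `CH = (SS_b / (k - 1)) / (SS_w / (n - k))` (higher is better) and the
#' Bayesian information criterion of the hard-assignment spherical Gaussian
#' mixture (x-means formulation; lower is better):
#' `BIC = -2 * LL + p * ln(n)` with pooled variance
#' `sigma^2 = SS_w / (d (n - k))`,
#' `LL = sum_c n_c ln(n_c / n) - (n d / 2) ln(2 pi sigma^2) - d (n - k) / 2`
#' and `p = (k - 1) + d k + 1` free parameters. Ties resolve toward smaller
#' `k`. The clustering may run in a reduced space while the scoring uses the
#' full embedding (`X_score`), which penalizes spurious splits that exploit
#' only the reduced axes.
#'
#' @param model a `consensus_model` from [run_wkm_ensemble()].
#' @param X the feature matrix the ensemble was run on.
#' @param X_score feature matrix used for the BIC/CH scoring (default `X`;
#'   e.g. the full PCo score matrix).
#' @param k_min,k_max range of candidate cluster numbers (defaults from the
#'   model's config). Values `> n - 1` are skipped with a warning.
#' @return the model, with `per_k` (list per k: `labels`, `BIC`, `CH`),
#'   `k_best_bic` and `k_best_ch` filled in.
#' @export
consensus_partition <- function(model, X, X_score = X,
                                k_min = model$cfg$k_min,
                                k_max = model$cfg$k_max) {
  X_score <- as.matrix(X_score)
  n <- nrow(X_score); d <- ncol(X_score)
  hc <- stats::hclust(stats::as.dist(1 - model$C), method = "average")
  ks <- k_min:k_max
  if (any(ks > n - 1)) {
    warning("skipping k > n - 1")
    ks <- ks[ks <= n - 1]
  }
  per_k <- list()
  for (k in ks) {
    lab <- stats::cutree(hc, k = k)
    ss <- .cluster_ss(X_score, lab)
    CH <- (ss$between / (k - 1)) / (ss$within / (n - k))
    nc <- table(lab)
    s2 <- ss$within / (d * (n - k))
    ll <- sum(nc * log(nc / n)) - n * d / 2 * log(2 * pi * s2) - d * (n - k) / 2
    BIC <- -2 * ll + ((k - 1) + d * k + 1) * log(n)
    per_k[[as.character(k)]] <- list(labels = lab, BIC = BIC, CH = CH)
  }
  bics <- vapply(per_k, function(e) e$BIC, 1)
  chs <- vapply(per_k, function(e) e$CH, 1)
  model$per_k <- per_k
  model$k_best_bic <- ks[which.min(bics)]   # which.min takes the first (smallest k) on ties
  model$k_best_ch <- ks[which.max(chs)]
  model$score_table <- data.frame(k = ks, BIC = unname(bics), CH = unname(chs))
  model
}

.cluster_ss <- function(X, lab) {
  grand <- colMeans(X)
  within <- 0; between <- 0
  for (g in unique(lab)) {
    idx <- which(lab == g)
    cen <- colMeans(X[idx, , drop = FALSE])
    within <- within + sum(sweep(X[idx, , drop = FALSE], 2, cen)^2)
    between <- between + length(idx) * sum((cen - grand)^2)
  }
  list(within = within, between = between)
}

#' @export
print.consensus_model <- function(x, ...) {
  cat(sprintf("consensus_model: %d samples, %d runs (mean weight %.3f)\n",
              nrow(x$C), length(x$weights), mean(x$weights)))
  if (!is.null(x$k_best_bic))
    cat(sprintf("  k_best (BIC) = %d, k_best (CH) = %d\n",
                x$k_best_bic, x$k_best_ch))
  invisible(x)
}

#' Taxon-level cluster assignment at the BIC-optimal k
#'
#' Maps each taxon to the consensus cluster holding the majority of its
#' samples at `k_best_bic`.
#'
#' @param model a scored `consensus_model`.
#' @param taxon named character vector (sample -> taxon).
#' @return named integer vector, taxon -> cluster.
#' @export
taxon_clusters <- function(model, taxon) {
  if (is.null(model$k_best_bic)) stop("run consensus_partition() first")
  lab <- model$per_k[[as.character(model$k_best_bic)]]$labels
  taxa <- unique(taxon[names(lab)])
  out <- stats::setNames(integer(length(taxa)), taxa)
  for (tx in taxa) {
    tl <- lab[names(lab) %in% names(taxon)[taxon == tx]]
    out[tx] <- as.integer(names(sort(table(tl), decreasing = TRUE))[1])
  }
  out
}
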