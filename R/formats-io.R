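#' Read genotypes from a VCF file
#'
#' Parses the GT field of a VCF 4.x file into allele-dosage vectors. Diploid
#' calls (`0/1`) and tetraploid calls (`0/0/0/1`) may be mixed in one file;
#' `./.` and `./././.` become missing. Multiallelic sites are retained with a
#' dosage slot per allele. With `dosage_coded = TRUE` tetraploid genotypes may
#' alternatively be encoded as diploid-style GT plus an `AD`-like dosage in
#' the GT itself is not expected; instead length-2 GT strings for tetraploids
#' are accepted and doubled (the convention used by some assemblers that emit
#' diploid-coded calls for polyploids).
#'
#' @param path path to an (uncompressed or gzipped) VCF file.
#' @param taxon_map named character vector, sample -> taxon.
#' @param ploidy_map named integer vector, sample -> ploidy (2 or 4).
#' @param dosage_coded accept diploid-coded GT for tetraploid samples by
#'   doubling the dosage vector (default `FALSE`: GT arity must equal ploidy).
#' @return a [genotype_matrix()].
#' @export
read_vcf_genotypes <- function(path, taxon_map, ploidy_map, dosage_coded = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  unknown <- setdiff(samples, names(ploidy_map))
  if (length(unknown)) stop("samples absent from ploidy_map: ",
                            paste(unknown, collapse = ", "))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  sites <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"],
                      alt = ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]),
                      stringsAsFactors = FALSE)
  n_alleles <- 1L + ifelse(nzchar(sites$alt),
                           vapply(strsplit(sites$alt, ","), length, 1L), 0L)
  A <- max(n_alleles)
  n <- length(samples)
  L <- nrow(sites)
  dosage <- array(NA_real_, c(n, L, A))
  for (s in seq_len(n)) {
    pl <- as.integer(ploidy_map[samples[s]])
    calls <- gt[, s]
    toks <- strsplit(calls, "[/|]")
    for (l in seq_len(L)) {
      tk <- toks[[l]]
      if (length(tk) == 0 || all(is.na(tk)) || any(tk == ".")) next
      al <- suppressWarnings(as.integer(tk))
      if (anyNA(al)) next
      if (length(al) != pl) {
        if (dosage_coded && pl == 4L && length(al) == 2L) {
          al <- rep(al, 2L)
        } else {
          stop(sprintf("GT arity %d disagrees with ploidy %d for sample '%s' at %s:%d",
                       length(al), pl, samples[s], sites$chrom[l], sites$pos[l]))
        }
      }
      if (any(al >= n_alleles[l]))
        stop(sprintf("allele index out of range for sample '%s' at %s:%d",
                     samples[s], sites$chrom[l], sites$pos[l]))
      d <- tabulate(al + 1L, nbins = A)
      dosage[s, l, ] <- d
    }
  }
  genotype_matrix(dosage, samples, taxon_map, ploidy_map, sites)
}

#' Write a genotype matrix to a VCF file
#'
#' Emits a minimal VCF 4.2 body (GT only) that [read_vcf_genotypes()] reads
#' back to exactly the same dosages.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$sample_ids), collapse = "\t")), con)
  n <- length(g$sample_ids)
  for (l in seq_len(nrow(g$sites))) {
    gts <- character(n)
    for (s in seq_len(n)) {
      d <- g$dosage[s, l, ]
      if (anyNA(d)) {
        gts[s] <- paste(rep(".", g$ploidy[s]), collapse = "/")
      } else {
        gts[s] <- paste(rep(seq_along(d) - 1L, d), collapse = "/")
      }
    }
    writeLines(paste(c(g$sites$chrom[l], g$sites$pos[l], ".", g$sites$ref[l],
                       if (nzchar(g$sites$alt[l])) g$sites$alt[l] else ".",
                       ".", "PASS", ".", "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read an occurrence table
#'
#' CSV with columns `taxon`, `lon`, `lat` (decimal degrees). Exact duplicate
#' rows are dropped with a message.
#'
#' @param path CSV path.
#' @return an `occurrence_set`: a data frame with attributes.
#' @export
read_occurrence_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon", "lon", "lat")
  if (!all(need %in% names(df))) stop("occurrence CSV must have columns taxon, lon, lat")
  if (nrow(df) == 0) {
    warning("empty occurrence table")
    return(occurrence_set(df[, need]))
  }
  bad <- which(df$lon < -180 | df$lon > 180 | df$lat < -90 | df$lat > 90 | is.na(df$lon) | is.na(df$lat))
  if (length(bad)) stop("coordinate out of range at row ", bad[1])
  occurrence_set(df[, need])
}

#' Construct an occurrence set
#'
#' @param df data frame with columns `taxon`, `lon`, `lat`.
#' @param dedup drop exact duplicate (taxon, lon, lat) rows (default `TRUE`).
#' @return data frame of class `occurrence_set`.
#' @export
occurrence_set <- function(df, dedup = TRUE) {
  df <- df[, c("taxon", "lon", "lat")]
  if (dedup && nrow(df)) {
    dup <- duplicated(df)
    if (any(dup)) message("dropped ", sum(dup), " duplicate occurrence record(s)")
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("occurrence_set", "data.frame")
  df
}

#' Environmental raster stack
#'
#' Named list of aligned grids sharing extent, resolution and nodata mask.
#' Row 1 is the northernmost row; cell membership is half-open
#' `[edge, edge + res)` from the west/north edges.
#'
#' @param layers named list of numeric matrices (`NA` = nodata).
#' @param extent `c(xmin, xmax, ymin, ymax)` in degrees.
#' @param res cell size in degrees.
#' @return object of class `env_stack`.
#' @export
env_stack <- function(layers, extent, res) {
  stopifnot(length(layers) >= 1, !is.null(names(layers)))
  d <- dim(layers[[1]])
  for (l in layers) if (!identical(dim(l), d)) stop("all layers must share one grid")
  if (abs(extent[2] - extent[1] - d[2] * res) > 1e-6 ||
      abs(extent[4] - extent[3] - d[1] * res) > 1e-6)
    stop("extent does not match grid dimensions and resolution")
  # union-of-nodata mask
  na <- Reduce(`|`, lapply(layers, is.na))
  layers <- lapply(layers, function(l) { l[na] <- NA; l })
  structure(list(layers = layers, extent = extent, res = res),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  d <- dim(x$layers[[1]])
  cat(sprintf("env_stack: %d layer(s), %d x %d cells, res %g deg, extent [%g, %g] x [%g, %g]\n",
              length(x$layers), d[1], d[2], x$res,
              x$extent[1], x$extent[2], x$extent[3], x$extent[4]))
  invisible(x)
}

#' Read an ESRI ASCII grid
#' @param path file path.
#' @return list with `z` (matrix, row 1 = north), `extent`, `res`.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  z <- matrix(scan(text = paste(lines[i:length(lines)], collapse = "\n"),
                   quiet = TRUE),
              nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) z[z == hdr$nodata_value] <- NA
  res <- hdr$cellsize
  xmin <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - res / 2
  ymin <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - res / 2
  list(z = z, extent = c(xmin, xmin + hdr$ncols * res, ymin, ymin + hdr$nrows * res),
       res = res)
}

#' Write an ESRI ASCII grid
#' @param z matrix (row 1 = northernmost row).
#' @param extent `c(xmin, xmax, ymin, ymax)`.
#' @param res cell size.
#' @param path output path.
#' @param nodata nodata sentinel written for `NA` (default -9999).
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(z, extent, res, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(z)), paste("nrows", nrow(z)),
               paste("xllcorner", format(extent[1], digits = 12)),
               paste("yllcorner", format(extent[3], digits = 12)),
               paste("cellsize", format(res, digits = 12)),
               paste("NODATA_value", nodata)), con)
  zz <- z
  zz[is.na(zz)] <- nodata
  utils::write.table(zz, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read environmental rasters into an aligned stack
#'
#' Reads ESRI ASCII grids, crops all layers to their shared extent and applies
#' the union-of-nodata mask. All layers must share the cell size and have
#' grid-aligned origins; disjoint extents are an error. Reading an
#' already-aligned stack changes no cell value.
#'
#' @param paths character vector of file paths; names become layer names
#'   (default: file base names).
#' @return an [env_stack()].
#' @export
read_env_rasters <- function(paths) {
  nms <- names(paths)
  if (is.null(nms)) nms <- sub("\\.[^.]*$", "", basename(paths))
  grids <- lapply(paths, read_esri_ascii)
  res <- grids[[1]]$res
  for (gr in grids) if (abs(gr$res - res) > 1e-9) stop("layers differ in resolution")
  ex <- sapply(grids, function(g) g$extent)  # 4 x n
  inter <- c(max(ex[1, ]), min(ex[2, ]), max(ex[3, ]), min(ex[4, ]))
  if (inter[1] >= inter[2] || inter[3] >= inter[4]) stop("layer extents are disjoint")
  for (gr in grids) {
    off <- c((inter[1] - gr$extent[1]) / res, (gr$extent[4] - inter[4]) / res)
    if (any(abs(off - round(off)) > 1e-6)) stop("layer grids are not aligned")
  }
  ncol_i <- round((inter[2] - inter[1]) / res)
  nrow_i <- round((inter[4] - inter[3]) / res)
  layers <- lapply(grids, function(gr) {
    c0 <- round((inter[1] - gr$extent[1]) / res)
    r0 <- round((gr$extent[4] - inter[4]) / res)
    gr$z[(r0 + 1):(r0 + nrow_i), (c0 + 1):(c0 + ncol_i), drop = FALSE]
  })
  names(layers) <- nms
  env_stack(layers, inter, res)
}

#' Write a distance matrix as a NEXUS DISTANCES block
#'
#' Full symmetric matrix with a TAXA block; labels containing whitespace are
#' quoted. Files round-trip through [read_distance_nexus()].
#'
#' @param labels taxon labels.
#' @param D symmetric distance matrix with zero diagonal.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_nexus <- function(labels, D, path) {
  D <- as.matrix(D)
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix is asymmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix diagonal must be zero")
  qlab <- ifelse(grepl("\\s", labels), paste0("'", labels, "'"), labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines(c("BEGIN TAXA;", paste0("  DIMENSIONS NTAX=", length(labels), ";"),
               paste0("  TAXLABELS ", paste(qlab, collapse = " "), ";"),
               "END;"), con)
  writeLines(c("BEGIN DISTANCES;",
               "  FORMAT TRIANGLE=BOTH DIAGONAL LABELS;", "  MATRIX"), con)
  for (i in seq_along(labels)) {
    writeLines(paste("   ", qlab[i],
                     paste(format(D[i, ], digits = 12, trim = TRUE), collapse = " ")), con)
  }
  writeLines(c("  ;", "END;"), con)
  invisible(path)
}

#' Read a NEXUS DISTANCES block written by [write_distance_nexus()]
#' @param path file path.
#' @return list with `labels` and `D`.
#' @export
read_distance_nexus <- function(path) {
  lines <- readLines(path)
  m0 <- grep("^\\s*MATRIX\\s*$", lines)[1]
  end <- m0 + which(grepl("^\\s*;", lines[(m0 + 1):length(lines)]))[1]
  rows <- trimws(lines[(m0 + 1):(end - 1)])
  labs <- character(0)
  vals <- list()
  for (r in rows) {
    if (startsWith(r, "'")) {
      lab <- sub("^'([^']*)'.*$", "\\1", r)
      rest <- sub("^'[^']*'\\s*", "", r)
    } else {
      lab <- sub("^(\\S+).*$", "\\1", r)
      rest <- sub("^\\S+\\s*", "", r)
    }
    labs <- c(labs, lab)
    vals[[length(vals) + 1]] <- as.numeric(strsplit(rest, "\\s+")[[1]])
  }
  D <- do.call(rbind, vals)
  dimnames(D) <- list(labs, labs)
  list(labels = labs, D = D)
}

#' Write a PHYLIP square distance matrix
#' @inheritParams write_distance_nexus
#' @return `path`, invisibly.
#' @export
write_distance_phylip <- function(labels, D, path) {
  D <- as.matrix(D)
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix is asymmetric")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("    ", length(labels)), con)
  lab10 <- formatC(gsub("\\s", "_", labels), width = 10, flag = "-")
  for (i in seq_along(labels)) {
    writeLines(paste0(lab10[i], paste(format(D[i, ], digits = 10, trim = TRUE),
                                      collapse = "  ")), con)
  }
  invisible(path)
}

#' Leaf annotation: outline polygon plus mid-vein polyline
#'
#' @param outline numeric matrix `n x 2` of pixel coordinates (closed simple
#'   polygon, last vertex need not repeat the first).
#' @param midvein numeric matrix `m x 2` (open polyline, at least 2 vertices).
#' @param specimen_id label.
#' @param image_size `c(h, w)` in pixels, optional.
#' @return object of class `leaf_annotation`.
#' @export
leaf_annotation <- function(outline, midvein, specimen_id = "leaf",
                            image_size = NULL) {
  outline <- as.matrix(outline)
  midvein <- as.matrix(midvein)
  if (nrow(outline) < 3) stop("outline needs at least 3 vertices")
  if (nrow(midvein) < 2) stop("midvein needs at least 2 vertices")
  if (.polygon_self_intersects(outline)) stop("outline polygon is self-intersecting")
  bb <- apply(outline, 2, range)
  if (any(midvein[, 1] < bb[1, 1] - 1e-9) || any(midvein[, 1] > bb[2, 1] + 1e-9) ||
      any(midvein[, 2] < bb[1, 2] - 1e-9) || any(midvein[, 2] > bb[2, 2] + 1e-9))
    stop("midvein lies outside the outline's bounding box")
  structure(list(specimen_id = specimen_id, outline = outline,
                 midvein = midvein, image_size = image_size),
            class = "leaf_annotation")
}

# segment-intersection based simplicity check, vectorized over all edge
# pairs (strict crossings only: shared endpoints of adjacent edges are not
# intersections).
.polygon_self_intersects <- function(p) {
  n <- nrow(p)
  nxt <- c(2:n, 1)
  ax <- p[, 1]; ay <- p[, 2]
  bx <- p[nxt, 1]; by <- p[nxt, 2]
  # orientation of point (px, py) relative to every edge, as n x n matrices
  # d[i, j]: cross product of edge j with endpoint of edge i
  cross_to <- function(px, py) {
    sweep(outer(py, bx - ax), 2, (by - ay) * ax - (bx - ax) * ay, "+") -
      outer(px, by - ay)
  }
  d1 <- t(cross_to(ax, ay))  # d1[j, i]: start of edge i vs edge j -> transpose
  d2 <- t(cross_to(bx, by))
  str1 <- d1 * d2 < 0                 # edge i's endpoints straddle edge j
  cross <- str1 & t(str1)
  # ignore self and adjacent edge pairs
  diag(cross) <- FALSE
  adj <- cbind(seq_len(n), nxt)
  cross[adj] <- FALSE
  cross[adj[, 2:1]] <- FALSE
  any(cross)
}

#' Read a leaf annotation file (JSON dialect or CVAT XML)
#'
#' The JSON dialect is `{"outline": [[x,y], ...], "midvein": [[x,y], ...]}`.
#' CVAT XML is parsed from `<polygon>` (outline) and `<polyline>` (midvein)
#' elements with `points="x1,y1;x2,y2;..."` attributes; one annotation per
#' image element is returned.
#'
#' @param path file path (`.json` or `.xml`).
#' @return a `leaf_annotation`, or a list of them for multi-image CVAT files.
#' @export
read_leaf_annotation <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::fromJSON(path)
    return(leaf_annotation(j$outline, j$midvein,
                           specimen_id = if (!is.null(j$specimen_id)) j$specimen_id
                           else sub("\\.json$", "", basename(path))))
  }
  doc <- xml2::read_xml(path)
  imgs <- xml2::xml_find_all(doc, ".//image")
  parse_pts <- function(s) {
    do.call(rbind, lapply(strsplit(strsplit(s, ";")[[1]], ","), as.numeric))
  }
  out <- lapply(imgs, function(im) {
    pg <- xml2::xml_find_first(im, ".//polygon")
    pl <- xml2::xml_find_first(im, ".//polyline")
    h <- as.numeric(xml2::xml_attr(im, "height"))
    w <- as.numeric(xml2::xml_attr(im, "width"))
    leaf_annotation(parse_pts(xml2::xml_attr(pg, "points")),
                    parse_pts(xml2::xml_attr(pl, "points")),
                    specimen_id = xml2::xml_attr(im, "name"),
                    image_size = c(h, w))
  })
  if (length(out) == 1) out[[1]] else out
}
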