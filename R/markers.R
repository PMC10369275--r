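#' Rotation grid of x-coordinate vectors
#'
#' Rotates the reconstructed coordinates on a two-plane grid — `a` steps
#' in the XY plane (about the z axis) followed by `b` steps in the XZ
#' plane (about the y axis), each step `step_deg` degrees — and retains
#' the rotated x coordinate for every (a, b) pair.  With the defaults
#' (12 degrees, 30 steps per plane) this yields 900 orientation vectors.
#'
#' @param coords samples x 3 coordinate matrix.
#' @param step_deg rotation step in degrees (default 12).
#' @param n_steps number of steps per plane (default 30);
#'   `step_deg * n_steps` must equal 360.
#' @return samples x (n_steps^2) matrix of rotated x coordinates; column
#'   `(a - 1) * n_steps + b` holds XY step `a - 1` and XZ step `b - 1`.
#'   Attributes `xy_deg` and `xz_deg` give the angle pair per column.
#' @export
rotation_grid <- function(coords, step_deg = 12, n_steps = 30L) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("'coords' must be samples x 3")
  if (abs(step_deg * n_steps - 360) > 1e-8)
    stop("step_deg * n_steps must equal 360")
  if (max(apply(coords, 2L, function(v) diff(range(v)))) == 0)
    stop("degenerate coordinates: all samples identical")
  ang <- (seq_len(n_steps) - 1L) * step_deg * pi / 180
  out <- matrix(NA_real_, nrow(coords), n_steps^2)
  xy <- xz <- numeric(n_steps^2)
  x <- coords[, 1L]; y <- coords[, 2L]; z <- coords[, 3L]
  col <- 0L
  for (a in seq_len(n_steps)) {
    xa <- cos(ang[a]) * x - sin(ang[a]) * y   # rotate in XY plane
    for (b in seq_len(n_steps)) {
      col <- col + 1L
      out[, col] <- cos(ang[b]) * xa - sin(ang[b]) * z  # then XZ plane
      xy[col] <- ang[a] * 180 / pi
      xz[col] <- ang[b] * 180 / pi
    }
  }
  rownames(out) <- rownames(coords)
  attr(out, "xy_deg") <- xy
  attr(out, "xz_deg") <- xz
  attr(out, "n_steps") <- n_steps
  out
}

#' Expression order correlation profile of one gene
#'
#' Spearman correlation between a gene's expression and every rotated
#' x-coordinate vector of the orientation grid.  The EOC score of the
#' gene is the maximum absolute correlation over the grid (a gene
#' decreasing along some axis is just as spatial as one increasing);
#' signs are retained in the grid itself.  A constant gene scores 0.
#'
#' @param gene_expr per-sample expression vector.
#' @param orientations output of [rotation_grid()].
#' @return an `eoc_profile`: list with `rcc_grid` (n_steps x n_steps),
#'   `eoc`, `best_orientation` (XY, XZ degrees).
#' @export
eoc_profile <- function(gene_expr, orientations) {
  gene_expr <- as.numeric(gene_expr)
  if (anyNA(gene_expr)) stop("missing expression values")
  if (length(gene_expr) != nrow(orientations))
    stop("expression and coordinates cover different sample sets")
  ns <- attr(orientations, "n_steps")
  if (stats::sd(gene_expr) == 0) {
    rcc <- rep(0, ncol(orientations))
  } else {
    rcc <- suppressWarnings(
      as.numeric(stats::cor(gene_expr, orientations, method = "spearman")))
    rcc[is.na(rcc)] <- 0
  }
  best <- which.max(abs(rcc))
  structure(list(rcc_grid = matrix(rcc, ns, ns, byrow = TRUE),
                 eoc = abs(rcc[best]),
                 best_orientation = c(xy_deg = attr(orientations, "xy_deg")[best],
                                      xz_deg = attr(orientations, "xz_deg")[best])),
            class = "eoc_profile")
}

#' EOC scan over all genes of an expression matrix
#'
#' Vectorised [eoc_profile()] across genes: one Spearman correlation per
#' gene per orientation.
#'
#' @param expr genes x samples expression matrix.
#' @param coords samples x 3 reconstructed coordinates (same sample
#'   order as the columns of `expr`).
#' @param step_deg,n_steps see [rotation_grid()].
#' @return an `eoc_scan`: list with `table` (data.frame of `gene_id`,
#'   `eoc`, `xy_deg`, `xz_deg`) and `grid` (genes x orientations signed
#'   correlation matrix).
#' @export
eoc_scan <- function(expr, coords, step_deg = 12, n_steps = 30L) {
  expr <- as_expression_matrix(expr)
  orient <- rotation_grid(coords, step_deg = step_deg, n_steps = n_steps)
  if (ncol(expr) != nrow(orient))
    stop("expression and coordinates cover different sample sets")
  grid <- suppressWarnings(
    stats::cor(t(expr), orient, method = "spearman"))
  grid[is.na(grid)] <- 0       # constant genes / degenerate orientations
  best <- max.col(abs(grid), ties.method = "first")
  tab <- data.frame(gene_id = rownames(expr),
                    eoc = abs(grid[cbind(seq_len(nrow(grid)), best)]),
                    xy_deg = attr(orient, "xy_deg")[best],
                    xz_deg = attr(orient, "xz_deg")[best],
                    stringsAsFactors = FALSE)
  structure(list(table = tab, grid = grid,
                 step_deg = step_deg, n_steps = n_steps),
            class = "eoc_scan")
}

#' @export
print.eoc_scan <- function(x, ...) {
  cat("EOC scan of", nrow(x$table), "genes over",
      ncol(x$grid), "orientations\n")
  top <- utils::head(x$table[order(-x$table$eoc), ], 5L)
  print(top, row.names = FALSE)
  invisible(x)
}

#' Nominate orthogonal spatial marker genes from EOC profiles
#'
#' Clusters the genes' flattened orientation-correlation vectors by
#' k-means into 2 (2D templates) or 3 (3D templates) clusters — genes
#' tracking the same spatial orientation land together — and picks the
#' top-EOC gene of each cluster, largest cluster first.
#'
#' @param scan an `eoc_scan`.
#' @param template_dim 2 or 3; sets the number of clusters/markers.
#' Orientation clusters are only meaningful among spatially expressed
#' genes: flat (noise-level) profiles would collapse the clustering into
#' spatial-vs-nonspatial, so only the top `top_frac` of genes by EOC
#' enter the clustering.
#'
#' @param k_seed RNG seed for k-means initialisation (fixed for
#'   reproducibility; 10 restarts, best inertia kept).
#' @param top_frac fraction of genes (by EOC) entering the orientation
#'   clustering (default 0.05, the usual "top spatial genes" cut; never
#'   fewer than `2 * k` genes).
#' @param min_eoc genes with EOC at or below this are excluded outright
#'   (default 0).
#' @return a `marker_set`: list with `markers` (gene ids, largest cluster
#'   first), `eoc_values`, `cluster_sizes`.
#' @export
select_markers <- function(scan, template_dim = 2L, k_seed = 1L,
                           top_frac = 0.05, min_eoc = 0) {
  stopifnot(inherits(scan, "eoc_scan"), template_dim %in% 2:3)
  k <- if (template_dim == 2L) 2L else 3L
  keep <- scan$table$eoc > min_eoc
  if (sum(keep) < k)
    stop("fewer genes with nonzero EOC (", sum(keep),
         ") than requested clusters (", k, ")")
  n_top <- min(sum(keep), max(2L * k, ceiling(top_frac * nrow(scan$table))))
  top <- order(-scan$table$eoc * keep)[seq_len(n_top)]
  grid <- scan$grid[top, , drop = FALSE]
  tab <- scan$table[top, , drop = FALSE]
  ndistinct <- nrow(unique(grid))
  if (ndistinct < k) {
    warning("fewer distinct EOC profiles (", ndistinct,
            ") than clusters; falling back to a single cluster")
    best <- which.max(tab$eoc)
    return(structure(list(markers = tab$gene_id[best],
                          eoc_values = tab$eoc[best],
                          cluster_sizes = nrow(tab)),
                     class = "marker_set"))
  }
  km <- local_rng(k_seed, stats::kmeans(grid, centers = k, nstart = 10L))
  sizes <- as.integer(table(factor(km$cluster, levels = seq_len(k))))
  ord <- order(-sizes, seq_len(k))        # largest cluster first
  markers <- character(0); eocs <- numeric(0)
  for (cl in ord) {
    idx <- which(km$cluster == cl)
    best <- idx[which.max(tab$eoc[idx])]
    markers <- c(markers, tab$gene_id[best])
    eocs <- c(eocs, tab$eoc[best])
  }
  structure(list(markers = markers, eoc_values = eocs,
                 cluster_sizes = sizes[ord]),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat("Spatial marker genes:",
      paste(sprintf("%s (EOC %.3f, cluster n=%d)", x$markers,
                    x$eoc_values, x$cluster_sizes), collapse = "; "), "\n")
  invisible(x)
}
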