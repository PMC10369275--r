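#' Pairwise sample-sample distance matrix from an expression matrix
#'
#' Computes one of the three plain distance metrics between sample
#' expression profiles: Spearman distance (`SD = 1 - RCC`), Pearson
#' distance (`PD = 1 - PCC`) or the Euclidean distance (`ED`) between
#' sample columns.  The paired similarity matrix is `1 - d / max(d)`.
#'
#' @param expr numeric genes x samples matrix (expression values, typically
#'   on a log scale); column names are sample identifiers.
#' @param metric one of `"PD"`, `"SD"`, `"ED"`.
#' @param apply_sqrt logical; take the elementwise square root of the
#'   distance matrix (compresses large distances relative to small ones).
#' @return a `dce_network` object: list with `distance`, `similarity`,
#'   `metric`, `sqrt_applied`.
#' @examples
#' x <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("s", 1:4)))
#' net <- compute_distance_matrix(x, "PD")
#' @export
compute_distance_matrix <- function(expr, metric = c("PD", "SD", "ED"),
                                    apply_sqrt = FALSE) {
  metric <- match.arg(metric)
  expr <- as_expression_matrix(expr)
  n <- ncol(expr)
  if (n < 3L)
    stop("at least 3 samples are required, got ", n)
  if (metric %in% c("PD", "SD")) {
    sds <- apply(expr, 2L, stats::sd)
    if (any(sds == 0))
      stop("constant expression profile (zero variance) for sample(s): ",
           paste(colnames(expr)[sds == 0], collapse = ", "),
           "; correlation distances are undefined")
    cc <- stats::cor(expr, method = if (metric == "SD") "spearman" else "pearson")
    d <- 1 - cc
  } else {
    d <- as.matrix(stats::dist(t(expr)))
  }
  d <- pmax(d, 0)               # guard tiny negative rounding of 1 - cor
  d <- (d + t(d)) / 2
  diag(d) <- 0
  if (apply_sqrt) d <- sqrt(d)
  dimnames(d) <- list(colnames(expr), colnames(expr))
  new_dce_network(distance = d, similarity = similarity_from_distance(d),
                  metric = metric, sqrt_applied = apply_sqrt)
}

similarity_from_distance <- function(d) {
  mx <- max(d)
  if (mx == 0) {
    warning("all pairwise distances are zero; similarity set to 1 everywhere")
    s <- matrix(1, nrow(d), ncol(d), dimnames = dimnames(d))
    return(s)
  }
  s <- 1 - d / mx
  diag(s) <- 1
  s
}

new_dce_network <- function(distance, similarity, metric, sqrt_applied,
                            csi = NULL) {
  structure(list(distance = distance, similarity = similarity,
                 metric = metric, sqrt_applied = sqrt_applied, csi = csi),
            class = "dce_network")
}

#' @export
print.dce_network <- function(x, ...) {
  cat("Sample association network (", x$metric,
      if (isTRUE(x$sqrt_applied)) ", sqrt-transformed" else "", ")\n",
      sep = "")
  cat("  samples:", nrow(x$distance),
      " max distance:", format(max(x$distance), digits = 4), "\n")
  invisible(x)
}

#' Connectivity specificity index (CSI) of a correlation network
#'
#' Soft-thresholds a sample-sample correlation matrix: the CSI of a pair
#' (i, j) is the fraction of nodes k whose correlation with *both* i and j
#' is below `corr[i, j] - delta`.  Pairs embedded in a neighbourhood of
#' uniformly high correlations are penalised; locally specific high
#' correlations are rewarded.  A zero CSI marks the pair as non-adjacent.
#'
#' @param corr symmetric correlation matrix with values in \[-1, 1\].
#' @param delta offset below the pair's correlation that other nodes must
#'   fall under to count (default 0.05).
#' @return symmetric CSI matrix with values in \[0, 1\] and zero diagonal.
#' @export
compute_csi <- function(corr, delta = 0.05) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr) ||
      max(abs(corr - t(corr))) > 1e-8)
    stop("'corr' must be a symmetric square matrix")
  n <- nrow(corr)
  csi <- matrix(0, n, n, dimnames = dimnames(corr))
  for (i in seq_len(n - 1L)) {
    ci <- corr[i, ]
    for (j in (i + 1L):n) {
      th <- corr[i, j] - delta
      csi[i, j] <- csi[j, i] <- sum(ci < th & corr[j, ] < th) / n
    }
  }
  csi
}

#' Reverse a sparse similarity matrix into a sparse distance matrix
#'
#' Every nonzero similarity x is mapped to `abs(x - min(x+) - max(x+))`
#' where `x+` is the set of nonzero off-diagonal values, so the largest
#' similarity becomes the smallest distance; zero entries (non-adjacent
#' pairs) are preserved as zeros.
#'
#' @param csi symmetric nonnegative similarity matrix (typically a CSI
#'   matrix) with zero diagonal.
#' @return symmetric sparse distance matrix; zeros mark non-adjacent pairs.
#' @export
reverse_similarity <- function(csi) {
  csi <- as.matrix(csi)
  off <- csi
  diag(off) <- 0
  nz <- off[off > 0]
  if (length(nz) == 0L)
    stop("network empty after CSI filtering (all-zero similarity matrix)")
  mn <- min(nz); mx <- max(nz)
  d <- matrix(0, nrow(csi), ncol(csi), dimnames = dimnames(csi))
  pos <- off > 0
  d[pos] <- abs(off[pos] - mn - mx)
  d
}

#' Complete a distance matrix by graph shortest paths
#'
#' Non-adjacent pairs (zero off-diagonal entries when `zero_absent = TRUE`)
#' receive the length of the shortest weighted path between them; adjacent
#' pairs may also shrink when a multi-hop path is shorter than the direct
#' edge (Pearson/Spearman distances need not satisfy the triangle
#' inequality).
#'
#' @param d symmetric nonnegative distance matrix.
#' @param zero_absent logical; if `TRUE` zero off-diagonal entries mean
#'   "no edge", if `FALSE` the graph is complete and zeros are genuine
#'   zero-length edges.
#' @return dense completed distance matrix (all entries finite).
#' @export
shortest_path_completion <- function(d, zero_absent = TRUE) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("'d' must be a symmetric square matrix")
  if (any(d < 0)) stop("'d' must be nonnegative")
  ij <- which(upper.tri(d), arr.ind = TRUE)
  if (zero_absent) ij <- ij[d[ij] > 0, , drop = FALSE]
  if (nrow(ij) == 0L) stop("no edges in the distance graph")
  g <- igraph::graph_from_data_frame(
    data.frame(from = ij[, 1L], to = ij[, 2L], weight = d[ij]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  sp <- igraph::distances(g, algorithm = "dijkstra")
  ord <- match(as.character(seq_len(n)), rownames(sp))
  sp <- sp[ord, ord]
  if (any(!is.finite(sp))) {
    comp <- igraph::components(g)
    stop("distance graph is disconnected (component sizes: ",
         paste(comp$csize, collapse = ", "),
         "); use bridge_components = TRUE or a denser metric")
  }
  dimnames(sp) <- dimnames(d)
  sp
}

#' Default distance metric for a given sample count
#'
#' The plain (square-rooted) Pearson distance outperforms CSI-filtered
#' correlation networks on small sample sets, and vice versa on large
#' ones; the crossover is taken at 150 samples.
#'
#' @param n_samples number of samples.
#' @return `"PD"` when `n_samples < 150`, else `"PCC_CSI"`.
#' @export
default_metric <- function(n_samples) {
  if (n_samples < 150L) "PD" else "PCC_CSI"
}

#' Build the sample association network for coalescent embedding
#'
#' One-stop network construction: picks (or is told) a metric, applies the
#' CSI soft threshold for the correlation-CSI strategies, reverses
#' similarities into distances, and completes the network by shortest
#' paths.
#'
#' @param expr numeric genes x samples matrix.
#' @param metric `"auto"` (default: [default_metric()] by sample count) or
#'   one of `"PD"`, `"SD"`, `"ED"`, `"PCC_CSI"`, `"RCC_CSI"`.
#' @param csi_delta CSI offset (default 0.05).
#' @param apply_sqrt elementwise square root of the distance matrix;
#'   `NULL` resolves to `TRUE` for plain metrics and `FALSE` for CSI
#'   metrics.
#' @param shortest_path run shortest-path completion (default `TRUE`);
#'   `FALSE` is an ablation switch for the plain dense metrics.
#' @param bridge_components if the CSI-filtered graph is disconnected,
#'   connect components through the highest-CSI inter-component pair
#'   instead of failing (each bridge is reported via `message()`).
#' @return a `dce_network` object; for CSI metrics the `similarity` slot
#'   holds the CSI matrix itself (used downstream for node strength) and
#'   `csi` keeps a copy.
#' @export
build_network <- function(expr, metric = "auto", csi_delta = 0.05,
                          apply_sqrt = NULL, shortest_path = TRUE,
                          bridge_components = FALSE) {
  expr <- as_expression_matrix(expr)
  n <- ncol(expr)
  if (identical(metric, "auto")) metric <- default_metric(n)
  metric <- match.arg(metric, c("PD", "SD", "ED", "PCC_CSI", "RCC_CSI"))

  if (metric %in% c("PD", "SD", "ED")) {
    if (is.null(apply_sqrt)) apply_sqrt <- TRUE
    net <- compute_distance_matrix(expr, metric, apply_sqrt = apply_sqrt)
    if (shortest_path) {
      d <- shortest_path_completion(net$distance, zero_absent = FALSE)
      net$distance <- d
      net$similarity <- similarity_from_distance(d)
    }
    return(net)
  }

  # CSI strategies: correlation -> CSI -> reversed distance -> completion
  if (n < 3L) stop("at least 3 samples are required, got ", n)
  sds <- apply(expr, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant expression profile (zero variance) for sample(s): ",
         paste(colnames(expr)[sds == 0], collapse = ", "))
  cc <- stats::cor(expr,
                   method = if (metric == "RCC_CSI") "spearman" else "pearson")
  csi <- compute_csi(cc, delta = csi_delta)
  d0 <- reverse_similarity(csi)
  d0 <- bridge_if_needed(d0, csi, cc, bridge = bridge_components)
  d <- shortest_path_completion(d0, zero_absent = TRUE)
  if (is.null(apply_sqrt)) apply_sqrt <- FALSE
  if (apply_sqrt) d <- sqrt(d)
  sim <- csi
  new_dce_network(distance = d, similarity = sim, metric = metric,
                  sqrt_applied = apply_sqrt, csi = csi)
}

# Connect components of a sparse distance graph by repeatedly adding the
# inter-component pair with the highest CSI (ties: highest correlation,
# then lexicographic sample order); the bridge edge gets the largest
# existing edge distance (weakest-link semantics).
bridge_if_needed <- function(d0, csi, cc, bridge = FALSE) {
  repeat {
    memb <- edge_components(d0)
    if (max(memb) == 1L) return(d0)
    if (!bridge) return(d0)  # completion will raise the descriptive error
    inter <- which(outer(memb, memb, "!=") & upper.tri(d0), arr.ind = TRUE)
    sc <- cbind(csi[inter], cc[inter])
    best <- order(-sc[, 1L], -sc[, 2L], inter[, 1L], inter[, 2L])[1L]
    i <- inter[best, 1L]; j <- inter[best, 2L]
    w <- max(d0)
    d0[i, j] <- d0[j, i] <- w
    message("bridging disconnected components: adding edge ",
            rownames(d0)[i], " -- ", colnames(d0)[j],
            " (CSI = ", format(csi[i, j], digits = 3),
            ", distance = ", format(w, digits = 3), ")")
  }
}

edge_components <- function(d0) {
  n <- nrow(d0)
  ij <- which(upper.tri(d0) & d0 > 0, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ij[, 1L], to = ij[, 2L]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  memb <- igraph::components(g)$membership
  memb[match(as.character(seq_len(n)), names(memb))]
}

# coerce/validate a genes x samples expression matrix
as_expression_matrix <- function(expr) {
  if (is.data.frame(expr)) expr <- as.matrix(expr)
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("'expr' must be a numeric genes x samples matrix")
  if (anyNA(expr)) stop("'expr' contains missing values")
  if (is.null(colnames(expr)))
    colnames(expr) <- paste0("s", seq_len(ncol(expr)))
  if (anyDuplicated(colnames(expr)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(expr)[duplicated(colnames(expr))]),
               collapse = ", "))
  if (is.null(rownames(expr)))
    rownames(expr) <- paste0("g", seq_len(nrow(expr)))
  expr
}
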