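#' Spatial template constructor
#'
#' A template is an ordered list of spatial positions (2D or 3D), with an
#' optional block of expected marker-gene expression per position used to
#' orient the fit.
#'
#' @param positions positions x d numeric coordinate matrix (d = 2 or 3).
#' @param position_ids identifiers (default `p1..pn`).
#' @param marker_expression optional positions x markers numeric matrix
#'   with marker gene names as column names.
#' @return a `dce_template` object.
#' @export
dce_template <- function(positions, position_ids = NULL,
                         marker_expression = NULL) {
  positions <- as.matrix(positions)
  if (!ncol(positions) %in% 2:3)
    stop("template positions must be 2- or 3-dimensional")
  if (any(!is.finite(positions))) stop("template coordinates must be finite")
  if (is.null(position_ids))
    position_ids <- rownames(positions) %||% paste0("p", seq_len(nrow(positions)))
  rownames(positions) <- position_ids
  if (!is.null(marker_expression)) {
    marker_expression <- as.matrix(marker_expression)
    stopifnot(nrow(marker_expression) == nrow(positions))
    rownames(marker_expression) <- position_ids
  }
  structure(list(positions = positions, position_ids = position_ids,
                 marker_expression = marker_expression),
            class = "dce_template")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a spatial template from TSV
#'
#' Expects columns `position_id`, `x`, `y` and optionally `z`; columns
#' prefixed `marker:` are collected into the per-position marker
#' expression block.
#'
#' @param path TSV file path.
#' @return a `dce_template`.
#' @export
read_template <- function(path) {
  tb <- utils::read.delim(path, check.names = FALSE)
  req <- c("position_id", "x", "y")
  if (!all(req %in% names(tb)))
    stop("template file must have columns position_id, x, y[, z]")
  axes <- intersect(c("x", "y", "z"), names(tb))
  mk <- grep("^marker:", names(tb), value = TRUE)
  marker <- NULL
  if (length(mk)) {
    marker <- as.matrix(tb[mk])
    colnames(marker) <- sub("^marker:", "", mk)
  }
  dce_template(as.matrix(tb[axes]), position_ids = as.character(tb$position_id),
               marker_expression = marker)
}

#' Geodesic cost blocks over k-nearest-neighbour graphs
#'
#' Builds the symmetrised union k-nearest-neighbour graph of the sample
#' coordinates and of the template positions separately, and returns the
#' all-pairs shortest-path (Dijkstra) matrices over each.
#'
#' @param sample_coords samples x d coordinates (e.g. a D-CE embedding).
#' @param template a `dce_template` (or positions matrix).
#' @param k neighbour count; default `max(3, ceiling(log2(n)))` per cloud.
#' @return list with `C_s` (samples x samples) and `C_t`
#'   (positions x positions) geodesic distance matrices.
#' @export
geodesic_cost_blocks <- function(sample_coords, template, k = NULL) {
  pos <- if (inherits(template, "dce_template")) template$positions else
    as.matrix(template)
  list(C_s = knn_geodesics(as.matrix(sample_coords), k),
       C_t = knn_geodesics(pos, k))
}

knn_geodesics <- function(coords, k = NULL) {
  n <- nrow(coords)
  if (is.null(k)) k <- max(3L, ceiling(log2(n)))
  if (k < 1L) stop("'k' must be at least 1")
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(coords))
  edges <- NULL
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1L)]   # skip self
    edges <- rbind(edges, cbind(i, nb))
  }
  edges <- t(apply(edges, 1L, sort))
  edges <- unique(edges)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1L], to = edges[, 2L],
               weight = d[edges]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  sp <- igraph::distances(g, algorithm = "dijkstra")
  ord <- match(as.character(seq_len(n)), rownames(sp))
  sp <- sp[ord, ord]
  if (any(!is.finite(sp)))
    stop("k-nearest-neighbour graph is disconnected; increase k")
  dimnames(sp) <- list(rownames(coords), rownames(coords))
  sp
}

#' Structural cost interaction between sample and template geodesics
#'
#' The bilinear interaction `C = C_s . plan . C_t`, with the coupling
#' `plan` defaulting to the independence coupling `p q'`.  Within
#' [fit_template()] this term is re-evaluated at the current transport
#' plan as the linearised square-loss matching cost.
#'
#' @param C_s samples x samples geodesic cost block.
#' @param C_t positions x positions geodesic cost block.
#' @param p,q sample and position weights.
#' @param plan optional samples x positions coupling (default `p %o% q`).
#' @return samples x positions nonnegative cost matrix.
#' @export
structural_cost <- function(C_s, C_t, p, q, plan = NULL) {
  C_s <- as.matrix(C_s); C_t <- as.matrix(C_t)
  m <- nrow(C_s); n <- nrow(C_t)
  if (length(p) != m || length(q) != n)
    stop("dimension mismatch between cost blocks and weights")
  if (is.null(plan)) plan <- outer(p, q)
  if (!all(dim(plan) == c(m, n)))
    stop("dimension mismatch: plan must be ", m, " x ", n)
  C_s %*% plan %*% C_t
}

#' Marker-expression cost between samples and template positions
#'
#' Euclidean distance between each sample's marker expression vector and
#' each template position's expected marker expression, normalised by the
#' maximum distance so values lie in \[0, 1\].
#'
#' @param sample_expr samples x markers matrix.
#' @param template_markers positions x markers matrix (same marker order).
#' @return samples x positions cost matrix in \[0, 1\] (all zeros, with a
#'   warning, when the markers are uninformative).
#' @export
marker_cost <- function(sample_expr, template_markers) {
  a <- as.matrix(sample_expr); b <- as.matrix(template_markers)
  if (ncol(a) != ncol(b))
    stop("sample and template marker sets must match")
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  d <- sqrt(pmax(d2, 0))
  mx <- max(d)
  if (mx == 0) {
    warning("all marker distances are zero; markers are uninformative")
    return(d)
  }
  d / mx
}

#' Entropic optimal transport by log-domain Sinkhorn iterations
#'
#' Solves `min <C, T> + epsilon * KL(T | p q')` over couplings with
#' marginals `p` and `q`, using numerically stabilised log-domain scaling
#' updates.
#'
#' @param C cost matrix (rows: samples, columns: positions).
#' @param p,q marginal weight vectors (sum to 1 each).
#' @param epsilon entropic regularisation (> 0).
#' @param max_iter maximum iterations (default 20000; small epsilon needs
#'   many scaling sweeps).
#' @param tol maximum marginal violation accepted (default 1e-6).
#' @return a `dce_transport`: list with `T`, `p`, `q`, `epsilon`,
#'   `iterations`, `residual`.
#' @export
sinkhorn_transport <- function(C, p, q, epsilon, max_iter = 20000L,
                               tol = 1e-6) {
  C <- as.matrix(C)
  m <- nrow(C); n <- ncol(C)
  stopifnot(length(p) == m, length(q) == n, epsilon > 0)
  p <- p / sum(p); q <- q / sum(q)
  f <- numeric(m); g <- numeric(n)
  lp <- log(p); lq <- log(q)
  resid <- Inf; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # f-update: row marginals exact after this step
    M <- (outer(rep(1, m), g) - C) / epsilon
    f <- epsilon * (lp - rowlogsumexp(M))
    M <- (outer(f, rep(1, n)) - C) / epsilon
    g <- epsilon * (lq - collogsumexp(M))
    Tm <- exp((outer(f, rep(1, n)) + outer(rep(1, m), g) - C) / epsilon)
    resid <- max(abs(rowSums(Tm) - p))
    if (resid < tol) break
  }
  if (resid >= tol)
    stop("Sinkhorn did not converge within ", max_iter,
         " iterations (marginal residual ", format(resid, digits = 3), ")")
  dimnames(Tm) <- dimnames(C)
  structure(list(T = Tm, p = p, q = q, epsilon = epsilon,
                 iterations = it, residual = resid),
            class = "dce_transport")
}

rowlogsumexp <- function(M) {
  mx <- apply(M, 1L, max)
  mx + log(rowSums(exp(M - mx)))
}
collogsumexp <- function(M) {
  mx <- apply(M, 2L, max)
  mx + log(colSums(exp(sweep(M, 2L, mx))))
}

#' Greedy one-to-one assignment from a transport plan
#'
#' Repeatedly selects the globally largest remaining entry of the
#' transport matrix, assigns that sample to that position, and removes
#' both, until every sample is mapped.  Ties at the global maximum are
#' broken by the lexicographically smallest (sample, position) index pair.
#'
#' @param plan a `dce_transport` (or raw samples x positions matrix) with
#'   at least as many positions as samples.
#' @param cost optional cost matrix used to report the total assignment
#'   cost.
#' @return a `dce_assignment`: list with `mapping` (position index per
#'   sample), `position_ids`, `total_weight`, `total_cost`.
#' @export
one_to_one_assign <- function(plan, cost = NULL) {
  Tm <- if (inherits(plan, "dce_transport")) plan$T else as.matrix(plan)
  m <- nrow(Tm); n <- ncol(Tm)
  if (n < m) stop("one-to-one mapping needs at least as many positions (",
                  n, ") as samples (", m, ")")
  W <- Tm
  mapping <- integer(m)
  for (step in seq_len(m)) {
    mx <- max(W)
    idx <- which(W == mx, arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE][1L, ]
    mapping[idx[1L]] <- idx[2L]
    W[idx[1L], ] <- -Inf
    W[, idx[2L]] <- -Inf
  }
  structure(list(mapping = mapping,
                 position_ids = colnames(Tm)[mapping] %||%
                   as.character(mapping),
                 sample_ids = rownames(Tm) %||% as.character(seq_len(m)),
                 total_weight = sum(Tm[cbind(seq_len(m), mapping)]),
                 total_cost = if (!is.null(cost))
                   sum(cost[cbind(seq_len(m), mapping)]) else NA_real_),
            class = "dce_assignment")
}

#' Maximum-probability (non-injective) mapping of samples to positions
#'
#' Maps every sample to the position carrying the largest mass in its row
#' of the transport plan; several samples may share a position (single
#' cell "scmap" mode).  Row ties go to the lowest position index, with a
#' warning.
#'
#' @param plan a `dce_transport` or raw matrix.
#' @return integer vector of position indices, one per sample, with the
#'   position identifiers as names.
#' @export
scmap_assign <- function(plan) {
  Tm <- if (inherits(plan, "dce_transport")) plan$T else as.matrix(plan)
  rmax <- apply(Tm, 1L, max)
  nties <- rowSums(Tm == rmax)
  if (any(nties > 1L))
    warning("row maximum ties for ", sum(nties > 1L),
            " sample(s); lowest position index chosen")
  idx <- apply(Tm, 1L, which.max)   # which.max already takes first maximum
  names(idx) <- rownames(Tm)
  pid <- colnames(Tm)[idx] %||% as.character(idx)
  structure(idx, position_ids = pid)
}

#' Fit an embedding one-to-one onto a spatial template (D-CE-t)
#'
#' Maps embedded samples to template positions by entropic optimal
#' transport over geodesic (kNN shortest-path) cost structures.  The
#' structural matching objective is the entropic Gromov-Wasserstein
#' square loss, iterated through its linearisation at the current plan:
#' at each outer step the cost `mean(C_s^2 p) (+) mean(C_t^2 q) -
#' 2 C_s T C_t` (first evaluated at the independence coupling `p q'`) is
#' blended with the marker cost and resolved by Sinkhorn, until the plan
#' stabilises.  The final plan is sharpened into a one-to-one assignment
#' greedily (or by row maxima when `scmap = TRUE`).
#'
#' @param embedding a `dce_embedding`, or a samples x d coordinate matrix.
#' @param template a `dce_template`.
#' @param markers optional character vector of marker gene ids (must be
#'   columns of `template$marker_expression`).
#' @param expr genes x samples expression matrix supplying the samples'
#'   marker expression (required when `markers` is given).
#' @param lambda blend weight of the marker cost in \[0, 1\] (default 0.5).
#' @param epsilon entropic regularisation; default `0.05 * mean(cost)` at
#'   the first outer iteration.
#' @param k neighbour count for the geodesic graphs.
#' @param scmap map each sample to its maximum-probability position
#'   (non-injective) instead of the greedy one-to-one assignment.
#' @param rescale scale each coordinate cloud to unit median pairwise
#'   distance before building costs (default `TRUE`).
#' @param max_outer maximum outer (linearisation) iterations.
#' @return a `dce_assignment` with the fitted template coordinates in
#'   `fitted_coords`, plus `plan`, `used_markers` and `epsilon`.
#' @export
fit_template <- function(embedding, template, markers = NULL, expr = NULL,
                         lambda = 0.5, epsilon = NULL, k = NULL,
                         scmap = FALSE, rescale = TRUE, max_outer = 100L) {
  coords <- if (inherits(embedding, "dce_embedding")) embedding$cartesian
            else as.matrix(embedding)
  if (!inherits(template, "dce_template")) template <- dce_template(template)
  m <- nrow(coords); n <- nrow(template$positions)
  if (!scmap && n < m)
    stop("template has fewer positions (", n, ") than samples (", m, ")")
  if (rescale) {
    coords <- scale_cloud(coords)
    pos <- scale_cloud(template$positions)
  } else pos <- template$positions

  blocks <- geodesic_cost_blocks(coords, pos, k = k)
  C_s <- blocks$C_s / max(blocks$C_s)
  C_t <- blocks$C_t / max(blocks$C_t)
  p <- rep(1 / m, m); q <- rep(1 / n, n)

  C_g <- NULL
  if (!is.null(markers) && length(markers)) {
    if (is.null(template$marker_expression))
      stop("template carries no marker expression")
    if (is.null(expr))
      stop("'expr' is required to extract the samples' marker expression")
    miss <- setdiff(markers, colnames(template$marker_expression))
    if (length(miss)) stop("markers absent from template: ",
                           paste(miss, collapse = ", "))
    miss <- setdiff(markers, rownames(expr))
    if (length(miss)) stop("markers absent from expression matrix: ",
                           paste(miss, collapse = ", "))
    sm <- t(expr[markers, , drop = FALSE])   # samples x markers
    sm <- scale(sm)           # per-marker z-score, units cancel
    tm <- scale(template$marker_expression[, markers, drop = FALSE])
    sm[is.nan(sm)] <- 0; tm[is.nan(tm)] <- 0
    C_g <- marker_cost(sm, tm)
  } else lambda <- 0

  # offsets of the square-loss linearisation (constant per row/column)
  cs2 <- as.numeric((C_s^2) %*% p)
  ct2 <- as.numeric((C_t^2) %*% q)
  off <- outer(cs2, rep(1, n)) + outer(rep(1, m), ct2)

  Tm <- outer(p, q)
  plan <- NULL
  for (it in seq_len(max_outer)) {
    C_struct <- off - 2 * structural_cost(C_s, C_t, p, q, plan = Tm)
    C_struct <- C_struct - min(C_struct)
    C_total <- (1 - lambda) * C_struct +
      if (lambda > 0) lambda * C_g else 0
    if (is.null(epsilon)) epsilon <- 0.05 * mean(C_total)
    plan <- sinkhorn_transport(C_total, p, q, epsilon)
    delta <- max(abs(plan$T - Tm))
    Tm <- plan$T
    if (delta < 1e-9) break
  }

  asn <- if (scmap) {
    idx <- scmap_assign(plan)
    structure(list(mapping = as.integer(idx),
                   position_ids = attr(idx, "position_ids"),
                   sample_ids = rownames(coords),
                   total_weight = sum(plan$T[cbind(seq_len(m), idx)]),
                   total_cost = sum(C_total[cbind(seq_len(m), idx)])),
              class = "dce_assignment")
  } else one_to_one_assign(plan, cost = C_total)
  asn$fitted_coords <- template$positions[asn$mapping, , drop = FALSE]
  rownames(asn$fitted_coords) <- rownames(coords)
  asn$used_markers <- markers %||% character(0)
  asn$plan <- plan
  asn$epsilon <- epsilon
  asn$outer_iterations <- it
  asn
}

#' @export
print.dce_assignment <- function(x, ...) {
  cat("Template assignment of", length(x$mapping), "samples",
      if (anyDuplicated(x$mapping)) "(scmap, non-injective)" else
        "(one-to-one)", "\n")
  if (length(x$used_markers))
    cat("  markers:", paste(x$used_markers, collapse = ", "), "\n")
  invisible(x)
}

#' Expected coordinates under a probabilistic coupling
#'
#' Evaluation utility: the transport-weighted average of the template
#' coordinates for each sample, `T L / rowSums(T)`.
#'
#' @param plan a `dce_transport`.
#' @param template a `dce_template`.
#' @return samples x d expected coordinates.
#' @export
expected_coords <- function(plan, template) {
  Tm <- plan$T
  (Tm %*% template$positions) / rowSums(Tm)
}

scale_cloud <- function(x) {
  x <- as.matrix(x)
  md <- stats::median(stats::dist(x))
  if (md == 0) stop("degenerate coordinate cloud (zero median distance)")
  sweep(x, 2L, colMeans(x)) / md
}
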