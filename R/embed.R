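#' Double-centre a distance matrix
#'
#' Subtracts row and column means and adds back the grand mean
#' (`J X J` centring), shifting the origin of the implied feature space to
#' the data centroid.  Every row and column of the result sums to zero.
#'
#' @param x square symmetric numeric matrix.
#' @return centred matrix of the same dimension.
#' @export
double_center <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) stop("'x' must be square")
  if (any(!is.finite(x))) stop("'x' must be finite")
  rm <- rowMeans(x); cm <- colMeans(x); gm <- mean(x)
  x - outer(rm, rep(1, ncol(x))) - outer(rep(1, nrow(x)), cm) + gm
}

#' Angular coordinates from the SVD of the centred kernel
#'
#' Decomposes the doubly-centred distance kernel as `X = U S V'` and
#' returns the first `dims` right singular vectors scaled columnwise by
#' the square roots of their singular values — the score matrix whose rows
#' are the (pre-radius) sample coordinates.  Sign indeterminacy is fixed
#' by forcing the largest-magnitude loading of every retained singular
#' vector to be positive.
#'
#' @param kernel centred symmetric matrix (see [double_center()]).
#' @param dims number of embedding dimensions (default 3; 2 for flat
#'   templates).
#' @return list with `coords` (samples x dims) and `singular_values`
#'   (the retained singular values, descending).
#' @export
svd_angular_coords <- function(kernel, dims = 3L) {
  kernel <- as.matrix(kernel)
  n <- nrow(kernel)
  if (dims > n) stop("'dims' (", dims, ") exceeds the sample count (", n, ")")
  if (max(abs(kernel)) < 1e-12 * n) stop("degenerate kernel (all zero)")
  s <- svd(kernel, nu = 0, nv = dims)
  v <- s$v
  for (k in seq_len(dims)) {
    j <- which.max(abs(v[, k]))
    if (v[j, k] < 0) v[, k] <- -v[, k]
  }
  sv <- s$d[seq_len(dims)]
  coords <- v %*% diag(sqrt(pmax(sv, 0)), dims)
  rownames(coords) <- rownames(kernel)
  list(coords = coords, singular_values = sv)
}

#' Node strength of an association network
#'
#' The strength of a sample is the sum of the off-diagonal similarities
#' incident on it (CSI values for CSI networks, `1 - d/max(d)` otherwise).
#' High-strength nodes sit high in the topological hierarchy and are
#' placed toward the centre of the embedding.
#'
#' @param net a `dce_network` or a symmetric similarity matrix.
#' @return named numeric vector of strengths.
#' @export
node_strength <- function(net) {
  s <- if (inherits(net, "dce_network")) net$similarity else as.matrix(net)
  rowSums(s) - diag(s)
}

#' Heterogeneity-adaptive radial coordinates (HAr)
#'
#' Samples are ranked by descending strength (rank 1 = strongest; ties
#' broken by input order, so re-runs are bit-identical) and the radius of
#' the sample ranked `o` is `1 - beta / (ln(o) + 1)`.  The heterogeneity
#' coefficient `beta = RSD / (1 + RSD)`, with RSD the relative standard
#' deviation (population SD / mean) of the strengths, squeezes strongly
#' hierarchical networks toward the centre: at `beta = 1/2` the strongest
#' node sits at radius 1/2, and as `beta -> 1` it approaches the origin.
#'
#' @param strength nonnegative strengths, not all zero.
#' @param beta optional fixed heterogeneity coefficient in \[0, 1);
#'   default `NULL` estimates it from `strength`.
#' @return list with `radius`, `rank` (permutation of `1..n`), `beta`.
#' @export
har_radii <- function(strength, beta = NULL) {
  nm <- names(strength)
  strength <- as.numeric(strength)
  names(strength) <- nm
  if (any(strength < 0)) stop("strengths must be nonnegative")
  m <- mean(strength)
  if (m == 0) stop("mean strength is zero; network has no similarity mass")
  if (is.null(beta)) {
    rsd <- sqrt(mean((strength - m)^2)) / m  # population SD convention
    beta <- rsd / (1 + rsd)
  }
  if (beta < 0 || beta >= 1) stop("'beta' must lie in [0, 1)")
  ord <- order(-strength)            # stable: ties keep input order
  rnk <- integer(length(strength))
  rnk[ord] <- seq_along(strength)
  radius <- 1 - beta / (log(rnk) + 1)
  names(radius) <- names(rnk) <- names(strength)
  list(radius = radius, rank = rnk, beta = beta)
}

#' Assemble the final embedding from angular directions and radii
#'
#' Keeps only the angular part of each sample's SVD coordinate (its unit
#' direction) and places the sample at `radius * direction`.
#'
#' @param coords samples x dims SVD score matrix.
#' @param radii per-sample radii.
#' @return samples x dims Cartesian coordinates with `||row_i|| = radii[i]`.
#' @export
assemble_embedding <- function(coords, radii) {
  coords <- as.matrix(coords)
  nrm <- sqrt(rowSums(coords^2))
  bad <- nrm < 1e-12 * max(nrm, 1e-300)
  if (any(bad))
    stop("zero-norm angular coordinates for sample(s): ",
         paste(rownames(coords)[bad], collapse = ", "),
         "; duplicate profiles? consider jitter = TRUE")
  unit <- coords / nrm
  cart <- unit * radii
  rownames(cart) <- rownames(coords)
  cart
}

#' De novo coalescent embedding of transcriptomic samples
#'
#' Full embedding pipeline: association network (unless one is supplied),
#' double centring of the distance kernel, SVD angular coordinates,
#' strength-ranked heterogeneity-adaptive radii, and assembly into
#' Cartesian coordinates.  The reconstruction has arbitrary global scale,
#' rotation and chirality; all evaluation indices in this package are
#' invariant to those.
#'
#' @param x genes x samples expression matrix, or a prebuilt
#'   `dce_network`.
#' @param dims embedding dimensionality (default 3).
#' @param metric,csi_delta,apply_sqrt,shortest_path,bridge_components
#'   passed to [build_network()] when `x` is an expression matrix.
#' @param jitter add a deterministic N(0, 1e-8 * scale) perturbation to
#'   the distances before centring (resolves exactly duplicated profiles).
#' @param jitter_seed seed for the jitter stream.
#' @return a `dce_embedding`: list with `cartesian` (samples x dims),
#'   `angular` (unit directions), `radius`, `rank`, `strength`, `beta`,
#'   `singular_values`, `sample_ids`, `metric`.
#' @examples
#' tis <- generate_grid_tissue(nx = 6, ny = 6, seed = 1)
#' emb <- dce_embed(tis$expr)
#' head(emb$cartesian)
#' @export
dce_embed <- function(x, dims = 3L, metric = "auto", csi_delta = 0.05,
                      apply_sqrt = NULL, shortest_path = TRUE,
                      bridge_components = FALSE, jitter = FALSE,
                      jitter_seed = 1L) {
  net <- if (inherits(x, "dce_network")) x else
    build_network(x, metric = metric, csi_delta = csi_delta,
                  apply_sqrt = apply_sqrt, shortest_path = shortest_path,
                  bridge_components = bridge_components)
  d <- net$distance
  if (jitter) {
    eps <- local_rng(jitter_seed, {
      e <- matrix(stats::rnorm(length(d), sd = 1e-8 * max(d)), nrow(d))
      e <- (e + t(e)) / 2; diag(e) <- 0; e
    })
    d <- d + abs(eps)
  }
  kern <- double_center(d)
  sv <- svd_angular_coords(kern, dims = dims)
  strength <- node_strength(net)
  hr <- har_radii(strength)
  cart <- assemble_embedding(sv$coords, hr$radius)
  structure(list(cartesian = cart,
                 angular = cart / hr$radius,
                 radius = hr$radius,
                 rank = hr$rank,
                 strength = strength,
                 beta = hr$beta,
                 singular_values = sv$singular_values,
                 sample_ids = rownames(d),
                 metric = net$metric),
            class = "dce_embedding")
}

#' @export
print.dce_embedding <- function(x, ...) {
  cat("Coalescent embedding of", length(x$sample_ids), "samples in",
      ncol(x$cartesian), "dimensions\n")
  cat("  metric:", x$metric,
      " beta:", format(x$beta, digits = 4),
      " top singular values:",
      paste(format(x$singular_values, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
local_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
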