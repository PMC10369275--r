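#' Synthetic planar-grid tissue with planted spatial structure
#'
#' Generates samples on an `nx` x `ny` unit grid (z = 0) with three gene
#' classes: *gradient* genes, monotone in one tissue coordinate (half
#' track x, half track y) plus Gaussian noise; *lineage* genes, whose
#' expression depends only on a randomly assigned lineage label that cuts
#' across spatial domains (a lineage confound); and *noise* genes, pure
#' Gaussian noise.  Quadrant labels (Q1..Q4, split at the coordinate
#' midpoints) and the x-column index (as a layer annotation) are emitted
#' for the separability and ordering indices.  Regeneration with the same
#' seed is bit-identical.
#'
#' @param nx,ny grid dimensions (default 10 x 10).
#' @param n_gradient,n_lineage,n_noise gene counts per class
#'   (defaults 20 / 20 / 60).
#' @param noise_sd Gaussian noise SD added to every gene (default 0.3;
#'   the gradient spans `gradient_amplitude` over the unit axis).
#' @param gradient_amplitude expression range of a gradient gene across
#'   the tissue (default 1).
#' @param lineage_effect expression offset of a lineage gene in its
#'   target lineage (default 0.5, i.e. half the gradient effect size: a
#'   nuisance signal that does not overwhelm the spatial covariance).
#' @param n_lineages number of lineages (default 3).
#' @param gradient_shape `"linear"` (default), `"sigmoid"` or `"stripe"`
#'   (two-period stripe pattern emulating pair-rule-like expression).
#' @param seed RNG seed.
#' @return a `dce_tissue`: list with `expr` (genes x samples),
#'   `true_coords` (samples x 3), `layers`, `domains`, `lineages`,
#'   `gradient_genes`, `lineage_genes`, `noise_genes`, `seed`.
#' @export
generate_grid_tissue <- function(nx = 10L, ny = 10L, n_gradient = 20L,
                                 n_lineage = 20L, n_noise = 60L,
                                 noise_sd = 0.3, gradient_amplitude = 1,
                                 lineage_effect = 0.5, n_lineages = 3L,
                                 gradient_shape = c("linear", "sigmoid",
                                                    "stripe"),
                                 seed = 1L) {
  gradient_shape <- match.arg(gradient_shape)
  stopifnot(nx >= 1, ny >= 1, n_gradient >= 1, n_lineage >= 1,
            n_noise >= 1, noise_sd >= 0)
  local_rng(seed, {
    gx <- if (nx > 1) seq(0, 1, length.out = nx) else 0.5
    gy <- if (ny > 1) seq(0, 1, length.out = ny) else 0.5
    grid <- expand.grid(x = gx, y = gy)
    n <- nrow(grid)
    coords <- cbind(x = grid$x, y = grid$y, z = 0)
    rownames(coords) <- sprintf("s%03d", seq_len(n))
    domains <- paste0("Q",
                      1L + (grid$x > stats::median(gx)) +
                        2L * (grid$y > stats::median(gy)))
    layers <- match(grid$x, gx)
    build_tissue(coords, layers, domains, n_gradient, n_lineage, n_noise,
                 noise_sd, gradient_amplitude, lineage_effect, n_lineages,
                 gradient_shape, seed,
                 grad_axes = c(1L, 2L))
  })
}

#' Synthetic layered (ellipsoid-shell) tissue
#'
#' Samples sit on rings of an ellipsoid shell: `n_layers` rings along the
#' proximal-distal (z) axis, `samples_per_layer` samples per ring, with
#' anterior/posterior/left/right (A/P/L/R) domains assigned by angular
#' quadrant.  Gene classes as in [generate_grid_tissue()]; half of the
#' gradient genes track the layer (z) axis and half the anterior-
#' posterior (x) axis.
#'
#' @inheritParams generate_grid_tissue
#' @param n_layers number of layers along the proximal-distal axis
#'   (default 11).
#' @param samples_per_layer samples per ring (default 8).
#' @return a `dce_tissue` (see [generate_grid_tissue()]); `layers` holds
#'   the ring index (1 = most proximal) and `domains` the A/P/L/R tag.
#' @export
generate_layered_tissue <- function(n_layers = 11L, samples_per_layer = 8L,
                                    n_gradient = 20L, n_lineage = 20L,
                                    n_noise = 60L, noise_sd = 0.3,
                                    gradient_amplitude = 1,
                                    lineage_effect = 0.5, n_lineages = 3L,
                                    gradient_shape = c("linear", "sigmoid",
                                                       "stripe"),
                                    seed = 1L) {
  gradient_shape <- match.arg(gradient_shape)
  stopifnot(n_layers >= 1, samples_per_layer >= 1, n_gradient >= 1,
            n_lineage >= 1, n_noise >= 1, noise_sd >= 0)
  local_rng(seed, {
    phi <- pi * (seq_len(n_layers) - 0.5) / n_layers  # polar angle of ring
    theta <- 2 * pi * (seq_len(samples_per_layer) - 1L) / samples_per_layer
    lay <- rep(seq_len(n_layers), each = samples_per_layer)
    th <- rep(theta, times = n_layers)
    coords <- cbind(x = sin(phi[lay]) * cos(th),
                    y = sin(phi[lay]) * sin(th),
                    z = 0.6 * cos(phi[lay]))   # mildly prolate shell
    n <- nrow(coords)
    rownames(coords) <- sprintf("s%03d", seq_len(n))
    sector <- (floor((th + pi / 4) / (pi / 2)) %% 4) + 1L
    domains <- c("A", "L", "P", "R")[sector]
    build_tissue(coords, lay, domains, n_gradient, n_lineage, n_noise,
                 noise_sd, gradient_amplitude, lineage_effect, n_lineages,
                 gradient_shape, seed,
                 grad_axes = c(3L, 1L))
  })
}

# shared gene-expression assembly (runs inside the caller's seeded RNG)
build_tissue <- function(coords, layers, domains, n_gradient, n_lineage,
                         n_noise, noise_sd, gradient_amplitude,
                         lineage_effect, n_lineages, gradient_shape, seed,
                         grad_axes) {
  n <- nrow(coords)
  shape <- switch(gradient_shape,
                  linear = function(t) t,
                  sigmoid = function(t) 1 / (1 + exp(-10 * (t - 0.5))),
                  stripe = function(t) (sin(4 * pi * t) + 1) / 2)
  unit01 <- function(v) {
    r <- range(v)
    if (diff(r) == 0) rep(0.5, length(v)) else (v - r[1L]) / diff(r)
  }
  ax_of_gene <- rep(grad_axes, length.out = n_gradient)
  grad_names <- sprintf("grad%s_%02d",
                        c("x", "y", "z")[ax_of_gene], seq_len(n_gradient))
  grad <- t(vapply(seq_len(n_gradient), function(g)
    gradient_amplitude * shape(unit01(coords[, ax_of_gene[g]])) +
      stats::rnorm(n, sd = noise_sd), numeric(n)))
  lineages <- sample.int(n_lineages, n, replace = TRUE)
  lin_target <- rep(seq_len(n_lineages), length.out = n_lineage)
  lin_names <- sprintf("lin%d_%02d", lin_target, seq_len(n_lineage))
  lin <- t(vapply(seq_len(n_lineage), function(g)
    lineage_effect * (lineages == lin_target[g]) +
      stats::rnorm(n, sd = noise_sd), numeric(n)))
  noise_names <- sprintf("noise_%02d", seq_len(n_noise))
  noi <- matrix(stats::rnorm(n_noise * n, sd = noise_sd), n_noise, n)
  expr <- rbind(grad, lin, noi)
  dimnames(expr) <- list(c(grad_names, lin_names, noise_names),
                         rownames(coords))
  structure(list(expr = expr, true_coords = coords,
                 layers = layers, domains = domains, lineages = lineages,
                 gradient_genes = grad_names, lineage_genes = lin_names,
                 noise_genes = noise_names, seed = seed),
            class = "dce_tissue")
}

#' @export
print.dce_tissue <- function(x, ...) {
  cat("Synthetic tissue:", ncol(x$expr), "samples x", nrow(x$expr),
      "genes (seed", x$seed, ")\n")
  cat("  gene classes:", length(x$gradient_genes), "gradient,",
      length(x$lineage_genes), "lineage,",
      length(x$noise_genes), "noise\n")
  invisible(x)
}

#' Random down-sampled replicates of a tissue
#'
#' Draws `n_repeats` independent subsets of the samples at the given
#' rate; each replicate records its own derived seed so any replicate can
#' be regenerated in isolation.
#'
#' @param tissue a `dce_tissue`.
#' @param rate fraction of samples kept (0 < rate <= 1).
#' @param n_repeats number of replicates (default 20).
#' @param seed RNG seed for the replicate stream.
#' @return list of `dce_tissue` objects; each carries its subset and a
#'   `seed` entry of the form `seed * 1000 + repeat`.
#' @export
downsample_tissue <- function(tissue, rate, n_repeats = 20L, seed = 1L) {
  stopifnot(inherits(tissue, "dce_tissue"), rate > 0, rate <= 1)
  n <- ncol(tissue$expr)
  keep_n <- max(3L, floor(rate * n))
  lapply(seq_len(n_repeats), function(r) {
    sub_seed <- seed * 1000L + r
    idx <- local_rng(sub_seed, sort(sample.int(n, keep_n)))
    out <- tissue
    out$expr <- tissue$expr[, idx, drop = FALSE]
    out$true_coords <- tissue$true_coords[idx, , drop = FALSE]
    out$layers <- tissue$layers[idx]
    out$domains <- tissue$domains[idx]
    out$lineages <- tissue$lineages[idx]
    out$seed <- sub_seed
    out
  })
}
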