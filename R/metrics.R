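#' Ordering index (OI) of reconstructed layer order
#'
#' Within each spatial domain, the centroid of each annotated layer's
#' samples is computed in the reconstruction; the chain starts at the
#' first layer's centroid and repeatedly steps to the nearest unvisited
#' centroid.  OI is the Spearman correlation between the annotated layer
#' ranks and the chained ranks; the overall OI is the minimum across
#' domains.  OI ranges over \[-1, 1\] with 1 meaning perfect agreement,
#' and depends only on pairwise distances (invariant to rotation,
#' reflection and uniform scaling).
#'
#' @param coords samples x d reconstructed coordinates.
#' @param layers per-sample integer layer labels (1 = first layer).
#' @param domains optional per-sample domain tags (e.g. A/P/L/R); OI is
#'   computed per domain and the minimum reported.
#' @return list with `overall` and named `per_domain` OIs.
#' @export
ordering_index <- function(coords, layers, domains = NULL) {
  coords <- as.matrix(coords)
  layers <- as.integer(layers)
  stopifnot(nrow(coords) == length(layers))
  if (is.null(domains)) domains <- rep("all", length(layers))
  per <- vapply(split(seq_along(layers), domains), function(idx) {
    chain_oi(layer_centers(coords[idx, , drop = FALSE], layers[idx]))
  }, numeric(1))
  list(overall = min(per), per_domain = per)
}

# centroids of each layer, rows ordered by ascending layer value
layer_centers <- function(coords, layers) {
  layers <- as.integer(layers)
  lv <- sort(unique(layers))
  if (length(lv) < 3L)
    stop("at least 3 layers are required per scored domain")
  if (!identical(lv, seq(min(lv), max(lv))))
    stop("layer(s) with zero samples: ",
         paste(setdiff(seq(min(lv), max(lv)), lv), collapse = ", "))
  centers <- t(vapply(lv, function(l)
    colMeans(coords[layers == l, , drop = FALSE]), numeric(ncol(coords))))
  centers
}

# OI of a centroid matrix whose row order is the annotated layer order:
# nearest-centre chaining from row 1, then Spearman against 1..L
chain_oi <- function(centers) {
  L <- nrow(centers)
  visited <- logical(L)
  chain <- integer(L)
  chain[1L] <- 1L; visited[1L] <- TRUE
  for (s in 2:L) {
    last <- centers[chain[s - 1L], ]
    d <- sqrt(colSums((t(centers) - last)^2))
    d[visited] <- Inf
    chain[s] <- which.min(d)
    visited[chain[s]] <- TRUE
  }
  rank_in_chain <- integer(L)
  rank_in_chain[chain] <- seq_len(L)
  spearman0(seq_len(L), rank_in_chain)
}

# Spearman correlation with the convention that undefined (constant
# input) correlations are 0
spearman0 <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  suppressWarnings(stats::cor(a, b, method = "spearman"))
}

#' Per-axis OI of a reconstruction against true coordinates
#'
#' For each axis of the true coordinates the samples are sorted by that
#' coordinate and divided into `n_groups` contiguous groups (the group
#' with the lowest mean coordinate is group 1); the group centroids in
#' the reconstruction are chained as in [ordering_index()] and the
#' Spearman correlation of group ranks is reported per axis.
#'
#' @param coords samples x d reconstructed coordinates.
#' @param true_coords samples x d0 reference coordinates.
#' @param n_groups number of groups per axis (default 10).
#' @return named numeric vector of per-axis OIs (`OI_x`, `OI_y`, ...).
#' @export
template_oi <- function(coords, true_coords, n_groups = 10L) {
  coords <- as.matrix(coords); true_coords <- as.matrix(true_coords)
  n <- nrow(coords)
  stopifnot(nrow(true_coords) == n)
  if (n < n_groups) stop("fewer samples (", n, ") than groups (", n_groups, ")")
  ax <- colnames(true_coords) %||% c("x", "y", "z")[seq_len(ncol(true_coords))]
  out <- vapply(seq_len(ncol(true_coords)), function(d) {
    rk <- rank(true_coords[, d], ties.method = "first")
    grp <- ceiling(rk * n_groups / n)
    chain_oi(layer_centers(coords, grp))
  }, numeric(1))
  names(out) <- paste0("OI_", ax)
  out
}

#' Projection separability index by Matthews correlation (PSImcc)
#'
#' For every pair of groups, the members are projected onto the line
#' joining the two group anchors (centroids by default); the `n1`
#' lowest-projection samples are labelled as one group and the rest as
#' the other, the Matthews correlation coefficient of that confusion
#' table is computed under both side assignments, and the larger value
#' kept.  PSImcc is the mean over all group pairs; 1 means every pair is
#' perfectly separated along its centroid line.
#'
#' @param coords samples x d coordinates.
#' @param groups per-sample group labels (>= 2 groups).
#' @param anchors `"centroid"` (default) or `"median"` line anchors.
#' @return scalar PSImcc.
#' @export
psi_mcc <- function(coords, groups, anchors = c("centroid", "median")) {
  anchors <- match.arg(anchors)
  coords <- as.matrix(coords)
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  if (length(lv) < 2L) stop("at least 2 groups are required")
  prs <- utils::combn(lv, 2L)
  vals <- apply(prs, 2L, function(pr) {
    idx <- groups %in% pr
    pts <- coords[idx, , drop = FALSE]
    lab <- groups[idx]
    a1 <- group_anchor(pts[lab == pr[1L], , drop = FALSE], anchors)
    a2 <- group_anchor(pts[lab == pr[2L], , drop = FALSE], anchors)
    dir <- a2 - a1
    if (sqrt(sum(dir^2)) < 1e-12) {
      warning("coincident anchors for groups ", pr[1L], "/", pr[2L],
              "; pair contributes 0")
      return(0)
    }
    proj <- as.numeric(pts %*% dir)
    n1 <- sum(lab == pr[1L]); n2 <- sum(lab == pr[2L])
    ord <- order(proj)                 # stable: sample order breaks ties
    predA <- predB <- character(n1 + n2)
    predA[ord] <- rep(pr, c(n1, n2))   # low side = group 1
    predB[ord] <- rep(rev(pr), c(n2, n1))  # low side = group 2
    max(mcc_binary(lab == pr[1L], predA == pr[1L]),
        mcc_binary(lab == pr[1L], predB == pr[1L]))
  })
  mean(vals)
}

group_anchor <- function(pts, anchors) {
  if (anchors == "median") apply(pts, 2L, stats::median) else colMeans(pts)
}

mcc_binary <- function(truth, pred) {
  tp <- sum(truth & pred); tn <- sum(!truth & !pred)
  fp <- sum(!truth & pred); fn <- sum(truth & !pred)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Angular separation index (ASI)
#'
#' Measures how cleanly labelled groups segregate by angular position:
#' coordinates are first projected onto the unit sphere (radius
#' information discarded), then each group is scored one-vs-rest by the
#' best central-hyperplane split — the direction search runs over
#' centroid-difference directions (group vs rest and group vs each other
#' group) and, per direction, over all thresholds along the projection;
#' the group's score is the largest fraction of samples falling on the
#' correct side of the split.  ASI is the mean over groups: 1 when every
#' group occupies a cleanly separable angular region.  Chance-level
#' labellings score around the majority fraction, which is why
#' [rank_strategies()] subtracts a label-randomisation baseline.
#'
#' @param coords samples x d coordinates (radii are normalised away).
#' @param groups per-sample group labels.
#' @return scalar in \[0, 1\].
#' @export
asi <- function(coords, groups) {
  coords <- as.matrix(coords)
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  if (length(lv) < 2L) stop("at least 2 groups are required")
  nrm <- sqrt(rowSums(coords^2))
  if (any(nrm < 1e-12))
    stop("sample(s) at the origin: angular position undefined")
  unit <- coords / nrm
  scores <- vapply(lv, function(g) {
    pos <- unit[groups == g, , drop = FALSE]
    neg <- unit[groups != g, , drop = FALSE]
    dirs <- rbind(colMeans(pos) - colMeans(neg),
                  t(vapply(setdiff(lv, g), function(h)
                    colMeans(pos) - colMeans(unit[groups == h, , drop = FALSE]),
                    numeric(ncol(unit)))))
    best <- max(sum(groups == g), sum(groups != g)) / length(groups)
    for (r in seq_len(nrow(dirs))) {
      w <- dirs[r, ]
      if (sqrt(sum(w^2)) < 1e-12) next
      best <- max(best, best_split_accuracy(as.numeric(unit %*% w),
                                            groups == g))
    }
    best
  }, numeric(1))
  mean(scores)
}

# best split accuracy (fraction of samples on the correct side) over all
# thresholds of a 1D score, both orientations considered; with no usable
# split the floor is the majority fraction
best_split_accuracy <- function(score, positive) {
  ord <- order(score)
  y <- positive[ord]
  P <- sum(y); N <- sum(!y)
  n <- P + N
  floor_acc <- max(P, N) / n           # degenerate: everything on one side
  cum_pos <- cumsum(y); cum_neg <- cumsum(!y)
  ks <- which(diff(score[ord]) > 0)    # splits between distinct values
  if (length(ks) == 0L) return(floor_acc)
  acc_pos_high <- ((P - cum_pos[ks]) + cum_neg[ks]) / n
  acc_pos_low <- (cum_pos[ks] + (N - cum_neg[ks])) / n
  max(c(acc_pos_high, acc_pos_low, floor_acc))
}

#' Evaluate an embedding against annotation
#'
#' Convenience wrapper returning the three reconstruction indices in one
#' report: OI (needs `layers`), and ASI / PSImcc (need `groups`,
#' computed on the angular coordinates with radii set to 1).
#'
#' @param coords samples x d coordinates (or a `dce_embedding`).
#' @param layers optional per-sample layer integers for OI.
#' @param domains optional per-sample domain tags for OI.
#' @param groups optional per-sample group labels for ASI/PSImcc.
#' @return a `metric_report`: list with `oi`, `oi_per_domain`, `asi`,
#'   `psimcc` (entries are `NA` when the matching annotation is absent).
#' @export
evaluate_embedding <- function(coords, layers = NULL, domains = NULL,
                               groups = NULL) {
  if (inherits(coords, "dce_embedding")) coords <- coords$cartesian
  coords <- as.matrix(coords)
  oi <- oi_dom <- NA
  if (!is.null(layers)) {
    o <- ordering_index(coords, layers, domains)
    oi <- o$overall; oi_dom <- o$per_domain
  }
  a <- p <- NA_real_
  if (!is.null(groups)) {
    nrm <- sqrt(rowSums(coords^2))
    unit <- coords / ifelse(nrm < 1e-12, 1, nrm)
    a <- asi(unit, groups)
    p <- psi_mcc(unit, groups)
  }
  structure(list(oi = oi, oi_per_domain = oi_dom, asi = a, psimcc = p),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("OI = %s  ASI = %s  PSImcc = %s\n",
              format(x$oi, digits = 4), format(x$asi, digits = 4),
              format(x$psimcc, digits = 4)))
  invisible(x)
}

#' Randomisation-normalised indices and max-rank strategy selection
#'
#' Each candidate embedding strategy is scored by OI (transformed to
#' `(1 + OI) / 2` so all indices share the \[0, 1\] range), ASI and
#' PSImcc; each index is normalised by subtracting the mean of `n_rand`
#' seeded label randomisations on the same coordinates.  Strategies are
#' ranked per index (1 = best) and the selection score of a strategy is
#' its maximum rank across the three indices — the strategy with the
#' lowest selection score (ties: alphabetical strategy name) wins.
#'
#' @param strategies named list; each element a list with `coords` plus
#'   the annotation used for scoring (`layers`, `domains`, `groups`, any
#'   subset, shared across strategies).
#' @param n_rand number of label randomisations (default 100).
#' @param seed RNG seed for the randomisations.
#' @return a `strategy_ranking`: data.frame with raw, normalised and
#'   rank columns plus `selection_score`, ordered best first.
#' @export
rank_strategies <- function(strategies, n_rand = 100L, seed = 1L) {
  stopifnot(is.list(strategies), length(names(strategies)) > 0)
  rows <- lapply(names(strategies), function(nm) {
    st <- strategies[[nm]]
    rep <- evaluate_embedding(st$coords, st$layers, st$domains, st$groups)
    base <- local_rng(seed, {
      b <- replicate(n_rand, {
        perm <- sample(nrow(as.matrix(st$coords)))
        r <- evaluate_embedding(st$coords,
                                if (!is.null(st$layers)) st$layers[perm],
                                if (!is.null(st$domains)) st$domains[perm],
                                if (!is.null(st$groups)) st$groups[perm])
        c(oi = if (is.na(r$oi[1])) NA_real_ else (1 + r$oi) / 2,
          asi = r$asi, psimcc = r$psimcc)
      })
      rowMeans(b)
    })
    data.frame(strategy = nm,
               oi = rep$oi, asi = rep$asi, psimcc = rep$psimcc,
               oi_norm = (1 + rep$oi) / 2 - base["oi"],
               asi_norm = rep$asi - base["asi"],
               psimcc_norm = rep$psimcc - base["psimcc"],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$strategy), ]
  for (ix in c("oi_norm", "asi_norm", "psimcc_norm")) {
    v <- df[[ix]]
    df[[sub("_norm", "_rank", ix)]] <- if (all(is.na(v))) NA_integer_ else
      rank(-v, ties.method = "min")
  }
  rks <- as.matrix(df[c("oi_rank", "asi_rank", "psimcc_rank")])
  df$selection_score <- apply(rks, 1L, max, na.rm = TRUE)
  df <- df[order(df$selection_score, df$strategy), ]
  rownames(df) <- NULL
  class(df) <- c("strategy_ranking", "data.frame")
  df
}

#' Rotation-search OI against a layered reference profile
#'
#' Searches orientations on a two-axis grid (rotations about the x and
#' y axes, step `pi/30` over \[0, 2*pi)); at each orientation the samples
#' are cut into `n_layers` equal-width bins along the rotated x axis, the
#' mean expression of a gene per bin is Spearman-correlated with the
#' supplied reference per-layer intensity profile, and the orientation
#' with the maximum correlation is returned.  Orientations leaving a bin
#' empty are skipped.
#'
#' @param coords samples x 3 coordinates.
#' @param reference_profile per-layer reference intensities (length
#'   `n_layers`).
#' @param gene_expr per-sample expression of the gene under test.
#' @param n_layers number of layers (default 10).
#' @param step angular step in radians (default `pi/30`).
#' @return list with `oi` (max Spearman correlation), `angles`
#'   (rx, ry in radians), `skipped` (number of skipped orientations).
#' @export
rotation_search_oi <- function(coords, reference_profile, gene_expr,
                               n_layers = 10L, step = pi / 30) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L,
            length(reference_profile) == n_layers,
            length(gene_expr) == nrow(coords))
  if (stats::sd(gene_expr) == 0) {
    warning("constant expression: rotation-search OI undefined, returning 0")
    return(list(oi = 0, angles = c(rx = 0, ry = 0), skipped = 0L))
  }
  ang <- seq(0, 2 * pi - step, by = step)
  best <- -Inf; best_ang <- c(rx = 0, ry = 0); skipped <- 0L
  for (a in ang) {
    ca <- cos(a); sa <- sin(a)
    # rotate about x: y' = ca*y - sa*z (x unchanged)
    y1 <- ca * coords[, 2L] - sa * coords[, 3L]
    z1 <- sa * coords[, 2L] + ca * coords[, 3L]
    for (b in ang) {
      cb <- cos(b); sb <- sin(b)
      xr <- cb * coords[, 1L] + sb * z1   # then about y: new x
      brk <- seq(min(xr), max(xr), length.out = n_layers + 1L)
      bin <- findInterval(xr, brk, rightmost.closed = TRUE)
      cnt <- tabulate(bin, n_layers)
      if (any(cnt == 0L)) { skipped <- skipped + 1L; next }
      prof <- vapply(seq_len(n_layers),
                     function(l) mean(gene_expr[bin == l]), numeric(1))
      r <- spearman0(prof, reference_profile)
      if (r > best) { best <- r; best_ang <- c(rx = a, ry = b) }
    }
  }
  if (!is.finite(best)) {
    warning("every orientation left an empty layer; returning 0")
    return(list(oi = 0, angles = c(rx = 0, ry = 0), skipped = skipped))
  }
  list(oi = best, angles = best_ang, skipped = skipped)
}

#' Spatial-domain dissection of a reconstruction
#'
#' k-means clustering of the reconstructed coordinates into putative
#' spatial domains, followed by ranking of domain-specific genes by the
#' log fold-change of mean expression inside versus outside each domain
#' (expression is assumed already log-scale, so the log fold-change is a
#' difference of means).
#'
#' @param coords samples x d coordinates.
#' @param k number of domains (>= 2); see [choose_k_elbow()] for a
#'   data-driven suggestion.
#' @param expr genes x samples expression matrix.
#' @param top_n genes reported per domain (default 500, or all if fewer).
#' @param seed k-means seed.
#' @return list with `clusters` (per-sample domain), `rankings` (one
#'   data.frame of `gene_id`, `lfc` per domain, ranked).
#' @export
domain_dissect <- function(coords, k, expr, top_n = 500L, seed = 1L) {
  coords <- as.matrix(coords)
  expr <- as_expression_matrix(expr)
  if (k < 2L) stop("'k' must be at least 2")
  if (k > nrow(coords)) stop("'k' exceeds the sample count")
  km <- local_rng(seed, stats::kmeans(coords, centers = k, nstart = 20L))
  cl <- km$cluster
  rankings <- lapply(seq_len(k), function(g) {
    inm <- rowMeans(expr[, cl == g, drop = FALSE])
    outm <- rowMeans(expr[, cl != g, drop = FALSE])
    lfc <- inm - outm
    ord <- order(-lfc)
    utils::head(data.frame(gene_id = rownames(expr)[ord], lfc = lfc[ord],
                           row.names = NULL, stringsAsFactors = FALSE),
                top_n)
  })
  names(rankings) <- paste0("domain", seq_len(k))
  list(clusters = cl, rankings = rankings)
}

#' Suggest k by the elbow of the within-cluster sum of squares
#'
#' @param coords samples x d coordinates.
#' @param k_max largest k scanned (default 8).
#' @param seed k-means seed.
#' @return suggested k (largest drop in marginal WSS reduction).
#' @export
choose_k_elbow <- function(coords, k_max = 8L, seed = 1L) {
  coords <- as.matrix(coords)
  k_max <- min(k_max, nrow(coords) - 1L)
  wss <- vapply(seq_len(k_max), function(k)
    local_rng(seed, stats::kmeans(coords, k, nstart = 10L))$tot.withinss,
    numeric(1))
  drops <- -diff(wss)
  which.max(-diff(drops)) + 1L
}

#' Best-match Jaccard agreement between two labellings
#'
#' For each cluster of `a`, the maximum Jaccard index against any cluster
#' of `b`; useful to compare k-means domains with reference domains.
#'
#' @param a,b per-sample labels.
#' @return named numeric vector, one best-match Jaccard per cluster of
#'   `a`.
#' @export
domain_jaccard <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  vapply(sort(unique(a)), function(ga) {
    ia <- a == ga
    max(vapply(unique(b), function(gb) {
      ib <- b == gb
      sum(ia & ib) / sum(ia | ib)
    }, numeric(1)))
  }, numeric(1))
}
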