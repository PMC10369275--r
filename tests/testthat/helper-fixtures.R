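# shared fixtures built in code

# small random expression matrix with named genes/samples
random_expr <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
         dimnames = list(paste0("g", seq_len(n_genes)),
                         paste0("s", seq_len(n_samples))))
}

# independent brute-force Pearson/Spearman pairwise distance oracle:
# explicit scalar loops, no call to the implementation under test
oracle_corr_distance <- function(expr, method = "pearson") {
  n <- ncol(expr)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- expr[, i]; b <- expr[, j]
    if (method == "spearman") { a <- rank(a); b <- rank(b) }
    am <- sum(a) / length(a); bm <- sum(b) / length(b)
    num <- sum((a - am) * (b - bm))
    den <- sqrt(sum((a - am)^2)) * sqrt(sum((b - bm)^2))
    d[i, j] <- 1 - num / den
  }
  diag(d) <- 0
  d
}

# brute-force CSI count straight from its definition
oracle_csi <- function(corr, delta = 0.05) {
  n <- nrow(corr)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    cnt <- 0
    for (k in seq_len(n))
      if (corr[i, k] < corr[i, j] - delta &&
          corr[j, k] < corr[i, j] - delta) cnt <- cnt + 1
    out[i, j] <- cnt / n
  }
  out
}

# exhaustive shortest-path oracle over all simple paths (tiny n only)
oracle_shortest_paths <- function(d, zero_absent = TRUE) {
  n <- nrow(d)
  adj <- function(i, j) if (zero_absent) d[i, j] > 0 else i != j
  best <- matrix(Inf, n, n); diag(best) <- 0
  walk <- function(path, len) {
    i <- path[1L]; j <- path[length(path)]
    if (len < best[i, j]) best[i, j] <<- len
    for (k in seq_len(n)) {
      if (k %in% path || !adj(j, k)) next
      walk(c(path, k), len + d[j, k])
    }
  }
  for (i in seq_len(n)) walk(i, 0)
  best
}

# exhaustive minimum-cost assignment over all permutations (square, tiny)
oracle_best_permutation <- function(cost) {
  n <- nrow(cost)
  perms <- permutations_of(n)
  costs <- vapply(perms, function(p) sum(cost[cbind(seq_len(n), p)]),
                  numeric(1))
  perms[[which.min(costs)]]
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in permutations_of(n - 1L))
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

# clean 1D line tissue for template-fitting tests: strong monotone
# gradients, negligible noise
line_tissue <- function(nx = 20, noise_sd = 0.01, seed = 1) {
  generate_grid_tissue(nx = nx, ny = 1, n_gradient = 20, n_lineage = 1,
                       n_noise = 1, noise_sd = noise_sd, lineage_effect = 0,
                       seed = seed)
}
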