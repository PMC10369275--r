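test_that("geodesic cost blocks follow the kNN graph structure", {
  # 4 collinear equally spaced points, k = 1: chain graph
  line <- cbind(c(0, 1, 2, 3), 0)
  g <- geodesic_cost_blocks(line, line, k = 1)
  expect_equal(g$C_s[1, 4], 3)
  # k = n - 1 on triangle-inequality-respecting points: plain Euclidean
  set.seed(1)
  pts <- matrix(rnorm(12), 6)
  gg <- geodesic_cost_blocks(pts, pts, k = 5)
  expect_equal(gg$C_s, as.matrix(dist(pts)), ignore_attr = TRUE)
  # 3x3 grid, k = 2 vs exhaustive enumeration oracle
  grid <- as.matrix(expand.grid(0:2, 0:2))
  gb <- geodesic_cost_blocks(grid, grid, k = 2)$C_t
  d <- as.matrix(dist(grid))
  adj <- matrix(0, 9, 9)
  for (i in 1:9) {
    nb <- order(d[i, ])[2:3]
    adj[i, nb] <- d[i, nb]; adj[nb, i] <- d[i, nb]
  }
  expect_equal(unname(gb), oracle_shortest_paths(adj), tolerance = 1e-12)

  far <- rbind(cbind(0:2, 0), cbind(0:2 + 100, 0))
  expect_error(geodesic_cost_blocks(far, far, k = 1), "disconnected")
})

test_that("structural cost reproduces the bilinear product", {
  C_s <- matrix(c(0, 1, 1, 0), 2)
  C_t <- matrix(c(0, 2, 2, 0), 2)
  expect_equal(structural_cost(C_s, C_t, c(0.5, 0.5), c(0.5, 0.5)),
               matrix(0.5, 2, 2))
  expect_equal(structural_cost(matrix(0, 2, 2), C_t, c(0.5, 0.5), c(0.5, 0.5)),
               matrix(0, 2, 2))
  # bilinearity in the weights
  set.seed(2)
  A <- as.matrix(dist(matrix(rnorm(8), 4)))
  B <- as.matrix(dist(matrix(rnorm(6), 3)))
  p <- runif(4); q <- runif(3)
  expect_equal(structural_cost(A, B, 2 * p, q),
               2 * structural_cost(A, B, p, q))
  expect_error(structural_cost(A, B, p, runif(4)), "mismatch")
})

test_that("marker cost is the max-normalised cross Euclidean distance", {
  expect_equal(marker_cost(cbind(c(0, 1)), cbind(c(0, 1))),
               matrix(c(0, 1, 1, 0), 2))
  set.seed(3)
  a <- matrix(rnorm(8), 4); b <- matrix(rnorm(6), 3)
  got <- marker_cost(a, b)
  hand <- matrix(0, 4, 3)
  for (i in 1:4) for (j in 1:3) hand[i, j] <- sqrt(sum((a[i, ] - b[j, ])^2))
  expect_equal(got, hand / max(hand), tolerance = 1e-12)
  expect_equal(max(got), 1)
  expect_warning(z <- marker_cost(matrix(1, 2, 1), matrix(1, 2, 1)),
                 "uninformative")
  expect_true(all(z == 0))
})

test_that("Sinkhorn satisfies marginals and known closed forms", {
  t1 <- sinkhorn_transport(matrix(1, 1, 1), 1, 1, epsilon = 0.1)
  expect_equal(t1$T, matrix(1, 1, 1), tolerance = 1e-9)

  # equal-row symmetric cost: uniform plan by symmetry
  t2 <- sinkhorn_transport(matrix(1, 2, 2), c(0.5, 0.5), c(0.5, 0.5), 0.3)
  expect_equal(t2$T, matrix(0.25, 2, 2), tolerance = 1e-9)

  set.seed(4)
  C <- matrix(runif(12), 3, 4)
  p <- rep(1 / 3, 3); q <- c(0.1, 0.2, 0.3, 0.4)
  pl <- sinkhorn_transport(C, p, q, 0.05)
  expect_lt(max(abs(rowSums(pl$T) - p)), 1e-6)
  expect_lt(max(abs(colSums(pl$T) - q)), 1e-6)
  expect_true(all(pl$T >= 0))
})

test_that("Sinkhorn + greedy matches the exhaustive assignment oracle on diagonal-favouring costs", {
  C <- matrix(1, 3, 3); diag(C) <- 0.05
  C[1, 2] <- 0.9
  pl <- sinkhorn_transport(C, rep(1 / 3, 3), rep(1 / 3, 3), epsilon = 0.01)
  expect_gt(sum(diag(pl$T)), 0.95)        # mass concentrates on the diagonal
  asn <- one_to_one_assign(pl, cost = C)
  expect_equal(asn$mapping, oracle_best_permutation(C))
  # sharpening: lower epsilon never increases the assignment cost
  costs <- sapply(c(0.5, 0.2, 0.1, 0.05, 0.02), function(e) {
    p <- sinkhorn_transport(C, rep(1 / 3, 3), rep(1 / 3, 3), epsilon = e)
    one_to_one_assign(p, cost = C)$total_cost
  })
  expect_true(all(diff(costs) <= 1e-9))
})

test_that("greedy one-to-one assignment follows the documented trace", {
  T1 <- matrix(c(0.6, 0.4, 0.3, 0.5), 2)   # [[0.6, 0.3], [0.4, 0.5]]
  asn <- one_to_one_assign(T1)
  expect_equal(asn$mapping, c(1L, 2L))
  # permutation-matrix plan: that exact permutation
  P <- matrix(0, 3, 3); P[cbind(1:3, c(2, 3, 1))] <- 1
  expect_equal(one_to_one_assign(P)$mapping, c(2L, 3L, 1L))
  # square plan: bijection
  set.seed(5)
  Tr <- matrix(runif(16), 4)
  expect_setequal(one_to_one_assign(Tr)$mapping, 1:4)
  expect_error(one_to_one_assign(matrix(runif(6), 3, 2)), "one-to-one")
})

test_that("scmap assignment takes row maxima with a deterministic tie rule", {
  Tm <- rbind(c(0.1, 0.7, 0.2), c(0.5, 0.2, 0.3))
  expect_equal(as.integer(scmap_assign(Tm)), c(2L, 1L))
  # two samples sharing a best position is allowed
  Tm2 <- rbind(c(0.1, 0.9), c(0.2, 0.8))
  expect_equal(as.integer(scmap_assign(Tm2)), c(2L, 2L))
  expect_warning(u <- scmap_assign(matrix(0.25, 1, 4)), "ties")
  expect_equal(as.integer(u), 1L)
})

test_that("an isometric 50-point cloud is recovered almost perfectly without markers", {
  set.seed(7)
  pts <- cbind(runif(50, 0, 2), runif(50))
  fit <- fit_template(pts, dce_template(pts))
  expect_gte(mean(fit$mapping == 1:50), 0.9)
})

test_that("template fitting recovers a line tissue, and a marker resolves the mirror", {
  tis <- line_tissue(nx = 20, seed = 1)
  emb <- dce_embed(tis$expr)
  tmpl <- dce_template(cbind(x = seq(0, 1, length.out = 20), y = 0),
                       marker_expression = cbind(mx = seq(0, 1, length.out = 20)))
  fit0 <- fit_template(emb, tmpl)
  oi0 <- cor(fit0$fitted_coords[, "x"], tis$true_coords[, "x"],
             method = "spearman")
  expect_equal(abs(oi0), 1)

  expr2 <- rbind(tis$expr, mx = tis$true_coords[, "x"])
  fit1 <- fit_template(emb, tmpl, markers = "mx", expr = expr2)
  oi1 <- cor(fit1$fitted_coords[, "x"], tis$true_coords[, "x"],
             method = "spearman")
  expect_equal(oi1, 1)
  expect_equal(fit1$used_markers, "mx")
})

test_that("template round-trips through TSV including marker columns", {
  tmpl <- dce_template(cbind(x = 1:4, y = c(0, 1, 0, 1)),
                       marker_expression = cbind(gx = c(1, 2, 3, 4)))
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(position_id = tmpl$position_ids, tmpl$positions,
                   `marker:gx` = tmpl$marker_expression[, "gx"],
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_template(path)
  expect_equal(back$positions, tmpl$positions, ignore_attr = TRUE)
  expect_equal(back$marker_expression[, "gx"], df$`marker:gx`,
               ignore_attr = TRUE)
})
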