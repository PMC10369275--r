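test_that("ordering index scores monotone and shuffled chains as documented", {
  # 5 layer centres in order on a line: OI = 1
  coords <- cbind(rep(1:5, each = 3) + rnorm(15, sd = 0.05), 0, 0)
  layers <- rep(1:5, each = 3)
  expect_equal(ordering_index(coords, layers)$overall, 1)

  # centres arranged so the chain visits 1, 3, 2, 4, 5: OI = 0.9
  centers <- c(0, 2, 1, 3, 4)      # layer i sits at centers[i]
  coords2 <- cbind(centers[rep(1:5, each = 2)], 0, 0)
  layers2 <- rep(1:5, each = 2)
  expect_equal(ordering_index(coords2, layers2)$overall, 0.9)

  # mirroring the coordinates changes nothing (distance-only chaining)
  expect_equal(ordering_index(-coords2, layers2)$overall, 0.9)

  # per-domain minimum
  dom <- rep(c("A", "P"), length.out = 15)
  oi <- ordering_index(coords, layers, dom)
  expect_equal(oi$overall, min(oi$per_domain))

  expect_error(ordering_index(coords, rep(c(1, 2, 4), 5)), "zero samples")
  expect_error(ordering_index(coords[1:6, ], rep(1:2, 3)), "3 layers")
})

test_that("ordering index is 1 for any monotone centroid chain (property)", {
  for (s in 1:5) {
    set.seed(s)
    L <- sample(3:11, 1)
    # strictly increasing centres along a random direction, noisy members
    gaps <- cumsum(runif(L, 1, 2))
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    centers <- outer(gaps, dir)
    coords <- centers[rep(1:L, each = 4), ] +
      matrix(rnorm(L * 12, sd = 0.01), L * 4)
    expect_equal(ordering_index(coords, rep(1:L, each = 4))$overall, 1)
  }
})

test_that("template OI is perfect on the truth and small on random coordinates", {
  # structured truth: axis bins have collinear centroids (10 distinct
  # values per axis so the 10 groups align with grid lines)
  true <- as.matrix(expand.grid(x = seq(0, 1, length.out = 10),
                                y = seq(0, 1, length.out = 10)))
  coords <- cbind(true, 0)
  oi <- template_oi(coords, true)
  expect_equal(unname(oi), c(1, 1))
  # permuting the reconstruction axes preserves the (absolute) OI
  oi_p <- template_oi(coords[, c(2, 1, 3)], true)
  expect_equal(abs(unname(oi_p)), c(1, 1))
  # random reconstructions: mean OI over seeds stays near the chain null
  # (the layer-1 anchor of the chaining step gives the null a small
  # positive offset, removed downstream by randomisation baselines)
  m <- mean(sapply(1:50, function(s) {
    set.seed(s)
    template_oi(matrix(rnorm(180), 60), true[1:60, ])[1]
  }))
  expect_lt(abs(m), 0.35)
  expect_error(template_oi(coords[1:5, ], true[1:5, ]), "fewer samples")
})

test_that("PSImcc matches hand-worked confusion tables", {
  # two well separated clusters: perfect separation
  coords <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 10), 10))
  groups <- rep(c("a", "b"), each = 10)
  expect_equal(psi_mcc(coords, groups), 1)

  # alternating clusters on a line, n1 = n2 = 2: MCC = 0
  inter <- cbind(c(1, 3, 2, 4), 0)
  expect_equal(psi_mcc(inter, c("a", "a", "b", "b")), 0)

  # one swapped sample out of 2 + 2: TP = TN = FP = FN = 1 -> 0
  swap <- cbind(1:4, 0)
  expect_equal(psi_mcc(swap, c("a", "b", "a", "b")), 0)

  # coincident anchors contribute 0 with a warning
  same <- rbind(diag(3), diag(3))
  expect_warning(v <- psi_mcc(same, rep(c("a", "b"), each = 3)),
                 "coincident")
  expect_equal(v, 0)
  expect_error(psi_mcc(coords, rep("a", 20)), "2 groups")
})

test_that("ASI is exact on antipodal clusters and degrades under shuffling", {
  set.seed(2)
  n <- 30
  up <- cbind(rnorm(n, 0, 0.1), rnorm(n, 0, 0.1), rnorm(n, 5, 0.1))
  dn <- -up
  coords <- rbind(up, dn)
  groups <- rep(c("top", "bottom"), each = n)
  expect_equal(asi(coords, groups), 1)

  # shuffled labels score lower than the true labels almost always
  tis <- generate_grid_tissue(nx = 6, ny = 6, noise_sd = 0.15, seed = 3)
  emb <- dce_embed(tis$expr)
  a0 <- asi(emb$cartesian, tis$domains)
  worse <- sum(sapply(1:100, function(s) {
    set.seed(s)
    asi(emb$cartesian, sample(tis$domains)) < a0
  }))
  expect_gte(worse, 95)

  # all samples at one angular position: floor = majority fraction
  one <- matrix(rep(c(1, 0, 0), each = 8), 8)
  expect_equal(asi(one, rep(c("a", "b"), 4)), 0.5)
  expect_error(asi(matrix(0, 4, 3), rep(c("a", "b"), 2)), "origin")
})

test_that("indices are invariant to rotation, reflection and scaling", {
  tis <- generate_grid_tissue(nx = 5, ny = 5, noise_sd = 0.1, seed = 4)
  emb <- dce_embed(tis$expr)
  a <- 0.7
  R <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  tr <- 3 * emb$cartesian %*% t(R)
  tr[, 1] <- -tr[, 1]                  # reflection
  expect_equal(asi(tr, tis$domains), asi(emb$cartesian, tis$domains),
               tolerance = 1e-9)
  expect_equal(psi_mcc(tr, tis$domains), psi_mcc(emb$cartesian, tis$domains),
               tolerance = 1e-9)
  expect_equal(ordering_index(tr, tis$layers)$overall,
               ordering_index(emb$cartesian, tis$layers)$overall)
})

test_that("strategy ranking rewards the all-index winner and normalises to chance", {
  set.seed(5)
  true <- cbind(runif(80), runif(80), 0)
  groups <- paste0("Q", 1 + (true[, 1] > 0.5) + 2 * (true[, 2] > 0.5))
  layers <- ceiling(rank(true[, 1]) / 8)
  good <- true + matrix(rnorm(240, sd = 0.02), 80)
  bad <- matrix(rnorm(240), 80)
  rk <- rank_strategies(list(good = list(coords = good, groups = groups,
                                         layers = layers),
                             bad = list(coords = bad, groups = groups,
                                        layers = layers)),
                        n_rand = 30, seed = 1)
  expect_equal(rk$strategy[1], "good")
  expect_equal(rk$selection_score[1], 1)
  # identical strategies tie and resolve by name order
  rk2 <- rank_strategies(list(b = list(coords = good, groups = groups),
                              a = list(coords = good, groups = groups)),
                         n_rand = 10, seed = 1)
  expect_equal(rk2$strategy, c("a", "b"))
  expect_equal(rk2$selection_score, c(1, 1))
  # randomised labels on a perfect embedding: normalised indices near 0
  # (averaged over draws; a single shuffle carries sampling noise)
  draws <- sapply(1:5, function(d) {
    set.seed(d)
    r <- rank_strategies(list(x = list(coords = good,
                                       groups = sample(groups),
                                       layers = sample(layers))),
                         n_rand = 40, seed = 2)
    c(r$asi_norm, r$psimcc_norm, r$oi_norm)
  })
  expect_lt(abs(mean(draws[1, ])), 0.1)
  expect_lt(abs(mean(draws[2, ])), 0.1)
  expect_lt(abs(mean(draws[3, ])), 0.15)
})

test_that("rotation-search OI finds the planted orientation and its reversal", {
  set.seed(7)
  tis <- generate_grid_tissue(nx = 8, ny = 8, noise_sd = 0, seed = 7)
  coords <- tis$true_coords + matrix(rnorm(192, sd = 1e-6), 64)
  gene <- tis$true_coords[, "x"]
  # reference: mean expression per equal-width x layer (8 layers = 8 grid
  # columns, so every layer is populated at the identity orientation)
  ref <- as.numeric(tapply(gene, tis$layers, mean))
  hit <- rotation_search_oi(coords, ref, gene, n_layers = 8)
  expect_equal(hit$oi, 1)
  expect_equal(unname(hit$angles), c(0, 0))   # identity scanned first
  # reversed reference: perfect only once the x axis is flipped
  rev_hit <- rotation_search_oi(coords, rev(ref), gene, n_layers = 8)
  expect_equal(rev_hit$oi, 1)
  expect_lt(cos(rev_hit$angles["ry"]), 0)     # a reversing rotation about y
  expect_warning(z <- rotation_search_oi(coords, ref, rep(1, 64),
                                         n_layers = 8), "constant")
  expect_equal(z$oi, 0)
})

test_that("domain dissection recovers planted domains and ranks their genes first", {
  set.seed(8)
  n <- 40
  coords <- rbind(cbind(rnorm(n / 2, 0, 0.2), 0, 0),
                  cbind(rnorm(n / 2, 5, 0.2), 0, 0))
  expr <- matrix(rnorm(20 * n, sd = 0.1), 20, n,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:n)))
  expr[1:3, 1:(n / 2)] <- expr[1:3, 1:(n / 2)] + 2       # domain-1 markers
  expr[4:6, (n / 2 + 1):n] <- expr[4:6, (n / 2 + 1):n] + 2
  dd <- domain_dissect(coords, k = 2, expr)
  truth <- rep(c(1, 2), each = n / 2)
  expect_equal(unname(domain_jaccard(dd$clusters, truth)), c(1, 1))
  planted <- list(c("g1", "g2", "g3"), c("g4", "g5", "g6"))
  for (cl in 1:2) {
    top3 <- dd$rankings[[cl]]$gene_id[1:3]
    expect_true(setequal(top3, planted[[1]]) || setequal(top3, planted[[2]]))
  }
  expect_error(domain_dissect(coords, k = 1, expr), "at least 2")
  # zero log fold-change ranks last
  flat <- domain_dissect(coords, k = 2, expr)
  expect_equal(nrow(flat$rankings[[1]]), 20)
})
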