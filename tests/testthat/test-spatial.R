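# Neighbor graphs, Moran's I, local diversity, the fitness proxy, and
# pairwise distance tables.

pos_table <- function(x, y, section = NULL, ids = NULL) {
  dt <- data.table::data.table(
    cell = ids %||% paste0("c", seq_along(x)), x_um = x, y_um = y)
  if (!is.null(section)) dt$section <- section
  dt
}

test_that("spatial graphs respect radius and sections", {
  pos <- pos_table(c(0, 50, 200), c(0, 0, 0))
  W <- build_neighbor_graph("spatial", positions = pos, parameter = 100)
  expect_equal(sum(W), 2) # only the 0-50 pair, both directions
  expect_true(W["c1", "c2"] == 1 && W["c1", "c3"] == 0)
  pos2 <- pos_table(c(0, 10), c(0, 0), section = c("s1", "s2"))
  W2 <- build_neighbor_graph("spatial", positions = pos2, parameter = 100)
  expect_equal(sum(W2), 0) # cross-section pairs excluded
})

test_that("phylogenetic graphs use the shared-ancestor window", {
  # cherry merged 2 days ago; other clade split 20 days ago
  phy <- ape::read.tree(text = "((a:2,b:2):18,(c:20,d:20):0);")
  W <- build_neighbor_graph("phylo", tree = phy, parameter = 10)
  expect_equal(unname(W["a", "b"]), 1)
  expect_equal(unname(W["c", "d"]), 0)
  expect_equal(unname(W["a", "c"]), 0)
  expect_true(Matrix::isSymmetric(W))
  expect_true(all(Matrix::diag(W) == 0))
})

test_that("Moran's I matches the formula and the double-loop oracle", {
  # two cliques with +1 / -1 values: maximal clustering, I = 1
  W <- Matrix::bdiag(matrix(1, 5, 5) - diag(5), matrix(1, 5, 5) - diag(5))
  dimnames(W) <- list(paste0("c", 1:10), paste0("c", 1:10))
  x <- rep(c(1, -1), each = 5)
  res <- morans_i(x, W, n_perm = 99, seed = 1)
  expect_equal(res$morans_i, 1)
  expect_lt(res$p_value, 0.05)

  # vectorized equals the naive double loop on random graphs
  set.seed(91)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    A <- matrix(rbinom(n * n, 1, 0.15), n, n)
    A <- pmax(A, t(A)); diag(A) <- 0
    if (sum(A) == 0) next
    Wr <- Matrix::Matrix(A, sparse = TRUE)
    x <- rnorm(n)
    got <- morans_i(x, Wr, n_perm = 19, seed = rep)$morans_i
    expect_equal(got, oracle_morans_i(x, A), tolerance = 1e-12)
  }

  # permutation-null mean of I is -1/(N-1)
  set.seed(92)
  n <- 40
  A <- matrix(rbinom(n * n, 1, 0.2), n, n); A <- pmax(A, t(A)); diag(A) <- 0
  x <- rnorm(n)
  z <- x - mean(x)
  perm_I <- replicate(2000, {
    zp <- sample(z)
    n / sum(A) * (zp %*% A %*% zp) / sum(zp^2)
  })
  expect_lt(abs(mean(perm_I) - (-1 / (n - 1))), 0.01)

  # constant feature is NA
  resc <- morans_i(cbind(const = rep(1, 10), ok = rnorm(10)),
                   W, n_perm = 19, seed = 3)
  expect_true(is.na(resc$morans_i[1]))
  expect_false(is.na(resc$morans_i[2]))
})

test_that("heritable traits show phylogenetic autocorrelation", {
  se <- sim_experiment(n_cells = 60, n_sites = 30, seed = 17)
  W <- build_neighbor_graph("phylo", tree = se$tree,
                            parameter = 0.5 * max(edittrace:::node_times(se$tree)))
  # trait = membership of one deep clade (heritable by construction)
  dt <- edittrace:::descendant_tips(se$tree)
  clade_tips <- se$tree$tip.label[dt[[ape::Ntip(se$tree) + 2L]]]
  trait <- as.numeric(rownames(W) %in% clade_tips)
  res <- morans_i(trait, W, n_perm = 199, seed = 4)
  expect_gt(res$morans_i, 0.2)
  expect_lt(res$p_value, 0.05)
})

test_that("local diversity is zero for clones, NA for isolates, oracle-exact", {
  cm <- character_matrix(matrix(rep(c(1L, 2L, 3L), each = 5), 5, 3), 8)
  pos <- pos_table(runif(5, 0, 50), runif(5, 0, 50),
                   ids = rownames(cm))
  div <- local_lm_diversity(cm, pos, radius = 100)
  expect_equal(unname(div), rep(0, 5))

  pos_iso <- pos_table(c(0, 500, 1000), c(0, 0, 0))
  cm3 <- character_matrix(matrix(sample(0:3, 9, TRUE), 3, 3,
                                 dimnames = list(pos_iso$cell, NULL)), 8)
  expect_true(all(is.na(local_lm_diversity(cm3, pos_iso, radius = 100))))

  set.seed(93)
  cm_r <- character_matrix(matrix(sample(0:4, 60, TRUE), 12, 5), 8)
  pos_r <- pos_table(runif(12, 0, 300), runif(12, 0, 300),
                     ids = rownames(cm_r))
  div_r <- local_lm_diversity(cm_r, pos_r, radius = 120)
  d <- weighted_hamming_matrix(cm_r)
  dsp <- as.matrix(dist(cbind(pos_r$x_um, pos_r$y_um)))
  for (i in 1:12) {
    nb <- which(dsp[i, ] <= 120)
    if (length(nb) < 2) expect_true(is.na(div_r[i]))
    else {
      sub <- d[nb, nb]
      expect_equal(unname(div_r[i]), mean(sub[upper.tri(sub)]))
    }
  }
})

test_that("the fitness proxy matches brute-force kNN and is zero on clones", {
  cm_same <- character_matrix(matrix(1L, 21, 4), 8)
  expect_equal(unname(mean_neighbor_lm_distance(cm_same, k = 20)),
               rep(0, 21))

  set.seed(94)
  cm_r <- character_matrix(matrix(sample(0:5, 150, TRUE), 30, 5), 8)
  got <- mean_neighbor_lm_distance(cm_r, k = 7)
  d <- weighted_hamming_matrix(cm_r)
  for (i in 1:30) {
    v <- sort(d[i, -i])[1:7]
    expect_equal(unname(got[i]), mean(v))
  }
})

test_that("recently expanded clades score fitter on the proxy", {
  wins <- 0L
  for (seed in 1:10) {
    se <- sim_experiment(n_cells = 60, n_sites = 40, seed = seed + 600)
    tm <- edittrace:::node_times(se$tree)
    dt <- edittrace:::descendant_tips(se$tree)
    ntip <- ape::Ntip(se$tree)
    internals <- (ntip + 1L):(ntip + se$tree$Nnode)
    sizes <- lengths(dt[internals])
    cands <- internals[sizes >= 8 & sizes <= 30]
    if (length(cands) < 2) next
    # fast clade: recent common ancestor; slow clade: old one
    fast <- cands[which.max(tm[cands])]
    slow <- cands[which.min(tm[cands])]
    prox <- mean_neighbor_lm_distance(se$cm, k = 7)
    f_fast <- mean(prox[se$tree$tip.label[dt[[fast]]]])
    f_slow <- mean(prox[se$tree$tip.label[setdiff(dt[[slow]], dt[[fast]])]])
    wins <- wins + (f_fast < f_slow)
  }
  expect_gte(wins, 6L)
})

test_that("pairwise distance tables cover all pairs and use path lengths", {
  phy <- ape::read.tree(text = "((a:2,b:3):1,c:4);")
  cm <- cm_from_rows(list(a = c(1L, 0L), b = c(1L, 2L), c = c(0L, 3L)))
  pos <- pos_table(c(0, 30, 400), c(0, 40, 0), ids = c("a", "b", "c"))
  tab <- pairwise_distance_table(phy, cm, pos, n_pairs = 100, seed = 1)
  expect_equal(nrow(tab), 3L) # all pairs emitted once
  ab <- tab[(cell1 == "a" & cell2 == "b") | (cell1 == "b" & cell2 == "a")]
  expect_equal(ab$phylo_dist, 2 + 3) # cherry: sum of terminal branches
  expect_equal(ab$spatial_dist, 50)
  expect_false(anyDuplicated(tab[, .(pmin(cell1, cell2), pmax(cell1, cell2))]) > 0)
})

test_that("phylogenetic and spatial distance correlate under diffusion", {
  wins <- 0L
  for (seed in 1:10) {
    se <- sim_experiment(n_cells = 50, n_sites = 40, seed = seed + 700)
    # diffusion-coupled positions: each division displaces the daughter
    phy <- se$tree
    tm <- edittrace:::node_times(phy)
    nn <- ape::Ntip(phy) + phy$Nnode
    xy <- matrix(0, nn, 2)
    set.seed(seed)
    ord <- order(edittrace:::node_depths(phy)[phy$edge[, 1]])
    for (i in ord) {
      p <- phy$edge[i, 1]; v <- phy$edge[i, 2]
      xy[v, ] <- xy[p, ] + rnorm(2, 0, 10 * sqrt(phy$edge.length[i] + 0.01))
    }
    pos <- pos_table(xy[1:50, 1], xy[1:50, 2], ids = phy$tip.label)
    tab <- pairwise_distance_table(phy, se$cm, pos, n_pairs = 800,
                                   seed = seed)
    r_real <- cor(tab$phylo_dist, tab$spatial_dist, method = "spearman")
    r_shuf <- cor(tab$phylo_dist, tab$shuffled_spatial_dist,
                  method = "spearman")
    wins <- wins + (r_real > r_shuf)
  }
  expect_gte(wins, 9L)
})

test_that("fitness correlations flag planted effects and spare nulls", {
  set.seed(95)
  fit <- rnorm(300)
  feats <- data.frame(self = fit, noise = rnorm(300),
                      anti = -fit + rnorm(300, 0, 0.5))
  res <- fitness_feature_correlation(fit, feats)
  expect_equal(res[feature == "self", r], 1, tolerance = 1e-12)
  expect_lt(abs(res[feature == "noise", r]), 0.15)
  expect_lt(res[feature == "anti", r], 0)
  expect_lt(res[feature == "anti", q_value], 0.05)
  expect_error(fitness_feature_correlation(c(1, 2), data.frame(a = c(1, 2))),
               class = "invalid_argument")
})
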