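# Sankoff ancestral states, branch collapse, branch-length estimation,
# LCA timing, extant counts, and installation efficiencies.

test_that("Sankoff handles the canonical small cases", {
  costs <- transition_costs(3)
  # cherry (unedited, LM1): unedited parent costs 0.6, LM1 parent costs 1
  phy <- ape::read.tree(text = "(a:1,b:1);")
  cm <- cm_from_rows(list(a = 0L, b = 1L), n_marks = 3)
  res <- sankoff_ancestral_states(phy, cm, costs)
  expect_equal(unname(res$states[3, 1]), 0L)
  expect_equal(res$total_cost, 0.6)

  # all leaves LM3 under a fixed unedited root: the cherry ancestor takes
  # LM3 (one 0.6 installation) and the directly attached leaf needs its
  # own installation, so the exhaustive minimum is 1.2
  phy3 <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  cm3 <- cm_from_rows(list(a = 3L, b = 3L, c = 3L), n_marks = 3)
  res3 <- sankoff_ancestral_states(phy3, cm3, costs)
  expect_equal(res3$total_cost, 1.2)
  expect_equal(res3$total_cost, oracle_sankoff_cost(phy3, cm3, costs))
  expect_true(all(res3$states[5, ] == 3L))

  # missing leaves are free
  cmna <- cm_from_rows(list(a = 3L, b = NA_integer_, c = 3L), n_marks = 3)
  resna <- sankoff_ancestral_states(phy3, cmna, costs)
  expect_equal(resna$total_cost, 1.2)
})

test_that("Sankoff total cost equals the exhaustive minimum", {
  set.seed(41)
  for (rep in 1:6) {
    n <- sample(4:6, 1)
    phy <- random_tree(n)
    S <- 3L
    m <- matrix(sample(c(NA_integer_, 0:S), n * 2, replace = TRUE,
                       prob = c(0.15, rep(0.85 / (S + 1), S + 1))), n, 2)
    rownames(m) <- phy$tip.label
    cm <- character_matrix(m, S)
    costs <- transition_costs(S)
    got <- sankoff_ancestral_states(phy, cm, costs)
    expect_equal(got$total_cost, oracle_sankoff_cost(phy, cm, costs))
  }
})

test_that("collapse removes exactly the unsupported edges", {
  # hand fixture: 6 leaves; one internal edge gains nothing
  phy <- ape::read.tree(text = "(((a:1,b:1):1,(c:1,d:1):1):1,(e:1,f:1):2);")
  cm <- cm_from_rows(list(a = c(1L, 2L), b = c(1L, 2L), c = c(1L, 3L),
                          d = c(1L, 3L), e = c(4L, 0L), f = c(5L, 0L)),
                     n_marks = 8)
  res <- sankoff_ancestral_states(phy, cm)
  col <- collapse_unsupported_branches(phy, res$states)
  # every surviving internal edge carries at least one state change
  par <- edittrace:::tree_parents(col$tree)
  ntip <- ape::Ntip(col$tree)
  for (v in seq_len(ntip + col$tree$Nnode)) {
    if (v <= ntip || par[v] == 0L) next
    expect_false(identical(col$states[v, ], col$states[par[v], ]))
  }
  expect_setequal(col$tree$tip.label, phy$tip.label)
  # collapsing is idempotent
  col2 <- collapse_unsupported_branches(col$tree, col$states)
  expect_equal(col2$tree$Nnode, col$tree$Nnode)
  expect_equal(normalized_rf(col2$tree, col$tree), 0)
})

test_that("star-like data collapses to a single multifurcation", {
  phy <- ape::read.tree(text = "(((a:1,b:1):1,c:1):1,d:1);")
  ntip <- 4L
  # identical state vectors everywhere: no internal edge is supported
  states <- matrix(0L, ntip + phy$Nnode, 2)
  col <- collapse_unsupported_branches(phy, states)
  expect_equal(col$tree$Nnode, 1L)
})

test_that("branch-length estimation follows the closed form and rescales", {
  # u = 10 unedited parent sites, k = 5 edited: raw = ln(2) / rate
  phy <- ape::read.tree(text = "(a:1,b:1);")
  states <- rbind(a = c(rep(1L, 5), rep(0L, 5)),
                  b = rep(0L, 10),
                  root = rep(0L, 10))
  states <- states[c("a", "b", "root"), ]
  timed <- estimate_branch_lengths(phy, states, rate = 0.1, total_time = 10)
  raw_a <- -log(1 - 5 / 10) / 0.1        # 6.93 days before rescaling
  tm <- edittrace:::node_times(timed)
  expect_equal(mean(tm[1:2]), 10, tolerance = 1e-9) # rescaling anchor
  # the no-edit edge carries no evidence of elapsed time
  expect_equal(timed$edge.length[2], 0)
  expect_equal(timed$edge.length[1], 20) # mean of (20, 0) is total_time
  expect_error(estimate_branch_lengths(phy, states, 0.1, 0),
               class = "invalid_argument")
})

test_that("estimated durations correlate with true durations", {
  rhos <- c()
  for (seed in 1:6) {
    se <- sim_experiment(n_cells = 50, n_sites = 40, seed = seed + 40)
    truth_tm <- edittrace:::node_times(se$tree)
    total <- max(truth_tm)
    rate <- edit_rate_for_target_fraction(0.7, total)
    timed <- estimate_branch_lengths(se$tree, se$states, rate, total)
    rho <- suppressWarnings(
      cor(se$tree$edge.length, timed$edge.length, method = "spearman"))
    rhos <- c(rhos, rho)
  }
  expect_gt(median(rhos), 0.5)
})

test_that("LCA timing reads off node times", {
  # balanced depth-16 fixture: cherry parent at 15
  phy <- ape::read.tree(text = "(((a:1,b:1):14,c:15):1,d:16);")
  expect_equal(lca_timing(phy, c("a", "b")), 16 - 1)
  expect_equal(lca_timing(phy, c("a", "b", "c", "d")), 0)
})

test_that("planted barcode rounds are timed in the right order", {
  hits <- 0L
  for (seed in 1:10) {
    se <- sim_experiment(n_cells = 60, n_sites = 40, seed = seed + 300)
    total <- max(edittrace:::node_times(se$tree))
    g_early <- plant_barcode_groups(se$tree, 0.3 * total)
    g_late <- plant_barcode_groups(se$tree, 0.6 * total)
    phy <- reconstruct_nj(se$cm)
    sank <- sankoff_ancestral_states(phy, se$cm)
    col <- collapse_unsupported_branches(phy, sank$states)
    rate <- edit_rate_for_target_fraction(0.7, total)
    timed <- estimate_branch_lengths(col$tree, col$states, rate, total)
    t_early <- mean(vapply(g_early, function(g) lca_timing(timed, g),
                           numeric(1)))
    t_late <- mean(vapply(g_late, function(g) lca_timing(timed, g),
                          numeric(1)))
    hits <- hits + (t_early < t_late)
  }
  expect_gte(hits, 9L)
})

test_that("extant counts cut the tree correctly", {
  phy <- ape::read.tree(text = "((a:2,b:2):2,(c:3,d:3):1);")
  phy$root.edge <- 1
  # times: root at 1; internal nodes at 3 and 2; tips at 5 and 5... tips: a,b at 5; c,d at 5
  ec <- extant_counts(phy, c(0, 1.5, 2.5, 3.5, 5))
  expect_equal(ec$count, c(1L, 2L, 3L, 4L, 4L))
  expect_error(extant_counts(phy, 99), class = "invalid_argument")

  # pure-birth growth is log-linear in time
  yule <- simulate_birth_death(80, death_rate = 0, seed = 51)
  tmax <- max(edittrace:::node_times(yule))
  ts <- seq(0.2 * tmax, 0.95 * tmax, length.out = 12)
  ec2 <- extant_counts(yule, ts)
  fit <- stats::lm(log(ec2$count) ~ ts)
  expect_gt(summary(fit)$r.squared, 0.9)
  # counts nondecreasing for pure birth
  expect_true(all(diff(ec2$count) >= 0))
})

test_that("installation efficiencies recover the mark distribution", {
  probs <- lm_distribution_for_entropy(8, 0.95)
  # big single-generation tree: ~2000 independent installation draws
  n <- 50
  phy <- ape::read.tree(text = paste0(
    "(", paste(sprintf("t%d:1", seq_len(n)), collapse = ","), ");"))
  ov <- overlay_lineage_marks(phy, 60, probs, edit_rate = 0.6, seed = 8)
  eff <- lm_installation_efficiency(phy, ov$states, 8)
  expect_equal(unname(rowSums(eff)), rep(1, 60), tolerance = 1e-12)
  pooled <- colSums(eff) / sum(eff)
  expect_true(all(abs(pooled - probs) < 0.05))

  # a site where only LM2 is installed is a point mass
  phy3 <- ape::read.tree(text = "(x:1,y:1,z:1);")
  st <- matrix(c(2L, 2L, 2L, 0L), 4, 1)
  eff2 <- lm_installation_efficiency(phy3, st, 4)
  expect_equal(unname(eff2[1, ]), c(0, 1, 0, 0))
})
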