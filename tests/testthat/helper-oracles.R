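# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (flood fills, exhaustive enumeration) so they share no
# code path with the package implementations they check.

# random binary rooted tree over n tips, optionally with random branch
# lengths and a fraction of internal edges collapsed into multifurcations
random_tree <- function(n, lengths = TRUE, collapse_frac = 0) {
  phy <- ape::rtree(n, rooted = TRUE)
  phy$tip.label <- paste0("t", seq_len(n))
  if (!lengths) phy$edge.length <- NULL
  if (collapse_frac > 0 && !is.null(phy$edge.length)) {
    internal <- which(phy$edge[, 2L] > ape::Ntip(phy))
    kill <- internal[runif(length(internal)) < collapse_frac]
    if (length(kill)) {
      phy$edge.length[kill] <- 0
      phy <- ape::di2multi(phy, tol = 1e-12)
    }
  }
  phy
}

# --- RF oracle: splits by removing each edge and flood-filling -------------

oracle_splits <- function(phy) {
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  adj <- vector("list", nn)
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1L]; b <- phy$edge[i, 2L]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  ref <- sort(phy$tip.label)
  keys <- character(0)
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1L]; b <- phy$edge[i, 2L]
    # flood fill from b avoiding the removed edge
    seen <- rep(FALSE, nn); seen[b] <- TRUE; queue <- b
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if ((v == a && w == b) || (v == b && w == a)) next
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    side <- sort(match(phy$tip.label[which(seen[seq_len(ntip)])], ref))
    if (length(side) < 2L || length(side) > ntip - 2L) next
    if (1L %in% side) side <- setdiff(seq_len(ntip), side)
    keys <- c(keys, paste(side, collapse = ","))
  }
  unique(keys)
}

oracle_rf <- function(t1, t2) {
  s1 <- oracle_splits(t1); s2 <- oracle_splits(t2)
  tot <- length(s1) + length(s2)
  if (tot == 0) return(0)
  (length(setdiff(s1, s2)) + length(setdiff(s2, s1))) / tot
}

# --- triplet oracle: prune to 3 tips, inspect the pruned topology ----------

oracle_out_taxon <- function(phy, trip_labels) {
  sub <- ape::keep.tip(phy, trip_labels)
  root <- ape::Ntip(sub) + 1L
  kids <- sub$edge[sub$edge[, 1L] == root, 2L]
  if (length(kids) >= 3L) return(NA_character_) # unresolved
  tipkid <- kids[kids <= ape::Ntip(sub)]
  if (length(tipkid) != 1L) return(NA_character_)
  sub$tip.label[tipkid]
}

oracle_triplets_all <- function(truth, recon) {
  tips <- truth$tip.label
  combs <- utils::combn(tips, 3L)
  ok <- vapply(seq_len(ncol(combs)), function(i) {
    a <- oracle_out_taxon(truth, combs[, i])
    b <- oracle_out_taxon(recon, combs[, i])
    identical(a, b) # both NA (unresolved) counts as correct
  }, logical(1))
  mean(ok)
}

# --- Sankoff oracle: exhaustive minimum over internal assignments ----------

oracle_sankoff_cost <- function(phy, cm, costs) {
  m <- unclass(cm)[phy$tip.label, , drop = FALSE]
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  internals <- (ntip + 1L):nn
  root <- ntip + 1L
  k <- nrow(costs)
  total <- 0
  for (site in seq_len(ncol(m))) {
    best <- Inf
    grid <- rep(list(seq_len(k)), length(internals))
    combos <- do.call(expand.grid, grid)
    for (ci in seq_len(nrow(combos))) {
      asg <- as.integer(combos[ci, ])
      names(asg) <- internals
      if (asg[as.character(root)] != 1L) next # root fixed unedited
      cost <- 0
      for (e in seq_len(nrow(phy$edge))) {
        p <- phy$edge[e, 1L]; v <- phy$edge[e, 2L]
        sp <- asg[as.character(p)]
        sv <- if (v <= ntip) {
          obs <- m[v, site]
          if (is.na(obs)) NA_integer_ else obs + 1L
        } else asg[as.character(v)]
        if (is.na(sv)) next # missing leaf: zero cost for any state
        cost <- cost + costs[sp, sv]
      }
      best <- min(best, cost)
    }
    total <- total + best
  }
  total
}

# --- Moran's I oracle: literal double loop ---------------------------------

oracle_morans_i <- function(x, W) {
  N <- length(x)
  z <- x - mean(x)
  s0 <- 0; num <- 0
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      s0 <- s0 + W[i, j]
      num <- num + W[i, j] * z[i] * z[j]
    }
  }
  N / s0 * num / sum(z^2)
}

# --- misc fixtures ---------------------------------------------------------

cm_from_rows <- function(rows, n_marks = 8L) {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows) %||% paste0("c", seq_along(rows))
  character_matrix(m, n_marks)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# default study-condition simulation used across tests: one experiment of
# the kind the recorder targets (S = 8 marks, Hnorm 0.95, F = 0.7)
sim_experiment <- function(n_cells = 50, n_sites = 40, detection = 1,
                           hnorm = 1, target_fraction = 0.7, seed = 1) {
  phy <- simulate_birth_death(n_cells, seed = derive_seed(seed, "tree"),
                              max_retries = 50L)
  probs <- lm_distribution_for_entropy(8L, hnorm)
  ov <- overlay_lineage_marks(phy, n_sites, probs,
                              target_fraction = target_fraction,
                              seed = derive_seed(seed, "marks"))
  cm <- if (detection < 1) {
    apply_detection_dropout(ov$cm, detection,
                            seed = derive_seed(seed, "dropout"))
  } else ov$cm
  list(tree = phy, truth_cm = ov$cm, cm = cm, states = ov$states,
       lm_probs = probs)
}
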