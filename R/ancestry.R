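# Ancestral lineage-mark inference (Sankoff parsimony with asymmetric
# costs), collapse of unsupported branches, constant-rate branch-length
# estimation, LCA timing, extant-lineage counting over time, and
# installation-efficiency estimation.

#' Asymmetric transition costs for ancestral-state inference
#'
#' Identity transitions cost 0; installing a mark at an unedited site costs
#' 0.6; reversing a mark or switching between marks costs 1. Installation is
#' cheaper than reversal because editing is irreversible in the recorder,
#' while mark-to-mark "transitions" only arise from readout noise or
#' reconstruction error.
#'
#' @param install Cost of unedited -> mark (default 0.6).
#' @param other Cost of mark -> unedited or mark -> different mark
#'   (default 1).
#' @param n_marks Mark alphabet size `S`.
#' @return An `(S+1) x (S+1)` cost matrix, rows = parent state (unedited
#'   first), columns = child state.
#' @export
transition_costs <- function(n_marks, install = 0.6, other = 1) {
  stopifnot(install >= 0, other >= 0)
  k <- n_marks + 1L
  cst <- matrix(other, k, k)
  diag(cst) <- 0
  cst[1L, ] <- c(0, rep(install, n_marks))
  dimnames(cst) <- list(0:n_marks, 0:n_marks)
  cst
}

#' Infer ancestral lineage-mark states by Sankoff parsimony
#'
#' Per edit site, a dynamic program over the state alphabet
#' {unedited, mark 1..S} minimizes the total transition cost over the tree.
#' Missing leaves contribute zero cost for every state. The root is
#' constrained to the all-unedited state (cells start unedited at day 0);
#' ties in the top-down backtrace resolve toward unedited, then the lowest
#' mark index.
#'
#' @param phy Rooted `phylo` tree whose tips match the rows of `cm`.
#' @param cm A [character_matrix()] covering all tips.
#' @param costs Cost matrix from [transition_costs()]; default costs.
#' @return A list with `states` (node x site integer matrix, phylo node
#'   numbering) and `total_cost` (summed over sites).
#' @export
sankoff_ancestral_states <- function(phy, cm, costs = NULL) {
  if (!all(phy$tip.label %in% rownames(cm))) {
    stop2("leaf_mismatch", "character matrix does not cover all tips")
  }
  S <- n_marks(cm)
  k <- S + 1L
  costs <- costs %||% transition_costs(S)
  stopifnot(nrow(costs) == k, ncol(costs) == k)
  m <- cm_data(cm)[phy$tip.label, , drop = FALSE]
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  M <- ncol(m)
  ch <- tree_children(phy)
  pre <- preorder_internal(phy)
  root <- tree_root(phy)

  # bottom-up cost tables: cost[node, state, site]
  C <- array(0, c(nn, k, M))
  for (v in seq_len(ntip)) {
    obs <- m[v, ]
    tab <- matrix(Inf, k, M)
    tab[cbind(ifelse(is.na(obs), 1L, obs + 1L), seq_len(M))] <- 0
    tab[, is.na(obs)] <- 0
    C[v, , ] <- tab
  }
  for (v in rev(pre)) {
    acc <- matrix(0, k, M)
    for (w in ch[[v]]) {
      cw <- C[w, , , drop = FALSE]
      dim(cw) <- c(k, M)
      # min over child state t of costs[s, t] + C_w[t, m], for each s
      best <- matrix(Inf, k, M)
      for (t in seq_len(k)) {
        cand <- outer(costs[, t], cw[t, ], "+")
        best <- pmin(best, cand)
      }
      acc <- acc + best
    }
    C[v, , ] <- acc
  }

  states <- matrix(NA_integer_, nn, M)
  states[root, ] <- 0L  # all-unedited root convention
  rootC <- C[root, , , drop = FALSE]; dim(rootC) <- c(k, M)
  total_cost <- sum(rootC[1L, ])
  for (v in pre) {
    for (w in ch[[v]]) {
      cw <- C[w, , , drop = FALSE]; dim(cw) <- c(k, M)
      ps <- states[v, ] + 1L
      scores <- costs[ps, , drop = FALSE] + t(cw)  # site x state
      pick <- max.col(-scores, ties.method = "first") # ties -> lowest index
      states[w, ] <- pick - 1L
    }
  }
  states[seq_len(ntip), ] <- ifelse(is.na(m), states[seq_len(ntip), ], m)
  colnames(states) <- colnames(m)
  list(states = states, total_cost = total_cost)
}

#' Collapse branches unsupported by any lineage mark
#'
#' Scans edges deepest-first; an edge whose parent and (internal) child have
#' identical inferred state vectors is removed, connecting the child's
#' children directly to the grandparent. The result may be multifurcating;
#' leaves are never removed.
#'
#' @param phy Rooted `phylo` tree.
#' @param states Node x site state matrix as from
#'   [sankoff_ancestral_states()].
#' @return A list with `tree` (collapsed `phylo`) and `states` (matrix
#'   re-indexed to the collapsed tree's node numbering).
#' @export
collapse_unsupported_branches <- function(phy, states) {
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  stopifnot(nrow(states) == nn)
  par <- tree_parents(phy)
  depth <- node_depths(phy)
  keep <- rep(TRUE, nn)
  internals <- setdiff(seq_len(nn), seq_len(ntip))
  root <- tree_root(phy)
  for (v in internals[order(depth[internals], decreasing = TRUE)]) {
    if (v == root) next
    if (identical(states[v, ], states[par[v], ])) keep[v] <- FALSE
  }
  # reattach children of removed nodes to their nearest kept ancestor
  eff_par <- par
  for (v in seq_len(nn)) {
    if (v == root) next
    p <- eff_par[v]
    while (p != root && !keep[p]) p <- par[p]
    eff_par[v] <- p
  }
  kept <- which(keep)
  kept_int <- setdiff(kept, seq_len(ntip))
  kept_int <- kept_int[order(depth[kept_int])]
  num <- integer(nn)
  num[seq_len(ntip)] <- seq_len(ntip)
  num[kept_int] <- ntip + seq_along(kept_int)
  edges <- cbind(num[eff_par[setdiff(kept, root)]], num[setdiff(kept, root)])
  new_phy <- structure(list(edge = edges,
                            tip.label = phy$tip.label,
                            Nnode = length(kept_int),
                            root.edge = phy$root.edge),
                       class = "phylo")
  if (!is.null(phy$edge.length)) {
    # edge length = summed length of the merged path
    lens <- numeric(nrow(edges))
    elen <- numeric(nn)
    elen[phy$edge[, 2L]] <- phy$edge.length
    kidx <- setdiff(kept, root)
    for (i in seq_along(kidx)) {
      v <- kidx[i]; tot <- elen[v]; p <- par[v]
      while (p != 0L && !keep[p]) { tot <- tot + elen[p]; p <- par[p] }
      lens[i] <- tot
    }
    new_phy$edge.length <- lens
  }
  new_phy <- ape::reorder.phylo(new_phy, "cladewise")
  new_states <- matrix(NA_integer_, ntip + length(kept_int), ncol(states))
  new_states[num[kept], ] <- states[kept, ]
  colnames(new_states) <- colnames(states)
  list(tree = new_phy, states = new_states)
}

#' Estimate branch lengths in days under constant-rate editing
#'
#' Per edge, with `u` parent-unedited sites of which `k` gain a mark along
#' the edge, the closed-form duration is `-log(max(1 - k/u, eps)) / rate`
#' with `eps = 1/(2u)` guarding full saturation; edges with `u = 0` receive
#' the minimum positive duration. The tree is then rescaled so the mean
#' root-to-leaf path equals `total_time`.
#'
#' @param phy Rooted `phylo` tree.
#' @param states Node x site state matrix (phylo numbering).
#' @param rate Per-day edit rate (> 0).
#' @param total_time Tracing duration in days (> 0).
#' @return `phy` with `edge.length` in days (mean root-to-tip depth equal to
#'   `total_time`) and `root.edge = 0`.
#' @export
estimate_branch_lengths <- function(phy, states, rate, total_time) {
  if (total_time <= 0) stop2("invalid_argument", "total_time must be > 0")
  stopifnot(rate > 0)
  ne <- nrow(phy$edge)
  raw <- numeric(ne)
  for (i in seq_len(ne)) {
    p <- phy$edge[i, 1L]; v <- phy$edge[i, 2L]
    ue <- states[p, ] == 0L
    u <- sum(ue)
    if (u == 0L) { raw[i] <- NA_real_; next }
    kk <- sum(states[v, ue] != 0L)
    eps <- 1 / (2 * u)
    raw[i] <- -log(max(1 - kk / u, eps)) / rate
  }
  floor_d <- suppressWarnings(min(raw[raw > 0], na.rm = TRUE))
  if (!is.finite(floor_d)) floor_d <- 1e-6
  raw[is.na(raw)] <- floor_d # no exposure: minimum positive duration
  phy$edge.length <- raw
  phy$root.edge <- 0
  mean_depth <- mean(node_times(phy)[seq_len(ape::Ntip(phy))])
  phy$edge.length <- phy$edge.length * total_time / mean_depth
  phy
}

#' Time of a cell group's best-matching ancestor
#'
#' Returns the root-to-node time (days since the start of tracing) of the
#' internal node maximizing the FMI with the group, i.e. the inferred time
#' at which the group's founding ancestor lived.
#'
#' @param phy Rooted `phylo` tree with branch lengths in days.
#' @param group Character vector of cell ids.
#' @param labeled Cells carrying a barcode; see [best_lca_clade()].
#' @return Time in days.
#' @export
lca_timing <- function(phy, group, labeled = phy$tip.label) {
  best <- best_lca_clade(phy, group, labeled)
  node_times(phy)[best$node]
}

#' Count extant lineages at given timepoints
#'
#' Cuts the tree at each timepoint and counts the branches alive then (the
#' ancestral cells present at that moment), optionally per clade.
#'
#' @param phy Rooted `phylo` tree with branch lengths in days.
#' @param timepoints Numeric vector of times in `[0, max tree time]`.
#' @param clades Optional named list of tip-label vectors; counts are
#'   restricted to branches whose descendants lie in the clade.
#' @return `data.table` with columns `time`, `clade`, `count`.
#' @export
extant_counts <- function(phy, timepoints, clades = NULL) {
  tm <- node_times(phy)
  ntip <- ape::Ntip(phy)
  tmax <- max(tm[seq_len(ntip)])
  if (any(timepoints < 0 | timepoints > tmax + 1e-9)) {
    stop2("invalid_argument", "timepoints must lie in [0, %g]", tmax)
  }
  dt <- descendant_tips(phy)
  pt <- tm[phy$edge[, 1L]]
  ct <- tm[phy$edge[, 2L]]
  child <- phy$edge[, 2L]
  is_leaf_edge <- child <= ntip
  groups <- clades %||% list(all = phy$tip.label)
  out <- list()
  for (g in names(groups)) {
    tipset <- match(groups[[g]], phy$tip.label)
    in_clade <- vapply(seq_along(child), function(i) {
      any(dt[[child[i]]] %in% tipset)
    }, logical(1))
    for (t in timepoints) {
      alive <- in_clade & pt <= t + 1e-12 &
        (t < ct - 1e-12 | (is_leaf_edge & abs(ct - t) <= 1e-9))
      n <- sum(alive)
      # before the first division only the founding lineage exists
      if (t <= tm[tree_root(phy)] + 1e-12) n <- 1L
      out[[length(out) + 1L]] <- data.table::data.table(
        time = t, clade = g, count = n)
    }
  }
  data.table::rbindlist(out)
}

#' Lineage-mark installation efficiencies from inferred transitions
#'
#' Per edit site, counts unedited -> mark transitions along branches,
#' divides by the number of branches whose parent is unedited at the site
#' (the exposures), and normalizes across marks within the site to sum to
#' one.
#'
#' @param phy Rooted `phylo` tree.
#' @param states Node x site state matrix (phylo numbering).
#' @param n_marks Mark alphabet size `S`.
#' @return A site x mark matrix of normalized installation probabilities;
#'   rows of sites with zero exposure are `NA`.
#' @export
lm_installation_efficiency <- function(phy, states, n_marks) {
  M <- ncol(states)
  counts <- matrix(0, M, n_marks)
  expo <- numeric(M)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; v <- phy$edge[i, 2L]
    ue <- states[p, ] == 0L
    expo <- expo + ue
    inst <- ue & states[v, ] > 0L
    if (any(inst)) {
      idx <- which(inst)
      for (j in idx) counts[j, states[v, j]] <- counts[j, states[v, j]] + 1
    }
  }
  res <- counts / expo
  rs <- rowSums(res)
  res <- res / ifelse(rs > 0, rs, NA_real_)
  res[expo == 0, ] <- NA_real_
  rownames(res) <- colnames(states)
  colnames(res) <- paste0("LM", seq_len(n_marks))
  res
}
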