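# Reconstruction-quality metrics: normalized Robinson-Foulds distance,
# depth-normalized triplets correct, Fowlkes-Mallows agreement between tree
# clades and static-barcode groups, and downsampling sweeps.

# canonical keys for the nontrivial bipartitions of a tree, treated as
# unrooted; each key is the tip-label set on one side, complemented so that
# the reference tip is always excluded
tree_splits <- function(phy, ref_labels) {
  ntip <- ape::Ntip(phy)
  dt <- descendant_tips(phy)
  keys <- character(0)
  for (i in seq_len(nrow(phy$edge))) {
    v <- phy$edge[i, 2L]
    if (v <= ntip) next
    side <- sort(match(phy$tip.label[dt[[v]]], ref_labels))
    if (length(side) < 2L || length(side) > length(ref_labels) - 2L) next
    if (1L %in% side) side <- setdiff(seq_along(ref_labels), side)
    keys <- c(keys, paste(side, collapse = ","))
  }
  unique(keys)
}

#' Normalized Robinson-Foulds distance between two trees
#'
#' Counts the nontrivial bipartitions unique to each tree (trees compared as
#' unrooted) and divides by the total number of nontrivial bipartitions in
#' both trees, so the value lies in `[0, 1]` and multifurcating trees
#' normalize sensibly; 0 iff the unrooted topologies are identical.
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @return Normalized RF distance in `[0, 1]`.
#' @export
normalized_rf <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop2("leaf_mismatch", "trees have different leaf sets")
  }
  ref <- sort(t1$tip.label)
  s1 <- tree_splits(t1, ref)
  s2 <- tree_splits(t2, ref)
  tot <- length(s1) + length(s2)
  if (tot == 0L) return(0)
  (length(setdiff(s1, s2)) + length(setdiff(s2, s1))) / tot
}

# out-taxon of a triplet: index 1..3 of the taxon outside the cherry, or 0L
# when the triplet is unresolved (all three pairwise LCAs coincide)
triplet_out <- function(trip, mrca_m, depth) {
  ab <- mrca_m[trip[1L], trip[2L]]
  ac <- mrca_m[trip[1L], trip[3L]]
  bc <- mrca_m[trip[2L], trip[3L]]
  d <- depth[c(ab, ac, bc)]
  mn <- min(d)
  deeper <- which(d > mn)
  if (length(deeper) != 1L) return(0L)
  c(3L, 2L, 1L)[deeper]  # pair (a,b) deeper -> out is c, etc.
}

#' Depth-normalized fraction of triplets correct
#'
#' Samples leaf triplets from the ground-truth tree, distributed evenly
#' across the occupied depths (edge count from root) of their lowest common
#' ancestor, and scores the fraction whose out-taxon agrees between the two
#' trees. A triplet left unresolved by a multifurcation counts as correct
#' only when it is unresolved in both trees.
#'
#' @param truth Ground-truth rooted `phylo` tree (defines LCA depths).
#' @param recon Reconstructed tree over the same leaves.
#' @param n_triplets Number of triplets to sample (default 1000).
#' @param seed Integer seed for triplet sampling.
#' @return Fraction in `[0, 1]`.
#' @export
depth_normalized_triplets_correct <- function(truth, recon,
                                              n_triplets = 1000L, seed = 1L) {
  if (!setequal(truth$tip.label, recon$tip.label)) {
    stop2("leaf_mismatch", "trees have different leaf sets")
  }
  n <- ape::Ntip(truth)
  if (n < 3) stop2("invalid_argument", "need at least 3 shared leaves")
  mt <- ape::mrca(truth)
  dt_ <- node_depths(truth)
  mr <- ape::mrca(recon)
  dr <- node_depths(recon)
  ridx <- match(truth$tip.label, recon$tip.label)

  cand <- with_seed(seed, {
    if (choose(n, 3) <= 60000) {
      t(utils::combn(n, 3L))
    } else {
      cm <- matrix(0L, 0L, 3L)
      while (nrow(cm) < 20L * n_triplets) {
        draw <- t(replicate(20L * n_triplets,
                            sort(sample.int(n, 3L))))
        cm <- unique(rbind(cm, draw))
      }
      cm
    }
  })
  # truth LCA depth per candidate (min over the three pairwise LCAs)
  d_ab <- dt_[mt[cand[, c(1, 2), drop = FALSE]]]
  d_ac <- dt_[mt[cand[, c(1, 3), drop = FALSE]]]
  d_bc <- dt_[mt[cand[, c(2, 3), drop = FALSE]]]
  lca_depth <- pmin(d_ab, d_ac, d_bc)

  strata <- sort(unique(lca_depth))
  k <- length(strata)
  base <- n_triplets %/% k
  extra <- n_triplets %% k
  take <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))

  sel <- with_seed(derive_seed(seed, "strata"), {
    idx <- integer(0)
    for (si in seq_len(k)) {
      pool <- which(lca_depth == strata[si])
      idx <- c(idx, if (length(pool) >= take[si]) {
        sample(pool, take[si])
      } else {
        sample(pool, take[si], replace = TRUE)
      })
    }
    idx
  })

  correct <- vapply(sel, function(i) {
    trip <- cand[i, ]
    ot <- triplet_out(trip, mt, dt_)
    or_ <- triplet_out(ridx[trip], mr, dr)
    (ot == or_)
  }, logical(1))
  mean(correct)
}

#' Fowlkes-Mallows index between a cell group and a tree clade
#'
#' `sqrt(precision x recall)` where TP is the overlap, FP the clade cells
#' outside the group and FN the group cells outside the clade.
#'
#' @param group Character vector of cell ids in the barcode group.
#' @param clade Character vector of cell ids in the clade.
#' @return FMI in `[0, 1]`; 0 when the overlap is empty.
#' @export
fmi <- function(group, clade) {
  if (length(group) == 0L) stop2("invalid_argument", "group is empty")
  tp <- length(intersect(group, clade))
  if (tp == 0L) return(0)
  fp <- length(setdiff(clade, group))
  fn <- length(setdiff(group, clade))
  sqrt(tp / (tp + fp) * tp / (tp + fn))
}

#' Best-matching clade for a cell group
#'
#' Evaluates the FMI between the group and the leaf-descendant set of every
#' internal node and returns the maximizer; ties go to the deepest node and
#' then the smallest clade. Cells not in `labeled` (e.g. cells lacking any
#' barcode) are excluded from clades before scoring.
#'
#' @param phy Rooted `phylo` tree.
#' @param group Character vector of cell ids (must be tips of `phy`).
#' @param labeled Cell ids carrying a barcode label; defaults to all tips.
#' @return A list with `node` (phylo node number), `fmi`, and `clade` (the
#'   labeled cells under the node).
#' @export
best_lca_clade <- function(phy, group, labeled = phy$tip.label) {
  if (length(group) == 0L) stop2("invalid_argument", "group is empty")
  stopifnot(all(group %in% phy$tip.label))
  dt <- descendant_tips(phy)
  depth <- node_depths(phy)
  ntip <- ape::Ntip(phy)
  internals <- ntip + seq_len(phy$Nnode)
  best <- list(node = NA_integer_, fmi = -1, clade = character(0))
  for (v in internals) {
    clade <- intersect(phy$tip.label[dt[[v]]], labeled)
    f <- fmi(group, clade)
    better <- f > best$fmi ||
      (f == best$fmi && !is.na(best$node) &&
         (depth[v] > depth[best$node] ||
            (depth[v] == depth[best$node] &&
               length(clade) < length(best$clade))))
    if (better) best <- list(node = v, fmi = f, clade = clade)
  }
  best
}

# thin each observed entry so the realized detection rate matches `target`
downsample_detection <- function(cm, target, seed) {
  realized <- mean(!is.na(cm))
  if (target >= realized) {
    return(list(cm = cm, realized = realized))
  }
  m <- cm_data(cm)
  with_seed(seed, {
    obs <- which(!is.na(m))
    drop <- obs[stats::runif(length(obs)) > target / realized]
    m[drop] <- NA_integer_
  })
  out <- character_matrix(m, n_marks(cm))
  list(cm = out, realized = mean(!is.na(out)))
}

#' Detection-rate and edit-site downsampling sweep
#'
#' For each grid point and repetition the character matrix is downsampled
#' (entries dropped to hit a target detection rate, or edit sites removed),
#' a tree is reconstructed by neighbor joining, and reconstruction quality
#' is scored: mean best-LCA FMI across barcode groups when `groups` is
#' given, and/or normalized RF and triplets correct against `truth`. When a
#' target exceeds what the data supports, no downsampling is performed and
#' the realized value is reported.
#'
#' @param cm A [character_matrix()].
#' @param truth Optional ground-truth `phylo` tree.
#' @param groups Optional named list of barcode groups (cell-id vectors).
#' @param detection_grid Target detection rates (default `seq(0.1, 1, 0.1)`).
#' @param site_grid Target edit-site counts (default `seq(5, 45, 5)`).
#' @param reps Repetitions per grid point (default 10).
#' @param seed Integer seed.
#' @return Long-form `data.table` with columns `sweep`, `target`,
#'   `realized`, `rep`, `metric`, `value`.
#' @export
downsampling_sweep <- function(cm, truth = NULL, groups = NULL,
                               detection_grid = seq(0.1, 1, 0.1),
                               site_grid = seq(5, 45, 5), reps = 10L,
                               seed = 1L) {
  if (is.null(truth) && is.null(groups)) {
    stop2("invalid_argument", "supply truth and/or groups")
  }
  score <- function(cm_i, tag) {
    phy <- reconstruct_nj(cm_i)
    rows <- list()
    if (!is.null(groups)) {
      fmis <- vapply(groups, function(g) best_lca_clade(phy, g)$fmi,
                     numeric(1))
      rows <- c(rows, list(data.table::data.table(metric = "fmi_mean",
                                                  value = mean(fmis))))
    }
    if (!is.null(truth)) {
      rows <- c(rows, list(data.table::data.table(
        metric = c("norm_rf", "triplets_correct"),
        value = c(normalized_rf(truth, phy),
                  depth_normalized_triplets_correct(truth, phy,
                                                    seed = derive_seed(seed, tag))))))
    }
    data.table::rbindlist(rows)
  }
  out <- list()
  for (d in detection_grid) {
    for (r in seq_len(reps)) {
      tag <- sprintf("det%.3f_%d", d, r)
      ds <- downsample_detection(cm, d, derive_seed(seed, tag))
      sc <- score(ds$cm, tag)
      sc[, c("sweep", "target", "realized", "rep") :=
           list("detection", d, ds$realized, r)]
      out[[length(out) + 1L]] <- sc
    }
  }
  for (ns in site_grid) {
    for (r in seq_len(reps)) {
      tag <- sprintf("sites%d_%d", ns, r)
      if (ns >= ncol(cm)) {
        cm_i <- cm; realized <- ncol(cm)
      } else {
        keep <- with_seed(derive_seed(seed, tag),
                          sort(sample.int(ncol(cm), ns)))
        cm_i <- character_matrix(cm_data(cm)[, keep, drop = FALSE],
                                 n_marks(cm))
        realized <- ns
      }
      sc <- score(cm_i, tag)
      sc[, c("sweep", "target", "realized", "rep") :=
           list("sites", ns, as.numeric(realized), r)]
      out[[length(out) + 1L]] <- sc
    }
  }
  data.table::rbindlist(out)[, c("sweep", "target", "realized", "rep",
                                 "metric", "value"), with = FALSE]
}
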