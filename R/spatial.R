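# Joint spatial-phylogenetic statistics: neighbor graphs, Moran's I with
# permutation testing, local lineage-mark diversity, the tree-independent
# fitness proxy, and pairwise distance comparisons.

#' Build a binary neighbor graph
#'
#' Phylogenetic graphs connect cells whose lowest common ancestor lies
#' within `parameter` days of both cells (recent shared ancestry); spatial
#' graphs connect cells within `parameter` micrometers in the x-y plane,
#' never across sections.
#'
#' @param kind `"phylo"` or `"spatial"`.
#' @param tree Rooted `phylo` tree with branch lengths in days (phylo
#'   kind).
#' @param positions `data.table`/data.frame with `cell`, `x_um`, `y_um`
#'   and optional `section` (spatial kind).
#' @param parameter Window in days (phylo, default 10) or radius in
#'   micrometers (spatial, default 100).
#' @return Sparse symmetric 0/1 `Matrix` with zero diagonal, dimnames =
#'   cell ids, and attributes `kind` and `parameter`.
#' @export
build_neighbor_graph <- function(kind = c("phylo", "spatial"), tree = NULL,
                                 positions = NULL, parameter = NULL) {
  kind <- match.arg(kind)
  if (kind == "phylo") {
    if (is.null(tree)) stop2("invalid_argument", "phylo kind needs a tree")
    if (is.null(tree$edge.length)) {
      stop2("no_branch_lengths", "tree lacks branch lengths")
    }
    parameter <- parameter %||% 10
    tm <- node_times(tree)
    ntip <- ape::Ntip(tree)
    mr <- ape::mrca(tree)
    tip_t <- tm[seq_len(ntip)]
    lca_t <- matrix(tm[mr], ntip, ntip)
    W <- (outer(tip_t, rep(1, ntip)) - lca_t <= parameter) &
      (outer(rep(1, ntip), tip_t) - lca_t <= parameter)
    diag(W) <- FALSE
    dimnames(W) <- list(tree$tip.label, tree$tip.label)
  } else {
    if (is.null(positions)) {
      stop2("invalid_argument", "spatial kind needs positions")
    }
    parameter <- parameter %||% 100
    pos <- data.table::as.data.table(positions)
    n <- nrow(pos)
    d <- as.matrix(stats::dist(cbind(pos$x_um, pos$y_um)))
    W <- d <= parameter
    if (!is.null(pos$section)) {
      same <- outer(pos$section, pos$section, "==")
      W <- W & same
    }
    diag(W) <- FALSE
    dimnames(W) <- list(pos$cell, pos$cell)
  }
  out <- Matrix::Matrix(W * 1, sparse = TRUE)
  attr(out, "kind") <- kind
  attr(out, "parameter") <- parameter
  out
}

#' Moran's I autocorrelation with permutation testing
#'
#' For z-scored values x, `I = N / sum(w) * sum(w_ij x_i x_j) / sum(x_i^2)`
#' over a binary neighbor graph. When `values` is a matrix (features in
#' columns) the statistic, one-sided permutation p-value (with +1
#' smoothing) and Benjamini-Hochberg q-value across the feature batch are
#' returned per feature. Constant features yield `NA`.
#'
#' @param values Numeric vector, or cells x features matrix.
#' @param graph Neighbor graph from [build_neighbor_graph()] (cells must
#'   match rows of `values`).
#' @param n_perm Permutations (default 1000).
#' @param seed Integer seed.
#' @return `data.table` with `feature`, `morans_i`, `p_value`, `q_value`.
#' @export
morans_i <- function(values, graph, n_perm = 1000L, seed = 1L) {
  V <- as.matrix(values)
  if (is.null(colnames(V))) {
    colnames(V) <- if (ncol(V) == 1L) "value" else
      paste0("feature", seq_len(ncol(V)))
  }
  N <- nrow(V)
  if (N < 3) stop2("invalid_argument", "need >= 3 cells")
  W <- graph
  S0 <- sum(W)
  if (S0 == 0) stop2("invalid_argument", "graph has no edges")
  stat_one <- function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    z <- x - mean(x)
    as.numeric(N / S0 * (z %*% (W %*% z)) / sum(z^2))
  }
  obs <- apply(V, 2L, stat_one)
  perms <- with_seed(seed, {
    replicate(n_perm, sample.int(N))
  })
  out <- data.table::data.table(feature = colnames(V), morans_i = obs,
                                p_value = NA_real_)
  for (j in seq_len(ncol(V))) {
    if (is.na(obs[j])) next
    x <- V[, j]; z <- x - mean(x); denom <- sum(z^2)
    Zp <- matrix(z[perms], N, n_perm)
    Ip <- N / S0 * colSums(Zp * as.matrix(W %*% Zp)) / denom
    out$p_value[j] <- (1 + sum(Ip >= obs[j])) / (1 + n_perm)
  }
  out[, q_value := stats::p.adjust(p_value, "BH")]
  out[]
}

#' Local lineage-mark diversity
#'
#' For each cell, the mean pairwise weighted-Hamming distance among the
#' cells within `radius` micrometers of it (the focal cell included).
#' Phylogenetically mixed neighborhoods score high; recent clonal patches
#' score near zero. Cells with fewer than 2 neighborhood members are `NA`.
#'
#' @param cm A [character_matrix()].
#' @param positions Table with `cell`, `x_um`, `y_um`, optional `section`.
#' @param radius Neighborhood radius in micrometers (default 100).
#' @param include_focal Include the focal cell in its own neighborhood
#'   (default TRUE).
#' @return Named numeric vector per cell.
#' @export
local_lm_diversity <- function(cm, positions, radius = 100,
                               include_focal = TRUE) {
  pos <- data.table::as.data.table(positions)
  stopifnot(all(pos$cell %in% rownames(cm)))
  d_lm <- weighted_hamming_matrix(cm)[pos$cell, pos$cell]
  d_sp <- as.matrix(stats::dist(cbind(pos$x_um, pos$y_um)))
  if (!is.null(pos$section)) {
    d_sp[!outer(pos$section, pos$section, "==")] <- Inf
  }
  n <- nrow(pos)
  out <- stats::setNames(rep(NA_real_, n), pos$cell)
  for (i in seq_len(n)) {
    nb <- which(d_sp[i, ] <= radius)
    if (!include_focal) nb <- setdiff(nb, i)
    if (length(nb) < 2L) next
    sub <- d_lm[nb, nb]
    out[i] <- mean(sub[upper.tri(sub)])
  }
  out
}

#' Mean neighbor lineage-mark distance (tree-independent fitness proxy)
#'
#' For each cell, the mean weighted-Hamming distance to its `k` nearest
#' cells in mark space. Fitter cells divide faster, leaving less time for
#' extra marks to accumulate between relatives, so lower values indicate
#' recent clonal expansion.
#'
#' @param cm A [character_matrix()] with more than `k` cells.
#' @param k Neighbors (default 20).
#' @return Named numeric vector per cell (lower = fitter).
#' @export
mean_neighbor_lm_distance <- function(cm, k = 20L) {
  d <- weighted_hamming_matrix(cm)
  n <- nrow(d)
  if (n <= k) stop2("invalid_argument", "need more than k = %d cells", k)
  vapply(seq_len(n), function(i) {
    v <- d[i, -i]
    ord <- order(v, names(v)) # ties at the k-th rank broken by cell id
    mean(v[ord[seq_len(k)]])
  }, numeric(1)) -> out
  stats::setNames(out, rownames(d))
}

#' Pairwise phylogenetic, mark, and spatial distances
#'
#' Samples random cell pairs (all pairs when fewer than `n_pairs` exist;
#' cross-section pairs excluded) and emits, per pair: the phylogenetic
#' distance (total path length through the LCA, in days), the
#' weighted-Hamming mark distance, the Euclidean spatial distance, and a
#' shuffled-position control distance.
#'
#' @param tree Rooted `phylo` with branch lengths in days.
#' @param cm A [character_matrix()].
#' @param positions Table with `cell`, `x_um`, `y_um`, optional `section`.
#' @param n_pairs Pairs to sample (default 20000).
#' @param seed Integer seed.
#' @return `data.table` with `cell1`, `cell2`, `phylo_dist`, `lm_dist`,
#'   `spatial_dist`, `shuffled_spatial_dist`.
#' @export
pairwise_distance_table <- function(tree, cm, positions, n_pairs = 20000L,
                                    seed = 1L) {
  pos <- data.table::as.data.table(positions)
  cells <- intersect(intersect(tree$tip.label, rownames(cm)), pos$cell)
  pos <- pos[match(cells, cell)]
  n <- length(cells)
  pairs <- t(utils::combn(n, 2L))
  if (!is.null(pos$section)) {
    pairs <- pairs[pos$section[pairs[, 1L]] == pos$section[pairs[, 2L]], ,
                   drop = FALSE]
  }
  if (nrow(pairs) > n_pairs) {
    pairs <- pairs[with_seed(seed, sample.int(nrow(pairs), n_pairs)), ,
                   drop = FALSE]
  }
  tm <- node_times(tree)
  mr <- ape::mrca(tree)
  tipidx <- match(cells, tree$tip.label)
  lca <- mr[cbind(tipidx[pairs[, 1L]], tipidx[pairs[, 2L]])]
  phylo_d <- (tm[tipidx[pairs[, 1L]]] - tm[lca]) +
    (tm[tipidx[pairs[, 2L]]] - tm[lca])
  d_lm <- weighted_hamming_matrix(cm)[cells, cells]
  lm_d <- d_lm[pairs]
  xy <- cbind(pos$x_um, pos$y_um)
  sp_d <- sqrt(rowSums((xy[pairs[, 1L], , drop = FALSE] -
                          xy[pairs[, 2L], , drop = FALSE])^2))
  shuf <- with_seed(derive_seed(seed, "shuffle"), sample.int(n))
  xs <- xy[shuf, , drop = FALSE]
  sh_d <- sqrt(rowSums((xs[pairs[, 1L], , drop = FALSE] -
                          xs[pairs[, 2L], , drop = FALSE])^2))
  data.table::data.table(cell1 = cells[pairs[, 1L]],
                         cell2 = cells[pairs[, 2L]],
                         phylo_dist = phylo_d, lm_dist = lm_d,
                         spatial_dist = sp_d, shuffled_spatial_dist = sh_d)
}

#' Correlate a fitness estimate with per-cell features
#'
#' Pearson correlation of fitness against each feature column, two-sided
#' t-test p-values and Benjamini-Hochberg q-values across the battery.
#'
#' @param fitness Named numeric vector per cell.
#' @param features Cells x features data.frame/matrix (rows matching
#'   `fitness`).
#' @return `data.table` with `feature`, `r`, `p_value`, `q_value`, `n`.
#' @export
fitness_feature_correlation <- function(fitness, features) {
  F_ <- as.data.frame(features)
  out <- lapply(names(F_), function(f) {
    x <- fitness; y <- F_[[f]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) {
      stop2("invalid_argument", "feature '%s' has < 3 complete pairs", f)
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.table::data.table(feature = f, r = unname(ct$estimate),
                           p_value = ct$p.value, n = sum(ok))
  })
  res <- data.table::rbindlist(out)
  res[, q_value := stats::p.adjust(p_value, "BH")]
  res[]
}
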