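# Small helpers around ape "phylo" objects, which the package uses as its
# lineage-tree representation (tips = observed cells, branch lengths = days,
# optional root.edge = lifetime of the founding cell).

# children list indexed by node number (tips have integer(0))
tree_children <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  ch <- vector("list", n)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]
    ch[[p]] <- c(ch[[p]], phy$edge[i, 2L])
  }
  ch
}

tree_root <- function(phy) ape::Ntip(phy) + 1L

# parent vector (0 for the root)
tree_parents <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  par <- integer(n)
  par[phy$edge[, 2L]] <- phy$edge[, 1L]
  par
}

# node depths in edge counts from the root
node_depths <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  par <- tree_parents(phy)
  d <- rep(NA_integer_, n)
  d[tree_root(phy)] <- 0L
  for (i in seq_len(nrow(phy$edge))) { # phylo edges are parent-before-child
    e <- phy$edge[i, ]
    d[e[2L]] <- d[e[1L]] + 1L
  }
  d
}

# node times in days since the start of the experiment; the founding cell is
# born at time 0 so the root node sits at root.edge (0 when absent)
node_times <- function(phy) {
  if (is.null(phy$edge.length)) {
    stop2("no_branch_lengths", "tree has no branch lengths")
  }
  n <- ape::Ntip(phy) + phy$Nnode
  t <- numeric(n)
  t[tree_root(phy)] <- phy$root.edge %||% 0
  for (i in seq_len(nrow(phy$edge))) {
    e <- phy$edge[i, ]
    t[e[2L]] <- t[e[1L]] + phy$edge.length[i]
  }
  t
}

# tip numbers (1..Ntip) descending from each node, as a list
descendant_tips <- function(phy) {
  ntip <- ape::Ntip(phy)
  n <- ntip + phy$Nnode
  ch <- tree_children(phy)
  out <- vector("list", n)
  for (v in seq_len(ntip)) out[[v]] <- v
  po <- rev(unique(phy$edge[, 1L][order(node_depths(phy)[phy$edge[, 1L]])]))
  for (v in po) out[[v]] <- unlist(out[ch[[v]]], use.names = FALSE)
  out
}

# internal nodes ordered parents-before-children
preorder_internal <- function(phy) {
  ints <- unique(phy$edge[, 1L])
  ints[order(node_depths(phy)[ints])]
}

#' Read a lineage tree from a Newick file
#'
#' @param path Newick file path.
#' @return An ape `phylo` object; branch lengths (days) and multifurcations
#'   are preserved when present.
#' @export
read_lineage_tree <- function(path) {
  phy <- tryCatch(ape::read.tree(path),
                  error = function(e) stop2("parse_error",
                                            "failed to parse Newick '%s': %s",
                                            path, conditionMessage(e)))
  if (is.null(phy)) stop2("parse_error", "failed to parse Newick '%s'", path)
  phy
}

#' Write a lineage tree to a Newick file
#'
#' @param phy An ape `phylo` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lineage_tree <- function(phy, path) {
  ape::write.tree(phy, file = path)
  invisible(path)
}
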