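# Distance-matrix construction and tree reconstruction (neighbor joining,
# UPGMA, greedy top-down splitting) from lineage-mark character matrices.

#' Weighted Hamming distance matrix between cells
#'
#' For each edit site the per-site cost is 0 when the two states match or
#' either is missing, 1 when exactly one of the pair is unedited, and 2 when
#' both carry different marks (a shared installed mark is stronger evidence
#' of relatedness than shared absence, so disagreeing installs count
#' double). The summed cost is divided by `L`, the total weight of sites
#' where both cells are detected. Optional per-site weights multiply the
#' cost and contribute their weight to `L` (used e.g. to manually upweight
#' trusted sites).
#'
#' Pairs with no co-detected site (`L = 0`) cannot be compared; they are
#' assigned the maximum finite distance in the matrix plus one and listed in
#' the `undetected_pairs` attribute rather than aborting the reconstruction.
#'
#' @param cm A [character_matrix()].
#' @param site_weights Optional positive per-site weights (default all 1).
#' @return A symmetric numeric matrix with zero diagonal, dimnames = cell
#'   ids, and attribute `undetected_pairs` (2-column matrix of cell-id
#'   pairs with no co-detected sites).
#' @export
weighted_hamming_matrix <- function(cm, site_weights = NULL) {
  m <- cm_data(cm)
  N <- nrow(m); M <- ncol(m)
  if (N < 2) stop2("invalid_argument", "need at least 2 cells")
  w <- site_weights %||% rep(1, M)
  stopifnot(length(w) == M, all(w > 0))
  num <- matrix(0, N, N)
  den <- matrix(0, N, N)
  for (j in seq_len(M)) {
    x <- m[, j]
    obs <- !is.na(x)
    B <- tcrossprod(obs)                 # both detected
    ue <- obs & x == 0L
    ed <- obs & x > 0L
    xs <- ifelse(is.na(x), -1L, x)
    diffm <- outer(xs, xs, "!=")
    one_ue <- outer(ue, ed, "&") | outer(ed, ue, "&")
    both_ed_diff <- tcrossprod(ed) * diffm
    num <- num + w[j] * (one_ue + 2 * both_ed_diff)
    den <- den + w[j] * B
  }
  d <- num / den
  diag(d) <- 0
  und <- which(den == 0 & upper.tri(den), arr.ind = TRUE)
  if (nrow(und)) {
    mx <- max(d[is.finite(d)], 0)
    d[den == 0] <- mx + 1
    diag(d) <- 0
  }
  dimnames(d) <- list(rownames(m), rownames(m))
  attr(d, "undetected_pairs") <-
    cbind(rownames(m)[und[, 1L]], rownames(m)[und[, 2L]])
  d
}

#' Reconstruct a rooted tree by neighbor joining
#'
#' A synthetic all-unedited cell is appended to the character matrix before
#' the distance computation; the unrooted NJ tree is rooted on that outgroup
#' (the experiment starts from an unedited founder) and the synthetic cell
#' is then removed. Negative NJ edge lengths are clipped at zero.
#'
#' @param cm A [character_matrix()].
#' @param site_weights Optional per-site weights, see
#'   [weighted_hamming_matrix()].
#' @return A rooted `phylo` tree over exactly the input cells.
#' @export
reconstruct_nj <- function(cm, site_weights = NULL) {
  m <- cm_data(cm)
  if (nrow(m) < 3) stop2("invalid_argument", "neighbor joining needs >= 3 cells")
  og <- ".unedited_outgroup."
  m2 <- rbind(m, matrix(0L, 1, ncol(m), dimnames = list(og, colnames(m))))
  d <- weighted_hamming_matrix(character_matrix(m2, n_marks(cm)),
                               site_weights)
  phy <- ape::nj(stats::as.dist(d))
  phy$edge.length[phy$edge.length < 0] <- 0
  phy <- ape::root(phy, outgroup = og, resolve.root = TRUE)
  phy <- ape::drop.tip(phy, og)
  phy
}

#' Reconstruct a rooted tree by UPGMA (average-linkage clustering)
#'
#' @param cm A [character_matrix()].
#' @param site_weights Optional per-site weights.
#' @return A rooted ultrametric `phylo` tree.
#' @export
reconstruct_upgma <- function(cm, site_weights = NULL) {
  if (nrow(cm) < 3) stop2("invalid_argument", "UPGMA needs >= 3 cells")
  d <- weighted_hamming_matrix(cm, site_weights)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ape::as.phylo(hc)
}

#' Reconstruct a tree by greedy top-down mark splitting
#'
#' Recursively selects a (site, mark) pair and splits the cells by presence
#' of that mark; cells missing at the chosen site follow the larger side.
#' By default the most frequent mark in the group is chosen (ties broken by
#' site then mark index); `prefer = "least"` inverts the criterion. Groups
#' with no informative mark (none present in a proper subset) become a
#' multifurcation.
#'
#' @param cm A [character_matrix()].
#' @param prefer `"most"` (default) or `"least"` frequent informative mark.
#' @return A rooted (possibly multifurcating) `phylo` tree.
#' @export
reconstruct_greedy <- function(cm, prefer = c("most", "least")) {
  prefer <- match.arg(prefer)
  m <- cm_data(cm)
  if (nrow(m) < 2) stop2("invalid_argument", "need at least 2 cells")
  nwk <- greedy_split(m, prefer)
  phy <- ape::read.tree(text = paste0(nwk, ";"))
  phy
}

greedy_split <- function(m, prefer) {
  if (nrow(m) == 1L) return(rownames(m))
  best <- NULL; best_n <- if (prefer == "most") -Inf else Inf
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    for (s in sort(unique(x[!is.na(x) & x > 0L]))) {
      cnt <- sum(x == s, na.rm = TRUE)
      informative <- cnt >= 1L && cnt + sum(is.na(x)) < nrow(m)
      if (!informative) next
      better <- if (prefer == "most") cnt > best_n else cnt < best_n
      if (better) { best <- c(j, s); best_n <- cnt }
    }
  }
  if (is.null(best)) { # multifurcation over the remaining cells
    return(paste0("(", paste(rownames(m), collapse = ","), ")"))
  }
  x <- m[, best[1L]]
  with_mark <- !is.na(x) & x == best[2L]
  miss <- is.na(x)
  # missing cells are carried with the larger resolved side
  if (sum(with_mark) >= sum(!with_mark & !miss)) with_mark[miss] <- TRUE
  left <- greedy_split(m[with_mark, , drop = FALSE], prefer)
  right <- greedy_split(m[!with_mark, , drop = FALSE], prefer)
  paste0("(", left, ",", right, ")")
}
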