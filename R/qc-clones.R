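# Sequencing-readout quality control and clone calling from UMI tables.
#
# A UMI table is a long-form data.table with one record per (cell, intBC,
# allele): columns `cell`, `intbc`, `site1..siteK` (integer state codes),
# `umis`, `reads`. The allele of a record is the tuple of site states.

site_cols <- function(table) grep("^site", names(table), value = TRUE)

allele_key <- function(table) {
  do.call(paste, c(as.list(table[, site_cols(table), with = FALSE]),
                   sep = ","))
}

#' Two-component mixture threshold on count data
#'
#' Fits a two-component Gaussian mixture to log-transformed counts and
#' removes the items assigned to the lower-mean component (PCR/sequencing
#' errors and ambient molecules form a separable low-count mode). The
#' threshold is the point between the two components where the posterior
#' responsibility flips. When the data do not support two components (fewer
#' than `min_n` values, no variance, or the fitted means coincide within
#' 1e-3) no filtering is applied and a warning is raised.
#'
#' @param values Positive counts.
#' @param min_n Minimum number of values to attempt a fit (default 20).
#' @return A list with `threshold` (on the original count scale, `-Inf`
#'   when no filtering applies) and `keep` (logical mask).
#' @export
gmm_threshold <- function(values, min_n = 20L) {
  stopifnot(all(values > 0))
  fallback <- list(threshold = -Inf, keep = rep(TRUE, length(values)))
  if (length(values) < min_n || stats::var(values) == 0) {
    warning("mixture fit not attempted; keeping all values")
    return(fallback)
  }
  lx <- log(values)
  # two-component Gaussian mixture EM with a deterministic midrange split
  # as initialization; mclust's top-level wrappers resolve their workers on
  # the attached search path, so the workers are addressed by namespace.
  # The unequal-variance model collapses when one mode is a point mass of
  # tied counts, in which case the pooled-variance model is used.
  z0 <- mclust::unmap(1L + (lx > mean(range(lx))))
  run_em <- function(worker) {
    tryCatch(suppressWarnings(
      utils::getFromNamespace(worker, "mclust")(data = lx, z = z0)),
      error = function(e) NULL)
  }
  ok <- function(f) {
    !is.null(f) && all(is.finite(f$parameters$mean)) &&
      all(is.finite(f$parameters$variance$sigmasq))
  }
  fit <- run_em("meV")
  if (!ok(fit)) fit <- run_em("meE")
  if (!ok(fit)) {
    warning("degenerate mixture fit; keeping all values")
    return(fallback)
  }
  mu <- fit$parameters$mean
  s2 <- fit$parameters$variance$sigmasq
  # Ashman's D: forced two-component fits of unimodal data land near 1.3,
  # genuinely bimodal count data far above 2
  D <- abs(diff(mu)) / sqrt(mean(s2))
  if (!is.finite(D) || D < 2) {
    warning("distribution not separable into two components; keeping all values")
    return(fallback)
  }
  lo <- which.min(mu)
  keep <- max.col(fit$z, ties.method = "first") != lo
  if (all(keep) || !any(keep)) {
    warning("mixture fit assigned a single component; keeping all values")
    return(fallback)
  }
  thr <- exp((max(lx[!keep]) + min(lx[keep])) / 2)
  list(threshold = thr, keep = keep)
}

#' Adaptive allele filtering for a UMI table
#'
#' Stage 1 fits the mixture threshold to reads per record across the whole
#' capture (removing low-read PCR/sequencing errors); stage 2 refits per
#' intBC on UMIs per record among stage-1 survivors (removing ambient
#' alleles whose support scales with the cassette's expression).
#'
#' @param table UMI table (`data.table`).
#' @param min_n Minimum records for a fit (default 20).
#' @return The filtered table.
#' @export
filter_alleles_gmm <- function(table, min_n = 20L) {
  tb <- data.table::as.data.table(table)
  k1 <- suppressWarnings(gmm_threshold(tb$reads, min_n))
  tb <- tb[k1$keep]
  keep <- rep(TRUE, nrow(tb))
  for (bc in unique(tb$intbc)) {
    idx <- which(tb$intbc == bc)
    if (length(idx) < min_n) next
    k2 <- suppressWarnings(gmm_threshold(tb$umis[idx], min_n))
    keep[idx] <- k2$keep
  }
  tb[keep]
}

#' Resolve conflicting alleles within (cell, intBC)
#'
#' When a cell carries several alleles for one intBC: if exactly two alleles
#' differ at a single edit site where one is unedited, the edited allele is
#' kept provided it accounts for more than 20% of that intBC's UMIs in the
#' cell (newly installed marks are underrepresented in RNA because of
#' transcript half-life); otherwise the maximum-UMI allele is kept, ties
#' broken lexicographically by allele.
#'
#' @param table UMI table.
#' @param edited_share Minimum UMI share for preferring the edited allele
#'   (default 0.2, strict).
#' @return Table with one record per (cell, intBC).
#' @export
resolve_conflicting_alleles <- function(table, edited_share = 0.2) {
  tb <- data.table::as.data.table(table)
  tb[, .allele := allele_key(tb)]
  sc <- site_cols(tb)
  pick <- function(sd) {
    if (nrow(sd) == 1L) return(sd)
    maxumi <- sd[order(-umis, .allele)][1L]
    if (nrow(sd) == 2L) {
      a <- unlist(sd[1L, sc, with = FALSE])
      b <- unlist(sd[2L, sc, with = FALSE])
      dif <- which(a != b)
      if (length(dif) == 1L && (a[dif] == 0L || b[dif] == 0L)) {
        edited <- if (a[dif] == 0L) 2L else 1L
        share <- sd$umis[edited] / sum(sd$umis)
        if (share > edited_share) return(sd[edited])
        return(sd[-edited])
      }
    }
    maxumi
  }
  out <- tb[, pick(.SD), by = .(cell, intbc)]
  out[, .allele := NULL]
  out[]
}

#' Remove duplicate intBC integrations clone-wide
#'
#' Two cassettes sharing one intBC in a clone accrue different marks and
#' cannot be disambiguated. Per (clone, intBC), the fraction of UMIs in
#' cells carrying more than one allele is computed; intBCs exceeding
#' `max_conflict_fraction` are dropped from the whole clone.
#'
#' @param table UMI table.
#' @param clones `data.table` with columns `cell`, `clone`.
#' @param max_conflict_fraction Strict threshold (default 0.25).
#' @return Filtered table.
#' @export
filter_duplicate_intbcs <- function(table, clones,
                                    max_conflict_fraction = 0.25) {
  tb <- data.table::as.data.table(table)
  cl <- data.table::as.data.table(clones)
  tb <- merge(tb, cl[, .(cell, clone)], by = "cell", all.x = TRUE)
  tb[, .nallele := .N, by = .(cell, intbc)]
  frac <- tb[!is.na(clone),
             .(conflict_frac = sum(umis[.nallele > 1L]) / sum(umis)),
             by = .(clone, intbc)]
  bad <- frac[conflict_frac > max_conflict_fraction]
  out <- tb[!bad, on = c("clone", "intbc")]
  out[, c(".nallele", "clone") := NULL]
  out[]
}

#' Flag doublet cells by conflicting-allele fraction
#'
#' A droplet (or segmentation mask) containing two cells shows many intBCs
#' with conflicting alleles. Per cell, the fraction of UMIs linked to
#' conflicted intBCs (those with more than one allele in the cell) is
#' computed; cells strictly above the threshold are flagged. The default
#' threshold 0.25 matches sequencing readouts; imaging readouts use 0.5.
#'
#' @param table UMI table.
#' @param threshold Strict conflict-fraction threshold (default 0.25).
#' @return Character vector of cell ids to drop.
#' @export
filter_conflict_doublets <- function(table, threshold = 0.25) {
  tb <- data.table::as.data.table(table)
  tb[, .nallele := .N, by = .(cell, intbc)]
  per_cell <- tb[, .(frac = sum(umis[.nallele > 1L]) / sum(umis)),
                 by = cell]
  per_cell[frac > threshold, cell]
}

# --- clone calling ----------------------------------------------------------

# nonnegative double-SVD initialization (Boutsidis & Gallopoulos)
nndsvd_init <- function(X, k) {
  sv <- svd(X, nu = k, nv = k)
  W <- matrix(0, nrow(X), k); H <- matrix(0, k, ncol(X))
  W[, 1L] <- sqrt(sv$d[1L]) * abs(sv$u[, 1L])
  H[1L, ] <- sqrt(sv$d[1L]) * abs(sv$v[, 1L])
  for (j in seq_len(k)[-1L]) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    npp <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    nnn <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (npp >= nnn) {
      W[, j] <- sqrt(sv$d[j] * npp) * up / max(sqrt(sum(up^2)), 1e-12)
      H[j, ] <- sqrt(sv$d[j] * npp) * vp / max(sqrt(sum(vp^2)), 1e-12)
    } else {
      W[, j] <- sqrt(sv$d[j] * nnn) * un / max(sqrt(sum(un^2)), 1e-12)
      H[j, ] <- sqrt(sv$d[j] * nnn) * vn / max(sqrt(sum(vn^2)), 1e-12)
    }
  }
  W[W == 0] <- 1e-6; H[H == 0] <- 1e-6
  list(W = W, H = H)
}

# multiplicative-update NMF under the Frobenius objective
nmf_frobenius <- function(X, k, iters = 200L) {
  init <- nndsvd_init(X, k)
  W <- init$W; H <- init$H
  eps <- 1e-9
  for (i in seq_len(iters)) {
    H <- H * (crossprod(W, X) / (crossprod(W, W %*% H) + eps))
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
  }
  list(W = W, H = H)
}

spectral_assign <- function(X, k, seed) {
  B <- (X > 0) * 1
  sim <- tcrossprod(B / pmax(sqrt(rowSums(B^2)), 1e-12)) # cosine similarity
  diag(sim) <- 0
  d <- pmax(rowSums(sim), 1e-12)
  L <- diag(1 / sqrt(d)) %*% sim %*% diag(1 / sqrt(d))
  ev <- eigen(L, symmetric = TRUE)
  U <- ev$vectors[, seq_len(k), drop = FALSE]
  U <- U / pmax(sqrt(rowSums(U^2)), 1e-12)
  with_seed(seed, stats::kmeans(U, k, nstart = 10L)$cluster)
}

#' Call clones from a cell-by-intBC UMI matrix
#'
#' Cells descending from one engineered founder share a set of intBC
#' integrations. Initial assignments come from non-negative matrix
#' factorization of the cell-by-intBC UMI matrix (argmax over the
#' cell-by-clone factor; `method = "spectral"` substitutes spectral
#' clustering of binarized detections, appropriate when doublets are rare).
#' Each clone's intBC set is the set detected in more than half of its
#' cells; every cell is then re-scored by Jaccard similarity between its
#' detected intBCs and each single clone and each pairwise clone union.
#' Pair-union winners are doublets; best similarity below 0.5 is
#' unassigned.
#'
#' @param table UMI table.
#' @param n_clones Number of clones (chosen by the analyst).
#' @param method `"nmf"` (default) or `"spectral"`.
#' @param seed Integer seed.
#' @return A list with `assignments` (`data.table` of `cell`, `clone`;
#'   labels `clone1..K`, `"DOUBLET"`, `"UNASSIGNED"`) and `intbc_sets`
#'   (named list of intBC ids per clone).
#' @export
call_clones <- function(table, n_clones, method = c("nmf", "spectral"),
                        seed = 1L) {
  method <- match.arg(method)
  tb <- data.table::as.data.table(table)
  agg <- tb[, .(umis = sum(umis)), by = .(cell, intbc)]
  cells <- sort(unique(agg$cell))
  bcs <- sort(unique(agg$intbc))
  if (n_clones > length(cells)) {
    stop2("invalid_argument", "n_clones exceeds the number of cells")
  }
  X <- matrix(0, length(cells), length(bcs), dimnames = list(cells, bcs))
  X[cbind(match(agg$cell, cells), match(agg$intbc, bcs))] <- agg$umis
  init_cl <- if (method == "nmf") {
    W <- nmf_frobenius(X / max(X), n_clones)$W
    max.col(W, ties.method = "first")
  } else {
    spectral_assign(X, n_clones, seed)
  }
  det <- X > 0
  sets <- lapply(seq_len(n_clones), function(k) {
    members <- det[init_cl == k, , drop = FALSE]
    if (nrow(members) == 0L) return(character(0))
    bcs[colMeans(members) > 0.5]
  })
  names(sets) <- paste0("clone", seq_len(n_clones))
  jac <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0L) return(0)
    length(intersect(a, b)) / u
  }
  pairs <- if (n_clones >= 2L) utils::combn(n_clones, 2L) else
    matrix(integer(0), 2L, 0L)
  labels <- vapply(seq_along(cells), function(i) {
    own <- bcs[det[i, ]]
    ssingle <- vapply(sets, jac, numeric(1), b = own)
    spair <- if (ncol(pairs)) {
      vapply(seq_len(ncol(pairs)), function(p) {
        jac(union(sets[[pairs[1L, p]]], sets[[pairs[2L, p]]]), own)
      }, numeric(1))
    } else numeric(0)
    best <- max(c(ssingle, spair))
    if (best < 0.5) return("UNASSIGNED")
    if (length(spair) && max(spair) > max(ssingle)) return("DOUBLET")
    names(sets)[which.max(ssingle)]
  }, character(1))
  list(assignments = data.table::data.table(cell = cells, clone = labels),
       intbc_sets = sets)
}

#' Greedy static-barcode group calling
#'
#' Iteratively: (1) seed with the barcode detected in the highest fraction
#' of unassigned cells (ties broken lexicographically, each barcode seeds
#' at most once); (2) cluster all barcodes present in more than 80% of the
#' cells where the seed is detected; (3) assign unassigned cells in which
#' the cluster's barcodes account for more than 80% of total barcode UMIs;
#' (4) retain the group only if at least `min_cells` cells were assigned.
#' Stops when no viable seed remains.
#'
#' @param table `data.table` with columns `cell`, `barcode`, `umis`.
#' @param min_cells Minimum group size (default 5).
#' @param co_detection Cluster co-detection threshold (default 0.8).
#' @param umi_share Cell-assignment UMI-share threshold (default 0.8).
#' @return A list with `groups` (`data.table` of `cell`, `group`),
#'   `barcodes` (named list of barcode ids per group) and `unassigned`
#'   (cell ids).
#' @export
call_barcode_groups <- function(table, min_cells = 5L, co_detection = 0.8,
                                umi_share = 0.8) {
  tb <- data.table::as.data.table(table)[umis > 0]
  cells <- sort(unique(tb$cell))
  unassigned <- cells
  used_seeds <- character(0)
  groups <- list(); barcodes <- list()
  assignment <- stats::setNames(rep(NA_character_, length(cells)), cells)
  repeat {
    if (!length(unassigned)) break
    sub <- tb[cell %in% unassigned]
    if (!nrow(sub)) break
    frac <- sub[, .(f = data.table::uniqueN(cell) / length(unassigned)),
                by = barcode][!barcode %in% used_seeds][order(-f, barcode)]
    if (!nrow(frac)) break
    seed_bc <- frac$barcode[1L]
    used_seeds <- c(used_seeds, seed_bc)
    seed_cells <- unique(sub[barcode == seed_bc, cell])
    present <- sub[cell %in% seed_cells,
                   .(f = data.table::uniqueN(cell) / length(seed_cells)),
                   by = barcode]
    cluster <- sort(union(seed_bc, present[f > co_detection, barcode]))
    share <- sub[, .(s = sum(umis[barcode %in% cluster]) / sum(umis)),
                 by = cell]
    members <- share[s > umi_share, cell]
    if (length(members) >= min_cells) {
      g <- paste0("group", length(groups) + 1L)
      groups[[g]] <- members
      barcodes[[g]] <- cluster
      assignment[members] <- g
      unassigned <- setdiff(unassigned, members)
    }
  }
  asg <- data.table::data.table(cell = names(assignment),
                                group = unname(assignment))
  list(groups = asg[!is.na(group)], barcodes = barcodes,
       unassigned = names(assignment)[is.na(assignment)])
}

#' Synthetic UMI table with planted ground truth
#'
#' Emulates an aggregated single-cell lineage-tracing capture: clones with
#' disjoint intBC sets and clone-specific alleles, high-count true records,
#' low-count PCR-error alleles (separable by [gmm_threshold()]), ambient
#' records copying alleles across cells at 1 UMI, merged doublet profiles,
#' optional duplicate integrations, and static-barcode UMIs over one or
#' more barcoding rounds.
#'
#' @param n_clones Number of clones (default 6).
#' @param cells_per_clone Cells per clone (default 100).
#' @param intbcs_per_clone intBC integrations per clone (default 10).
#' @param umi_depth Mean UMIs per true record (default 20).
#' @param ambient_rate Per-cell probability of an ambient record
#'   (default 0.05).
#' @param doublet_rate Fraction of cells that are doublets (default 0.05).
#' @param error_rate Per-record probability of an accompanying low-count
#'   error allele (default 0.1).
#' @param duplicate_intbc_rate Per-clone probability that one intBC is a
#'   duplicate integration (default 0).
#' @param barcode_rounds Static barcoding rounds (default 2).
#' @param groups_per_round Barcode groups per round; each clone is split
#'   into this many groups at round 2+ (default 2).
#' @param n_marks Mark alphabet size (default 8).
#' @param seed Integer seed.
#' @return A list with `table` (UMI table), `barcode_table` (`cell`,
#'   `round`, `barcode`, `umis`) and `truth` (clone per cell, doublet cell
#'   ids, intBC sets, barcode groups per round, duplicated intBCs).
#' @export
synth_umi_table <- function(n_clones = 6L, cells_per_clone = 100L,
                            intbcs_per_clone = 10L, umi_depth = 20,
                            ambient_rate = 0.05, doublet_rate = 0.05,
                            error_rate = 0.1, duplicate_intbc_rate = 0,
                            barcode_rounds = 2L, groups_per_round = 2L,
                            n_marks = 8L, seed = 1L) {
  with_seed(seed, {
    clones <- paste0("clone", seq_len(n_clones))
    intbcs <- split(sprintf("iBC%03d", seq_len(n_clones * intbcs_per_clone)),
                    rep(clones, each = intbcs_per_clone))
    rand_allele <- function() {
      s <- sample(0:n_marks, 3L, replace = TRUE,
                  prob = c(0.3, rep(0.7 / n_marks, n_marks)))
      s
    }
    true_alleles <- lapply(clones, function(cl) {
      al <- replicate(intbcs_per_clone, rand_allele())
      dimnames(al) <- list(NULL, intbcs[[cl]])
      al
    })
    names(true_alleles) <- clones
    dup_bc <- character(0)
    for (cl in clones) {
      if (stats::runif(1) < duplicate_intbc_rate) {
        dup_bc <- c(dup_bc, sample(intbcs[[cl]], 1L))
      }
    }

    n_cells <- n_clones * cells_per_clone
    cell_ids <- sprintf("c%04d", seq_len(n_cells))
    cell_clone <- rep(clones, each = cells_per_clone)
    n_doublets <- round(doublet_rate * n_cells)
    doublet_cells <- if (n_doublets > 0) sample(cell_ids, n_doublets) else
      character(0)
    partner <- stats::setNames(
      vapply(doublet_cells, function(cc) {
        sample(setdiff(clones, cell_clone[match(cc, cell_ids)]), 1L)
      }, character(1)), doublet_cells)

    recs <- list()
    emit <- function(cell, cl, scale = 1) {
      al <- true_alleles[[cl]]
      for (bc in intbcs[[cl]]) {
        u <- max(1L, stats::rpois(1L, umi_depth * scale))
        recs[[length(recs) + 1L]] <<- data.table::data.table(
          cell = cell, intbc = bc, site1 = al[1L, bc], site2 = al[2L, bc],
          site3 = al[3L, bc], umis = u, reads = u * (8L + stats::rpois(1L, 4L)))
        if (bc %in% dup_bc && stats::runif(1) < 0.5) {
          v <- rand_allele()
          recs[[length(recs) + 1L]] <<- data.table::data.table(
            cell = cell, intbc = bc, site1 = v[1L], site2 = v[2L],
            site3 = v[3L], umis = max(1L, stats::rpois(1L, umi_depth * scale)),
            reads = u * (8L + stats::rpois(1L, 4L)))
        }
        if (stats::runif(1) < error_rate) { # PCR-error allele, low reads
          v <- al[, bc]; j <- sample(3L, 1L)
          v[j] <- sample(setdiff(0:n_marks, v[j]), 1L)
          recs[[length(recs) + 1L]] <<- data.table::data.table(
            cell = cell, intbc = bc, site1 = v[1L], site2 = v[2L],
            site3 = v[3L], umis = 1L, reads = 1L + stats::rpois(1L, 1))
        }
      }
    }
    for (i in seq_len(n_cells)) {
      emit(cell_ids[i], cell_clone[i])
      if (cell_ids[i] %in% doublet_cells) {
        emit(cell_ids[i], partner[[cell_ids[i]]], scale = 0.8)
      }
      if (stats::runif(1) < ambient_rate) { # ambient record from elsewhere
        ocl <- sample(clones, 1L)
        bc <- sample(intbcs[[ocl]], 1L)
        al <- true_alleles[[ocl]][, bc]
        recs[[length(recs) + 1L]] <- data.table::data.table(
          cell = cell_ids[i], intbc = bc, site1 = al[1L], site2 = al[2L],
          site3 = al[3L], umis = 1L, reads = 10L + stats::rpois(1L, 4L))
      }
    }
    tb <- data.table::rbindlist(recs)
    tb <- tb[, .(umis = sum(umis), reads = sum(reads)),
             by = .(cell, intbc, site1, site2, site3)]

    bc_recs <- list(); group_truth <- list()
    for (r in seq_len(barcode_rounds)) {
      ng <- if (r == 1L) 1L else groups_per_round
      gt <- stats::setNames(rep(NA_character_, n_cells), cell_ids)
      for (ci in seq_along(clones)) {
        members <- cell_ids[cell_clone == clones[ci]]
        part <- sample(rep(seq_len(ng), length.out = length(members)))
        for (g in seq_len(ng)) {
          gname <- sprintf("r%d_%s_g%d", r, clones[ci], g)
          bc <- sprintf("BC_%s", gname)
          mg <- members[part == g]
          gt[mg] <- gname
          for (cc in mg) {
            bc_recs[[length(bc_recs) + 1L]] <- data.table::data.table(
              cell = cc, round = r, barcode = bc,
              umis = 3L + stats::rpois(1L, 5))
          }
        }
      }
      group_truth[[paste0("round", r)]] <- gt
    }

    list(table = tb[],
         barcode_table = data.table::rbindlist(bc_recs),
         truth = list(clone = stats::setNames(cell_clone, cell_ids),
                      doublets = doublet_cells,
                      intbc_sets = intbcs,
                      groups = group_truth,
                      duplicate_intbcs = dup_bc))
  })
}
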