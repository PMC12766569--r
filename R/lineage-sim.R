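# Birth-death lineage simulation with stochastic lineage-mark accrual, plus
# the recorder-design calculators (edit rates, saturation, minimum edit
# sites).
#
# The simulation model: a single founding cell divides repeatedly; the time
# between divisions is log-normal with mean 1 day, and each cell's lifetime
# competes against an exponential death clock. Edit sites start unedited and
# irreversibly acquire one of S lineage marks (LMs); an unedited site edits
# along a branch of duration t days with probability 1 - (1 - R)^t.

#' Simulate a birth-death lineage tree
#'
#' Division times are log-normal with natural-scale mean 1 day
#' (`meanlog = -sdlog^2/2`) and `sdlog = 0.5` by default; death is a
#' competing exponential clock at `death_rate` per cell per day (a cell dies
#' if its death draw precedes its division draw). The process stops when the
#' number of living lineages reaches `n_extant`; living cells at that moment
#' become the tips, with lifetimes truncated at the stop time. Dead lineages
#' are pruned and pass-through nodes suppressed.
#'
#' @param n_extant Target number of extant cells (>= 2).
#' @param death_rate Death rate per lineage per day (default 0.25).
#' @param lifetime_sdlog Log-scale standard deviation of the division-time
#'   distribution (default 0.5).
#' @param lifetime_meanlog Log-scale mean; default `-lifetime_sdlog^2/2` so
#'   the natural-scale mean lifetime is 1 day.
#' @param seed Integer seed.
#' @param max_retries Number of automatic retries (with seeds derived from
#'   `seed`) when the population goes extinct before reaching `n_extant`;
#'   0 surfaces extinction as an error of class `"EXTINCTION"`.
#' @return An ape `phylo` tree whose tips are the extant cells
#'   (`cell1..celln`), with branch lengths in days and `root.edge` carrying
#'   the founding cell's lifetime.
#' @export
simulate_birth_death <- function(n_extant, death_rate = 0.25,
                                 lifetime_sdlog = 0.5,
                                 lifetime_meanlog = -lifetime_sdlog^2 / 2,
                                 seed = 1L, max_retries = 0L) {
  if (n_extant < 2) stop2("invalid_argument", "n_extant must be >= 2")
  stopifnot(death_rate >= 0)
  for (attempt in 0:max_retries) {
    s <- if (attempt == 0L) seed else derive_seed(seed, paste0("retry", attempt))
    phy <- with_seed(s, tryCatch(
      bd_sim_once(n_extant, death_rate, lifetime_meanlog, lifetime_sdlog),
      EXTINCTION = function(e) e))
    if (!inherits(phy, "condition")) return(phy)
  }
  stop2("EXTINCTION",
        "all lineages died before reaching %d extant cells (%d attempt(s))",
        n_extant, max_retries + 1L)
}

bd_sim_once <- function(n_extant, death_rate, meanlog, sdlog) {
  cap <- 4L * n_extant + 8L
  parent <- integer(cap)    # record index of the parent division node
  btime <- numeric(cap)     # birth time of the cell
  alive <- logical(cap)     # currently a living, undivided cell
  etime <- numeric(cap)     # pending event time for living cells
  edeath <- logical(cap)    # pending event is a death
  nrec <- 0L

  new_cell <- function(par, t0) {
    nrec <<- nrec + 1L
    if (nrec > length(parent)) { # grow
      grow <- length(parent)
      parent <<- c(parent, integer(grow)); btime <<- c(btime, numeric(grow))
      alive <<- c(alive, logical(grow)); etime <<- c(etime, numeric(grow))
      edeath <<- c(edeath, logical(grow))
    }
    div <- stats::rlnorm(1L, meanlog, sdlog)
    dth <- if (death_rate > 0) stats::rexp(1L, death_rate) else Inf
    parent[nrec] <<- par; btime[nrec] <<- t0; alive[nrec] <<- TRUE
    if (dth < div) { etime[nrec] <<- t0 + dth; edeath[nrec] <<- TRUE }
    else           { etime[nrec] <<- t0 + div; edeath[nrec] <<- FALSE }
    nrec
  }

  new_cell(0L, 0)
  repeat {
    live_idx <- which(alive[seq_len(nrec)])
    n_alive <- length(live_idx)
    if (n_alive == 0L) stop2("EXTINCTION", "population extinct")
    i <- live_idx[which.min(etime[live_idx])]
    t <- etime[i]
    alive[i] <- FALSE
    if (edeath[i]) next
    new_cell(i, t)
    new_cell(i, t)
    if (n_alive + 1L == n_extant) {
      # observe the population just before its next event, so extant cells
      # have strictly positive ages
      rest <- which(alive[seq_len(nrec)])
      stop_time <- min(etime[rest])
      break
    }
  }

  live_idx <- which(alive[seq_len(nrec)])
  parent <- parent[seq_len(nrec)]; btime <- btime[seq_len(nrec)]
  alive <- alive[seq_len(nrec)]
  # mark ancestors of extant cells
  keep <- logical(nrec)
  for (i in live_idx) {
    j <- i
    while (j != 0L && !keep[j]) { keep[j] <- TRUE; j <- parent[j] }
  }
  end_time <- numeric(nrec)
  end_time[live_idx] <- stop_time
  divided <- keep & !alive[seq_len(nrec)]
  # a divided record's end time is its children's birth time
  for (j in which(keep)) if (parent[j] != 0L) end_time[parent[j]] <- btime[j]

  # suppress kept nodes with a single kept child (division whose other
  # branch went extinct)
  kids <- vector("list", nrec)
  for (j in which(keep)) if (parent[j] != 0L) {
    kids[[parent[j]]] <- c(kids[[parent[j]]], j)
  }
  eff_parent <- parent; eff_len <- end_time - btime
  for (j in which(divided)) {
    if (length(kids[[j]]) == 1L) {
      ch <- kids[[j]]
      eff_parent[ch] <- eff_parent[j]
      eff_len[ch] <- eff_len[ch] + eff_len[j]
      keep[j] <- FALSE
    }
  }
  # recompute child lists on the collapsed structure
  kids <- vector("list", nrec)
  root <- 0L
  for (j in which(keep)) {
    p <- eff_parent[j]
    while (p != 0L && !keep[p]) p <- eff_parent[p]
    eff_parent[j] <- p
    if (p == 0L) root <- j else kids[[p]] <- c(kids[[p]], j)
  }

  tips <- live_idx
  ntip <- length(tips)
  stopifnot(ntip == n_extant)
  nint <- sum(keep) - ntip
  num <- integer(nrec)
  num[tips] <- seq_len(ntip)
  internals <- setdiff(which(keep), tips)
  # order internals root-first for a valid phylo numbering
  internals <- internals[order(btime[internals])]
  num[internals] <- ntip + seq_len(nint)

  edge <- matrix(0L, ntip + nint - 1L, 2L)
  elen <- numeric(nrow(edge))
  k <- 0L
  for (j in which(keep)) {
    if (j == root) next
    k <- k + 1L
    edge[k, ] <- c(num[eff_parent[j]], num[j])
    elen[k] <- eff_len[j]
  }
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = paste0("cell", seq_len(ntip)),
                        Nnode = nint, root.edge = eff_len[root]),
                   class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy
}

#' Per-day edit rate needed to reach a target edit fraction
#'
#' Inverts the saturation law `F = 1 - (1 - R)^T`: applying an independent
#' per-day editing probability `R` for `T` days leaves an expected unedited
#' fraction `1 - F`.
#'
#' @param target_fraction Target edit fraction `F` in `[0, 1)`.
#' @param duration_days Experiment length `T` in days (> 0).
#' @return Per-day edit rate `R` in `[0, 1)`.
#' @export
edit_rate_for_target_fraction <- function(target_fraction, duration_days) {
  if (target_fraction < 0 || target_fraction >= 1) {
    stop2("invalid_argument", "target_fraction must be in [0, 1)")
  }
  if (duration_days <= 0) stop2("invalid_argument", "duration_days must be > 0")
  1 - (1 - target_fraction)^(1 / duration_days)
}

#' Overlay stochastic lineage-mark accrual on a tree
#'
#' Starting from an all-unedited root, each unedited site edits along a
#' branch of duration `t` days with probability `1 - (1 - R)^t`; an edited
#' site never changes again (irreversibility), and the installed mark is
#' drawn from `lm_probs`. Editing on the founding cell's own lifetime
#' (`root.edge`) is included.
#'
#' @param phy `phylo` tree with branch lengths in days.
#' @param n_sites Number of edit sites `M`.
#' @param lm_probs Probability vector over the `S` lineage marks.
#' @param edit_rate Per-day edit rate `R`; if `NULL`, derived from
#'   `target_fraction` and the experiment duration (maximum root-to-tip
#'   time) via [edit_rate_for_target_fraction()].
#' @param target_fraction Target end-point edit fraction `F` (used only when
#'   `edit_rate` is `NULL`).
#' @param seed Integer seed.
#' @return A list with `states` (full per-node state matrix, rows indexed by
#'   phylo node number) and `cm` (leaf [character_matrix()], no missing
#'   entries).
#' @export
overlay_lineage_marks <- function(phy, n_sites, lm_probs, edit_rate = NULL,
                                  target_fraction = NULL, seed = 1L) {
  if (is.null(phy$edge.length)) {
    stop2("no_branch_lengths", "tree has no branch lengths")
  }
  stopifnot(n_sites >= 1, abs(sum(lm_probs) - 1) < 1e-9)
  S <- length(lm_probs)
  if (is.null(edit_rate)) {
    if (is.null(target_fraction)) {
      stop2("invalid_argument", "supply edit_rate or target_fraction")
    }
    edit_rate <- edit_rate_for_target_fraction(target_fraction,
                                               max(node_times(phy)))
  }
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  states <- matrix(0L, nn, n_sites)
  with_seed(seed, {
    root <- tree_root(phy)
    redge <- phy$root.edge %||% 0
    if (redge > 0) {
      states[root, ] <- edit_sites(states[root, ], edit_rate, redge, lm_probs)
    }
    ord <- order(node_depths(phy)[phy$edge[, 1L]]) # parents before children
    for (i in ord) {
      p <- phy$edge[i, 1L]; v <- phy$edge[i, 2L]
      states[v, ] <- edit_sites(states[p, ], edit_rate,
                                phy$edge.length[i], lm_probs)
    }
  })
  cm <- states[seq_len(ntip), , drop = FALSE]
  rownames(cm) <- phy$tip.label
  colnames(cm) <- paste0("site", seq_len(n_sites))
  list(states = states, cm = character_matrix(cm, S))
}

# one inheritance step: unedited sites edit w.p. 1-(1-R)^t
edit_sites <- function(state, rate, t, lm_probs) {
  ue <- which(state == 0L)
  if (!length(ue)) return(state)
  p <- 1 - (1 - rate)^t
  hit <- ue[stats::runif(length(ue)) < p]
  if (length(hit)) {
    state[hit] <- sample.int(length(lm_probs), length(hit), replace = TRUE,
                             prob = lm_probs)
  }
  state
}

#' Apply detection dropout to a character matrix
#'
#' Each entry is independently replaced by missing with probability
#' `1 - detection`, emulating imperfect cassette readout.
#'
#' @param cm A [character_matrix()].
#' @param detection Detection efficiency `D` in `[0, 1]`.
#' @param seed Integer seed.
#' @return A new [character_matrix()]; the input is not modified.
#' @export
apply_detection_dropout <- function(cm, detection, seed = 1L) {
  if (detection < 0 || detection > 1) {
    stop2("invalid_argument", "detection must be in [0, 1]")
  }
  m <- cm_data(cm)
  with_seed(seed, {
    drop <- stats::runif(length(m)) > detection
    m[drop] <- NA_integer_
  })
  character_matrix(m, n_marks(cm))
}

#' Normalized entropy of a lineage-mark distribution
#'
#' `H_norm = -sum(p_i log p_i) / log S`, in `[0, 1]`; 1 iff uniform.
#'
#' @param probs Probability vector over `S >= 2` marks.
#' @return Normalized entropy.
#' @export
normalized_entropy <- function(probs) {
  S <- length(probs)
  if (S < 2) stop2("invalid_argument", "need at least 2 marks")
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9) {
    stop2("invalid_argument", "probs must be nonnegative and sum to 1")
  }
  nz <- probs[probs > 0]
  -sum(nz * log(nz)) / log(S)
}

#' Exponential-family LM distribution achieving a target entropy
#'
#' Mark probabilities follow `p_i` proportional to `exp(-lambda * i)`;
#' `lambda` is found by monotone bisection so the normalized entropy matches
#' `target_hnorm` within `tol`. A target of 1 returns the exact uniform
#' distribution (the `lambda -> 0` limit).
#'
#' @param n_marks Number of marks `S >= 2`.
#' @param target_hnorm Target normalized entropy in `(0, 1]`.
#' @param tol Entropy tolerance (default 1e-3).
#' @return Probability vector of length `n_marks`.
#' @export
lm_distribution_for_entropy <- function(n_marks, target_hnorm, tol = 1e-3) {
  if (n_marks < 2) stop2("invalid_argument", "n_marks must be >= 2")
  if (target_hnorm <= 0 || target_hnorm > 1) {
    stop2("invalid_argument", "target_hnorm must be in (0, 1]")
  }
  if (target_hnorm == 1) return(rep(1 / n_marks, n_marks))
  pfun <- function(lam) {
    w <- exp(-lam * seq_len(n_marks))
    w / sum(w)
  }
  lo <- 1e-9; hi <- 1
  while (normalized_entropy(pfun(hi)) > target_hnorm) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    h <- normalized_entropy(pfun(mid))
    if (abs(h - target_hnorm) < tol / 4) break
    if (h > target_hnorm) lo <- mid else hi <- mid
  }
  pfun(mid)
}

# --- recorder-design calculators -------------------------------------------
#
# These use the simplified uniform-division framework: 100 modeled lineages,
# one division per day, no death, per-day per-site Bernoulli editing with
# site depletion.

#' Expected marked-division fraction under the simplified framework
#'
#' Closed form for the expected fraction of divisions marked by at least one
#' new edit over `n_divisions` one-day divisions: the number of still-unedited
#' sites entering division `t` is Binomial(`n_sites`, `(1-r)^(t-1)`), so the
#' marking probability at division `t` is
#' `1 - (1 - (1-r)^(t-1) * r)^n_sites`.
#'
#' @param rate Per-day per-site edit probability.
#' @param n_sites Number of edit sites.
#' @param n_divisions Number of divisions (days).
#' @return Expected fraction of marked divisions.
#' @export
expected_marked_fraction <- function(rate, n_sites, n_divisions) {
  q <- 1 - rate
  t <- seq_len(n_divisions)
  mean(1 - (1 - q^(t - 1) * rate)^n_sites)
}

# simulate the marked-division fraction: lineages x divisions, site depletion
simulate_marked_fraction <- function(rate, n_sites, n_divisions,
                                     n_lineages = 100L, reps = 10L) {
  nl <- n_lineages * reps
  u <- rep(n_sites, nl)
  marked <- 0L
  for (t in seq_len(n_divisions)) {
    e <- stats::rbinom(nl, u, rate)
    marked <- marked + sum(e > 0L)
    u <- u - e
  }
  marked / (nl * n_divisions)
}

# simulate end-point edit saturation through the explicit daily process
simulate_saturation <- function(rate, n_days, n_lineages = 100L,
                                n_sites = 100L, reps = 10L) {
  per_rep <- numeric(reps)
  for (r in seq_len(reps)) {
    u <- rep(n_sites, n_lineages)
    for (t in seq_len(n_days)) u <- u - stats::rbinom(n_lineages, u, rate)
    per_rep[r] <- 1 - mean(u) / n_sites
  }
  per_rep
}

#' Edit rates achieving target saturation levels
#'
#' For each experiment length and saturation target, scans the rate grid and
#' returns the rate whose mean simulated end-point edit fraction (100
#' modeled lineages, one division per day, no death, averaged over `reps`
#' repetitions) is closest to the target. The end-point edit count per
#' lineage is drawn exactly as Binomial(`n_sites`, `1-(1-r)^T`), the marginal
#' law of the daily per-site Bernoulli process.
#'
#' @param experiment_lengths Integer vector of experiment lengths in days.
#' @param targets Saturation targets (default `c(0.5, 0.6, 0.7, 0.8, 0.9)`).
#' @param rate_grid Candidate rates (default `seq(0, 0.3, 0.001)`).
#' @param reps Repetitions per grid point (default 10).
#' @param n_lineages Modeled lineages (default 100).
#' @param n_sites Edit sites per modeled lineage (default 100).
#' @param seed Integer seed.
#' @return A `data.table` with columns `days`, `target`, `rate`, `achieved`
#'   and `capped` (TRUE when the best grid rate still falls short by more
#'   than 0.01, i.e. the target is out of reach on this grid).
#' @export
saturation_rate_table <- function(experiment_lengths = 1:100,
                                  targets = c(0.5, 0.6, 0.7, 0.8, 0.9),
                                  rate_grid = seq(0, 0.3, 0.001),
                                  reps = 10L, n_lineages = 100L,
                                  n_sites = 100L, seed = 1L) {
  stopifnot(length(experiment_lengths) > 0, length(rate_grid) > 0)
  out <- vector("list", length(experiment_lengths))
  with_seed(seed, {
    for (k in seq_along(experiment_lengths)) {
      T <- experiment_lengths[k]
      sat <- vapply(rate_grid, function(r) {
        p <- 1 - (1 - r)^T
        mean(stats::rbinom(n_lineages * reps, n_sites, p)) / n_sites
      }, numeric(1))
      rows <- lapply(targets, function(tg) {
        i <- which.min(abs(sat - tg))
        data.table::data.table(days = T, target = tg, rate = rate_grid[i],
                               achieved = sat[i],
                               capped = sat[i] < tg - 0.01)
      })
      out[[k]] <- data.table::rbindlist(rows)
    }
  })
  data.table::rbindlist(out)
}

#' Minimum edit sites to mark a target fraction of divisions
#'
#' Implements the simplified recorder-design scan: 100 modeled lineages each
#' undergoing `n_divisions` one-day divisions with no death; per division,
#' every still-unedited site edits with the per-day rate; a division is
#' marked when at least one site edits. For each candidate site count `M`
#' the rate grid is scanned, the marked-division fraction is averaged over
#' `reps` repetitions, and the smallest `M` whose best rate reaches
#' `target` is returned.
#'
#' The closed-form expectation ([expected_marked_fraction()]) prunes the
#' scan: site counts whose analytic optimum is more than `prune_margin`
#' below the target cannot win (the margin is several Monte-Carlo standard
#' errors wide), and only rates within `prune_margin` of the per-`M`
#' analytic optimum are simulated.
#'
#' @param n_divisions Divisions per lineage (= experiment days/doublings).
#' @param target Target marked-division fraction (e.g. 0.9).
#' @param site_grid Candidate site counts (default `1:120`).
#' @param rate_grid Candidate rates (default `seq(0, 0.3, 0.001)`).
#' @param reps Repetitions per (site count, rate) cell (default 10).
#' @param n_lineages Modeled lineages (default 100).
#' @param seed Integer seed.
#' @param prune_margin Analytic pruning margin (default 0.01); set to `Inf`
#'   to simulate the full grid.
#' @return A list with `n_sites` (minimal `M`, or `NA` with
#'   `achievable = FALSE` when no site count in the grid reaches the
#'   target), `rate` (the optimizing rate), `achieved` (its mean marked
#'   fraction) and `achievable`.
#' @export
min_edit_sites_for_marked_fraction <- function(n_divisions, target = 0.9,
                                               site_grid = 1:120,
                                               rate_grid = seq(0, 0.3, 0.001),
                                               reps = 10L, n_lineages = 100L,
                                               seed = 1L,
                                               prune_margin = 0.01) {
  stopifnot(length(site_grid) > 0, length(rate_grid) > 0, target > 0,
            target < 1)
  site_grid <- sort(site_grid)
  exp_best <- matrix(NA_real_, length(site_grid), length(rate_grid))
  for (i in seq_along(site_grid)) {
    exp_best[i, ] <- vapply(rate_grid, expected_marked_fraction,
                            numeric(1), n_sites = site_grid[i],
                            n_divisions = n_divisions)
  }
  per_m_best <- apply(exp_best, 1L, max)
  candidates <- which(per_m_best >= target - prune_margin)
  result <- list(n_sites = NA_integer_, rate = NA_real_,
                 achieved = NA_real_, achievable = FALSE)
  with_seed(seed, {
    for (i in candidates) {
      keep <- which(exp_best[i, ] >= per_m_best[i] - prune_margin)
      sim <- vapply(rate_grid[keep], simulate_marked_fraction, numeric(1),
                    n_sites = site_grid[i], n_divisions = n_divisions,
                    n_lineages = n_lineages, reps = reps)
      j <- which.max(sim)
      if (sim[j] >= target) {
        result <- list(n_sites = site_grid[i], rate = rate_grid[keep][j],
                       achieved = sim[j], achievable = TRUE)
        break
      }
    }
  })
  result
}

#' Plant static-barcode groups on a simulated tree
#'
#' Emulates a lentiviral barcoding round at time `at_time`: every lineage
#' alive at that moment receives a distinct barcode, and the group of a
#' barcode is the set of extant descendants of that lineage. Ground truth
#' for clade-recovery benchmarking.
#'
#' @param phy `phylo` tree with branch lengths in days (from
#'   [simulate_birth_death()]).
#' @param at_time Barcoding time in days since the start.
#' @return Named list of tip-label vectors, one per barcoded lineage.
#' @export
plant_barcode_groups <- function(phy, at_time) {
  tm <- node_times(phy)
  ntip <- ape::Ntip(phy)
  if (at_time <= tm[tree_root(phy)]) {
    return(list(bc1 = phy$tip.label))
  }
  pt <- tm[phy$edge[, 1L]]
  ct <- tm[phy$edge[, 2L]]
  alive <- which(pt <= at_time & (at_time < ct |
                                    (phy$edge[, 2L] <= ntip &
                                       abs(ct - at_time) < 1e-9)))
  dt <- descendant_tips(phy)
  groups <- lapply(alive, function(i) {
    phy$tip.label[dt[[phy$edge[i, 2L]]]]
  })
  names(groups) <- paste0("bc", seq_along(groups))
  groups
}
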