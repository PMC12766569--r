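# Imaging-readout decoding: constant-weight error-correcting codebooks for
# integration barcodes, EM intensity normalization and nearest-codeword
# assignment, lineage-mark decoding with an optional calibrated classifier,
# and the imaging QC rules.

#' Build a constant-weight codebook by greedy lexicographic accumulation
#'
#' Enumerates all weight-`weight` binary vectors of length `n_bits` in
#' lexicographic order and admits a candidate iff its Hamming distance to
#' every accepted codeword is at least `min_dist`. The defaults give the
#' weight-6, distance-4, 21-bit code family used for integration barcodes.
#' The construction is deterministic.
#'
#' @param n_bits Code length (default 21).
#' @param weight Hamming weight per codeword (default 6).
#' @param min_dist Minimum pairwise Hamming distance (default 4).
#' @param target_size Stop after this many codewords (default: exhaust the
#'   candidate list).
#' @return A list of class `"codebook"`: `codewords` (0/1 matrix, one row
#'   per codeword, rownames = intBC ids), `n_bits`, `weight`, `min_dist`.
#' @export
build_codebook <- function(n_bits = 21L, weight = 6L, min_dist = 4L,
                           target_size = NULL) {
  stopifnot(n_bits >= weight, weight >= min_dist / 2)
  combos <- utils::combn(n_bits, weight)
  accepted <- matrix(0L, 0L, n_bits)
  for (i in seq_len(ncol(combos))) {
    cand <- integer(n_bits); cand[combos[, i]] <- 1L
    if (nrow(accepted) == 0L ||
        all(colSums(abs(t(accepted) - cand)) >= min_dist)) {
      accepted <- rbind(accepted, cand)
      if (!is.null(target_size) && nrow(accepted) >= target_size) break
    }
  }
  if (!is.null(target_size) && nrow(accepted) < target_size) {
    stop2("codebook_too_small",
          "only %d codewords achievable (requested %d)",
          nrow(accepted), target_size)
  }
  rownames(accepted) <- sprintf("intBC%04d", seq_len(nrow(accepted)))
  structure(list(codewords = accepted, n_bits = n_bits, weight = weight,
                 min_dist = min_dist),
            class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("codebook: %d codewords, %d bits, weight %d, min distance %d\n",
              nrow(x$codewords), x$n_bits, x$weight, x$min_dist))
  invisible(x)
}

#' Validate a codebook's structural constraints
#'
#' Checks constant Hamming weight, minimum pairwise distance, and id
#' uniqueness; every violation is reported.
#'
#' @param cb A [build_codebook()] object (or a compatible list).
#' @return Character vector of violations; empty when valid.
#' @export
validate_codebook <- function(cb) {
  cw <- cb$codewords
  viol <- character(0)
  w <- rowSums(cw)
  bad_w <- which(w != cb$weight)
  for (i in bad_w) {
    viol <- c(viol, sprintf("codeword %s has weight %d (expected %d)",
                            rownames(cw)[i], w[i], cb$weight))
  }
  if (anyDuplicated(rownames(cw))) {
    viol <- c(viol, "duplicate codeword ids")
  }
  if (nrow(cw) >= 2L) {
    dm <- as.matrix(stats::dist(cw, method = "manhattan"))
    bad <- which(dm < cb$min_dist & upper.tri(dm), arr.ind = TRUE)
    for (k in seq_len(nrow(bad))) {
      viol <- c(viol, sprintf("codewords %s and %s at distance %d (< %d)",
                              rownames(cw)[bad[k, 1L]],
                              rownames(cw)[bad[k, 2L]],
                              dm[bad[k, 1L], bad[k, 2L]], cb$min_dist))
    }
  }
  viol
}

#' Read / write a codebook as CSV
#'
#' Columns `intbc_id`, `bitstring` (`n_bits` characters of 0/1).
#'
#' @param path CSV path.
#' @param cb A codebook (for writing).
#' @param min_dist Declared minimum distance when reading (default 4).
#' @return [read_codebook()] returns a codebook; [write_codebook()] returns
#'   `path` invisibly.
#' @export
read_codebook <- function(path, min_dist = 4L) {
  dt <- data.table::fread(path)
  bits <- do.call(rbind, lapply(strsplit(dt$bitstring, ""), as.integer))
  rownames(bits) <- dt$intbc_id
  structure(list(codewords = bits, n_bits = ncol(bits),
                 weight = as.integer(stats::median(rowSums(bits))),
                 min_dist = min_dist),
            class = "codebook")
}

#' @rdname read_codebook
#' @export
write_codebook <- function(cb, path) {
  dt <- data.table::data.table(
    intbc_id = rownames(cb$codewords),
    bitstring = apply(cb$codewords, 1L, paste, collapse = ""))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Decode spot intensities to integration barcodes by EM
#'
#' Iterates intensity normalization and nearest-codeword assignment.
#' Intensities are first column-balanced across color channels, then
#' corrected as `X / (s_intensity . b_intensity)` where `s_intensity` is
#' the per-spot mean over its codeword's "1" bits (initialized at the 95th
#' row percentile) and `b_intensity` the per-bit mean over spots
#' (initialized at the 95th column percentile after spot scaling), then
#' adjusted for each bit's noise floor `(X - 1/b_snr) / (1 - 1/b_snr)` and
#' clipped at 1. The E-step assigns each spot to the codeword minimizing
#' the Euclidean distance to its corrected intensity vector; spots at
#' distance >= `max_dist` are masked. The M-step re-estimates `s_intensity`
#' from all spots and `b_intensity`/`b_snr` from confidently assigned
#' (unmasked) spots.
#'
#' @param X Spots x bits nonnegative intensity matrix.
#' @param cb A codebook whose bit length matches `ncol(X)`.
#' @param max_dist Masking distance (default 1.7; the in vivo whitelist
#'   variant uses 2).
#' @param iterations EM iterations (default 10).
#' @param whitelist Optional intBC-id subset to decode against.
#' @param channel_map Optional integer vector mapping each bit to a color
#'   channel for color balancing; default cycles 3 channels.
#' @return A list: `assignments` (`data.table` of `spot`, `intbc`,
#'   `distance`, `masked`), `bit_efficiency`, `bit_snr`, `spot_intensity`,
#'   `mean_distance_trace`.
#' @export
em_decode_intbc <- function(X, cb, max_dist = 1.7, iterations = 10L,
                            whitelist = NULL, channel_map = NULL) {
  X <- as.matrix(X)
  if (ncol(X) != cb$n_bits) {
    stop2("dim_mismatch", "X has %d bits but codebook %d", ncol(X), cb$n_bits)
  }
  cw <- cb$codewords
  if (!is.null(whitelist)) {
    miss <- setdiff(whitelist, rownames(cw))
    if (length(miss)) stop2("invalid_argument",
                            "whitelist ids not in codebook: %s",
                            paste(miss, collapse = ", "))
    cw <- cw[whitelist, , drop = FALSE]
  }
  N <- nrow(X)
  spot_ids <- rownames(X) %||% as.character(seq_len(N))
  zero_rows <- rowSums(X) == 0
  channel_map <- channel_map %||% rep_len(1:3, ncol(X))
  # color balance once: equalize mean intensity across channels
  ch_mean <- tapply(colMeans(X), channel_map, mean)
  target <- mean(ch_mean)
  for (ch in names(ch_mean)) {
    idx <- which(channel_map == as.integer(ch))
    if (ch_mean[[ch]] > 0) X[, idx] <- X[, idx] * target / ch_mean[[ch]]
  }

  q95 <- function(v) stats::quantile(v, 0.95, names = FALSE, type = 7)
  s_int <- apply(X, 1L, q95)
  s_int[s_int <= 0] <- 1
  b_int <- apply(X / s_int, 2L, q95)
  b_int[b_int <= 0] <- 1
  b_snr <- rep(Inf, ncol(X))
  cw_norm2 <- rowSums(cw^2)
  trace <- numeric(iterations)
  assign_idx <- integer(N); dist_best <- numeric(N)

  for (it in seq_len(iterations)) {
    Xc <- X / (s_int %o% b_int)
    corr <- 1 / b_snr
    corr[!is.finite(corr)] <- 0
    Xc <- sweep(sweep(Xc, 2L, corr, "-"), 2L, 1 - corr, "/")
    Xc[Xc > 1] <- 1
    Xc[Xc < 0] <- 0
    # nearest codeword by Euclidean distance
    d2 <- outer(rowSums(Xc^2), cw_norm2, "+") - 2 * Xc %*% t(cw)
    assign_idx <- max.col(-d2, ties.method = "first")
    dist_best <- sqrt(pmax(0, d2[cbind(seq_len(N), assign_idx)]))
    dist_best[zero_rows] <- Inf
    masked <- dist_best >= max_dist
    trace[it] <- mean(dist_best[!masked & is.finite(dist_best)])
    on_bits <- cw[assign_idx, , drop = FALSE] == 1L
    # M-step: s from all rows, b and snr from confidently assigned spots
    s_int <- vapply(seq_len(N), function(i) {
      v <- X[i, on_bits[i, ]] / b_int[on_bits[i, ]]
      if (!length(v)) 1 else mean(v)
    }, numeric(1))
    s_int[s_int <= 0 | !is.finite(s_int)] <- 1
    conf <- !masked
    if (any(conf)) {
      Xs <- X[conf, , drop = FALSE] / s_int[conf]
      on <- on_bits[conf, , drop = FALSE]
      for (b in seq_len(ncol(X))) {
        on_v <- Xs[on[, b], b]; off_v <- Xs[!on[, b], b]
        if (length(on_v)) b_int[b] <- mean(on_v)
        if (length(on_v) && length(off_v) && mean(off_v) > 0) {
          b_snr[b] <- max(mean(on_v) / mean(off_v), 1.05)
        }
      }
      b_int[b_int <= 0 | !is.finite(b_int)] <- 1
    }
  }
  list(assignments = data.table::data.table(
    spot = spot_ids,
    intbc = ifelse(dist_best >= max_dist, NA_character_,
                   rownames(cw)[assign_idx]),
    distance = dist_best,
    masked = dist_best >= max_dist),
    bit_efficiency = b_int, bit_snr = b_snr, spot_intensity = s_int,
    mean_distance_trace = trace)
}

#' Decode lineage marks from per-site intensity vectors
#'
#' Each edit site is read out over `S + 1` bits (the `S` marks plus the
#' unedited state). Rows are normalized to sum to one; the baseline call is
#' the argmax bit. When a trained classifier is supplied (see
#' [train_lm_classifier()]) its prediction and probability are used
#' instead; calls with probability below `min_prob` are flagged
#' low-confidence. Zero-sum rows return `NA` with zero confidence.
#'
#' @param X_site Spots x (S+1) nonnegative intensity matrix; column 1 is
#'   the unedited bit, columns 2..S+1 the marks.
#' @param classifier Optional `nnet::multinom` model.
#' @param min_prob Confidence threshold (default 0.7).
#' @return `data.table` with `spot`, `state` (0 = unedited, 1..S = mark,
#'   `NA` for zero rows), `prob`, `low_confidence`.
#' @export
decode_lm <- function(X_site, classifier = NULL, min_prob = 0.7) {
  X_site <- as.matrix(X_site)
  spot_ids <- rownames(X_site) %||% as.character(seq_len(nrow(X_site)))
  rs <- rowSums(X_site)
  Xn <- X_site / ifelse(rs > 0, rs, 1)
  if (is.null(classifier)) {
    state <- max.col(Xn, ties.method = "first") - 1L
    prob <- Xn[cbind(seq_len(nrow(Xn)), state + 1L)]
  } else {
    pr <- predict_lm_classifier(classifier, Xn)
    state <- pr$state; prob <- pr$prob
  }
  state[rs == 0] <- NA_integer_
  prob[rs == 0] <- 0
  data.table::data.table(spot = spot_ids, state = state, prob = prob,
                         low_confidence = prob < min_prob)
}

#' Train a per-site lineage-mark classifier
#'
#' Multinomial logistic regression (with a mild L2 ridge through
#' `nnet::multinom`'s weight decay) on row-normalized per-site intensity
#' vectors, learning probe-affinity and cross-hybridization structure that
#' the argmax baseline ignores.
#'
#' @param X_site Spots x (S+1) intensity matrix (training spots).
#' @param states True states (0 = unedited, 1..S).
#' @param decay L2 penalty (default 1).
#' @return A fitted classifier for [decode_lm()].
#' @export
train_lm_classifier <- function(X_site, states, decay = 1) {
  X_site <- as.matrix(X_site)
  rs <- rowSums(X_site)
  Xn <- X_site / ifelse(rs > 0, rs, 1)
  df <- data.frame(Xn)
  names(df) <- paste0("b", seq_len(ncol(Xn)))
  df$.state <- factor(states, levels = sort(unique(states)))
  nnet::multinom(.state ~ ., data = df, decay = decay, trace = FALSE,
                 maxit = 300)
}

predict_lm_classifier <- function(classifier, Xn) {
  df <- data.frame(Xn)
  names(df) <- paste0("b", seq_len(ncol(Xn)))
  pp <- predict(classifier, df, type = "probs")
  if (is.null(dim(pp))) pp <- cbind(1 - pp, pp) # two-class edge case
  lev <- as.integer(classifier$lev)
  idx <- max.col(pp, ties.method = "first")
  list(state = lev[idx], prob = pp[cbind(seq_len(nrow(pp)), idx)])
}

#' Imaging lineage-mark quality control
#'
#' Applies, in order: (1) drop amplicons with mean mark-assignment
#' probability below `min_mean_prob` across the edit sites; (2) among
#' amplicons with identical (intBC, mark set) in a cell, keep only the
#' brightest (duplicate spot detections); (3) drop intBCs detected with
#' conflicting mark sets in more than `max_dup_fraction` of a clone's
#' cells (duplicate integrations); (4) drop cells whose conflicting-
#' amplicon fraction exceeds `max_cell_conflict` (segmentation doublets);
#' (5) resolve remaining conflicts per (cell, intBC) by preferring in-mask
#' amplicons, then the brightest.
#'
#' @param amplicons `data.table` with columns `cell`, `intbc`, `site1..`,
#'   `mean_prob`, `brightness`, `in_mask` (logical), `clone`.
#' @param min_mean_prob Rule-1 threshold (default 0.7).
#' @param max_dup_fraction Rule-3 threshold (default 0.4, strict).
#' @param max_cell_conflict Rule-4 threshold (default 0.5, strict).
#' @return Filtered table with one record per (cell, intBC).
#' @export
imaging_lm_qc <- function(amplicons, min_mean_prob = 0.7,
                          max_dup_fraction = 0.4, max_cell_conflict = 0.5) {
  tb <- data.table::as.data.table(amplicons)
  sc <- site_cols(tb)
  tb <- tb[mean_prob >= min_mean_prob]
  tb[, .lm := do.call(paste, c(.SD, sep = ",")), .SDcols = sc]
  # duplicate spot detections: keep the brightest per identical call
  tb <- tb[order(-brightness)][, .SD[1L], by = c("cell", "intbc", ".lm")]
  # duplicate integrations: conflicting mark sets across a clone's cells
  conf_cell <- tb[, .(n_lm = data.table::uniqueN(.lm)),
                  by = .(clone, intbc, cell)]
  dup <- conf_cell[, .(frac = mean(n_lm > 1L)), by = .(clone, intbc)]
  tb <- tb[!dup[frac > max_dup_fraction], on = c("clone", "intbc")]
  # segmentation doublets: cells dominated by conflicting amplicons
  cnt <- tb[, .(n = .N, n_unique = data.table::uniqueN(.lm)),
            by = .(cell, intbc)]
  cellfrac <- cnt[, .(frac = sum(n[n_unique > 1L]) / sum(n)), by = cell]
  tb <- tb[!cellfrac[frac > max_cell_conflict], on = "cell"]
  # resolve remaining conflicts: in-mask first, then brightest
  tb <- tb[order(-in_mask, -brightness)][, .SD[1L], by = .(cell, intbc)]
  tb[, .lm := NULL]
  tb[]
}

#' Simulate spot intensities for decoder benchmarking
#'
#' Generates the intensity structure the EM model assumes: per-spot
#' brightness (log-normal) times per-bit efficiency on "1" bits, a
#' background level set by the per-bit signal-to-noise ratio on "0" bits,
#' and additive half-normal noise. Per-site mark bit matrices are emitted
#' alongside the integration-barcode bits.
#'
#' @param cb A codebook.
#' @param n_spots Number of spots.
#' @param n_sites Edit sites per cassette (default 3).
#' @param n_marks Marks per site (default 8; each site reads out over
#'   `n_marks + 1` bits).
#' @param brightness_meanlog,brightness_sdlog Spot-brightness log-normal
#'   parameters (defaults 0 and 0.5).
#' @param bit_efficiency_range Per-bit efficiency range (default
#'   `c(0.5, 1.5)`).
#' @param snr Signal-to-noise ratio (default 8; `Inf` for noiseless).
#' @param noise_sd Additive noise scale relative to signal (default 0.05;
#'   0 for noiseless).
#' @param bleed Fraction of a mark bit's intensity bleeding into the other
#'   bits of its site (default 0).
#' @param seed Integer seed.
#' @return A list: `X` (spots x bits intBC intensities), `site_X` (list of
#'   spots x (n_marks+1) matrices), `truth` (`data.table` of `spot`,
#'   `intbc`, `site1..`), `bit_efficiency`.
#' @export
synth_spot_intensities <- function(cb, n_spots, n_sites = 3L, n_marks = 8L,
                                   brightness_meanlog = 0,
                                   brightness_sdlog = 0.5,
                                   bit_efficiency_range = c(0.5, 1.5),
                                   snr = 8, noise_sd = 0.05, bleed = 0,
                                   seed = 1L) {
  with_seed(seed, {
    K <- nrow(cb$codewords)
    idx <- sample.int(K, n_spots, replace = TRUE)
    bright <- stats::rlnorm(n_spots, brightness_meanlog, brightness_sdlog)
    eff <- stats::runif(cb$n_bits, bit_efficiency_range[1L],
                        bit_efficiency_range[2L])
    on <- cb$codewords[idx, , drop = FALSE]
    sig <- bright %o% eff
    bg <- if (is.finite(snr)) sig / snr else 0
    X <- on * sig + (1 - on) * bg
    if (noise_sd > 0) {
      X <- X + abs(stats::rnorm(length(X), 0, noise_sd * mean(sig))) *
        matrix(1, n_spots, cb$n_bits)
    }
    rownames(X) <- sprintf("spot%05d", seq_len(n_spots))

    site_states <- matrix(sample(0:n_marks, n_spots * n_sites,
                                 replace = TRUE), n_spots, n_sites)
    site_X <- lapply(seq_len(n_sites), function(s) {
      onehot <- matrix(0, n_spots, n_marks + 1L)
      onehot[cbind(seq_len(n_spots), site_states[, s] + 1L)] <- 1
      if (bleed > 0) {
        onehot <- onehot * (1 - bleed) + bleed / n_marks
      }
      eff_s <- stats::runif(n_marks + 1L, bit_efficiency_range[1L],
                            bit_efficiency_range[2L])
      Xs <- onehot * (bright %o% eff_s)
      if (is.finite(snr)) Xs <- Xs + (bright %o% eff_s) / snr * (onehot == 0)
      if (noise_sd > 0) {
        Xs <- Xs + abs(stats::rnorm(length(Xs), 0, noise_sd * mean(bright)))
      }
      rownames(Xs) <- rownames(X)
      Xs
    })
    truth <- data.table::data.table(spot = rownames(X),
                                    intbc = rownames(cb$codewords)[idx])
    for (s in seq_len(n_sites)) truth[[paste0("site", s)]] <- site_states[, s]
    list(X = X, site_X = site_X, truth = truth, bit_efficiency = eff)
  })
}
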