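# Editing-kinetics estimation: per-cell edit fractions and the saturating
# exponential fit f(t) = s * (1 - exp(-r t)).

#' Per-cell edit fraction
#'
#' Fraction of detected (non-missing) edit sites carrying a mark, per cell.
#' Cells with no detected site are excluded with a warning.
#'
#' @param cm A [character_matrix()].
#' @return Named numeric vector (cell id -> fraction).
#' @export
per_cell_edit_fraction <- function(cm) {
  m <- cm_data(cm)
  detected <- rowSums(!is.na(m))
  edited <- rowSums(m > 0L, na.rm = TRUE)
  if (any(detected == 0L)) {
    warning(sprintf("%d cell(s) with no detected site excluded",
                    sum(detected == 0L)))
  }
  keep <- detected > 0L
  stats::setNames(edited[keep] / detected[keep], rownames(m)[keep])
}

#' Fit a saturating exponential to an edit-fraction time course
#'
#' Fits `f(t) = s * (1 - exp(-r t))` by bounded nonlinear least squares,
#' with the saturation level `s` constrained to `[0.8, 1]` (a small
#' fraction of cells never edits) and the edit rate `r` (edits per site per
#' day) to `[1e-4, 0.6]`. Timepoints supported by fewer than `min_cells`
#' cells are dropped before fitting. Three starts across the rate range
#' guard against the flat-objective corner at small `r`; optionally each
#' timepoint's squared residual is weighted by its cell count.
#'
#' @param times Timepoints in days.
#' @param fractions Mean edit fraction per timepoint.
#' @param cell_counts Cells per timepoint (default: all large).
#' @param min_cells Minimum cells for a timepoint to enter the fit
#'   (default 20).
#' @param weighted Weight residuals by cell count (default FALSE).
#' @param include_day0 Add an implicit (t = 0, f = 0) anchor when day 0 is
#'   absent (editing starts at induction; default TRUE).
#' @return A list of class `"kinetics_fit"`: `rate`, `saturation`, `rss`,
#'   `n_timepoints`, `fitted` (`data.table` of `time`, `fraction`,
#'   `fitted`).
#' @export
fit_saturating_exponential <- function(times, fractions, cell_counts = NULL,
                                       min_cells = 20L, weighted = FALSE,
                                       include_day0 = TRUE) {
  stopifnot(length(times) == length(fractions))
  cell_counts <- cell_counts %||% rep(min_cells, length(times))
  keep <- cell_counts >= min_cells
  t <- times[keep]; f <- fractions[keep]; w <- cell_counts[keep]
  if (include_day0 && length(t) && !any(t == 0)) {
    t <- c(0, t); f <- c(0, f); w <- c(max(w), w)
  }
  if (length(t) < 2L) {
    stop2("INSUFFICIENT_TIMEPOINTS",
          "need >= 2 timepoints with >= %d cells", min_cells)
  }
  if (!weighted) w <- rep(1, length(t))
  lower <- c(r = 1e-4, s = 0.8); upper <- c(r = 0.6, s = 1)
  dat <- data.frame(t = t, f = f, w = w)
  best <- NULL
  for (r0 in c(0.01, 0.1, 0.4)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(f ~ s * (1 - exp(-r * t)), data = dat,
                        start = list(r = r0, s = 0.95),
                        lower = lower, upper = upper, weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(w * stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(rate = unname(cf["r"]), saturation = unname(cf["s"]),
                   rss = rss)
    }
  }
  if (is.null(best)) stop2("fit_failed", "nonlinear least squares failed")
  fitted <- best$saturation * (1 - exp(-best$rate * t))
  structure(c(best, list(n_timepoints = length(t),
                         fitted = data.table::data.table(
                           time = t, fraction = f, fitted = fitted))),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("saturating-exponential fit: r = %.4f /site/day, s = %.3f (rss %.4g, %d timepoints)\n",
              x$rate, x$saturation, x$rss, x$n_timepoints))
  invisible(x)
}
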