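#' Detrend a normalized trace with running medians
#'
#' Two-stage running-median detrending: a short window (\code{smooth_k})
#' removes frame-to-frame noise, a long window (\code{bias_k}) estimates the
#' slow baseline which is subtracted; negative residuals are clipped to 0 and
#' the result is rescaled to [0, 1] by its own maximum (all-zero results stay
#' zero). Running-median windows must be odd: even windows are incremented by
#' one, and windows longer than the trace are truncated to the largest odd
#' value that fits, each with a warning.
#'
#' @param trace Numeric vector, a normalized (or at least finite) trace.
#' @param smooth_k Short median window in frames.
#' @param bias_k Long baseline median window in frames.
#' @return Numeric vector of the same length in [0, 1].
#' @examples
#' x <- c(rep(0.1, 20), 0.9, 0.9, rep(0.1, 20))
#' d <- detrend_trace(x, smooth_k = 3, bias_k = 25)
#' which(d > 0.5)
#' @export
detrend_trace <- function(trace, smooth_k = 3, bias_k = 25) {
  if (!all(is.finite(trace))) stop("trace must be finite")
  n <- length(trace)
  k1 <- odd_window(smooth_k, n, "smooth_k")
  k2 <- odd_window(bias_k, n, "bias_k")
  smoothed <- stats::runmed(trace, k1)
  baseline <- stats::runmed(smoothed, k2)
  d <- pmax(smoothed - baseline, 0)
  m <- max(d)
  if (m > 0) d <- d / m
  as.numeric(d)
}

# Coerce a running-median window to a usable odd width.
odd_window <- function(k, n, name) {
  k <- as.integer(k)
  if (k %% 2L == 0L) {
    k <- k + 1L
    warning(sprintf("'%s' must be odd; using %d", name, k))
  }
  if (k > n) {
    k <- if (n %% 2L == 1L) n else n - 1L
    warning(sprintf("'%s' longer than trace; truncated to %d", name, k))
  }
  max(k, 1L)
}

#' Binarize a detrended trace into active / inactive frames
#'
#' Frames with detrended value \code{>= bin_thr} are candidate-active; a
#' maximal candidate run is kept only if its peak reaches \code{peak_thr}.
#' With the default thresholds (bin 0.4 >= peak 0.3) every candidate run is
#' kept; the peak filter matters when users set \code{peak_thr > bin_thr}.
#'
#' @param detrended Numeric vector in [0, 1] from [detrend_trace()].
#' @param peak_thr Minimum peak value for a run to survive.
#' @param bin_thr Frame-level activity threshold.
#' @return Integer vector of 0/1 active states.
#' @examples
#' binarize_trace(c(0, 0.5, 0.6, 0.1))
#' @export
binarize_trace <- function(detrended, peak_thr = 0.3, bin_thr = 0.4) {
  active <- as.integer(detrended >= bin_thr)
  if (peak_thr > bin_thr && any(active == 1L)) {
    r <- rle(active)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values == 1L)) {
      if (max(detrended[starts[i]:ends[i]]) < peak_thr)
        active[starts[i]:ends[i]] <- 0L
    }
  }
  active
}

# First frames of maximal runs of 1s in a 0/1 vector.
run_onsets <- function(active) {
  which(active == 1L & c(0L, active[-length(active)]) == 0L)
}

#' Detect per-cell activity from normalized traces
#'
#' Applies [detrend_trace()] and [binarize_trace()] to every cell. Cells
#' flagged as constant during normalization are forced inactive everywhere.
#'
#' @param normalized A \code{"normalized_traces"} object.
#' @param params An [analysis_params()] object.
#' @return An object of class \code{"activity_matrix"} with elements
#'   \code{active} (0/1 matrix [cell x frame]), \code{detrended} (matrix),
#'   \code{onsets} (list of onset frame vectors, one per cell) and
#'   \code{frame_interval}.
#' @export
detect_activity <- function(normalized, params = analysis_params()) {
  stopifnot(inherits(normalized, "normalized_traces"))
  vals <- normalized$values
  nc <- nrow(vals)
  nf <- ncol(vals)
  active <- matrix(0L, nc, nf, dimnames = dimnames(vals))
  detrended <- matrix(0, nc, nf, dimnames = dimnames(vals))
  for (i in seq_len(nc)) {
    if (normalized$constant[i]) next
    d <- detrend_trace(vals[i, ], params$smooth_k, params$bias_k)
    detrended[i, ] <- d
    active[i, ] <- binarize_trace(d, params$peak_thr, params$bin_thr)
  }
  onsets <- apply(active, 1, run_onsets, simplify = FALSE)
  structure(list(active = active,
                 detrended = detrended,
                 onsets = onsets,
                 frame_interval = normalized$frame_interval),
            class = "activity_matrix")
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("Activity: %d cells x %d frames, %d activation(s) total\n",
              nrow(x$active), ncol(x$active),
              sum(lengths(x$onsets))))
  invisible(x)
}

#' Per-cell and mean activation rate
#'
#' Counts activation onsets per cell and divides by the recording duration
#' in minutes.
#'
#' @param activity An \code{"activity_matrix"} object.
#' @return List with \code{per_cell} (activations/min, named by cell) and
#'   \code{mean} (average over cells).
#' @examples
#' # 4 onsets in a 2-minute recording -> 2 activations/min
#' @export
activation_rate <- function(activity) {
  stopifnot(inherits(activity, "activity_matrix"))
  dur_min <- ncol(activity$active) * activity$frame_interval / 60
  if (dur_min <= 0) stop("zero-duration recording")
  per_cell <- lengths(activity$onsets) / dur_min
  list(per_cell = per_cell, mean = mean(per_cell))
}

#' Mean local cell density
#'
#' For each cell, counts the other cells inside an axis-aligned square of
#' side \code{window} centered on it (|dx| <= window/2 and |dy| <= window/2,
#' self excluded).
#'
#' @param pos Numeric matrix of cell positions with columns x, y (um).
#' @param window Square side length in um.
#' @return List with \code{per_cell} counts and their \code{mean}.
#' @export
local_density <- function(pos, window = 14) {
  if (window <= 0) stop("'window' must be positive")
  pos <- as.matrix(pos)
  half <- window / 2
  dx <- abs(outer(pos[, 1], pos[, 1], "-"))
  dy <- abs(outer(pos[, 2], pos[, 2], "-"))
  inside <- dx <= half & dy <= half
  diag(inside) <- FALSE
  per_cell <- rowSums(inside)
  names(per_cell) <- rownames(pos)
  list(per_cell = per_cell, mean = mean(per_cell))
}

#' Relative spike magnitude (z-score against the cell's background)
#'
#' A cell's background is every frame whose distance to all of its active
#' frames exceeds \code{guard} frames (a +/- guard-band around each active
#' run is excluded). Each spike (maximal active run) is scored as
#' z = (peak normalized value - background mean) / background SD, and the
#' cell's magnitude is the mean z over its spikes. Cells with no spikes,
#' fewer than 2 background frames, or zero background SD are flagged and get
#' \code{NA}.
#'
#' @param normalized A \code{"normalized_traces"} object.
#' @param activity The matching \code{"activity_matrix"}.
#' @param guard Width of the exclusion band in frames.
#' @return List with \code{per_cell} (mean z per cell, NA when flagged) and
#'   \code{flagged} (logical).
#' @export
spike_magnitude <- function(normalized, activity, guard = 3) {
  stopifnot(inherits(normalized, "normalized_traces"),
            inherits(activity, "activity_matrix"))
  vals <- normalized$values
  nc <- nrow(vals)
  nf <- ncol(vals)
  out <- rep(NA_real_, nc)
  flagged <- rep(FALSE, nc)
  for (i in seq_len(nc)) {
    act <- which(activity$active[i, ] == 1L)
    if (length(act) == 0) { flagged[i] <- TRUE; next }
    # frames farther than `guard` from every active frame
    near <- unique(unlist(lapply(act, function(f)
      max(1L, f - guard):min(nf, f + guard))))
    bg <- setdiff(seq_len(nf), near)
    if (length(bg) < 2) { flagged[i] <- TRUE; next }
    mu <- mean(vals[i, bg])
    sd_bg <- stats::sd(vals[i, bg])
    if (sd_bg == 0) { flagged[i] <- TRUE; next }
    onsets <- activity$onsets[[i]]
    runs_end <- run_ends(activity$active[i, ])
    z <- vapply(seq_along(onsets), function(k) {
      peak <- max(vals[i, onsets[k]:runs_end[k]])
      (peak - mu) / sd_bg
    }, numeric(1))
    out[i] <- mean(z)
  }
  names(out) <- rownames(vals)
  names(flagged) <- rownames(vals)
  list(per_cell = out, flagged = flagged)
}

# Last frames of maximal runs of 1s.
run_ends <- function(active) {
  which(active == 1L & c(active[-1], 0L) == 0L)
}
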