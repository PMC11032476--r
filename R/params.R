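#' Analysis parameters for community detection
#'
#' Bundles every tunable threshold of the pipeline into one validated list.
#' Defaults correspond to the configuration used for lymph-gland blood
#' progenitor recordings: a 14 um neighborhood (about two cell diameters),
#' communities of at least three cells, a maximum activation lag of 15 s,
#' and running-median binarization with a short smoothing window and a long
#' baseline window.
#'
#' @param eps Neighborhood radius in um: the distance threshold for
#'   synchronous activation and for all adjacency graphs.
#' @param min_total_event_size Minimum number of distinct cells participating
#'   in a collective event over its whole lifetime.
#' @param min_cluster_size Minimum number of co-active cells per frame for a
#'   frame-level cluster to enter an event (1 allows single-cell growth steps).
#' @param max_lag Maximum time lag in seconds between activations that are
#'   still linked into the same event. Converted to frames with
#'   \code{ceiling(max_lag / frame_interval)}.
#' @param min_duration Minimum event lifetime in frames.
#' @param smooth_k Short running-median window (frames) used to smooth traces
#'   before baseline removal. Must be odd; even values are incremented.
#' @param bias_k Long running-median window (frames) used to estimate the
#'   slow baseline that is subtracted. Must be odd; even values are
#'   incremented.
#' @param peak_thr Minimum rescaled-detrended peak value a candidate active
#'   run must reach to be kept.
#' @param bin_thr Threshold on the rescaled detrended signal above which a
#'   frame is candidate-active.
#' @param close_far_cutoff Distance in um splitting cell pairs into close
#'   (\code{<= cutoff}) and far (\code{> cutoff}) groups.
#' @param density_window Side length in um of the axis-aligned square used
#'   for local cell density.
#' @param n_permutations Number of spatial-shuffle permutations.
#' @param alpha Significance level for all tests.
#'
#' @return An object of class \code{"analysis_params"}: a named list of the
#'   validated parameter values.
#' @examples
#' p <- analysis_params()
#' p$eps
#' analysis_params(eps = 10, n_permutations = 500)
#' @export
analysis_params <- function(eps = 14,
                            min_total_event_size = 3,
                            min_cluster_size = 1,
                            max_lag = 15,
                            min_duration = 1,
                            smooth_k = 3,
                            bias_k = 25,
                            peak_thr = 0.3,
                            bin_thr = 0.4,
                            close_far_cutoff = 14,
                            density_window = 14,
                            n_permutations = 1000,
                            alpha = 0.05) {
  p <- list(eps = eps,
            min_total_event_size = min_total_event_size,
            min_cluster_size = min_cluster_size,
            max_lag = max_lag,
            min_duration = min_duration,
            smooth_k = smooth_k,
            bias_k = bias_k,
            peak_thr = peak_thr,
            bin_thr = bin_thr,
            close_far_cutoff = close_far_cutoff,
            density_window = density_window,
            n_permutations = n_permutations,
            alpha = alpha)
  stopifnot(vapply(p, is.numeric, logical(1)),
            vapply(p, length, integer(1)) == 1L)
  if (!is.finite(p$eps) || p$eps <= 0) stop("'eps' must be a positive distance (um)")
  if (p$min_total_event_size < 1) stop("'min_total_event_size' must be >= 1")
  if (p$min_cluster_size < 1) stop("'min_cluster_size' must be >= 1")
  if (p$max_lag <= 0) stop("'max_lag' must be positive (seconds)")
  if (p$min_duration < 1) stop("'min_duration' must be >= 1 frame")
  if (p$smooth_k < 1 || p$bias_k < 1) stop("median windows must be >= 1 frame")
  if (p$bin_thr < 0 || p$peak_thr < 0) stop("thresholds must be non-negative")
  if (p$close_far_cutoff <= 0) stop("'close_far_cutoff' must be positive")
  if (p$density_window <= 0) stop("'density_window' must be positive")
  if (p$n_permutations < 1) stop("'n_permutations' must be >= 1")
  if (p$alpha <= 0 || p$alpha >= 1) stop("'alpha' must be in (0, 1)")
  structure(p, class = "analysis_params")
}

#' @export
print.analysis_params <- function(x, ...) {
  cat("Analysis parameters:\n")
  cat(sprintf("  neighborhood (eps):      %g um\n", x$eps))
  cat(sprintf("  min event size:          %g cells (min per-frame cluster %g)\n",
              x$min_total_event_size, x$min_cluster_size))
  cat(sprintf("  max activation lag:      %g s, min duration %g frame(s)\n",
              x$max_lag, x$min_duration))
  cat(sprintf("  binarization:            smooth_k=%g, bias_k=%g, peak_thr=%g, bin_thr=%g\n",
              x$smooth_k, x$bias_k, x$peak_thr, x$bin_thr))
  cat(sprintf("  close/far cutoff:        %g um; density window %g um\n",
              x$close_far_cutoff, x$density_window))
  cat(sprintf("  permutations:            %g (alpha = %g)\n",
              x$n_permutations, x$alpha))
  invisible(x)
}

#' Read analysis parameters from a YAML or JSON config file
#'
#' Field names mirror the arguments of [analysis_params()]; absent fields
#' keep their defaults and unknown fields are an error, so typos do not
#' silently fall back to defaults.
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return An \code{"analysis_params"} object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(analysis_params))
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0)
    stop("unknown parameter field(s) in config: ", paste(extra, collapse = ", "))
  do.call(analysis_params, cfg)
}

# Lag window in frames for a given sampling interval.
lag_frames <- function(params, frame_interval) {
  as.integer(ceiling(params$max_lag / frame_interval))
}
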