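#' Full analysis of one recording
#'
#' The central entry point: runs the whole pipeline on one recording —
#' normalization, binarization, collective-event detection, pairwise
#' correlation analysis, the spatial-shuffle permutation test, propagation
#' speeds, hotspot detection with trace-swap validation, and hotspot
#' interaction profiles — and returns everything as one classed object.
#'
#' @param recording A \code{"recording"} object.
#' @param params An [analysis_params()] object.
#' @param n_perm Spatial-shuffle permutations (defaults to
#'   \code{params$n_permutations}).
#' @param seed Integer seed for the permutation and bootstrap streams.
#' @param hotspot_validation Run the trace-swap bootstrap for each hotspot
#'   candidate (can be slow; disable for quick passes).
#' @param max_tries,min_valid Bootstrap controls, see [validate_hotspot()].
#' @return An object of class \code{"lg_analysis"}; see
#'   \code{summary.lg_analysis}. Components include \code{normalized},
#'   \code{activity}, \code{events}, \code{event_summaries},
#'   \code{speeds}, \code{shuffle}, \code{pairs}, \code{close_far},
#'   \code{community_relation}, \code{activation}, \code{density},
#'   \code{magnitudes}, \code{hotspots}, \code{hotspot_validations},
#'   \code{hotspot_profiles}.
#' @examples
#' cfg <- simulation_config(n_cells = 20, duration = 120, seed = 7)
#' rec <- simulate_recording(cfg)$recording
#' fit <- analyze_recording(rec, n_perm = 20, seed = 1,
#'                          hotspot_validation = FALSE)
#' fit
#' @export
analyze_recording <- function(recording, params = analysis_params(),
                              n_perm = NULL, seed = 1,
                              hotspot_validation = TRUE,
                              max_tries = 1000, min_valid = 100) {
  stopifnot(inherits(recording, "recording"))
  pos <- positions(recording)
  normalized <- suppressWarnings(normalize_traces(recording))
  activity <- suppressWarnings(detect_activity(normalized, params))
  events <- detect_events(activity, pos, params)
  ev_sum <- lapply(events, summarize_event, recording$frame_interval)
  speeds <- vapply(events, propagation_speed, numeric(1),
                   pos = pos, frame_interval = recording$frame_interval,
                   eps = params$eps)
  shuffle <- spatial_shuffle_test(recording, activity, params,
                                  n_perm = n_perm, seed = seed)
  pairs <- pair_correlations(normalized, pos)
  close_far <- suppressWarnings(close_far_split(pairs, params$close_far_cutoff))
  relation <- community_relation_correlation(close_far$pairs, events)
  counts <- participation_counts(events, recording$cells$cell_id)
  hotspots <- detect_hotspots(counts, pos, params)
  validations <- list()
  profiles <- list()
  for (i in seq_along(hotspots)) {
    if (hotspot_validation)
      validations[[i]] <- validate_hotspot(
        hotspots[[i]], recording, activity, params,
        max_tries = max_tries, min_valid = min_valid, seed = seed + i)
    profiles[[i]] <- interaction_profile(hotspots[[i]], events, pos, params)
  }
  structure(list(recording = recording,
                 params = params,
                 normalized = normalized,
                 activity = activity,
                 events = events,
                 event_summaries = ev_sum,
                 speeds = speeds,
                 mean_speed = if (length(speeds)) mean(speeds) else NA_real_,
                 mec = mec(events, n_cells(recording)),
                 mec_rate = mec_rate(events, n_cells(recording),
                                     duration_s(recording)),
                 shuffle = shuffle,
                 pairs = relation$pairs,
                 close_far = close_far[c("stats", "kruskal_p")],
                 community_relation = relation[c("mean_intra", "mean_inter",
                                                 "kruskal_p")],
                 activation = activation_rate(activity),
                 density = local_density(pos, params$density_window),
                 magnitudes = spike_magnitude(normalized, activity),
                 participation = counts,
                 hotspots = hotspots,
                 hotspot_validations = validations,
                 hotspot_profiles = profiles,
                 seed = seed),
            class = "lg_analysis")
}

#' @export
print.lg_analysis <- function(x, ...) {
  rec <- x$recording
  cat(sprintf("Collective Ca2+ signaling analysis: %d cells x %d frames (%.1f s/frame)\n",
              n_cells(rec), n_frames(rec), rec$frame_interval))
  cat(sprintf("  events: %d (MEC %.3f, %.3f events/cell/min)\n",
              length(x$events), x$mec, x$mec_rate))
  cat(sprintf("  spatial shuffle: magnitude %.2f, p = %.4f (%s)\n",
              x$shuffle$magnitude, x$shuffle$p_spatial,
              if (x$shuffle$significant) "significant" else "not significant"))
  nval <- sum(vapply(x$hotspot_validations, function(v)
    v$status == "validated", logical(1)))
  cat(sprintf("  hotspots: %d candidate(s), %d validated\n",
              length(x$hotspots), nval))
  invisible(x)
}

#' @export
summary.lg_analysis <- function(object, ...) {
  x <- object
  sizes <- vapply(x$event_summaries, `[[`, integer(1), "size")
  out <- list(
    n_cells = n_cells(x$recording),
    n_frames = n_frames(x$recording),
    frame_interval = x$recording$frame_interval,
    n_events = length(x$events),
    event_sizes = if (length(sizes)) summary(sizes) else NULL,
    mec = x$mec,
    mec_rate = x$mec_rate,
    magnitude = x$shuffle$magnitude,
    p_spatial = x$shuffle$p_spatial,
    significant = x$shuffle$significant,
    mean_speed = x$mean_speed,
    mean_activation_rate = x$activation$mean,
    mean_density = x$density$mean,
    close_far = x$close_far,
    n_hotspots = length(x$hotspots),
    hotspot_statuses = vapply(x$hotspot_validations, `[[`, character(1),
                              "status"))
  class(out) <- "summary.lg_analysis"
  out
}

#' @export
print.summary.lg_analysis <- function(x, ...) {
  cat(sprintf("Recording: %d cells, %d frames at %.1f s\n",
              x$n_cells, x$n_frames, x$frame_interval))
  cat(sprintf("Collective events: %d; MEC = %.3f (%.3f /cell/min)\n",
              x$n_events, x$mec, x$mec_rate))
  if (!is.null(x$event_sizes)) {
    cat("Event sizes:\n"); print(x$event_sizes)
  }
  cat(sprintf("Spatial-shuffle magnitude %.2f, p = %.4f (%s)\n",
              x$magnitude, x$p_spatial,
              if (x$significant) "spatially significant" else "not significant"))
  cat(sprintf("Mean propagation speed: %.2f um/s\n", x$mean_speed))
  cat(sprintf("Mean activation rate: %.2f /min; mean local density: %.2f cells\n",
              x$mean_activation_rate, x$mean_density))
  if (x$n_hotspots > 0)
    cat(sprintf("Hotspots: %d candidate(s) [%s]\n", x$n_hotspots,
                paste(x$hotspot_statuses, collapse = ", ")))
  invisible(x)
}

#' Plot an analyzed recording
#'
#' Two base-graphics panels: the pair correlation against distance
#' (close/far cutoff marked), and the cell map with marker area scaled by
#' community participation, hotspot hulls outlined.
#'
#' @param x An \code{"lg_analysis"} object.
#' @param which Panels to draw (1 = correlation vs distance, 2 = map).
#' @param ... Passed to \code{plot}.
#' @return Invisibly, \code{x}.
#' @export
plot.lg_analysis <- function(x, which = c(1, 2), ...) {
  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old))
  graphics::par(mfrow = c(1, length(which)))
  if (1 %in% which) {
    ok <- !is.na(x$pairs$r)
    graphics::plot(x$pairs$distance[ok], x$pairs$r[ok],
                   xlab = "pair distance (um)", ylab = "Pearson r",
                   pch = 16, col = grDevices::adjustcolor("steelblue", 0.6),
                   main = "Pair synchronization vs distance", ...)
    graphics::abline(v = x$params$close_far_cutoff, lty = 2)
  }
  if (2 %in% which) {
    pos <- positions(x$recording)
    cex <- 0.7 + 1.5 * x$participation / max(1, max(x$participation))
    graphics::plot(pos[, 1], pos[, 2], cex = cex, pch = 21,
                   bg = grDevices::adjustcolor("firebrick", 0.5),
                   xlab = "x (um)", ylab = "y (um)", asp = 1,
                   main = "Participation map", ...)
    for (h in x$hotspots) {
      hull <- rbind(h$hull, h$hull[1, , drop = FALSE])
      graphics::lines(hull[, 1], hull[, 2], col = "darkorange", lwd = 2)
    }
  }
  invisible(x)
}

#' Run the pipeline over a study manifest
#'
#' Analyzes every recording in a manifest and aggregates condition-level
#' statistics. The manifest is a data.frame with one row per recording and
#' columns \code{traces_path}, \code{coords_path}, \code{layout},
#' \code{frame_interval_s}, \code{condition} and optionally \code{stage}
#' and \code{id}; alternatively, pass a list of \code{"recording"} objects
#' plus a \code{conditions} vector. Failures on individual recordings are
#' caught and flagged so the rest of the study completes. Pooled
#' propagation-speed statistics only include recordings whose frame
#' interval lies in the admissible 2.32-4 s range, to avoid confounding by
#' temporal resolution.
#'
#' @param manifest data.frame of file paths (see above) or list of
#'   recordings.
#' @param conditions Condition labels when \code{manifest} is a list.
#' @param params An [analysis_params()] object.
#' @param n_perm Spatial-shuffle permutations per recording.
#' @param seed Base seed; recording i uses \code{seed + i}.
#' @param speed_interval_range Admissible frame-interval range (s) for
#'   pooled speed statistics.
#' @param ... Passed to [analyze_recording()].
#' @return An object of class \code{"lg_study"} with \code{analyses} (one
#'   \code{"lg_analysis"} or error flag per recording), \code{results}
#'   (per-recording summary data.frame), \code{pooled_speeds} (per
#'   condition) and \code{comparisons} (from [compare_conditions()]).
#' @export
run_study <- function(manifest, conditions = NULL,
                      params = analysis_params(), n_perm = NULL, seed = 1,
                      speed_interval_range = c(2.32, 4), ...) {
  if (is.data.frame(manifest)) {
    need <- c("traces_path", "coords_path", "layout", "frame_interval_s",
              "condition")
    if (!all(need %in% names(manifest)))
      stop("manifest must have columns: ", paste(need, collapse = ", "))
    recs <- vector("list", nrow(manifest))
    conds <- manifest$condition
    ids <- if ("id" %in% names(manifest)) manifest$id
           else sprintf("rec%02d", seq_len(nrow(manifest)))
    for (i in seq_len(nrow(manifest))) {
      recs[[i]] <- tryCatch(
        read_recording(manifest$traces_path[i], manifest$coords_path[i],
                       manifest$layout[i], manifest$frame_interval_s[i],
                       metadata = list(condition = conds[i], id = ids[i])),
        error = function(e) e)
    }
  } else {
    recs <- manifest
    if (is.null(conditions) || length(conditions) != length(recs))
      stop("a 'conditions' label per recording is required")
    conds <- conditions
    ids <- sprintf("rec%02d", seq_along(recs))
  }

  analyses <- vector("list", length(recs))
  rows <- list()
  for (i in seq_along(recs)) {
    if (inherits(recs[[i]], "error")) {
      analyses[[i]] <- recs[[i]]
    } else {
      analyses[[i]] <- tryCatch(
        analyze_recording(recs[[i]], params, n_perm = n_perm,
                          seed = seed + i, ...),
        error = function(e) e)
    }
    a <- analyses[[i]]
    failed <- inherits(a, "error")
    if (failed)
      warning("recording ", ids[i], " failed: ", conditionMessage(a))
    rows[[i]] <- data.frame(
      id = ids[i], condition = conds[i],
      failed = failed,
      n_cells = if (failed) NA else n_cells(a$recording),
      frame_interval = if (failed) NA else a$recording$frame_interval,
      n_events = if (failed) NA else length(a$events),
      mec = if (failed) NA else a$mec,
      mec_rate = if (failed) NA else a$mec_rate,
      magnitude = if (failed) NA else a$shuffle$magnitude,
      p_spatial = if (failed) NA else a$shuffle$p_spatial,
      significant = if (failed) NA else a$shuffle$significant,
      mean_speed = if (failed) NA else a$mean_speed,
      activation_rate = if (failed) NA else a$activation$mean,
      density = if (failed) NA else a$density$mean,
      n_hotspots = if (failed) NA else length(a$hotspots),
      n_validated = if (failed) NA else
        sum(vapply(a$hotspot_validations, function(v)
          v$status == "validated", logical(1))),
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  if (all(results$failed)) stop("all recordings failed")

  # pooled per-event speeds, filtered by admissible temporal resolution
  pooled <- list()
  for (cond in unique(conds)) {
    sp <- numeric(0)
    for (i in which(conds == cond)) {
      a <- analyses[[i]]
      if (inherits(a, "error")) next
      fi <- a$recording$frame_interval
      if (fi >= speed_interval_range[1] && fi <= speed_interval_range[2])
        sp <- c(sp, a$speeds)
    }
    pooled[[cond]] <- sp
  }
  ok <- !results$failed
  comparisons <- if (length(unique(conds[ok])) >= 2) {
    compare_conditions(results[ok, c("condition", "significant", "magnitude",
                                     "mec_rate", "mean_speed",
                                     "activation_rate")])
  } else list(fisher = data.frame(), kruskal = data.frame())

  structure(list(analyses = analyses, results = results,
                 pooled_speeds = pooled, comparisons = comparisons,
                 params = params, seed = seed),
            class = "lg_study")
}

#' @export
print.lg_study <- function(x, ...) {
  cat(sprintf("Study of %d recording(s), %d condition(s)\n",
              nrow(x$results), length(unique(x$results$condition))))
  agg <- stats::aggregate(significant ~ condition, data = x$results,
                          FUN = function(s) sprintf("%d/%d", sum(s), length(s)))
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %s: %s spatially significant\n",
                agg$condition[i], agg$significant[i]))
  invisible(x)
}

#' Write study tables and a human-readable summary to a directory
#'
#' Writes the per-recording results table, the per-event tables, hotspot
#' tables and validations, condition comparisons, a shuffle-result JSON
#' per recording, and \code{summary.txt}. Calling it twice overwrites
#' identically.
#'
#' @param study An \code{"lg_study"} object.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
report_study <- function(study, outdir) {
  stopifnot(inherits(study, "lg_study"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) stop("cannot create output dir: ", outdir)
  }
  files <- character(0)
  w <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  w(study$results, "recordings.csv")

  ev_rows <- list(); ev_sum <- list(); hs_rows <- list(); pr_rows <- list()
  shuffle_list <- list()
  for (i in seq_along(study$analyses)) {
    a <- study$analyses[[i]]
    if (inherits(a, "error")) next
    id <- study$results$id[i]
    for (e in a$events) {
      frames <- rep(as.integer(names(e$members_by_frame)),
                    lengths(e$members_by_frame))
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        recording = id, event_id = e$event_id, frame = frames,
        cell_id = unlist(e$members_by_frame, use.names = FALSE),
        stringsAsFactors = FALSE)
      s <- summarize_event(e, a$recording$frame_interval)
      ev_sum[[length(ev_sum) + 1L]] <- data.frame(
        recording = id, event_id = e$event_id, size = s$size,
        max_concurrent = s$max_concurrent,
        start_s = (e$start_frame - 1) * a$recording$frame_interval,
        end_s = (e$end_frame - 1) * a$recording$frame_interval,
        speed_um_s = a$speeds[e$event_id], stringsAsFactors = FALSE)
    }
    for (k in seq_along(a$hotspots)) {
      h <- a$hotspots[[k]]
      v <- if (length(a$hotspot_validations) >= k)
        a$hotspot_validations[[k]] else NULL
      hs_rows[[length(hs_rows) + 1L]] <- data.frame(
        recording = id, hotspot_id = h$hotspot_id,
        cell_id = h$member_cells,
        participation = as.integer(h$participation_counts),
        lg_threshold = h$lg_threshold,
        p_value = if (is.null(v)) NA else v$p_value,
        status = if (is.null(v)) "not_run" else v$status,
        stringsAsFactors = FALSE)
      p <- a$hotspot_profiles[[k]]
      pr_rows[[length(pr_rows) + 1L]] <- data.frame(
        recording = id, hotspot_id = h$hotspot_id,
        hotspot_size = p$hotspot_size, p_interact = p$p_interact,
        init_fraction = p$init_fraction,
        transmission_prob = p$transmission_prob,
        expected_initiator_prob = p$expected_initiator_prob,
        stringsAsFactors = FALSE)
    }
    shuffle_list[[id]] <- list(
      observed_mec = a$shuffle$observed_mec,
      permuted_mecs = a$shuffle$permuted_mecs,
      p_spatial = a$shuffle$p_spatial,
      magnitude = a$shuffle$magnitude,
      n_permutations = a$shuffle$n_permutations,
      seed = a$shuffle$seed)
  }
  empty <- function(cols) {
    df <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)),
                                        cols))
    df
  }
  w(if (length(ev_rows)) do.call(rbind, ev_rows) else
      empty(c("recording", "event_id", "frame", "cell_id")), "events.csv")
  w(if (length(ev_sum)) do.call(rbind, ev_sum) else
      empty(c("recording", "event_id", "size", "max_concurrent", "start_s",
              "end_s", "speed_um_s")), "event_summaries.csv")
  w(if (length(hs_rows)) do.call(rbind, hs_rows) else
      empty(c("recording", "hotspot_id", "cell_id", "participation",
              "lg_threshold", "p_value", "status")), "hotspots.csv")
  w(if (length(pr_rows)) do.call(rbind, pr_rows) else
      empty(c("recording", "hotspot_id", "hotspot_size", "p_interact",
              "init_fraction", "transmission_prob",
              "expected_initiator_prob")), "hotspot_profiles.csv")
  w(study$comparisons$fisher, "comparisons_fisher.csv")
  w(study$comparisons$kruskal, "comparisons_kruskal.csv")

  shuffle_path <- file.path(outdir, "shuffle_tests.json")
  jsonlite::write_json(shuffle_list, shuffle_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, shuffle_path)

  txt <- file.path(outdir, "summary.txt")
  con <- file(txt, "w")
  on.exit(close(con))
  writeLines(utils::capture.output({
    print(study)
    cat("\nPer-recording results:\n")
    print(study$results)
    cat("\nPooled propagation speeds (admissible temporal resolution):\n")
    for (cond in names(study$pooled_speeds)) {
      sp <- study$pooled_speeds[[cond]]
      cat(sprintf("  %s: N = %d communities, mean = %.2f um/s\n",
                  cond, length(sp),
                  if (length(sp)) mean(sp) else NA))
    }
  }), con)
  files <- c(files, txt)
  invisible(files)
}
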