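#' Pairwise trace correlation versus distance
#'
#' Pearson correlation (with the standard t-approximation two-sided p-value)
#' between the full-length normalized traces of every unordered cell pair,
#' together with the pair's Euclidean distance. Pairs involving a
#' zero-variance (constant) trace have undefined correlation and are
#' flagged with \code{NA}.
#'
#' @param normalized A \code{"normalized_traces"} object (>= 3 frames).
#' @param pos Position matrix (columns x, y), rows aligned with the traces.
#' @return A data.frame with one row per unordered pair: \code{cell_i},
#'   \code{cell_j}, \code{distance}, \code{r}, \code{p},
#'   \code{significant} (p < 0.05).
#' @export
pair_correlations <- function(normalized, pos) {
  stopifnot(inherits(normalized, "normalized_traces"))
  vals <- normalized$values
  nc <- nrow(vals)
  nf <- ncol(vals)
  if (nc < 2) stop("need at least 2 cells")
  if (nf < 3) stop("need at least 3 frames")
  pos <- as.matrix(pos)
  ids <- rownames(vals)
  if (is.null(ids)) ids <- as.character(seq_len(nc))
  sds <- apply(vals, 1, stats::sd)
  cm <- suppressWarnings(stats::cor(t(vals)))
  cm[sds == 0, ] <- NA
  cm[, sds == 0] <- NA
  d <- as.matrix(stats::dist(pos))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[idx]
  tt <- r * sqrt((nf - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = nf - 2)
  data.frame(cell_i = ids[idx[, 1]],
             cell_j = ids[idx[, 2]],
             distance = d[idx],
             r = r,
             p = p,
             significant = !is.na(p) & p < 0.05,
             stringsAsFactors = FALSE)
}

#' Split cell pairs into close and far groups
#'
#' Close pairs are those at distance \code{<= cutoff}, far pairs at
#' \code{> cutoff}. For each group the mean, SD and N of the pair
#' correlations are reported along with the complementary cumulative
#' ("survival") curve F_g(x) = P(r > x), and the two distributions are
#' compared with a Kruskal-Wallis test.
#'
#' @param pairs A pair table from [pair_correlations()].
#' @param cutoff Distance threshold in um.
#' @return List with \code{pairs} (the table plus a \code{class} column),
#'   \code{stats} (per-group mean/sd/n), \code{survival} (a function
#'   \code{(x, group)} returning P(r > x)), and \code{kruskal_p}.
#' @export
close_far_split <- function(pairs, cutoff = 14) {
  if (cutoff <= 0) stop("'cutoff' must be positive")
  pairs$class <- ifelse(pairs$distance <= cutoff, "close", "far")
  ok <- !is.na(pairs$r)
  grp <- split(pairs$r[ok], pairs$class[ok])
  stats_df <- data.frame(
    class = names(grp),
    n = lengths(grp),
    mean = vapply(grp, mean, numeric(1)),
    sd = vapply(grp, stats::sd, numeric(1)),
    row.names = NULL)
  kw_p <- NA_real_
  if (length(grp) == 2 && all(lengths(grp) > 0)) {
    kw_p <- stats::kruskal.test(pairs$r[ok], factor(pairs$class[ok]))$p.value
  } else {
    warning("one of the close/far groups is empty; comparison skipped")
  }
  survival <- function(x, group) {
    if (!group %in% names(grp)) stop("unknown group: ", group)
    vapply(x, function(xx) mean(grp[[group]] > xx), numeric(1))
  }
  list(pairs = pairs, stats = stats_df, survival = survival, kruskal_p = kw_p)
}

#' Intra- versus inter-community pair synchronization
#'
#' Classifies cell pairs by their community relation: \code{intra} pairs
#' co-participated in at least one collective event, \code{inter} pairs both
#' participate in events but never the same one, \code{none} otherwise. The
#' correlation distributions of intra and inter pairs are compared with a
#' Kruskal-Wallis test.
#'
#' @param pairs A pair table from [pair_correlations()].
#' @param events A \code{"collective_events"} object.
#' @return List with \code{pairs} (plus a \code{relation} column),
#'   \code{mean_intra}, \code{mean_inter} and \code{kruskal_p}.
#' @export
community_relation_correlation <- function(pairs, events) {
  parts <- lapply(events, `[[`, "participants")
  in_any <- unique(unlist(parts))
  key <- paste(pairs$cell_i, pairs$cell_j, sep = "\r")
  intra_keys <- unique(unlist(lapply(parts, function(p) {
    if (length(p) < 2) return(character(0))
    cmb <- utils::combn(sort(p), 2)
    paste(cmb[1, ], cmb[2, ], sep = "\r")
  })))
  # pair keys are built on sorted ids so orientation matches
  key_sorted <- ifelse(pairs$cell_i <= pairs$cell_j,
                       paste(pairs$cell_i, pairs$cell_j, sep = "\r"),
                       paste(pairs$cell_j, pairs$cell_i, sep = "\r"))
  relation <- rep("none", nrow(pairs))
  both_active <- pairs$cell_i %in% in_any & pairs$cell_j %in% in_any
  relation[both_active] <- "inter"
  relation[key_sorted %in% intra_keys] <- "intra"
  pairs$relation <- relation
  ok <- !is.na(pairs$r)
  ri <- pairs$r[ok & relation == "intra"]
  re <- pairs$r[ok & relation == "inter"]
  kw_p <- if (length(ri) > 0 && length(re) > 0) {
    stats::kruskal.test(list(ri, re))$p.value
  } else NA_real_
  list(pairs = pairs,
       mean_intra = if (length(ri)) mean(ri) else NA_real_,
       mean_inter = if (length(re)) mean(re) else NA_real_,
       kruskal_p = kw_p)
}

#' Mean events per cell (MEC)
#'
#' The average, over all cells, of the number of distinct collective events
#' each cell participates in (equivalently, the sum of event sizes divided
#' by the number of cells).
#'
#' @param events A \code{"collective_events"} object (or list of events).
#' @param n_cells Total number of cells in the recording.
#' @return Events per cell (numeric scalar).
#' @examples
#' # one 3-cell event among 10 cells -> MEC 0.3
#' @export
mec <- function(events, n_cells) {
  if (n_cells <= 0) stop("'n_cells' must be positive")
  if (length(events) == 0) return(0)
  sum(vapply(events, function(e) length(e$participants), integer(1))) / n_cells
}

#' MEC rate (events per cell per minute)
#'
#' @inheritParams mec
#' @param duration_s Recording duration in seconds.
#' @return Events per cell per minute.
#' @export
mec_rate <- function(events, n_cells, duration_s) {
  if (duration_s <= 0) stop("'duration_s' must be positive")
  mec(events, n_cells) / (duration_s / 60)
}

#' Spatial-shuffle permutation test for the locality of collective events
#'
#' Tests whether the observed mean events per cell (MEC) depends on the
#' actual spatial arrangement of the cells. Each permutation reassigns the
#' cells' time series to positions uniformly at random (equivalent to
#' randomizing cell locations), reruns event detection, and records the
#' permuted MEC. Because binarization is strictly per cell, permuting the
#' binarized activity rows is identical to re-binarizing permuted traces.
#'
#' The p-value is the fraction of permutations whose MEC is greater than or
#' equal to the observed MEC (ties count as extreme), and the magnitude is
#' the ratio of the observed MEC to the mean permuted MEC (1 means no
#' spatial structure; if all permuted MECs are 0 while the observed MEC is
#' positive the magnitude is \code{Inf}, and if both are 0 it is 1).
#'
#' @param recording A \code{"recording"} object.
#' @param activity Optional precomputed \code{"activity_matrix"}; computed
#'   from the recording when omitted.
#' @param params An [analysis_params()] object.
#' @param n_perm Number of permutations (defaults to
#'   \code{params$n_permutations}).
#' @param seed Integer seed for the permutation stream.
#' @return An object of class \code{"shuffle_test"} with
#'   \code{observed_mec}, \code{permuted_mecs}, \code{p_spatial},
#'   \code{magnitude}, \code{significant}, \code{n_permutations},
#'   \code{seed}.
#' @export
spatial_shuffle_test <- function(recording, activity = NULL,
                                 params = analysis_params(),
                                 n_perm = NULL, seed = NULL) {
  stopifnot(inherits(recording, "recording"))
  if (is.null(n_perm)) n_perm <- params$n_permutations
  if (n_perm < 1) stop("'n_perm' must be >= 1")
  if (is.null(activity))
    activity <- detect_activity(normalize_traces(recording), params)
  if (!is.null(seed)) set.seed(seed)
  adj <- eps_adjacency(positions(recording), params$eps)
  lag <- lag_frames(params, recording$frame_interval)
  active <- activity$active
  nc <- nrow(active)
  obs <- mean(participation_from_active(active, adj, lag,
                                        params$min_total_event_size,
                                        params$min_duration))
  perm_mecs <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(nc)
    perm_mecs[b] <- mean(participation_from_active(
      active[perm, , drop = FALSE], adj, lag,
      params$min_total_event_size, params$min_duration))
  }
  p <- mean(perm_mecs >= obs)
  mp <- mean(perm_mecs)
  magnitude <- if (mp > 0) obs / mp else if (obs > 0) Inf else 1
  structure(list(observed_mec = obs,
                 permuted_mecs = perm_mecs,
                 p_spatial = p,
                 magnitude = magnitude,
                 significant = p <= params$alpha,
                 n_permutations = n_perm,
                 seed = seed),
            class = "shuffle_test")
}

#' @export
print.shuffle_test <- function(x, ...) {
  cat(sprintf("Spatial-shuffle test (%d permutations)\n", x$n_permutations))
  cat(sprintf("  observed MEC: %.4f, mean permuted MEC: %.4f\n",
              x$observed_mec, mean(x$permuted_mecs)))
  cat(sprintf("  magnitude: %.3f, p = %.4f (%s)\n", x$magnitude, x$p_spatial,
              if (x$significant) "spatially significant" else "not significant"))
  invisible(x)
}

# Significance stars at the conventional thresholds.
p_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 1e-4, "****", ifelse(p < 1e-3, "***",
    ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))))
}

#' Compare per-recording results across experimental conditions
#'
#' For every pair of conditions, a Fisher's exact test compares the counts
#' of spatially significant versus insignificant recordings (chosen for the
#' small per-condition sample sizes). For every numeric summary column
#' (e.g. magnitude, propagation speed, activation rate) a Kruskal-Wallis
#' test compares its distribution across all conditions.
#'
#' @param results A data.frame with one row per recording, a
#'   \code{condition} column, a logical \code{significant} column, and any
#'   number of numeric summary columns.
#' @return List with \code{fisher} (data.frame: condition_a, condition_b,
#'   p, stars) and \code{kruskal} (data.frame: variable, p, stars).
#' @export
compare_conditions <- function(results) {
  stopifnot(is.data.frame(results), "condition" %in% names(results))
  conds <- unique(results$condition)
  if (length(conds) < 2) {
    warning("fewer than 2 conditions; no tests performed")
    return(list(fisher = data.frame(), kruskal = data.frame()))
  }
  fisher <- data.frame()
  if ("significant" %in% names(results)) {
    cmb <- utils::combn(conds, 2)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1, k]; b <- cmb[2, k]
      tab <- table(factor(results$condition[results$condition %in% c(a, b)],
                          levels = c(a, b)),
                   factor(results$significant[results$condition %in% c(a, b)],
                          levels = c(FALSE, TRUE)))
      p <- tryCatch(stats::fisher.test(tab)$p.value,
                    error = function(e) {
                      warning("Fisher test skipped for ", a, " vs ", b,
                              ": ", conditionMessage(e))
                      NA_real_
                    })
      fisher <- rbind(fisher, data.frame(condition_a = a, condition_b = b,
                                         p = p, stars = p_stars(p),
                                         stringsAsFactors = FALSE))
    }
  }
  num_cols <- names(results)[vapply(results, is.numeric, logical(1))]
  kruskal <- data.frame()
  for (v in num_cols) {
    vals <- results[[v]]
    ok <- is.finite(vals)
    if (length(unique(results$condition[ok])) < 2) next
    p <- tryCatch(
      stats::kruskal.test(vals[ok], factor(results$condition[ok]))$p.value,
      error = function(e) NA_real_)
    kruskal <- rbind(kruskal, data.frame(variable = v, p = p,
                                         stars = p_stars(p),
                                         stringsAsFactors = FALSE))
  }
  list(fisher = fisher, kruskal = kruskal)
}
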