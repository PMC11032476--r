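#' Per-cell participation counts in collective events
#'
#' @param events A \code{"collective_events"} object.
#' @param cell_ids Character vector of all cell ids in the recording.
#' @return Named integer vector: number of distinct events each cell
#'   participates in (0 for cells in no event).
#' @export
participation_counts <- function(events, cell_ids) {
  counts <- integer(length(cell_ids))
  names(counts) <- cell_ids
  for (e in events) counts[e$participants] <- counts[e$participants] + 1L
  counts
}

#' Detect hotspot candidates of recurrent community participation
#'
#' Cells participating in at least \code{max(5, max_count / 2)} collective
#' events are marked (the threshold adapts to the recording's most active
#' cell and is kept as a real number); connected components of marked cells
#' in the \code{<= eps} neighborhood graph with at least \code{min_size}
#' members become hotspot candidates, each with its convex hull.
#'
#' @param counts Named participation counts from [participation_counts()].
#' @param pos Position matrix with cell ids as row names.
#' @param params An [analysis_params()] object (supplies \code{eps}).
#' @param min_size Minimum number of member cells (a 1-2 cell component is
#'   not a community).
#' @return An object of class \code{"hotspots"}: list of \code{"hotspot"}
#'   objects with \code{hotspot_id}, \code{member_cells},
#'   \code{participation_counts}, \code{hull} (vertex coordinates),
#'   \code{hull_area} (um^2), \code{lg_max}, \code{lg_threshold}.
#' @export
detect_hotspots <- function(counts, pos, params = analysis_params(),
                            min_size = 3) {
  pos <- as.matrix(pos)
  stopifnot(!is.null(names(counts)), !is.null(rownames(pos)))
  lg_max <- if (length(counts) > 0) max(counts) else 0
  threshold <- max(5, lg_max / 2)
  marked <- which(counts >= threshold)
  out <- list()
  if (length(marked) > 0) {
    adj <- eps_adjacency(pos, params$eps)
    comps <- components_of(marked, adj)
    comps <- Filter(function(x) length(x) >= min_size, comps)
    for (i in seq_along(comps)) {
      cells <- sort(comps[[i]])
      ids <- names(counts)[cells]
      pts <- pos[ids, , drop = FALSE]
      hull_idx <- grDevices::chull(pts)
      hull <- pts[hull_idx, , drop = FALSE]
      out[[i]] <- structure(list(
        hotspot_id = i,
        member_cells = ids,
        participation_counts = counts[ids],
        hull = hull,
        hull_area = polygon_area(hull),
        lg_max = lg_max,
        lg_threshold = threshold), class = "hotspot")
    }
  }
  structure(out, class = "hotspots")
}

# Shoelace area of a polygon given as a matrix of vertices.
polygon_area <- function(v) {
  n <- nrow(v)
  if (n < 3) return(0)
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' @export
print.hotspots <- function(x, ...) {
  cat(sprintf("%d hotspot candidate(s)\n", length(x)))
  for (h in x)
    cat(sprintf("  hotspot %d: %d cells (counts %s; threshold %.1f)\n",
                h$hotspot_id, length(h$member_cells),
                paste(h$participation_counts, collapse = ","),
                h$lg_threshold))
  invisible(x)
}

#' Validate a hotspot with an activity-matched trace-swap bootstrap
#'
#' Tests whether a hotspot's recurrent participation is a genuine local
#' property rather than a byproduct of its members being more active. Each
#' bootstrap iteration matches hotspot cells, uniformly at random and
#' without replacement, to distinct non-hotspot cells with at least as many
#' activations; an iteration is valid when at least half the hotspot cells
#' are matched. The time series of each matched pair are swapped, events
#' are re-detected, and the mean events per cell over the hotspot member
#' positions is recorded. The p-value is the fraction of valid iterations
#' whose hotspot MEC equals or exceeds the observed one; a hotspot is
#' \code{validated} when at least \code{min_valid} valid iterations were
#' obtained and \code{p <= alpha}, and \code{insufficient_data} when fewer
#' than \code{min_valid} valid iterations exist.
#'
#' @param hotspot A \code{"hotspot"} object.
#' @param recording The \code{"recording"} it was detected on.
#' @param activity The matching \code{"activity_matrix"}.
#' @param params An [analysis_params()] object.
#' @param max_tries Maximum number of bootstrap iterations.
#' @param min_valid Minimum number of valid iterations required for a
#'   verdict.
#' @param seed Integer seed.
#' @return An object of class \code{"hotspot_validation"} with
#'   \code{observed_mec_hotspot}, \code{permuted_mecs},
#'   \code{n_valid_permutations}, \code{p_value} and \code{status}
#'   (\code{"validated"}, \code{"not_significant"} or
#'   \code{"insufficient_data"}).
#' @export
validate_hotspot <- function(hotspot, recording, activity,
                             params = analysis_params(),
                             max_tries = 1000, min_valid = 100,
                             seed = NULL) {
  stopifnot(inherits(hotspot, "hotspot"), inherits(recording, "recording"),
            inherits(activity, "activity_matrix"))
  if (!is.null(seed)) set.seed(seed)
  ids <- recording$cells$cell_id
  members <- match(hotspot$member_cells, ids)
  if (anyNA(members)) stop("hotspot members not found in recording")
  nonmembers <- setdiff(seq_along(ids), members)
  act_count <- lengths(activity$onsets)
  adj <- eps_adjacency(positions(recording), params$eps)
  lag <- lag_frames(params, recording$frame_interval)
  active <- activity$active
  obs <- mean(participation_from_active(active, adj, lag,
                                        params$min_total_event_size,
                                        params$min_duration)[members])
  perm_mecs <- numeric(0)
  half <- length(members) / 2
  for (b in seq_len(max_tries)) {
    avail <- nonmembers
    matched_h <- integer(0)
    matched_n <- integer(0)
    for (m in sample(members)) {
      elig <- avail[act_count[avail] >= act_count[m]]
      if (length(elig) == 0) next
      pick <- if (length(elig) == 1) elig else sample(elig, 1)
      matched_h <- c(matched_h, m)
      matched_n <- c(matched_n, pick)
      avail <- setdiff(avail, pick)
    }
    if (length(matched_h) < half) next
    swapped <- active
    swapped[matched_h, ] <- active[matched_n, , drop = FALSE]
    swapped[matched_n, ] <- active[matched_h, , drop = FALSE]
    perm_mecs <- c(perm_mecs,
                   mean(participation_from_active(
                     swapped, adj, lag, params$min_total_event_size,
                     params$min_duration)[members]))
  }
  n_valid <- length(perm_mecs)
  p <- if (n_valid > 0) mean(perm_mecs >= obs) else NA_real_
  status <- if (n_valid < min_valid) "insufficient_data"
            else if (p <= params$alpha) "validated"
            else "not_significant"
  structure(list(observed_mec_hotspot = obs,
                 permuted_mecs = perm_mecs,
                 n_valid_permutations = n_valid,
                 p_value = p,
                 status = status,
                 seed = seed),
            class = "hotspot_validation")
}

#' @export
print.hotspot_validation <- function(x, ...) {
  cat(sprintf("Hotspot bootstrap: %d valid permutation(s), p = %s -> %s\n",
              x$n_valid_permutations,
              if (is.na(x$p_value)) "NA" else sprintf("%.4f", x$p_value),
              x$status))
  invisible(x)
}

# Events containing at least one hotspot member.
hotspot_events <- function(hotspot, events) {
  Filter(function(e) any(e$participants %in% hotspot$member_cells), events)
}

#' Probability that a hotspot's communities involve outside cells
#'
#' A hotspot community is any collective event containing at least one
#' hotspot cell; the interaction probability is the fraction of hotspot
#' communities that also contain at least one non-hotspot cell.
#'
#' @param hotspot A \code{"hotspot"} object.
#' @param events A \code{"collective_events"} object.
#' @return Probability in [0, 1]; \code{NA} (with a warning) when the
#'   hotspot has no communities.
#' @export
interaction_probability <- function(hotspot, events) {
  he <- hotspot_events(hotspot, events)
  if (length(he) == 0) {
    warning("hotspot has no communities; interaction probability undefined")
    return(NA_real_)
  }
  mixed <- vapply(he, function(e)
    any(!e$participants %in% hotspot$member_cells), logical(1))
  mean(mixed)
}

#' Fraction of mixed hotspot communities initiated by hotspot cells
#'
#' Initiators are the cells active in a community's first frame. The
#' analysis covers hotspot communities that involve at least one
#' non-hotspot cell; communities whose first frame contains both hotspot
#' and non-hotspot cells are excluded as ambiguous.
#'
#' @inheritParams interaction_probability
#' @return Fraction in [0, 1]; \code{NA} (with a warning) when every
#'   community is excluded.
#' @export
initiation_fraction <- function(hotspot, events) {
  he <- hotspot_events(hotspot, events)
  he <- Filter(function(e)
    any(!e$participants %in% hotspot$member_cells), he)
  verdicts <- vapply(he, function(e) {
    first <- e$members_by_frame[[1]]
    in_h <- first %in% hotspot$member_cells
    if (all(in_h)) "hotspot" else if (all(!in_h)) "nonhotspot" else "ambiguous"
  }, character(1))
  verdicts <- verdicts[verdicts != "ambiguous"]
  if (length(verdicts) == 0) {
    warning("no unambiguously initiated mixed communities; fraction undefined")
    return(NA_real_)
  }
  mean(verdicts == "hotspot")
}

#' Transmission probability from hotspot to non-hotspot cells
#'
#' Over all (hotspot cell, non-hotspot cell) pairs within the same hotspot
#' community at distance \code{<= eps} with distinct first-activation
#' frames, the fraction where the hotspot cell activated strictly earlier.
#' Same-frame pairs are excluded from the denominator.
#'
#' @inheritParams interaction_probability
#' @param pos Position matrix with cell ids as row names.
#' @param params An [analysis_params()] object (supplies \code{eps}).
#' @return Fraction in [0, 1]; \code{NA} (with a warning) when no pair
#'   qualifies.
#' @export
transmission_probability <- function(hotspot, events, pos,
                                     params = analysis_params()) {
  pos <- as.matrix(pos)
  he <- hotspot_events(hotspot, events)
  n_first <- 0L
  n_total <- 0L
  for (e in he) {
    act <- first_activation(e)
    h_ids <- intersect(names(act), hotspot$member_cells)
    n_ids <- setdiff(names(act), hotspot$member_cells)
    if (length(h_ids) == 0 || length(n_ids) == 0) next
    for (h in h_ids) {
      d <- sqrt((pos[n_ids, 1] - pos[h, 1])^2 + (pos[n_ids, 2] - pos[h, 2])^2)
      keep <- d <= params$eps & act[n_ids] != act[h]
      n_total <- n_total + sum(keep)
      n_first <- n_first + sum(keep & act[h] < act[n_ids])
    }
  }
  if (n_total == 0) {
    warning("no qualifying hotspot/non-hotspot pairs; transmission undefined")
    return(NA_real_)
  }
  n_first / n_total
}

#' Expected probability of a hotspot cell initiating a community
#'
#' Under random activation order, the chance that a hotspot cell initiates
#' a hotspot community equals the proportion of hotspot cells among its
#' participants; this proportion is averaged across hotspot communities.
#'
#' @inheritParams interaction_probability
#' @return Mean proportion in [0, 1]; \code{NA} when the hotspot has no
#'   communities.
#' @export
expected_initiator_probability <- function(hotspot, events) {
  he <- hotspot_events(hotspot, events)
  if (length(he) == 0) return(NA_real_)
  mean(vapply(he, function(e)
    mean(e$participants %in% hotspot$member_cells), numeric(1)))
}

#' Full interaction profile of a hotspot
#'
#' Convenience wrapper computing every hotspot-environment statistic at
#' once.
#'
#' @inheritParams transmission_probability
#' @return List with \code{hotspot_size}, \code{p_interact},
#'   \code{init_fraction}, \code{transmission_prob},
#'   \code{expected_initiator_prob}.
#' @export
interaction_profile <- function(hotspot, events, pos,
                                params = analysis_params()) {
  list(hotspot_size = length(hotspot$member_cells),
       p_interact = suppressWarnings(interaction_probability(hotspot, events)),
       init_fraction = suppressWarnings(initiation_fraction(hotspot, events)),
       transmission_prob = suppressWarnings(
         transmission_probability(hotspot, events, pos, params)),
       expected_initiator_prob =
         expected_initiator_probability(hotspot, events))
}
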