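#' Detect transient collective signaling events
#'
#' Links active cells into transient multicellular communities: at every
#' frame, co-active cells within \code{eps} of each other belong to the same
#' community, and a newly activating cell joins an existing community if any
#' of its cells was active within the preceding lag window
#' (\code{ceiling(max_lag / frame_interval)} frames) at a distance
#' \code{<= eps}. Communities that become linked through a shared cell or
#' neighborhood are merged; a community closes after a full lag window with
#' no member activity. Detected events are filtered to
#' \code{min_total_event_size} distinct participants and
#' \code{min_duration} frames of lifetime. With
#' \code{min_cluster_size > 1}, per-frame groups of co-active neighbors
#' smaller than that size are ignored for that frame.
#'
#' @param activity An \code{"activity_matrix"} object.
#' @param pos Position matrix (columns x, y, um), rows aligned with the
#'   activity matrix.
#' @param params An [analysis_params()] object.
#' @return An object of class \code{"collective_events"}: a list of events,
#'   each with \code{event_id}, \code{participants} (cell ids),
#'   \code{members_by_frame} (named list: frame -> active member ids),
#'   \code{frames}, \code{start_frame}, \code{end_frame}.
#' @seealso [brute_force_events()] for the exhaustive reference
#'   implementation, [summarize_event()], [propagation_speed()].
#' @export
detect_events <- function(activity, pos, params = analysis_params()) {
  stopifnot(inherits(activity, "activity_matrix"))
  pos <- as.matrix(pos)
  if (nrow(pos) != nrow(activity$active))
    stop("positions and activity must share the cell roster")
  if (params$eps <= 0) stop("'eps' must be positive")
  adj <- eps_adjacency(pos, params$eps)
  lag <- lag_frames(params, activity$frame_interval)
  active <- activity$active
  if (params$min_cluster_size > 1)
    active <- drop_small_clusters(active, adj, params$min_cluster_size)
  lr <- link_runs(active, adj, lag)
  build_events(lr, rownames(activity$active), params)
}

# Symmetric logical adjacency at distance <= eps, FALSE diagonal.
eps_adjacency <- function(pos, eps) {
  d <- as.matrix(stats::dist(pos))
  adj <- d <= eps
  diag(adj) <- FALSE
  adj
}

# Remove per-frame connected groups of co-active neighbors smaller than k.
drop_small_clusters <- function(active, adj, k) {
  nf <- ncol(active)
  for (t in seq_len(nf)) {
    on <- which(active[, t] == 1L)
    if (length(on) < 2) {
      if (length(on) == 1 && k > 1) active[on, t] <- 0L
      next
    }
    comp <- components_of(on, adj)
    for (cells in comp) if (length(cells) < k) active[cells, t] <- 0L
  }
  active
}

# Connected components of the subgraph induced by `nodes` under `adj`,
# by breadth-first search. Returns a list of integer vectors.
components_of <- function(nodes, adj) {
  seen <- logical(length(nodes))
  names(seen) <- nodes
  out <- list()
  for (start in nodes) {
    if (seen[as.character(start)]) next
    queue <- start
    comp <- integer(0)
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      if (seen[as.character(v)]) next
      seen[as.character(v)] <- TRUE
      comp <- c(comp, v)
      nb <- nodes[adj[v, nodes] & !seen[as.character(nodes)]]
      queue <- c(queue, nb)
    }
    out[[length(out) + 1L]] <- comp
  }
  out
}

# Extract maximal active runs of every cell: parallel vectors of
# cell index, start frame, end frame.
extract_runs <- function(active) {
  cells <- integer(0); starts <- integer(0); ends <- integer(0)
  for (i in seq_len(nrow(active))) {
    row <- active[i, ]
    on <- run_onsets(row)
    if (length(on) == 0) next
    off <- run_ends(row)
    cells <- c(cells, rep.int(i, length(on)))
    starts <- c(starts, on)
    ends <- c(ends, off)
  }
  list(cells = cells, starts = starts, ends = ends)
}

# Online single sweep over activation-run starts: each starting run is
# unioned with every run (its own cell's previous run included) that was
# active within the preceding `lag` frames at distance <= eps. Union-find
# over run nodes; returns runs plus their component root.
link_runs <- function(active, adj, lag) {
  r <- extract_runs(active)
  n <- length(r$cells)
  root <- integer(n)
  if (n > 0) {
    parent <- seq_len(n)
    find <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]
        x <- parent[x]
      }
      x
    }
    nc <- nrow(active)
    cur_node <- integer(nc)        # latest registered run per cell (0 = none)
    cur_end <- rep(-1e9, nc)       # its end frame
    for (k in order(r$starts, r$cells)) {
      c0 <- r$cells[k]
      s <- r$starts[k]
      thr <- s - lag
      if (cur_node[c0] > 0L && cur_end[c0] >= thr) {
        ra <- find(k); rb <- find(cur_node[c0])
        if (ra != rb) parent[ra] <- rb
      }
      cur_node[c0] <- k
      cur_end[c0] <- r$ends[k]
      nb <- which(adj[, c0] & cur_node > 0L & cur_end >= thr)
      for (j in nb) {
        ra <- find(k); rb <- find(cur_node[j])
        if (ra != rb) parent[ra] <- rb
      }
    }
    root <- vapply(seq_len(n), find, integer(1))
  }
  list(cells = r$cells, starts = r$starts, ends = r$ends, root = root)
}

# Assemble filtered event objects from linked runs.
build_events <- function(lr, cell_ids, params) {
  comps <- split(seq_along(lr$root), lr$root)
  events <- list()
  for (comp in comps) {
    pc <- sort(unique(lr$cells[comp]))
    start <- min(lr$starts[comp])
    end <- max(lr$ends[comp])
    if (length(pc) < params$min_total_event_size) next
    if (end - start + 1 < params$min_duration) next
    mbf <- members_by_frame(lr, comp, cell_ids)
    events[[length(events) + 1L]] <- list(
      participants = cell_ids[pc],
      members_by_frame = mbf,
      frames = as.integer(names(mbf)),
      start_frame = start,
      end_frame = end)
  }
  ord <- order(vapply(events, `[[`, numeric(1), "start_frame"))
  events <- events[ord]
  for (i in seq_along(events)) {
    events[[i]]$event_id <- i
    class(events[[i]]) <- "collective_event"
  }
  structure(events, class = "collective_events")
}

members_by_frame <- function(lr, comp, cell_ids) {
  frames <- unlist(lapply(comp, function(k) lr$starts[k]:lr$ends[k]))
  cells <- rep.int(lr$cells[comp], lr$ends[comp] - lr$starts[comp] + 1L)
  m <- split(cell_ids[cells], frames)
  m[order(as.integer(names(m)))]
}

#' @export
print.collective_events <- function(x, ...) {
  cat(sprintf("%d collective event(s)\n", length(x)))
  if (length(x) > 0) {
    sizes <- vapply(x, function(e) length(e$participants), integer(1))
    cat(sprintf("  sizes: %s\n", paste(sizes, collapse = ", ")))
  }
  invisible(x)
}

#' @export
print.collective_event <- function(x, ...) {
  cat(sprintf("Event %d: %d participants, frames %d-%d\n",
              x$event_id, length(x$participants), x$start_frame, x$end_frame))
  invisible(x)
}

#' Exhaustive reference detector for collective events
#'
#' Independent reference implementation used to cross-check
#' [detect_events()] on small instances: builds the full graph whose nodes
#' are (cell, activation run) pairs and whose edges connect runs of
#' neighboring cells (distance \code{<= eps}, or the same cell) whose
#' temporal gap is at most the lag window, then takes connected components
#' and applies the same size and duration filters. Refuses instances larger
#' than 12 cells x 40 frames and requires \code{min_cluster_size = 1}.
#'
#' @inheritParams detect_events
#' @return A \code{"collective_events"} object.
#' @export
brute_force_events <- function(activity, pos, params = analysis_params()) {
  stopifnot(inherits(activity, "activity_matrix"))
  active <- activity$active
  if (nrow(active) > 12 || ncol(active) > 40)
    stop("brute_force_events is restricted to <= 12 cells and <= 40 frames")
  if (params$min_cluster_size != 1)
    stop("brute_force_events requires min_cluster_size = 1")
  pos <- as.matrix(pos)
  lag <- lag_frames(params, activity$frame_interval)
  d <- as.matrix(stats::dist(pos))
  r <- extract_runs(active)
  n <- length(r$cells)
  root <- integer(0)
  if (n > 0) {
    edges <- integer(0)
    if (n > 1) {
      for (a in seq_len(n - 1)) {
        for (b in (a + 1):n) {
          same_cell <- r$cells[a] == r$cells[b]
          close_enough <- same_cell || d[r$cells[a], r$cells[b]] <= params$eps
          gap <- max(r$starts[a] - r$ends[b], r$starts[b] - r$ends[a])
          if (close_enough && gap <= lag) edges <- c(edges, a, b)
        }
      }
    }
    g <- igraph::make_graph(edges, n = n, directed = FALSE)
    root <- igraph::components(g)$membership
  }
  lr <- list(cells = r$cells, starts = r$starts, ends = r$ends, root = root)
  build_events(lr, rownames(active), params)
}

#' Summarize a collective event
#'
#' @param event A \code{"collective_event"}.
#' @param frame_interval Seconds per frame, for the duration in seconds.
#' @return List with \code{size} (distinct participants),
#'   \code{max_concurrent} (largest per-frame member count),
#'   \code{duration_frames} (lifetime span) and \code{duration_s}.
#' @export
summarize_event <- function(event, frame_interval = NULL) {
  stopifnot(inherits(event, "collective_event"))
  dur <- event$end_frame - event$start_frame + 1L
  list(size = length(event$participants),
       max_concurrent = max(lengths(event$members_by_frame)),
       duration_frames = dur,
       duration_s = if (is.null(frame_interval)) NA_real_
                    else dur * frame_interval)
}

#' First activation frame of each participant within an event
#'
#' @param event A \code{"collective_event"}.
#' @return Named integer vector: first frame at which each participant is
#'   active inside the event.
#' @export
first_activation <- function(event) {
  frames <- rep(as.integer(names(event$members_by_frame)),
                lengths(event$members_by_frame))
  cells <- unlist(event$members_by_frame, use.names = FALSE)
  vapply(split(frames, cells), min, integer(1))[event$participants]
}

#' Intercellular signaling propagation speed of an event
#'
#' Over all participant pairs at distance \code{<= eps} whose first
#' activations fall on different frames, the pair speed is distance divided
#' by the absolute activation-time difference; the event speed is the mean
#' over those pairs. Simultaneous (same-frame) pairs are excluded; an event
#' with no sequential adjacent pair has speed 0.
#'
#' @param event A \code{"collective_event"}.
#' @param pos Position matrix with cell ids as row names.
#' @param frame_interval Seconds per frame.
#' @param eps Adjacency distance in um.
#' @return Speed in um/s (0 if no qualifying pair).
#' @export
propagation_speed <- function(event, pos, frame_interval, eps = 14) {
  stopifnot(inherits(event, "collective_event"))
  pos <- as.matrix(pos)
  act <- first_activation(event)
  ids <- names(act)
  if (length(ids) < 2) return(0)
  p <- pos[ids, , drop = FALSE]
  d <- as.matrix(stats::dist(p))
  dt <- abs(outer(act, act, "-")) * frame_interval
  keep <- upper.tri(d) & d <= eps & dt > 0
  if (!any(keep)) return(0)
  mean(d[keep] / dt[keep])
}

# Fast internal path: per-cell distinct-event participation counts straight
# from a 0/1 activity matrix and a precomputed adjacency. Used by the
# permutation and bootstrap loops where only counts (and MEC) are needed.
participation_from_active <- function(active, adj, lag,
                                      min_size, min_duration = 1) {
  lr <- link_runs(active, adj, lag)
  counts <- integer(nrow(active))
  if (length(lr$root) == 0) return(counts)
  comps <- split(seq_along(lr$root), lr$root)
  for (comp in comps) {
    pc <- unique(lr$cells[comp])
    if (length(pc) < min_size) next
    if (max(lr$ends[comp]) - min(lr$starts[comp]) + 1 < min_duration) next
    counts[pc] <- counts[pc] + 1L
  }
  counts
}
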