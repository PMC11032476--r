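# Fixtures built in code, shared across the suite.

# Recording reconstructing a six-cell propagation event: a chain of cells
# 10 um apart activates sequentially with overlapping active periods so
# that at most five cells are concurrently active while six participate
# overall. Distractors: a far isolated active cell, a silent (constant)
# cell next to the chain, and a far co-active pair (below the three-cell
# community floor).
make_propagation_recording <- function(frame_interval = 3) {
  nf <- 60
  cells <- data.frame(
    cell_id = c(paste0("chain", 1:6), "far_single", "silent", "pairA", "pairB"),
    x = c(0, 10, 20, 30, 40, 50, 200, 25, 300, 305),
    y = c(0, 0, 0, 0, 0, 0, 0, 8, 300, 300),
    stringsAsFactors = FALSE)
  active_frames <- list(
    chain1 = 10:14, chain2 = 11:15, chain3 = 12:16,
    chain4 = 13:16, chain5 = 14:17, chain6 = 16:18,
    far_single = 12:13, silent = integer(0),
    pairA = 20:21, pairB = 20:21)
  raw <- matrix(100, nrow = nrow(cells), ncol = nf,
                dimnames = list(cells$cell_id, NULL))
  for (id in names(active_frames)) {
    raw[id, active_frames[[id]]] <- 1000
  }
  recording(cells, raw, frame_interval)
}

# Wrap a 0/1 matrix into an activity object for direct event-level tests.
make_activity <- function(active, frame_interval = 3) {
  active <- matrix(as.integer(active), nrow = nrow(active),
                   dimnames = dimnames(active))
  structure(list(active = active,
                 detrended = active * 1.0,
                 onsets = apply(active, 1, cacomm:::run_onsets,
                                simplify = FALSE),
                 frame_interval = frame_interval),
            class = "activity_matrix")
}

# Random small instance for the oracle-equivalence sweep.
random_instance <- function(max_cells = 12, max_frames = 40, p_active = 0.2) {
  nc <- sample(3:max_cells, 1)
  nf <- sample(8:max_frames, 1)
  pos <- cbind(x = stats::runif(nc, 0, 60), y = stats::runif(nc, 0, 60))
  rownames(pos) <- paste0("c", seq_len(nc))
  active <- matrix(stats::rbinom(nc * nf, 1, p_active), nc, nf,
                   dimnames = list(rownames(pos), NULL))
  list(activity = make_activity(active), pos = pos)
}

# Canonical participant-set signature of an event list, order-independent.
event_signature <- function(events) {
  sort(vapply(events, function(e) paste(sort(e$participants), collapse = ","),
              character(1)))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Hand-made event for operations that take a single event.
make_event <- function(members_by_frame, event_id = 1L) {
  frames <- as.integer(names(members_by_frame))
  structure(list(event_id = event_id,
                 participants = sort(unique(unlist(members_by_frame))),
                 members_by_frame = members_by_frame,
                 frames = frames,
                 start_frame = min(frames),
                 end_frame = max(frames)),
            class = "collective_event")
}
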