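#' Construct a recording of single-cell fluorescence traces
#'
#' A recording couples static 2-D cell centroids (um) with one raw
#' fluorescence trace per cell sampled at a fixed frame interval. Centroids
#' are treated as static over the recording; all distances are Euclidean in
#' the imaging plane.
#'
#' @param cells data.frame with columns \code{cell_id}, \code{x}, \code{y}
#'   (um). \code{cell_id} must be unique; coordinates must be finite.
#' @param raw Numeric matrix of raw intensities, one row per cell (same
#'   order as \code{cells}), one column per frame; at least 2 frames.
#' @param frame_interval Seconds per frame (> 0).
#' @param metadata Optional named list (condition, stage, recording id, ...).
#' @return An object of class \code{"recording"}.
#' @examples
#' cells <- data.frame(cell_id = c("a", "b"), x = c(0, 10), y = c(0, 0))
#' raw <- rbind(c(5, 7, 6), c(4, 9, 5))
#' rec <- recording(cells, raw, frame_interval = 3)
#' rec
#' @export
recording <- function(cells, raw, frame_interval, metadata = list()) {
  if (!is.data.frame(cells) || !all(c("cell_id", "x", "y") %in% names(cells)))
    stop("'cells' must be a data.frame with columns cell_id, x, y")
  cells$cell_id <- as.character(cells$cell_id)
  if (anyDuplicated(cells$cell_id))
    stop("duplicate cell_id(s): ",
         paste(unique(cells$cell_id[duplicated(cells$cell_id)]), collapse = ", "))
  if (!all(is.finite(cells$x)) || !all(is.finite(cells$y)))
    stop("cell coordinates must be finite")
  raw <- as.matrix(raw)
  if (!is.numeric(raw)) stop("'raw' must be a numeric matrix")
  if (nrow(raw) != nrow(cells))
    stop("'raw' must have one row per cell (", nrow(cells), "), got ", nrow(raw))
  if (ncol(raw) < 2) stop("a recording needs at least 2 frames")
  if (anyNA(raw) || any(!is.finite(raw)))
    stop("raw traces must be finite and complete")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1 ||
      !is.finite(frame_interval) || frame_interval <= 0)
    stop("'frame_interval' must be a positive number of seconds per frame")
  rownames(raw) <- cells$cell_id
  structure(list(cells = cells[, c("cell_id", "x", "y")],
                 raw = raw,
                 frame_interval = as.numeric(frame_interval),
                 metadata = metadata),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  dur <- ncol(x$raw) * x$frame_interval
  cat(sprintf("Recording: %d cells x %d frames (%.1f s/frame, %.1f min)\n",
              nrow(x$raw), ncol(x$raw), x$frame_interval, dur / 60))
  if (length(x$metadata) > 0) {
    meta <- vapply(x$metadata, function(v) paste(format(v), collapse = ","),
                   character(1))
    cat("  metadata:", paste(names(meta), meta, sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

#' Number of cells / frames / duration of a recording
#'
#' @param recording A \code{"recording"} object.
#' @return \code{n_cells}: integer; \code{n_frames}: integer;
#'   \code{duration_s}: recording length in seconds.
#' @export
n_cells <- function(recording) nrow(recording$raw)

#' @rdname n_cells
#' @export
n_frames <- function(recording) ncol(recording$raw)

#' @rdname n_cells
#' @export
duration_s <- function(recording) ncol(recording$raw) * recording$frame_interval

#' Cell positions as a matrix
#'
#' @param recording A \code{"recording"} object.
#' @return Numeric matrix with columns \code{x}, \code{y} and cell ids as
#'   row names.
#' @export
positions <- function(recording) {
  m <- cbind(x = recording$cells$x, y = recording$cells$y)
  rownames(m) <- recording$cells$cell_id
  m
}

#' Read a recording from CSV files
#'
#' Two layouts are accepted, matching common Fiji z-profile exports.
#' \describe{
#'   \item{wide}{\code{traces_path} has one row per cell: a \code{cell_id}
#'     column followed by one column per frame (any names, read in order).}
#'   \item{long}{\code{traces_path} has columns \code{cell_id},
#'     \code{frame}, \code{intensity}, with frames numbered 1..T for every
#'     cell.}
#' }
#' In both layouts \code{coords_path} is a CSV with columns \code{cell_id},
#' \code{x}, \code{y}. Cells are ordered by first appearance in the traces
#' file; intensities are kept unmodified.
#'
#' @param traces_path CSV of intensities in the declared layout.
#' @param coords_path CSV of cell centroids (um).
#' @param layout \code{"wide"} or \code{"long"}.
#' @param frame_interval Seconds per frame.
#' @param metadata Optional named list.
#' @return A \code{"recording"} object.
#' @seealso [write_recording()] for the inverse operation.
#' @export
read_recording <- function(traces_path, coords_path,
                           layout = c("wide", "long"),
                           frame_interval, metadata = list()) {
  layout <- match.arg(layout)
  coords <- utils::read.csv(coords_path, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "x", "y") %in% names(coords)))
    stop("coordinates file must have columns cell_id, x, y: ", coords_path)
  coords$cell_id <- as.character(coords$cell_id)
  tr <- utils::read.csv(traces_path, stringsAsFactors = FALSE)

  if (layout == "wide") {
    if (!"cell_id" %in% names(tr))
      stop("wide traces file must have a cell_id column: ", traces_path)
    ids <- as.character(tr$cell_id)
    raw <- as.matrix(tr[, setdiff(names(tr), "cell_id"), drop = FALSE])
    storage.mode(raw) <- "double"
    dimnames(raw) <- NULL
    if (anyNA(raw)) {
      bad <- ids[apply(is.na(raw), 1, any)]
      stop("incomplete trace for cell(s): ", paste(bad, collapse = ", "))
    }
  } else {
    need <- c("cell_id", "frame", "intensity")
    if (!all(need %in% names(tr)))
      stop("long traces file must have columns cell_id, frame, intensity: ",
           traces_path)
    tr$cell_id <- as.character(tr$cell_id)
    ids <- unique(tr$cell_id)
    frames <- sort(unique(tr$frame))
    if (!identical(as.numeric(frames), as.numeric(seq_along(frames))))
      stop("long layout frames must be numbered 1..T without gaps")
    raw <- matrix(NA_real_, nrow = length(ids), ncol = length(frames))
    raw[cbind(match(tr$cell_id, ids), match(tr$frame, frames))] <- tr$intensity
    if (anyNA(raw)) {
      bad <- ids[apply(is.na(raw), 1, any)]
      stop("incomplete trace for cell(s): ", paste(bad, collapse = ", "))
    }
  }

  missing_coord <- setdiff(ids, coords$cell_id)
  if (length(missing_coord) > 0)
    stop("missing coordinates for cell(s): ",
         paste(missing_coord, collapse = ", "))
  cells <- coords[match(ids, coords$cell_id), c("cell_id", "x", "y")]
  rownames(cells) <- NULL
  recording(cells, raw, frame_interval, metadata)
}

#' Write a recording to CSV files
#'
#' Inverse of [read_recording()]: writes the traces in the requested layout
#' plus the coordinates table. A read-write-read round trip reproduces the
#' recording exactly.
#'
#' @param recording A \code{"recording"} object.
#' @param traces_path,coords_path Output CSV paths.
#' @param layout \code{"wide"} or \code{"long"}.
#' @return Invisibly, the recording.
#' @export
write_recording <- function(recording, traces_path, coords_path,
                            layout = c("wide", "long")) {
  layout <- match.arg(layout)
  utils::write.csv(recording$cells, coords_path, row.names = FALSE)
  if (layout == "wide") {
    df <- data.frame(cell_id = recording$cells$cell_id,
                     recording$raw, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df) <- c("cell_id", paste0("f", seq_len(ncol(recording$raw))))
    utils::write.csv(df, traces_path, row.names = FALSE)
  } else {
    nf <- ncol(recording$raw)
    df <- data.frame(cell_id = rep(recording$cells$cell_id, each = nf),
                     frame = rep(seq_len(nf), times = nrow(recording$raw)),
                     intensity = as.vector(t(recording$raw)),
                     stringsAsFactors = FALSE)
    utils::write.csv(df, traces_path, row.names = FALSE)
  }
  invisible(recording)
}
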