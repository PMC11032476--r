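#' Min-max normalize raw fluorescence traces
#'
#' Maps each cell's raw trace F to F' = (F - Fmin) / (Fmax - Fmin), so every
#' non-constant trace spans exactly [0, 1]. Normalization is per cell, which
#' makes downstream thresholds comparable across cells with different
#' indicator expression levels. Constant traces (Fmax == Fmin) cannot be
#' scaled; they are mapped to all zeros, flagged, and later excluded from
#' spike calling while still counting for geometry (density, shuffling).
#'
#' @param recording A \code{"recording"} object.
#' @return An object of class \code{"normalized_traces"} with elements
#'   \describe{
#'     \item{values}{matrix [cell x frame] in [0, 1]}
#'     \item{f_min, f_max}{per-cell raw extrema}
#'     \item{constant}{logical vector flagging constant traces}
#'     \item{frame_interval}{copied from the recording}
#'   }
#' @examples
#' cells <- data.frame(cell_id = c("a", "b"), x = c(0, 10), y = c(0, 0))
#' rec <- recording(cells, rbind(c(2, 4, 6), c(1, 1, 1)), frame_interval = 3)
#' nt <- suppressWarnings(normalize_traces(rec))
#' nt$values
#' nt$constant
#' @export
normalize_traces <- function(recording) {
  stopifnot(inherits(recording, "recording"))
  raw <- recording$raw
  f_min <- apply(raw, 1, min)
  f_max <- apply(raw, 1, max)
  rng <- f_max - f_min
  constant <- rng == 0
  vals <- (raw - f_min) / ifelse(constant, 1, rng)
  vals[constant, ] <- 0
  if (any(constant))
    warning("constant trace(s) normalized to zero: ",
            paste(rownames(raw)[constant], collapse = ", "))
  structure(list(values = vals,
                 f_min = f_min,
                 f_max = f_max,
                 constant = constant,
                 frame_interval = recording$frame_interval),
            class = "normalized_traces")
}

#' @export
print.normalized_traces <- function(x, ...) {
  cat(sprintf("Normalized traces: %d cells x %d frames (%d constant)\n",
              nrow(x$values), ncol(x$values), sum(x$constant)))
  invisible(x)
}
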