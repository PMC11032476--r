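#' Configuration for the synthetic recording generator
#'
#' Describes a simulated field of spiking, optionally coupled, cells. Cells
#' are placed in a rectangular field, fire source spikes as independent
#' Poisson processes, and propagate each spike to neighbors within the
#' coupling radius with a per-link transmission probability after a delay
#' of distance/speed (with multiplicative jitter). Localized regions can be
#' declared as planted hotspots with their own rate and transmission
#' multipliers. The defaults emulate the recordings the pipeline is built
#' for: dozens of cells in a ~150 um field imaged every ~3 s for a few
#' minutes, GCaMP-like traces with baseline noise and transient spikes,
#' neighbor-to-neighbor propagation at ~1.6 um/s over <= 14 um links.
#'
#' @param n_cells Number of cells.
#' @param field Field size in um, \code{c(width, height)}.
#' @param placement \code{"uniform"}, \code{"clustered"} (Thomas process:
#'   Poisson parents, Gaussian offspring) or \code{"manual"} (supply
#'   \code{positions}).
#' @param parent_rate Parent intensity per um^2 for clustered placement.
#' @param offspring_sd Gaussian offspring SD in um for clustered placement.
#' @param positions Optional n x 2 matrix of positions for manual placement.
#' @param frame_interval Seconds per frame.
#' @param duration Recording length in seconds.
#' @param baseline_mean,baseline_sd Baseline fluorescence level and Gaussian
#'   noise SD (arbitrary intensity units).
#' @param spike_amplitude Peak added intensity of one spike.
#' @param tau Exponential decay time constant of the spike kernel (s).
#' @param saturation Fluorescence response ceiling as a multiple of
#'   \code{spike_amplitude}: overlapping transients sum only up to this
#'   level, emulating indicator saturation (\code{Inf} = linear
#'   summation).
#' @param rate Per-cell source-spike rate in spikes/min (the population
#'   mean when \code{rate_cv > 0}).
#' @param rate_cv Coefficient of variation of per-cell source rates: rates
#'   are Gamma-distributed with mean \code{rate} and this CV (0 =
#'   homogeneous population).
#' @param coupling_radius Maximum link length for propagation (um).
#' @param p_t Per-link transmission probability in [0, 1].
#' @param speed Propagation speed in um/s (hop delay = distance / speed).
#' @param jitter Relative uniform jitter on hop delays (0.2 = +/-20%).
#' @param hotspots List of planted hotspots; each element is a list with
#'   \code{center} (c(x, y)), \code{radius} (um), and optionally
#'   \code{n_seeded} (cells placed inside the disc, default 0),
#'   \code{rate_mult} (source-rate multiplier for in-region cells, default
#'   1), \code{pt_mult} (transmission multiplier for links whose two
#'   endpoints both lie in the region, default 1; enhanced mutual coupling
#'   is a property of the cell-cell interface) and \code{renewal_shape}
#'   (Gamma-renewal shape of the region's joint source process: 1 = Poisson
#'   clumping, larger values give regular pacemaker-like recurrence;
#'   default 1).
#' @param mode \code{"wildtype"} or \code{"uncoupled"}; uncoupled sets the
#'   transmission probability to zero and multiplies the source rate by
#'   \code{uncoupled_rate_mult}, emulating gap-junction-inhibited tissue
#'   with elevated per-cell spiking.
#' @param uncoupled_rate_mult Source-rate multiplier applied in uncoupled
#'   mode.
#' @param seed Integer seed; fully determines the simulated output.
#' @return An object of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_cells = 50,
                              field = c(150, 150),
                              placement = c("uniform", "clustered", "manual"),
                              parent_rate = 5e-4,
                              offspring_sd = 10,
                              positions = NULL,
                              frame_interval = 3,
                              duration = 450,
                              baseline_mean = 100,
                              baseline_sd = 5,
                              spike_amplitude = 50,
                              tau = 8,
                              saturation = 1,
                              rate = 1,
                              rate_cv = 0,
                              coupling_radius = 14,
                              p_t = 0.35,
                              speed = 1.6,
                              jitter = 0.2,
                              hotspots = list(),
                              mode = c("wildtype", "uncoupled"),
                              uncoupled_rate_mult = 2,
                              seed) {
  placement <- match.arg(placement)
  mode <- match.arg(mode)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1)
    stop("an integer 'seed' is mandatory")
  if (n_cells < 1) stop("'n_cells' must be >= 1")
  if (length(field) != 2 || any(field <= 0)) stop("'field' must be c(w, h) > 0")
  if (frame_interval <= 0 || duration <= 0)
    stop("'frame_interval' and 'duration' must be positive")
  if (duration < 2 * frame_interval) stop("'duration' must span >= 2 frames")
  if (baseline_sd < 0 || spike_amplitude < 0 || tau <= 0)
    stop("trace parameters must be non-negative (tau > 0)")
  if (saturation <= 0) stop("'saturation' must be positive (Inf = linear)")
  if (rate < 0 || rate_cv < 0 || coupling_radius < 0 || jitter < 0)
    stop("rates, radii and jitter must be >= 0")
  if (p_t < 0 || p_t > 1) stop("'p_t' must be in [0, 1]")
  if (speed <= 0) stop("'speed' must be positive")
  if (placement == "manual") {
    if (is.null(positions) || nrow(positions) != n_cells)
      stop("manual placement requires a 'positions' matrix with n_cells rows")
  }
  hotspots <- lapply(hotspots, function(h) {
    if (is.null(h$center) || length(h$center) != 2 || is.null(h$radius))
      stop("each hotspot needs 'center' (x, y) and 'radius'")
    if (h$radius < 0) stop("hotspot radius must be >= 0")
    list(center = as.numeric(h$center), radius = h$radius,
         n_seeded = if (is.null(h$n_seeded)) 0L else as.integer(h$n_seeded),
         rate_mult = if (is.null(h$rate_mult)) 1 else h$rate_mult,
         pt_mult = if (is.null(h$pt_mult)) 1 else h$pt_mult,
         renewal_shape = if (is.null(h$renewal_shape)) 1 else h$renewal_shape)
  })
  if (sum(vapply(hotspots, `[[`, integer(1), "n_seeded")) > n_cells)
    stop("more seeded hotspot cells than cells")
  structure(list(n_cells = as.integer(n_cells), field = field,
                 placement = placement, parent_rate = parent_rate,
                 offspring_sd = offspring_sd, positions = positions,
                 frame_interval = frame_interval, duration = duration,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 spike_amplitude = spike_amplitude, tau = tau,
                 saturation = saturation, rate = rate,
                 rate_cv = rate_cv,
                 coupling_radius = coupling_radius, p_t = p_t, speed = speed,
                 jitter = jitter, hotspots = hotspots, mode = mode,
                 uncoupled_rate_mult = uncoupled_rate_mult,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a recording with planted cascades and ground truth
#'
#' Places cells, draws per-cell Poisson source spikes (rates scaled inside
#' hotspot regions; a hotspot may instead pace its members with a joint
#' Gamma-renewal process), propagates every spike independently to each
#' neighbor within the coupling radius with the per-link transmission
#' probability (scaled on intra-hotspot links) after a delay of
#' distance/speed plus jitter, with a per-cascade no-reactivation guard (a
#' cell fires at most once per cascade). Fluorescence is baseline +
#' Gaussian noise + a saturating sum of instant-rise, exponential-decay
#' spike kernels. The same seed always produces bit-identical output.
#'
#' @param config A [simulation_config()] object.
#' @return List with \code{recording} (a \code{"recording"}) and
#'   \code{truth}: \code{spikes} (data.frame cell_id, time, cascade,
#'   parent, delay), \code{cascades} (list of cell-id rosters),
#'   \code{hotspot_members} (list of cell ids inside each planted hotspot
#'   region), \code{positions}.
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cfg <- config
  n <- cfg$n_cells
  pos <- place_cells(cfg)
  ids <- sprintf("cell%03d", seq_len(n))
  rownames(pos) <- ids

  hotspot_members <- list()
  for (h in cfg$hotspots) {
    inside <- sqrt((pos[, 1] - h$center[1])^2 +
                   (pos[, 2] - h$center[2])^2) <= h$radius
    hotspot_members[[length(hotspot_members) + 1L]] <- ids[inside]
  }

  rate <- if (cfg$rate_cv > 0) {
    sh <- 1 / cfg$rate_cv^2
    cfg$rate * stats::rgamma(n, shape = sh, rate = sh)
  } else rep(cfg$rate, n)
  # per-link transmission probability; the hotspot multiplier applies to
  # links whose two endpoints both lie inside the hotspot region (enhanced
  # mutual coupling is a property of the cell-cell interface)
  pt_link <- matrix(cfg$p_t, n, n)
  for (k in seq_along(cfg$hotspots)) {
    inside <- ids %in% hotspot_members[[k]]
    rate[inside] <- rate[inside] * cfg$hotspots[[k]]$rate_mult
    pt_link[inside, inside] <- pmin(
      pt_link[inside, inside] * cfg$hotspots[[k]]$pt_mult, 1)
  }
  if (cfg$mode == "uncoupled") {
    rate <- rate * cfg$uncoupled_rate_mult
    pt_link[] <- 0
  }

  # source spikes: homogeneous Poisson per cell; cells of a hotspot with
  # renewal_shape > 1 instead share a Gamma-renewal source process (regular,
  # pacemaker-like recurrence; shape 1 recovers Poisson clumping)
  renewal <- rep(FALSE, n)
  src_cell <- integer(0); src_time <- numeric(0)
  for (k in seq_along(cfg$hotspots)) {
    h <- cfg$hotspots[[k]]
    if (h$renewal_shape <= 1 || cfg$mode == "uncoupled") next
    idx <- which(ids %in% hotspot_members[[k]] & !renewal)
    if (length(idx) == 0) next
    renewal[idx] <- TRUE
    # pacing is deterministic: the joint rate ignores per-cell dispersion
    total_rate <- cfg$rate * h$rate_mult * length(idx) / 60  # spikes/s
    if (total_rate <= 0) next
    tt <- stats::runif(1, 0, 1 / total_rate)
    while (tt < cfg$duration) {
      src_cell <- c(src_cell, idx[sample.int(length(idx), 1)])
      src_time <- c(src_time, tt)
      tt <- tt + stats::rgamma(1, shape = h$renewal_shape,
                               rate = h$renewal_shape * total_rate)
    }
  }
  for (i in which(!renewal)) {
    k <- stats::rpois(1, rate[i] * cfg$duration / 60)
    if (k > 0) {
      src_cell <- c(src_cell, rep.int(i, k))
      src_time <- c(src_time, stats::runif(k, 0, cfg$duration))
    }
  }
  ord <- order(src_time)
  src_cell <- src_cell[ord]; src_time <- src_time[ord]

  dmat <- as.matrix(stats::dist(pos))
  nbrs <- lapply(seq_len(n), function(i)
    which(dmat[i, ] <= cfg$coupling_radius & seq_len(n) != i))

  sp_cell <- integer(0); sp_time <- numeric(0)
  sp_casc <- integer(0); sp_parent <- integer(0); sp_delay <- numeric(0)
  for (s in seq_along(src_cell)) {
    fired <- logical(n)
    # queue of (cell, time, parent); processed in time order
    q_cell <- src_cell[s]; q_time <- src_time[s]; q_par <- NA_integer_
    q_del <- NA_real_
    while (length(q_cell) > 0) {
      j <- which.min(q_time)
      c0 <- q_cell[j]; t0 <- q_time[j]; p0 <- q_par[j]; d0 <- q_del[j]
      q_cell <- q_cell[-j]; q_time <- q_time[-j]
      q_par <- q_par[-j]; q_del <- q_del[-j]
      if (fired[c0]) next
      fired[c0] <- TRUE
      sp_cell <- c(sp_cell, c0); sp_time <- c(sp_time, t0)
      sp_casc <- c(sp_casc, s); sp_parent <- c(sp_parent, p0)
      sp_delay <- c(sp_delay, d0)
      for (nb in nbrs[[c0]]) {
        if (fired[nb]) next
        if (stats::runif(1) < pt_link[c0, nb]) {
          delay <- dmat[c0, nb] / cfg$speed *
            (1 + stats::runif(1, -cfg$jitter, cfg$jitter))
          tt <- t0 + delay
          if (tt < cfg$duration) {
            q_cell <- c(q_cell, nb); q_time <- c(q_time, tt)
            q_par <- c(q_par, c0); q_del <- c(q_del, delay)
          }
        }
      }
    }
  }

  nf <- floor(cfg$duration / cfg$frame_interval)
  ft <- (seq_len(nf) - 1) * cfg$frame_interval
  resp <- matrix(0, nrow = n, ncol = nf)
  for (k in seq_along(sp_cell)) {
    after <- ft >= sp_time[k]
    resp[sp_cell[k], after] <- resp[sp_cell[k], after] +
      cfg$spike_amplitude * exp(-(ft[after] - sp_time[k]) / cfg$tau)
  }
  # indicator saturation: overlapping transients cannot sum without bound
  resp <- pmin(resp, cfg$saturation * cfg$spike_amplitude)
  raw <- resp + matrix(stats::rnorm(n * nf, cfg$baseline_mean, cfg$baseline_sd),
                       nrow = n, ncol = nf)

  cells <- data.frame(cell_id = ids, x = pos[, 1], y = pos[, 2],
                      stringsAsFactors = FALSE)
  rec <- recording(cells, raw, cfg$frame_interval,
                   metadata = list(condition = cfg$mode,
                                   seed = cfg$seed,
                                   simulated = TRUE))
  spikes <- data.frame(cell_id = ids[sp_cell],
                       time = sp_time,
                       cascade = sp_casc,
                       parent = ifelse(is.na(sp_parent), NA_character_,
                                       ids[sp_parent]),
                       delay = sp_delay,
                       stringsAsFactors = FALSE)
  truth <- list(spikes = spikes,
                cascades = split(spikes$cell_id, spikes$cascade),
                hotspot_members = hotspot_members,
                positions = pos)
  list(recording = rec, truth = truth)
}

place_cells <- function(cfg) {
  n <- cfg$n_cells
  pos <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("x", "y")))
  placed <- 0L
  for (h in cfg$hotspots) {
    k <- h$n_seeded
    if (k == 0) next
    # seeded cells form a compact cluster: uniform in the disc around the
    # hotspot center
    r <- h$radius * sqrt(stats::runif(k))
    th <- stats::runif(k, 0, 2 * pi)
    pos[placed + seq_len(k), ] <- cbind(
      pmin(pmax(h$center[1] + r * cos(th), 0), cfg$field[1]),
      pmin(pmax(h$center[2] + r * sin(th), 0), cfg$field[2]))
    placed <- placed + k
  }
  rest <- n - placed
  if (rest > 0) {
    rows <- placed + seq_len(rest)
    if (cfg$placement == "manual") {
      pos[rows, ] <- as.matrix(cfg$positions)[rows, ]
    } else if (cfg$placement == "uniform") {
      pos[rows, ] <- cbind(stats::runif(rest, 0, cfg$field[1]),
                           stats::runif(rest, 0, cfg$field[2]))
    } else {
      n_par <- max(1L, stats::rpois(1, cfg$parent_rate * prod(cfg$field)))
      par_xy <- cbind(stats::runif(n_par, 0, cfg$field[1]),
                      stats::runif(n_par, 0, cfg$field[2]))
      pick <- sample.int(n_par, rest, replace = TRUE)
      pos[rows, ] <- cbind(
        pmin(pmax(par_xy[pick, 1] + stats::rnorm(rest, 0, cfg$offspring_sd),
                  0), cfg$field[1]),
        pmin(pmax(par_xy[pick, 2] + stats::rnorm(rest, 0, cfg$offspring_sd),
                  0), cfg$field[2]))
    }
  }
  pos
}

#' Simulate an uncoupled, spatially unstructured null recording
#'
#' Runs [simulate_recording()] with the transmission probability forced to
#' zero and all hotspot multipliers removed: homogeneous independent
#' spiking, the null model for calibrating the spatial-shuffle test.
#'
#' @param config A [simulation_config()] object.
#' @return A \code{"recording"} object.
#' @export
null_recording <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  config$p_t <- 0
  config$hotspots <- list()
  config$mode <- "wildtype"
  simulate_recording(config)$recording
}

#' Simulate an activity-confounded recording
#'
#' Transmission is disabled (\code{p_t = 0}) but the hotspot regions keep
#' their source-rate multipliers: any elevated participation of the
#' designated subset arises purely from chance co-activation of hyperactive
#' cells, not from coupling. This is the null model for the hotspot
#' trace-swap bootstrap, which should reject such pseudo-hotspots.
#'
#' @param config A [simulation_config()] object with at least one hotspot.
#' @return List with \code{recording} and \code{truth} as in
#'   [simulate_recording()].
#' @export
activity_confounded_recording <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  config$p_t <- 0
  config$hotspots <- lapply(config$hotspots, function(h) {
    h$pt_mult <- 1
    h
  })
  simulate_recording(config)
}

#' Write simulation ground truth to JSON
#'
#' @param truth The \code{truth} element returned by
#'   [simulate_recording()].
#' @param path Output JSON path.
#' @return Invisibly, \code{path}.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(spikes = truth$spikes,
              cascades = truth$cascades,
              hotspot_members = truth$hotspot_members,
              positions = as.data.frame(truth$positions))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' Field names mirror the arguments of [simulation_config()]; a seed is
#' mandatory.
#'
#' @param path Path to a YAML file.
#' @return A \code{"simulation_config"} object.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0)
    stop("unknown simulation field(s): ", paste(extra, collapse = ", "))
  do.call(simulation_config, cfg)
}
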