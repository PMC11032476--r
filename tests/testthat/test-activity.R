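test_that("running-median detrending isolates transient pulses", {
  # flat baseline with one rectangular pulse: detrended is exactly the
  # pulse, rescaled to 1
  x <- rep(0, 100)
  x[50:51] <- 1
  d <- detrend_trace(x, 3, 25)
  expect_equal(d[50:51], c(1, 1))
  expect_equal(d[-(50:51)], rep(0, 98))

  # a slow monotone ramp is pure baseline: residual is exactly zero
  ramp <- seq(0, 1, length.out = 100)
  expect_equal(detrend_trace(ramp, 3, 25), rep(0, 100))
  expect_equal(detrend_trace(rep(0, 50), 3, 25), rep(0, 50))
})

test_that("window hygiene: even windows bumped, long windows truncated", {
  x <- c(rep(0, 14), 1, 1, rep(0, 14))
  expect_warning(d1 <- detrend_trace(x, 4, 25), "smooth_k")
  expect_warning(d2 <- detrend_trace(x, 3, 51), "bias_k")
  expect_equal(length(d1), length(x))
  expect_equal(length(d2), length(x))
})

test_that("binarization thresholds frames and filters weak runs", {
  expect_identical(binarize_trace(c(0, 0.5, 0.6, 0.1)), c(0L, 1L, 1L, 0L))
  expect_identical(cacomm:::run_onsets(binarize_trace(c(0, 0.5, 0.6, 0.1))), 2L)
  expect_identical(binarize_trace(rep(0.39, 10)), rep(0L, 10))
  # peak filter only bites when peak_thr > bin_thr
  d <- c(0, 0.45, 0.6, 0.45, 0, 0.45, 0.45, 0)
  expect_identical(binarize_trace(d, peak_thr = 0.5, bin_thr = 0.4),
                   c(0L, 1L, 1L, 1L, 0L, 0L, 0L, 0L))
})

test_that("binarization is monotone in bin_thr", {
  set.seed(21)
  for (i in 1:20) {
    d <- runif(60)
    thr <- sort(runif(2, 0.1, 0.9))
    lo <- binarize_trace(d, bin_thr = thr[1])
    hi <- binarize_trace(d, bin_thr = thr[2])
    expect_true(all(hi <= lo))
  }
})

test_that("onsets are exactly the first frames of maximal active runs", {
  set.seed(22)
  for (i in 1:20) {
    a <- as.integer(rbinom(50, 1, 0.3))
    ons <- cacomm:::run_onsets(a)
    ends <- cacomm:::run_ends(a)
    r <- rle(a)
    expect_equal(length(ons), sum(r$values == 1L))
    expect_equal(length(ons), length(ends))
    expect_true(all(a[ons] == 1L))
    expect_true(all(ons == 1L | a[pmax(ons - 1L, 1L)] == 0L))
  }
})

test_that("constant-trace cells are inactive everywhere", {
  rec <- make_propagation_recording()
  nt <- suppressWarnings(normalize_traces(rec))
  act <- detect_activity(nt)
  expect_true(all(act$active["silent", ] == 0L))
  expect_length(act$onsets[["silent"]], 0)
  expect_true(any(act$active["chain1", ] == 1L))
})

test_that("activation rate is onsets per minute, averaged over cells", {
  a <- matrix(0L, 2, 40)           # 40 frames at 3 s = 2 min
  a[1, c(1, 10, 20, 30)] <- 1L     # 4 onsets -> 2/min
  act <- make_activity(a, frame_interval = 3)
  r <- activation_rate(act)
  expect_equal(unname(r$per_cell), c(2, 0))
  expect_equal(r$mean, 1)
})

test_that("local density counts cells in the surrounding square", {
  pos <- rbind(a = c(0, 0), b = c(5, 0))
  expect_equal(unname(local_density(pos, 14)$per_cell), c(1, 1))
  pos2 <- rbind(a = c(0, 0), b = c(10, 10))   # both offsets beyond 7 um
  expect_equal(unname(local_density(pos2, 14)$per_cell), c(0, 0))
  # boundary: |dx| = 7 exactly is inside
  pos3 <- rbind(a = c(0, 0), b = c(7, 0))
  expect_equal(unname(local_density(pos3, 14)$per_cell), c(1, 1))
  expect_error(local_density(pos, -1), "positive")
})

test_that("mean local density matches the uniform-field expectation", {
  # 100 cells uniform in 100x100 um, 14 um window: interior expectation
  # 99 * (14/100)^2 = 1.94, reduced by border truncation to ~1.81
  set.seed(33)
  means <- replicate(40, {
    pos <- cbind(runif(100, 0, 100), runif(100, 0, 100))
    local_density(pos, 14)$mean
  })
  expect_gt(mean(means), 1.6)
  expect_lt(mean(means), 2.1)
})

test_that("spike magnitude is the z-score against the guarded background", {
  set.seed(44)
  nf <- 120
  vals <- matrix(0.2 + rnorm(nf, 0, 0.05), 1, nf,
                 dimnames = list("c1", NULL))
  vals[1, 60:62] <- c(0.7, 0.65, 0.5)
  active <- matrix(0L, 1, nf, dimnames = dimnames(vals))
  active[1, 60:62] <- 1L
  nt <- structure(list(values = vals, constant = FALSE, frame_interval = 3),
                  class = "normalized_traces")
  act <- make_activity(active)
  m <- spike_magnitude(nt, act)
  bg <- c(1:56, 66:nf)             # > 3 frames away from the active run
  expected <- (max(vals[1, 60:62]) - mean(vals[1, bg])) / sd(vals[1, bg])
  expect_equal(unname(m$per_cell), expected)
  expect_gt(m$per_cell[1], 5)      # a 0.5 jump over sd 0.05 background
  expect_false(m$flagged[1])
})

test_that("spike magnitude flags degenerate cells", {
  nf <- 20
  # continuously active cell: no background frames left
  vals <- matrix(runif(nf), 1, nf, dimnames = list("c1", NULL))
  act <- make_activity(matrix(1L, 1, nf, dimnames = dimnames(vals)))
  nt <- structure(list(values = vals, constant = FALSE, frame_interval = 3),
                  class = "normalized_traces")
  m <- spike_magnitude(nt, act)
  expect_true(m$flagged[1])
  expect_true(is.na(m$per_cell[1]))
  # spike peak equal to the background mean gives z = 0
  vals2 <- matrix(rep(c(0.2, 0.3), 30), 1, 60, dimnames = list("c1", NULL))
  a2 <- matrix(0L, 1, 60, dimnames = dimnames(vals2))
  a2[1, 30] <- 1L
  vals2[1, 30] <- mean(vals2[1, c(1:26, 34:60)])
  m2 <- spike_magnitude(structure(list(values = vals2, constant = FALSE,
                                       frame_interval = 3),
                                  class = "normalized_traces"),
                        make_activity(a2))
  expect_equal(unname(m2$per_cell), 0)
})

test_that("onset calling recovers ground-truth spikes on synthetic traces", {
  # sparse spiking so transients are resolvable at the kernel decay;
  # matching tolerance +/-3 frames (~tau); precision over spiking cells
  # (a truly silent cell's noise spans [0,1] after per-cell rescaling)
  recall_num <- 0; recall_den <- 0; prec_num <- 0; prec_den <- 0
  for (s in 1:4) {
    sim <- simulate_recording(null_config(s, rate = 0.4))
    act <- detect_activity(suppressWarnings(normalize_traces(sim$recording)))
    sp <- sim$truth$spikes
    ids <- sim$recording$cells$cell_id
    fi <- sim$recording$frame_interval
    for (i in seq_along(ids)) {
      tf <- floor(sp$time[sp$cell_id == ids[i]] / fi) + 1
      if (length(tf) == 0) next
      ons <- act$onsets[[i]]
      recall_den <- recall_den + length(tf)
      recall_num <- recall_num +
        sum(vapply(tf, function(f) length(ons) > 0 && min(abs(ons - f)) <= 3,
                   logical(1)))
      prec_den <- prec_den + length(ons)
      prec_num <- prec_num +
        sum(vapply(ons, function(o) min(abs(tf - o)) <= 3, logical(1)))
    }
  }
  expect_gte(recall_num / recall_den, 0.9)
  expect_gte(prec_num / prec_den, 0.9)
})
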