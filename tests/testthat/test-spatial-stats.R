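make_normalized <- function(vals) {
  structure(list(values = vals,
                 constant = apply(vals, 1, function(r) sd(r) == 0),
                 frame_interval = 3),
            class = "normalized_traces")
}

test_that("pair correlations recover exact relationships", {
  set.seed(51)
  base <- runif(30)
  vals <- rbind(c1 = base, c2 = base, c3 = 1 - base, c4 = rep(0.5, 30))
  pos <- cbind(x = c(0, 5, 30, 100), y = 0)
  rownames(pos) <- rownames(vals)
  pt <- suppressWarnings(pair_correlations(make_normalized(vals), pos))
  expect_equal(nrow(pt), 6)
  get <- function(i, j) pt[pt$cell_i == i & pt$cell_j == j, ]
  expect_equal(get("c1", "c2")$r, 1)
  expect_equal(get("c1", "c3")$r, -1)
  expect_equal(get("c1", "c2")$distance, 5)
  # constant cell: undefined, excluded from significance
  expect_true(is.na(get("c1", "c4")$r))
  expect_false(get("c1", "c4")$significant)
})

test_that("under independence about 5% of pairs reach p < 0.05", {
  set.seed(52)
  vals <- matrix(rnorm(50 * 60), 50, 60,
                 dimnames = list(paste0("c", 1:50), NULL))
  pos <- cbind(runif(50, 0, 100), runif(50, 0, 100))
  rownames(pos) <- rownames(vals)
  pt <- pair_correlations(make_normalized(vals), pos)
  frac <- mean(pt$significant)           # 1225 pairs
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)
})

test_that("close/far split respects the cutoff and compares groups", {
  pairs <- data.frame(cell_i = c("a", "a", "b"), cell_j = c("b", "c", "c"),
                      distance = c(10, 14, 20), r = c(0.5, 0.4, 0.1),
                      p = 0.01, significant = TRUE)
  cf <- close_far_split(pairs, cutoff = 14)
  # distance exactly 14 is close (<=), beyond is far
  expect_identical(cf$pairs$class, c("close", "close", "far"))
  st <- cf$stats
  expect_equal(st$n[st$class == "close"], 2L)
  expect_equal(st$mean[st$class == "close"], 0.45)
  expect_equal(cf$survival(0.3, "close"), 1)
  expect_equal(cf$survival(0.45, "close"), 0.5)
  expect_equal(cf$survival(0.5, "far"), 0)
  expect_true(is.finite(cf$kruskal_p))
  # degenerate split warns and skips the comparison
  pairs_far <- pairs; pairs_far$distance <- 100
  expect_warning(cf2 <- close_far_split(pairs_far, 14), "empty")
  expect_true(is.na(cf2$kruskal_p))
})

test_that("close pairs are more synchronized under distance-decaying coupling", {
  sim <- simulate_recording(simulation_config(seed = 31, p_t = 0.6))
  nt <- suppressWarnings(normalize_traces(sim$recording))
  pt <- pair_correlations(nt, positions(sim$recording))
  cf <- close_far_split(pt, 14)
  st <- cf$stats
  expect_gt(st$mean[st$class == "close"], st$mean[st$class == "far"])
  expect_lt(cf$kruskal_p, 0.05)
})

test_that("community relation labels intra, inter and uninvolved pairs", {
  ev <- structure(list(
    make_event(list("1" = c("a", "b", "c"))),
    make_event(list("5" = c("d", "e", "f")))), class = "collective_events")
  pairs <- data.frame(
    cell_i = c("a", "a", "a", "g"), cell_j = c("b", "d", "g", "h"),
    distance = 10, r = c(0.8, 0.2, 0.1, 0),
    p = 0.01, significant = TRUE, stringsAsFactors = FALSE)
  rel <- community_relation_correlation(pairs, ev)
  expect_identical(rel$pairs$relation, c("intra", "inter", "none", "none"))
  expect_equal(rel$mean_intra, 0.8)
  expect_equal(rel$mean_inter, 0.2)
})

test_that("intra-community pairs correlate more than inter-community pairs", {
  sim <- simulate_recording(simulation_config(seed = 32, p_t = 0.5))
  rec <- sim$recording
  nt <- suppressWarnings(normalize_traces(rec))
  ev <- detect_events(detect_activity(nt), positions(rec))
  rel <- community_relation_correlation(pair_correlations(nt, positions(rec)),
                                        ev)
  expect_gt(rel$mean_intra, rel$mean_inter)
})

test_that("MEC counts distinct participations per cell", {
  ev1 <- structure(list(make_event(list("1" = c("a", "b", "c")))),
                   class = "collective_events")
  expect_equal(mec(ev1, 10), 0.3)
  expect_equal(mec(list(), 10), 0)
  # two events sharing one cell, sizes 3 and 4: 7 participations
  ev2 <- structure(list(
    make_event(list("1" = c("a", "b", "c"))),
    make_event(list("9" = c("c", "d", "e", "f")), event_id = 2L)),
    class = "collective_events")
  expect_equal(mec(ev2, 10), 0.7)
  expect_equal(mec_rate(ev2, 10, duration_s = 120), 0.35)
  expect_error(mec(ev1, 0), "n_cells")
  expect_error(mec_rate(ev1, 10, 0), "duration")
})

test_that("binarization commutes with spatial shuffling of traces", {
  sim <- simulate_recording(simulation_config(seed = 33, n_cells = 20,
                                              duration = 120))
  nt <- suppressWarnings(normalize_traces(sim$recording))
  act <- detect_activity(nt)
  perm <- sample(20)
  nt_perm <- nt
  nt_perm$values <- nt$values[perm, ]
  nt_perm$constant <- nt$constant[perm]
  act_perm <- detect_activity(nt_perm)
  expect_identical(unname(act_perm$active), unname(act$active[perm, ]))
})

test_that("the spatial-shuffle test is seeded, bounded and arithmetic-correct", {
  sim <- simulate_recording(simulation_config(seed = 34, n_cells = 25,
                                              duration = 180))
  st1 <- spatial_shuffle_test(sim$recording, n_perm = 50, seed = 7)
  st2 <- spatial_shuffle_test(sim$recording, n_perm = 50, seed = 7)
  expect_identical(st1$permuted_mecs, st2$permuted_mecs)
  expect_gte(st1$p_spatial, 0)
  expect_lte(st1$p_spatial, 1)
  expect_equal(st1$p_spatial, mean(st1$permuted_mecs >= st1$observed_mec))
  expect_equal(st1$magnitude, st1$observed_mec / mean(st1$permuted_mecs))
  expect_identical(st1$significant, st1$p_spatial <= 0.05)
})

test_that("strong planted coupling is declared spatially significant", {
  sim <- simulate_recording(simulation_config(seed = 42))
  st <- spatial_shuffle_test(sim$recording, n_perm = 200, seed = 1)
  expect_lte(st$p_spatial, 0.05)
  expect_gt(st$magnitude, 1)
})

test_that("condition comparisons run Fisher and Kruskal-Wallis machinery", {
  # 11/12 versus 0/8 spatially significant recordings
  res <- data.frame(
    condition = c(rep("wt", 12), rep("blocked", 8)),
    significant = c(rep(TRUE, 11), FALSE, rep(FALSE, 8)),
    magnitude = c(rnorm(12, 2, 0.3), rnorm(8, 1, 0.1)))
  out <- compare_conditions(res)
  expect_equal(out$fisher$p[1],
               fisher.test(matrix(c(11, 1, 0, 8), 2, byrow = TRUE))$p.value)
  expect_lt(out$fisher$p[1], 0.05)
  expect_true("magnitude" %in% out$kruskal$variable)
  # identical distributions: Kruskal-Wallis p = 1
  res2 <- data.frame(condition = rep(c("a", "b"), each = 3),
                     significant = TRUE,
                     magnitude = rep(c(1, 2, 3), 2))
  out2 <- compare_conditions(res2)
  expect_equal(out2$kruskal$p[out2$kruskal$variable == "magnitude"], 1)
  # single condition: warning, no tests
  expect_warning(out3 <- compare_conditions(data.frame(condition = "a",
                                                       significant = TRUE)),
                 "fewer than 2")
  expect_equal(nrow(out3$fisher), 0)
})
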