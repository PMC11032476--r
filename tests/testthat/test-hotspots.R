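# A hand-made hotspot over cells h1..h3 with n1..n3 outside.
toy_hotspot <- function(members = c("h1", "h2", "h3")) {
  structure(list(hotspot_id = 1L, member_cells = members,
                 participation_counts = setNames(rep(6L, length(members)),
                                                 members),
                 hull = NULL, hull_area = 0, lg_max = 6, lg_threshold = 5),
            class = "hotspot")
}

events_of <- function(...) structure(list(...), class = "collective_events")

test_that("participation counts distinct events per cell", {
  ev <- events_of(
    make_event(list("1" = c("a", "b", "c"))),
    make_event(list("4" = c("a", "b", "c"), "5" = c("b", "d")), event_id = 2L))
  counts <- participation_counts(ev, c("a", "b", "c", "d", "e"))
  expect_identical(unname(counts), c(2L, 2L, 2L, 1L, 0L))
})

test_that("the participation threshold is max(5, half the maximum)", {
  pos <- cbind(x = seq(0, 90, by = 10), y = 0)
  rownames(pos) <- paste0("c", 1:10)
  # lg_max 8 -> threshold 5: counts 5 qualify, 4 do not
  counts <- setNames(c(8L, 5L, 5L, 4L, rep(0L, 6)), rownames(pos))
  hs <- detect_hotspots(counts, pos)
  expect_length(hs, 1)
  expect_setequal(hs[[1]]$member_cells, c("c1", "c2", "c3"))
  expect_equal(hs[[1]]$lg_threshold, 5)
  # lg_max 14 -> threshold 7 (not rounded): 7 in, 6 out
  counts2 <- setNames(c(14L, 7L, 7L, 6L, rep(0L, 6)), rownames(pos))
  hs2 <- detect_hotspots(counts2, pos)
  expect_setequal(hs2[[1]]$member_cells, c("c1", "c2", "c3"))
  expect_equal(hs2[[1]]$lg_threshold, 7)
})

test_that("hotspot candidates are connected components of at least 3 cells", {
  # two marked groups separated by > eps; one has only 2 cells
  pos <- rbind(a = c(0, 0), b = c(10, 0), c = c(20, 0),
               d = c(100, 0), e = c(110, 0))
  counts <- setNames(c(6L, 6L, 6L, 6L, 6L), rownames(pos))
  hs <- detect_hotspots(counts, pos)
  expect_length(hs, 1)
  expect_setequal(hs[[1]]$member_cells, c("a", "b", "c"))
  # no marked cells at all
  expect_length(detect_hotspots(setNames(rep(0L, 5), rownames(pos)), pos), 0)
})

test_that("convex hull area follows the member geometry", {
  pos <- rbind(a = c(0, 0), b = c(10, 0), c = c(0, 10), d = c(100, 100))
  counts <- setNames(c(6L, 6L, 6L, 0L), rownames(pos))
  hs <- detect_hotspots(counts, pos)
  expect_equal(hs[[1]]$hull_area, 50)  # right triangle, legs 10
})

test_that("hotspot members stay eps-connected", {
  for (s in 1:3) {
    sim <- simulate_recording(strong_coupling_config(s))
    rec <- sim$recording
    act <- detect_activity(suppressWarnings(normalize_traces(rec)))
    ev <- detect_events(act, positions(rec))
    hs <- detect_hotspots(participation_counts(ev, rec$cells$cell_id),
                          positions(rec))
    for (h in hs) {
      idx <- match(h$member_cells, rec$cells$cell_id)
      adj <- cacomm:::eps_adjacency(positions(rec)[idx, , drop = FALSE], 14)
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      expect_equal(igraph::components(g)$no, 1)
    }
  }
})

test_that("planted hotspots are recovered and certified by the bootstrap", {
  sim <- simulate_recording(strong_coupling_config(3))
  rec <- sim$recording
  act <- detect_activity(suppressWarnings(normalize_traces(rec)))
  ev <- detect_events(act, positions(rec))
  hs <- detect_hotspots(participation_counts(ev, rec$cells$cell_id),
                        positions(rec))
  planted <- sim$truth$hotspot_members[[1]]
  j <- vapply(hs, function(h) jaccard(h$member_cells, planted), numeric(1))
  expect_gte(max(j), 0.5)
  v <- validate_hotspot(hs[[which.max(j)]], rec, act,
                        max_tries = 200, seed = 30)
  expect_identical(v$status, "validated")
  expect_lte(v$p_value, 0.05)
  expect_gte(v$n_valid_permutations, 100)
})

test_that("matching is impossible when no cell is as active as the members", {
  # hotspot cells spike, every other cell is silent
  cells <- data.frame(cell_id = paste0("c", 1:10),
                      x = c(0, 10, 20, seq(50, 110, by = 10)), y = 0)
  raw <- matrix(100, 10, 60, dimnames = list(cells$cell_id, NULL))
  for (i in 1:3) raw[i, c(10, 11, 30, 31, 50, 51)] <- 1000
  rec <- recording(cells, raw, 3)
  act <- suppressWarnings(detect_activity(normalize_traces(rec)))
  h <- toy_hotspot(c("c1", "c2", "c3"))
  v <- validate_hotspot(h, rec, act, max_tries = 50, seed = 1)
  expect_identical(v$status, "insufficient_data")
  expect_equal(v$n_valid_permutations, 0)
})

test_that("interaction probability is the mixed-community fraction", {
  h <- toy_hotspot()
  mixed <- lapply(1:7, function(i)
    make_event(list("1" = c("h1", "h2", paste0("n", i %% 3 + 1)))))
  internal <- lapply(1:3, function(i)
    make_event(list("1" = c("h1", "h2", "h3"))))
  ev <- do.call(events_of, c(mixed, internal))
  expect_equal(interaction_probability(h, ev), 0.7)
  expect_equal(interaction_probability(h, do.call(events_of, internal)), 0)
  expect_equal(interaction_probability(h, do.call(events_of, mixed)), 1)
  # no hotspot communities at all: undefined
  expect_warning(
    p <- interaction_probability(h, events_of(
      make_event(list("1" = c("n1", "n2", "n3"))))),
    "undefined")
  expect_true(is.na(p))
})

test_that("initiation fraction excludes ambiguous first frames", {
  h <- toy_hotspot()
  ev <- events_of(
    make_event(list("1" = "h1", "2" = c("h1", "n1", "h2"))),       # hotspot
    make_event(list("1" = c("h1", "h2"), "2" = c("h2", "n2"))),    # hotspot
    make_event(list("1" = "n1", "3" = c("n1", "h3", "n2"))),       # nonhotspot
    make_event(list("1" = c("h1", "n1"), "2" = c("h1", "n1", "h2"))))  # ambiguous
  expect_equal(initiation_fraction(h, ev), 2 / 3)
  all_h <- events_of(make_event(list("1" = c("h1", "h2"), "2" = c("h2", "n1"))))
  expect_equal(initiation_fraction(h, all_h), 1)
  all_n <- events_of(make_event(list("1" = "n1", "2" = c("n1", "h1", "h2"))))
  expect_equal(initiation_fraction(h, all_n), 0)
  only_amb <- events_of(make_event(list("1" = c("h1", "n1"), "2" = "h2")))
  expect_warning(f <- initiation_fraction(h, only_amb), "undefined")
  expect_true(is.na(f))
})

test_that("transmission probability counts hotspot-first adjacent pairs", {
  h <- toy_hotspot(c("h1", "h2"))
  pos <- rbind(h1 = c(0, 0), h2 = c(10, 0), n1 = c(5, 5), n2 = c(10, 5),
               n3 = c(100, 0))
  # qualifying (hotspot, nonhotspot) pairs with distinct first frames:
  # h1->n1 (h first), h2->n1 (h first), n2->h2 (n first);
  # n3 is beyond eps of everyone; h1/n2 at same frame are excluded
  ev <- events_of(make_event(list(
    "1" = c("h1", "n2"), "2" = c("h2", "n3"), "4" = "n1")))
  expect_equal(transmission_probability(h, ev, pos), 2 / 3)
  # all nonhotspot-first
  ev2 <- events_of(make_event(list("1" = "n1", "3" = c("h1", "h2", "n1"))))
  expect_equal(transmission_probability(h, ev2, pos), 0)
  # simultaneous-only pairs: undefined
  ev3 <- events_of(make_event(list("1" = c("h1", "n1", "n2"))))
  expect_warning(tp <- transmission_probability(h, ev3, pos), "undefined")
  expect_true(is.na(tp))
})

test_that("expected initiator probability averages hotspot proportions", {
  h <- toy_hotspot()
  e_mixed <- make_event(list("1" = c("h1", "h2", "h3", "n1")))   # 0.75
  e_pure <- make_event(list("1" = c("h1", "h2", "h3")))          # 1
  expect_equal(expected_initiator_probability(h, events_of(e_mixed)), 0.75)
  expect_equal(expected_initiator_probability(h, events_of(e_pure)), 1)
  expect_equal(expected_initiator_probability(h, events_of(e_mixed, e_pure)),
               0.875)
  prof <- interaction_profile(h, events_of(e_mixed, e_pure),
                              rbind(h1 = c(0, 0), h2 = c(5, 0), h3 = c(10, 0),
                                    n1 = c(5, 5)))
  expect_equal(prof$hotspot_size, 3)
  expect_equal(prof$expected_initiator_prob, 0.875)
})

test_that("transmission is direction-symmetric for exchangeable member sets", {
  # random labels on a homogeneous field: no rate, coupling or density
  # asymmetry, so activation order across the label boundary is symmetric.
  # (A *densely seeded* disc is not symmetric even without multipliers:
  # cascades amplify inside it and exit through many links, biasing mixed
  # events toward internal initiation.)
  fracs <- c()
  for (s in 16:30) {
    sim <- simulate_recording(simulation_config(seed = s, p_t = 0.5,
                                                duration = 600))
    rec <- sim$recording
    act <- detect_activity(suppressWarnings(normalize_traces(rec)))
    ev <- detect_events(act, positions(rec))
    set.seed(s + 300)
    h <- toy_hotspot(sample(rec$cells$cell_id, 10))
    tp <- suppressWarnings(transmission_probability(h, ev, positions(rec)))
    if (!is.na(tp)) fracs <- c(fracs, tp)
  }
  expect_gt(length(fracs), 10)
  expect_gt(mean(fracs), 0.4)
  expect_lt(mean(fracs), 0.6)
})
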