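test_that("boxes map to every lane they overlap", {
  geom <- geometry_config() # lanes 0.23 m, overlap 0.015
  b <- data.frame(x_min = 0.50, x_max = 0.80, y_min = 1, y_max = 1.05)
  lanes <- assign_lanes(b, geom)
  expect_equal(which(vapply(lanes, nrow, 0L) > 0), c(3L, 4L))
  expect_equal(lanes[[3]][1, ], c(y_min = 1, y_max = 1.05))

  # boundary box triggers both adjacent lanes (closed-interval convention)
  geom0 <- geometry_config(nozzle_overlap = 0)
  b2 <- data.frame(x_min = 0.60, x_max = 3 * geom0$lane_width,
                   y_min = 0, y_max = 0.1)
  lanes2 <- assign_lanes(b2, geom0)
  expect_equal(which(vapply(lanes2, nrow, 0L) > 0), c(3L, 4L))

  expect_equal(sum(vapply(assign_lanes(b[0, ], geom), nrow, 0L)), 0L)
  expect_warning(assign_lanes(data.frame(x_min = 5, x_max = 6, y_min = 0,
                                         y_max = 1), geom),
                 "outside the lane range")
})

test_that("expand_and_merge closes sub-d_min gaps and keeps larger ones", {
  r <- response_config(d_min = 0.05)
  m1 <- expand_and_merge(rbind(c(0, 0.05), c(0.09, 0.14)), r) # gap 0.04
  expect_equal(unname(m1), rbind(c(0, 0.14)))
  m2 <- expand_and_merge(rbind(c(0, 0.05), c(0.11, 0.16)), r) # gap 0.06
  expect_equal(unname(m2), rbind(c(0, 0.05), c(0.11, 0.16)))
  # closing is the identity on a single interval
  expect_equal(unname(expand_and_merge(rbind(c(0.2, 0.31)), r)),
               rbind(c(0.2, 0.31)))
  expect_error(expand_and_merge(rbind(c(0, Inf)), r), "finite")
  expect_error(expand_and_merge(rbind(c(1, 0.5)), r), "precedes")
})

test_that("merging matches a fine-grid morphological closing oracle", {
  set.seed(101)
  for (case in 1:120) {
    n <- sample(1:8, 1)
    d_min <- sample(c(0.02, 0.05, 0.11), 1)
    lo <- runif(n, 0, 1)
    m <- cbind(lo, lo + runif(n, 0.01, 0.12))
    r <- response_config(d_min = d_min)
    got <- expand_and_merge(m, r)
    # compare against the grid oracle only away from its 1 mm resolution
    ms <- m[order(m[, 1]), , drop = FALSE]
    gaps <- if (n > 1) ms[-1, 1] - cummax(ms[-n, 2]) else numeric(0)
    if (!any(abs(gaps - d_min) < 2e-3)) {
      want <- closing_oracle(m, d_min)
      expect_equal(nrow(got), nrow(want))
      if (nrow(got) == nrow(want))
        expect_true(all(abs(got - want) < 2e-3))
    }
    # containment: every original interval inside exactly one merged one
    cover <- vapply(seq_len(n), function(i)
      sum(got[, 1] <= m[i, 1] + 1e-12 & got[, 2] >= m[i, 2] - 1e-12), 0L)
    expect_true(all(cover == 1L))
    # outer bounds preserved
    expect_equal(min(got[, 1]), min(m[, 1]))
    expect_equal(max(got[, 2]), max(m[, 2]))
    # remaining gaps at least d_min
    if (nrow(got) > 1)
      expect_true(all(got[-1, 1] - got[-nrow(got), 2] >= d_min - 1e-12))
  }
})

test_that("larger d_min never increases the merged interval count", {
  set.seed(202)
  for (case in 1:40) {
    n <- sample(2:10, 1)
    lo <- runif(n, 0, 2)
    m <- cbind(lo, lo + runif(n, 0.01, 0.1))
    counts <- vapply(c(0, 0.02, 0.05, 0.1, 0.3), function(d)
      nrow(expand_and_merge(m, response_config(d_min = d))), 0L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("grid determination follows band overlap and emits edges", {
  st <- new_lane_grid_state(4)
  grid <- c(1.00, 1.02)
  up <- update_grid(st, rbind(c(0.5, 0.8)), grid, t = 0, v0 = 0.5)
  expect_equal(up$state$determination, 0L)
  expect_equal(nrow(up$events), 0)
  up <- update_grid(up$state, rbind(c(0.9, 1.00)), grid, t = 0.1, v0 = 0.5)
  expect_equal(up$state$determination, 1L) # touching counts as overlap
  expect_equal(up$events$kind, "rising")
  expect_equal(up$events$v0, 0.5)
  up <- update_grid(up$state, rbind(c(1.01, 1.2)), grid, t = 0.2, v0 = 0.4)
  expect_equal(up$state$determination, 1L)
  expect_equal(nrow(up$events), 0) # still in band: no edge
  up <- update_grid(up$state, rbind(c(1.21, 1.4)), grid, t = 0.3, v0 = 0.4)
  expect_equal(up$events$kind, "falling")
  expect_equal(up$state$determination, 0L)
})

test_that("two clusters passing the band give alternating edge pairs", {
  # sweep a band over two merged clusters, checking against a brute-force
  # frame-by-frame overlap predicate
  resp <- response_config(d_min = 0.05)
  ints <- rbind(c(1.0, 1.1), c(1.3, 1.38)) # gap 0.2 >= d_min: two clusters
  merged <- expand_and_merge(ints, resp)
  st <- new_lane_grid_state(1)
  events <- NULL
  for (s in seq(0, 2, by = 0.005)) {
    grid <- c(s, s + 0.02)
    brute <- any(merged[, 1] <= grid[2] & merged[, 2] >= grid[1])
    up <- update_grid(st, merged, grid, t = s, v0 = 0.5)
    st <- up$state
    expect_equal(st$determination, as.integer(brute))
    if (nrow(up$events) > 0) events <- rbind(events, up$events)
  }
  expect_equal(events$kind, c("rising", "falling", "rising", "falling"))
})

test_that("decision_step wires lanes, merging and grid updates together", {
  geom <- geometry_config()
  resp <- response_config(d_min = 0.05)
  states <- lapply(seq_len(geom$n_lanes), new_lane_grid_state)
  boxes <- data.frame(x_min = c(0.10, 1.00), x_max = c(0.20, 1.10),
                      y_min = c(0.99, 2.00), y_max = c(1.05, 2.10))
  out <- decision_step(boxes, states, geom, resp, grid_region = c(1.0, 1.02),
                       t = 0, v0 = 0.5)
  det <- vapply(out$states, function(s) s$determination, 0L)
  expect_equal(which(det == 1L), 1L) # only the first box overlaps the band
  expect_equal(out$events$lane, 1L)
  expect_equal(out$events$kind, "rising")
})
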