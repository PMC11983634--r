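test_that("delay time is the sum of the three hardware delays", {
  expect_equal(delay_time(delay_config(0.03, 0.02, 0.01)), 0.06)
  expect_equal(delay_time(delay_config(0, 0, 0)), 0)
  expect_equal(delay_time(delay_config(0.1, 0.05, 0.15)), 0.30)
})

test_that("activation distance follows the two compensation conventions", {
  expect_equal(activation_distance(1.0, 0.5, 0.2, 0.05), 1.15)
  expect_equal(activation_distance(0.5, 0.5, 0.2, 0, "lead"), 0.40)
  # degenerate: no delay, no margin -> A = L1 in both modes
  expect_equal(activation_distance(0.7, 0.5, 0, 0, "as_printed"), 0.7)
  expect_equal(activation_distance(0.7, 0.5, 0, 0, "lead"), 0.7)
  # lead mode floors at zero
  expect_equal(activation_distance(0.1, 1.0, 0.5, 0, "lead"), 0)
  expect_error(activation_distance(-1, 0.5, 0.1), "positive")
})

test_that("trapezoid distance is exact for constant and linear speeds", {
  s <- data.frame(t = seq(0, 1, 0.1), v = rep(0.5, 11))
  expect_equal(trapezoid_distance(s), 0.5)
  lin <- data.frame(t = seq(0, 1, 0.1), v = seq(0, 1, 0.1))
  expect_equal(trapezoid_distance(lin), 0.5)
})

test_that("trapezoid distance matches closed form and independent oracle", {
  tt <- seq(0, 1, 0.1)
  s <- data.frame(t = tt, v = sin(tt))
  m <- trapezoid_distance(s)
  expect_lt(abs(m - (1 - cos(1))), 1e-3)
  expect_identical(m, trapz_oracle(sin(tt), 0.1))
  set.seed(11)
  for (case in 1:50) {
    v <- runif(sample(2:30, 1), 0, 1)
    expect_equal(trapezoid_distance(v, h = 0.1), trapz_oracle(v, 0.1))
  }
})

test_that("trapezoid distance rejects bad sampling", {
  expect_warning(d <- trapezoid_distance(data.frame(t = 0, v = 0.5)),
                 "fewer than 2")
  expect_equal(d, 0)
  expect_error(trapezoid_distance(data.frame(t = c(0, 0.1, 0.25),
                                             v = c(1, 1, 1))),
               "nonuniform")
})

test_that("spray events queue FIFO per nozzle and start zeroed", {
  ctrl <- new_controller(3)
  ctrl <- push_event(ctrl, 1, "open", 0.3, 0, 0.5)
  ev <- pending_events(ctrl)
  expect_equal(ev$M, 0)
  expect_equal(ev$k, 0L)
  ctrl <- push_event(ctrl, 1, "close", 0.35, 0.2, 0.5)
  ev <- pending_events(ctrl)
  expect_equal(ev$kind, c("open", "close"))
  # creation order preserved under arbitrary interleaving across nozzles
  set.seed(3)
  ctrl <- new_controller(4)
  ledger <- list()
  for (i in 1:40) {
    nz <- sample(1:4, 1)
    kind <- if (i %% 2 == 1) "open" else "close"
    ctrl <- push_event(ctrl, nz, kind, runif(1, 0.1, 0.5), i * 0.01, 0.5)
    ledger[[length(ledger) + 1]] <- c(nz = nz, t = i * 0.01)
  }
  ev <- pending_events(ctrl)
  for (nz in 1:4) {
    want <- vapply(Filter(function(x) x["nz"] == nz, ledger),
                   function(x) x[["t"]], 0)
    expect_equal(ev$created_t[ev$nozzle == nz], want)
  }
})

test_that("events fire when their accumulator reaches the target", {
  # A = 0.05 at constant v = 0.5: fires on the first sample after creation
  ctrl <- new_controller(1)
  ctrl <- push_event(ctrl, 1, "open", 0.05, 0, 0.5)
  res <- on_speed_sample(ctrl, list(t = 0.1, v = 0.5))
  expect_equal(res$commands$action, "open")
  expect_equal(res$commands$t, 0.1)
  # A = 0 fires on the next sample regardless of speed
  ctrl <- push_event(res$ctrl, 1, "close", 0, 0.1, 0)
  res <- on_speed_sample(ctrl, list(t = 0.2, v = 0))
  expect_equal(res$commands$action, "close")
  # nothing pending: no commands
  res <- on_speed_sample(res$ctrl, list(t = 0.3, v = 0.5))
  expect_equal(nrow(res$commands), 0)
})

test_that("constant speed firing takes ceil(A / (v h)) samples", {
  for (A in c(0.04, 0.05, 0.12, 0.5)) for (v in c(0.3, 0.45, 0.6)) {
    ctrl <- new_controller(1, h = 0.1)
    ctrl <- push_event(ctrl, 1, "open", A, 0, v)
    k <- 0
    repeat {
      k <- k + 1
      res <- on_speed_sample(ctrl, list(t = k * 0.1, v = v))
      ctrl <- res$ctrl
      if (nrow(res$commands) > 0) break
      if (k > 100) stop("never fired")
    }
    expect_equal(k, ceiling(A / (v * 0.1)))
    # fired-position overshoot below one sample of travel
    expect_lt(k * v * 0.1 - A, v * 0.1 + 1e-12)
  }
})

test_that("each event's accumulator equals the trapezoid of its own history", {
  set.seed(21)
  h <- 0.1
  ctrl <- new_controller(2, h = h)
  vs <- runif(40, 0.3, 0.6)
  created <- list()
  for (k in seq_along(vs)) {
    if (k %in% c(3, 9, 15)) { # create events at staggered times, large A
      nz <- (k %% 2) + 1
      v0 <- if (k == 3) vs[2] else vs[k - 1]
      ctrl <- push_event(ctrl, nz, "open", 10, (k - 1) * h, v0)
      created[[length(created) + 1]] <- list(k = k, nz = nz, v0 = v0)
    }
    ctrl <- on_speed_sample(ctrl, list(t = k * h, v = vs[k]))$ctrl
    ev <- pending_events(ctrl)
    for (cr in created) {
      hist <- c(cr$v0, vs[cr$k:k]) # its v0 then every sample since creation
      row <- ev[ev$nozzle == cr$nz & ev$created_t == (cr$k - 1) * h, ]
      expect_equal(row$M, trapz_oracle(hist, h))
      expect_equal(row$k, k - cr$k + 1L)
    }
  }
})

test_that("a larger target distance never fires earlier", {
  set.seed(5)
  vs <- runif(60, 0.3, 0.6)
  fire_tick <- function(A) {
    ctrl <- push_event(new_controller(1), 1, "open", A, 0, vs[1])
    for (k in seq_along(vs)) {
      res <- on_speed_sample(ctrl, list(t = k * 0.1, v = vs[k]))
      ctrl <- res$ctrl
      if (nrow(res$commands) > 0) return(k)
    }
    Inf
  }
  ticks <- vapply(c(0.1, 0.3, 0.5, 1.0, 2.0), fire_tick, 0)
  expect_true(all(diff(ticks) >= 0))
})

test_that("sample spacing is policed at one percent", {
  ctrl <- new_controller(1, h = 0.1)
  ctrl <- on_speed_sample(ctrl, list(t = 0, v = 0.5))$ctrl
  expect_error(on_speed_sample(ctrl, list(t = 0.12, v = 0.5)), "spacing")
  expect_no_error(on_speed_sample(ctrl, list(t = 0.1005, v = 0.5)))
})
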