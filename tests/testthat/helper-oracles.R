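# Independent oracles used across the suite. These deliberately share no code
# with the package internals they check.

# Morphological closing of 1-D intervals on a fine grid: dilate each interval
# by d_min/2, rasterise the union, take connected runs, erode run ends by
# d_min/2. Resolution-limited brute force.
closing_oracle <- function(intervals, d_min, step = 0.001) {
  m <- as.matrix(intervals)
  if (nrow(m) == 0) return(matrix(numeric(0), 0, 2))
  r <- d_min / 2
  lo <- min(m[, 1]) - d_min
  hi <- max(m[, 2]) + d_min
  grid <- seq(lo, hi, by = step)
  covered <- rep(FALSE, length(grid))
  for (i in seq_len(nrow(m)))
    covered <- covered | (grid >= m[i, 1] - r - step / 2 &
                            grid <= m[i, 2] + r + step / 2)
  runs <- rle(covered)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  out <- NULL
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    out <- rbind(out, c(grid[starts[k]] + r, grid[ends[k]] - r))
  }
  out
}

# Plain trapezoid quadrature, coded independently of trapezoid_distance().
trapz_oracle <- function(v, h) {
  n <- length(v)
  if (n < 2) return(0)
  sum((v[-1] + v[-n]) / 2) * h
}

derive_trial_seed <- function(i) 20000L + 37L * as.integer(i)

# Common small fixtures
geom_default <- function() geometry_config()
lead_delays <- function() delay_config(t1 = 0.02, t2 = 0.05, t3 = 0.10,
                                       comp_mode = "lead")

constant_cfg <- function(v, seed = 1L, delays = lead_delays(), ...) {
  sim_config(speed_interval = c(v, v), speed_mode = "constant",
             delays = delays, seed = seed, ...)
}

two_weed_scene <- function(gap, lane = 3, width = 0.06, depth = 0.06,
                           y0 = 1.0, belt_length = 3,
                           geom = geometry_config()) {
  xc <- (lane - 0.5) * geom$lane_width
  w1 <- weed_instance(1, c(xc - width / 2, xc + width / 2), c(y0, y0 + depth))
  w2 <- weed_instance(2, c(xc - width / 2, xc + width / 2),
                      c(y0 + depth + gap, y0 + 2 * depth + gap))
  w <- rbind(w1, w2)
  w$group <- 1L; w$group_type <- "vertical_close"
  cfg <- scenario_config("vertical_close", n_weeds = 2,
                         gap_range = c(gap, gap), belt_length = belt_length,
                         belt_width = belt_width(geom), seed = 1L)
  spotspray:::new_belt_scene(w, cfg)
}
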