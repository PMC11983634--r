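#' Nozzle-bar and camera geometry
#'
#' Describes the spray bar and the judgment grid used by the spraying decision.
#' The camera image is divided into `n_lanes` lanes across travel, one per
#' nozzle; each lane is `lane_width` wide (the footprint of one 30-degree fan
#' nozzle at working height). Along travel, a thin judgment band of depth
#' `grid_depth` sits a distance `L1` upstream of the nozzle line; a per-lane
#' determination value flips to 1 while any (merged) prediction box overlaps
#' the band. `L1` is measured from the nozzle line to the band centre, so the
#' band widens the wetted zone symmetrically rather than biasing it.
#'
#' @param n_lanes number of nozzles / lanes.
#' @param lane_width lane width in meters (nozzle spray coverage).
#' @param L1 distance from the judgment band centre to the nozzle line, m.
#' @param grid_depth along-travel depth of the judgment band, m.
#' @param view_len along-travel extent of the camera view, m.
#' @param view_margin how far the view extends downstream past the judgment
#'   band, m. Must exceed the valve's minimum respondable spacing `d_min`:
#'   a cluster's leading box has to stay visible after it passes the band so
#'   that merging can bridge the gap to its follower, otherwise clusters with
#'   gaps between `grid_depth` and `d_min` would be split.
#' @param nozzle_overlap spray overlap per lane side, m; boxes within this
#'   margin of a lane seam trigger the adjacent nozzle too.
#' @return a `geometry_config` list.
#' @examples
#' geom <- geometry_config()
#' belt_width(geom) # 2.3 m
#' @export
geometry_config <- function(n_lanes = 10, lane_width = 0.23, L1 = 0.5,
                            grid_depth = 0.02, view_len = 1.0,
                            view_margin = 0.25, nozzle_overlap = 0.015) {
  stopifnot(n_lanes >= 1, lane_width > 0, L1 > 0, grid_depth > 0,
            view_margin >= 0, nozzle_overlap >= 0)
  if (view_margin + grid_depth > view_len)
    stop("judgment band does not fit inside the camera view: ",
         "view_margin + grid_depth > view_len")
  if (L1 - grid_depth / 2 < 0)
    stop("judgment band extends past the nozzle line: L1 < grid_depth/2")
  g <- list(n_lanes = as.integer(n_lanes), lane_width = lane_width, L1 = L1,
            grid_depth = grid_depth, view_len = view_len,
            view_margin = view_margin, nozzle_overlap = nozzle_overlap,
            # travel-axis position of the band's upstream-facing (lower) edge,
            # relative to the nozzle line
            grid_y = L1 - grid_depth / 2)
  class(g) <- "geometry_config"
  g
}

#' @rdname geometry_config
#' @export
belt_width <- function(geom) geom$n_lanes * geom$lane_width

#' Valve response / minimum target spacing
#'
#' The solenoid valve's cycling frequency bounds how closely spaced two weeds
#' can be and still receive separate spray bursts. Targets with a travel-axis
#' gap below `d_min` are merged into one burst by [expand_and_merge()]. When
#' `d_min` is not given it defaults to `v_nominal / f_valve`, the distance
#' traveled during one valve open/close cycle at nominal speed.
#'
#' @param d_min minimum separately-serviceable gap, m; expansion half-width is
#'   `d_min / 2`.
#' @param v_nominal nominal travel speed used to derive the default, m/s.
#' @param f_valve valve open/close cycling frequency, Hz.
#' @return a `response_config` list.
#' @examples
#' response_config()$d_min # 0.05 m at 0.5 m/s and 10 Hz
#' @export
response_config <- function(d_min = NULL, v_nominal = 0.5, f_valve = 10) {
  if (is.null(d_min)) d_min <- v_nominal / f_valve
  stopifnot(d_min >= 0)
  r <- list(d_min = d_min, v_nominal = v_nominal, f_valve = f_valve)
  class(r) <- "response_config"
  r
}

#' Hardware delay model
#'
#' The lag between a grid determination change and liquid reaching the ground
#' is `t_c = t1 + t2 + t3`: equipment processing, solenoid response and
#' droplet settling. The controller compensates the distance traveled during
#' `t_c` plus a fixed margin `L3`. Two sign conventions for the compensation
#' term are provided: `"as_printed"` schedules the action after
#' `L1 + v0*t_c + L3` of travel; `"lead"` schedules it after
#' `L1 - v0*t_c + L3`, so that after the real delays elapse the liquid state
#' changes when the target is at the nozzle. Defaults are an idealised rig
#' (all delays zero), under which the two modes coincide; set the delays from
#' your hardware's measurements.
#'
#' @param t1 equipment processing time, s.
#' @param t2 solenoid valve response time, s.
#' @param t3 droplet settling time, s.
#' @param L3 compensation margin, m (shifts the whole spray window downstream).
#' @param comp_mode `"as_printed"` or `"lead"`; see Details.
#' @return a `delay_config` list.
#' @export
delay_config <- function(t1 = 0, t2 = 0, t3 = 0, L3 = 0,
                         comp_mode = c("as_printed", "lead")) {
  comp_mode <- match.arg(comp_mode)
  stopifnot(t1 >= 0, t2 >= 0, t3 >= 0)
  d <- list(t1 = t1, t2 = t2, t3 = t3, L3 = L3, comp_mode = comp_mode)
  class(d) <- "delay_config"
  d
}

#' Total delay time t_c
#'
#' @param cfg a [delay_config()].
#' @return `t1 + t2 + t3`, seconds.
#' @examples
#' delay_time(delay_config(0.03, 0.02, 0.01)) # 0.06
#' @export
delay_time <- function(cfg) {
  stopifnot(inherits(cfg, "delay_config"))
  cfg$t1 + cfg$t2 + cfg$t3
}

#' Closed-loop bench simulation configuration
#'
#' @param speed_interval `c(v_lo, v_hi)` m/s; the belt speed varies randomly
#'   within this interval (bounded random walk) or is held constant.
#' @param frame_rate camera frame rate, Hz. Must be an integer multiple of
#'   `speed_feedback_rate` (the event loop runs on the frame clock).
#' @param speed_feedback_rate speed feedback rate, Hz (10 Hz GNSS/odometer).
#' @param geometry a [geometry_config()].
#' @param response a [response_config()].
#' @param delays a [delay_config()].
#' @param footprint_len spray footprint along travel, m.
#' @param n_weeds weeds per trial.
#' @param seed integer seed for the trial's randomness.
#' @param speed_mode `"walk"` (bounded random walk, one step per feedback
#'   tick) or `"constant"` (one value drawn from the interval and held).
#' @param walk_step maximum speed change per feedback tick, m/s.
#' @param speed_noise_sd sd of Gaussian noise added to the speed samples the
#'   controller sees (the true belt motion is unaffected); 0 disables.
#' @return a `sim_config` list.
#' @export
sim_config <- function(speed_interval = c(0.3, 0.4), frame_rate = 60,
                       speed_feedback_rate = 10,
                       geometry = geometry_config(),
                       response = response_config(),
                       delays = delay_config(),
                       footprint_len = 0.02, n_weeds = 20, seed = 1L,
                       speed_mode = c("walk", "constant"),
                       walk_step = 0.01, speed_noise_sd = 0) {
  speed_mode <- match.arg(speed_mode)
  stopifnot(length(speed_interval) == 2, speed_interval[1] > 0,
            speed_interval[1] <= speed_interval[2],
            frame_rate > 0, speed_feedback_rate > 0,
            inherits(geometry, "geometry_config"),
            inherits(response, "response_config"),
            inherits(delays, "delay_config"),
            footprint_len >= 0, n_weeds >= 0)
  if (frame_rate %% speed_feedback_rate != 0)
    stop("frame_rate must be an integer multiple of speed_feedback_rate")
  cfg <- list(speed_interval = speed_interval, frame_rate = frame_rate,
              speed_feedback_rate = speed_feedback_rate, geometry = geometry,
              response = response, delays = delays,
              footprint_len = footprint_len, n_weeds = as.integer(n_weeds),
              seed = as.integer(seed), speed_mode = speed_mode,
              walk_step = walk_step, speed_noise_sd = speed_noise_sd)
  class(cfg) <- "sim_config"
  cfg
}

#' Read / write a simulation configuration as YAML
#'
#' The YAML mirrors [sim_config()] field names; nested geometry, response and
#' delay blocks mirror their constructors' argument names.
#'
#' @param path file path.
#' @param cfg a `sim_config`.
#' @return `read_sim_config()` returns a `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(block, ctor) {
    if (is.null(block)) return(ctor())
    do.call(ctor, block)
  }
  args <- y[setdiff(names(y), c("geometry", "response", "delays"))]
  args$geometry <- take(y$geometry, geometry_config)
  args$response <- take(y$response, response_config)
  args$delays <- take(y$delays, delay_config)
  if (!is.null(args$speed_interval)) args$speed_interval <- unlist(args$speed_interval)
  do.call(sim_config, args)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  y <- unclass(cfg)
  y$geometry <- unclass(cfg$geometry)[c("n_lanes", "lane_width", "L1",
                                        "grid_depth", "view_len",
                                        "nozzle_overlap")]
  y$response <- unclass(cfg$response)["d_min"]
  y$delays <- unclass(cfg$delays)
  yaml::write_yaml(y, path)
  invisible(path)
}

# Run code under a local, restorable RNG state so library calls never disturb
# the caller's stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  force(code)
}

# Splittable per-trial seed derived from a master seed; stays below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) + as.double(i) * 1299709) %% 2147483629)
}
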