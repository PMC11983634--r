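#' Random belt speed profile
#'
#' Emulates a belt moving at randomly varying speed within a set interval:
#' a bounded random walk that changes by at most `walk_step` at each feedback
#' tick and is clipped to `speed_interval`; or a single constant value drawn
#' from the interval (`speed_mode = "constant"`). The true speed is piecewise
#' constant between feedback ticks, so the trial's "truth" is exactly
#' integrable while the controller only ever sees the discrete samples.
#'
#' @param cfg a [sim_config()].
#' @param duration profile length, s.
#' @param seed integer seed; defaults to `cfg$seed`.
#' @return a `speed_profile`: list with `t` (tick times), `v` (speed on
#'   `[t_k, t_{k+1})`), and `h` (tick spacing, s).
#' @export
make_speed_profile <- function(cfg, duration, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"), duration > 0)
  h <- 1 / cfg$speed_feedback_rate
  n <- ceiling(duration / h) + 1L
  lo <- cfg$speed_interval[1]; hi <- cfg$speed_interval[2]
  v <- with_seed(seed, {
    if (cfg$speed_mode == "constant" || lo == hi) {
      rep(stats::runif(1, lo, hi), n)
    } else {
      steps <- stats::runif(n - 1, -cfg$walk_step, cfg$walk_step)
      v <- numeric(n)
      v[1] <- stats::runif(1, lo, hi)
      for (k in seq_len(n - 1)) v[k + 1] <- min(max(v[k] + steps[k], lo), hi)
      v
    }
  })
  p <- list(t = (seq_len(n) - 1) * h, v = v, h = h)
  class(p) <- "speed_profile"
  p
}

#' Evaluate a speed profile
#'
#' `profile_speed_at()` returns the true (piecewise-constant) speed;
#' `profile_distance_at()` returns the exactly integrated distance traveled
#' since `t = 0`.
#'
#' @param profile a [make_speed_profile()] value.
#' @param t times, s (vectorised); clamped to the profile's range.
#' @return numeric vector.
#' @export
profile_speed_at <- function(profile, t) {
  k <- pmin(pmax(floor(t / profile$h + 1e-9), 0), length(profile$v) - 1)
  profile$v[k + 1]
}

#' @rdname profile_speed_at
#' @export
profile_distance_at <- function(profile, t) {
  cum <- c(0, cumsum(profile$v * profile$h))
  t <- pmin(pmax(t, 0), profile$t[length(profile$t)])
  k <- pmin(pmax(floor(t / profile$h + 1e-9), 0), length(profile$v) - 1)
  cum[k + 1] + profile$v[k + 1] * (t - k * profile$h)
}

#' Write a speed trace as CSV (`t, v`)
#'
#' @param profile a `speed_profile`.
#' @param path file path.
#' @export
write_speed_csv <- function(profile, path) {
  utils::write.csv(data.frame(t = profile$t, v = profile$v), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
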