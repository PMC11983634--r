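#' Run one closed-loop bench trial
#'
#' Emulates the test bed end to end: the belt advances by exact integration of
#' the (piecewise-constant) true speed profile; at each camera frame the
#' detector produces boxes, the decision algorithm updates the per-lane grid
#' determinations, and each edge schedules a valve event with its activation
#' distance; at each 10 Hz feedback tick every pending event's accumulator
#' advances by the composite-trapezoid increment and events whose accumulator
#' has reached their target fire. A fired command takes physical effect
#' `t1 + t2 + t3` later (processing, valve, droplet settling); the ground
#' interval wetted by an open/close pair is
#' `[nozzle position at liquid-on - footprint_len/2,
#'    nozzle position at liquid-off + footprint_len/2]` in belt coordinates.
#'
#' Detector noise: misses are drawn once per weed (a detector that fails on a
#' plant tends to fail on it in every frame), box-edge jitter is drawn per
#' frame. The controller sees the (optionally noisy) discrete speed samples
#' only; the belt's true motion is unaffected.
#'
#' @param scene a `belt_scene`.
#' @param cfg a [sim_config()]; `cfg$seed` drives all of the trial's
#'   randomness (speed profile, misses, jitter).
#' @param detector a function `(scene, t, view_window)` returning a
#'   `frame_detections`; default [oracle_detect()].
#' @param noise a [noise_params()] or `NULL` for a noise-free detector.
#' @return a `sim_log`: list with `scene`, `profile`, `detected` (per-weed
#'   logical), `edges`, `commands` (fire times), `effects` (liquid on/off
#'   times), `deposition` (wetted intervals per nozzle), `weed_results` (one
#'   row per weed: detected, sprayed, discoloration, targeting error,
#'   coverage), and bookkeeping fields.
#' @export
run_trial <- function(scene, cfg, detector = oracle_detect, noise = NULL) {
  stopifnot(inherits(scene, "belt_scene"), inherits(cfg, "sim_config"))
  geom <- cfg$geometry; resp <- cfg$response; delays <- cfg$delays
  if (abs(scene$config$belt_width - belt_width(geom)) > 1e-9)
    stop("scene belt_width does not match the geometry")
  t_c <- delay_time(delays)
  v_hi <- cfg$speed_interval[2]
  if (delays$comp_mode == "lead" && geom$L1 + delays$L3 - v_hi * t_c <= 0)
    stop("inconsistent config: L1 + L3 (", geom$L1 + delays$L3,
         " m) does not cover the distance traveled during t_c at v_hi (",
         v_hi * t_c, " m) in lead mode")

  vl <- geom$view_len
  vm <- geom$view_margin
  if (vm < resp$d_min)
    stop("inconsistent config: view_margin (", vm, " m) must be at least ",
         "d_min (", resp$d_min, " m) so merging can bridge cluster gaps ",
         "after the leading box passes the band")
  # nozzle pos = s - view_origin; band lower edge sits geom$grid_y upstream
  # of the nozzle and view_margin above the view's downstream edge
  view_origin <- vl - vm + geom$grid_y
  bl <- scene$config$belt_length
  s_end <- bl + view_origin + delays$L3 + 0.3
  duration <- s_end / cfg$speed_interval[1] + t_c + 5
  profile <- make_speed_profile(cfg, duration, seed = derive_seed(cfg$seed, 101))

  h <- 1 / cfg$speed_feedback_rate
  fpf <- as.integer(cfg$frame_rate / cfg$speed_feedback_rate)
  dt <- 1 / cfg$frame_rate
  n_frames_max <- length(profile$v) * fpf

  w <- scene$weeds
  n_weeds <- nrow(w)
  oracle_fast <- identical(detector, oracle_detect)

  with_seed(cfg$seed, {
    # controller's view of the speed samples
    vs <- profile$v
    if (cfg$speed_noise_sd > 0)
      vs <- pmax(vs + stats::rnorm(length(vs), 0, cfg$speed_noise_sd), 0)
    missed <- if (!is.null(noise) && noise$miss_prob > 0)
      stats::runif(n_weeds) < noise$miss_prob else rep(FALSE, n_weeds)
    jitter_par <- if (!is.null(noise) &&
                      (noise$jitter_sd > 0 || !is.null(noise$confidence_range)))
      noise_params(0, noise$jitter_sd, noise$confidence_range) else NULL

    states_det <- integer(geom$n_lanes)
    ctrl <- new_controller(geom$n_lanes, h)
    detected <- rep(FALSE, n_weeds)
    edges <- list(); cmds <- list()
    lane_lo <- (seq_len(geom$n_lanes) - 1) * geom$lane_width -
      geom$nozzle_overlap
    lane_hi <- seq_len(geom$n_lanes) * geom$lane_width + geom$nozzle_overlap
    d_min <- resp$d_min
    i <- 0L
    repeat {
      t <- i * dt
      if (i >= n_frames_max) break
      s <- profile_distance_at(profile, t)
      k_sample <- i %/% fpf
      # feedback tick first: events created this frame integrate from t on
      if (i %% fpf == 0L) {
        res <- on_speed_sample(ctrl, list(t = t, v = vs[k_sample + 1]))
        ctrl <- res$ctrl
        if (nrow(res$commands) > 0) cmds[[length(cmds) + 1]] <- res$commands
      }
      view <- c(s - vl, s)
      grid_region <- c(s - vl + vm, s - vl + vm + geom$grid_depth)
      in_view <- w$y_min <= view[2] & w$y_max >= view[1]
      if (any(in_view) || any(states_det == 1L)) {
        if (oracle_fast && is.null(jitter_par)) {
          keep <- in_view & !missed
          boxes <- list(x_min = w$x_min[keep], x_max = w$x_max[keep],
                        y_min = pmax(w$y_min[keep], view[1]),
                        y_max = pmin(w$y_max[keep], view[2]),
                        weed_id = w$id[keep])
        } else {
          boxes <- if (oracle_fast) {
            keep <- in_view & !missed
            data.frame(x_min = w$x_min[keep], x_max = w$x_max[keep],
                       y_min = pmax(w$y_min[keep], view[1]),
                       y_max = pmin(w$y_max[keep], view[2]),
                       conf = rep(1, sum(keep)), weed_id = w$id[keep])
          } else {
            fd <- detector(scene, t, view)
            b <- fd$boxes
            if (any(missed) && !is.null(b$weed_id))
              b <- b[!(b$weed_id %in% w$id[missed]), , drop = FALSE]
            b
          }
          if (!is.null(jitter_par) && nrow(boxes) > 0)
            boxes <- perturb_boxes_(boxes, jitter_par, view)
        }
        if (length(boxes$x_min) > 0 && !is.null(boxes$weed_id))
          detected[boxes$weed_id[!is.na(boxes$weed_id)]] <- TRUE
        v0 <- vs[k_sample + 1]
        for (ln in seq_len(geom$n_lanes)) {
          hit <- boxes$x_min <= lane_hi[ln] & boxes$x_max >= lane_lo[ln]
          det <- 0L
          if (any(hit)) {
            ys <- boxes$y_min[hit]; ye <- boxes$y_max[hit]
            o <- order(ys); ys <- ys[o]; ye <- ye[o]
            # sweep-merge with gap <= d_min, testing band overlap on the fly
            lo_c <- ys[1]; hi_c <- ye[1]
            for (b in seq_along(ys)[-1]) {
              if (ys[b] <= hi_c + d_min) hi_c <- max(hi_c, ye[b])
              else {
                if (lo_c <= grid_region[2] && hi_c >= grid_region[1]) det <- 1L
                lo_c <- ys[b]; hi_c <- ye[b]
              }
            }
            if (lo_c <= grid_region[2] && hi_c >= grid_region[1]) det <- 1L
          }
          if (det != states_det[ln]) {
            kind <- if (det == 1L) "rising" else "falling"
            edges[[length(edges) + 1]] <-
              list(lane = ln, kind = kind, t = t, v0 = v0)
            A <- activation_distance(geom$L1, v0, t_c, delays$L3,
                                     delays$comp_mode)
            ctrl <- push_event(ctrl, ln,
                               if (kind == "rising") "open" else "close",
                               A, t, v0)
            states_det[ln] <- det
          }
        }
      }
      if (s > s_end && all(lengths(ctrl$queues) == 0L) &&
          all(states_det == 0L)) break
      i <- i + 1L
    }
    t_last <- i * dt

    edges_df <- if (length(edges))
      data.frame(lane = vapply(edges, `[[`, 0L, "lane"),
                 kind = vapply(edges, `[[`, "", "kind"),
                 t = vapply(edges, `[[`, 0, "t"),
                 v0 = vapply(edges, `[[`, 0, "v0"),
                 stringsAsFactors = FALSE)
    else data.frame(lane = integer(0), kind = character(0), t = numeric(0),
                    v0 = numeric(0), stringsAsFactors = FALSE)
    cmds_df <- if (length(cmds)) do.call(rbind, cmds) else no_commands()

    # physical effects: command -> liquid state change t1+t2+t3 later
    effects <- cmds_df
    effects$t_effect <- effects$t + t_c
    deposition <- vector("list", geom$n_lanes)
    forced <- 0L
    for (ln in seq_len(geom$n_lanes)) {
      e <- effects[effects$nozzle == ln, , drop = FALSE]
      ints <- NULL
      if (nrow(e) > 0) {
        e <- e[order(e$t_effect), , drop = FALSE]
        j <- 1
        while (j <= nrow(e)) {
          if (e$action[j] != "open") stop("close command without prior open")
          t_on <- e$t_effect[j]
          if (j + 1 <= nrow(e) && e$action[j + 1] == "close") {
            t_off <- e$t_effect[j + 1]; j <- j + 2
          } else { # unmatched open at trial end: force close
            t_off <- t_last + t_c; j <- j + 1; forced <- forced + 1L
          }
          on_pos <- profile_distance_at(profile, t_on) - view_origin -
            cfg$footprint_len / 2
          off_pos <- profile_distance_at(profile, t_off) - view_origin +
            cfg$footprint_len / 2
          ints <- rbind(ints, c(on_pos, off_pos))
        }
        # liquid-state intervals are disjoint by construction except when a
        # close and the next open coincide; union those
        if (nrow(ints) > 1) {
          merged <- ints[1, , drop = FALSE]
          for (r in 2:nrow(ints)) {
            last <- nrow(merged)
            if (ints[r, 1] <= merged[last, 2])
              merged[last, 2] <- max(merged[last, 2], ints[r, 2])
            else merged <- rbind(merged, ints[r, , drop = FALSE])
          }
          ints <- merged
        }
        ints[, 1] <- pmax(ints[, 1], 0)
        ints[, 2] <- pmin(ints[, 2], bl)
        ints <- ints[ints[, 2] > ints[, 1], , drop = FALSE]
      }
      deposition[[ln]] <- if (is.null(ints))
        matrix(numeric(0), 0, 2, dimnames = list(NULL, c("on", "off")))
      else {dimnames(ints) <- list(NULL, c("on", "off")); ints}
    }
    if (forced > 0)
      warning(forced, " open command(s) had no matching close; ",
              "closed at trial end")

    weed_results <- score_deposition(scene, deposition, geom)
    weed_results$detected <- detected
    weed_results$missed_by_detector <- missed
    burst_results <- score_bursts(scene, deposition, geom, resp)

    log <- list(scene = scene, profile = profile, detected = detected,
                edges = edges_df, commands = cmds_df, effects = effects,
                deposition = deposition, weed_results = weed_results,
                burst_results = burst_results,
                config = cfg, t_end = t_last, n_frames = i)
    class(log) <- "sim_log"
    log
  })
}

#' @export
print.sim_log <- function(x, ...) {
  cat("<sim_log> ", nrow(x$scene$weeds), " weeds, ",
      sum(x$weed_results$sprayed), " sprayed, ",
      nrow(x$commands), " valve commands over ",
      round(x$t_end, 1), " s\n", sep = "")
  invisible(x)
}

#' Score spray deposition against the scene (virtual water-sensitive paper)
#'
#' Each lane carries a virtual indicator strip; the wetted intervals are its
#' discoloration. A weed counts as sprayed iff some wetted interval in a lane
#' its footprint overlaps intersects its travel span (closed intervals:
#' touching counts). Per weed, the discoloration readout is taken from the
#' lane containing its centre: the wetted intervals within `neighborhood` of
#' the weed centre, summarised by their overall span midpoint (targeting
#' error reference) and total wetted length (coverage denominator).
#'
#' @param scene a `belt_scene`.
#' @param deposition list (per nozzle) of 2-column wetted-interval matrices.
#' @param geom the [geometry_config()] used in the trial.
#' @param neighborhood half-width, m, of the readout window around each weed.
#' @return data frame, one row per weed: `id, sprayed, disc_len, disc_lo,
#'   disc_hi, disc_center, error, coverage_as_printed, coverage_overlap`.
#' @export
score_deposition <- function(scene, deposition, geom = geometry_config(),
                             neighborhood = 0.15) {
  w <- scene$weeds
  lane_lo <- (seq_len(geom$n_lanes) - 1) * geom$lane_width -
    geom$nozzle_overlap
  lane_hi <- seq_len(geom$n_lanes) * geom$lane_width + geom$nozzle_overlap
  out <- lapply(seq_len(nrow(w)), function(r) {
    span <- c(w$y_min[r], w$y_max[r])
    wl <- diff(span)
    xc <- (w$x_min[r] + w$x_max[r]) / 2
    yc <- mean(span)
    lanes <- which(w$x_min[r] <= lane_hi & w$x_max[r] >= lane_lo)
    sprayed <- any(vapply(lanes, function(ln) {
      d <- deposition[[ln]]
      nrow(d) > 0 && any(d[, 1] <= span[2] & d[, 2] >= span[1])
    }, TRUE))
    primary <- min(max(floor(xc / geom$lane_width) + 1, 1), geom$n_lanes)
    d <- deposition[[primary]]
    nb <- d[d[, 1] <= yc + neighborhood & d[, 2] >= yc - neighborhood, ,
            drop = FALSE]
    if (nrow(nb) == 0) {
      data.frame(id = w$id[r], sprayed = sprayed, disc_len = 0,
                 disc_lo = NA_real_, disc_hi = NA_real_,
                 disc_center = NA_real_, error = NA_real_,
                 coverage_as_printed = 0, coverage_overlap = 0)
    } else {
      disc_lo <- min(nb[, 1]); disc_hi <- max(nb[, 2])
      dlen <- sum(nb[, 2] - nb[, 1])
      center <- (disc_lo + disc_hi) / 2
      olap <- sum(pmax(0, pmin(nb[, 2], span[2]) - pmax(nb[, 1], span[1])))
      data.frame(id = w$id[r], sprayed = sprayed, disc_len = dlen,
                 disc_lo = disc_lo, disc_hi = disc_hi, disc_center = center,
                 error = center - yc,
                 coverage_as_printed = min(wl / dlen, 1),
                 coverage_overlap = olap / wl)
    }
  })
  do.call(rbind, out)
}

#' Ground-truth spray targets of a scene
#'
#' The spray bursts an ideal controller should produce: per lane, the weed
#' travel spans assigned to that lane, merged by the same minimum-spacing rule
#' the decision algorithm applies ([expand_and_merge()]). Each target is the
#' unit the hysteresis controller actually aims a burst at; per-target
#' centring error is the controller's controllable quantity (per-weed error
#' inside a merged cluster is offset by the cluster geometry, not by control).
#'
#' @param scene a `belt_scene`.
#' @param geom a [geometry_config()].
#' @param resp a [response_config()].
#' @return data frame: `lane, y_min, y_max, n_weeds`.
#' @export
spray_targets <- function(scene, geom = geometry_config(),
                          resp = response_config()) {
  lanes <- assign_lanes(scene$weeds, geom)
  out <- lapply(seq_along(lanes), function(ln) {
    if (nrow(lanes[[ln]]) == 0) return(NULL)
    m <- expand_and_merge(lanes[[ln]], resp)
    counts <- vapply(seq_len(nrow(m)), function(r)
      sum(lanes[[ln]][, 1] <= m[r, 2] & lanes[[ln]][, 2] >= m[r, 1]), 0L)
    data.frame(lane = ln, y_min = m[, 1], y_max = m[, 2], n_weeds = counts)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(lane = integer(0), y_min = numeric(0),
                      y_max = numeric(0), n_weeds = integer(0))
  out
}

#' @rdname spray_targets
#' @param deposition per-nozzle wetted intervals (see [run_trial()]).
#' @return `score_bursts()`: one row per contiguous wetted strip:
#'   `lane, disc_lo, disc_hi, n_weeds, span_lo, span_hi, error`. `span_lo` /
#'   `span_hi` bound the travel extents of the weeds the strip services and
#'   `error` is the strip centre minus that span's centre — the centring
#'   error the hysteresis controller actually governs. Adjacent bursts whose
#'   on/off quantisation fuses them into one strip are scored as the single
#'   strip they physically are; the strip's edge extensions (half judgment
#'   band plus half footprint on each side) are symmetric and cancel in the
#'   centre, so for an ideal detector at constant speed `|error|` is bounded
#'   by the speed-sampling resolution `v * h` plus half a footprint.
#' @export
score_bursts <- function(scene, deposition, geom = geometry_config(),
                         resp = response_config()) {
  lanes <- assign_lanes(scene$weeds, geom)
  rows <- lapply(seq_along(deposition), function(ln) {
    d <- deposition[[ln]]
    if (nrow(d) == 0) return(NULL)
    spans <- lanes[[ln]]
    out <- lapply(seq_len(nrow(d)), function(r) {
      hit <- spans[, 1] <= d[r, 2] & spans[, 2] >= d[r, 1]
      if (!any(hit))
        return(data.frame(lane = ln, disc_lo = d[r, 1], disc_hi = d[r, 2],
                          n_weeds = 0L, span_lo = NA_real_,
                          span_hi = NA_real_, error = NA_real_))
      lo <- min(spans[hit, 1]); hi <- max(spans[hit, 2])
      data.frame(lane = ln, disc_lo = d[r, 1], disc_hi = d[r, 2],
                 n_weeds = sum(hit), span_lo = lo, span_hi = hi,
                 error = (d[r, 1] + d[r, 2]) / 2 - (lo + hi) / 2)
    })
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(lane = integer(0), disc_lo = numeric(0),
                      disc_hi = numeric(0), n_weeds = integer(0),
                      span_lo = numeric(0), span_hi = numeric(0),
                      error = numeric(0))
  out
}

#' Run a bench campaign over speed intervals
#'
#' For each speed interval, runs `n_trials` trials of `n_weeds` freshly
#' generated mixed-scenario weeds and pools the counts, mirroring the bench
#' protocol (50 trials x 20 weeds per speed setting). Rates are computed from
#' pooled counts: recognition = detected/total, spraying = wetted-detected/
#' detected, hit = recognition x spraying; coverage, MAE and RMSE are computed
#' over weeds with a discoloration readout.
#'
#' @param speed_intervals list of `c(v_lo, v_hi)` m/s.
#' @param n_trials trials per interval.
#' @param n_weeds weeds per trial.
#' @param cfg a [sim_config()] template (its speed interval and seed are
#'   overridden per trial).
#' @param noise a [noise_params()] or `NULL`.
#' @param seed master seed.
#' @return list with `summary` (one row per interval: rates in percent to one
#'   decimal, errors in cm) and `pooled` (raw counts and unrounded values).
#' @export
run_bench <- function(speed_intervals = list(c(0.3, 0.4), c(0.4, 0.5),
                                             c(0.5, 0.6)),
                      n_trials = 50, n_weeds = 20,
                      cfg = sim_config(), noise = NULL, seed = 1L) {
  pooled <- lapply(seq_along(speed_intervals), function(si) {
    iv <- speed_intervals[[si]]
    scenes <- bench_trial_scenes(n_trials, n_weeds,
                                 seed = derive_seed(seed, si * 1000),
                                 geom = cfg$geometry)
    res <- lapply(seq_len(n_trials), function(tr) {
      cfg_t <- cfg
      cfg_t$speed_interval <- iv
      cfg_t$seed <- derive_seed(seed, si * 1000 + tr)
      run_trial(scenes[[tr]], cfg_t, noise = noise)$weed_results
    })
    res <- do.call(rbind, res)
    n_total <- nrow(res)
    n_det <- sum(res$detected)
    n_wet_det <- sum(res$detected & res$sprayed)
    errs <- res$error[!is.na(res$error)]
    te <- if (length(errs)) targeting_errors(errs)
          else list(mae = NA_real_, rmse = NA_real_)
    list(interval = iv, n_total = n_total, n_detected = n_det,
         n_wetted_detected = n_wet_det,
         recognition = recognition_rate(n_det, n_total),
         spraying = spraying_rate(n_wet_det, n_det),
         coverage = mean(res$coverage_as_printed[res$sprayed]),
         mae = te$mae, rmse = te$rmse,
         results = res)
  })
  summary <- do.call(rbind, lapply(pooled, function(p) data.frame(
    speed_range = sprintf("%.1f~%.1f", p$interval[1], p$interval[2]),
    recognition_pct = round(100 * p$recognition, 1),
    spraying_pct = round(100 * p$spraying, 1),
    hit_pct = round(100 * hit_rate(p$recognition, p$spraying), 1),
    coverage_pct = round(100 * p$coverage, 1),
    mae_cm = round(100 * p$mae, 1),
    rmse_cm = round(100 * p$rmse, 1),
    stringsAsFactors = FALSE)))
  list(summary = summary, pooled = pooled)
}
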