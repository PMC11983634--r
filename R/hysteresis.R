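#' Valve activation distance for an edge event
#'
#' When a lane's determination value changes, the controller schedules the
#' corresponding valve action for a travel distance `A` ahead: the judgment
#' band sits `L1` upstream of the nozzle, the hardware lags by `t_c` during
#' which the sprayer travels `L2 = v0 * t_c`, and a fixed margin `L3` is
#' added. Two sign conventions are provided: `"as_printed"` gives
#' `A = L1 + v0 * t_c + L3`; `"lead"` gives `A = L1 - v0 * t_c + L3` (floored
#' at 0), which issues the command early so the physical delays land the
#' liquid-state change exactly at `L1 + L3`. A command issued *later* than the
#' target cannot cancel a downstream delay, so closed-loop use wants `"lead"`;
#' both are kept and flagged rather than silently corrected.
#'
#' @param L1 judgment-band-to-nozzle distance, m (> 0).
#' @param v0 speed feedback at edge time, m/s.
#' @param t_c total delay time, s (see [delay_time()]).
#' @param L3 compensation margin, m.
#' @param comp_mode `"as_printed"` or `"lead"`.
#' @return target distance `A`, meters.
#' @examples
#' activation_distance(1.0, 0.5, 0.2, 0.05) # 1.15
#' activation_distance(0.5, 0.5, 0.2, 0, comp_mode = "lead") # 0.40
#' @export
activation_distance <- function(L1, v0, t_c, L3 = 0,
                                comp_mode = c("as_printed", "lead")) {
  comp_mode <- match.arg(comp_mode)
  if (!is.finite(L1) || L1 <= 0) stop("L1 must be positive")
  stopifnot(v0 >= 0, t_c >= 0)
  if (comp_mode == "as_printed") L1 + v0 * t_c + L3
  else max(0, L1 - v0 * t_c + L3)
}

#' Distance from discrete speed samples by the composite trapezoidal rule
#'
#' Speed feedback arrives as discrete samples at uniform spacing `h` (10 Hz
#' by default, so `h = 0.1` s); distance traveled is estimated as
#' `(h/2) * (v(0) + v(t_n) + 2 * sum(v(t_k), k = 1..n-1))`. The composite
#' Simpson rule would need an even number of sub-intervals, which a running
#' controller cannot guarantee; the trapezoidal rule applies to any count.
#'
#' @param samples data frame with columns `t` (s) and `v` (m/s), uniformly
#'   spaced; or a numeric vector of speeds (then `h` is used directly).
#' @param h nominal sample spacing, s. Spacing is checked against `h` with a
#'   1 percent tolerance when `samples` carries timestamps.
#' @return distance, meters. Fewer than 2 samples returns 0 with a warning.
#' @examples
#' trapezoid_distance(data.frame(t = seq(0, 1, 0.1), v = rep(0.5, 11))) # 0.5
#' @export
trapezoid_distance <- function(samples, h = 0.1) {
  if (is.numeric(samples)) {
    v <- samples
  } else {
    stopifnot(all(c("t", "v") %in% names(samples)))
    v <- samples$v
    if (length(v) >= 2) {
      dt <- diff(samples$t)
      if (any(abs(dt - h) > 0.01 * h))
        stop("nonuniform sample spacing: expected h = ", h)
    }
  }
  n <- length(v)
  if (n < 2) {
    warning("fewer than 2 speed samples; distance is 0")
    return(0)
  }
  if (any(v < 0)) stop("speeds must be nonnegative")
  (h / 2) * (v[1] + v[n] + 2 * sum(v[-c(1, n)]))
}

#' Per-nozzle FIFO queues of pending spray events
#'
#' The bookkeeping array of the hysteresis algorithm: each determination edge
#' appends a pending open or close action holding its own target distance `A`,
#' a private distance accumulator `M` (starting at 0) and a sample counter
#' `k`. The printed subscript shifting (`a = a + 1`, `m = m + 1`) is realised
#' as queue rotation, which also stays correct when more than two events are
#' pending on one nozzle (fast belt, slow valve).
#'
#' @param n_nozzles number of nozzles.
#' @param h speed-sample spacing, s.
#' @return a `spray_controller` list with one empty FIFO per nozzle.
#' @export
new_controller <- function(n_nozzles, h = 0.1) {
  ctrl <- list(queues = rep(list(list()), n_nozzles), h = h,
               last_sample_t = NA_real_)
  class(ctrl) <- "spray_controller"
  ctrl
}

#' Append a pending spray event
#'
#' Each new event starts with a zeroed accumulator and sample counter and
#' integrates its own speed history from its creation onward.
#'
#' @param ctrl a [new_controller()] value.
#' @param nozzle nozzle index.
#' @param kind `"open"` or `"close"`.
#' @param A target distance from [activation_distance()], m.
#' @param created_t creation (edge) time, s.
#' @param v0 speed feedback at the edge, m/s.
#' @return the updated controller.
#' @export
push_event <- function(ctrl, nozzle, kind, A, created_t, v0) {
  stopifnot(inherits(ctrl, "spray_controller"),
            kind %in% c("open", "close"), A >= 0, v0 >= 0)
  q <- ctrl$queues[[nozzle]]
  q[[length(q) + 1]] <- list(nozzle = as.integer(nozzle), kind = kind,
                             A = A, M = 0, k = 0L, created_t = created_t,
                             v0 = v0, v_prev = v0)
  ctrl$queues[[nozzle]] <- q
  ctrl
}

no_commands <- function()
  data.frame(nozzle = integer(0), action = character(0), t = numeric(0),
             stringsAsFactors = FALSE)

#' Advance all pending events by one speed sample
#'
#' Every pending event's accumulator advances by the trapezoid increment
#' `(h/2) * (v_prev + v_now)` over its own history (its first increment pairs
#' the sample with the event's `v0`). An event fires when `M >= A` first
#' holds, emitting its valve command and leaving the queue; firing is
#' head-first per nozzle, so commands always fire in creation order, and
#' several events may fire on one sample.
#'
#' @param ctrl a [new_controller()] value.
#' @param sample list or one-row data frame with `t` (s) and `v` (m/s).
#' @return list with the updated `ctrl` and `commands`, a data frame with
#'   columns `nozzle, action, t`.
#' @export
on_speed_sample <- function(ctrl, sample) {
  stopifnot(inherits(ctrl, "spray_controller"))
  t <- sample$t; v <- sample$v
  stopifnot(is.finite(t), is.finite(v), v >= 0)
  if (!is.na(ctrl$last_sample_t) &&
      abs((t - ctrl$last_sample_t) - ctrl$h) > 0.01 * ctrl$h)
    stop("speed sample spacing deviates from h = ", ctrl$h,
         " by more than 1%")
  ctrl$last_sample_t <- t
  cmds <- list()
  half_h <- ctrl$h / 2
  for (nz in seq_along(ctrl$queues)) {
    q <- ctrl$queues[[nz]]
    if (length(q) == 0) next
    for (i in seq_along(q)) {
      q[[i]]$M <- q[[i]]$M + half_h * (q[[i]]$v_prev + v)
      q[[i]]$v_prev <- v
      q[[i]]$k <- q[[i]]$k + 1L
    }
    while (length(q) > 0 && q[[1]]$M >= q[[1]]$A) {
      cmds[[length(cmds) + 1]] <- data.frame(nozzle = q[[1]]$nozzle,
                                             action = q[[1]]$kind, t = t,
                                             stringsAsFactors = FALSE)
      q <- q[-1]
    }
    ctrl$queues[[nz]] <- q
  }
  list(ctrl = ctrl,
       commands = if (length(cmds)) do.call(rbind, cmds) else no_commands())
}

#' @rdname on_speed_sample
#' @return `pending_events()`: data frame of all queued events in creation
#'   order within each nozzle.
#' @export
pending_events <- function(ctrl) {
  rows <- lapply(ctrl$queues, function(q)
    if (length(q) == 0) NULL
    else do.call(rbind, lapply(q, function(e)
      data.frame(nozzle = e$nozzle, kind = e$kind, A = e$A, M = e$M,
                 k = e$k, created_t = e$created_t, v0 = e$v0,
                 stringsAsFactors = FALSE))))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(nozzle = integer(0), kind = character(0),
                      A = numeric(0), M = numeric(0), k = integer(0),
                      created_t = numeric(0), v0 = numeric(0),
                      stringsAsFactors = FALSE)
  out
}

#' Write a valve command log as CSV
#'
#' @param commands data frame with columns `nozzle, action, t`.
#' @param path file path.
#' @export
write_commands_csv <- function(commands, path) {
  utils::write.csv(commands, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
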