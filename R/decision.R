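#' Assign detection boxes to nozzle lanes
#'
#' The camera view is divided across travel into one region per nozzle, each
#' `lane_width` wide, extended by `nozzle_overlap` on both sides (the nozzles'
#' spray overlap at lane seams). A box is assigned to every lane its
#' across-travel span overlaps, closed-interval convention: a box exactly on a
#' lane boundary triggers both adjacent nozzles, so multi-lane targets never
#' fall through a seam. Boxes entirely outside the lane range are dropped with
#' a warning.
#'
#' @param boxes data frame with columns `x_min, x_max, y_min, y_max` (belt
#'   frame, m).
#' @param geom a [geometry_config()].
#' @return list of length `n_lanes`; element `i` is a 2-column matrix
#'   (`y_min`, `y_max`) of the travel spans assigned to lane `i`.
#' @examples
#' geom <- geometry_config()
#' b <- data.frame(x_min = 0.5, x_max = 0.8, y_min = 1, y_max = 1.05)
#' lengths(assign_lanes(b, geom)) / 2 # box spanning lanes 3-4
#' @export
assign_lanes <- function(boxes, geom) {
  out <- rep(list(matrix(numeric(0), 0, 2,
                         dimnames = list(NULL, c("y_min", "y_max")))),
             geom$n_lanes)
  if (is.null(boxes) || nrow(boxes) == 0) return(out)
  lo <- (seq_len(geom$n_lanes) - 1) * geom$lane_width - geom$nozzle_overlap
  hi <- seq_len(geom$n_lanes) * geom$lane_width + geom$nozzle_overlap
  outside <- boxes$x_max < lo[1] | boxes$x_min > hi[geom$n_lanes]
  if (any(outside)) {
    warning(sum(outside), " box(es) outside the lane range ignored")
    boxes <- boxes[!outside, , drop = FALSE]
  }
  for (i in seq_len(geom$n_lanes)) {
    hit <- boxes$x_min <= hi[i] & boxes$x_max >= lo[i]
    if (any(hit))
      out[[i]] <- cbind(y_min = boxes$y_min[hit], y_max = boxes$y_max[hit])
  }
  out
}

#' Merge travel intervals closer than the valve can cycle
#'
#' Morphological closing along the travel axis: each interval is dilated by
#' `d_min / 2` on both ends, overlapping or touching dilated intervals are
#' unioned, and the union is eroded by `d_min / 2` at its outer ends. The
#' result spans the original outer bounds, fills every gap `<= d_min`
#' (touching counts as overlap — conservative, favors spraying), and leaves
#' all remaining gaps `> d_min`. This realises the expansion boxes drawn
#' around each prediction box and the filler box generated where expansions
#' intersect.
#'
#' @param intervals 2-column matrix or data frame of `(y_min, y_max)` rows.
#' @param resp a [response_config()].
#' @return sorted 2-column matrix of merged `(y_min, y_max)` intervals.
#' @examples
#' r <- response_config(d_min = 0.05)
#' expand_and_merge(rbind(c(0, 0.05), c(0.09, 0.14)), r) # gap 0.04: merged
#' expand_and_merge(rbind(c(0, 0.05), c(0.11, 0.16)), r) # gap 0.06: kept
#' @export
expand_and_merge <- function(intervals, resp) {
  stopifnot(inherits(resp, "response_config"))
  m <- as.matrix(intervals)
  empty <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("y_min", "y_max")))
  if (nrow(m) == 0) return(empty)
  if (any(!is.finite(m))) stop("intervals must be finite")
  if (any(m[, 2] < m[, 1])) stop("interval end precedes its start")
  m <- m[order(m[, 1]), , drop = FALSE]
  lo <- m[1, 1]; hi <- m[1, 2]
  res <- NULL
  if (nrow(m) > 1) for (i in 2:nrow(m)) {
    if (m[i, 1] <= hi + resp$d_min) {
      hi <- max(hi, m[i, 2])
    } else {
      res <- rbind(res, c(lo, hi))
      lo <- m[i, 1]; hi <- m[i, 2]
    }
  }
  res <- rbind(res, c(lo, hi))
  dimnames(res) <- list(NULL, c("y_min", "y_max"))
  res
}

#' Per-lane grid determination state
#'
#' Each lane carries a binary determination value: 1 while any merged
#' prediction box overlaps the judgment band, else 0. Changes emit edge
#' events, stamped with the frame time and the current speed feedback value,
#' which the hysteresis controller turns into valve open/close schedules.
#'
#' @param lane lane (nozzle) index.
#' @return a `lane_grid_state` list with fields `lane`, `determination`,
#'   `active_intervals`.
#' @export
new_lane_grid_state <- function(lane) {
  s <- list(lane = as.integer(lane), determination = 0L,
            active_intervals = matrix(numeric(0), 0, 2,
                                      dimnames = list(NULL,
                                                      c("y_min", "y_max"))))
  class(s) <- "lane_grid_state"
  s
}

#' Update a lane's grid determination from the current merged intervals
#'
#' Determination is 1 iff any merged interval intersects the judgment band
#' (closed intervals: touching counts). A 0 to 1 change emits a rising edge,
#' 1 to 0 a falling edge, stamped with `(t, v0)`.
#'
#' @param state a [new_lane_grid_state()] value.
#' @param merged merged travel intervals for this lane (matrix).
#' @param grid_region `c(lo, hi)` of the judgment band in the same frame.
#' @param t frame time, s.
#' @param v0 current speed feedback value, m/s.
#' @return list with the updated `state` and `events`, a data frame with
#'   columns `lane, kind, t, v0` (zero rows when no edge occurred).
#' @export
update_grid <- function(state, merged, grid_region, t, v0) {
  hit <- nrow(merged) > 0 &&
    any(merged[, 1] <= grid_region[2] & merged[, 2] >= grid_region[1])
  det <- as.integer(hit)
  events <- if (det != state$determination)
    data.frame(lane = state$lane,
               kind = if (det == 1L) "rising" else "falling",
               t = t, v0 = v0, stringsAsFactors = FALSE)
  else
    data.frame(lane = integer(0), kind = character(0), t = numeric(0),
               v0 = numeric(0), stringsAsFactors = FALSE)
  state$determination <- det
  state$active_intervals <- if (hit)
    merged[merged[, 1] <= grid_region[2] & merged[, 2] >= grid_region[1], ,
           drop = FALSE]
  else merged[0, , drop = FALSE]
  list(state = state, events = events)
}

#' One decision step over all lanes
#'
#' Convenience wrapper: assign boxes to lanes, expand-and-merge per lane, and
#' update every lane's grid state.
#'
#' @param boxes frame detection boxes (data frame).
#' @param states list of `lane_grid_state`, one per lane.
#' @param geom a [geometry_config()].
#' @param resp a [response_config()].
#' @param grid_region judgment band `c(lo, hi)` in the boxes' frame.
#' @param t frame time, s.
#' @param v0 current speed feedback, m/s.
#' @return list with updated `states` and row-bound `events`.
#' @export
decision_step <- function(boxes, states, geom, resp, grid_region, t, v0) {
  lanes <- assign_lanes(boxes, geom)
  ev <- vector("list", length(states))
  for (i in seq_along(states)) {
    merged <- expand_and_merge(lanes[[i]], resp)
    up <- update_grid(states[[i]], merged, grid_region, t, v0)
    states[[i]] <- up$state
    ev[[i]] <- up$events
  }
  list(states = states, events = do.call(rbind, ev))
}

#' Write an edge-event log as CSV
#'
#' @param events data frame with columns `lane, kind, t, v0`.
#' @param path file path.
#' @export
write_edges_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
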