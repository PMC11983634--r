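#' Exact detection oracle for a camera view
#'
#' Stands in for the real-time detector: emits one prediction box per weed
#' whose footprint intersects the camera's current view window, equal to the
#' weed's true bounding box clipped to the window, with confidence 1. A pure
#' function of `(scene, t, view_window)` — all coordinates are in the belt
#' frame and the *window* moves with the sprayer, so no belt-position argument
#' is needed.
#'
#' @param scene a `belt_scene`.
#' @param t frame time, s (stamped on the output; does not affect the boxes).
#' @param view_window `c(lo, hi)` travel-axis extent of the camera view in
#'   belt coordinates at time `t`.
#' @return a `frame_detections` list: `t`, `view_window`, and `boxes`, a data
#'   frame with columns `x_min, x_max, y_min, y_max, conf, weed_id`.
#' @export
oracle_detect <- function(scene, t, view_window) {
  w <- scene$weeds
  hit <- w$y_min <= view_window[2] & w$y_max >= view_window[1]
  boxes <- data.frame(x_min = w$x_min[hit], x_max = w$x_max[hit],
                      y_min = pmax(w$y_min[hit], view_window[1]),
                      y_max = pmin(w$y_max[hit], view_window[2]),
                      conf = rep(1, sum(hit)),
                      weed_id = w$id[hit])
  new_frame_detections(t, view_window, boxes)
}

new_frame_detections <- function(t, view_window, boxes) {
  f <- list(t = t, view_window = view_window, boxes = boxes)
  class(f) <- "frame_detections"
  f
}

#' Detector noise model
#'
#' @param miss_prob probability each box is dropped, in `[0, 1)` (1 allowed
#'   for the degenerate drop-everything case).
#' @param jitter_sd sd of zero-mean Gaussian jitter added to each box edge, m.
#' @param confidence_range interval from which surviving boxes' confidences
#'   are redrawn uniformly; `NULL` keeps the input confidences.
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return a `noise_params` list.
#' @export
noise_params <- function(miss_prob = 0, jitter_sd = 0,
                         confidence_range = NULL, seed = NULL) {
  stopifnot(miss_prob >= 0, miss_prob <= 1, jitter_sd >= 0)
  p <- list(miss_prob = miss_prob, jitter_sd = jitter_sd,
            confidence_range = confidence_range,
            seed = if (is.null(seed)) NULL else as.integer(seed))
  class(p) <- "noise_params"
  p
}

perturb_boxes_ <- function(boxes, params, view_window) {
  n <- nrow(boxes)
  if (n == 0) return(boxes)
  keep <- stats::runif(n) >= params$miss_prob
  boxes <- boxes[keep, , drop = FALSE]
  n <- nrow(boxes)
  if (n > 0 && params$jitter_sd > 0) {
    j <- matrix(stats::rnorm(4 * n, 0, params$jitter_sd), n, 4)
    x <- cbind(boxes$x_min + j[, 1], boxes$x_max + j[, 2])
    y <- cbind(boxes$y_min + j[, 3], boxes$y_max + j[, 4])
    boxes$x_min <- pmin(x[, 1], x[, 2]); boxes$x_max <- pmax(x[, 1], x[, 2])
    boxes$y_min <- pmin(y[, 1], y[, 2]); boxes$y_max <- pmax(y[, 1], y[, 2])
    if (!is.null(view_window)) { # boxes stay clipped to the view
      boxes$y_min <- pmax(boxes$y_min, view_window[1])
      boxes$y_max <- pmin(boxes$y_max, view_window[2])
      ok <- boxes$y_max - boxes$y_min > 0 & boxes$x_max - boxes$x_min > 0
      boxes <- boxes[ok, , drop = FALSE]
      n <- nrow(boxes)
    }
  }
  if (n > 0 && !is.null(params$confidence_range))
    boxes$conf <- stats::runif(n, params$confidence_range[1],
                               params$confidence_range[2])
  rownames(boxes) <- NULL
  boxes
}

#' Perturb detections with misses and box jitter
#'
#' Each box is independently dropped with probability `miss_prob`; surviving
#' box edges receive zero-mean Gaussian jitter (`jitter_sd`) and are re-clipped
#' to the view window; confidences are redrawn from `confidence_range` when
#' given. Deterministic when `params$seed` is set.
#'
#' @param frames a `frame_detections`, or a list of them (processed
#'   sequentially under one RNG stream).
#' @param params a [noise_params()].
#' @return perturbed object of the same shape as `frames`.
#' @export
perturb_detections <- function(frames, params) {
  stopifnot(inherits(params, "noise_params"))
  run <- function() {
    if (inherits(frames, "frame_detections")) {
      frames$boxes <- perturb_boxes_(frames$boxes, params, frames$view_window)
      frames
    } else {
      lapply(frames, function(f) {
        f$boxes <- perturb_boxes_(f$boxes, params, f$view_window)
        f
      })
    }
  }
  if (is.null(params$seed)) run() else with_seed(params$seed, run())
}

#' Read / write per-frame detection logs as JSONL
#'
#' One JSON record per line:
#' `{"t": ..., "view_window": [lo, hi], "boxes": [{...}, ...]}`. This is the
#' hook for an external detector: convert its pixel boxes to belt-frame
#' meters (linear meters-per-pixel scale plus principal-point offset) and
#' stream them in this format.
#'
#' @param frames list of `frame_detections`.
#' @param path file path.
#' @return `read_detections_jsonl()` returns a list of `frame_detections`.
#' @export
write_detections_jsonl <- function(frames, path) {
  if (inherits(frames, "frame_detections")) frames <- list(frames)
  lines <- vapply(frames, function(f) {
    jsonlite::toJSON(list(t = f$t, view_window = f$view_window,
                          boxes = f$boxes),
                     dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_detections_jsonl
#' @export
read_detections_jsonl <- function(path) {
  lapply(readLines(path), function(ln) {
    rec <- jsonlite::fromJSON(ln)
    boxes <- if (length(rec$boxes) == 0)
      data.frame(x_min = numeric(0), x_max = numeric(0), y_min = numeric(0),
                 y_max = numeric(0), conf = numeric(0), weed_id = integer(0))
    else as.data.frame(rec$boxes)
    if (is.null(boxes$weed_id)) boxes$weed_id <- rep(NA_integer_, nrow(boxes))
    new_frame_detections(rec$t, unlist(rec$view_window), boxes)
  })
}
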