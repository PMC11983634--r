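#' Scenario configuration for synthetic belt scenes
#'
#' A scene is a set of weed footprints (axis-aligned rectangles, meters) on a
#' conveyor belt, emulating the bench tests: simulated weeds whose position
#' and grouping change between trials. Scenarios reproduce the spatial
#' structures the decision algorithm must handle: weeds too close together
#' along travel (`vertical_close`), across travel in adjacent lanes
#' (`horizontal_close`), several clustered together (`cluster`), overlapping
#' footprints (`overlapping`), isolated plants (`single`), and a `mixed`
#' scenario that draws group types uniformly (the default for bench trials).
#'
#' @param scenario one of `"single"`, `"vertical_close"`, `"horizontal_close"`,
#'   `"cluster"`, `"overlapping"`, `"mixed"`.
#' @param n_weeds number of weeds to place (>= 1).
#' @param gap_range interval, m, from which within-group footprint gaps are
#'   drawn.
#' @param belt_length usable belt length, m; default scales with `n_weeds`.
#' @param belt_width belt width, m; must equal `n_lanes * lane_width` of the
#'   geometry used downstream.
#' @param seed integer seed.
#' @param max_diameter maximum along-travel weed extent, m. Tillering-stage
#'   weeds rarely exceed 0.10 m.
#' @param min_sep minimum travel separation between independent groups, m;
#'   the default keeps each group's spray burst outside the 0.15 m
#'   water-sensitive-paper readout window of any other group's weeds.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(scenario = c("mixed", "single", "vertical_close",
                                         "horizontal_close", "cluster",
                                         "overlapping"),
                            n_weeds = 20, gap_range = c(0.02, 0.08),
                            belt_length = NULL, belt_width = 2.3,
                            seed = 1L, max_diameter = 0.10, min_sep = 0.25) {
  scenario <- match.arg(scenario)
  if (is.null(belt_length)) belt_length <- max(3, 0.6 * n_weeds)
  stopifnot(n_weeds >= 1, length(gap_range) == 2, gap_range[1] >= 0,
            gap_range[1] <= gap_range[2], belt_length > 0, belt_width > 0,
            max_diameter > 0)
  cfg <- list(scenario = scenario, n_weeds = as.integer(n_weeds),
              gap_range = gap_range, belt_length = belt_length,
              belt_width = belt_width, seed = as.integer(seed),
              max_diameter = max_diameter, min_sep = min_sep)
  class(cfg) <- "scenario_config"
  cfg
}

weed_species <- c("Silene conoidea", "Malcolmia africana",
                  "Descurainia sophia", "Capsella bursa-pastoris")

#' A single weed footprint
#'
#' @param id integer id.
#' @param lane_span `c(x_min, x_max)` across-travel extent, m.
#' @param travel_span `c(y_min, y_max)` along-travel extent (belt frame), m.
#' @param label species tag (cosmetic).
#' @param max_diameter maximum permitted along-travel extent, m.
#' @return one-row data frame with columns
#'   `id, label, x_min, x_max, y_min, y_max`.
#' @export
weed_instance <- function(id, lane_span, travel_span, label = "weed",
                          max_diameter = 0.10) {
  stopifnot(length(lane_span) == 2, length(travel_span) == 2)
  if (diff(lane_span) <= 0 || diff(travel_span) <= 0)
    stop("weed footprint must have strictly positive extents")
  if (diff(travel_span) > max_diameter + 1e-12)
    stop("weed travel extent exceeds max_diameter (", max_diameter, " m)")
  data.frame(id = as.integer(id), label = label,
             x_min = lane_span[1], x_max = lane_span[2],
             y_min = travel_span[1], y_max = travel_span[2],
             stringsAsFactors = FALSE)
}

#' @rdname weed_instance
#' @param weeds a scene's weed data frame.
#' @return `weed_centers()`: data frame of footprint centers (`x`, `y`).
#' @export
weed_centers <- function(weeds) {
  data.frame(id = weeds$id, x = (weeds$x_min + weeds$x_max) / 2,
             y = (weeds$y_min + weeds$y_max) / 2)
}

new_belt_scene <- function(weeds, config) {
  rownames(weeds) <- NULL
  s <- list(weeds = weeds, config = config)
  class(s) <- "belt_scene"
  s
}

#' @export
print.belt_scene <- function(x, ...) {
  cat("<belt_scene> ", nrow(x$weeds), " weeds, scenario '",
      x$config$scenario, "', belt ", x$config$belt_length, " m x ",
      x$config$belt_width, " m (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

# ---- group builders -------------------------------------------------------
# Each builder returns footprints with absolute lane (x) coordinates and
# travel (y) coordinates local to the group (starting at 0).

draw_widths <- function(n) stats::runif(n, 0.04, 0.10)
draw_depths <- function(n, max_d) stats::runif(n, min(0.04, max_d), max_d)
draw_gap <- function(n, gr) stats::runif(n, gr[1], gr[2])

grp_single <- function(cfg, W) {
  w <- draw_widths(1); d <- draw_depths(1, cfg$max_diameter)
  xc <- stats::runif(1, w / 2, W - w / 2)
  data.frame(x_min = xc - w / 2, x_max = xc + w / 2, y_min = 0, y_max = d)
}

grp_vertical <- function(cfg, W, n) {
  w <- draw_widths(n); d <- draw_depths(n, cfg$max_diameter)
  xc <- stats::runif(1, max(w) / 2, W - max(w) / 2)
  gaps <- draw_gap(n - 1, cfg$gap_range)
  y0 <- cumsum(c(0, d[-n] + gaps))
  data.frame(x_min = xc - w / 2, x_max = xc + w / 2,
             y_min = y0, y_max = y0 + d)
}

grp_horizontal <- function(cfg, W, n, lane_width) {
  n_lanes <- floor(W / lane_width + 1e-9)
  if (n > n_lanes)
    stop("horizontal_close group wider than the belt: ", n, " > ", n_lanes,
         " lanes")
  w <- pmin(draw_widths(n), lane_width * 0.9)
  d <- draw_depths(n, cfg$max_diameter)
  j <- if (n_lanes == n) 1L else sample.int(n_lanes - n + 1L, 1L)
  xc <- (j + seq_len(n) - 1.5) * lane_width
  yc <- max(d) / 2
  data.frame(x_min = xc - w / 2, x_max = xc + w / 2,
             y_min = yc - d / 2, y_max = yc + d / 2)
}

grp_cluster <- function(cfg, W, n) {
  ncol_ <- ceiling(sqrt(n))
  w <- draw_widths(n); d <- draw_depths(n, cfg$max_diameter)
  col_id <- (seq_len(n) - 1) %% ncol_ + 1
  row_id <- (seq_len(n) - 1) %/% ncol_ + 1
  col_w <- vapply(seq_len(ncol_), function(j) max(w[col_id == j]), 0)
  col_gap <- draw_gap(ncol_ - 1, cfg$gap_range)
  col_x0 <- cumsum(c(0, col_w[-ncol_] + col_gap))
  nrow_ <- max(row_id)
  row_d <- vapply(seq_len(nrow_), function(i) max(d[row_id == i]), 0)
  row_gap <- draw_gap(max(nrow_ - 1, 1), cfg$gap_range)
  row_y0 <- cumsum(c(0, (row_d[-nrow_] + row_gap[seq_len(nrow_ - 1)])))
  total_w <- col_x0[ncol_] + col_w[ncol_]
  if (total_w > W) stop("cluster group wider than the belt")
  x_off <- stats::runif(1, 0, W - total_w)
  xc <- x_off + col_x0[col_id] + col_w[col_id] / 2
  yc <- row_y0[row_id] + row_d[row_id] / 2
  data.frame(x_min = xc - w / 2, x_max = xc + w / 2,
             y_min = yc - d / 2, y_max = yc + d / 2)
}

grp_overlapping <- function(cfg, W, n) {
  w <- draw_widths(n); d <- draw_depths(n, cfg$max_diameter)
  xc <- numeric(n); y0 <- numeric(n)
  xc[1] <- stats::runif(1, max(w) / 2 + 0.05, W - max(w) / 2 - 0.05)
  y0[1] <- 0
  for (i in seq_len(n)[-1]) {
    ov <- stats::runif(1, 0.25, 0.6) * min(d[i - 1], d[i])
    y0[i] <- y0[i - 1] + d[i - 1] - ov
    shift <- stats::runif(1, -0.3, 0.3) * min(w[i - 1], w[i])
    xc[i] <- min(max(xc[i - 1] + shift, w[i] / 2), W - w[i] / 2)
  }
  data.frame(x_min = xc - w / 2, x_max = xc + w / 2,
             y_min = y0, y_max = y0 + d)
}

group_sizes <- c(single = 1L, vertical_close = 2L, horizontal_close = 2L,
                 cluster = 3L, overlapping = 2L)

build_group <- function(type, cfg, W, n, lane_width) {
  switch(type,
         single = grp_single(cfg, W),
         vertical_close = grp_vertical(cfg, W, n),
         horizontal_close = grp_horizontal(cfg, W, n, lane_width),
         cluster = grp_cluster(cfg, W, n),
         overlapping = grp_overlapping(cfg, W, n),
         stop("unknown scenario type: ", type))
}

# ---- scene generation -----------------------------------------------------

#' Generate a synthetic belt scene
#'
#' Deterministic given `(config, seed)`. Weeds are placed in groups whose
#' internal structure follows the scenario (see [scenario_config()]); groups
#' are separated along travel by at least `min_sep` so they behave as
#' independent targets, with the remaining belt length distributed randomly.
#'
#' @param config a [scenario_config()].
#' @param geom a [geometry_config()]; `config$belt_width` must equal
#'   `belt_width(geom)`.
#' @return a `belt_scene`: list with `weeds` (data frame of footprints, plus
#'   `group` and `group_type` provenance columns) and `config`.
#' @examples
#' sc <- generate_scene(scenario_config("vertical_close", n_weeds = 2,
#'                                      gap_range = c(0.03, 0.03), seed = 7))
#' sc$weeds
#' @export
generate_scene <- function(config, geom = geometry_config()) {
  stopifnot(inherits(config, "scenario_config"))
  if (abs(config$belt_width - belt_width(geom)) > 1e-9)
    stop("config$belt_width (", config$belt_width,
         ") must equal n_lanes * lane_width (", belt_width(geom), ")")
  with_seed(config$seed, {
    n <- config$n_weeds
    W <- config$belt_width
    # decide group composition
    if (config$scenario == "mixed") {
      types <- character(0); sizes <- integer(0); left <- n
      while (left > 0) {
        ok <- names(group_sizes)[group_sizes <= left]
        ty <- sample(ok, 1)
        types <- c(types, ty); sizes <- c(sizes, group_sizes[[ty]])
        left <- left - group_sizes[[ty]]
      }
    } else if (config$scenario == "single") {
      types <- rep("single", n); sizes <- rep(1L, n)
    } else {
      if (n < 2 || (config$scenario == "cluster" && n < 3))
        stop(config$scenario, " scenario needs at least ",
             if (config$scenario == "cluster") 3 else 2, " weeds")
      types <- config$scenario; sizes <- n
    }
    groups <- lapply(seq_along(types), function(g)
      build_group(types[g], config, W, sizes[g], geom$lane_width))
    extents <- vapply(groups, function(df) max(df$y_max), 0)
    G <- length(groups)
    pad <- 0.1
    usable <- config$belt_length - 2 * pad
    need <- sum(extents) + (G - 1) * config$min_sep
    if (need > usable)
      stop("belt too short: placing ", n, " weeds in ", G, " groups needs ",
           round(need + 2 * pad, 2), " m of travel but belt_length is ",
           config$belt_length, " m (group separation >= ", config$min_sep,
           " m)")
    wts <- stats::runif(G + 1)
    slack <- (usable - need) * wts / sum(wts)
    ord <- sample.int(G) # shuffle group order along the belt
    cursor <- pad
    placed <- vector("list", G)
    for (k in seq_len(G)) {
      g <- ord[k]
      cursor <- cursor + slack[k]
      df <- groups[[g]]
      df$y_min <- df$y_min + cursor
      df$y_max <- df$y_max + cursor
      df$group <- g
      df$group_type <- types[g]
      placed[[g]] <- df
      cursor <- cursor + extents[g] + config$min_sep
    }
    weeds <- do.call(rbind, placed)
    weeds <- weeds[order(weeds$y_min), , drop = FALSE]
    weeds <- data.frame(id = seq_len(nrow(weeds)),
                        label = sample(weed_species, nrow(weeds),
                                       replace = TRUE),
                        weeds, stringsAsFactors = FALSE)
    new_belt_scene(weeds, config)
  })
}

#' Generate the scene series for a bench campaign
#'
#' Bench protocol: `n_trials` trials of `n_weeds` simulated weeds each, with
#' positions and grouping re-drawn every trial (`mixed` scenario). Per-trial
#' seeds are derived reproducibly from the master seed and recorded in each
#' scene's config.
#'
#' @param n_trials number of trials (>= 1).
#' @param n_weeds weeds per trial.
#' @param seed master seed.
#' @param geom a [geometry_config()].
#' @param belt_length belt length per trial, m (default auto).
#' @return list of `belt_scene`.
#' @export
bench_trial_scenes <- function(n_trials, n_weeds = 20, seed = 1L,
                               geom = geometry_config(),
                               belt_length = NULL) {
  stopifnot(n_trials >= 1)
  lapply(seq_len(n_trials), function(i) {
    cfg <- scenario_config("mixed", n_weeds = n_weeds,
                           belt_length = belt_length,
                           belt_width = belt_width(geom),
                           seed = derive_seed(seed, i))
    generate_scene(cfg, geom)
  })
}

# ---- scenario predicates --------------------------------------------------

rect_disjoint <- function(a, b) {
  a["x_max"] < b["x_min"] || b["x_max"] < a["x_min"] ||
    a["y_max"] < b["y_min"] || b["y_max"] < a["y_min"]
}

#' Check a scene against its scenario's structural constraints
#'
#' Verifies belt bounds, the maximum-diameter invariant, group separation,
#' and per-group structure (same-lane chains with gaps inside `gap_range`,
#' matched travel centers in adjacent lanes, pairwise-overlapping footprints,
#' compact clusters). Intended for tests and data validation.
#'
#' @param scene a `belt_scene`.
#' @param geom the geometry the scene was generated against.
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validate_scene <- function(scene, geom = geometry_config()) {
  w <- scene$weeds
  cfg <- scene$config
  tol <- 1e-9
  if (any(w$x_min < -tol) || any(w$x_max > cfg$belt_width + tol) ||
      any(w$y_min < -tol) || any(w$y_max > cfg$belt_length + tol))
    stop("weed footprint outside belt bounds")
  if (any(w$y_max - w$y_min > cfg$max_diameter + 1e-9))
    stop("weed travel extent exceeds max_diameter")
  if (any(w$x_max - w$x_min <= 0) || any(w$y_max - w$y_min <= 0))
    stop("degenerate weed footprint")
  for (g in unique(w$group)) {
    grp <- w[w$group == g, , drop = FALSE]
    ty <- grp$group_type[1]
    if (ty == "vertical_close") {
      if (diff(range((grp$x_min + grp$x_max) / 2)) > tol)
        stop("vertical_close group not in a single lane column")
      grp <- grp[order(grp$y_min), ]
      gaps <- grp$y_min[-1] - grp$y_max[-nrow(grp)]
      if (any(gaps < cfg$gap_range[1] - tol | gaps > cfg$gap_range[2] + tol))
        stop("vertical_close gap outside gap_range")
    } else if (ty == "horizontal_close") {
      yc <- (grp$y_min + grp$y_max) / 2
      if (diff(range(yc)) > tol)
        stop("horizontal_close travel centers not matched")
      lanes <- sort(floor((grp$x_min + grp$x_max) / 2 / geom$lane_width))
      if (any(diff(lanes) != 1))
        stop("horizontal_close weeds not in adjacent lanes")
    } else if (ty == "overlapping") {
      grp <- grp[order(grp$y_min), ]
      for (i in seq_len(nrow(grp) - 1))
        if (rect_disjoint(unlist(grp[i, c("x_min", "x_max", "y_min", "y_max")]),
                          unlist(grp[i + 1, c("x_min", "x_max", "y_min",
                                              "y_max")])))
          stop("overlapping group has disjoint consecutive footprints")
    } else if (ty == "cluster") {
      if (nrow(grp) < 3) stop("cluster group has fewer than 3 weeds")
      if (diff(range(grp$y_min)) > 0.5 || diff(range(grp$x_min)) > 0.6)
        stop("cluster group not compact")
    }
  }
  # non-overlapping groups must be pairwise disjoint across the scene
  non_ov <- w[w$group_type != "overlapping", , drop = FALSE]
  if (nrow(non_ov) > 1) {
    m <- as.matrix(non_ov[, c("x_min", "x_max", "y_min", "y_max")])
    for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
      same_grp <- non_ov$group[i] == non_ov$group[j]
      if (!rect_disjoint(m[i, ], m[j, ]) && !same_grp)
        stop("weeds from different groups overlap")
    }
  }
  invisible(TRUE)
}
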