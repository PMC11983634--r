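#' Bench evaluation rates
#'
#' Recognition rate is detected weeds over all weeds; spraying rate is weeds
#' whose indicator paper discolored over detected weeds; hit rate is their
#' product. All are fractions in `[0, 1]`; report layers convert to percent.
#'
#' @param n_detected,n_total,n_wetted_detected counts.
#' @return fraction in `[0, 1]`.
#' @examples
#' recognition_rate(985, 1000) # 0.985
#' hit_rate(0.985, 0.998) # 0.98303
#' @export
recognition_rate <- function(n_detected, n_total) {
  if (length(n_total) != 1 || n_total < 1) stop("n_total must be >= 1")
  stopifnot(n_detected >= 0, n_detected <= n_total)
  n_detected / n_total
}

#' @rdname recognition_rate
#' @export
spraying_rate <- function(n_wetted_detected, n_detected) {
  stopifnot(n_wetted_detected >= 0)
  if (n_detected == 0) {
    warning("no detected weeds; spraying rate is 0")
    return(0)
  }
  if (n_wetted_detected > n_detected)
    stop("n_wetted_detected exceeds n_detected")
  n_wetted_detected / n_detected
}

#' @rdname recognition_rate
#' @param recognition,spraying fractions in `[0, 1]`.
#' @export
hit_rate <- function(recognition, spraying) {
  stopifnot(recognition >= 0, recognition <= 1, spraying >= 0, spraying <= 1)
  recognition * spraying
}

#' Spray coverage of a weed
#'
#' Two definitions are kept. `"as_printed"` follows the bench write-up
#' literally: the ratio of the weed's length to the discoloration length,
#' capped at 1 (an inverted-looking definition — a longer wetted strip scores
#' *lower* — flagged here rather than corrected). `"overlap"` is the more
#' conventional fraction of the weed's span actually wetted:
#' `overlap_len / weed_len`.
#'
#' @param weed_len weed along-travel length, m (> 0).
#' @param discoloration_len total discolored length, m.
#' @param mode `"as_printed"` or `"overlap"`.
#' @param overlap_len length of the intersection between discoloration and
#'   the weed span, m; required for `"overlap"` mode.
#' @return coverage fraction in `[0, 1]`.
#' @export
coverage_rate <- function(weed_len, discoloration_len,
                          mode = c("as_printed", "overlap"),
                          overlap_len = NULL) {
  mode <- match.arg(mode)
  stopifnot(weed_len > 0, discoloration_len >= 0)
  if (mode == "as_printed") {
    if (discoloration_len == 0) return(0)
    min(weed_len / discoloration_len, 1)
  } else {
    if (is.null(overlap_len))
      stop("overlap mode needs overlap_len")
    stopifnot(overlap_len >= 0, overlap_len <= weed_len + 1e-12)
    min(overlap_len / weed_len, 1)
  }
}

#' Targeting error summaries
#'
#' Mean absolute error and root mean square error of the offsets between weed
#' centres and discoloration centres.
#'
#' @param offsets numeric vector of signed offsets, m (nonempty).
#' @return list with `mae` and `rmse`, meters.
#' @examples
#' targeting_errors(c(0.01, 0.02, 0.03)) # mae 0.02, rmse ~0.0216
#' @export
targeting_errors <- function(offsets) {
  if (length(offsets) == 0) stop("offsets must be nonempty")
  stopifnot(all(is.finite(offsets)))
  list(mae = mean(abs(offsets)), rmse = sqrt(mean(offsets^2)))
}

#' Ablation / comparison table arithmetic
#'
#' `percent_reduction()` is `100 * (before - after) / before`, to one decimal;
#' `metric_delta()` is the difference of two percentages in percentage points,
#' to one decimal.
#'
#' @param before,after positive quantities (GFLOPs, model size, ...).
#' @return percent, rounded to one decimal.
#' @examples
#' percent_reduction(15.9, 7.6) # 52.2
#' metric_delta(84.9, 83.4) # 1.5
#' @export
percent_reduction <- function(before, after) {
  if (!is.finite(before) || before <= 0) stop("before must be positive")
  round(100 * (before - after) / before, 1)
}

#' @rdname percent_reduction
#' @param a,b percentages.
#' @export
metric_delta <- function(a, b) round(a - b, 1)

#' Write / read a metrics table as TSV
#'
#' Numeric columns are serialised with full (17 significant digit) precision
#' so a written table reads back bit-exactly; use the rounded columns of
#' [run_bench()]'s summary for presentation.
#'
#' @param df data frame.
#' @param path file path.
#' @return `read_metrics_tsv()` returns the data frame.
#' @export
write_metrics_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics_tsv
#' @export
read_metrics_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Ablation-style report table
#'
#' Builds a model-comparison table (GFLOPs, size, mAP, F1) with reduction and
#' delta columns relative to a named baseline row, shaped like the detector
#' ablation/comparison reports these controllers are published with.
#'
#' @param models data frame with columns `model, gflops, size_kb, map_pct,
#'   f1_pct`.
#' @param baseline model name to compare against.
#' @return the input with `gflops_reduction_pct`, `size_reduction_pct`,
#'   `map_delta`, `f1_delta` columns appended.
#' @export
ablation_table <- function(models, baseline) {
  stopifnot(all(c("model", "gflops", "size_kb", "map_pct", "f1_pct") %in%
                  names(models)))
  b <- models[models$model == baseline, , drop = FALSE]
  if (nrow(b) != 1) stop("baseline '", baseline, "' not found exactly once")
  models$gflops_reduction_pct <-
    vapply(models$gflops, function(x) percent_reduction(b$gflops, x), 0)
  models$size_reduction_pct <-
    vapply(models$size_kb, function(x) percent_reduction(b$size_kb, x), 0)
  models$map_delta <- vapply(models$map_pct,
                             function(x) metric_delta(x, b$map_pct), 0)
  models$f1_delta <- vapply(models$f1_pct,
                            function(x) metric_delta(x, b$f1_pct), 0)
  models
}
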