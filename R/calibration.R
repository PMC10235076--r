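#' Molecular-weight ladder specifications
#'
#' A ladder is a lane of DNA fragments of known sizes used to calibrate
#' migration distance against fragment size. Two fit subsets are designated:
#' the high-molecular-weight bands used for the upper calibration segment
#' and the low-molecular-weight bands for the lower segment. Bands outside
#' both subsets (e.g. sub-2 kb bands) are retained for QC display only.
#'
#' @param name ladder name.
#' @param sizes_kb all band sizes in kb, strictly decreasing.
#' @param hi_fit_kb,lo_fit_kb fit subsets (each a subset of `sizes_kb`, at
#'   least 2 bands); every high-MW fit size must exceed every low-MW fit
#'   size except at a shared boundary band.
#' @return A `ladder_spec` object.
#' @export
ladder_spec <- function(name, sizes_kb, hi_fit_kb, lo_fit_kb) {
  sizes_kb <- as.numeric(sizes_kb)
  if (any(diff(sizes_kb) >= 0)) stop("band sizes must be strictly decreasing")
  if (!all(hi_fit_kb %in% sizes_kb) || !all(lo_fit_kb %in% sizes_kb))
    stop("fit subsets must be subsets of the band sizes")
  if (length(hi_fit_kb) < 2L || length(lo_fit_kb) < 2L)
    stop("each fit subset needs at least 2 bands")
  if (!setequal(hi_fit_kb, lo_fit_kb) && min(hi_fit_kb) < max(lo_fit_kb))
    stop("high-MW fit sizes must not descend below the low-MW fit range")
  structure(list(name = name, sizes_kb = sizes_kb,
                 hi_fit_kb = sort(as.numeric(hi_fit_kb), decreasing = TRUE),
                 lo_fit_kb = sort(as.numeric(lo_fit_kb), decreasing = TRUE)),
            class = "ladder_spec")
}

#' Built-in ladders
#'
#' `builtin_ladder("smartladder")` is the Eurogentec SmartLadder
#' (10-0.2 kb); for it both calibration segments use the same 10-2 kb
#' bands, so the piecewise scale degenerates to a single line.
#' `builtin_ladder("quickload-1kb-extend")` is the NEB QuickLoad 1 kb Extend
#' ladder (48.5-0.5 kb) with the high segment fitted on 48.5, 20 and 15 kb
#' and the low segment on 10, 8, 6, 5, 4, 3, 2.5 and 2 kb.
#'
#' @param name `"smartladder"` or `"quickload-1kb-extend"`.
#' @return A [ladder_spec()].
#' @export
builtin_ladder <- function(name = c("smartladder", "quickload-1kb-extend")) {
  name <- match.arg(name)
  lo <- c(10, 8, 6, 5, 4, 3, 2.5, 2)
  switch(name,
    "smartladder" = ladder_spec("smartladder",
      sizes_kb = c(10, 8, 6, 5, 4, 3, 2.5, 2, 1.5, 1, 0.8, 0.6, 0.4, 0.2),
      hi_fit_kb = lo, lo_fit_kb = lo),
    "quickload-1kb-extend" = ladder_spec("quickload-1kb-extend",
      sizes_kb = c(48.5, 20, 15, 10, 8, 6, 5, 4, 3, 2.5, 2, 1.5, 1, 0.5),
      hi_fit_kb = c(48.5, 20, 15), lo_fit_kb = lo))
}

#' Refine ladder peak positions
#'
#' Manually reported (seeded) band positions are refined by searching for
#' the maximum intensity within a window of `window` pixels on either side
#' of each seed along the extracted lane profile. Ties are broken toward
#' the seed, then toward the smaller (upper) row.
#'
#' @param profile ladder [lane_profile()].
#' @param seeds data frame with columns `size_kb` and `seed_row`.
#' @param window search half-width in pixels (default 10).
#' @return A `peak_set`: data frame `size_kb, seed_row, refined_row,
#'   peak_intensity` sorted by decreasing size, plus the lane id.
#' @export
refine_peaks <- function(profile, seeds, window = 10L) {
  stopifnot(inherits(profile, "lane_profile"), window >= 0)
  seeds <- seeds[order(-seeds$size_kb), , drop = FALSE]
  if (any(!seeds$seed_row %in% profile$row))
    stop("seed row outside profile range for lane ", profile$lane_id)
  ref <- vapply(seq_len(nrow(seeds)), function(i) {
    s <- seeds$seed_row[i]
    in_win <- abs(profile$row - s) <= window
    rows <- profile$row[in_win]; val <- profile$intensity[in_win]
    best <- val == max(val)
    cand <- rows[best]
    d <- abs(cand - s)
    cand <- cand[d == min(d)]
    min(cand)
  }, numeric(1))
  pk <- data.frame(size_kb = seeds$size_kb, seed_row = seeds$seed_row,
                   refined_row = as.integer(ref),
                   peak_intensity = profile$intensity[match(ref, profile$row)])
  if (any(diff(pk$refined_row) <= 0))
    stop("refined peak rows are not strictly increasing with decreasing ",
         "size; ladder lane ", profile$lane_id, " appears mis-seeded")
  structure(list(lane_id = profile$lane_id,
                 membrane_id = profile$membrane_id, peaks = pk),
            class = "peak_set")
}

#' Fit one log2-linear calibration segment
#'
#' Ordinary least squares of `log2(size kb)` on peak pixel row:
#' `log2(L) = a + b * row`.
#'
#' @param size_kb band sizes (kb), positive.
#' @param row peak pixel rows.
#' @return Named numeric `c(a = intercept, b = slope)`.
#' @export
fit_segment <- function(size_kb, row) {
  if (length(size_kb) < 2L) stop("at least 2 points required for a segment")
  if (length(unique(row)) < 2L) stop("degenerate segment: identical rows")
  fit <- stats::lm(log2(size_kb) ~ row)
  stats::setNames(as.numeric(stats::coef(fit)), c("a", "b"))
}

#' Build a two-segment pixel-to-size scale from ladder peaks
#'
#' Gel migration is not log-linear over the whole size range (the high-MW
#' region is compressed), so the pixel-to-size map is modeled as two linear
#' segments in log2(size): one fitted on the ladder's high-MW bands, one on
#' its low-MW bands. The switch row is chosen for continuity: among rows
#' where the low segment predicts a size in `switch_range_kb` (8-10 kb),
#' the row minimizing the absolute log2 gap between the two segments.
#'
#' @param peaks a `peak_set` from [refine_peaks()].
#' @param ladder a [ladder_spec()].
#' @param continuity_tol maximum tolerated log2 gap at the switch before a
#'   warning (default 0.15, about 11% in size).
#' @param switch_range_kb permitted switch-size interval, default `c(8, 10)`.
#' @return A `piecewise_scale` with coefficients `a_hi, b_hi, a_lo, b_lo`,
#'   the switch row and size, the continuity gap, the calibrated size range
#'   and the source lane id.
#' @export
build_scale <- function(peaks, ladder, continuity_tol = 0.15,
                        switch_range_kb = c(8, 10)) {
  stopifnot(inherits(peaks, "peak_set"), inherits(ladder, "ladder_spec"))
  pk <- peaks$peaks
  pick <- function(sizes) {
    sub <- pk[pk$size_kb %in% sizes, , drop = FALSE]
    if (nrow(sub) < 2L)
      stop("fewer than 2 fitted bands available for a segment in lane ",
           peaks$lane_id)
    if (nrow(sub) < length(sizes))
      warning(sprintf("lane %s: %d of %d fit bands missing",
                      peaks$lane_id, length(sizes) - nrow(sub),
                      length(sizes)))
    sub
  }
  hi <- pick(ladder$hi_fit_kb)
  lo <- pick(ladder$lo_fit_kb)
  c_hi <- fit_segment(hi$size_kb, hi$refined_row)
  c_lo <- fit_segment(lo$size_kb, lo$refined_row)
  if (c_hi["b"] >= 0 || c_lo["b"] >= 0)
    stop("calibration slope must be negative (size decreases down the gel)")
  # rows where the low segment predicts a size inside the switch window
  r_top <- (log2(max(switch_range_kb)) - c_lo["a"]) / c_lo["b"]
  r_bot <- (log2(min(switch_range_kb)) - c_lo["a"]) / c_lo["b"]
  rows <- seq.int(ceiling(r_top), floor(r_bot))
  if (length(rows) == 0L)
    stop("no pixel row maps into the ", min(switch_range_kb), "-",
         max(switch_range_kb), " kb switch window; check ladder geometry")
  gap <- abs((c_hi["a"] + c_hi["b"] * rows) - (c_lo["a"] + c_lo["b"] * rows))
  switch_row <- rows[which.min(gap)]
  gap_at <- min(gap)
  if (gap_at > continuity_tol)
    warning(sprintf("lane %s: continuity gap %.3f log2 units at switch row %d exceeds tolerance %.3f",
                    peaks$lane_id, gap_at, switch_row, continuity_tol))
  fitted <- pk[pk$size_kb %in% c(ladder$hi_fit_kb, ladder$lo_fit_kb), ]
  structure(list(a_hi = unname(c_hi["a"]), b_hi = unname(c_hi["b"]),
                 a_lo = unname(c_lo["a"]), b_lo = unname(c_lo["b"]),
                 switch_row = as.integer(switch_row),
                 switch_size_kb = unname(2^(c_lo["a"] + c_lo["b"] * switch_row)),
                 continuity_gap = unname(gap_at),
                 valid_min_kb = min(fitted$size_kb),
                 valid_max_kb = max(fitted$size_kb),
                 ladder_lane_id = peaks$lane_id,
                 membrane_id = peaks$membrane_id),
            class = "piecewise_scale")
}

#' @export
print.piecewise_scale <- function(x, ...) {
  cat(sprintf(
    "<piecewise_scale lane '%s'> hi: log2(kb)=%.4f%+.5f*row, lo: %.4f%+.5f*row\n  switch at row %d (%.2f kb, gap %.4f log2), valid %.1f-%.1f kb\n",
    x$ladder_lane_id, x$a_hi, x$b_hi, x$a_lo, x$b_lo, x$switch_row,
    x$switch_size_kb, x$continuity_gap, x$valid_min_kb, x$valid_max_kb))
  invisible(x)
}

#' Convert pixel row to fragment size
#'
#' Applies the high-MW segment above the switch row and the low-MW segment
#' at and below it. Strictly decreasing in row. Extrapolation outside the
#' fitted band range is permitted (sizes below 2 kb are discarded later
#' anyway) and can be detected by comparing against the scale's valid range.
#'
#' @param scale a `piecewise_scale`.
#' @param row pixel row(s).
#' @return Fragment size(s) in kb.
#' @export
size_at <- function(scale, row) {
  stopifnot(inherits(scale, "piecewise_scale"))
  ifelse(row < scale$switch_row,
         2^(scale$a_hi + scale$b_hi * row),
         2^(scale$a_lo + scale$b_lo * row))
}

#' Assign a sample lane to its nearest ladder scale
#'
#' Membranes carry ladders at the left and right ends (and sometimes the
#' middle); each sample lane is calibrated with the ladder whose lane
#' center is laterally nearest. Ties go to the leftmost ladder.
#'
#' @param sample_roi the sample's [lane_roi()].
#' @param scales list of `piecewise_scale` objects.
#' @param ladder_centers numeric lateral centers (columns) of the ladder
#'   lanes, same length/order as `scales`.
#' @return The selected `piecewise_scale`.
#' @export
assign_scale <- function(sample_roi, scales, ladder_centers) {
  if (length(scales) == 0L) stop("no ladder scales available")
  stopifnot(length(scales) == length(ladder_centers))
  center <- (sample_roi$col_start + sample_roi$col_end) / 2
  ord <- order(ladder_centers)
  scales <- scales[ord]; ladder_centers <- ladder_centers[ord]
  d <- abs(ladder_centers - center)
  scales[[which(d == min(d))[1]]]
}

#' Read ladder seed tables
#'
#' CSV with header `membrane_id,lane_id,size_kb,seed_row`.
#'
#' @param path CSV path.
#' @return Data frame of seeds.
#' @export
read_seeds <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("membrane_id", "lane_id", "size_kb", "seed_row")
  if (!all(need %in% names(df)))
    stop("seed file missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' @rdname read_seeds
#' @param seeds data frame with the seed columns.
#' @export
write_seeds <- function(seeds, path) {
  utils::write.csv(seeds[, c("membrane_id", "lane_id", "size_kb",
                             "seed_row")], path, row.names = FALSE)
  invisible(path)
}

#' Serialize scales to JSON
#'
#' @param scales list of `piecewise_scale` objects.
#' @param path JSON output path.
#' @return `path` invisibly / list of `piecewise_scale`.
#' @export
write_scales <- function(scales, path) {
  lst <- lapply(scales, function(s)
    s[c("a_hi", "b_hi", "a_lo", "b_lo", "switch_row", "switch_size_kb",
        "continuity_gap", "valid_min_kb", "valid_max_kb", "ladder_lane_id",
        "membrane_id")])
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_scales
#' @export
read_scales <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lapply(lst, function(s) {
    s$switch_row <- as.integer(s$switch_row)
    structure(s, class = "piecewise_scale")
  })
}
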