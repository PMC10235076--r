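#' Background-subtract a lane profile
#'
#' Levels the lane by subtracting the minimal intensity of that lane from
#' every position, so the output minimum is exactly zero. All downstream
#' telomere statistics are therefore invariant to any constant offset on
#' the raw trace.
#'
#' @param profile a [lane_profile()].
#' @return A background-subtracted [lane_profile()].
#' @export
subtract_background <- function(profile) {
  stopifnot(inherits(profile, "lane_profile"))
  profile$intensity <- profile$intensity - min(profile$intensity)
  profile
}

#' Construct a telomere-length distribution directly
#'
#' For pre-extracted data: pairs of (fragment size, raw intensity) sorted
#' by size. Normally distributions come from [profile_to_distribution()].
#'
#' @param size_kb fragment sizes in kb (any order; must be distinct).
#' @param raw non-negative raw intensities.
#' @param lane_id,membrane_id,probe,scale_id metadata.
#' @return A `tl_distribution` (weights unset; apply
#'   [normalize_by_size()]).
#' @export
tl_distribution <- function(size_kb, raw, lane_id = "lane",
                            membrane_id = "membrane", probe = "none",
                            scale_id = NA_character_) {
  stopifnot(length(size_kb) == length(raw), all(raw >= 0))
  if (anyDuplicated(size_kb)) stop("duplicate sizes in distribution")
  ord <- order(size_kb)
  structure(list(lane_id = lane_id, membrane_id = membrane_id,
                 probe = probe, scale_id = scale_id,
                 table = data.frame(size_kb = size_kb[ord], raw = raw[ord],
                                    weight = NA_real_)),
            class = "tl_distribution")
}

#' Map a lane profile onto the fragment-size axis
#'
#' Each pixel row is converted to a fragment size with [size_at()] and the
#' entries are re-sorted size-ascending. Per-pixel intensities are carried
#' over unchanged — no bin-width (Jacobian) reweighting — mirroring the
#' per-pixel treatment of the quantification procedure; set
#' `jacobian = TRUE` to multiply each intensity by the local |d size/d row|
#' for sensitivity analysis.
#'
#' @param profile a background-subtracted [lane_profile()].
#' @param scale a `piecewise_scale`.
#' @param jacobian logical, default `FALSE`.
#' @return A `tl_distribution`: data frame `size_kb, raw, weight` sorted by
#'   increasing size (weights `NA` until [normalize_by_size()] is applied),
#'   plus lane metadata.
#' @export
profile_to_distribution <- function(profile, scale, jacobian = FALSE) {
  stopifnot(inherits(profile, "lane_profile"),
            inherits(scale, "piecewise_scale"))
  size <- size_at(scale, profile$row)
  raw <- profile$intensity
  if (jacobian) {
    b <- ifelse(profile$row < scale$switch_row, scale$b_hi, scale$b_lo)
    raw <- raw * abs(b * log(2) * size)   # |d size / d row| per pixel
  }
  ord <- order(size)
  structure(list(lane_id = profile$lane_id,
                 membrane_id = profile$membrane_id, probe = profile$probe,
                 scale_id = scale$ladder_lane_id,
                 table = data.frame(size_kb = size[ord], raw = raw[ord],
                                    weight = NA_real_)),
            class = "tl_distribution")
}

#' Correct probe hybridization bias
#'
#' Longer telomeric fragments carry proportionally more repeat units and so
#' bind proportionally more probe; the raw smear intensity therefore
#' overweights long fragments. Dividing each intensity by its fragment
#' size, `w_i = I_i / L_i`, converts signal into (relative) fragment
#' number, the weighting under which distribution statistics are computed.
#'
#' @param dist a `tl_distribution`.
#' @return The distribution with `weight = raw / size_kb` filled in.
#' @export
normalize_by_size <- function(dist) {
  stopifnot(inherits(dist, "tl_distribution"))
  if (any(dist$table$size_kb <= 0)) stop("non-positive fragment size")
  dist$table$weight <- dist$table$raw / dist$table$size_kb
  dist
}

#' Discard the sub-cutoff region of a distribution
#'
#' Signal below 2 kb is dominated by genomic background, interstitial
#' telomeric sequences and the blow-up of the 1/L normalization, and is
#' discarded. The boundary is kept: entries with `size_kb >= min_kb`
#' survive.
#'
#' @param dist a `tl_distribution`.
#' @param min_kb truncation cutoff in kb, default 2.
#' @return The truncated distribution; attribute `n_removed` counts the
#'   dropped entries.
#' @export
truncate_low <- function(dist, min_kb = 2.0) {
  stopifnot(inherits(dist, "tl_distribution"))
  keep <- dist$table$size_kb >= min_kb
  if (!any(keep))
    stop("no signal above the ", min_kb, " kb cutoff in lane ",
         dist$lane_id)
  dist$table <- dist$table[keep, , drop = FALSE]
  rownames(dist$table) <- NULL
  attr(dist, "n_removed") <- sum(!keep)
  dist
}

weighted_step_quantile <- function(size, w, probs) {
  # smallest size whose cumulative normalized weight (ascending in size)
  # reaches the quantile; sizes assumed sorted ascending
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) size[which(cw >= p - 1e-12)[1]], numeric(1))
}

#' Summarize a telomere-length distribution
#'
#' Computes the five TL parameters describing location and shape of the
#' size-normalized distribution:
#' * mean TL `= sum(I_i) / sum(I_i / L_i)`, identically the weighted mean
#'   of size under the bias-corrected weights `w_i = I_i / L_i`;
#' * med, Q1, Q3: weighted quantiles at 0.5 / 0.25 / 0.75 under the step
#'   convention (smallest size whose cumulative normalized weight reaches
#'   the probability; no interpolation, so results are exact on the
#'   discrete pixel grid);
#' * IQ `= Q3 - Q1`, a spread/skewness descriptor.
#'
#' All five are invariant under positive rescaling of the raw intensities.
#'
#' @param dist a normalized, truncated `tl_distribution`.
#' @param qc_flags optional character vector of QC flags to attach.
#' @return A `tl_summary` with fields `mean_kb, med_kb, q1_kb, q3_kb,
#'   iq_kb, total_signal, total_weight, n_rows, qc_flags` plus lane
#'   metadata.
#' @export
summarize_distribution <- function(dist, qc_flags = character()) {
  stopifnot(inherits(dist, "tl_distribution"))
  tb <- dist$table
  if (anyNA(tb$weight))
    stop("distribution not normalized; call normalize_by_size() first")
  tw <- sum(tb$weight)
  if (tw <= 0) stop("zero total weight in lane ", dist$lane_id)
  q <- weighted_step_quantile(tb$size_kb, tb$weight, c(0.25, 0.5, 0.75))
  structure(list(lane_id = dist$lane_id, membrane_id = dist$membrane_id,
                 probe = dist$probe, scale_id = dist$scale_id,
                 mean_kb = sum(tb$raw) / tw,
                 med_kb = q[2], q1_kb = q[1], q3_kb = q[3],
                 iq_kb = q[3] - q[1],
                 total_signal = sum(tb$raw), total_weight = tw,
                 n_rows = nrow(tb), qc_flags = qc_flags),
            class = "tl_summary")
}

#' @export
print.tl_summary <- function(x, ...) {
  cat(sprintf(
    "<tl_summary lane '%s' (%s)> mean %.2f kb, med %.2f, Q1 %.2f, Q3 %.2f, IQ %.2f | n=%d%s\n",
    x$lane_id, x$probe, x$mean_kb, x$med_kb, x$q1_kb, x$q3_kb, x$iq_kb,
    x$n_rows,
    if (length(x$qc_flags)) paste0(" [", paste(x$qc_flags, collapse = ","),
                                   "]") else ""))
  invisible(x)
}

#' Quantify one sample lane
#'
#' Full per-lane pipeline, in order: background subtraction, pixel-to-size
#' conversion, size normalization (probe-bias correction), truncation below
#' `min_kb`, and distribution summary. Deterministic for fixed inputs.
#'
#' @param profile the raw (not background-subtracted) sample
#'   [lane_profile()].
#' @param scale the `piecewise_scale` assigned to this lane.
#' @param min_kb truncation cutoff, default 2 kb.
#' @param low_signal_threshold absolute background-subtracted total signal
#'   below which the `low_signal` QC flag is set (default 0; callers
#'   typically pass a fraction of the ladder lane total).
#' @param jacobian passed to [profile_to_distribution()].
#' @return A `tl_summary`.
#' @export
quantify_lane <- function(profile, scale, min_kb = 2.0,
                          low_signal_threshold = 0, jacobian = FALSE) {
  bg <- subtract_background(profile)
  flags <- character()
  if (sum(bg$intensity) < low_signal_threshold) flags <- c(flags, "low_signal")
  dist <- profile_to_distribution(bg, scale, jacobian = jacobian)
  dist <- normalize_by_size(dist)
  dist <- truncate_low(dist, min_kb = min_kb)
  summarize_distribution(dist, qc_flags = flags)
}

#' Lane quality control
#'
#' Two checks modeled after the membrane-level controls of a TRF
#' experiment: (i) the stripping control — a membrane re-exposed after
#' probe stripping should retain essentially no signal before re-probing,
#' summarized as the residual ratio (total after-strip signal over total
#' before-strip signal); (ii) a low-signal check on the
#' background-subtracted lane total, a configurable proxy for the
#' human-observer "no or poor signal" exclusion. The report never drops a
#' lane itself; exclusion is the caller's decision, and `observer_override`
#' records a manual verdict.
#'
#' @param before the lane profile before stripping (probed exposure).
#' @param after_strip the same lane imaged after stripping, or `NULL`.
#' @param strip_threshold maximum acceptable residual ratio (default 0.1).
#' @param low_signal_threshold minimum background-subtracted lane total.
#' @param observer_override optional "pass"/"fail" manual verdict.
#' @return A `qc_report` list with `residual_ratio`, `signal_total`,
#'   `low_signal`, `strip_fail`, `degraded` and `observer_override`.
#' @export
qc_lane <- function(before, after_strip = NULL, strip_threshold = 0.1,
                    low_signal_threshold = 0, observer_override = NA) {
  stopifnot(inherits(before, "lane_profile"))
  if (!is.null(after_strip)) {
    stopifnot(inherits(after_strip, "lane_profile"))
    if (length(after_strip$row) != length(before$row))
      stop("before/after-strip profiles have mismatched lengths")
    ratio <- sum(after_strip$intensity) / sum(before$intensity)
  } else {
    ratio <- 0
  }
  total <- sum(subtract_background(before)$intensity)
  structure(list(lane_id = before$lane_id,
                 residual_ratio = ratio,
                 signal_total = total,
                 low_signal = total < low_signal_threshold,
                 strip_fail = ratio > strip_threshold,
                 degraded = FALSE,
                 observer_override = observer_override),
            class = "qc_report")
}

#' Write TL summaries to CSV
#'
#' Header: `membrane_id,lane_id,probe,mean_kb,med_kb,q1_kb,q3_kb,iq_kb,
#' total_signal,n_rows,qc_flags` (flags `;`-separated).
#'
#' @param summaries list of `tl_summary` objects.
#' @param path CSV output path.
#' @return `path` invisibly.
#' @export
write_tl_summaries <- function(summaries, path) {
  df <- do.call(rbind, lapply(summaries, function(s)
    data.frame(membrane_id = s$membrane_id, lane_id = s$lane_id,
               probe = s$probe, mean_kb = s$mean_kb, med_kb = s$med_kb,
               q1_kb = s$q1_kb, q3_kb = s$q3_kb, iq_kb = s$iq_kb,
               total_signal = s$total_signal, n_rows = s$n_rows,
               qc_flags = paste(s$qc_flags, collapse = ";"))))
  if (is.null(df))
    df <- data.frame(membrane_id = character(), lane_id = character(),
                     probe = character(), mean_kb = numeric(),
                     med_kb = numeric(), q1_kb = numeric(),
                     q3_kb = numeric(), iq_kb = numeric(),
                     total_signal = numeric(), n_rows = integer(),
                     qc_flags = character())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
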