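#' Gel image and lane-profile input/output
#'
#' A `gel_image` holds the raw densitometry matrix of a Southern-blot gel or
#' phosphorimager scan: rows follow the migration axis with row 1 at the top
#' of the image (the gel-well side), columns follow the lateral axis. Values
#' are non-negative integer counts on the original bit-depth scale.
#'
#' @param data numeric matrix of non-negative intensities, at least 2x2.
#' @param bit_depth integer, 8 or 16.
#' @param image_id character scalar identifying the image.
#' @return An object of class `gel_image` with elements `data`, `bit_depth`
#'   and `image_id`.
#' @export
gel_image <- function(data, bit_depth = 16L, image_id = "image") {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix")
  if (nrow(data) < 2L || ncol(data) < 2L)
    stop("gel image must have at least 2 rows and 2 columns")
  if (any(!is.finite(data)) || any(data < 0))
    stop("gel image intensities must be finite and non-negative")
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  structure(list(data = data, bit_depth = as.integer(bit_depth),
                 image_id = as.character(image_id)),
            class = "gel_image")
}

#' @export
print.gel_image <- function(x, ...) {
  cat(sprintf("<gel_image '%s'> %d rows x %d cols, %d-bit, max %g\n",
              x$image_id, nrow(x$data), ncol(x$data), x$bit_depth,
              max(x$data)))
  invisible(x)
}

#' Read a grayscale gel image
#'
#' Reads an 8- or 16-bit grayscale TIFF or PNG into a [gel_image()]. Values
#' are returned on the native integer scale of the file (0..255 or 0..65535)
#' with the first matrix row corresponding to the top of the image.
#' Multi-channel (color) images are rejected: densitometry data is
#' single-channel and a silent channel choice would be ambiguous.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @param image_id identifier stored on the result; defaults to the file name.
#' @return A [gel_image()].
#' @export
read_gel_image <- function(path, image_id = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(img, "bits.per.sample")
    if (is.null(bits)) bits <- 16L
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    bits <- attr(img, "info")$bit.depth
    if (is.null(bits)) bits <- 8L
  } else {
    stop("unsupported image format: ", ext, " (expected TIFF or PNG)")
  }
  if (length(dim(img)) == 3L && dim(img)[3] > 1L)
    stop("multi-channel image: expected single-channel grayscale data")
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  scale <- 2^bits - 1
  m <- round(img * scale)
  attributes(m) <- list(dim = dim(m))
  gel_image(m, bit_depth = as.integer(bits),
            image_id = if (is.null(image_id)) basename(path) else image_id)
}

#' Write a gel image to disk
#'
#' Inverse of [read_gel_image()]: writes the integer intensity matrix as a
#' grayscale TIFF (8/16-bit, lossless) or PNG (8-bit).
#'
#' @param image a [gel_image()].
#' @param path output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_gel_image <- function(image, path) {
  stopifnot(inherits(image, "gel_image"))
  scale <- 2^image$bit_depth - 1
  if (max(image$data) > scale)
    stop("image values exceed the ", image$bit_depth, "-bit range")
  m <- image$data / scale
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m, path, bits.per.sample = image$bit_depth)
  } else if (ext == "png") {
    if (image$bit_depth != 8L)
      stop("PNG output supports 8-bit images only; use TIFF for 16-bit")
    png::writePNG(m, path)
  } else {
    stop("unsupported image format: ", ext)
  }
  invisible(path)
}

lane_roles <- c("ladder-left", "ladder-middle", "ladder-right", "sample")
lane_probes <- c("host", "symbiont", "none")

#' Define a lane region of interest
#'
#' Lanes are drawn manually on TRF membranes; an ROI names the column band a
#' lane occupies and (optionally) a row interval, e.g. starting below the gel
#' wells. All coordinates are 0-based, half-open `[start, end)`, row 0 being
#' the top (well side) of the image.
#'
#' @param lane_id,membrane_id character identifiers.
#' @param col_start,col_end lateral extent, 0-based half-open.
#' @param row_start,row_end migration-axis extent, 0-based half-open;
#'   `NA` means the full image height.
#' @param role one of `"ladder-left"`, `"ladder-middle"`, `"ladder-right"`,
#'   `"sample"`.
#' @param probe one of `"host"`, `"symbiont"`, `"none"` — the host probe is
#'   the (TTAGGG)n repeat, the algal symbiont probe (TTTAGGG)n.
#' @return A `lane_roi` object.
#' @export
lane_roi <- function(lane_id, col_start, col_end, row_start = NA,
                     row_end = NA, role = "sample", probe = "none",
                     membrane_id = "membrane") {
  if (col_end <= col_start) stop("empty column interval for lane ", lane_id)
  if (col_start < 0) stop("negative column start for lane ", lane_id)
  role <- match.arg(role, lane_roles)
  probe <- match.arg(probe, lane_probes)
  structure(list(lane_id = as.character(lane_id),
                 membrane_id = as.character(membrane_id),
                 col_start = as.integer(col_start),
                 col_end = as.integer(col_end),
                 row_start = if (is.na(row_start)) NA_integer_ else as.integer(row_start),
                 row_end = if (is.na(row_end)) NA_integer_ else as.integer(row_end),
                 role = role, probe = probe),
            class = "lane_roi")
}

#' Construct a lane intensity profile
#'
#' @param lane_id,membrane_id identifiers.
#' @param row integer vector of 0-based row indices, strictly increasing.
#' @param intensity non-negative intensities, same length as `row`.
#' @param role,probe lane annotations (see [lane_roi()]).
#' @return A `lane_profile` object.
#' @export
lane_profile <- function(lane_id, row, intensity, role = "sample",
                         probe = "none", membrane_id = "membrane") {
  if (length(row) != length(intensity))
    stop("`row` and `intensity` must have the same length")
  if (length(row) == 0L) stop("empty profile for lane ", lane_id)
  if (any(diff(row) <= 0)) stop("row indices must be strictly increasing")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be finite and non-negative")
  structure(list(lane_id = as.character(lane_id),
                 membrane_id = as.character(membrane_id),
                 row = as.integer(row), intensity = as.numeric(intensity),
                 role = match.arg(role, lane_roles),
                 probe = match.arg(probe, lane_probes)),
            class = "lane_profile")
}

#' @export
print.lane_profile <- function(x, ...) {
  cat(sprintf("<lane_profile '%s'> %s/%s, %d rows, total signal %g\n",
              x$lane_id, x$role, x$probe, length(x$row), sum(x$intensity)))
  invisible(x)
}

#' Extract a 1-D lane profile from a gel image
#'
#' Sums image intensity laterally across the ROI's columns at every row of
#' the ROI's row interval, the standard densitometry reduction of a lane to
#' a migration-axis trace. Downstream telomere statistics are invariant to
#' positive rescaling, so summation versus averaging is inconsequential.
#'
#' @param image a [gel_image()].
#' @param roi a [lane_roi()].
#' @return A [lane_profile()] carrying the ROI's annotations.
#' @export
extract_profile <- function(image, roi) {
  stopifnot(inherits(image, "gel_image"), inherits(roi, "lane_roi"))
  nr <- nrow(image$data); nc <- ncol(image$data)
  r0 <- if (is.na(roi$row_start)) 0L else roi$row_start
  r1 <- if (is.na(roi$row_end)) nr else roi$row_end
  if (roi$col_end > nc || r1 > nr || r0 < 0L)
    stop("ROI for lane ", roi$lane_id, " lies outside the image")
  if (r1 <= r0) stop("empty row interval for lane ", roi$lane_id)
  block <- image$data[(r0 + 1L):r1, (roi$col_start + 1L):roi$col_end,
                      drop = FALSE]
  lane_profile(roi$lane_id, row = r0:(r1 - 1L),
               intensity = rowSums(block), role = roi$role,
               probe = roi$probe, membrane_id = roi$membrane_id)
}

#' Read and write lane ROI tables
#'
#' CSV with header
#' `lane_id,membrane_id,col_start,col_end,row_start,row_end,role,probe`;
#' empty `row_start`/`row_end` mean the full image height.
#'
#' @param rois list of [lane_roi()] objects.
#' @param path CSV path.
#' @return `write_rois` returns `path` invisibly; `read_rois` a list of
#'   [lane_roi()] objects.
#' @export
write_rois <- function(rois, path) {
  df <- do.call(rbind, lapply(rois, function(r)
    data.frame(lane_id = r$lane_id, membrane_id = r$membrane_id,
               col_start = r$col_start, col_end = r$col_end,
               row_start = r$row_start, row_end = r$row_end,
               role = r$role, probe = r$probe)))
  if (is.null(df))
    df <- data.frame(lane_id = character(), membrane_id = character(),
                     col_start = integer(), col_end = integer(),
                     row_start = integer(), row_end = integer(),
                     role = character(), probe = character())
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lane_id", "membrane_id", "col_start", "col_end", "row_start",
            "row_end", "role", "probe")
  if (!all(need %in% names(df)))
    stop("ROI file missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    lane_roi(df$lane_id[i], df$col_start[i], df$col_end[i],
             row_start = if (is.na(df$row_start[i])) NA else df$row_start[i],
             row_end = if (is.na(df$row_end[i])) NA else df$row_end[i],
             role = df$role[i], probe = df$probe[i],
             membrane_id = df$membrane_id[i]))
}

#' Read and write lane profile tables
#'
#' Long-format CSV with header
#' `membrane_id,lane_id,role,probe,row,intensity`; one row per (lane, pixel
#' row). The roundtrip is lossless for all profile fields.
#'
#' @param profiles list of [lane_profile()] objects.
#' @param path CSV path.
#' @return `write_profiles` returns `path` invisibly; `read_profiles` a list
#'   of [lane_profile()] objects in file order.
#' @export
write_profiles <- function(profiles, path) {
  df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(membrane_id = p$membrane_id, lane_id = p$lane_id,
               role = p$role, probe = p$probe, row = p$row,
               intensity = p$intensity)))
  if (is.null(df))
    df <- data.frame(membrane_id = character(), lane_id = character(),
                     role = character(), probe = character(),
                     row = integer(), intensity = numeric())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("membrane_id", "lane_id", "role", "probe", "row", "intensity")
  if (!all(need %in% names(df)))
    stop("profile file missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (nrow(df) == 0L) return(list())
  if (any(df$intensity < 0))
    stop("negative intensity in profile file: ", path)
  key <- paste(df$membrane_id, df$lane_id, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(d) {
    d <- d[order(d$row), ]
    lane_profile(d$lane_id[1], d$row, d$intensity, role = d$role[1],
                 probe = d$probe[1], membrane_id = d$membrane_id[1])
  }) |> unname()
}
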