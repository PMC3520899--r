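#' Nuclear segmentation parameters
#'
#' Defaults give the simplest pipeline consistent with per-nucleus
#' high-content readouts: Gaussian smoothing (sigma 2 px), global Otsu
#' threshold, hole filling, 8-connected components, and an area filter of
#' 30-5000 px^2. Two guards reject degenerate Otsu thresholds on images
#' with no real objects (a global threshold on unimodal background noise
#' just splits the noise distribution): segmentation returns zero objects
#' when the foreground covers more than `max_fill` of the frame, or when
#' the foreground mean exceeds the background mean by fewer than
#' `min_separation` background SDs.
#'
#' @param smooth_sigma Gaussian smoothing sigma in px (0 disables).
#' @param threshold_method `"otsu"` (global, default) or `"fixed"`.
#' @param fixed_threshold threshold (a.u.) when `threshold_method="fixed"`.
#' @param min_area,max_area object area filter in px^2.
#' @param connectivity pixel connectivity, 4 or 8.
#' @param max_fill maximum admissible foreground fraction.
#' @param min_separation minimum foreground-background contrast, in units
#'   of the background SD (Otsu path only).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(smooth_sigma = 2,
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NA_real_,
                                min_area = 30, max_area = 5000,
                                connectivity = 8,
                                max_fill = 0.5,
                                min_separation = 4) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" && !is.finite(fixed_threshold))
    stop("configuration error: fixed_threshold must be finite")
  if (!(min_area > 0 && min_area < max_area))
    stop("configuration error: need 0 < min_area < max_area")
  if (!connectivity %in% c(4, 8))
    stop("configuration error: connectivity must be 4 or 8")
  structure(list(smooth_sigma = smooth_sigma,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_area = min_area, max_area = max_area,
                 connectivity = as.integer(connectivity),
                 max_fill = max_fill,
                 min_separation = min_separation),
            class = "segmentation_params")
}

# Connected-component labelling of a logical mask (4- or 8-connectivity)
# via a foreground-pixel adjacency graph.
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  n <- length(fg)
  lab <- matrix(0L, nr, nc)
  if (n == 0L) return(lab)
  id <- matrix(0L, nr, nc)
  id[fg] <- seq_len(n)
  offsets <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  ea <- integer(0); eb <- integer(0)
  for (o in offsets) {
    dr <- o[1]; dc <- o[2]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0L) seq_len(nc - dc) else seq.int(1L - dc, nc)
    a <- id[r1, c1, drop = FALSE]
    b <- id[r1 + dr, c1 + dc, drop = FALSE]
    keep <- a > 0L & b > 0L
    ea <- c(ea, a[keep]); eb <- c(eb, b[keep])
  }
  membership <- if (length(ea)) {
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, as.vector(rbind(ea, eb)))
    igraph::components(g)$membership
  } else seq_len(n)
  lab[fg] <- as.integer(membership)
  lab
}

empty_segmentation <- function(dims, threshold = NA_real_) {
  structure(list(labels = matrix(0L, dims[1], dims[2]),
                 nuclei = data.frame(nucleus = integer(0), row = numeric(0),
                                     col = numeric(0), area = numeric(0)),
                 threshold = threshold),
            class = "nucleus_segmentation")
}

#' Segment nuclei from a nuclear-stain channel
#'
#' Gaussian smooth, global threshold (Otsu by default), fill holes, label
#' connected components, filter by area. Returns a label matrix plus one
#' record per retained nucleus with 0-based centroid coordinates and area
#' in px^2. A constant image (or one where the threshold degenerates so
#' the foreground exceeds `max_fill`) yields zero nuclei, not an error.
#'
#' @param image 2-D numeric matrix of non-negative intensities.
#' @param params a [segmentation_params()].
#' @return Object of class `nucleus_segmentation`: `labels` (integer
#'   matrix, 0 = background), `nuclei` (data.frame `nucleus, row, col,
#'   area`), `threshold` (a.u. used).
#' @export
segment_nuclei <- function(image, params = segmentation_params()) {
  if (length(dim(image)) != 2L)
    stop("input error: image must be a 2-D matrix")
  img <- matrix(as.numeric(image), nrow(image), ncol(image))
  if (any(!is.finite(img)) || any(img < 0))
    stop("input error: intensities must be finite and >= 0")
  sm <- if (params$smooth_sigma > 0)
    EBImage::gblur(img, sigma = params$smooth_sigma) else img
  if (params$threshold_method == "fixed") {
    thr <- params$fixed_threshold
  } else {
    rg <- range(sm)
    if (diff(rg) == 0) return(empty_segmentation(dim(img)))
    thr <- EBImage::otsu(sm, range = rg, levels = 65536L)
  }
  mask <- sm > thr
  if (!any(mask) || mean(mask) > params$max_fill)
    return(empty_segmentation(dim(img), thr))
  if (params$threshold_method == "otsu") {
    bg <- sm[!mask]
    if (length(bg) > 1L &&
        mean(sm[mask]) - mean(bg) < params$min_separation * sd(bg))
      return(empty_segmentation(dim(img), thr))
  }
  mask <- EBImage::fillHull(mask) > 0
  lab <- label_components(mask, params$connectivity)
  sizes <- tabulate(lab)
  keep <- which(sizes >= params$min_area & sizes <= params$max_area)
  if (!length(keep)) return(empty_segmentation(dim(img), thr))

  # compact labels, ordered by first (top-left-most) pixel
  fg <- which(lab > 0L & matrix(lab %in% keep, nrow(lab), ncol(lab)))
  old_lab <- lab[fg]
  first_px <- tapply(fg, old_lab, min)
  new_of_old <- integer(max(keep))
  new_of_old[as.integer(names(first_px))[order(first_px)]] <-
    seq_along(first_px)
  lab2 <- matrix(0L, nrow(lab), ncol(lab))
  lab2[fg] <- new_of_old[old_lab]

  rc <- arrayInd(fg, dim(lab2))
  lab_vec <- lab2[fg]
  area <- as.numeric(tabulate(lab_vec))
  crow <- as.numeric(rowsum(rc[, 1], lab_vec)) / area - 1
  ccol <- as.numeric(rowsum(rc[, 2], lab_vec)) / area - 1
  structure(list(labels = lab2,
                 nuclei = data.frame(nucleus = seq_along(area),
                                     row = crow, col = ccol, area = area),
                 threshold = thr),
            class = "nucleus_segmentation")
}

#' Score per-nucleus mean marker intensity
#'
#' For each segmented nucleus, computes the arithmetic mean of the marker
#' channel's pixels under the nuclear mask.
#'
#' @param seg a [segment_nuclei()] result.
#' @param marker 2-D numeric matrix, same shape as the segmented channel.
#' @return The `nuclei` data.frame with a `marker_mean` column appended.
#' @export
score_marker <- function(seg, marker) {
  stopifnot(inherits(seg, "nucleus_segmentation"))
  if (!identical(dim(seg$labels), dim(marker)))
    stop("input error: marker image shape does not match segmentation")
  rec <- seg$nuclei
  rec$marker_mean <- numeric(nrow(rec))
  if (nrow(rec)) {
    fg <- seg$labels > 0L
    lv <- seg$labels[fg]
    sums <- rowsum(as.numeric(marker[fg]), lv)
    rec$marker_mean <- as.numeric(sums) / rec$area
  }
  rec
}

#' Calibrate the marker-positivity threshold from mock wells
#'
#' Untransduced (mock) wells define the null distribution of per-nucleus
#' marker means; the positivity threshold is its empirical `q`-quantile
#' (default 0.995). With fewer than `min_n_quantile` mock nuclei the
#' extreme quantile is unstable, and the threshold falls back to
#' mean + 3 SD.
#'
#' @param mock_means numeric vector of mock per-nucleus marker means.
#' @param q quantile used for the threshold.
#' @param min_n_quantile minimum mock nuclei for the quantile path.
#' @return A single threshold (a.u.).
#' @export
calibrate_marker_threshold <- function(mock_means, q = 0.995,
                                       min_n_quantile = 200L) {
  if (!length(mock_means))
    stop("calibration error: no mock nucleus intensities supplied")
  if (any(!is.finite(mock_means)))
    stop("calibration error: non-finite mock intensities")
  if (length(mock_means) < min_n_quantile) {
    s <- if (length(mock_means) > 1L) sd(mock_means) else 0
    mean(mock_means) + 3 * s
  } else {
    unname(quantile(mock_means, q))
  }
}

#' Per-well transduction rate from scored nuclei
#'
#' A nucleus is marker-positive when its mean marker intensity is
#' strictly greater than the calibrated threshold; the transduction rate
#' is positives over total nuclei. A well with no nuclei reports a
#' missing rate rather than 0.
#'
#' @param records a [score_marker()] result.
#' @param threshold positivity threshold (a.u.), finite.
#' @param well well identifier carried into the result.
#' @return List of class `well_image_result`: `result` (one-row
#'   data.frame `well, n_nuclei, n_positive, rate, threshold_used`) and
#'   `records` (per-nucleus table with `marker_positive` appended).
#' @export
transduction_rate <- function(records, threshold, well = NA_character_) {
  if (!is.finite(threshold))
    stop("input error: threshold must be finite")
  records$marker_positive <- records$marker_mean > threshold
  n <- nrow(records)
  pos <- sum(records$marker_positive)
  structure(list(result = data.frame(well = well,
                                     n_nuclei = n,
                                     n_positive = pos,
                                     rate = if (n > 0) pos / n else NA_real_,
                                     threshold_used = threshold),
                 records = records),
            class = "well_image_result")
}

#' Quantify one two-channel well image
#'
#' Convenience wrapper: segment the nuclear channel, score the marker
#' channel, and compute the transduction rate.
#'
#' @param channels named list of 2-D matrices containing
#'   `nuclear_channel` and `marker_channel`.
#' @param threshold marker-positivity threshold (a.u.).
#' @param nuclear_channel,marker_channel channel names.
#' @param params a [segmentation_params()].
#' @param well well identifier.
#' @return A [transduction_rate()] result.
#' @export
quantify_well <- function(channels, threshold,
                          nuclear_channel = "DAPI", marker_channel = "GFP",
                          params = segmentation_params(),
                          well = NA_character_) {
  if (!all(c(nuclear_channel, marker_channel) %in% names(channels)))
    stop("input error: channels must contain ", nuclear_channel,
         " and ", marker_channel)
  seg <- segment_nuclei(channels[[nuclear_channel]], params)
  rec <- score_marker(seg, channels[[marker_channel]])
  transduction_rate(rec, threshold, well = well)
}

#' Count live/dead objects in a three-channel Hoechst/PI/GFP well
#'
#' The Hoechst and PI channels are segmented independently (each with its
#' own object count); the GFP status of each Hoechst nucleus is scored as
#' mean GFP intensity under its mask versus `gfp_threshold`, giving the
#' proportion of GFP-positive cells in the Hoechst-stained population.
#' The GFP channel is also segmented for its own object count.
#'
#' @param hoechst,pi,gfp 2-D matrices of identical shape.
#' @param gfp_threshold GFP positivity threshold (a.u.).
#' @param params a [segmentation_params()] used for all three channels.
#' @param well well identifier.
#' @return One-row data.frame of class `livecell_result`: `well,
#'   hoechst_count, pi_count, gfp_count, gfp_fraction_of_hoechst`.
#' @export
count_live_dead <- function(hoechst, pi, gfp, gfp_threshold,
                            params = segmentation_params(),
                            well = NA_character_) {
  if (!identical(dim(hoechst), dim(pi)) || !identical(dim(hoechst), dim(gfp)))
    stop("input error: the three channels must share one shape")
  if (!is.finite(gfp_threshold))
    stop("input error: gfp_threshold must be finite")
  seg_h <- segment_nuclei(hoechst, params)
  seg_p <- segment_nuclei(pi, params)
  seg_g <- segment_nuclei(gfp, params)
  nh <- nrow(seg_h$nuclei)
  frac <- if (nh > 0) {
    rec <- score_marker(seg_h, gfp)
    mean(rec$marker_mean > gfp_threshold)
  } else NA_real_
  out <- data.frame(well = well,
                    hoechst_count = nh,
                    pi_count = nrow(seg_p$nuclei),
                    gfp_count = nrow(seg_g$nuclei),
                    gfp_fraction_of_hoechst = frac)
  class(out) <- c("livecell_result", class(out))
  out
}
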