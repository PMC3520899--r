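TITER_CATEGORIES <- c("excluded_low_dna", "undetected", "detected",
                      "sufficient", "high_tail")

#' Normalize plate-reader fluorescence on the mock-well mean
#'
#' Batch background varies between plates, so each plate is zeroed on the
#' mean raw fluorescence of its mock (no-plasmid) control wells:
#' `v_norm = fluor_raw - mean(mock)`. The per-plate mock mean and sample
#' SD (divisor n-1) are recorded; normalized mock wells average exactly 0
#' on every plate.
#'
#' @param plates data.frame with columns `plate_id`, `well`, `role`,
#'   `fluor_raw` (one or more plates; extra columns are carried through).
#' @return List of class `normalized_plates`:
#'   \describe{
#'     \item{wells}{the input table plus a `v_norm` column.}
#'     \item{mock_stats}{data.frame `plate_id, mock_mean, mock_sd, n_mock`.}
#'   }
#' @export
normalize_plates <- function(plates) {
  req <- c("plate_id", "well", "role", "fluor_raw")
  miss <- setdiff(req, names(plates))
  if (length(miss))
    stop("input error: missing columns: ", paste(miss, collapse = ", "))
  meas <- plates$role != "empty"
  bad <- meas & !is.finite(plates$fluor_raw)
  if (any(bad))
    stop("input error: non-finite fluorescence in well ",
         plates$plate_id[bad][1], ":", plates$well[bad][1])

  out <- plates
  out$v_norm <- NA_real_
  ids <- unique(plates$plate_id)
  stats <- data.frame(plate_id = ids, mock_mean = NA_real_,
                      mock_sd = NA_real_, n_mock = NA_integer_)
  for (i in seq_along(ids)) {
    sel <- plates$plate_id == ids[i]
    mocks <- plates$fluor_raw[sel & plates$role == "mock"]
    if (length(mocks) < 2L)
      stop("normalization error: plate ", ids[i],
           " has fewer than 2 mock wells")
    mu <- mean(mocks)
    out$v_norm[sel] <- plates$fluor_raw[sel] - mu
    stats$mock_mean[i] <- mu
    stats$mock_sd[i] <- sd(mocks)
    stats$n_mock[i] <- length(mocks)
  }
  structure(list(wells = out, mock_stats = stats),
            class = "normalized_plates")
}

#' @rdname normalize_plates
#' @export
normalize_plate <- function(plates) normalize_plates(plates)

#' Derive the titer classification thresholds from control wells
#'
#' The detection threshold is two standard deviations of the normalized
#' mock wells, pooled across all plates (sample SD, divisor n-1); the
#' sufficiency threshold is the minimum normalized fluorescence observed
#' over all empty-vector wells in the library. The tail and DNA cutoffs
#' default to the screen's operating values: high tail above 50,000 a.u.,
#' low tail below 3,000 a.u., DNA detectable above 20 ng/ul.
#'
#' @param norm a [normalize_plates()] result.
#' @param t_high,t_low,dna_min overrides of the tail and DNA cutoffs.
#' @param per_plate also compute per-plate detection thresholds
#'   (2 x per-plate mock SD) for diagnostics.
#' @return List of class `threshold_set` with `t_detect`, `t_pass`,
#'   `t_high`, `t_low`, `dna_min`, the pooled `mock_sd`, `n_mock`,
#'   `n_vector`, and (optionally) a `per_plate` table.
#' @export
compute_thresholds <- function(norm, t_high = 50000, t_low = 3000,
                               dna_min = 20, per_plate = FALSE) {
  stopifnot(inherits(norm, "normalized_plates"))
  if (t_low >= t_high)
    stop("threshold error: t_low must be below t_high")
  w <- norm$wells
  mocks <- w$v_norm[w$role == "mock"]
  vectors <- w$v_norm[w$role == "vector"]
  if (!length(vectors))
    stop("threshold error: no empty-vector wells found")
  pooled_sd <- if (length(mocks) > 1L) sd(mocks) else 0
  ts <- list(t_detect = 2 * pooled_sd,
             t_pass = min(vectors),
             t_high = t_high, t_low = t_low, dna_min = dna_min,
             mock_sd = pooled_sd,
             n_mock = length(mocks), n_vector = length(vectors))
  if (per_plate) {
    agg <- aggregate(v_norm ~ plate_id, data = w[w$role == "mock", ],
                     FUN = sd)
    names(agg)[2] <- "mock_sd"
    agg$t_detect <- 2 * agg$mock_sd
    ts$per_plate <- agg
  }
  structure(ts, class = "threshold_set")
}

#' Classify normalized well fluorescence into titer categories
#'
#' Applies the screen's category scheme with fixed precedence:
#' wells whose measured DNA concentration is below the detectable range
#' are excluded first; then fluorescence strictly above the high-tail
#' cutoff is `high_tail`; at or above the empty-vector minimum is
#' `sufficient`; at or above the detection threshold is `detected`;
#' anything lower is `undetected`. Wells with no DNA measurement are not
#' excluded. Independently, a well is flagged as a low-tail candidate if
#' it is not DNA-excluded and its fluorescence is strictly below the
#' low-tail cutoff.
#'
#' @param v numeric vector of normalized fluorescence (a.u.).
#' @param dna_ng_ul DNA concentrations (ng/ul), recycled; `NA` = not
#'   measured.
#' @param thresholds a [compute_thresholds()] result.
#' @return data.frame with `category` (factor over the five categories)
#'   and `low_tail_candidate` (logical).
#' @export
classify_titer <- function(v, dna_ng_ul = NA_real_, thresholds) {
  if (missing(thresholds) || !inherits(thresholds, "threshold_set"))
    stop("state error: thresholds must be computed before classification")
  if (any(!is.finite(v)))
    stop("input error: non-finite normalized fluorescence")
  dna <- rep_len(dna_ng_ul, length(v))
  excluded <- !is.na(dna) & dna < thresholds$dna_min
  category <- rep("undetected", length(v))
  category[v >= thresholds$t_detect] <- "detected"
  category[v >= thresholds$t_pass] <- "sufficient"
  category[v > thresholds$t_high] <- "high_tail"
  category[excluded] <- "excluded_low_dna"
  data.frame(category = factor(category, levels = TITER_CATEGORIES),
             low_tail_candidate = (v < thresholds$t_low) & !excluded)
}

#' Classify every sample well of a normalized plate set
#'
#' @param norm a [normalize_plates()] result whose wells carry
#'   `dna_ng_ul` (and optionally `gene_id`, `insert_bp`).
#' @param thresholds a [compute_thresholds()] result.
#' @return data.frame of sample wells with `v_norm`, `category` and
#'   `low_tail_candidate` columns appended.
#' @export
classify_wells <- function(norm, thresholds) {
  stopifnot(inherits(norm, "normalized_plates"))
  w <- norm$wells[norm$wells$role == "sample", , drop = FALSE]
  dna <- if ("dna_ng_ul" %in% names(w)) w$dna_ng_ul else NA_real_
  cls <- classify_titer(w$v_norm, dna, thresholds)
  w$category <- cls$category
  w$low_tail_candidate <- cls$low_tail_candidate
  rownames(w) <- NULL
  w
}

#' Library-level summary of classified sample wells
#'
#' Counts and fractions per titer category over sample wells, the number
#' of low-tail candidates, and insert-size QC (range and the count of
#' inserts above the size limit, beyond which fluorescence and insert
#' length are no longer unrelated).
#'
#' @param calls a [classify_wells()] result (may be empty).
#' @param insert_limit_bp insert-size QC limit in bp (default 3500).
#' @return List of class `library_summary`: `n_sample`,
#'   `category_counts` (data.frame `category, n, fraction`),
#'   `n_low_tail_candidates`, `insert_min`, `insert_max`,
#'   `n_insert_over_limit`, `frac_insert_over_limit`, `insert_limit_bp`.
#' @export
library_summary <- function(calls, insert_limit_bp = 3500) {
  n <- nrow(calls)
  counts <- if (n) table(calls$category) else
    table(factor(character(0), levels = TITER_CATEGORIES))
  cc <- data.frame(category = names(counts), n = as.integer(counts),
                   fraction = if (n) as.numeric(counts) / n else 0)
  ins <- if (n && "insert_bp" %in% names(calls))
    calls$insert_bp[!is.na(calls$insert_bp)] else numeric(0)
  n_over <- sum(ins > insert_limit_bp)
  structure(list(n_sample = n,
                 category_counts = cc,
                 n_low_tail_candidates = if (n) sum(calls$low_tail_candidate) else 0L,
                 insert_min = if (length(ins)) min(ins) else NA_real_,
                 insert_max = if (length(ins)) max(ins) else NA_real_,
                 n_insert_over_limit = n_over,
                 frac_insert_over_limit = if (length(ins)) n_over / length(ins) else NA_real_,
                 insert_limit_bp = insert_limit_bp),
            class = "library_summary")
}

#' Frequency histogram with half-open bins
#'
#' Bins are `[lo, hi)` with the last bin closed on the right, so every
#' value in range falls in exactly one bin and counts conserve `n`.
#'
#' @param values finite numeric vector.
#' @param bin_width positive bin width.
#' @param range optional `c(lo, hi)`; defaults to a bin-aligned cover of
#'   the data. All values must lie within it.
#' @return List of class `fluor_histogram` with `edges` (length
#'   `n_bins + 1`, strictly increasing) and `counts`.
#' @export
frequency_histogram <- function(values, bin_width, range = NULL) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("input error: bin_width must be a single positive number")
  if (any(!is.finite(values)))
    stop("input error: non-finite values in histogram input")
  if (is.null(range)) {
    lo <- if (length(values)) min(values) else 0
    n_bins <- if (length(values)) max(1L, ceiling((max(values) - lo) / bin_width)) else 1L
    if (length(values) && lo + n_bins * bin_width <= max(values))
      n_bins <- n_bins + 1L
  } else {
    lo <- range[1]
    n_bins <- max(1L, ceiling((range[2] - lo) / bin_width))
    if (length(values) && (min(values) < lo || max(values) > lo + n_bins * bin_width))
      stop("input error: values outside histogram range")
  }
  edges <- lo + bin_width * (0:n_bins)
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(edges = edges, counts = counts, bin_width = bin_width),
            class = "fluor_histogram")
}
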