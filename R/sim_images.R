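#' Configuration for the synthetic well-image generator
#'
#' Describes a single simulated microscopy well: frame size, nucleus count
#' and radii, the fraction of marker-positive nuclei, per-class marker
#' intensities, background and pixel noise, and (for the three-channel
#' live/dead mode) the dead-cell fraction.
#'
#' Nuclei are rendered as flat-core discs with a Gaussian edge falloff
#' (`edge_sigma`), placed without overlap by rejection sampling with a
#' minimum boundary gap of `min_gap` pixels, so segmentation ground truth
#' (centroid, rasterized area, class) is exact. Channels are quantized to
#' 16-bit unsigned integers.
#'
#' @param width,height frame size in pixels.
#' @param n_nuclei number of nuclei to place.
#' @param nucleus_radius_range length-2 numeric, uniform radius range (px).
#' @param marker_positive_fraction probability a nucleus is
#'   marker-positive (GFP/EdU transduced class).
#' @param neg_intensity,pos_intensity mean marker intensity (a.u.) added
#'   over a negative / positive nucleus.
#' @param nuclear_intensity amplitude (a.u.) of the nuclear-stain discs.
#' @param background additive background level (a.u.), all channels.
#' @param noise_sd SD (a.u.) of i.i.d. Gaussian pixel noise per channel.
#' @param edge_sigma Gaussian falloff scale (px) of disc edges.
#' @param min_gap minimum gap (px) between nucleus boundaries.
#' @param channel_set `"nuclear_marker"` (2-channel: nuclear stain +
#'   marker) or `"live_dead"` (3-channel Hoechst/PI/GFP).
#' @param dead_fraction probability a nucleus is dead (PI-positive);
#'   used by the 3-channel mode.
#' @param seed integer RNG seed; mandatory.
#' @return An object of class `image_sim_config`.
#' @export
image_sim_config <- function(width = 320L, height = 320L,
                             n_nuclei = 100L,
                             nucleus_radius_range = c(4, 6),
                             marker_positive_fraction = 0.6,
                             neg_intensity = 300,
                             pos_intensity = 8000,
                             nuclear_intensity = 20000,
                             background = 150,
                             noise_sd = 80,
                             edge_sigma = 1,
                             min_gap = 8,
                             channel_set = c("nuclear_marker", "live_dead"),
                             dead_fraction = 0,
                             seed) {
  if (missing(seed)) stop("'seed' is mandatory for the image generator")
  channel_set <- match.arg(channel_set)
  width <- as.integer(width); height <- as.integer(height)
  n_nuclei <- as.integer(n_nuclei)
  if (width < 8L || height < 8L) stop("configuration error: frame too small")
  if (n_nuclei < 0L) stop("configuration error: n_nuclei must be >= 0")
  r <- sort(as.numeric(nucleus_radius_range))
  if (length(r) != 2L || r[1] <= 0)
    stop("configuration error: nucleus_radius_range must be two positive values")
  fr <- c(marker_positive_fraction, dead_fraction)
  if (any(fr < 0 | fr > 1)) stop("configuration error: fractions must be in [0, 1]")
  ints <- c(neg_intensity, pos_intensity, nuclear_intensity, background)
  if (any(ints < 0)) stop("configuration error: intensities must be >= 0")
  if (noise_sd < 0) stop("configuration error: noise_sd must be >= 0")
  structure(list(width = width, height = height, n_nuclei = n_nuclei,
                 nucleus_radius_range = r,
                 marker_positive_fraction = marker_positive_fraction,
                 neg_intensity = neg_intensity, pos_intensity = pos_intensity,
                 nuclear_intensity = nuclear_intensity,
                 background = background, noise_sd = noise_sd,
                 edge_sigma = edge_sigma, min_gap = min_gap,
                 channel_set = channel_set, dead_fraction = dead_fraction,
                 seed = as.integer(seed)),
            class = "image_sim_config")
}

# Rejection-sampling placement of non-overlapping discs.
# Returns data.frame(row, col) of centres (1-based, fractional), or errors
# after a bounded number of attempts.
place_nuclei <- function(n, width, height, radii, min_gap, max_attempts = NULL) {
  if (n == 0L) return(data.frame(row = numeric(0), col = numeric(0)))
  if (is.null(max_attempts)) max_attempts <- 2000L * n
  rows <- numeric(n); cols <- numeric(n)
  attempts <- 0L
  for (i in seq_len(n)) {
    m <- radii[i] + 2
    if (2 * m >= min(width, height))
      stop("placement error: frame too small for nucleus radius")
    repeat {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("placement error: could not place ", n,
             " non-overlapping nuclei in a ", height, "x", width, " frame")
      r0 <- runif(1, m, height - m)
      c0 <- runif(1, m, width - m)
      if (i == 1L) break
      j <- seq_len(i - 1L)
      d <- sqrt((rows[j] - r0)^2 + (cols[j] - c0)^2)
      if (all(d >= radii[j] + radii[i] + min_gap)) break
    }
    rows[i] <- r0; cols[i] <- c0
  }
  data.frame(row = rows, col = cols)
}

# Adds a flat-core disc with Gaussian edge falloff to `canvas` and returns
# it together with the rasterized area (pixels with distance <= radius).
add_disc <- function(canvas, row, col, radius, amplitude, edge_sigma) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  ext <- ceiling(radius + 4 * edge_sigma)
  r_idx <- max(1L, floor(row - ext)):min(nr, ceiling(row + ext))
  c_idx <- max(1L, floor(col - ext)):min(nc, ceiling(col + ext))
  d <- sqrt(outer((r_idx - row)^2, (c_idx - col)^2, "+"))
  prof <- amplitude * exp(-pmax(d - radius, 0)^2 / (2 * edge_sigma^2))
  canvas[r_idx, c_idx] <- canvas[r_idx, c_idx] + prof
  list(canvas = canvas, area = sum(d <= radius))
}

quantize16 <- function(x) {
  storage.mode(x) <- "double"
  m <- matrix(as.integer(pmin(pmax(round(x), 0), 65535)), nrow(x), ncol(x))
  m
}

# Shared draw order (documented, relied on by stream-replay tests):
# radii, marker class, dead class, placement, then per-channel pixel noise.
simulate_nuclei <- function(config) {
  n <- config$n_nuclei
  rr <- config$nucleus_radius_range
  radii <- runif(n, rr[1], rr[2])
  marker_positive <- runif(n) < config$marker_positive_fraction
  dead <- runif(n) < config$dead_fraction
  centres <- place_nuclei(n, config$width, config$height, radii, config$min_gap)
  list(radii = radii, marker_positive = marker_positive, dead = dead,
       centres = centres)
}

render_channel <- function(config, nuc, which_nuclei, amplitudes) {
  canvas <- matrix(config$background, config$height, config$width)
  areas <- rep(NA_real_, config$n_nuclei)
  for (i in which_nuclei) {
    res <- add_disc(canvas, nuc$centres$row[i], nuc$centres$col[i],
                    nuc$radii[i], amplitudes[i], config$edge_sigma)
    canvas <- res$canvas
    areas[i] <- res$area
  }
  if (config$noise_sd > 0)
    canvas <- canvas + rnorm(length(canvas), 0, config$noise_sd)
  list(image = quantize16(canvas), areas = areas)
}

nucleus_truth <- function(nuc, areas) {
  n <- length(nuc$radii)
  data.frame(nucleus = seq_len(n),
             row = nuc$centres$row - 1,   # 0-based pixel coordinates
             col = nuc$centres$col - 1,
             radius = nuc$radii,
             area_px = areas,
             marker_positive = nuc$marker_positive,
             dead = nuc$dead)
}

#' Generate a two-channel well image (nuclear stain + marker) with truth
#'
#' Renders a nuclear-stain channel with one disc per nucleus and a marker
#' channel whose discs have class-dependent mean intensity
#' (`pos_intensity` for marker-positive nuclei, `neg_intensity`
#' otherwise), both over background plus Gaussian pixel noise. The truth
#' table records every nucleus with 0-based centroid, rasterized area and
#' true class.
#'
#' @param config an [image_sim_config()] with
#'   `channel_set = "nuclear_marker"`.
#' @param nuclear_channel,marker_channel channel labels used to name the
#'   output (e.g. DAPI/GFP or DAPI/EdU).
#' @return List of class `well_image_sim`: `channels` (named list of
#'   16-bit integer matrices), `truth` (data.frame), `config`.
#' @export
generate_well_image <- function(config, nuclear_channel = "DAPI",
                                marker_channel = "GFP") {
  stopifnot(inherits(config, "image_sim_config"))
  if (config$channel_set != "nuclear_marker")
    stop("generate_well_image requires channel_set = 'nuclear_marker'")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)

  nuc <- simulate_nuclei(config)
  all_idx <- seq_len(config$n_nuclei)
  nuclear <- render_channel(config, nuc, all_idx,
                            rep(config$nuclear_intensity, config$n_nuclei))
  marker_amp <- ifelse(nuc$marker_positive, config$pos_intensity,
                       config$neg_intensity)
  marker <- render_channel(config, nuc, all_idx, marker_amp)

  channels <- list(nuclear$image, marker$image)
  names(channels) <- c(nuclear_channel, marker_channel)
  structure(list(channels = channels,
                 truth = nucleus_truth(nuc, nuclear$areas),
                 config = config),
            class = "well_image_sim")
}

#' Generate a three-channel live/dead well image (Hoechst/PI/GFP) with truth
#'
#' The Hoechst channel carries a disc per nucleus; the PI channel carries
#' discs only at nuclei whose true class is dead; the GFP channel carries
#' discs only at marker-positive (transduced) nuclei. Dead and
#' marker-positive classes are drawn independently.
#'
#' @param config an [image_sim_config()] with `channel_set = "live_dead"`.
#' @return List of class `well_image_sim` with channels
#'   `Hoechst`, `PI`, `GFP` and the truth table.
#' @export
generate_livecell_image <- function(config) {
  stopifnot(inherits(config, "image_sim_config"))
  if (config$channel_set != "live_dead")
    stop("generate_livecell_image requires channel_set = 'live_dead'")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)

  nuc <- simulate_nuclei(config)
  n <- config$n_nuclei
  amp <- rep(config$nuclear_intensity, n)
  hoechst <- render_channel(config, nuc, seq_len(n), amp)
  pi_ch <- render_channel(config, nuc, which(nuc$dead), amp)
  gfp <- render_channel(config, nuc, which(nuc$marker_positive), amp)

  structure(list(channels = list(Hoechst = hoechst$image,
                                 PI = pi_ch$image,
                                 GFP = gfp$image),
                 truth = nucleus_truth(nuc, hoechst$areas),
                 config = config),
            class = "well_image_sim")
}
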