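# Shared fixtures and independent oracles used across the suite.

# Hand-built single-plate table: known mocks, vectors and samples.
tiny_plate <- function(mocks = c(100, 102, 98, 100),
                       vectors = c(700, 800, 900, 1000),
                       sample_raw = 600) {
  wl <- well_labels()
  roles <- rep("sample", 96)
  roles[wl %in% well_label(1:4, 12)] <- "vector"
  roles[wl %in% well_label(5:8, 12)] <- "mock"
  raw <- rep(sample_raw, 96)
  raw[roles == "mock"] <- mocks
  raw[roles == "vector"] <- vectors
  data.frame(plate_id = "P001", well = wl, role = roles, fluor_raw = raw,
             stringsAsFactors = FALSE)
}

# Threshold set built directly (white-box), for boundary-convention tests.
make_thresholds <- function(t_detect, t_pass, t_high = 50000, t_low = 3000,
                            dna_min = 20) {
  structure(list(t_detect = t_detect, t_pass = t_pass, t_high = t_high,
                 t_low = t_low, dna_min = dna_min,
                 mock_sd = t_detect / 2, n_mock = NA_integer_,
                 n_vector = NA_integer_),
            class = "threshold_set")
}

# Two-pass standard deviation oracle (explicit mean, then sum of squares).
two_pass_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# Brute-force per-nucleus mean oracle: explicit loop over label pixels.
pixel_loop_means <- function(labels, marker) {
  ids <- sort(unique(labels[labels > 0]))
  vapply(ids, function(id) {
    s <- 0; n <- 0L
    px <- which(labels == id)
    for (p in px) {
      s <- s + marker[p]
      n <- n + 1L
    }
    s / n
  }, numeric(1))
}

# Plate-mixture configuration whose components sit far from every
# threshold, so classification of observed values must agree with the
# truth labels exactly.
separated_plate_config <- function(seed, n_plates = 10) {
  plate_sim_config(
    n_plates = n_plates,
    background_mean = 1000, background_sd = 200,
    mock_noise_sd = 100,
    vector_mean = 6000, vector_sd = 100,
    component_fractions = c(failed = 0.02, low = 0.28,
                            typical = 0.60, high = 0.10),
    component_params = list(
      failed  = list(meanlog = 1, sdlog = 0.3, shift = 0),      # ~3 a.u.
      low     = list(meanlog = 7, sdlog = 0.1, shift = 1000),   # ~2.1k
      typical = list(meanlog = 8, sdlog = 0.2, shift = 8000),   # ~11k
      high    = list(meanlog = 8, sdlog = 0.3, shift = 60000)), # >50k
    dna_fail_fraction = 0.05,
    seed = seed)
}

# Expected category of a sample well from its true normalized value,
# replicating the classification scheme on the noise-free truth.
truth_category <- function(v_true, dna, thr) {
  if (!is.na(dna) && dna < thr$dna_min) return("excluded_low_dna")
  if (v_true > thr$t_high) return("high_tail")
  if (v_true >= thr$t_pass) return("sufficient")
  if (v_true >= thr$t_detect) return("detected")
  "undetected"
}

# Small well-image configuration for fast image tests.
small_image_config <- function(seed, n_nuclei = 40, frac = 0.5, ...) {
  image_sim_config(width = 192, height = 192, n_nuclei = n_nuclei,
                   marker_positive_fraction = frac, seed = seed, ...)
}
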