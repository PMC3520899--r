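#' Configuration for the synthetic plate-fluorescence generator
#'
#' Defines the statistical structure of a simulated arrayed lentiviral
#' library: per-plate batch background, mock-well noise, empty-vector
#' control fluorescence, and a four-component mixture
#' (failed / low / typical / high) for sample-well normalized GFP
#' fluorescence, together with expression-plasmid DNA concentrations and
#' predicted insert sizes.
#'
#' Defaults describe a 205-plate screen whose control column carries
#' 4 empty-vector and 4 mock wells per plate. The raw mock noise SD of
#' 1422 a.u. is chosen so that the pooled SD of plate-centred mock values
#' is near 1232 a.u. (centring on each plate's own 4-mock mean shrinks
#' the residual SD by sqrt(1 - 1/4)), which puts the two-SD detection
#' threshold near 2464 a.u. Empty-vector fluorescence is centred at
#' 12,420 a.u. with its library-wide
#' minimum near 4,000 a.u., about 95% of sample wells above detection and
#' about 90% above the empty-vector floor, a right-skewed log-normal bulk
#' reaching past 50,000 a.u., roughly 4% of inserts longer than 3500 bp,
#' and a small fraction of wells with sub-20 ng/ul DNA preps.
#'
#' @param n_plates number of 96-well plates.
#' @param background_mean,background_sd per-plate batch background
#'   fluorescence (a.u.): each plate draws one offset from this normal.
#' @param mock_noise_sd SD (a.u.) of mock-well fluorescence about the
#'   plate background.
#' @param vector_mean,vector_sd normal parameters (a.u.) of the
#'   empty-vector wells' true normalized fluorescence (truncated at 0).
#' @param component_fractions named probabilities over
#'   `c("failed","low","typical","high")`; must sum to 1.
#' @param component_params named list (same names) of
#'   `list(meanlog, sdlog, shift)` for shifted log-normal normalized
#'   fluorescence per component.
#' @param insert_meanlog,insert_sdlog log-normal parameters of predicted
#'   insert size (bp), clamped to the 75-13037 bp library range.
#' @param dna_mean,dna_sd normal parameters (ng/ul) of successful DNA
#'   preps (truncated at 20 ng/ul).
#' @param dna_fail_fraction probability a sample well's DNA prep fails,
#'   i.e. falls below the 20 ng/ul detectable range.
#' @param seed integer RNG seed; mandatory.
#' @return An object of class `plate_sim_config` (a validated list).
#' @export
plate_sim_config <- function(n_plates = 205L,
                             background_mean = 2000,
                             background_sd = 400,
                             mock_noise_sd = 1422,
                             vector_mean = 12420,
                             vector_sd = 2700,
                             component_fractions = c(failed = 0.030,
                                                     low = 0.050,
                                                     typical = 0.900,
                                                     high = 0.020),
                             component_params = list(
                               failed  = list(meanlog = 6.0, sdlog = 0.80, shift = 0),
                               low     = list(meanlog = 8.0, sdlog = 0.35, shift = 0),
                               typical = list(meanlog = 9.6, sdlog = 0.60, shift = 0),
                               high    = list(meanlog = 9.0, sdlog = 0.70, shift = 50000)),
                             insert_meanlog = 7.2,
                             insert_sdlog = 0.55,
                             dna_mean = 60,
                             dna_sd = 15,
                             dna_fail_fraction = 0.02,
                             seed) {
  if (missing(seed)) stop("'seed' is mandatory for the plate generator")
  seed <- as.integer(seed)
  n_plates <- as.integer(n_plates)
  if (n_plates < 1L) stop("configuration error: n_plates must be >= 1")
  sds <- c(background_sd, mock_noise_sd, vector_sd, dna_sd)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("configuration error: all SDs must be finite and >= 0")
  comp_names <- c("failed", "low", "typical", "high")
  if (!setequal(names(component_fractions), comp_names) ||
      !setequal(names(component_params), comp_names))
    stop("configuration error: components must be named failed/low/typical/high")
  component_fractions <- component_fractions[comp_names]
  component_params <- component_params[comp_names]
  if (any(component_fractions < 0) ||
      abs(sum(component_fractions) - 1) > 1e-12)
    stop("configuration error: component_fractions must be >= 0 and sum to 1")
  if (dna_fail_fraction < 0 || dna_fail_fraction > 1)
    stop("configuration error: dna_fail_fraction must be in [0, 1]")
  structure(list(n_plates = n_plates,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 mock_noise_sd = mock_noise_sd,
                 vector_mean = vector_mean,
                 vector_sd = vector_sd,
                 component_fractions = component_fractions,
                 component_params = component_params,
                 insert_meanlog = insert_meanlog,
                 insert_sdlog = insert_sdlog,
                 dna_mean = dna_mean,
                 dna_sd = dna_sd,
                 dna_fail_fraction = dna_fail_fraction,
                 seed = seed),
            class = "plate_sim_config")
}

# Control-column convention: column 12; rows A-D empty-vector, E-H mock.
control_column_roles <- function() {
  roles <- rep("sample", 96L)
  wl <- well_labels()
  roles[wl %in% well_label(1:4, 12L)] <- "vector"
  roles[wl %in% well_label(5:8, 12L)] <- "mock"
  roles
}

#' Generate a seeded synthetic plate set with ground truth
#'
#' Simulates raw plate-reader fluorescence for `n_plates` 96-well plates.
#' Each plate draws one batch background offset; its control column
#' (column 12) carries 4 empty-vector wells (rows A-D) and 4 mock wells
#' (rows E-H); the remaining 88 sample wells draw a mixture component and
#' a shifted log-normal true normalized fluorescence. Raw fluorescence is
#' plate background plus the true normalized value (mock wells: background
#' plus mock noise). Sample wells additionally get a gene ID, a predicted
#' insert size and a DNA prep concentration with a configured failure
#' fraction below 20 ng/ul.
#'
#' The full RNG stream derives from `config$seed`, so identical
#' configurations reproduce byte-identical tables.
#'
#' @param config a [plate_sim_config()].
#' @return A list of class `plate_sim` with elements
#'   \describe{
#'     \item{plates}{data.frame with columns `plate_id, well, role,
#'       gene_id, insert_bp, dna_ng_ul, fluor_raw` (96 rows per plate).}
#'     \item{truth}{data.frame with per-well `component` (mixture label,
#'       `NA` for controls), `v_true` (true normalized fluorescence,
#'       `NA` for mocks) and `background` (plate batch offset).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
generate_plate_set <- function(config) {
  stopifnot(inherits(config, "plate_sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)

  wl <- well_labels()
  roles <- control_column_roles()
  n_sample <- sum(roles == "sample")
  comp_names <- names(config$component_fractions)

  plates <- vector("list", config$n_plates)
  truths <- vector("list", config$n_plates)
  gene_counter <- 0L

  for (p in seq_len(config$n_plates)) {
    plate_id <- sprintf("P%03d", p)
    background <- rnorm(1L, config$background_mean, config$background_sd)

    # sample wells: mixture component, then true normalized value
    comp <- sample(comp_names, n_sample, replace = TRUE,
                   prob = config$component_fractions)
    v_sample <- numeric(n_sample)
    for (k in comp_names) {
      idx <- which(comp == k)
      if (!length(idx)) next
      pr <- config$component_params[[k]]
      v_sample[idx] <- pr$shift + rlnorm(length(idx), pr$meanlog, pr$sdlog)
    }
    # vector wells: truncated normal (> 0)
    v_vector <- rnorm(4L, config$vector_mean, config$vector_sd)
    while (any(v_vector <= 0))
      v_vector[v_vector <= 0] <- rnorm(sum(v_vector <= 0),
                                       config$vector_mean, config$vector_sd)
    mock_noise <- rnorm(4L, 0, config$mock_noise_sd)

    dna_failed <- runif(n_sample) < config$dna_fail_fraction
    dna <- pmax(rnorm(n_sample, config$dna_mean, config$dna_sd), 20)
    dna[dna_failed] <- runif(sum(dna_failed), 2, 18)
    insert_bp <- pmin(pmax(round(rlnorm(n_sample, config$insert_meanlog,
                                        config$insert_sdlog)), 75), 13037)

    gene_id <- rep(NA_character_, 96L)
    gene_id[roles == "sample"] <- sprintf("ORF%05d", gene_counter + seq_len(n_sample))
    gene_counter <- gene_counter + n_sample

    v_true <- rep(NA_real_, 96L)
    v_true[roles == "sample"] <- v_sample
    v_true[roles == "vector"] <- v_vector
    component <- rep(NA_character_, 96L)
    component[roles == "sample"] <- comp

    fluor_raw <- rep(NA_real_, 96L)
    fluor_raw[roles != "mock"] <- background + v_true[roles != "mock"]
    fluor_raw[roles == "mock"] <- background + mock_noise

    dna_col <- rep(NA_real_, 96L)
    dna_col[roles == "sample"] <- dna
    ins_col <- rep(NA_real_, 96L)
    ins_col[roles == "sample"] <- insert_bp

    plates[[p]] <- data.frame(plate_id = plate_id, well = wl, role = roles,
                              gene_id = gene_id, insert_bp = ins_col,
                              dna_ng_ul = dna_col, fluor_raw = fluor_raw,
                              stringsAsFactors = FALSE)
    truths[[p]] <- data.frame(plate_id = plate_id, well = wl, role = roles,
                              component = component, v_true = v_true,
                              background = background,
                              stringsAsFactors = FALSE)
  }
  structure(list(plates = do.call(rbind, plates),
                 truth = do.call(rbind, truths),
                 config = config),
            class = "plate_sim")
}
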