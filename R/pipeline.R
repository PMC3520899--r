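demo_seed <- function(seed, k) (as.integer(seed) + 7919L * as.integer(k)) %% 2147483647L

#' Run the full screen pipeline end-to-end on synthetic data
#'
#' Exercises every stage deterministically from one seed: simulate a
#' plate set, normalize on mock wells, derive thresholds, classify titer
#' categories, summarize the library; simulate mock and gene well images,
#' calibrate the marker threshold on mock nuclei, quantify per-well
#' transduction rates; compare low- vs high-titer gene groups with the
#' Aspin-Welch test; and count objects in one three-channel live/dead
#' well. All tables are written as CSV under `out_dir` together with the
#' resolved run configuration, and one image stack is persisted as a
#' 16-bit TIFF with its channel sidecar. The same seed reproduces
#' byte-identical outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed driving every stage.
#' @param n_plates plates to simulate.
#' @param n_genes_low,n_genes_high genes per titer group imaged.
#' @param wells_per_gene replicate wells per gene.
#' @param image_size frame edge (px) of simulated well images.
#' @param n_nuclei nuclei per simulated well image.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory results
#'   (`summary`, `thresholds`, `well_rates`, `comparison`, `livecell`,
#'   `files`).
#' @export
run_screen_demo <- function(out_dir, seed, n_plates = 6L,
                            n_genes_low = 6L, n_genes_high = 6L,
                            wells_per_gene = 4L,
                            image_size = 192L, n_nuclei = 40L,
                            quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  fp <- function(f) file.path(out_dir, f)

  ## 1. simulate plates
  say("simulating ", n_plates, " plates")
  pcfg <- plate_sim_config(n_plates = n_plates, seed = demo_seed(seed, 1L))
  sim <- generate_plate_set(pcfg)
  write_screen_csv(sim$plates, fp("plates.csv"))
  write_screen_csv(sim$truth, fp("plate_truth.csv"))

  ## 2. normalize + thresholds + classify + summarize
  norm <- normalize_plates(sim$plates)
  thr <- compute_thresholds(norm)
  calls <- classify_wells(norm, thr)
  summ <- library_summary(calls)
  write_screen_csv(norm$mock_stats, fp("mock_stats.csv"))
  write_screen_csv(calls, fp("classified_wells.csv"))
  write_screen_csv(summ$category_counts, fp("library_summary.csv"))
  say(sprintf("thresholds: detect %.0f, pass %.0f; %d/%d sample wells sufficient or above",
              thr$t_detect, thr$t_pass,
              sum(calls$category %in% c("sufficient", "high_tail")),
              summ$n_sample))

  ## 3. image quantification: mock calibration + gene wells
  say("quantifying well images")
  seg <- segmentation_params()
  mock_means <- numeric(0)
  for (i in 1:4) {
    icfg <- image_sim_config(width = image_size, height = image_size,
                             n_nuclei = n_nuclei,
                             marker_positive_fraction = 0,
                             seed = demo_seed(seed, 100L + i))
    img <- generate_well_image(icfg)
    s <- segment_nuclei(img$channels$DAPI, seg)
    mock_means <- c(mock_means, score_marker(s, img$channels$GFP)$marker_mean)
  }
  marker_thr <- calibrate_marker_threshold(mock_means)

  genes <- data.frame(
    gene_id = c(sprintf("LOW%02d", seq_len(n_genes_low)),
                sprintf("HIGH%02d", seq_len(n_genes_high))),
    group = rep(c("low", "high"), c(n_genes_low, n_genes_high)))
  # gene-specific true transduction fractions
  set.seed(demo_seed(seed, 2L))
  genes$true_p <- ifelse(genes$group == "low",
                         runif(nrow(genes), 0.02, 0.15),
                         runif(nrow(genes), 0.60, 0.95))
  rates <- vector("list", nrow(genes) * wells_per_gene)
  k <- 0L
  for (g in seq_len(nrow(genes))) {
    for (wll in seq_len(wells_per_gene)) {
      k <- k + 1L
      icfg <- image_sim_config(width = image_size, height = image_size,
                               n_nuclei = n_nuclei,
                               marker_positive_fraction = genes$true_p[g],
                               seed = demo_seed(seed, 1000L + k))
      img <- generate_well_image(icfg)
      q <- quantify_well(img$channels, marker_thr, params = seg,
                         well = sprintf("%s_w%d", genes$gene_id[g], wll))
      res <- q$result
      res$gene_id <- genes$gene_id[g]
      res$group <- genes$group[g]
      res$cell_line <- "demo"
      res$true_fraction <- genes$true_p[g]
      rates[[k]] <- res
    }
  }
  well_rates <- do.call(rbind, rates)
  write_screen_csv(well_rates, fp("well_rates.csv"))

  ## 4. group comparison (pooled wells, Aspin-Welch)
  vals <- data.frame(gene_id = well_rates$gene_id,
                     cell_line = well_rates$cell_line,
                     well = well_rates$well,
                     value = well_rates$rate)
  comparison <- compare_groups(vals, genes[, c("gene_id", "group")])
  gene_summ <- per_gene_summary(vals)
  write_screen_csv(comparison, fp("group_comparison.csv"))
  write_screen_csv(gene_summ, fp("gene_summaries.csv"))
  say(sprintf("low vs high titer: t = %.3f, df = %.1f, p = %.3g",
              comparison$t, comparison$df, comparison$p))

  ## 5. live/dead counting on one three-channel well
  lcfg <- image_sim_config(width = image_size, height = image_size,
                           n_nuclei = n_nuclei,
                           marker_positive_fraction = 0.6,
                           channel_set = "live_dead", dead_fraction = 0.25,
                           seed = demo_seed(seed, 3L))
  lc <- generate_livecell_image(lcfg)
  write_channel_stack(lc$channels, fp("livecell_demo.tif"))
  livecell <- count_live_dead(lc$channels$Hoechst, lc$channels$PI,
                              lc$channels$GFP, gfp_threshold = marker_thr,
                              params = seg, well = "livecell_demo")
  write_screen_csv(livecell, fp("livecell_counts.csv"))

  ## resolved run configuration and log
  write_run_config(list(package = "titerscreen",
                        version = as.character(packageVersion("titerscreen")),
                        seed = seed,
                        n_plates = n_plates,
                        n_genes_low = n_genes_low,
                        n_genes_high = n_genes_high,
                        wells_per_gene = wells_per_gene,
                        image_size = image_size,
                        n_nuclei = n_nuclei,
                        marker_threshold = marker_thr,
                        t_detect = thr$t_detect,
                        t_pass = thr$t_pass),
                   fp("run_config.txt"))

  invisible(list(summary = summ, thresholds = thr, calls = calls,
                 well_rates = well_rates, comparison = comparison,
                 gene_summaries = gene_summ, livecell = livecell,
                 marker_threshold = marker_thr,
                 files = list.files(out_dir, full.names = TRUE)))
}
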