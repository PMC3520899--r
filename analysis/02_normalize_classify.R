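#!/usr/bin/env Rscript

# Step 2 — normalize on mock wells, derive thresholds, classify titer.
#
# Zeroes each plate on its 4-mock mean, pools the normalized mock SD
# across plates for the detection threshold (2 SD), takes the
# empty-vector minimum as the sufficiency floor, classifies every sample
# well, and writes the classification, the library summary and the
# fluorescence frequency histogram under results/.
#
# Usage: Rscript analysis/02_normalize_classify.R   (after 01_simulate.R)

suppressMessages(library(titerscreen))

plates_csv <- "results/library/plates.csv"
if (!file.exists(plates_csv))
  stop("run analysis/01_simulate.R first (missing ", plates_csv, ")")
plates <- read_screen_csv(plates_csv)

norm <- normalize_plates(plates)
thr <- compute_thresholds(norm)
calls <- classify_wells(norm, thr)
summ <- library_summary(calls)

out <- "results"
write_screen_csv(norm$mock_stats, file.path(out, "mock_stats.csv"))
write_screen_csv(calls, file.path(out, "classified_wells.csv"))
write_screen_csv(summ$category_counts, file.path(out, "library_summary.csv"))
write_run_config(list(t_detect = thr$t_detect, t_pass = thr$t_pass,
                      t_high = thr$t_high, t_low = thr$t_low,
                      dna_min = thr$dna_min),
                 file.path(out, "thresholds.txt"))

hist_norm <- frequency_histogram(calls$v_norm, bin_width = 2500)
write_screen_csv(data.frame(bin_lo = head(hist_norm$edges, -1),
                            bin_hi = hist_norm$edges[-1],
                            n_wells = hist_norm$counts),
                 file.path(out, "fluorescence_histogram.csv"))

cat(sprintf("Detection threshold (2 x pooled mock SD): %.0f a.u.\n", thr$t_detect))
cat(sprintf("Sufficiency floor (empty-vector minimum): %.0f a.u.\n", thr$t_pass))
cat(sprintf("%.1f%% of sample wells above detection; %.1f%% above the vector floor.\n",
            100 * mean(calls$v_norm >= thr$t_detect),
            100 * mean(calls$v_norm >= thr$t_pass)))
cat(sprintf("%d wells flagged as low-tail candidates (< %.0f a.u., DNA in range);\n",
            summ$n_low_tail_candidates, thr$t_low))
cat(sprintf("%d inserts (%.1f%%) above 3500 bp.\n",
            summ$n_insert_over_limit, 100 * summ$frac_insert_over_limit))
print(summ$category_counts)
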