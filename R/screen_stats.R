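#' Summarize replicate wells per gene and cell line
#'
#' Computes mean and sample SD of the per-well values over non-excluded
#' replicates for every gene x cell-line combination. Exclusions (for
#' example clones that failed sequencing QC) are matched on `gene_id` and
#' `well` and recorded with their reasons. A single surviving replicate
#' reports a missing SD; a group with no survivors is flagged missing.
#'
#' @param values data.frame with columns `gene_id`, `cell_line`, `well`,
#'   `value` (finite).
#' @param exclusions optional data.frame `gene_id, well, reason`.
#' @return data.frame with one row per gene x cell line: `gene_id,
#'   cell_line, n_replicates, mean, sd, n_excluded, excluded_wells,
#'   excluded_reasons, missing`.
#' @export
per_gene_summary <- function(values, exclusions = NULL) {
  req <- c("gene_id", "cell_line", "well", "value")
  miss <- setdiff(req, names(values))
  if (length(miss))
    stop("input error: missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(values$value)))
    stop("input error: non-finite replicate values")
  excl_key <- character(0)
  if (!is.null(exclusions) && nrow(exclusions))
    excl_key <- paste(exclusions$gene_id, exclusions$well)
  values$.excluded <- paste(values$gene_id, values$well) %in% excl_key

  groups <- split(values, list(values$gene_id, values$cell_line), drop = TRUE)
  rows <- lapply(groups, function(g) {
    keep <- g[!g$.excluded, , drop = FALSE]
    exc <- g[g$.excluded, , drop = FALSE]
    reasons <- if (nrow(exc) && !is.null(exclusions)) {
      m <- match(paste(exc$gene_id, exc$well), excl_key)
      paste(exclusions$reason[m], collapse = "; ")
    } else ""
    n <- nrow(keep)
    data.frame(gene_id = g$gene_id[1], cell_line = g$cell_line[1],
               n_replicates = n,
               mean = if (n) mean(keep$value) else NA_real_,
               sd = if (n > 1) sd(keep$value) else NA_real_,
               n_excluded = nrow(exc),
               excluded_wells = paste(exc$well, collapse = "; "),
               excluded_reasons = reasons,
               missing = n == 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$cell_line, out$gene_id), , drop = FALSE]
}

#' Aspin-Welch unequal-variance two-sample test
#'
#' Location test for two groups without assuming equal variances:
#' \deqn{t = (m_1 - m_2) / \sqrt{s_1^2/n_1 + s_2^2/n_2}}
#' with Welch-Satterthwaite degrees of freedom
#' \deqn{\nu = (s_1^2/n_1 + s_2^2/n_2)^2 /
#'   [ (s_1^2/n_1)^2/(n_1-1) + (s_2^2/n_2)^2/(n_2-1) ]}
#' and a two-sided p-value from the t distribution. When both variances
#' are zero and the means are equal, t is defined as 0 with p = 1.
#'
#' @param x,y numeric vectors, each of length >= 2, finite, with at least
#'   one nonzero variance between them.
#' @param labels length-2 character, group names for reporting.
#' @return List of class `group_comparison`: `group1, group2, n1, n2,
#'   mean1, mean2, sd1, sd2, statistic, df, p.value`.
#' @export
welch_test <- function(x, y, labels = c("group1", "group2")) {
  if (length(x) < 2L || length(y) < 2L)
    stop("test error: each group needs at least 2 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("test error: non-finite values")
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 && v2 == 0) {
    if (m1 == m2) {
      t <- 0; df <- n1 + n2 - 2; p <- 1
    } else {
      stop("test error: both group variances are zero with unequal means")
    }
  } else {
    se2 <- v1 / n1 + v2 / n2
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * pt(-abs(t), df)
  }
  structure(list(group1 = labels[1], group2 = labels[2],
                 n1 = n1, n2 = n2, mean1 = m1, mean2 = m2,
                 sd1 = sqrt(v1), sd2 = sqrt(v2),
                 statistic = t, df = df, p.value = p),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Aspin-Welch comparison: %s (n=%d, mean=%.4g, sd=%.4g) vs %s (n=%d, mean=%.4g, sd=%.4g)\n",
              x$group1, x$n1, x$mean1, x$sd1,
              x$group2, x$n2, x$mean2, x$sd2))
  cat(sprintf("  t = %.4f, df = %.3f, two-sided p = %.4g\n",
              x$statistic, x$df, x$p.value))
  invisible(x)
}

#' Compare low- versus high-titer gene groups per cell line
#'
#' Pools the per-well values of each group within every cell line and
#' runs the Aspin-Welch test (low vs high, so t is negative when the low
#' group's mean is smaller). With `by_gene = TRUE`, per-gene means are
#' computed first and the test runs on gene-level means instead of
#' pooled wells.
#'
#' @param values data.frame `gene_id, cell_line, value` (a `well` column
#'   is allowed and ignored here).
#' @param groups data.frame `gene_id, group` with group in
#'   `c("low", "high")`.
#' @param by_gene aggregate replicate wells to gene means before testing.
#' @return data.frame, one row per cell line: `cell_line, n_low, n_high,
#'   mean_low, mean_high, sd_low, sd_high, t, df, p`.
#' @export
compare_groups <- function(values, groups, by_gene = FALSE) {
  req <- c("gene_id", "cell_line", "value")
  miss <- setdiff(req, names(values))
  if (length(miss))
    stop("input error: missing columns: ", paste(miss, collapse = ", "))
  if (!all(groups$group %in% c("low", "high")))
    stop("input error: groups must be 'low' or 'high'")
  values$group <- groups$group[match(values$gene_id, groups$gene_id)]
  values <- values[!is.na(values$group), , drop = FALSE]
  if (!nrow(values)) stop("input error: no wells matched the gene groups")

  rows <- lapply(split(values, values$cell_line), function(v) {
    cl <- v$cell_line[1]
    if (by_gene) {
      v <- aggregate(value ~ gene_id + group, data = v, FUN = mean)
      v$cell_line <- cl
    }
    lo <- v$value[v$group == "low"]
    hi <- v$value[v$group == "high"]
    if (length(lo) < 2L || length(hi) < 2L)
      stop("test error in cell line ", v$cell_line[1],
           ": each group needs at least 2 observations")
    w <- welch_test(lo, hi, labels = c("low", "high"))
    data.frame(cell_line = v$cell_line[1],
               n_low = w$n1, n_high = w$n2,
               mean_low = w$mean1, mean_high = w$mean2,
               sd_low = w$sd1, sd_high = w$sd2,
               t = w$statistic, df = w$df, p = w$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Packaged low/high titer gene table
#'
#' Returns the packaged table of genes that consistently produced very
#' low or very high viral titer in repeated supernatant production
#' (symbol, description, insert size, accession, titer group), used as a
#' fixture for group comparisons.
#'
#' @return data.frame with columns `titer, symbol, description, size_bp,
#'   accession`.
#' @export
titer_gene_table <- function() {
  path <- system.file("extdata", "table1_titer_genes.csv",
                      package = "titerscreen", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
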