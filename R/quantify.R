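# Tier filtering, RPM normalization, differential abundance and the
# direction / circ-linear summaries.

#' Assemble a count matrix from per-sample circRNA call tables
#'
#' Rows are the union of BSJ keys across samples; cells are junction-read
#' counts (0 where a junction was not called in a sample).  A parallel matrix
#' of non-junction (linear) reads is kept alongside, as is a per-sample
#' mappable-read total from the sample sheet.
#'
#' @param records Tibble of BSJ calls from [read_ciri_table()] (rows from all
#'   samples bound together).
#' @param sheet Sample sheet tibble (`sample_id`, `group`, `mappable_reads`).
#' @return An object of class `circ_counts`: list with `counts` and `linear`
#'   (integer matrices, circRNAs x samples), `mappable_reads` (named vector),
#'   `samples` (the sheet) and `features` (per-circRNA metadata tibble).
#' @export
build_count_matrix <- function(records, sheet) {
  assert_that(all(records$sample_id %in% sheet$sample_id),
              "records contain sample_ids absent from the sample sheet")
  samples <- sheet$sample_id
  records <- mutate(records,
                    key = circ_key(chrom, start, end, strand))
  features <- records |>
    group_by(key, circ_id, chrom, start, end, strand) |>
    summarise(reported_type = reported_type[1], gene_id = gene_id[1],
              intergenic_flag = intergenic_flag[1], .groups = "drop") |>
    arrange(chrom, start, end, strand)
  keys <- features$key
  counts <- matrix(0L, nrow = length(keys), ncol = length(samples),
                   dimnames = list(keys, samples))
  linear <- counts
  ij <- cbind(match(records$key, keys), match(records$sample_id, samples))
  counts[ij] <- records$junction_reads
  linear[ij] <- records$non_junction_reads
  structure(list(counts = counts, linear = linear,
                 mappable_reads = setNames(sheet$mappable_reads,
                                           sheet$sample_id),
                 samples = sheet, features = features),
            class = "circ_counts")
}

#' @export
print.circ_counts <- function(x, ...) {
  cat(sprintf("<circ_counts> %d circRNAs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Apply tiered read-support confidence filters
#'
#' Three independent per-circRNA predicates over the junction-read counts:
#' \describe{
#'   \item{tier1}{at least 2 junction reads in at least one sample.}
#'   \item{tier2}{present (count >= `presence_threshold`) in at least two
#'     samples AND total junction reads across samples >= 5 (the default,
#'     sum-based rule); with `tier2_rule = "per_sample"`, at least 5 junction
#'     reads in each of at least two samples.}
#'   \item{tier3}{present (count >= `presence_threshold`) in all or in all
#'     but one of the samples, regardless of read number.}
#' }
#' The tiers are deliberately not nested: tier 3 ignores read depth, so a
#' junction seen once in every sample is tier 3 but not tier 1.
#'
#' @param counts A `circ_counts` object or a bare counts matrix
#'   (circRNAs x samples).
#' @param presence_threshold Minimum count for a circRNA to be "present" in a
#'   sample (tiers 2 and 3); default 1.
#' @param tier2_rule `"sum"` (default) or `"per_sample"` (see above).
#' @return Tibble with `circ_key` and logical columns `tier1`, `tier2`,
#'   `tier3`.
#' @export
apply_tier_filters <- function(counts, presence_threshold = 1L,
                               tier2_rule = c("sum", "per_sample")) {
  tier2_rule <- match.arg(tier2_rule)
  m <- if (inherits(counts, "circ_counts")) counts$counts else as.matrix(counts)
  if (nrow(m) == 0) {
    return(tibble(circ_key = character(), tier1 = logical(),
                  tier2 = logical(), tier3 = logical()))
  }
  n_samples <- ncol(m)
  present <- m >= presence_threshold
  n_present <- rowSums(present)
  tier1 <- apply(m, 1, max) >= 2
  tier2 <- if (tier2_rule == "sum") {
    n_present >= 2 & rowSums(m) >= 5
  } else {
    rowSums(m >= 5) >= 2
  }
  tier3 <- n_present >= n_samples - 1
  tibble(circ_key = rownames(m) %||% as.character(seq_len(nrow(m))),
         tier1 = unname(tier1), tier2 = unname(tier2), tier3 = unname(tier3))
}

#' Reads-per-million normalization
#'
#' `rpm = count * 1e6 / mappable_reads`, applied per cell.  The same
#' transformation serves junction and non-junction (linear) counts.
#'
#' @param counts A `circ_counts` object or a counts matrix.
#' @param mappable_reads Per-sample mappable-read totals (named vector,
#'   required when `counts` is a bare matrix).
#' @return A numeric RPM matrix with the input's dimnames; for a
#'   `circ_counts` input, a list with `rpm` and `linear_rpm`.
#' @export
rpm_normalize <- function(counts, mappable_reads = NULL) {
  if (inherits(counts, "circ_counts")) {
    mr <- counts$mappable_reads[colnames(counts$counts)]
    return(list(rpm = rpm_normalize(counts$counts, mr),
                linear_rpm = rpm_normalize(counts$linear, mr)))
  }
  m <- as.matrix(counts)
  assert_that(!is.null(mappable_reads),
              "mappable_reads required for a bare matrix")
  mr <- if (!is.null(colnames(m)) && !is.null(names(mappable_reads)))
    mappable_reads[colnames(m)] else mappable_reads
  assert_that(length(mr) == ncol(m),
              "mappable_reads length (%d) != number of samples (%d)",
              length(mr), ncol(m))
  assert_that(all(mr > 0), "mappable_reads must be positive")
  sweep(m, 2, as.numeric(mr), function(x, s) x * 1e6 / s)
}

#' Two-group differential circRNA abundance
#'
#' Per circRNA: `log2fc = log2((mean_case + eps) / (mean_control + eps))` on
#' group-mean RPMs, and a two-tailed two-sample t-test on the per-sample RPM
#' values (Welch by default; pooled-variance Student via
#' `var_equal = TRUE`).  Direction is `up` when `log2fc >= lfc_threshold` and
#' `p < p_threshold`, `down` for the mirrored condition, else `none`.
#'
#' @param rpm RPM matrix (circRNAs x samples).
#' @param sheet Sample sheet with `sample_id` and `group` columns; both
#'   groups need >= 2 samples.
#' @param epsilon Pseudocount added to the group means for the fold change
#'   (RPM units); default 0.01.
#' @param var_equal Use pooled-variance Student's t instead of Welch.
#' @param log_transform Run the t-test on `log2(rpm + epsilon)` instead of
#'   raw RPM.
#' @param p_adjust Multiple-testing correction passed to [stats::p.adjust()]
#'   (default `"none"`: raw p-values with a fold-change threshold).
#' @param lfc_threshold,p_threshold Direction-call thresholds (defaults 1 and
#'   0.05).
#' @return Tibble: `circ_key`, `mean_rpm_case`, `mean_rpm_control`, `log2fc`,
#'   `p_value`, `direction`.
#' @export
differential_abundance <- function(rpm, sheet, epsilon = 0.01,
                                   var_equal = FALSE, log_transform = FALSE,
                                   p_adjust = "none", lfc_threshold = 1,
                                   p_threshold = 0.05) {
  rpm <- as.matrix(rpm)
  case_ids <- sheet$sample_id[sheet$group == "case"]
  ctrl_ids <- sheet$sample_id[sheet$group == "control"]
  for (g in list(c("case", length(case_ids)), c("control", length(ctrl_ids)))) {
    if (as.integer(g[2]) < 2) {
      stop_circkit("group '%s' has %s sample(s); >= 2 required", g[1], g[2])
    }
  }
  xs <- rpm[, case_ids, drop = FALSE]
  ys <- rpm[, ctrl_ids, drop = FALSE]
  test_in <- if (log_transform) {
    list(x = log2(xs + epsilon), y = log2(ys + epsilon))
  } else list(x = xs, y = ys)

  n <- nrow(rpm)
  p <- numeric(n)
  for (i in seq_len(n)) {
    x <- test_in$x[i, ]; y <- test_in$y[i, ]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      p[i] <- if (mean(x) == mean(y)) 1 else 0
    } else {
      p[i] <- t.test(x, y, var.equal = var_equal)$p.value
    }
  }
  p <- stats::p.adjust(p, method = p_adjust)
  mean_case <- rowMeans(xs)
  mean_ctrl <- rowMeans(ys)
  lfc <- ifelse(mean_case == mean_ctrl, 0,
                log2((mean_case + epsilon) / (mean_ctrl + epsilon)))
  direction <- rep("none", n)
  direction[lfc >= lfc_threshold & p < p_threshold] <- "up"
  direction[lfc <= -lfc_threshold & p < p_threshold] <- "down"
  tibble(circ_key = rownames(rpm) %||% as.character(seq_len(n)),
         mean_rpm_case = unname(mean_case),
         mean_rpm_control = unname(mean_ctrl),
         log2fc = unname(lfc), p_value = unname(p), direction = direction)
}

#' Summarize differential direction calls
#'
#' Counts up/down calls and the percentage upregulated.  With two result
#' collections, a Pearson chi-squared test (no continuity correction) on the
#' 2x2 collection-by-direction table; with one, a goodness-of-fit test
#' against a 50:50 up/down split.
#'
#' @param results Tibble from [differential_abundance()].
#' @param other Optional second tibble for the two-collection comparison.
#' @return List: `n_up`, `n_down`, `pct_up` (`NA` when nothing is
#'   significant), and `chisq`, `df`, `p_value` when a test was run.
#' @export
direction_summary <- function(results, other = NULL) {
  tally <- function(res) c(up = sum(res$direction == "up"),
                           down = sum(res$direction == "down"))
  a <- tally(results)
  out <- list(n_up = unname(a["up"]), n_down = unname(a["down"]),
              pct_up = if (sum(a) == 0) NA_real_ else
                unname(100 * a["up"] / sum(a)))
  if (is.null(other)) {
    if (sum(a) > 0) {
      ht <- suppressWarnings(chisq.test(a, p = c(0.5, 0.5)))
      out$chisq <- unname(ht$statistic)
      out$df <- unname(ht$parameter)
      out$p_value <- ht$p.value
    }
    return(out)
  }
  b <- tally(other)
  out$n_up_other <- unname(b["up"])
  out$n_down_other <- unname(b["down"])
  out$pct_up_other <- if (sum(b) == 0) NA_real_ else
    unname(100 * b["up"] / sum(b))
  if (sum(a) > 0 && sum(b) > 0) {
    ht <- suppressWarnings(chisq.test(rbind(a, b), correct = FALSE))
    out$chisq <- unname(ht$statistic)
    out$df <- unname(ht$parameter)
    out$p_value <- ht$p.value
  }
  out
}

#' Correlation between circular and linear host-transcript abundance
#'
#' Squared Pearson correlation (and least-squares slope) between paired mean
#' RPM vectors, one entry per circRNA.  Constant input yields a missing
#' result rather than an error.
#'
#' @param circ_rpm,linear_rpm Equal-length numeric vectors (>= 3 entries).
#' @return List with `r_squared` and `slope` (`NA` for degenerate input).
#' @export
circ_linear_correlation <- function(circ_rpm, linear_rpm) {
  assert_that(length(circ_rpm) == length(linear_rpm),
              "circ and linear vectors differ in length (%d vs %d)",
              length(circ_rpm), length(linear_rpm))
  assert_that(length(circ_rpm) >= 3, "need >= 3 paired values")
  if (stats::sd(circ_rpm) == 0 || stats::sd(linear_rpm) == 0) {
    return(list(r_squared = NA_real_, slope = NA_real_))
  }
  r <- stats::cor(circ_rpm, linear_rpm)
  list(r_squared = r^2,
       slope = r * stats::sd(linear_rpm) / stats::sd(circ_rpm))
}
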