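# End-to-end orchestration: read a dataset directory, run every analysis
# stage, write result tables and a summary report.

#' Pipeline parameters
#'
#' Thresholds and options for [run_pipeline()], with the package defaults:
#' tier-3 selection, Welch t-test on untransformed RPM, |log2FC| >= 1 and
#' p < 0.05 direction calls, RCM thresholds of 20 nt / 80% identity, 250-nt
#' motif windows.
#'
#' @param tier Analysis set: `"tier1"`, `"tier2"` or `"tier3"`.
#' @param tier2_rule `"sum"` or `"per_sample"` (see [apply_tier_filters()]).
#' @param presence_threshold Presence count for tiers 2/3.
#' @param epsilon Fold-change pseudocount (RPM).
#' @param var_equal,log_transform,p_adjust t-test options (see
#'   [differential_abundance()]).
#' @param lfc_threshold,p_threshold Direction-call thresholds.
#' @param rcm_min_len,rcm_min_ident RCM thresholds (nt, percent).
#' @param motif_window Intronic motif window (nt).
#' @param boundary_slop Exon-boundary matching tolerance (nt).
#' @param seed Seed for the pipeline's own sampling (control-intron
#'   subsampling).
#' @return A named list of parameters.
#' @export
pipeline_params <- function(tier = "tier3", tier2_rule = "sum",
                            presence_threshold = 1L, epsilon = 0.01,
                            var_equal = FALSE, log_transform = FALSE,
                            p_adjust = "none", lfc_threshold = 1,
                            p_threshold = 0.05, rcm_min_len = 20L,
                            rcm_min_ident = 80, motif_window = 250L,
                            boundary_slop = 0L, seed = 1L) {
  list(tier = tier, tier2_rule = tier2_rule,
       presence_threshold = presence_threshold, epsilon = epsilon,
       var_equal = var_equal, log_transform = log_transform,
       p_adjust = p_adjust, lfc_threshold = lfc_threshold,
       p_threshold = p_threshold, rcm_min_len = rcm_min_len,
       rcm_min_ident = rcm_min_ident, motif_window = motif_window,
       boundary_slop = boundary_slop, seed = seed)
}

#' Run the full circRNA analysis pipeline on a dataset directory
#'
#' Expects the layout written by [emit_dataset()] (and accepted from any
#' producer): `genome.fa`, `annotation.gtf`, `repeats.bed`, `samples.tsv`
#' and one `ciri_<sample_id>.tsv` per sample.  Stages: read all inputs,
#' build the count matrix, apply tier filters, RPM-normalize, exclude
#' intergenic calls, test differential abundance, classify structure,
#' summarize genes and isoforms, measure flanking-intron features, detect
#' RCMs, score splice sites and BSJ dinucleotides, and profile motifs.
#' All stage tables are written to `out_dir` together with `report.json`
#' and a human-readable `report.txt`.
#'
#' @param input_dir Dataset directory.
#' @param out_dir Output directory.
#' @param params [pipeline_params()].
#' @return Invisibly, the report (named list).
#' @export
run_pipeline <- function(input_dir, out_dir, params = pipeline_params()) {
  stage <- "read_inputs"
  report <- list()
  result <- tryCatch({
    sheet <- read_sample_sheet(file.path(input_dir, "samples.tsv"))
    records <- bind_rows(lapply(sheet$sample_id, function(s)
      read_ciri_table(file.path(input_dir, paste0("ciri_", s, ".tsv")), s)))
    models <- read_gene_models(file.path(input_dir, "annotation.gtf"))
    genome <- read_genome(file.path(input_dir, "genome.fa"))
    repeats <- read_repeat_annotation(file.path(input_dir, "repeats.bed"))

    stage <- "quantify"
    cm <- build_count_matrix(records, sheet)
    tiers <- apply_tier_filters(cm, params$presence_threshold,
                                params$tier2_rule)
    rpms <- rpm_normalize(cm)
    selected_keys <- tiers$circ_key[tiers[[params$tier]]]
    feats <- cm$features
    selected_keys <- setdiff(selected_keys,
                             feats$key[feats$intergenic_flag])
    sel <- feats[match(selected_keys, feats$key), ]
    report$n_samples <- nrow(sheet)
    report$n_circ_total <- nrow(feats)
    report$n_tier1 <- sum(tiers$tier1)
    report$n_tier2 <- sum(tiers$tier2)
    report$n_tier3 <- sum(tiers$tier3)
    report$n_excluded_intergenic <- sum(feats$intergenic_flag)
    report$n_selected <- length(selected_keys)
    assert_that(length(selected_keys) > 0,
                "no circRNAs pass the %s filter", params$tier)

    stage <- "differential"
    diff <- differential_abundance(
      rpms$rpm[selected_keys, , drop = FALSE], sheet,
      epsilon = params$epsilon, var_equal = params$var_equal,
      log_transform = params$log_transform, p_adjust = params$p_adjust,
      lfc_threshold = params$lfc_threshold, p_threshold = params$p_threshold)
    dsum <- direction_summary(diff)
    report$n_differential <- dsum$n_up + dsum$n_down
    report$n_up <- dsum$n_up
    report$n_down <- dsum$n_down
    report$pct_up <- dsum$pct_up
    report$chisq_vs_5050 <- dsum$chisq %||% NA_real_
    cl <- circ_linear_correlation(
      rowMeans(rpms$rpm[selected_keys, , drop = FALSE]),
      rowMeans(rpms$linear_rpm[selected_keys, , drop = FALSE]))
    report$circ_linear_r2 <- cl$r_squared

    stage <- "structure"
    calls <- classify_structure(sel, models,
                                boundary_slop = params$boundary_slop)
    report$category_counts <- as.list(table(calls$category))
    report$length_class_counts <- as.list(table(calls$length_class))
    lin_by_gene <- tibble(gene_id = sel$gene_id,
                          rpm = rowMeans(rpms$linear_rpm[selected_keys, ,
                                                         drop = FALSE])) |>
      filter(gene_id != "") |>
      group_by(gene_id) |>
      summarise(mean_linear_rpm = mean(rpm), .groups = "drop")
    gsum <- summarize_genes(calls, models, lin_by_gene)
    report$scg_pct <- gsum$scg_pct
    report$mcg_pct <- gsum$mcg_pct
    report$r2_circ_count_vs_gene_length <- gsum$r2_length
    report$r2_circ_count_vs_expression <- gsum$r2_expression
    isoforms <- group_isoforms(calls)
    report$n_isoform_groups <- length(unique(isoforms$group_id))

    stage <- "locus_features"
    flanks <- extract_flanking_introns(sel, models)
    other_pool <- unlist(flanks$other_lengths)
    icomp <- compare_intron_features(flanks$up_length, flanks$down_length,
                                     other_pool, seed = params$seed)
    report$mean_up_intron <- icomp$mean_up
    report$mean_down_intron <- icomp$mean_down
    report$mean_other_intron <- icomp$mean_other
    report$p_up_vs_other <- icomp$p_up_vs_other
    report$p_down_vs_other <- icomp$p_down_vs_other

    rcm_rows <- list()
    for (i in seq_len(nrow(flanks))) {
      ctx <- c(as.list(flanks[i, ]), chrom = sel$chrom[i])
      hits <- find_rcms(ctx, repeats, genome,
                        min_len = params$rcm_min_len,
                        min_ident = params$rcm_min_ident)
      if (nrow(hits) > 0) {
        hits$circ_key <- flanks$circ_key[i]
        rcm_rows[[length(rcm_rows) + 1L]] <- hits
      }
    }
    rcms <- if (length(rcm_rows)) bind_rows(rcm_rows) else
      tibble(up_start = integer(), up_end = integer(),
             down_start = integer(), down_end = integer(),
             aln_length = integer(), identity = numeric(), score = numeric(),
             circ_key = character())
    report$n_rcm_pairs <- nrow(rcms)
    report$n_circ_with_rcm <- length(unique(rcms$circ_key))

    scorer <- build_pwm_scorer(models, genome)
    scores <- score_splice_sites(sel, genome, scorer)
    report$mean_donor_score <- mean(scores$donor_score, na.rm = TRUE)
    report$mean_acceptor_score <- mean(scores$acceptor_score, na.rm = TRUE)
    sites <- classify_bsj_sites(sel, models, genome)
    dinuc <- dinucleotide_frequency(sites)
    report$pct_canonical <- 100 * mean(sites$canonical)
    lab <- c(sites$start_label, sites$end_label)
    report$n_annotated_ends <- sum(lab == "annotated")
    report$n_ie_ends <- sum(lab == "ie_bsj")
    report$n_ii_ends <- sum(lab == "ii_bsj")

    stage <- "motifs"
    exonic <- sel[calls$category == "exonic", , drop = FALSE]
    profiles <- if (nrow(exonic) > 0) {
      profile_regions(exonic, models, genome, window = params$motif_window)
    } else {
      profile_regions(sel[0, ], models, genome, window = params$motif_window)
    }
    msum <- profiles |>
      group_by(motif_set, region) |>
      summarise(total = sum(count), .groups = "drop")
    report$motif_totals <- split(setNames(msum$total, msum$region),
                                 msum$motif_set)

    stage <- "write_outputs"
    write_result_tables(list(
      tiers = tiers, differential = diff,
      structure = calls, gene_summary = gsum$genes, isoform_groups = isoforms,
      flanking_introns = flanks[, setdiff(names(flanks), "other_lengths")],
      rcm_pairs = rcms, splice_scores = scores, bsj_sites = sites,
      dinucleotide_freq = dinuc, motif_profiles = profiles), out_dir)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(format_report(report, params), file.path(out_dir, "report.txt"))
    report
  }, error = function(e) {
    stop_circkit("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e), class = "circkit_pipeline_error")
  })
  invisible(result)
}

format_report <- function(r, params) {
  fmt <- function(x) if (is.numeric(x)) sprintf("%.4f", x) else
    as.character(x)
  lines <- c(
    "circkit pipeline report",
    "=======================",
    sprintf("samples: %d   circRNAs: %d", r$n_samples, r$n_circ_total),
    sprintf("tier counts: tier1=%d tier2=%d tier3=%d (analysis set: %s, %d after intergenic exclusion)",
            r$n_tier1, r$n_tier2, r$n_tier3, params$tier, r$n_selected),
    sprintf("differential: %d (up=%d down=%d, pct_up=%s) at |log2FC|>=%s, p<%s",
            r$n_differential, r$n_up, r$n_down, fmt(r$pct_up),
            fmt(params$lfc_threshold), fmt(params$p_threshold)),
    sprintf("circ-linear R2: %s", fmt(r$circ_linear_r2)),
    sprintf("categories: %s",
            paste(sprintf("%s=%d", names(r$category_counts),
                          unlist(r$category_counts)), collapse = " ")),
    sprintf("length classes: %s",
            paste(sprintf("%s=%d", names(r$length_class_counts),
                          unlist(r$length_class_counts)), collapse = " ")),
    sprintf("genes: SCG %s%% / MCG %s%%; R2(count~length)=%s R2(count~expr)=%s",
            fmt(r$scg_pct), fmt(r$mcg_pct),
            fmt(r$r2_circ_count_vs_gene_length),
            fmt(r$r2_circ_count_vs_expression)),
    sprintf("flanking introns: up=%s down=%s other=%s (p up/other=%s, down/other=%s)",
            fmt(r$mean_up_intron), fmt(r$mean_down_intron),
            fmt(r$mean_other_intron), fmt(r$p_up_vs_other),
            fmt(r$p_down_vs_other)),
    sprintf("RCMs: %d pairs over %d circRNAs (>=%d nt, >=%s%% identity)",
            r$n_rcm_pairs, r$n_circ_with_rcm, params$rcm_min_len,
            fmt(params$rcm_min_ident)),
    sprintf("splice sites: mean donor=%s mean acceptor=%s; canonical GT/AG %s%%",
            fmt(r$mean_donor_score), fmt(r$mean_acceptor_score),
            fmt(r$pct_canonical)),
    sprintf("BSJ ends: annotated=%d ie=%d ii=%d",
            r$n_annotated_ends, r$n_ie_ends, r$n_ii_ends),
    "motif totals:")
  for (ms in names(r$motif_totals)) {
    v <- r$motif_totals[[ms]]
    lines <- c(lines, sprintf("  %s: %s", ms,
                              paste(sprintf("%s=%d", names(v), v),
                                    collapse = " ")))
  }
  lines
}

#' Simulate a dataset and run the full pipeline on it
#'
#' Convenience wrapper: [simulate_dataset()], [emit_dataset()] into
#' `<out_dir>/dataset`, then [run_pipeline()] into `<out_dir>/results`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param params [pipeline_params()].
#' @return Invisibly, the pipeline report.
#' @export
run_all <- function(config = sim_config(), out_dir,
                    params = pipeline_params(seed = config$seed)) {
  sim <- simulate_dataset(config)
  emit_dataset(sim, file.path(out_dir, "dataset"))
  run_pipeline(file.path(out_dir, "dataset"),
               file.path(out_dir, "results"), params)
}
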