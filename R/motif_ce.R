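# Splicing-factor binding-motif profiling around circularized exons and the
# single-exon circRNA vs cassette-exon comparison.

#' Define a motif set
#'
#' Patterns are over the A/C/G/U (or T) alphabet; the IUPAC code Y expands
#' to C or U/T.  Counting is by overlapping sliding-window occurrences; N in
#' the scanned sequence never matches.
#'
#' @param name Set name (e.g. `"MBNL1"`).
#' @param patterns Character vector of patterns.
#' @param mode `"overlap"` (count overlapping occurrences of each pattern)
#'   or `"runs"` (count maximal `(UG)n` runs with `n >= run_min`; for UG-rich
#'   sets).
#' @param run_min Minimum dinucleotide repeat count in `"runs"` mode.
#' @return A `motif_set` object.
#' @export
motif_set <- function(name, patterns, mode = c("overlap", "runs"),
                      run_min = 3L) {
  mode <- match.arg(mode)
  assert_that(length(patterns) > 0, "patterns must be nonempty")
  structure(list(name = name, patterns = toupper(patterns), mode = mode,
                 run_min = run_min), class = "motif_set")
}

#' Default MBNL1 motif set: YGCY 4-mers plus the UGCUU and GCUGC 5-mers
#' @return A `motif_set`.
#' @export
mbnl1_motifs <- function() {
  motif_set("MBNL1", c("YGCY", "UGCUU", "GCUGC"))
}

#' Default CUGBP1 UG-rich motif set: overlapping UGUG occurrences
#' @param mode `"overlap"` (default) or `"runs"` (maximal (UG)n runs,
#'   n >= 3).
#' @return A `motif_set`.
#' @export
cugbp1_motifs <- function(mode = "overlap") {
  motif_set("CUGBP1", "UGUG", mode = mode)
}

# DNA-alphabet regex for a pattern: U -> T, Y -> [CT].
pattern_regex <- function(pattern) {
  p <- gsub("U", "T", toupper(pattern))
  gsub("Y", "[CT]", p, fixed = TRUE)
}

#' Count motif occurrences in a sequence
#'
#' Overlapping occurrences of each pattern (or maximal UG-run count in
#' `"runs"` mode).  The sequence may be DNA or RNA; U and T are equivalent.
#'
#' @param sequence A character scalar over A/C/G/T/U/N.
#' @param motifs A [motif_set()].
#' @return Named integer vector of per-pattern counts plus a `total`
#'   element.
#' @export
count_motifs <- function(sequence, motifs) {
  assert_that(inherits(motifs, "motif_set"), "motifs must be a motif_set")
  seq_dna <- gsub("U", "T", toupper(sequence %||% ""))
  if (is.na(seq_dna) || nchar(seq_dna) == 0) {
    counts <- setNames(rep(0L, length(motifs$patterns)), motifs$patterns)
    return(c(counts, total = 0L))
  }
  if (motifs$mode == "runs") {
    # maximal (UG)n runs, n >= run_min
    rx <- sprintf("(TG){%d,}", motifs$run_min)
    hits <- gregexpr(rx, seq_dna, perl = TRUE)[[1]]
    n <- if (hits[1] == -1) 0L else length(hits)
    return(setNames(c(n, n), c(motifs$patterns[1], "total")))
  }
  counts <- vapply(motifs$patterns, function(p) {
    rx <- sprintf("(?=%s)", pattern_regex(p))  # lookahead: overlapping hits
    hits <- gregexpr(rx, seq_dna, perl = TRUE)[[1]]
    if (hits[1] == -1) 0L else length(hits)
  }, integer(1))
  c(counts, total = sum(counts))
}

#' Motif profiles around circularized exons
#'
#' For each circRNA, three transcript-orientation regions are scanned: the
#' circularized exon(s) themselves (`exon_body`), and windows of `window` nt
#' into the upstream and downstream flanking introns (`upstream_250`,
#' `downstream_250` at the default window).  A window longer than its
#' flanking intron is truncated and flagged.
#'
#' @param circs Tibble with `chrom`, `start`, `end`, `strand`, optional
#'   `gene_id`.
#' @param models A `gene_models` object.
#' @param genome A `genome_seq` object.
#' @param motif_sets List of [motif_set()]s.
#' @param window Intronic window size (nt), default 250.
#' @return Tibble: `circ_key`, `region`, `motif_set`, `count`, `truncated`.
#' @export
profile_regions <- function(circs, models, genome, motif_sets =
                              list(mbnl1_motifs(), cugbp1_motifs()),
                            window = 250L) {
  circs <- as_tibble(circs)
  flanks <- extract_flanking_introns(circs, models)
  rows <- list()
  for (i in seq_len(nrow(circs))) {
    chrom <- circs$chrom[i]; s <- circs$start[i]; e <- circs$end[i]
    strand <- circs$strand[i]; plus <- strand == "+"
    fl <- flanks[i, ]
    regions <- list(exon_body = list(iv = c(s, e), trunc = FALSE))
    if (window > 0) {
      if (!is.na(fl$up_start)) {
        avail <- min(window, fl$up_length)
        iv <- if (plus) c(s - avail, s - 1L) else c(e + 1L, e + avail)
        regions$upstream_250 <- list(iv = iv, trunc = avail < window)
      }
      if (!is.na(fl$down_start)) {
        avail <- min(window, fl$down_length)
        iv <- if (plus) c(e + 1L, e + avail) else c(s - avail, s - 1L)
        regions$downstream_250 <- list(iv = iv, trunc = avail < window)
      }
    }
    key <- circ_key(chrom, s, e, strand)
    for (rn in names(regions)) {
      rg <- regions[[rn]]
      seqs <- safe_get_seq(genome, chrom, rg$iv[1], rg$iv[2], strand)
      for (ms in motif_sets) {
        cnt <- count_motifs(seqs, ms)
        rows[[length(rows) + 1L]] <- tibble(
          circ_key = key, region = rn, motif_set = ms$name,
          count = unname(cnt["total"]), truncated = rg$trunc)
      }
    }
  }
  if (length(rows)) bind_rows(rows) else
    tibble(circ_key = character(), region = character(),
           motif_set = character(), count = integer(), truncated = logical())
}

#' Compare single-exon circRNAs with cassette exons
#'
#' Single-exon circRNAs (BSJ coordinates exactly matching one annotated
#' exon) are compared with a supplied cassette-exon table on exon length,
#' flanking intron lengths and splice-site strength, using two-tailed
#' pooled-variance Student t-tests per feature.  The number of exons shared
#' between the two sets (exact coordinates) is also reported.
#'
#' @param se_circs Tibble of single-exon circRNA records (`chrom`, `start`,
#'   `end`, `strand`, optional `gene_id`).
#' @param ces Cassette-exon tibble: `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, optional `psi`.
#' @param models A `gene_models` object.
#' @param genome A `genome_seq` object.
#' @param scorer A `splice_scorer`.
#' @return List: `features` (long tibble of per-entry feature values),
#'   `tests` (tibble: feature, group means, p-value), `overlap_count`.
#' @export
compare_se_vs_ce <- function(se_circs, ces, models, genome, scorer) {
  se_circs <- as_tibble(se_circs); ces <- as_tibble(ces)
  assert_that(nrow(se_circs) > 0 && nrow(ces) > 0,
              "both collections must be nonempty")
  feat_of <- function(df, group) {
    fl <- extract_flanking_introns(df, models)
    sc <- score_splice_sites(df, genome, scorer)
    tibble(group = group,
           key = circ_key(df$chrom, df$start, df$end, df$strand),
           exon_length = as.numeric(df$end - df$start + 1L),
           up_intron_length = as.numeric(fl$up_length),
           down_intron_length = as.numeric(fl$down_length),
           donor_score = sc$donor_score, acceptor_score = sc$acceptor_score)
  }
  se <- feat_of(se_circs, "se_circ")
  ce <- feat_of(ces, "cassette_exon")
  features <- bind_rows(se, ce)
  test_rows <- lapply(
    c("exon_length", "up_intron_length", "down_intron_length",
      "donor_score", "acceptor_score"),
    function(f) {
      x <- se[[f]][!is.na(se[[f]])]
      y <- ce[[f]][!is.na(ce[[f]])]
      tibble(feature = f, mean_se = mean(x), mean_ce = mean(y),
             n_se = length(x), n_ce = length(y),
             p_value = student_t_p(x, y))
    })
  overlap <- sum(circ_id(se_circs$chrom, se_circs$start, se_circs$end) %in%
                   circ_id(ces$chrom, ces$start, ces$end))
  list(features = features, tests = bind_rows(test_rows),
       overlap_count = overlap)
}
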