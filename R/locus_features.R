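# Genomic features of circRNA-producing loci: flanking introns, reverse
# complementary matches (RCMs) between intronic repeats, splice-site strength
# and BSJ dinucleotide / cryptic-site classification.

# Host transcript for a BSJ: the longest transcript (genomic span) containing
# both ends; failing that, the longest overlapping one.  Ties break to the
# lexicographically smallest transcript id.
select_host_transcript <- function(chrom, start, end, models,
                                   gene_id = NULL) {
  tx <- models$transcripts
  tx <- tx[tx$chrom == chrom, ]
  if (!is.null(gene_id) && !is.na(gene_id) && gene_id != "" &&
      gene_id %in% tx$gene_id) {
    tx <- tx[tx$gene_id == gene_id, ]
  }
  if (nrow(tx) == 0) return(NULL)
  containing <- tx[tx$start <= start & tx$end >= end, ]
  cand <- if (nrow(containing) > 0) containing else
    tx[tx$start <= end & tx$end >= start, ]
  if (nrow(cand) == 0) return(NULL)
  cand <- cand[order(-cand$span, cand$transcript_id), ]
  cand[1, ]
}

#' Flanking introns of a circRNA
#'
#' Locates the introns immediately upstream and downstream of the BSJ ends in
#' transcript orientation, against the host transcript (longest transcript
#' containing both ends, else longest overlapping).  circRNAs on a terminal
#' exon get a missing value on the absent side; the host gene's remaining
#' introns are returned as `other_lengths`.
#'
#' @param circs Tibble with `chrom`, `start`, `end`, `strand` and optionally
#'   `gene_id`.
#' @param models A `gene_models` object.
#' @return Tibble: `circ_key`, `transcript_id`, `up_start`, `up_end`,
#'   `up_length`, `down_start`, `down_end`, `down_length`, `other_lengths`
#'   (list column), `no_host` flag.
#' @export
extract_flanking_introns <- function(circs, models) {
  circs <- as_tibble(circs)
  if (!"gene_id" %in% names(circs)) circs$gene_id <- ""
  rows <- lapply(seq_len(nrow(circs)), function(i) {
    key <- circ_key(circs$chrom[i], circs$start[i], circs$end[i],
                    circs$strand[i])
    host <- select_host_transcript(circs$chrom[i], circs$start[i],
                                   circs$end[i], models, circs$gene_id[i])
    if (is.null(host)) {
      return(tibble(circ_key = key, transcript_id = NA_character_,
                    up_start = NA_integer_, up_end = NA_integer_,
                    up_length = NA_integer_, down_start = NA_integer_,
                    down_end = NA_integer_, down_length = NA_integer_,
                    other_lengths = list(integer(0)), no_host = TRUE))
    }
    gin <- models$introns[models$introns$transcript_id == host$transcript_id, ]
    gin <- gin[order(gin$start), ]
    before <- gin[gin$end < circs$start[i], ]   # genomically left of the BSJ
    after <- gin[gin$start > circs$end[i], ]    # genomically right
    left <- if (nrow(before) > 0) before[nrow(before), ] else NULL
    right <- if (nrow(after) > 0) after[1, ] else NULL
    if (host$strand == "+") {
      up <- left; down <- right
    } else {
      up <- right; down <- left
    }
    iv <- function(x) if (is.null(x)) c(NA_integer_, NA_integer_) else
      c(x$start, x$end)
    u <- iv(up); d <- iv(down)
    flank_keys <- c(if (!is.null(up)) paste(up$start, up$end),
                    if (!is.null(down)) paste(down$start, down$end))
    other <- gin[!(paste(gin$start, gin$end) %in% flank_keys), ]
    tibble(circ_key = key, transcript_id = host$transcript_id,
           up_start = u[1], up_end = u[2],
           up_length = u[2] - u[1] + 1L,
           down_start = d[1], down_end = d[2],
           down_length = d[2] - d[1] + 1L,
           other_lengths = list(as.integer(other$end - other$start + 1L)),
           no_host = FALSE)
  })
  bind_rows(rows)
}

# Pooled-variance two-tailed Student t with a zero-variance guard: equal
# constant groups give p = 1; distinct constant groups give p ~ 0 via an
# epsilon-inflated pooled variance.
student_t_p <- function(x, y, eps = 1e-12) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) return(NA_real_)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 == 0) {
    if (mean(x) == mean(y)) return(1)
    sp2 <- eps
  }
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tt), df = nx + ny - 2)
}

#' Compare flanking-intron lengths with the gene's other introns
#'
#' Group means of upstream-flanking, downstream-flanking and "other" intron
#' lengths, with pairwise two-tailed Student t-tests (up vs other, down vs
#' other).  The control group can be subsampled without replacement under a
#' fixed seed.
#'
#' @param up_lengths,down_lengths,other_lengths Numeric length vectors (nt).
#' @param subsample Optional size of a seeded subsample of `other_lengths`.
#' @param seed Seed for the subsample.
#' @return List of group means, sizes and p-values.
#' @export
compare_intron_features <- function(up_lengths, down_lengths, other_lengths,
                                    subsample = NULL, seed = 1L) {
  up_lengths <- up_lengths[!is.na(up_lengths)]
  down_lengths <- down_lengths[!is.na(down_lengths)]
  other_lengths <- other_lengths[!is.na(other_lengths)]
  if (!is.null(subsample) && subsample < length(other_lengths)) {
    other_lengths <- with_seed(seed,
                               sample(other_lengths, subsample))
  }
  list(mean_up = mean(up_lengths), mean_down = mean(down_lengths),
       mean_other = mean(other_lengths),
       n_up = length(up_lengths), n_down = length(down_lengths),
       n_other = length(other_lengths),
       p_up_vs_other = student_t_p(up_lengths, other_lengths),
       p_down_vs_other = student_t_p(down_lengths, other_lengths))
}

#' Reverse complementary matches between flanking-intron repeats
#'
#' For every pair of repeats (one in the upstream flanking intron, one in the
#' downstream), the upstream repeat sequence is locally aligned
#' (Smith-Waterman; match +1, mismatch -1, gap -2) against the reverse
#' complement of the downstream repeat sequence.  Pairs reaching the length
#' and identity thresholds are reported; co-oriented (non-inverted) copies do
#' not align against the reverse complement and yield nothing.
#'
#' @param context One row of [extract_flanking_introns()] output (or any list
#'   with `up_start`, `up_end`, `down_start`, `down_end`) plus `chrom`.
#' @param repeats Repeat tibble from [read_repeat_annotation()].
#' @param genome A `genome_seq` object.
#' @param min_len Minimum alignment length (nt), default 20.
#' @param min_ident Minimum percent identity over the alignment, default 80.
#' @param match,mismatch,gap Alignment scores (defaults +1/-1/-2).
#' @return Tibble of RCM pairs: repeat coordinates, `aln_length`,
#'   `identity`, `score`.
#' @export
find_rcms <- function(context, repeats, genome, min_len = 20L,
                      min_ident = 80, match = 1, mismatch = -1, gap = -2) {
  empty <- tibble(up_start = integer(), up_end = integer(),
                  down_start = integer(), down_end = integer(),
                  aln_length = integer(), identity = numeric(),
                  score = numeric())
  if (is.na(context$up_start) || is.na(context$down_start)) return(empty)
  chrom <- context$chrom
  assert_that(!is.null(chrom), "context must carry a chrom")
  in_iv <- function(s, e) {
    r <- repeats[repeats$chrom == chrom & repeats$start <= e &
                   repeats$end >= s, ]
    if (nrow(r) == 0) return(r)
    r$start <- pmax(r$start, s); r$end <- pmin(r$end, e)
    r
  }
  up_reps <- in_iv(context$up_start, context$up_end)
  dn_reps <- in_iv(context$down_start, context$down_end)
  if (nrow(up_reps) == 0 || nrow(dn_reps) == 0) return(empty)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  out <- list()
  for (i in seq_len(nrow(up_reps))) {
    useq <- get_seq(genome, chrom, up_reps$start[i], up_reps$end[i], "+")
    for (j in seq_len(nrow(dn_reps))) {
      dseq_rc <- get_seq(genome, chrom, dn_reps$start[j], dn_reps$end[j], "-")
      aln <- Biostrings::pairwiseAlignment(
        useq, dseq_rc, type = "local", substitutionMatrix = submat,
        gapOpening = 0, gapExtension = abs(gap))
      alen <- Biostrings::nchar(aln)
      ident <- if (alen > 0) Biostrings::pid(aln, type = "PID1") else 0
      if (alen >= min_len && ident >= min_ident) {
        out[[length(out) + 1L]] <- tibble(
          up_start = up_reps$start[i], up_end = up_reps$end[i],
          down_start = dn_reps$start[j], down_end = dn_reps$end[j],
          aln_length = as.integer(alen), identity = ident,
          score = Biostrings::score(aln))
      }
    }
  }
  if (length(out)) bind_rows(out) else empty
}

# ---- splice-site windows and scoring --------------------------------------

#' Genomic window of a splice site
#'
#' Donor (5'ss): 9 nt, 3 exonic + 6 intronic; acceptor (3'ss): 23 nt, 20
#' intronic + 3 exonic; both in transcript orientation.  `boundary` is the
#' exonic boundary position: the exon's last base for a donor, its first
#' base for an acceptor (in transcript orientation).
#'
#' @param boundary Genomic position of the exon boundary.
#' @param strand `"+"` or `"-"`.
#' @param kind `"donor"` or `"acceptor"`.
#' @return List: `start`, `end`, `strand` for [get_seq()].
#' @export
splice_window <- function(boundary, strand, kind = c("donor", "acceptor")) {
  kind <- match.arg(kind)
  if (kind == "donor") {
    if (strand == "+") list(start = boundary - 2L, end = boundary + 6L,
                            strand = "+")
    else list(start = boundary - 6L, end = boundary + 2L, strand = "-")
  } else {
    if (strand == "+") list(start = boundary - 20L, end = boundary + 2L,
                            strand = "+")
    else list(start = boundary - 2L, end = boundary + 20L, strand = "-")
  }
}

safe_get_seq <- function(genome, chrom, start, end, strand) {
  tryCatch(get_seq(genome, chrom, start, end, strand),
           error = function(e) NA_character_)
}

#' Construct a position-weight-matrix splice-site scorer
#'
#' @param donor,acceptor Probability matrices (4 rows named A, C, G, T;
#'   9 and 23 columns).
#' @param background Named base-frequency vector (A, C, G, T).
#' @return A `splice_scorer` object; the score of a window is
#'   `sum(log2(p[base, pos] / background[base]))`, a log-odds value in bits.
#' @export
pwm_scorer <- function(donor, acceptor, background) {
  assert_that(all(rownames(donor) == c("A", "C", "G", "T")) &&
                all(rownames(acceptor) == c("A", "C", "G", "T")),
              "PWM rows must be named A, C, G, T")
  assert_that(ncol(donor) == 9 && ncol(acceptor) == 23,
              "donor PWM must have 9 columns and acceptor 23")
  structure(list(type = "pwm", donor = donor, acceptor = acceptor,
                 background = background[c("A", "C", "G", "T")]),
            class = "splice_scorer")
}

#' Train the default splice-site scorer from annotation
#'
#' Estimates first-order-free position weight matrices for the 9-nt donor
#' and 23-nt acceptor windows from every annotated internal splice site in
#' the gene models, with additive smoothing, against the genome's base
#' composition as background.
#'
#' @param models A `gene_models` object.
#' @param genome A `genome_seq` object.
#' @param pseudocount Additive smoothing count per base and position
#'   (default 1).
#' @return A `splice_scorer` (see [pwm_scorer()]).
#' @export
build_pwm_scorer <- function(models, genome, pseudocount = 1) {
  sites <- annotated_splice_sites(models)
  grab <- function(df, kind) {
    seqs <- vapply(seq_len(nrow(df)), function(i) {
      w <- splice_window(df$boundary[i], df$strand[i], kind)
      safe_get_seq(genome, df$chrom[i], w$start, w$end, w$strand) %||%
        NA_character_
    }, character(1))
    seqs[!is.na(seqs) & !grepl("[^ACGT]", seqs)]
  }
  donor_seqs <- grab(sites[sites$kind == "donor", ], "donor")
  acc_seqs <- grab(sites[sites$kind == "acceptor", ], "acceptor")
  assert_that(length(donor_seqs) > 0 && length(acc_seqs) > 0,
              "no usable annotated splice sites to train on")
  count_pwm <- function(seqs, w) {
    m <- matrix(pseudocount, 4, w, dimnames = list(c("A", "C", "G", "T"),
                                                   NULL))
    sm <- do.call(rbind, strsplit(seqs, ""))
    for (p in seq_len(w)) {
      tab <- table(factor(sm[, p], levels = c("A", "C", "G", "T")))
      m[, p] <- m[, p] + as.numeric(tab)
    }
    sweep(m, 2, colSums(m), "/")
  }
  af <- Biostrings::alphabetFrequency(genome$seqs, collapse = TRUE)
  bg <- af[c("A", "C", "G", "T")]
  bg <- bg / sum(bg)
  pwm_scorer(count_pwm(donor_seqs, 9L), count_pwm(acc_seqs, 23L), bg)
}

#' Load a lookup-table splice-site scorer
#'
#' Reads a model directory with `donor.tsv` and `acceptor.tsv`, each a TSV
#' with columns `sequence` and `score` (an exact window-sequence to score
#' lookup, e.g. exported from a published maximum-entropy model).
#'
#' @param dir Directory containing the two tables.
#' @return A `splice_scorer` of type `"lookup"`.
#' @export
load_splice_model <- function(dir) {
  d <- read_tsv_plain(file.path(dir, "donor.tsv"))
  a <- read_tsv_plain(file.path(dir, "acceptor.tsv"))
  assert_that(all(c("sequence", "score") %in% names(d)) &&
                all(c("sequence", "score") %in% names(a)),
              "model tables need 'sequence' and 'score' columns")
  structure(list(type = "lookup",
                 donor = setNames(d$score, toupper(d$sequence)),
                 acceptor = setNames(a$score, toupper(a$sequence))),
            class = "splice_scorer")
}

#' Score one splice-site window sequence
#'
#' @param scorer A `splice_scorer`.
#' @param seq Window sequence (9 nt donor / 23 nt acceptor).
#' @param kind `"donor"` or `"acceptor"`.
#' @return Numeric score, or `NA` for unknown bases or (lookup scorers)
#'   unknown sequences.
#' @export
score_window <- function(scorer, seq, kind = c("donor", "acceptor")) {
  kind <- match.arg(kind)
  if (is.na(seq)) return(NA_real_)
  seq <- toupper(seq)
  if (scorer$type == "lookup") {
    return(unname(scorer[[kind]][seq]) %||% NA_real_)
  }
  pwm <- scorer[[kind]]
  if (nchar(seq) != ncol(pwm) || grepl("[^ACGT]", seq)) return(NA_real_)
  bases <- strsplit(seq, "")[[1]]
  ri <- match(bases, rownames(pwm))
  sum(log2(pwm[cbind(ri, seq_len(ncol(pwm)))] /
             scorer$background[bases]))
}

# Every annotated internal splice site of the models, one row per site:
# chrom, strand, kind (donor/acceptor), boundary (exonic boundary position).
annotated_splice_sites <- function(models) {
  rows <- list()
  ex <- models$exons
  for (tx in unique(ex$transcript_id)) {
    e <- ex[ex$transcript_id == tx, ]
    if (nrow(e) < 2) next
    e <- e[order(e$start), ]
    plus <- e$strand[1] == "+"
    # donors: transcript 3' boundaries of non-terminal exons
    donors <- if (plus) e$end[-nrow(e)] else e$start[-1]
    acceptors <- if (plus) e$start[-1] else e$end[-nrow(e)]
    rows[[tx]] <- tibble(
      chrom = e$chrom[1], strand = e$strand[1],
      kind = rep(c("donor", "acceptor"), c(length(donors),
                                           length(acceptors))),
      boundary = c(donors, acceptors), transcript_id = tx)
  }
  if (length(rows)) bind_rows(rows) else
    tibble(chrom = character(), strand = character(), kind = character(),
           boundary = integer(), transcript_id = character())
}

#' Splice-site strength at circRNA BSJs
#'
#' Extracts and scores the 9-nt donor and 23-nt acceptor windows of the
#' back-splice's would-be intron ends: the donor at the circRNA's 3' end and
#' the acceptor at its 5' end, both in transcript orientation.  Windows
#' running past a contig end, or containing unknown bases, yield `NA` scores
#' with a flag.
#'
#' @param circs Tibble with `chrom`, `start`, `end`, `strand`.
#' @param genome A `genome_seq` object.
#' @param scorer A `splice_scorer` ([build_pwm_scorer()], [pwm_scorer()] or
#'   [load_splice_model()]).
#' @return Tibble: `circ_key`, `donor_seq`, `donor_score`, `acceptor_seq`,
#'   `acceptor_score`, `incomplete` flag.
#' @export
score_splice_sites <- function(circs, genome, scorer) {
  circs <- as_tibble(circs)
  rows <- lapply(seq_len(nrow(circs)), function(i) {
    plus <- circs$strand[i] == "+"
    donor_boundary <- if (plus) circs$end[i] else circs$start[i]
    acc_boundary <- if (plus) circs$start[i] else circs$end[i]
    dw <- splice_window(donor_boundary, circs$strand[i], "donor")
    aw <- splice_window(acc_boundary, circs$strand[i], "acceptor")
    dseq <- safe_get_seq(genome, circs$chrom[i], dw$start, dw$end, dw$strand)
    aseq <- safe_get_seq(genome, circs$chrom[i], aw$start, aw$end, aw$strand)
    tibble(circ_key = circ_key(circs$chrom[i], circs$start[i], circs$end[i],
                               circs$strand[i]),
           donor_seq = dseq, donor_score = score_window(scorer, dseq, "donor"),
           acceptor_seq = aseq,
           acceptor_score = score_window(scorer, aseq, "acceptor"),
           incomplete = is.na(dseq) || is.na(aseq))
  })
  bind_rows(rows)
}

#' Classify BSJ ends against annotated splice sites
#'
#' Each BSJ end is `annotated` (exact match to an annotated exon boundary of
#' the host gene: the genomic start of an exon for the circRNA start, the
#' genomic end of an exon for the circRNA end), `ie_bsj` (inside an exon),
#' `ii_bsj` (inside an intron; the containing intron's transcript-orientation
#' ordinal is recorded), or `outside` any gene.  The dinucleotides
#' immediately outside the BSJ — the would-be intron ends of the
#' circularizing event — are read from the genome on the transcript strand;
#' `canonical` flags the GT/AG (GU/AG in RNA) configuration.  An `ie_bsj`
#' end inside the host transcript's terminal exon sets `last_exon`; when CDS
#' annotation is available, `utr3` marks ends beyond the stop codon.
#'
#' @param circs Tibble with `chrom`, `start`, `end`, `strand`, optional
#'   `gene_id`.
#' @param models A `gene_models` object.
#' @param genome A `genome_seq` object.
#' @return Tibble: `circ_key`, `start_label`, `end_label` (genomic ends),
#'   `donor_label`, `acceptor_label` (transcript orientation),
#'   `intron_index`, `last_exon`, `utr3`, `donor_dinuc`, `acceptor_dinuc`,
#'   `canonical`.
#' @export
classify_bsj_sites <- function(circs, models, genome) {
  circs <- as_tibble(circs)
  if (!"gene_id" %in% names(circs)) circs$gene_id <- ""
  genes <- models$genes
  rows <- lapply(seq_len(nrow(circs)), function(i) {
    chrom <- circs$chrom[i]; s <- circs$start[i]; e <- circs$end[i]
    strand <- circs$strand[i]
    key <- circ_key(chrom, s, e, strand)
    gid <- circs$gene_id[i]
    gid <- if (is.na(gid)) "" else gid
    if (gid == "" || !gid %in% genes$gene_id) {
      hit <- genes[genes$chrom == chrom & genes$start <= e & genes$end >= s, ]
      gid <- if (nrow(hit) > 0) sort(hit$gene_id)[1] else ""
    }
    host <- select_host_transcript(chrom, s, e, models, gid)
    gex <- if (gid != "") models$exons[models$exons$gene_id == gid, ] else
      models$exons[0, ]
    grow <- if (gid != "") genes[genes$gene_id == gid, ] else NULL
    label_of <- function(pos, side) {
      if (nrow(gex) == 0 || is.null(grow)) return("outside")
      bnd <- if (side == "start") gex$start else gex$end
      if (any(bnd == pos)) return("annotated")
      if (any(pos >= gex$start & pos <= gex$end)) return("ie_bsj")
      if (pos >= grow$start && pos <= grow$end) return("ii_bsj")
      "outside"
    }
    start_label <- label_of(s, "start")
    end_label <- label_of(e, "end")
    # containing-intron ordinal for the first ii end (transcript orientation)
    intron_index <- NA_integer_
    if (!is.null(host)) {
      gin <- models$introns[models$introns$transcript_id ==
                              host$transcript_id, ]
      idx_of <- function(pos) {
        hit <- which(gin$start <= pos & gin$end >= pos)
        if (length(hit)) gin$intron_index[hit[1]] else NA_integer_
      }
      if (start_label == "ii_bsj") intron_index <- idx_of(s)
      if (is.na(intron_index) && end_label == "ii_bsj")
        intron_index <- idx_of(e)
    }
    # terminal-exon membership of ie ends
    last_exon <- FALSE
    if (!is.null(host) && (start_label == "ie_bsj" || end_label == "ie_bsj")) {
      hex <- models$exons[models$exons$transcript_id == host$transcript_id, ]
      hex <- hex[order(hex$start), ]
      term <- if (host$strand == "+") hex[nrow(hex), ] else hex[1, ]
      inside_term <- function(pos) pos >= term$start && pos <= term$end
      last_exon <- (start_label == "ie_bsj" && inside_term(s)) ||
        (end_label == "ie_bsj" && inside_term(e))
    }
    utr3 <- NA
    if (!is.null(models$cds) && !is.null(host)) {
      cc <- models$cds[models$cds$transcript_id == host$transcript_id, ]
      if (nrow(cc) > 0) {
        utr3 <- if (host$strand == "+") e > max(cc$end) else s < min(cc$start)
      }
    }
    plus <- strand == "+"
    donor_dinuc <- if (plus)
      safe_get_seq(genome, chrom, e + 1L, e + 2L, "+") else
      safe_get_seq(genome, chrom, s - 2L, s - 1L, "-")
    acceptor_dinuc <- if (plus)
      safe_get_seq(genome, chrom, s - 2L, s - 1L, "+") else
      safe_get_seq(genome, chrom, e + 1L, e + 2L, "-")
    tibble(circ_key = key, host_gene = gid,
           start_label = start_label, end_label = end_label,
           donor_label = if (plus) end_label else start_label,
           acceptor_label = if (plus) start_label else end_label,
           intron_index = intron_index, last_exon = last_exon, utr3 = utr3,
           donor_dinuc = donor_dinuc, acceptor_dinuc = acceptor_dinuc,
           canonical = identical(donor_dinuc, "GT") &&
             identical(acceptor_dinuc, "AG"))
  })
  bind_rows(rows)
}

#' Aggregate BSJ dinucleotide frequencies
#'
#' @param calls Output of [classify_bsj_sites()].
#' @return Tibble of donor/acceptor dinucleotide combinations with counts
#'   and frequencies.
#' @export
dinucleotide_frequency <- function(calls) {
  calls |>
    group_by(donor_dinuc, acceptor_dinuc) |>
    summarise(count = n(), .groups = "drop") |>
    mutate(frequency = count / sum(count)) |>
    arrange(-count)
}
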