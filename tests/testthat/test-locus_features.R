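# Flanking introns, intron-length comparisons, RCM detection, splice-site
# windows/scoring and BSJ site classification.

test_that("flanking introns locate in transcript orientation", {
  m <- toy_models("+")  # exons 1-100, 201-300, 401-500
  fl <- extract_flanking_introns(circ_row("chrT", 201, 300, gene_id = "gA"), m)
  expect_equal(c(fl$up_start, fl$up_end), c(101L, 200L))
  expect_equal(fl$up_length, 100L)
  expect_equal(c(fl$down_start, fl$down_end), c(301L, 400L))
  expect_equal(fl$other_lengths[[1]], integer(0))

  # same locus on '-': upstream/downstream swap
  fm <- extract_flanking_introns(circ_row("chrT", 201, 300, "-", "gA"),
                                 toy_models("-"))
  expect_equal(c(fm$up_start, fm$up_end), c(301L, 400L))
  expect_equal(c(fm$down_start, fm$down_end), c(101L, 200L))

  # first-exon circRNA: upstream missing, downstream present
  f1 <- extract_flanking_introns(circ_row("chrT", 1, 100, gene_id = "gA"), m)
  expect_true(is.na(f1$up_start))
  expect_equal(f1$down_start, 101L)

  # no overlapping transcript: flagged empty context
  f0 <- extract_flanking_introns(circ_row("chrT", 10000, 10100), m)
  expect_true(f0$no_host)
})

test_that("intron-length comparison matches the pooled-t oracle", {
  cmp <- compare_intron_features(c(10, 11, 9), c(30, 29, 31), c(20, 21, 19))
  expect_equal(cmp$p_up_vs_other, pooled_t_p(c(10, 11, 9), c(20, 21, 19)),
               tolerance = 1e-12)
  expect_equal(cmp$p_down_vs_other, pooled_t_p(c(30, 29, 31), c(20, 21, 19)),
               tolerance = 1e-12)
  expect_equal(cmp$mean_up, 10)

  # identical constant groups -> p = 1 via the zero-variance guard
  cmp2 <- compare_intron_features(c(10, 10, 10), c(10, 10, 10), c(10, 10, 10))
  expect_equal(cmp2$p_up_vs_other, 1)
  # distinct constant groups -> p ~ 0
  cmp3 <- compare_intron_features(c(10, 10, 10), c(20, 20, 20), c(20, 20, 20))
  expect_lt(cmp3$p_up_vs_other, 1e-6)
  expect_equal(cmp3$p_down_vs_other, 1)

  # seeded subsampling is reproducible
  other <- 1:100
  a <- compare_intron_features(c(1, 2), c(3, 4), other, subsample = 10,
                               seed = 5)
  b <- compare_intron_features(c(1, 2), c(3, 4), other, subsample = 10,
                               seed = 5)
  expect_identical(a$p_up_vs_other, b$p_up_vs_other)
  expect_equal(a$n_other, 10)
})

make_rcm_fixture <- function(orientation = "inverted", seed = 1,
                             intron_len = 2000L) {
  set.seed(seed)
  # layout: exon 1-100 | intron | exon (intron_len+101)-(intron_len+200) |
  # intron | exon ... circ over the middle exon
  L <- 30L
  up_iv <- c(500L, 500L + L - 1L)
  e2 <- c(intron_len + 101L, intron_len + 200L)
  dn_iv <- c(e2[2] + 700L, e2[2] + 700L + L - 1L)
  total <- e2[2] + intron_len + 200L
  seqv <- strsplit(rand_seq(total), "")[[1]]
  rseq <- rand_seq(L)
  dseq <- if (orientation == "inverted") revcomp_str(rseq) else rseq
  seqv[up_iv[1]:up_iv[2]] <- strsplit(rseq, "")[[1]]
  seqv[dn_iv[1]:dn_iv[2]] <- strsplit(dseq, "")[[1]]
  genome <- genome_from_seqs(setNames(list(paste(seqv, collapse = "")), "cF"))
  repeats <- tibble::tibble(chrom = "cF",
                            start = c(up_iv[1], dn_iv[1]),
                            end = c(up_iv[2], dn_iv[2]),
                            strand = c("+", "-"), family = "SINE_synth")
  ctx <- list(chrom = "cF", up_start = 101L, up_end = e2[1] - 1L,
              down_start = e2[2] + 1L, down_end = e2[2] + intron_len)
  list(genome = genome, repeats = repeats, ctx = ctx, up = up_iv, dn = dn_iv)
}

test_that("RCM detection finds planted inverted pairs and rejects co-oriented ones", {
  fx <- make_rcm_fixture("inverted")
  hits <- find_rcms(fx$ctx, fx$repeats, fx$genome)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$identity, 100)
  expect_equal(hits$aln_length, 30L)
  expect_equal(c(hits$up_start, hits$up_end), fx$up)

  # the same sequence co-oriented in both introns is not an RCM
  fx2 <- make_rcm_fixture("co_oriented")
  expect_equal(nrow(find_rcms(fx2$ctx, fx2$repeats, fx2$genome)), 0)

  # no repeats annotated -> empty
  expect_equal(nrow(find_rcms(fx$ctx, fx$repeats[0, ], fx$genome)), 0)

  # a missing flanking intron -> empty
  ctx_na <- fx$ctx; ctx_na$up_start <- NA_integer_
  expect_equal(nrow(find_rcms(ctx_na, fx$repeats, fx$genome)), 0)
})

test_that("RCM calls agree with an exhaustive Smith-Waterman oracle", {
  set.seed(1234)
  for (rep in 1:30) {
    orientation <- sample(c("inverted", "co_oriented", "random"), 1)
    fx <- make_rcm_fixture(sample(c("inverted", "co_oriented"), 1),
                           seed = rep + 100)
    reps <- fx$repeats
    if (orientation == "random") {
      # replace the down repeat annotation by an unrelated random interval
      reps$start[2] <- reps$start[2] + 40L
      reps$end[2] <- reps$end[2] + 40L
      orientation <- "none_expected"
    }
    got <- find_rcms(fx$ctx, reps, fx$genome)
    # oracle: all-pairs SW of up sequence vs revcomp(down sequence)
    useq <- get_seq(fx$genome, "cF", reps$start[1], reps$end[1], "+")
    dseq_rc <- get_seq(fx$genome, "cF", reps$start[2], reps$end[2], "-")
    oracle <- brute_sw(useq, dseq_rc)
    oracle_pass <- oracle$length >= 20 && oracle$identity >= 80
    expect_equal(nrow(got) > 0, oracle_pass, info = sprintf("rep %d", rep))
    if (nrow(got) > 0) {
      expect_equal(got$score, oracle$score, info = sprintf("rep %d", rep))
    }
  }
})

test_that("splice windows have the exact 9/23-nt geometry on both strands", {
  g <- toy_genome(600)
  chrseq <- get_seq(g, "chrT", 1, 600, "+")

  # donor for an exon ending at 100 on '+': genomic 98-106 (3 exon + 6 intron)
  w <- splice_window(100L, "+", "donor")
  expect_equal(c(w$start, w$end), c(98L, 106L))
  expect_equal(get_seq(g, "chrT", w$start, w$end, w$strand),
               substr(chrseq, 98, 106))
  expect_equal(nchar(substr(chrseq, 98, 106)), 9)

  # acceptor for an exon starting at 201 on '+': genomic 181-203 (20 + 3)
  wa <- splice_window(201L, "+", "acceptor")
  expect_equal(c(wa$start, wa$end), c(181L, 203L))
  expect_equal(nchar(substr(chrseq, 181, 203)), 23)

  # '-' strand donor at an exon whose transcript-end boundary is genomic 201:
  # 6 intronic bases genomically left, 3 exonic right, reverse-complemented
  wm <- splice_window(201L, "-", "donor")
  expect_equal(c(wm$start, wm$end), c(195L, 203L))
  expect_equal(get_seq(g, "chrT", wm$start, wm$end, "-"),
               revcomp_str(substr(chrseq, 195, 203)))

  wma <- splice_window(100L, "-", "acceptor")
  expect_equal(c(wma$start, wma$end), c(98L, 120L))
})

test_that("PWM scoring: background-equal PWM scores 0; consensus matches closed form", {
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  uniform <- matrix(0.25, 4, 9, dimnames = list(names(bg), NULL))
  uniform23 <- matrix(0.25, 4, 23, dimnames = list(names(bg), NULL))
  sc0 <- pwm_scorer(uniform, uniform23, bg)
  expect_equal(score_window(sc0, "ACGTACGTA", "donor"), 0)
  expect_equal(score_window(sc0, paste(rep("G", 23), collapse = ""),
                            "acceptor"), 0)

  # consensus-A PWM with 0.7/0.1/0.1/0.1 per position
  skew <- matrix(0.1, 4, 9, dimnames = list(names(bg), NULL))
  skew["A", ] <- 0.7
  sc1 <- pwm_scorer(skew, uniform23, bg)
  expect_equal(score_window(sc1, paste(rep("A", 9), collapse = ""), "donor"),
               9 * log2(0.7 / 0.25), tolerance = 1e-12)
  # one non-consensus base swaps one log-odds term
  expect_equal(score_window(sc1, paste(c(rep("A", 8), "C"), collapse = ""),
                            "donor"),
               8 * log2(0.7 / 0.25) + log2(0.1 / 0.25), tolerance = 1e-12)

  # unknown base or wrong width -> missing
  expect_true(is.na(score_window(sc1, "ACGTNCGTA", "donor")))
  expect_true(is.na(score_window(sc1, "ACGT", "donor")))
})

test_that("the trained PWM ranks annotated donors above random 9-mers", {
  locus <- build_locus_set(sim_config(seed = 31, n_genes = 20L))
  scorer <- build_pwm_scorer(locus$models, locus$genome)
  sites <- circkit:::annotated_splice_sites(locus$models)
  don <- sites[sites$kind == "donor", ]
  don_scores <- vapply(seq_len(nrow(don)), function(i) {
    w <- splice_window(don$boundary[i], don$strand[i], "donor")
    score_window(scorer, get_seq(locus$genome, don$chrom[i], w$start, w$end,
                                 w$strand), "donor")
  }, numeric(1))
  set.seed(9)
  len <- seq_lengths(locus$genome)[1]
  rand_scores <- vapply(1:200, function(i) {
    p <- sample(len - 10L, 1)
    score_window(scorer, get_seq(locus$genome, names(len), p, p + 8L, "+"),
                 "donor")
  }, numeric(1))
  expect_gt(mean(don_scores, na.rm = TRUE), mean(rand_scores, na.rm = TRUE))
})

test_that("lookup splice models score by exact window sequence", {
  d <- withr::local_tempdir()
  writeLines(c("sequence\tscore", "ACGTACGTA\t7.5"),
             file.path(d, "donor.tsv"))
  writeLines(c("sequence\tscore",
               paste0(paste(rep("A", 23), collapse = ""), "\t-1.25")),
             file.path(d, "acceptor.tsv"))
  sc <- load_splice_model(d)
  expect_equal(score_window(sc, "ACGTACGTA", "donor"), 7.5)
  expect_equal(score_window(sc, paste(rep("A", 23), collapse = ""),
                            "acceptor"), -1.25)
  expect_true(is.na(score_window(sc, "AAAAAAAAA", "donor")))
})

test_that("BSJ site classification labels ends and dinucleotides correctly", {
  # genome with known splice dinucleotides around toy exons
  set.seed(12)
  seqv <- strsplit(rand_seq(600), "")[[1]]
  # '+' introns 101-200 and 301-400: GT...AG
  seqv[101:102] <- c("G", "T"); seqv[199:200] <- c("A", "G")
  seqv[301:302] <- c("G", "T"); seqv[399:400] <- c("A", "G")
  g <- genome_from_seqs(setNames(list(paste(seqv, collapse = "")), "chrT"))
  m <- toy_models("+")

  # annotated-annotated BSJ with canonical dinucleotides
  s1 <- classify_bsj_sites(circ_row("chrT", 201, 300, gene_id = "gA"), m, g)
  expect_equal(s1$start_label, "annotated")
  expect_equal(s1$end_label, "annotated")
  expect_equal(s1$donor_dinuc, "GT")
  expect_equal(s1$acceptor_dinuc, "AG")
  expect_true(s1$canonical)

  # end inside the terminal exon -> ie_bsj with last_exon flag
  s2 <- classify_bsj_sites(circ_row("chrT", 201, 420, gene_id = "gA"), m, g)
  expect_equal(s2$end_label, "ie_bsj")
  expect_true(s2$last_exon)

  # both ends inside intron 2 -> ii_bsj with intron index 2
  s3 <- classify_bsj_sites(circ_row("chrT", 320, 380, gene_id = "gA"), m, g)
  expect_equal(s3$start_label, "ii_bsj")
  expect_equal(s3$end_label, "ii_bsj")
  expect_equal(s3$intron_index, 2L)
  # on '-', the same genomic intron is transcript intron 1
  s3m <- classify_bsj_sites(circ_row("chrT", 320, 380, "-", "gA"),
                            toy_models("-"), g)
  expect_equal(s3m$intron_index, 1L)

  # outside any gene: labels outside, dinucleotides still reported
  s4 <- classify_bsj_sites(circ_row("chrT", 550, 580), m, g)
  expect_equal(s4$start_label, "outside")
  expect_equal(nchar(s4$donor_dinuc), 2)

  # aggregate dinucleotide table sums to 1
  freq <- dinucleotide_frequency(dplyr::bind_rows(s1, s2, s3))
  expect_equal(sum(freq$frequency), 1)
  expect_equal(sum(freq$count), 3)
})

test_that("strand symmetry: mirrored genome and annotation give identical features", {
  locus <- build_locus_set(sim_config(seed = 45, n_genes = 10L))
  len <- unname(seq_lengths(locus$genome)[1])
  flip <- function(x) len - x + 1L
  # reverse-complement the genome and flip all coordinates/strands
  rc_genome <- genome_from_seqs(setNames(
    list(revcomp_str(get_seq(locus$genome, "chr1", 1, len, "+"))), "chr1"))
  ex <- locus$models$exons
  rc_models <- gene_models(tibble::tibble(
    gene_id = ex$gene_id, transcript_id = ex$transcript_id, chrom = ex$chrom,
    strand = ifelse(ex$strand == "+", "-", "+"),
    start = flip(ex$end), end = flip(ex$start)))
  m <- locus$manifest
  rc_circs <- tibble::tibble(chrom = m$chrom, start = flip(m$end),
                             end = flip(m$start),
                             strand = ifelse(m$strand == "+", "-", "+"),
                             gene_id = m$gene_id)
  s_fwd <- classify_bsj_sites(m, locus$models, locus$genome)
  s_rc <- classify_bsj_sites(rc_circs, rc_models, rc_genome)
  # genomic start/end labels swap; transcript-level labels are invariant
  expect_equal(s_rc$donor_label, s_fwd$donor_label)
  expect_equal(s_rc$acceptor_label, s_fwd$acceptor_label)
  expect_equal(s_rc$donor_dinuc, s_fwd$donor_dinuc)
  expect_equal(s_rc$acceptor_dinuc, s_fwd$acceptor_dinuc)
  expect_equal(s_rc$canonical, s_fwd$canonical)
  expect_equal(s_rc$intron_index, s_fwd$intron_index)
  cls_fwd <- classify_structure(m, locus$models)
  cls_rc <- classify_structure(rc_circs, rc_models)
  expect_equal(cls_rc$category, cls_fwd$category)
})
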