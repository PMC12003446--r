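# Structural classification, length classes, gene summaries, isoform
# grouping and set overlap.

test_that("end contexts and categories follow the classification rules", {
  m <- toy_models("+")  # exons 1-100, 201-300, 401-500

  # both ends on exon boundaries -> exonic
  c1 <- classify_structure(circ_row("chrT", 201, 300, gene_id = "gA"), m)
  expect_equal(c1$category, "exonic")
  expect_equal(c1$end5_context, "exon_boundary")
  expect_equal(c1$end3_context, "exon_boundary")

  # one end inside an exon -> still exonic (partial exon, ie-BSJ feeder)
  c2 <- classify_structure(circ_row("chrT", 250, 300, gene_id = "gA"), m)
  expect_equal(c2$category, "exonic")
  expect_equal(c2$end5_context, "inside_exon")

  # entirely within one intron -> intronic
  c3 <- classify_structure(circ_row("chrT", 120, 180, gene_id = "gA"), m)
  expect_equal(c3$category, "intronic")

  # exon boundary to inside-intron -> exonic+intronic
  c4 <- classify_structure(circ_row("chrT", 201, 350, gene_id = "gA"), m)
  expect_equal(c4$category, "exonic+intronic")

  # ends in two different introns span exons -> exonic+intronic
  c5 <- classify_structure(circ_row("chrT", 150, 350, gene_id = "gA"), m)
  expect_equal(c5$category, "exonic+intronic")

  # outside any gene -> intergenic
  c6 <- classify_structure(circ_row("chrT", 550, 590), m)
  expect_equal(c6$category, "intergenic")

  # minus-strand record: end5/end3 contexts swap genomic ends
  c7 <- classify_structure(circ_row("chrT", 250, 300, "-", "gA"),
                           toy_models("-"))
  expect_equal(c7$end5_context, "exon_boundary")  # genomic end is 5' on '-'
  expect_equal(c7$end3_context, "inside_exon")

  # one category and one length class per circRNA (partition property)
  expect_true(all(!is.na(c(c1$category, c2$category, c3$category,
                           c4$category, c5$category, c6$category))))
})

test_that("length classes bin with a left-inclusive lower edge", {
  expect_equal(length_class(60), "<200")
  expect_equal(length_class(199), "<200")
  expect_equal(length_class(200), "200-1000")
  expect_equal(length_class(1000), "1000-5000")
  expect_equal(length_class(4999), "1000-5000")
  expect_equal(length_class(5000), ">5000")
  expect_equal(length_class(10001), ">5000")
})

test_that("gene summaries split SCG/MCG and flag top MCGs", {
  m <- gene_models(tibble::tibble(
    gene_id = rep(c("g1", "g2", "g3"), each = 2),
    transcript_id = rep(c("t1", "t2", "t3"), each = 2),
    chrom = "c", strand = "+",
    start = c(1, 201, 1001, 1201, 2001, 2201),
    end = c(100, 300, 1100, 1300, 2100, 2300)))
  calls <- tibble::tibble(
    host_gene = c("g1", "g2", "g3", "g3", "g3"),
    circ_key = c("k1", "k2", "k3", "k4", "k5"))
  s <- summarize_genes(calls, m)
  expect_equal(s$scg_pct, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(s$mcg_pct, 100 / 3, tolerance = 1e-12)
  expect_equal(s$genes$class[s$genes$host_gene == "g3"], "MCG")
  expect_false(any(s$genes$is_top_mcg))

  # a gene with 11 distinct BSJs is a top MCG
  calls11 <- tibble::tibble(host_gene = "g1",
                            circ_key = paste0("k", 1:11))
  s11 <- summarize_genes(calls11, m)
  expect_true(s11$genes$is_top_mcg)

  # identical circ counts across genes -> zero length correlation
  calls_flat <- tibble::tibble(host_gene = c("g1", "g2", "g3"),
                               circ_key = c("a", "b", "c"))
  expect_true(is.na(summarize_genes(calls_flat, m)$r2_length))

  # counts invariant to duplicates and row order
  s_dup <- summarize_genes(calls[c(5, 1, 3, 2, 4, 4, 1), ], m)
  expect_equal(sort(s_dup$genes$n_distinct_circ),
               sort(s$genes$n_distinct_circ))
})

test_that("isoform grouping matches definitions and a brute-force oracle", {
  # same BSJ with two distinct exon chains -> one same_bsj group
  calls <- tibble::tibble(
    circ_key = c("c:100|500:+a", "c:100|500:+b", "c:100|800:+"),
    chrom = "c", start = c(100L, 100L, 100L), end = c(500L, 500L, 800L),
    strand = "+", host_gene = "g1")
  chains <- tibble::tibble(circ_key = calls$circ_key[1:2],
                           chain = c("e2-e3", "e2-e3-e4"))
  g <- group_isoforms(calls, chains)
  expect_equal(sum(g$kind == "same_bsj"), 2)

  # shared genomic start 100 on '+': the start is the acceptor side
  shared <- g[g$kind == "shared_acceptor", ]
  expect_equal(nrow(shared), 3)
  expect_equal(unique(shared$shared_end), 100L)
  # on '-', the same shared coordinate is the donor side
  calls_m <- calls; calls_m$strand <- "-"
  gm <- group_isoforms(calls_m)
  expect_equal(unique(gm$kind), "shared_donor")

  # brute-force pairwise oracle on random BSJ sets
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    bsjs <- tibble::tibble(
      circ_key = paste0("k", 1:n), chrom = "c",
      start = sample(seq(100, 400, 100), n, replace = TRUE),
      end = sample(seq(1000, 1300, 100), n, replace = TRUE),
      strand = "+", host_gene = "g1")
    bsjs <- bsjs[!duplicated(bsjs[, c("start", "end")]), ]
    got <- group_isoforms(bsjs)
    # oracle: a pair shares a group iff exactly one coordinate matches
    pair_in_group <- function(i, j, kind) {
      coord <- if (kind == "shared_acceptor") "start" else "end"
      other <- setdiff(c("start", "end"), coord)
      bsjs[[coord]][i] == bsjs[[coord]][j] &&
        bsjs[[other]][i] != bsjs[[other]][j]
    }
    for (kind in c("shared_acceptor", "shared_donor")) {
      gk <- got[got$kind == kind, ]
      for (i in seq_len(nrow(bsjs))) {
        for (j in seq_len(nrow(bsjs))) {
          if (i >= j) next
          same_group <- any(vapply(unique(gk$group_id), function(id) {
            mem <- gk$circ_key[gk$group_id == id]
            all(bsjs$circ_key[c(i, j)] %in% mem)
          }, logical(1)))
          expect_equal(same_group, pair_in_group(i, j, kind),
                       info = sprintf("rep %d %s pair %d-%d", rep, kind, i, j))
        }
      }
    }
  }
})

test_that("dataset overlap counts match set enumeration", {
  A <- c("k1", "k2", "k3"); B <- c("k2", "k3", "k4"); C <- "k3"
  ov <- intersect_datasets(list(A = A, B = B, C = C))
  r <- setNames(ov$regions$count, ov$regions$region)
  expect_equal(unname(r["A"]), 1)        # k1
  expect_equal(unname(r["B"]), 1)        # k4
  expect_equal(unname(r["C"]), 0)
  expect_equal(unname(r["A&B"]), 1)      # k2
  expect_equal(unname(r["A&B&C"]), 1)    # k3
  expect_equal(unname(ov$frac_shared["A"]), 2 / 3)

  # identical sets: everything common
  ov2 <- intersect_datasets(list(X = A, Y = A))
  r2 <- setNames(ov2$regions$count, ov2$regions$region)
  expect_equal(unname(r2["X&Y"]), 3)
  expect_equal(unname(r2["X"]), 0)

  # disjoint sets: nothing common
  ov3 <- intersect_datasets(list(X = A, Y = c("q1", "q2")))
  r3 <- setNames(ov3$regions$count, ov3$regions$region)
  expect_equal(unname(r3["X&Y"]), 0)
  expect_equal(unname(ov3$frac_shared["X"]), 0)
})
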