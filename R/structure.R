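# Structural classification of circRNAs against gene annotation, length
# classes, gene-level SCG/MCG summaries, isoform grouping and cross-dataset
# overlap.

# Context of one genomic position against one gene's exon/intron structure.
# Boundary matches outrank inside-exon, which outranks inside-intron.
end_context <- function(pos, gene_exons, gene_start, gene_end,
                        boundary_slop = 0L, side = c("start", "end")) {
  side <- match.arg(side)
  bnd <- if (side == "start") gene_exons$start else gene_exons$end
  if (any(abs(bnd - pos) <= boundary_slop)) return("exon_boundary")
  if (any(pos >= gene_exons$start & pos <= gene_exons$end)) return("inside_exon")
  if (pos >= gene_start && pos <= gene_end) return("inside_intron")
  "outside_gene"
}

category_from_contexts <- function(c5, c3, same_intron) {
  exonish <- c("exon_boundary", "inside_exon")
  if (c5 %in% exonish && c3 %in% exonish) return("exonic")
  if (c5 == "inside_intron" && c3 == "inside_intron") {
    return(if (same_intron) "intronic" else "exonic+intronic")
  }
  if ((c5 %in% exonish && c3 == "inside_intron") ||
      (c3 %in% exonish && c5 == "inside_intron")) return("exonic+intronic")
  if ((c5 %in% exonish && c3 == "outside_gene") ||
      (c3 %in% exonish && c5 == "outside_gene")) return("exonic+intergenic")
  if ((c5 == "inside_intron" && c3 == "outside_gene") ||
      (c3 == "inside_intron" && c5 == "outside_gene"))
    return("intronic+intergenic")
  "intergenic"
}

#' Classify circRNA structure against gene models
#'
#' Each BSJ end is assigned a context against the host gene (exact exon
#' boundary, inside an exon, inside an intron, or outside the gene); the
#' category follows from the two contexts: both exonish gives `exonic`, both
#' inside one intron gives `intronic`, mixed combinations give the
#' corresponding mixed category, both outside gives `intergenic`.  The host
#' gene is the one named in the record; when absent, the gene overlapping the
#' BSJ (flagged `ambiguous` if several, classified against the first by id).
#'
#' @param circs Tibble of circRNA records (`chrom`, `start`, `end`, `strand`,
#'   `gene_id`; e.g. the `features` table of a `circ_counts`).
#' @param models A `gene_models` object.
#' @param length_bins Numeric bin edges for the length classes (default
#'   `c(200, 1000, 5000)`).
#' @param boundary_slop Tolerance (nt) for boundary matching; default 0
#'   (CIRI2 coordinates are splice-site resolved).
#' @return Tibble: input keys plus `category`, `end5_context`,
#'   `end3_context` (transcript orientation), `genomic_span`, `length_class`,
#'   `strand_mismatch`, `ambiguous`.
#' @export
classify_structure <- function(circs, models, length_bins = c(200, 1000, 5000),
                               boundary_slop = 0L) {
  circs <- as_tibble(circs)
  if (!"gene_id" %in% names(circs)) circs$gene_id <- ""
  n <- nrow(circs)
  category <- character(n); ctx_start <- character(n); ctx_end <- character(n)
  strand_mismatch <- logical(n); ambiguous <- logical(n)
  host_gene <- character(n)
  genes <- models$genes
  for (i in seq_len(n)) {
    gid <- circs$gene_id[i] %||% ""
    gid <- if (is.na(gid)) "" else gid
    if (gid == "" || !gid %in% genes$gene_id) {
      hit <- genes[genes$chrom == circs$chrom[i] &
                     genes$start <= circs$end[i] &
                     genes$end >= circs$start[i], ]
      ambiguous[i] <- nrow(hit) > 1
      gid <- if (nrow(hit) > 0) sort(hit$gene_id)[1] else ""
    }
    host_gene[i] <- gid
    if (gid == "") {
      ctx_start[i] <- "outside_gene"; ctx_end[i] <- "outside_gene"
      category[i] <- "intergenic"
      next
    }
    grow <- genes[genes$gene_id == gid, ]
    gex <- models$exons[models$exons$gene_id == gid, ]
    cs <- end_context(circs$start[i], gex, grow$start, grow$end,
                      boundary_slop, "start")
    ce <- end_context(circs$end[i], gex, grow$start, grow$end,
                      boundary_slop, "end")
    same_intron <- FALSE
    if (cs == "inside_intron" && ce == "inside_intron") {
      gin <- models$introns[models$introns$gene_id == gid, ]
      in5 <- which(gin$start <= circs$start[i] & gin$end >= circs$start[i])
      in3 <- which(gin$start <= circs$end[i] & gin$end >= circs$end[i])
      same_intron <- length(in5) > 0 && length(in3) > 0 &&
        any(outer(gin$start[in5], gin$start[in3], "==") &
              outer(gin$end[in5], gin$end[in3], "=="))
    }
    category[i] <- category_from_contexts(cs, ce, same_intron)
    strand_mismatch[i] <- circs$strand[i] != grow$strand
    ctx_start[i] <- cs; ctx_end[i] <- ce
  }
  span <- as.integer(circs$end - circs$start + 1L)
  # end5/end3 are transcript-orientation: on '-' the genomic end is the 5' end
  minus <- circs$strand == "-"
  tibble(circ_key = circ_key(circs$chrom, circs$start, circs$end,
                             circs$strand),
         chrom = circs$chrom, start = circs$start, end = circs$end,
         strand = circs$strand, host_gene = host_gene,
         category = category,
         end5_context = ifelse(minus, ctx_end, ctx_start),
         end3_context = ifelse(minus, ctx_start, ctx_end),
         genomic_span = span,
         length_class = length_class(span, length_bins),
         strand_mismatch = strand_mismatch, ambiguous = ambiguous)
}

#' Length class of a circRNA
#'
#' Bins a genomic span into the named length classes.  With the default
#' edges `c(200, 1000, 5000)` the labels are `<200`, `200-1000`,
#' `1000-5000`, `>5000`; each class includes its lower edge.
#'
#' @param span Genomic span(s) in nt.
#' @param bins Increasing bin edges.
#' @return Character vector of class labels.
#' @export
length_class <- function(span, bins = c(200, 1000, 5000)) {
  labels <- c(paste0("<", bins[1]),
              paste(bins[-length(bins)], bins[-1], sep = "-"),
              paste0(">", bins[length(bins)]))
  idx <- findInterval(span, bins)  # left-inclusive: span == edge -> upper class
  labels[idx + 1L]
}

#' Per-gene circRNA summaries (SCG/MCG)
#'
#' Counts distinct BSJ keys per host gene and classifies genes as
#' single-circRNA (SCG, exactly 1) or multi-circRNA (MCG, >= 2); genes with
#' more than 10 distinct circRNAs are flagged `is_top_mcg`.  When a linear
#' RPM table is supplied the gene's mean linear RPM is attached and the
#' Pearson R^2 of circRNA count against gene length and against expression is
#' reported.
#'
#' @param calls Structure calls from [classify_structure()] (duplicate rows
#'   and row order do not affect the counts).
#' @param models A `gene_models` object (for gene lengths).
#' @param linear_rpm Optional tibble `gene_id`, `mean_linear_rpm`.
#' @return List: `genes` (tibble of `GeneCircSummary` rows), `scg_pct`,
#'   `mcg_pct`, `r2_length`, `r2_expression`.
#' @export
summarize_genes <- function(calls, models, linear_rpm = NULL) {
  calls <- calls[!is.na(calls$host_gene) & calls$host_gene != "", ]
  assert_that(nrow(calls) > 0, "no gene-assigned circRNAs to summarize")
  per_gene <- calls |>
    distinct(host_gene, circ_key) |>
    group_by(host_gene) |>
    summarise(n_distinct_circ = n(), .groups = "drop")
  per_gene <- left_join(per_gene,
                        models$genes[, c("gene_id", "gene_length")],
                        by = c(host_gene = "gene_id"))
  per_gene$class <- ifelse(per_gene$n_distinct_circ >= 2, "MCG", "SCG")
  per_gene$is_top_mcg <- per_gene$n_distinct_circ > 10
  if (!is.null(linear_rpm)) {
    per_gene <- left_join(per_gene, linear_rpm, by = c(host_gene = "gene_id"))
  } else {
    per_gene$mean_linear_rpm <- NA_real_
  }
  n_scg <- sum(per_gene$class == "SCG")
  list(genes = per_gene,
       scg_pct = 100 * n_scg / nrow(per_gene),
       mcg_pct = 100 * (1 - n_scg / nrow(per_gene)),
       r2_length = pearson_r2(per_gene$n_distinct_circ,
                              as.numeric(per_gene$gene_length)),
       r2_expression = pearson_r2(per_gene$n_distinct_circ,
                                  per_gene$mean_linear_rpm))
}

#' Group circRNA isoforms
#'
#' Three group kinds: `same_bsj` (identical BSJ coordinates but different
#' internal exon chains; formed only when a chains table is supplied),
#' `shared_donor` and `shared_acceptor` (distinct BSJs within one gene
#' sharing exactly the donor or the acceptor coordinate).  On the plus
#' strand the BSJ start is the acceptor and the end the donor; minus-strand
#' genes are mirrored.
#'
#' @param calls Structure calls (needs `circ_key`, `chrom`, `start`, `end`,
#'   `strand`, `host_gene`).
#' @param chains Optional tibble `circ_key`, `chain` (exon-chain label, e.g.
#'   `"e2-e3"`).
#' @return Tibble: `group_id`, `kind`, `circ_key`, `shared_end` (the shared
#'   genomic coordinate; `NA` for same_bsj groups).
#' @export
group_isoforms <- function(calls, chains = NULL) {
  out <- list()
  gid <- 0L
  if (!is.null(chains)) {
    bsj_of <- calls[match(chains$circ_key, calls$circ_key), ]
    key_bsj <- circ_id(bsj_of$chrom, bsj_of$start, bsj_of$end)
    for (b in unique(key_bsj)) {
      rows <- which(key_bsj == b)
      if (length(unique(chains$chain[rows])) >= 2) {
        gid <- gid + 1L
        out[[length(out) + 1L]] <- tibble(
          group_id = sprintf("same_bsj_%03d", gid), kind = "same_bsj",
          circ_key = chains$circ_key[rows], chain = chains$chain[rows],
          shared_end = NA_integer_)
      }
    }
  }
  uniq <- distinct(calls, circ_key, chrom, start, end, strand, host_gene)
  uniq <- uniq[!is.na(uniq$host_gene) & uniq$host_gene != "", ]
  sdid <- 0L; said <- 0L
  for (g in unique(uniq$host_gene)) {
    u <- uniq[uniq$host_gene == g, ]
    if (nrow(u) < 2) next
    minus <- u$strand[1] == "-"
    # donor = transcript 3' boundary: genomic end on '+', start on '-'
    donor <- if (minus) u$start else u$end
    acceptor <- if (minus) u$end else u$start
    for (d in unique(donor[duplicated(donor)])) {
      rows <- which(donor == d)
      if (length(unique(acceptor[rows])) >= 2) {
        sdid <- sdid + 1L
        out[[length(out) + 1L]] <- tibble(
          group_id = sprintf("shared_donor_%03d", sdid),
          kind = "shared_donor", circ_key = u$circ_key[rows],
          chain = NA_character_, shared_end = as.integer(d))
      }
    }
    for (a in unique(acceptor[duplicated(acceptor)])) {
      rows <- which(acceptor == a)
      if (length(unique(donor[rows])) >= 2) {
        said <- said + 1L
        out[[length(out) + 1L]] <- tibble(
          group_id = sprintf("shared_acceptor_%03d", said),
          kind = "shared_acceptor", circ_key = u$circ_key[rows],
          chain = NA_character_, shared_end = as.integer(a))
      }
    }
  }
  if (length(out)) bind_rows(out) else
    tibble(group_id = character(), kind = character(), circ_key = character(),
           chain = character(), shared_end = integer())
}

#' Overlap of named circRNA key sets
#'
#' Exact-key intersections for 2-3 named sets, one row per membership
#' region (as in a Venn layout), plus the fraction of each set shared with
#' at least one other set.
#'
#' @param sets Named list of 2-3 character vectors of circRNA keys.
#' @return List: `regions` (tibble `region`, `count`) and `frac_shared`
#'   (named numeric).
#' @export
intersect_datasets <- function(sets) {
  assert_that(is.list(sets) && !is.null(names(sets)) &&
                length(sets) >= 2 && length(sets) <= 3,
              "sets must be a named list of 2-3 key vectors")
  sets <- lapply(sets, unique)
  all_keys <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_keys %in% s,
                   logical(length(all_keys)))
  if (length(all_keys) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(r)
    paste(names(sets)[r], collapse = "&"))
  nm <- names(sets)
  all_patterns <- unlist(lapply(seq_along(nm), function(k)
    apply(utils::combn(nm, k), 2, paste, collapse = "&")))
  counts <- vapply(all_patterns, function(p) sum(pattern == p), integer(1))
  frac_shared <- vapply(nm, function(a) {
    others <- unique(unlist(sets[setdiff(nm, a)]))
    if (length(sets[[a]]) == 0) NA_real_ else
      mean(sets[[a]] %in% others)
  }, numeric(1))
  list(regions = tibble(region = all_patterns, count = unname(counts)),
       frac_shared = frac_shared)
}
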