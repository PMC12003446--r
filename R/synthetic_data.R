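# Seeded synthetic dataset: genome, annotation, repeats, per-sample CIRI2-style
# call tables, and a planted truth manifest covering circRNA categories,
# differential fold changes, inverted repeat pairs and RBP motif placements.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Parameters of the synthetic two-group circRNA experiment.  Defaults
#' describe a compact but realistic multi-sample study: genes of 4-8 exons of
#' 80-400 nt, circRNA-flanking introns of 2-20 kb versus 0.2-2 kb elsewhere,
#' 8 samples per group, negative-binomial junction counts, planted |log2FC|
#' of 2 with 90% of differential circRNAs upregulated, and 30-nt inverted
#' repeat pairs planted in flanking introns.
#'
#' @param seed Integer seed; fixes every downstream draw.
#' @param n_genes Number of genes.
#' @param exons_per_gene,exon_length,intron_length_flank,intron_length_other
#'   Integer ranges `c(min, max)` (nt).  Flanking introns of planted
#'   circRNAs are drawn from `intron_length_flank`, all others from
#'   `intron_length_other`.
#' @param n_samples_per_group Samples in each of case and control.
#' @param frac_circ_genes Fraction of genes hosting >= 1 planted circRNA.
#' @param frac_multi_circ Fraction of circRNA genes hosting several distinct
#'   BSJs (multi-circRNA genes).
#' @param frac_differential Fraction of planted circRNAs given a non-zero
#'   fold change.
#' @param planted_log2fc Magnitude of the planted log2 fold change.
#' @param frac_upregulated Fraction of differential circRNAs planted as up.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param base_mean_junction_reads,base_mean_linear_reads Log-normal location
#'   of per-circRNA baseline junction / linear counts at the nominal library
#'   size.
#' @param library_size Nominal mappable reads per sample (actual per-sample
#'   totals vary uniformly within +/- 10%).
#' @param frac_intergenic Fraction of planted circRNAs placed between genes.
#' @param repeat_plant List: `length` (nt), `identity` (percent),
#'   `frac_inverted` and `frac_co_oriented` — the fractions of eligible circ
#'   loci receiving an inverted repeat pair or a co-oriented (control) pair
#'   in their flanking introns.
#' @param motif_plant List of plans, each a list with `motif` (RNA or DNA
#'   alphabet), `region` (`exon_body`, `upstream_250`, `downstream_250`),
#'   `copies`, and `fraction` of eligible circRNAs receiving the plant.
#' @param spacer_length Intergenic spacer between genes (nt).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 40L,
                       exons_per_gene = c(4L, 8L),
                       exon_length = c(80L, 400L),
                       intron_length_flank = c(2000L, 20000L),
                       intron_length_other = c(200L, 2000L),
                       n_samples_per_group = 8L,
                       frac_circ_genes = 0.5,
                       frac_multi_circ = 0.2,
                       frac_differential = 0.5,
                       planted_log2fc = 2.0,
                       frac_upregulated = 0.9,
                       nb_dispersion = 0.1,
                       base_mean_junction_reads = 50,
                       base_mean_linear_reads = 200,
                       library_size = 2e6,
                       frac_intergenic = 0.005,
                       repeat_plant = list(length = 30L, identity = 100,
                                           frac_inverted = 0.6,
                                           frac_co_oriented = 0.2),
                       motif_plant = list(list(motif = "UGCUU",
                                               region = "downstream_250",
                                               copies = 5L, fraction = 0.5)),
                       spacer_length = 400L) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length = as.integer(exon_length),
              intron_length_flank = as.integer(intron_length_flank),
              intron_length_other = as.integer(intron_length_other),
              n_samples_per_group = as.integer(n_samples_per_group),
              frac_circ_genes = frac_circ_genes,
              frac_multi_circ = frac_multi_circ,
              frac_differential = frac_differential,
              planted_log2fc = planted_log2fc,
              frac_upregulated = frac_upregulated,
              nb_dispersion = nb_dispersion,
              base_mean_junction_reads = base_mean_junction_reads,
              base_mean_linear_reads = base_mean_linear_reads,
              library_size = library_size,
              frac_intergenic = frac_intergenic,
              repeat_plant = repeat_plant, motif_plant = motif_plant,
              spacer_length = as.integer(spacer_length))
  for (f in c("frac_circ_genes", "frac_multi_circ", "frac_differential",
              "frac_upregulated", "frac_intergenic")) {
    assert_that(cfg[[f]] >= 0 && cfg[[f]] <= 1, "%s must be in [0, 1]", f)
  }
  assert_that(cfg$n_samples_per_group >= 1, "need >= 1 sample per group")
  assert_that(cfg$library_size > 0, "library_size must be positive")
  assert_that(cfg$intron_length_flank[1] >=
                cfg$repeat_plant$length + 600L,
              "flanking introns too short for the planted repeat + margins")
  structure(cfg, class = "sim_config")
}

rand_range <- function(lo_hi, n = 1L) {
  as.integer(sample(seq(lo_hi[1], lo_hi[2]), n, replace = TRUE))
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# circRNA plan types cycled over single-circ genes so every structural class
# and end-label class is represented in even small simulations.
SINGLE_CIRC_TYPES <- c("exonic", "exonic", "se", "intronic", "ei", "ie",
                       "ie_last")

#' Build the synthetic locus set
#'
#' Generates the genome sequence, exon/intron annotation, repeat annotation
#' and the skeleton truth manifest: planted circRNAs with known structural
#' categories and end labels, inverted or co-oriented repeat pairs in
#' flanking introns, and motif copies written into the configured windows.
#'
#' @param config A [sim_config()].
#' @return An object of class `circ_locus_set`: `genome` (a `genome_seq`),
#'   `models` (a `gene_models`), `repeats` (tibble), `manifest` (planted
#'   circRNAs), `repeat_pairs` and `motif_plants` (tibbles), `config`.
#' @export
build_locus_set <- function(config) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  with_seed(config$seed, build_locus_set_impl(config))
}

build_locus_set_impl <- function(config) {
  n_genes <- config$n_genes
  n_circ_genes <- round(config$frac_circ_genes * n_genes)
  circ_gene_idx <- if (n_circ_genes > 0) sort(sample(n_genes, n_circ_genes))
    else integer(0)
  n_multi <- round(config$frac_multi_circ * n_circ_genes)
  multi_idx <- if (n_multi > 0) circ_gene_idx[seq_len(n_multi)] else integer(0)
  single_idx <- setdiff(circ_gene_idx, multi_idx)
  single_types <- rep(SINGLE_CIRC_TYPES, length.out = length(single_idx))

  chrom <- "chr1"
  chrom_parts <- list()   # sequence fragments, assembled at the end
  cursor <- 0L            # last filled genomic position
  exon_rows <- list()
  circ_rows <- list()
  repeat_rows <- list()
  spacers <- list()
  gi <- 0L

  add_spacer <- function() {
    s <- rand_dna(config$spacer_length)
    chrom_parts[[length(chrom_parts) + 1L]] <<- s
    sp <- c(cursor + 1L, cursor + config$spacer_length)
    cursor <<- cursor + config$spacer_length
    spacers[[length(spacers) + 1L]] <<- sp
    sp
  }

  for (g in seq_len(n_genes)) {
    add_spacer()
    gene_id <- sprintf("g%03d", g)
    tx_id <- paste0(gene_id, ".t1")
    strand <- sample(c("+", "-"), 1)
    is_circ <- g %in% circ_gene_idx
    is_multi <- g %in% multi_idx
    n_ex <- rand_range(config$exons_per_gene)
    if (is_circ) n_ex <- max(n_ex, 6L)
    plan_type <- if (is_multi) "multi" else if (is_circ)
      single_types[match(g, single_idx)] else "none"

    # Per-plan geometry in gene-local genomic order -------------------------
    n_int <- n_ex - 1L
    el <- rand_range(config$exon_length, n_ex)
    flank_set <- integer(0)  # genomic intron ordinals drawn from flank range
    plans <- list()
    tx_intron_of_genomic <- function(k) if (strand == "+") k else n_int + 1L - k

    if (plan_type == "multi") {
      # base (3,4) plus variants sharing one BSJ end each
      plans <- list(list(kind = "exonic", a = 3L, b = 4L),
                    list(kind = "exonic", a = 3L, b = 5L),
                    list(kind = "exonic", a = 2L, b = 4L))
      flank_set <- 1:5
    } else if (plan_type == "exonic") {
      a <- sample(2:(n_ex - 2L), 1)
      b <- a + 1L
      plans <- list(list(kind = "exonic", a = a, b = b))
      flank_set <- c(a - 1L, b)
    } else if (plan_type == "se") {
      a <- sample(2:(n_ex - 1L), 1)
      plans <- list(list(kind = "se", a = a, b = a))
      flank_set <- c(a - 1L, a)
    } else if (plan_type == "intronic") {
      t_idx <- sample(1:2, 1)            # transcript-orientation intron index
      k <- if (strand == "+") t_idx else n_int + 1L - t_idx
      plans <- list(list(kind = "intronic", k = k, t_idx = t_idx))
      flank_set <- k
    } else if (plan_type == "ei") {
      a <- sample(2:(n_ex - 1L), 1)
      plans <- list(list(kind = "ei", a = a))
      flank_set <- c(a - 1L, a)
    } else if (plan_type == "ie") {
      a <- sample(2:(n_ex - 2L), 1)
      plans <- list(list(kind = "ie", a = a, b = a + 1L))
      flank_set <- c(a - 1L, a + 1L)
    } else if (plan_type == "ie_last") {
      if (strand == "+") {
        plans <- list(list(kind = "ie_last", a = n_ex - 1L, b = n_ex))
        flank_set <- n_ex - 2L
      } else {
        plans <- list(list(kind = "ie_last", a = 1L, b = 2L))
        flank_set <- 2L
      }
    }

    il <- rand_range(config$intron_length_other, max(n_int, 1L))[seq_len(n_int)]
    if (length(flank_set)) {
      flank_set <- flank_set[flank_set >= 1 & flank_set <= n_int]
      il[flank_set] <- rand_range(config$intron_length_flank,
                                  length(flank_set))
    }

    # Local coordinates -> absolute ----------------------------------------
    ex_start <- integer(n_ex); ex_end <- integer(n_ex)
    in_start <- integer(n_int); in_end <- integer(n_int)
    pos <- cursor + 1L
    for (k in seq_len(n_ex)) {
      ex_start[k] <- pos; ex_end[k] <- pos + el[k] - 1L
      pos <- ex_end[k] + 1L
      if (k <= n_int) {
        in_start[k] <- pos; in_end[k] <- pos + il[k] - 1L
        pos <- in_end[k] + 1L
      }
    }
    gene_len <- pos - 1L - cursor
    gene_seq <- strsplit(rand_dna(gene_len), "")[[1]]
    gene_offset <- cursor  # absolute = local + gene_offset

    # canonical GT...AG at every intron's transcribed ends: on '+' the
    # genomic intron starts GT and ends AG; on '-' the transcribed GT/AG map
    # to genomic CT at the intron start and AC at its end
    for (k in seq_len(n_int)) {
      ls <- in_start[k] - gene_offset; le <- in_end[k] - gene_offset
      if (strand == "+") {
        gene_seq[ls:(ls + 1L)] <- c("G", "T")
        gene_seq[(le - 1L):le] <- c("A", "G")
      } else {
        gene_seq[ls:(ls + 1L)] <- c("C", "T")
        gene_seq[(le - 1L):le] <- c("A", "C")
      }
    }

    exon_rows[[length(exon_rows) + 1L]] <- tibble(
      gene_id = gene_id, transcript_id = tx_id, chrom = chrom,
      strand = strand, start = ex_start, end = ex_end)
    # a second, exon-skipping transcript for some non-circ genes
    if (!is_circ && n_ex >= 4 && g %% 5 == 0) {
      keep <- setdiff(seq_len(n_ex), 2L)
      exon_rows[[length(exon_rows) + 1L]] <- tibble(
        gene_id = gene_id, transcript_id = paste0(gene_id, ".t2"),
        chrom = chrom, strand = strand,
        start = ex_start[keep], end = ex_end[keep])
    }

    flank_of <- function(up_k, down_k) {
      # genomic intron ordinals before/after the circ; orient to transcript
      up <- if (!is.na(up_k) && up_k >= 1 && up_k <= n_int)
        c(in_start[up_k], in_end[up_k]) else c(NA_integer_, NA_integer_)
      dn <- if (!is.na(down_k) && down_k >= 1 && down_k <= n_int)
        c(in_start[down_k], in_end[down_k]) else c(NA_integer_, NA_integer_)
      if (strand == "+") list(up = up, down = dn) else list(up = dn, down = up)
    }

    for (pl in plans) {
      row <- NULL
      if (pl$kind %in% c("exonic", "se")) {
        fl <- flank_of(pl$a - 1L, pl$b)
        row <- list(start = ex_start[pl$a], end = ex_end[pl$b],
                    category = "exonic",
                    start_label = "annotated", end_label = "annotated",
                    intron_index = NA_integer_, single_exon = pl$a == pl$b,
                    last_exon = FALSE, fl = fl)
      } else if (pl$kind == "intronic") {
        k <- pl$k
        cstart <- in_start[k] + 150L
        cend <- cstart + rand_range(c(100L, 400L))
        row <- list(start = cstart, end = cend, category = "intronic",
                    start_label = "ii_bsj", end_label = "ii_bsj",
                    intron_index = pl$t_idx, single_exon = FALSE,
                    last_exon = FALSE,
                    fl = list(up = c(NA_integer_, NA_integer_),
                              down = c(NA_integer_, NA_integer_)))
      } else if (pl$kind == "ei") {
        a <- pl$a
        cend <- in_start[a] + 100L + rand_range(c(0L, 200L))
        fl <- flank_of(a - 1L, NA_integer_)
        row <- list(start = ex_start[a], end = cend,
                    category = "exonic+intronic",
                    start_label = "annotated", end_label = "ii_bsj",
                    intron_index = tx_intron_of_genomic(a),
                    single_exon = FALSE, last_exon = FALSE, fl = fl)
      } else if (pl$kind == "ie") {
        fl <- flank_of(pl$a - 1L, pl$b)
        row <- list(start = ex_start[pl$a], end = ex_end[pl$b] - 10L,
                    category = "exonic",
                    start_label = "annotated", end_label = "ie_bsj",
                    intron_index = NA_integer_, single_exon = FALSE,
                    last_exon = FALSE, fl = fl)
      } else if (pl$kind == "ie_last") {
        if (strand == "+") {
          fl <- flank_of(pl$a - 1L, NA_integer_)
          row <- list(start = ex_start[pl$a], end = ex_start[pl$b] + 20L,
                      category = "exonic",
                      start_label = "annotated", end_label = "ie_bsj",
                      intron_index = NA_integer_, single_exon = FALSE,
                      last_exon = TRUE, fl = fl)
        } else {
          fl <- flank_of(NA_integer_, pl$b)
          row <- list(start = ex_end[pl$a] - 20L, end = ex_end[pl$b],
                      category = "exonic",
                      start_label = "ie_bsj", end_label = "annotated",
                      intron_index = NA_integer_, single_exon = FALSE,
                      last_exon = TRUE, fl = fl)
        }
      }
      circ_rows[[length(circ_rows) + 1L]] <- tibble(
        chrom = chrom, start = row$start, end = row$end, strand = strand,
        gene_id = gene_id, transcript_id = tx_id, category = row$category,
        start_label = row$start_label, end_label = row$end_label,
        intron_index = row$intron_index, single_exon = row$single_exon,
        last_exon = row$last_exon,
        up_intron_start = row$fl$up[1], up_intron_end = row$fl$up[2],
        down_intron_start = row$fl$down[1], down_intron_end = row$fl$down[2],
        multi_gene = is_multi)
    }

    chrom_parts[[length(chrom_parts) + 1L]] <- paste(gene_seq, collapse = "")
    cursor <- cursor + gene_len
    gi <- gi + 1L
  }
  final_spacer <- add_spacer()

  chrom_seq <- strsplit(paste(unlist(chrom_parts), collapse = ""), "")[[1]]
  manifest <- if (length(circ_rows)) bind_rows(circ_rows) else
    empty_manifest()

  # Intergenic circRNAs in spacer regions ---------------------------------
  n_intergenic <- if (config$frac_intergenic > 0 && nrow(manifest) > 0)
    as.integer(ceiling(config$frac_intergenic * nrow(manifest))) else 0L
  if (n_intergenic > 0) {
    sp_pick <- spacers[seq_len(min(n_intergenic, length(spacers)))]
    inter <- bind_rows(lapply(sp_pick, function(sp) {
      tibble(chrom = chrom, start = sp[1] + 50L, end = sp[1] + 250L,
             strand = "+", gene_id = "", transcript_id = "",
             category = "intergenic", start_label = "outside",
             end_label = "outside", intron_index = NA_integer_,
             single_exon = FALSE, last_exon = FALSE,
             up_intron_start = NA_integer_, up_intron_end = NA_integer_,
             down_intron_start = NA_integer_, down_intron_end = NA_integer_,
             multi_gene = FALSE)
    }))
    manifest <- bind_rows(manifest, inter)
  }
  if (nrow(manifest) > 0) {
    manifest$circ_id <- circ_id(manifest$chrom, manifest$start, manifest$end)
    manifest$key <- circ_key(manifest$chrom, manifest$start, manifest$end,
                             manifest$strand)
  } else {
    manifest$circ_id <- character(0); manifest$key <- character(0)
  }

  # Planted fold changes ---------------------------------------------------
  manifest$log2fc <- 0
  eligible_diff <- which(manifest$category != "intergenic")
  n_diff <- round(config$frac_differential * length(eligible_diff))
  if (n_diff > 0) {
    diff_idx <- sample(eligible_diff, n_diff)
    n_up <- round(config$frac_upregulated * n_diff)
    sign_vec <- sample(c(rep(1, n_up), rep(-1, n_diff - n_up)))
    manifest$log2fc[diff_idx] <- sign_vec * config$planted_log2fc
  }
  manifest$base_mean <- if (nrow(manifest) > 0)
    rlnorm(nrow(manifest), log(config$base_mean_junction_reads), 0.5) else
    numeric(0)

  # Repeat pairs in flanking introns ---------------------------------------
  rp <- config$repeat_plant
  # multi-circRNA genes share flanking introns between their BSJ variants,
  # so planting there would overwrite one pair with another; skip them
  eligible_rep <- which(!is.na(manifest$up_intron_start) &
                          !is.na(manifest$down_intron_start) &
                          !manifest$multi_gene)
  manifest$repeat_status <- "none"
  repeat_pairs <- list()
  if (length(eligible_rep) > 0 && rp$length > 0) {
    ord <- sample(eligible_rep)
    n_inv <- round(rp$frac_inverted * length(ord))
    n_co <- round(rp$frac_co_oriented * length(ord))
    status <- rep("none", length(ord))
    status[seq_len(n_inv)] <- "inverted"
    if (n_co > 0) status[n_inv + seq_len(n_co)] <- "co_oriented"
    for (j in seq_along(ord)) {
      if (status[j] == "none") next
      i <- ord[j]
      L <- rp$length
      up_mid <- (manifest$up_intron_start[i] + manifest$up_intron_end[i]) %/% 2L
      dn_mid <- (manifest$down_intron_start[i] +
                   manifest$down_intron_end[i]) %/% 2L
      up_iv <- c(up_mid, up_mid + L - 1L)
      dn_iv <- c(dn_mid, dn_mid + L - 1L)
      rseq <- rand_dna(L)
      dseq <- if (status[j] == "inverted") revcomp_chr(rseq) else rseq
      n_mut <- round((1 - rp$identity / 100) * L)
      if (n_mut > 0) {
        posm <- sample(L, n_mut)
        dv <- strsplit(dseq, "")[[1]]
        for (p in posm) dv[p] <- sample(setdiff(c("A", "C", "G", "T"), dv[p]), 1)
        dseq <- paste(dv, collapse = "")
      }
      chrom_seq[up_iv[1]:up_iv[2]] <- strsplit(rseq, "")[[1]]
      chrom_seq[dn_iv[1]:dn_iv[2]] <- strsplit(dseq, "")[[1]]
      manifest$repeat_status[i] <- status[j]
      repeat_rows[[length(repeat_rows) + 1L]] <- tibble(
        chrom = chrom, start = c(up_iv[1], dn_iv[1]),
        end = c(up_iv[2], dn_iv[2]),
        strand = c("+", if (status[j] == "inverted") "-" else "+"),
        family = "SINE_synth")
      repeat_pairs[[length(repeat_pairs) + 1L]] <- tibble(
        key = manifest$key[i], up_start = up_iv[1], up_end = up_iv[2],
        down_start = dn_iv[1], down_end = dn_iv[2],
        orientation = status[j], length = L, identity = rp$identity)
    }
  }
  # background repeats far from any circ (first "other" intron of non-circ
  # genes is left unannotated; a light decoy set keeps the BED realistic)
  repeats <- if (length(repeat_rows)) bind_rows(repeat_rows) else
    tibble(chrom = character(), start = integer(), end = integer(),
           strand = character(), family = character())

  # Motif plants ------------------------------------------------------------
  manifest_motifs <- list()
  for (mp in config$motif_plant %||% list()) {
    motif_dna <- toupper(gsub("U", "T", mp$motif))
    elig <- which(manifest$category == "exonic" & !manifest$multi_gene &
                    manifest$start_label == "annotated" &
                    manifest$end_label == "annotated")
    if (mp$region == "upstream_250") {
      elig <- elig[!is.na(manifest$up_intron_start[elig])]
    } else if (mp$region == "downstream_250") {
      elig <- elig[!is.na(manifest$down_intron_start[elig])]
    }
    if (length(elig) == 0) next
    n_take <- max(1L, round(mp$fraction * length(elig)))
    take <- sample(elig, min(n_take, length(elig)))
    for (i in take) {
      ivs <- motif_plant_positions(manifest[i, ], mp$region, nchar(motif_dna),
                                   mp$copies)
      for (r in seq_len(nrow(ivs))) {
        mseq <- if (ivs$revcomp[r]) revcomp_chr(motif_dna) else motif_dna
        chrom_seq[ivs$start[r]:ivs$end[r]] <- strsplit(mseq, "")[[1]]
      }
      manifest_motifs[[length(manifest_motifs) + 1L]] <- tibble(
        key = manifest$key[i], motif = mp$motif, region = mp$region,
        copies = mp$copies)
    }
  }

  genome <- genome_from_seqs(setNames(
    list(paste(chrom_seq, collapse = "")), chrom))
  models <- gene_models(bind_rows(exon_rows))
  structure(list(
    genome = genome, models = models, repeats = repeats,
    manifest = manifest,
    repeat_pairs = if (length(repeat_pairs)) bind_rows(repeat_pairs) else
      tibble(key = character(), up_start = integer(), up_end = integer(),
             down_start = integer(), down_end = integer(),
             orientation = character(), length = integer(),
             identity = numeric()),
    motif_plants = if (length(manifest_motifs)) bind_rows(manifest_motifs) else
      tibble(key = character(), motif = character(), region = character(),
             copies = integer()),
    config = config), class = "circ_locus_set")
}

empty_manifest <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         strand = character(), gene_id = character(),
         transcript_id = character(), category = character(),
         start_label = character(), end_label = character(),
         intron_index = integer(), single_exon = logical(),
         last_exon = logical(), up_intron_start = integer(),
         up_intron_end = integer(), down_intron_start = integer(),
         down_intron_end = integer(), multi_gene = logical())
}

# Genomic intervals for `copies` motif placements in a transcript-orientation
# window next to (or inside) a planted circRNA.  Offsets step by motif length
# + 10 nt so copies never overlap.
motif_plant_positions <- function(m, region, L, copies) {
  step <- L + 10L
  offs <- 10L + step * (seq_len(copies) - 1L)
  plus <- m$strand == "+"
  if (region == "exon_body") {
    gstart <- if (plus) m$start + offs else m$end - offs - L + 1L
  } else if (region == "downstream_250") {
    gstart <- if (plus) m$end + offs + 1L else m$start - offs - L
  } else if (region == "upstream_250") {
    gstart <- if (plus) m$start - offs - L else m$end + offs + 1L
  } else stop_circkit("unknown motif region '%s'", region)
  tibble(start = as.integer(gstart), end = as.integer(gstart + L - 1L),
         revcomp = !plus)
}

#' Simulate junction and linear counts for planted circRNAs
#'
#' Junction reads per circRNA and sample are negative-binomial with mean
#' `base_mean * 2^(log2fc * case_indicator) * library_size_s / nominal`, and
#' variance `mu + dispersion * mu^2` (`dispersion = 0` gives Poisson).
#' Non-junction (linear) counts are drawn independently of the junction
#' counts, so circular-linear correlation is ~0 by construction.
#'
#' @param manifest Tibble with at least `circ_id` (or `key`); optional
#'   `log2fc` (default 0) and `base_mean` columns.
#' @param config A [sim_config()]; `n_samples_per_group`, `nb_dispersion`,
#'   `library_size` and the base means are taken from it.
#' @return A list of class `circ_sim_counts`: `counts` and `linear` matrices
#'   (circRNAs x samples), `sheet` (sample sheet tibble).
#' @export
simulate_counts <- function(manifest, config) {
  manifest <- as_tibble(manifest)
  keys <- if ("key" %in% names(manifest)) manifest$key else
    manifest[["circ_id"]]
  assert_that(!is.null(keys), "manifest needs a key or circ_id column")
  with_seed(config$seed + 1L, {
    n <- nrow(manifest)
    npg <- config$n_samples_per_group
    sheet <- tibble(
      sample_id = c(sprintf("case_%02d", seq_len(npg)),
                    sprintf("ctrl_%02d", seq_len(npg))),
      group = rep(c("case", "control"), each = npg),
      mappable_reads = as.integer(round(config$library_size *
                                          runif(2 * npg, 0.9, 1.1))),
      tissue = "synthetic")
    lfc <- if ("log2fc" %in% names(manifest)) manifest$log2fc else rep(0, n)
    base_mean <- if ("base_mean" %in% names(manifest)) manifest$base_mean else
      rlnorm(n, log(config$base_mean_junction_reads), 0.5)
    base_linear <- rlnorm(n, log(config$base_mean_linear_reads), 0.5)
    draw <- function(mu) {
      if (config$nb_dispersion <= 0) rpois(length(mu), mu) else
        rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    }
    counts <- matrix(0L, n, 2 * npg, dimnames = list(keys, sheet$sample_id))
    linear <- counts
    for (s in seq_len(2 * npg)) {
      scale_s <- sheet$mappable_reads[s] / config$library_size
      is_case <- sheet$group[s] == "case"
      mu <- base_mean * 2^(lfc * as.numeric(is_case)) * scale_s
      counts[, s] <- as.integer(draw(mu))
      linear[, s] <- as.integer(draw(base_linear * scale_s))
    }
    structure(list(counts = counts, linear = linear, sheet = sheet),
              class = "circ_sim_counts")
  })
}

#' Simulate a complete dataset (locus set + counts)
#'
#' @param config A [sim_config()].
#' @return List of class `circ_sim`: `locus` (a `circ_locus_set`) and
#'   `counts` (a `circ_sim_counts`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  locus <- build_locus_set(config)
  counts <- simulate_counts(locus$manifest, config)
  structure(list(locus = locus, counts = counts, config = config),
            class = "circ_sim")
}

#' Write a simulated dataset to disk
#'
#' Emits: `genome.fa`, `annotation.gtf`, `repeats.bed`, one
#' `ciri_<sample>.tsv` per sample in the CIRI2 output dialect (a circRNA
#' appears in a sample's table only when it has >= 1 junction read there),
#' `samples.tsv`, and the truth tables `truth_circ.tsv`,
#' `truth_repeats.tsv`, `truth_motifs.tsv`.
#'
#' @param sim A `circ_sim` from [simulate_dataset()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
emit_dataset <- function(sim, out_dir) {
  assert_that(inherits(sim, "circ_sim"), "sim must come from simulate_dataset()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  locus <- sim$locus; cm <- sim$counts
  paths <- list()

  paths$genome <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(locus$genome$seqs, paths$genome, width = 70L)

  paths$gtf <- file.path(out_dir, "annotation.gtf")
  ex <- locus$models$exons
  gtf_lines <- sprintf(
    '%s\tcirckit_sim\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    ex$chrom, ex$start, ex$end, ex$strand, ex$gene_id, ex$transcript_id)
  writeLines(gtf_lines, paths$gtf)

  paths$repeats <- file.path(out_dir, "repeats.bed")
  write_repeat_annotation(locus$repeats, paths$repeats)

  paths$samples <- file.path(out_dir, "samples.tsv")
  write_tsv_plain(cm$sheet, paths$samples)

  m <- locus$manifest
  type_map <- c(exonic = "exon", intronic = "intron",
                `exonic+intronic` = "exon", intergenic = "intergenic_region")
  reported <- unname(type_map[m$category])
  ciri_paths <- character(0)
  for (s in cm$sheet$sample_id) {
    j <- cm$counts[m$key, s]
    nj <- cm$linear[m$key, s]
    keep <- which(j >= 1)
    df <- data.frame(
      circRNA_ID = m$circ_id[keep], chr = m$chrom[keep],
      circRNA_start = m$start[keep], circRNA_end = m$end[keep],
      junction_reads = j[keep], SM_MS_SMS = "0_0_0",
      non_junction_reads = nj[keep],
      junction_reads_ratio = sprintf("%.3f",
        2 * j[keep] / pmax(2 * j[keep] + nj[keep], 1)),
      circRNA_type = reported[keep],
      gene_id = ifelse(m$gene_id[keep] == "", "n/a", m$gene_id[keep]),
      strand = m$strand[keep], junction_reads_ID = ".",
      check.names = FALSE)
    names(df)[names(df) == "junction_reads"] <- "#junction_reads"
    names(df)[names(df) == "non_junction_reads"] <- "#non_junction_reads"
    p <- file.path(out_dir, paste0("ciri_", s, ".tsv"))
    write_tsv_plain(df, p)
    ciri_paths <- c(ciri_paths, p)
  }
  paths$ciri <- ciri_paths

  paths$truth_circ <- file.path(out_dir, "truth_circ.tsv")
  write_tsv_plain(m, paths$truth_circ)
  paths$truth_repeats <- file.path(out_dir, "truth_repeats.tsv")
  write_tsv_plain(locus$repeat_pairs, paths$truth_repeats)
  paths$truth_motifs <- file.path(out_dir, "truth_motifs.tsv")
  write_tsv_plain(locus$motif_plants, paths$truth_motifs)
  invisible(paths)
}
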