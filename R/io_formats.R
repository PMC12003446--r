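# Readers and writers for the external formats the pipeline touches.
# Internal convention everywhere: 1-based, inclusive genomic coordinates.

CIRI_COLUMNS <- c("circRNA_ID", "chr", "circRNA_start", "circRNA_end",
                  "#junction_reads", "SM_MS_SMS", "#non_junction_reads",
                  "junction_reads_ratio", "circRNA_type", "gene_id", "strand",
                  "junction_reads_ID")

#' Read a CIRI2 circRNA call table
#'
#' Parses one per-sample circRNA table in the CIRI2 output dialect (TSV with a
#' header line).  Coordinates are kept 1-based inclusive as in the source.
#' Rows typed `intergenic_region` are retained but flagged
#' (`intergenic_flag`), so that downstream stages can apply the usual
#' exclusion of intergenic and mixed-intergenic calls.  Duplicate rows for the
#' same junction (identical chrom/start/end/strand) have their junction and
#' non-junction reads summed, with a warning.
#'
#' @param path Path to a CIRI2-dialect TSV file.
#' @param sample_id Sample identifier attached to every record.
#' @return A tibble with one row per BSJ call: `circ_id`, `chrom`, `start`,
#'   `end`, `strand`, `junction_reads`, `non_junction_reads`, `reported_type`,
#'   `gene_id`, `sample_id`, `intergenic_flag`, plus the opaque carried
#'   columns `SM_MS_SMS`, `junction_reads_ratio`, `junction_reads_ID`.
#' @export
read_ciri_table <- function(path, sample_id) {
  assert_that(file.exists(path), "CIRI table not found: %s", path)
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(setdiff(CIRI_COLUMNS, c("junction_reads_ID")),
                          names(raw))
  if (length(missing_cols) > 0) {
    stop_circkit("CIRI table %s is missing required column(s): %s",
                 path, paste(missing_cols, collapse = ", "),
                 class = "circkit_format_error")
  }
  if (nrow(raw) == 0) return(empty_circ_table())

  parse_int <- function(x, colname) {
    bad <- !grepl("^[0-9]+$", x)
    if (any(bad)) {
      stop_circkit("non-integer value '%s' in column %s of %s (line %d)",
                   x[which(bad)[1]], colname, path, which(bad)[1] + 1L,
                   class = "circkit_parse_error")
    }
    as.integer(x)
  }
  strand <- raw[["strand"]]
  bad_strand <- !(strand %in% c("+", "-"))
  if (any(bad_strand)) {
    stop_circkit("invalid strand '%s' in %s (line %d); expected + or -",
                 strand[which(bad_strand)[1]], path, which(bad_strand)[1] + 1L,
                 class = "circkit_parse_error")
  }

  out <- tibble(
    chrom = raw[["chr"]],
    start = parse_int(raw[["circRNA_start"]], "circRNA_start"),
    end = parse_int(raw[["circRNA_end"]], "circRNA_end"),
    strand = strand,
    junction_reads = parse_int(raw[["#junction_reads"]], "#junction_reads"),
    non_junction_reads = parse_int(raw[["#non_junction_reads"]],
                                   "#non_junction_reads"),
    reported_type = raw[["circRNA_type"]],
    gene_id = ifelse(raw[["gene_id"]] %in% c("n/a", "."), "", raw[["gene_id"]]),
    sample_id = sample_id,
    SM_MS_SMS = raw[["SM_MS_SMS"]],
    junction_reads_ratio = raw[["junction_reads_ratio"]],
    junction_reads_ID = if ("junction_reads_ID" %in% names(raw))
      raw[["junction_reads_ID"]] else ""
  )
  assert_that(all(out$start <= out$end),
              "circRNA with start > end in %s", path)
  out$circ_id <- circ_id(out$chrom, out$start, out$end)
  out$intergenic_flag <- out$reported_type == "intergenic_region"

  dup <- duplicated(out[, c("chrom", "start", "end", "strand")])
  if (any(dup)) {
    warning(sprintf("%s: %d duplicate circRNA row(s) merged (reads summed)",
                    path, sum(dup)))
    out <- out |>
      group_by(chrom, start, end, strand) |>
      summarise(
        junction_reads = sum(junction_reads),
        non_junction_reads = sum(non_junction_reads),
        reported_type = reported_type[1], gene_id = gene_id[1],
        sample_id = sample_id[1], SM_MS_SMS = SM_MS_SMS[1],
        junction_reads_ratio = junction_reads_ratio[1],
        junction_reads_ID = junction_reads_ID[1], circ_id = circ_id[1],
        intergenic_flag = intergenic_flag[1], .groups = "drop")
  }
  out[, c("circ_id", "chrom", "start", "end", "strand", "junction_reads",
          "non_junction_reads", "reported_type", "gene_id", "sample_id",
          "intergenic_flag", "SM_MS_SMS", "junction_reads_ratio",
          "junction_reads_ID")]
}

empty_circ_table <- function() {
  tibble(circ_id = character(), chrom = character(), start = integer(),
         end = integer(), strand = character(), junction_reads = integer(),
         non_junction_reads = integer(), reported_type = character(),
         gene_id = character(), sample_id = character(),
         intergenic_flag = logical(), SM_MS_SMS = character(),
         junction_reads_ratio = character(), junction_reads_ID = character())
}

#' Build gene models from an exon table
#'
#' Constructs the internal gene-model object from a table of exon intervals.
#' Exons are grouped by transcript and sorted by genomic position; introns are
#' derived as the gaps between consecutive exons.  Intron indices
#' (`intron_index`) are numbered in transcript orientation, so index 1 is the
#' intron following the first transcribed exon on either strand.
#'
#' @param exons A data frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end` (1-based inclusive).
#' @param cds Optional data frame of CDS intervals (`transcript_id`, `start`,
#'   `end`); used only to flag 3'-UTR membership of BSJ ends.
#' @return An object of class `gene_models`: a list with tibbles `exons`,
#'   `introns`, `transcripts` and `genes`.
#' @export
gene_models <- function(exons, cds = NULL) {
  exons <- as_tibble(exons)
  needed <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  assert_that(all(needed %in% names(exons)),
              "exon table must have columns: %s", paste(needed, collapse = ", "))
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  exons <- arrange(exons, gene_id, transcript_id, start)

  introns_list <- list()
  for (tx in unique(exons$transcript_id)) {
    ex <- exons[exons$transcript_id == tx, ]
    if (nrow(ex) > 1) {
      overlap <- any(ex$start[-1] <= ex$end[-nrow(ex)])
      if (overlap) {
        stop_circkit("overlapping exons within transcript %s", tx,
                     class = "circkit_format_error")
      }
      istart <- ex$end[-nrow(ex)] + 1L
      iend <- ex$start[-1] - 1L
      genomic_ord <- seq_len(nrow(ex) - 1L)
      # transcript orientation: on '-' the first transcribed intron is the
      # genomically last gap
      idx <- if (ex$strand[1] == "+") genomic_ord else rev(genomic_ord)
      introns_list[[tx]] <- tibble(
        gene_id = ex$gene_id[1], transcript_id = tx, chrom = ex$chrom[1],
        strand = ex$strand[1], start = istart, end = iend,
        intron_index = idx)
    }
  }
  introns <- if (length(introns_list)) bind_rows(introns_list) else
    tibble(gene_id = character(), transcript_id = character(),
           chrom = character(), strand = character(), start = integer(),
           end = integer(), intron_index = integer())
  assert_that(all(introns$end >= introns$start),
              "derived intron of length < 1; adjacent exons must not touch")

  transcripts <- exons |>
    group_by(gene_id, transcript_id, chrom, strand) |>
    summarise(start = min(start), end = max(end), n_exons = n(),
              .groups = "drop") |>
    mutate(span = end - start + 1L)
  genes <- transcripts |>
    group_by(gene_id, chrom, strand) |>
    summarise(start = min(start), end = max(end),
              n_transcripts = n(), .groups = "drop") |>
    mutate(gene_length = end - start + 1L)

  structure(list(exons = exons, introns = introns, transcripts = transcripts,
                 genes = genes, cds = if (is.null(cds)) NULL else as_tibble(cds)),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d genes, %d transcripts, %d exons, %d introns\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons),
              nrow(x$introns)))
  invisible(x)
}

#' Read gene models from a GTF file
#'
#' Imports `exon` features from an Ensembl-dialect GTF and derives introns as
#' inter-exon gaps.  Exon rows without a `transcript_id` attribute are skipped
#' with a warning; overlapping exons within one transcript are an error.
#' CDS features, when present, are retained for 3'-UTR flagging.
#'
#' @param path Path to a GTF file.
#' @return A `gene_models` object (see [gene_models()]).
#' @export
read_gene_models <- function(path) {
  assert_that(file.exists(path), "GTF not found: %s", path)
  gr <- rtracklayer::import(path, format = "gtf")
  feat <- as.character(gr$type)
  ex <- gr[feat == "exon"]
  tx_id <- as.character(ex$transcript_id)
  no_tx <- is.na(tx_id) | tx_id == ""
  if (any(no_tx)) {
    warning(sprintf("%s: skipped %d exon feature(s) without transcript_id",
                    path, sum(no_tx)))
    ex <- ex[!no_tx]
    tx_id <- tx_id[!no_tx]
  }
  exons <- tibble(
    gene_id = as.character(ex$gene_id),
    transcript_id = tx_id,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex),
    end = GenomicRanges::end(ex))
  cds <- NULL
  if (any(feat == "CDS")) {
    cc <- gr[feat == "CDS"]
    cds <- tibble(transcript_id = as.character(cc$transcript_id),
                  start = GenomicRanges::start(cc),
                  end = GenomicRanges::end(cc))
  }
  gene_models(exons, cds = cds)
}

#' Read repeat annotation from a BED6 file
#'
#' BED coordinates (0-based, half-open) are converted to the package's
#' internal 1-based inclusive convention: `start_internal = start_bed + 1`,
#' `end_internal = end_bed`.
#'
#' @param path Path to a BED6 file (chrom, start, end, name, score, strand).
#' @return A tibble of repeat features: `chrom`, `start`, `end`, `strand`,
#'   `family` (from the BED name field).
#' @export
read_repeat_annotation <- function(path) {
  assert_that(file.exists(path), "BED not found: %s", path)
  if (file.size(path) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), family = character()))
  }
  raw <- read.delim(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  assert_that(ncol(raw) >= 6, "BED6 requires 6 columns, got %d", ncol(raw))
  bad <- raw[[3]] <= raw[[2]]
  if (any(bad)) {
    stop_circkit("BED interval with end <= start at line %d of %s",
                 which(bad)[1], path, class = "circkit_format_error")
  }
  tibble(chrom = as.character(raw[[1]]),
         start = as.integer(raw[[2]]) + 1L,
         end = as.integer(raw[[3]]),
         strand = as.character(raw[[6]]),
         family = as.character(raw[[4]]))
}

#' Write repeat features to BED6
#'
#' Inverse of [read_repeat_annotation()]: internal 1-based inclusive
#' coordinates are converted back to BED's 0-based half-open convention.
#'
#' @param repeats Tibble as returned by [read_repeat_annotation()].
#' @param path Output path.
#' @export
write_repeat_annotation <- function(repeats, path) {
  df <- data.frame(repeats$chrom, repeats$start - 1L, repeats$end,
                   repeats$family, 0L, repeats$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Load a genome FASTA as a sequence accessor
#'
#' @param path Path to a FASTA file with unique headers.
#' @return An object of class `genome_seq`; query it with [get_seq()].
#' @export
read_genome <- function(path) {
  assert_that(file.exists(path), "FASTA not found: %s", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  assert_that(!anyDuplicated(names(seqs)), "duplicate FASTA headers in %s", path)
  structure(list(seqs = seqs), class = "genome_seq")
}

#' Wrap in-memory sequences as a genome accessor
#'
#' @param seqs Named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @return A `genome_seq` object.
#' @export
genome_from_seqs <- function(seqs) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(unlist(seqs))
  }
  structure(list(seqs = seqs), class = "genome_seq")
}

#' Extract genomic sequence
#'
#' Returns the uppercase sequence of `chrom:start-end` (1-based inclusive);
#' for `strand = "-"` the reverse complement is returned.
#'
#' @param genome A `genome_seq` object from [read_genome()].
#' @param chrom Chromosome name (exact match).
#' @param start,end 1-based inclusive positions, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return A character scalar.
#' @export
get_seq <- function(genome, chrom, start, end, strand = "+") {
  assert_that(inherits(genome, "genome_seq"), "not a genome_seq object")
  if (!chrom %in% names(genome$seqs)) {
    stop_circkit("unknown chromosome '%s'", chrom, class = "circkit_key_error")
  }
  len <- Biostrings::width(genome$seqs[chrom])
  if (start < 1 || end > len || start > end) {
    stop_circkit("out-of-range request %s:%d-%d (contig length %d)",
                 chrom, start, end, len, class = "circkit_bounds_error")
  }
  s <- Biostrings::subseq(genome$seqs[[chrom]], start, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  toupper(as.character(s))
}

#' Chromosome lengths of a genome accessor
#' @param genome A `genome_seq` object.
#' @return Named integer vector.
#' @export
seq_lengths <- function(genome) {
  setNames(Biostrings::width(genome$seqs), names(genome$seqs))
}

#' Write pipeline result tables to a directory
#'
#' Writes each element of a named list of data frames to
#' `<out_dir>/<name>.tsv` with a one-line header.  Tables carrying `chrom`,
#' `start` and `end` columns are sorted by (chrom, start, end) first, so two
#' runs on the same input produce byte-identical files.
#'
#' @param results Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_result_tables <- function(results, out_dir) {
  assert_that(is.list(results) && !is.null(names(results)),
              "results must be a named list of data frames")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(results)) {
    df <- as.data.frame(results[[nm]])
    if (all(c("chrom", "start", "end") %in% names(df))) {
      df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
    }
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv_plain(df, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read back a result table written by [write_result_tables()]
#' @param path Path to one TSV.
#' @return A tibble.
#' @export
read_result_table <- function(path) read_tsv_plain(path)

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `group` (`case`/`control`),
#' `mappable_reads`, and optionally `tissue`.
#'
#' @param path Path to the sample sheet TSV.
#' @return A tibble, validated (positive mappable reads, known groups).
#' @export
read_sample_sheet <- function(path) {
  sheet <- read_tsv_plain(path)
  needed <- c("sample_id", "group", "mappable_reads")
  assert_that(all(needed %in% names(sheet)),
              "sample sheet must have columns: %s", paste(needed, collapse = ", "))
  assert_that(all(sheet$group %in% c("case", "control")),
              "sample sheet group must be 'case' or 'control'")
  assert_that(all(sheet$mappable_reads > 0), "mappable_reads must be > 0")
  if (!"tissue" %in% names(sheet)) sheet$tissue <- ""
  sheet
}
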