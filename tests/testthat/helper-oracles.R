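# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately brute-force and free of the package's own
# code paths.

# ---- tier rules, re-evaluated literally per circRNA -----------------------
brute_tiers <- function(counts_row, n_samples, presence = 1L) {
  present <- sum(counts_row >= presence)
  list(tier1 = max(counts_row) >= 2,
       tier2 = present >= 2 && sum(counts_row) >= 5,
       tier3 = present >= n_samples - 1)
}

# ---- closed-form two-sample t statistics ----------------------------------
welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tt <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * pt(-abs(tt), df)
}

pooled_t_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (nx + ny - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tt), nx + ny - 2)
}

# Pearson chi-squared on a 2x2 table, sum (O-E)^2 / E, no correction.
pearson_chisq_2x2 <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E)
}

# Pearson R^2 straight from the definition sums.
def_r2 <- function(x, y) {
  sx <- sum((x - mean(x))^2); sy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  (sxy / sqrt(sx * sy))^2
}

# ---- regex-free motif enumeration -----------------------------------------
# Expand one pattern (U/T equivalent, Y = C or T) to its literal DNA k-mers.
expand_pattern <- function(pattern) {
  p <- gsub("U", "T", toupper(pattern))
  chars <- strsplit(p, "")[[1]]
  opts <- lapply(chars, function(ch) if (ch == "Y") c("C", "T") else ch)
  apply(do.call(expand.grid, c(opts, stringsAsFactors = FALSE)), 1, paste,
        collapse = "")
}

brute_motif_count <- function(sequence, patterns) {
  s <- gsub("U", "T", toupper(sequence))
  total <- 0L
  for (p in patterns) {
    lits <- expand_pattern(p)
    L <- nchar(lits[1])
    if (nchar(s) < L) next
    kmers <- substring(s, seq_len(nchar(s) - L + 1L),
                       seq_len(nchar(s) - L + 1L) + L - 1L)
    total <- total + sum(kmers %in% lits)
  }
  total
}

# ---- Smith-Waterman local alignment with traceback ------------------------
# Linear gap penalty; returns best score, alignment length (incl. gaps) and
# percent identity of one optimal alignment.
brute_sw <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  P <- matrix(0L, n + 1, m + 1)  # 1 diag, 2 up, 3 left
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- if (av[i] == bv[j]) match else mismatch
      cand <- c(H[i, j] + sc, H[i, j + 1] + gap, H[i + 1, j] + gap, 0)
      k <- which.max(cand)
      H[i + 1, j + 1] <- cand[k]
      P[i + 1, j + 1] <- if (cand[k] == 0) 0L else k
      if (cand[k] > best) { best <- cand[k]; bi <- i + 1L; bj <- j + 1L }
    }
  }
  len <- 0L; ident <- 0L
  i <- bi; j <- bj
  while (i > 1 && j > 1 && P[i, j] != 0L) {
    len <- len + 1L
    if (P[i, j] == 1L) {
      if (av[i - 1] == bv[j - 1]) ident <- ident + 1L
      i <- i - 1L; j <- j - 1L
    } else if (P[i, j] == 2L) i <- i - 1L else j <- j - 1L
  }
  list(score = best, length = len,
       identity = if (len > 0) 100 * ident / len else 0)
}

revcomp_str <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# ---- tiny fixture builders -------------------------------------------------
# Gene with exons (1-100), (201-300), (401-500) on the given strand.
toy_models <- function(strand = "+") {
  gene_models(tibble::tibble(
    gene_id = "gA", transcript_id = "gA.t1", chrom = "chrT", strand = strand,
    start = c(1L, 201L, 401L), end = c(100L, 300L, 500L)))
}

toy_genome <- function(len = 600L, seed = 42L) {
  set.seed(seed)
  genome_from_seqs(setNames(list(rand_seq(len)), "chrT"))
}

circ_row <- function(chrom, start, end, strand = "+", gene_id = "") {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand, gene_id = gene_id)
}

circ_key_of <- function(tab) sprintf("%s:%d|%d:%s", tab$chrom, tab$start,
                                     tab$end, tab$strand)

write_ciri_fixture <- function(path, rows) {
  header <- paste(c("circRNA_ID", "chr", "circRNA_start", "circRNA_end",
                    "#junction_reads", "SM_MS_SMS", "#non_junction_reads",
                    "junction_reads_ratio", "circRNA_type", "gene_id",
                    "strand", "junction_reads_ID"), collapse = "\t")
  writeLines(c(header, rows), path)
}

ciri_row <- function(chrom, start, end, jr, njr = 0, type = "exon",
                     gene = "gA", strand = "+") {
  paste(c(sprintf("%s:%d|%d", chrom, start, end), chrom, start, end, jr,
          "0_0_0", njr, "0.9", type, gene, strand, "."), collapse = "\t")
}
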