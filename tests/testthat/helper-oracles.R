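# Shared fixtures and independent brute-force oracles. Oracles work on
# plain data.frames of 0-based half-open intervals and enumerate base
# membership sets, deliberately avoiding the package's interval code.

rand_interval_df <- function(n, chroms = c("chrA", "chrB"),
                             max_pos = 10000L, max_len = 400L) {
  start <- sample.int(max_pos - max_len, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len,
             strand = sample(c("+", "-", "."), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

df_to_gr <- function(df) {
  genomic_intervals(df$chrom, df$start, df$end, df$strand)
}

# base-membership overlap: do the two intervals share any base?
oracle_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(FALSE)
  length(intersect(seq(a$start, a$end - 1L), seq(b$start, b$end - 1L))) > 0L
}

# does interval i overlap any interval in df?
oracle_overlap_any <- function(i, df) {
  if (nrow(df) == 0L) return(FALSE)
  any(vapply(seq_len(nrow(df)), function(j) oracle_overlap(i, df[j, ]),
             logical(1L)))
}

# covered base set of an interval data.frame, per chromosome
oracle_coverage <- function(df) {
  out <- list()
  for (ch in unique(df$chrom)) {
    rows <- df[df$chrom == ch, , drop = FALSE]
    out[[ch]] <- sort(unique(unlist(
      lapply(seq_len(nrow(rows)),
             function(j) seq(rows$start[j], rows$end[j] - 1L)))))
  }
  out
}

# simple two-gene-per-strand toy gene table
toy_genes <- function() {
  g <- data.frame(
    gene_id = c("gplus", "gminus"),
    chrom = "chr1",
    strand = c("+", "-"),
    tx_start = c(5000L, 20000L),
    tx_end = c(12000L, 28000L),
    cds_start = c(6300L, 21000L),
    cds_end = c(11000L, 27000L),
    stringsAsFactors = FALSE
  )
  g$exon_starts <- list(c(5000L, 8000L, 10500L), c(20000L, 24000L))
  g$exon_ends <- list(c(6500L, 9000L, 12000L), c(22000L, 28000L))
  g
}

rbind_genes <- function(a, b) {
  if (is.null(b$exon_starts)) {
    b$exon_starts <- as.list(b$tx_start)
    b$exon_ends <- as.list(b$tx_end)
  }
  rbind(a, b[names(a)])
}

# hand-built SignalMatrix for classification unit tests
make_matrix <- function(values, flank_bp = 1500L, bin_bp = NULL,
                        total_reads = 1e6, genome_size = NULL,
                        ids = NULL) {
  values <- as.matrix(values)
  if (is.null(bin_bp)) bin_bp <- as.integer(2L * flank_bp / ncol(values))
  if (is.null(ids)) ids <- sprintf("p%03d", seq_len(nrow(values)))
  structure(list(values = values,
                 counts = round(values * total_reads / 1e6),
                 anchor_ids = ids,
                 bin_edges = seq(-flank_bp, flank_bp, by = bin_bp),
                 bin_bp = bin_bp, flank_bp = flank_bp,
                 total_reads = total_reads, genome_size = genome_size),
            class = "SignalMatrix")
}

small_cfg <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_genes = 400L, chrom_length_bp = 1e6,
             read_depth = 2e5, ...)
}

# mirror a dataset through position L - x on every chromosome,
# flipping strands; used for the strand-symmetry invariants
mirror_genes <- function(genes, L) {
  out <- genes
  out$strand <- ifelse(genes$strand == "+", "-", "+")
  out$tx_start <- L - genes$tx_end
  out$tx_end <- L - genes$tx_start
  if (!is.null(genes$cds_start)) {
    out$cds_start <- L - genes$cds_end
    out$cds_end <- L - genes$cds_start
  }
  if (!is.null(genes$exon_starts)) {
    out$exon_starts <- lapply(genes$exon_ends, function(e) rev(L - e))
    out$exon_ends <- lapply(genes$exon_starts, function(s) rev(L - s))
  }
  out
}

mirror_gr <- function(gr, L) {
  s <- as.character(GenomicRanges::strand(gr))
  flipped <- ifelse(s == "+", "-", ifelse(s == "-", "+", "."))
  genomic_intervals(as.character(GenomicRanges::seqnames(gr)),
                    L - interval_end0(gr), L - interval_start0(gr),
                    flipped)
}

# id of the mirrored promoter: chrom:(L - tss):flipped strand
mirror_promoter_id <- function(ids, L) {
  parts <- strsplit(ids, ":", fixed = TRUE)
  vapply(parts, function(p) {
    paste0(p[1L], ":", L - as.numeric(p[2L]), ":",
           if (p[3L] == "+") "-" else "+")
  }, character(1L))
}
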