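# Gene models are plain data.frames with one row per transcript:
#   gene_id, chrom, strand (+/-), tx_start, tx_end (0-based half-open),
#   cds_start, cds_end (optional; equal values mean non-coding),
#   exon_starts, exon_ends (list columns of sorted integer vectors),
#   expression (optional, arbitrary units >= 0).
# This mirrors the UCSC refFlat table the pipeline consumes.

#' Validate a gene-model table
#'
#' Checks transcript coordinates and exon structure; malformed rows
#' (`tx_start >= tx_end`, exon lists of unequal length, exons outside
#' the transcript, unsorted exons) are dropped with a warning rather
#' than aborting, so one bad annotation line does not kill a run.
#'
#' @param genes Gene-model data.frame (see format above).
#' @return The validated (possibly reduced) data.frame.
#' @export
validate_gene_models <- function(genes) {
  stopifnot(is.data.frame(genes))
  required <- c("gene_id", "chrom", "strand", "tx_start", "tx_end")
  missing <- setdiff(required, names(genes))
  if (length(missing)) {
    stop("gene table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(genes) == 0L) return(genes)
  bad <- genes$tx_start >= genes$tx_end |
    genes$tx_start < 0 |
    !genes$strand %in% c("+", "-")
  if (!is.null(genes$exon_starts)) {
    exon_bad <- mapply(function(s, e, ts, te) {
      length(s) != length(e) ||
        (length(s) > 0L && (is.unsorted(s) || is.unsorted(e) ||
                              any(e <= s) || s[1L] < ts || e[length(e)] > te))
    }, genes$exon_starts, genes$exon_ends, genes$tx_start, genes$tx_end)
    bad <- bad | exon_bad
  }
  if (any(bad)) {
    warning(sum(bad), " malformed gene record(s) dropped")
    genes <- genes[!bad, , drop = FALSE]
  }
  genes
}

#' Build strand-aware, TSS-deduplicated promoters
#'
#' One promoter is created per unique (chromosome, strand, TSS) triple.
#' The TSS is `tx_start` for `+` transcripts and `tx_end` for `-`
#' transcripts (0-based convention: for a minus-strand gene the first
#' transcribed base sits at `tx_end - 1`). Transcripts sharing a TSS —
#' alternative isoforms — are merged: their `gene_id`s are concatenated
#' and the merged promoter takes the maximum expression of its
#' contributors, so an active gene is not diluted by a silent isoform.
#'
#' The returned `GRanges` spans the promoter window
#' `[-upstream_bp, +downstream_bp)` around the TSS, oriented by strand
#' (upstream means 5' of the gene). Metadata columns carry
#' `promoter_id`, `tss`, `gene_ids` (comma-joined), `expression`,
#' `group` (initialised `"unassigned"`) and annotation flags filled in
#' by later stages.
#'
#' @param genes Gene-model data.frame.
#' @param upstream_bp,downstream_bp Window half-sizes in bp (> 0).
#' @return `GRanges` of promoter windows, sorted by (chrom, tss).
#' @examples
#' genes <- data.frame(
#'   gene_id = c("a", "b"), chrom = "chr1", strand = c("+", "+"),
#'   tx_start = c(5000, 5000), tx_end = c(7000, 9000)
#' )
#' define_promoters(genes)  # one promoter: shared TSS at 5000
#' @export
define_promoters <- function(genes, upstream_bp = 1000L,
                             downstream_bp = 1000L) {
  if (!is.data.frame(genes) || nrow(genes) == 0L) {
    stop("gene table is empty")
  }
  if (upstream_bp <= 0L || downstream_bp <= 0L) {
    stop("promoter window sizes must be positive")
  }
  genes <- validate_gene_models(genes)
  if (nrow(genes) == 0L) stop("no valid gene records")

  tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end)
  expr <- if (is.null(genes$expression)) rep(NA_real_, nrow(genes)) else
    as.numeric(genes$expression)

  key <- paste(genes$chrom, genes$strand, tss, sep = "\r")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  gene_ids <- vapply(split(genes$gene_id, idx), paste,
                     character(1L), collapse = ",")
  expression <- vapply(split(expr, idx), function(x) {
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  }, numeric(1L))

  u <- genes[first, , drop = FALSE]
  utss <- tss[first]
  ord <- order(u$chrom, utss, u$strand)

  chrom <- u$chrom[ord]
  strand <- u$strand[ord]
  utss <- utss[ord]
  win_start <- ifelse(strand == "+", utss - upstream_bp,
                      utss - downstream_bp)
  win_end <- ifelse(strand == "+", utss + downstream_bp,
                    utss + upstream_bp)
  win_start <- pmax(win_start, 0)

  prom <- genomic_intervals(chrom, win_start, win_end, strand)
  prom$promoter_id <- paste0(chrom, ":", utss, ":", strand)
  prom$tss <- utss
  prom$gene_ids <- unname(gene_ids[as.character(seq_len(sum(first)))[ord]])
  prom$expression <- unname(expression[as.character(seq_len(sum(first)))[ord]])
  prom$group <- "unassigned"
  prom$cpg_flag <- NA
  prom$tata_flag <- FALSE
  prom$ets_flag <- FALSE
  prom$tf_event_count <- NA_integer_
  S4Vectors::metadata(prom)$window <- c(upstream_bp = upstream_bp,
                                        downstream_bp = downstream_bp)
  prom
}

# 0-based position of the first transcribed base: the anchor all
# strand-oriented offsets are measured from. For "+" this is the TSS
# itself; for "-" it is tss - 1 (tss is the exclusive transcript end).
promoter_anchor0 <- function(promoters) {
  s <- as.character(GenomicRanges::strand(promoters))
  ifelse(s == "-", promoters$tss - 1L, promoters$tss)
}

#' Rebuild promoter windows with a different size
#'
#' Returns windows `[-upstream_bp, +downstream_bp)` around each
#' promoter's TSS, strand-oriented, without touching the promoter
#' metadata. Used when a stage needs a window other than the one the
#' promoters were defined with (e.g. the wider heatmap flank).
#'
#' @param promoters Promoter `GRanges` from [define_promoters()].
#' @param upstream_bp,downstream_bp Window half-sizes in bp.
#' @return `GRanges` parallel to `promoters`.
#' @export
promoter_windows <- function(promoters, upstream_bp, downstream_bp) {
  s <- as.character(GenomicRanges::strand(promoters))
  tss <- promoters$tss
  ws <- ifelse(s == "+", tss - upstream_bp, tss - downstream_bp)
  we <- ifelse(s == "+", tss + downstream_bp, tss + upstream_bp)
  ws <- pmax(ws, 0)
  out <- genomic_intervals(as.character(GenomicRanges::seqnames(promoters)),
                           ws, we, s)
  out$promoter_id <- promoters$promoter_id
  out
}

#' Read and write refFlat-style gene tables
#'
#' The refFlat layout is 11 tab-separated columns: geneName, name,
#' chrom, strand, txStart, txEnd, cdsStart, cdsEnd, exonCount,
#' exonStarts, exonEnds (the last two comma-separated with a trailing
#' comma). `read_refflat()` uses the second (transcript) name column as
#' `gene_id` when gene and transcript names differ, otherwise the first.
#'
#' @param path File path.
#' @param expression Optional named numeric vector of per-gene
#'   expression merged into the returned table.
#' @param genes Gene-model data.frame to write.
#' @return `read_refflat()`: a gene-model data.frame;
#'   `write_refflat()`: `path`, invisibly.
#' @export
read_refflat <- function(path, expression = NULL) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("geneName", "name", "chrom",
                                         "strand", "txStart", "txEnd",
                                         "cdsStart", "cdsEnd", "exonCount",
                                         "exonStarts", "exonEnds"))
  split_csv <- function(x) lapply(strsplit(x, ",", fixed = TRUE),
                                  function(v) as.integer(v[nzchar(v)]))
  genes <- data.frame(
    gene_id = ifelse(raw$name == raw$geneName, raw$geneName, raw$name),
    chrom = raw$chrom,
    strand = raw$strand,
    tx_start = raw$txStart,
    tx_end = raw$txEnd,
    cds_start = raw$cdsStart,
    cds_end = raw$cdsEnd,
    stringsAsFactors = FALSE
  )
  genes$exon_starts <- split_csv(raw$exonStarts)
  genes$exon_ends <- split_csv(raw$exonEnds)
  if (!is.null(expression)) {
    genes$expression <- unname(expression[genes$gene_id])
  }
  genes
}

#' @rdname read_refflat
#' @export
write_refflat <- function(genes, path) {
  join_csv <- function(col, n) {
    if (is.null(col)) return(rep("", n))
    vapply(col, function(v) paste0(paste(v, collapse = ","), ","),
           character(1L))
  }
  n <- nrow(genes)
  cds_start <- if (is.null(genes$cds_start)) genes$tx_start else genes$cds_start
  cds_end <- if (is.null(genes$cds_end)) genes$tx_start else genes$cds_end
  exon_count <- if (is.null(genes$exon_starts)) rep(0L, n) else
    vapply(genes$exon_starts, length, integer(1L))
  out <- data.frame(genes$gene_id, genes$gene_id, genes$chrom, genes$strand,
                    genes$tx_start, genes$tx_end, cds_start, cds_end,
                    exon_count,
                    join_csv(genes$exon_starts, n),
                    join_csv(genes$exon_ends, n))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
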