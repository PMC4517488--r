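# Genomic intervals use the BED convention throughout the public API:
# 0-based, half-open [start, end). Internally intervals are GRanges
# (1-based, closed); the two helpers below are the only place the
# conversion happens.

#' Construct genomic intervals from 0-based half-open coordinates
#'
#' The package-wide interval container is a [GenomicRanges::GRanges];
#' this constructor takes BED-convention coordinates (0-based starts,
#' exclusive ends) and validates them.
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start,end Integer vectors, 0-based half-open: `start < end`,
#'   `start >= 0`.
#' @param strand Strand per interval: `"+"`, `"-"` or `"."`
#'   (unstranded; stored as `"*"`).
#' @param name,score Optional per-interval label and numeric score.
#' @return A `GRanges` with optional `name`/`score` metadata columns.
#' @examples
#' genomic_intervals("chr1", c(0, 100), c(50, 200), strand = "+")
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".",
                              name = NULL, score = NULL) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  strand <- rep_len(as.character(strand), n)
  if (any(is.na(chrom) | !nzchar(chrom))) {
    stop("chromosome names must be non-empty")
  }
  if (any(start < 0)) stop("interval starts must be >= 0")
  if (any(start >= end)) stop("intervals must satisfy start < end")
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand
  )
  if (!is.null(name)) gr$name <- rep_len(as.character(name), n)
  if (!is.null(score)) gr$score <- rep_len(as.numeric(score), n)
  gr
}

#' 0-based coordinates of a GRanges
#'
#' @param gr A `GRanges`.
#' @return `interval_start0()`: 0-based start positions;
#'   `interval_end0()`: exclusive end positions.
#' @export
interval_start0 <- function(gr) GenomicRanges::start(gr) - 1L

#' @rdname interval_start0
#' @export
interval_end0 <- function(gr) GenomicRanges::end(gr)

#' Pairwise interval overlap test
#'
#' Two half-open intervals overlap iff they share a chromosome and
#' `a.start < b.end && b.start < a.end`. `a` and `b` are compared
#' element-wise (recycled to a common length); strand is ignored, as in
#' all overlap-based feature definitions in this package.
#'
#' @param a,b `GRanges` of equal length (or length 1).
#' @return Logical vector.
#' @examples
#' a <- genomic_intervals("chr1", 0, 10)
#' overlaps(a, genomic_intervals("chr1", 10, 20))  # FALSE: half-open
#' overlaps(a, genomic_intervals("chr1", 9, 20))   # TRUE
#' @export
overlaps <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) != n) a <- rep(a, length.out = n)
  if (length(b) != n) b <- rep(b, length.out = n)
  same_chrom <- as.character(GenomicRanges::seqnames(a)) ==
    as.character(GenomicRanges::seqnames(b))
  same_chrom &
    interval_start0(a) < interval_end0(b) &
    interval_start0(b) < interval_end0(a)
}

#' Read and write BED interval files
#'
#' Thin wrappers over [rtracklayer::import]/[rtracklayer::export] pinned
#' to the BED format, so all interval tracks (peaks, TFBS, CpG islands,
#' TBP sites, G4 sites, enhancers) go through one code path.
#'
#' @param path File path.
#' @param gr A `GRanges` to write.
#' @return `read_bed()` returns a `GRanges`; `write_bed()` returns
#'   `path` invisibly.
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' @rdname read_bed
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
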