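# Simplified Poisson local-background peak caller. Deliberately not a
# MACS clone: no model building or shift estimation — the fragment
# shift is a fixed parameter — but the same local-lambda idea: each
# window is tested against the most conservative of the genome-wide,
# 5 kb and 10 kb background rates.

#' Reduce mapped reads to shifted 5' tag positions
#'
#' Each read contributes one genomic point: its 5' end moved
#' `shift_bp` towards 3' (towards the fragment centre). Unstranded
#' reads are treated as plus-strand.
#'
#' @param reads `GRanges` of mapped reads.
#' @param shift_bp Shift in bp (default 100, half a 200 bp fragment).
#' @return data.frame with columns `chrom` and `pos` (0-based).
#' @export
read_points <- function(reads, shift_bp = 100L) {
  s <- as.character(GenomicRanges::strand(reads))
  pos <- ifelse(s == "-",
                interval_end0(reads) - 1L - shift_bp,
                interval_start0(reads) + shift_bp)
  data.frame(chrom = as.character(GenomicRanges::seqnames(reads)),
             pos = pos, stringsAsFactors = FALSE)
}

#' Poisson upper-tail probability
#'
#' `P(X >= k)` for `X ~ Poisson(lambda)`; equals 1 for `k = 0`.
#'
#' @param k Observed count(s).
#' @param lambda Expected count(s).
#' @return Numeric vector of tail probabilities in (0, 1].
#' @export
poisson_upper_tail <- function(k, lambda) {
  stats::ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Call peaks with a sliding-window Poisson test
#'
#' Fixed windows of `window_bp` slide in steps of `window_bp / 2`.
#' A window with tag count `k` is significant when the Poisson upper
#' tail `P(X >= k; lambda_local) < p_cutoff`, where `lambda_local` is
#' the maximum of the genome-wide rate and the rates in 5 kb and 10 kb
#' windows centred on the tested window, all scaled to `window_bp`.
#' Overlapping/adjacent significant windows are merged into one peak
#' reporting the merged interval's tag count, the minimum window
#' p-value and the local lambda at that window.
#'
#' @param reads `GRanges` of mapped reads.
#' @param genome_size Effective genome size in bp (> 0).
#' @param window_bp Window size in bp (default 300).
#' @param p_cutoff Poisson p-value cutoff in (0, 1); 1e-4 matches the
#'   stringency used for the main factor, 1e-5 for histone marks.
#' @param shift_bp Read 5'-end shift (see [read_points()]).
#' @return Sorted `GRanges` of peaks with metadata columns
#'   `tag_count`, `lambda_local`, `p_value`.
#' @export
call_peaks <- function(reads, genome_size, window_bp = 300L,
                       p_cutoff = 1e-4, shift_bp = 100L) {
  if (!is.numeric(genome_size) || genome_size <= 0) {
    stop("genome_size must be positive")
  }
  if (p_cutoff <= 0 || p_cutoff >= 1) stop("p_cutoff must be in (0, 1)")
  empty <- GenomicRanges::GRanges(
    tag_count = integer(0), lambda_local = numeric(0), p_value = numeric(0))
  if (length(reads) == 0L) return(empty)

  pts <- read_points(reads, shift_bp)
  n_total <- nrow(pts)
  rate_bg <- n_total / genome_size           # reads per bp, genome-wide
  step <- as.integer(window_bp / 2L)
  seq_lens <- GenomeInfoDb::seqlengths(reads)

  out <- list()
  for (chrom in unique(pts$chrom)) {
    p <- sort(pts$pos[pts$chrom == chrom])
    L <- seq_lens[chrom]
    if (is.na(L)) L <- max(p) + window_bp
    starts <- seq(0L, max(0L, L - 1L), by = step)
    # count of points in [lo, hi): integer points, sorted
    cnt <- function(lo, hi) {
      findInterval(hi - 1L, p) - findInterval(lo - 1L, p)
    }
    mids <- starts + window_bp / 2
    k <- cnt(starts, starts + window_bp)
    rate_5k <- cnt(mids - 2500, mids + 2500) / 5000
    rate_10k <- cnt(mids - 5000, mids + 5000) / 10000
    lambda <- pmax(rate_bg, rate_5k, rate_10k) * window_bp
    pv <- poisson_upper_tail(k, lambda)
    sig <- which(k > 0L & pv < p_cutoff)
    if (length(sig) == 0L) next

    # merge runs of overlapping significant windows
    brk <- c(TRUE, diff(sig) * step >= window_bp)
    run <- cumsum(brk)
    for (r in unique(run)) {
      i <- sig[run == r]
      lo <- starts[i[1L]]
      hi <- min(starts[i[length(i)]] + window_bp, L)
      best <- i[which.min(pv[i])]
      pk <- genomic_intervals(chrom, lo, hi)
      pk$tag_count <- cnt(lo, hi)
      pk$lambda_local <- lambda[best]
      pk$p_value <- pv[best]
      out[[length(out) + 1L]] <- pk
    }
  }
  if (length(out) == 0L) return(empty)
  sort(do.call(c, out), ignore.strand = TRUE)
}
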