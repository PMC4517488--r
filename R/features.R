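# Overlap-based feature definitions. All of these treat intervals as
# unstranded (a histone peak or TFBS annotates a promoter regardless of
# which strand it was called on), so every findOverlaps call here uses
# ignore.strand = TRUE.

.overlaps_any <- function(query, subject) {
  if (length(subject) == 0L) return(rep(FALSE, length(query)))
  # suppress the "no sequence levels in common" warning: a query on a
  # chromosome absent from the subject simply does not overlap
  suppressWarnings(IRanges::overlapsAny(query, subject,
                                        ignore.strand = TRUE))
}

#' Define enhancers from co-occurring H3K4me1 and H3K27ac peaks
#'
#' An enhancer is the intersection region of an overlapping
#' H3K4me1/H3K27ac peak pair that does not touch any promoter window.
#' Intersections of all overlapping pairs are computed, promoter-
#' overlapping pieces are discarded, and the remainder is merged into a
#' non-overlapping set.
#'
#' @param h3k4me1_peaks,h3k27ac_peaks `GRanges` of mark peaks.
#' @param promoters Promoter `GRanges`; its windows (conventionally
#'   -1000/+1000 around the TSS) define the exclusion zone.
#' @return Merged, sorted `GRanges` of enhancer intervals.
#' @export
define_enhancers <- function(h3k4me1_peaks, h3k27ac_peaks, promoters) {
  if (length(h3k4me1_peaks) == 0L || length(h3k27ac_peaks) == 0L) {
    return(GenomicRanges::GRanges())
  }
  hits <- GenomicRanges::findOverlaps(h3k4me1_peaks, h3k27ac_peaks,
                                      ignore.strand = TRUE)
  if (length(hits) == 0L) return(GenomicRanges::GRanges())
  inter <- IRanges::pintersect(
    GenomicRanges::granges(h3k4me1_peaks)[S4Vectors::queryHits(hits)],
    GenomicRanges::granges(h3k27ac_peaks)[S4Vectors::subjectHits(hits)],
    ignore.strand = TRUE
  )
  inter <- inter[!.overlaps_any(inter, promoters)]
  sort(GenomicRanges::reduce(inter, ignore.strand = TRUE))
}

#' Keep G-quadruplex sites away from promoters and enhancers
#'
#' Restricts a predicted G4 track to sites overlapping neither a
#' promoter window nor an enhancer, i.e. the fraction of the track that
#' can be attributed to binding outside regulatory elements.
#'
#' @param g4 `GRanges` of predicted G4 sites.
#' @param promoters Promoter `GRanges`.
#' @param enhancers Enhancer `GRanges` (from [define_enhancers()]).
#' @return Subset of `g4`.
#' @export
filter_g4_sites <- function(g4, promoters, enhancers) {
  g4[!.overlaps_any(g4, promoters) & !.overlaps_any(g4, enhancers)]
}

#' Flag promoters carrying a conserved TBP site (TATA box)
#'
#' A promoter is TATA-positive iff at least one conserved TBP binding
#' site overlaps its window.
#'
#' @param promoters Promoter `GRanges`.
#' @param tbp_sites `GRanges` of conserved TBP sites.
#' @return `promoters` with `tata_flag` updated.
#' @export
flag_tata_promoters <- function(promoters, tbp_sites) {
  promoters$tata_flag <- .overlaps_any(promoters, tbp_sites)
  promoters
}

#' Flag promoters bound by an ETS-family factor
#'
#' @param promoters Promoter `GRanges`.
#' @param ets_peaks `GRanges` of ETS ChIP peaks.
#' @return `promoters` with `ets_flag` updated.
#' @export
flag_ets_promoters <- function(promoters, ets_peaks) {
  promoters$ets_flag <- .overlaps_any(promoters, ets_peaks)
  promoters
}

#' Count transcription-factor binding events per promoter
#'
#' One event is one clustered-TFBS record overlapping the promoter
#' window; a promoter bound by many factors (or the same factor at
#' several clustered sites) accumulates one count per record.
#'
#' @param promoters Promoter `GRanges`.
#' @param tfbs `GRanges` of clustered TFBS records.
#' @return `promoters` with `tf_event_count` updated.
#' @export
count_tf_events <- function(promoters, tfbs) {
  promoters$tf_event_count <- GenomicRanges::countOverlaps(
    promoters, tfbs, ignore.strand = TRUE)
  promoters
}

#' Assign each peak a single genomic category
#'
#' Categories follow the fixed precedence
#' promoter > 5'-UTR > 3'-UTR > exon > intron > intergenic: a peak is
#' labelled with the highest-precedence feature it overlaps anywhere,
#' so category fractions over a peak set always sum to one. UTRs are
#' the exonic regions outside the CDS (strand-aware); transcripts
#' without a CDS (`cds_start == cds_end`) contribute plain exons.
#'
#' @param peaks `GRanges` of peaks to annotate.
#' @param genes Gene-model data.frame with exon (and optionally CDS)
#'   structure.
#' @param promoters Promoter `GRanges`.
#' @return Factor parallel to `peaks` with levels
#'   `promoter, utr5, utr3, exon, intron, intergenic`.
#' @export
annotate_peak_category <- function(peaks, genes, promoters) {
  genes <- validate_gene_models(genes)
  feats <- .gene_feature_ranges(genes)
  lv <- c("promoter", "utr5", "utr3", "exon", "intron", "intergenic")
  cat <- rep("intergenic", length(peaks))
  # ascending precedence: later assignments overwrite earlier ones
  cat[.overlaps_any(peaks, feats$intron)] <- "intron"
  cat[.overlaps_any(peaks, feats$exon)] <- "exon"
  cat[.overlaps_any(peaks, feats$utr3)] <- "utr3"
  cat[.overlaps_any(peaks, feats$utr5)] <- "utr5"
  cat[.overlaps_any(peaks, promoters)] <- "promoter"
  factor(cat, levels = lv)
}

#' Fraction of peaks per genomic category
#'
#' @param categories Factor from [annotate_peak_category()].
#' @return Named numeric vector summing to 1.
#' @export
category_fractions <- function(categories) {
  tab <- table(categories)
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}

# Decompose gene models into exon / utr5 / utr3 / intron GRanges
# (0-based half-open inputs; returned as GRanges).
.gene_feature_ranges <- function(genes) {
  empty <- GenomicRanges::GRanges()
  if (nrow(genes) == 0L) {
    return(list(exon = empty, utr5 = empty, utr3 = empty, intron = empty))
  }
  has_exons <- !is.null(genes$exon_starts)
  ex_chrom <- character(0); ex_s <- numeric(0); ex_e <- numeric(0)
  u5_chrom <- character(0); u5_s <- numeric(0); u5_e <- numeric(0)
  u3_chrom <- character(0); u3_s <- numeric(0); u3_e <- numeric(0)
  in_chrom <- character(0); in_s <- numeric(0); in_e <- numeric(0)
  for (i in seq_len(nrow(genes))) {
    es <- if (has_exons) genes$exon_starts[[i]] else genes$tx_start[i]
    ee <- if (has_exons) genes$exon_ends[[i]] else genes$tx_end[i]
    if (length(es) == 0L) { es <- genes$tx_start[i]; ee <- genes$tx_end[i] }
    cs <- if (is.null(genes$cds_start)) genes$tx_start[i] else genes$cds_start[i]
    ce <- if (is.null(genes$cds_end)) genes$tx_start[i] else genes$cds_end[i]
    chrom <- genes$chrom[i]
    coding <- !is.na(cs) && !is.na(ce) && cs < ce
    for (j in seq_along(es)) {
      s <- es[j]; e <- ee[j]
      if (!coding) {
        ex_chrom <- c(ex_chrom, chrom); ex_s <- c(ex_s, s); ex_e <- c(ex_e, e)
        next
      }
      # left of CDS
      if (s < cs) {
        lo <- s; hi <- min(e, cs)
        if (genes$strand[i] == "+") {
          u5_chrom <- c(u5_chrom, chrom); u5_s <- c(u5_s, lo); u5_e <- c(u5_e, hi)
        } else {
          u3_chrom <- c(u3_chrom, chrom); u3_s <- c(u3_s, lo); u3_e <- c(u3_e, hi)
        }
      }
      # CDS-overlapping part
      if (e > cs && s < ce) {
        ex_chrom <- c(ex_chrom, chrom)
        ex_s <- c(ex_s, max(s, cs)); ex_e <- c(ex_e, min(e, ce))
      }
      # right of CDS
      if (e > ce) {
        lo <- max(s, ce); hi <- e
        if (genes$strand[i] == "+") {
          u3_chrom <- c(u3_chrom, chrom); u3_s <- c(u3_s, lo); u3_e <- c(u3_e, hi)
        } else {
          u5_chrom <- c(u5_chrom, chrom); u5_s <- c(u5_s, lo); u5_e <- c(u5_e, hi)
        }
      }
    }
    # introns: gaps between consecutive exons
    if (length(es) > 1L) {
      gs <- ee[-length(ee)]; ge <- es[-1L]
      keep <- ge > gs
      if (any(keep)) {
        in_chrom <- c(in_chrom, rep(chrom, sum(keep)))
        in_s <- c(in_s, gs[keep]); in_e <- c(in_e, ge[keep])
      }
    }
  }
  mk <- function(chrom, s, e) {
    if (length(chrom) == 0L) return(empty)
    genomic_intervals(chrom, s, e)
  }
  list(exon = mk(ex_chrom, ex_s, ex_e),
       utr5 = mk(u5_chrom, u5_s, u5_e),
       utr3 = mk(u3_chrom, u3_s, u3_e),
       intron = mk(in_chrom, in_s, in_e))
}
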