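# Synthetic-data generator: a miniature genome with the statistical
# structure the analysis assumes, and full ground truth. Promoters come
# in three classes — "I" (strong binding, peak upstream of the TSS),
# "II" (weaker binding, peak downstream with an upstream shoulder) and
# "unbound" (background-level binding) — with class proportions,
# amplitude ratio and peak offsets configurable.

#' Simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: an
#' ~8-fold binding-amplitude ratio between promoter groups I and II,
#' group I peaking 60 bp upstream of the TSS and group II 60 bp
#' downstream with an upstream shoulder, ~13% of promoters bound with
#' ~7.5% of the bound set in group I, 112 vs 75 mean TF binding events
#' per group I/II promoter, and a DE table with 150 consistently
#' upregulated and 58 downregulated genes planted among 20,000.
#'
#' @param seed Integer seed; every downstream stage derives its RNG
#'   stream from it.
#' @param n_chroms,chrom_length_bp Genome layout (2 x 5 Mb default).
#' @param n_genes Number of non-overlapping genes (2,000 default).
#' @param frac_bound Fraction of promoters bound by the factor.
#' @param frac_group_I Fraction of bound promoters in group I.
#' @param groupI_amplitude_fold Group I : group II mean amplitude ratio.
#' @param unbound_amplitude_frac Unbound amplitude as a fraction of the
#'   group II amplitude (residual coupling to transcription).
#' @param groupI_peak_offset_bp,groupII_peak_offset_bp Peak positions
#'   relative to the TSS (upstream negative).
#' @param groupII_shoulder Add an upstream shoulder to the group II
#'   profile?
#' @param shoulder_offset_bp,shoulder_frac Shoulder position and its
#'   amplitude relative to the main peak.
#' @param binding_sd_bp SD of the Gaussian positional kernel.
#' @param read_depth Reads per simulated ChIP factor.
#' @param read_length_bp,fragment_bp Read and fragment lengths.
#' @param background_frac Fraction of reads drawn uniformly from the
#'   genome rather than from promoter profiles.
#' @param expression_meanlog,expression_sdlog Log-normal expression
#'   parameters (arbitrary units).
#' @param expression_coupling Exponent coupling per-promoter binding
#'   amplitude to expression within a class (1 = proportional).
#' @param feature_folds Named list, one entry per annotation factor,
#'   each `c(fold_I, fold_II)` scaling that factor's mean tag count at
#'   group I / group II promoters.
#' @param feature_base_mean Baseline mean tag count for annotation
#'   factors.
#' @param tf_event_means `c(mean_I, mean_II)` Poisson means of TF
#'   binding events per promoter.
#' @param tf_event_mean_unbound Poisson mean at unbound promoters.
#' @param cpg_probs,tata_probs,ets_probs Named probabilities
#'   (`I`, `II`, `unbound`) of a promoter carrying a CpG island,
#'   conserved TBP site, or ETS peak.
#' @param n_g4 Number of predicted G4 sites.
#' @param n_enhancers Number of true enhancer loci.
#' @param de_plant `c(n_up, n_down)` consistently changed genes to
#'   plant in the DE table.
#' @param de_n_genes DE-table size.
#' @param de_null_sd SD of null log2 fold-changes (truncated to
#'   (-0.9, 0.9) so null genes can never cross the two-fold cutoff).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length_bp = 5e6,
                       n_genes = 2000L,
                       frac_bound = 0.13,
                       frac_group_I = 0.075,
                       groupI_amplitude_fold = 8,
                       unbound_amplitude_frac = 0.05,
                       groupI_peak_offset_bp = -60,
                       groupII_peak_offset_bp = 60,
                       groupII_shoulder = TRUE,
                       shoulder_offset_bp = -150,
                       shoulder_frac = 0.4,
                       binding_sd_bp = 75,
                       read_depth = 1e6,
                       read_length_bp = 36L,
                       fragment_bp = 200L,
                       background_frac = 0.3,
                       expression_meanlog = 2,
                       expression_sdlog = 1,
                       expression_coupling = 0.5,
                       feature_folds = list(TAF1 = c(1.5, 1),
                                            H3K122ac = c(1.4, 1),
                                            CHD7 = c(1.3, 1),
                                            TBP = c(1.0, 1),
                                            H3K27me3 = c(0.6, 1)),
                       feature_base_mean = 200,
                       tf_event_means = c(112, 75),
                       tf_event_mean_unbound = 50,
                       cpg_probs = c(I = 0.95, II = 0.85, unbound = 0.55),
                       tata_probs = c(I = 0.05, II = 0.10, unbound = 0.30),
                       ets_probs = c(I = 0.90, II = 0.60, unbound = 0.30),
                       n_g4 = 2000L,
                       n_enhancers = 300L,
                       de_plant = c(n_up = 150L, n_down = 58L),
                       de_n_genes = 20000L,
                       de_null_sd = 0.3) {
  cfg <- as.list(environment())
  stopifnot(cfg$seed == as.integer(cfg$seed),
            cfg$n_chroms >= 1L, cfg$chrom_length_bp > 0,
            cfg$n_genes >= 0L,
            cfg$frac_bound > 0, cfg$frac_bound < 1,
            cfg$frac_group_I > 0, cfg$frac_group_I < 1,
            cfg$groupI_amplitude_fold > 0,
            cfg$unbound_amplitude_frac >= 0,
            abs(cfg$groupI_peak_offset_bp) < 1500,
            abs(cfg$groupII_peak_offset_bp) < 1500,
            abs(cfg$shoulder_offset_bp) < 1500,
            cfg$binding_sd_bp > 0, cfg$read_depth > 0,
            cfg$background_frac >= 0, cfg$background_frac <= 1,
            all(vapply(cfg$feature_folds, function(f) all(f > 0), logical(1))),
            all(cfg$tf_event_means >= 0),
            cfg$de_n_genes >= cfg$n_genes + sum(cfg$de_plant))
  class(cfg) <- "sim_config"
  cfg
}

.chrom_names <- function(cfg) paste0("chr", seq_len(cfg$n_chroms))

.sim_seqinfo <- function(cfg) {
  GenomeInfoDb::Seqinfo(seqnames = .chrom_names(cfg),
                        seqlengths = rep(cfg$chrom_length_bp, cfg$n_chroms))
}

#' Simulate gene models with known promoter classes
#'
#' Genes are laid out in disjoint slots (one gene per slot, random
#' offset and strand) so transcripts never overlap and every TSS is
#' unique. Expression is log-normal. Bound promoters are sampled with
#' probability increasing in expression (bound promoters are more
#' active than average), and group I is the top-expression tail of the
#' bound set (group I promoters have the highest transcriptional
#' activity).
#'
#' @param cfg A [sim_config()].
#' @return List with `genes` (gene-model data.frame, including
#'   `expression`) and `truth` (data.frame: `gene_id`, `promoter_id`,
#'   `class`, `expression`).
#' @export
simulate_genes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes == 0L) {
    genes <- data.frame(gene_id = character(0), chrom = character(0),
                        strand = character(0), tx_start = integer(0),
                        tx_end = integer(0))
    truth <- data.frame(gene_id = character(0), promoter_id = character(0),
                        class = character(0), expression = numeric(0))
    return(list(genes = genes, truth = truth))
  }
  .with_seed(cfg$seed, {
    n <- cfg$n_genes
    per_chrom <- ceiling(n / cfg$n_chroms)
    slot <- floor(cfg$chrom_length_bp / per_chrom)
    if (slot < 2000L) stop("genes do not fit on the chromosomes")
    chrom_idx <- rep(seq_len(cfg$n_chroms), each = per_chrom)[seq_len(n)]
    slot_idx <- (seq_len(n) - 1L) %% per_chrom
    slot_start <- slot_idx * slot

    # every TSS keeps >= `clearance` bp from its slot boundaries, so
    # neighbouring TSSs are always >= 2 * clearance apart and promoter
    # windows never capture a neighbour's signal (closely spaced
    # divergent promoter pairs are deliberately not modelled)
    clearance <- 1250L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    len <- floor(stats::runif(n, 0.4, 0.95) * (slot - clearance - 2L))
    lo <- ifelse(strand == "+", clearance, 1L)
    hi <- ifelse(strand == "+", slot - len - 2L, slot - clearance - len)
    offset <- lo + floor(stats::runif(n) * (hi - lo + 1L))
    tx_start <- slot_start + offset
    tx_end <- tx_start + len
    expression <- stats::rlnorm(n, cfg$expression_meanlog,
                                cfg$expression_sdlog)

    exon_starts <- vector("list", n)
    exon_ends <- vector("list", n)
    n_ex <- sample(2:5, n, replace = TRUE)
    for (i in seq_len(n)) {
      cuts <- sort(sample(seq(tx_start[i] + 1L, tx_end[i] - 1L),
                          2L * (n_ex[i] - 1L)))
      exon_starts[[i]] <- c(tx_start[i], cuts[seq(2L, length(cuts), 2L)])
      exon_ends[[i]] <- c(cuts[seq(1L, length(cuts), 2L)], tx_end[i])
    }
    cds_start <- tx_start + round(0.15 * len)
    cds_end <- tx_end - round(0.15 * len)

    genes <- data.frame(
      gene_id = sprintf("gene%05d", seq_len(n)),
      chrom = .chrom_names(cfg)[chrom_idx],
      strand = strand,
      tx_start = tx_start,
      tx_end = tx_end,
      cds_start = cds_start,
      cds_end = cds_end,
      expression = expression,
      stringsAsFactors = FALSE
    )
    genes$exon_starts <- exon_starts
    genes$exon_ends <- exon_ends

    n_bound <- round(cfg$frac_bound * n)
    bound <- sample.int(n, n_bound, prob = expression^0.5)
    n_I <- max(2L, round(cfg$frac_group_I * n_bound))
    group_I <- bound[order(expression[bound], decreasing = TRUE)][seq_len(n_I)]
    cls <- rep("unbound", n)
    cls[bound] <- "II"
    cls[group_I] <- "I"

    tss <- ifelse(strand == "+", tx_start, tx_end)
    truth <- data.frame(
      gene_id = genes$gene_id,
      promoter_id = paste0(genes$chrom, ":", tss, ":", strand),
      class = cls,
      expression = expression,
      stringsAsFactors = FALSE
    )
    list(genes = genes, truth = truth)
  })
}

# Per-promoter binding amplitude for one factor, coupled to expression
# within each class so the class-mean amplitude is exactly the
# configured value.
.factor_amplitudes <- function(cfg, truth, factor) {
  cls <- truth$class
  e <- truth$expression
  coupling <- switch(factor,
                     PolII = 1,
                     cfg$expression_coupling)
  class_amp <- switch(factor,
    ALKBH3 = c(I = cfg$groupI_amplitude_fold, II = 1,
               unbound = cfg$unbound_amplitude_frac),
    XPB = c(I = 4, II = 1, unbound = 0.2),
    PolII = c(I = 1, II = 1, unbound = 1),
    IgG = c(I = 0, II = 0, unbound = 0),
    stop("unknown factor: ", factor)
  )
  amp <- numeric(length(cls))
  for (k in c("I", "II", "unbound")) {
    in_k <- cls == k
    if (!any(in_k)) next
    rel <- (e[in_k] / mean(e[in_k]))^coupling
    amp[in_k] <- class_amp[[k]] * rel / mean(rel)
  }
  amp
}

# Peak-position mixture for one factor/class: main peak offset and
# optional shoulder with its mixture weight.
.factor_shape <- function(cfg, factor, class) {
  upstream_peak <- list(main = cfg$groupI_peak_offset_bp, shoulder = NA,
                        w_shoulder = 0)
  downstream_peak <- list(
    main = cfg$groupII_peak_offset_bp,
    shoulder = if (cfg$groupII_shoulder) cfg$shoulder_offset_bp else NA,
    w_shoulder = if (cfg$groupII_shoulder)
      cfg$shoulder_frac / (1 + cfg$shoulder_frac) else 0)
  switch(factor,
         ALKBH3 = if (class == "I") upstream_peak else downstream_peak,
         XPB = if (class == "I") upstream_peak else downstream_peak,
         PolII = downstream_peak,
         IgG = upstream_peak)
}

#' Simulate ChIP-seq reads for one factor
#'
#' Reads are background (uniform over the genome) plus signal
#' fragments whose centres are Gaussian-positioned around a
#' class-dependent offset from each promoter's TSS, strand-oriented,
#' with per-promoter amplitudes from [.factor_amplitudes] semantics:
#' `ALKBH3` is 8-fold stronger at group I and peaks upstream; `PolII`
#' tracks expression at every promoter and peaks downstream with a
#' shoulder; `XPB` is group-I-skewed like ALKBH3; `IgG` is pure
#' background. Each fragment yields one read from a random end.
#'
#' @param cfg A [sim_config()].
#' @param genes,truth Output of [simulate_genes()].
#' @param factor One of `"ALKBH3"`, `"IgG"`, `"PolII"`, `"XPB"`.
#' @return `GRanges` of reads with seqlengths set.
#' @export
simulate_reads <- function(cfg, genes, truth,
                           factor = c("ALKBH3", "IgG", "PolII", "XPB")) {
  factor <- match.arg(factor)
  stopifnot(inherits(cfg, "sim_config"))
  sub_seed <- cfg$seed + 7919L * match(factor,
                                       c("ALKBH3", "IgG", "PolII", "XPB"))
  .with_seed(sub_seed, {
    amp <- .factor_amplitudes(cfg, truth, factor)
    bg_frac <- if (factor == "IgG" || sum(amp) == 0) 1 else
      cfg$background_frac
    depth <- round(cfg$read_depth)
    n_bg <- round(bg_frac * depth)
    n_sig <- depth - n_bg

    chrom <- character(0)
    centre <- numeric(0)
    if (n_sig > 0L) {
      gidx <- sample.int(nrow(genes), n_sig, replace = TRUE, prob = amp)
      tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end)
      anchor <- ifelse(genes$strand == "+", tss, tss - 1L)
      dir <- ifelse(genes$strand == "+", 1L, -1L)
      cls <- truth$class
      off <- numeric(n_sig)
      for (k in unique(cls[gidx])) {
        sel <- cls[gidx] == k
        shape <- .factor_shape(cfg, factor, k)
        m <- sum(sel)
        use_shoulder <- stats::runif(m) < shape$w_shoulder
        mu <- ifelse(use_shoulder, shape$shoulder, shape$main)
        off[sel] <- stats::rnorm(m, mu, cfg$binding_sd_bp)
      }
      chrom <- genes$chrom[gidx]
      centre <- anchor[gidx] + dir[gidx] * off
    }
    if (n_bg > 0L) {
      chrom <- c(chrom, sample(.chrom_names(cfg), n_bg, replace = TRUE))
      centre <- c(centre, stats::runif(n_bg, 0, cfg$chrom_length_bp))
    }

    left <- round(centre - cfg$fragment_bp / 2)
    n <- length(left)
    read_minus <- stats::runif(n) < 0.5
    start0 <- ifelse(read_minus,
                     left + cfg$fragment_bp - cfg$read_length_bp, left)
    start0 <- pmax(start0, 0)
    start0 <- pmin(start0, cfg$chrom_length_bp - cfg$read_length_bp)
    reads <- genomic_intervals(chrom, start0, start0 + cfg$read_length_bp,
                               ifelse(read_minus, "-", "+"))
    GenomeInfoDb::seqlevels(reads) <- .chrom_names(cfg)
    GenomeInfoDb::seqinfo(reads) <- .sim_seqinfo(cfg)
    reads
  })
}

#' Simulate annotation tracks, factor counts and expression tables
#'
#' Emits, with class-dependent statistics: clustered TFBS records
#' (Poisson event counts per promoter), CpG islands, conserved TBP
#' sites, ETS peaks, predicted G4 sites (inside promoters, at
#' enhancers, and elsewhere), H3K4me1/H3K27ac peak pairs at true
#' enhancer loci plus single-mark and promoter-overlapping decoys, a
#' per-factor tag-count table for the enrichment score, and a
#' two-timepoint DE table with planted consistent up/down gene sets.
#'
#' @param cfg A [sim_config()].
#' @param genes,truth Output of [simulate_genes()].
#' @return List: `tfbs`, `cpg`, `tbp_sites`, `ets_peaks`, `g4`,
#'   `h3k4me1`, `h3k27ac` (`GRanges`); `factor_counts` (matrix,
#'   promoters x factors); `expression` (data.frame); `de_table`
#'   (data.frame); `de_truth` (list `up`, `down`);
#'   `enhancer_truth` (`GRanges` of true enhancer cores).
#' @export
simulate_tracks <- function(cfg, genes, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed + 104729L, {
    n <- nrow(genes)
    tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end)
    anchor <- ifelse(genes$strand == "+", tss, tss - 1L)
    cls <- truth$class
    chrom <- genes$chrom
    empty <- GenomicRanges::GRanges()

    # clustered TFBS: one record per binding event
    tf_mean <- c(I = cfg$tf_event_means[1L], II = cfg$tf_event_means[2L],
                 unbound = cfg$tf_event_mean_unbound)
    k <- stats::rpois(n, tf_mean[cls])
    tfbs <- empty
    if (sum(k) > 0L) {
      pc <- rep(chrom, k)
      pa <- rep(anchor, k)
      pos <- pa + round(stats::runif(sum(k), -1000, 1000 - 15))
      pos <- pmax(pos, 0)
      tfbs <- genomic_intervals(pc, pos, pos + 15L,
                                name = sprintf("TF%02d",
                                               sample.int(40L, sum(k),
                                                          replace = TRUE)))
    }

    bern_track <- function(probs, half_width, width = NULL) {
      flag <- stats::runif(n) < probs[cls]
      if (!any(flag)) return(list(flag = flag, gr = empty))
      if (is.null(width)) {  # symmetric interval around the anchor
        s <- pmax(anchor[flag] - half_width, 0)
        gr <- genomic_intervals(chrom[flag], s, anchor[flag] + half_width)
      } else {               # narrow site placed randomly in the window
        pos <- anchor[flag] + round(stats::runif(sum(flag),
                                                 -half_width,
                                                 half_width - width))
        pos <- pmax(pos, 0)
        gr <- genomic_intervals(chrom[flag], pos, pos + width)
      }
      list(flag = flag, gr = gr)
    }
    cpg <- bern_track(cfg$cpg_probs, 300L)
    tbp <- bern_track(cfg$tata_probs, 1000L, width = 15L)
    ets <- bern_track(cfg$ets_probs, 100L)

    # enhancer loci: intergenic midpoints >= 2.5 kb from any TSS
    cand <- round(stats::runif(4L * cfg$n_enhancers, 3000,
                               cfg$chrom_length_bp - 3000))
    cand_chrom <- sample(.chrom_names(cfg), length(cand), replace = TRUE)
    ok <- vapply(seq_along(cand), function(i) {
      near <- chrom == cand_chrom[i] & abs(anchor - cand[i]) < 2500
      !any(near)
    }, logical(1L))
    mid <- cand[ok][seq_len(min(cfg$n_enhancers, sum(ok)))]
    mid_chrom <- cand_chrom[ok][seq_len(length(mid))]
    k4 <- genomic_intervals(mid_chrom, mid - 700, mid + 300)
    k27 <- genomic_intervals(mid_chrom, mid - 300, mid + 700)
    enhancer_truth <- genomic_intervals(mid_chrom, mid - 300, mid + 300)
    # decoys: single marks anywhere, and co-occurring pairs at promoters
    n_dec <- max(1L, round(cfg$n_enhancers / 3))
    dec_pos <- function(m) {
      p <- round(stats::runif(m, 1000, cfg$chrom_length_bp - 1000))
      list(chrom = sample(.chrom_names(cfg), m, replace = TRUE), pos = p)
    }
    d1 <- dec_pos(n_dec)
    d2 <- dec_pos(n_dec)
    prom_idx <- sample.int(n, min(n, max(1L, round(cfg$n_enhancers / 6))))
    k4 <- c(k4, genomic_intervals(d1$chrom, d1$pos - 500, d1$pos + 500),
            genomic_intervals(chrom[prom_idx], pmax(anchor[prom_idx] - 600, 0),
                              anchor[prom_idx] + 400))
    k27 <- c(k27, genomic_intervals(d2$chrom, d2$pos - 500, d2$pos + 500),
             genomic_intervals(chrom[prom_idx], pmax(anchor[prom_idx] - 400, 0),
                               anchor[prom_idx] + 600))

    # predicted G4 sites: half anywhere, a quarter in promoters,
    # a quarter at enhancers
    n_any <- round(cfg$n_g4 / 2)
    n_prom <- round(cfg$n_g4 / 4)
    n_enh <- cfg$n_g4 - n_any - n_prom
    g4_pos <- round(stats::runif(n_any, 0, cfg$chrom_length_bp - 30))
    g4_chrom <- sample(.chrom_names(cfg), n_any, replace = TRUE)
    pi <- sample.int(n, n_prom, replace = TRUE)
    g4_pos <- c(g4_pos, pmax(anchor[pi] + round(stats::runif(n_prom, -900, 900)),
                             0))
    g4_chrom <- c(g4_chrom, chrom[pi])
    if (length(mid) > 0L && n_enh > 0L) {
      ei <- sample.int(length(mid), n_enh, replace = TRUE)
      g4_pos <- c(g4_pos, mid[ei] + round(stats::runif(n_enh, -250, 250)))
      g4_chrom <- c(g4_chrom, mid_chrom[ei])
    }
    g4 <- genomic_intervals(g4_chrom, g4_pos, g4_pos + 30L)

    # per-factor tag counts for the enrichment score
    fold_by_class <- function(f) {
      c(I = f[1L], II = f[2L], unbound = f[2L])[cls]
    }
    factor_counts <- vapply(cfg$feature_folds, function(f) {
      stats::rpois(n, cfg$feature_base_mean * fold_by_class(f))
    }, numeric(n))
    rownames(factor_counts) <- truth$promoter_id

    expression <- data.frame(gene_id = genes$gene_id,
                             expression = genes$expression)

    # DE table with planted consistent changes outside the bound set
    ids <- c(genes$gene_id,
             sprintf("xgene%05d", seq_len(cfg$de_n_genes - n)))
    bound_ids <- genes$gene_id[cls != "unbound"]
    plantable <- setdiff(ids, bound_ids)
    planted <- sample(plantable, sum(cfg$de_plant))
    up_ids <- planted[seq_len(cfg$de_plant[1L])]
    down_ids <- planted[-seq_len(cfg$de_plant[1L])]
    m <- length(ids)
    clamp <- function(x) pmax(pmin(x, 0.89), -0.89)
    fc48 <- clamp(stats::rnorm(m, 0, cfg$de_null_sd))
    fc96 <- clamp(stats::rnorm(m, 0, cfg$de_null_sd))
    p48 <- stats::runif(m)
    p96 <- stats::runif(m)
    iu <- match(up_ids, ids)
    id_dn <- match(down_ids, ids)
    fc48[iu] <- stats::runif(length(iu), 1.0, 3.0)
    fc96[iu] <- stats::runif(length(iu), 1.0, 3.0)
    fc48[id_dn] <- -stats::runif(length(id_dn), 1.0, 3.0)
    fc96[id_dn] <- -stats::runif(length(id_dn), 1.0, 3.0)
    sig <- c(iu, id_dn)
    p48[sig] <- stats::runif(length(sig), 1e-4, 0.049)
    p96[sig] <- stats::runif(length(sig), 1e-4, 0.049)
    de_table <- data.frame(gene_id = ids, log2_fc_48h = fc48, p_48h = p48,
                           log2_fc_96h = fc96, p_96h = p96,
                           stringsAsFactors = FALSE)

    list(tfbs = tfbs, cpg = cpg$gr, tbp_sites = tbp$gr, ets_peaks = ets$gr,
         g4 = g4, h3k4me1 = sort(k4, ignore.strand = TRUE),
         h3k27ac = sort(k27, ignore.strand = TRUE),
         factor_counts = factor_counts,
         expression = expression, de_table = de_table,
         de_truth = list(up = up_ids, down = down_ids),
         enhancer_truth = enhancer_truth)
  })
}

#' Simulate a complete dataset
#'
#' Runs [simulate_genes()], [simulate_reads()] for the requested
#' factors and [simulate_tracks()] under one configuration.
#'
#' @param cfg A [sim_config()].
#' @param factors ChIP factors to simulate reads for.
#' @return List with `config`, `genes`, `truth`, `reads` (named list
#'   of `GRanges`) and all [simulate_tracks()] components under
#'   `tracks`.
#' @export
simulate_dataset <- function(cfg = sim_config(),
                             factors = c("ALKBH3", "IgG", "PolII")) {
  gt <- simulate_genes(cfg)
  reads <- lapply(stats::setNames(factors, factors), function(f) {
    simulate_reads(cfg, gt$genes, gt$truth, f)
  })
  tracks <- simulate_tracks(cfg, gt$genes, gt$truth)
  list(config = cfg, genes = gt$genes, truth = gt$truth,
       reads = reads, tracks = tracks)
}

#' Write / read a simulated dataset as plain-text files
#'
#' Interval tracks and reads go to BED, the gene models to a
#' refFlat-style table, expression / DE / factor-count tables to TSV,
#' and the ground truth to TSV, so a dataset round-trips losslessly
#' through the package's own readers.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `write_sim_dataset()`: `dir`, invisibly;
#'   `read_sim_dataset()`: a list mirroring [simulate_dataset()]
#'   (without `config`).
#' @export
write_sim_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_refflat(dataset$genes, fp("genes.refflat"))
  utils::write.table(dataset$truth, fp("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (f in names(dataset$reads)) {
    write_bed(dataset$reads[[f]], fp(paste0("reads_", f, ".bed")))
  }
  tr <- dataset$tracks
  for (nm in c("tfbs", "cpg", "tbp_sites", "ets_peaks", "g4",
               "h3k4me1", "h3k27ac")) {
    write_bed(tr[[nm]], fp(paste0(nm, ".bed")))
  }
  utils::write.table(data.frame(promoter_id = rownames(tr$factor_counts),
                                tr$factor_counts, check.names = FALSE),
                     fp("factor_counts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(tr$expression, fp("expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tr$de_table, fp("de_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_sim_dataset
#' @export
read_sim_dataset <- function(dir) {
  fp <- function(f) file.path(dir, f)
  expr <- utils::read.table(fp("expression.tsv"), header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  genes <- read_refflat(fp("genes.refflat"),
                        expression = stats::setNames(expr$expression,
                                                     expr$gene_id))
  truth <- utils::read.table(fp("truth.tsv"), header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  read_files <- list.files(dir, pattern = "^reads_.*\\.bed$")
  reads <- lapply(stats::setNames(
    read_files, sub("^reads_(.*)\\.bed$", "\\1", read_files)),
    function(f) read_bed(fp(f)))
  fc <- utils::read.table(fp("factor_counts.tsv"), header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  factor_counts <- as.matrix(fc[, -1L, drop = FALSE])
  rownames(factor_counts) <- fc$promoter_id
  tracks <- lapply(stats::setNames(
    c("tfbs", "cpg", "tbp_sites", "ets_peaks", "g4", "h3k4me1", "h3k27ac"),
    c("tfbs", "cpg", "tbp_sites", "ets_peaks", "g4", "h3k4me1", "h3k27ac")),
    function(nm) read_bed(fp(paste0(nm, ".bed"))))
  tracks$factor_counts <- factor_counts
  tracks$expression <- expr
  tracks$de_table <- read_de_table(fp("de_table.tsv"))
  list(genes = genes, truth = truth, reads = reads, tracks = tracks)
}
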