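test_that("configuration is validated", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(frac_bound = 0), "frac_bound")
  expect_error(sim_config(groupI_amplitude_fold = -1))
  expect_error(sim_config(de_n_genes = 100))
})

test_that("gene simulation is deterministic and structurally sound", {
  cfg <- small_cfg(seed = 5)
  a <- simulate_genes(cfg)
  b <- simulate_genes(cfg)
  expect_identical(a, b)

  g <- a$genes
  expect_equal(nrow(g), 400L)
  expect_identical(validate_gene_models(g), g)   # nothing dropped
  # non-overlapping transcripts per chromosome
  for (ch in unique(g$chrom)) {
    rows <- g[g$chrom == ch, ]
    rows <- rows[order(rows$tx_start), ]
    expect_true(all(rows$tx_start[-1] >= rows$tx_end[-nrow(rows)]))
  }
  # unique TSSs: one promoter per gene
  expect_equal(length(define_promoters(g)), nrow(g))
  # class proportions as configured
  expect_equal(sum(a$truth$class != "unbound"),
               round(cfg$frac_bound * cfg$n_genes))
  # group I promoters are the most active bound promoters
  bnd <- a$truth[a$truth$class != "unbound", ]
  expect_gte(min(bnd$expression[bnd$class == "I"]),
             max(bnd$expression[bnd$class == "II"]))

  empty <- simulate_genes(sim_config(n_genes = 0L))
  expect_equal(nrow(empty$genes), 0L)
})

test_that("strand assignment is balanced over seeds", {
  frac <- vapply(1:20, function(s) {
    mean(simulate_genes(small_cfg(seed = s))$genes$strand == "+")
  }, numeric(1))
  expect_gt(mean(frac), 0.45)
  expect_lt(mean(frac), 0.55)
})

test_that("read simulation hits its depth and amplitude targets", {
  cfg <- small_cfg(seed = 12)
  gt <- simulate_genes(cfg)
  reads <- simulate_reads(cfg, gt$genes, gt$truth, "ALKBH3")
  expect_equal(length(reads), cfg$read_depth)
  expect_identical(reads, simulate_reads(cfg, gt$genes, gt$truth, "ALKBH3"))

  prom <- define_promoters(gt$genes)
  cnt <- count_tags(reads, prom)
  cls <- stats::setNames(gt$truth$class, gt$truth$promoter_id)[
    prom$promoter_id]
  ratio <- mean(cnt$count[cls == "I"]) / mean(cnt$count[cls == "II"])
  expect_lt(abs(ratio / cfg$groupI_amplitude_fold - 1), 0.10)

  # control IgG is flat: promoter windows look like the genome average
  igg <- simulate_reads(cfg, gt$genes, gt$truth, "IgG")
  icnt <- count_tags(igg, prom)
  expected_bg <- cfg$read_depth * 2000 /
    (cfg$n_chroms * cfg$chrom_length_bp)
  expect_lt(abs(mean(icnt$count) / expected_bg - 1), 0.10)
  expect_error(simulate_reads(cfg, gt$genes, gt$truth, "H3K4me3"))
})

test_that("profile peak positions match the configured offsets", {
  cfg <- small_cfg(seed = 33)
  gt <- simulate_genes(cfg)
  prom <- define_promoters(gt$genes)
  m <- build_matrix(simulate_reads(cfg, gt$genes, gt$truth, "ALKBH3"),
                    prom)
  cls <- stats::setNames(gt$truth$class, gt$truth$promoter_id)
  pI <- average_profile(m, prom$promoter_id[cls[prom$promoter_id] == "I"])
  pII <- average_profile(m, prom$promoter_id[cls[prom$promoter_id] == "II"])
  # group I peaks upstream of the TSS, group II downstream near +60
  expect_lt(as.numeric(names(pI)[which.max(pI)]), 0)
  peak_II <- as.numeric(names(pII)[which.max(pII)])
  expect_gte(peak_II, 0)
  expect_lte(peak_II, 150)
  # Pol II mirrors the group II shape at bound and unbound promoters
  mp <- build_matrix(simulate_reads(cfg, gt$genes, gt$truth, "PolII"),
                     prom)
  pPol <- average_profile(mp)
  expect_gt(as.numeric(names(pPol)[which.max(pPol)]), 0)
})

test_that("track simulation honours its class-dependent statistics", {
  # 500 promoters per class for tight estimates of the event means
  cfg <- sim_config(seed = 2, n_genes = 1100, chrom_length_bp = 3e6,
                    frac_bound = 0.95, frac_group_I = 0.5,
                    read_depth = 1e5)
  gt <- simulate_genes(cfg)
  tr <- simulate_tracks(cfg, gt$genes, gt$truth)
  prom <- count_tf_events(define_promoters(gt$genes), tr$tfbs)
  cls <- stats::setNames(gt$truth$class, gt$truth$promoter_id)[
    prom$promoter_id]
  mI <- mean(prom$tf_event_count[cls == "I"])
  mII <- mean(prom$tf_event_count[cls == "II"])
  expect_lt(abs(mI / cfg$tf_event_means[1] - 1), 0.05)
  expect_lt(abs(mII / cfg$tf_event_means[2] - 1), 0.05)

  zero <- sim_config(seed = 2, n_genes = 200, chrom_length_bp = 1e6,
                     tf_event_means = c(0, 0), tf_event_mean_unbound = 0,
                     read_depth = 1e5)
  zt <- simulate_genes(zero)
  ztr <- simulate_tracks(zero, zt$genes, zt$truth)
  expect_length(ztr$tfbs, 0L)

  # planted DE recovery is exercised in test-de-filter; here check the
  # enhancer decoys: true enhancer cores survive the definition,
  # promoter-overlapping pairs do not
  prom2 <- define_promoters(gt$genes)
  enh <- define_enhancers(tr$h3k4me1, tr$h3k27ac, prom2)
  expect_gte(sum(IRanges::overlapsAny(tr$enhancer_truth, enh)),
             0.95 * length(tr$enhancer_truth))
  expect_false(any(IRanges::overlapsAny(enh, prom2)))
})

test_that("datasets round-trip losslessly through their text formats", {
  cfg <- sim_config(seed = 6, n_genes = 60, chrom_length_bp = 1e6,
                    read_depth = 5000)
  ds <- simulate_dataset(cfg, factors = c("ALKBH3", "IgG"))
  dir <- withr::local_tempdir()
  write_sim_dataset(ds, dir)
  back <- read_sim_dataset(dir)

  expect_equal(back$genes$gene_id, ds$genes$gene_id)
  expect_equal(back$genes$tx_start, ds$genes$tx_start)
  expect_equal(back$genes$exon_starts, ds$genes$exon_starts)
  expect_equal(back$genes$expression, ds$genes$expression,
               tolerance = 1e-12)
  expect_equal(back$truth, ds$truth)
  for (f in names(ds$reads)) {
    expect_equal(interval_start0(back$reads[[f]]),
                 interval_start0(ds$reads[[f]]))
    expect_equal(as.character(GenomicRanges::strand(back$reads[[f]])),
                 as.character(GenomicRanges::strand(ds$reads[[f]])))
  }
  for (nm in c("tfbs", "cpg", "g4")) {
    expect_equal(interval_start0(back$tracks[[nm]]),
                 interval_start0(ds$tracks[[nm]]))
    expect_equal(interval_end0(back$tracks[[nm]]),
                 interval_end0(ds$tracks[[nm]]))
  }
  expect_equal(back$tracks$factor_counts, ds$tracks$factor_counts)
  expect_equal(back$tracks$de_table$log2_fc_48h,
               ds$tracks$de_table$log2_fc_48h, tolerance = 1e-12)
})
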