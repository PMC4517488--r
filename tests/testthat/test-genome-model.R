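test_that("interval constructor validates coordinates", {
  gr <- genomic_intervals("chr1", 0, 10, "+")
  expect_s4_class(gr, "GRanges")
  expect_equal(interval_start0(gr), 0)
  expect_equal(interval_end0(gr), 10)
  expect_error(genomic_intervals("chr1", 10, 10), "start < end")
  expect_error(genomic_intervals("chr1", -1, 10), ">= 0")
  expect_error(genomic_intervals("", 0, 10), "non-empty")
})

test_that("overlap test uses half-open semantics", {
  a <- genomic_intervals("chr1", 0, 10)
  expect_false(overlaps(a, genomic_intervals("chr1", 10, 20)))
  expect_true(overlaps(a, genomic_intervals("chr1", 9, 20)))
  expect_false(overlaps(a, genomic_intervals("chr2", 0, 10)))
})

test_that("overlap test matches base-membership oracle on random pairs", {
  set.seed(42)
  a_df <- rand_interval_df(1000)
  b_df <- rand_interval_df(1000)
  got <- overlaps(df_to_gr(a_df), df_to_gr(b_df))
  want <- vapply(seq_len(1000), function(i) {
    oracle_overlap(a_df[i, ], b_df[i, ])
  }, logical(1L))
  expect_identical(got, want)
})

test_that("promoters deduplicate shared TSSs and merge attributes", {
  genes <- data.frame(
    gene_id = c("a", "b", "c"), chrom = "chr1",
    strand = c("+", "+", "-"),
    tx_start = c(5000, 5000, 1000), tx_end = c(7000, 9000, 2000),
    expression = c(3, 7, 1)
  )
  prom <- define_promoters(genes)
  expect_length(prom, 2L)
  shared <- prom[prom$tss == 5000]
  expect_equal(shared$gene_ids, "a,b")
  expect_equal(shared$expression, 7)    # max of contributors
  minus <- prom[as.character(GenomicRanges::strand(prom)) == "-"]
  expect_equal(minus$tss, 2000)         # TSS of a minus gene = tx_end
})

test_that("promoter construction rejects bad input and is idempotent-sized", {
  expect_error(define_promoters(data.frame()), "empty")
  genes <- data.frame(gene_id = c("ok", "bad"), chrom = "chr1",
                      strand = "+", tx_start = c(100, 500),
                      tx_end = c(400, 500))
  expect_warning(prom <- define_promoters(genes), "malformed")
  expect_length(prom, 1L)

  set.seed(7)
  g <- data.frame(gene_id = sprintf("g%d", 1:50), chrom = "chr1",
                  strand = sample(c("+", "-"), 50, TRUE),
                  tx_start = s <- sample.int(1e6, 50),
                  tx_end = s + sample.int(5000, 50))
  prom <- define_promoters(g)
  expect_lte(length(prom), nrow(g))
  key <- paste(GenomicRanges::seqnames(prom), prom$tss,
               GenomicRanges::strand(prom))
  expect_false(any(duplicated(key)))
})

test_that("enhancers are promoter-free intersections of the two marks", {
  prom_far <- define_promoters(data.frame(
    gene_id = "far", chrom = "chr1", strand = "+",
    tx_start = 50000, tx_end = 60000))
  k4 <- genomic_intervals("chr1", 0, 1000)
  k27 <- genomic_intervals("chr1", 500, 1500)
  enh <- define_enhancers(k4, k27, prom_far)
  expect_equal(interval_start0(enh), 500)
  expect_equal(interval_end0(enh), 1000)

  prom_near <- define_promoters(data.frame(
    gene_id = "near", chrom = "chr1", strand = "+",
    tx_start = 700, tx_end = 5000))
  expect_length(define_enhancers(k4, k27, prom_near), 0L)
  expect_length(define_enhancers(GenomicRanges::GRanges(), k27, prom_far), 0L)
})

test_that("enhancer definition matches brute-force pair enumeration", {
  set.seed(11)
  k4_df <- rand_interval_df(200, max_pos = 50000, max_len = 800)
  k27_df <- rand_interval_df(200, max_pos = 50000, max_len = 800)
  tss <- sample.int(47000, 50)
  prom <- define_promoters(data.frame(
    gene_id = sprintf("g%d", 1:50),
    chrom = sample(c("chrA", "chrB"), 50, TRUE), strand = "+",
    tx_start = tss, tx_end = tss + 2000))
  enh <- define_enhancers(df_to_gr(k4_df), df_to_gr(k27_df), prom)

  prom_df <- data.frame(chrom = as.character(GenomicRanges::seqnames(prom)),
                        start = interval_start0(prom),
                        end = interval_end0(prom))
  pieces <- list()
  for (i in seq_len(nrow(k4_df))) {
    for (j in seq_len(nrow(k27_df))) {
      if (!oracle_overlap(k4_df[i, ], k27_df[j, ])) next
      piece <- data.frame(chrom = k4_df$chrom[i],
                          start = max(k4_df$start[i], k27_df$start[j]),
                          end = min(k4_df$end[i], k27_df$end[j]))
      if (!oracle_overlap_any(piece, prom_df)) {
        pieces[[length(pieces) + 1L]] <- piece
      }
    }
  }
  want <- oracle_coverage(do.call(rbind, pieces))
  got <- oracle_coverage(data.frame(
    chrom = as.character(GenomicRanges::seqnames(enh)),
    start = interval_start0(enh), end = interval_end0(enh)))
  expect_identical(got[order(names(got))], want[order(names(want))])
})

test_that("G4 filtering equals the set-difference oracle", {
  tss <- seq(1000, 9000, by = 400)
  prom <- define_promoters(data.frame(
    gene_id = sprintf("g%d", seq_along(tss)), chrom = "chrA",
    strand = "+", tx_start = tss, tx_end = tss + 300),
    upstream_bp = 100, downstream_bp = 100)
  enh <- genomic_intervals("chrB", c(100, 5000), c(400, 5600))

  inside <- genomic_intervals("chrA", 1000, 1030)
  expect_length(filter_g4_sites(inside, prom, enh), 0L)
  lonely <- genomic_intervals("chrC", 1000, 1030)
  expect_length(filter_g4_sites(lonely, prom, enh), 1L)

  set.seed(23)
  g4_df <- rand_interval_df(500, max_len = 40)
  kept <- filter_g4_sites(df_to_gr(g4_df), prom, enh)
  feat_df <- data.frame(
    chrom = c(as.character(GenomicRanges::seqnames(prom)),
              as.character(GenomicRanges::seqnames(enh))),
    start = c(interval_start0(prom), interval_start0(enh)),
    end = c(interval_end0(prom), interval_end0(enh)))
  want_keep <- vapply(seq_len(nrow(g4_df)), function(i) {
    !oracle_overlap_any(g4_df[i, ], feat_df)
  }, logical(1L))
  expect_equal(length(kept), sum(want_keep))
  expect_equal(sort(interval_start0(kept)), sort(g4_df$start[want_keep]))
})

test_that("TATA/ETS flags match a brute-force membership oracle", {
  tss <- seq(2000, 8000, by = 1500)
  prom <- define_promoters(data.frame(
    gene_id = sprintf("g%d", seq_along(tss)), chrom = "chrA",
    strand = rep(c("+", "-"), length.out = length(tss)),
    tx_start = tss, tx_end = tss + 1000))

  hit <- genomic_intervals("chrA", prom$tss[1] + 10, prom$tss[1] + 25)
  flagged <- flag_tata_promoters(prom, hit)
  expect_true(flagged$tata_flag[1])
  expect_false(any(flagged$tata_flag[-1]))
  expect_false(any(flag_tata_promoters(prom,
                                       GenomicRanges::GRanges())$tata_flag))

  set.seed(31)
  sites_df <- rand_interval_df(500, chroms = "chrA", max_len = 30)
  sites <- df_to_gr(sites_df)
  prom_df <- data.frame(chrom = "chrA", start = interval_start0(prom),
                        end = interval_end0(prom))
  want <- vapply(seq_len(length(prom)), function(i) {
    oracle_overlap_any(prom_df[i, ], sites_df)
  }, logical(1L))
  expect_identical(unname(flag_tata_promoters(prom, sites)$tata_flag), want)
  expect_identical(unname(flag_ets_promoters(prom, sites)$ets_flag), want)
})

test_that("TF events count one per overlapping record", {
  prom <- define_promoters(data.frame(
    gene_id = "g", chrom = "chr1", strand = "+",
    tx_start = 5000, tx_end = 8000))
  three <- genomic_intervals("chr1", c(4200, 5000, 5500),
                             c(4300, 5100, 5600))
  expect_equal(count_tf_events(prom, three)$tf_event_count, 3L)
  expect_equal(count_tf_events(prom,
                               GenomicRanges::GRanges())$tf_event_count, 0L)
})

test_that("peak categories follow promoter-first precedence and partition", {
  genes <- toy_genes()
  prom <- define_promoters(genes)

  spans_tss <- genomic_intervals("chr1", 4900, 5100)
  expect_equal(as.character(annotate_peak_category(spans_tss, genes, prom)),
               "promoter")
  # inside gplus's first intron, but also within gminus's promoter
  # window if we move the window: construct a second gene whose
  # promoter covers gplus's intron
  genes2 <- rbind_genes(genes, data.frame(
    gene_id = "g3", chrom = "chr1", strand = "-",
    tx_start = 1000, tx_end = 7000,
    cds_start = 1500, cds_end = 6500, stringsAsFactors = FALSE))
  prom2 <- define_promoters(genes2)
  in_intron <- genomic_intervals("chr1", 6600, 6700)  # gplus intron 1
  expect_equal(as.character(annotate_peak_category(in_intron, genes2, prom2)),
               "promoter")
  expect_equal(as.character(annotate_peak_category(in_intron, genes, prom)),
               "intron")

  utr <- genomic_intervals("chr1", 6100, 6200)   # exonic, left of CDS, +
  expect_equal(as.character(annotate_peak_category(utr, genes, prom)),
               "utr5")
  nowhere <- genomic_intervals("chr1", 40000, 40100)
  expect_equal(as.character(annotate_peak_category(nowhere, genes, prom)),
               "intergenic")

  set.seed(5)
  peaks <- df_to_gr(rand_interval_df(1000, chroms = "chr1",
                                     max_pos = 35000, max_len = 500))
  fr <- category_fractions(annotate_peak_category(peaks, genes, prom))
  expect_equal(sum(fr), 1)
})

test_that("mirroring the genome preserves promoters and overlap flags", {
  L <- 1e6
  set.seed(13)
  n <- 60
  s <- sort(sample.int(L - 20000, n))
  genes <- data.frame(gene_id = sprintf("g%d", 1:n), chrom = "chr1",
                      strand = sample(c("+", "-"), n, TRUE),
                      tx_start = s, tx_end = s + 3000)
  sites <- df_to_gr(rand_interval_df(300, chroms = "chr1",
                                     max_pos = L, max_len = 50))
  prom <- define_promoters(genes)
  prom_m <- define_promoters(mirror_genes(genes, L))
  expect_equal(length(prom), length(prom_m))

  f <- flag_tata_promoters(prom, sites)
  f_m <- flag_tata_promoters(prom_m, mirror_gr(sites, L))
  map <- match(mirror_promoter_id(f$promoter_id, L), f_m$promoter_id)
  expect_false(anyNA(map))
  expect_identical(unname(f$tata_flag), unname(f_m$tata_flag[map]))

  c1 <- count_tf_events(prom, sites)$tf_event_count
  c2 <- count_tf_events(prom_m, mirror_gr(sites, L))$tf_event_count[map]
  expect_identical(unname(c1), unname(c2))
})
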