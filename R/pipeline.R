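# End-to-end convenience wrapper used by the worked example, the
# acceptance script and the recovery tests: promoters -> signal
# matrices -> bound selection -> k-means groups -> annotation,
# enrichment, quintile correlation and the DE filter.

#' Run the full promoter-classification analysis
#'
#' @param dataset A dataset in the layout of [simulate_dataset()]:
#'   `genes`, `reads` (named list with at least the main factor and a
#'   control), `tracks` (annotation tracks and tables).
#' @param factor_name,control_name Names of the main-factor and
#'   control read sets inside `dataset$reads`.
#' @param min_fold Bound-promoter enrichment threshold over control.
#' @param flank_bp,bin_bp Signal-matrix geometry.
#' @param shift_bp Read 5'-end shift.
#' @param seed,n_restarts k-means reproducibility parameters.
#' @param genome_size Effective genome size; taken from the dataset
#'   config when present.
#' @return List with `promoters` (annotated `GRanges`), `matrix`,
#'   `control_matrix`, `bound_ids`, `assignment`, `fold_ratio`,
#'   `enrichment` (per-factor table), `quintile_r` (when a `"PolII"`
#'   read set is present), and `de` (up/down gene sets, when a DE
#'   table is present).
#' @export
run_pipeline <- function(dataset, factor_name = "ALKBH3",
                         control_name = "IgG", min_fold = 2,
                         flank_bp = 1500L, bin_bp = 50L, shift_bp = 100L,
                         seed = 1L, n_restarts = 10L, genome_size = NULL) {
  if (is.null(genome_size) && !is.null(dataset$config)) {
    genome_size <- dataset$config$n_chroms * dataset$config$chrom_length_bp
  }
  promoters <- define_promoters(dataset$genes)
  mat <- build_matrix(dataset$reads[[factor_name]], promoters,
                      flank_bp = flank_bp, bin_bp = bin_bp,
                      shift_bp = shift_bp, genome_size = genome_size)
  ctrl <- build_matrix(dataset$reads[[control_name]], promoters,
                       flank_bp = flank_bp, bin_bp = bin_bp,
                       shift_bp = shift_bp, genome_size = genome_size)
  bound <- select_bound_promoters(mat, ctrl, min_fold = min_fold)
  assignment <- kmeans_groups(mat, bound, k = 2L,
                              n_restarts = n_restarts, seed = seed)
  groupI <- assignment$promoter_id[assignment$group == "I"]
  groupII <- assignment$promoter_id[assignment$group == "II"]
  promoters$group <- "unbound"
  promoters$group[promoters$promoter_id %in% groupII] <- "II"
  promoters$group[promoters$promoter_id %in% groupI] <- "I"

  tr <- dataset$tracks
  if (!is.null(tr$tbp_sites)) {
    promoters <- flag_tata_promoters(promoters, tr$tbp_sites)
  }
  if (!is.null(tr$ets_peaks)) {
    promoters <- flag_ets_promoters(promoters, tr$ets_peaks)
  }
  if (!is.null(tr$tfbs)) promoters <- count_tf_events(promoters, tr$tfbs)
  if (!is.null(tr$cpg)) {
    promoters$cpg_flag <- IRanges::overlapsAny(promoters, tr$cpg,
                                               ignore.strand = TRUE)
  }

  enrichment <- NULL
  if (!is.null(tr$factor_counts) && length(groupI) && length(groupII)) {
    enrichment <- enrichment_table(tr$factor_counts, groupI, groupII,
                                   promoters$promoter_id)
  }

  quintile_r <- NULL
  if ("PolII" %in% names(dataset$reads)) {
    expr <- stats::setNames(promoters$expression, promoters$promoter_id)
    main_counts <- stats::setNames(
      count_tags(dataset$reads[[factor_name]], promoters,
                 shift_bp = shift_bp)$tags_per_million,
      promoters$promoter_id)
    pol2_counts <- stats::setNames(
      count_tags(dataset$reads$PolII, promoters,
                 shift_bp = shift_bp)$tags_per_million,
      promoters$promoter_id)
    quintile_r <- quintile_correlation(expr, groupI, main_counts,
                                       pol2_counts)
  }

  de <- if (!is.null(tr$de_table)) consistent_de_genes(tr$de_table)

  list(promoters = promoters, matrix = mat, control_matrix = ctrl,
       bound_ids = bound, assignment = assignment,
       fold_ratio = group_fold_ratio(mat, assignment),
       enrichment = enrichment, quintile_r = quintile_r, de = de)
}
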