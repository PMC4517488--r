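# Knockdown differential-expression filtering: the volcano cutoff
# (two-fold change, p < 0.05, at both timepoints) and the bound-gene
# expression-shift test.

#' Read a two-timepoint fold-change/p-value table
#'
#' Expects tab- or comma-separated columns `gene_id`, `log2_fc_48h`,
#' `p_48h`, `log2_fc_96h`, `p_96h` (any order, by name).
#'
#' @param path File path.
#' @return data.frame in the expected column layout.
#' @export
read_de_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("gene_id", "log2_fc_48h", "p_48h", "log2_fc_96h", "p_96h")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("DE table lacks columns: ", paste(missing, collapse = ", "))
  }
  df[required]
}

#' Genes consistently changed at both knockdown timepoints
#'
#' Applies the volcano cutoff at each timepoint and keeps genes
#' passing at both: upregulated genes have
#' `log2 fold-change >= log2(fc_cutoff)` (fold inclusive) and
#' `p < p_cutoff` (strict) at 48 h and 96 h; downregulated genes the
#' mirror image. Genes with a missing timepoint are excluded with a
#' message. The returned sets are disjoint by construction.
#'
#' @param table data.frame as from [read_de_table()].
#' @param fc_cutoff Fold-change cutoff on the linear scale (default 2).
#' @param p_cutoff P-value cutoff (default 0.05, uncorrected —
#'   set `adjust = "BH"` to filter on Benjamini-Hochberg-adjusted
#'   p-values instead).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return List with character vectors `up` and `down`.
#' @export
consistent_de_genes <- function(table, fc_cutoff = 2, p_cutoff = 0.05,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  complete <- stats::complete.cases(
    table[c("log2_fc_48h", "p_48h", "log2_fc_96h", "p_96h")])
  if (any(!complete)) {
    message(sum(!complete), " gene(s) with a missing timepoint excluded")
    table <- table[complete, , drop = FALSE]
  }
  p48 <- table$p_48h
  p96 <- table$p_96h
  if (adjust == "BH") {
    p48 <- stats::p.adjust(p48, method = "BH")
    p96 <- stats::p.adjust(p96, method = "BH")
  }
  lfc <- log2(fc_cutoff)
  sig <- p48 < p_cutoff & p96 < p_cutoff
  up <- sig & table$log2_fc_48h >= lfc & table$log2_fc_96h >= lfc
  down <- sig & table$log2_fc_48h <= -lfc & table$log2_fc_96h <= -lfc
  list(up = table$gene_id[up], down = table$gene_id[down])
}

#' Expression shift of factor-bound genes after knockdown
#'
#' Compares the mean log2 fold-change (averaged over the two
#' timepoints) of bound versus unbound genes with a Welch t-test —
#' the check behind the claim that binding alone does not predict an
#' expression response.
#'
#' @param table data.frame as from [read_de_table()].
#' @param bound_ids Gene ids bound by the factor.
#' @return List with `effect_size` (mean bound minus mean unbound,
#'   log2 units), `t`, `df` and `p`.
#' @export
bound_gene_expression_shift <- function(table, bound_ids) {
  fc <- (table$log2_fc_48h + table$log2_fc_96h) / 2
  is_bound <- table$gene_id %in% bound_ids
  a <- fc[is_bound & !is.na(fc)]
  b <- fc[!is_bound & !is.na(fc)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("bound and unbound sets must each contain at least 2 genes")
  }
  tt <- unpaired_t_test(a, b)
  list(effect_size = mean(a) - mean(b), t = tt$t, df = tt$df, p = tt$p)
}

#' Write gene lists as TSV
#'
#' @param sets Named list of character vectors (e.g. the result of
#'   [consistent_de_genes()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_lists <- function(sets, path) {
  df <- data.frame(
    gene_id = unlist(sets, use.names = FALSE),
    set = rep(names(sets), lengths(sets))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
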