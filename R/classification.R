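# Bound-promoter selection and the k-means group I / group II split.

# Run an expression under a fixed RNG seed without disturbing the
# caller's RNG state.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Select promoters enriched over a matched control
#'
#' A promoter is bound when its windowed signal strictly exceeds
#' `min_fold` times the matched control (IgG or depth-scaled input)
#' at the same promoter. Without a control the expected uniform
#' background over the window — `1e6 * window / genome_size` tags per
#' million — substitutes for it, with a warning.
#'
#' @param matrix `SignalMatrix` for the factor of interest.
#' @param control_matrix Matched control `SignalMatrix` sharing the
#'   same anchors, or `NULL`.
#' @param min_fold Enrichment threshold (default 2).
#' @param window_bp Half-width of the window the comparison is made
#'   over (default 1,000 bp: the promoter window, even when the matrix
#'   carries a wider flank).
#' @return Character vector of bound promoter ids.
#' @export
select_bound_promoters <- function(matrix, control_matrix = NULL,
                                   min_fold = 2, window_bp = 1000L) {
  window_bp <- min(window_bp, matrix$flank_bp)
  signal <- windowed_signal(matrix, window_bp)
  if (is.null(control_matrix)) {
    if (is.null(matrix$genome_size)) {
      stop("no control matrix and no genome_size for a background fallback")
    }
    warning("no control matrix; using uniform genome background as control")
    bg <- 1e6 * (2 * window_bp) / matrix$genome_size
    ctrl <- rep(bg, length(signal))
  } else {
    if (!identical(control_matrix$anchor_ids, matrix$anchor_ids)) {
      stop("signal and control matrices must share anchors")
    }
    ctrl <- windowed_signal(control_matrix, window_bp)
  }
  names(signal)[signal > min_fold * ctrl]
}

#' Split bound promoters into groups I and II by k-means
#'
#' Rows of the binned matrix restricted to the bound promoters are
#' scaled by their maximum, so peak position (profile shape) and not
#' only amplitude drives the clustering; amplitude re-enters through
#' the labelling rule: the cluster with the higher mean windowed
#' signal is always group I. Plain Euclidean k-means with `n_restarts`
#' random starts under a fixed seed makes the split reproducible.
#'
#' If the bound profiles contain fewer distinct rows than `k` the
#' clustering is degenerate: all promoters are returned in group I and
#' the result carries `attr(, "degenerate") = TRUE` with zero
#' within-cluster sum of squares.
#'
#' @param matrix A `SignalMatrix`.
#' @param bound_ids Promoter ids to cluster (length >= `k`).
#' @param k Number of clusters (default 2).
#' @param n_restarts Random restarts; best fit by within-cluster SS.
#' @param seed RNG seed for the restarts.
#' @param window_bp Half-width of the promoter window `mean_signal`
#'   and the group-labelling rule are computed over (default 1,000 bp).
#' @return data.frame with `promoter_id`, `group` (`"I"`, `"II"`, ...),
#'   `mean_signal` (windowed tags per million) and `cluster_distance`
#'   (Euclidean distance to the assigned centroid in scaled space);
#'   attributes `degenerate` and `tot_withinss`.
#' @export
kmeans_groups <- function(matrix, bound_ids, k = 2L, n_restarts = 10L,
                          seed = 1L, window_bp = 1000L) {
  rows <- match(bound_ids, matrix$anchor_ids)
  if (anyNA(rows)) stop("unknown promoter ids in bound_ids")
  if (length(rows) < k) stop("fewer bound promoters than clusters")
  X <- matrix$values[rows, , drop = FALSE]
  mean_signal <- windowed_signal(matrix, min(window_bp, matrix$flank_bp))[rows]
  rmax <- apply(X, 1L, max)
  Xs <- X / pmax(rmax, .Machine$double.eps)

  if (nrow(unique(Xs)) < k) {
    out <- data.frame(promoter_id = bound_ids, group = "I",
                      mean_signal = mean_signal, cluster_distance = 0)
    attr(out, "degenerate") <- TRUE
    attr(out, "tot_withinss") <- 0
    return(out)
  }

  km <- .with_seed(seed, stats::kmeans(Xs, centers = k,
                                       nstart = n_restarts, iter.max = 100L))
  # rank clusters by mean windowed signal: strongest is always group I
  cl_mean <- tapply(mean_signal, km$cluster, mean)
  rank_desc <- rank(-cl_mean, ties.method = "first")
  labels <- stats::setNames(as.character(utils::as.roman(rank_desc)),
                            names(cl_mean))
  dist_to_centre <- sqrt(rowSums((Xs - km$centers[km$cluster, ,
                                                  drop = FALSE])^2))
  out <- data.frame(promoter_id = bound_ids,
                    group = unname(labels[as.character(km$cluster)]),
                    mean_signal = mean_signal,
                    cluster_distance = dist_to_centre)
  attr(out, "degenerate") <- FALSE
  attr(out, "tot_withinss") <- km$tot.withinss
  out
}

#' Ratio of mean binding strength, group I over group II
#'
#' @param matrix A `SignalMatrix`.
#' @param assignment data.frame from [kmeans_groups()].
#' @param window_bp Half-width of the promoter window (default
#'   1,000 bp).
#' @return Mean windowed signal of group I divided by that of
#'   group II.
#' @export
group_fold_ratio <- function(matrix, assignment, window_bp = 1000L) {
  sig <- windowed_signal(matrix, min(window_bp, matrix$flank_bp))
  m1 <- mean(sig[assignment$promoter_id[assignment$group == "I"]])
  m2 <- mean(sig[assignment$promoter_id[assignment$group == "II"]])
  if (!is.finite(m1) || !is.finite(m2)) stop("both groups must be non-empty")
  if (m2 == 0) stop("group II mean signal is zero")
  m1 / m2
}
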