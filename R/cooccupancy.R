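## TF co-localization: Euler region counts over per-TF site sets, pairwise
## overlap percentages with hypergeometric enrichment p-values, and Ward
## clustering of the occupancy matrix.

#' Site-set overlap analysis across TFs
#'
#' Computes exact Euler region counts (one count per subset signature of
#' TFs sharing a site), pairwise shared-site counts with percentages of
#' each set, and one-sided upper-tail hypergeometric enrichment p-values
#' `P(X >= n_shared)` with `X ~ Hypergeom(universe, |A|, |B|)`. No
#' multiple-testing correction is applied across pairs; Bonferroni-adjusted
#' values are reported alongside for convenience.
#'
#' @param assignments named list TF -> vector of site ids (drawn from one
#'   library).
#' @param universe size of the site universe (>= the union of all sets).
#' @return list of class `OverlapResult`: `set_sizes`, `region_counts`
#'   (named by `&`-joined subset signature), `pairwise` (data.frame with
#'   `tf_a`, `tf_b`, `n_shared`, `pct_a_shared`, `pct_b_shared`, `p_hyper`,
#'   `p_bonferroni`), `universe`.
#' @export
overlap_analysis <- function(assignments, universe) {
  stopifnot(is.list(assignments), !is.null(names(assignments)))
  sets <- lapply(assignments, function(x) unique(as.character(x)))
  all_ids <- unique(unlist(sets, use.names = FALSE))
  if (universe < length(all_ids))
    stop("universe (", universe, ") smaller than the union of the sets (",
         length(all_ids), ")")
  tfs <- names(sets)
  sig <- vapply(all_ids, function(id)
    paste(tfs[vapply(sets, function(s) id %in% s, logical(1L))],
          collapse = "&"), character(1L))
  region_counts <- table(sig)
  region_counts <- stats::setNames(as.integer(region_counts),
                                   names(region_counts))
  pairwise <- NULL
  if (length(tfs) >= 2L) {
    cmb <- utils::combn(tfs, 2L)
    rows <- lapply(seq_len(ncol(cmb)), function(i) {
      a <- cmb[1L, i]; b <- cmb[2L, i]
      na <- length(sets[[a]]); nb <- length(sets[[b]])
      sh <- length(intersect(sets[[a]], sets[[b]]))
      p <- stats::phyper(sh - 1L, na, universe - na, nb, lower.tail = FALSE)
      data.frame(tf_a = a, tf_b = b, n_shared = sh,
                 pct_a_shared = if (na) round(100 * sh / na, 1L) else NA_real_,
                 pct_b_shared = if (nb) round(100 * sh / nb, 1L) else NA_real_,
                 p_hyper = p)
    })
    pairwise <- do.call(rbind, rows)
    pairwise$p_bonferroni <- pmin(1, pairwise$p_hyper * nrow(pairwise))
  }
  structure(list(set_sizes = vapply(sets, length, integer(1L)),
                 region_counts = region_counts,
                 pairwise = pairwise, universe = universe),
            class = "OverlapResult")
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat(sprintf("OverlapResult: %d sets, universe %d, %d Euler regions\n",
              length(x$set_sizes), x$universe, length(x$region_counts)))
  if (!is.null(x$pairwise)) print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Optional transform before clustering
#'
#' @param matrix occupancy matrix (sites x TFs).
#' @param mode `"none"` (identity, the default), `"log1p"`, or
#'   `"row-scale"` (each row centered and scaled to unit s.d.; constant
#'   rows become 0).
#' @return transformed matrix of the same shape.
#' @export
transform_for_clustering <- function(matrix, mode = c("none", "log1p",
                                                      "row-scale")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(matrix), all(is.finite(matrix)))
  switch(mode,
         none = matrix,
         log1p = log1p(matrix),
         `row-scale` = {
           mu <- rowMeans(matrix)
           sdv <- apply(matrix, 1L, stats::sd)
           out <- sweep(matrix, 1L, mu, "-")
           sdv[sdv == 0] <- Inf   # constant rows -> 0 after division
           sweep(out, 1L, sdv, "/")
         })
}

#' Ward clustering of TFs by occupancy profile
#'
#' Agglomerative hierarchical clustering of the TF column vectors (one
#' entry per site) using Euclidean distances under the Ward.D2 objective
#' (minimum within-cluster variance increase); labels are obtained by
#' cutting the tree into `k` groups.
#'
#' @param matrix occupancy matrix (sites x TFs) from
#'   [build_signal_matrix()].
#' @param k number of clusters to cut (default 6).
#' @param method `stats::hclust` linkage method (default `"ward.D2"`).
#' @return list of class `TFClustering`: `hclust` (merge tree), `k`,
#'   `labels` (named integer vector TF -> cluster id).
#' @export
cluster_tfs <- function(matrix, k = 6L, method = "ward.D2") {
  stopifnot(is.matrix(matrix), all(is.finite(matrix)))
  if (ncol(matrix) < 2L) stop("need at least 2 TFs to cluster")
  if (k > ncol(matrix)) stop("k (", k, ") exceeds the number of TFs (",
                             ncol(matrix), ")")
  if (k < 1L) stop("k must be >= 1")
  hc <- stats::hclust(stats::dist(t(matrix)), method = method)
  labels <- stats::cutree(hc, k = k)
  structure(list(hclust = hc, k = as.integer(k), labels = labels),
            class = "TFClustering")
}

#' Cluster labels at another cut level
#' @param clustering `TFClustering` from [cluster_tfs()].
#' @param k number of groups.
#' @return named integer vector TF -> cluster id.
#' @export
cluster_labels <- function(clustering, k = clustering$k) {
  stopifnot(inherits(clustering, "TFClustering"))
  stats::cutree(clustering$hclust, k = k)
}

#' @export
print.TFClustering <- function(x, ...) {
  cat(sprintf("TFClustering: %d TFs cut into %d cluster(s)\n",
              length(x$labels), x$k))
  print(x$labels)
  invisible(x)
}
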