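# Hierarchical clustering of descriptor (or MSA-aligned RMSF) vectors for
# variant discrimination.

#' Euclidean distances between the non-null bits of descriptor vectors
#'
#' Columns that are zero across every vector (alignment gap columns shared
#' by the compared set, or unresolved positions of RMSF vectors) carry no
#' information and are removed before computing pairwise Euclidean
#' distances; removing them never changes a distance. RMSF vectors may use
#' `NA` for unresolved positions; columns containing any `NA` are treated
#' as null.
#'
#' @param vectors Named list of equal-length numeric vectors.
#' @return A `dist` object (zero diagonal, symmetric).
#' @export
descriptor_distance_matrix <- function(vectors) {
  stopifnot(length(vectors) >= 2)
  len <- unique(vapply(vectors, length, integer(1)))
  if (length(len) != 1) stop("vectors have unequal lengths")
  m <- do.call(rbind, lapply(vectors, as.numeric))
  rownames(m) <- names(vectors)
  drop <- apply(m, 2, function(col) any(is.na(col)) || all(col == 0))
  stats::dist(m[, !drop, drop = FALSE], method = "euclidean")
}

#' Agglomerative clustering of a distance matrix
#'
#' @param dist A `dist` object (or symmetric non-negative matrix).
#' @param linkage Linkage method (default `"average"`, i.e. UPGMA).
#' @return A `ddpd_tree`: the `hclust` tree plus `D_max`, the final merge
#'   distance. Ties are resolved deterministically by input label order.
#' @export
hierarchical_cluster <- function(dist, linkage = "average") {
  if (is.matrix(dist)) {
    if (!isSymmetric(unname(dist)) || any(dist < 0)) {
      stop("distance matrix must be symmetric and non-negative")
    }
    dist <- stats::as.dist(dist)
  }
  if (attr(dist, "Size") == 1) {
    return(structure(list(hclust = NULL, labels = attr(dist, "Labels"),
                          D_max = 0, linkage = linkage), class = "ddpd_tree"))
  }
  hc <- stats::hclust(dist, method = linkage)
  structure(list(hclust = hc, labels = hc$labels, D_max = max(hc$height),
                 linkage = linkage), class = "ddpd_tree")
}

#' @export
print.ddpd_tree <- function(x, ...) {
  cat("ddpd_tree:", length(x$labels), "leaves,", x$linkage,
      "linkage, final merge at", signif(x$D_max, 4), "\n")
  invisible(x)
}

#' @export
plot.ddpd_tree <- function(x, ...) {
  plot(x$hclust, ...)
  invisible(x)
}

#' Flat clusters at a fraction of the final merge distance
#'
#' Merges whose distance is strictly below `fraction * D_max` are joined;
#' at `fraction = 1` only the final merge is cut, giving at most two
#' clusters.
#'
#' @param tree A `ddpd_tree`.
#' @param fraction Cut height as a fraction of the final merge distance
#'   (0 < fraction <= 1; default 0.7).
#' @return Named integer vector: label -> cluster id (ids numbered by
#'   first appearance in label order).
#' @export
cut_clusters <- function(tree, fraction = 0.7) {
  stopifnot(fraction > 0, fraction <= 1)
  if (is.null(tree$hclust)) return(stats::setNames(1L, tree$labels))
  hc <- tree$hclust
  n <- length(hc$labels)
  n_merged <- sum(hc$height < fraction * tree$D_max)
  cl <- stats::cutree(hc, k = n - n_merged)
  # renumber by first appearance for label-order determinism
  ids <- unique(cl)
  stats::setNames(as.integer(match(cl, ids)), hc$labels)
}
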