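## Network-based subtyping: rank edges by ECv variance across patients,
## keep the top N, and cluster patients on the reduced matrix by
## agglomerative hierarchical clustering.

#' Rank edges by ECv variance across patients
#'
#' Unbiased sample variance (divisor n-1) per edge column, ranked in
#' descending order; ties broken by ascending edge id.
#'
#' @param ecv samples x edges ECv matrix with >= 2 rows
#' @return data.frame(edge, variance) in rank order, class `edge_selection`
#' @export
rank_edges_by_variance <- function(ecv) {
  if (nrow(ecv) < 2L) stop("need at least two samples to compute variances")
  v <- apply(ecv, 2, stats::var)
  ord <- order(-v, colnames(ecv))
  structure(data.frame(edge = colnames(ecv)[ord], variance = v[ord],
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("edge_selection", "data.frame"))
}

#' Reduce an ECv matrix to its top-N-variance edges
#'
#' @param selection `edge_selection` from [rank_edges_by_variance()]
#' @param ecv the ECv matrix the selection was computed from
#' @param n_edges number of edges to keep (default 250, the headline setting
#'   for TCGA-scale networks); capped at the number of available edges
#' @return reduced ECv matrix, columns in rank order
#' @export
select_top_edges <- function(selection, ecv, n_edges = 250L) {
  stopifnot(inherits(selection, "edge_selection"))
  if (n_edges < 1L) stop("n_edges must be >= 1")
  keep <- selection$edge[seq_len(min(n_edges, nrow(selection)))]
  ecv[, keep, drop = FALSE]
}

#' Hierarchically cluster patients into subtypes
#'
#' Agglomerative clustering of the rows of the (reduced) ECv matrix, tree cut
#' to exactly `k` clusters. Cluster labels are renumbered 1..k in decreasing
#' cluster size, ties broken by the smallest member sample id, so labels are
#' deterministic and invariant to row/column order.
#'
#' @param ecv samples x edges matrix (typically from [select_top_edges()])
#' @param k number of subtypes (default 3)
#' @param linkage one of "ward", "single", "complete", "average"
#' @param distance "euclidean" or any method of [stats::dist()]
#' @param scale_columns if TRUE, z-score each column before clustering
#'   (default FALSE: raw ECvs)
#' @return object of class `subtype_assignment`: `labels` (named integer
#'   vector), `tree` (hclust), `params`
#' @export
cluster_patients <- function(ecv, k = 3L, linkage = c("ward", "single",
                             "complete", "average"),
                             distance = "euclidean", scale_columns = FALSE) {
  linkage <- match.arg(linkage)
  n <- nrow(ecv)
  if (n < 2L) stop("need at least two patients")
  if (k > n) stop("k (", k, ") cannot exceed the number of patients (", n, ")")
  if (k < 1L) stop("k must be >= 1")
  M <- ecv[, order(colnames(ecv)), drop = FALSE]  # column-order invariance
  M <- M[order(rownames(M)), , drop = FALSE]      # row-order invariance
  if (scale_columns) {
    sds <- apply(M, 2, stats::sd)
    sds[sds == 0] <- 1
    M <- scale(M, center = TRUE, scale = sds)
  }
  hc_method <- if (linkage == "ward") "ward.D2" else linkage
  tree <- stats::hclust(stats::dist(M, method = distance), method = hc_method)
  raw <- stats::cutree(tree, k = k)
  labels <- relabel_by_size(raw)
  structure(list(labels = labels, tree = tree,
                 params = list(k = k, linkage = linkage, distance = distance,
                               scale_columns = scale_columns)),
            class = "subtype_assignment")
}

# renumber cluster labels 1..k by decreasing size; ties by the smallest
# member sample id (lexicographic)
relabel_by_size <- function(raw) {
  sizes <- table(raw)
  firsts <- vapply(names(sizes), function(l) min(names(raw)[raw == l]),
                   character(1))
  ord <- names(sizes)[order(-as.integer(sizes), firsts)]
  out <- match(as.character(raw), ord)
  names(out) <- names(raw)
  out
}

#' @export
print.subtype_assignment <- function(x, ...) {
  cat("subtype_assignment:", length(x$labels), "patients in",
      length(unique(x$labels)), "subtypes (sizes:",
      paste(table(x$labels), collapse = "/"), ")\n")
  invisible(x)
}

#' Write a subtype assignment to TSV and the dendrogram to Newick
#' @param assignment `subtype_assignment`
#' @param path TSV output path (columns sample_id, subtype)
#' @param newick_path optional path for the dendrogram in Newick format
#' @return `path`, invisibly
#' @export
write_assignment <- function(assignment, path, newick_path = NULL) {
  df <- data.frame(sample_id = names(assignment$labels),
                   subtype = assignment$labels, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(newick_path)) {
    ape::write.tree(ape::as.phylo(assignment$tree), file = newick_path)
  }
  invisible(path)
}

#' Cross-tabulate two subtype assignments and compute the adjusted Rand index
#'
#' Restricted to samples present in both assignments. The ARI is the standard
#' pair-counting, chance-corrected agreement: 1 for identical partitions, ~0
#' for independent ones.
#'
#' @param a,b named label vectors (or `subtype_assignment` objects)
#' @return list: `table` (contingency counts), `ari`, `n` (overlap size)
#' @export
compare_assignments <- function(a, b) {
  if (inherits(a, "subtype_assignment")) a <- a$labels
  if (inherits(b, "subtype_assignment")) b <- b$labels
  common <- intersect(names(a), names(b))
  if (!length(common)) stop("no overlapping samples between assignments")
  tab <- table(a = as.character(a[common]), b = as.character(b[common]))
  list(table = tab, ari = adjusted_rand_index(tab), n = length(common))
}

#' Adjusted Rand index from a contingency table
#' @param tab contingency table of two labelings over the same samples
#' @return scalar ARI
#' @export
adjusted_rand_index <- function(tab) {
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)  # degenerate: e.g. all-in-one vs all-in-one
  (sum_ij - expected) / (max_index - expected)
}

#' Silhouette-based scan over candidate k (guidance only)
#'
#' Computes the mean silhouette width of the hierarchical-clustering cut for
#' each candidate k. The number of subtypes remains an explicit user choice;
#' this scan only offers a diagnostic.
#'
#' @param ecv samples x edges matrix
#' @param ks candidate cluster counts
#' @param ... passed to [cluster_patients()]
#' @return data.frame(k, mean_silhouette)
#' @export
silhouette_scan <- function(ecv, ks = 2:6, ...) {
  D <- as.matrix(stats::dist(ecv[order(rownames(ecv)),
                                 order(colnames(ecv)), drop = FALSE]))
  res <- vapply(ks, function(k) {
    lab <- cluster_patients(ecv, k = k, ...)$labels[rownames(D)]
    mean(vapply(seq_along(lab), function(i) {
      own <- lab[i]
      a <- if (sum(lab == own) > 1L) mean(D[i, lab == own & seq_along(lab) != i])
           else return(0)
      b <- min(vapply(setdiff(unique(lab), own), function(g)
        mean(D[i, lab == g]), numeric(1)))
      (b - a) / max(a, b)
    }, numeric(1)))
  }, numeric(1))
  data.frame(k = ks, mean_silhouette = res)
}

#' Expression-based comparison clustering (top-variance genes)
#'
#' Mirrors the network-free baseline: select the `n_genes` genes with the
#' highest expression variance across samples and cluster patients on them
#' with the same settings as [cluster_patients()]. When `n_genes` is NULL it
#' defaults to the number of distinct genes spanned by `edge_ids` (so the two
#' clusterings use comparably sized feature sets).
#'
#' @param X expression matrix (genes x samples)
#' @param n_genes number of top-variance genes, or NULL to derive from
#'   `edge_ids`
#' @param edge_ids optional edge id vector used to derive `n_genes`
#' @param ... passed to [cluster_patients()]
#' @return `subtype_assignment`
#' @export
cluster_on_expression <- function(X, n_genes = NULL, edge_ids = NULL, ...) {
  X <- expression_matrix(X)
  if (is.null(n_genes)) {
    if (is.null(edge_ids)) stop("give n_genes or edge_ids")
    pc <- split_edge_id(edge_ids)
    n_genes <- length(unique(c(pc$parent, pc$child)))
  }
  v <- apply(X, 1, stats::var)
  keep <- rownames(X)[order(-v, rownames(X))][seq_len(min(n_genes, nrow(X)))]
  cluster_patients(t(X[keep, , drop = FALSE]), ...)
}
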