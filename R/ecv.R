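## Edge Contribution values.
##
## For an edge parent -> child of a fitted network, the ECv of sample i is
## the value of the fitted smooth component m_k at that sample's parent
## expression: the contribution of the edge to the child's fitted value.
## Collecting ECvs over all edges gives each patient a "quantified network"
## vector; patients whose regulatory systems use an edge differently get
## different ECvs even when marginal expression looks alike.

#' Compute the patients x edges ECv matrix
#'
#' For every edge `parent -> child` of the fitted network and every sample in
#' `X`, evaluates the fitted component of that edge at the sample's parent
#' expression. Samples need not be the training samples; out-of-range parent
#' values are clamped to the training range. Because every component is
#' centered to zero mean over the training samples, training-set ECv columns
#' average to zero, and `intercept + sum of incoming ECvs` reproduces the
#' fitted child value exactly.
#'
#' @param fit `bn_fit` (from [estimate_network()], [score_network()] or
#'   [read_network_json()])
#' @param X expression matrix (genes x samples); must contain every parent
#'   gene of the network
#' @return numeric matrix, rows = samples of `X`, columns = edge ids
#'   `"parent->child"` in the network's edge order
#' @export
compute_ecv <- function(fit, X) {
  stopifnot(inherits(fit, "bn_fit"))
  X <- expression_matrix(X)
  ed <- fit$structure$edges
  need <- unique(c(ed$parent, ed$child))
  miss <- setdiff(need, rownames(X))
  if (length(miss)) stop("gene(s) in the network but absent from X: ",
                         paste(miss, collapse = ", "))
  samples <- colnames(X)
  out <- matrix(NA_real_, nrow = length(samples), ncol = nrow(ed),
                dimnames = list(samples, if (nrow(ed))
                  edge_id(ed$parent, ed$child) else NULL))
  for (v in seq_len(nrow(ed))) {
    m <- fit$models[[ed$child[v]]]
    out[, v] <- eval_component(m, ed$parent[v], X[ed$parent[v], ])
  }
  out
}

#' Multi-group delta-ECv statistic
#'
#' For each group r and each edge, the absolute difference between the mean
#' ECv within the group and the mean ECv over all samples of all *other*
#' groups pooled. With two groups the statistic is symmetric (both groups get
#' |mean1 - mean2|); with more groups it contrasts each group against the
#' pooled rest.
#'
#' @param ecv samples x edges ECv matrix
#' @param groups named vector (names = sample ids, values = group labels)
#'   with at least two non-empty groups; every named sample must be a row of
#'   `ecv`
#' @return object of class `delta_ecv_table`: `values` (groups x edges
#'   matrix of the statistic), plus empty `top_sets`/`exclusive_sets` filled
#'   by [extract_subtype_specific_edges()]
#' @export
delta_ecv <- function(ecv, groups) {
  groups <- validate_groups(groups, rownames(ecv))
  labs <- sort(unique(groups))
  if (length(labs) < 2L) stop("need at least two groups")
  sums <- rowsum(ecv[names(groups), , drop = FALSE], groups[names(groups)])
  cnt <- as.numeric(table(groups)[rownames(sums)])
  means <- sums / cnt
  if (length(labs) == 2L) {
    # both groups get |mean1 - mean2|, bit-identical by construction
    d <- abs(means[1, , drop = FALSE] - means[2, , drop = FALSE])
    vals <- rbind(d, d)
  } else {
    tot <- colSums(sums); ntot <- sum(cnt)
    vals <- abs(means - sweep(-sums, 2, tot, `+`) / (ntot - cnt))
  }
  rownames(vals) <- rownames(sums)
  structure(list(values = vals[labs, , drop = FALSE],
                 top_sets = NULL, exclusive_sets = NULL,
                 top_fraction = NULL),
            class = "delta_ecv_table")
}

validate_groups <- function(groups, sample_ids) {
  if (is.null(names(groups))) stop("groups must be named by sample id")
  groups <- groups[!is.na(groups)]
  miss <- setdiff(names(groups), sample_ids)
  if (length(miss)) stop("grouped sample(s) absent from the ECv matrix: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  g <- as.character(groups)
  names(g) <- names(groups)
  if (any(!nzchar(g))) stop("empty group label")
  if (min(table(g)) < 1L) stop("a group has zero samples")
  g
}

#' @export
print.delta_ecv_table <- function(x, ...) {
  cat("delta_ecv_table:", nrow(x$values), "groups x", ncol(x$values), "edges")
  if (!is.null(x$top_sets)) {
    cat("; top", length(x$top_sets[[1]]), "edges/group,",
        "exclusive sizes:", paste(lengths(x$exclusive_sets), collapse = "/"))
  }
  cat("\n")
  invisible(x)
}

#' Select subtype-specific edges (top fraction + Venn exclusion)
#'
#' Per group, takes the `ceiling(top_fraction * E)` edges with the largest
#' delta-ECv (E = total edges in the table; ties broken by ascending edge
#' id). An edge is *subtype-specific* for a group when it is in that group's
#' top set and in no other group's top set, mirroring the exclusive regions
#' of a Venn diagram over the groups' selections.
#'
#' @param table `delta_ecv_table` from [delta_ecv()]
#' @param top_fraction fraction of all edges to select per group (default
#'   0.01, the top 1 percent of edges of the total edges)
#' @return the table with `top_sets` and `exclusive_sets` filled
#' @export
extract_subtype_specific_edges <- function(table, top_fraction = 0.01) {
  stopifnot(inherits(table, "delta_ecv_table"),
            top_fraction > 0, top_fraction <= 1)
  E <- ncol(table$values)
  n_top <- min(E, ceiling(top_fraction * E))
  ids <- colnames(table$values)
  top_sets <- lapply(rownames(table$values), function(g) {
    v <- table$values[g, ]
    ids[order(-v, ids)][seq_len(n_top)]
  })
  names(top_sets) <- rownames(table$values)
  counts <- table(unlist(top_sets, use.names = FALSE))
  shared <- names(counts)[counts > 1L]
  table$exclusive_sets <- lapply(top_sets, function(s) setdiff(s, shared))
  table$top_sets <- top_sets
  table$top_fraction <- top_fraction
  table
}

#' Write a delta-ECv table (long format TSV)
#'
#' Columns: edge, group, delta_ecv, selected (in the group's top set),
#' exclusive (subtype-specific for the group).
#'
#' @param table `delta_ecv_table` (selection filled or not)
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_delta_ecv <- function(table, path) {
  stopifnot(inherits(table, "delta_ecv_table"))
  long <- do.call(rbind, lapply(rownames(table$values), function(g) {
    data.frame(edge = colnames(table$values), group = g,
               delta_ecv = table$values[g, ],
               selected = if (!is.null(table$top_sets))
                 colnames(table$values) %in% table$top_sets[[g]] else NA,
               exclusive = if (!is.null(table$exclusive_sets))
                 colnames(table$values) %in% table$exclusive_sets[[g]] else NA,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subnetwork induced by an edge set
#'
#' Returns the subgraph of the network on the given edges; optionally only
#' its largest weakly connected component. Node out-degrees within the
#' subnetwork are attached (attribute `out_degree`) for hub identification.
#'
#' @param g `bn_structure` or `bn_fit`
#' @param edge_ids character vector of `"parent->child"` ids, all present in
#'   the network
#' @param largest_component if TRUE, keep only the largest weakly connected
#'   component (ties broken by smallest member node id)
#' @return `bn_structure` with attribute `out_degree` (named integer vector)
#' @export
induced_subnetwork <- function(g, edge_ids, largest_component = FALSE) {
  if (inherits(g, "bn_fit")) g <- g$structure
  stopifnot(inherits(g, "bn_structure"))
  all_ids <- if (nrow(g$edges)) edge_id(g$edges$parent, g$edges$child) else character(0)
  miss <- setdiff(edge_ids, all_ids)
  if (length(miss)) stop("edge(s) not in the network: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  ed <- g$edges[all_ids %in% edge_ids, , drop = FALSE]
  sub <- network_structure(if (nrow(ed)) ed else NULL)
  if (largest_component && length(sub$nodes)) {
    ig <- igraph::graph_from_data_frame(sub$edges, directed = TRUE,
                                        vertices = sub$nodes)
    comp <- igraph::components(ig, mode = "weak")
    sizes <- comp$csize
    cands <- which(sizes == max(sizes))
    firsts <- vapply(cands, function(cc)
      min(igraph::V(ig)$name[comp$membership == cc]), character(1))
    pick <- cands[order(firsts)[1]]
    keep <- igraph::V(ig)$name[comp$membership == pick]
    ed2 <- sub$edges[sub$edges$parent %in% keep & sub$edges$child %in% keep, ,
                     drop = FALSE]
    sub <- network_structure(if (nrow(ed2)) ed2 else NULL, nodes = keep)
  }
  od <- stats::setNames(integer(length(sub$nodes)), sub$nodes)
  if (nrow(sub$edges)) {
    tb <- table(sub$edges$parent)
    od[names(tb)] <- as.integer(tb)
  }
  attr(sub, "out_degree") <- od
  sub
}
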