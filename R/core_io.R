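#' @keywords internal
"_PACKAGE"

## Domain containers are deliberately light-weight:
##  - expression data: base numeric matrix, rows = genes, cols = samples
##  - network structure: S3 "bn_structure" (node vector + parent/child edge table)
##  - clinical data: data.frame(sample_id, time, event[, group])
## All modules address rows/columns by id, never by position.

#' Construct and validate an expression matrix
#'
#' Expression data are stored as a base numeric matrix with genes as rows and
#' samples as columns (the usual convention for TCGA-style log-normalized
#' RNA-seq tables). Values must be finite; ids must be unique and non-empty.
#'
#' @param values numeric matrix (genes x samples)
#' @param gene_ids character vector of row ids (defaults to `rownames(values)`)
#' @param sample_ids character vector of column ids (defaults to `colnames(values)`)
#' @return a validated numeric matrix with dimnames set
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene_ids and sample_ids are required")
  }
  if (length(gene_ids) != nrow(values)) stop("gene_ids length != nrow(values)")
  if (length(sample_ids) != ncol(values)) stop("sample_ids length != ncol(values)")
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) stop("duplicated gene id(s): ", paste(dup, collapse = ", "))
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup)) stop("duplicated sample id(s): ", paste(dup, collapse = ", "))
  if (anyNA(values) || !all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 gene_ids[bad[1]], sample_ids[bad[2]]))
  }
  dimnames(values) <- list(as.character(gene_ids), as.character(sample_ids))
  values
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-delimited file whose header row holds sample ids and whose
#' first column holds gene ids; the body must be numeric. Row and column
#' order are preserved.
#'
#' @param path file path
#' @return numeric matrix, genes x samples
#' @export
read_expression <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("expression file needs a header and >= 1 gene row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  widths <- vapply(fields[-1L], length, integer(1))
  # header may or may not carry a corner label for the id column
  ncol_body <- if (length(header) %in% widths) length(header) else length(header) + 1L
  if (any(widths != ncol_body)) {
    bad <- which(widths != ncol_body)[1]
    stop("ragged expression file: row ", bad + 1L, " has ", widths[bad],
         " fields, expected ", ncol_body)
  }
  sample_ids <- if (length(header) == ncol_body) header[-1L] else header
  gene_ids <- vapply(fields[-1L], `[[`, character(1), 1L)
  body <- vapply(fields[-1L], function(f) {
    suppressWarnings(as.numeric(f[-1L]))
  }, numeric(length(sample_ids)))
  body <- if (is.null(dim(body))) matrix(body, nrow = 1L) else t(body)
  if (anyNA(body)) {
    bad <- which(is.na(body), arr.ind = TRUE)[1, ]
    raw <- fields[[bad[1] + 1L]][bad[2] + 1L]
    stop(sprintf("non-numeric cell '%s' at gene row %d ('%s'), sample column %d ('%s')",
                 raw, bad[1], gene_ids[bad[1]], bad[2], sample_ids[bad[2]]))
  }
  expression_matrix(body, gene_ids, sample_ids)
}

#' Write an expression matrix to TSV
#'
#' Full float precision (17 significant digits) so that
#' `read_expression(write_expression(X))` is the identity.
#'
#' @param X expression matrix (genes x samples)
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_expression <- function(X, path) {
  X <- expression_matrix(X)
  header <- paste(c("gene_id", colnames(X)), collapse = "\t")
  body <- vapply(seq_len(nrow(X)), function(i) {
    paste(c(rownames(X)[i], formatC(X[i, ], format = "g", digits = 17)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Construct a directed acyclic network structure
#'
#' @param edges two-column data.frame or matrix (parent, child); may have 0 rows
#' @param nodes optional node id vector; nodes appearing in edges are added
#' @return object of class `bn_structure` with fields `nodes` and `edges`
#' @export
network_structure <- function(edges = NULL, nodes = character(0)) {
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(parent = character(0), child = character(0),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (ncol(edges) < 2L) stop("edges need two columns (parent, child)")
    edges <- data.frame(parent = as.character(edges[[1]]),
                        child = as.character(edges[[2]]),
                        stringsAsFactors = FALSE)
  }
  if (any(edges$parent == edges$child)) {
    stop("self-loop on node '", edges$parent[edges$parent == edges$child][1], "'")
  }
  key <- paste(edges$parent, edges$child, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate edge: ", sub("\r", " -> ", key[duplicated(key)][1]))
  }
  nodes <- unique(c(as.character(nodes), edges$parent, edges$child))
  g <- structure(list(nodes = nodes, edges = edges), class = "bn_structure")
  cyc <- find_cycle(g)
  if (!is.null(cyc)) {
    stop("network contains a cycle: ", paste(cyc, collapse = " -> "))
  }
  g
}

# returns one cycle as a node vector (closed walk) or NULL if acyclic
find_cycle <- function(g) {
  if (nrow(g$edges) == 0L) return(NULL)
  ig <- igraph::graph_from_data_frame(g$edges, directed = TRUE,
                                      vertices = g$nodes)
  if (igraph::is_dag(ig)) return(NULL)
  comp <- igraph::components(ig, mode = "strong")
  cm <- which(comp$membership == which(comp$csize >= 2)[1])
  sub <- igraph::induced_subgraph(ig, cm)
  v1 <- igraph::V(sub)[1]
  nb <- igraph::neighbors(sub, v1, mode = "out")[1]
  pth <- igraph::shortest_paths(sub, from = nb, to = v1, mode = "out")$vpath[[1]]
  c(igraph::V(sub)$name[v1], igraph::V(sub)$name[pth])
}

#' @export
print.bn_structure <- function(x, ...) {
  cat("bn_structure:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Canonical edge id strings
#'
#' Edges are addressed everywhere (ECv matrix columns, delta tables, SIF
#' export) by the canonical string `"parent->child"`.
#'
#' @param parent,child character vectors of equal length
#' @return character vector of edge ids
#' @export
edge_id <- function(parent, child) {
  if (any(parent == child)) stop("edge parent must differ from child")
  paste0(parent, "->", child)
}

#' Split canonical edge ids back into (parent, child)
#' @param ids character vector of `"parent->child"` strings
#' @return data.frame with columns parent, child
#' @export
split_edge_id <- function(ids) {
  parts <- strsplit(ids, "->", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad)) stop("malformed edge id: ", ids[bad][1])
  data.frame(parent = vapply(parts, `[[`, character(1), 1L),
             child = vapply(parts, `[[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Read a network from a two-column edge-list TSV
#'
#' Lines are `parent<TAB>child`; a header line is detected (and skipped) when
#' its cells are literally `parent`/`child`. Cycles and self-loops are errors.
#'
#' @param path file path
#' @param nodes optional extra node ids (isolated nodes)
#' @return `bn_structure`
#' @export
read_edges <- function(path, nodes = character(0)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(network_structure(nodes = nodes))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (identical(tolower(fields[[1]][1:2]), c("parent", "child"))) {
    fields <- fields[-1L]
  }
  if (any(vapply(fields, length, integer(1)) < 2L)) {
    stop("edge list rows need at least two tab-separated columns")
  }
  network_structure(data.frame(parent = vapply(fields, `[[`, character(1), 1L),
                               child = vapply(fields, `[[`, character(1), 2L)),
                    nodes = nodes)
}

#' Write a network as a Cytoscape SIF file
#'
#' One line per edge, `parent<TAB>pd<TAB>child` ("pd" = protein->DNA, the
#' conventional interaction type for directed regulatory edges).
#'
#' @param g `bn_structure`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_sif <- function(g, path) {
  stopifnot(inherits(g, "bn_structure"))
  writeLines(paste(g$edges$parent, "pd", g$edges$child, sep = "\t"), path)
  invisible(path)
}

#' Read a clinical (survival) table from TSV
#'
#' Requires a header with columns `sample_id`, `time`, `event`; an optional
#' `group` column is carried along. `time` is in days and must be
#' non-negative; `event` is 1 for an observed death, 0 for censoring.
#'
#' @param path file path
#' @return data.frame(sample_id, time, event[, group]), row order preserved
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical file missing column(s): ",
                         paste(miss, collapse = ", "))
  out <- data.frame(sample_id = as.character(df$sample_id),
                    time = as.numeric(df$time),
                    event = as.numeric(df$event),
                    stringsAsFactors = FALSE)
  if ("group" %in% names(df)) out$group <- as.character(df$group)
  validate_clinical(out)
}

validate_clinical <- function(df) {
  if (anyNA(df$time) || any(df$time < 0)) {
    stop("survival time must be a non-negative number (row ",
         which(is.na(df$time) | df$time < 0)[1], ")")
  }
  if (anyNA(df$event) || !all(df$event %in% c(0, 1))) {
    stop("event indicator must be 0 or 1 (row ",
         which(is.na(df$event) | !(df$event %in% c(0, 1)))[1], ")")
  }
  df
}

#' Write a samples x edges ECv matrix to TSV
#' @param ecv numeric matrix, rows = samples, columns = `"parent->child"` ids
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_ecv <- function(ecv, path) {
  header <- paste(c("sample_id", colnames(ecv)), collapse = "\t")
  body <- vapply(seq_len(nrow(ecv)), function(i) {
    paste(c(rownames(ecv)[i], formatC(ecv[i, ], format = "g", digits = 17)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ECv matrix written by [write_ecv()]
#' @param path file path
#' @return numeric matrix, rows = samples, columns = edge ids
#' @export
read_ecv <- function(path) {
  read_expression(path)  # same physical layout: row ids x column ids
}
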