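## End-to-end workflow: estimate (or load) the basal network, quantify each
## patient as ECvs, select high-variance edges, cluster into subtypes,
## extract subtype-specific edges, and (when clinical data are given) compare
## survival across subtypes. Every output and every parameter is recorded in
## a JSON run manifest so a run can be reproduced byte-for-byte.

#' Pipeline configuration
#'
#' @param n_edges number of top-variance edges used for clustering (default
#'   250)
#' @param k number of subtypes (default 3)
#' @param top_fraction fraction of total edges per group for the
#'   subtype-specific edge selection (default 0.01, the top 1 percent of edges)
#' @param linkage,distance,scale_columns clustering settings, see
#'   [cluster_patients()]
#' @param score_cfg `score_config`
#' @param search_cfg `search_config`
#' @param seed integer seed for the structure search
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(n_edges = 250L, k = 3L, top_fraction = 0.01,
                            linkage = "ward", distance = "euclidean",
                            scale_columns = FALSE,
                            score_cfg = score_config(),
                            search_cfg = search_config(), seed = 1L) {
  search_cfg$seed <- as.integer(seed)
  structure(list(n_edges = as.integer(n_edges), k = as.integer(k),
                 top_fraction = top_fraction, linkage = linkage,
                 distance = distance, scale_columns = scale_columns,
                 score_cfg = score_cfg, search_cfg = search_cfg,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full subtyping workflow
#'
#' Stages: (1) estimate the basal network from `X`, or use `network` if
#' supplied; (2) compute the ECv matrix; (3) rank edges by ECv variance and
#' keep the top `n_edges`; (4) hierarchically cluster patients into `k`
#' subtypes; (5) compute per-subtype delta-ECv and extract subtype-specific
#' edges; (6) if `clinical` is given, run the multi-group and pairwise
#' log-rank tests. When `out_dir` is given, all tables (assignment, ECv,
#' delta-ECv, subtype subnetwork SIFs, survival results, model JSON) and a
#' manifest are written there; on a stage failure the partially written
#' output directory content from this run is removed.
#'
#' @param X expression matrix (genes x samples)
#' @param config `pipeline_config`
#' @param network optional pre-estimated `bn_fit` (skips estimation)
#' @param clinical optional data.frame(sample_id, time, event)
#' @param out_dir optional output directory
#' @return list: network, ecv, selection, reduced, assignment, delta,
#'   subnetworks, survival (NULL without clinical), manifest
#' @export
run_pipeline <- function(X, config = pipeline_config(), network = NULL,
                         clinical = NULL, out_dir = NULL) {
  X <- expression_matrix(X)
  t0 <- Sys.time()
  stage <- "estimate"
  written <- character(0)
  res <- tryCatch({
    fit <- if (is.null(network)) {
      estimate_network(X, config$score_cfg, config$search_cfg)
    } else network
    stage <- "ecv"
    ecv <- compute_ecv(fit, X)
    if (ncol(ecv) == 0L) stop("estimated network has no edges; nothing to cluster")
    stage <- "select"
    sel <- rank_edges_by_variance(ecv)
    reduced <- select_top_edges(sel, ecv, config$n_edges)
    stage <- "cluster"
    assignment <- cluster_patients(reduced, k = config$k,
                                   linkage = config$linkage,
                                   distance = config$distance,
                                   scale_columns = config$scale_columns)
    stage <- "delta_ecv"
    groups <- stats::setNames(as.character(assignment$labels),
                              names(assignment$labels))
    delta <- delta_ecv(ecv, groups)
    delta <- extract_subtype_specific_edges(delta, config$top_fraction)
    subnets <- lapply(delta$exclusive_sets, function(es)
      induced_subnetwork(fit, es))
    stage <- "survival"
    surv <- NULL
    if (!is.null(clinical)) {
      surv <- list(overall = logrank_test(clinical, assignment),
                   pairwise = pairwise_logrank(clinical, assignment))
    }
    stage <- "write"
    manifest <- list(
      package = "ecvnet",
      version = as.character(utils::packageVersion("ecvnet")),
      timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
      seed = config$seed,
      n_genes = nrow(X), n_samples = ncol(X),
      n_edges_network = nrow(fit$structure$edges),
      network_score = fit$score,
      params = list(n_edges = config$n_edges, k = config$k,
                    top_fraction = config$top_fraction,
                    linkage = config$linkage, distance = config$distance,
                    scale_columns = config$scale_columns,
                    max_parents = config$search_cfg$max_parents,
                    restarts = config$search_cfg$restarts,
                    n_basis = config$score_cfg$n_basis,
                    degree = config$score_cfg$degree),
      input_checksum = input_checksum(X),
      subtype_sizes = as.integer(table(assignment$labels)))
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      pth <- function(f) file.path(out_dir, f)
      written <<- c(written, pth("assignment.tsv"))
      write_assignment(assignment, pth("assignment.tsv"),
                       newick_path = pth("dendrogram.nwk"))
      written <<- c(written, pth("dendrogram.nwk"), pth("ecv.tsv"),
                    pth("delta_ecv.tsv"), pth("network.sif"),
                    pth("model.json"), pth("manifest.json"))
      write_ecv(ecv, pth("ecv.tsv"))
      write_delta_ecv(delta, pth("delta_ecv.tsv"))
      write_sif(fit$structure, pth("network.sif"))
      write_network_json(fit, pth("model.json"))
      for (gl in names(subnets)) {
        f <- pth(sprintf("subnetwork_subtype%s.sif", gl))
        written <<- c(written, f)
        write_sif(subnets[[gl]], f)
      }
      if (!is.null(surv)) {
        f <- pth("survival.tsv")
        written <<- c(written, f)
        sv <- rbind(
          data.frame(group1 = "all", group2 = "all",
                     statistic = surv$overall$statistic,
                     p_value = surv$overall$p_value),
          surv$pairwise)
        utils::write.table(sv, f, sep = "\t", quote = FALSE, row.names = FALSE)
      }
      jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    }
    list(network = fit, ecv = ecv, selection = sel, reduced = reduced,
         assignment = assignment, delta = delta, subnetworks = subnets,
         survival = surv, manifest = manifest)
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  res
}

# order-insensitive checksum of the input values + ids (no digest dependency:
# fold a numeric hash)
input_checksum <- function(X) {
  v <- c(as.numeric(X), as.numeric(utf8ToInt(paste(rownames(X), collapse = ""))),
         as.numeric(utf8ToInt(paste(colnames(X), collapse = ""))))
  sprintf("%.0f", sum(v * seq_along(v)) %% 2^31)
}
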