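## Structure search over DAG space. The score is decomposable (sum of family
## scores + log structure prior), so moves are evaluated by re-scoring only
## the families they change, with a per-run cache keyed by
## (child, sorted parent set).
##
## Full-scale gene networks in this problem domain are estimated with
## massively parallel samplers on supercomputers; at desk scale we use greedy
## hill-climbing (best-improvement add/delete/reverse, random restarts) and
## bound its correctness on small instances with an exhaustive enumerator.

#' Search configuration for structure learning
#'
#' @param max_parents maximum number of parents per node (default 3)
#' @param restarts number of random restarts (default 5); restart 1 always
#'   starts from the empty graph, later restarts from random DAGs
#' @param seed integer seed making the search deterministic
#' @param max_candidate_parents optional cap: each child only considers the
#'   strongest candidates by absolute Pearson correlation (NULL = no cap)
#' @return list of class `search_config`
#' @export
search_config <- function(max_parents = 3L, restarts = 5L, seed = 1L,
                          max_candidate_parents = NULL) {
  stopifnot(max_parents >= 0L, restarts >= 1L)
  structure(list(max_parents = as.integer(max_parents),
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 max_candidate_parents = max_candidate_parents),
            class = "search_config")
}

# internal: adjacency as a named list child -> character vector of parents
new_family_cache <- function() new.env(parent = emptyenv(), hash = TRUE)

cached_family <- function(cache, X, child, parents, score_cfg) {
  key <- paste(child, paste(sort(parents), collapse = "|"), sep = "\r")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  pm <- if (length(parents)) t(X[parents, , drop = FALSE]) else NULL
  fit <- fit_local_model(X[child, ], pm, score_cfg, child = child)
  if (!is.finite(fit$score)) {
    stop("non-finite score for family of '", child, "' with parents {",
         paste(parents, collapse = ", "), "}")
  }
  cache[[key]] <- fit
  fit
}

# would adding parent->child create a cycle, given parent lists `pl`?
creates_cycle <- function(pl, parent, child) {
  # cycle iff child is an ancestor of parent: walk up from `parent`
  seen <- character(0)
  frontier <- parent
  while (length(frontier)) {
    if (child %in% frontier) return(TRUE)
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(pl[frontier], use.names = FALSE)), seen)
  }
  FALSE
}

total_score_of <- function(fits, n_edges, score_cfg) {
  sum(vapply(fits, function(f) f$score, numeric(1))) +
    score_cfg$log_prior_edge * n_edges
}

assemble_fit <- function(X, pl, fits, score_cfg, search_cfg = NULL) {
  genes <- rownames(X)
  edges <- do.call(rbind, lapply(genes, function(ch) {
    if (length(pl[[ch]]))
      data.frame(parent = pl[[ch]], child = ch, stringsAsFactors = FALSE)
  }))
  n_edges <- if (is.null(edges)) 0L else nrow(edges)
  structure(list(structure = network_structure(edges, nodes = genes),
                 models = fits[genes],
                 score = total_score_of(fits[genes], n_edges, score_cfg),
                 sample_ids = colnames(X),
                 score_config = score_cfg, search_config = search_cfg),
            class = "bn_fit")
}

#' @export
print.bn_fit <- function(x, ...) {
  cat("bn_fit:", length(x$structure$nodes), "genes,",
      nrow(x$structure$edges), "edges, score =", signif(x$score, 10), "\n")
  invisible(x)
}

# one greedy hill-climb from the given starting parent lists
hill_climb <- function(X, pl, cache, score_cfg, search_cfg) {
  genes <- rownames(X)
  fits <- stats::setNames(lapply(genes, function(ch)
    cached_family(cache, X, ch, pl[[ch]], score_cfg)), genes)
  cand <- candidate_parents(X, search_cfg)
  le <- score_cfg$log_prior_edge
  repeat {
    best_gain <- 1e-9
    best_move <- NULL
    for (ch in genes) {
      cur <- fits[[ch]]$score
      pa <- pl[[ch]]
      # add
      if (length(pa) < search_cfg$max_parents) {
        for (pp in setdiff(cand[[ch]], c(ch, pa))) {
          if (creates_cycle(pl, pp, ch)) next
          gain <- cached_family(cache, X, ch, c(pa, pp), score_cfg)$score -
            cur + le
          if (gain > best_gain) {
            best_gain <- gain; best_move <- list("add", pp, ch)
          }
        }
      }
      # delete
      for (pp in pa) {
        gain <- cached_family(cache, X, ch, setdiff(pa, pp), score_cfg)$score -
          cur - le
        if (gain > best_gain) {
          best_gain <- gain; best_move <- list("delete", pp, ch)
        }
      }
      # reverse pp->ch  =>  ch->pp
      for (pp in pa) {
        if (length(pl[[pp]]) >= search_cfg$max_parents) next
        pl2 <- pl; pl2[[ch]] <- setdiff(pa, pp)
        if (creates_cycle(pl2, ch, pp)) next
        gain <- cached_family(cache, X, ch, setdiff(pa, pp), score_cfg)$score +
          cached_family(cache, X, pp, c(pl[[pp]], ch), score_cfg)$score -
          cur - fits[[pp]]$score
        if (gain > best_gain) {
          best_gain <- gain; best_move <- list("reverse", pp, ch)
        }
      }
    }
    if (is.null(best_move)) {
      # Entry trap escape: an additive family can score worse than empty for
      # every single parent yet far better for a pair (each component alone
      # explains too little to pay the complexity cost). When no single move
      # improves, consider adding the best parent *pair* to one family.
      n_pairs <- 0L
      pair_moves <- list()
      for (ch in genes) {
        if (length(pl[[ch]]) > search_cfg$max_parents - 2L) next
        cur <- fits[[ch]]$score
        cands <- setdiff(cand[[ch]], c(ch, pl[[ch]]))
        ok <- cands[!vapply(cands, function(pp)
          creates_cycle(pl, pp, ch), logical(1))]
        if (length(ok) < 2L) next
        for (i1 in seq_len(length(ok) - 1L)) for (i2 in (i1 + 1L):length(ok)) {
          n_pairs <- n_pairs + 1L
          gain <- cached_family(cache, X, ch,
                                c(pl[[ch]], ok[i1], ok[i2]), score_cfg)$score -
            cur + 2 * le
          if (gain > best_gain) {
            best_gain <- gain
            best_move <- list("addpair", c(ok[i1], ok[i2]), ch)
          }
        }
      }
      # multiplicity guard: the best of ~n_pairs chance-level pairs gains
      # about log(n_pairs) nats, so demand more than that before entering
      if (!is.null(best_move) && best_gain <= log(max(n_pairs, 1L))) {
        best_move <- NULL
      }
      if (is.null(best_move)) break
    }
    type <- best_move[[1]]; pp <- best_move[[2]]; ch <- best_move[[3]]
    if (type == "addpair") {
      pl[[ch]] <- c(pl[[ch]], pp)
      fits[[ch]] <- cached_family(cache, X, ch, pl[[ch]], score_cfg)
      next
    }
    if (type == "add") {
      pl[[ch]] <- c(pl[[ch]], pp)
    } else if (type == "delete") {
      pl[[ch]] <- setdiff(pl[[ch]], pp)
    } else {
      pl[[ch]] <- setdiff(pl[[ch]], pp)
      pl[[pp]] <- c(pl[[pp]], ch)
      fits[[pp]] <- cached_family(cache, X, pp, pl[[pp]], score_cfg)
    }
    fits[[ch]] <- cached_family(cache, X, ch, pl[[ch]], score_cfg)
  }
  list(pl = pl, fits = fits)
}

candidate_parents <- function(X, search_cfg) {
  genes <- rownames(X)
  cap <- search_cfg$max_candidate_parents
  if (is.null(cap) || cap >= length(genes) - 1L) {
    return(stats::setNames(lapply(genes, function(g) setdiff(genes, g)), genes))
  }
  cors <- abs(stats::cor(t(X)))
  diag(cors) <- -Inf
  stats::setNames(lapply(genes, function(g) {
    genes[order(cors[g, ], decreasing = TRUE)[seq_len(cap)]]
  }), genes)
}

random_parent_lists <- function(genes, max_parents) {
  p <- length(genes)
  ord <- sample(genes)
  pl <- stats::setNames(vector("list", p), genes)
  for (j in seq_len(p)) {
    pl[[ord[j]]] <- character(0)
    if (j > 1L && max_parents > 0L) {
      k <- sample.int(min(max_parents, j - 1L) + 1L, 1L) - 1L
      if (k > 0L) pl[[ord[j]]] <- sample(ord[seq_len(j - 1L)], k)
    }
  }
  pl
}

#' Estimate a gene network by score-based greedy search
#'
#' Greedy hill-climbing with best-improvement moves (add / delete / reverse),
#' acyclicity and parent-cap constraints, and random restarts; the
#' best-scoring network over all restarts is returned. Deterministic given
#' `search_cfg$seed`; the result depends on the sample set, not its order.
#'
#' @param X expression matrix (genes x samples)
#' @param score_cfg `score_config`
#' @param search_cfg `search_config`
#' @return object of class `bn_fit`: structure, per-gene local models, total
#'   score, sample ids, configs
#' @export
estimate_network <- function(X, score_cfg = score_config(),
                             search_cfg = search_config()) {
  X <- expression_matrix(X)
  if (nrow(X) < 1L) stop("need at least one gene")
  genes <- rownames(X)
  cache <- new_family_cache()
  best <- NULL
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(search_cfg$seed)
  for (r in seq_len(search_cfg$restarts)) {
    pl0 <- if (r == 1L) {
      stats::setNames(rep(list(character(0)), length(genes)), genes)
    } else {
      random_parent_lists(genes, search_cfg$max_parents)
    }
    res <- hill_climb(X, pl0, cache, score_cfg, search_cfg)
    fit <- assemble_fit(X, res$pl, res$fits, score_cfg, search_cfg)
    if (is.null(best) || fit$score > best$score) best <- fit
  }
  best
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Fit every family of a fixed structure and return the scored network
#'
#' @param X expression matrix (genes x samples)
#' @param g `bn_structure` over (a subset of) the genes of `X`
#' @param score_cfg `score_config`
#' @return `bn_fit`
#' @export
score_network <- function(X, g, score_cfg = score_config()) {
  X <- expression_matrix(X)
  stopifnot(inherits(g, "bn_structure"))
  miss <- setdiff(g$nodes, rownames(X))
  if (length(miss)) stop("network gene(s) absent from X: ",
                         paste(miss, collapse = ", "))
  genes <- rownames(X)
  pl <- stats::setNames(rep(list(character(0)), length(genes)), genes)
  for (i in seq_len(nrow(g$edges))) {
    pl[[g$edges$child[i]]] <- c(pl[[g$edges$child[i]]], g$edges$parent[i])
  }
  cache <- new_family_cache()
  fits <- stats::setNames(lapply(genes, function(ch)
    cached_family(cache, X, ch, pl[[ch]], score_cfg)), genes)
  assemble_fit(X, pl, fits, score_cfg)
}

#' Exhaustive structure search (test oracle, p <= 5)
#'
#' Enumerates every DAG on the labelled genes (subject to the parent cap) by
#' recursive assignment of parent sets with acyclicity pruning, scoring each
#' via the family-score cache. Ties are broken in favour of fewer edges, then
#' the lexicographically smallest edge list. The number of complete DAGs
#' enumerated is attached as attribute `n_dags`.
#'
#' @param X expression matrix, at most 5 genes
#' @param score_cfg `score_config`
#' @param max_parents parent cap (default: no cap beyond p-1)
#' @return `bn_fit` with attribute `n_dags`
#' @export
exhaustive_search <- function(X, score_cfg = score_config(),
                              max_parents = NULL) {
  X <- expression_matrix(X)
  p <- nrow(X)
  if (p > 5L) stop("exhaustive_search is limited to p <= 5 genes (got ", p, ")")
  genes <- rownames(X)
  if (is.null(max_parents)) max_parents <- p - 1L
  cache <- new_family_cache()
  # candidate parent sets per child, ordered: empty set first, then by size
  # and lexicographically -- the enumeration order makes the tie-break
  # (fewest edges, then smallest edge list) fall out of strict inequality
  subsets_of <- function(v) {
    out <- list(character(0))
    for (k in seq_len(min(max_parents, length(v)))) {
      cm <- utils::combn(sort(v), k, simplify = FALSE)
      out <- c(out, cm)
    }
    out
  }
  cand <- lapply(genes, function(g) subsets_of(setdiff(genes, g)))
  fam_score <- function(j, pa) {
    cached_family(cache, X, genes[j], pa, score_cfg)$score +
      score_cfg$log_prior_edge * length(pa)
  }
  best <- list(score = -Inf, pl = NULL, n_edges = Inf, key = "")
  n_dags <- 0L
  pl <- stats::setNames(rep(list(character(0)), p), genes)
  edge_key <- function(pl) {
    es <- sort(unlist(lapply(names(pl), function(ch)
      if (length(pl[[ch]])) paste(pl[[ch]], ch, sep = "->")), use.names = FALSE))
    paste(es, collapse = ";")
  }
  recurse <- function(j, acc) {
    for (pa in cand[[j]]) {
      pl[[j]] <<- pa
      # prune: partial assignment must stay acyclic
      if (length(pa) && has_cycle_partial(pl, j)) next
      s <- acc + fam_score(j, pa)
      if (j == p) {
        n_dags <<- n_dags + 1L
        ne <- sum(lengths(pl))
        better <- s > best$score ||
          (s == best$score && (ne < best$n_edges ||
             (ne == best$n_edges && edge_key(pl) < best$key)))
        if (better) best <<- list(score = s, pl = pl, n_edges = ne,
                                  key = edge_key(pl))
      } else {
        recurse(j + 1L, s)
      }
    }
    pl[[j]] <<- character(0)
  }
  # cycle check restricted to edges among genes 1..j (later genes have no
  # parents assigned yet)
  has_cycle_partial <- function(pl, j) {
    sub <- pl[seq_len(j)]
    creates_cycle_any(sub)
  }
  creates_cycle_any <- function(pl) {
    nodes <- names(pl)
    indeg <- stats::setNames(integer(length(nodes)), nodes)
    for (ch in nodes) {
      pa <- intersect(pl[[ch]], nodes)
      indeg[ch] <- length(pa)
    }
    active <- nodes
    repeat {
      zero <- active[indeg[active] == 0L]
      if (!length(zero)) return(length(active) > 0L)
      for (z in zero) {
        for (ch in active) {
          if (z %in% pl[[ch]]) indeg[ch] <- indeg[ch] - 1L
        }
      }
      active <- setdiff(active, zero)
      if (!length(active)) return(FALSE)
    }
  }
  recurse(1L, 0)
  fits <- stats::setNames(lapply(genes, function(ch)
    cached_family(cache, X, ch, best$pl[[ch]], score_cfg)), genes)
  out <- assemble_fit(X, best$pl, fits, score_cfg)
  attr(out, "n_dags") <- n_dags
  out
}

#' Serialize a fitted network to a JSON model file
#'
#' Stores, per child gene: parents, spline degree, knots, coefficients,
#' intercept, residual variance, smoothness weights, and local score, plus
#' the edge list and total score. [read_network_json()] restores an
#' equivalent `bn_fit` usable for ECv computation and prediction.
#'
#' @param fit `bn_fit`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_network_json <- function(fit, path) {
  stopifnot(inherits(fit, "bn_fit"))
  models <- lapply(fit$models, function(m) {
    list(child = m$child, parents = m$parents, intercept = m$intercept,
         sigma2 = m$sigma2, score = m$score,
         lambda = as.numeric(m$lambda),
         components = lapply(m$parents, function(pp) {
           b <- m$bases[[pp]]
           list(parent = pp, degree = b$degree, knots = b$knots,
                range = b$range, coefficients = m$coefficients[[pp]])
         }))
  })
  obj <- list(format = "ecvnet-model-v1",
              nodes = fit$structure$nodes,
              edges = fit$structure$edges,
              score = fit$score,
              sample_ids = fit$sample_ids,
              models = models)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Restore a fitted network written by [write_network_json()]
#' @param path model JSON file
#' @return `bn_fit`
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  if (!identical(obj$format, "ecvnet-model-v1")) {
    stop("not an ecvnet model file: ", path)
  }
  models <- lapply(obj$models, function(m) {
    comps <- m$components
    if (is.data.frame(comps)) comps <- split(comps, seq_len(nrow(comps)))
    parents <- as.character(unlist(m$parents))
    bases <- list(); coefs <- list()
    for (cmp in comps) {
      pp <- as.character(cmp$parent)
      bases[[pp]] <- structure(list(degree = as.integer(cmp$degree),
                                    knots = as.numeric(unlist(cmp$knots)),
                                    n_basis = length(unlist(cmp$coefficients)),
                                    range = as.numeric(unlist(cmp$range))),
                               class = "spline_basis")
      coefs[[pp]] <- as.numeric(unlist(cmp$coefficients))
    }
    structure(list(child = m$child, parents = parents,
                   intercept = as.numeric(m$intercept),
                   bases = bases[parents], coefficients = coefs[parents],
                   lambda = as.numeric(unlist(m$lambda)),
                   sigma2 = as.numeric(m$sigma2),
                   score = as.numeric(m$score), config = NULL),
              class = "bn_local_model")
  })
  names(models) <- vapply(models, function(m) m$child, character(1))
  edges <- as.data.frame(obj$edges, stringsAsFactors = FALSE)
  structure(list(structure = network_structure(
                   if (nrow(edges)) edges else NULL, nodes = obj$nodes),
                 models = models, score = as.numeric(obj$score),
                 sample_ids = as.character(obj$sample_ids),
                 score_config = NULL, search_config = NULL),
            class = "bn_fit")
}
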