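# Edge contribution values, the multi-group delta statistic, and the
# subtype-specific edge selection.

test_that("ECv reconstructs fitted values and is centered on training data", {
  X <- chain3_data(n = 300, seed = 1)
  fit <- estimate_network(X, fast_score_config(), search_config(seed = 1))
  ecv <- compute_ecv(fit, X)
  expect_identical(rownames(ecv), colnames(X))
  # reconstruction: intercept + incoming ECvs = predict() for every child
  for (gn in rownames(X)) {
    m <- fit$models[[gn]]
    if (!length(m$parents)) next
    cols <- edge_id(m$parents, rep(gn, length(m$parents)))
    recon <- m$intercept + rowSums(ecv[, cols, drop = FALSE])
    pred <- predict(m, t(X[m$parents, , drop = FALSE]))
    expect_lt(max(abs(recon - pred)), 1e-9)
  }
  # centering: training-set column means are 0
  expect_lt(max(abs(colMeans(ecv))), 1e-7)
})

test_that("ECv columns follow network edge order and arity rules", {
  set.seed(2)
  x <- rnorm(100)
  X <- expression_matrix(rbind(A = x, B = x + rnorm(100, 0, 0.1)),
                         c("A", "B"), sprintf("s%03d", 1:100))
  g <- network_structure(data.frame(parent = "A", child = "B"))
  fit <- score_network(X, g, fast_score_config())
  ecv <- compute_ecv(fit, X)
  expect_identical(colnames(ecv), "A->B")
  # identity-like relation: ECv tracks centered parent values closely
  expect_gt(cor(ecv[, 1], x), 0.99)
  # unknown gene in the evaluation matrix
  X2 <- expression_matrix(matrix(rnorm(100), 1, 100,
                                 dimnames = list("A", colnames(X))))
  expect_error(compute_ecv(fit, X2), "B")
})

test_that("intercept-only children contribute no columns", {
  set.seed(3)
  X <- expression_matrix(rbind(a = rnorm(200), b = rnorm(200)),
                         c("a", "b"), sprintf("s%03d", 1:200))
  fit <- score_network(X, network_structure(nodes = c("a", "b")),
                       fast_score_config())
  expect_equal(ncol(compute_ecv(fit, X)), 0L)
})

test_that("delta_ecv reproduces the hand-computed M=3 example exactly", {
  # groups R1 = {1,3}, R2 = {2,4}, R3 = {5,7} on one edge:
  # R1: |2 - (2+4+5+7)/4| = 2.5
  ecv <- matrix(c(1, 3, 2, 4, 5, 7), ncol = 1,
                dimnames = list(paste0("s", 1:6), "A->B"))
  groups <- setNames(c("R1", "R1", "R2", "R2", "R3", "R3"), paste0("s", 1:6))
  tab <- delta_ecv(ecv, groups)
  expect_equal(unname(tab$values["R1", "A->B"]), 2.5)
  expect_equal(unname(tab$values["R2", "A->B"]), abs(3 - (1 + 3 + 5 + 7) / 4))
  expect_equal(unname(tab$values["R3", "A->B"]), abs(6 - (1 + 3 + 2 + 4) / 4))
})

test_that("delta_ecv: M=2 symmetry, translation invariance, loop oracle", {
  naive_delta <- function(ecv, groups) {
    labs <- sort(unique(groups))
    out <- matrix(NA_real_, length(labs), ncol(ecv),
                  dimnames = list(labs, colnames(ecv)))
    for (g in labs) for (e in colnames(ecv)) {
      inn <- names(groups)[groups == g]
      outg <- names(groups)[groups != g]
      out[g, e] <- abs(mean(ecv[inn, e]) - mean(ecv[outg, e]))
    }
    out
  }
  set.seed(4)
  for (rep in 1:100) {
    n <- sample(4:12, 1); E <- sample(1:5, 1)
    M <- sample(2:4, 1)
    if (n < M + 1) next
    ecv <- matrix(rnorm(n * E), n, E,
                  dimnames = list(paste0("s", 1:n), paste0("e", 1:E, "->x")))
    groups <- setNames(c(as.character(1:M),
                         as.character(sample.int(M, n - M, TRUE))),
                       paste0("s", 1:n))
    tab <- delta_ecv(ecv, groups)
    expect_equal(tab$values, naive_delta(ecv, groups), tolerance = 1e-12)
    if (M == 2) expect_equal(tab$values[1, ], tab$values[2, ])
  }
  # adding a constant to an edge's column changes nothing
  ecv <- matrix(rnorm(20), 10, 2,
                dimnames = list(paste0("s", 1:10), c("a->b", "b->c")))
  groups <- setNames(rep(c("g1", "g2"), 5), paste0("s", 1:10))
  t1 <- delta_ecv(ecv, groups)
  ecv2 <- ecv; ecv2[, 1] <- ecv2[, 1] + 7
  expect_equal(delta_ecv(ecv2, groups)$values, t1$values)
  expect_error(delta_ecv(ecv, setNames("g1", "missing")), "absent")
})

test_that("top-fraction selection and Venn exclusion match set arithmetic", {
  # 10 edges, 3 groups with disjoint top-1 edges
  ids <- sprintf("e%02d->x", 1:10)
  vals <- rbind(R1 = c(9, rep(1, 9)),
                R2 = c(1, 9, rep(1, 8)),
                R3 = c(1, 1, 9, rep(1, 7)))
  colnames(vals) <- ids
  tab <- structure(list(values = vals, top_sets = NULL, exclusive_sets = NULL,
                        top_fraction = NULL), class = "delta_ecv_table")
  out <- extract_subtype_specific_edges(tab, top_fraction = 0.1)  # 1 edge each
  expect_identical(out$exclusive_sets$R1, "e01->x")
  expect_identical(out$exclusive_sets$R2, "e02->x")
  expect_identical(out$exclusive_sets$R3, "e03->x")

  # full overlap -> all exclusive sets empty
  vals2 <- rbind(R1 = 10:1, R2 = 10:1)
  colnames(vals2) <- ids
  tab2 <- structure(list(values = vals2), class = "delta_ecv_table")
  out2 <- extract_subtype_specific_edges(tab2, top_fraction = 0.3)
  expect_identical(out2$top_sets$R1, out2$top_sets$R2)
  expect_length(out2$exclusive_sets$R1, 0L)
  expect_length(out2$exclusive_sets$R2, 0L)

  # brute-force oracle on random tables, including the ceiling rule and
  # invariance of exclusive sets under group relabelling
  set.seed(5)
  for (rep in 1:20) {
    E <- sample(5:40, 1); M <- sample(2:4, 1)
    frac <- runif(1, 0.05, 0.5)
    vals <- matrix(abs(rnorm(M * E)), M, E,
                   dimnames = list(paste0("G", 1:M), sprintf("e%03d->x", 1:E)))
    tab <- structure(list(values = vals), class = "delta_ecv_table")
    out <- extract_subtype_specific_edges(tab, frac)
    n_top <- min(E, ceiling(frac * E))
    ids <- colnames(vals)
    ref_top <- lapply(rownames(vals), function(g)
      ids[order(-vals[g, ], ids)][seq_len(n_top)])
    names(ref_top) <- rownames(vals)
    expect_identical(out$top_sets, ref_top)
    for (g in rownames(vals)) {
      others <- unlist(ref_top[setdiff(rownames(vals), g)])
      expect_setequal(out$exclusive_sets[[g]], setdiff(ref_top[[g]], others))
    }
    # pairwise disjoint
    all_ex <- unlist(out$exclusive_sets)
    expect_identical(anyDuplicated(all_ex), 0L)
  }
})

test_that("induced subnetwork, largest component, and out-degrees", {
  g <- network_structure(data.frame(parent = c("A", "B", "D", "B"),
                                    child = c("B", "C", "E", "A2")))
  sub <- induced_subnetwork(g, c("A->B", "B->C", "D->E"))
  expect_equal(nrow(sub$edges), 3L)
  lc <- induced_subnetwork(g, c("A->B", "B->C", "D->E"),
                           largest_component = TRUE)
  expect_setequal(lc$nodes, c("A", "B", "C"))
  g2 <- network_structure(data.frame(parent = c("B", "B"), child = c("A", "C")))
  od <- attr(induced_subnetwork(g2, c("B->A", "B->C")), "out_degree")
  expect_equal(unname(od["B"]), 2L)
  expect_error(induced_subnetwork(g, "Z->Q"), "not in the network")
  empty <- induced_subnetwork(g, character(0))
  expect_equal(nrow(empty$edges), 0L)
})
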