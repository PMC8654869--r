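# Kaplan-Meier estimation and log-rank tests, cross-checked against the
# survival package as an independent oracle.

test_that("KM matches hand-computed product-limit values on a mixed fixture", {
  # records: times 1,2,2,3,4,5 events 1,1,0,1,0,1
  # t=1: 6 at risk, 1 event -> 5/6
  # t=2: 5 at risk, 1 event -> 5/6 * 4/5 = 2/3
  # t=3: 3 at risk, 1 event -> 2/3 * 2/3 = 4/9
  # t=5: 1 at risk, 1 event -> 0
  cv <- km_estimate(km_fixture())
  expect_equal(cv$time, c(1, 2, 3, 5))
  expect_equal(cv$surv, c(5 / 6, 2 / 3, 4 / 9, 0), tolerance = 1e-12)
  expect_equal(cv$n_risk, c(6, 5, 3, 1))

  # oracle: survival::survfit
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = km_fixture())
  expect_equal(cv$surv, sf$surv[sf$n.event > 0], tolerance = 1e-12)
})

test_that("KM degenerate cases: no events, no censoring", {
  allc <- data.frame(sample_id = paste0("s", 1:4), time = 1:4, event = 0)
  cv <- km_estimate(allc)
  expect_equal(nrow(cv), 0L)
  expect_equal(km_survival_at(cv, c(0, 10)), c(1, 1))

  alle <- data.frame(sample_id = paste0("s", 1:4), time = 1:4, event = 1)
  cv2 <- km_estimate(alle)
  expect_equal(cv2$surv, c(0.75, 0.5, 0.25, 0))
  expect_error(km_estimate(allc[0, ]), "empty")
})

test_that("log-rank agrees with survival::survdiff across fixtures", {
  set.seed(1)
  for (rep in 1:20) {
    n <- sample(20:60, 1)
    M <- sample(2:4, 1)
    d <- data.frame(sample_id = paste0("s", 1:n),
                    time = round(rexp(n, 0.01), 1),
                    event = rbinom(n, 1, 0.7))
    groups <- setNames(as.character(c(1:M, sample.int(M, n - M, TRUE))),
                       d$sample_id)
    if (sum(d$event) == 0) next
    res <- logrank_test(d, groups)
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ g,
                              data = cbind(d, g = groups[d$sample_id]))
    expect_equal(res$statistic, sd_$chisq, tolerance = 1e-8)
    expect_equal(res$df, M - 1L)
    expect_equal(unname(res$observed), unname(sd_$obs), tolerance = 1e-9)
    expect_equal(unname(res$expected), unname(sd_$exp), tolerance = 1e-8)
    expect_equal(sum(res$observed), sum(res$expected), tolerance = 1e-9)
  }
})

test_that("identical groups give statistic 0 and two-group p matches a permutation oracle", {
  base <- data.frame(sample_id = paste0("a", 1:8),
                     time = c(1, 3, 5, 7, 9, 11, 13, 15),
                     event = c(1, 1, 0, 1, 1, 0, 1, 1))
  dup <- base; dup$sample_id <- paste0("b", 1:8)
  d <- rbind(base, dup)
  groups <- setNames(rep(c("g1", "g2"), each = 8), d$sample_id)
  res <- logrank_test(d, groups)
  expect_lt(res$statistic, 1e-10)
  expect_equal(res$p_value, 1)

  # permutation oracle on a separated fixture
  d2 <- data.frame(sample_id = paste0("s", 1:12),
                   time = c(1, 2, 3, 4, 5, 6, 10, 11, 12, 13, 14, 15),
                   event = rep(1, 12))
  g2 <- setNames(rep(c("A", "B"), each = 6), d2$sample_id)
  obs <- logrank_test(d2, g2)$statistic
  set.seed(2)
  perm <- replicate(10000, {
    gp <- setNames(sample(g2), d2$sample_id)
    logrank_test(d2, gp)$statistic
  })
  p_perm <- mean(perm >= obs - 1e-12)
  p_chisq <- logrank_test(d2, g2)$p_value
  # agreement within Monte-Carlo error (3 binomial sds + chi-square approx slack)
  mc_sd <- sqrt(p_perm * (1 - p_perm) / 10000)
  expect_lt(abs(p_perm - p_chisq), 3 * mc_sd + 0.005)
})

test_that("log-rank input validation", {
  d <- data.frame(sample_id = paste0("s", 1:4), time = 1:4, event = 1)
  expect_error(logrank_test(d, setNames(rep("g1", 4), d$sample_id)),
               "two groups")
  d0 <- d; d0$event <- 0
  expect_error(logrank_test(d0, setNames(rep(c("a", "b"), 2), d$sample_id)),
               "no events")
})

test_that("pairwise log-rank is self-consistent and adjustable", {
  set.seed(3)
  n <- 60
  d <- data.frame(sample_id = paste0("s", 1:n),
                  time = rexp(n, rep(c(0.02, 0.01, 0.005), each = 20)),
                  event = rbinom(n, 1, 0.8))
  groups <- setNames(rep(c("g1", "g2", "g3"), each = 20), d$sample_id)
  pw <- pairwise_logrank(d, groups)
  expect_equal(nrow(pw), 3L)
  for (i in seq_len(nrow(pw))) {
    sub <- d[groups[d$sample_id] %in% c(pw$group1[i], pw$group2[i]), ]
    ref <- logrank_test(sub, groups[sub$sample_id])
    expect_equal(pw$statistic[i], ref$statistic, tolerance = 1e-12)
    expect_equal(pw$p_value[i], ref$p_value, tolerance = 1e-12)
  }
  pwb <- pairwise_logrank(d, groups, adjust = "bonferroni")
  expect_equal(pwb$p_value, pmin(pw$p_value * 3, 1))
  # 2 groups -> single row identical to the global test
  d2 <- d[1:40, ]; g2 <- groups[d2$sample_id]
  pw2 <- pairwise_logrank(d2, g2)
  expect_equal(nrow(pw2), 1L)
  expect_equal(pw2$statistic, logrank_test(d2, g2)$statistic)
})

test_that("statistic is invariant to label permutation and time rescaling", {
  set.seed(4)
  n <- 45
  d <- data.frame(sample_id = paste0("s", 1:n),
                  time = rexp(n, 0.01), event = rbinom(n, 1, 0.7))
  groups <- setNames(rep(c("x", "y", "z"), each = 15), d$sample_id)
  s0 <- logrank_test(d, groups)$statistic
  relab <- setNames(c(x = "z", y = "x", z = "y")[groups], names(groups))
  expect_equal(logrank_test(d, relab)$statistic, s0, tolerance = 1e-12)
  d2 <- d; d2$time <- d$time * 365.25
  expect_equal(logrank_test(d2, groups)$statistic, s0, tolerance = 1e-12)
})
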