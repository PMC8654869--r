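## Kaplan-Meier estimation and the M-sample log-rank test used to compare
## the prognoses of identified subtypes. Implemented directly (the
## product-limit estimator and the standard hypergeometric log-rank with tie
## correction) so the test suite can cross-check against the survival
## package as an independent oracle.

#' Kaplan-Meier product-limit estimate for one group
#'
#' @param records data.frame(sample_id, time, event) with `event` 1 = death
#'   observed, 0 = right-censored
#' @return data.frame of class `km_curve`: time (distinct event times),
#'   n_risk, n_event, surv (survival probability just after each event time)
#' @export
km_estimate <- function(records) {
  records <- validate_clinical(records)
  if (nrow(records) == 0L) stop("empty group: no records")
  et <- sort(unique(records$time[records$event == 1]))
  if (!length(et)) {
    out <- data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), surv = numeric(0))
    attr(out, "n") <- nrow(records)
    class(out) <- c("km_curve", "data.frame")
    return(out)
  }
  n_risk <- vapply(et, function(t) sum(records$time >= t), numeric(1))
  n_event <- vapply(et, function(t)
    sum(records$time == t & records$event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = et, n_risk = n_risk, n_event = n_event, surv = surv)
  attr(out, "n") <- nrow(records)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a KM curve at arbitrary times
#' @param curve `km_curve`
#' @param times evaluation times
#' @return survival probabilities (1 before the first event)
#' @export
km_survival_at <- function(curve, times) {
  vapply(times, function(t) {
    i <- sum(curve$time <= t)
    if (i == 0L) 1 else curve$surv[i]
  }, numeric(1))
}

# join records with a named group vector; silently drops samples without a
# group and reports how many records lacked clinical/group information
join_groups <- function(records, groups) {
  if (is.null(names(groups))) stop("groups must be named by sample id")
  idx <- match(records$sample_id, names(groups))
  dropped <- sum(is.na(idx))
  if (dropped) message(dropped, " record(s) without a group label dropped")
  out <- records[!is.na(idx), , drop = FALSE]
  out$group <- as.character(groups[idx[!is.na(idx)]])
  out
}

#' M-sample log-rank test
#'
#' At each distinct event time, the observed events in each group are
#' compared with their expectation under the null (proportional to at-risk
#' counts), with the hypergeometric variance correction for tied events. The
#' statistic is referred to a chi-square distribution with M-1 degrees of
#' freedom.
#'
#' @param records data.frame(sample_id, time, event)
#' @param groups named group-label vector (or a `subtype_assignment`);
#'   records without a label are dropped with a message
#' @return list of class `logrank_result`: statistic, df, p_value, and
#'   per-group observed/expected event counts
#' @export
logrank_test <- function(records, groups) {
  if (inherits(groups, "subtype_assignment")) groups <- groups$labels
  records <- validate_clinical(records)
  d <- join_groups(records, groups)
  labs <- sort(unique(d$group))
  M <- length(labs)
  if (M < 2L) stop("need at least two groups with records")
  if (sum(d$event) == 0L) stop("no events observed: log-rank undefined")
  g <- match(d$group, labs)
  et <- sort(unique(d$time[d$event == 1]))
  obs <- exp_ <- stats::setNames(numeric(M), labs)
  V <- matrix(0, M, M)
  for (t in et) {
    at_risk <- d$time >= t
    n_t <- sum(at_risk)
    n_jt <- vapply(seq_len(M), function(j) sum(at_risk & g == j), numeric(1))
    d_t <- sum(d$time == t & d$event == 1)
    d_jt <- vapply(seq_len(M), function(j)
      sum(d$time == t & d$event == 1 & g == j), numeric(1))
    obs <- obs + d_jt
    exp_ <- exp_ + d_t * n_jt / n_t
    if (n_t > 1) {
      # hypergeometric covariance with tie correction
      fac <- d_t * (n_t - d_t) / (n_t - 1)
      V <- V + fac * (diag(n_jt / n_t, M) - tcrossprod(n_jt / n_t))
    }
  }
  z <- (obs - exp_)[-M]
  Vsub <- V[-M, -M, drop = FALSE]
  stat <- tryCatch(drop(t(z) %*% solve(Vsub, z)), error = function(e) {
    drop(t(z) %*% MASS_ginv(Vsub) %*% z)
  })
  stat <- max(stat, 0)
  df <- M - 1L
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 observed = obs, expected = exp_, groups = labs),
            class = "logrank_result")
}

# minimal Moore-Penrose pseudoinverse (avoid a MASS dependency for the rare
# singular-variance case, e.g. a group entirely censored before any event)
MASS_ginv <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * s$d[1]
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank test: chi-square = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Pairwise two-sample log-rank tests
#'
#' One test per unordered group pair, each computed on the records restricted
#' to that pair. P-values are unadjusted by default (the usual reporting for
#' subtype comparisons); `adjust = "bonferroni"` multiplies by the number of
#' pairs (capped at 1).
#'
#' @inheritParams logrank_test
#' @param adjust "none" (default) or "bonferroni"
#' @return data.frame: group1, group2, statistic, p_value
#' @export
pairwise_logrank <- function(records, groups, adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (inherits(groups, "subtype_assignment")) groups <- groups$labels
  records <- validate_clinical(records)
  d <- join_groups(records, groups)
  labs <- sort(unique(d$group))
  if (length(labs) < 2L) stop("need at least two groups with records")
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    sub <- d[d$group %in% pr, , drop = FALSE]
    res <- logrank_test(sub[, c("sample_id", "time", "event")],
                        stats::setNames(sub$group, sub$sample_id))
    data.frame(group1 = pr[1], group2 = pr[2], statistic = res$statistic,
               p_value = res$p_value, stringsAsFactors = FALSE)
  }))
  if (adjust == "bonferroni") {
    out$p_value <- pmin(out$p_value * length(pairs), 1)
  }
  out
}

#' Write KM curves for several groups as a long TSV (for plotting)
#' @param records data.frame(sample_id, time, event)
#' @param groups named group-label vector
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_km_curves <- function(records, groups, path) {
  if (inherits(groups, "subtype_assignment")) groups <- groups$labels
  d <- join_groups(validate_clinical(records), groups)
  long <- do.call(rbind, lapply(sort(unique(d$group)), function(gl) {
    cv <- km_estimate(d[d$group == gl, , drop = FALSE])
    if (!nrow(cv)) return(NULL)
    cbind(group = gl, as.data.frame(cv))
  }))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
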