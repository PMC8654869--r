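## Additive B-spline nonparametric regression for one child gene given its
## parents, and the Laplace-approximated marginal-likelihood score used to
## score Bayesian-network families.
##
## Model:   y_i = mu + sum_k m_k(pa_ik) + eps_i,   eps ~ N(0, sigma2)
## Each m_k is a cubic B-spline expansion; coefficients solve a penalized
## least-squares problem with a second-difference smoothness penalty whose
## weight lambda is chosen by empirical Bayes (maximizing the approximated
## marginal likelihood over a log-spaced grid). Each m_k is re-centered to
## zero training mean, the offset being absorbed into the intercept, so the
## absolute scale of edge contributions is fixed.

#' Score / fit configuration
#'
#' @param n_basis number of B-spline basis functions per parent (default 10)
#' @param degree spline degree (default 3, cubic)
#' @param lambda_grid candidate smoothness weights, all > 0; empirical Bayes
#'   picks the grid point maximizing the approximate marginal likelihood
#' @param ridge extra ridge on the spline coefficients; a proper prior on
#'   the penalty null space (constant + linear directions). The default 1e-3
#'   is deliberately moderate: a near-improper value (say 1e-6) inflates the
#'   per-parent complexity cost so much that genuinely additive families
#'   cannot be entered one parent at a time by a greedy search
#' @param log_prior_edge additive log-prior contribution per edge; 0 gives a
#'   uniform structure prior, negative values penalize dense graphs
#' @return list of class `score_config`
#' @export
score_config <- function(n_basis = 10L, degree = 3L,
                         lambda_grid = 10^seq(-3, 3, length.out = 10),
                         ridge = 1e-3, log_prior_edge = 0) {
  stopifnot(n_basis >= degree + 1L, degree >= 1L,
            all(lambda_grid > 0), ridge > 0)
  structure(list(n_basis = as.integer(n_basis), degree = as.integer(degree),
                 lambda_grid = sort(as.numeric(lambda_grid)),
                 ridge = ridge, log_prior_edge = log_prior_edge),
            class = "score_config")
}

#' Build a B-spline basis for one covariate
#'
#' Interior knots are placed at equally spaced quantiles of the training
#' values; boundary knots are replicated `degree + 1` times so the basis is a
#' partition of unity over the training range. Evaluation outside the range
#' clamps the input to the range boundary (constant extension).
#'
#' @param x training covariate values
#' @param n_basis number of basis functions
#' @param degree spline degree
#' @return list of class `spline_basis`: degree, knots, n_basis, range
#' @export
build_basis <- function(x, n_basis = 10L, degree = 3L) {
  ux <- sort(unique(x))
  if (length(ux) < degree + 2L) {
    stop("need at least degree+2 distinct covariate values (got ",
         length(ux), "); reduce n_basis/degree or check the input")
  }
  n_interior <- n_basis - degree - 1L
  if (n_interior < 0L) stop("n_basis must be at least degree + 1")
  rng <- range(ux)
  interior <- if (n_interior > 0L) {
    qs <- stats::quantile(x, probs = seq_len(n_interior) / (n_interior + 1L),
                          names = FALSE, type = 7)
    # strictly inside the range; collapse of quantiles is tolerated by
    # splineDesign but degrades conditioning, so nudge exact boundary hits
    pmin(pmax(qs, rng[1] + 1e-10 * diff(rng)), rng[2] - 1e-10 * diff(rng))
  } else numeric(0)
  knots <- c(rep(rng[1], degree + 1L), sort(interior), rep(rng[2], degree + 1L))
  structure(list(degree = as.integer(degree), knots = knots,
                 n_basis = as.integer(n_basis), range = rng),
            class = "spline_basis")
}

#' Evaluate all basis functions at given points (with range clamping)
#' @param basis `spline_basis`
#' @param x points of evaluation
#' @return matrix `length(x)` x `n_basis`
#' @export
eval_basis <- function(basis, x) {
  xc <- pmin(pmax(x, basis$range[1]), basis$range[2])
  splines::splineDesign(basis$knots, xc, ord = basis$degree + 1L,
                        outer.ok = FALSE)
}

# second-difference penalty matrix t(D2) %*% D2 for nb coefficients
second_diff_penalty <- function(nb) {
  if (nb < 3L) return(diag(0, nb))
  D <- diff(diag(nb), differences = 2L)
  crossprod(D)
}

# Marginal-likelihood machinery ------------------------------------------
#
# Conditional on lambda, the model is Bayesian ridge regression:
#   ytil | gamma ~ N(Z gamma, sigma2 I),  gamma ~ N(0, sigma2 K(lambda)^-1)
# with K = blockdiag(lambda_k * P_k) + ridge * I. Integrating gamma and
# profiling sigma2 (MLE) gives, up to constants shared across families,
#   log ML = -n/2 log(2 pi sigma2_hat) - n/2
#            - 1/2 [ logdet(Z'Z + K) - logdet(K) ] - 1/2 log(n)
# The last term is the Laplace factor for the flat-prior intercept. The
# empty-parent family keeps only the intercept terms, so scores are
# comparable across parent sets (decomposable network score).
evidence_given_lambda <- function(ZtZ, Zty, yty, n, K) {
  R <- tryCatch(chol(ZtZ + K), error = function(e) NULL)
  if (is.null(R)) return(list(score = -Inf))
  gamma <- backsolve(R, forwardsolve(t(R), Zty))
  quad <- yty - sum(Zty * gamma)           # = RSS + gamma' K gamma
  quad <- max(quad, 1e-12 * max(yty, 1))
  sigma2 <- quad / n
  logdet_post <- 2 * sum(log(diag(R)))
  logdet_K <- determinant(K, logarithm = TRUE)$modulus[1]
  score <- -n / 2 * log(2 * pi * sigma2) - n / 2 -
    0.5 * (logdet_post - logdet_K) - 0.5 * log(n)
  list(score = score, gamma = gamma, sigma2 = sigma2)
}

#' Fit the additive B-spline local model of one child gene
#'
#' @param y child expression over n samples
#' @param parents numeric matrix n x q of parent expression values (columns
#'   named by parent gene id), or NULL/0-column for an orphan gene
#' @param config `score_config`
#' @param child id of the child gene (metadata only)
#' @return list of class `bn_local_model`: child, parents, intercept, bases,
#'   coefficients, lambda, sigma2, score
#' @export
fit_local_model <- function(y, parents = NULL, config = score_config(),
                            child = NA_character_) {
  n <- length(y)
  if (is.null(parents)) parents <- matrix(numeric(0), nrow = n, ncol = 0)
  parents <- as.matrix(parents)
  q <- ncol(parents)
  if (q > 0 && nrow(parents) != n) stop("parents must have one row per sample")
  mu <- mean(y)
  ytil <- y - mu

  if (q == 0L) {
    sigma2 <- max(sum(ytil^2) / n, 1e-300)
    score <- -n / 2 * log(2 * pi * sigma2) - n / 2 - 0.5 * log(n)
    return(structure(list(child = child, parents = character(0),
                          intercept = mu, bases = list(), coefficients = list(),
                          lambda = numeric(0), sigma2 = sigma2, score = score,
                          config = config),
                     class = "bn_local_model"))
  }

  pnames <- colnames(parents)
  if (is.null(pnames)) pnames <- paste0("parent", seq_len(q))
  bases <- lapply(seq_len(q), function(k)
    build_basis(parents[, k], config$n_basis, config$degree))
  Zs <- lapply(seq_len(q), function(k) eval_basis(bases[[k]], parents[, k]))
  Z <- do.call(cbind, Zs)
  nb <- vapply(bases, function(b) b$n_basis, integer(1))
  if (n <= sum(nb)) {
    stop("need more samples (", n, ") than total basis dimension (", sum(nb), ")")
  }
  ZtZ <- crossprod(Z)
  Zty <- crossprod(Z, ytil)
  yty <- sum(ytil^2)
  Pk <- lapply(nb, second_diff_penalty)
  make_K <- function(lams) {
    K <- matrix(0, sum(nb), sum(nb))
    off <- 0L
    for (k in seq_len(q)) {
      idx <- off + seq_len(nb[k])
      K[idx, idx] <- lams[k] * Pk[[k]]
      off <- off + nb[k]
    }
    K + config$ridge * diag(sum(nb))
  }

  # empirical Bayes: one shared lambda over the grid (fast path), then one
  # coordinate-ascent sweep per parent to allow per-parent smoothness
  best <- list(score = -Inf)
  best_l <- rep(config$lambda_grid[1], q)
  for (l in config$lambda_grid) {
    fit <- evidence_given_lambda(ZtZ, Zty, yty, n, make_K(rep(l, q)))
    if (fit$score > best$score) { best <- fit; best_l <- rep(l, q) }
  }
  if (q > 1L) {
    for (k in seq_len(q)) {
      for (l in config$lambda_grid) {
        lams <- best_l; lams[k] <- l
        fit <- evidence_given_lambda(ZtZ, Zty, yty, n, make_K(lams))
        if (fit$score > best$score) { best <- fit; best_l <- lams }
      }
    }
  }
  if (!is.finite(best$score)) {
    stop("singular penalized normal equations for child '", child,
         "'; try a smaller basis")
  }

  # split coefficients per parent and re-center each component
  coefs <- vector("list", q)
  off <- 0L
  for (k in seq_len(q)) {
    g <- best$gamma[off + seq_len(nb[k])]
    mk <- Zs[[k]] %*% g
    shift <- mean(mk)
    # subtracting a constant from a partition-of-unity expansion is exact:
    # shifting every coefficient by `shift` shifts the curve by `shift`
    coefs[[k]] <- as.numeric(g - shift)
    mu <- mu + shift
    off <- off + nb[k]
  }
  names(coefs) <- pnames
  names(bases) <- pnames

  structure(list(child = child, parents = pnames, intercept = mu,
                 bases = bases, coefficients = coefs,
                 lambda = stats::setNames(best_l, pnames),
                 sigma2 = max(best$sigma2, 1e-300), score = best$score,
                 config = config),
            class = "bn_local_model")
}

#' Evaluate one fitted smooth component m_k at arbitrary parent values
#'
#' This is the Edge Contribution value of the edge `parent -> child` at the
#' given parent expression: the contribution of that edge to the child's
#' fitted expression. Out-of-range inputs are clamped to the training range.
#'
#' @param model `bn_local_model`
#' @param parent parent gene id (must be one of `model$parents`)
#' @param x parent expression value(s)
#' @return numeric vector of contributions
#' @export
eval_component <- function(model, parent, x) {
  k <- match(parent, model$parents)
  if (is.na(k)) stop("'", parent, "' is not a parent of '", model$child, "'")
  drop(eval_basis(model$bases[[k]], x) %*% model$coefficients[[k]])
}

#' Predict the child's expression for new samples
#'
#' Returns `intercept + sum_k m_k(parent_k)`, parent values clamped to the
#' training range of each component.
#'
#' @param object `bn_local_model`
#' @param newdata numeric matrix/data.frame with one column per parent (named
#'   by parent id), or a named vector for a single sample
#' @param ... unused
#' @return numeric vector of fitted values
#' @export
predict.bn_local_model <- function(object, newdata = NULL, ...) {
  q <- length(object$parents)
  if (q == 0L) {
    nout <- if (is.null(newdata)) 1L else NROW(newdata)
    return(rep(object$intercept, nout))
  }
  if (is.null(newdata)) stop("newdata required: model has parents")
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    miss <- setdiff(object$parents, colnames(newdata))
    if (length(miss)) stop("newdata missing parent column(s): ",
                           paste(miss, collapse = ", "))
    newdata <- newdata[, object$parents, drop = FALSE]
  } else if (ncol(newdata) != q) {
    stop("newdata has ", ncol(newdata), " columns; model expects ", q)
  }
  out <- rep(object$intercept, nrow(newdata))
  for (k in seq_len(q)) {
    out <- out + drop(eval_basis(object$bases[[k]], newdata[, k]) %*%
                        object$coefficients[[k]])
  }
  out
}

#' Local Bayesian score of a family (child given a parent set)
#'
#' Deterministic, and decomposable: it depends only on the child's values and
#' its parents' values, so a network score is the sum of family scores.
#'
#' @inheritParams fit_local_model
#' @return scalar log marginal-likelihood score (larger is better)
#' @export
local_score <- function(y, parents = NULL, config = score_config()) {
  fit_local_model(y, parents, config)$score
}

#' @export
print.bn_local_model <- function(x, ...) {
  cat("bn_local_model for '", x$child, "': ", length(x$parents),
      " parent(s)", if (length(x$parents))
        paste0(" [", paste(x$parents, collapse = ", "), "]") else "",
      ", sigma2 = ", signif(x$sigma2, 4),
      ", score = ", signif(x$score, 8), "\n", sep = "")
  invisible(x)
}
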