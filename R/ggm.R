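#' @useDynLib resilnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Pearson correlation matrix of an analysis matrix
#'
#' @param data Numeric matrix or data frame, participants in rows, named
#'   variable columns; requires more rows than columns and no constant
#'   columns.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(data) {
  x <- as.matrix(data)
  if (anyNA(x)) stop("missing values in data", call. = FALSE)
  if (nrow(x) < ncol(x) + 1) {
    stop("need n >= p + 1 rows to estimate correlations", call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("constant column: %s", colnames(x)[sds == 0][1]),
         call. = FALSE)
  }
  stats::cor(x)
}

#' Partial correlations from a correlation (or covariance) matrix
#'
#' Standardizes the negative inverse: with `K = solve(R)`,
#' `P[i,j] = -K[i,j] / sqrt(K[i,i] * K[j,j])` off the diagonal and 0 on it.
#' Each entry is the correlation of two variables conditioning on all others.
#'
#' @param R Positive-definite correlation or covariance matrix.
#' @return Symmetric partial-correlation matrix with zero diagonal.
#' @export
partials_from_correlation <- function(R) {
  R <- as.matrix(R)
  stopifnot(nrow(R) == ncol(R))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf("matrix is not positive definite (min eigenvalue %.3g)",
                 min(ev)), call. = FALSE)
  }
  K <- solve(R)
  d <- 1 / sqrt(diag(K))
  P <- -K * tcrossprod(d)
  diag(P) <- 0
  P <- (P + t(P)) / 2
  dimnames(P) <- dimnames(R)
  P
}

#' Gaussian log-likelihood of a precision matrix
#'
#' Profile multivariate-normal log-likelihood at sample covariance `S`:
#' `(n/2) * (log det K - tr(S K) - p * log(2*pi))`.
#' @keywords internal
gaussian_loglik <- function(K, S, n) {
  p <- nrow(S)
  ld <- determinant(K, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  (n / 2) * (as.numeric(ld$modulus) - sum(S * K) - p * log(2 * pi))
}

#' Constrained maximum-likelihood GGM fit for a fixed edge structure
#'
#' Fits the Gaussian model whose precision matrix is zero wherever `mask` has
#' no edge, by cyclic regression updates of the implied covariance. At
#' convergence the implied covariance equals `S` on the diagonal and on every
#' masked edge, the classical covariance-selection ML conditions.
#'
#' @param S Positive-definite covariance or correlation matrix.
#' @param mask Symmetric logical matrix with `FALSE` diagonal: `TRUE` where
#'   an edge (free off-diagonal precision element) is allowed.
#' @param n Sample size, used for the log-likelihood.
#' @param tol Convergence tolerance on the maximum absolute change of the
#'   implied covariance per sweep; default 1e-8.
#' @param max_iter Sweep cap; default 10000.
#' @return List with `precision`, `partials` (fitted partial correlations,
#'   exactly zero off the mask), `implied_cov`, `loglik`, `iterations`,
#'   `converged`.
#' @export
fit_constrained_ggm <- function(S, mask, n, tol = 1e-8, max_iter = 10000) {
  S <- as.matrix(S)
  p <- nrow(S)
  mask <- as.matrix(mask)
  stopifnot(nrow(mask) == p, ncol(mask) == p)
  if (!isTRUE(all.equal(mask, t(mask))) || any(diag(mask) != 0)) {
    stop("mask must be symmetric with a FALSE diagonal", call. = FALSE)
  }
  fit <- .ips_fit_cpp(S, matrix(as.integer(mask != 0), p, p), tol, max_iter)
  if (!fit$converged) {
    stop(sprintf("constrained fit did not converge in %d sweeps (tol %g)",
                 max_iter, tol), call. = FALSE)
  }
  K <- fit$precision
  dimnames(K) <- dimnames(S)
  d <- 1 / sqrt(diag(K))
  P <- -K * tcrossprod(d)
  diag(P) <- 0
  P[mask == 0] <- 0   # exact zeros off-structure
  P <- (P + t(P)) / 2
  list(precision = K, partials = P, implied_cov = fit$implied_cov,
       loglik = gaussian_loglik(K, S, n), iterations = fit$iterations,
       converged = fit$converged)
}

#' Extended Bayesian information criterion for a GGM
#'
#' `-2 * loglik + k * log(n) + 4 * k * gamma * log(p)`, where `k` counts the
#' free off-diagonal parameters (edges). With `gamma = 0` this is the
#' ordinary BIC. Diagonal parameters are present in every model and omitted
#' from `k`.
#'
#' @param loglik Model log-likelihood.
#' @param k_edges Number of edges.
#' @param n Sample size.
#' @param p Number of nodes.
#' @param gamma EBIC hyperparameter, >= 0.
#' @return Scalar EBIC (smaller is better).
#' @export
ebic_score <- function(loglik, k_edges, n, p, gamma = 0) {
  stopifnot(n > 0, p >= 2, k_edges >= 0, gamma >= 0)
  -2 * loglik + k_edges * log(n) + 4 * k_edges * gamma * log(p)
}

mask_key <- function(mask) {
  paste(as.integer(mask[upper.tri(mask)]), collapse = "")
}

edge_count <- function(mask) sum(mask[upper.tri(mask)])

#' Candidate structures from a sparsity path over saturated partials
#'
#' Thresholds the absolute saturated partial correlations at `n_levels`
#' log-spaced levels between the largest absolute partial and `min_ratio`
#' times it, giving a nested family of candidate masks from empty to (near)
#' saturated. Duplicate masks are collapsed before refitting.
#' @keywords internal
threshold_path_masks <- function(P, n_levels = 100, min_ratio = 0.01) {
  p <- nrow(P)
  a <- abs(P[upper.tri(P)])
  amax <- max(a)
  empty <- matrix(FALSE, p, p)
  saturated <- matrix(TRUE, p, p); diag(saturated) <- FALSE
  if (amax == 0) return(list(empty))
  levels <- exp(seq(log(amax), log(amax * min_ratio), length.out = n_levels))
  masks <- list(empty, saturated)
  seen <- c(mask_key(empty), mask_key(saturated))
  for (lv in levels) {
    m <- abs(P) >= lv
    diag(m) <- FALSE
    key <- mask_key(m)
    if (!key %in% seen) {
      seen <- c(seen, key)
      masks[[length(masks) + 1]] <- m
    }
  }
  masks
}

#' Estimate an unregularized GGM by stepwise EBIC search
#'
#' Two stages. (1) Initialization: a scan over a log-spaced sparsity path of
#' the saturated partial-correlation matrix produces candidate structures;
#' each is refit by constrained maximum likelihood and the EBIC-minimal
#' candidate seeds the search. (2) Greedy stepwise: every single-edge
#' addition or removal is refit and scored; the best strict EBIC improvement
#' is accepted, until no single toggle improves the criterion. Ties are
#' broken toward the sparser model, then by lexicographic edge order, so the
#' search is deterministic. Edge weights of the returned network are the
#' constrained-ML partial correlations.
#'
#' @param data Numeric matrix or data frame (participants x variables), or a
#'   precomputed correlation matrix if `n` is supplied.
#' @param gamma EBIC hyperparameter; 0 (the default) gives BIC selection.
#' @param n Sample size; required when `data` is a correlation matrix.
#' @param n_levels,min_ratio Initialization-path settings (see
#'   [threshold_path_masks]); defaults 100 levels down to 1% of the largest
#'   absolute partial.
#' @param tol,max_iter Passed to [fit_constrained_ggm()].
#' @return Object of class `ggm_network`: `labels`, `weights` (fitted partial
#'   correlations, zero off-structure), `mask`, `n`, `gamma`, `loglik`,
#'   `ebic`, `n_edges`, `steps` (accepted stepwise moves).
#' @export
ggm_model_select <- function(data, gamma = 0, n = NULL, n_levels = 100,
                             min_ratio = 0.01, tol = 1e-8, max_iter = 10000) {
  if (is.null(n)) {
    R <- correlation_matrix(data)
    n <- nrow(as.matrix(data))
  } else {
    R <- as.matrix(data)
    stopifnot(nrow(R) == ncol(R), all(abs(diag(R) - 1) < 1e-12))
  }
  p <- nrow(R)
  if (n < p + 1) stop("need n >= p + 1", call. = FALSE)
  labels <- colnames(R)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))

  score_mask <- function(mask) {
    fit <- fit_constrained_ggm(R, mask, n, tol = tol, max_iter = max_iter)
    list(fit = fit,
         ebic = ebic_score(fit$loglik, edge_count(mask), n, p, gamma))
  }

  P_sat <- partials_from_correlation(R)
  candidates <- threshold_path_masks(P_sat, n_levels, min_ratio)
  best <- NULL
  cur_mask <- NULL
  for (m in candidates) {
    sc <- score_mask(m)
    if (is.null(best) || sc$ebic < best$ebic) {
      best <- sc
      cur_mask <- m
    }
  }

  pairs <- which(upper.tri(cur_mask), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  visited <- mask_key(cur_mask)
  steps <- character(0)
  eps <- 1e-10
  repeat {
    cand_ebic <- rep(NA_real_, nrow(pairs))
    cand_fits <- vector("list", nrow(pairs))
    cand_masks <- vector("list", nrow(pairs))
    for (e in seq_len(nrow(pairs))) {
      i <- pairs[e, 1]; j <- pairs[e, 2]
      m <- cur_mask
      m[i, j] <- m[j, i] <- !m[i, j]
      key <- mask_key(m)
      if (key %in% visited) next
      sc <- tryCatch(score_mask(m), error = function(e) NULL)
      if (is.null(sc)) next
      cand_ebic[e] <- sc$ebic
      cand_fits[[e]] <- sc
      cand_masks[[e]] <- m
    }
    ok <- which(!is.na(cand_ebic) & cand_ebic < best$ebic - eps)
    if (length(ok) == 0) break
    best_val <- min(cand_ebic[ok])
    tied <- ok[cand_ebic[ok] <= best_val + eps]
    if (length(tied) > 1) {
      # prefer the sparser result (a removal), then lexicographic edge order
      is_removal <- vapply(tied, function(e) {
        cur_mask[pairs[e, 1], pairs[e, 2]]
      }, logical(1))
      if (any(is_removal)) tied <- tied[is_removal]
    }
    pick <- tied[1]
    i <- pairs[pick, 1]; j <- pairs[pick, 2]
    steps <- c(steps, sprintf("%s %s--%s",
                              if (cur_mask[i, j]) "remove" else "add",
                              labels[i], labels[j]))
    cur_mask <- cand_masks[[pick]]
    best <- cand_fits[[pick]]
    visited <- c(visited, mask_key(cur_mask))
  }

  W <- best$fit$partials
  dimnames(W) <- list(labels, labels)
  dimnames(cur_mask) <- list(labels, labels)
  structure(list(labels = labels, weights = W, mask = cur_mask, n = n,
                 gamma = gamma, loglik = best$fit$loglik, ebic = best$ebic,
                 n_edges = edge_count(cur_mask), steps = steps),
            class = "ggm_network")
}

#' @export
print.ggm_network <- function(x, ...) {
  cat(sprintf("Gaussian graphical model: %d nodes, %d edges (n = %d, gamma = %g)\n",
              length(x$labels), x$n_edges, x$n, x$gamma))
  cat(sprintf("EBIC = %.2f, log-likelihood = %.2f\n", x$ebic, x$loglik))
  el <- network_edge_list(x)
  if (nrow(el) > 0) {
    cat("edges:\n")
    for (r in seq_len(nrow(el))) {
      cat(sprintf("  %s -- %s  % .3f\n", el$node_i[r], el$node_j[r],
                  el$partial_r[r]))
    }
  }
  invisible(x)
}

#' Undirected edge list of a GGM
#'
#' @param net A `ggm_network`.
#' @return Data frame with `node_i`, `node_j`, `partial_r`, one row per edge.
#' @export
network_edge_list <- function(net) {
  stopifnot(inherits(net, "ggm_network"))
  idx <- which(upper.tri(net$mask) & net$mask, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(
    node_i = net$labels[idx[, 1]],
    node_j = net$labels[idx[, 2]],
    partial_r = net$weights[idx],
    stringsAsFactors = FALSE
  )
}
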