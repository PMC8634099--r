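subset_r2 <- function(R, y, xs) {
  if (length(xs) == 0) return(0)
  ryx <- R[y, xs, drop = FALSE]
  as.numeric(ryx %*% solve(R[xs, xs, drop = FALSE], t(ryx)))
}

#' LMG relative-importance decomposition of R-squared
#'
#' Attributes the explained variance of a regression to each predictor as its
#' incremental R-squared averaged over all orderings in which predictors can
#' enter the model (the Shapley value of the R-squared game). Computed from
#' covariance algebra alone; equivalent to explicit enumeration of all `k!`
#' orderings but evaluated over the `2^k` predictor subsets with factorial
#' weights. Contributions are nonnegative and sum to the full-model
#' R-squared.
#'
#' @param S Positive-definite covariance or correlation matrix with named
#'   rows/columns.
#' @param y Outcome variable (name or index).
#' @param predictors Predictor set (names or indices), 1 to `max_predictors`
#'   variables.
#' @param max_predictors Enumeration cap; larger sets are rejected rather
#'   than approximated. Default 10.
#' @return Named numeric vector of per-predictor contributions, with the
#'   full-model R-squared attached as attribute `r_squared`.
#' @examples
#' R <- matrix(c(1, .5, .5, .5, 1, .5, .5, .5, 1), 3, 3,
#'             dimnames = rep(list(c("y", "x1", "x2")), 2))
#' lmg_contributions(R, "y", c("x1", "x2"))  # each 1/6, summing to R2 = 1/3
#' @export
lmg_contributions <- function(S, y, predictors, max_predictors = 10) {
  S <- as.matrix(S)
  R <- stats::cov2cor(S)
  if (is.character(y)) y <- match(y, colnames(R))
  if (is.character(predictors)) predictors <- match(predictors, colnames(R))
  if (anyNA(c(y, predictors))) stop("unknown variable name", call. = FALSE)
  k <- length(predictors)
  if (k < 1) stop("at least one predictor is required", call. = FALSE)
  if (k > max_predictors) {
    stop(sprintf(paste0("%d predictors exceeds the exact-enumeration cap of ",
                        "%d; reduce the neighbor set or raise max_predictors"),
                 k, max_predictors), call. = FALSE)
  }
  ev <- eigen(R[c(y, predictors), c(y, predictors)], symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) <= 1e-12) {
    stop("covariance submatrix is singular", call. = FALSE)
  }
  # R2 for every predictor subset, indexed by bitmask
  n_sub <- 2L^k
  r2 <- numeric(n_sub)
  for (b in seq_len(n_sub - 1L)) {
    xs <- predictors[bitwAnd(b, bitwShiftL(1L, 0:(k - 1))) != 0]
    r2[b + 1L] <- subset_r2(R, y, xs)
  }
  wts <- factorial(0:(k - 1)) * factorial(k - 1 - 0:(k - 1)) / factorial(k)
  out <- numeric(k)
  for (i in seq_len(k)) {
    bit_i <- bitwShiftL(1L, i - 1L)
    for (b in 0:(n_sub - 1L)) {
      if (bitwAnd(b, bit_i) != 0) next
      t_size <- sum(bitwAnd(b, bitwShiftL(1L, 0:(k - 1))) != 0)
      out[i] <- out[i] + wts[t_size + 1] * (r2[bitwOr(b, bit_i) + 1L] - r2[b + 1L])
    }
  }
  names(out) <- colnames(R)[predictors]
  attr(out, "r_squared") <- r2[n_sub]
  out
}

relimp_weights_from_cov <- function(S, mask, max_predictors = 10) {
  S <- as.matrix(S)
  p <- nrow(S)
  labels <- colnames(S)
  W <- matrix(0, p, p, dimnames = list(labels, labels))
  for (j in seq_len(p)) {
    nb <- which(mask[, j])
    if (length(nb) == 0) next
    W[nb, j] <- lmg_contributions(S, j, nb, max_predictors = max_predictors)
  }
  W
}

#' Directed relative-importance network on a GGM structure
#'
#' For every node with at least one GGM neighbor, the node is regressed on
#' exactly its neighbors and the explained variance is split among them with
#' the LMG metric: the directed weight `i -> j` is predictor `i`'s
#' contribution to the R-squared of outcome `j`. Each GGM edge therefore
#' yields two opposing directed edges; isolated nodes receive and emit
#' nothing. Regressions use the sample correlation of the supplied data; the
#' GGM contributes only the neighbor sets.
#'
#' @param data Participants-by-variables matrix or data frame with the same
#'   variables as `ggm`.
#' @param ggm A `ggm_network` (or any object with a logical `mask` and
#'   `labels`).
#' @param max_predictors Enumeration cap passed to [lmg_contributions()].
#' @return Object of class `relimp_network`: `labels`, `weights` (p x p,
#'   `weights[i, j]` is the contribution of `i` to the variance of `j`),
#'   `mask`.
#' @export
relative_importance_network <- function(data, ggm, max_predictors = 10) {
  S <- correlation_matrix(data)
  if (!identical(colnames(S), ggm$labels)) {
    stop("data variables do not match the GGM node labels", call. = FALSE)
  }
  relimp_network_from_cov(S, ggm$mask, max_predictors = max_predictors)
}

#' Relative-importance network from a covariance matrix
#'
#' Covariance-algebra variant of [relative_importance_network()], useful for
#' population-level calculations on a known covariance or correlation matrix.
#'
#' @param S Positive-definite covariance or correlation matrix.
#' @param mask Symmetric logical edge structure (FALSE diagonal).
#' @param max_predictors Enumeration cap passed to [lmg_contributions()].
#' @return A `relimp_network`.
#' @export
relimp_network_from_cov <- function(S, mask, max_predictors = 10) {
  S <- as.matrix(S)
  mask <- as.matrix(mask) != 0
  stopifnot(nrow(S) == ncol(S), all(dim(mask) == dim(S)))
  labels <- colnames(S)
  if (is.null(labels)) labels <- paste0("V", seq_len(nrow(S)))
  colnames(S) <- rownames(S) <- labels
  W <- relimp_weights_from_cov(S, mask, max_predictors)
  structure(list(labels = labels, weights = W, mask = mask),
            class = "relimp_network")
}

#' @export
print.relimp_network <- function(x, ...) {
  cat(sprintf("Relative-importance network: %d nodes, %d directed edges\n",
              length(x$labels), sum(x$weights > 0)))
  s <- strength_summaries(x)
  print(s, digits = 3)
  invisible(x)
}

#' Node out- and instrength of a relative-importance network
#'
#' Outstrength of node `i` is the total variance it explains in its
#' neighbors, `sum_j w[i -> j]`; instrength the total variance of `i`
#' explained by its neighbors, `sum_j w[j -> i]`. With a `focus` subset, the
#' restricted columns sum only edges whose other endpoint lies in `focus`,
#' e.g. the direct relationships of the resilience factors with the
#' quality-of-life node(s) alone.
#'
#' @param rin A `relimp_network`.
#' @param focus Optional character vector of node labels to restrict to.
#' @return Data frame with `node`, `outstrength`, `instrength`, `difference`
#'   (out minus in), plus `focus_outstrength`, `focus_instrength`,
#'   `focus_difference` when `focus` is given.
#' @export
strength_summaries <- function(rin, focus = NULL) {
  stopifnot(inherits(rin, "relimp_network"))
  W <- rin$weights
  out <- data.frame(
    node = rin$labels,
    outstrength = rowSums(W),
    instrength = colSums(W),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$difference <- out$outstrength - out$instrength
  if (!is.null(focus)) {
    unknown <- setdiff(focus, rin$labels)
    if (length(unknown) > 0) {
      stop(sprintf("unknown focus label: %s", unknown[1]), call. = FALSE)
    }
    fsel <- rin$labels %in% focus
    out$focus_outstrength <- rowSums(W[, fsel, drop = FALSE])
    out$focus_instrength <- colSums(W[fsel, , drop = FALSE])
    out$focus_difference <- out$focus_outstrength - out$focus_instrength
  }
  out
}
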