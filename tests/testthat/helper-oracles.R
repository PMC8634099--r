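# Independent oracles used across the suite. These deliberately take the
# slow, literal route (explicit permutations, generic numerical
# optimization) so they share no code path with the package implementation.

# random positive-definite correlation matrix
rand_corr <- function(p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * (p + 2)), p + 2, p)
  R <- stats::cov2cor(crossprod(A) / (p + 2))
  dimnames(R) <- rep(list(paste0("V", seq_len(p))), 2)
  R
}

all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(all_perms(v[-i]), function(rest) c(v[i], rest))
  }))
}

oracle_r2 <- function(R, y, xs) {
  if (length(xs) == 0) return(0)
  ryx <- R[y, xs, drop = FALSE]
  as.numeric(ryx %*% solve(R[xs, xs, drop = FALSE], t(ryx)))
}

# LMG by explicit enumeration of every predictor ordering
lmg_bruteforce <- function(S, y, predictors) {
  R <- stats::cov2cor(S)
  out <- stats::setNames(numeric(length(predictors)), predictors)
  orderings <- all_perms(predictors)
  for (ord in orderings) {
    entered <- character(0)
    for (x in ord) {
      out[x] <- out[x] + oracle_r2(R, y, c(entered, x)) -
        oracle_r2(R, y, entered)
      entered <- c(entered, x)
    }
  }
  out / length(orderings)
}

# constrained Gaussian ML by generic numerical optimization over the free
# precision entries (diagonal + masked off-diagonals), with analytic gradient
constrained_ml_optim <- function(S, mask, n) {
  p <- nrow(S)
  free_off <- which(upper.tri(mask) & mask, arr.ind = TRUE)
  build_K <- function(theta) {
    K <- diag(exp(theta[seq_len(p)]), p)
    if (nrow(free_off) > 0) {
      for (e in seq_len(nrow(free_off))) {
        K[free_off[e, 1], free_off[e, 2]] <- theta[p + e]
        K[free_off[e, 2], free_off[e, 1]] <- theta[p + e]
      }
    }
    K
  }
  negll <- function(theta) {
    K <- build_K(theta)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) return(1e10)
    -(sum(log(ev)) - sum(S * K))
  }
  grad <- function(theta) {
    K <- build_K(theta)
    W <- solve(K)
    gd <- (-diag(W) + diag(S)) * exp(theta[seq_len(p)])
    go <- numeric(nrow(free_off))
    if (nrow(free_off) > 0) {
      for (e in seq_len(nrow(free_off))) {
        i <- free_off[e, 1]; j <- free_off[e, 2]
        go[e] <- -2 * W[i, j] + 2 * S[i, j]
      }
    }
    c(gd, go)
  }
  theta0 <- c(rep(0, p), rep(0, nrow(free_off)))
  fit <- stats::optim(theta0, negll, grad, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-14))
  K <- build_K(fit$par)
  d <- 1 / sqrt(diag(K))
  P <- -K * tcrossprod(d)
  diag(P) <- 0
  list(precision = K, partials = P,
       loglik = (n / 2) * (determinant(K)$modulus[1] - sum(S * K) -
                             p * log(2 * pi)))
}

# exhaustive EBIC minimum over all masks for small p
exhaustive_ebic_min <- function(R, n, gamma = 0) {
  p <- nrow(R)
  pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
  n_edge_slots <- nrow(pairs)
  best <- Inf
  for (code in 0:(2^n_edge_slots - 1)) {
    mask <- matrix(FALSE, p, p)
    for (e in seq_len(n_edge_slots)) {
      if (bitwAnd(code, bitwShiftL(1L, e - 1L)) != 0) {
        mask[pairs[e, 1], pairs[e, 2]] <- TRUE
        mask[pairs[e, 2], pairs[e, 1]] <- TRUE
      }
    }
    fit <- fit_constrained_ggm(R, mask, n)
    val <- ebic_score(fit$loglik, sum(mask[upper.tri(mask)]), n, p, gamma)
    if (val < best) best <- val
  }
  best
}
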