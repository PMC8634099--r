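test_that("correlation matrix matches the direct Pearson formula", {
  x <- cbind(a = c(1, 2, 4, 7), b = c(2, 1, 5, 9), c = c(3, 0, 1, 2))
  R <- correlation_matrix(x)
  hand <- function(u, v) {
    sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  }
  expect_equal(R["a", "b"], hand(x[, "a"], x[, "b"]))
  expect_equal(R["a", "c"], hand(x[, "a"], x[, "c"]))
  expect_equal(diag(R), c(a = 1, b = 1, c = 1))
  expect_error(correlation_matrix(x[1:3, ]), "n >= p")
  expect_equal(correlation_matrix(cbind(u = 1:5, v = 2 * (1:5)))["u", "v"], 1)
  expect_error(correlation_matrix(cbind(u = 1:5, v = rep(2, 5))),
               "constant column: v")
})

test_that("partials match closed forms", {
  # p = 2: partial equals marginal
  R2 <- matrix(c(1, .37, .37, 1), 2)
  expect_equal(partials_from_correlation(R2)[1, 2], 0.37)
  # p = 3 with all pairwise r = 0.5: every partial is 1/3
  R3 <- matrix(.5, 3, 3); diag(R3) <- 1
  P3 <- partials_from_correlation(R3)
  expect_equal(unique(round(P3[upper.tri(P3)], 12)), 1 / 3)
  # identity -> all zero
  expect_true(all(partials_from_correlation(diag(4)) == 0))
  # random p = 3 against the textbook closed form
  R <- rand_corr(3, seed = 8)
  P <- partials_from_correlation(R)
  closed <- (R[1, 2] - R[1, 3] * R[2, 3]) /
    sqrt((1 - R[1, 3]^2) * (1 - R[2, 3]^2))
  expect_equal(P[1, 2], closed, tolerance = 1e-12)
  expect_error(partials_from_correlation(matrix(c(1, 1, 1, 1), 2)),
               "positive definite")
})

test_that("constrained ML fit honors its moment conditions", {
  R <- rand_corr(5, seed = 2)
  p <- 5
  sat <- matrix(TRUE, p, p); diag(sat) <- FALSE
  fit <- fit_constrained_ggm(R, sat, n = 100)
  expect_equal(fit$partials, partials_from_correlation(R), tolerance = 1e-7)

  empty <- matrix(FALSE, p, p)
  fit0 <- fit_constrained_ggm(R, empty, n = 100)
  expect_equal(fit0$precision, diag(1 / diag(R)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(fit0$partials == 0))
  # independence log-likelihood in closed form
  expect_equal(fit0$loglik,
               (100 / 2) * (-sum(log(diag(R))) - p - p * log(2 * pi)),
               tolerance = 1e-8)

  # implied covariance matches S on the diagonal and on every allowed edge
  chain <- matrix(FALSE, p, p)
  for (i in 1:(p - 1)) chain[i, i + 1] <- chain[i + 1, i] <- TRUE
  fitc <- fit_constrained_ggm(R, chain, n = 100)
  expect_equal(diag(fitc$implied_cov), diag(R), tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_equal(fitc$implied_cov[chain], R[chain], tolerance = 1e-6)
  expect_true(all(fitc$precision[!chain & !diag(p)] == 0))
})

test_that("constrained ML fit matches a generic numeric optimizer", {
  for (seed in 1:6) {
    p <- sample(3:5, 1)
    R <- rand_corr(p, seed = 100 + seed)
    set.seed(seed)
    mask <- matrix(FALSE, p, p)
    for (i in 1:(p - 1)) {
      for (j in (i + 1):p) {
        mask[i, j] <- mask[j, i] <- runif(1) < 0.5
      }
    }
    fit <- fit_constrained_ggm(R, mask, n = 200)
    oracle <- constrained_ml_optim(R, mask, n = 200)
    expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-6)
    expect_equal(fit$partials, unname(oracle$partials), tolerance = 1e-4,
                 ignore_attr = TRUE)
  }
})

test_that("log-likelihood never decreases when edges are added", {
  R <- rand_corr(5, seed = 33)
  mask <- matrix(FALSE, 5, 5)
  lls <- numeric(0)
  pairs <- which(upper.tri(mask), arr.ind = TRUE)
  for (e in seq_len(nrow(pairs))) {
    mask[pairs[e, 1], pairs[e, 2]] <- mask[pairs[e, 2], pairs[e, 1]] <- TRUE
    lls <- c(lls, fit_constrained_ggm(R, mask, n = 50)$loglik)
  }
  expect_true(all(diff(lls) >= -1e-8))
})

test_that("EBIC reduces to BIC at gamma zero and matches hand arithmetic", {
  expect_equal(ebic_score(-50, 4, 120, 6, gamma = 0),
               100 + 4 * log(120))
  expect_equal(ebic_score(-50, 0, 120, 6, gamma = 1), 100)
  # -2(-100) + 3 log 1392 + 4*3*0.5 log 6
  expect_equal(ebic_score(-100, 3, 1392, 6, gamma = 0.5),
               232.4660472, tolerance = 1e-7)
})

test_that("model selection returns an empty network for orthogonal data", {
  set.seed(4)
  x <- matrix(rnorm(400 * 4), 400, 4)
  x <- qr.Q(qr(x)) * 20  # exactly orthogonal columns
  colnames(x) <- paste0("V", 1:4)
  net <- ggm_model_select(x)
  expect_equal(net$n_edges, 0L)
})

test_that("model selection is invariant to column permutation and rescaling", {
  spec <- reference_network_spec(n = 500)
  x <- generate_dataset(spec, seed = 7)
  net <- ggm_model_select(x)
  perm <- c(4, 1, 6, 2, 5, 3)
  net_p <- ggm_model_select(x[, perm])
  expect_equal(net_p$weights[net$labels, net$labels], net$weights,
               tolerance = 1e-6)
  x_s <- sweep(sweep(x, 2, c(2, 0.1, 40, 1, 5, 0.3), "*"),
               2, c(-3, 0, 10, 2, 0, 1), "+")
  net_s <- ggm_model_select(x_s)
  expect_equal(net_s$mask, net$mask)
  expect_equal(net_s$weights, net$weights, tolerance = 1e-6)
})

test_that("a four-node chain is recovered at n = 2000 in nearly all seeds", {
  p <- 4
  P <- matrix(0, p, p, dimnames = rep(list(paste0("V", 1:p)), 2))
  for (i in 1:(p - 1)) P[i, i + 1] <- P[i + 1, i] <- 0.4
  spec <- generator_spec(paste0("V", 1:p), P, means = rep(0, p),
                         sds = rep(1, p), n = 2000)
  hits <- 0L
  for (seed in 1:100) {
    x <- generate_dataset(spec, seed = seed)
    net <- ggm_model_select(x)
    if (identical(unname(net$mask), unname(P != 0))) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})
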