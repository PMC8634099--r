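#' Implied covariance of a partial-correlation structure
#'
#' Inverts the standardized precision implied by a partial-correlation
#' matrix: with `Omega = I - P` (unit diagonal, `Omega[i,j] = -P[i,j]`), the
#' correlation matrix of `solve(Omega)` reproduces `P` exactly under
#' [partials_from_correlation()]; the result is then rescaled so its diagonal
#' equals `sds^2`.
#'
#' @param P Symmetric partial-correlation matrix with zero diagonal.
#' @param sds Positive per-variable standard deviations.
#' @return Covariance matrix with `diag = sds^2`.
#' @export
implied_covariance <- function(P, sds) {
  P <- as.matrix(P)
  p <- nrow(P)
  stopifnot(ncol(P) == p, length(sds) == p, all(sds > 0))
  if (any(diag(P) != 0) || !isTRUE(all.equal(P, t(P)))) {
    stop("P must be symmetric with a zero diagonal", call. = FALSE)
  }
  Omega <- diag(p) - P
  ev <- eigen(Omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf("implied precision is not positive definite (min eigenvalue %.4g)",
                 min(ev)), call. = FALSE)
  }
  R <- stats::cov2cor(solve(Omega))
  Sigma <- diag(sds) %*% R %*% diag(sds)
  dimnames(Sigma) <- dimnames(P)
  Sigma
}

#' Construct a synthetic-data generator specification
#'
#' Bundles everything needed to simulate scale-score datasets with a known
#' conditional-dependence structure: node labels, the generating
#' partial-correlation matrix, per-variable means and SDs, the sample size,
#' and optional physical-activity realism settings (a monotone right-skew
#' transform and injected gross outliers for exercising the robust filter).
#'
#' @param labels Character vector of node names.
#' @param partials Symmetric generating partial-correlation matrix (zero
#'   diagonal; `I - partials` must be positive definite).
#' @param means,sds Per-variable means and positive SDs.
#' @param n Default sample size.
#' @param phy_skew `NULL` for plain Gaussian output, or a list with `variable`
#'   (column to skew), `lambda` (skew strength of the monotone transform
#'   `(exp(lambda * z) - 1) / lambda`) and `truncate` (bulk truncation, in SD
#'   units, applied before skewing so the clean bulk stays inside the robust
#'   outlier fence). See [phy_skew_settings()].
#' @param outliers `NULL`, or a list with `rate` (fraction of rows, at most
#'   0.2) and `min_z` (minimum robust-SD displacement, e.g. 6) of injected
#'   gross outliers on the skewed variable.
#' @param likert `TRUE` to also emit item-level questionnaire responses (see
#'   [generate_item_responses()]).
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(labels, partials, means, sds, n,
                           phy_skew = NULL, outliers = NULL, likert = FALSE) {
  p <- length(labels)
  partials <- as.matrix(partials)
  stopifnot(nrow(partials) == p, length(means) == p, length(sds) == p,
            all(sds > 0), n >= 2)
  dimnames(partials) <- list(labels, labels)
  # validates symmetry / positive definiteness as a side effect
  invisible(implied_covariance(partials, sds))
  if (!is.null(outliers)) {
    stopifnot(outliers$rate >= 0, outliers$rate <= 0.2, outliers$min_z > 0)
  }
  structure(list(labels = labels, partials = partials,
                 means = stats::setNames(means, labels),
                 sds = stats::setNames(sds, labels), n = as.integer(n),
                 phy_skew = phy_skew, outliers = outliers, likert = likert),
            class = "generator_spec")
}

#' Default physical-activity skew settings
#'
#' The weekly MET-minute score is right-skewed and bounded in practice; the
#' generator emulates this with a truncated-bulk exponential transform. The
#' defaults (`lambda = 0.15`, `truncate = 2`) keep the skewed bulk inside
#' the 2.5 robust-SD outlier fence, so that injected gross outliers - and
#' only they - are removed by [mad_outlier_mask()].
#'
#' @param variable Column to transform; default `"PHY"`.
#' @param lambda Skew strength; 0 degenerates to the identity.
#' @param truncate Bulk truncation in SD units before skewing.
#' @return List usable as the `phy_skew` field of [generator_spec()].
#' @export
phy_skew_settings <- function(variable = "PHY", lambda = 0.15, truncate = 2) {
  list(variable = variable, lambda = lambda, truncate = truncate)
}

#' Default gross-outlier injection settings
#'
#' A 7.2 percent contamination rate reflects the share of participants a
#' robust pre-screen of the activity variable removes in cohorts of this
#' kind; displacements start at 6 robust SDs so injected rows are
#' unambiguous.
#'
#' @param rate Fraction of rows replaced by outliers.
#' @param min_z Minimum displacement in SD units.
#' @return List usable as the `outliers` field of [generator_spec()].
#' @export
outlier_settings <- function(rate = 0.072, min_z = 6) {
  list(rate = rate, min_z = min_z)
}

#' Generator specification for the published six-node network
#'
#' Returns the scale-score generating model for the six-node network of
#' overall quality of life (QoL), behavioral coping (BC), positive appraisal
#' style (PAS), self-management ability (SMA), physical activity (PHY) and
#' the COVID-19 stringency index (SI): seven nonzero partial correlations
#' (QoL-SMA 0.39, QoL-PAS 0.15, BC-SMA 0.31, PAS-SMA 0.29, BC-PAS 0.14,
#' SMA-PHY 0.18, BC-PHY -0.09), SI isolated, zeros elsewhere, with the
#' reported per-variable means and SDs and a default sample size of 1392.
#' The facet-level networks are not available as fixtures: their edge
#' weights were published only in supplementary material and cannot be fixed
#' numerically.
#'
#' @param which Fixture name; only `"qol6"` is available.
#' @param n Sample size; default 1392.
#' @param phy_skew,outliers,likert Overrides passed to [generator_spec()];
#'   all disabled by default, giving a plain multivariate-normal generator
#'   at the scale-score level.
#' @return A `generator_spec`.
#' @export
reference_network_spec <- function(which = c("qol6", "facets11", "smas15"),
                                   n = 1392, phy_skew = NULL, outliers = NULL,
                                   likert = FALSE) {
  which <- match.arg(which)
  if (which != "qol6") {
    stop(sprintf(paste0("only partial information is available for the '%s' ",
                        "network: its edge weights were never published in ",
                        "full and no fixture can be constructed"), which),
         call. = FALSE)
  }
  labels <- c("QoL", "BC", "PAS", "SMA", "PHY", "SI")
  P <- matrix(0, 6, 6, dimnames = list(labels, labels))
  edges <- rbind(
    c("QoL", "SMA", 0.39),
    c("QoL", "PAS", 0.15),
    c("BC",  "SMA", 0.31),
    c("PAS", "SMA", 0.29),
    c("BC",  "PAS", 0.14),
    c("SMA", "PHY", 0.18),
    c("BC",  "PHY", -0.09)
  )
  for (e in seq_len(nrow(edges))) {
    P[edges[e, 1], edges[e, 2]] <- as.numeric(edges[e, 3])
    P[edges[e, 2], edges[e, 1]] <- as.numeric(edges[e, 3])
  }
  means <- c(QoL = 94.6, BC = 21.5, PAS = 0.03, SMA = 69.2,
             PHY = 3641.6, SI = 65.9)
  sds <- c(QoL = 9.52, BC = 3.71, PAS = 0.60, SMA = 11.6,
           PHY = 2109.6, SI = 8.4)
  generator_spec(labels, P, means, sds, n = n, phy_skew = phy_skew,
                 outliers = outliers, likert = likert)
}

#' Simulate a scale-score dataset from a generator specification
#'
#' Draws `n` rows from the multivariate normal with [implied_covariance()]
#' of the spec. When `phy_skew` is set, the designated column's bulk is
#' truncated, passed through the monotone transform
#' `(exp(lambda * z) - 1) / lambda`, and re-standardized to the target mean
#' and SD (the transform preserves ranks, so cross-variable ordering
#' information survives). When `outliers` is set, a random subset of rows
#' then has that column replaced by gross positive outliers at least `min_z`
#' SDs above the mean; their row indices are recorded in the attribute
#' `outlier_rows`.
#'
#' @param spec A `generator_spec`.
#' @param seed Integer seed; identical seeds give identical matrices.
#' @param n Optional sample-size override.
#' @return Numeric `n x p` matrix with named columns and row names
#'   `P1..Pn`; attribute `outlier_rows` holds injected row indices (integer,
#'   possibly empty).
#' @export
generate_dataset <- function(spec, seed = 1, n = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  if (is.null(n)) n <- spec$n
  p <- length(spec$labels)
  Sigma <- implied_covariance(spec$partials, spec$sds)
  L <- chol(Sigma)
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * p), n, p)
  X <- Z %*% L
  X <- sweep(X, 2, spec$means, "+")
  colnames(X) <- spec$labels
  rownames(X) <- paste0("P", seq_len(n))
  out_rows <- integer(0)
  if (!is.null(spec$phy_skew)) {
    v <- spec$phy_skew$variable
    lam <- spec$phy_skew$lambda
    trunc <- spec$phy_skew$truncate
    mu <- spec$means[v]; sdv <- spec$sds[v]
    z <- (X[, v] - mu) / sdv
    z <- pmin(pmax(z, -trunc), trunc)
    g <- if (lam == 0) z else (exp(lam * z) - 1) / lam
    X[, v] <- mu + sdv * as.numeric(scale(g))
  }
  if (!is.null(spec$outliers) && spec$outliers$rate > 0) {
    v <- if (is.null(spec$phy_skew)) "PHY" else spec$phy_skew$variable
    if (!v %in% spec$labels) v <- spec$labels[length(spec$labels)]
    k <- max(1L, round(spec$outliers$rate * n))
    out_rows <- sort(sample.int(n, k))
    mu <- spec$means[v]; sdv <- spec$sds[v]
    X[out_rows, v] <- mu + sdv * (spec$outliers$min_z + stats::rexp(k, 1))
  }
  attr(X, "outlier_rows") <- out_rows
  X
}

likert_cutpoints <- function(n_levels) {
  stats::qnorm(seq_len(n_levels - 1) / n_levels)
}

discretize_latent <- function(z, n_levels) {
  findInterval(z, likert_cutpoints(n_levels)) + 1L
}

#' Simulate item-level questionnaire responses
#'
#' Optional layer on top of the scale-score generator for exercising the
#' scoring module: per instrument, correlated latent normals are discretized
#' into instrument-valid Likert responses, and the resulting item matrices
#' are scored with the package's own scoring functions. The returned
#' `scores` are exactly the scores of the returned items, so scoring the
#' items reproduces them; the latent correlation (default 0.45 within an
#' instrument) gives realistic internal consistency without claiming any
#' particular factor structure.
#'
#' @param n Number of participants.
#' @param seed Integer seed.
#' @param latent_cor Common within-instrument latent correlation.
#' @return List with `items` (matrices `whoqol` n x 24, `smas` n x 18,
#'   `bcs` n x 8, `pass` n x 14) and `scores` (data frame of the scored
#'   scales: six QoL facets, `QoL`, six SMA facets, `SMA`, `BC`, `PAS`).
#' @export
generate_item_responses <- function(n, seed = 1, latent_cor = 0.45) {
  set.seed(seed)
  draw_latent <- function(n_items) {
    R <- matrix(latent_cor, n_items, n_items)
    diag(R) <- 1
    matrix(stats::rnorm(n * n_items), n, n_items) %*% chol(R)
  }
  whoqol_raw <- apply(draw_latent(24), 2, discretize_latent, n_levels = 5L)
  # negatively keyed items are *stored* flipped, as a respondent would answer
  rev_idx <- whoqol_default_reverse_items()
  whoqol_raw[, rev_idx] <- 6L - whoqol_raw[, rev_idx]
  opts <- smas_default_options()
  smas_lat <- draw_latent(18)
  smas_raw <- vapply(seq_len(18), function(j) {
    discretize_latent(smas_lat[, j], opts[j])
  }, integer(n))
  bcs_raw <- apply(draw_latent(8), 2, discretize_latent, n_levels = 4L)
  pass_levels <- rep(c(4L, 5L), length.out = 14)
  pass_lat <- draw_latent(14)
  pass_raw <- vapply(seq_len(14), function(j) {
    discretize_latent(pass_lat[, j], pass_levels[j])
  }, integer(n))
  qol <- score_whoqol(whoqol_raw)
  sma <- score_smas(smas_raw)
  scores <- cbind(qol, sma,
                  BC = score_bcs(bcs_raw),
                  PAS = score_pass(pass_raw)$scores)
  list(items = list(whoqol = whoqol_raw, smas = smas_raw, bcs = bcs_raw,
                    pass = pass_raw),
       scores = scores)
}
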