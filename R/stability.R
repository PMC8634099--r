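#' Nonparametric bootstrap of an arbitrary network statistic
#'
#' Resamples the rows of `data` with replacement `B` times, applies
#' `estimator` to each resample, and summarizes the replicate distribution
#' with empirical quantile intervals (type-7 interpolation, so intervals are
#' reproducible bit-for-bit) and per-statistic proportions of exact zeros
#' (informative for model-selected edge weights). Replicate-level estimator
#' failures are recorded and tolerated up to 5 percent of `B`.
#'
#' @param data Participants-by-variables matrix or data frame.
#' @param estimator Function `data -> named numeric vector` of fixed length,
#'   e.g. the edge weights of a re-selected network.
#' @param B Number of bootstrap replicates; default 1000.
#' @param seed Integer seed governing all resampling.
#' @param level Coverage of the quantile interval; default 0.95 (2.5 and
#'   97.5 percent quantiles).
#' @return Object of class `bootstrap_result`: `statistics` (labels),
#'   `point` (estimates on the full sample), `replicates` (B x m matrix,
#'   failed rows NA), `lower`, `upper`, `prop_zero`, `B`, `seed`,
#'   `n_failed`, `level`.
#' @export
nonparametric_bootstrap <- function(data, estimator, B = 1000, seed = 1,
                                    level = 0.95) {
  stopifnot(B >= 2)
  x <- as.matrix(data)
  n <- nrow(x)
  point <- estimator(x)
  if (is.null(names(point))) {
    names(point) <- paste0("stat", seq_along(point))
  }
  m <- length(point)
  reps <- matrix(NA_real_, B, m, dimnames = list(NULL, names(point)))
  set.seed(seed)
  n_failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    val <- tryCatch(estimator(x[idx, , drop = FALSE]), error = function(e) NULL)
    if (is.null(val) || length(val) != m) {
      n_failed <- n_failed + 1L
    } else {
      reps[b, ] <- val
    }
  }
  if (n_failed > 0.05 * B) {
    stop(sprintf("%d of %d bootstrap replicates failed (> 5%% tolerated)",
                 n_failed, B), call. = FALSE)
  }
  alpha <- 1 - level
  ok <- stats::complete.cases(reps)
  lower <- apply(reps[ok, , drop = FALSE], 2, stats::quantile,
                 probs = alpha / 2, type = 7)
  upper <- apply(reps[ok, , drop = FALSE], 2, stats::quantile,
                 probs = 1 - alpha / 2, type = 7)
  structure(list(statistics = names(point), point = point, replicates = reps,
                 lower = lower, upper = upper,
                 prop_zero = colMeans(reps[ok, , drop = FALSE] == 0),
                 B = B, seed = seed, n_failed = n_failed, level = level),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Nonparametric bootstrap: %d statistics, B = %d (%d failed), seed = %d\n",
              length(x$statistics), x$B, x$n_failed, x$seed))
  df <- data.frame(statistic = x$statistics, point = x$point,
                   lower = x$lower, upper = x$upper,
                   prop_zero = x$prop_zero, row.names = NULL)
  print(utils::head(df, 20), digits = 3)
  if (nrow(df) > 20) cat(sprintf("... and %d more\n", nrow(df) - 20))
  invisible(x)
}

#' Paired bootstrap difference test between two statistics
#'
#' Forms the per-replicate difference `stat_a - stat_b` over the shared
#' resamples of a [nonparametric_bootstrap()] run and builds the
#' `(alpha/2, 1 - alpha/2)` empirical quantile interval around it. The
#' difference is deemed significant when zero lies outside the interval.
#' Pairing is essential: both statistics must come from the same bootstrap
#' object so each difference compares the same resample.
#'
#' @param boot A `bootstrap_result` containing both labels.
#' @param stat_a,stat_b Statistic labels to compare.
#' @param alpha Significance level; default 0.05.
#' @return List with `difference` (point estimate), `lower`, `upper`,
#'   `significant`, `alpha`.
#' @export
bootstrap_difference_test <- function(boot, stat_a, stat_b, alpha = 0.05) {
  stopifnot(inherits(boot, "bootstrap_result"))
  miss <- setdiff(c(stat_a, stat_b), boot$statistics)
  if (length(miss) > 0) {
    stop(sprintf("statistic '%s' not present in the bootstrap result; both ",
                 miss[1]), "statistics must come from the same (paired) run",
         call. = FALSE)
  }
  d <- boot$replicates[, stat_a] - boot$replicates[, stat_b]
  d <- d[!is.na(d)]
  lo <- unname(stats::quantile(d, alpha / 2, type = 7))
  hi <- unname(stats::quantile(d, 1 - alpha / 2, type = 7))
  list(difference = unname(boot$point[stat_a] - boot$point[stat_b]),
       lower = lo, upper = hi,
       significant = (0 < lo) || (0 > hi),
       alpha = alpha)
}

#' Case-dropping correlation-stability analysis
#'
#' Quantifies how stable a per-node statistic (typically in- or outstrength
#' of a re-estimated relative-importance network) is when participants are
#' dropped. For each proportion `q` in `grid`, `B` subsamples of
#' `ceiling((1 - q) * n)` rows are drawn without replacement, the statistic
#' is re-estimated on each, and its Pearson correlation with the full-sample
#' statistic (across nodes) is recorded. The correlation-stability (CS)
#' coefficient is the largest `q` at which at least `certainty` of the
#' correlations are `>= r_threshold` (equivalently, the `1 - certainty`
#' empirical quantile of the correlations reaches the threshold), or 0 if no
#' grid value qualifies.
#'
#' @param data Participants-by-variables matrix or data frame.
#' @param stat_fn Function mapping a data matrix to a numeric vector (one
#'   statistic) or a matrix/data frame with one column per statistic family
#'   (e.g. columns `outstrength` and `instrength`, rows = nodes); each column
#'   gets its own stability curve and CS value.
#' @param grid Drop proportions in (0, 1); default `0.1, 0.2, ..., 0.7, 0.75`.
#' @param B Subsamples per proportion; default 100.
#' @param r_threshold Correlation the subsample statistic must retain;
#'   default 0.7.
#' @param certainty Required certainty; default 0.95.
#' @param seed Integer seed for all subsampling.
#' @return Object of class `cs_result`: `grid`, `correlations` (list, per
#'   proportion a B x n-measure matrix, NA where re-estimation failed or the
#'   proportion was infeasible), `cs` (named per measure), `r_threshold`,
#'   `certainty`, `B`, `seed`, `infeasible` (grid values with too few rows).
#' @export
case_dropping_cs <- function(data, stat_fn, grid = c(seq(0.1, 0.7, by = 0.1), 0.75),
                             B = 100, r_threshold = 0.7, certainty = 0.95,
                             seed = 1) {
  stopifnot(all(grid > 0 & grid < 1), B >= 2)
  grid <- sort(unique(grid))
  x <- as.matrix(data)
  n <- nrow(x)
  p <- ncol(x)
  as_stat_matrix <- function(v) {
    if (is.null(dim(v))) v <- matrix(v, ncol = 1,
                                     dimnames = list(NULL, "statistic"))
    as.matrix(v)
  }
  full <- as_stat_matrix(stat_fn(x))
  measures <- colnames(full)
  cors <- lapply(grid, function(q) {
    matrix(NA_real_, B, length(measures), dimnames = list(NULL, measures))
  })
  names(cors) <- format(grid)
  infeasible <- numeric(0)
  set.seed(seed)
  for (gi in seq_along(grid)) {
    m <- ceiling((1 - grid[gi]) * n)
    if (m <= p) {
      infeasible <- c(infeasible, grid[gi])
      next
    }
    for (b in seq_len(B)) {
      idx <- sample.int(n, m, replace = FALSE)
      sub <- tryCatch(as_stat_matrix(stat_fn(x[idx, , drop = FALSE])),
                      error = function(e) NULL)
      if (is.null(sub)) next
      for (mm in seq_along(measures)) {
        if (stats::sd(sub[, mm]) > 0 && stats::sd(full[, mm]) > 0) {
          cors[[gi]][b, mm] <- stats::cor(full[, mm], sub[, mm])
        }
      }
    }
  }
  cs <- vapply(measures, function(mm) {
    best <- 0
    for (gi in seq_along(grid)) {
      if (grid[gi] %in% infeasible) next
      v <- cors[[gi]][, mm]
      v <- v[!is.na(v)]
      if (length(v) < 0.95 * B) next
      if (stats::quantile(v, 1 - certainty, type = 7) >= r_threshold) {
        best <- max(best, grid[gi])
      }
    }
    best
  }, numeric(1))
  structure(list(grid = grid, correlations = cors, cs = cs,
                 r_threshold = r_threshold, certainty = certainty, B = B,
                 seed = seed, infeasible = infeasible),
            class = "cs_result")
}

#' @export
print.cs_result <- function(x, ...) {
  cat(sprintf("Case-dropping stability (B = %d per proportion, threshold r >= %g at %g%% certainty)\n",
              x$B, x$r_threshold, 100 * x$certainty))
  for (mm in names(x$cs)) {
    cat(sprintf("  CS(%s) = %g\n", mm, x$cs[[mm]]))
  }
  invisible(x)
}
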