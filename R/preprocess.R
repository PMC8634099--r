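#' Robust MAD-based outlier mask
#'
#' Flags observations whose distance from the median exceeds `threshold`
#' robust standard deviations, where the robust scale is the median absolute
#' deviation times the normal-consistency constant 1.4826. Used to strip
#' gross outliers from the heavily skewed physical-activity variable before
#' network estimation.
#'
#' @param x Numeric vector, length >= 3.
#' @param threshold Cutoff in robust SD units; default 2.5. Two-sided.
#' @return Logical keep-mask: `TRUE` for observations to retain. The robust
#'   center and scale are attached as attributes `center` and `scale`.
#' @examples
#' mad_outlier_mask(c(1:9, 100))  # drops only the 100
#' @export
mad_outlier_mask <- function(x, threshold = 2.5) {
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x)) stop("missing values in x", call. = FALSE)
  stopifnot(is.numeric(threshold), length(threshold) == 1, threshold > 0)
  ctr <- stats::median(x)
  sc <- 1.4826 * stats::median(abs(x - ctr))
  if (sc == 0) {
    if (all(x == x[1])) {
      keep <- rep(TRUE, length(x))
      attr(keep, "center") <- ctr
      attr(keep, "scale") <- 0
      return(keep)
    }
    stop("MAD is zero for a non-constant vector; robust scale undefined",
         call. = FALSE)
  }
  keep <- abs(x - ctr) / sc <= threshold
  attr(keep, "center") <- ctr
  attr(keep, "scale") <- sc
  keep
}

#' Drop participants with outlying values on one variable
#'
#' Applies [mad_outlier_mask()] to a single column and removes flagged rows,
#' mirroring the pre-estimation exclusion step: the filter acts on the
#' physical-activity score only, but whole participants are dropped.
#'
#' @param data Numeric matrix or data frame of scale scores (participants in
#'   rows, named columns).
#' @param variable Column to screen; default `"PHY"`.
#' @param threshold Passed to [mad_outlier_mask()].
#' @return List with `data` (filtered), `report` (kept/dropped row ids,
#'   threshold, robust center and scale, counts before/after).
#' @export
filter_outliers <- function(data, variable = "PHY", threshold = 2.5) {
  x <- as.matrix(data)
  if (!variable %in% colnames(x)) {
    stop(sprintf("variable '%s' not found in data", variable), call. = FALSE)
  }
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  keep <- mad_outlier_mask(x[, variable], threshold = threshold)
  list(
    data = x[keep, , drop = FALSE],
    report = list(
      variable = variable,
      threshold = threshold,
      center = attr(keep, "center"),
      scale = attr(keep, "scale"),
      n_before = nrow(x),
      n_after = sum(keep),
      kept_ids = ids[keep],
      dropped_ids = ids[!keep]
    )
  )
}

#' Per-variable descriptive statistics
#'
#' Mean, sample standard deviation (n-1 denominator), minimum and maximum for
#' each column, in column order.
#'
#' @param data Numeric matrix or data frame, participants in rows.
#' @return Data frame with columns `variable`, `mean`, `sd`, `min`, `max`.
#' @export
describe_variables <- function(data) {
  x <- as.matrix(data)
  if (nrow(x) < 2) stop("need at least 2 rows for descriptives", call. = FALSE)
  data.frame(
    variable = colnames(x),
    mean = colMeans(x),
    sd = apply(x, 2, stats::sd),
    min = apply(x, 2, min),
    max = apply(x, 2, max),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
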