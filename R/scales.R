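#' Facet layout of the WHOQOL-OLD
#'
#' The 24 items are grouped four per facet, in the fixed order sensory
#' abilities (SAB), autonomy (AUT), past/present/future activities (PPF),
#' social participation (SOP), death and dying (DAD), intimacy (INT).
#' @keywords internal
whoqol_facets <- function() {
  c("SAB", "AUT", "PPF", "SOP", "DAD", "INT")
}

#' Default reverse-scored WHOQOL-OLD items
#'
#' All four death-and-dying items are negatively keyed and must be reversed
#' before summation; so are the negatively phrased sensory-impairment items of
#' the first facet and the first (restriction-of-freedom) item of the autonomy
#' facet. The instrument manual is the authority for a given translation, so
#' the set is an argument of [score_whoqol()] rather than a constant.
#'
#' @return Integer vector of item positions (in the fixed facet-grouped
#'   ordering) that are reverse-coded by default.
#' @export
whoqol_default_reverse_items <- function() {
  c(1L, 2L, 3L, 5L, 17L, 18L, 19L, 20L)
}

check_items <- function(items, n_items, lo, hi, instrument) {
  if (length(items) != n_items) {
    stop(sprintf("%s expects %d items, got %d", instrument, n_items,
                 length(items)), call. = FALSE)
  }
  if (anyNA(items)) {
    stop(sprintf("%s items contain missing values (item %d)", instrument,
                 which(is.na(items))[1]), call. = FALSE)
  }
  bad <- which(items < lo | items > hi | items != round(items))
  if (length(bad) > 0) {
    stop(sprintf("%s item %d has value %s outside %d..%d", instrument,
                 bad[1], format(items[bad[1]]), lo, hi), call. = FALSE)
  }
  invisible(items)
}

#' Score the WHOQOL-OLD quality-of-life instrument
#'
#' Reverse-codes the negatively keyed items (`x -> 6 - x` on the 1-5 response
#' scale), sums four items per facet, and sums the six facets into the total
#' quality-of-life score. Facet scores range 4-20 and the total 24-120; higher
#' is better.
#'
#' @param items Integer vector of 24 raw responses in 1..5, facet-grouped in
#'   the order SAB, AUT, PPF, SOP, DAD, INT (four items each). A matrix with
#'   24 columns scores one participant per row.
#' @param reverse_items Item positions to reverse-code before summation.
#' @return Named numeric vector with the six facet scores and `QoL` total
#'   (or a data frame of such rows for matrix input).
#' @examples
#' score_whoqol(rep(4, 24))
#' @export
score_whoqol <- function(items, reverse_items = whoqol_default_reverse_items()) {
  if (is.matrix(items) || is.data.frame(items)) {
    out <- t(apply(as.matrix(items), 1, score_whoqol,
                   reverse_items = reverse_items))
    return(as.data.frame(out))
  }
  items <- as.numeric(items)
  check_items(items, 24L, 1L, 5L, "WHOQOL-OLD")
  if (length(reverse_items) > 0) {
    stopifnot(all(reverse_items %in% 1:24))
    items[reverse_items] <- 6 - items[reverse_items]
  }
  facets <- vapply(seq_len(6), function(f) sum(items[(4 * f - 3):(4 * f)]),
                   numeric(1))
  names(facets) <- whoqol_facets()
  c(facets, QoL = sum(facets))
}

#' Default SMAS-18 item option counts
#'
#' Three items per facet in the order INI, INV, PFM, VAR, MUL, SEF.
#' Initiative, investment, positive-frame-of-mind and variety items have six
#' response options; multifunctionality has five. The self-efficacy items are
#' treated as six options (their printed anchors run from 0 to 5); the count
#' is data, not code, so a deviating administration can override it.
#'
#' @return Integer vector of length 18 giving each item's number of options.
#' @export
smas_default_options <- function() {
  rep(c(INI = 6L, INV = 6L, PFM = 6L, VAR = 6L, MUL = 5L, SEF = 6L),
      each = 3L)
}

smas_facets <- function() c("INI", "INV", "PFM", "VAR", "MUL", "SEF")

#' Score the SMAS-18 self-management ability scale
#'
#' Raw responses (1..options) are recoded to start at zero, rescaled so each
#' item spans 0-20 (six-option items x4, five-option items x5), facet scores
#' are five times the mean of their three items (range 0-100), and the total
#' is the mean of the six facet scores.
#'
#' @param items Integer vector of 18 raw responses, facet-grouped in the order
#'   INI, INV, PFM, VAR, MUL, SEF; or a matrix with 18 columns.
#' @param option_counts Number of response options per item (5 or 6).
#' @return Named numeric vector of six facet scores plus `SMA` total, each in
#'   0..100 (or a data frame for matrix input).
#' @examples
#' score_smas(rep(6, 18), option_counts = rep(6, 18))
#' @export
score_smas <- function(items, option_counts = smas_default_options()) {
  if (is.matrix(items) || is.data.frame(items)) {
    out <- t(apply(as.matrix(items), 1, score_smas,
                   option_counts = option_counts))
    return(as.data.frame(out))
  }
  items <- as.numeric(items)
  if (length(items) != 18L) {
    stop(sprintf("SMAS-18 expects 18 items, got %d", length(items)),
         call. = FALSE)
  }
  stopifnot(length(option_counts) == 18L, all(option_counts %in% c(5L, 6L)))
  bad <- which(items < 1 | items > option_counts | items != round(items))
  if (length(bad) > 0) {
    stop(sprintf("SMAS item %d has value %s outside 1..%d", bad[1],
                 format(items[bad[1]]), option_counts[bad[1]]), call. = FALSE)
  }
  item20 <- (items - 1) * ifelse(option_counts == 6L, 4, 5)
  facets <- vapply(seq_len(6), function(f) {
    5 * mean(item20[(3 * f - 2):(3 * f)])
  }, numeric(1))
  names(facets) <- smas_facets()
  c(facets, SMA = mean(facets))
}

#' Score the behavioral coping scale
#'
#' Plain sum of the eight 4-point items, giving a total in 8..32.
#'
#' @param items Integer vector of 8 responses in 1..4, or a matrix with 8
#'   columns.
#' @return Scalar total (or numeric vector for matrix input).
#' @examples
#' score_bcs(c(2, 3, 2, 3, 2, 3, 2, 3))
#' @export
score_bcs <- function(items) {
  if (is.matrix(items) || is.data.frame(items)) {
    return(apply(as.matrix(items), 1, score_bcs))
  }
  items <- as.numeric(items)
  check_items(items, 8L, 1L, 4L, "BCS")
  sum(items)
}

#' Score the positive appraisal style scale
#'
#' Each of the 14 items (mixed 4- and 5-point scales) is z-standardized over
#' the scoring sample; a participant's score is the mean of their 14 z-values.
#' The per-item means and standard deviations are returned so that later
#' participants can be scored on the same scale with [apply_pass_norms()].
#'
#' @param item_matrix Numeric matrix, participants in rows, 14 item columns.
#' @return List with `scores` (numeric, mean exactly 0 over the sample),
#'   `item_means` and `item_sds` (the normalization constants, sample SD with
#'   n-1 denominator).
#' @export
score_pass <- function(item_matrix) {
  x <- as.matrix(item_matrix)
  if (ncol(x) != 14L) {
    stop(sprintf("PASS expects 14 item columns, got %d", ncol(x)),
         call. = FALSE)
  }
  if (nrow(x) < 2L) stop("PASS scoring needs at least 2 participants",
                         call. = FALSE)
  if (anyNA(x)) stop("PASS items contain missing values", call. = FALSE)
  m <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  if (any(s == 0)) {
    stop(sprintf("PASS item column %d is constant; z-scores undefined",
                 which(s == 0)[1]), call. = FALSE)
  }
  z <- sweep(sweep(x, 2, m, "-"), 2, s, "/")
  list(scores = rowMeans(z), item_means = m, item_sds = s)
}

#' Score new participants with stored PASS normalization constants
#'
#' @param item_matrix Numeric matrix with 14 item columns.
#' @param norms A list with `item_means` and `item_sds`, as returned by
#'   [score_pass()].
#' @return Numeric vector of scores on the original sample's z-scale.
#' @export
apply_pass_norms <- function(item_matrix, norms) {
  x <- as.matrix(item_matrix)
  stopifnot(ncol(x) == 14L, length(norms$item_means) == 14L,
            length(norms$item_sds) == 14L)
  z <- sweep(sweep(x, 2, norms$item_means, "-"), 2, norms$item_sds, "/")
  rowMeans(z)
}

#' MET-weighted physical activity score
#'
#' Weekly minutes of light-to-moderate activity are weighted by an average
#' MET value of 3.75 and vigorous minutes by 6, summed, and multiplied by a
#' wheelchair correction factor (none = 1, normal = 0.8, mechanical = 0.5).
#' Units are MET-minutes per week.
#'
#' @param light_minutes,vigorous_minutes Nonnegative past-week durations in
#'   minutes. Vectorized.
#' @param wheelchair One of `"none"`, `"normal"`, `"mechanical"` (recycled).
#' @return Nonnegative score(s).
#' @examples
#' score_phy(480, 150)           # 2700
#' score_phy(480, 150, "mechanical")  # 1350
#' @export
score_phy <- function(light_minutes, vigorous_minutes, wheelchair = "none") {
  if (any(light_minutes < 0) || any(vigorous_minutes < 0)) {
    stop("activity durations must be nonnegative", call. = FALSE)
  }
  factors <- c(none = 1, normal = 0.8, mechanical = 0.5)
  wheelchair <- match.arg(wheelchair, names(factors), several.ok = TRUE)
  (3.75 * light_minutes + 6 * vigorous_minutes) *
    unname(factors[rep_len(wheelchair, max(length(light_minutes),
                                           length(vigorous_minutes)))])
}

#' Average policy stringency over participation days
#'
#' Participation could span several days; the participant-level stringency
#' index is the arithmetic mean of the daily values (0-100 scale).
#'
#' @param daily_values Numeric vector of daily stringency-index values.
#' @return Scalar mean.
#' @export
average_si <- function(daily_values) {
  if (length(daily_values) == 0) {
    stop("at least one daily stringency value is required", call. = FALSE)
  }
  if (any(daily_values < 0 | daily_values > 100)) {
    stop("stringency values must lie in 0..100", call. = FALSE)
  }
  mean(daily_values)
}
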