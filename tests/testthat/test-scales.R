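test_that("WHOQOL-OLD scoring hits its bounds and applies reversal", {
  # maximum after reverse coding: reversed items answered 1, others 5
  hi <- rep(5, 24)
  hi[whoqol_default_reverse_items()] <- 1
  s <- score_whoqol(hi)
  expect_equal(unname(s[whoqol_facets()]), rep(20, 6))
  expect_equal(unname(s["QoL"]), 120)

  lo <- rep(1, 24)
  lo[whoqol_default_reverse_items()] <- 5
  s <- score_whoqol(lo)
  expect_equal(unname(s[whoqol_facets()]), rep(4, 6))
  expect_equal(unname(s["QoL"]), 24)

  # DAD facet (items 17-20, all reversed): raw 4s become 2s, summing to 8
  items <- rep(3, 24)
  items[17:20] <- 4
  expect_equal(unname(score_whoqol(items, reverse_items = 17:20)["DAD"]), 8)
})

test_that("WHOQOL-OLD scoring is monotone in post-reversal responses", {
  set.seed(11)
  for (rep_i in 1:20) {
    items <- sample(1:5, 24, replace = TRUE)
    s0 <- score_whoqol(items, reverse_items = integer(0))
    j <- sample(which(items < 5), 1)
    items2 <- items
    items2[j] <- items2[j] + 1
    s1 <- score_whoqol(items2, reverse_items = integer(0))
    expect_true(all(s1 >= s0))
  }
})

test_that("WHOQOL-OLD scoring rejects malformed input with the item index", {
  expect_error(score_whoqol(rep(3, 23)), "24 items")
  bad <- rep(3, 24); bad[7] <- 6
  expect_error(score_whoqol(bad), "item 7")
})

test_that("SMAS-18 scoring follows the recode-rescale-average rule", {
  opts <- smas_default_options()
  expect_equal(unname(score_smas(opts, option_counts = opts)),
               rep(100, 7), tolerance = 1e-12)
  expect_equal(unname(score_smas(rep(1, 18), option_counts = opts)),
               rep(0, 7))
  # a six-option facet answered (4,5,6): recoded (3,4,5) x4 = (12,16,20),
  # mean 16, facet 5*16 = 80
  items <- rep(1, 18)
  items[1:3] <- c(4, 5, 6)
  expect_equal(unname(score_smas(items, option_counts = opts)["INI"]), 80)
  # total is the mean of the six facet scores
  s <- score_smas(items, option_counts = opts)
  expect_equal(unname(s["SMA"]), mean(s[smas_facets()]))
  expect_error(score_smas(rep(1, 17)), "18 items")
  bad <- rep(1, 18); bad[14] <- 6  # MUL items have five options
  expect_error(score_smas(bad), "item 14")
})

test_that("behavioral coping scale is a plain bounded sum", {
  expect_equal(score_bcs(rep(1, 8)), 8)
  expect_equal(score_bcs(rep(4, 8)), 32)
  expect_equal(score_bcs(c(2, 3, 2, 3, 2, 3, 2, 3)), 20)
  expect_error(score_bcs(rep(5, 8)), "item 1")
})

test_that("PASS scores are sample z-means with reusable norms", {
  set.seed(3)
  x <- matrix(sample(1:5, 20 * 14, replace = TRUE), 20, 14)
  res <- score_pass(x)
  expect_equal(mean(res$scores), 0, tolerance = 1e-10)
  # participant sitting at every item mean scores exactly zero
  xm <- rbind(x, colMeans(x))
  expect_equal(unname(score_pass(xm)$scores[21]),
               0, tolerance = 1e-10)
  # two participants: symmetric scores summing to zero
  res2 <- score_pass(matrix(c(1, 3, 2, 4, 1, 5, 2, 3, 1, 4, 2, 5, 1, 3,
                              3, 1, 4, 2, 5, 1, 3, 2, 4, 1, 5, 2, 3, 1),
                            2, 14, byrow = TRUE))
  expect_equal(sum(res2$scores), 0, tolerance = 1e-12)
  expect_equal(res2$scores[1], -res2$scores[2], tolerance = 1e-12)
  # hand z-normalization oracle on a small matrix (first 3 columns checked
  # by explicit arithmetic, remaining columns constant-free filler)
  toy <- cbind(c(1, 2, 3), c(2, 2, 5), c(0, 4, 2),
               matrix(rep(c(1, 2, 3), 11), 3, 11))
  manual_z <- apply(toy, 2, function(col) (col - mean(col)) / sd(col))
  expect_equal(score_pass(toy)$scores, rowMeans(manual_z), tolerance = 1e-12)
  # norms reproduce in-sample scores on new data
  expect_equal(apply_pass_norms(x, res), res$scores, tolerance = 1e-12)
  xc <- x; xc[, 5] <- 3
  expect_error(score_pass(xc), "column 5")
  expect_error(score_pass(x[1, , drop = FALSE]), "at least 2")
})

test_that("MET-weighted activity scoring uses the stated weights and factors", {
  expect_equal(score_phy(0, 0), 0)
  expect_equal(score_phy(480, 150), 3.75 * 480 + 6 * 150)  # 2700
  expect_equal(score_phy(480, 150, "mechanical"), 2700 * 0.5)
  expect_equal(score_phy(480, 150, "normal"), 2700 * 0.8)
  expect_error(score_phy(-1, 0), "nonnegative")
})

test_that("stringency index averages participation days", {
  expect_equal(average_si(65.9), 65.9)
  expect_equal(average_si(c(60, 70)), 65)
  expect_equal(average_si(c(56.48, 82.41, 65.9)),
               (56.48 + 82.41 + 65.9) / 3)
  expect_error(average_si(numeric(0)), "at least one")
})

test_that("scoring the synthetic item-level output reproduces its scores", {
  gen <- generate_item_responses(n = 60, seed = 9)
  rescored <- cbind(
    score_whoqol(gen$items$whoqol),
    score_smas(gen$items$smas),
    BC = score_bcs(gen$items$bcs),
    PAS = score_pass(gen$items$pass)$scores
  )
  expect_equal(as.matrix(rescored), as.matrix(gen$scores))
  # and all scores respect the instruments' possible ranges
  sc <- gen$scores
  expect_true(all(sc$QoL >= 24 & sc$QoL <= 120))
  expect_true(all(sc$QoL == sc$SAB + sc$AUT + sc$PPF + sc$SOP +
                    sc$DAD + sc$INT))
  expect_true(all(sc$SMA >= 0 & sc$SMA <= 100))
  expect_true(all(sc$BC >= 8 & sc$BC <= 32))
})
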