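make_counts <- function(mat, ids = sprintf("D%02d", seq_len(nrow(mat)))) {
  colnames(mat) <- behavior_names_for_test()
  data.frame(driver_id = ids, mat, exposure_hours = 560, check.names = FALSE)
}

test_that("an all-identical cohort collapses to one class everywhere and index 6", {
  counts <- make_counts(matrix(5, nrow = 12, ncol = 6))
  sch <- build_scheme(counts)
  expect_true(all(sch$profiles$risk_index == 6))
  expect_true(all(sch$profiles$risk_level == 1))
  expect_true(all(as.matrix(sch$profiles[behavior_names_for_test()]) == 1))
})

test_that("planted four-group structure is recovered with high GVF", {
  set.seed(88)
  centers <- c(5, 60, 150, 300)
  for (rep in 1:5) {
    grp <- sample(rep(1:4, each = 10))
    mat <- sapply(1:6, function(b) rpois(40, centers[grp]))
    sch <- build_scheme(make_counts(mat))
    expect_true(all(sch$behavior_gvf > 0.7))
    for (b in behavior_names_for_test()) {
      bd <- sch$behavior_boundaries[[b]]
      # each fitted class interval brackets its planted group mean
      expect_true(all(bd$lower <= centers & centers <= bd$upper))
      expect_equal(nrow(bd), 4)
    }
  }
})

test_that("per-class tallies and percentages conserve the cohort", {
  set.seed(2)
  mat <- sapply(1:6, function(b) rnbinom(40, size = 1, mu = c(1676, 143, 11, 6, 573, 35)[b]))
  sch <- build_scheme(make_counts(mat))
  expect_true(all(colSums(sch$class_tally) == 40))
  expect_true(all(abs(colSums(sch$class_pct) - 100) < 1e-9))
  expect_equal(sum(sch$level_tally), 40)
  expect_equal(sch$level_pct, sch$level_tally / 40 * 100)
})

test_that("an all-minimal driver scores the index floor of 6", {
  set.seed(13)
  mat <- sapply(1:6, function(b) rnbinom(40, size = 1, mu = c(1676, 143, 11, 6, 573, 35)[b]))
  sch <- build_scheme(make_counts(mat))
  prof <- classify_driver(setNames(rep(0, 6), behavior_names_for_test()), sch)
  expect_equal(prof$risk_index, 6L)
  expect_equal(unname(prof$behavior_class), rep(1L, 6))
  expect_equal(prof$risk_level, 1L)
})

test_that("class upper boundaries are inclusive and gaps split at the midpoint", {
  set.seed(41)
  mat <- sapply(1:6, function(b) sample(c(0:10, 50:60, 200:210, 500:510), 40, TRUE))
  sch <- build_scheme(make_counts(mat))
  bd <- sch$behavior_boundaries[[1]]
  # value exactly on an upper boundary stays in that class
  for (cl in 1:4) {
    v <- rep(0, 6); v[1] <- bd$upper[cl]
    expect_equal(unname(classify_driver(setNames(v, behavior_names_for_test()),
                                        sch)$behavior_class[1]), cl)
  }
  # out-of-sample gap values: naive nearest-boundary-midpoint oracle
  for (rep in 1:100) {
    cl <- sample(1:3, 1)
    lo <- bd$upper[cl]; hi <- bd$lower[cl + 1]
    if (hi - lo < 2) next
    g <- runif(1, lo + 1e-6, hi - 1e-6)
    want <- if (abs(g - lo) <= abs(g - hi)) cl else cl + 1L
    v <- rep(0, 6); v[1] <- g
    expect_equal(unname(classify_driver(setNames(v, behavior_names_for_test()),
                                        sch)$behavior_class[1]), want)
  }
  # beyond the extremes: clamp to classes 1 and 4
  v <- rep(0, 6); v[1] <- max(bd$upper) + 1e6
  expect_equal(unname(classify_driver(setNames(v, behavior_names_for_test()),
                                      sch)$behavior_class[1]), 4L)
})

test_that("the risk index is monotone in any single behavior count", {
  set.seed(19)
  mat <- sapply(1:6, function(b) rnbinom(30, size = 1, mu = 50))
  sch <- build_scheme(make_counts(mat))
  base <- setNames(c(10, 10, 10, 10, 10, 10), behavior_names_for_test())
  i0 <- classify_driver(base, sch)$risk_index
  for (b in 1:6) {
    for (bump in c(5, 50, 500)) {
      v <- base; v[b] <- v[b] + bump
      expect_gte(classify_driver(v, sch)$risk_index, i0)
    }
  }
})

test_that("negative counts are refused", {
  mat <- sapply(1:6, function(b) rpois(20, 20))
  sch <- build_scheme(make_counts(mat))
  expect_error(classify_driver(setNames(c(-1, 0, 0, 0, 0, 0),
                                        behavior_names_for_test()), sch),
               "non-negative")
})

test_that("cohort summary reproduces published averages and a naive recomputation", {
  ref <- reference_tables()$behavior_totals
  # totals over 40 drivers: put the full total on one driver, zeros elsewhere
  mat <- matrix(0, 40, 6); mat[1, ] <- ref$total
  cs <- cohort_summary(make_counts(mat))
  expect_equal(cs$average, ref$average)

  set.seed(6)
  mat2 <- sapply(1:6, function(b) rpois(17, 30))
  cs2 <- cohort_summary(make_counts(mat2))
  expect_equal(cs2$total, colSums(mat2), ignore_attr = TRUE)
  expect_equal(cs2$average_raw, colMeans(mat2), ignore_attr = TRUE)
  expect_equal(cs2$min, apply(mat2, 2, min), ignore_attr = TRUE)
  expect_equal(cs2$max, apply(mat2, 2, max), ignore_attr = TRUE)

  one <- cohort_summary(make_counts(mat2[1, , drop = FALSE]))
  expect_equal(one$total, one$average_raw)
  expect_equal(one$min, one$max)
})

test_that("correlation screening matches the textbook formula and flags significance", {
  set.seed(77)
  n <- 10
  tr <- as.data.frame(matrix(runif(n * 5, 1, 5), n, 5))
  names(tr) <- trait_names_for_test()
  ct <- as.data.frame(matrix(rpois(n * 6, 30), n, 6))
  names(ct) <- behavior_names_for_test()
  scr <- correlation_screen(tr, ct)
  x <- tr$neuroticism; y <- ct$abnormal_stay
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(scr$trait_behavior$r["neuroticism", "abnormal_stay"], r_hand,
               tolerance = 1e-12)
  p_ref <- cor.test(x, y)$p.value
  expect_equal(scr$trait_behavior$p["neuroticism", "abnormal_stay"], p_ref,
               tolerance = 1e-9)

  # identical and anti-correlated columns
  ct$exceeding_speed_limit <- tr$neuroticism
  ct$hard_acceleration <- -tr$neuroticism
  scr2 <- correlation_screen(tr, ct)
  expect_equal(scr2$trait_behavior$r["neuroticism", "exceeding_speed_limit"], 1)
  expect_equal(scr2$trait_behavior$r["neuroticism", "hard_acceleration"], -1)
  expect_equal(scr2$trait_behavior$flags["neuroticism", "exceeding_speed_limit"], "**")

  # zero-variance column: undefined, not an error
  ct$driving_overtime <- 0
  scr3 <- correlation_screen(tr, ct)
  expect_true(is.na(scr3$trait_behavior$r["neuroticism", "driving_overtime"]))
})
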