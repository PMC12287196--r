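test_that("neutral filtering keeps the closed vote window [-0.5, 0.5]", {
  s <- data.frame(tsv = c(-1, -0.5, 0, 0.5, 2), x = 1:5)
  kept <- filter_neutral(s)
  expect_equal(kept$tsv, c(-0.5, 0, 0.5)) # bounds inclusive
  all0 <- data.frame(tsv = rep(0, 4), x = 1:4)
  expect_equal(nrow(filter_neutral(all0)), 4)
  expect_warning(filter_neutral(data.frame(tsv = c(2, 3))), "no thermally neutral")
  expect_error(filter_neutral(data.frame(tsv = 5)), "nine-point")
})

test_that("a generated series keeps roughly its planted neutral fraction", {
  tr <- data.frame(segment = "chest", lo = 33, hi = 34)
  s <- gen_skin_series(tr, n_samples = 2000, neutral_fraction = 0.6, seed = 8)
  p <- nrow(filter_neutral(s)) / nrow(s)
  expect_equal(p, 0.6, tolerance = 0.05)
})

test_that("interquartile ranges use the linear-interpolation convention", {
  r <- iqr_range(c(1, 2, 3, 4, 5))
  expect_equal(c(r$lo, r$hi), c(2, 4))
  rc <- iqr_range(rep(33.1, 6))
  expect_equal(c(rc$lo, rc$hi), c(33.1, 33.1)) # degenerate
  set.seed(4)
  x <- rnorm(50, 34, 0.5)
  r1 <- iqr_range(x)
  r2 <- iqr_range(sample(x)) # permutation invariant
  expect_equal(c(r1$lo, r1$hi), c(r2$lo, r2$hi))
  expect_error(iqr_range(c(1, 2, 3)), "at least 4")
})

test_that("interval Jaccard matches hand-computed overlaps", {
  expect_equal(jaccard(temp_range(30, 32), temp_range(30, 32)), 1)
  expect_equal(jaccard(temp_range(30, 31), temp_range(32, 33)), 0)
  expect_equal(jaccard(temp_range(1, 3), temp_range(2, 4)), 1 / 3)
  # degenerate conventions
  expect_equal(jaccard(temp_range(30, 30), temp_range(30, 30)), 1)
  expect_equal(jaccard(temp_range(30, 30), temp_range(31, 31)), 0)
  expect_equal(jaccard(temp_range(30, 30), temp_range(29, 31)), 0)
})

test_that("interval Jaccard is symmetric, translation-invariant, and 1 iff equal", {
  set.seed(31)
  for (i in 1:100) {
    a <- temp_range(lo <- runif(1, 25, 35), lo + runif(1, 0, 4))
    b <- temp_range(lo2 <- runif(1, 25, 35), lo2 + runif(1, 0, 4))
    j <- jaccard(a, b)
    expect_gte(j, 0); expect_lte(j, 1)
    expect_equal(jaccard(b, a), j)
    dl <- runif(1, -3, 3)
    expect_equal(jaccard(temp_range(a$lo + dl, a$hi + dl),
                         temp_range(b$lo + dl, b$hi + dl)), j)
    if (j == 1) expect_equal(c(a$lo, a$hi), c(b$lo, b$hi))
  }
  expect_error(temp_range(2, 1), "lo <= hi")
})

test_that("interval Jaccard agrees with the fine-grid counting oracle", {
  set.seed(17)
  for (i in 1:100) {
    a <- temp_range(lo <- round(runif(1, 25, 38), 3), lo + round(runif(1, 0.5, 5), 3))
    b <- temp_range(lo2 <- round(runif(1, 25, 38), 3), lo2 + round(runif(1, 0.5, 5), 3))
    expect_equal(jaccard(a, b), grid_jaccard(a, b), tolerance = 1e-3)
  }
})

test_that("the JSC report scores variants per segment and on average", {
  mea <- data.frame(segment = c("chest", "back", "arm"),
                    lo = c(33, 33.5, 33), hi = c(34, 34.5, 34))
  perfect <- mea
  disjoint <- data.frame(segment = mea$segment, lo = mea$lo + 10, hi = mea$hi + 10)
  rep_ <- jsc_report(mea, list(A = perfect, B = disjoint))
  expect_equal(rep_$per_segment$A, rep(1, 3))
  expect_equal(rep_$per_segment$B, rep(0, 3))
  expect_equal(unname(rep_$mean), c(1, 0))
  expect_equal(rep_$deltas$delta_mean_jsc, 1)
  # mean lies between min and max of the per-segment values
  shifted <- data.frame(segment = mea$segment, lo = mea$lo + c(0, 0.5, 10),
                        hi = mea$hi + c(0, 0.5, 10))
  rep2 <- jsc_report(mea, list(C = shifted))
  expect_gte(rep2$mean[["C"]], min(rep2$per_segment$C))
  expect_lte(rep2$mean[["C"]], max(rep2$per_segment$C))
  # missing segments are excluded with a warning
  expect_warning(rep3 <- jsc_report(mea, list(D = perfect[1:2, ])),
                 "lacks segment")
  expect_equal(rep3$mean[["D"]], 1)
})

test_that("measured ranges pool neutral samples segment by segment", {
  tr <- data.frame(segment = c("chest", "leg"), lo = c(33, 31), hi = c(34, 32))
  s <- gen_skin_series(tr, n_samples = 4000, neutral_fraction = 0.8,
                       noise_sd = 0, seed = 5)
  mr <- measured_ranges(s)
  expect_equal(mr$segment, c("chest", "leg"))
  # IQR of uniform draws converges to the middle half of the true range
  expect_equal(mr$lo, tr$lo + 0.25 * (tr$hi - tr$lo), tolerance = 0.05)
  expect_equal(mr$hi, tr$hi - 0.25 * (tr$hi - tr$lo), tolerance = 0.05)
})
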