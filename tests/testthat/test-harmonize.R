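test_that("clo/SI conversion uses 0.155 m2K/W per clo and rejects bad input", {
  expect_equal(clo_to_si(1), 0.155)
  expect_equal(clo_to_si(0), 0)
  expect_equal(clo_to_si(2), 0.310)
  expect_equal(si_to_clo(0.155), 1)
  expect_equal(si_to_clo(clo_to_si(1.37)), 1.37)
  expect_error(clo_to_si(-0.1), "non-negative")
  expect_error(si_to_clo(NaN), "finite")
})

test_that("effective insulation plus nude baseline gives the regional total", {
  expect_equal(effective_to_total(0, 0.5), 0.5)
  expect_equal(effective_to_total(0.3, 0.5), 0.8)
  expect_equal(effective_to_total(1.2, 0.45), 1.65)
  expect_error(effective_to_total(-1, 0.5))
})

test_that("local clothing area factor follows 1 + 0.28 I", {
  expect_equal(fcl_from_local(0), 1)
  expect_equal(fcl_from_local(1), 1.28)
  expect_equal(fcl_from_local(0.5), 1.14)
})

test_that("total->local inversion matches the fixed-point oracle", {
  expect_equal(total_to_local(0.5, 0.5), 0)
  expect_equal(total_to_local(1.0, 0.5), 0.5687, tolerance = 1e-3)
  expect_equal(total_to_local(1.0, 0.5), total_to_local_fixed_point(1.0, 0.5),
               tolerance = 1e-9)
  # round-trip at the spec'd example
  x <- total_to_local(1.65, 0.45)
  expect_equal(local_to_total(x, 0.45), 1.65, tolerance = 1e-9)
})

test_that("total->local round-trips and is monotone", {
  set.seed(11)
  for (i in 1:200) {
    x <- runif(1, 0, 3)
    ia <- runif(1, 0.05, 1)
    expect_equal(total_to_local(local_to_total(x, ia), ia), x,
                 tolerance = 1e-9)
  }
  grid <- seq(0.4, 3, by = 0.05)
  vals <- total_to_local(grid, 0.4)
  expect_true(all(diff(vals) >= 0))
  expect_warning(out <- total_to_local(0.3, 0.5), "clipped")
  expect_equal(out, 0)
})

test_that("parallel remapping is the area-weighted harmonic mean", {
  expect_equal(remap_parallel(1, 0.8), 0.8)
  expect_equal(remap_parallel(c(1, 1), c(1, 1)), 1)
  expect_equal(remap_parallel(c(1, 1), c(1, 2)), 4 / 3, tolerance = 1e-4)
  set.seed(7)
  for (i in 1:50) {
    a <- runif(4, 0.1, 2)
    v <- runif(4, 0.2, 2)
    r <- remap_parallel(a, v)
    expect_gte(r, min(v))
    expect_lte(r, max(v))
    expect_equal(remap_parallel(3.7 * a, v), r) # area-rescale invariance
    expect_equal(remap_parallel(a, rep(v[1], 4)), v[1]) # equal values
  }
  expect_error(remap_parallel(c(1, 1), c(1, 0)), "positive")
  expect_error(remap_parallel(c(1, -1), c(1, 1)), "positive")
})

test_that("local-convention ensembles pass through harmonization unchanged", {
  vals <- c(0.13, 0, 0.6, 0.65, 1.1, 0.2, 0.1, 0, 0.62, 0.05, 0.42)
  rec <- make_raw_ensemble("e1", "local", vals, overall = 0.3)
  res <- harmonize_dataset(rec)
  expect_equal(res$log$status, "ok")
  expect_equal(as.numeric(res$ensembles[1, body_segments()]), vals)
  expect_equal(res$ensembles$overall_clo, 0.3)
})

test_that("nude effective ensembles harmonize to all-zero locals", {
  rec <- make_raw_ensemble("nude", "effective_local",
                           values = rep(0, 11), nude = runif(11, 0.4, 0.7))
  res <- harmonize_dataset(rec)
  expect_equal(res$log$status, "ok")
  expect_equal(as.numeric(res$ensembles[1, body_segments()]), rep(0, 11))
})

test_that("forward-simulated ensembles round-trip through harmonization", {
  set.seed(23)
  truth <- runif(11, 0, 2)
  ia <- runif(11, 0.4, 0.7)
  tot <- local_to_total(truth, ia)
  for (conv in c("regional_total", "effective_local")) {
    vals <- if (conv == "regional_total") tot else tot - ia
    rec <- make_raw_ensemble(paste0("rt_", conv), conv, vals, nude = ia)
    res <- harmonize_dataset(rec)
    expect_equal(res$log$status, "ok")
    expect_equal(as.numeric(res$ensembles[1, body_segments()]), truth,
                 tolerance = 1e-6)
  }
})

test_that("left/right segments merge through the area map before conversion", {
  am <- read_area_map()
  set.seed(5)
  truth <- setNames(runif(11, 0.1, 1.5), body_segments())
  ia11 <- setNames(runif(11, 0.4, 0.7), body_segments())
  # identical left/right values: the harmonic mean must return them unchanged
  rec <- data.frame(
    ensemble_id = "lr", posture = "standing", sex = "female",
    segment = am$original_segment, convention = "regional_total",
    value_clo = local_to_total(truth[am$target_segment], ia11[am$target_segment]),
    nude_baseline_clo = ia11[am$target_segment],
    overall_clo = 0.9, stringsAsFactors = FALSE)
  res <- harmonize_dataset(rec, am)
  expect_equal(res$log$status, "ok")
  expect_equal(as.numeric(res$ensembles[1, body_segments()]),
               as.numeric(truth), tolerance = 1e-9)
})

test_that("bad ensembles are rejected individually, not globally", {
  good <- make_raw_ensemble("good", "local", rep(0.5, 11))
  missing <- make_raw_ensemble("missing", "local", rep(0.5, 10),
                               segments = body_segments()[-3])
  mixed <- make_raw_ensemble("mixed", "local", rep(0.5, 11))
  mixed$convention[4] <- "regional_total"
  mixed$nude_baseline_clo <- 0.5
  nobase <- make_raw_ensemble("nobase", "regional_total", rep(0.8, 11))
  res <- harmonize_dataset(rbind(good, missing, mixed, nobase))
  expect_equal(nrow(res$ensembles), 1)
  expect_equal(res$ensembles$ensemble_id, "good")
  st <- setNames(res$log$status, res$log$ensemble_id)
  expect_equal(unname(st[c("missing", "mixed", "nobase")]), rep("rejected", 3))
  expect_match(res$log$detail[res$log$ensemble_id == "missing"], "missing")
  expect_match(res$log$detail[res$log$ensemble_id == "mixed"], "mixed conventions")
  expect_match(res$log$detail[res$log$ensemble_id == "nobase"], "nude_baseline")
})

test_that("harmonized locals are always finite and non-negative", {
  raw <- gen_clothing_dataset(n_ensembles = 30, seed = 99,
                              convention = "regional_total")
  res <- harmonize_dataset(raw)
  locs <- as.matrix(res$ensembles[, body_segments()])
  expect_true(all(is.finite(locs)))
  expect_true(all(locs >= 0))
})
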