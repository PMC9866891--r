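# Homologous-series templates, decoys, score simulation, and the benchmark.

test_that("homologous series match their structural templates", {
  tfa <- homologous_series("C", 0)
  expect_equal(tfa$smiles, "OC(=O)C(F)(F)F")

  ftoh <- parse_smiles(homologous_series("F", 9, m = 2)$smiles[1])
  counts <- table(ftoh$atoms$element)
  expect_equal(unname(counts["C"]), 12L)
  expect_equal(unname(counts["F"]), 21L)
  expect_equal(unname(counts["O"]), 1L)
  expect_equal(ftoh$n_heavy, 34L)

  y3 <- parse_smiles(homologous_series("Y", 3)$smiles[1])
  counts <- table(y3$atoms$element)
  expect_equal(unname(counts["C"]), 5L)
  expect_equal(unname(counts["F"]), 6L)
  expect_equal(unname(counts["O"]), 4L)

  # every member of every group parses to a connected graph
  for (grp in c("C", "S", "P", "F", "Y")) {
    series <- homologous_series(grp, 0:6)
    for (s in series$smiles) expect_s3_class(parse_smiles(s), "molgraph")
  }
  expect_error(homologous_series("Z", 1), "unknown group")
})

test_that("decoys are deterministic, parsable, and structurally diverse", {
  d1 <- decoy_structures(12, seed = 4)
  d2 <- decoy_structures(12, seed = 4)
  expect_identical(d1, d2)
  expect_false(identical(d1$smiles, decoy_structures(12, seed = 5)$smiles))

  for (s in d1$smiles) expect_s3_class(parse_smiles(s), "molgraph")
  expect_equal(nrow(decoy_structures(0, seed = 1)), 0L)

  # against a linear-PFAS reference, some decoy exceeds h*
  ref <- descriptor_table(homologous_series("C", 2:10), pool = FALSE)
  ref$bs <- simulate_scores(ref, -7.5, c(icr = -0.9, pw2 = -0.4),
                            sigma = 0.1, seed = 3)
  m <- fit_qsar(ref, c("icr", "pw2"))
  qd <- descriptor_table(d1, pool = FALSE)
  ad <- assess_domain(m, ref, qd)
  expect_gt(max(ad$h), unique(ad$h_star))
})

test_that("simulate_scores follows the linear + Gaussian endpoint model", {
  tbl <- descriptor_table(homologous_series("C", 0:9), pool = FALSE)

  # sigma = 0: refit recovers the generating coefficients exactly
  y0 <- simulate_scores(tbl, -7.499, c(icr = -0.947, pw2 = -0.394),
                        sigma = 0, seed = 1)
  tbl$bs <- y0
  m <- suppressWarnings(fit_qsar(tbl, c("icr", "pw2")))
  expect_equal(m$intercept, -7.499, tolerance = 1e-10)
  expect_equal(unname(m$coefficients), c(-0.947, -0.394), tolerance = 1e-10)
  expect_equal(goodness_of_fit(y0, predict(m, tbl))$r2, 1, tolerance = 1e-10)

  # doubling sigma roughly doubles the calibration RMSE
  rmse_at <- function(sg) {
    mean(vapply(1:20, function(s) {
      y <- simulate_scores(tbl, -7.5, c(icr = -0.9, pw2 = -0.4),
                           sigma = sg, seed = 1000 + s)
      d <- tbl; d$bs <- y
      mm <- fit_qsar(d, c("icr", "pw2"))
      goodness_of_fit(y, predict(mm, d))$rmse
    }, numeric(1)))
  }
  expect_equal(rmse_at(0.7) / rmse_at(0.35), 2, tolerance = 0.25)

  expect_error(
    simulate_scores(tibble::tibble(flat = rep(1, 5)), 0, c(flat = 1),
                    sigma = 0.1, seed = 1),
    "flat")
})

test_that("the benchmark mirrors the study design", {
  b <- make_benchmark(seed = 11)
  expect_equal(nrow(b), 43L)
  expect_false(anyNA(b))
  expect_setequal(unique(b$group), c("C", "S", "P", "F", "Y"))

  s <- split_one_to_z(b, 3)
  expect_equal(nrow(s$training), 29L)
  expect_equal(nrow(s$validation), 14L)

  # reproducible by seed
  expect_identical(b$bs, make_benchmark(seed = 11)$bs)

  # fitted calibration error lands in the published RMSE_C neighbourhood
  # (benchmark structures are fixed; only the endpoint is resimulated)
  rmse <- vapply(1:25, function(s) {
    bb <- b
    bb$bs <- simulate_scores(bb, -7.499, c(icr = -0.947, pw2 = -0.394),
                             sigma = 0.35, seed = 2000 + s)
    sp <- split_one_to_z(bb, 3)
    m <- fit_qsar(sp$training, c("icr", "pw2"))
    goodness_of_fit(sp$training$bs, predict(m, sp$training))$rmse
  }, numeric(1))
  expect_gt(mean(rmse > 0.25 & rmse < 0.42), 0.7)
})

test_that("generating coefficients are recovered across seeds", {
  b <- make_benchmark(seed = 1, pool = FALSE)
  err <- t(vapply(1:100, function(s) {
    b$bs <- simulate_scores(b, -7.499, c(icr = -0.947, pw2 = -0.394),
                            sigma = 0.35, seed = 3000 + s)
    m <- fit_qsar(b, c("icr", "pw2"))
    abs(unname(m$coefficients) - c(-0.947, -0.394))
  }, numeric(2)))
  expect_lt(mean(err[, 1]), 0.08)
  expect_lt(mean(err[, 2]), 0.08)
})
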