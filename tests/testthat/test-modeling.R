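# Splitting, scaling, OLS fitting, GA selection, serialization.

test_that("1:Z split reproduces the published set sizes", {
  withr::with_seed(3, {
    d43 <- tibble::tibble(id = sprintf("c%02d", 1:43), bs = rnorm(43))
  })
  s3 <- split_one_to_z(d43, 3)
  expect_equal(nrow(s3$training), 29L)
  expect_equal(nrow(s3$validation), 14L)
  s4 <- split_one_to_z(d43, 4)
  expect_equal(nrow(s4$training), 33L)
  expect_equal(nrow(s4$validation), 10L)

  # disjoint and exhaustive
  expect_length(intersect(s3$train_idx, s3$val_idx), 0L)
  expect_setequal(c(s3$train_idx, s3$val_idx), 1:43)
})

test_that("1:Z split holds out every Z-th endpoint-sorted compound", {
  d <- tibble::tibble(id = letters[1:5], bs = c(3, 1, 5, 2, 4))
  s <- split_one_to_z(d, 5)
  expect_equal(s$validation$id, "c")  # the largest endpoint
  s2 <- split_one_to_z(d, 2)
  # sorted order b,d,a,e,c -> positions 2 and 4 are d and e
  expect_setequal(s2$validation$id, c("d", "e"))

  # ties keep input order (stable sort)
  dt <- tibble::tibble(id = c("p", "q", "r"), bs = c(1, 1, 1))
  expect_equal(split_one_to_z(dt, 3)$validation$id, "r")

  expect_error(split_one_to_z(d, 6), "empty validation")
  expect_error(split_one_to_z(d, 1), ">= 2")
})

test_that("standard scaling centers with sample SD and reuses parameters", {
  sc <- standard_scale(cbind(a = c(1, 2, 3), b = c(10, 20, 60)))
  expect_equal(unname(sc$scaled[, "a"]), c(-1, 0, 1))
  expect_equal(unname(colMeans(sc$scaled)), c(0, 0))
  expect_equal(unname(apply(sc$scaled, 2, sd)), c(1, 1))

  # a validation row equal to the training mean maps to zero
  row <- standard_scale(cbind(a = 2, b = 30), center = sc$center,
                        scale = sc$scale)
  expect_equal(unname(row$scaled[1, ]), c(0, 0))

  expect_error(standard_scale(cbind(ok = 1:3, flat = c(2, 2, 2))), "flat")
})

test_that("fit_mlr matches the normal-equation oracle", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      n <- sample(10:30, 1)
      p <- sample(1:3, 1)
      x <- matrix(rnorm(n * p), n, p,
                  dimnames = list(NULL, paste0("d", seq_len(p))))
      y <- rnorm(n)
      fm <- fit_mlr(x, y)
      or <- oracle_ols(x, y)
      expect_equal(unname(c(fm$intercept, fm$coefficients)), unname(or$beta),
                   tolerance = 1e-10)
      expect_equal(unname(c(fm$se_intercept, fm$se_coefficients)),
                   unname(or$se), tolerance = 1e-10)
    }
  })
})

test_that("fit_mlr recovers noiseless models exactly and flags collinearity", {
  withr::with_seed(8, {
    z1 <- rnorm(10); z2 <- rnorm(10)
  })
  y <- 2 + 3 * z1 - 1 * z2
  fm <- suppressWarnings(fit_mlr(cbind(z1 = z1, z2 = z2), y))
  expect_equal(fm$intercept, 2, tolerance = 1e-10)
  expect_equal(unname(fm$coefficients), c(3, -1), tolerance = 1e-10)
  expect_lt(max(fm$se_coefficients), 1e-8)

  # intercept equals mean(y) when predictors are standardized
  xs <- standard_scale(cbind(z1 = z1, z2 = z2))$scaled
  withr::with_seed(9, yn <- y + rnorm(10, 0, 0.3))
  expect_equal(fit_mlr(xs, yn)$intercept, mean(yn), tolerance = 1e-12)

  expect_error(fit_mlr(cbind(a = z1, b = 2 * z1), y), "collinear")
})

test_that("fit_qsar + predict realize the standardized-space equation", {
  d <- noise_pool_data(n = 43, sigma = 0.35, seed = 4)
  m <- fit_qsar(d, c("true1", "true2"))
  # centroid row predicts the intercept exactly
  centroid <- tibble::tibble(true1 = mean(d$true1), true2 = mean(d$true2))
  expect_equal(unname(predict(m, centroid)), m$intercept, tolerance = 1e-12)
  # prediction is affine
  r1 <- d[1, ]; r2 <- d[2, ]
  mix <- tibble::tibble(true1 = 0.3 * r1$true1 + 0.7 * r2$true1,
                        true2 = 0.3 * r1$true2 + 0.7 * r2$true2)
  expect_equal(unname(predict(m, mix)),
               unname(0.3 * predict(m, r1) + 0.7 * predict(m, r2)),
               tolerance = 1e-12)
  expect_error(predict(m, tibble::tibble(true1 = 1)), "true2")
  # recovered standardized effects are near the generating ones
  expect_equal(unname(m$coefficients), c(-0.9, -0.4), tolerance = 0.25)
})

test_that("GA selection finds the generating pair and obeys the cap", {
  d <- noise_pool_data(n = 40, n_noise = 3, sigma = 0.1, seed = 2)
  pool <- setdiff(names(d), "bs")
  ga <- ga_select(d, pool, seed = 31)
  expect_setequal(ga$descriptors, c("true1", "true2"))
  ex <- exhaustive_select(d, pool)
  expect_setequal(ga$descriptors, ex$descriptors)
  expect_equal(ga$q2_loo, ex$q2_loo, tolerance = 1e-12)

  # identical seeds give identical selections
  ga2 <- ga_select(d, pool, seed = 31)
  expect_identical(ga$descriptors, ga2$descriptors)

  # correlated pair above the cap is infeasible
  withr::with_seed(6, {
    z <- rnorm(30)
    dc <- tibble::tibble(a = z, b = z + rnorm(30, 0, 0.1), bs = rnorm(30))
  })
  expect_gt(abs(cor(dc$a, dc$b)), 0.9)
  expect_error(ga_select(dc, c("a", "b"), seed = 1), "no feasible")
  expect_error(exhaustive_select(dc, c("a", "b")), "no feasible")

  # size-1 selection equals the exhaustive single-descriptor scan
  ga1 <- ga_select(d, pool, size = 1, seed = 17)
  ex1 <- exhaustive_select(d, pool, size = 1)
  expect_identical(ga1$descriptors, ex1$descriptors)
})

test_that("model serialization round-trips bit-exactly", {
  d <- noise_pool_data(n = 25, sigma = 0.2, seed = 12)
  m <- fit_qsar(d, c("true1", "true2"))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  for (f in c("intercept", "coefficients", "se_intercept",
              "se_coefficients", "sigma", "scaler_center", "scaler_scale")) {
    expect_identical(m[[f]], m2[[f]], info = f)
  }
  expect_identical(m$descriptors, m2$descriptors)
  expect_equal(predict(m2, d), predict(m, d), tolerance = 0)
})
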