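# Goodness of fit, LOO cross-validation, external validation, Y-scrambling.

test_that("goodness_of_fit matches hand arithmetic", {
  y <- c(0, 1, 2)
  perfect <- goodness_of_fit(y, y)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mae, 0)

  g <- goodness_of_fit(y, c(0, 1, 1))
  expect_equal(g$r2, 0.5)
  expect_equal(g$rmse, sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(g$mae, 1 / 3, tolerance = 1e-12)

  expect_equal(goodness_of_fit(y, rep(mean(y), 3))$r2, 0)
  expect_error(goodness_of_fit(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("loo_cv predicts held-out rows from refitted scaler and model", {
  # noiseless linear endpoint: LOO is exact
  d <- noise_pool_data(n = 20, sigma = 0, seed = 5)
  cv <- suppressWarnings(loo_cv(d, c("true1", "true2")))
  expect_equal(cv$q2_loo, 1, tolerance = 1e-10)
  expect_equal(cv$rmse_cv, 0, tolerance = 1e-6)

  # shrinkage: Q2_LOO <= R2 on the same data
  dn <- noise_pool_data(n = 29, sigma = 0.35, seed = 23)
  m <- fit_qsar(dn, c("true1", "true2"))
  r2 <- goodness_of_fit(dn$bs, predict(m, dn))$r2
  cvn <- loo_cv(dn, c("true1", "true2"))
  expect_lt(cvn$q2_loo, r2)

  # the explicit refit loop equals the PRESS/hat identity
  x1 <- cbind(1, as.matrix(dn[, c("true1", "true2")]))
  qr_x <- qr(x1)
  e <- residuals(lm.fit(x1, dn$bs))
  h <- rowSums(qr.Q(qr_x)^2)
  press <- sum((e / (1 - h))^2)
  expect_equal(cvn$q2_loo, 1 - press / sum((dn$bs - mean(dn$bs))^2),
               tolerance = 1e-10)
})

test_that("loo Q2 stays in the published envelope on synthetic data", {
  q2 <- vapply(1:25, function(s) {
    b <- noise_pool_data(n = 29, sigma = 0.35, seed = 100 + s)
    loo_cv(b, c("true1", "true2"))$q2_loo
  }, numeric(1))
  expect_true(all(q2 > 0.6))
  expect_gt(mean(q2 > 0.75 & q2 < 0.95), 0.7)
})

test_that("external validation statistics match hand arithmetic", {
  d <- noise_pool_data(n = 20, sigma = 0, seed = 31)
  m <- suppressWarnings(fit_qsar(d, c("true1", "true2")))
  ext <- external_validation(m, d, d)
  expect_equal(ext$q2_f1, 1, tolerance = 1e-10)
  expect_equal(ext$q2_f2, 1, tolerance = 1e-10)
  expect_equal(ext$q2_f3, 1, tolerance = 1e-10)
  expect_equal(ext$ccc_ext, 1, tolerance = 1e-10)

  # definitional: predicting the external mean gives Q2_F2 = 0
  y_ext <- c(1, 2, 4)
  sse <- sum((y_ext - mean(y_ext))^2)
  expect_equal(1 - sse / sum((y_ext - mean(y_ext))^2), 0)

  # frozen worked example: y = [1,2,3], yhat = [1.1, 2.0, 2.9], mean_TR = 2
  y <- c(1, 2, 3); yh <- c(1.1, 2.0, 2.9)
  sse <- sum((y - yh)^2)
  q2f1 <- 1 - sse / sum((y - 2)^2)
  expect_equal(q2f1, 0.99, tolerance = 1e-12)
  expect_equal(ccc(y, yh), 0.994475138121547, tolerance = 1e-12)

  expect_error(external_validation(m, d[0, ], d), "empty")
})

test_that("Q2_F1 >= Q2_F2 and |CCC| <= |r| hold on random samples", {
  withr::with_seed(77, {
    for (rep in 1:10) {
      y <- rnorm(8); yh <- y + rnorm(8, 0, 0.4)
      ybar_tr <- mean(y) + runif(1, 0.1, 1)
      sse <- sum((y - yh)^2)
      q2f1 <- 1 - sse / sum((y - ybar_tr)^2)
      q2f2 <- 1 - sse / sum((y - mean(y))^2)
      expect_gte(q2f1, q2f2)
      expect_lte(abs(ccc(y, yh)), abs(cor(y, yh)) + 1e-12)
    }
  })
})

test_that("y_scramble mean R2 sits at the chance level p/(n-1)", {
  d29 <- noise_pool_data(n = 29, sigma = 0.35, seed = 41)
  ys <- y_scramble(d29, c("true1", "true2"), n_iter = 1000, seed = 13)
  expect_lt(abs(ys$r2_yscr - 2 / 28), 0.015)
  expect_length(ys$r2_values, 1000L)

  d33 <- noise_pool_data(n = 33, sigma = 0.35, seed = 42)
  ys33 <- y_scramble(d33, c("true1", "true2"), n_iter = 1000, seed = 13)
  expect_lt(abs(ys33$r2_yscr - 2 / 32), 0.015)

  # deterministic under a fixed seed
  ys2 <- y_scramble(d29, c("true1", "true2"), n_iter = 1000, seed = 13)
  expect_identical(ys$r2_yscr, ys2$r2_yscr)

  expect_error(y_scramble(d29, c("true1", "true2"), n_iter = 50, seed = 1),
               "at least 100")
})

test_that("validate_model assembles a finite, well-formed report", {
  b <- make_benchmark(seed = 19)
  s <- split_one_to_z(b, 3)
  rep <- validate_model(s$training, s$validation, c("icr", "pw2"),
                        n_scramble = 200, seed = 19)
  fields <- c("r2", "rmse_c", "mae_c", "q2_loo", "rmse_cv", "mae_cv",
              "q2_f1", "q2_f2", "q2_f3", "rmse_ext", "mae_ext", "ccc_ext",
              "r2_yscr")
  for (f in fields) expect_true(is.finite(rep[[f]]), info = f)
  expect_gte(rep$rmse_c, 0)
  expect_gte(rep$rmse_c, rep$mae_c)
  expect_gte(rep$rmse_ext, rep$mae_ext)
  expect_equal(rep$n_train, 29L)
  expect_equal(rep$n_val, 14L)

  lines <- format(rep)
  expect_match(lines[grepl("^R2 ", lines)], "\\d\\.\\d{3}$")

  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  doc <- jsonlite::read_json(path)
  expect_equal(doc$r2, rep$r2, tolerance = 0)
})
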