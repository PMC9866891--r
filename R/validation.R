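# Goodness of fit, leave-one-out cross-validation, external validation
# (Q2_F1..F3, CCC), and Y-scrambling — the full statistics block reported
# for each receptor model.

#' Goodness of fit on the training set
#'
#' `R2 = 1 - SSE/SST` about the training mean, `RMSE = sqrt(SSE/n)` and
#' `MAE = mean(|residual|)` (n-denominator calibration errors).
#'
#' @param y Observed endpoint values.
#' @param y_hat Model predictions for the same rows.
#' @return List with `r2`, `rmse`, `mae`.
#' @export
goodness_of_fit <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) > 1)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("constant endpoint: R2 undefined", call. = FALSE)
  sse <- sum((y - y_hat)^2)
  list(r2 = 1 - sse / sst,
       rmse = sqrt(sse / length(y)),
       mae = mean(abs(y - y_hat)))
}

#' Leave-one-out cross-validation
#'
#' For each training row, the scaler and the OLS fit are recomputed on the
#' remaining n-1 rows and the held-out row is predicted from them.
#' `Q2_LOO = 1 - PRESS / SST` about the full training mean; RMSE and MAE
#' are taken over the held-out predictions.
#'
#' @param train Data frame with descriptor columns and the endpoint.
#' @param descriptors Descriptor column names.
#' @param endpoint Endpoint column name (default `"bs"`).
#' @return List with `q2_loo`, `rmse_cv`, `mae_cv`, and the per-row
#'   `predictions`.
#' @export
loo_cv <- function(train, descriptors, endpoint = "bs") {
  stopifnot(is.data.frame(train), all(descriptors %in% names(train)))
  n <- nrow(train)
  p <- length(descriptors)
  if (n < p + 3L) stop("too few rows for leave-one-out", call. = FALSE)
  y <- train[[endpoint]]
  preds <- numeric(n)
  for (i in seq_len(n)) {
    fold <- train[-i, , drop = FALSE]
    m <- tryCatch(
      fit_qsar(fold, descriptors, endpoint),
      error = function(e) {
        stop(sprintf("LOO refit failed with row %d held out: %s", i,
                     conditionMessage(e)), call. = FALSE)
      }
    )
    preds[i] <- predict(m, train[i, , drop = FALSE])
  }
  press <- sum((y - preds)^2)
  sst <- sum((y - mean(y))^2)
  list(q2_loo = 1 - press / sst,
       rmse_cv = sqrt(press / n),
       mae_cv = mean(abs(y - preds)),
       predictions = preds)
}

#' External validation statistics
#'
#' Predictive squared coefficients on the held-out set:
#' `Q2_F1 = 1 - SSE_ext / sum((y_ext - mean(y_train))^2)`,
#' `Q2_F2 = 1 - SSE_ext / sum((y_ext - mean(y_ext))^2)`,
#' `Q2_F3 = 1 - (SSE_ext/n_ext) / (SST_train/n_train)`,
#' plus RMSE/MAE of prediction and Lin's concordance correlation
#' coefficient in its sample-moment form.
#'
#' @param model An `mlr_model`.
#' @param validation Held-out data frame (descriptors + endpoint).
#' @param train Training data frame (supplies the reference mean and SST).
#' @return List with `q2_f1`, `q2_f2`, `q2_f3`, `rmse_ext`, `mae_ext`,
#'   `ccc_ext`, and the `predictions`.
#' @export
external_validation <- function(model, validation, train) {
  stopifnot(inherits(model, "mlr_model"))
  if (nrow(validation) == 0L) stop("empty validation set", call. = FALSE)
  ep <- model$endpoint
  y <- validation[[ep]]
  y_tr <- train[[ep]]
  y_hat <- predict(model, validation)
  sse <- sum((y - y_hat)^2)
  n_ext <- length(y)
  list(
    q2_f1 = 1 - sse / sum((y - mean(y_tr))^2),
    q2_f2 = 1 - sse / sum((y - mean(y))^2),
    q2_f3 = 1 - (sse / n_ext) / (sum((y_tr - mean(y_tr))^2) / length(y_tr)),
    rmse_ext = sqrt(sse / n_ext),
    mae_ext = mean(abs(y - y_hat)),
    ccc_ext = ccc(y, y_hat),
    predictions = y_hat
  )
}

#' Lin's concordance correlation coefficient
#'
#' Sample (n-denominator) moment form:
#' `2 * s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)`. Equals 1 only for
#' perfect agreement; bounded by the Pearson correlation in absolute value.
#'
#' @param x,y Paired observation vectors.
#' @return CCC in \[-1, 1\].
#' @export
ccc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) > 1)
  mx <- mean(x); my <- mean(y)
  sxy <- mean((x - mx) * (y - my))
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

#' Y-scrambling (response randomization)
#'
#' Permutes the endpoint uniformly at random `n_iter` times, refits the
#' model on the unchanged descriptors each time, and returns the mean R2
#' across permutations. For a p-descriptor OLS model the chance-correlation
#' expectation is `p / (n - 1)`, so small values (well below the model's
#' real R2) indicate the fit is not a correlation by chance.
#'
#' @param train Data frame with descriptor columns and the endpoint.
#' @param descriptors Descriptor column names.
#' @param n_iter Number of permutations (default 1000; at least 100).
#' @param seed Integer seed (required).
#' @param endpoint Endpoint column name (default `"bs"`).
#' @return List with `r2_yscr` (mean scrambled R2) and `r2_values`.
#' @export
y_scramble <- function(train, descriptors, n_iter = 1000, seed,
                       endpoint = "bs") {
  stopifnot(is.data.frame(train), all(descriptors %in% names(train)))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (n_iter < 100L) stop("`n_iter` must be at least 100", call. = FALSE)
  y <- train[[endpoint]]
  x1 <- cbind(1, as.matrix(train[, descriptors, drop = FALSE]))
  qr_x <- qr(x1)
  if (qr_x$rank < ncol(x1)) stop("rank-deficient design", call. = FALSE)
  r2s <- withr::with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      yp <- sample(y)
      fitted <- qr.fitted(qr_x, yp)
      1 - sum((yp - fitted)^2) / sum((yp - mean(yp))^2)
    }, numeric(1))
  })
  list(r2_yscr = mean(r2s), r2_values = r2s)
}

#' Full validation report for one model
#'
#' Assembles the complete statistics block — goodness of fit, leave-one-out
#' cross-validation, external validation, and Y-scrambling — for a model
#' defined by its descriptor pair on a training/validation split.
#'
#' @param train,validation Training and held-out data frames.
#' @param descriptors Descriptor column names.
#' @param endpoint Endpoint column name (default `"bs"`).
#' @param n_scramble Y-scrambling iterations (default 1000).
#' @param seed Seed for the scrambling permutations.
#' @return An object of class `validation_report`: the fitted `model` plus
#'   fields `r2`, `rmse_c`, `mae_c`, `q2_loo`, `rmse_cv`, `mae_cv`,
#'   `q2_f1`, `q2_f2`, `q2_f3`, `rmse_ext`, `mae_ext`, `ccc_ext`,
#'   `r2_yscr`, `n_train`, `n_val`.
#' @export
validate_model <- function(train, validation, descriptors, endpoint = "bs",
                           n_scramble = 1000, seed) {
  model <- fit_qsar(train, descriptors, endpoint)
  gof <- goodness_of_fit(train[[endpoint]], predict(model, train))
  cv <- loo_cv(train, descriptors, endpoint)
  ext <- external_validation(model, validation, train)
  ysc <- y_scramble(train, descriptors, n_iter = n_scramble, seed = seed,
                    endpoint = endpoint)
  structure(
    list(
      model = model,
      r2 = gof$r2, rmse_c = gof$rmse, mae_c = gof$mae,
      q2_loo = cv$q2_loo, rmse_cv = cv$rmse_cv, mae_cv = cv$mae_cv,
      q2_f1 = ext$q2_f1, q2_f2 = ext$q2_f2, q2_f3 = ext$q2_f3,
      rmse_ext = ext$rmse_ext, mae_ext = ext$mae_ext, ccc_ext = ext$ccc_ext,
      r2_yscr = ysc$r2_yscr,
      n_train = nrow(train), n_val = nrow(validation)
    ),
    class = "validation_report"
  )
}

.report_fields <- c("r2", "rmse_c", "mae_c", "q2_loo", "rmse_cv", "mae_cv",
                    "q2_f1", "q2_f2", "q2_f3", "rmse_ext", "mae_ext",
                    "ccc_ext", "r2_yscr")

#' Format a validation report as a statistics table
#'
#' Renders the report in the conventional one-column QSAR layout, values
#' rounded to three decimals.
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return Character vector of table lines, invisibly (also printed).
#' @export
format.validation_report <- function(x, ...) {
  labels <- c(
    r2 = "R2", rmse_c = "RMSE_C", mae_c = "MAE_C",
    q2_loo = "Q2_LOO", rmse_cv = "RMSE_CV", mae_cv = "MAE_CV",
    q2_f1 = "Q2_F1", q2_f2 = "Q2_F2", q2_f3 = "Q2_F3",
    rmse_ext = "RMSE_EXT", mae_ext = "MAE_EXT", ccc_ext = "CCC_EXT",
    r2_yscr = "R2_YSCR"
  )
  lines <- c(
    sprintf("n        %d", x$n_train),
    sprintf("k        %d", x$n_val),
    sprintf("%-8s %.3f", labels, unlist(x[names(labels)]))
  )
  lines
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(paste0("  ", format(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' Same flat key-value document format as [write_model()]; full precision
#' (17 significant digits).
#'
#' @param report A `validation_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  doc <- report[c(.report_fields, "n_train", "n_val")]
  doc$class <- "validation_report"
  doc$descriptors <- report$model$descriptors
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}
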