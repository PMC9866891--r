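# Leverage-based applicability domain: Williams-plot quantities for labeled
# sets, Insubria-graph logic (leverage + prediction range) for unlabeled
# screening sets.

#' Leverage (hat values) of descriptor rows
#'
#' `h = x' (X'X)^-1 x` with an intercept column included in both the
#' training design `X` and the query row `x`. Training leverages sum to
#' `p + 1` (the hat-matrix trace); rows far from the descriptor centroid
#' get large h.
#'
#' @param train_xs Scaled training descriptor matrix (n x p).
#' @param query_xs Scaled query rows (defaults to the training matrix
#'   itself).
#' @return Numeric vector of leverages, one per query row.
#' @export
leverage <- function(train_xs, query_xs = train_xs) {
  x1 <- cbind(1, as.matrix(train_xs))
  q1 <- cbind(1, as.matrix(query_xs))
  xtx <- crossprod(x1)
  inv <- tryCatch(chol2inv(chol(xtx)), error = function(e) {
    stop("singular design: cannot invert X'X", call. = FALSE)
  })
  rowSums((q1 %*% inv) * q1)
}

#' Critical leverage threshold h*
#'
#' The conventional warning leverage `h* = 3 (p + 1) / n`. For the
#' published receptor models: `h*(29, 2) = 0.310` and `h*(33, 2) = 0.273`.
#'
#' @param n Training-set size.
#' @param p Number of descriptors in the model.
#' @return h* (report rounded to three decimals).
#' @export
critical_leverage <- function(n, p) {
  stopifnot(n > p + 1)
  3 * (p + 1) / n
}

#' Standardized residuals
#'
#' Residuals divided by the RMSE of the set the compounds belong to
#' (calibration RMSE for training rows, external RMSE for validation
#' rows). Compounds with |z| > 3 are the residual outliers of the Williams
#' plot.
#'
#' @param y Observed endpoint values.
#' @param y_hat Predictions.
#' @param rmse RMSE of the designated set.
#' @return Numeric vector of residual z-scores.
#' @export
standardized_residuals <- function(y, y_hat, rmse) {
  stopifnot(length(y) == length(y_hat), rmse >= 0)
  if (rmse == 0) return(rep(0, length(y)))
  (y - y_hat) / rmse
}

#' Assess the applicability domain of query compounds
#'
#' For every query row computes the leverage against the training design,
#' the prediction, and an in-domain verdict. Unlabeled rows are in-domain
#' iff `h < h*` (strict) and the predicted score lies within the
#' training-set endpoint range (Insubria-graph rule); labeled rows are
#' additionally flagged when their standardized residual exceeds 3 in
#' absolute value (Williams-plot rule). Reason codes:
#' `"high-leverage"`, `"residual-outlier"`, `"out-of-range"`,
#' `"in-domain"` (precedence in that order).
#'
#' @param model An `mlr_model`.
#' @param train Training data frame (descriptors + endpoint).
#' @param query Query data frame; may lack the endpoint column.
#' @param rmse RMSE used to standardize residuals of labeled query rows
#'   (default: the model's calibration RMSE computed on `train`).
#' @param range_basis `"observed"` (default) bounds predictions by the
#'   training endpoint range; `"predicted"` uses the range of training-set
#'   predictions instead.
#' @return Tibble with columns `h`, `h_star`, `pred_bs`, `z` (NA for
#'   unlabeled rows), `in_domain`, `reason`, preceded by an `id` column
#'   when the query has one.
#' @export
assess_domain <- function(model, train, query, rmse = NULL,
                          range_basis = c("observed", "predicted")) {
  stopifnot(inherits(model, "mlr_model"))
  range_basis <- match.arg(range_basis)
  ep <- model$endpoint

  sc_train <- standard_scale(train[, model$descriptors, drop = FALSE],
                             center = model$scaler_center,
                             scale = model$scaler_scale)
  sc_query <- standard_scale(query[, model$descriptors, drop = FALSE],
                             center = model$scaler_center,
                             scale = model$scaler_scale)
  h <- leverage(sc_train$scaled, sc_query$scaled)
  h_star <- critical_leverage(model$n_train, model$p)
  pred <- predict(model, query)

  train_pred <- predict(model, train)
  rng <- if (range_basis == "observed") {
    range(train[[ep]])
  } else {
    range(train_pred)
  }

  labeled <- ep %in% names(query) && !anyNA(query[[ep]])
  z <- rep(NA_real_, nrow(query))
  if (labeled) {
    if (is.null(rmse)) {
      rmse <- sqrt(mean((train[[ep]] - train_pred)^2))
    }
    z <- standardized_residuals(query[[ep]], pred, rmse)
  }

  high_lev <- h >= h_star
  res_out <- labeled & !is.na(z) & abs(z) > 3
  # range rule is the Insubria-graph check for unlabeled screening rows;
  # labeled rows are judged by leverage and residuals (Williams plot)
  out_rng <- if (labeled) rep(FALSE, nrow(query)) else
    pred < rng[1] | pred > rng[2]
  reason <- rep("in-domain", nrow(query))
  reason[out_rng] <- "out-of-range"
  reason[res_out] <- "residual-outlier"
  reason[high_lev] <- "high-leverage"

  out <- tibble::tibble(
    h = h, h_star = h_star, pred_bs = pred, z = z,
    in_domain = reason == "in-domain", reason = reason
  )
  if ("id" %in% names(query)) {
    out <- dplyr::bind_cols(query["id"], out)
  }
  out
}
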