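# Model calibration: 1:Z dataset splitting, standard scaling, MLR fitting in
# standardized descriptor space, and genetic-algorithm descriptor selection.

#' Split a labeled dataset by the 1:Z rule
#'
#' Rows are sorted by the endpoint in ascending order (stable sort, so ties
#' keep input order) and every Z-th compound of the sorted sequence goes to
#' the validation set; the rest form the training set. With n = 43 and
#' Z = 3 this yields 29 training / 14 validation compounds; Z = 4 yields
#' 33 / 10.
#'
#' @param data Data frame with an endpoint column.
#' @param z Integer >= 2; every Z-th sorted row is held out.
#' @param endpoint Name of the endpoint column (default `"bs"`).
#' @return List with `training` and `validation` tibbles, the integer row
#'   indices `train_idx` / `val_idx` (into `data`), and `z`.
#' @export
split_one_to_z <- function(data, z, endpoint = "bs") {
  stopifnot(is.data.frame(data), endpoint %in% names(data))
  z <- as.integer(z)
  if (is.na(z) || z < 2L) stop("`z` must be an integer >= 2", call. = FALSE)
  n <- nrow(data)
  if (floor(n / z) < 1L) {
    stop(sprintf("Z = %d exceeds the dataset size (%d): empty validation set",
                 z, n), call. = FALSE)
  }
  y <- data[[endpoint]]
  if (anyNA(y)) stop("endpoint contains missing values", call. = FALSE)
  ord <- order(y)  # stable: ties keep input order
  val_pos <- seq(z, n, by = z)
  val_idx <- ord[val_pos]
  train_idx <- ord[-val_pos]
  list(
    training = tibble::as_tibble(data[sort(train_idx), , drop = FALSE]),
    validation = tibble::as_tibble(data[sort(val_idx), , drop = FALSE]),
    train_idx = sort(train_idx),
    val_idx = sort(val_idx),
    z = z
  )
}

#' Standard-scale a descriptor matrix
#'
#' Column-wise `(x - mean) / sd` with the sample (n-1) standard deviation.
#' When `center`/`scale` are supplied (training-set statistics), they are
#' applied unchanged — the transform for validation and screening data.
#'
#' @param x Numeric matrix or data frame of descriptor columns.
#' @param center,scale Optional named numeric vectors of means and SDs to
#'   apply; both must be given together.
#' @return List with `scaled` (matrix), `center`, and `scale`.
#' @export
standard_scale <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(center) != is.null(scale)) {
    stop("supply both `center` and `scale`, or neither", call. = FALSE)
  }
  if (is.null(center)) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
    zero <- scale <= 0 | !is.finite(scale)
    if (any(zero)) {
      stop(sprintf("zero-variance descriptor column(s): %s",
                   paste(colnames(x)[zero], collapse = ", ")), call. = FALSE)
    }
  } else {
    center <- center[colnames(x)]
    scale <- scale[colnames(x)]
    if (anyNA(center) || anyNA(scale)) {
      stop("`center`/`scale` lack entries for some descriptor columns",
           call. = FALSE)
    }
  }
  scaled <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  list(scaled = scaled, center = center, scale = scale)
}

#' Ordinary least squares on scaled descriptors
#'
#' Fits `y ~ 1 + Xs` by OLS and returns the intercept, coefficients, and
#' their standard errors from the residual variance estimate on
#' `n - p - 1` degrees of freedom.
#'
#' @param xs Scaled descriptor matrix (n x p).
#' @param y Endpoint vector (kcal/mol).
#' @return List with `intercept`, `coefficients` (named), `se_intercept`,
#'   `se_coefficients`, `sigma`, `fitted`, `residuals`, `n`, `p`.
#' @export
fit_mlr <- function(xs, y) {
  xs <- as.matrix(xs)
  n <- nrow(xs)
  p <- ncol(xs)
  stopifnot(length(y) == n)
  if (n <= p + 1L) {
    stop("need more observations than descriptors plus intercept",
         call. = FALSE)
  }
  df <- as.data.frame(xs)
  df$.y <- y
  fit <- stats::lm(.y ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  sm <- summary(fit)
  cf <- sm$coefficients
  list(
    intercept = unname(cf[1, 1]),
    coefficients = stats::setNames(cf[-1, 1], colnames(xs)),
    se_intercept = unname(cf[1, 2]),
    se_coefficients = stats::setNames(cf[-1, 2], colnames(xs)),
    sigma = sm$sigma,
    fitted = unname(stats::fitted(fit)),
    residuals = unname(stats::residuals(fit)),
    n = n,
    p = p
  )
}

#' Calibrate a standardized-space MLR QSAR model
#'
#' Scales the named descriptor columns on the training data (sample-SD
#' standardization) and fits OLS in the scaled space, mirroring the
#' calibration used for the published receptor models. The returned model
#' carries the scaler parameters so it can predict from raw descriptor
#' values.
#'
#' @param train Data frame with descriptor columns and the endpoint.
#' @param descriptors Character vector of descriptor column names.
#' @param endpoint Endpoint column name (default `"bs"`).
#' @return An object of class `mlr_model`.
#' @export
fit_qsar <- function(train, descriptors, endpoint = "bs") {
  stopifnot(is.data.frame(train),
            all(descriptors %in% names(train)),
            endpoint %in% names(train))
  sc <- standard_scale(train[, descriptors, drop = FALSE])
  fm <- fit_mlr(sc$scaled, train[[endpoint]])
  structure(
    list(
      descriptors = descriptors,
      intercept = fm$intercept,
      coefficients = fm$coefficients,
      se_intercept = fm$se_intercept,
      se_coefficients = fm$se_coefficients,
      sigma = fm$sigma,
      scaler_center = sc$center,
      scaler_scale = sc$scale,
      endpoint = endpoint,
      n_train = fm$n,
      p = fm$p
    ),
    class = "mlr_model"
  )
}

#' @export
print.mlr_model <- function(x, ...) {
  terms <- paste(sprintf("%+.3f (±%.3f) × %s",
                         x$coefficients, x$se_coefficients, x$descriptors),
                 collapse = " ")
  cat(sprintf("<mlr_model> BS = %.3f (±%.3f) %s\n  n = %d, p = %d\n",
              x$intercept, x$se_intercept, terms, x$n_train, x$p))
  invisible(x)
}

#' Predict binding scores from raw descriptor values
#'
#' Applies the stored scaler parameters to the raw descriptor columns and
#' evaluates `intercept + sum(coef_j * z_j)`. A row equal to the training
#' means predicts exactly the intercept.
#'
#' @param object An `mlr_model`.
#' @param newdata Data frame containing the model's descriptor columns.
#' @param ... Unused.
#' @return Numeric vector of predicted binding scores (kcal/mol).
#' @export
predict.mlr_model <- function(object, newdata, ...) {
  miss <- setdiff(object$descriptors, names(newdata))
  if (length(miss) > 0L) {
    stop(sprintf("missing descriptor column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  sc <- standard_scale(newdata[, object$descriptors, drop = FALSE],
                       center = object$scaler_center,
                       scale = object$scaler_scale)
  drop(object$intercept + sc$scaled %*% object$coefficients)
}

# Q2_LOO via the PRESS identity for OLS: e_loo = e / (1 - h). Used as the
# selection fitness; algebraically identical to an explicit refit loop
# (standardization is affine and does not move OLS predictions).
.q2_press <- function(x, y) {
  x1 <- cbind(1, as.matrix(x))
  qr_x <- qr(x1)
  if (qr_x$rank < ncol(x1)) return(-Inf)
  e <- stats::residuals(stats::lm.fit(x1, y))
  h <- rowSums(qr.Q(qr_x)^2)
  press <- sum((e / (1 - h))^2)
  1 - press / sum((y - mean(y))^2)
}

.pairwise_feasible <- function(x, subset, cap) {
  if (length(subset) < 2L) return(TRUE)
  cm <- stats::cor(x[, subset, drop = FALSE])
  all(abs(cm[upper.tri(cm)]) <= cap)
}

#' Exhaustive descriptor-subset selection
#'
#' Scans all size-`size` subsets of the pool, discards any whose pairwise
#' absolute Pearson correlation exceeds `cor_cap`, and returns the subset
#' with the highest leave-one-out Q2. Tractable for the pool sizes used
#' here; serves as the reference for the genetic search.
#'
#' @param data Data frame with the pool columns and the endpoint.
#' @param pool Character vector of candidate descriptor names.
#' @param size Subset size (default 2).
#' @param endpoint Endpoint column name.
#' @param cor_cap Maximum allowed pairwise |r| (default 0.6).
#' @return List with `descriptors` (character vector) and `q2_loo`.
#' @export
exhaustive_select <- function(data, pool, size = 2, endpoint = "bs",
                              cor_cap = 0.6) {
  stopifnot(all(pool %in% names(data)), length(pool) >= size)
  x <- as.matrix(data[, pool, drop = FALSE])
  y <- data[[endpoint]]
  combos <- utils::combn(pool, size, simplify = FALSE)
  best <- NULL
  best_q2 <- -Inf
  for (s in combos) {
    if (!.pairwise_feasible(x, s, cor_cap)) next
    q2 <- .q2_press(x[, s, drop = FALSE], y)
    if (q2 > best_q2) {
      best_q2 <- q2
      best <- s
    }
  }
  if (is.null(best)) {
    stop(sprintf("no feasible subset of size %d under |r| <= %g", size,
                 cor_cap), call. = FALSE)
  }
  list(descriptors = best, q2_loo = best_q2)
}

#' Genetic-algorithm descriptor selection
#'
#' Searches fixed-size descriptor subsets maximizing leave-one-out Q2 under
#' a hard pairwise-correlation cap (candidates with any |r| > `cor_cap` are
#' infeasible). Fixed-size subset encoding; tournament selection (size 3),
#' union-resampling crossover, per-gene replacement mutation, elitism of 1.
#' Deterministic for a given seed.
#'
#' @param data Data frame with the pool columns and the endpoint.
#' @param pool Character vector of candidate descriptor names.
#' @param size Subset size (default 2, matching the published models).
#' @param endpoint Endpoint column name.
#' @param cor_cap Maximum allowed pairwise |r| (default 0.6).
#' @param pop_size,generations,p_mutation GA controls (defaults 50, 100,
#'   0.01).
#' @param seed Integer seed (required).
#' @return List with `descriptors`, `q2_loo`, and `history` (best fitness
#'   per generation).
#' @export
ga_select <- function(data, pool, size = 2, endpoint = "bs", cor_cap = 0.6,
                      pop_size = 50, generations = 100, p_mutation = 0.01,
                      seed) {
  stopifnot(all(pool %in% names(data)), length(pool) >= size)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  x <- as.matrix(data[, pool, drop = FALSE])
  y <- data[[endpoint]]
  npool <- length(pool)

  fitness <- function(subset) {
    if (!.pairwise_feasible(x, subset, cor_cap)) return(-Inf)
    .q2_press(x[, subset, drop = FALSE], y)
  }

  withr::with_seed(seed, {
    popn <- replicate(pop_size, sort(sample.int(npool, size)),
                      simplify = FALSE)
    fit <- vapply(popn, function(s) fitness(pool[s]), numeric(1))
    history <- numeric(generations)
    for (gen in seq_len(generations)) {
      tournament <- function() {
        cand <- sample.int(pop_size, 3L)
        cand[which.max(fit[cand])]
      }
      offspring <- vector("list", pop_size)
      elite <- which.max(fit)
      offspring[[1L]] <- popn[[elite]]
      for (i in seq(2L, pop_size)) {
        pa <- popn[[tournament()]]
        pb <- popn[[tournament()]]
        gene_pool <- unique(c(pa, pb))
        child <- if (length(gene_pool) <= size) {
          gene_pool
        } else {
          sample(gene_pool, size)
        }
        while (length(child) < size) {
          child <- unique(c(child, sample.int(npool, 1L)))
        }
        mutate <- stats::runif(size) < p_mutation
        for (gidx in which(mutate)) {
          repl <- setdiff(seq_len(npool), child)
          if (length(repl) > 0L) child[gidx] <- sample(repl, 1L)
        }
        offspring[[i]] <- sort(unique(child))[seq_len(size)]
        # guard against duplicate collapse after mutation
        while (length(unique(offspring[[i]])) < size) {
          offspring[[i]] <- sort(unique(c(offspring[[i]],
                                          sample.int(npool, 1L))))[seq_len(size)]
        }
      }
      popn <- offspring
      fit <- vapply(popn, function(s) fitness(pool[s]), numeric(1))
      history[gen] <- max(fit)
    }
    best <- which.max(fit)
    if (!is.finite(fit[best])) {
      stop(sprintf("no feasible subset of size %d under |r| <= %g", size,
                   cor_cap), call. = FALSE)
    }
    list(descriptors = pool[popn[[best]]], q2_loo = fit[best],
         history = history)
  })
}

#' Serialize a fitted model to JSON
#'
#' Writes every field of the model (descriptor names, intercept,
#' coefficients, standard errors, scaler parameters, dimensions) as a flat
#' JSON document with 17 significant digits, so a write/read round-trip is
#' bit-exact.
#'
#' @param model An `mlr_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "mlr_model"))
  doc <- list(
    class = "mlr_model",
    descriptors = model$descriptors,
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    se_intercept = model$se_intercept,
    se_coefficients = as.list(model$se_coefficients),
    sigma = model$sigma,
    scaler_center = as.list(model$scaler_center),
    scaler_scale = as.list(model$scaler_scale),
    endpoint = model$endpoint,
    n_train = model$n_train,
    p = model$p
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized model
#'
#' @param path Path written by [write_model()].
#' @return An `mlr_model`.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$class, "mlr_model")) {
    stop("not an mlr_model document", call. = FALSE)
  }
  num <- function(x) vapply(x, as.numeric, numeric(1))
  structure(
    list(
      descriptors = vapply(doc$descriptors, as.character, character(1)),
      intercept = as.numeric(doc$intercept),
      coefficients = num(doc$coefficients),
      se_intercept = as.numeric(doc$se_intercept),
      se_coefficients = num(doc$se_coefficients),
      sigma = as.numeric(doc$sigma),
      scaler_center = num(doc$scaler_center),
      scaler_scale = num(doc$scaler_scale),
      endpoint = as.character(doc$endpoint),
      n_train = as.integer(doc$n_train),
      p = as.integer(doc$p)
    ),
    class = "mlr_model"
  )
}
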