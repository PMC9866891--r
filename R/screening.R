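# Virtual screening with the frozen published receptor models: load the
# registry of equations and thresholds, classify scores into four
# binding-probability classes, and screen query sets with AD flags.

BINDING_CLASSES <- c("high", "moderately_high", "moderate", "low")
CLASS_COLORS <- c(high = "red", moderately_high = "orange",
                  moderate = "yellow", low = "green")

#' Frozen receptor model registry
#'
#' Loads the five published standardized-space MLR equations and their
#' class thresholds from the registry document bundled with the package.
#' Each entry carries the receptor's PDB code, descriptor pair, intercept,
#' coefficients with standard errors, and the threshold triple
#' `T1 < T2 < T3` (kcal/mol, all negative; T1 the most negative).
#'
#' @return Named list of `receptor_spec` objects, keyed by receptor id
#'   (`PPARA`, `PPARB`, `PPARG`, `TRA`, `TRB`).
#' @export
frozen_registry <- function() {
  path <- system.file("extdata", "receptor_registry.json",
                      package = "pfasscreen", mustWork = TRUE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(names(doc$receptors), function(id) {
    r <- doc$receptors[[id]]
    num <- function(x) vapply(x, as.numeric, numeric(1))
    spec <- list(
      receptor = id,
      name = r$name,
      pdb = r$pdb,
      n_train = as.integer(r$n_train),
      descriptors = vapply(r$descriptors, as.character, character(1)),
      intercept = as.numeric(r$intercept),
      se_intercept = as.numeric(r$se_intercept),
      coefficients = num(r$coefficients),
      se_coefficients = num(r$se_coefficients),
      thresholds = num(r$thresholds)
    )
    stopifnot(length(spec$descriptors) == 2L,
              spec$thresholds["t1"] < spec$thresholds["t2"],
              spec$thresholds["t2"] < spec$thresholds["t3"])
    structure(spec, class = "receptor_spec")
  })
  names(out) <- names(doc$receptors)
  out
}

#' @export
print.receptor_spec <- function(x, ...) {
  cat(sprintf(
    "<receptor_spec> %s (%s, PDB %s)\n  BS = %.3f %s\n  thresholds: %s kcal/mol\n",
    x$receptor, x$name, x$pdb, x$intercept,
    paste(sprintf("%+.3f x %s", x$coefficients, names(x$coefficients)),
          collapse = " "),
    paste(sprintf("%.1f", x$thresholds), collapse = " / ")))
  invisible(x)
}

#' Classify a binding score into a probability class
#'
#' Maps a docking-style binding score (kcal/mol, more negative = stronger)
#' to one of four classes using the receptor's threshold triple:
#' `high` below T1, `moderately_high` in \[T1, T2), `moderate` in
#' \[T2, T3), `low` at or above T3. A score exactly at a threshold goes to
#' the weaker class.
#'
#' @param score Numeric binding score(s) in kcal/mol.
#' @param spec A `receptor_spec` from [frozen_registry()].
#' @return Character vector of class labels (`"high"`,
#'   `"moderately_high"`, `"moderate"`, `"low"`).
#' @export
classify_score <- function(score, spec) {
  stopifnot(inherits(spec, "receptor_spec"), all(is.finite(score)))
  t <- spec$thresholds
  dplyr::case_when(
    score < t["t1"] ~ "high",
    score < t["t2"] ~ "moderately_high",
    score < t["t3"] ~ "moderate",
    TRUE ~ "low"
  )
}

#' Color code of a binding class
#'
#' @param class Character vector of class labels.
#' @return `"red"`, `"orange"`, `"yellow"`, or `"green"`.
#' @export
class_color <- function(class) {
  unname(CLASS_COLORS[class])
}

#' Realize a frozen receptor equation against a reference dataset
#'
#' The published equations act on standard-scaled descriptors, but the
#' original training means and SDs were not published. This helper binds a
#' frozen equation to the descriptor statistics of an explicit reference
#' dataset (a re-derived training table or a synthetic calibration set),
#' producing an `mlr_model` that predicts from raw descriptor values.
#'
#' @param spec A `receptor_spec`.
#' @param reference Data frame with the spec's descriptor columns (and an
#'   endpoint column if AD range checks are wanted downstream).
#' @param endpoint Endpoint column name recorded on the model (default
#'   `"bs"`).
#' @return An `mlr_model` with the frozen coefficients and the reference
#'   scaler.
#' @export
frozen_model <- function(spec, reference, endpoint = "bs") {
  stopifnot(inherits(spec, "receptor_spec"),
            all(spec$descriptors %in% names(reference)))
  sc <- standard_scale(reference[, spec$descriptors, drop = FALSE])
  structure(
    list(
      descriptors = spec$descriptors,
      intercept = spec$intercept,
      coefficients = spec$coefficients[spec$descriptors],
      se_intercept = spec$se_intercept,
      se_coefficients = spec$se_coefficients[spec$descriptors],
      sigma = NA_real_,
      scaler_center = sc$center,
      scaler_scale = sc$scale,
      endpoint = endpoint,
      n_train = nrow(reference),
      p = length(spec$descriptors)
    ),
    class = "mlr_model"
  )
}

#' Screen a compound set against a frozen receptor model
#'
#' Runs the full screening path for one receptor: compute descriptors for
#' the query compounds (if not already present), scale them with the
#' reference set's statistics, evaluate the frozen equation, classify the
#' predicted score, and attach the applicability-domain verdict (leverage
#' against the reference design plus the prediction-range rule).
#' Out-of-domain compounds still receive a score and class but are marked
#' not in-domain. Unparsable query rows are routed to the `"rejects"`
#' attribute of the result.
#'
#' @param query Data frame with `id` and `smiles` columns, or with the
#'   descriptor columns already computed.
#' @param spec A `receptor_spec`.
#' @param reference Labeled reference data frame supplying the scaler
#'   statistics and AD geometry; must contain the descriptor columns and
#'   the endpoint.
#' @param endpoint Endpoint column of `reference` (default `"bs"`).
#' @return Tibble with per-compound descriptor values, `pred_bs`,
#'   `class`, `color`, `h`, `h_star`, `in_domain`, `reason`.
#' @export
screen <- function(query, spec, reference, endpoint = "bs") {
  stopifnot(inherits(spec, "receptor_spec"), is.data.frame(query))
  if (nrow(query) == 0L) {
    out <- tibble::tibble(id = character(), pred_bs = numeric(),
                          class = character(), color = character(),
                          h = numeric(), h_star = numeric(),
                          in_domain = logical(), reason = character())
    attr(out, "rejects") <- tibble::tibble(id = character(),
                                           smiles = character(),
                                           reason = character())
    return(out)
  }
  if (!all(spec$descriptors %in% names(query))) {
    query <- descriptor_table(query, pool = FALSE)
  }
  rejects <- descriptor_rejects(query)

  model <- frozen_model(spec, reference, endpoint)
  ad <- assess_domain(model, reference, query)
  cls <- classify_score(ad$pred_bs, spec)

  out <- dplyr::bind_cols(
    tibble::as_tibble(query),
    tibble::tibble(pred_bs = ad$pred_bs, class = cls,
                   color = class_color(cls), h = ad$h, h_star = ad$h_star,
                   in_domain = ad$in_domain, reason = ad$reason)
  )
  attr(out, "rejects") <- rejects
  out
}
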