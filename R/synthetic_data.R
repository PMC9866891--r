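# Synthetic PFAS structures and simulated binding scores: homologous series
# built from the five structural-group templates, randomized decoys that
# exercise out-of-domain paths, and a 43-compound labeled benchmark with the
# statistical structure the modeling layer assumes.

SERIES_GROUPS <- c("C", "S", "P", "F", "Y")

.series_smiles <- function(group, n, m) {
  cf2 <- strrep("C(F)(F)", n)
  switch(group,
    C = paste0("OC(=O)", cf2, "C(F)(F)F"),
    S = paste0("OS(=O)(=O)", cf2, "C(F)(F)F"),
    P = paste0("OP(=O)(O)", cf2, "C(F)(F)F"),
    F = paste0("O", strrep("C", m), cf2, "C(F)(F)F"),
    Y = paste0("OC(=O)", cf2, "C(=O)O"),
    stop(sprintf("unknown group %s (expected one of %s)", sQuote(group),
                 paste(SERIES_GROUPS, collapse = ", ")), call. = FALSE)
  )
}

#' Homologous PFAS series from structural-group templates
#'
#' Builds SMILES for one of the five PFAS structural groups by repeated
#' CF2 insertion:
#' * `C` — perfluoroalkyl carboxylic acids, `COOH-(CF2)n-CF3`
#' * `S` — perfluoroalkane sulfonic acids, `SO3H-(CF2)n-CF3`
#' * `P` — perfluoroalkyl phosphonic acids, `PO3H2-(CF2)n-CF3`
#' * `F` — fluorotelomer alcohols, `OH-(CH2)m-(CF2)n-CF3`
#' * `Y` — perfluoroalkyl dicarboxylic acids, `COOH-(CF2)n-COOH`
#'
#' `n = 0` of group `C` is trifluoroacetic acid. Output is deterministic.
#'
#' @param group One of `"C"`, `"S"`, `"P"`, `"F"`, `"Y"`.
#' @param n_range Integer vector of inner CF2 counts (each >= 0).
#' @param m CH2 spacer length for fluorotelomer alcohols (default 2).
#' @return Tibble with columns `id`, `smiles`, `group`, `n`.
#' @export
homologous_series <- function(group, n_range, m = 2) {
  if (!is.character(group) || length(group) != 1L ||
      !group %in% SERIES_GROUPS) {
    stop(sprintf("unknown group %s (expected one of %s)", sQuote(group),
                 paste(SERIES_GROUPS, collapse = ", ")), call. = FALSE)
  }
  stopifnot(all(n_range >= 0), m >= 1)
  tibble::tibble(
    id = paste0(group, n_range),
    smiles = vapply(n_range, function(n) .series_smiles(group, n, m),
                    character(1)),
    group = group,
    n = as.integer(n_range)
  )
}

# Decoy generators: branched perfluoro-alcohols, partially fluorinated
# rings, ether-linked chains, and lightly fluorinated hydrocarbons.
.decoy_branched <- function(k) {
  # alcohol carbon with k CF3 arms plus one chain CF3 (k in 1..2;
  # k = 2 is perfluoro-tert-butanol)
  arms <- strrep("(C(F)(F)F)", k)
  paste0("OC", arms, "C(F)(F)F")
}
.decoy_ring <- function(size, fluorinated) {
  inner <- size - 2L
  if (fluorinated) {
    paste0("FC1(F)", strrep("C(F)(F)", inner), "C1(F)F")
  } else {
    paste0("C1", strrep("C", inner), "C1")
  }
}
.decoy_ether <- function(a, b) {
  paste0("FC(F)(F)", strrep("C(F)(F)", a), "O", strrep("C(F)(F)", b),
         "C(F)(F)F")
}
.decoy_alkyl <- function(len) {
  paste0("OC(=O)", strrep("C", len), "C(F)(F)F")
}

#' Randomized decoy structures
#'
#' Generates branched, cyclic, ether-linked, and partially fluorinated
#' structures outside the linear homologous series, to exercise
#' high-leverage and out-of-range applicability-domain paths. All outputs
#' parse into connected molecular graphs; output is deterministic for a
#' given seed.
#'
#' @param count Number of decoys (>= 0).
#' @param seed Integer seed (required).
#' @return Tibble with columns `id`, `smiles`, `group` (`"decoy"`).
#' @export
decoy_structures <- function(count, seed) {
  stopifnot(count >= 0)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (count == 0L) {
    return(tibble::tibble(id = character(), smiles = character(),
                          group = character()))
  }
  smiles <- withr::with_seed(seed, {
    vapply(seq_len(count), function(i) {
      kind <- sample(c("branched", "ring", "ether", "alkyl"), 1L)
      switch(kind,
        branched = .decoy_branched(sample(1:2, 1L)),
        ring = .decoy_ring(sample(4:6, 1L), sample(c(TRUE, FALSE), 1L)),
        ether = .decoy_ether(sample(1:4, 1L), sample(1:4, 1L)),
        alkyl = .decoy_alkyl(sample(3:8, 1L))
      )
    }, character(1))
  })
  tibble::tibble(
    id = sprintf("D%02d", seq_len(count)),
    smiles = smiles,
    group = "decoy"
  )
}

#' Simulate binding scores from a descriptor table
#'
#' Draws `y = b0 + sum_j beta_j z_j + eps`, where `z` are the named
#' descriptor columns standard-scaled within the generated set and
#' `eps ~ N(0, sigma^2)`. This is the endpoint model the calibration layer
#' assumes; with `sigma = 0` a subsequent fit recovers the coefficients
#' exactly.
#'
#' @param desc_table Data frame containing the descriptor columns named in
#'   `coefficients`.
#' @param intercept Intercept b0 (kcal/mol).
#' @param coefficients Named numeric vector of standardized effects
#'   (kcal/mol per SD).
#' @param sigma Noise SD in kcal/mol (>= 0).
#' @param seed Integer seed (required).
#' @return Numeric endpoint vector (kcal/mol).
#' @export
simulate_scores <- function(desc_table, intercept, coefficients, sigma,
                            seed) {
  stopifnot(is.data.frame(desc_table), sigma >= 0,
            all(names(coefficients) %in% names(desc_table)))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  sc <- standard_scale(desc_table[, names(coefficients), drop = FALSE])
  mu <- intercept + drop(sc$scaled %*% coefficients)
  withr::with_seed(seed, mu + stats::rnorm(nrow(desc_table), 0, sigma))
}

#' Build the synthetic 43-compound benchmark
#'
#' Mirrors the study design: 43 compounds drawn from the five structural
#' groups (10 carboxylic acids including TFA, 8 sulfonic acids, 8
#' phosphonic acids, 9 fluorotelomer alcohols, 8 dicarboxylic acids),
#' descriptors attached, and a simulated endpoint. The default generating
#' model copies the PPAR-alpha equation (intercept -7.499, standardized
#' effects -0.947 on ICR and -0.394 on PW2) with sigma = 0.35 kcal/mol
#' noise, so downstream calibration statistics land near the published
#' magnitudes.
#'
#' @param seed Integer seed (required).
#' @param intercept,coefficients,sigma Generating model (see defaults
#'   above).
#' @param pool Attach the auxiliary pool descriptors? Default `TRUE`.
#' @return Labeled tibble (`id`, `smiles`, `group`, `n`, descriptor
#'   columns, `bs`), with the generating parameters in attribute
#'   `"truth"`.
#' @export
make_benchmark <- function(seed,
                           intercept = -7.499,
                           coefficients = c(icr = -0.947, pw2 = -0.394),
                           sigma = 0.35,
                           pool = TRUE) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  compounds <- dplyr::bind_rows(
    homologous_series("C", 0:9),       # includes TFA (n = 0)
    homologous_series("S", 1:8),
    homologous_series("P", 1:8),
    homologous_series("F", 1:9, m = 2),
    homologous_series("Y", 1:8)
  )
  stopifnot(nrow(compounds) == 43L)
  tbl <- descriptor_table(compounds, pool = pool)
  stopifnot(nrow(tbl) == 43L)
  tbl$bs <- simulate_scores(tbl, intercept = intercept,
                            coefficients = coefficients, sigma = sigma,
                            seed = seed)
  attr(tbl, "truth") <- list(intercept = intercept,
                             coefficients = coefficients, sigma = sigma,
                             seed = seed)
  tbl
}
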