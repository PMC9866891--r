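# The four model descriptors (X%, ICR, PW2, TPC) plus a small pool of
# auxiliary 2D descriptors used to exercise descriptor selection.

#' Halogen percentage (X%)
#'
#' Percentage of halogen atoms (F, Cl, Br, I) over all atoms of the
#' molecule, hydrogens included: `100 * n_halogen / (heavy + implicit H)`.
#' For perfluorinated homologues X% grows with every added CF2 unit.
#'
#' @param g A `molgraph`.
#' @return Numeric percentage in \[0, 100\] at full precision (round to two
#'   decimals for reporting).
#' @examples
#' x_percent(parse_smiles("OC(=O)C(F)(F)F"))  # 37.5 for TFA
#' @export
x_percent <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  n_hal <- sum(g$atoms$element %in% HALOGENS)
  100 * n_hal / total_atoms(g)
}

#' Radial centric information index (ICR)
#'
#' Shannon entropy, in bits, of the partition of heavy atoms into classes of
#' equal eccentricity: `-sum_g (n_g/A) log2(n_g/A)`. Zero when all atoms
#' share one eccentricity (e.g. ethane); bounded above by `log2(A)`. Larger
#' values indicate molecules whose atoms sit at many distinct distances from
#' the periphery — long chains and branched skeletons.
#'
#' @param g A `molgraph`.
#' @return ICR in bits (>= 0).
#' @export
icr <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  ecc <- eccentricities(g)
  p <- as.numeric(table(ecc)) / length(ecc)
  -sum(p * log2(p))
}

#' Path/walk-2 Randic shape index (PW2)
#'
#' Ratio of order-2 path counts to order-2 walk counts. The default
#' (`"atom_average"`) is the Randic convention: the per-atom ratios
#' `p2(i)/w2(i)` averaged over atoms, with atoms having no 2-walks
#' contributing zero. `"total_quotient"` instead divides the molecular path
#' total by the molecular walk total; both are exposed because published
#' descriptor engines differ.
#'
#' @param g A `molgraph`.
#' @param method `"atom_average"` (default) or `"total_quotient"`.
#' @return Dimensionless ratio in \[0, 1\].
#' @export
pw2 <- function(g, method = c("atom_average", "total_quotient")) {
  stopifnot(inherits(g, "molgraph"))
  method <- match.arg(method)
  pw <- atomic_path_walk_counts(g, 2)
  if (method == "atom_average") {
    ratio <- ifelse(pw[, "walk"] > 0, pw[, "path"] / pw[, "walk"], 0)
    mean(ratio)
  } else {
    w <- sum(pw[, "walk"])
    if (w == 0) 0 else sum(pw[, "path"]) / w
  }
}

#' Total path count descriptor (TPC)
#'
#' Natural log of the number of simple paths of length >= 0 in the
#' hydrogen-suppressed graph, counting each atom as one zero-length path:
#' `ln(A + P)` where `P = count_simple_paths(g)`. Reflects molecular size;
#' for trees it equals `ln(A + A(A-1)/2)` exactly.
#'
#' @param g A `molgraph`.
#' @return Log-count (>= 0) at full precision.
#' @export
tpc <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  log(g$n_heavy + count_simple_paths(g))
}

#' Auxiliary pool descriptors
#'
#' Cheap 2D descriptors used to pad the selection pool in demonstrations of
#' descriptor selection: heavy-atom count, halogen count, Wiener index (sum
#' of pairwise topological distances), number of branch atoms (degree >= 3),
#' and graph diameter.
#'
#' @param g A `molgraph`.
#' @return Named numeric vector.
#' @export
pool_descriptors <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  d <- igraph::distances(g$graph)
  deg <- igraph::degree(g$graph)
  c(
    heavy_atoms = as.numeric(g$n_heavy),
    halogens = sum(g$atoms$element %in% HALOGENS),
    wiener = sum(d[upper.tri(d)]),
    branch_atoms = sum(deg >= 3),
    diameter = if (g$n_heavy == 1L) 0 else max(d)
  )
}

#' Compute the descriptor table for a batch of compounds
#'
#' Parses each SMILES and computes X%, ICR, PW2, TPC (plus, optionally, the
#' auxiliary pool). Rows that fail to parse are collected into a rejects
#' table attached as the `"rejects"` attribute instead of aborting the
#' batch.
#'
#' @param compounds A data frame with columns `id` and `smiles` (extra
#'   columns are carried through).
#' @param pool Include the auxiliary pool descriptors? Default `TRUE`.
#' @return A tibble with one row per successfully parsed compound, in input
#'   order, with descriptor columns `x_percent`, `icr`, `pw2`, `tpc` (and
#'   pool columns). Attribute `"rejects"`: tibble of `id`, `smiles`,
#'   `reason` for failed rows.
#' @export
descriptor_table <- function(compounds, pool = TRUE) {
  stopifnot(is.data.frame(compounds),
            all(c("id", "smiles") %in% names(compounds)))
  n <- nrow(compounds)
  rows <- vector("list", n)
  rejects <- list()
  for (i in seq_len(n)) {
    res <- tryCatch({
      g <- parse_smiles(compounds$smiles[i])
      vals <- c(x_percent = x_percent(g), icr = icr(g),
                pw2 = pw2(g), tpc = tpc(g))
      if (pool) vals <- c(vals, pool_descriptors(g))
      tibble::as_tibble_row(as.list(vals))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      rejects[[length(rejects) + 1L]] <- tibble::tibble(
        id = compounds$id[i], smiles = compounds$smiles[i], reason = res)
    } else {
      rows[[i]] <- dplyr::bind_cols(compounds[i, , drop = FALSE], res)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (n > 0 && nrow(out) == 0) {
    # preserve schema even when everything was rejected
    out <- compounds[0, , drop = FALSE]
  }
  attr(out, "rejects") <- if (length(rejects)) {
    dplyr::bind_rows(rejects)
  } else {
    tibble::tibble(id = character(), smiles = character(), reason = character())
  }
  out
}

#' Rejected rows of a descriptor table
#'
#' @param x A table returned by [descriptor_table()].
#' @return The rejects tibble (`id`, `smiles`, `reason`).
#' @export
descriptor_rejects <- function(x) {
  r <- attr(x, "rejects")
  if (is.null(r)) {
    tibble::tibble(id = character(), smiles = character(), reason = character())
  } else {
    r
  }
}
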