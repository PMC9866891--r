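# Hydrogen-suppressed molecular graphs parsed from SMILES, plus the graph
# primitives (eccentricities, simple-path counts, order-2 path/walk counts)
# that the topological descriptors consume.

ORGANIC_SUBSET <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")
HALOGENS <- c("F", "Cl", "Br", "I")

# Default valences of the SMILES organic subset; for S and P the smallest
# standard valence not below the bond-order sum is used (so sulfonic S is 6,
# phosphonic P is 5, thioether S is 2).
.default_valences <- list(
  C = 4, N = 3, O = 2, F = 1, Cl = 1, Br = 1, I = 1,
  S = c(2, 4, 6), P = c(3, 5)
)

# SDF atom-block charge codes: 0 none, 1..3 = +3..+1, 4 radical, 5..7 = -1..-3
.charge_from_code <- function(code) {
  ifelse(code %in% c(0, 4), 0L, 4L - as.integer(code))
}

.implicit_h <- function(element, bond_sum, charge) {
  allowed <- .default_valences[[element]]
  target <- allowed[allowed >= bond_sum][1]
  if (is.na(target)) target <- max(allowed)
  # charge adjustment in the usual SMILES sense: N+ carries 4 bonds+H,
  # O- carries 1, etc.
  target <- target + charge
  max(0, round(target - bond_sum))
}

# Matches a lone atom token ("C", "Cl", "[NH4+]", ...); returns a molgraph
# or NULL when the SMILES is not a single atom.
.parse_single_atom <- function(smiles) {
  m <- regmatches(smiles, regexec(
    "^(?:([A-Z][a-z]?)|\\[([A-Z][a-z]?)(H\\d*)?([+-]\\d*)?\\])$", smiles))[[1]]
  if (length(m) == 0L) return(NULL)
  bracket <- nzchar(m[3])
  element <- if (bracket) m[3] else m[2]
  if (!element %in% ORGANIC_SUBSET) {
    stop(sprintf("unsupported element(s) %s in %s", element, sQuote(smiles)),
         call. = FALSE)
  }
  charge <- 0L
  if (bracket && nzchar(m[5])) {
    digits <- sub("^[+-]", "", m[5])
    mag <- if (nzchar(digits)) as.integer(digits) else 1L
    charge <- if (startsWith(m[5], "-")) -mag else mag
  }
  implicit_h <- if (bracket) {
    # bracket atoms carry only the hydrogens they spell out
    if (nzchar(m[4])) {
      digits <- sub("^H", "", m[4])
      if (nzchar(digits)) as.integer(digits) else 1L
    } else 0L
  } else {
    .implicit_h(element, 0, charge)
  }
  structure(
    list(
      atoms = tibble::tibble(element = element,
                             implicit_h = as.integer(implicit_h),
                             formal_charge = as.integer(charge)),
      edges = matrix(integer(0), ncol = 2),
      bond_order = numeric(0),
      graph = igraph::make_empty_graph(1, directed = FALSE),
      n_heavy = 1L,
      smiles = smiles
    ),
    class = "molgraph"
  )
}

#' Parse a SMILES string into a hydrogen-suppressed molecular graph
#'
#' Heavy atoms become vertices; bonds become undirected edges (bond order is
#' retained for valence bookkeeping but ignored by all graph primitives).
#' Implicit hydrogen counts are recorded per atom from standard SMILES
#' valence rules so that total atom counts (heavy + H) are available to
#' constitutional descriptors. Stereochemical markers are accepted and
#' discarded; multi-fragment (disconnected) input is rejected.
#'
#' @param smiles A single SMILES string over the organic subset
#'   (C, N, O, S, P, F, Cl, Br, I).
#' @return An object of class `molgraph`: a list with elements `atoms`
#'   (tibble with `element`, `implicit_h`, `formal_charge`), `edges`
#'   (two-column integer matrix of bonds), `bond_order` (numeric vector
#'   parallel to `edges`), `graph` (the igraph adjacency), and `n_heavy`.
#' @examples
#' g <- parse_smiles("OC(=O)C(F)(F)F")  # trifluoroacetic acid
#' g$n_heavy            # 7
#' sum(g$atoms$implicit_h)  # 1 (hydroxyl O)
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    stop("`smiles` must be a single non-empty string", call. = FALSE)
  }
  smiles <- trimws(smiles)
  # single-atom molecules: the SDF round-trip degenerates on bond-free
  # molecules, so build the one-vertex graph directly
  single <- .parse_single_atom(smiles)
  if (!is.null(single)) return(single)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) {
      stop(sprintf("SMILES parse error in %s: %s", sQuote(smiles),
                   conditionMessage(e)), call. = FALSE)
    }
  )
  ab <- ChemmineR::atomblock(sdf[[1]])
  if (is.null(ab) || nrow(ab) == 0L) {
    stop(sprintf("SMILES parse error in %s: no atoms produced", sQuote(smiles)),
         call. = FALSE)
  }
  element <- sub("_\\d+$", "", rownames(ab))
  bad <- setdiff(unique(element), ORGANIC_SUBSET)
  if (length(bad) > 0L) {
    stop(sprintf("unsupported element(s) %s in %s",
                 paste(bad, collapse = ", "), sQuote(smiles)), call. = FALSE)
  }
  charge_col <- ab[, "C6"]
  charge <- .charge_from_code(charge_col)

  bb <- ChemmineR::bondblock(sdf[[1]])
  n <- length(element)
  if (is.null(bb) || nrow(bb) == 0L) {
    edges <- matrix(integer(0), ncol = 2)
    order <- numeric(0)
  } else {
    edges <- cbind(as.integer(bb[, "C1"]), as.integer(bb[, "C2"]))
    order <- as.numeric(bb[, "C3"])
    order[order == 4] <- 1.5  # aromatic code, if the writer emits it
  }
  if (nrow(edges) > 0L && any(edges[, 1] == edges[, 2])) {
    stop("self-loop in parsed structure", call. = FALSE)
  }

  bond_sum <- numeric(n)
  for (b in seq_len(nrow(edges))) {
    bond_sum[edges[b, 1]] <- bond_sum[edges[b, 1]] + order[b]
    bond_sum[edges[b, 2]] <- bond_sum[edges[b, 2]] + order[b]
  }
  implicit_h <- vapply(seq_len(n), function(i) {
    .implicit_h(element[i], bond_sum[i], charge[i])
  }, numeric(1))

  graph <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges) > 0L) graph <- igraph::add_edges(graph, t(edges))
  if (igraph::components(graph)$no != 1L) {
    stop(sprintf("disconnected structure (multiple fragments) in %s",
                 sQuote(smiles)), call. = FALSE)
  }

  structure(
    list(
      atoms = tibble::tibble(
        element = element,
        implicit_h = as.integer(implicit_h),
        formal_charge = as.integer(charge)
      ),
      edges = edges,
      bond_order = order,
      graph = graph,
      n_heavy = n,
      smiles = smiles
    ),
    class = "molgraph"
  )
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %s\n  %d heavy atoms, %d bonds, %d implicit H\n",
              x$smiles, x$n_heavy, nrow(x$edges), sum(x$atoms$implicit_h)))
  invisible(x)
}

#' Total atom count (heavy atoms plus implicit hydrogens)
#'
#' @param g A `molgraph`.
#' @return Integer count of all atoms in the molecule.
#' @export
total_atoms <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  g$n_heavy + sum(g$atoms$implicit_h)
}

#' Heavy-atom eccentricities
#'
#' The eccentricity of an atom is its maximum shortest-path distance, in
#' bonds, to any other heavy atom. A single-atom graph has eccentricity 0.
#'
#' @param g A `molgraph`.
#' @return Integer vector, one value per heavy atom.
#' @export
eccentricities <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  if (g$n_heavy == 1L) return(0L)
  d <- igraph::distances(g$graph)
  as.integer(apply(d, 1, max))
}

# Adjacency list (integer neighbour indices per vertex).
.adj_list <- function(g) {
  lapply(igraph::adjacent_vertices(g$graph, seq_len(g$n_heavy)), as.integer)
}

#' Count simple paths between heavy-atom pairs
#'
#' Counts simple paths of length >= 1 between unordered pairs of heavy atoms
#' (each path counted once, not per direction). For acyclic molecules the
#' count is exactly `choose(A, 2)` since a tree has a unique path between any
#' two vertices; that closed form is used as a fast path. Cyclic molecules
#' are handled by exhaustive depth-first enumeration over simple vertex
#' sequences.
#'
#' @param g A `molgraph`.
#' @return Integer path count.
#' @export
count_simple_paths <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  n <- g$n_heavy
  m <- nrow(g$edges)
  if (m == n - 1L) return(as.integer(choose(n, 2)))  # connected + acyclic
  adj <- .adj_list(g)
  visited <- logical(n)
  total <- 0L
  dfs <- function(v) {
    visited[v] <<- TRUE
    for (w in adj[[v]]) {
      if (!visited[w]) {
        total <<- total + 1L
        dfs(w)
      }
    }
    visited[v] <<- FALSE
  }
  for (s in seq_len(n)) dfs(s)
  # each path enumerated once per direction
  as.integer(total %/% 2L)
}

#' Atomic path and walk counts of a given order
#'
#' For order `k = 2`: the walk count of atom i is the number of 2-step walks
#' starting at i (the sum of its neighbours' degrees); the path count is the
#' number of 2-edge simple paths starting at i, found by exhaustive
#' enumeration over distinct vertex triples. Order `k = 1` returns the degree
#' for both counts.
#'
#' @param g A `molgraph`.
#' @param k Walk/path order; 1 or 2.
#' @return A matrix with one row per atom and columns `path`, `walk`.
#' @export
atomic_path_walk_counts <- function(g, k = 2) {
  stopifnot(inherits(g, "molgraph"), k >= 1)
  if (!k %in% c(1, 2)) {
    stop("only orders 1 and 2 are implemented", call. = FALSE)
  }
  adj <- .adj_list(g)
  deg <- lengths(adj)
  if (k == 1) {
    out <- cbind(path = as.numeric(deg), walk = as.numeric(deg))
    return(out)
  }
  walk2 <- vapply(adj, function(nb) sum(deg[nb]), numeric(1))
  path2 <- vapply(seq_along(adj), function(i) {
    cnt <- 0L
    for (j in adj[[i]]) {
      for (l in adj[[j]]) {
        if (l != i && l != j) cnt <- cnt + 1L
      }
    }
    cnt
  }, integer(1))
  cbind(path = as.numeric(path2), walk = walk2)
}
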