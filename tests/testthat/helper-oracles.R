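# Independent brute-force oracles and fixture generators. These never call
# the code paths they check: adjacency is rebuilt from the edge list, path
# counts come from a per-pair DFS, and regression quantities from explicit
# normal equations.

# adjacency list straight from the edge matrix
adj_from_edges <- function(g) {
  adj <- vector("list", g$n_heavy)
  for (i in seq_len(g$n_heavy)) adj[[i]] <- integer(0)
  for (b in seq_len(nrow(g$edges))) {
    u <- g$edges[b, 1]; v <- g$edges[b, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  adj
}

# count simple paths between every unordered vertex pair by per-pair DFS
oracle_simple_paths <- function(g) {
  adj <- adj_from_edges(g)
  n <- g$n_heavy
  total <- 0L
  for (a in seq_len(n - 1L)) {
    for (b in seq(a + 1L, n)) {
      cnt <- 0L
      visited <- logical(n)
      rec <- function(v) {
        if (v == b) {
          cnt <<- cnt + 1L
          return(invisible())
        }
        visited[v] <<- TRUE
        for (w in adj[[v]]) if (!visited[w]) rec(w)
        visited[v] <<- FALSE
      }
      rec(a)
      total <- total + cnt
    }
  }
  total
}

# eccentricities by explicit BFS over the rebuilt adjacency
oracle_eccentricities <- function(g) {
  adj <- adj_from_edges(g)
  n <- g$n_heavy
  vapply(seq_len(n), function(s) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
      }
    }
    max(dist)
  }, integer(1))
}

# random alkane tree: each new carbon attaches to a random carbon with
# fewer than four neighbours; emitted as a branched SMILES by DFS
random_alkane_smiles <- function(n_atoms) {
  stopifnot(n_atoms >= 1)
  if (n_atoms == 1L) return("C")
  parent <- integer(n_atoms)
  degree <- integer(n_atoms)
  for (v in 2:n_atoms) {
    open <- which(degree[seq_len(v - 1L)] < 4L)
    p <- if (length(open) == 1L) open else sample(open, 1L)
    parent[v] <- p
    degree[p] <- degree[p] + 1L
    degree[v] <- degree[v] + 1L
  }
  children <- split(seq_len(n_atoms)[-1L], parent[-1L])
  emit <- function(v) {
    kids <- children[[as.character(v)]]
    if (is.null(kids)) return("C")
    subs <- vapply(kids, emit, character(1))
    k <- length(subs)
    paste0("C",
           if (k > 1L) paste0("(", subs[-k], ")", collapse = "") else "",
           subs[k])
  }
  emit(1L)
}

# OLS by explicit normal equations, with coefficient SEs
oracle_ols <- function(x, y) {
  x1 <- cbind(1, as.matrix(x))
  xtx_inv <- solve(t(x1) %*% x1)
  beta <- drop(xtx_inv %*% t(x1) %*% y)
  res <- y - drop(x1 %*% beta)
  df <- length(y) - ncol(x1)
  sigma2 <- sum(res^2) / df
  list(beta = beta, se = sqrt(diag(xtx_inv) * sigma2))
}

# a fixed panel of SMILES pairs writing the same molecule two ways
equivalent_smiles_pairs <- list(
  tfa = c("OC(=O)C(F)(F)F", "FC(F)(F)C(O)=O"),
  pfba = c("OC(=O)C(F)(F)C(F)(F)C(F)(F)F", "FC(F)(F)C(F)(F)C(F)(F)C(=O)O"),
  ftoh = c("OCCC(F)(F)C(F)(F)F", "FC(F)(F)C(F)(F)CCO"),
  branched = c("CC(C)(C)C", "C(C)(C)(C)C")
)

# synthetic regression fixture: two informative standardized predictors
# plus pure-noise columns
noise_pool_data <- function(n = 40, n_noise = 3, sigma = 0.1, seed = 1) {
  withr::with_seed(seed, {
    z1 <- rnorm(n); z2 <- rnorm(n)
    d <- tibble::tibble(true1 = z1, true2 = z2)
    for (j in seq_len(n_noise)) d[[paste0("noise", j)]] <- rnorm(n)
    d$bs <- -7.5 - 0.9 * scale(z1)[, 1] - 0.4 * scale(z2)[, 1] +
      rnorm(n, 0, sigma)
    d
  })
}
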