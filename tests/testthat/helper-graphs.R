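# Shared fixtures and independent oracle implementations.
# The oracles deliberately use naive loops and adjacency-power reachability,
# independent of the igraph-based production path.

# Build a molecular_graph directly (all-carbon skeleton, no hydrogens),
# bypassing SMILES, for abstract-graph property tests.
make_graph <- function(n, edges, element = rep("C", n),
                       charge = rep(0L, n), n_h = rep(0L, n)) {
  edges <- if (length(edges)) matrix(as.integer(edges), ncol = 2,
                                     byrow = TRUE)
  else matrix(integer(), 0, 2)
  g <- list(element = element, charge = charge, n_h = as.integer(n_h),
            edges = edges,
            component = ilqsar:::graph_components(n, edges))
  class(g) <- "molecular_graph"
  g
}

# n-alkane heavy-atom path graph
alkane_graph <- function(n) {
  edges <- if (n > 1) cbind(1:(n - 1), 2:n) else matrix(integer(), 0, 2)
  n_h <- if (n == 1) 4L else c(3L, rep(2L, max(n - 2, 0)), 3L)
  make_graph(n, t(edges), n_h = n_h)
}

# Oracle all-pairs shortest paths by adjacency powers: d_ij = smallest k
# with (A^k)_ij > 0.
oracle_distances <- function(n, edges) {
  A <- matrix(0, n, n)
  if (nrow(edges)) { A[edges] <- 1; A[edges[, 2:1, drop = FALSE]] <- 1 }
  D <- matrix(Inf, n, n); diag(D) <- 0
  P <- diag(n)
  for (k in seq_len(n)) {
    P <- P %*% A
    hit <- P > 0 & !is.finite(D)
    D[hit] <- k
  }
  D
}

oracle_gmti <- function(g) {
  n <- length(g$element)
  D <- oracle_distances(n, g$edges)
  deg <- vapply(seq_len(n), function(i)
    sum(g$edges == i), numeric(1))
  s <- 0
  if (n >= 2)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      s <- s + deg[i] * deg[j] * D[i, j]
  s
}

oracle_mddd <- function(g) {
  n <- length(g$element)
  D <- oracle_distances(n, g$edges)
  sigma <- rowSums(D)
  mean(abs(sigma - mean(sigma)))
}

oracle_valence_degree <- function(g) {
  tab <- element_table()
  vapply(seq_along(g$element), function(i) {
    row <- tab[tab$symbol == g$element[i], ]
    zve <- row$Zv - g$charge[i]
    if (row$L <= 2) zve - g$n_h[i]
    else (zve - g$n_h[i]) / (row$Z - row$Zv - 1)
  }, numeric(1))
}

oracle_smtiv <- function(g) {
  n <- length(g$element)
  D <- oracle_distances(n, g$edges)
  A <- matrix(0, n, n)
  if (nrow(g$edges)) { A[g$edges] <- 1; A[g$edges[, 2:1, drop = FALSE]] <- 1 }
  dv <- oracle_valence_degree(g)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    s <- s + (A[i, j] + D[i, j]) * dv[j]
  s
}

oracle_psi_i_0 <- function(g) {
  tab <- element_table()
  dv <- oracle_valence_degree(g)
  n <- length(g$element)
  deg <- vapply(seq_len(n), function(i) sum(g$edges == i), numeric(1))
  s <- 0
  for (i in seq_len(n)) {
    L <- tab$L[tab$symbol == g$element[i]]
    d <- if (deg[i] == 0) 1 else deg[i]
    I <- ((2 / L)^2 * dv[i] + 1) / d
    s <- s + 1 / sqrt(I)
  }
  s
}

# All labeled connected graphs on n vertices (edge-subset enumeration).
connected_graphs <- function(n) {
  pairs <- t(utils::combn(n, 2))
  out <- list()
  for (mask in seq_len(2^nrow(pairs)) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(nrow(pairs)) - 1L)) > 0)
    edges <- pairs[sel, , drop = FALSE]
    if (all(is.finite(oracle_distances(n, edges))))
      out[[length(out) + 1L]] <- make_graph(n, t(edges))
  }
  out
}

# Seeded random connected graphs for sizes where enumeration is too large.
random_connected_graphs <- function(n, k, seed) {
  withr::with_seed(seed, {
    pairs <- t(utils::combn(n, 2))
    out <- list()
    while (length(out) < k) {
      sel <- which(stats::runif(nrow(pairs)) < 0.4)
      edges <- pairs[sel, , drop = FALSE]
      if (all(is.finite(oracle_distances(n, edges))))
        out[[length(out) + 1L]] <- make_graph(n, t(edges))
    }
    out
  })
}

# Cached expensive fixtures (parsed once per test run)
.cache <- new.env(parent = emptyenv())
fixture_registry <- function() {
  if (is.null(.cache$reg))
    .cache$reg <- load_ion_registry(ilqsar_example("ions.csv"))
  .cache$reg
}
fixture_ion_descriptors <- function() {
  if (is.null(.cache$idesc))
    .cache$idesc <- suppressWarnings(ion_descriptors(fixture_registry()))
  .cache$idesc
}
fixture_ils <- function() {
  if (is.null(.cache$ils))
    .cache$ils <- load_il_table(ilqsar_example("ils_synthetic24.csv"),
                                fixture_registry())
  .cache$ils
}
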