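# Shared in-code fixtures for the test suite.

# Expression matrix from a bare numeric matrix; metadata parsed from
# CONDITION_TIME_REPLICATE column names.
make_expr <- function(values) {
  expression_matrix(values, parse_sample_headers(colnames(values)))
}

# Tiny matrix: 3 genes x (2 conditions x 2 times x 1 replicate).
tiny_expr <- function() {
  m <- matrix(c(1, 2, 3, 4,
                2, 4, 6, 8,
                5, 5, 5, 5), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"),
                              c("A_0_1", "A_3_1", "B_0_1", "B_3_1")))
  make_expr(m)
}

# Undirected graph from a two-column edge matrix.
make_graph <- function(edges, vertices = NULL) {
  df <- data.frame(from = edges[, 1], to = edges[, 2],
                   stringsAsFactors = FALSE)
  if (is.null(vertices))
    igraph::graph_from_data_frame(df, directed = FALSE)
  else
    igraph::graph_from_data_frame(df, directed = FALSE,
                                  vertices = vertices)
}

path_graph <- function(nodes) {
  make_graph(cbind(nodes[-length(nodes)], nodes[-1]))
}

# Random connected graph on n named nodes: random tree plus extra edges.
random_graph <- function(n, extra = n, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  from <- nodes[vapply(2:n, function(i) sample(i - 1, 1), 1L)]
  tree <- cbind(from, nodes[2:n])
  more <- cbind(nodes[sample(n, extra, TRUE)],
                nodes[sample(n, extra, TRUE)])
  more <- more[more[, 1] != more[, 2], , drop = FALSE]
  igraph::simplify(make_graph(rbind(tree, more)))
}

# Random layout positions for a gene set (unit square).
random_positions <- function(genes, seed = 1) {
  set.seed(seed)
  matrix(runif(2 * length(genes)), ncol = 2,
         dimnames = list(genes, c("x", "y")))
}

# Naive double-loop signal-field oracle, independent of the separable
# implementation.
naive_field <- function(pos, e, sigma, grid_size) {
  centers <- (seq_len(grid_size) - 0.5) / grid_size
  if (length(sigma) == 1)
    sigma <- stats::setNames(rep(sigma, length(e)), names(e))
  out <- matrix(0, grid_size, grid_size)
  for (i in seq_len(grid_size)) {
    for (j in seq_len(grid_size)) {
      x <- centers[j]; y <- centers[i]
      s <- 0
      for (g in names(e)) {
        d2 <- (x - pos[g, 1])^2 + (y - pos[g, 2])^2
        s <- s + e[[g]] * exp(-d2 / (2 * sigma[[g]]^2))
      }
      out[i, j] <- s
    }
  }
  out
}

# Term-by-term energy oracle over unordered pairs.
naive_energy <- function(pos, l, k = 1, repulsion = TRUE) {
  n <- nrow(pos)
  e <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    e <- e + k^2 * (d - l[i, j])^2 / l[i, j] +
      (if (repulsion) k^2 / d else 0)
  }
  e
}

# Floyd-Warshall all-pairs shortest paths oracle.
floyd_warshall <- function(g) {
  n <- igraph::vcount(g)
  nodes <- igraph::V(g)$name
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  el <- igraph::as_edgelist(g, names = TRUE)
  for (r in seq_len(nrow(el))) {
    D[el[r, 1], el[r, 2]] <- 1
    D[el[r, 2], el[r, 1]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}
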