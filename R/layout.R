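#' Layout container
#'
#' Per-gene 2-D coordinates plus the optimization trace. Positions are a
#' numeric matrix with gene identifiers as rownames and columns x, y.
#'
#' @param positions n x 2 numeric matrix, rownames = genes.
#' @param energy_trace Numeric vector of accepted per-iteration energies.
#' @param converged Logical: did the energy decrease fall below epsilon?
#' @return A `gt_layout` object.
#' @export
gt_layout <- function(positions, energy_trace = numeric(0), converged = NA) {
  if (!is.matrix(positions) || ncol(positions) != 2 ||
      is.null(rownames(positions)))
    stop("`positions` must be an n x 2 matrix with gene rownames")
  colnames(positions) <- c("x", "y")
  structure(list(positions = positions, energy_trace = energy_trace,
                 converged = converged),
            class = "gt_layout")
}

#' @export
print.gt_layout <- function(x, ...) {
  cat("<gt_layout> ", nrow(x$positions), " genes",
      if (length(x$energy_trace))
        paste0(", ", length(x$energy_trace), " iterations, final energy ",
               signif(utils::tail(x$energy_trace, 1), 6),
               ", converged: ", x$converged),
      "\n", sep = "")
  invisible(x)
}

#' Extract the position matrix of a layout
#' @param layout A `gt_layout` (or a bare position matrix, returned as-is).
#' @return n x 2 numeric matrix with gene rownames.
#' @export
layout_positions <- function(layout) {
  if (inherits(layout, "gt_layout")) layout$positions else layout
}

#' Parameters of the layout energy minimization
#'
#' @param k Spring scaling constant (default 1).
#' @param area Display area mapped by the layout (default 1, the unit
#'   square the terrains are rasterized on).
#' @param eta Initial gradient-descent learning rate (default 0.01);
#'   steps are halved by backtracking until the energy does not increase.
#' @param epsilon Convergence tolerance on the per-iteration energy
#'   decrease (default 1e-6).
#' @param max_iterations Iteration cap (default 5000).
#' @param seed Seed for the random initial positions (default 17).
#' @param disconnected_distance_policy How to define graph distances
#'   between components: `"diameter_plus_one"` substitutes the largest
#'   finite diameter + 1, `"largest_component_only"` drops minor
#'   components with a warning.
#' @param spring_scope `"all_pairs"` (default; the spring term is applied
#'   to every node pair using graph-theoretic ideal distances, classic
#'   Kamada-Kawai behavior) or `"edges_only"` (spring term restricted to
#'   network edges; the repulsive term always covers all pairs).
#' @param repulsion Include the k^2 / d repulsive term (default `TRUE`;
#'   disabling it gives the pure-spring system whose two-node optimum is
#'   exactly the ideal distance, a useful sanity limit).
#' @return A `gt_layout_params` list.
#' @export
layout_params <- function(k = 1, area = 1, eta = 0.01, epsilon = 1e-6,
                          max_iterations = 5000, seed = 17,
                          disconnected_distance_policy =
                            c("diameter_plus_one", "largest_component_only"),
                          spring_scope = c("all_pairs", "edges_only"),
                          repulsion = TRUE) {
  if (k <= 0 || area <= 0) stop("`k` and `area` must be positive")
  if (eta <= 0) stop("`eta` must be positive")
  if (epsilon <= 0) stop("`epsilon` must be positive")
  if (max_iterations < 1) stop("`max_iterations` must be >= 1")
  structure(list(
    k = k, area = area, eta = eta, epsilon = epsilon,
    max_iterations = as.integer(max_iterations), seed = as.integer(seed),
    disconnected_distance_policy = match.arg(disconnected_distance_policy),
    spring_scope = match.arg(spring_scope),
    repulsion = isTRUE(repulsion)
  ), class = "gt_layout_params")
}

#' All-pairs shortest path lengths with a disconnected-pair policy
#'
#' Unweighted breadth-first hop counts between every pair of nodes. Pairs
#' in different components have no finite distance; under
#' `"diameter_plus_one"` they are assigned the largest finite diameter
#' plus one so the energy stays defined, under
#' `"largest_component_only"` the minor components are dropped with a
#' warning.
#'
#' @param network An undirected igraph.
#' @param policy Disconnected-pair rule (see [layout_params()]).
#' @return Symmetric numeric matrix of hop counts, dimnames = genes.
#' @export
shortest_path_lengths <- function(network,
                                  policy = c("diameter_plus_one",
                                             "largest_component_only")) {
  policy <- match.arg(policy)
  if (igraph::vcount(network) == 0) stop("empty graph")
  if (policy == "largest_component_only") {
    comp <- igraph::components(network)
    if (comp$no > 1) {
      keep <- which(comp$membership == which.max(comp$csize))
      warning("dropping ", igraph::vcount(network) - length(keep),
              " node(s) outside the largest component")
      network <- igraph::induced_subgraph(network, keep)
    }
  }
  L <- igraph::distances(network, algorithm = "unweighted")
  if (any(is.infinite(L))) {
    sub <- max(L[is.finite(L)]) + 1
    L[is.infinite(L)] <- sub
  }
  L
}

#' Ideal layout distances from hop counts
#'
#' Scales graph-theoretic distances to display coordinates:
#' l_ij = k * sqrt(area / |V|) * L_ij.
#'
#' @param L Hop-count matrix from [shortest_path_lengths()].
#' @param k,area See [layout_params()].
#' @param v_count Number of vertices |V|.
#' @return Matrix of ideal distances, same shape as `L`.
#' @export
ideal_distances <- function(L, k = 1, area = 1, v_count = nrow(L)) {
  if (v_count <= 0) stop("`v_count` must be positive")
  if (any(!is.finite(L))) stop("hop counts must be finite")
  k * sqrt(area / v_count) * L
}

# Pairwise Euclidean distance matrix with an informative error on
# coincident nodes (the repulsive term diverges there).
.pairwise_dist <- function(pos) {
  D <- as.matrix(stats::dist(pos))
  zero <- which(D == 0 & upper.tri(D), arr.ind = TRUE)
  if (nrow(zero) > 0)
    stop("coincident nodes: ", rownames(pos)[zero[1, 1]], " and ",
         rownames(pos)[zero[1, 2]])
  D
}

# Spring-scope mask: 1 where the spring term applies, 0 elsewhere.
.spring_mask <- function(n, edges, spring_scope, node_names) {
  if (spring_scope == "all_pairs") return(matrix(1, n, n))
  mask <- matrix(0, n, n, dimnames = list(node_names, node_names))
  if (!is.null(edges) && nrow(edges) > 0) {
    ia <- match(edges[, 1], node_names)
    ib <- match(edges[, 2], node_names)
    mask[cbind(ia, ib)] <- 1
    mask[cbind(ib, ia)] <- 1
  }
  mask
}

#' Layout energy
#'
#' Sum over unordered node pairs of a spring term penalizing deviation of
#' the Euclidean distance d_ij from the ideal distance l_ij, plus a
#' repulsive term:
#' E = sum_\{i<j\} k^2 (d_ij - l_ij)^2 / l_ij + k^2 / d_ij.
#' By default the spring term covers all pairs (classic Kamada-Kawai);
#' `spring_scope = "edges_only"` restricts it to network edges.
#'
#' @param positions n x 2 position matrix with gene rownames (or a
#'   `gt_layout`).
#' @param l Ideal-distance matrix from [ideal_distances()].
#' @param k Scaling constant.
#' @param edges Two-column character matrix of edges (needed only for
#'   `spring_scope = "edges_only"`).
#' @param spring_scope,repulsion See [layout_params()].
#' @return Scalar energy.
#' @export
layout_energy <- function(positions, l, k = 1, edges = NULL,
                          spring_scope = "all_pairs", repulsion = TRUE) {
  pos <- layout_positions(positions)
  D <- .pairwise_dist(pos)
  mask <- .spring_mask(nrow(pos), edges, spring_scope, rownames(pos))
  up <- upper.tri(D)
  spring <- mask[up] * k^2 * (D[up] - l[up])^2 / l[up]
  sum(spring) + if (repulsion) sum(k^2 / D[up]) else 0
}

#' Analytic gradient of the layout energy
#'
#' Partial derivatives of [layout_energy()] with respect to each node
#' position. For one pair, dE/dd = 2 k^2 (d - l) / l - k^2 / d^2 and the
#' gradient on node i is dE/dd times the unit vector from j to i.
#'
#' @inheritParams layout_energy
#' @return n x 2 matrix of gradients, same rownames as `positions`.
#' @export
layout_energy_gradient <- function(positions, l, k = 1, edges = NULL,
                                   spring_scope = "all_pairs",
                                   repulsion = TRUE) {
  pos <- layout_positions(positions)
  n <- nrow(pos)
  D <- .pairwise_dist(pos)
  mask <- .spring_mask(n, edges, spring_scope, rownames(pos))
  W <- matrix(0, n, n)
  off <- row(D) != col(D)
  W[off] <- mask[off] * 2 * k^2 * (D[off] - l[off]) / l[off] -
    (if (repulsion) k^2 / D[off]^2 else 0)
  C <- W
  C[off] <- W[off] / D[off]
  g <- cbind(rowSums(C) * pos[, 1] - C %*% pos[, 1],
             rowSums(C) * pos[, 2] - C %*% pos[, 2])
  dimnames(g) <- dimnames(pos)
  g
}

# Run a block of code with a temporary RNG seed, restoring global state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Kamada-Kawai layout by gradient descent
#'
#' Positions the network's genes in the plane by minimizing
#' [layout_energy()]: seeded uniform random initialization in the unit
#' square, then gradient descent with backtracking step halving so that
#' accepted iterates never increase the energy. Iteration stops when the
#' energy decrease falls below `epsilon` or after `max_iterations`.
#'
#' @param network An undirected igraph with at least two nodes.
#' @param params A [layout_params()] object.
#' @return A `gt_layout` with positions, the accepted energy trace, and a
#'   convergence flag. Positions are not yet normalized to the unit
#'   square; apply [normalize_layout()] before rasterizing.
#' @export
kk_layout <- function(network, params = layout_params()) {
  stopifnot(inherits(params, "gt_layout_params"))
  L <- shortest_path_lengths(network, params$disconnected_distance_policy)
  n <- nrow(L)
  if (n < 2) stop("layout needs at least two nodes")
  l <- ideal_distances(L, params$k, params$area, n)
  nodes <- rownames(L)
  edges <- NULL
  if (params$spring_scope == "edges_only")
    edges <- igraph::as_edgelist(network, names = TRUE)
  pos <- .with_seed(params$seed, {
    matrix(stats::runif(2 * n), ncol = 2, dimnames = list(nodes, c("x", "y")))
  })
  e_fun <- function(p) layout_energy(p, l, params$k, edges,
                                     params$spring_scope, params$repulsion)
  g_fun <- function(p) layout_energy_gradient(p, l, params$k, edges,
                                              params$spring_scope,
                                              params$repulsion)
  e_cur <- e_fun(pos)
  trace <- e_cur
  converged <- FALSE
  for (it in seq_len(params$max_iterations)) {
    g <- g_fun(pos)
    step <- params$eta
    repeat {
      cand <- pos - step * g
      e_new <- tryCatch(e_fun(cand), error = function(e) Inf)
      if (e_new <= e_cur || step < 1e-14) break
      step <- step / 2
    }
    if (e_new > e_cur) { # no decreasing step found: local minimum
      converged <- TRUE
      break
    }
    pos <- cand
    if (e_cur - e_new < params$epsilon) {
      e_cur <- e_new
      trace <- c(trace, e_cur)
      converged <- TRUE
      break
    }
    e_cur <- e_new
    trace <- c(trace, e_cur)
  }
  gt_layout(pos, energy_trace = trace, converged = converged)
}

#' Normalize a layout into the unit square
#'
#' Applies one uniform scale and translation (a similarity transform, so
#' all distance ratios are preserved) mapping the bounding box into
#' [0.05, 0.95]^2: the longer side spans the full range and the shorter
#' side is centered.
#'
#' @param layout A `gt_layout` with at least two distinct positions.
#' @return The normalized `gt_layout`.
#' @export
normalize_layout <- function(layout) {
  pos <- layout_positions(layout)
  rng_x <- range(pos[, 1]); rng_y <- range(pos[, 2])
  span <- max(diff(rng_x), diff(rng_y))
  if (span == 0) stop("all layout positions coincide")
  scale <- 0.9 / span
  ctr <- c(mean(rng_x), mean(rng_y))
  out <- sweep(pos, 2, ctr) * scale
  out <- sweep(out, 2, c(0.5, 0.5), `+`)
  res <- gt_layout(out, energy_trace = layout$energy_trace,
                   converged = layout$converged)
  res
}
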