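test_that("shortest paths match hop counts and the disconnected policy", {
  g <- path_graph(c("a", "b", "c"))
  L <- shortest_path_lengths(g)
  expect_equal(L["a", "c"], 2)

  # diameter-3 component plus an isolated pair: substitute = 4
  g2 <- make_graph(cbind(c("a", "b", "c", "x"), c("b", "c", "d", "y")))
  L2 <- shortest_path_lengths(g2, "diameter_plus_one")
  expect_equal(L2["a", "d"], 3)
  expect_equal(L2["a", "x"], 4)

  expect_warning(L3 <- shortest_path_lengths(g2, "largest_component_only"),
                 "dropping 2")
  expect_setequal(rownames(L3), c("a", "b", "c", "d"))
})

test_that("shortest paths equal a Floyd-Warshall oracle on random graphs", {
  for (seed in 1:3) {
    g <- random_graph(12, extra = 8, seed = seed)
    L <- shortest_path_lengths(g)
    FW <- floyd_warshall(g)
    expect_equal(L[rownames(FW), colnames(FW)], FW)
  }
})

test_that("ideal distances scale hop counts by k * sqrt(area/|V|)", {
  L <- matrix(c(0, 2, 2, 0), 2)
  expect_equal(ideal_distances(L, k = 1, area = 1, v_count = 4)[1, 2], 1.0)
  expect_equal(ideal_distances(matrix(c(0, 1, 1, 0), 2),
                               k = 2, area = 9, v_count = 1)[1, 2], 6)
  expect_equal(ideal_distances(3 * L, 1, 1, 4), 3 * ideal_distances(L, 1, 1, 4))
})

test_that("energy matches closed forms and a term-by-term oracle", {
  two <- function(d) {
    pos <- rbind(a = c(0, 0), b = c(d, 0))
    colnames(pos) <- c("x", "y")
    layout_energy(pos, matrix(c(0, 1, 1, 0), 2), k = 1)
  }
  expect_equal(two(1), 1)          # spring term vanishes, repulsion 1/1
  expect_equal(two(2), 1.5)        # (2-1)^2/1 + 1/2

  for (seed in 1:3) {
    pos <- random_positions(sprintf("n%d", 1:8), seed = seed)
    set.seed(seed + 100)
    L <- matrix(sample(1:4, 64, TRUE), 8)
    L <- (L + t(L)) / 2; diag(L) <- 0
    l <- ideal_distances(L, 1, 1, 8)
    expect_equal(layout_energy(pos, l, k = 1.3),
                 naive_energy(pos, l, k = 1.3), tolerance = 1e-12)
  }
})

test_that("energy errors on coincident nodes, naming the pair", {
  pos <- rbind(a = c(0.2, 0.2), b = c(0.2, 0.2))
  colnames(pos) <- c("x", "y")
  expect_error(layout_energy(pos, matrix(c(0, 1, 1, 0), 2)), "a.*b")
})

test_that("energy is invariant under rigid motions", {
  pos <- random_positions(sprintf("n%d", 1:6), seed = 2)
  set.seed(3)
  L <- matrix(sample(1:3, 36, TRUE), 6); L <- (L + t(L)) / 2; diag(L) <- 0
  l <- ideal_distances(L, 1, 1, 6)
  e0 <- layout_energy(pos, l)
  for (i in 1:5) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    shift <- matrix(rnorm(2), nrow(pos), 2, byrow = TRUE)
    moved <- pos %*% R + shift
    rownames(moved) <- rownames(pos)
    expect_equal(layout_energy(moved, l), e0, tolerance = 1e-9)
  }
})

test_that("analytic gradient matches central differences", {
  for (seed in 1:4) {
    n <- 7
    pos <- random_positions(sprintf("n%d", 1:n), seed = seed)
    set.seed(seed + 50)
    L <- matrix(sample(1:3, n * n, TRUE), n)
    L <- (L + t(L)) / 2; diag(L) <- 0
    l <- ideal_distances(L, 1, 1, n)
    gr <- layout_energy_gradient(pos, l)
    h <- 1e-6
    num <- matrix(0, n, 2)
    for (i in seq_len(n)) for (j in 1:2) {
      p1 <- pos; p1[i, j] <- p1[i, j] + h
      p2 <- pos; p2[i, j] <- p2[i, j] - h
      num[i, j] <- (layout_energy(p1, l) - layout_energy(p2, l)) / (2 * h)
    }
    expect_lt(max(abs(gr - num) / pmax(abs(num), 1e-4)), 1e-5)
  }
})

test_that("gradient vanishes at the two-node optimum", {
  # 1-D optimum of (d-1)^2 + 1/d located independently
  d_star <- uniroot(function(d) 2 * (d - 1) - 1 / d^2, c(1, 2),
                    tol = 1e-14)$root
  pos <- rbind(a = c(0, 0), b = c(d_star, 0))
  colnames(pos) <- c("x", "y")
  gr <- layout_energy_gradient(pos, matrix(c(0, 1, 1, 0), 2))
  expect_lt(max(abs(gr)), 1e-8)
})

test_that("symmetric equilateral gradients are purely radial", {
  th <- 2 * pi * (0:2) / 3
  r0 <- 0.4
  pos <- cbind(x = 0.5 + r0 * cos(th), y = 0.5 + r0 * sin(th))
  rownames(pos) <- c("a", "b", "c")
  l <- matrix(1, 3, 3); diag(l) <- 0
  gr <- layout_energy_gradient(pos, l)
  for (i in 1:3) {
    radial <- c(cos(th[i]), sin(th[i]))
    tangential <- gr[i, ] - sum(gr[i, ] * radial) * radial
    expect_lt(max(abs(tangential)), 1e-9)
  }
})

test_that("two connected nodes settle at the 1-D oracle separation", {
  d_star <- optimize(function(d) (d - 1)^2 + 1 / d, c(0.1, 5),
                     tol = 1e-12)$minimum
  g <- path_graph(c("a", "b"))
  lay <- kk_layout(g, layout_params(k = 1, area = 2, eta = 0.05,
                                    epsilon = 1e-12,
                                    max_iterations = 20000))
  sep <- as.numeric(dist(layout_positions(lay)))
  expect_equal(sep, d_star, tolerance = 1e-3)
})

test_that("spring-only system converges to the ideal separation", {
  g <- path_graph(c("a", "b"))
  pars <- layout_params(k = 1, area = 4, eta = 0.05, epsilon = 1e-14,
                        max_iterations = 20000, repulsion = FALSE)
  lay <- kk_layout(g, pars)
  # l = k*sqrt(area/2)*1
  expect_equal(as.numeric(dist(layout_positions(lay))), sqrt(2),
               tolerance = 1e-4)
})

test_that("accepted energy trace is monotonically non-increasing", {
  g <- random_graph(8, extra = 6, seed = 4)
  for (seed in 1:20) {
    lay <- kk_layout(g, layout_params(seed = seed, max_iterations = 120))
    expect_true(all(diff(lay$energy_trace) <= 0))
  }
})

test_that("different seeds reach energies within 5 percent", {
  g <- path_graph(c("a", "b", "c", "d"))
  pars1 <- layout_params(seed = 1, epsilon = 1e-10, max_iterations = 20000)
  pars2 <- layout_params(seed = 2, epsilon = 1e-10, max_iterations = 20000)
  e1 <- tail(kk_layout(g, pars1)$energy_trace, 1)
  e2 <- tail(kk_layout(g, pars2)$energy_trace, 1)
  expect_lt(abs(e1 - e2) / min(e1, e2), 0.05)
})

test_that("same seed and inputs give bit-identical layouts", {
  g <- random_graph(10, extra = 5, seed = 9)
  l1 <- kk_layout(g, layout_params(seed = 31, max_iterations = 50))
  l2 <- kk_layout(g, layout_params(seed = 31, max_iterations = 50))
  expect_identical(l1, l2)
})

test_that("layout computation leaves the global RNG state alone", {
  g <- path_graph(c("a", "b", "c"))
  set.seed(123)
  before <- .Random.seed
  kk_layout(g, layout_params(max_iterations = 10))
  expect_identical(.Random.seed, before)
})

test_that("layout parameters are validated", {
  expect_error(layout_params(eta = 0), "eta")
  expect_error(layout_params(epsilon = -1), "epsilon")
  expect_error(layout_params(k = 0), "positive")
})

test_that("normalization maps the bounding box into [0.05, 0.95]^2", {
  pos <- rbind(a = c(0, 0), b = c(10, 10))
  colnames(pos) <- c("x", "y")
  out <- layout_positions(normalize_layout(gt_layout(pos)))
  expect_equal(unname(out["a", ]), c(0.05, 0.05))
  expect_equal(unname(out["b", ]), c(0.95, 0.95))

  pos2 <- rbind(a = c(0, 0), b = c(10, 5))
  colnames(pos2) <- c("x", "y")
  out2 <- layout_positions(normalize_layout(gt_layout(pos2)))
  expect_equal(range(out2[, "x"]), c(0.05, 0.95))
  expect_equal(range(out2[, "y"]), c(0.275, 0.725))
})

test_that("normalization preserves distance ratios and rejects a point mass", {
  pos <- random_positions(sprintf("n%d", 1:6), seed = 12) * 40 - 3
  out <- layout_positions(normalize_layout(gt_layout(pos)))
  r1 <- as.vector(dist(pos)); r2 <- as.vector(dist(out))
  expect_equal(r2 / r2[1], r1 / r1[1], tolerance = 1e-12)

  same <- rbind(a = c(1, 1), b = c(1, 1))
  colnames(same) <- c("x", "y")
  expect_error(normalize_layout(gt_layout(same)), "coincide")
})

test_that("layout distances agree qualitatively with igraph's Kamada-Kawai", {
  # independent cross-check: both layouts should separate the two
  # modules of a barbell-like graph
  g <- make_graph(cbind(c("a1", "a1", "a2", "b1", "b1", "b2", "a1"),
                        c("a2", "a3", "a3", "b2", "b3", "b3", "b1")))
  lay <- normalize_layout(kk_layout(g, layout_params(seed = 5,
                                                     max_iterations = 3000)))
  pos <- layout_positions(lay)
  ref <- igraph::layout_with_kk(g)
  rownames(ref) <- igraph::V(g)$name
  sep <- function(p) {
    a <- grep("^a", rownames(p)); b <- grep("^b", rownames(p))
    intra <- c(dist(p[a, ]), dist(p[b, ]))
    inter <- as.vector(as.matrix(dist(p))[a, b])
    mean(inter) / mean(intra)
  }
  expect_gt(sep(pos), 1)
  expect_gt(sep(ref), 1)
})
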