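# Small two-condition, six-time-point matrix over 4 genes, 2 replicates.
small_timecourse <- function(seed = 77, conditions = c("TM", "DMSO")) {
  set.seed(seed)
  genes <- paste0("g", 1:4)
  tp <- c(0, 3, 6, 9, 12, 24)
  cols <- expand.grid(rep = 1:2, t = tp, cond = conditions,
                      stringsAsFactors = FALSE)
  ids <- sprintf("%s_%g_%d", cols$cond, cols$t, cols$rep)
  m <- matrix(rnorm(length(genes) * length(ids)), nrow = length(genes),
              dimnames = list(genes, ids))
  make_expr(m)
}

small_layout <- function(genes = paste0("g", 1:4), seed = 78) {
  gt_layout(random_positions(genes, seed = seed))
}

test_that("a series holds one field per time point on one frozen layout", {
  x <- small_timecourse()
  lay <- small_layout()
  s <- build_series(x, lay, "TM", grid_size = 16)
  expect_length(s$fields, 6)
  expect_equal(s$time_points, c(0, 3, 6, 9, 12, 24))
  expect_identical(layout_positions(s$layout), layout_positions(lay))
  expect_equal(s$fields[[3]]$time_h, 6)
  # replicate means drive the fields
  expect_equal(s$expressions[, "0"],
               rowMeans(x$values[, c("TM_0_1", "TM_0_2")]))
})

test_that("constant expression gives pixelwise identical fields", {
  genes <- paste0("g", 1:4)
  tp <- c(0, 6, 12)
  ids <- sprintf("TM_%g_1", tp)
  m <- matrix(rep(c(1, -2, 0.5, 3), length(tp)), nrow = 4,
              dimnames = list(genes, ids))
  s <- build_series(make_expr(m), small_layout(), "TM", grid_size = 16)
  expect_identical(s$fields[[1]]$grid, s$fields[[2]]$grid)
  expect_identical(s$fields[[1]]$grid, s$fields[[3]]$grid)
})

test_that("series construction ignores sample column order", {
  x <- small_timecourse()
  perm <- sample(ncol(x$values))
  xp <- expression_matrix(x$values[, perm], x$samples[perm, ])
  s1 <- build_series(x, small_layout(), "TM", grid_size = 16)
  s2 <- build_series(xp, small_layout(), "TM", grid_size = 16)
  expect_equal(s1$expressions, s2$expressions)
  expect_identical(s1$fields[[4]]$grid, s2$fields[[4]]$grid)
})

test_that("duplicating every replicate leaves the series unchanged", {
  x <- small_timecourse()
  dup_meta <- x$samples
  dup_meta$replicate <- dup_meta$replicate + 10L
  dup_meta$sample_id <- sprintf("%s_%g_%d", dup_meta$condition,
                                dup_meta$time_h, dup_meta$replicate)
  dup_vals <- x$values
  colnames(dup_vals) <- dup_meta$sample_id
  xdup <- expression_matrix(cbind(x$values, dup_vals),
                            rbind(x$samples, dup_meta))
  s1 <- build_series(x, small_layout(), "TM", grid_size = 16)
  s2 <- build_series(xdup, small_layout(), "TM", grid_size = 16)
  expect_equal(s1$expressions, s2$expressions)
})

test_that("unknown conditions are reported with the available ones", {
  x <- small_timecourse()
  expect_error(build_series(x, small_layout(), "TMW", grid_size = 16),
               "TM.*DMSO|DMSO.*TM")
})

test_that("interval deltas follow the symmetric threshold rule", {
  genes <- paste0("g", 1:3)
  tp <- c(0, 3)
  m <- cbind(`TM_0_1` = c(0, 0, 0), `TM_3_1` = c(2.5, -0.3, -1.7))
  rownames(m) <- genes
  s <- build_series(make_expr(m), small_layout(genes), "TM",
                    grid_size = 16)
  d <- interval_deltas(s, threshold = 1.0)
  expect_length(d, 1)
  expect_identical(d[[1]]$up_genes, "g1")
  expect_identical(d[[1]]$down_genes, "g3")
  expect_equal(d[[1]]$interval, c(0, 3))

  d2 <- interval_deltas(s, threshold = 10)
  expect_length(d2[[1]]$up_genes, 0)
  expect_length(d2[[1]]$down_genes, 0)
  expect_error(interval_deltas(s, threshold = 0), "positive")
})

test_that("six time points yield five interval deltas", {
  s <- build_series(small_timecourse(), small_layout(), "TM",
                    grid_size = 16)
  expect_length(interval_deltas(s, 1.0), 5)
})

test_that("delta gene sets do not depend on grid resolution", {
  x <- small_timecourse(seed = 80)
  for (g in c(16, 32, 64)) {
    s <- build_series(x, small_layout(), "TM", grid_size = g)
    d <- interval_deltas(s, 0.8)
    if (g == 16) ref <- d
    for (i in seq_along(d)) {
      expect_identical(d[[i]]$up_genes, ref[[i]]$up_genes)
      expect_identical(d[[i]]$down_genes, ref[[i]]$down_genes)
    }
  }
})

test_that("top-k mode returns at most k genes per direction, signed", {
  genes <- paste0("g", 1:4)
  m <- cbind(`TM_0_1` = c(0, 0, 0, 0), `TM_3_1` = c(3, 1, -2, 0.5))
  rownames(m) <- genes
  s <- build_series(make_expr(m), small_layout(), "TM", grid_size = 16)
  d <- interval_deltas(s, mode = "top_k", k = 2)[[1]]
  expect_identical(d$up_genes, c("g1", "g2"))
  expect_identical(d$down_genes, "g3")  # only one actual decrease
})

test_that("delta terrain equals the difference of endpoint terrains", {
  x <- small_timecourse(seed = 81)
  s <- build_series(x, small_layout(), "TM", grid_size = 24)
  d <- interval_deltas(s, 1.0)
  for (i in seq_along(d)) {
    expect_lt(max(abs(d[[i]]$field$grid -
                        (s$fields[[i + 1]]$grid - s$fields[[i]]$grid))),
              1e-10)
  }
})

test_that("adaptive series use per-gene sigma on delta fields only", {
  x <- small_timecourse(seed = 82)
  pol <- sigma_policy("adaptive", sigma_base = 0.03)
  s <- build_series(x, small_layout(), "TM", policy = pol, grid_size = 16)
  expect_equal(s$fields[[1]]$sigma_used, 0.03)  # absolute field: fixed
  d <- interval_deltas(s, 1.0)
  expect_length(d[[1]]$field$sigma_used, 4)     # delta field: per gene
})

test_that("interpolated frames are exact at endpoints, linear inside", {
  x <- small_timecourse(seed = 83)
  s <- build_series(x, small_layout(), "TM", grid_size = 16)
  fr <- interpolate_frames(s, 4)
  expect_length(fr, 5 * 4 + 1)
  expect_lt(max(abs(fr[[1]]$grid - s$fields[[1]]$grid)), 1e-12)
  expect_lt(max(abs(fr[[21]]$grid - s$fields[[6]]$grid)), 1e-12)
  expect_lt(max(abs(fr[[5]]$grid - s$fields[[2]]$grid)), 1e-12)

  fr2 <- interpolate_frames(s, 2)
  mid <- fr2[[2]]$grid
  expect_lt(max(abs(mid - (s$fields[[1]]$grid + s$fields[[2]]$grid) / 2)),
            1e-10)
  expect_error(interpolate_frames(s, 0), ">= 1")
})

test_that("variability summary normalizes counts into proportions", {
  set.seed(84)
  genes <- sprintf("g%02d", 1:40)
  # condition A moves 30 genes, condition B moves 10
  mk <- function(cond, n_eff) {
    v0 <- matrix(0, 40, 1, dimnames = list(genes,
                                           sprintf("%s_0_1", cond)))
    v1 <- matrix(0, 40, 1, dimnames = list(genes,
                                           sprintf("%s_3_1", cond)))
    v1[seq_len(n_eff), 1] <- 5
    cbind(v0, v1)
  }
  x <- make_expr(cbind(mk("A", 30), mk("B", 10)))
  comp <- data.frame(condition = c("A", "B"), t_a = 0, t_b = 3)
  vs <- variability_summary(x, comp, threshold = 1)
  expect_equal(vs$count, c(30L, 10L))
  expect_equal(vs$proportion, c(0.75, 0.25))
  expect_equal(sum(vs$proportion), 1, tolerance = 1e-12)

  expect_error(variability_summary(x, comp, threshold = 100),
               "undefined")
})
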