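#' Gaussian smoothing policy
#'
#' Fixed-sigma smoothing uses one dispersion for every gene (0.03 in
#' normalized unit-square coordinates by default). The adaptive variant
#' modulates sigma per gene by the magnitude of its expression change:
#' the largest change gets `sigma_min` (sharpest peak), zero change gets
#' `sigma_max` (smoothest), linearly in between.
#'
#' @param mode `"fixed"` or `"adaptive"`.
#' @param sigma_base Baseline dispersion (default 0.03, unit-square
#'   coordinates).
#' @param sigma_min,sigma_max Bounds of the adaptive range; defaults
#'   0.5 and 2 times `sigma_base`.
#' @return A `gt_sigma_policy` list.
#' @export
sigma_policy <- function(mode = c("fixed", "adaptive"), sigma_base = 0.03,
                         sigma_min = 0.5 * sigma_base,
                         sigma_max = 2 * sigma_base) {
  mode <- match.arg(mode)
  if (!(sigma_min > 0 && sigma_min <= sigma_base && sigma_base <= sigma_max))
    stop("need 0 < sigma_min <= sigma_base <= sigma_max")
  structure(list(mode = mode, sigma_base = sigma_base,
                 sigma_min = sigma_min, sigma_max = sigma_max),
            class = "gt_sigma_policy")
}

#' Terrain field container
#' @param grid H x W numeric matrix, stored y-up: row i holds the values
#'   at height y = (i - 0.5) / H, so row 1 is the bottom of the square.
#' @param sigma_used Scalar or per-gene sigma used to build the field.
#' @param time_h,condition Optional provenance metadata.
#' @return A `gt_field` object.
#' @export
gt_field <- function(grid, sigma_used = NA_real_, time_h = NA_real_,
                     condition = NA_character_) {
  if (!is.matrix(grid) || nrow(grid) < 16 || ncol(grid) < 16)
    stop("field grid must be a matrix of at least 16 x 16")
  if (!all(is.finite(grid))) stop("field values must be finite")
  structure(list(grid = grid, extent = c(0, 1, 0, 1),
                 sigma_used = sigma_used, time_h = time_h,
                 condition = condition),
            class = "gt_field")
}

#' @export
print.gt_field <- function(x, ...) {
  cat("<gt_field> ", nrow(x$grid), "x", ncol(x$grid),
      ", range [", signif(min(x$grid), 4), ", ", signif(max(x$grid), 4),
      "]", if (!is.na(x$time_h)) paste0(", t = ", x$time_h, " h"),
      if (!is.na(x$condition)) paste0(", ", x$condition), "\n", sep = "")
  invisible(x)
}

#' Rasterize expression on a layout as a Gaussian signal field
#'
#' Evaluates S(x, y) = sum_i e_i exp(-((x - x_i)^2 + (y - y_i)^2) /
#' (2 sigma_i^2)) at the pixel centers of a square raster over the unit
#' square. Each gene contributes an isotropic Gaussian bump centered at
#' its layout position with amplitude equal to its expression value;
#' positive amplitudes are upregulation, negative downregulation. The sum
#' runs over all genes exactly by default (no kernel truncation), so the
#' field is linear in the expression vector.
#'
#' The isotropic Gaussian is separable, so the field is assembled from
#' per-axis kernel matrices rather than a loop over pixels.
#'
#' @param layout A `gt_layout` (or position matrix) covering every
#'   expression gene.
#' @param expression Named numeric vector, gene -> amplitude e_i.
#' @param sigma Scalar dispersion, or a named per-gene vector (as
#'   produced by [adaptive_sigma()]).
#' @param grid_size Raster side length in pixels (default 512, min 16).
#'   Pixel centers sit at (j - 0.5) / grid_size.
#' @param truncate If `TRUE`, zero each gene's kernel beyond 4 sigma per
#'   axis: faster and approximate, off by default.
#' @param time_h,condition Metadata stored on the result.
#' @return A `gt_field`.
#' @export
signal_field <- function(layout, expression, sigma = 0.03, grid_size = 512,
                         truncate = FALSE, time_h = NA_real_,
                         condition = NA_character_) {
  pos <- layout_positions(layout)
  if (is.null(names(expression)))
    stop("`expression` must be a named vector")
  missing <- setdiff(names(expression), rownames(pos))
  if (length(missing) > 0)
    stop("gene(s) missing from layout: ", paste(missing, collapse = ", "))
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (grid_size < 16) stop("grid_size must be at least 16")
  g <- names(expression)
  if (length(sigma) == 1) {
    sig <- rep(sigma, length(g))
  } else {
    if (is.null(names(sigma)) || !all(g %in% names(sigma)))
      stop("per-gene sigma must be named and cover every expression gene")
    sig <- unname(sigma[g])
  }
  xy <- pos[g, , drop = FALSE]
  centers <- (seq_len(grid_size) - 0.5) / grid_size
  kern <- function(coord) {
    # grid_size x n_genes matrix of 1-D Gaussian factors
    d <- outer(centers, xy[, coord], `-`)
    s <- matrix(sig, nrow = grid_size, ncol = length(g), byrow = TRUE)
    k <- exp(-d^2 / (2 * s^2))
    if (truncate) k[abs(d) > 4 * s] <- 0
    k
  }
  ky <- kern("y")
  kx <- kern("x")
  grid <- ky %*% (unname(expression) * t(kx))
  gt_field(grid, sigma_used = if (length(sigma) == 1) sigma else sig,
           time_h = time_h, condition = condition)
}

#' Per-gene adaptive sigma from expression-change magnitudes
#'
#' Maps each gene's absolute expression change, rescaled by the largest
#' change, linearly onto [sigma_min, sigma_max] in reverse: the gene with
#' the largest |delta| gets `sigma_min`, sharpening transient spikes,
#' while unchanged genes get `sigma_max`, emphasizing sustained trends.
#'
#' @param delta Named numeric vector of expression changes.
#' @param policy A [sigma_policy()] with mode `"adaptive"`.
#' @return Named per-gene sigma vector. If every delta is zero the
#'   mapping is undefined and all genes get `sigma_base`, with a warning.
#' @export
adaptive_sigma <- function(delta, policy = sigma_policy("adaptive")) {
  stopifnot(inherits(policy, "gt_sigma_policy"))
  if (policy$mode != "adaptive")
    stop("`policy` must have mode \"adaptive\"")
  if (is.null(names(delta))) stop("`delta` must be a named vector")
  amax <- max(abs(delta))
  if (amax == 0) {
    warning("all deltas are zero; using sigma_base for every gene")
    return(stats::setNames(rep(policy$sigma_base, length(delta)),
                           names(delta)))
  }
  m <- abs(delta) / amax
  stats::setNames(policy$sigma_max - m * (policy$sigma_max - policy$sigma_min),
                  names(delta))
}

#' Expression change between two time points
#'
#' @param expr_t1,expr_t2 Named numeric vectors over the same gene set.
#' @return Named vector of differences e(t2) - e(t1), in `expr_t1` gene
#'   order.
#' @export
delta_expression <- function(expr_t1, expr_t2) {
  if (is.null(names(expr_t1)) || is.null(names(expr_t2)))
    stop("expression vectors must be named")
  if (!setequal(names(expr_t1), names(expr_t2)))
    stop("gene sets differ between the two time points")
  expr_t2[names(expr_t1)] - expr_t1
}
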