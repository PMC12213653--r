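# Replicate-aggregated genes x time matrix for one condition.
.condition_profile <- function(x, condition, genes = NULL,
                               aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  sel <- x$samples$condition == condition
  if (!any(sel))
    stop("condition '", condition, "' not found; available: ",
         paste(unique(x$samples$condition), collapse = ", "))
  if (is.null(genes)) genes <- rownames(x$values)
  missing <- setdiff(genes, rownames(x$values))
  if (length(missing) > 0)
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  times <- sort(unique(x$samples$time_h[sel]))
  agg <- vapply(times, function(t) {
    cols <- which(sel & x$samples$time_h == t)
    block <- x$values[genes, cols, drop = FALSE]
    if (aggregate == "mean") rowMeans(block)
    else apply(block, 1, stats::median)
  }, numeric(length(genes)))
  agg <- matrix(agg, nrow = length(genes),
                dimnames = list(genes, as.character(times)))
  list(values = agg, time_points = times)
}

#' Build a temporal series of terrains on a frozen layout
#'
#' For one condition, aggregates replicates at each time point and
#' rasterizes one signal field per time point on the shared layout. The
#' layout object is stored once and every field in the series uses
#' exactly the same coordinates, so pixelwise differences between fields
#' reflect expression changes only. Absolute fields always use the fixed
#' `sigma_base`; the adaptive policy, if chosen, applies to delta fields
#' (see [interval_deltas()]).
#'
#' @param x A `gt_expression` with at least two time points for the
#'   condition.
#' @param layout A `gt_layout`; its genes define the plotted gene set and
#'   must all be present in `x`.
#' @param condition Condition label to extract.
#' @param policy A [sigma_policy()].
#' @param aggregate Replicate aggregation, `"mean"` (default) or
#'   `"median"`.
#' @param grid_size Raster side length (default 512).
#' @return A `gt_series` with the layout, ordered time points, one
#'   `gt_field` per time point, and the aggregated genes x time
#'   expression matrix.
#' @export
build_series <- function(x, layout, condition, policy = sigma_policy(),
                         aggregate = c("mean", "median"), grid_size = 512) {
  stopifnot(inherits(x, "gt_expression"), inherits(policy, "gt_sigma_policy"))
  pos <- layout_positions(layout)
  prof <- .condition_profile(x, condition, genes = rownames(pos),
                             aggregate = aggregate)
  if (length(prof$time_points) < 2)
    stop("condition '", condition, "' has fewer than two time points")
  fields <- lapply(seq_along(prof$time_points), function(i) {
    signal_field(pos, prof$values[, i], sigma = policy$sigma_base,
                 grid_size = grid_size, time_h = prof$time_points[i],
                 condition = condition)
  })
  structure(list(layout = if (inherits(layout, "gt_layout")) layout
                 else gt_layout(pos),
                 time_points = prof$time_points, condition = condition,
                 fields = fields, expressions = prof$values,
                 grid_size = grid_size, policy = policy),
            class = "gt_series")
}

#' @export
print.gt_series <- function(x, ...) {
  cat("<gt_series> condition ", x$condition, ", ",
      length(x$time_points), " time points (",
      paste(x$time_points, collapse = ", "), " h), ",
      nrow(x$expressions), " genes, grid ", x$grid_size, "\n", sep = "")
  invisible(x)
}

#' Interval delta terrains with up/down gene sets
#'
#' For each consecutive pair of time points, computes the per-gene
#' expression change, rasterizes it on the frozen layout, and extracts
#' the genes exceeding a symmetric magnitude threshold:
#' up = \{delta >= threshold\}, down = \{delta <= -threshold\}. An
#' alternative `"top_k"` mode takes the k largest increases and k largest
#' decreases per interval instead. If the series policy is adaptive, the
#' delta fields use per-gene [adaptive_sigma()].
#'
#' @param series A `gt_series`.
#' @param threshold Positive magnitude threshold on the expression delta
#'   (default 1.0; on Z-scored input this is one pooled standard
#'   deviation).
#' @param mode `"threshold"` (default) or `"top_k"`.
#' @param k Number of genes per direction in `"top_k"` mode.
#' @return List of `gt_delta` objects, one per interval, each holding the
#'   interval, the delta `gt_field`, `up_genes`, and `down_genes`.
#' @export
interval_deltas <- function(series, threshold = 1.0,
                            mode = c("threshold", "top_k"), k = 50) {
  stopifnot(inherits(series, "gt_series"))
  mode <- match.arg(mode)
  if (mode == "threshold" && threshold <= 0)
    stop("`threshold` must be positive")
  tp <- series$time_points
  lapply(seq_len(length(tp) - 1), function(i) {
    d <- delta_expression(series$expressions[, i],
                          series$expressions[, i + 1])
    sig <- if (series$policy$mode == "adaptive" && any(d != 0))
      adaptive_sigma(d, series$policy) else series$policy$sigma_base
    fld <- signal_field(series$layout, d, sigma = sig,
                        grid_size = series$grid_size,
                        time_h = tp[i + 1], condition = series$condition)
    if (mode == "threshold") {
      up <- names(d)[d >= threshold]
      down <- names(d)[d <= -threshold]
    } else {
      ord <- order(d, decreasing = TRUE)
      up <- names(d)[utils::head(ord, k)]
      up <- up[d[up] > 0]
      down <- names(d)[utils::tail(ord, k)]
      down <- down[d[down] < 0]
    }
    structure(list(interval = c(tp[i], tp[i + 1]), field = fld,
                   up_genes = up, down_genes = down,
                   threshold = if (mode == "threshold") threshold else NA),
              class = "gt_delta")
  })
}

#' Interpolate terrain frames between time points
#'
#' Linearly interpolates the expression vectors (not the pixels) between
#' consecutive time points at equally spaced fractions and rasterizes
#' each interpolated vector on the frozen layout, producing a smooth
#' animation trajectory. With fixed sigma the field is linear in the
#' expression vector, so pixel- and expression-space interpolation
#' coincide; interpolating expression keeps adaptive-sigma variants
#' well-defined. Frame endpoints reproduce the original per-time-point
#' fields exactly.
#'
#' @param series A `gt_series` with at least two time points.
#' @param frames_per_interval Number of frames per interval (>= 1); the
#'   total frame count is `n_intervals * frames_per_interval + 1`.
#' @return Ordered list of `gt_field` frames, each tagged with its
#'   interpolated time.
#' @export
interpolate_frames <- function(series, frames_per_interval = 4) {
  stopifnot(inherits(series, "gt_series"))
  if (frames_per_interval < 1)
    stop("`frames_per_interval` must be >= 1")
  tp <- series$time_points
  if (length(tp) < 2) stop("interpolation needs at least two time points")
  frames <- list()
  for (i in seq_len(length(tp) - 1)) {
    e1 <- series$expressions[, i]
    e2 <- series$expressions[, i + 1]
    fr <- seq_len(frames_per_interval) - 1L
    for (f in fr) {
      a <- f / frames_per_interval
      e <- (1 - a) * e1 + a * e2
      t_h <- (1 - a) * tp[i] + a * tp[i + 1]
      frames[[length(frames) + 1L]] <-
        signal_field(series$layout, e, sigma = series$policy$sigma_base,
                     grid_size = series$grid_size, time_h = t_h,
                     condition = series$condition)
    }
  }
  frames[[length(frames) + 1L]] <-
    signal_field(series$layout, series$expressions[, length(tp)],
                 sigma = series$policy$sigma_base,
                 grid_size = series$grid_size, time_h = tp[length(tp)],
                 condition = series$condition)
  frames
}

#' Counts and proportions of high-variation genes per comparison
#'
#' For each (condition, t_a, t_b) comparison, counts the genes whose
#' replicate-aggregated expression change exceeds the magnitude
#' threshold, and normalizes the counts to proportions across
#' comparisons (they sum to 1).
#'
#' @param x A `gt_expression`.
#' @param comparisons Data frame with columns `condition`, `t_a`, `t_b`.
#' @param threshold Positive magnitude threshold on the delta.
#' @param aggregate Replicate aggregation rule.
#' @param genes Optional gene subset (default: all genes).
#' @return Data frame with columns condition, t_a, t_b, count,
#'   proportion.
#' @export
variability_summary <- function(x, comparisons, threshold = 1.0,
                                aggregate = c("mean", "median"),
                                genes = NULL) {
  stopifnot(inherits(x, "gt_expression"))
  if (threshold <= 0) stop("`threshold` must be positive")
  req <- c("condition", "t_a", "t_b")
  if (!is.data.frame(comparisons) || !all(req %in% names(comparisons)))
    stop("`comparisons` needs columns condition, t_a, t_b")
  counts <- vapply(seq_len(nrow(comparisons)), function(i) {
    prof <- .condition_profile(x, comparisons$condition[i], genes = genes,
                               aggregate = aggregate)
    ta <- as.character(comparisons$t_a[i])
    tb <- as.character(comparisons$t_b[i])
    if (!all(c(ta, tb) %in% colnames(prof$values)))
      stop("comparison ", i, ": time point(s) absent for condition '",
           comparisons$condition[i], "'")
    d <- prof$values[, tb] - prof$values[, ta]
    sum(abs(d) >= threshold)
  }, 1L)
  if (sum(counts) == 0)
    stop("no gene exceeds the threshold in any comparison; ",
         "proportions are undefined")
  data.frame(comparisons[req], count = counts,
             proportion = counts / sum(counts), row.names = NULL)
}
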