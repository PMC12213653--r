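#' Validated end-to-end run configuration
#'
#' Collects every stage's tunables with their case-study defaults:
#' top 1000 variance-ranked genes, co-expression threshold r >= 0.5,
#' sigma 0.03, colormap range -10..+10, 512 px grid. Validation happens
#' here, before any stage runs.
#'
#' @param expr Path to the expression matrix (TSV/CSV).
#' @param network Path to the interaction network (edge list or SIF).
#' @param out Output directory (created if absent).
#' @param layout Optional path to a precomputed layout TSV; when given,
#'   the layout stage is skipped and these frozen coordinates are used.
#' @param conditions Conditions to process (default: all in the data).
#' @param top_n Variance-ranked gene count.
#' @param threshold_r Co-expression retention threshold in [-1, 1].
#' @param sigma Gaussian dispersion (unit-square coordinates).
#' @param adaptive If `TRUE`, delta terrains use [adaptive_sigma()].
#' @param grid Raster side length in pixels.
#' @param delta_threshold Magnitude threshold for up/down gene sets
#'   (Z-score units).
#' @param frames_per_interval Interpolated animation frames per interval
#'   (0 disables frame output).
#' @param vmin,vmax Colormap range.
#' @param seed Seed for layout initialization.
#' @param network_dialect `"edge_list"` or `"sif"`.
#' @param layout_args Extra arguments passed to [layout_params()].
#' @return A validated `gt_run_config`.
#' @export
run_config <- function(expr, network, out, layout = NULL,
                       conditions = NULL, top_n = 1000, threshold_r = 0.5,
                       sigma = 0.03, adaptive = FALSE, grid = 512,
                       delta_threshold = 1.0, frames_per_interval = 0,
                       vmin = -10, vmax = 10, seed = 17,
                       network_dialect = "edge_list",
                       layout_args = list()) {
  if (top_n < 1) stop("top_n must be >= 1")
  if (threshold_r < -1 || threshold_r > 1)
    stop("threshold_r must lie in [-1, 1]")
  if (sigma <= 0) stop("sigma must be positive")
  if (grid < 16) stop("grid must be at least 16")
  if (delta_threshold <= 0) stop("delta_threshold must be positive")
  if (frames_per_interval < 0) stop("frames_per_interval must be >= 0")
  if (vmin >= vmax || vmin >= 0 || vmax <= 0)
    stop("need vmin < 0 < vmax")
  structure(list(expr = expr, network = network, out = out,
                 layout = layout, conditions = conditions,
                 top_n = as.integer(top_n), threshold_r = threshold_r,
                 sigma = sigma, adaptive = isTRUE(adaptive),
                 grid = as.integer(grid),
                 delta_threshold = delta_threshold,
                 frames_per_interval = as.integer(frames_per_interval),
                 vmin = vmin, vmax = vmax, seed = as.integer(seed),
                 network_dialect = network_dialect,
                 layout_args = layout_args),
            class = "gt_run_config")
}

#' Read a run configuration from YAML
#' @param path Path to a YAML file whose keys mirror [run_config()]
#'   arguments.
#' @return A validated `gt_run_config`.
#' @export
run_config_from_yaml <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full terrain pipeline
#'
#' Ordered execution: read inputs, variance + co-expression gene
#' selection, Z-score normalization, layout (computed once and frozen,
#' or loaded from `config$layout`), one temporal series per condition,
#' interval delta terrains with GMT gene-set export, per-time-point and
#' delta PNG renders, a condition x interval montage, a variability
#' summary, and a manifest recording the configuration, seed, stage
#' logs and an MD5 content hash of every output file.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "gt_run_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  expr <- stage("read_expression", read_expression(config$expr))
  net <- stage("read_network",
               read_network(config$network, config$network_dialect))
  log$input <- list(genes = nrow(expr$values), samples = ncol(expr$values),
                    network_nodes = igraph::vcount(net),
                    network_edges = igraph::ecount(net))

  sel <- stage("preprocess", {
    sel <- select_top_variance(expr, config$top_n)
    retained <- correlation_filter(expr, sel$selected, config$threshold_r)
    in_net <- intersect(retained, igraph::V(net)$name)
    if (length(in_net) < length(retained))
      warning(length(retained) - length(in_net),
              " retained gene(s) absent from the network were dropped")
    if (length(in_net) < 2)
      stop("fewer than two retained genes are present in the network")
    in_net
  })
  log$selection <- list(top_n = config$top_n,
                        after_correlation = length(sel))
  norm <- stage("normalize", zscore_normalize(expr))

  lay <- stage("layout", {
    if (!is.null(config$layout)) {
      lay <- read_layout(config$layout)
      miss <- setdiff(sel, rownames(layout_positions(lay)))
      if (length(miss) > 0)
        stop("precomputed layout missing gene(s): ",
             paste(utils::head(miss, 5), collapse = ", "))
      gt_layout(layout_positions(lay)[sel, , drop = FALSE])
    } else {
      sub <- igraph::induced_subgraph(net, sel)
      pars <- do.call(layout_params,
                      c(list(seed = config$seed), config$layout_args))
      lay <- normalize_layout(kk_layout(sub, pars))
      # canonical row order so reruns and frozen-layout reuse match
      gt_layout(layout_positions(lay)[sel, , drop = FALSE])
    }
  })
  layout_path <- file.path(config$out, "layout.tsv")
  write_layout(lay, layout_path)

  conds <- config$conditions %||% unique(expr$samples$condition)
  pol <- sigma_policy(if (config$adaptive) "adaptive" else "fixed",
                      sigma_base = config$sigma)
  cmap <- colormap_spec(config$vmin, config$vmax)
  outputs <- layout_path
  delta_rows <- list()
  comparisons <- NULL
  for (cond in conds) {
    series <- stage(paste0("series_", cond),
                    build_series(norm, lay, cond, policy = pol,
                                 grid_size = config$grid))
    for (f in series$fields) {
      p <- file.path(config$out,
                     sprintf("terrain_%s_t%g.png", cond, f$time_h))
      render_field(f, p, cmap)
      outputs <- c(outputs, p)
    }
    deltas <- stage(paste0("deltas_", cond),
                    interval_deltas(series, config$delta_threshold))
    delta_rows[[cond]] <- deltas
    sets <- list()
    for (d in deltas) {
      lab <- sprintf("%s_%gto%g", cond, d$interval[1], d$interval[2])
      sets[[paste0(lab, "_up")]] <- d$up_genes
      sets[[paste0(lab, "_down")]] <- d$down_genes
      p <- file.path(config$out, sprintf("delta_%s.png", lab))
      render_field(d$field, p, cmap)
      outputs <- c(outputs, p)
    }
    gmt <- file.path(config$out, sprintf("genesets_%s.gmt", cond))
    suppressWarnings(write_gene_sets(sets, gmt))
    outputs <- c(outputs, gmt)
    if (config$frames_per_interval > 0) {
      frames <- interpolate_frames(series, config$frames_per_interval)
      for (i in seq_along(frames)) {
        p <- file.path(config$out,
                       sprintf("frame_%s_%03d.png", cond, i))
        render_field(frames[[i]], p, cmap)
        outputs <- c(outputs, p)
      }
    }
    tpn <- series$time_points
    comparisons <- rbind(comparisons, data.frame(
      condition = cond, t_a = tpn[-length(tpn)], t_b = tpn[-1]))
    log$conditions[[cond]] <- list(
      time_points = series$time_points,
      n_deltas = length(deltas),
      up_counts = vapply(deltas, function(d) length(d$up_genes), 1L),
      down_counts = vapply(deltas, function(d) length(d$down_genes), 1L))
  }
  montage_path <- file.path(config$out, "montage.png")
  stage("montage", render_montage(delta_rows, montage_path, cmap))
  outputs <- c(outputs, montage_path)

  summary_path <- file.path(config$out, "variability.json")
  vs <- tryCatch(
    variability_summary(norm, comparisons, config$delta_threshold,
                        genes = sel),
    error = function(e) NULL)
  if (!is.null(vs)) {
    jsonlite::write_json(vs, summary_path, digits = NA)
    outputs <- c(outputs, summary_path)
  }

  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    log = log,
    outputs = data.frame(
      path = basename(outputs),
      md5 = unname(tools::md5sum(outputs)),
      stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
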