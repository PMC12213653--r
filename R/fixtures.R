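#' Specification of a synthetic network + time-course fixture
#'
#' Describes a modular interaction network (stochastic block model) and a
#' time-course expression experiment with programmed per-module temporal
#' patterns, emulating a multi-condition drug perturbation design with
#' triplicate sampling at 0, 3, 6, 9, 12 and 24 hours. Everything is
#' deterministic under the seed.
#'
#' Patterns (assigned per module, per condition):
#' \describe{
#'   \item{transient_spike}{ramps from baseline over `rise` hours to a
#'     peak at `t_peak`, then decays back over `fall` hours
#'     (defaults t_peak = 12, rise = 4, fall = 12).}
#'   \item{sustained_shift}{steps from baseline to the full amplitude at
#'     `t_on` (default 6) and stays up.}
#'   \item{delayed}{a sustained shift switching on late
#'     (default t_on = 24).}
#'   \item{flat}{stays at baseline; all variation is noise.}
#' }
#' A pattern is given as a name string or as
#' `list(pattern = "transient_spike", t_peak = 12)` to override
#' parameters. The default assignment cycles spike / sustained / delayed
#' / flat over modules, identically for every condition.
#'
#' @param n_modules,genes_per_module Network block structure.
#' @param p_within,p_between Intra/inter-module edge probabilities
#'   (require `p_between < p_within`).
#' @param time_points Sampling times in hours.
#' @param conditions Condition labels.
#' @param n_replicates Replicates per condition and time point.
#' @param noise_sd Standard deviation of additive Gaussian replicate
#'   noise on the expression scale.
#' @param amplitude Peak effect size of the programmed patterns, in
#'   expression units; each gene scales it by a multiplicative loading
#'   drawn uniformly from [0.5, 1.5].
#' @param seed Integer seed fixing network, loadings and noise.
#' @param pattern_assignments Optional named list, condition -> list of
#'   per-module patterns (length `n_modules`).
#' @return A `gt_fixture_spec` list.
#' @export
fixture_spec <- function(n_modules = 4, genes_per_module = 50,
                         p_within = 0.3, p_between = 0.02,
                         time_points = c(0, 3, 6, 9, 12, 24),
                         conditions = "TM", n_replicates = 3,
                         noise_sd = 0.2, amplitude = 3, seed = 1,
                         pattern_assignments = NULL) {
  if (n_modules < 1 || genes_per_module < 1)
    stop("need at least one module and one gene per module")
  if (!(p_between >= 0 && p_between < p_within && p_within <= 1))
    stop("need 0 <= p_between < p_within <= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.unsorted(time_points, strictly = TRUE))
    stop("time_points must be strictly increasing")
  if (is.null(pattern_assignments)) {
    base <- rep(list("transient_spike", "sustained_shift", "delayed",
                     "flat"), length.out = n_modules)
    pattern_assignments <- stats::setNames(
      rep(list(base), length(conditions)), conditions)
  }
  if (!all(conditions %in% names(pattern_assignments)))
    stop("pattern_assignments must cover every condition")
  structure(list(
    n_modules = as.integer(n_modules),
    genes_per_module = as.integer(genes_per_module),
    p_within = p_within, p_between = p_between,
    time_points = time_points, conditions = conditions,
    n_replicates = as.integer(n_replicates), noise_sd = noise_sd,
    amplitude = amplitude, seed = as.integer(seed),
    pattern_assignments = pattern_assignments
  ), class = "gt_fixture_spec")
}

# Pattern -> trajectory f(t) in [0, 1] at the given times.
.pattern_trajectory <- function(pat, times) {
  if (is.character(pat)) pat <- list(pattern = pat)
  name <- pat$pattern
  if (is.null(name)) stop("pattern entry without a `pattern` name")
  switch(name,
    transient_spike = {
      t_peak <- pat$t_peak %||% 12
      rise <- pat$rise %||% 4
      fall <- pat$fall %||% 12
      ifelse(times <= t_peak,
             pmax(0, 1 - (t_peak - times) / rise),
             pmax(0, 1 - (times - t_peak) / fall))
    },
    sustained_shift = as.numeric(times >= (pat$t_on %||% 6)),
    delayed = as.numeric(times >= (pat$t_on %||% 24)),
    flat = rep(0, length(times)),
    stop("unknown pattern name: ", name)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a modular synthetic interaction network
#'
#' Seeded stochastic block model: gene pairs within a module are wired
#' with probability `p_within`, pairs across modules with `p_between`.
#' A spanning chain of bridges between consecutive modules is added so
#' the graph is always connected. Vertices carry a `module` attribute.
#'
#' @param spec A [fixture_spec()].
#' @return An undirected simple igraph, including any degree-zero genes.
#' @export
make_network <- function(spec) {
  stopifnot(inherits(spec, "gt_fixture_spec"))
  n <- spec$n_modules * spec$genes_per_module
  module <- rep(seq_len(spec$n_modules), each = spec$genes_per_module)
  genes <- sprintf("m%02dg%03d", module,
                   sequence(rep(spec$genes_per_module, spec$n_modules)))
  pairs <- utils::combn(n, 2)
  same <- module[pairs[1, ]] == module[pairs[2, ]]
  prob <- ifelse(same, spec$p_within, spec$p_between)
  keep <- .with_seed(spec$seed, stats::runif(ncol(pairs)) < prob)
  from <- genes[pairs[1, keep]]
  to <- genes[pairs[2, keep]]
  # spanning chain: first gene of module m to first gene of module m+1
  if (spec$n_modules > 1) {
    first <- genes[match(seq_len(spec$n_modules), module)]
    from <- c(from, first[-spec$n_modules])
    to <- c(to, first[-1])
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = genes, module = module,
                          stringsAsFactors = FALSE))
  igraph::simplify(g)
}

#' Generate synthetic time-course expression with programmed patterns
#'
#' Each module follows its assigned mean trajectory (see
#' [fixture_spec()]): expression of gene g in condition c at time t is
#' `amplitude * f_c,module(g)(t) * loading_g + noise`, with loading_g
#' drawn once per gene from Uniform(0.5, 1.5) and independent
#' Normal(0, noise_sd) noise per replicate measurement.
#'
#' @param spec A [fixture_spec()].
#' @param network Network from [make_network()] (defines genes and
#'   module membership).
#' @return List with `expression` (a `gt_expression`) and `truth` (a
#'   data frame with condition, gene, module, pattern, loading).
#' @export
make_expression <- function(spec, network) {
  stopifnot(inherits(spec, "gt_fixture_spec"))
  genes <- igraph::V(network)$name
  module <- igraph::V(network)$module
  n <- length(genes)
  tp <- spec$time_points
  grid <- expand.grid(replicate = seq_len(spec$n_replicates),
                      time_h = tp, condition = spec$conditions,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("condition", "time_h", "replicate")]
  grid$sample_id <- sprintf("%s_%g_%d", grid$condition, grid$time_h,
                            grid$replicate)
  res <- .with_seed(spec$seed + 1L, {
    loading <- stats::runif(n, 0.5, 1.5)
    vals <- matrix(0, n, nrow(grid), dimnames = list(genes, grid$sample_id))
    truth <- NULL
    for (cond in spec$conditions) {
      pats <- spec$pattern_assignments[[cond]]
      if (length(pats) != spec$n_modules)
        stop("pattern assignment for '", cond, "' must have ",
             spec$n_modules, " entries")
      traj <- vapply(pats, .pattern_trajectory, numeric(length(tp)),
                     times = tp)               # time x module
      for (j in which(grid$condition == cond)) {
        f <- traj[match(grid$time_h[j], tp), module]
        vals[, j] <- spec$amplitude * f * loading
      }
      pat_names <- vapply(pats, function(p)
        if (is.character(p)) p else p$pattern, "")
      truth <- rbind(truth, data.frame(
        condition = cond, gene = genes, module = module,
        pattern = pat_names[module], loading = loading,
        stringsAsFactors = FALSE))
    }
    vals <- vals + stats::rnorm(length(vals), 0, spec$noise_sd)
    list(vals = vals, truth = truth)
  })
  meta <- grid[, c("sample_id", "condition", "time_h", "replicate")]
  list(expression = expression_matrix(res$vals, meta),
       truth = res$truth)
}
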