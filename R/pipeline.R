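# End-to-end pipeline: preprocess -> all-pairs causality -> association
# network -> quantile threshold -> dense-region detection -> summary stats,
# with every stage parameter validated up front, logged, and recorded in a
# manifest alongside content hashes of the outputs.

#' Validated pipeline configuration
#'
#' @param input Path to the expression matrix (TSV/CSV), or a numeric
#'   matrix supplied directly.
#' @param out_dir Output directory (created if missing).
#' @param diff Apply first differencing? Default TRUE.
#' @param flat_filter_k Flat-profile filter multiplier ([filter_flat()]);
#'   `NULL` disables the filter. Default 2.
#' @param top_n Optional spectral-power pre-selection
#'   ([rank_by_spectral_power()]); `NULL` disables.
#' @param alpha F-test significance level in (0, 1). Default 0.05.
#' @param lag `"auto"` (AIC) or a fixed positive integer lag order.
#' @param p_max Lag-selection bound; `NULL` means the data-driven default
#'   [default_p_max()].
#' @param q Threshold quantile in (0, 1). Default 0.975.
#' @param vwp Complex-expansion vertex weight percentage in [0, 1).
#' @param min_core Complex post-filter core level. Default 2.
#' @param haircut Trim degree-1 vertices from complexes? Default TRUE.
#' @param seed Integer recorded for provenance (the pipeline itself is
#'   deterministic given its input).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input, out_dir, diff = TRUE, flat_filter_k = 2,
                            top_n = NULL, alpha = 0.05, lag = "auto",
                            p_max = NULL, q = 0.975, vwp = 0.2,
                            min_core = 2L, haircut = TRUE, seed = 1L) {
  ok_num <- function(v, lo, hi) is.numeric(v) && length(v) == 1L &&
    is.finite(v) && v > lo && v < hi
  if (!ok_num(alpha, 0, 1)) stop("alpha must lie in (0, 1)")
  if (!ok_num(q, 0, 1)) stop("q must lie in (0, 1)")
  if (!(is.numeric(vwp) && vwp >= 0 && vwp < 1)) stop("vwp must lie in [0, 1)")
  if (!identical(lag, "auto") && (!is.numeric(lag) || lag < 1)) {
    stop("lag must be \"auto\" or a positive integer")
  }
  if (!is.null(p_max) && (!is.numeric(p_max) || p_max < 1)) {
    stop("p_max must be NULL or a positive integer")
  }
  if (!is.null(flat_filter_k) && (!is.numeric(flat_filter_k) || flat_filter_k < 0)) {
    stop("flat_filter_k must be NULL or non-negative")
  }
  if (!is.null(top_n) && (!is.numeric(top_n) || top_n < 1)) {
    stop("top_n must be NULL or a positive integer")
  }
  if (min_core < 0) stop("min_core must be >= 0")
  structure(list(input = input, out_dir = out_dir, diff = isTRUE(diff),
                 flat_filter_k = flat_filter_k, top_n = top_n, alpha = alpha,
                 lag = lag, p_max = p_max, q = q, vwp = vwp,
                 min_core = as.integer(min_core), haircut = isTRUE(haircut),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.log_stage <- function(verbose, ...) if (verbose) message("[grangernet] ", ...)

#' Run the full clustering pipeline
#'
#' Executes preprocess -> [pairwise_causality()] -> [symmetrize_max()] ->
#' [threshold_quantile()] -> [find_complexes()] -> [network_summary()],
#' writing the thresholded network (edge-list TSV + GraphML), the complex
#' table (TSV), the network statistics (JSON), and a manifest recording
#' the configuration and an md5 hash of every output. A failing stage
#' aborts with the stage name and removes partial outputs.
#'
#' @param cfg A [pipeline_config()].
#' @param verbose Log stage progress to stderr. Default TRUE.
#' @return List with `network` (thresholded `assoc_network`), `complexes`
#'   (`complex_list`), `stats` (`network_stats`), and `manifest`.
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  stage <- "setup"
  result <- tryCatch({
    stage <- "read"
    m <- if (is.character(cfg$input)) read_expression(cfg$input)
         else .check_expr(cfg$input)
    .log_stage(verbose, sprintf("input: %d genes x %d time points",
                                nrow(m), ncol(m)))
    stage <- "preprocess"
    if (!is.null(cfg$flat_filter_k)) {
      ff <- filter_flat(m, cfg$flat_filter_k)
      m <- ff$matrix
      .log_stage(verbose, sprintf("flat filter (k = %g): removed %d gene(s)",
                                  cfg$flat_filter_k, length(ff$removed)))
    }
    if (!is.null(cfg$top_n)) {
      m <- rank_by_spectral_power(m, min(cfg$top_n, nrow(m)))
      .log_stage(verbose, sprintf("spectral selection: kept %d gene(s)", nrow(m)))
    }
    if (cfg$diff) {
      m <- first_difference(m)
      .log_stage(verbose, sprintf("first differencing: %d time points remain",
                                  ncol(m)))
    }
    stage <- "causality"
    p_max <- if (is.null(cfg$p_max)) default_p_max(ncol(m)) else as.integer(cfg$p_max)
    d <- pairwise_causality(m, alpha = cfg$alpha, p = cfg$lag, p_max = p_max)
    .log_stage(verbose, sprintf("causality scan: %d directed tests, %d rejections",
                                attr(d, "n_tests"), sum(d > 0)))
    stage <- "network"
    a <- symmetrize_max(d)
    net <- threshold_quantile(a, cfg$q)
    thr <- attr(net, "threshold")
    .log_stage(verbose, sprintf("threshold q = %g: cutoff %.4g, %d edge(s) retained",
                                cfg$q, thr$cutoff, nrow(network_edges(net))))
    stage <- "complexes"
    cx <- find_complexes(net, vwp = cfg$vwp, haircut = cfg$haircut,
                         min_core = cfg$min_core)
    .log_stage(verbose, sprintf("dense regions: %d complex(es)", length(cx)))
    stage <- "stats"
    st <- network_summary(as_igraph(net))
    stage <- "write"
    f_edges <- file.path(cfg$out_dir, "network.tsv")
    f_graphml <- file.path(cfg$out_dir, "network.graphml")
    f_cx <- file.path(cfg$out_dir, "complexes.tsv")
    f_stats <- file.path(cfg$out_dir, "stats.json")
    write_network(net, f_edges); written <- c(written, f_edges)
    write_network(net, f_graphml); written <- c(written, f_graphml)
    utils::write.table(as.data.frame(cx), f_cx, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, f_cx)
    jsonlite::write_json(list(
      n_nodes = st$n_nodes, n_edges = st$n_edges, sparsity = st$sparsity,
      n_components = st$n_components,
      mean_shortest_path = st$mean_shortest_path, diameter = st$diameter,
      degree_distribution = as.list(st$degree_distribution),
      shared_neighbors = as.list(st$shared_neighbors),
      closeness = as.list(st$closeness),
      topological_coefficient = as.list(st$topological$tc_k)),
      f_stats, auto_unbox = TRUE, digits = NA)
    written <- c(written, f_stats)
    manifest <- list(
      config = cfg[setdiff(names(cfg), "input")],
      input = if (is.character(cfg$input)) cfg$input else "<in-memory matrix>",
      files = lapply(stats::setNames(written, basename(written)),
                     function(f) unname(tools::md5sum(f))))
    f_manifest <- file.path(cfg$out_dir, "manifest.json")
    jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, digits = NA)
    written <- c(written, f_manifest)
    list(network = net, complexes = cx, stats = st, manifest = manifest)
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}
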