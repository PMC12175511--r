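#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML path or a nested list; fills defaults and reports all
#' problems at once. Exactly one of \code{input} (paths to table /
#' metadata / taxonomy TSVs) or \code{synthetic} (arguments for
#' [syntheticConfig()]) may be given; an empty configuration means
#' synthetic mode with defaults.
#'
#' @param config NULL, a YAML file path, or a list.
#' @return normalized configuration list (class \code{pipeline_config}).
#' @export
validateConfig <- function(config = NULL) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  errors <- character()
  defaults <- list(
    input = NULL,
    synthetic = list(),
    min_reads = 5000,
    core_thresholds = c(bacteria = 10, fungi = 5),
    ncm = list(by = "location", ci = 0.95, d = NULL),
    nti = list(n_null = 199, weighted = FALSE),
    networks = list(enabled = TRUE, infer_threshold = 0.6,
                    null_model = "rewire", n_null = 199),
    seed = 1,
    output_dir = NULL)
  cfg <- utils::modifyList(defaults, config)
  if (!is.null(config$core_thresholds))
    cfg$core_thresholds <- unlist(config$core_thresholds)

  if (!is.null(cfg$input) && length(config$synthetic))
    errors <- c(errors, "give either input paths or a synthetic block, not both")
  if (!is.null(cfg$input)) {
    need <- c("table", "metadata", "taxonomy")
    miss <- setdiff(need, names(cfg$input))
    if (length(miss))
      errors <- c(errors, paste("input block missing:",
                                paste(miss, collapse = ", ")))
  }
  if (cfg$ncm$ci <= 0 || cfg$ncm$ci >= 1)
    errors <- c(errors, "ci must be in (0,1)")
  if (!is.null(cfg$ncm$d) && (cfg$ncm$d <= 0 || cfg$ncm$d >= 1))
    errors <- c(errors, "d must be in (0,1)")
  if (!cfg$ncm$by %in% c("location", "pooled"))
    errors <- c(errors, "ncm$by must be 'location' or 'pooled'")
  if (cfg$min_reads <= 0) errors <- c(errors, "min_reads must be > 0")
  if (cfg$nti$n_null < 99) errors <- c(errors, "nti n_null must be >= 99")
  if (!cfg$networks$null_model %in% c("rewire", "er"))
    errors <- c(errors, "network null_model must be 'rewire' or 'er'")
  if (length(errors)) stop(paste(errors, collapse = "; "))
  if (is.null(cfg$input))
    cfg$synthetic <- do.call(syntheticConfig,
                             utils::modifyList(list(seed = cfg$seed),
                                               cfg$synthetic))
  class(cfg) <- "pipeline_config"
  cfg
}

.stageLog <- function(name, t0, ...) {
  message(sprintf("[%s] %s (%.1fs)", name, paste(..., collapse = " "),
                  as.numeric(Sys.time()) - t0))
}

#' Run the full community-assembly pipeline
#'
#' Stages, mirroring the analysis order of a typical assembly study:
#' depth filter; core microbiome / Venn partition / abundance-occupancy;
#' Sloan NCM per location (or pooled); per-sample NTI plus per-plot
#' t-tests; network statistics; cross-network shared-edge test; and NCM
#' class integration into the networks. A single global seed is fanned
#' out to per-stage seeds by fixed offsets so each stage is reproducible
#' in isolation. Per-stage TSVs and a machine-readable
#' \code{summary.json} are written when \code{output_dir} is set.
#'
#' @param config a [validateConfig()]-accepted configuration.
#' @param networks optional named list of igraph networks per location;
#'   when absent and networks are enabled, naive sparse-correlation
#'   networks are inferred per location as a demonstration.
#' @param tree optional \code{phylo} for NTI (synthetic mode generates
#'   one).
#' @return named list of per-stage summary blocks (also serialized to
#'   JSON when \code{output_dir} is set).
#' @export
runPipeline <- function(config = NULL, networks = NULL, tree = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validateConfig(config)
  out <- list(options = cfg[setdiff(names(cfg), "synthetic")])
  t0 <- as.numeric(Sys.time())
  seeds <- cfg$seed + c(simulate = 0, nti = 1000, networks = 2000,
                        shared = 3000)

  # -- data
  if (is.null(cfg$input)) {
    sim <- simulateDataset(cfg$synthetic)
    x <- sim$table
    truth <- sim$truth
    if (is.null(tree))
      tree <- simulateTree(nrow(x), seed = seeds[["simulate"]],
                           tip_labels = rownames(x))
    out$data <- list(mode = "synthetic", n_taxa = nrow(x),
                     n_samples = ncol(x))
  } else {
    x <- loadDataset(cfg$input$table, cfg$input$metadata,
                     cfg$input$taxonomy)
    truth <- NULL
    out$data <- list(mode = "files", n_taxa = nrow(x),
                     n_samples = ncol(x))
  }
  .stageLog("data", t0, out$data$n_taxa, "taxa x", out$data$n_samples,
            "samples")

  # -- 1. depth filter
  x <- filterLowDepth(x, cfg$min_reads)
  out$filter <- list(min_reads = cfg$min_reads,
                     n_samples_kept = ncol(x),
                     dropped_samples = metadata(x)$dropped_samples)
  .stageLog("filter", t0, ncol(x), "samples kept")

  # -- 2. core / Venn / abundance-occupancy
  part <- corePartition(x, cfg$core_thresholds)
  frac <- coreAbundanceFraction(x, part$core)
  locs <- unique(as.character(colData(x)$location))
  ao <- lapply(locs, function(l) {
    r <- abundanceOccupancy(x, l)
    list(location = l, rho = r$rho, p_value = r$p_value,
         n_otus = r$n_otus)
  })
  out$core_ao <- list(
    venn_counts = as.list(part$venn_counts),
    core_size = length(part$core),
    core_by_domain = lapply(part$core_by_domain, length),
    core_abundance_mean = as.list(frac$mean),
    abundance_occupancy = ao)
  .stageLog("core", t0, "core size", length(part$core))

  # -- 3. NCM
  ncm_groups <- if (cfg$ncm$by == "location") locs else "pooled"
  fits <- lapply(ncm_groups, function(g) {
    sel <- if (g == "pooled") rep(TRUE, ncol(x)) else
      as.character(colData(x)$location) == g
    ncmFit(x, d = cfg$ncm$d, ci = cfg$ncm$ci, samples = sel)
  })
  names(fits) <- ncm_groups
  out$ncm <- lapply(fits, function(f) list(
    Nm = f@Nm, m = f@m, N = f@N, d = f@d, r_squared = f@rSquared,
    n_samples = f@nSamples,
    class_summary = ncmClassSummary(f)))
  .stageLog("ncm", t0, length(fits), "fits")

  # -- 4. NTI + plot tests
  nti_df <- sampleNti(x, tree, n_null = cfg$nti$n_null,
                      seed = seeds[["nti"]],
                      weighted = cfg$nti$weighted)
  ptest <- ntiPlotTest(nti_df)
  out$nti <- list(n_null = cfg$nti$n_null,
                  n_communities = nrow(nti_df),
                  location_means = ptest$locations,
                  n_plots_significant = sum(ptest$plots$significant,
                                            na.rm = TRUE),
                  n_plots = nrow(ptest$plots))
  .stageLog("nti", t0, nrow(nti_df), "communities")

  if (isTRUE(cfg$networks$enabled)) {
    # -- 5. networks + statistics
    if (is.null(networks)) {
      set.seed(seeds[["networks"]])
      networks <- lapply(locs, function(l) {
        sub <- x[, as.character(colData(x)$location) == l]
        sub <- sub[rowSums(otuCounts(sub) > 0) >= 5, ]
        extractBfEdges(naiveNetworkInference(sub,
                                             cfg$networks$infer_threshold))
      })
      names(networks) <- locs
      out$network_inference <- "naive sparse correlation (demonstration)"
    }
    stats_by_loc <- lapply(networks, networkStats)
    out$network_stats <- lapply(stats_by_loc, function(s)
      s[c("n_nodes", "n_bacteria", "n_fungi", "n_edges",
          "linkage_density", "edge_density", "max_degree", "n_modules")])
    .stageLog("networks", t0, length(networks), "networks")

    # -- 6. shared-edge test
    shared <- sharedAssociations(networks)
    st <- sharedEdgeTest(networks, n = cfg$networks$n_null,
                         null_model = cfg$networks$null_model,
                         seed = seeds[["shared"]])
    out$shared_edges <- list(observed_shared = st$observed_shared,
                             p_value = st$p_value,
                             null_model = st$null_model,
                             n_null = st$n,
                             null_mean = mean(st$null_counts))
    .stageLog("shared", t0, "observed", st$observed_shared,
              "p", signif(st$p_value, 3))

    # -- 7. NCM-network integration
    fit0 <- fits[[1]]
    integ <- lapply(names(networks), function(l) {
      f <- if (l %in% names(fits)) fits[[l]] else fit0
      a <- attachNcmClasses(networks[[l]], f)
      list(location = l,
           domain_percent = a$domain_percent,
           pair_counts = as.data.frame.matrix(a$pair_counts))
    })
    out$ncm_integration <- integ
    .stageLog("integration", t0, "done")
  }

  if (!is.null(truth))
    out$truth_summary <- as.list(table(truth$class))
  out$runtime_seconds <- as.numeric(Sys.time()) - t0

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    writeOtuTable(x, file.path(cfg$output_dir, "filtered_counts.tsv"))
    utils::write.table(nti_df, file.path(cfg$output_dir, "nti.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ptest$plots,
                       file.path(cfg$output_dir, "nti_plot_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (g in names(fits))
      utils::write.table(ncmOtuTable(fits[[g]]),
                         file.path(cfg$output_dir,
                                   paste0("ncm_", g, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(out,
                         file.path(cfg$output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
  }
  out
}
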