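.CONFIG_DEFAULTS <- list(
  herb_targets = NULL,        # character vector of target-table paths
  disease_targets = NULL,     # character vector of target-table paths
  ppi = NULL,                 # character vector of edge-list paths
  gene_sets = NULL,           # one GMT path (optional)
  id_map = NULL,              # optional two-column TSV
  expansion_rule = "first_neighbor",
  hub_factor = 2,
  threshold_mode = "median_derived",  # or "explicit" / "zjw"
  degree_min = NULL, betweenness_min = NULL,
  closeness_min = NULL, coreness_min = NULL,
  null_replicates = 100,
  enrichment_alpha = 0.05,
  enrichment_use_q = TRUE,
  seed = 1,
  output_dir = NULL)

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a plain list; fills defaults, rejects
#' unknown keys, and reports every violation at once.
#'
#' @param config path to a YAML file, or a named list.
#' @return the resolved configuration list.
#' @export
validateConfig <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  errs <- character()
  unknown <- setdiff(names(config), names(.CONFIG_DEFAULTS))
  if (length(unknown))
    errs <- c(errs, paste("unknown config key(s):",
                          paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(.CONFIG_DEFAULTS, config, keep.null = TRUE)
  for (key in c("herb_targets", "disease_targets", "ppi")) {
    if (is.null(cfg[[key]]))
      errs <- c(errs, paste0("required key '", key, "' (path list) missing"))
    else {
      miss <- cfg[[key]][!file.exists(unlist(cfg[[key]]))]
      if (length(miss))
        errs <- c(errs, paste0(key, ": file(s) not found: ",
                               paste(miss, collapse = ", ")))
    }
  }
  for (key in c("gene_sets", "id_map"))
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      errs <- c(errs, paste0(key, ": file not found: ", cfg[[key]]))
  if (!cfg$expansion_rule %in% c("first_neighbor", "seed_only", "full_ppi"))
    errs <- c(errs, "expansion_rule must be first_neighbor/seed_only/full_ppi")
  if (!is.numeric(cfg$hub_factor) || cfg$hub_factor <= 0)
    errs <- c(errs, "hub_factor must be a positive number")
  if (!cfg$threshold_mode %in% c("median_derived", "explicit", "zjw"))
    errs <- c(errs, "threshold_mode must be median_derived/explicit/zjw")
  if (cfg$threshold_mode == "explicit") {
    need <- c("degree_min", "betweenness_min", "closeness_min", "coreness_min")
    bad <- need[vapply(cfg[need], is.null, logical(1))]
    if (length(bad))
      errs <- c(errs, paste("explicit thresholds require:",
                            paste(bad, collapse = ", ")))
  }
  if (!is.numeric(cfg$null_replicates) || cfg$null_replicates < 0)
    errs <- c(errs, "null_replicates must be >= 0")
  if (!is.numeric(cfg$enrichment_alpha) || cfg$enrichment_alpha <= 0 ||
      cfg$enrichment_alpha > 1)
    errs <- c(errs, "enrichment_alpha must lie in (0, 1]")
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    errs <- c(errs, "seed must be an integer")
  if (length(errs)) stop(paste(errs, collapse = "\n  "))
  cfg
}

.resolveThresholds <- function(cfg) {
  switch(cfg$threshold_mode,
         median_derived = NULL,
         zjw = zjwThresholds(),
         explicit = screenThresholds(cfg$degree_min, cfg$betweenness_min,
                                     cfg$closeness_min, cfg$coreness_min,
                                     hubFactor = cfg$hub_factor,
                                     mode = "explicit"))
}

#' Run the full screening pipeline
#'
#' Ingest -> network build -> two-stage hub screen -> G(n, m) null contrast
#' -> pathway over-representation, with every intermediate written under
#' `output_dir` (network as GraphML, per-node screen table and enrichment
#' as TSV, report as JSON). Identical inputs, config and seed give
#' identical report bodies.
#'
#' @param config a validated config list or YAML path (see
#'   [validateConfig()]).
#' @return the report list, invisibly.
#' @export
runPipeline <- function(config) {
  cfg <- validateConfig(config)
  outDir <- cfg$output_dir
  if (!is.null(outDir)) dir.create(outDir, recursive = TRUE,
                                   showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  message("[ingest] reading target tables and PPI sources")
  herbSets <- stage("ingest", lapply(unlist(cfg$herb_targets), readTargetTable,
                                     idMap = cfg$id_map))
  putative <- stage("ingest", mergeTargetSets(herbSets))
  disease <- stage("ingest", mergeTargetSets(
    lapply(unlist(cfg$disease_targets), readTargetTable, idMap = cfg$id_map)))
  ppi <- stage("ingest", mergePpiSources(
    lapply(unlist(cfg$ppi), readEdgeList, fromColumn = 1, toColumn = 2,
           idMap = cfg$id_map)))
  network <- stage("build", buildInteractionNetwork(
    putative, disease, ppi, expansionRule = cfg$expansion_rule))
  thresholds <- .resolveThresholds(cfg)
  message("[screen] two-stage hub screen (", cfg$threshold_mode, ")")
  screen <- stage("screen", screenHubs(network, hubFactor = cfg$hub_factor,
                                       thresholds = thresholds))
  nullReport <- NULL
  if (cfg$null_replicates >= 1) {
    message("[null] screening ", cfg$null_replicates, " G(n,m) replicates")
    nullReport <- stage("null", nullScreen(
      network, nReplicates = cfg$null_replicates, baseSeed = cfg$seed,
      thresholds = thresholds, hubFactor = cfg$hub_factor))
  }
  enrichment <- NULL
  if (!is.null(cfg$gene_sets) && length(screen@majorHubIds)) {
    message("[enrich] over-representation of ",
            length(screen@majorHubIds), " major hubs")
    annotation <- stage("enrich", readGeneSets(cfg$gene_sets))
    enrichment <- stage("enrich", enrich(screen@majorHubIds, annotation,
                                         universe = nodeIds(network)))
  }
  summary <- networkSummary(network)
  th <- screen@thresholds
  report <- list(
    version = as.character(utils::packageVersion("netscreen")),
    seed = cfg$seed,
    config = cfg[!vapply(cfg, is.null, logical(1))],
    network = summary,
    screen = list(
      nHubs = length(screen@hubIds),
      nMajorHubs = length(screen@majorHubIds),
      majorHubsByClass = as.list(screen@classCounts),
      thresholds = list(mode = th@mode, hubFactor = th@hubFactor,
                        degree = th@degreeMin, betweenness = th@betweennessMin,
                        closeness = th@closenessMin, coreness = th@corenessMin),
      majorHubIds = screen@majorHubIds),
    null = if (!is.null(nullReport)) list(
      nReplicates = nullReport@nReplicates,
      realCount = nullReport@realCount,
      replicateMedian = stats::median(nullReport@replicateCounts),
      replicateMax = max(nullReport@replicateCounts),
      exceedance = nullReport@exceedance),
    enrichment = if (!is.null(enrichment)) list(
      nTested = nrow(enrichment@table),
      nSignificant = nrow(significantPathways(enrichment,
                                              cfg$enrichment_alpha,
                                              cfg$enrichment_use_q)),
      top = topPathways(enrichment, 10, cfg$enrichment_alpha,
                        cfg$enrichment_use_q)[, c("pathway", "K", "k", "p", "q")]))
  if (!is.null(outDir)) {
    writeNetwork(network, file.path(outDir, "network.graphml"), "graphml")
    utils::write.table(screenTable(screen, network),
                       file.path(outDir, "screen.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(nullReport))
      utils::write.table(
        cbind(replicate = seq_len(nullReport@nReplicates),
              majorHubs = nullReport@replicateCounts,
              nullReport@replicateSummary),
        file.path(outDir, "null_replicates.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    if (!is.null(enrichment))
      utils::write.table(enrichment@table,
                         file.path(outDir, "enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA),
               file.path(outDir, "report.json"))
  }
  invisible(report)
}

#' Generate and write a synthetic study fixture
#'
#' Convenience wrapper: [generateStudyFixture()] + [writeStudyFixture()],
#' returning a pipeline config pointing at the written files so the output
#' is immediately consumable by [runPipeline()].
#'
#' @param config a [SyntheticConfig-class].
#' @param dir output directory.
#' @return list with `dataset` (the [SyntheticDataset-class]) and `config`
#'   (a [runPipeline()]-ready list), invisibly.
#' @export
simulateStudyData <- function(config = syntheticConfig(), dir) {
  dataset <- generateStudyFixture(config)
  paths <- writeStudyFixture(dataset, dir)
  runCfg <- list(
    herb_targets = unname(paths[c("herbA", "herbB")]),
    disease_targets = unname(paths[["disease"]]),
    ppi = unname(paths[["ppi"]]),
    gene_sets = unname(paths[["geneSets"]]),
    # the synthetic PPI already emulates the assembled study network (its
    # nodes are the targets plus their interactors), so the identity
    # expansion reproduces it
    expansion_rule = "full_ppi",
    seed = config@seed,
    output_dir = file.path(dir, "results"))
  invisible(list(dataset = dataset, config = runCfg))
}
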