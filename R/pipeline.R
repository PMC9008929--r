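#' Read an analysis configuration file
#'
#' YAML configuration naming a dataset label, per-run tree files (NEXUS),
#' burn-in fraction, retained-taxa sets for pruning, metric settings and
#' seeds. Alternatively a `simulate` block (backbone size, wildcards,
#' locality, nniProb, nTrees) generates a pseudo-posterior instead of
#' reading files.
#'
#' @param path path to a YAML file.
#' @return a validated config list of class `treesumConfig`.
#' @export
readAnalysisConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateAnalysisConfig(cfg)
}

#' @rdname readAnalysisConfig
#' @param cfg a config list.
#' @export
validateAnalysisConfig <- function(cfg) {
  if (is.null(cfg$label)) stop("config: 'label' is required")
  defaults <- list(burninFraction = 0.1, retained = list(), seed = 1L,
                   exactLimit = 30, mcSamples = 1e5, quartetBudget = 1000,
                   stability = TRUE, outputDir = NULL)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (is.null(cfg$trees) && is.null(cfg$simulate)) {
    stop("config: either 'trees' (file paths) or 'simulate' is required")
  }
  if (!is.null(cfg$trees)) {
    missing <- cfg$trees[!file.exists(unlist(cfg$trees))]
    if (length(missing)) stop("config: missing tree files: ",
                              paste(unlist(missing), collapse = ", "))
  }
  if (!is.list(cfg$retained)) cfg$retained <- list(cfg$retained)
  class(cfg) <- "treesumConfig"
  cfg
}

#' Run the full summary pipeline on one dataset
#'
#' Orchestrates the analysis flow: load (or simulate) the posterior runs,
#' remove burn-in and combine, build the annotated full MCC tree, pruned MCC
#' trees and equivalent-node tables for each retained set, compare the MCC
#' tree(s) to the posterior sample with both similarity metrics, and compute
#' the per-taxon stability report. When `outputDir` is set, writes annotated
#' NEXUS trees, TSV tables and a JSON run manifest (seeds, burn-in counts,
#' estimator modes).
#'
#' @param config a `treesumConfig`, or a path to a YAML config.
#' @return an invisible `treesumBundle` list: `label`, `sample`, `fullMcc`,
#'   `meanCladePP`, `cladeTable`, `pruned` (per retained set: `mcc`,
#'   `equivalentNodes`, `support`), `similarity`, `stability`, `manifest`.
#' @export
runSummary <- function(config) {
  if (is.character(config)) config <- readAnalysisConfig(config)
  config <- validateAnalysisConfig(unclass(config))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  sample <- stage("load", loadConfiguredSample(config))
  fullMcc <- stage("mcc", mccTree(sample))
  cladeTab <- stage("clade_posteriors", cladePosteriors(sample))
  mpp <- stage("mean_clade_pp", meanCladePP(fullMcc))
  pruned <- lapply(seq_along(config$retained), function(i) {
    stage(paste0("pruned_mcc_", i), {
      retained <- config$retained[[i]]
      pm <- prunedMcc(sample, retained)
      eq <- equivalentNodes(fullMcc, pm, retained)
      list(retained = retained, mcc = pm, equivalentNodes = eq,
           support = summarizeSupport(eq), meanCladePP = meanCladePP(pm))
    })
  })
  sim <- stage("similarity", similarityToSample(
    fullMcc, sample, exactLimit = config$exactLimit,
    mcSamples = config$mcSamples, seed = config$seed + 1L))
  stab <- if (isTRUE(config$stability)) {
    stage("stability", stabilityReport(sample, fullMcc,
                                       quartetBudget = config$quartetBudget,
                                       seed = config$seed + 2L))
  }
  manifest <- list(
    label = config$label,
    nTrees = length(sample),
    burninFraction = config$burninFraction,
    seed = config$seed,
    exactLimit = config$exactLimit,
    mcSamples = config$mcSamples,
    quartetBudget = config$quartetBudget,
    estimators = unique(sim$estimator),
    package = as.character(utils::packageVersion("treesum"))
  )
  bundle <- structure(list(label = config$label, sample = sample,
                           fullMcc = fullMcc, meanCladePP = mpp,
                           cladeTable = cladeTab, pruned = pruned,
                           similarity = sim, stability = stab,
                           manifest = manifest),
                      class = "treesumBundle")
  if (!is.null(config$outputDir)) writeBundle(bundle, config$outputDir)
  invisible(bundle)
}

loadConfiguredSample <- function(config) {
  if (!is.null(config$trees)) {
    runs <- lapply(unlist(config$trees), readNexusTrees)
    return(combineRuns(runs, config$burninFraction))
  }
  s <- config$simulate
  backbone <- if (!is.null(s$backboneFile)) {
    readNexusTrees(s$backboneFile)[[1L]]
  } else {
    randomTimeTree(s$nTips, seed = config$seed)
  }
  generatePseudoPosterior(
    backbone,
    wildcards = if (is.null(s$wildcards)) character(0) else s$wildcards,
    nTrees = if (is.null(s$nTrees)) 200 else s$nTrees,
    locality = if (is.null(s$locality)) 0 else s$locality,
    nniProb = if (is.null(s$nniProb)) 0 else s$nniProb,
    seed = config$seed + 1000L)
}

writeBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  at <- function(f) file.path(dir, f)
  writeAnnotatedTree(bundle$fullMcc, "nexus", at("full_mcc.nex"))
  writeCladeTable(bundle$cladeTable, at("clade_table.tsv"))
  for (i in seq_along(bundle$pruned)) {
    p <- bundle$pruned[[i]]
    writeAnnotatedTree(p$mcc, "nexus", at(sprintf("pruned_mcc_%d.nex", i)))
    utils::write.table(p$equivalentNodes, at(sprintf("equivalent_nodes_%d.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(bundle$pruned)) {
    supp <- do.call(rbind, lapply(bundle$pruned, `[[`, "support"))
    utils::write.table(supp, at("support_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(bundle$similarity, at("similarity_posterior.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$stability)) {
    utils::write.table(bundle$stability, at("stability.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(bundle$manifest, at("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.treesumBundle <- function(x, ...) {
  cat(sprintf("treesum bundle '%s': %d trees, mean clade PP %.3f, %d pruned set(s)\n",
              x$label, length(x$sample), x$meanCladePP, length(x$pruned)))
  invisible(x)
}

#' Compare summary bundles across datasets
#'
#' Pairwise MCC-vs-MCC similarities (bipartition, quartet, rescaled quartet;
#' restricted to shared taxa) and per-dataset support summaries.
#'
#' @param bundles a list of `treesumBundle` objects (>= 2).
#' @param seed seed for Monte Carlo quartet estimation on large trees.
#' @return a list: `support` (per-dataset mean clade PP, full and pruned) and
#'   `pairwise` (long-format data.frame of MCC pairs with all three
#'   similarities).
#' @export
compareDatasets <- function(bundles, seed = 1L) {
  stopifnot(length(bundles) >= 2L)
  labels <- vapply(bundles, `[[`, character(1), "label")
  support <- data.frame(
    label = labels,
    meanCladePP = vapply(bundles, `[[`, numeric(1), "meanCladePP"),
    meanCladePPPruned = vapply(bundles, function(b) {
      if (length(b$pruned)) mean(vapply(b$pruned, `[[`, numeric(1), "meanCladePP"))
      else NA_real_
    }, numeric(1))
  )
  pairs <- utils::combn(length(bundles), 2L)
  rows <- lapply(c(seq_along(bundles), split(pairs, col(pairs))), function(ix) {
    i <- ix[1L]; j <- ix[length(ix)]
    a <- bundles[[i]]$fullMcc; b <- bundles[[j]]$fullMcc
    qs <- if (length(intersect(a$tip.label, b$tip.label)) <= 30) {
      quartetSimilarityExact(a, b)
    } else {
      quartetSimilarityMC(a, b, seed = seed)$estimate
    }
    data.frame(a = labels[i], b = labels[j],
               bipartition = bipartitionSimilarity(a, b),
               quartet = qs, rescaledQuartet = rescaleQuartet(qs))
  })
  list(support = support, pairwise = do.call(rbind, rows))
}
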