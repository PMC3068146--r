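# End-to-end orchestration: simulate -> select (GA + BVS) -> summarize ->
# specificity -> PCA -> enrichment, driven by one declarative config so a
# single manifest records every parameter and seed.

.pipelineStages <- c("simulate", "select_ga", "select_bvs", "summarize",
                     "specificity", "pca", "enrich")

# Fill a user config with explicit defaults; the manifest records the merged
# result so no default stays silent.
.mergeConfig <- function(config) {
  defaults <- list(
    seed = 1L,
    endpoint = "gleason",
    tissue = "normal",
    stages = .pipelineStages[1:6],
    simulate = list(nPatients = 60L, nGenes = 500L, nInformative = 10L,
                    effectSize = 1.5, signalTissue = "normal",
                    classBalance = 0.5, noiseSd = 1, blockCorrelation = 0,
                    blockSize = 10L),
    input = list(normalPrefix = NULL, tumourPrefix = NULL),
    select_ga = list(populationSize = 30L, generations = 20L,
                     chromosomeSize = 5L, mutationRate = 0.01,
                     crossoverRate = 0.8, elitism = 2L, goalAccuracy = 1.0,
                     nRuns = 5L),
    select_bvs = list(expectedModelSize = 10L, priorScale = 10,
                      nIterations = 3000L, burnIn = 500L, nChains = 2L),
    summarize = list(topFraction = 0.01, maxSize = 10L, tolerance = 0.001,
                     patience = 5L),
    specificity = list(signatureTissue = "normal", nRepeats = 5L,
                       selector = "ga"),
    pca = list(nComponents = 2L, threshold = 0.3),
    enrich = list(gmt = NULL),
    cv = list(innerK = 5L, outerSplits = 40L, trainFraction = 2 / 3,
              stratified = TRUE)
  )
  for (nm in names(config)) {
    if (is.list(defaults[[nm]]) && is.list(config[[nm]])) {
      for (k in names(config[[nm]])) defaults[[nm]][[k]] <- config[[nm]][[k]]
    } else {
      defaults[[nm]] <- config[[nm]]
    }
  }
  defaults
}

.validatePipelineConfig <- function(cfg) {
  bad <- setdiff(cfg$stages, .pipelineStages)
  if (length(bad))
    stop("unknown stage name(s): ", paste(bad, collapse = ", "))
  needData <- setdiff(cfg$stages, "simulate")
  if (length(needData) && !"simulate" %in% cfg$stages &&
      (is.null(cfg$input$normalPrefix) || is.null(cfg$input$tumourPrefix)))
    stop("stages beyond 'simulate' need either the simulate stage or ",
         "input$normalPrefix / input$tumourPrefix")
  if ("enrich" %in% cfg$stages && is.null(cfg$enrich$gmt))
    stop("the enrich stage requires enrich$gmt (a GMT gene-set file)")
  invisible(TRUE)
}

#' Run the full signature-discovery pipeline
#'
#' Executes the configured stages in dependency order inside `outdir`,
#' writing one or more TSV files per stage plus a JSON manifest
#' (`manifest.json`) that snapshots the fully-resolved configuration, all
#' derived seeds, MD5 digests of every input and output file, and the
#' package version. Re-running with the same manifest configuration
#' reproduces byte-identical outputs. Configuration errors (unknown stage,
#' missing endpoint, missing inputs) are raised before any computation.
#'
#' @param config a YAML file path or a named list with entries such as
#'   `seed`, `endpoint`, `tissue`, `stages`, and per-stage sections
#'   (`simulate`, `select_ga`, `select_bvs`, `summarize`, `specificity`,
#'   `pca`, `enrich`, `cv`); anything omitted takes the recorded default.
#' @param outdir output directory (created if needed).
#' @param seed optional override of the config seed.
#' @return The manifest, invisibly, as a list; also written to
#'   `file.path(outdir, "manifest.json")`.
#' @export
runPipeline <- function(config = list(), outdir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  .validatePipelineConfig(cfg)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(
    version = as.character(utils::packageVersion("TissueSig")),
    seed = cfg$seed, config = cfg, stages = list(), digests = list())
  outputs <- character()
  endpoint <- cfg$endpoint

  getPair <- local({
    pair <- NULL
    function() {
      if (!is.null(pair)) return(pair)
      if (!is.null(cfg$input$normalPrefix)) {
        pair <<- list(normal = readDataset(cfg$input$normalPrefix),
                      tumour = readDataset(cfg$input$tumourPrefix))
      } else stop("datasets not available: run the simulate stage or ",
                  "provide input prefixes")
      pair
    }
  })
  env <- environment()

  for (stage in intersect(.pipelineStages, cfg$stages)) {
    stageSeed <- deriveSeed(cfg$seed, match(stage, .pipelineStages))
    stageOut <- tryCatch(switch(stage,
      simulate = {
        sc <- cfg$simulate
        pair <- generatePaired(syntheticConfig(
          nPatients = sc$nPatients, nGenes = sc$nGenes,
          nInformative = sc$nInformative, effectSize = sc$effectSize,
          signalTissue = sc$signalTissue, classBalance = sc$classBalance,
          noiseSd = sc$noiseSd, blockCorrelation = sc$blockCorrelation,
          blockSize = sc$blockSize, seed = stageSeed))
        assign("pair", pair, envir = environment(getPair))
        f1 <- writeDataset(pair$normal, file.path(outdir, "normal"))
        f2 <- writeDataset(pair$tumour, file.path(outdir, "tumour"))
        unname(c(f1, f2))
      },
      select_ga = {
        ds <- getPair()[[cfg$tissue]]
        g <- cfg$select_ga
        pop <- gaEvolve(ds, endpoint, gaConfig(
          populationSize = g$populationSize, generations = g$generations,
          chromosomeSize = g$chromosomeSize, mutationRate = g$mutationRate,
          crossoverRate = g$crossoverRate, elitism = g$elitism,
          goalAccuracy = g$goalAccuracy, nRuns = g$nRuns,
          seed = stageSeed),
          cvConfig(innerK = cfg$cv$innerK, seed = stageSeed))
        assign("gaPop", pop, envir = env)
        p <- file.path(outdir, "ga_population.tsv")
        writeModelPopulation(pop, ds, p)
        p
      },
      select_bvs = {
        ds <- getPair()[[cfg$tissue]]
        b <- cfg$select_bvs
        bcfg <- bvsConfig(expectedModelSize = b$expectedModelSize,
                          priorScale = b$priorScale,
                          nIterations = b$nIterations, burnIn = b$burnIn,
                          nChains = b$nChains, seed = stageSeed)
        chains <- lapply(seq_len(b$nChains), function(i)
          bvsChain(ds, endpoint, bcfg, chainSeed = deriveSeed(stageSeed, i)))
        assign("bvsChains", chains, envir = env)
        paths <- character()
        for (i in seq_along(chains)) {
          tp <- file.path(outdir, sprintf("bvs_chain%d_trace.tsv", i))
          sp <- file.path(outdir, sprintf("bvs_chain%d_subsets.tsv", i))
          writeChainSummary(chains[[i]], tp, sp)
          paths <- c(paths, tp, sp)
        }
        paths
      },
      summarize = {
        ds <- getPair()[[cfg$tissue]]
        s <- cfg$summarize
        models <- list()
        if (exists("gaPop", envir = env, inherits = FALSE)) {
          freq <- geneFrequency(get("gaPop", env), s$topFraction,
                                geneIds(ds))
          models <- c(models, forwardSelectRepresentative(
            freq$index, ds, endpoint,
            cvConfig(innerK = cfg$cv$innerK,
                     outerSplits = cfg$cv$outerSplits,
                     trainFraction = cfg$cv$trainFraction,
                     seed = stageSeed),
            maxSize = s$maxSize, tolerance = s$tolerance,
            patience = s$patience))
        }
        if (exists("bvsChains", envir = env, inherits = FALSE)) {
          models <- c(models, poolChains(get("bvsChains", env), ds,
                                         endpoint, seed = stageSeed))
        }
        if (length(models) == 0L)
          stop("summarize needs at least one of select_ga / select_bvs")
        assign("repModels", models, envir = env)
        p <- file.path(outdir, "representative_models.tsv")
        writeRepresentativeModels(models, p)
        p
      },
      specificity = {
        pair <- getPair()
        sp <- cfg$specificity
        sel <- if (identical(sp$selector, "univariate"))
          univariateSelector(cfg$select_ga$chromosomeSize)
        else gaRepresentativeSelector(gaConfig(
          populationSize = cfg$select_ga$populationSize,
          generations = cfg$select_ga$generations,
          chromosomeSize = cfg$select_ga$chromosomeSize,
          nRuns = cfg$select_ga$nRuns, goalAccuracy = 0.99),
          cvConfig(innerK = cfg$cv$innerK, innerRepeats = 3L))
        res <- specificityTest(pair$normal, pair$tumour, endpoint,
                               signatureTissue = sp$signatureTissue,
                               selector = sel, nRepeats = sp$nRepeats,
                               seed = stageSeed,
                               trainFraction = cfg$cv$trainFraction)
        assign("specRes", res, envir = env)
        p <- file.path(outdir, "specificity.tsv")
        writeSpecificityReport(res, p)
        p
      },
      pca = {
        ds <- getPair()[[cfg$tissue]]
        genes <- if (exists("repModels", envir = env, inherits = FALSE)) {
          modelGenes(get("repModels", env)[[1L]])
        } else {
          utils::head(univariateRank(ds, endpoint)$gene, 5L)
        }
        if (length(genes) < 2L)
          genes <- utils::head(univariateRank(ds, endpoint)$gene, 5L)
        contrib <- pcaContributions(ds, genes, cfg$pca$nComponents,
                                    cfg$pca$threshold)
        p <- file.path(outdir, "pca_loadings.tsv")
        writeLoadingReport(contrib, p)
        p
      },
      enrich = {
        ds <- getPair()[[cfg$tissue]]
        sets <- readGMT(cfg$enrich$gmt)
        focus <- if (exists("repModels", envir = env, inherits = FALSE))
          unique(unlist(lapply(get("repModels", env), modelGenes)))
        else utils::head(univariateRank(ds, endpoint)$gene, 20L)
        tab <- scoreGeneSets(focus, sets, geneIds(ds))
        p <- file.path(outdir, "enrichment.tsv")
        write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
        p
      }),
      error = function(e) stop("stage '", stage, "' failed: ",
                               conditionMessage(e), call. = FALSE))
    manifest$stages[[stage]] <- list(seed = stageSeed, outputs = stageOut)
    outputs <- c(outputs, stageOut)
  }

  for (f in outputs)
    manifest$digests[[basename(f)]] <- unname(tools::md5sum(f))
  manifestPath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Consolidated pipeline report
#'
#' Reads a manifest produced by [runPipeline()] and assembles one summary
#' with a row per representative model (endpoint, tissue, method, genes,
#' accuracies, size), the per-repeat specificity accuracies, and the
#' enrichment table, written both as TSV and as JSON carrying identical
#' values. Stages absent from the manifest simply contribute no rows.
#'
#' @param manifest manifest list or path to `manifest.json`.
#' @param path output TSV path (the JSON goes to the same path with a
#'   `.json` extension).
#' @return The report as a list, invisibly.
#' @export
pipelineReport <- function(manifest, path) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(
    manifest, simplifyVector = TRUE)
  report <- list()
  st <- manifest$stages
  readTsv <- function(f) read.delim(f, check.names = FALSE,
                                    stringsAsFactors = FALSE)
  if (!is.null(st$summarize))
    report$models <- readTsv(st$summarize$outputs[[1L]])
  if (!is.null(st$specificity))
    report$specificity <- readTsv(st$specificity$outputs[[1L]])
  if (!is.null(st$enrich))
    report$enrichment <- readTsv(st$enrich$outputs[[1L]])

  lines <- character()
  for (nm in names(report)) {
    df <- report[[nm]]
    lines <- c(lines, paste0("# ", nm),
               paste(colnames(df), collapse = "\t"),
               apply(df, 1L, function(r) paste(r, collapse = "\t")))
  }
  writeLines(lines, path)
  jsonlite::write_json(report, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(report)
}
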