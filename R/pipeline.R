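#' @include AllClasses.R AllGenerics.R simulate.R mcmc.R trace.R ratestats.R
NULL

## Provenance record written next to every stage output.
.provenance <- function(outDir, stage, cfgPath, seed, files) {
  rec <- list(stage = stage,
              seed = seed,
              config_md5 = if (!is.null(cfgPath) && file.exists(cfgPath))
                unname(tools::md5sum(cfgPath)) else NA,
              package_version = as.character(utils::packageVersion("CastorClock")),
              r_version = R.version.string,
              outputs = files,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(outDir, paste0(stage, ".provenance.json"))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

.requireArtifact <- function(path, stage, producer) {
  if (is.null(path) || !file.exists(path))
    stop("stage '", stage, "' is missing its input '", path,
         "'; run the '", producer, "' stage first or point the config at ",
         "an existing file")
  path
}

#' Read a pipeline configuration
#'
#' YAML with top-level keys `seed`, `out_dir`, and optional blocks `paths`
#' (alignment, tree, traits, trace(s)), `model` (exchangeabilities,
#' frequencies, p_invariant, gamma_shape, n_categories), `simulation`
#' (n_taxa, birth_rate, clock_mean, clock_sigma, slow_multiplier,
#' sequence_length, trait intercept/slope/noise_sd), `mcmc` (chain_length,
#' log_every, burnin_fraction), `calibrations` (list of clade/mean/sd) and
#' `groups` (named taxon sets for the rate tests). Defaults are filled for
#' anything omitted.
#'
#' @param path YAML file.
#' @return Named list of configuration values.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$`_path` <- path
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$out_dir)) cfg$out_dir <- "."
  cfg
}

.modelFromConfig <- function(cfg) {
  m <- cfg$model
  if (is.null(m)) return(substitutionModel())
  substitutionModel(
    exchangeabilities = m$exchangeabilities %||% c(1, 4, 1, 1, 4, 1),
    baseFrequencies = m$frequencies %||% c(0.32, 0.28, 0.12, 0.28),
    pInvariant = m$p_invariant %||% 0.2559,
    gammaShape = m$gamma_shape %||% 0.4721,
    nCategories = m$n_categories %||% 4L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the dating-and-rates pipeline
#'
#' Executes the requested stages in order on a shared output directory:
#' \describe{
#'   \item{simulate}{[beaverLikeFixture()]-style synthetic data: FASTA
#'     alignment, rate-annotated Newick tree, TSV traits and a JSON truth
#'     file.}
#'   \item{date}{[runMCMC()] on the alignment and (topology of the) tree,
#'     writing a TSV trace.}
#'   \item{summarize}{Burn-in removal, clade-age summaries (TSV) and a
#'     posterior-annotated Newick via [annotatePosteriorRates()].}
#'   \item{ratetest}{[rateComparisonReport()] rank-sum tables (TSV).}
#'   \item{regress}{Rate-trait regressions (TSV) with the focal group
#'     collapsed.}
#' }
#' Each stage writes a provenance JSON (config hash, seed, versions) and is
#' independently re-runnable from the files of earlier stages.
#'
#' @param cfg Configuration list from [readPipelineConfig()] (or built in
#'   code).
#' @param stages Character subset of
#'   `c("simulate", "date", "summarize", "ratetest", "regress")`.
#' @return Named list of output file paths, invisibly.
#' @export
runPipeline <- function(cfg, stages = c("simulate", "date", "summarize",
                                        "ratetest", "regress")) {
  stages <- match.arg(stages, several.ok = TRUE)
  outDir <- cfg$out_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  cfgPath <- cfg$`_path`
  paths <- cfg$paths %||% list()
  out <- list()

  alnPath <- paths$alignment %||% file.path(outDir, "alignment.fasta")
  treePath <- paths$tree %||% file.path(outDir, "tree.nwk")
  traitPath <- paths$traits %||% file.path(outDir, "traits.tsv")
  groupPath <- file.path(outDir, "groups.json")
  tracePath <- paths$trace %||% file.path(outDir, "trace.tsv")

  if ("simulate" %in% stages) {
    sim <- cfg$simulation %||% list()
    fx <- beaverLikeFixture(
      seed,
      nTaxa = sim$n_taxa %||% 24L,
      slowCladeSize = sim$slow_clade_size %||% 6L,
      birthRate = sim$birth_rate %||% 0.04,
      clockMean = sim$clock_mean %||% 0.02,
      clockSigma = sim$clock_sigma %||% 0.4,
      slowMultiplier = sim$slow_multiplier %||% 0.5,
      sequenceLength = sim$sequence_length %||% 2000L,
      model = .modelFromConfig(cfg),
      traitIntercept = sim$trait_intercept %||% 27,
      traitSlope = sim$trait_slope %||% -1000,
      traitNoiseSd = sim$trait_noise_sd %||% 4)
    writeAlignment(fx$alignment, alnPath)
    writeTimeTree(fx$tree, treePath)
    writeTraitTable(fx$traits, traitPath)
    jsonlite::write_json(fx$cladeLabels, groupPath, auto_unbox = FALSE)
    truthPath <- file.path(outDir, "truth.json")
    jsonlite::write_json(fx$truth, truthPath, auto_unbox = TRUE, digits = NA)
    files <- c(alignment = alnPath, tree = treePath, traits = traitPath,
               groups = groupPath, truth = truthPath)
    .provenance(outDir, "simulate", cfgPath, seed, as.list(files))
    out <- c(out, as.list(files))
  }

  if ("date" %in% stages) {
    .requireArtifact(alnPath, "date", "simulate")
    .requireArtifact(treePath, "date", "simulate")
    a <- readAlignment(alnPath)
    topo <- readTimeTree(treePath)
    mc <- cfg$mcmc %||% list()
    cals <- cfg$calibrations
    if (is.null(cals))
      cals <- list(list(clade = "root", mean = rootAge(topo),
                        sd = 0.2 * rootAge(topo)))
    calObjs <- lapply(cals, function(cc)
      calibrationPrior(unlist(cc$clade), cc$mean, cc$sd,
                       cc$truncate_at_zero %||% TRUE))
    mcfg <- mcmcConfig(chainLength = mc$chain_length %||% 20000,
                       logEvery = mc$log_every %||% 20,
                       burninFraction = mc$burnin_fraction %||% 0.10,
                       seed = seed)
    tr <- runMCMC(a, topo, .modelFromConfig(cfg), calObjs, mcfg)
    writeTrace(tr, tracePath)
    .provenance(outDir, "date", cfgPath, seed, list(trace = tracePath))
    out$trace <- tracePath
  }

  if ("summarize" %in% stages) {
    .requireArtifact(tracePath, "summarize", "date")
    .requireArtifact(treePath, "summarize", "simulate")
    topo <- readTimeTree(treePath)
    tr <- readTrace(tracePath)
    burn <- (cfg$mcmc %||% list())$burnin_fraction %||% 0.10
    post <- combineTraces(list(tr), burn)
    rootSum <- summarizeCladeAge(post, "root", topo)
    sumPath <- file.path(outDir, "clade_ages.tsv")
    sumTab <- data.frame(clade = "root", mean = rootSum$mean,
                         median = rootSum$median,
                         hpd_low = rootSum$hpd[1], hpd_high = rootSum$hpd[2])
    if (file.exists(groupPath)) {
      groups <- jsonlite::read_json(groupPath, simplifyVector = TRUE)
      for (nm in names(groups)) {
        if (length(groups[[nm]]) < 2 ||
            length(groups[[nm]]) >= nTaxa(topo)) next
        sm <- summarizeCladeAge(post, groups[[nm]], topo)
        sumTab <- rbind(sumTab,
                        data.frame(clade = nm, mean = sm$mean,
                                   median = sm$median, hpd_low = sm$hpd[1],
                                   hpd_high = sm$hpd[2]))
      }
    }
    utils::write.table(sumTab, sumPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    annotated <- annotatePosteriorRates(post, topo)
    annPath <- file.path(outDir, "annotated_tree.nwk")
    writeTimeTree(annotated, annPath)
    .provenance(outDir, "summarize", cfgPath, seed,
                list(clade_ages = sumPath, annotated_tree = annPath))
    out$clade_ages <- sumPath
    out$annotated_tree <- annPath
  }

  if ("ratetest" %in% stages || "regress" %in% stages) {
    annPath <- file.path(outDir, "annotated_tree.nwk")
    ratedTreePath <- if (file.exists(annPath)) annPath else treePath
    .requireArtifact(ratedTreePath, "ratetest", "summarize")
    rtree <- readTimeTree(ratedTreePath)
    if (all(is.na(branchRates(rtree))))
      stop("stage 'ratetest' needs a rate-annotated tree; run 'summarize' ",
           "(or supply an annotated Newick) first")
    groups <- if (file.exists(groupPath))
      jsonlite::read_json(groupPath, simplifyVector = TRUE)
    else stop("stage 'ratetest' is missing its input '", groupPath,
              "'; run the 'simulate' stage first")
    focal <- cfg$focal_group %||% "slow_clade"
    comparisons <- groups[setdiff(names(groups), focal)]
    traits <- if ("regress" %in% stages) {
      .requireArtifact(traitPath, "regress", "simulate")
      readTraitTable(traitPath)
    } else NULL
    rep <- rateComparisonReport(rtree, groups[[focal]], comparisons,
                                traits = traits)
    if ("ratetest" %in% stages) {
      testPath <- file.path(outDir, "rank_sum_tests.tsv")
      utils::write.table(rep$tests, testPath, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      .provenance(outDir, "ratetest", cfgPath, seed, list(tests = testPath))
      out$tests <- testPath
    }
    if ("regress" %in% stages) {
      regPath <- file.path(outDir, "regressions.tsv")
      utils::write.table(rep$regressions, regPath, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      .provenance(outDir, "regress", cfgPath, seed,
                  list(regressions = regPath))
      out$regressions <- regPath
    }
  }

  invisible(out)
}
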