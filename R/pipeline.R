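#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML file (or an equivalent nested list) with a
#' mandatory top-level `seed` and `outdir`, an optional `genome` block
#' (`table` TSV path plus optional `pericentromere_bed`; the synthetic
#' five-chromosome genome is used when absent), and one optional block per
#' stage: `simulate`, `filter`, `call`, `ploidy`, `interference`,
#' `landscape`, `rf`. Unknown keys anywhere are rejected.
#'
#' @param config path to a YAML file, or a named list.
#' @return the validated configuration list.
#' @export
readRunConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML file or a list")
  allowed <- list(
    top = c("seed", "outdir", "genome", "simulate", "filter", "call",
            "ploidy", "interference", "landscape", "rf", "stages"),
    genome = c("table", "pericentromere_bed"),
    simulate = c("n_individuals", "class1_mean", "nu", "class2_mean",
                 "obligate_escape_p", "geno_error_p", "marker_spacing",
                 "mean_lib_reads", "mean_marker_cov"),
    filter = c("min_qual", "min_cov", "min_lib_reads"),
    call = c("window_markers", "purity", "min_segment_markers"),
    ploidy = c("window_bp", "base_depth", "noise_sd", "trisomy", "monosomy"),
    interference = c("bin_width", "null_n", "bootstrap"),
    landscape = c("window", "arm_bins"),
    rf = c("green", "red", "total", "bootstrap")
  )
  checkKeys <- function(x, set, where) {
    unknown <- setdiff(names(x), allowed[[set]])
    if (length(unknown))
      stop("unknown config key(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
  }
  checkKeys(config, "top", "top level")
  for (blk in intersect(names(config), names(allowed)[-1]))
    checkKeys(config[[blk]], blk, blk)
  if (is.null(config$seed)) stop("config must set a seed")
  if (is.null(config$outdir)) stop("config must set an outdir")
  config
}

.stageError <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — simulate, filter, call,
#' ploidy, interference, landscape, rf — writing every output as TSV/BED/
#' JSON under `outdir` and finishing with a `manifest.json` that lists each
#' output file with its row count, the configuration hash, and the seed.
#' Any stage error aborts with a message naming the stage. The same
#' configuration and seed always produce identical outputs.
#'
#' @param config a YAML path or list accepted by [readRunConfig()].
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config) {
  cfg <- readRunConfig(config)
  stages <- cfg$stages %||% c("simulate", "filter", "call", "ploidy",
                              "interference", "landscape", "rf")
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  addFile <- function(path, rows) {
    files[[length(files) + 1L]] <<- list(path = path, rows = rows)
  }
  note <- function(...) message("[meioscope] ", ...)

  genome <- .stageError("genome", {
    if (is.null(cfg$genome)) syntheticGenomeModel()
    else readGenomeModel(cfg$genome$table, cfg$genome$pericentromere_bed)
  })

  sim <- NULL; ge <- NULL; covTrack <- NULL
  if ("simulate" %in% stages) {
    s <- cfg$simulate %||% list()
    sim <- .stageError("simulate", {
      conf <- simConfig(
        genome = genome,
        class1Mean = s$class1_mean %||% 1.8,
        nu = s$nu %||% 5,
        class2Mean = s$class2_mean %||% 0.3,
        obligateEscapeP = s$obligate_escape_p %||% 0,
        genoErrorP = s$geno_error_p %||% 0.02,
        markerSpacing = s$marker_spacing %||% 5e4,
        meanLibReads = s$mean_lib_reads %||% 2e5,
        meanMarkerCov = s$mean_marker_cov %||% 5,
        seed = cfg$seed
      )
      simulateF2Population(conf, s$n_individuals %||% 200)
    })
    ge <- sim$genotypes
    p <- cfg$ploidy %||% list()
    covTrack <- .stageError("simulate", simulateCoverage(
      sim$truth, genome, windowBp = p$window_bp %||% 1e5,
      baseDepth = p$base_depth %||% 20, noiseSd = p$noise_sd %||% 2))
    f <- file.path(outdir, "genotypes.tsv")
    writeGenotypeTable(ge, f); addFile(f, nrow(ge) * ncol(ge))
    f <- file.path(outdir, "true_crossovers.tsv")
    utils::write.table(sim$truth@crossovers, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    addFile(f, nrow(sim$truth@crossovers))
    f <- file.path(outdir, "coverage.tsv")
    writeCoverageTrack(covTrack, f)
    addFile(f, nrow(covTrack) * ncol(covTrack))
    note("simulated ", ncol(ge), " individuals")
  }
  if (is.null(ge)) stop("stage 'filter': no genotype data (run simulate ",
                        "or extend the pipeline to accept input paths)")

  if ("filter" %in% stages) {
    fl <- cfg$filter %||% list()
    ge <- .stageError("filter", suppressMessages(filterLibraries(
      filterSnps(ge, fl$min_qual %||% 100, fl$min_cov %||% 2.5),
      fl$min_lib_reads %||% 5e4)))
    note("after filtering: ", ncol(ge), " libraries")
  }

  segments <- NULL; events <- NULL
  if ("call" %in% stages) {
    cl <- cfg$call %||% list()
    segments <- .stageError("call", segmentGenotypes(
      ge, cl$window_markers %||% 15, cl$purity %||% 0.8,
      cl$min_segment_markers %||% 5))
    events <- .stageError("call", callCrossovers(segments))
    f <- file.path(outdir, "crossovers.bed")
    writeCrossoverBed(events, f); addFile(f, length(events))
    perInd <- as.data.frame(table(
      individual = mcols(events)$individual,
      chrom = as.character(seqnames(events))))
    names(perInd)[3] <- "n_CO"
    f <- file.path(outdir, "crossovers_per_individual.tsv")
    utils::write.table(perInd, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    addFile(f, nrow(perInd))
    note("called ", length(events), " crossovers")
  }

  ploidy <- NULL
  if ("ploidy" %in% stages) {
    if (is.null(covTrack)) stop("stage 'ploidy': no coverage track")
    p <- cfg$ploidy %||% list()
    ploidy <- .stageError("ploidy", callPloidy(
      covTrack, genome, p$trisomy %||% 1.2, p$monosomy %||% 0.8))
    f <- file.path(outdir, "ploidy.tsv")
    utils::write.table(ploidy, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    addFile(f, nrow(ploidy))
    if (!is.null(events))
      events <- .stageError("ploidy", excludeAneuploids(events, ploidy))
  }

  if ("interference" %in% stages) {
    if (is.null(segments)) stop("stage 'interference': no segments")
    it <- cfg$interference %||% list()
    segUse <- segments
    if (!is.null(ploidy)) {
      badIds <- unique(ploidy$individual[ploidy$class != "disomy" |
                                           ploidy$call != "disomy"])
      segUse <- segments[!(segments$individual %in% badIds), ]
    }
    res <- .stageError("interference", interferenceAnalysis(
      segUse, nullN = it$null_n %||% 400,
      bootstrapIters = it$bootstrap %||% 1000,
      binWidth = it$bin_width %||% 3.5e6, seed = cfg$seed))
    f <- file.path(outdir, "cis_dco_distances.tsv")
    utils::write.table(
      data.frame(set = rep(c("observed", "expected"),
                           c(length(res$observed), length(res$expected))),
                 distance = c(res$observed, res$expected)),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    addFile(f, length(res$observed) + length(res$expected))
    f <- file.path(outdir, "gamma_fit.json")
    jsonlite::write_json(list(
      observed = list(shape = res$fitObserved@shape,
                      rate = res$fitObserved@rate,
                      boot_q = stats::quantile(bootstrapShapes(res$fitObserved),
                                               c(.025, .5, .975))),
      expected = list(shape = res$fitExpected@shape,
                      rate = res$fitExpected@rate,
                      boot_q = stats::quantile(bootstrapShapes(res$fitExpected),
                                               c(.025, .5, .975))),
      shape_p = res$shapeP,
      median_observed = res$medianObserved,
      median_expected = res$medianExpected
    ), f, auto_unbox = TRUE, digits = NA)
    addFile(f, 1L)
    f <- file.path(outdir, "coc.tsv")
    utils::write.table(res$coc, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    addFile(f, nrow(res$coc))
    note("interference: shape p = ", signif(res$shapeP, 3))
  }

  if ("landscape" %in% stages) {
    if (is.null(events)) stop("stage 'landscape': no crossover events")
    if (length(pericentromere(genome)) == 0)
      stop("stage 'landscape': genome has no pericentromere annotation")
    ls <- cfg$landscape %||% list()
    prof <- .stageError("landscape", windowFrequency(
      events, ncol(ge), genome, ls$window %||% 3e5))
    f <- file.path(outdir, "landscape.tsv")
    utils::write.table(prof, f, sep = "\t", quote = FALSE, row.names = FALSE)
    addFile(f, nrow(prof))
    scaled <- .stageError("landscape", scaleArms(prof, genome,
                                                 ls$arm_bins %||% 20))
    f <- file.path(outdir, "scaled_arm_profile.tsv")
    utils::write.table(scaled, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    addFile(f, nrow(scaled))
  }

  if ("rf" %in% stages && !is.null(cfg$rf)) {
    r <- cfg$rf
    res <- .stageError("rf", {
      cnt <- seedCounts(r$green, r$red, r$total)
      set.seed(cfg$seed)
      list(rf = recombinationFrequency(cnt),
           ci = rfBootstrapCi(cnt, r$bootstrap %||% 1000))
    })
    f <- file.path(outdir, "rf.json")
    jsonlite::write_json(list(rf_cM = res$rf, ci_low = res$ci[[1]],
                              ci_high = res$ci[[2]]),
                         f, auto_unbox = TRUE, digits = NA)
    addFile(f, 1L)
    note("rf = ", signif(res$rf, 4), " cM")
  }

  manifest <- list(
    seed = cfg$seed,
    parameter_hash = rlang::hash(cfg),
    stages = stages,
    files = files
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
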