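#' Default pipeline configuration
#'
#' @param outDir output directory.
#' @param seed run seed.
#' @return nested config list (YAML-serializable).
#' @export
defaultConfig <- function(outDir = tempfile("mitopause_run_"), seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = outDir,
    simulate = simParams(),
    pausecall = list(window = 201L, zmin = 3, min_cov = 1,
                     min_samples = 2L, sweep = 3:6),
    g4 = list(mode = "hunter", window = 25L, min_tract = 2L,
              loop_min = 1L, loop_max = 7L, max_len = 45L),
    association = list(k = 50L, up = 100L, down = 100L,
                       control = "uniform"),
    genome_fasta = NULL, coverage = NULL, annotation = NULL,
    variants = NULL)
}

#' Validate a pipeline configuration
#'
#' Checks every cross-field constraint and returns the full list of
#' problems, not just the first; an empty character vector means the config
#' is valid.
#'
#' @param config config list (or YAML path).
#' @return character vector of error messages (empty if ok).
#' @export
validateConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errs <- character(0)
  add <- function(e) errs <<- c(errs, e)
  pc <- config$pausecall
  if (is.null(pc)) add("missing pausecall block") else {
    if (is.null(pc$window) || pc$window %% 2L == 0L || pc$window < 1L)
      add("pausecall window must be odd positive")
    if (is.null(pc$zmin) || pc$zmin <= 0) add("zmin must be > 0")
    if (!is.null(pc$min_cov) && pc$min_cov < 0)
      add("min_cov must be >= 0")
    if (is.null(pc$min_samples) || pc$min_samples < 1L)
      add("min_samples must be >= 1")
  }
  g4 <- config$g4
  if (!is.null(g4)) {
    if (!is.null(g4$mode) && !g4$mode %in% c("hunter", "qgrs"))
      add("g4 mode must be hunter or qgrs")
    if (!is.null(g4$loop_min) && g4$loop_min < 0)
      add("g4 loop_min must be >= 0")
    if (!is.null(g4$loop_min) && !is.null(g4$loop_max) &&
        g4$loop_min > g4$loop_max)
      add("g4 loop range inverted")
    if (!is.null(g4$window) && g4$window %% 2L == 0L)
      add("g4 window must be odd")
  }
  nSamples <- NA_integer_
  if (!is.null(config$simulate)) nSamples <- config$simulate$reps
  if (!is.null(config$coverage)) nSamples <- length(config$coverage)
  if (!is.na(nSamples) && !is.null(pc$min_samples) &&
      pc$min_samples > nSamples)
    add("min_samples exceeds the number of samples")
  if (is.null(config$simulate) && is.null(config$coverage))
    add("either a simulate block or coverage inputs required")
  if (!is.null(config$genome_fasta) && !file.exists(config$genome_fasta))
    add("genome_fasta path does not exist")
  for (p in c("annotation", "variants"))
    if (!is.null(config[[p]]) && !file.exists(config[[p]]))
      add(paste(p, "path does not exist"))
  if (is.null(config$seed)) add("seed required")
  if (is.null(config$out_dir)) add("out_dir required")
  errs
}

#' Run the full pipeline
#'
#' Stages run in order: coverage (simulation or bedGraph input, RPM
#' normalization), pause calling (per-sample peaks, consensus, threshold
#' sweep), G4 scoring (hunter track and qgrs motifs), association
#' (metaprofiles around summits, upstream-G enrichment against seeded random
#' controls, strand asymmetry, grouping by upstream G, optional variant
#' overlap and gene annotation). Every stage's outputs and parameters are
#' written under \code{out_dir}; a Markdown report summarizes the run.
#' Reruns with the same config and seed are identical.
#'
#' @param config config list (e.g. \code{\link{defaultConfig}}) or a YAML
#'   file path.
#' @return invisibly, a list with genome, tracks, sites, sweep, g4 tracks,
#'   association results and (for simulated runs) the recovery table.
#' @export
runPipeline <- function(config = defaultConfig()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errs <- validateConfig(config)
  if (length(errs))
    stop("invalid config:\n  ", paste(errs, collapse = "\n  "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  seed <- as.integer(config$seed)
  report <- c("# mitopause run report", "")

  ## stage: genome + coverage ------------------------------------------------
  message("[coverage] building coverage tracks")
  truth <- NULL
  if (!is.null(config$simulate)) {
    sp <- do.call(simParams, config$simulate[setdiff(names(config$simulate),
                                                     "seed")])
    sim <- simulateGenome(sp, seed = seed)
    genome <- sim$genome
    cv <- simulateCoverage(genome, sim$truth, sp, seed = seed + 1L)
    truth <- cv$truth
    rawTracks <- cv$tracks
    denominators <- rep(sp$librarySize, sp$reps)
    writeFasta(genome, out("genome.synthetic.fasta"))
    writeTruth(truth, out("truth"), chrom = genomeName(genome))
  } else {
    genome <- readFastaCircular(config$genome_fasta)
    rawTracks <- lapply(config$coverage, function(cc)
      readBedGraphPair(cc$prefix, genome))
    denominators <- vapply(config$coverage, function(cc)
      as.numeric(cc$library_size), 0)
  }
  mode <- if (!is.null(config$norm_mode)) config$norm_mode else "rpm_total"
  tracks <- mapply(function(tr, d) {
    if (normMode(tr) == "raw") normalizeTrack(tr, mode, d) else tr
  }, rawTracks, denominators, SIMPLIFY = FALSE)
  for (tr in tracks)
    writeBedGraphPair(tr, out(paste0(trackSample(tr), ".rpm")), genome)
  L <- genomeLength(genome)
  report <- c(report,
              sprintf("- genome: %s, %d nt", genomeName(genome), L),
              sprintf("- samples: %d", length(tracks)), "")

  ## stage: pause calling -----------------------------------------------------
  message("[pausecall] calling peaks and consensus sites")
  pc <- config$pausecall
  params <- pauseCallParams(pc$window, pc$zmin,
                            if (is.null(pc$min_cov)) 1 else pc$min_cov,
                            pc$min_samples)
  peaks <- lapply(tracks, callPeaks, params = params)
  for (i in seq_along(peaks))
    utils::write.table(peaks[[i]],
                       out(paste0(trackSample(tracks[[i]]), ".peaks.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  sites <- consensusSites(peaks, params, L)
  writeSites(sites, out("pause_sites.bed"), chrom = genomeName(genome))
  sweep <- thresholdSweep(tracks, params,
                          zGrid = if (is.null(pc$sweep)) 3:6 else pc$sweep)
  utils::write.table(sweep, out("threshold_sweep.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  st <- siteTable(sites)
  report <- c(report, sprintf("- consensus pause sites: %d (+: %d, -: %d)",
                              nSites(sites), sum(st$strand == "+"),
                              sum(st$strand == "-")),
              "- threshold sweep:",
              paste0("    z>=", sweep$zmin, ": ", sweep$nSites, " sites"),
              "")

  ## stage: G4 scoring ---------------------------------------------------------
  message("[g4score] scoring G-quadruplex propensity")
  g4cfg <- config$g4
  hunter <- g4HunterTrack(genome, w = g4cfg$window)
  motifs <- qgrsFindMotifs(genome, minTract = g4cfg$min_tract,
                           loopRange = c(g4cfg$loop_min, g4cfg$loop_max),
                           maxLen = g4cfg$max_len)
  qtrack <- g4MetaTrack(genome, "qgrs", motifs = motifs)
  utils::write.table(motifTable(motifs), out("g4_motifs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report <- c(report, sprintf("- qgrs motifs: %d", nrow(motifTable(motifs))),
              "")

  ## stage: association --------------------------------------------------------
  message("[associate] pause-G4 association statistics")
  as <- config$association
  res <- list(genome = genome, tracks = tracks, sites = sites,
              sweep = sweep, hunter = hunter, motifs = motifs,
              truth = truth)
  if (nSites(sites) > 0L) {
    mpHunter <- metaprofile(hunter, sites, up = as$up, down = as$down)
    mpQgrs <- metaprofile(qtrack, sites, up = as$up, down = as$down)
    utils::write.table(mpHunter, out("metaprofile_hunter.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(mpQgrs, out("metaprofile_qgrs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ctrl <- randomControlSites(
      genome, nSites(sites), propPlus = mean(st$strand == "+"),
      exclude = st, seed = seed + 2L,
      matchCoverage = if (identical(as$control, "coverage_matched"))
        tracks[[1L]] else NULL)
    enr <- upstreamEnrichmentTest(genome, st, ctrl, k = as$k)
    asym <- strandAsymmetryTest(sum(st$strand == "+"),
                                sum(st$strand == "-"))
    grp <- groupByUpstreamG(genome, st, tracks, k = as$k)
    res <- c(res, list(metaHunter = mpHunter, metaQgrs = mpQgrs,
                       enrichment = enr, asymmetry = asym, grouping = grp))
    tests <- list(upstream_enrichment = enr,
                  strand_asymmetry = asym,
                  grouping_global = grp$global,
                  grouping_pairwise = grp$pairwise)
    if (!is.null(config$variants)) {
      vs <- readVariantSet(config$variants)
      res$variantOverlap <- variantOverlap(sites, vs)
      tests$variant_overlap <- res$variantOverlap
    }
    if (!is.null(config$annotation)) {
      ann <- readGeneAnnotation(config$annotation)
      res$annotation <- annotateSites(sites, ann, L)
      utils::write.table(res$annotation$sites, out("sites_annotated.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(tests, out("tests.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
    peakOff <- mpHunter$offset[which.max(mpHunter$mean)]
    report <- c(report,
      sprintf("- strand asymmetry: chi2 = %.2f, p = %.3g",
              asym$chisq, asym$p),
      sprintf("- upstream-G enrichment (pooled): p = %.3g",
              enr$p[enr$group == "pooled"]),
      sprintf("- hunter metaprofile peak offset: %d", peakOff), "")
  }
  if (!is.null(truth)) {
    rec <- evaluateRecovery(sites, truth, tolerance = 1L, genomeLength = L)
    res$recovery <- rec
    report <- c(report, sprintf(
      "- recovery vs planted truth: recall %.3f, precision %.3f (%d/%d/%d)",
      rec$recall, rec$precision, rec$matched, rec$nCalled, rec$nTruth), "")
  }
  manifest <- list(seed = seed, params = params,
                   g4 = g4cfg, association = as,
                   nSamples = length(tracks))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  writeLines(report, out("report.md"))
  invisible(res)
}
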