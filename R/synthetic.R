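#' Simulation parameters
#'
#' Defaults emulate the study conditions: a mitochondrial-length circle with
#' strand-asymmetric guanine content (~13% G on the reference strand, ~31%
#' on its complement), planted four-tract motifs with doublet/triplet tracts
#' and 1-7 nt loops, pauses offset 20-40 nt downstream of a motif's 3' end
#' in transcription direction, negative-binomial background counts, a
#' 30-fold mean elevation at pause bases shared across replicates, and a
#' library size putting the mitochondrial contig at a realistic fraction of
#' a deep nuclear run.
#'
#' @param L genome length (default 16569).
#' @param baseProbPlus reference-strand base probabilities (named A,C,G,T).
#' @param nG4PerStrand planted motifs per strand (default 20).
#' @param tractProb probabilities of tract lengths 2 and 3.
#' @param loopRange loop-length bounds (default 1-7).
#' @param pauseProb probability a motif is coupled to a pause (default 0.8).
#' @param offsetRange motif-3'-end to pause offsets (default 20:40).
#' @param nNoise pauses not coupled to any motif (default 5).
#' @param mu negative-binomial background mean per base per strand.
#' @param size negative-binomial dispersion (size) parameter.
#' @param fold mean elevation factor at pause bases (default 30).
#' @param reps number of replicate samples (default 3).
#' @param librarySize total mapped reads per sample, the RPM denominator.
#' @return parameter list.
#' @export
simParams <- function(L = 16569L,
                      baseProbPlus = c(A = 0.31, C = 0.31, G = 0.13,
                                       T = 0.25),
                      nG4PerStrand = 20L,
                      tractProb = c(`2` = 0.5, `3` = 0.5),
                      loopRange = c(1L, 7L), pauseProb = 0.8,
                      offsetRange = 20:40, nNoise = 5L, mu = 5,
                      size = 10, fold = 30, reps = 3L,
                      librarySize = 2e7) {
  stopifnot(abs(sum(baseProbPlus) - 1) < 1e-8, pauseProb >= 0,
            pauseProb <= 1, fold > 1, mu > 0, size > 0, reps >= 1,
            librarySize > 0)
  maxWidth <- 4L * 3L + 3L * loopRange[2L]
  if (L <= 4L * maxWidth) stop("genome too short for the motif widths")
  list(L = as.integer(L), baseProbPlus = baseProbPlus,
       nG4PerStrand = as.integer(nG4PerStrand), tractProb = tractProb,
       loopRange = as.integer(loopRange), pauseProb = pauseProb,
       offsetRange = as.integer(offsetRange), nNoise = as.integer(nNoise),
       mu = mu, size = size, fold = fold, reps = as.integer(reps),
       librarySize = librarySize)
}

#' Simulate a circular genome with planted G4 motifs
#'
#' Background bases are drawn i.i.d. from the strand-asymmetric composition;
#' motifs (G_x N_l1 G_x N_l2 G_x N_l3 G_x, loop bases from A/C/T) are
#' written at non-overlapping positions with at least 100 nt margins, on
#' both strands (minus-strand motifs are written as their reverse
#' complement), with non-G flanking bases so each planted motif's tracts are
#' exact. Deterministic under a fixed seed.
#'
#' @param params from \code{\link{simParams}}.
#' @param seed RNG seed.
#' @return list with \code{genome} (\linkS4class{CircularGenome}) and
#'   \code{truth} (\linkS4class{SyntheticTruth}, motifs only).
#' @export
simulateGenome <- function(params = simParams(), seed = 1L) {
  .withSeed(seed, {
    L <- params$L
    bases <- sample(names(params$baseProbPlus), L, replace = TRUE,
                    prob = params$baseProbPlus)
    margin <- 100L
    occupied <- logical(L)
    motifs <- list()
    nTotal <- 2L * params$nG4PerStrand
    strands <- rep(c("+", "-"), each = params$nG4PerStrand)
    for (i in seq_len(nTotal)) {
      x <- as.integer(sample(names(params$tractProb), 1L,
                             prob = params$tractProb))
      ls <- sample(params$loopRange[1L]:params$loopRange[2L], 3L,
                   replace = TRUE)
      width <- 4L * x + sum(ls)
      placed <- FALSE
      for (try in seq_len(1000L)) {
        a <- sample(seq.int(margin, L - margin - width), 1L)
        span <- (a - margin):(a + width + margin - 1L)
        if (!any(occupied[span + 1L])) {
          occupied[span + 1L] <- TRUE
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place motif ", i,
                        ": too many motifs for the genome")
      loopSeq <- lapply(ls, function(l) sample(c("A", "C", "T"), l,
                                               replace = TRUE))
      motif <- c(rep("G", x), loopSeq[[1L]], rep("G", x), loopSeq[[2L]],
                 rep("G", x), loopSeq[[3L]], rep("G", x))
      s <- strands[i]
      # scrub same-sense guanines in a loop-width buffer so no candidate
      # can chain a planted tract to a background run: the planted motif is
      # then the unique top-scoring candidate over its own footprint
      buf <- params$loopRange[2L] + 1L
      left <- (a - buf):(a - 1L); right <- (a + width):(a + width + buf - 1L)
      if (s == "+") {
        bases[(a + 1L):(a + width)] <- motif
        bases[c(left, right) + 1L] <-
          ifelse(bases[c(left, right) + 1L] == "G", "A",
                 bases[c(left, right) + 1L])
      } else {
        bases[(a + 1L):(a + width)] <- rev(chartr("ACGT", "TGCA", motif))
        bases[c(left, right) + 1L] <-
          ifelse(bases[c(left, right) + 1L] == "C", "T",
                 bases[c(left, right) + 1L])
      }
      motifs[[i]] <- data.frame(start = a, end = a + width, width = width,
                                strand = s, tract = x, l1 = ls[1L],
                                l2 = ls[2L], l3 = ls[3L],
                                stringsAsFactors = FALSE)
    }
    mdf <- if (length(motifs)) do.call(rbind, motifs) else
      data.frame(start = integer(0), end = integer(0), width = integer(0),
                 strand = character(0), tract = integer(0),
                 l1 = integer(0), l2 = integer(0), l3 = integer(0))
    genome <- circularGenome(paste(bases, collapse = ""), name = "chrM")
    truth <- new("SyntheticTruth", motifs = mdf,
                 pauses = data.frame(pos = integer(0),
                                     strand = character(0),
                                     source = character(0),
                                     motif = integer(0)),
                 params = c(params, seed = seed))
    list(genome = genome, truth = truth)
  })
}

#' Simulate replicate 3'-end coverage with planted pauses
#'
#' Each planted motif is coupled to a pause with probability
#' \code{pauseProb}; the pause sits a uniform 20-40 nt downstream of the
#' motif's 3'-most base in transcription direction, so the motif ends up
#' 20-40 nt upstream of the pause on the nascent RNA. Additional noise
#' pauses are placed uniformly. Counts are negative binomial with mean
#' \code{mu} at background bases and \code{mu * fold} at pause bases; pause
#' positions are shared across replicates, count draws independent.
#'
#' @param genome the simulated \linkS4class{CircularGenome}.
#' @param truth \linkS4class{SyntheticTruth} from \code{\link{simulateGenome}}.
#' @param params from \code{\link{simParams}}.
#' @param seed RNG seed.
#' @return list with \code{tracks} (list of raw
#'   \linkS4class{EndCoverageTrack}s) and \code{truth} (pauses filled in).
#' @export
simulateCoverage <- function(genome, truth, params = simParams(),
                             seed = 2L) {
  .withSeed(seed, {
    L <- genomeLength(genome)
    m <- truthMotifs(truth)
    pauses <- list()
    taken <- character(0)
    for (i in seq_len(nrow(m))) {
      if (stats::runif(1L) > params$pauseProb) next
      off <- sample(params$offsetRange, 1L)
      pos <- if (m$strand[i] == "+")
        .modpos(m$end[i] - 1L + off, L) else .modpos(m$start[i] - off, L)
      key <- paste(pos, m$strand[i])
      if (key %in% taken) next
      taken <- c(taken, key)
      pauses[[length(pauses) + 1L]] <- data.frame(
        pos = pos, strand = m$strand[i], source = "g4", motif = i,
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(params$nNoise)) {
      repeat {
        pos <- sample.int(L, 1L) - 1L
        s <- sample(c("+", "-"), 1L)
        if (!paste(pos, s) %in% taken) break
      }
      taken <- c(taken, paste(pos, s))
      pauses[[length(pauses) + 1L]] <- data.frame(
        pos = pos, strand = s, source = "noise", motif = NA_integer_,
        stringsAsFactors = FALSE)
    }
    pdf <- if (length(pauses)) do.call(rbind, pauses) else
      data.frame(pos = integer(0), strand = character(0),
                 source = character(0), motif = integer(0))
    tracks <- lapply(seq_len(params$reps), function(r) {
      draw <- function(strand) {
        x <- stats::rnbinom(L, size = params$size, mu = params$mu)
        at <- pdf$pos[pdf$strand == strand]
        if (length(at))
          x[at + 1L] <- stats::rnbinom(length(at), size = params$size,
                                       mu = params$mu * params$fold)
        x
      }
      endCoverageTrack(draw("+"), draw("-"),
                       sample = paste0("rep", r))
    })
    truth@pauses <- pdf
    truth@params <- c(truth@params[setdiff(names(truth@params),
                                           "coverageSeed")],
                      coverageSeed = seed)
    list(tracks = tracks, truth = truth)
  })
}

#' Write and read simulation truth
#'
#' \code{writeTruth} writes \code{motifs.bed}, \code{pauses.bed} and
#' \code{params.json} into a directory; \code{readTruth} reconstructs the
#' truth object (read-back identity on coordinates, strands, sources).
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param dir output directory (created if needed).
#' @param chrom contig name for the BED files.
#' @return \code{writeTruth}: the directory, invisibly; \code{readTruth}: a
#'   \linkS4class{SyntheticTruth}.
#' @export
writeTruth <- function(truth, dir, chrom = "chrM") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- truthMotifs(truth)
  writeBed(data.frame(chrom = chrom, start = m$start, end = m$end,
                      name = paste0("motif_", seq_len(nrow(m)), "_x",
                                    m$tract, "_", m$l1, m$l2, m$l3),
                      score = 0, strand = m$strand),
           file.path(dir, "motifs.bed"))
  p <- truthPauses(truth)
  writeBed(data.frame(chrom = chrom, start = p$pos, end = p$pos + 1L,
                      name = paste0("pause_", seq_len(nrow(p)), "_",
                                    p$source),
                      score = 0, strand = p$strand),
           file.path(dir, "pauses.bed"))
  jsonlite::write_json(truthParams(truth), file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeTruth
#' @export
readTruth <- function(dir) {
  mb <- readBed(file.path(dir, "motifs.bed"))
  parts <- strsplit(sub("^motif_[0-9]+_x", "", mb$name), "_")
  m <- data.frame(start = mb$start, end = mb$end,
                  width = mb$end - mb$start, strand = mb$strand,
                  tract = as.integer(vapply(parts, `[`, "", 1L)),
                  stringsAsFactors = FALSE)
  loops <- vapply(parts, `[`, "", 2L)
  m$l1 <- as.integer(substr(loops, 1, 1))
  m$l2 <- as.integer(substr(loops, 2, 2))
  m$l3 <- as.integer(substr(loops, 3, 3))
  pb <- readBed(file.path(dir, "pauses.bed"))
  p <- data.frame(pos = pb$start, strand = pb$strand,
                  source = sub("^pause_[0-9]+_", "", pb$name),
                  motif = NA_integer_, stringsAsFactors = FALSE)
  params <- jsonlite::read_json(file.path(dir, "params.json"),
                                simplifyVector = TRUE)
  new("SyntheticTruth", motifs = m, pauses = p, params = params)
}

#' Precision and recall of called sites against planted truth
#'
#' A truth pause is recovered when a called summit on the same strand lies
#' within \code{tolerance} nt (circular distance); matching is one-to-one,
#' greedy by distance. Precision = matched called / called; recall =
#' matched truth / truth. With no calls, precision is NA.
#'
#' @param sites a \linkS4class{PauseSiteSet} or site frame.
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param tolerance nt tolerance (default 1).
#' @param genomeLength contig length (from a PauseSiteSet automatically).
#' @return list: nCalled, nTruth, matched, precision, recall.
#' @export
evaluateRecovery <- function(sites, truth, tolerance = 1L,
                             genomeLength = NULL) {
  if (is(sites, "PauseSiteSet")) {
    if (is.null(genomeLength)) genomeLength <- sites@genomeLength
    sites <- siteTable(sites)
  }
  L <- as.integer(genomeLength)
  p <- truthPauses(truth)
  nC <- nrow(sites); nT <- nrow(p)
  if (nC == 0L)
    return(list(nCalled = 0L, nTruth = nT, matched = 0L,
                precision = NA_real_, recall = if (nT) 0 else NA_real_))
  pairs <- list()
  for (i in seq_len(nC)) {
    same <- which(p$strand == sites$strand[i])
    if (!length(same)) next
    d <- .circDist(sites$summit[i], p$pos[same], L)
    for (k in which(d <= tolerance))
      pairs[[length(pairs) + 1L]] <- c(i, same[k], d[k])
  }
  matched <- 0L
  if (length(pairs)) {
    pm <- do.call(rbind, pairs)
    pm <- pm[order(pm[, 3L]), , drop = FALSE]
    usedC <- logical(nC); usedT <- logical(nT)
    for (r in seq_len(nrow(pm))) {
      ci <- pm[r, 1L]; ti <- pm[r, 2L]
      if (!usedC[ci] && !usedT[ti]) {
        usedC[ci] <- TRUE; usedT[ti] <- TRUE
        matched <- matched + 1L
      }
    }
  }
  list(nCalled = nC, nTruth = nT, matched = matched,
       precision = matched / nC,
       recall = if (nT) matched / nT else NA_real_)
}
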