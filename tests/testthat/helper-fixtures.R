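# fixtures are built in code; nothing binary is stored in the repo

# a random genome string with given base probabilities
randomSeq <- function(L, prob = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(prob), L, replace = TRUE, prob = prob), collapse = "")
}

# minimal SAM text for a single circular contig
writeSAM <- function(reads, L = 1000L, contig = "chrM",
                     path = tempfile(fileext = ".sam")) {
  # reads: data.frame(qname, flag, pos1 (1-based), cigar)
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", contig, L),
    vapply(seq_len(nrow(reads)), function(i) {
      w <- sum(as.integer(
        regmatches(reads$cigar[i],
                   gregexpr("[0-9]+(?=[MIS=X])", reads$cigar[i],
                            perl = TRUE))[[1]]))
      paste(reads$qname[i], reads$flag[i], contig, reads$pos1[i], 60,
            reads$cigar[i], "*", 0, 0, strrep("A", w), strrep("I", w),
            sep = "\t")
    }, ""))
  writeLines(lines, path)
  path
}

# naive per-base circular window statistics (population sd)
naiveRollingStats <- function(x, W) {
  L <- length(x)
  h <- (W - 1L) / 2L
  m <- numeric(L); s <- numeric(L)
  for (i in seq_len(L)) {
    idx <- ((i - 1L - h):(i - 1L + h)) %% L + 1L
    v <- x[idx]
    m[i] <- mean(v)
    s[i] <- sqrt(mean((v - m[i])^2))
  }
  list(mean = m, sd = s)
}

# independent candidate oracle for four-tract motifs: regex lookahead per
# (tract, loop triple) combination
regexQgrsOracle <- function(seq, minTract = 2L, loopRange = c(1L, 7L),
                            maxLen = 45L) {
  out <- list()
  n <- nchar(seq)
  maxTract <- floor((maxLen - 3 * max(1, loopRange[1])) / 4)
  for (x in minTract:maxTract) {
    for (l1 in loopRange[1]:loopRange[2])
      for (l2 in loopRange[1]:loopRange[2])
        for (l3 in loopRange[1]:loopRange[2]) {
          width <- 4 * x + l1 + l2 + l3
          if (width > maxLen || width > n) next
          pat <- sprintf("(?=G{%d}.{%d}G{%d}.{%d}G{%d}.{%d}G{%d})",
                         x, l1, x, l2, x, l3, x)
          m <- gregexpr(pat, seq, perl = TRUE)[[1]]
          if (m[1] == -1) next
          out[[length(out) + 1L]] <- data.frame(
            start = as.integer(m) - 1L, width = width, tract = x,
            l1 = l1, l2 = l2, l3 = l3)
        }
  }
  if (!length(out))
    return(data.frame(start = integer(0), width = integer(0),
                      tract = integer(0), l1 = integer(0),
                      l2 = integer(0), l3 = integer(0)))
  o <- do.call(rbind, out)
  o[order(o$start, o$width, o$tract, o$l1, o$l2, o$l3), ]
}

# a small simulated data set shared by several tests
smallSim <- function(seed = 5L) {
  p <- simParams(L = 5000L, nG4PerStrand = 6L, nNoise = 2L, reps = 3L)
  sg <- simulateGenome(p, seed = seed)
  cv <- simulateCoverage(sg$genome, sg$truth, p, seed = seed + 1L)
  tracks <- lapply(cv$tracks, normalizeTrack, mode = "rpm_total",
                   denominator = p$librarySize)
  list(genome = sg$genome, truth = cv$truth, tracks = tracks, params = p)
}
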