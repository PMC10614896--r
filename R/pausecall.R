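#' Pause-calling parameters
#'
#' @param window odd window width in nt for the local Z-score (default 201).
#' @param zmin minimal Z-score for a peak (default 3).
#' @param minCov minimal normalized coverage in RPM (default 1).
#' @param minSamples samples required to support a consensus site
#'   (default 2).
#' @return a list of class parameters used by the caller functions.
#' @export
pauseCallParams <- function(window = 201L, zmin = 3, minCov = 1,
                            minSamples = 2L) {
  if (window %% 2L == 0L || window < 1L) stop("window must be odd positive")
  if (zmin <= 0) stop("zmin must be positive")
  if (minCov < 0) stop("minCov must be non-negative")
  if (minSamples < 1L) stop("minSamples must be >= 1")
  list(window = as.integer(window), zmin = zmin, minCov = minCov,
       minSamples = as.integer(minSamples))
}

#' Rolling circular window statistics
#'
#' Mean and population standard deviation of the \code{W} values centered at
#' each base, with circular wrap; the center base is included in its own
#' window. Values are centered on the global mean before accumulating to
#' avoid cancellation, so results agree with a naive per-base loop to well
#' below 1e-9 relative error.
#'
#' @param x numeric per-base track.
#' @param W odd window width, \code{W <= length(x)}.
#' @return list with numeric vectors \code{mean} and \code{sd}.
#' @export
rollingWindowStats <- function(x, W) {
  L <- length(x)
  if (W %% 2L == 0L) stop("window width must be odd")
  if (W > L) stop("window width exceeds track length")
  mu <- mean(x)
  xc <- x - mu
  m <- .circMovingMean(xc, W)
  m2 <- .circMovingMean(xc * xc, W)
  v <- pmax(m2 - m * m, 0)
  list(mean = m + mu, sd = sqrt(v))
}

#' Per-base window Z-scores
#'
#' \code{Z_i = (x_i - mean_i) / sd_i} against the centered circular window;
#' where the window standard deviation is zero the base equals its window
#' mean and Z is defined as 0.
#'
#' @inheritParams rollingWindowStats
#' @return numeric Z-score vector.
#' @export
zscoreTrack <- function(x, W = 201L) {
  st <- rollingWindowStats(x, W)
  z <- (x - st$mean) / st$sd
  z[st$sd == 0] <- 0
  z
}

#' Call per-sample peaks
#'
#' Emits exactly the bases with window Z-score >= \code{zmin} and coverage
#' >= \code{minCov}, per strand. The coverage gate is in normalized units,
#' so a raw track is a unit-mismatch error.
#'
#' @param track normalized \linkS4class{EndCoverageTrack}.
#' @param params from \code{\link{pauseCallParams}}.
#' @param sample sample id for the emitted peaks.
#' @return data.frame with columns pos (0-based), strand, z, coverage,
#'   sample.
#' @export
callPeaks <- function(track, params = pauseCallParams(),
                      sample = trackSample(track)) {
  if (normMode(track) == "raw")
    stop("raw track: minCov is in RPM units; normalize first")
  out <- lapply(c("+", "-"), function(s) {
    v <- trackValues(track, s)
    z <- zscoreTrack(v, params$window)
    hit <- which(z >= params$zmin & v >= params$minCov)
    data.frame(pos = hit - 1L, strand = rep(s, length(hit)),
               z = z[hit], coverage = v[hit],
               sample = rep(sample, length(hit)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# runs of TRUE on a circle, each returned as an ordered 0-based position
# vector (wrap runs ordered along the circle)
#' @noRd
.circularRuns <- function(flag) {
  L <- length(flag)
  if (!any(flag)) return(list())
  if (all(flag)) return(list(0:(L - 1L)))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  runs <- lapply(idx, function(i) (starts[i]:ends[i]) - 1L)
  if (flag[1L] && flag[L]) {
    k <- length(runs)
    runs[[1L]] <- c(runs[[k]], runs[[1L]])
    runs <- runs[-k]
  }
  runs
}

#' Consensus pause sites across samples
#'
#' Per-base voting on each strand: a base is a consensus base when it is a
#' peak in at least \code{minSamples} samples; runs of consecutive consensus
#' bases on the same strand (wrap-aware) merge into one site. The summit is
#' the base with maximal Z summed over supporting samples, ties broken by
#' the first base in transcription direction.
#'
#' @param peakList list of per-sample peak data.frames from
#'   \code{\link{callPeaks}}.
#' @param params from \code{\link{pauseCallParams}}.
#' @param genomeLength contig length L.
#' @return a \linkS4class{PauseSiteSet}.
#' @export
consensusSites <- function(peakList, params, genomeLength) {
  L <- as.integer(genomeLength)
  if (length(peakList) < params$minSamples)
    stop("fewer samples than minSamples")
  for (p in peakList)
    if (nrow(p) && any(p$pos < 0 | p$pos >= L))
      stop("peak positions outside genome (mismatched genome length?)")
  rows <- list()
  for (s in c("+", "-")) {
    votes <- integer(L); zsum <- numeric(L); zmax <- numeric(L)
    for (p in peakList) {
      ps <- p[p$strand == s, , drop = FALSE]
      if (!nrow(ps)) next
      votes[ps$pos + 1L] <- votes[ps$pos + 1L] + 1L
      zsum[ps$pos + 1L] <- zsum[ps$pos + 1L] + ps$z
      zmax[ps$pos + 1L] <- pmax(zmax[ps$pos + 1L], ps$z)
    }
    runs <- .circularRuns(votes >= params$minSamples)
    for (run in runs) {
      trav <- if (s == "+") run else rev(run)
      summit <- trav[which.max(zsum[trav + 1L])]
      w <- length(run)
      rows[[length(rows) + 1L]] <- data.frame(
        start = run[1L], end = .modpos(run[w] + 1L, L), width = w,
        strand = s, summit = summit,
        nSupport = max(votes[run + 1L]),
        maxZ = max(zmax[run + 1L]), sumZ = zsum[summit + 1L],
        stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(0), end = integer(0), width = integer(0),
               strand = character(0), summit = integer(0),
               nSupport = integer(0), maxZ = numeric(0), sumZ = numeric(0))
  sites <- sites[order(sites$start, sites$strand), , drop = FALSE]
  rownames(sites) <- NULL
  new("PauseSiteSet", sites = sites, genomeLength = L,
      params = c(params, nSamples = length(peakList)))
}

#' Sweep the Z-score threshold
#'
#' Re-calls consensus sites over a grid of Z thresholds (the other gates
#' unchanged); site counts are non-increasing in the threshold.
#'
#' @param tracks list of normalized \linkS4class{EndCoverageTrack}s.
#' @param params from \code{\link{pauseCallParams}}.
#' @param zGrid ascending numeric thresholds (default 3:6).
#' @return data.frame with columns zmin, nSites, nConsensusBases.
#' @export
thresholdSweep <- function(tracks, params = pauseCallParams(),
                           zGrid = 3:6) {
  if (is.unsorted(zGrid)) stop("zGrid must be ascending")
  L <- trackLength(tracks[[1L]])
  # peaks at the loosest threshold, filtered per grid point
  base <- pauseCallParams(params$window, min(zGrid), params$minCov,
                          params$minSamples)
  peaks <- lapply(tracks, callPeaks, params = base)
  out <- lapply(zGrid, function(zt) {
    filt <- lapply(peaks, function(p) p[p$z >= zt, , drop = FALSE])
    ss <- consensusSites(filt, params, L)
    data.frame(zmin = zt, nSites = nSites(ss),
               nConsensusBases = sum(siteTable(ss)$width))
  })
  do.call(rbind, out)
}

#' Write pause sites as BED6
#'
#' Name = \code{site_<i>}, score = 10 x summit summed Z rounded (capped at
#' 1000), strand set. A site wrapping the origin is split into two BED lines
#' sharing a name. An empty set writes a header comment only.
#'
#' @param sites a \linkS4class{PauseSiteSet}.
#' @param path output path.
#' @param chrom contig name for column 1.
#' @return the path, invisibly.
#' @export
writeSites <- function(sites, path, chrom = "chrM") {
  s <- siteTable(sites)
  L <- sites@genomeLength
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# pause sites; 0-based half-open; score = min(1000,",
                    " round(10*sumZ))"), con)
  if (nrow(s) == 0L) return(invisible(path))
  for (i in seq_len(nrow(s))) {
    nm <- paste0("site_", i)
    sc <- min(1000L, as.integer(round(10 * s$sumZ[i])))
    if (s$end[i] > s$start[i]) {
      seg <- data.frame(a = s$start[i], b = s$end[i])
    } else {
      seg <- data.frame(a = c(s$start[i], 0L), b = c(L, s$end[i]))
      seg <- seg[seg$b > seg$a, , drop = FALSE]
    }
    for (j in seq_len(nrow(seg)))
      writeLines(paste(chrom, seg$a[j], seg$b[j], nm, sc, s$strand[i],
                       sep = "\t"), con)
  }
  invisible(path)
}
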