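test_that("rolling circular stats match a naive per-base loop", {
  set.seed(10)
  for (rep in 1:5) {
    L <- sample(300:800, 1)
    x <- rnbinom(L, size = 5, mu = 4)
    W <- sample(c(11L, 51L, 201L), 1)
    if (W > L) W <- 51L
    got <- rollingWindowStats(x, W)
    want <- naiveRollingStats(x, W)
    expect_equal(got$mean, want$mean, tolerance = 1e-11)
    expect_equal(got$sd, want$sd, tolerance = 1e-11)
  }
  expect_error(rollingWindowStats(1:10, 4), "odd")
  expect_error(rollingWindowStats(1:10, 11), "exceeds")
})

test_that("rolling stats and Z-scores are rotation equivariant", {
  set.seed(11)
  x <- rnbinom(400, size = 5, mu = 3)
  k <- 137
  xr <- c(x[(k + 1):400], x[1:k])
  a <- rollingWindowStats(x, 51)
  b <- rollingWindowStats(xr, 51)
  expect_equal(b$mean, c(a$mean[(k + 1):400], a$mean[1:k]))
  expect_equal(zscoreTrack(xr, 51),
               c(zscoreTrack(x, 51)[(k + 1):400], zscoreTrack(x, 51)[1:k]))
})

test_that("Z-score conventions: constant, spike, scale invariance", {
  expect_equal(zscoreTrack(rep(4, 300), 201), rep(0, 300))
  for (h in c(1, 5, 1000)) {
    x <- numeric(1000); x[500] <- h
    z <- zscoreTrack(x, 201)
    expect_equal(z[500], sqrt(200), tolerance = 1e-9)
  }
  set.seed(12)
  x <- rnbinom(500, size = 5, mu = 4)
  expect_equal(zscoreTrack(2 * x, 201), zscoreTrack(x, 201),
               tolerance = 1e-9)
})

test_that("peak calling applies both gates and refuses raw tracks", {
  L <- 1000L
  mkTrack <- function(h) {
    plus <- numeric(L); plus[500] <- h
    endCoverageTrack(plus, numeric(L), normalization = "rpm_total",
                     denominator = 1e6)
  }
  params <- pauseCallParams()
  # spike passes Z but fails the 1-RPM gate
  expect_equal(nrow(callPeaks(mkTrack(0.5), params)), 0)
  # spike passes both gates
  pk <- callPeaks(mkTrack(2), params)
  expect_equal(pk$pos, 499)
  expect_equal(pk$strand, "+")
  expect_gt(pk$z, 3)
  # all-zero track yields no peaks
  expect_equal(nrow(callPeaks(mkTrack(0), params)), 0)
  raw <- endCoverageTrack(numeric(L), numeric(L))
  expect_error(callPeaks(raw, params), "normalize")
})

test_that("consensus voting, merging and summit tie-breaks", {
  params <- pauseCallParams(minSamples = 2L)
  L <- 100L
  peak <- function(pos, strand = "+", z = 5, sample = "s") {
    data.frame(pos = pos, strand = strand, z = z, coverage = 2,
               sample = sample)
  }
  # peak at p in samples 1 and 2 of 3 -> one site
  ss <- consensusSites(list(peak(10), peak(10), peak(99)), params, L)
  expect_equal(nSites(ss), 1)
  expect_equal(siteTable(ss)$summit, 10)
  expect_equal(siteTable(ss)$nSupport, 2)
  # peak in one sample only -> no site
  expect_equal(nSites(consensusSites(list(peak(10), peak(99)), params, L)),
               0)
  # adjacent consensus bases merge into one site of width 2
  two <- rbind(peak(10), peak(11))
  ss2 <- consensusSites(list(two, two), params, L)
  expect_equal(nSites(ss2), 1)
  expect_equal(siteTable(ss2)$width, 2)
  # a run crossing the origin merges into a single wrapped site
  wrap <- rbind(peak(99), peak(0))
  ss3 <- consensusSites(list(wrap, wrap), params, L)
  expect_equal(nSites(ss3), 1)
  expect_equal(siteTable(ss3)$start, 99)
  expect_equal(siteTable(ss3)$end, 1)
  expect_equal(siteTable(ss3)$width, 2)
  # tie on summed Z: first base in transcription direction wins
  tie <- rbind(peak(20), peak(21))
  ssP <- consensusSites(list(tie, tie), params, L)
  expect_equal(siteTable(ssP)$summit, 20)
  tieM <- rbind(peak(20, "-"), peak(21, "-"))
  ssM <- consensusSites(list(tieM, tieM), params, L)
  expect_equal(siteTable(ssM)$summit, 21)
  # strands are called independently
  mixed <- rbind(peak(10, "+"), peak(10, "-"))
  ss4 <- consensusSites(list(mixed, mixed), params, L)
  expect_equal(nSites(ss4), 2)
})

test_that("raising thresholds never increases the site count", {
  sim <- smallSim()
  params <- pauseCallParams()
  sw <- thresholdSweep(sim$tracks, params, zGrid = 3:6)
  expect_equal(nrow(sw), 4)
  expect_true(all(diff(sw$nSites) <= 0))
  # zmin above the global max -> 0 sites
  sw2 <- thresholdSweep(sim$tracks, params, zGrid = c(3, 1e6))
  expect_equal(sw2$nSites[2], 0)
  # monotone in minSamples and minCov as well
  peaks <- lapply(sim$tracks, callPeaks, params = params)
  L <- genomeLength(sim$genome)
  n2 <- nSites(consensusSites(peaks, pauseCallParams(minSamples = 2), L))
  n3 <- nSites(consensusSites(peaks, pauseCallParams(minSamples = 3), L))
  expect_lte(n3, n2)
  strict <- lapply(sim$tracks, callPeaks,
                   params = pauseCallParams(minCov = 5))
  expect_lte(nSites(consensusSites(strict, params, L)), n2)
  expect_error(thresholdSweep(sim$tracks, params, zGrid = c(5, 3)),
               "ascending")
})

test_that("site BED output splits wrapped sites and caps scores", {
  params <- pauseCallParams(minSamples = 2L)
  peak <- function(pos, z = 5) data.frame(pos = pos, strand = "+", z = z,
                                          coverage = 2, sample = "s")
  wrap <- rbind(peak(298), peak(299), peak(0), peak(200, z = 200))
  ss <- consensusSites(list(wrap, wrap), params, 300L)
  path <- tempfile(fileext = ".bed")
  writeSites(ss, path, chrom = "chrM")
  lines <- grep("^[^#]", readLines(path), value = TRUE)
  f <- do.call(rbind, strsplit(lines, "\t"))
  # wrapped site -> two lines sharing a name
  wrapName <- names(which(table(f[, 4]) == 2))
  expect_length(wrapName, 1)
  seg <- f[f[, 4] == wrapName, ]
  expect_setequal(paste(seg[, 2], seg[, 3]), c("298 300", "0 1"))
  # score capped at 1000 (z 200 in two samples -> sumZ 400 -> 4000 raw)
  expect_true(any(f[, 5] == "1000"))
  # empty set writes only the header comment
  empty <- consensusSites(list(peak(10)[0, ], peak(10)[0, ]), params, 300L)
  p2 <- tempfile(fileext = ".bed")
  writeSites(empty, p2)
  expect_true(all(grepl("^#", readLines(p2))))
})

test_that("calling on a rotated track yields rotated sites", {
  sim <- smallSim(seed = 21)
  params <- pauseCallParams()
  L <- genomeLength(sim$genome)
  k <- 1234L
  rot <- function(tr) {
    idx <- c((k + 1):L, 1:k)
    endCoverageTrack(trackValues(tr, "+")[idx], trackValues(tr, "-")[idx],
                     sample = trackSample(tr),
                     normalization = normMode(tr),
                     denominator = normDenominator(tr))
  }
  s1 <- consensusSites(lapply(sim$tracks, callPeaks, params = params),
                       params, L)
  s2 <- consensusSites(lapply(lapply(sim$tracks, rot), callPeaks,
                              params = params), params, L)
  expect_equal(sort((siteTable(s1)$summit - k) %% L),
               sort(siteTable(s2)$summit))
})
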