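test_that("metaprofiles orient windows by transcription direction", {
  L <- 500L
  sites <- data.frame(summit = c(100L, 300L), strand = c("+", "+"))
  const <- list(plus = rep(3, L), minus = rep(3, L))
  mp <- metaprofile(const, sites, up = 20, down = 20)
  expect_equal(mp$mean, rep(3, 41))
  expect_equal(mp$sem, rep(0, 41))
  expect_equal(attr(mp, "n"), 2)
  # delta at the summit appears at offset 0
  delta <- list(plus = replace(numeric(L), 101, 1), minus = numeric(L))
  mp2 <- metaprofile(delta, data.frame(summit = 100L, strand = "+"),
                     up = 10, down = 10)
  expect_equal(mp2$mean[mp2$offset == 0], 1)
  expect_equal(sum(mp2$mean), 1)
  # minus-strand site, spike 10 nt left of the summit -> offset +10
  spike <- list(plus = numeric(L), minus = replace(numeric(L), 201, 1))
  mp3 <- metaprofile(spike, data.frame(summit = 210L, strand = "-"),
                     up = 20, down = 20)
  expect_equal(mp3$offset[mp3$mean == 1], 10)
  expect_error(metaprofile(const, sites[0, ], 10, 10), "empty")
})

test_that("random controls are seeded, exclusive and strand-matched", {
  g <- circularGenome(randomSeq(300))
  excl <- data.frame(summit = 0:99, strand = "+")
  a <- randomControlSites(g, 60, propPlus = 0.5, exclude = excl, seed = 9)
  b <- randomControlSites(g, 60, propPlus = 0.5, exclude = excl, seed = 9)
  expect_identical(a, b)
  expect_false(any(a$summit[a$strand == "+"] %in% 0:99))
  expect_equal(sum(a$strand == "+"), 30)
  expect_equal(sum(a$strand == "-"), 30)
  expect_error(randomControlSites(g, 250, propPlus = 1, exclude = excl),
               "cannot draw")
  # coverage-matched mode restricts to covered bases
  tr <- normalizeTrack(
    endCoverageTrack(replace(numeric(300), 1:50, 100), numeric(300)),
    "rpm_total", 1e6)
  cm <- randomControlSites(g, 10, propPlus = 1, seed = 1,
                           matchCoverage = tr, minCov = 1)
  expect_true(all(cm$summit %in% 0:49))
})

test_that("upstream guanine counting is strand-aware and summit-exclusive", {
  # plus-strand summit at 100: window is reference [50, 100)
  s <- paste0(strrep("A", 50), strrep("G", 50), "T", strrep("A", 99))
  g <- circularGenome(s)
  up <- upstreamGContent(g, data.frame(summit = 100L, strand = "+"), k = 50)
  expect_equal(up$gCount, 50)
  expect_equal(up$gFrac, 1)
  # the summit base itself is excluded
  g2 <- circularGenome(paste0(strrep("A", 100), "G", strrep("A", 99)))
  up2 <- upstreamGContent(g2, data.frame(summit = 100L, strand = "+"),
                          k = 50)
  expect_equal(up2$gCount, 0)
  # minus-strand summit on a 10-nt toy: upstream is (summit, summit+k],
  # complemented; reference C counts as nascent G
  gm <- circularGenome("AACCCAAAAA")
  upm <- upstreamGContent(gm, data.frame(summit = 1L, strand = "-"), k = 4)
  expect_equal(upm$gCount, 3)
  upp <- upstreamGContent(gm, data.frame(summit = 1L, strand = "+"), k = 4)
  expect_equal(upp$gCount, 0)
  # agreement with direct window extraction on random sites
  set.seed(40)
  gr <- circularGenome(randomSeq(200, c(A = .2, C = .35, G = .25, T = .2)))
  sites <- data.frame(summit = sample(0:199, 30),
                      strand = sample(c("+", "-"), 30, TRUE))
  fast <- upstreamGContent(gr, sites, k = 21)$gCount
  slow <- vapply(seq_len(30), function(i) {
    w <- windowSequence(gr, sites$summit[i], 21, 0, sites$strand[i])
    sum(strsplit(substr(w, 1, 21), "")[[1]] == "G")
  }, 0L)
  expect_equal(fast, slow)
})

test_that("upstream enrichment test separates, degenerates and directs", {
  g <- circularGenome(paste0(strrep("G", 500), strrep("A", 500)))
  pause <- data.frame(summit = rep(300L, 20) + 0:19, strand = "+")
  ctrl <- data.frame(summit = rep(700L, 20) + 0:19, strand = "+")
  res <- upstreamEnrichmentTest(g, pause, ctrl, k = 50)
  pooled <- res[res$group == "pooled", ]
  expect_lt(pooled$p, 1e-6)
  expect_equal(pooled$direction, "enriched")
  # identical lists -> all tied -> p = 1 with warning
  w <- capture_warnings(same <- upstreamEnrichmentTest(g, pause, pause,
                                                       k = 50))
  expect_true(any(grepl("tied", w)))
  expect_equal(same$p[same$group == "pooled"], 1)
})

test_that("strand asymmetry chi-square matches closed forms", {
  t1 <- strandAsymmetryTest(100, 100)
  expect_equal(t1$chisq, 0)
  expect_equal(t1$p, 1)
  t2 <- strandAsymmetryTest(60, 40)
  expect_equal(t2$chisq, 4.0)
  expect_equal(t2$p, stats::pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  t3 <- strandAsymmetryTest(314, 151)
  expect_lt(t3$p, 1e-4)
  expect_error(strandAsymmetryTest(0, 0), "no sites")
  # non-even null proportions are honoured
  t4 <- strandAsymmetryTest(30, 70, nullProp = 0.3)
  expect_equal(t4$chisq, 0)
})

test_that("grouping by upstream G detects perfect dependence and skips empty bins", {
  set.seed(41)
  g <- circularGenome(randomSeq(2000, c(A = .25, C = .25, G = .25, T = .25)))
  sites <- data.frame(summit = sample(0:1999, 120), strand = "+")
  gc <- upstreamGContent(g, sites, k = 50)$gCount
  # abundance exactly equal to the upstream G count
  plus <- numeric(2000)
  plus[sites$summit + 1] <- gc + 1
  tr <- normalizeTrack(endCoverageTrack(plus, numeric(2000)), "rpm_total",
                       1e6)
  res <- suppressWarnings(groupByUpstreamG(g, sites, list(tr), k = 50))
  expect_true(all(diff(res$table$medianAbundance) > 0))
  expect_true(all(res$pairwise$padj < 0.05))
  expect_lt(res$global$p, 1e-10)
  # fixed edges leaving a bin nearly empty -> comparison skipped, warning
  w <- capture_warnings(
    res2 <- groupByUpstreamG(g, sites, list(tr), k = 50,
                             breaks = c(-1, 5, 100, 101)))
  expect_true(any(grepl("skipped", w)))
})

test_that("variant overlap uses half-open wrap-aware intervals", {
  sites <- data.frame(start = 10L, end = 12L, width = 2L, strand = "+",
                      summit = 10L, nSupport = 2L, maxZ = 5, sumZ = 10)
  ov <- variantOverlap(sites, c(10, 11, 12), genomeLength = 100L)
  expect_equal(ov$nVariantsInSites, 2)   # 12 is outside [10,12)
  expect_equal(ov$nSitesWithVariant, 1)
  # wrapped site crossing the origin contains position 1
  wrapped <- data.frame(start = 95L, end = 3L, width = 8L, strand = "+",
                        summit = 0L, nSupport = 2L, maxZ = 5, sumZ = 10)
  ov2 <- variantOverlap(wrapped, c(1), genomeLength = 100L)
  expect_equal(ov2$nVariantsInSites, 1)
  # empty variant set
  ov3 <- variantOverlap(sites, numeric(0), genomeLength = 100L)
  expect_equal(ov3$nVariantsInSites, 0)
  expect_equal(ov3$pctVariantsOfSites, 0)
})

test_that("variant overlap agrees with an interval-tree oracle", {
  set.seed(42)
  L <- 200L
  for (rep in 1:100) {
    nS <- sample(1:6, 1)
    start <- sample(0:(L - 1), nS)
    width <- sample(1:30, nS, replace = TRUE)
    sites <- data.frame(start = start, end = (start + width) %% L,
                        width = width, strand = "+", summit = start,
                        nSupport = 2L, maxZ = 1, sumZ = 1)
    vars <- sample(0:(L - 1), sample(1:20, 1))
    got <- variantOverlap(sites, vars, genomeLength = L)
    # oracle: split wrapped intervals, use IRanges overlap counting
    segs <- do.call(rbind, lapply(seq_len(nS), function(i) {
      if (start[i] + width[i] <= L)
        data.frame(site = i, a = start[i], b = start[i] + width[i])
      else
        data.frame(site = c(i, i), a = c(start[i], 0),
                   b = c(L, start[i] + width[i] - L))
    }))
    ir <- IRanges::IRanges(start = segs$a + 1, end = segs$b)
    vr <- IRanges::IRanges(start = vars + 1, width = 1)
    hits <- IRanges::findOverlaps(vr, ir)
    expect_equal(got$nVariantsInSites,
                 length(unique(S4Vectors::queryHits(hits))))
    expect_equal(got$nSitesWithVariant,
                 length(unique(segs$site[S4Vectors::subjectHits(hits)])))
  }
})

test_that("sites annotate to same-strand genes with end classification", {
  ann <- data.frame(gene = c("RNR1", "TF", "ND6"),
                    start = c(100L, 300L, 500L),
                    end = c(200L, 400L, 600L),
                    strand = c("+", "+", "-"),
                    biotype = c("rRNA", "tRNA", "mRNA"))
  sites <- data.frame(summit = c(150L, 100L, 199L, 250L, 550L, 599L),
                      strand = c("+", "+", "+", "+", "-", "-"),
                      start = 0L, end = 1L, width = 1L, nSupport = 2L,
                      maxZ = 1, sumZ = 1)
  res <- annotateSites(sites, ann, genomeLength = 1000L)
  s <- res$sites
  expect_equal(s$gene, c("RNR1", "RNR1", "RNR1", "intergenic", "ND6",
                         "ND6"))
  expect_equal(s$posClass[1:3], c("body", "5prime", "3prime"))
  # minus-strand gene: summit 599 is the gene 5' end
  expect_equal(s$posClass[5:6], c("body", "5prime"))
  bs <- res$biotypeSummary
  expect_equal(bs$genesWithSites[bs$biotype == "rRNA"], 1)
  expect_equal(bs$genesWithSites[bs$biotype == "tRNA"], 0)
  # a site on the opposite strand of a gene is intergenic
  opp <- annotateSites(data.frame(summit = 150L, strand = "-", start = 0L,
                                  end = 1L, width = 1L, nSupport = 2L,
                                  maxZ = 1, sumZ = 1),
                       ann, genomeLength = 1000L)
  expect_equal(opp$sites$gene, "intergenic")
})
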