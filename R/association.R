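# Sites passed to these functions are either a PauseSiteSet or a data.frame
# with at least `summit` and `strand` columns (0-based summits).
#' @noRd
.asSiteFrame <- function(sites) {
  if (is(sites, "PauseSiteSet")) sites <- siteTable(sites)
  if (!all(c("summit", "strand") %in% names(sites)))
    stop("sites must provide summit and strand")
  sites
}

#' Anchor-centered metaprofile
#'
#' Averages a per-strand signal over windows centered on site summits,
#' oriented by transcription direction: offset -k is k bases upstream (5' on
#' the nascent RNA), so minus-strand windows are flipped. On a circular
#' genome every site contributes every offset.
#'
#' @param signal a \linkS4class{G4Track}, an \linkS4class{EndCoverageTrack},
#'   or a list with numeric elements \code{plus} and \code{minus}.
#' @param sites a \linkS4class{PauseSiteSet} or data.frame with
#'   \code{summit}, \code{strand}.
#' @param up,down window extent in nt (defaults 100/100).
#' @return data.frame with columns offset, mean, sem and attribute
#'   \code{n} (number of sites).
#' @export
metaprofile <- function(signal, sites, up = 100L, down = 100L) {
  if (is(signal, "G4Track"))
    signal <- list(plus = signal@plus, minus = signal@minus)
  if (is(signal, "EndCoverageTrack"))
    signal <- list(plus = signal@plus, minus = signal@minus)
  sites <- .asSiteFrame(sites)
  if (nrow(sites) == 0L) stop("empty site list")
  L <- length(signal$plus)
  offs <- (-up):down
  mat <- matrix(NA_real_, nrow = nrow(sites), ncol = length(offs))
  for (i in seq_len(nrow(sites))) {
    s <- sites$strand[i]
    pos <- .modpos(sites$summit[i] + (if (s == "+") offs else -offs), L)
    mat[i, ] <- (if (s == "+") signal$plus else signal$minus)[pos + 1L]
  }
  n <- nrow(mat)
  mu <- colMeans(mat)
  sem <- if (n > 1L) apply(mat, 2L, stats::sd) / sqrt(n) else rep(0, ncol(mat))
  out <- data.frame(offset = offs, mean = mu, sem = sem)
  attr(out, "n") <- n
  out
}

#' Random control sites
#'
#' Uniform positions without replacement avoiding the excluded (pause)
#' positions, with strands assigned to match the query set's strand
#' proportions. With \code{matchCoverage}, candidate positions are
#' restricted to bases with coverage at or above \code{minCov} in the
#' supplied track (coverage-matched controls).
#'
#' @param genome a \linkS4class{CircularGenome}.
#' @param n number of control sites.
#' @param propPlus fraction of sites on the plus strand.
#' @param exclude data.frame with \code{summit}/\code{pos} and
#'   \code{strand}, or NULL.
#' @param seed RNG seed (local to this call).
#' @param matchCoverage optional \linkS4class{EndCoverageTrack}.
#' @param minCov coverage floor for matched controls (default 1).
#' @return data.frame with columns summit, strand.
#' @export
randomControlSites <- function(genome, n, propPlus = 0.5, exclude = NULL,
                               seed = NULL, matchCoverage = NULL,
                               minCov = 1) {
  L <- genomeLength(genome)
  excl <- list(`+` = integer(0), `-` = integer(0))
  if (!is.null(exclude)) {
    ex <- .asSiteFrame(if (is(exclude, "PauseSiteSet")) exclude else
      if (is.null(exclude$summit) && !is.null(exclude$pos)) {
        transform(exclude, summit = pos)
      } else exclude)
    for (s in c("+", "-")) excl[[s]] <- ex$summit[ex$strand == s]
  }
  nPlus <- round(n * propPlus)
  nMinus <- n - nPlus
  .withSeed(seed, {
    out <- lapply(c("+", "-"), function(s) {
      need <- if (s == "+") nPlus else nMinus
      allowed <- setdiff(0:(L - 1L), excl[[s]])
      if (!is.null(matchCoverage))
        allowed <- intersect(allowed,
          which(trackValues(matchCoverage, s) >= minCov) - 1L)
      if (need > length(allowed))
        stop("cannot draw ", need, " control sites on strand ", s)
      data.frame(summit = sample(allowed, need), strand = rep(s, need),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Guanine content upstream of summits
#'
#' Counts guanines in the \code{k} bases 5' of each summit on the
#' nascent-RNA sense strand (the summit base itself excluded).
#'
#' @param genome a \linkS4class{CircularGenome}.
#' @param sites site data.frame or \linkS4class{PauseSiteSet}.
#' @param k upstream window in nt (default 50).
#' @return data.frame with columns summit, strand, gCount, gFrac.
#' @export
upstreamGContent <- function(genome, sites, k = 50L) {
  sites <- .asSiteFrame(sites)
  L <- genomeLength(genome)
  if (k >= L) stop("k must be smaller than the genome")
  # circular cumulative base counts: a guanine on the nascent sense of the
  # minus strand is a cytosine on the reference
  ch <- .chars(genomeSequence(genome))
  csum <- function(flag) cumsum(c(flag, flag))  # doubled for wrap
  cg <- csum(ch == "G")
  cc <- csum(ch == "C")
  rangeCount <- function(cs, from, width) {
    # count over reference positions [from, from + width), from in [0, 2L)
    cs[from + width] - if (from > 0L) cs[from] else 0L
  }
  gc <- vapply(seq_len(nrow(sites)), function(i) {
    su <- sites$summit[i]
    if (sites$strand[i] == "+")
      rangeCount(cg, .modpos(su - k, L), k)
    else
      rangeCount(cc, su + 1L, k)
  }, 0L)
  data.frame(summit = sites$summit, strand = sites$strand, gCount = gc,
             gFrac = gc / k, stringsAsFactors = FALSE)
}

#' @noRd
.ranksumRow <- function(a, b, label) {
  if (!length(a) || !length(b))
    return(NULL)
  if (length(unique(c(a, b))) == 1L) {
    warning("degenerate (all-tied) inputs in group '", label, "': p = 1")
    return(data.frame(group = label, nPause = length(a),
                      nControl = length(b), W = NA_real_, p = 1,
                      direction = "none", stringsAsFactors = FALSE))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b))
  dir <- if (stats::median(a) > stats::median(b)) "enriched"
         else if (stats::median(a) < stats::median(b)) "depleted" else "none"
  data.frame(group = label, nPause = length(a), nControl = length(b),
             W = unname(wt$statistic), p = wt$p.value, direction = dir,
             stringsAsFactors = FALSE)
}

#' Upstream-guanine enrichment at pause sites
#'
#' Two-sample rank-sum (Wilcoxon) test comparing upstream-G counts at pause
#' summits against control summits, pooled and per strand.
#'
#' @param genome a \linkS4class{CircularGenome}.
#' @param pauseSites,controlSites site frames or \linkS4class{PauseSiteSet}.
#' @param k upstream window (default 50).
#' @return data.frame with one row per group (pooled, plus, minus):
#'   statistic, p-value, sizes and direction.
#' @export
upstreamEnrichmentTest <- function(genome, pauseSites, controlSites,
                                   k = 50L) {
  gp <- upstreamGContent(genome, pauseSites, k)
  gctl <- upstreamGContent(genome, controlSites, k)
  if (!nrow(gp) || !nrow(gctl)) stop("both site lists must be non-empty")
  rows <- list(
    .ranksumRow(gp$gCount, gctl$gCount, "pooled"),
    .ranksumRow(gp$gCount[gp$strand == "+"],
                gctl$gCount[gctl$strand == "+"], "plus"),
    .ranksumRow(gp$gCount[gp$strand == "-"],
                gctl$gCount[gctl$strand == "-"], "minus"))
  do.call(rbind, rows)
}

#' Strand asymmetry of pause counts
#'
#' One-degree-of-freedom chi-square goodness of fit of the plus/minus split
#' against a null proportion.
#'
#' @param nPlus,nMinus site counts per strand.
#' @param nullProp null plus-strand proportion (default 0.5).
#' @return list with chisq, df, p, nPlus, nMinus.
#' @examples strandAsymmetryTest(60, 40)$chisq  # 4
#' @export
strandAsymmetryTest <- function(nPlus, nMinus, nullProp = 0.5) {
  if (nPlus + nMinus <= 0) stop("no sites")
  ct <- suppressWarnings(
    stats::chisq.test(c(nPlus, nMinus), p = c(nullProp, 1 - nullProp)))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, nPlus = nPlus, nMinus = nMinus)
}

#' Polymerase abundance grouped by upstream guanine content
#'
#' Bins sites by upstream-G count (quartile bins by default), then compares
#' summit coverage (mean across samples) between bins with pairwise rank-sum
#' tests (Benjamini-Hochberg adjusted; unadjusted values also emitted, as
#' conventions differ) and a global rank-based one-way (Kruskal-Wallis)
#' test.
#'
#' @param genome a \linkS4class{CircularGenome}.
#' @param sites site frame or \linkS4class{PauseSiteSet}.
#' @param tracks list of normalized \linkS4class{EndCoverageTrack}s.
#' @param k upstream window (default 50).
#' @param breaks optional fixed bin edges for the G count; default quartile
#'   edges.
#' @return list with elements \code{table} (bin, n, median abundance),
#'   \code{pairwise} (bin pair, W, p, padj), \code{global} (statistic, p).
#' @export
groupByUpstreamG <- function(genome, sites, tracks, k = 50L, breaks = NULL) {
  sites <- .asSiteFrame(sites)
  g <- upstreamGContent(genome, sites, k)$gCount
  abundance <- vapply(seq_len(nrow(sites)), function(i) {
    mean(vapply(tracks, function(tr)
      trackValues(tr, sites$strand[i])[sites$summit[i] + 1L], 0))
  }, 0)
  if (is.null(breaks))
    breaks <- unique(stats::quantile(g, probs = seq(0, 1, 0.25)))
  if (length(breaks) < 2L) breaks <- c(min(g) - 1, max(g))
  bin <- cut(g, breaks = breaks, include.lowest = TRUE)
  tab <- data.frame(bin = levels(bin),
                    n = as.integer(table(bin)),
                    medianAbundance = vapply(levels(bin), function(b)
                      stats::median(abundance[bin == b]), 0))
  rownames(tab) <- NULL
  lev <- levels(bin)
  pw <- list()
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    if (j <= i) next
    a <- abundance[bin == lev[i]]; b <- abundance[bin == lev[j]]
    if (length(a) < 2L || length(b) < 2L) {
      warning("bin comparison ", lev[i], " vs ", lev[j],
              " skipped (fewer than 2 sites)")
      next
    }
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    pw[[length(pw) + 1L]] <- data.frame(
      bin1 = lev[i], bin2 = lev[j], W = unname(wt$statistic),
      p = wt$p.value, stringsAsFactors = FALSE)
  }
  pairwise <- if (length(pw)) do.call(rbind, pw) else
    data.frame(bin1 = character(0), bin2 = character(0), W = numeric(0),
               p = numeric(0))
  pairwise$padj <- stats::p.adjust(pairwise$p, method = "BH")
  keep <- !is.na(bin) & bin %in% lev[table(bin)[lev] > 0]
  global <- if (length(unique(bin[keep])) >= 2L) {
    kw <- stats::kruskal.test(abundance[keep], droplevels(bin[keep]))
    list(statistic = unname(kw$statistic), p = kw$p.value)
  } else list(statistic = NA_real_, p = NA_real_)
  list(table = tab, pairwise = pairwise, global = global,
       bins = bin, gCount = g, abundance = abundance)
}

#' Overlap of variants with pause sites
#'
#' Counts variants falling inside any site interval (half-open, wrap-aware;
#' strand ignored, as in a plain interval intersection) and sites containing
#' at least one variant. Both percent conventions are reported: variants per
#' site count and sites-with-variant per site count.
#'
#' @param sites a \linkS4class{PauseSiteSet} (or data.frame with start, end,
#'   width columns).
#' @param variants data.frame with column \code{pos} (0-based), or a numeric
#'   vector of positions.
#' @param genomeLength contig length (taken from a PauseSiteSet
#'   automatically).
#' @return list: nVariantsInSites, nSitesWithVariant, nSites,
#'   pctVariantsOfSites, pctSitesWithVariant.
#' @export
variantOverlap <- function(sites, variants, genomeLength = NULL) {
  if (is(sites, "PauseSiteSet")) {
    if (is.null(genomeLength)) genomeLength <- sites@genomeLength
    sites <- siteTable(sites)
  }
  if (is.null(genomeLength)) stop("genomeLength required")
  L <- as.integer(genomeLength)
  pos <- if (is.data.frame(variants)) variants$pos else variants
  pos <- .modpos(as.integer(pos), L)
  nS <- nrow(sites)
  if (nS == 0L || length(pos) == 0L)
    return(list(nVariantsInSites = 0L, nSitesWithVariant = 0L, nSites = nS,
                pctVariantsOfSites = 0, pctSitesWithVariant = 0))
  inAny <- logical(length(pos))
  siteHit <- logical(nS)
  for (i in seq_len(nS)) {
    cov <- .intervalPositions(sites$start[i], sites$end[i], L)
    if (sites$start[i] == sites$end[i] && sites$width[i] == L)
      cov <- 0:(L - 1L)
    hit <- pos %in% cov
    inAny <- inAny | hit
    siteHit[i] <- any(hit)
  }
  a <- sum(inAny); b <- sum(siteHit)
  list(nVariantsInSites = a, nSitesWithVariant = b, nSites = nS,
       pctVariantsOfSites = 100 * a / nS,
       pctSitesWithVariant = 100 * b / nS)
}

#' Annotate sites with genes, biotypes and gene-end class
#'
#' Labels each site with the same-strand gene containing its summit (or
#' \code{"intergenic"}), classifies in-gene sites by relative position along
#' the gene in transcription direction (first \code{endFrac} of the gene =
#' 5' end, last \code{endFrac} = 3' end, otherwise body), and summarizes how
#' many genes of each biotype carry at least one site.
#'
#' @param sites site frame or \linkS4class{PauseSiteSet}.
#' @param annotation data.frame from \code{\link{readGeneAnnotation}}.
#' @param genomeLength contig length (for wrap-aware containment).
#' @param endFrac fraction of gene length counting as an end (default 0.1).
#' @return list with \code{sites} (annotated frame) and \code{biotypeSummary}
#'   (biotype, genes with sites, total genes).
#' @export
annotateSites <- function(sites, annotation, genomeLength = NULL,
                          endFrac = 0.1) {
  if (is(sites, "PauseSiteSet")) {
    if (is.null(genomeLength)) genomeLength <- sites@genomeLength
    sites <- siteTable(sites)
  }
  if (is.null(genomeLength)) stop("genomeLength required")
  L <- as.integer(genomeLength)
  gene <- rep("intergenic", nrow(sites))
  biotype <- rep(NA_character_, nrow(sites))
  posClass <- rep(NA_character_, nrow(sites))
  gw <- .modpos(annotation$end - annotation$start, L)
  gw[gw == 0L] <- L
  for (i in seq_len(nrow(sites))) {
    su <- sites$summit[i]; st <- sites$strand[i]
    off <- .modpos(su - annotation$start, L)
    hit <- which(annotation$strand == st & off < gw)
    if (!length(hit)) next
    j <- hit[1L]
    gene[i] <- annotation$gene[j]
    biotype[i] <- annotation$biotype[j]
    rel <- if (st == "+") off[j] / gw[j] else (gw[j] - 1L - off[j]) / gw[j]
    posClass[i] <- if (rel < endFrac) "5prime"
                   else if (rel >= 1 - endFrac) "3prime" else "body"
  }
  ann <- cbind(sites, gene = gene, biotype = biotype, posClass = posClass,
               stringsAsFactors = FALSE)
  bs <- lapply(unique(annotation$biotype), function(bt) {
    genes <- annotation$gene[annotation$biotype == bt]
    data.frame(biotype = bt,
               genesWithSites = length(intersect(genes, ann$gene)),
               nGenes = length(unique(genes)), stringsAsFactors = FALSE)
  })
  list(sites = ann, biotypeSummary = do.call(rbind, bs))
}
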