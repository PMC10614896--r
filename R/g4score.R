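#' Run-based per-base G4 propensity scores
#'
#' Every base inside a run of n consecutive guanines scores
#' \code{+min(n, 4)}; bases in cytosine runs score \code{-min(n, 4)}
#' (quadruplex propensity on the complementary strand); A, T and N score 0.
#' On a circular sequence a run spanning the origin is merged.
#'
#' @param sequence DNA string over \code{A,C,G,T,N}.
#' @param circular merge a G/C run crossing the origin.
#' @return integer vector of per-base scores.
#' @examples g4HunterBaseScores("AGGGT")  # 0 3 3 3 0
#' @export
g4HunterBaseScores <- function(sequence, circular = FALSE) {
  if (grepl("[^ACGTNacgtn]", sequence))
    stop("sequence contains characters outside {A,C,G,T,N}")
  ch <- .chars(toupper(sequence))
  L <- length(ch)
  r <- rle(ch)
  score <- rep.int(ifelse(r$values == "G", 1L,
                          ifelse(r$values == "C", -1L, 0L)) *
                   pmin(r$lengths, 4L), r$lengths)
  if (circular && length(r$lengths) > 1L &&
      r$values[1L] == r$values[length(r$values)] &&
      r$values[1L] %in% c("G", "C")) {
    n1 <- r$lengths[1L]; n2 <- r$lengths[length(r$lengths)]
    val <- min(n1 + n2, 4L) * if (r$values[1L] == "G") 1L else -1L
    score[c(1:n1, (L - n2 + 1L):L)] <- val
  }
  score
}

#' Windowed G4 propensity
#'
#' Centered circular moving average of the run-based base scores
#' (default window 25 nt).
#'
#' @param baseScores integer vector from \code{\link{g4HunterBaseScores}}.
#' @param w odd window width (default 25).
#' @return numeric vector of windowed means.
#' @export
g4HunterWindowScore <- function(baseScores, w = 25L) {
  if (w > length(baseScores)) stop("window wider than sequence")
  .circMovingMean(baseScores, w)
}

#' Per-strand windowed G4 propensity track for a genome
#'
#' The plus-strand track scores the reference sequence; the minus-strand
#' track scores the reverse complement, mapped back to reference
#' coordinates. By G/C antisymmetry of the base scores the two tracks are
#' negatives of each other base by base.
#'
#' @param genome a \linkS4class{CircularGenome}.
#' @param w odd window width (default 25).
#' @return a \linkS4class{G4Track} in hunter mode.
#' @export
g4HunterTrack <- function(genome, w = 25L) {
  seq <- genomeSequence(genome)
  circ <- genome@circular
  plus <- g4HunterWindowScore(g4HunterBaseScores(seq, circular = circ), w)
  mscore <- g4HunterBaseScores(revComp(seq), circular = circ)
  minus <- g4HunterWindowScore(mscore, w)[genomeLength(genome):1L]
  new("G4Track", plus = plus, minus = minus, window = as.numeric(w),
      mode = "hunter")
}

# G-score for a four-tract motif: more tetrads, shorter loops, uniform
# loops. The loop-range term uses coefficient 1 so that lengthening any
# single loop can never raise the score.
#' @noRd
.gscore <- function(x, l1, l2, l3) {
  lmax <- pmax(l1, l2, l3); lmin <- pmin(l1, l2, l3)
  20L * (x - 2L) + (24L - l1 - l2 - l3) - (lmax - lmin)
}

# all candidate motifs of a linear/padded sequence; vectorized over start
#' @noRd
.qgrsCandidates <- function(sequence, minTract = 2L, loopRange = c(1L, 7L),
                            maxLen = 45L, circular = FALSE) {
  if (loopRange[1L] < 0L) stop("loop lower bound must be >= 0")
  if (loopRange[1L] > loopRange[2L]) stop("invalid loop range")
  if (minTract < 2L) stop("minTract must be >= 2")
  ch <- .chars(toupper(sequence))
  L0 <- length(ch)
  if (circular && L0 > maxLen) ch <- c(ch, ch[1:(maxLen - 1L)])
  isG <- ch == "G"
  gc <- c(0L, cumsum(isG))
  Lp <- length(ch)
  maxRun <- if (any(isG)) max(rle(isG)$lengths[rle(isG)$values]) else 0L
  maxTract <- min(maxRun, floor((maxLen - 3L * max(1L, loopRange[1L])) / 4L))
  res <- list()
  allG <- function(s0, x) gc[s0 + x + 1L] - gc[s0 + 1L] == x
  for (x in seq_len(maxTract)) {
    if (x < minTract) next
    for (l1 in loopRange[1L]:loopRange[2L]) for (l2 in
         loopRange[1L]:loopRange[2L]) for (l3 in
         loopRange[1L]:loopRange[2L]) {
      width <- 4L * x + l1 + l2 + l3
      if (width > maxLen || width > Lp) next
      smax <- if (circular) L0 - 1L else Lp - width
      if (smax < 0L) next
      s1 <- 0:smax
      ok <- allG(s1, x) & allG(s1 + x + l1, x) &
            allG(s1 + 2L * x + l1 + l2, x) &
            allG(s1 + 3L * x + l1 + l2 + l3, x)
      if (any(ok))
        res[[length(res) + 1L]] <- data.frame(
          start = s1[ok], width = width, tract = x,
          l1 = l1, l2 = l2, l3 = l3,
          gscore = .gscore(x, l1, l2, l3))
    }
  }
  if (!length(res))
    return(data.frame(start = integer(0), width = integer(0),
                      tract = integer(0), l1 = integer(0), l2 = integer(0),
                      l3 = integer(0), gscore = integer(0)))
  out <- do.call(rbind, res)
  out[order(out$start, out$width), , drop = FALSE]
}

# greedy non-overlapping selection: score desc, then leftmost
#' @noRd
.qgrsSelect <- function(cands, L, circular = FALSE) {
  if (!nrow(cands)) return(cands)
  o <- order(-cands$gscore, cands$start, cands$width)
  occupied <- logical(L)
  keep <- logical(nrow(cands))
  for (i in o) {
    pos <- .modpos(cands$start[i] + 0:(cands$width[i] - 1L), L) + 1L
    if (!any(occupied[pos])) {
      occupied[pos] <- TRUE
      keep[i] <- TRUE
    }
  }
  cands[keep, , drop = FALSE]
}

#' Enumerate four-tract G-quadruplex motifs
#'
#' Finds all substrings matching G_x N_l1 G_x N_l2 G_x N_l3 G_x with tract
#' length \code{x >= minTract}, each loop within \code{loopRange} (loops may
#' contain any base, including G) and total width at most \code{maxLen},
#' then reduces overlapping candidates to the highest-scoring
#' non-overlapping set (greedy by score, then leftmost). For a
#' \linkS4class{CircularGenome} both strands are scanned (wrap-aware) and
#' minus-strand hits are reported in reference coordinates.
#'
#' @param x a sequence string or a \linkS4class{CircularGenome}.
#' @param minTract minimal guanine tract length (default 2).
#' @param loopRange integer bounds on each loop (default \code{c(1, 7)}).
#' @param maxLen maximal motif width (default 45).
#' @param keepCandidates return the full pre-reduction candidate list in the
#'   params (genome input) or as an attribute (string input).
#' @return for a string: data.frame of selected motifs (0-based
#'   \code{start}, \code{width}, \code{tract}, loops, \code{gscore}); for a
#'   genome: a \linkS4class{G4MotifSet}.
#' @export
qgrsFindMotifs <- function(x, minTract = 2L, loopRange = c(1L, 7L),
                           maxLen = 45L, keepCandidates = FALSE) {
  if (is(x, "CircularGenome")) {
    L <- genomeLength(x)
    seq <- genomeSequence(x)
    circ <- x@circular
    strands <- list()
    candAll <- list()
    for (s in c("+", "-")) {
      sq <- if (s == "+") seq else revComp(seq)
      cand <- .qgrsCandidates(sq, minTract, loopRange, maxLen,
                              circular = circ)
      if (s == "-" && nrow(cand))
        cand$start <- .modpos(L - cand$start - cand$width, L)
      sel <- .qgrsSelect(cand, L, circular = circ)
      sel$strand <- rep(s, nrow(sel))
      cand$strand <- rep(s, nrow(cand))
      strands[[s]] <- sel
      candAll[[s]] <- cand
    }
    m <- do.call(rbind, strands)
    if (is.null(m) || !nrow(m))
      m <- data.frame(start = integer(0), width = integer(0),
                      tract = integer(0), l1 = integer(0), l2 = integer(0),
                      l3 = integer(0), gscore = integer(0),
                      strand = character(0))
    m$end <- .modpos(m$start + m$width, L)
    m <- m[order(m$start, m$strand),
           c("start", "end", "width", "strand", "tract", "l1", "l2", "l3",
             "gscore")]
    rownames(m) <- NULL
    params <- list(minTract = minTract, loopRange = loopRange,
                   maxLen = maxLen)
    if (keepCandidates) params$candidates <- do.call(rbind, candAll)
    new("G4MotifSet", motifs = m, genomeLength = L, params = params)
  } else {
    cand <- .qgrsCandidates(x, minTract, loopRange, maxLen)
    sel <- .qgrsSelect(cand, nchar(x))
    rownames(sel) <- NULL
    if (keepCandidates) attr(sel, "candidates") <- cand
    sel
  }
}

#' Per-base G4 propensity track from motifs or windowed scores
#'
#' In \code{"qgrs"} mode each base covered by a motif carries the maximal
#' G-score over covering motifs (0 elsewhere), per strand. In
#' \code{"hunter"} mode this is the windowed-mean track of
#' \code{\link{g4HunterTrack}}.
#'
#' @param genome a \linkS4class{CircularGenome}.
#' @param mode \code{"hunter"} or \code{"qgrs"}.
#' @param motifs optional precomputed \linkS4class{G4MotifSet} (qgrs mode).
#' @param w hunter window (default 25).
#' @param ... passed to \code{\link{qgrsFindMotifs}} in qgrs mode.
#' @return a \linkS4class{G4Track}.
#' @export
g4MetaTrack <- function(genome, mode = c("hunter", "qgrs"), motifs = NULL,
                        w = 25L, ...) {
  mode <- match.arg(mode)
  if (mode == "hunter") return(g4HunterTrack(genome, w = w))
  L <- genomeLength(genome)
  if (is.null(motifs)) motifs <- qgrsFindMotifs(genome, ...)
  m <- motifTable(motifs)
  tr <- list(`+` = numeric(L), `-` = numeric(L))
  for (i in seq_len(nrow(m))) {
    pos <- .modpos(m$start[i] + 0:(m$width[i] - 1L), L) + 1L
    s <- m$strand[i]
    tr[[s]][pos] <- pmax(tr[[s]][pos], m$gscore[i])
  }
  new("G4Track", plus = tr[["+"]], minus = tr[["-"]], window = NA_real_,
      mode = "qgrs")
}
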