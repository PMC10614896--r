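#' CircularGenome: a single circular contig
#'
#' Holds one contig (typically the 16.6 kb human mitochondrial genome) as an
#' upper-case string over \code{A,C,G,T,N}, with a flag marking it circular.
#' All coordinate arithmetic in the package treats the sequence as a circle
#' when the flag is set: windows and intervals wrap the origin.
#'
#' @slot name contig label used in BED/bedGraph output (e.g. \code{"chrM"}).
#' @slot sequence upper-case sequence string.
#' @slot circular logical; \code{TRUE} for the mitochondrial genome.
#'
#' @exportClass CircularGenome
setClass("CircularGenome",
  representation(name = "character", sequence = "character",
                 circular = "logical"))

setValidity("CircularGenome", function(object) {
  msg <- character(0)
  if (length(object@sequence) != 1L || nchar(object@sequence) < 1L)
    msg <- c(msg, "sequence must be a single non-empty string")
  if (grepl("[^ACGTN]", object@sequence))
    msg <- c(msg, "sequence may only contain A, C, G, T, N")
  if (length(object@name) != 1L) msg <- c(msg, "name must be length 1")
  if (length(object@circular) != 1L) msg <- c(msg, "circular must be length 1")
  if (length(msg)) msg else TRUE
})

#' Construct a CircularGenome
#'
#' @param sequence character string over \code{A,C,G,T,N} (lower case is
#'   accepted and upper-cased).
#' @param name contig name; default \code{"chrM"}.
#' @param circular logical flag, default \code{TRUE}.
#' @return a \linkS4class{CircularGenome}.
#' @examples
#' g <- circularGenome("ACGTACGT")
#' genomeLength(g)
#' @export
circularGenome <- function(sequence, name = "chrM", circular = TRUE) {
  new("CircularGenome", name = name, sequence = toupper(sequence),
      circular = circular)
}

#' @rdname circularGenome
#' @param x a CircularGenome.
#' @export
genomeLength <- function(x) nchar(x@sequence)

#' @rdname circularGenome
#' @export
genomeName <- function(x) x@name

#' @rdname circularGenome
#' @export
genomeSequence <- function(x) x@sequence

setMethod("show", "CircularGenome", function(object) {
  cat("CircularGenome", object@name, "-", genomeLength(object), "nt,",
      if (object@circular) "circular" else "linear", "\n")
  L <- genomeLength(object)
  cat("  ", substr(object@sequence, 1, min(50, L)),
      if (L > 50) "..." else "", "\n", sep = "")
})

#' EndCoverageTrack: per-base, per-strand 3'-end counts
#'
#' One array per strand, length equal to the genome, holding the number of
#' nascent-RNA 3' ends at each base (raw integer counts) or their
#' library-size normalized values (reads per million). The normalization
#' state and denominator travel with the object so downstream thresholds in
#' RPM units can refuse raw input.
#'
#' @slot sample sample identifier.
#' @slot plus,minus numeric vectors of length L.
#' @slot normalization one of \code{"raw"}, \code{"rpm_total"},
#'   \code{"rpm_nuclear"}.
#' @slot denominator read count used for normalization (\code{NA} when raw).
#'
#' @exportClass EndCoverageTrack
setClass("EndCoverageTrack",
  representation(sample = "character", plus = "numeric", minus = "numeric",
                 normalization = "character", denominator = "numeric"))

setValidity("EndCoverageTrack", function(object) {
  msg <- character(0)
  if (length(object@plus) != length(object@minus))
    msg <- c(msg, "plus and minus arrays must have equal length")
  if (!object@normalization %in% c("raw", "rpm_total", "rpm_nuclear"))
    msg <- c(msg, "unknown normalization mode")
  if (any(object@plus < 0) || any(object@minus < 0))
    msg <- c(msg, "counts must be non-negative")
  if (object@normalization == "raw" &&
      (any(object@plus != floor(object@plus)) ||
       any(object@minus != floor(object@minus))))
    msg <- c(msg, "raw counts must be integers")
  if (length(msg)) msg else TRUE
})

#' Construct an EndCoverageTrack
#'
#' @param plus,minus per-base values, one per strand.
#' @param sample sample identifier.
#' @param normalization normalization state.
#' @param denominator reads used for normalization (NA for raw).
#' @return an \linkS4class{EndCoverageTrack}.
#' @export
endCoverageTrack <- function(plus, minus, sample = "sample",
                             normalization = "raw", denominator = NA_real_) {
  new("EndCoverageTrack", sample = sample, plus = as.numeric(plus),
      minus = as.numeric(minus), normalization = normalization,
      denominator = denominator)
}

#' @rdname endCoverageTrack
#' @param x an EndCoverageTrack.
#' @param strand \code{"+"} or \code{"-"}.
#' @export
trackValues <- function(x, strand = c("+", "-")) {
  strand <- match.arg(strand)
  if (strand == "+") x@plus else x@minus
}

#' @rdname endCoverageTrack
#' @export
trackSample <- function(x) x@sample

#' @rdname endCoverageTrack
#' @export
trackLength <- function(x) length(x@plus)

#' @rdname endCoverageTrack
#' @export
normMode <- function(x) x@normalization

#' @rdname endCoverageTrack
#' @export
normDenominator <- function(x) x@denominator

setMethod("show", "EndCoverageTrack", function(object) {
  cat("EndCoverageTrack", object@sample, "-", trackLength(object), "nt,",
      object@normalization, "\n")
  cat("  total (+):", round(sum(object@plus), 2),
      " total (-):", round(sum(object@minus), 2), "\n")
})

#' PauseSiteSet: consensus polymerase pause sites
#'
#' Runs of bases called as peaks (window Z-score and coverage above
#' threshold) in at least \code{minSamples} samples, merged per strand into
#' sites. Intervals are 0-based half-open and may wrap the origin
#' (\code{start > end}).
#'
#' @slot sites data.frame with columns \code{start}, \code{end},
#'   \code{width}, \code{strand}, \code{summit} (base of maximal summed Z,
#'   first in transcription direction on ties), \code{nSupport} (samples
#'   supporting the summit run), \code{maxZ} (largest single-sample Z in the
#'   site), \code{sumZ} (summed Z at the summit).
#' @slot genomeLength contig length the coordinates refer to.
#' @slot params parameter echo from the call.
#'
#' @exportClass PauseSiteSet
setClass("PauseSiteSet",
  representation(sites = "data.frame", genomeLength = "integer",
                 params = "list"))

setValidity("PauseSiteSet", function(object) {
  s <- object@sites
  need <- c("start", "end", "width", "strand", "summit", "nSupport",
            "maxZ", "sumZ")
  if (!all(need %in% names(s))) return("missing site columns")
  L <- object@genomeLength
  if (nrow(s)) {
    if (any(s$start < 0 | s$start >= L)) return("start out of range")
    inside <- mapply(function(st, w, su) .modpos(su - st, L) < w,
                     s$start, s$width, s$summit)
    if (!all(inside)) return("summit outside its site interval")
  }
  TRUE
})

#' @rdname consensusSites
#' @param x a PauseSiteSet.
#' @export
siteTable <- function(x) x@sites

#' @rdname consensusSites
#' @export
nSites <- function(x) nrow(x@sites)

setMethod("show", "PauseSiteSet", function(object) {
  s <- object@sites
  cat("PauseSiteSet:", nrow(s), "sites on a", object@genomeLength,
      "nt circular contig\n")
  if (nrow(s))
    cat("  strand + :", sum(s$strand == "+"),
        "  strand - :", sum(s$strand == "-"),
        "  median width:", stats::median(s$width), "\n")
})

#' G4Track: per-base windowed G-quadruplex propensity
#'
#' Per-strand arrays of windowed scores. In hunter mode these are centered
#' circular moving averages of run-based base scores; in qgrs mode each base
#' carries the maximal G-score of the motifs covering it. Positive values
#' mark G4-forming propensity on the indexed strand.
#'
#' @slot plus,minus numeric per-base arrays indexed by reference position.
#' @slot window window width used (hunter mode; NA for qgrs mode).
#' @slot mode \code{"hunter"} or \code{"qgrs"}.
#' @exportClass G4Track
setClass("G4Track",
  representation(plus = "numeric", minus = "numeric", window = "numeric",
                 mode = "character"))

setValidity("G4Track", function(object) {
  if (length(object@plus) != length(object@minus))
    return("strand arrays differ in length")
  if (!object@mode %in% c("hunter", "qgrs")) return("unknown mode")
  TRUE
})

#' @rdname g4HunterTrack
#' @param x a G4Track.
#' @param strand \code{"+"} or \code{"-"}.
#' @export
g4Scores <- function(x, strand = c("+", "-")) {
  strand <- match.arg(strand)
  if (strand == "+") x@plus else x@minus
}

setMethod("show", "G4Track", function(object) {
  cat("G4Track (", object@mode, " mode), ", length(object@plus),
      " nt; max + : ", round(max(object@plus), 3),
      ", max - : ", round(max(object@minus), 3), "\n", sep = "")
})

#' G4MotifSet: four-tract quadruplex motifs
#'
#' Motifs of the form G_x N_l1 G_x N_l2 G_x N_l3 G_x found on either strand,
#' with loop lengths bounded (default 1-7 nt) and a G-score favouring more
#' tetrads, shorter loops and uniform loops. Coordinates are 0-based
#' half-open on the reference; \code{start > end} wraps the origin.
#'
#' @slot motifs data.frame with columns \code{start}, \code{end},
#'   \code{width}, \code{strand}, \code{tract}, \code{l1}, \code{l2},
#'   \code{l3}, \code{gscore}.
#' @slot genomeLength contig length.
#' @slot params search parameter echo.
#' @exportClass G4MotifSet
setClass("G4MotifSet",
  representation(motifs = "data.frame", genomeLength = "integer",
                 params = "list"))

#' @rdname qgrsFindMotifs
#' @param x a G4MotifSet.
#' @export
motifTable <- function(x) x@motifs

setMethod("show", "G4MotifSet", function(object) {
  m <- object@motifs
  cat("G4MotifSet:", nrow(m), "motifs\n")
  if (nrow(m))
    cat("  tract lengths:", paste(sort(unique(m$tract)), collapse = ","),
        " gscore range:", paste(range(m$gscore), collapse = "-"), "\n")
})

#' SyntheticTruth: planted motifs and pauses of a simulation
#'
#' @slot motifs data.frame (start, end, width, strand, tract, l1, l2, l3).
#' @slot pauses data.frame (pos, strand, source, motif) where source is
#'   \code{"g4"} for motif-coupled pauses or \code{"noise"}.
#' @slot params full simulation parameter echo (list).
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(motifs = "data.frame", pauses = "data.frame",
                 params = "list"))

#' @rdname simulateGenome
#' @param x a SyntheticTruth.
#' @export
truthMotifs <- function(x) x@motifs

#' @rdname simulateGenome
#' @export
truthPauses <- function(x) x@pauses

#' @rdname simulateGenome
#' @export
truthParams <- function(x) x@params

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", nrow(object@motifs), "planted motifs,",
      nrow(object@pauses), "planted pauses\n")
})
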