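#' Read aligned reads from SAM/BAM
#'
#' Loads primary alignments on the single circular contig. SAM text files
#' are converted on the fly with \code{Rsamtools::asBam}. The 3' reference
#' end of each read is computed from the CIGAR-aligned span (soft clips
#' excluded): the last aligned base for a forward read, the first for a
#' reverse read. An optional UMI is taken from the read-name suffix (after
#' the last \code{_} or \code{:}) or from the \code{RX} tag.
#'
#' @param path SAM or BAM file.
#' @param contig expected contig name; a mismatch is an error. NULL skips
#'   the check.
#' @param umiFrom \code{"name"}, \code{"tag"} or \code{"none"}.
#' @return data.frame with columns qname, strand, start0 (0-based leftmost
#'   aligned base), refWidth, pos3 (0-based 3'-end, not yet wrapped), umi.
#' @export
readAlignments <- function(path, contig = NULL,
                           umiFrom = c("name", "tag", "none")) {
  umiFrom <- match.arg(umiFrom)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = TRUE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "strand"),
    tag = "RX",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  b <- Rsamtools::scanBam(path, param = param)[[1L]]
  if (!is.null(contig) && length(b$rname) &&
      any(as.character(b$rname) != contig))
    stop("alignment contig does not match genome contig '", contig, "'")
  refWidth <- GenomicAlignments::cigarWidthAlongReferenceSpace(b$cigar)
  strand <- as.character(b$strand)
  start0 <- b$pos - 1L
  pos3 <- ifelse(strand == "+", start0 + refWidth - 1L, start0)
  umi <- switch(umiFrom,
    none = rep(NA_character_, length(b$qname)),
    tag = if (!is.null(b$tag$RX)) as.character(b$tag$RX)
          else rep(NA_character_, length(b$qname)),
    name = {
      u <- sub("^.*[_:]", "", b$qname)
      ifelse(u == b$qname, NA_character_, u)
    })
  data.frame(qname = b$qname, strand = strand, start0 = start0,
             refWidth = refWidth, pos3 = pos3, umi = umi,
             stringsAsFactors = FALSE)
}

#' UMI deduplication
#'
#' Among reads sharing the same (3'-end position, strand, UMI) exactly one
#' survives; reads without a UMI pass through untouched. The key uses the
#' 3'-end position rather than full sequence identity, which is equivalent
#' for fixed-length reads and robust to base-call errors elsewhere in the
#' read. Idempotent and never count-increasing.
#'
#' @param alignments data.frame from \code{\link{readAlignments}}.
#' @return deduplicated data.frame.
#' @export
dedupUMI <- function(alignments) {
  has <- !is.na(alignments$umi)
  if (!any(has)) return(alignments)
  key <- paste(alignments$pos3, alignments$strand, alignments$umi, sep = "\r")
  keep <- !has | !duplicated(key)
  alignments[keep, , drop = FALSE]
}

#' Tally 3'-end counts into a coverage track
#'
#' One increment per read at its 3' reference end (mod genome length for
#' circle-aware alignments that run past the origin). By default the read
#' strand is taken as the nascent-RNA strand; \code{flipStrand = TRUE}
#' accommodates reverse-complemented library preparations.
#'
#' @param alignments data.frame from \code{\link{readAlignments}} (after
#'   optional \code{\link{dedupUMI}}).
#' @param genome a \linkS4class{CircularGenome}.
#' @param sample sample identifier.
#' @param flipStrand flip read strand to transcript strand.
#' @return raw \linkS4class{EndCoverageTrack}.
#' @export
extractThreePrimeEnds <- function(alignments, genome, sample = "sample",
                                  flipStrand = FALSE) {
  L <- genomeLength(genome)
  pos <- .modpos(alignments$pos3, L)
  strand <- alignments$strand
  if (flipStrand) strand <- ifelse(strand == "+", "-", "+")
  plus <- tabulate(pos[strand == "+"] + 1L, nbins = L)
  minus <- tabulate(pos[strand == "-"] + 1L, nbins = L)
  endCoverageTrack(plus, minus, sample = sample)
}

#' Library-size normalization
#'
#' Multiplies every value by \code{1e6 / denominator}. The denominator is
#' supplied by the caller: total mapped reads for \code{rpm_total}, or reads
#' mapping to the nuclear genome for \code{rpm_nuclear} (the variant used
#' when mitochondrial content itself responds to treatment). Normalizing an
#' already-normalized track is an error.
#'
#' @param track raw \linkS4class{EndCoverageTrack}.
#' @param mode \code{"rpm_total"} or \code{"rpm_nuclear"}.
#' @param denominator positive read count.
#' @return normalized \linkS4class{EndCoverageTrack}.
#' @export
normalizeTrack <- function(track, mode = c("rpm_total", "rpm_nuclear"),
                           denominator) {
  mode <- match.arg(mode)
  if (normMode(track) != "raw")
    stop("track is already normalized (", normMode(track), ")")
  if (!is.numeric(denominator) || length(denominator) != 1L ||
      denominator <= 0)
    stop("denominator must be a single positive number")
  f <- 1e6 / denominator
  endCoverageTrack(track@plus * f, track@minus * f,
                   sample = trackSample(track), normalization = mode,
                   denominator = denominator)
}

# -- bedGraph I/O -------------------------------------------------------------

#' @noRd
.readBedGraphVector <- function(path, L) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr)) {
    if (any(GenomicRanges::end(gr) > L))
      stop("bedGraph span beyond genome length")
    cov <- IRanges::coverage(GenomicRanges::ranges(gr))
    if (any(S4Vectors::runValue(cov) > 1L))
      stop("overlapping bedGraph spans")
  }
  x <- numeric(L)
  if (length(gr)) {
    st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
    for (i in seq_along(gr)) x[st[i]:en[i]] <- gr$score[i]
  }
  x
}

#' @noRd
.writeBedGraphVector <- function(x, path, chrom) {
  r <- rle(x)
  en <- cumsum(r$lengths)
  st <- en - r$lengths + 1L
  keep <- r$values != 0
  gr <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(start = st[keep], end = en[keep]),
          score = r$values[keep])
  rtracklayer::export(gr, path, format = "bedGraph")
}

#' Stranded bedGraph I/O for coverage tracks
#'
#' A track is stored as two bedGraph files (plus / minus strand) plus a JSON
#' sidecar recording the sample id, normalization mode and denominator.
#' Spans are 0-based half-open; overlapping spans are a format error;
#' zero-valued spans are omitted on write.
#'
#' @param prefix path prefix; files are \code{<prefix>.plus.bedGraph},
#'   \code{<prefix>.minus.bedGraph}, \code{<prefix>.json}.
#' @param genome the \linkS4class{CircularGenome} the track refers to.
#' @return \code{readBedGraphPair}: an \linkS4class{EndCoverageTrack};
#'   \code{writeBedGraphPair}: the prefix, invisibly.
#' @export
readBedGraphPair <- function(prefix, genome) {
  L <- genomeLength(genome)
  plus <- .readBedGraphVector(paste0(prefix, ".plus.bedGraph"), L)
  minus <- .readBedGraphVector(paste0(prefix, ".minus.bedGraph"), L)
  # without a sidecar, integer-valued tracks are raw counts; fractional
  # values are taken as externally normalized signal (e.g. a public RPM or
  # ChIP-seq track) with an unknown denominator
  integral <- all(plus == floor(plus)) && all(minus == floor(minus))
  meta <- list(sample = basename(prefix),
               normalization = if (integral) "raw" else "rpm_total",
               denominator = NA_real_)
  sidecar <- paste0(prefix, ".json")
  if (file.exists(sidecar)) {
    m <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    meta[names(m)] <- m
  }
  d <- meta$denominator
  endCoverageTrack(plus, minus, sample = meta$sample,
                   normalization = meta$normalization,
                   denominator = if (is.null(d) || !length(d))
                     NA_real_ else as.numeric(d))
}

#' @rdname readBedGraphPair
#' @param track an \linkS4class{EndCoverageTrack}.
#' @export
writeBedGraphPair <- function(track, prefix, genome) {
  chrom <- genomeName(genome)
  .writeBedGraphVector(track@plus, paste0(prefix, ".plus.bedGraph"), chrom)
  .writeBedGraphVector(track@minus, paste0(prefix, ".minus.bedGraph"), chrom)
  jsonlite::write_json(
    list(sample = trackSample(track), normalization = normMode(track),
         denominator = normDenominator(track)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(prefix)
}
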