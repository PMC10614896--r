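#' Read a FASTA file as a circular genome
#'
#' Reads the first record of a FASTA file into a \linkS4class{CircularGenome}.
#' The pipeline operates on a single circular contig (the mitochondrial
#' genome); a multi-record file triggers a warning and only the first record
#' is used. Characters outside \code{A,C,G,T,N} (IUPAC ambiguity codes) are
#' converted to \code{N} with a warning.
#'
#' @param path FASTA file path.
#' @param circular logical; treat the contig as circular (default TRUE).
#' @param name optional contig name override; default is the first word of
#'   the FASTA header.
#' @return a \linkS4class{CircularGenome}.
#' @export
readFastaCircular <- function(path, circular = TRUE, name = NULL) {
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("malformed FASTA file: ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA file contains no records")
  if (length(set) > 1L)
    warning("multi-record FASTA: using first record only")
  seq <- toupper(as.character(set[[1L]]))
  if (grepl("[^ACGTN]", seq)) {
    warning("non-ACGTN characters converted to N")
    seq <- gsub("[^ACGTN]", "N", seq)
  }
  if (is.null(name)) name <- strsplit(names(set)[1L], "\\s+")[[1L]][1L]
  circularGenome(seq, name = name, circular = circular)
}

#' Write a genome to FASTA
#'
#' @param genome a \linkS4class{CircularGenome}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genomeSequence(genome))
  names(set) <- genomeName(genome)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' Strict alphabet \code{A,C,G,T,N}; anything else is an error. An
#' involution: \code{revComp(revComp(s)) == s}.
#'
#' @param sequence character string (or vector of strings).
#' @return reverse-complemented string(s).
#' @examples revComp("GGA")  # "TCC"
#' @export
revComp <- function(sequence) {
  if (any(grepl("[^ACGTNacgtn]", sequence)))
    stop("sequence contains characters outside {A,C,G,T,N}")
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(toupper(sequence))))
}

#' Extract a window around a position, in transcription orientation
#'
#' Returns the \code{upstream + 1 + downstream} bases centered at
#' \code{center}, read 5' to 3' on the nascent-RNA sense of \code{strand}.
#' For the minus strand the reverse complement is returned, so "upstream"
#' always means 5' of the center on the transcript. Windows wrap the origin
#' on a circular genome.
#'
#' @param genome a \linkS4class{CircularGenome}.
#' @param center 0-based reference position.
#' @param upstream,downstream number of bases 5' and 3' of the center.
#' @param strand \code{"+"} or \code{"-"}.
#' @return character string of width \code{upstream + downstream + 1}.
#' @export
windowSequence <- function(genome, center, upstream, downstream,
                           strand = c("+", "-")) {
  strand <- match.arg(strand)
  L <- genomeLength(genome)
  w <- upstream + downstream + 1L
  if (w > L) stop("window wider than the genome")
  if (!genome@circular && (center - upstream < 0 || center + downstream >= L))
    stop("window out of range on a linear genome")
  if (strand == "+") {
    .circSubstr(genomeSequence(genome), center - upstream, w, L)
  } else {
    revComp(.circSubstr(genomeSequence(genome), center - downstream, w, L))
  }
}

#' Base composition of a sequence
#'
#' Fractions of A, C, G, T; \code{N} bases are excluded from the
#' denominator. Errors if no non-N base exists.
#'
#' @param x a sequence string or a \linkS4class{CircularGenome}.
#' @return named numeric vector over A, C, G, T summing to 1.
#' @examples baseComposition("GGCC")["G"]  # 0.5
#' @export
baseComposition <- function(x) {
  if (is(x, "CircularGenome")) x <- genomeSequence(x)
  if (nchar(x) == 0L) stop("empty sequence")
  ch <- .chars(toupper(x))
  if (any(!ch %in% c("A", "C", "G", "T", "N")))
    stop("sequence contains characters outside {A,C,G,T,N}")
  ch <- ch[ch != "N"]
  if (length(ch) == 0L) stop("composition undefined: all bases are N")
  counts <- vapply(c("A", "C", "G", "T"), function(b) sum(ch == b), 0L)
  counts / length(ch)
}

#' Rotate a circular genome
#'
#' Moves the origin forward by \code{k}: reference position \code{p} of the
#' original maps to \code{(p - k) mod L} in the rotated genome. Used to
#' verify rotation invariance of downstream operations.
#'
#' @param genome a \linkS4class{CircularGenome}.
#' @param k rotation offset in nt.
#' @return rotated \linkS4class{CircularGenome}.
#' @export
rotateGenome <- function(genome, k) {
  L <- genomeLength(genome)
  k <- .modpos(k, L)
  s <- genomeSequence(genome)
  circularGenome(paste0(substr(s, k + 1L, L), substr(s, 1L, k)),
                 name = genomeName(genome), circular = genome@circular)
}

# -- BED / variant I/O --------------------------------------------------------

#' @noRd
.validateBedText <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(invisible(TRUE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (f in fields) {
    if (length(f) < 3L) stop("BED line with fewer than 3 fields")
    if (!all(grepl("^[0-9]+$", f[2:3])))
      stop("non-integer BED coordinates")
    st <- as.integer(f[2L])
    en <- as.integer(f[3L])
    if (en <= st) stop("BED interval with end <= start")
  }
  invisible(TRUE)
}

#' Read and write BED intervals
#'
#' BED3/BED6 I/O with native 0-based half-open coordinates. \code{readBed}
#' validates coordinates (non-integer or \code{end <= start} is an error)
#' and returns a plain data.frame; write then read is the identity on
#' (chrom, start, end, name, strand).
#'
#' @param path file path.
#' @return \code{readBed}: data.frame with columns chrom, start, end, name,
#'   score, strand.
#' @export
readBed <- function(path) {
  .validateBedText(path)
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else NA_character_,
    score = if (!is.null(gr$score)) gr$score else 0,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  df$score[is.na(df$score)] <- 0
  df
}

#' @rdname readBed
#' @param records data.frame with columns chrom, start, end and optionally
#'   name, score, strand.
#' @export
writeBed <- function(records, path) {
  n <- nrow(records)
  gr <- GenomicRanges::GRanges(
    seqnames = records$chrom,
    ranges = IRanges::IRanges(start = records$start + 1L, end = records$end),
    strand = if (!is.null(records$strand)) records$strand else "*")
  gr$name <- if (!is.null(records$name)) records$name else
    paste0("feature_", seq_len(n))
  gr$score <- if (!is.null(records$score)) records$score else 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read and write variant positions
#'
#' Accepts either a BED file (position = interval start) or a two-column TSV
#' with header \code{pos<TAB>id}; positions are 0-based.
#'
#' @param path input path.
#' @return data.frame with columns \code{pos} (0-based) and \code{id}.
#' @export
readVariantSet <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^pos\tid", first)) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (any(df$pos != floor(df$pos))) stop("non-integer variant positions")
    out <- data.frame(pos = as.integer(df$pos), id = as.character(df$id),
                      stringsAsFactors = FALSE)
  } else {
    bed <- readBed(path)
    out <- data.frame(pos = bed$start, id = bed$name,
                      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(out$id)) stop("variant ids must be unique")
  out
}

#' @rdname readVariantSet
#' @param variants data.frame with columns pos, id.
#' @export
writeVariantSet <- function(variants, path) {
  utils::write.table(variants[, c("pos", "id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation
#'
#' BED6 (name = gene) with an optional seventh column giving the biotype
#' (\code{mRNA}, \code{tRNA}, \code{rRNA} or \code{other}); rows without a
#' biotype column get \code{"other"}.
#'
#' @param path BED path.
#' @return data.frame with columns gene, start, end, strand, biotype.
#' @export
readGeneAnnotation <- function(path) {
  .validateBedText(path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(f)
  if (any(nfield < 6L)) stop("gene annotation requires BED6(+1)")
  df <- data.frame(
    gene = vapply(f, `[`, "", 4L),
    start = as.integer(vapply(f, `[`, "", 2L)),
    end = as.integer(vapply(f, `[`, "", 3L)),
    strand = vapply(f, `[`, "", 6L),
    biotype = ifelse(nfield >= 7L, vapply(f, function(x) x[7L], ""), "other"),
    stringsAsFactors = FALSE)
  ok <- c("mRNA", "tRNA", "rRNA", "other")
  if (any(!df$biotype %in% ok))
    stop("biotype must be one of ", paste(ok, collapse = ", "))
  df
}
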