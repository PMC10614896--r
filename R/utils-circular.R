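# Circular-coordinate helpers. All public coordinates in this package are
# 0-based, half-open; an interval with start > end wraps the origin.

#' @noRd
.modpos <- function(i, L) ((i %% L) + L) %% L

#' @noRd
.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

# substring of a circular sequence: `start0` is 0-based, may be any integer
#' @noRd
.circSubstr <- function(seq, start0, width, L) {
  stopifnot(width >= 0L, width <= L)
  s <- .modpos(start0, L)
  if (s + width <= L) {
    substr(seq, s + 1L, s + width)
  } else {
    paste0(substr(seq, s + 1L, L), substr(seq, 1L, s + width - L))
  }
}

# 0-based positions covered by a (possibly wrapped) half-open interval
#' @noRd
.intervalPositions <- function(start, end, L) {
  if (end > start) start:(end - 1L)
  else if (end == start) integer(0)
  else c(start:(L - 1L), if (end > 0L) 0:(end - 1L))
}

# interval width mod L, in (0, L]
#' @noRd
.intervalWidth <- function(start, end, L) {
  w <- .modpos(end - start, L)
  if (w == 0L) L else w
}

# centered circular moving average; w must be odd
#' @noRd
.circMovingMean <- function(x, w) {
  if (w %% 2L == 0L) stop("window width must be odd")
  if (w > length(x)) stop("window width exceeds track length")
  if (w == 1L) return(as.numeric(x))
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2L, circular = TRUE))
}

# evaluate expr under a temporary RNG seed, restoring the caller's stream
#' @noRd
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# circular distance between two positions
#' @noRd
.circDist <- function(a, b, L) {
  d <- abs(.modpos(a - b, L))
  pmin(d, L - d)
}
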