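# Conserved-block detection and degenerate primer construction.

#' Find conserved blocks in a multiple alignment
#'
#' Scans the alignment left to right for maximal windows in which every
#' column's gap fraction is at most \code{maxGapFraction} and the cumulative
#' degeneracy (product of per-column IUPAC consensus sizes) stays within
#' \code{maxBlockDegeneracy}. Extension is greedy and maximal, ties resolved
#' leftmost; emitted blocks are non-overlapping, sorted, and at least
#' \code{minLen} columns long. Block coordinates are also projected onto a
#' reference row (gap columns skipped), so primer anchors can be reported in
#' the ungapped coordinate system of a reference gene.
#'
#' @param aln Alignment (see \code{\link{columnProfiles}} for accepted forms).
#' @param minLen Minimum block length in columns (default 17, the length of
#'   the shortest panel primer). Must be at least 8.
#' @param maxBlockDegeneracy Cumulative degeneracy budget per block
#'   (default 64).
#' @param maxGapFraction Maximum per-column gap fraction (default 0).
#' @param referenceId Row id used for coordinate projection (default: the
#'   first row).
#' @return A \link[S4Vectors]{DataFrame} with columns start, end (1-based
#'   inclusive alignment columns), referenceStart, consensus, degeneracy and
#'   meanIdentity (fraction of strictly identical columns).
#' @export
findConservedBlocks <- function(aln, minLen = 17L, maxBlockDegeneracy = 64,
                                maxGapFraction = 0, referenceId = NULL) {
  if (minLen < 8L) stop("minLen must be at least 8")
  m <- .asAlnMatrix(aln)
  empty <- S4Vectors::DataFrame(
    start = integer(0), end = integer(0), referenceStart = integer(0),
    consensus = character(0), degeneracy = numeric(0), meanIdentity = numeric(0)
  )
  if (minLen > ncol(m)) {
    warning("minLen (", minLen, ") exceeds alignment length (", ncol(m), ")")
    return(empty)
  }
  if (is.null(referenceId)) referenceId <- rownames(m)[1L]
  if (!referenceId %in% rownames(m)) {
    stop("reference row '", referenceId, "' not found in alignment")
  }
  ref <- m[referenceId, ]
  refPos <- cumsum(ref != "-")        # non-gap reference chars up to each column

  cm <- .columnMasks(m)
  colDeg <- .maskSize(cm$mask)
  identical <- colDeg == 1L & cm$gapFraction == 0
  eligible <- cm$mask > 0L & cm$gapFraction <= maxGapFraction &
    colDeg <= maxBlockDegeneracy

  L <- ncol(m)
  res <- list()
  s <- 1L
  while (s <= L) {
    if (!eligible[s]) { s <- s + 1L; next }
    e <- s
    dprod <- colDeg[s]
    while (e < L && eligible[e + 1L] && dprod * colDeg[e + 1L] <= maxBlockDegeneracy) {
      e <- e + 1L
      dprod <- dprod * colDeg[e]
    }
    if (e - s + 1L >= minLen) {
      if (ref[s] == "-") {
        message("block at column ", s,
                " begins in a reference-gap column; reporting the next reference position")
      }
      refStart <- if (ref[s] == "-") refPos[s] + 1L else refPos[s]
      res[[length(res) + 1L]] <- S4Vectors::DataFrame(
        start = s, end = e,
        referenceStart = as.integer(refStart),
        consensus = paste(.BITS_TO_CODE[cm$mask[s:e]], collapse = ""),
        degeneracy = dprod,
        meanIdentity = mean(identical[s:e])
      )
      s <- e + 1L
    } else {
      s <- s + 1L
    }
  }
  if (length(res) == 0L) return(empty)
  do.call(rbind, res)
}

#' Wallace-rule melting temperature range of a degenerate oligo
#'
#' Evaluates the Wallace rule, 2(A+T) + 4(G+C) degrees C, over the AT-richest
#' and GC-richest concrete expansions of an IUPAC string: per position, a code
#' that can be A or T contributes 2 to the minimum and a code that can be G or
#' C contributes 4 to the maximum.
#'
#' @param seq An IUPAC string, or a \code{DegeneratePrimer}.
#' @return Named numeric vector \code{c(min=, max=)} in degrees Celsius.
#' @examples
#' tmEstimate("AY")  # 4 (AT) to 6 (AC)
#' @export
tmEstimate <- function(seq) {
  if (methods::is(seq, "DegeneratePrimer")) seq <- primerSeq(seq)
  bits <- .encodeSeq(seq, allowGaps = FALSE, what = "primer")
  hasAT <- bitwAnd(bits, 1L + 8L) > 0L
  hasGC <- bitwAnd(bits, 2L + 4L) > 0L
  c(min = sum(ifelse(hasAT, 2, 4)), max = sum(ifelse(hasGC, 4, 2)))
}

#' Construct a DegeneratePrimer
#'
#' @param name Primer name.
#' @param seq 5'-to-3' IUPAC string (for reverse primers: the
#'   strand-of-synthesis sequence).
#' @param orientation "forward" or "reverse".
#' @param anchor Optional 1-based reference start of the plus-strand footprint.
#' @return A \code{\linkS4class{DegeneratePrimer}}.
#' @export
degeneratePrimer <- function(name, seq, orientation = c("forward", "reverse"),
                             anchor = NA_integer_) {
  orientation <- match.arg(orientation)
  seq <- toupper(as.character(seq))
  tm <- tmEstimate(seq)
  methods::new("DegeneratePrimer",
    name = as.character(name), sequence = seq, orientation = orientation,
    degeneracy = degeneracy(seq), anchor = as.integer(anchor),
    tmMin = unname(tm["min"]), tmMax = unname(tm["max"])
  )
}

#' Turn a conserved block into a primer
#'
#' Forward primers take the block consensus as is; reverse primers take its
#' IUPAC reverse complement (the strand of synthesis). The block's reference
#' start becomes the primer anchor and the Wallace Tm range is attached.
#'
#' @param block One row of the \code{\link{findConservedBlocks}} result (or
#'   any list with \code{consensus} and \code{referenceStart}).
#' @param orientation "forward" or "reverse".
#' @param name Primer name.
#' @param maxDegeneracy Per-primer degeneracy cap (default 256).
#' @return A \code{\linkS4class{DegeneratePrimer}}.
#' @export
blockToPrimer <- function(block, orientation = c("forward", "reverse"), name,
                          maxDegeneracy = 256) {
  orientation <- match.arg(orientation)
  consensus <- as.character(block$consensus)[1L]
  deg <- degeneracy(consensus)
  if (deg > maxDegeneracy) {
    stop("block degeneracy ", format(deg, scientific = FALSE),
         " exceeds the per-primer cap ", maxDegeneracy)
  }
  seq <- if (orientation == "forward") consensus else revComp(consensus)
  anchor <- as.integer(block$referenceStart)[1L]
  degeneratePrimer(name, seq, orientation, anchor = anchor)
}
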