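# In-silico PCR: degenerate primer binding-site search and amplicon
# prediction. Matching is per-position IUPAC base-set intersection on a 4-bit
# encoding, so degenerate template symbols (sequencing ambiguities) are
# handled the same way as degenerate primer positions.

#' In-silico PCR stringency settings
#'
#' @param maxMismatch,threePrimeWindow,threePrimeMaxMismatch,minProduct,maxProduct
#'   See \code{\linkS4class{PCRConfig}}.
#' @return A \code{\linkS4class{PCRConfig}}.
#' @export
pcrConfig <- function(maxMismatch = 2L, threePrimeWindow = 3L,
                      threePrimeMaxMismatch = 0L,
                      minProduct = 50L, maxProduct = 5000L) {
  methods::new("PCRConfig",
    maxMismatch = as.integer(maxMismatch),
    threePrimeWindow = as.integer(threePrimeWindow),
    threePrimeMaxMismatch = as.integer(threePrimeMaxMismatch),
    minProduct = as.integer(minProduct),
    maxProduct = as.integer(maxProduct)
  )
}

# Slide a pattern (bitmask vector) along a template (bitmask vector).
# threeAt: which end of the pattern, as laid on the plus strand, is the
# primer's 3' terminus ("right" for plus-strand hits, "left" for minus).
# Returns start, mismatches and 3'-window mismatches for windows within the
# overall mismatch budget.
.scanPattern <- function(tbits, pbits, cfg, threeAt = c("right", "left")) {
  threeAt <- match.arg(threeAt)
  k <- length(pbits)
  W <- length(tbits) - k + 1L
  none <- data.frame(start = integer(0), mismatches = integer(0),
                     threePrimeMismatches = integer(0))
  if (W < 1L) return(none)
  mm <- integer(W)
  mm3 <- integer(W)
  w3 <- min(cfg@threePrimeWindow, k)
  three <- if (threeAt == "right") seq.int(k - w3 + 1L, length.out = w3)
           else seq_len(w3)
  for (j in seq_len(k)) {
    miss <- as.integer(bitwAnd(tbits[j:(j + W - 1L)], pbits[j]) == 0L)
    mm <- mm + miss
    if (j %in% three) mm3 <- mm3 + miss
  }
  hit <- mm <= cfg@maxMismatch & mm3 <= cfg@threePrimeMaxMismatch
  data.frame(start = which(hit), mismatches = mm[hit],
             threePrimeMismatches = mm3[hit])
}

.templateBits <- function(template, what = "template") {
  if (methods::is(template, "XString")) template <- as.character(template)
  .encodeSeq(template, allowGaps = FALSE, what = what)
}

#' Find binding sites of a degenerate primer on a template
#'
#' Scans both strands: the primer in forward sense against the plus strand,
#' and (as its reverse complement) against the plus-strand rendering of the
#' minus strand. A position matches when the primer code's base set and the
#' template code's base set intersect. A site is reported when total
#' mismatches are within \code{maxMismatch} and mismatches inside the
#' 3'-terminal window are within \code{threePrimeMaxMismatch}.
#'
#' @param template A single gap-free sequence (string, DNAString, or a
#'   length-1 DNAStringSet).
#' @param primer A \code{\linkS4class{DegeneratePrimer}}.
#' @param cfg A \code{\linkS4class{PCRConfig}}.
#' @param templateId Label for the template (defaults to the template's name,
#'   or "template").
#' @return A \link[GenomicRanges]{GRanges} of primer footprints (1-based,
#'   inclusive, plus-strand coordinates) with metadata columns primer,
#'   mismatches, threePrimeMismatches; sorted by start. Empty when the primer
#'   is longer than the template or nothing binds.
#' @export
findBindingSites <- function(template, primer, cfg = pcrConfig(),
                             templateId = NULL) {
  if (methods::is(template, "XStringSet")) {
    if (length(template) != 1L) stop("give a single template (or use lapply)")
    if (is.null(templateId)) templateId <- .fastaId(names(template))
    template <- as.character(template)[1L]
  }
  if (is.null(templateId) || !length(templateId) || is.na(templateId)) {
    templateId <- "template"
  }
  tbits <- .templateBits(template)
  pseq <- primerSeq(primer)
  k <- nchar(pseq)

  plus <- .scanPattern(tbits, .encodeSeq(pseq), cfg, threeAt = "right")
  minus <- .scanPattern(tbits, .encodeSeq(revComp(pseq)), cfg, threeAt = "left")

  starts <- c(plus$start, minus$start)
  if (length(starts) == 0L) {
    return(GenomicRanges::GRanges(seqnames = character(0),
                                  ranges = IRanges::IRanges(),
                                  strand = character(0),
                                  primer = character(0),
                                  mismatches = integer(0),
                                  threePrimeMismatches = integer(0)))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = templateId,
    ranges = IRanges::IRanges(start = starts, width = k),
    strand = c(rep("+", nrow(plus)), rep("-", nrow(minus))),
    primer = primerName(primer),
    mismatches = c(plus$mismatches, minus$mismatches),
    threePrimeMismatches = c(plus$threePrimeMismatches, minus$threePrimeMismatches)
  )
  gr[order(GenomicRanges::start(gr))]
}

.predictOne <- function(template, fwd, rev, cfg, templateId, seqUniverse = templateId) {
  emptyAmp <- GenomicRanges::GRanges(
    seqnames = factor(character(0), levels = seqUniverse),
    ranges = IRanges::IRanges(),
    strand = character(0),
    fwdPrimer = character(0), revPrimer = character(0),
    productLength = integer(0),
    fwdMismatches = integer(0), revMismatches = integer(0),
    sequence = character(0)
  )
  sf <- findBindingSites(template, fwd, cfg, templateId)
  sf <- sf[BiocGenerics::strand(sf) == "+"]
  if (length(sf) == 0L) return(emptyAmp)
  sr <- findBindingSites(template, rev, cfg, templateId)
  sr <- sr[BiocGenerics::strand(sr) == "-"]
  if (length(sr) == 0L) return(emptyAmp)

  pairs <- expand.grid(f = seq_along(sf), r = seq_along(sr))
  fs <- GenomicRanges::start(sf)[pairs$f]
  re <- GenomicRanges::end(sr)[pairs$r]
  rs <- GenomicRanges::start(sr)[pairs$r]
  len <- re - fs + 1L
  keep <- fs < rs & len >= cfg@minProduct & len <= cfg@maxProduct
  if (!any(keep)) return(emptyAmp)
  pairs <- pairs[keep, , drop = FALSE]
  fs <- fs[keep]; re <- re[keep]; len <- len[keep]
  tchar <- if (methods::is(template, "XStringSet")) as.character(template)[1L]
           else as.character(template)
  gr <- GenomicRanges::GRanges(
    seqnames = factor(templateId, levels = seqUniverse),
    ranges = IRanges::IRanges(start = fs, end = re),
    strand = "+",
    fwdPrimer = primerName(fwd),
    revPrimer = primerName(rev),
    productLength = len,
    fwdMismatches = sf$mismatches[pairs$f],
    revMismatches = sr$mismatches[pairs$r],
    sequence = substring(toupper(tchar), fs, re)
  )
  gr[order(GenomicRanges::start(gr), GenomicRanges::end(gr))]
}

#' Predict PCR products of a degenerate primer pair
#'
#' Pairs every plus-strand site of the forward primer with every minus-strand
#' site of the reverse primer downstream of it and reports products whose
#' length (both primer footprints counted inclusively) falls within the
#' configured bounds. Templates without compatible site pairs yield no
#' products -- the behavior expected of marker-negative strains.
#'
#' @param templates A DNAStringSet (one entry per template) or a single
#'   sequence.
#' @param fwd Forward \code{\linkS4class{DegeneratePrimer}}.
#' @param rev Reverse \code{\linkS4class{DegeneratePrimer}}.
#' @param cfg A \code{\linkS4class{PCRConfig}}.
#' @return A \link[GenomicRanges]{GRanges} of predicted products with
#'   metadata columns fwdPrimer, revPrimer, productLength, fwdMismatches,
#'   revMismatches and sequence.
#' @export
predictAmplicons <- function(templates, fwd, rev, cfg = pcrConfig()) {
  if (primerOrientation(fwd) != "forward") stop("fwd must be a forward primer")
  if (primerOrientation(rev) != "reverse") stop("rev must be a reverse primer")
  if (!methods::is(templates, "XStringSet")) {
    templates <- Biostrings::DNAStringSet(toupper(as.character(templates)))
  }
  if (is.null(names(templates))) {
    names(templates) <- if (length(templates) == 1L) "template"
                        else paste0("template", seq_along(templates))
  }
  ids <- .fastaId(names(templates))
  out <- lapply(seq_along(templates), function(i) {
    .predictOne(as.character(templates)[i], fwd, rev, cfg, ids[i],
                seqUniverse = ids)
  })
  do.call(c, out)
}

#' Amplicon sequences as a DNAStringSet
#'
#' @param amplicons Result of \code{\link{predictAmplicons}}.
#' @param labels Optional names; default is the template id (made unique with
#'   a suffix when one template yields several products).
#' @return A \link[Biostrings]{DNAStringSet}.
#' @export
ampliconSequences <- function(amplicons, labels = NULL) {
  seqs <- Biostrings::DNAStringSet(amplicons$sequence)
  if (is.null(labels)) {
    labels <- make.unique(as.character(GenomicRanges::seqnames(amplicons)), sep = "_")
  }
  names(seqs) <- labels
  seqs
}

#' Tabular stand-in for an electrophoresis gel
#'
#' One row per template: the sorted unique predicted band lengths and a
#' presence/absence flag.
#'
#' @param amplicons A \link[GenomicRanges]{GRanges} from
#'   \code{\link{predictAmplicons}}.
#' @param templateIds Universe of template ids (so templates without products
#'   appear as negative rows). Default: the ids present in \code{amplicons}.
#' @return A data.frame with columns template, nBands, bands (comma-joined
#'   lengths, "" when none) and positive.
#' @export
virtualGel <- function(amplicons, templateIds = NULL) {
  ids <- as.character(GenomicRanges::seqnames(amplicons))
  if (is.null(templateIds)) templateIds <- unique(ids)
  rows <- lapply(templateIds, function(tid) {
    lens <- sort(unique(amplicons$productLength[ids == tid]))
    data.frame(template = tid, nBands = length(lens),
               bands = paste(lens, collapse = ","),
               positive = length(lens) > 0L)
  })
  do.call(rbind, rows)
}
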