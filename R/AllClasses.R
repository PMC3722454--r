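#' @import methods
NULL

#' DegeneratePrimer: a named IUPAC oligonucleotide
#'
#' A 5'-to-3' oligo over the IUPAC alphabet with an orientation, its
#' degeneracy (number of concrete variants), an optional anchor giving the
#' 1-based start of its target footprint on a reference sequence, and a
#' Wallace-rule melting-temperature range evaluated over the AT-richest and
#' GC-richest expansions. Reverse primers store the strand-of-synthesis
#' sequence, i.e. the reverse complement of the plus-strand consensus they
#' were designed from.
#'
#' @slot name Primer name.
#' @slot sequence IUPAC string, 5' to 3'.
#' @slot orientation "forward" or "reverse".
#' @slot degeneracy Number of concrete expansions.
#' @slot anchor 1-based reference start of the plus-strand footprint
#'   (NA when unanchored).
#' @slot tmMin,tmMax Wallace-rule Tm bounds in degrees Celsius.
#' @export
setClass("DegeneratePrimer",
  representation(
    name = "character",
    sequence = "character",
    orientation = "character",
    degeneracy = "numeric",
    anchor = "integer",
    tmMin = "numeric",
    tmMax = "numeric"
  )
)

setValidity("DegeneratePrimer", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L || !nzchar(object@name)) {
    msg <- c(msg, "name must be a single non-empty string")
  }
  if (length(object@orientation) != 1L ||
      !object@orientation %in% c("forward", "reverse")) {
    msg <- c(msg, "orientation must be 'forward' or 'reverse'")
  }
  ok <- tryCatch({
    .encodeSeq(object@sequence, allowGaps = FALSE, what = "primer")
    TRUE
  }, error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) msg <- c(msg, ok)
  if (isTRUE(ok) && object@degeneracy != degeneracy(object@sequence)) {
    msg <- c(msg, "degeneracy slot disagrees with the sequence")
  }
  if (object@tmMin > object@tmMax) msg <- c(msg, "tmMin exceeds tmMax")
  if (length(msg)) msg else TRUE
})

#' PCRConfig: stringency settings for in-silico PCR
#'
#' @slot maxMismatch Maximum IUPAC-incompatible positions tolerated across the
#'   whole primer footprint (default 2).
#' @slot threePrimeWindow Length of the 3'-terminal window under the stricter
#'   mismatch rule (default 3).
#' @slot threePrimeMaxMismatch Maximum mismatches tolerated inside that window
#'   (default 0: a clamped 3' end, mirroring polymerase extension requirements).
#' @slot minProduct,maxProduct Product length bounds in bp, both footprints
#'   counted inclusively (defaults 50 and 5000).
#' @export
setClass("PCRConfig",
  representation(
    maxMismatch = "integer",
    threePrimeWindow = "integer",
    threePrimeMaxMismatch = "integer",
    minProduct = "integer",
    maxProduct = "integer"
  )
)

setValidity("PCRConfig", function(object) {
  v <- c(object@maxMismatch, object@threePrimeWindow,
         object@threePrimeMaxMismatch, object@minProduct, object@maxProduct)
  if (length(v) != 5L || anyNA(v)) return("all settings must be single integers")
  if (any(v < 0L)) return("all settings must be non-negative")
  if (object@minProduct > object@maxProduct) return("minProduct exceeds maxProduct")
  TRUE
})

#' AlignedPair: a pairwise global alignment
#'
#' Result of an end-to-end (Needleman-Wunsch style, affine gap) alignment of
#' two ungapped nucleotide sequences, with its score and percent identity
#' (terminal gap overhangs excluded from the denominator).
#'
#' @slot idA,idB Sequence labels.
#' @slot alignedA,alignedB Equal-length gapped strings.
#' @slot score Alignment score.
#' @slot identityPct Percent identity, one decimal place.
#' @export
setClass("AlignedPair",
  representation(
    idA = "character",
    idB = "character",
    alignedA = "character",
    alignedB = "character",
    score = "numeric",
    identityPct = "numeric"
  )
)

setValidity("AlignedPair", function(object) {
  a <- object@alignedA; b <- object@alignedB
  if (nchar(a) != nchar(b)) return("aligned strings differ in length")
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  if (any(ca == "-" & cb == "-")) return("column gapped in both rows")
  TRUE
})
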