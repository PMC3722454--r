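# Accessors and show() methods.

#' @rdname DegeneratePrimer-class
#' @export
setMethod("primerName", "DegeneratePrimer", function(x) x@name)

#' @rdname DegeneratePrimer-class
#' @export
setMethod("primerSeq", "DegeneratePrimer", function(x) x@sequence)

#' @rdname DegeneratePrimer-class
#' @export
setMethod("primerOrientation", "DegeneratePrimer", function(x) x@orientation)

#' @rdname DegeneratePrimer-class
#' @export
setMethod("primerDegeneracy", "DegeneratePrimer", function(x) x@degeneracy)

#' @rdname DegeneratePrimer-class
#' @export
setMethod("primerAnchor", "DegeneratePrimer", function(x) x@anchor)

#' @rdname DegeneratePrimer-class
#' @export
setMethod("tmRange", "DegeneratePrimer", function(x) c(min = x@tmMin, max = x@tmMax))

setMethod("show", "DegeneratePrimer", function(object) {
  cat("DegeneratePrimer ", object@name, " (", object@orientation, ")\n",
      "  5'-", object@sequence, "-3'  [", nchar(object@sequence), " nt]\n",
      "  degeneracy: ", format(object@degeneracy, scientific = FALSE),
      "   Tm (Wallace): ", object@tmMin, "-", object@tmMax, " C",
      if (!is.na(object@anchor)) paste0("   anchor: ", object@anchor) else "",
      "\n", sep = "")
})

setMethod("show", "PCRConfig", function(object) {
  cat("PCRConfig: <=", object@maxMismatch, "mismatches;",
      object@threePrimeMaxMismatch, "allowed in the 3'-terminal",
      object@threePrimeWindow, "nt; product",
      object@minProduct, "-", object@maxProduct, "bp\n")
})

#' @rdname AlignedPair-class
#' @export
setMethod("alignedStrings", "AlignedPair", function(x) {
  stats::setNames(c(x@alignedA, x@alignedB), c(x@idA, x@idB))
})

#' @rdname AlignedPair-class
#' @export
setMethod("pairScore", "AlignedPair", function(x) x@score)

#' @rdname AlignedPair-class
#' @export
setMethod("pairIdentity", "AlignedPair", function(x) x@identityPct)

setMethod("show", "AlignedPair", function(object) {
  cat("AlignedPair ", object@idA, " / ", object@idB,
      ": score ", object@score,
      ", identity ", object@identityPct, "%\n", sep = "")
})
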