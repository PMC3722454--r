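#' @rdname DegeneratePrimer-class
#' @param x A DegeneratePrimer.
#' @export
setGeneric("primerName", function(x) standardGeneric("primerName"))

#' @rdname DegeneratePrimer-class
#' @export
setGeneric("primerSeq", function(x) standardGeneric("primerSeq"))

#' @rdname DegeneratePrimer-class
#' @export
setGeneric("primerOrientation", function(x) standardGeneric("primerOrientation"))

#' @rdname DegeneratePrimer-class
#' @export
setGeneric("primerDegeneracy", function(x) standardGeneric("primerDegeneracy"))

#' @rdname DegeneratePrimer-class
#' @export
setGeneric("primerAnchor", function(x) standardGeneric("primerAnchor"))

#' @rdname DegeneratePrimer-class
#' @export
setGeneric("tmRange", function(x) standardGeneric("tmRange"))

#' @rdname AlignedPair-class
#' @param x An AlignedPair.
#' @export
setGeneric("alignedStrings", function(x) standardGeneric("alignedStrings"))

#' @rdname AlignedPair-class
#' @export
setGeneric("pairScore", function(x) standardGeneric("pairScore"))

#' @rdname AlignedPair-class
#' @export
setGeneric("pairIdentity", function(x) standardGeneric("pairIdentity"))
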