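# IUPAC nucleotide algebra: the 15 ambiguity codes, their base sets, a 4-bit
# encoding (A=1, C=2, G=4, T=8) used throughout for O(1) compatibility tests,
# and the complement table.

.IUPAC_BASES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.IUPAC_LETTERS <- names(.IUPAC_BASES)

.BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

.IUPAC_BITS <- vapply(
  .IUPAC_BASES,
  function(b) as.integer(sum(.BASE_BITS[b])),
  integer(1)
)

# inverse map: bitmask (1..15) -> IUPAC letter
.BITS_TO_CODE <- character(15L)
.BITS_TO_CODE[.IUPAC_BITS] <- .IUPAC_LETTERS

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' IUPAC base set of a code
#'
#' @param code Character vector of single IUPAC letters (case-insensitive).
#' @return For a single code, the character vector of concrete bases it
#'   covers; for several codes, a list of such vectors.
#' @examples
#' iupacBases("W")
#' @export
iupacBases <- function(code) {
  code <- toupper(as.character(code))
  bad <- !(code %in% .IUPAC_LETTERS)
  if (any(bad)) {
    stop("not an IUPAC nucleotide code: ", paste(unique(code[bad]), collapse = ", "))
  }
  out <- .IUPAC_BASES[code]
  if (length(out) == 1L) out[[1L]] else unname(out)
}

#' Minimal IUPAC code covering a set of bases
#'
#' @param bases Character vector drawn from A, C, G, T (a non-empty set).
#' @return The single IUPAC letter whose base set is exactly the input set.
#' @examples
#' consensusCode(c("A", "T"))  # "W"
#' @export
consensusCode <- function(bases) {
  bases <- unique(toupper(as.character(bases)))
  if (length(bases) == 0L) stop("empty base set has no IUPAC code")
  bad <- !(bases %in% names(.BASE_BITS))
  if (any(bad)) stop("not a concrete base: ", paste(bases[bad], collapse = ", "))
  .BITS_TO_CODE[sum(.BASE_BITS[bases])]
}

# Encode a sequence string as an integer vector of 4-bit masks.
# Gap characters get 0 when allowGaps, otherwise error; any letter outside the
# alphabet errors with its 1-based position.
.encodeSeq <- function(seq, allowGaps = FALSE, what = "sequence") {
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L || is.na(seq)) stop(what, " must be a single string")
  if (!nzchar(seq)) stop(what, " is empty")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bits <- .IUPAC_BITS[chars]
  gap <- chars == "-"
  if (any(gap)) {
    if (!allowGaps) {
      stop(what, ": gap character '-' at position ", which(gap)[1L],
           " (gaps are only valid inside alignments)")
    }
    bits[gap] <- 0L
  }
  bad <- is.na(bits) & !gap
  if (any(bad)) {
    p <- which(bad)[1L]
    stop(what, ": invalid character '", chars[p], "' at position ", p)
  }
  unname(bits)
}

.decodeBits <- function(bits) {
  out <- .BITS_TO_CODE[bits]
  out[bits == 0L] <- "-"
  paste(out, collapse = "")
}

#' IUPAC-aware reverse complement
#'
#' Reverse-complements a nucleotide string over the full 15-letter IUPAC
#' alphabet (W and S are self-complementary, Y pairs with R, K with M,
#' B with V, D with H, N with N). Gap characters are rejected.
#'
#' @param seq A single nucleotide string (IUPAC letters, case-insensitive).
#' @return The reverse complement, upper case, same length.
#' @examples
#' revComp("ACGT")                  # "ACGT" (palindrome)
#' revComp("GGYTGRTTGGTVAGCACRTC")  # "GAYGTGCTBACCAAYCARCC"
#' @export
revComp <- function(seq) {
  .encodeSeq(seq, allowGaps = FALSE)  # validates, errors name the position
  chars <- strsplit(toupper(as.character(seq)), "", fixed = TRUE)[[1L]]
  paste(rev(.IUPAC_COMPLEMENT[chars]), collapse = "")
}

#' Degeneracy of an IUPAC string
#'
#' The number of concrete A/C/G/T strings a degenerate oligo encodes:
#' the product over positions of each code's base-set size.
#'
#' @param seq A single IUPAC nucleotide string without gaps.
#' @return A numeric count (can exceed integer range for long, highly
#'   degenerate strings).
#' @examples
#' degeneracy("ATGTGCACWGSYGTYCGTTT")  # 16
#' @export
degeneracy <- function(seq) {
  bits <- .encodeSeq(seq, allowGaps = FALSE)
  sizes <- vapply(bits, function(b) sum(bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L), numeric(1))
  prod(sizes)
}

#' Expand a degenerate sequence into its concrete variants
#'
#' @param seq A single IUPAC nucleotide string without gaps.
#' @param cap Safety cap on the number of expansions (default 65536); if the
#'   degeneracy exceeds it, the call refuses and reports the cardinality.
#' @return Character vector of all concrete A/C/G/T strings the input encodes.
#' @examples
#' expandDegenerate("AY")  # "AC" "AT"
#' @export
expandDegenerate <- function(seq, cap = 65536L) {
  .encodeSeq(seq, allowGaps = FALSE)
  n <- degeneracy(seq)
  if (n > cap) {
    stop("refusing to expand: degeneracy ", format(n, scientific = FALSE),
         " exceeds cap ", cap)
  }
  chars <- strsplit(toupper(as.character(seq)), "", fixed = TRUE)[[1L]]
  sets <- .IUPAC_BASES[chars]
  out <- ""
  for (s in sets) {
    out <- as.vector(outer(out, s, paste0))
  }
  out
}

#' Compatibility of two IUPAC codes
#'
#' Two codes are compatible when their base sets intersect, i.e. at least one
#' concrete base is encoded by both. This is the per-position test used for
#' primer-template matching.
#'
#' @param a,b Single IUPAC letters (vectors are matched element-wise and
#'   recycled to equal length).
#' @return Logical vector; symmetric in its arguments.
#' @examples
#' iupacMatch("Y", "K")  # TRUE: both encode T
#' iupacMatch("W", "S")  # FALSE: {A,T} and {C,G} are disjoint
#' @export
iupacMatch <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (any(a == "-") || any(b == "-")) stop("gap character is not an IUPAC code")
  ba <- .IUPAC_BITS[a]; bb <- .IUPAC_BITS[b]
  if (anyNA(ba)) stop("not an IUPAC code: ", a[which(is.na(ba))[1L]])
  if (anyNA(bb)) stop("not an IUPAC code: ", b[which(is.na(bb))[1L]])
  unname(bitwAnd(ba, bb) > 0L)
}
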