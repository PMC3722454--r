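# Pairwise global alignment and percent-identity matrices. The alignment
# itself is Biostrings::pairwiseAlignment (end-to-end, affine gaps); the
# identity statistic -- matches over columns, terminal-gap overhangs
# excluded, one decimal place -- is computed here from the gapped strings.

# +1/-1 substitution matrix over the full IUPAC alphabet: identity means
# identical symbols, so ambiguity codes only match themselves.
.subMatrix <- function(match, mismatch) {
  n <- length(.IUPAC_LETTERS)
  m <- matrix(mismatch, n, n, dimnames = list(.IUPAC_LETTERS, .IUPAC_LETTERS))
  diag(m) <- match
  m
}

#' Global pairwise alignment of two nucleotide sequences
#'
#' End-to-end (terminal gaps penalized) affine-gap alignment. A gap of length
#' L costs \code{gapOpen + L * gapExtend}. Defaults (+1 match, -1 mismatch,
#' 2/1 gap open/extend) approximate Clustal-like behavior on near-homologous
#' DNA.
#'
#' @param a,b Gap-free nucleotide sequences (strings or DNAString); when
#'   unnamed, labeled "A" and "B".
#' @param match,mismatch Substitution scores (defaults +1 / -1).
#' @param gapOpen,gapExtend Gap penalties as positive costs (defaults 2 / 1).
#' @param idA,idB Labels for the two sequences.
#' @return An \code{\linkS4class{AlignedPair}}.
#' @export
globalAlign <- function(a, b, match = 1, mismatch = -1,
                        gapOpen = 2, gapExtend = 1,
                        idA = "A", idB = "B") {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  .encodeSeq(a, what = "sequence a")
  .encodeSeq(b, what = "sequence b")
  pa <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = .subMatrix(match, mismatch),
    gapOpening = gapOpen, gapExtension = gapExtend
  )
  ga <- as.character(Biostrings::alignedPattern(pa))
  gb <- as.character(Biostrings::alignedSubject(pa))
  pair <- methods::new("AlignedPair",
    idA = idA, idB = idB, alignedA = ga, alignedB = gb,
    score = BiocGenerics::score(pa), identityPct = 0
  )
  pair@identityPct <- percentIdentity(pair)
  pair
}

#' Percent identity of an aligned pair
#'
#' 100 * matches / columns, where the counted columns run from the first to
#' the last column in which both rows are aligned (terminal gap overhangs are
#' excluded; internal gap columns count in the denominator), and a match
#' requires identical symbols. Reported to one decimal place.
#'
#' @param pair An \code{\linkS4class{AlignedPair}}, or a gapped string (then
#'   \code{b} must be the second gapped string).
#' @param b Second gapped string when \code{pair} is a string.
#' @return Percent identity in [0, 100], rounded to one decimal.
#' @export
percentIdentity <- function(pair, b = NULL) {
  if (methods::is(pair, "AlignedPair")) {
    ga <- pair@alignedA; gb <- pair@alignedB
  } else {
    ga <- toupper(as.character(pair)); gb <- toupper(as.character(b))
  }
  ca <- strsplit(ga, "", fixed = TRUE)[[1L]]
  cb <- strsplit(gb, "", fixed = TRUE)[[1L]]
  if (length(ca) != length(cb)) stop("gapped strings differ in length")
  na <- which(ca != "-"); nb <- which(cb != "-")
  if (length(na) == 0L || length(nb) == 0L) stop("no countable columns")
  from <- max(na[1L], nb[1L])
  to <- min(na[length(na)], nb[length(nb)])
  if (from > to) stop("no countable columns: alignment is all overhang")
  idx <- from:to
  round(100 * sum(ca[idx] == cb[idx] & ca[idx] != "-") / length(idx), 1)
}

#' Pairwise percent-identity matrix
#'
#' Aligns every unordered pair globally and collects percent identities into
#' a symmetric matrix with a diagonal of exactly 100. The range and the
#' extreme pairs are reported via \code{message}.
#'
#' @param seqs A named DNAStringSet or named character vector (at least 2,
#'   gap-free).
#' @param ... Scoring parameters passed to \code{\link{globalAlign}}.
#' @return A symmetric numeric matrix with sequence ids as dimnames.
#' @export
identityMatrix <- function(seqs, ...) {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences")
  ids <- .fastaId(names(seqs))
  if (anyDuplicated(ids)) stop("duplicate sequence ids")
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pid <- pairIdentity(globalAlign(seqs[[i]], seqs[[j]],
                                      idA = ids[i], idB = ids[j], ...))
      m[i, j] <- pid
      m[j, i] <- pid
    }
  }
  off <- m[upper.tri(m)]
  lo <- which(m == min(off) & upper.tri(m), arr.ind = TRUE)[1L, ]
  hi <- which(m == max(off) & upper.tri(m), arr.ind = TRUE)[1L, ]
  message("identity range ", min(off), "-", max(off), "% (min: ",
          ids[lo[1L]], "/", ids[lo[2L]], "; max: ",
          ids[hi[1L]], "/", ids[hi[2L]], ")")
  m
}
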