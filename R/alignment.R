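# Multiple-alignment ingestion and per-column profiles.

#' Read a multiple sequence alignment
#'
#' Accepts aligned FASTA or Clustal (.aln) files via
#' \link[Biostrings]{readDNAMultipleAlignment}. Format is guessed from the
#' file extension and first line when "auto".
#'
#' @param path Alignment file.
#' @param format "auto", "fasta" or "clustal".
#' @return A \link[Biostrings]{DNAMultipleAlignment}.
#' @export
readAlignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^CLUSTAL", first, ignore.case = TRUE)) "clustal"
              else if (grepl("\\.aln$", path, ignore.case = TRUE)) "clustal"
              else "fasta"
  }
  aln <- Biostrings::readDNAMultipleAlignment(path, format = format)
  if (nrow(aln) < 2L) stop("an alignment needs at least 2 rows")
  aln
}

# Normalize any alignment-like input to an upper-case character matrix
# (rows = sequences, columns = alignment positions) with unique rownames.
.asAlnMatrix <- function(aln) {
  if (methods::is(aln, "MultipleAlignment")) {
    return(.asAlnMatrix(Biostrings::unmasked(aln)))
  }
  if (methods::is(aln, "XStringSet")) {
    if (length(unique(Biostrings::width(aln))) != 1L) {
      stop("alignment rows must all have the same length")
    }
    m <- t(vapply(as.character(aln),
                  function(s) strsplit(s, "", fixed = TRUE)[[1L]],
                  character(Biostrings::width(aln)[1L])))
  } else if (is.matrix(aln)) {
    m <- aln
  } else if (is.character(aln)) {
    if (length(unique(nchar(aln))) != 1L) {
      stop("alignment rows must all have the same length")
    }
    m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
    rownames(m) <- names(aln)
  } else {
    stop("cannot interpret object of class '", class(aln)[1L], "' as an alignment")
  }
  m[] <- toupper(m)
  if (nrow(m) < 2L) stop("an alignment needs at least 2 rows")
  if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))
  if (anyDuplicated(rownames(m))) stop("duplicate row ids in alignment")
  m
}

# Per-column bitmasks of observed bases (OR over rows, gaps contribute 0),
# plus gap fractions. Shared by profiles and the block finder.
.columnMasks <- function(m) {
  bits <- matrix(.IUPAC_BITS[m], nrow = nrow(m))
  gap <- m == "-"
  if (any(is.na(bits) & !gap)) {
    bad <- which(is.na(bits) & !gap, arr.ind = TRUE)[1L, ]
    stop("invalid character '", m[bad[1L], bad[2L]], "' in alignment row ",
         rownames(m)[bad[1L]], ", column ", bad[2L])
  }
  bits[gap] <- 0L
  mask <- integer(ncol(m))
  for (b in c(1L, 2L, 4L, 8L)) {
    hasB <- bitwAnd(bits, b) > 0L   # bitwAnd drops dim; restore it
    dim(hasB) <- dim(bits)
    mask <- bitwOr(mask, b * as.integer(colSums(hasB) > 0L))
  }
  list(mask = mask, gapFraction = colMeans(gap))
}

.maskSize <- function(mask) {
  vapply(mask, function(b) sum(bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L), integer(1))
}

#' Per-column profiles of an alignment
#'
#' For every alignment column: counts of the concrete bases among non-gap
#' residues, the gap fraction, the minimal IUPAC code covering all observed
#' bases (ambiguity codes in the rows contribute their whole base set), its
#' size (column degeneracy), and whether the column is strictly identical
#' (exactly one base observed and no gaps) -- the "asterisk" columns of a
#' Clustal-style alignment display.
#'
#' @param aln A DNAMultipleAlignment, equal-width DNAStringSet, character
#'   matrix or character vector of equal-length gapped strings.
#' @return A \link[S4Vectors]{DataFrame} with one row per column.
#' @export
columnProfiles <- function(aln) {
  m <- .asAlnMatrix(aln)
  cm <- .columnMasks(m)
  counts <- vapply(c("A", "C", "G", "T"),
                   function(b) colSums(m == b), numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L,
                                      dimnames = list(NULL, c("A", "C", "G", "T")))
  consensus <- ifelse(cm$mask > 0L, .BITS_TO_CODE[cm$mask], "-")
  S4Vectors::DataFrame(
    column = seq_len(ncol(m)),
    A = as.integer(counts[, "A"]),
    C = as.integer(counts[, "C"]),
    G = as.integer(counts[, "G"]),
    T = as.integer(counts[, "T"]),
    gapFraction = cm$gapFraction,
    consensus = consensus,
    degeneracy = .maskSize(cm$mask),
    isIdentical = .maskSize(cm$mask) == 1L & cm$gapFraction == 0 &
      colSums(matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))) == nrow(m)
  )
}
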