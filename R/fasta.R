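# FASTA I/O. Reading goes through Biostrings but canonicalizes case,
# transliterates U to T (RNA-derived records), and enforces the alphabet,
# unique ids and non-empty records.

.fastaId <- function(header) sub("\\s.*$", "", header)

#' Read nucleotide sequences from FASTA
#'
#' Records are upper-cased on ingest; U is transliterated to T with a warning.
#' Every residue must be an IUPAC nucleotide code (gaps are rejected unless
#' \code{allowGaps = TRUE}); ids (the first whitespace-delimited token of each
#' header) must be unique and records non-empty.
#'
#' @param path Path to a FASTA file.
#' @param allowGaps Accept '-' characters (alignment input).
#' @return A \link[Biostrings]{DNAStringSet} named by the full headers.
#' @export
readFasta <- function(path, allowGaps = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("FASTA file contains no records: ", path)
  seqs <- toupper(as.character(x))
  if (any(grepl("U", seqs, fixed = TRUE))) {
    warning("U residues transliterated to T on ingest")
    seqs <- chartr("U", "T", seqs)
  }
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty record at index ", which(empty)[1L])
  }
  ids <- .fastaId(names(x))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id: ", dup[1L])
  for (i in seq_along(seqs)) {
    .encodeSeq(seqs[i], allowGaps = allowGaps,
               what = paste0("record '", ids[i], "'"))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(x)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs A DNAStringSet or a named character vector.
#' @param path Output path. Lines wrap at 70 columns.
#' @return Invisibly, \code{path}.
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs)) {
    if (is.null(names(seqs))) stop("sequences must be named")
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  }
  Biostrings::writeXStringSet(seqs, filepath = path, width = 70L)
  invisible(path)
}
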