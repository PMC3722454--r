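# The packaged bsh primer panel and primer-table I/O.

# name, 5'->3' sequence, orientation, anchor (1-based start of the plus-strand
# footprint on the B. bifidum reference bsh gene). Bif-bshB-2F is stored as a
# contiguous 23-mer.
.BSH_PANEL <- data.frame(
  name = c("Bif-bshA-1F", "Bif-bshB-2F", "Bif-bshC-1R",
           "Bif-bshD-2R", "Bif-bshE-3F", "Bif-bshF-3R"),
  sequence = c("ATGTGCACWGSYGTYCGTTT",
               "TTCGGCCGYAAYCTCGAYTGGAG",
               "TCGAYGACGATGCTDCG",
               "GGYTGRTTGGTVAGCACRTC",
               "TTCGGCCGYAAYCTYGAYTGG",
               "TCGAYGACGATGSTDCG"),
  orientation = c("forward", "forward", "reverse",
                  "reverse", "forward", "reverse"),
  anchor = c(1L, 46L, 448L, 505L, 46L, 448L),
  stringsAsFactors = FALSE
)

#' The six-primer bile salt hydrolase (bsh) screening panel
#'
#' Universal degenerate primers for amplifying the partial bsh gene of
#' bifidobacteria: two nested forward/reverse screening-and-sequencing pairs
#' (A-1F/D-2R spanning anchors 1-524 of the reference gene, B-2F/C-1R the
#' internal 46-464 fragment) and an RT-PCR pair (E-3F/F-3R). Anchors are
#' 1-based starts of the plus-strand footprints on the reference bsh gene;
#' reverse primers are given on their strand of synthesis.
#'
#' @return A data.frame with columns name, sequence, orientation, anchor,
#'   length, degeneracy, tmMin, tmMax.
#' @examples
#' bshPrimerPanel()
#' @export
bshPrimerPanel <- function() {
  p <- .BSH_PANEL
  p$length <- nchar(p$sequence)
  p$degeneracy <- vapply(p$sequence, degeneracy, numeric(1), USE.NAMES = FALSE)
  tm <- t(vapply(p$sequence, tmEstimate, c(min = 0, max = 0)))
  p$tmMin <- unname(tm[, "min"])
  p$tmMax <- unname(tm[, "max"])
  p
}

#' Extract one panel primer as a DegeneratePrimer object
#'
#' @param name Primer name as listed in the panel.
#' @param panel A panel data.frame (default \code{\link{bshPrimerPanel}()}).
#' @return A \code{\linkS4class{DegeneratePrimer}}.
#' @export
panelPrimer <- function(name, panel = bshPrimerPanel()) {
  i <- match(name, panel$name)
  if (is.na(i)) {
    stop("no primer named '", name, "' in the panel (have: ",
         paste(panel$name, collapse = ", "), ")")
  }
  degeneratePrimer(panel$name[i], panel$sequence[i], panel$orientation[i],
                   anchor = panel$anchor[i])
}

#' Write / read a primer panel as TSV
#'
#' Columns: name, sequence, orientation, degeneracy, anchor, tm_min, tm_max.
#'
#' @param panel Panel data.frame (as from \code{\link{bshPrimerPanel}}).
#' @param path File path.
#' @return \code{writePrimerTable} returns \code{path} invisibly;
#'   \code{readPrimerTable} returns the panel data.frame.
#' @export
writePrimerTable <- function(panel, path) {
  out <- data.frame(
    name = panel$name, sequence = panel$sequence,
    orientation = panel$orientation,
    degeneracy = vapply(panel$sequence, degeneracy, numeric(1), USE.NAMES = FALSE),
    anchor = panel$anchor,
    tm_min = vapply(panel$sequence, function(s) tmEstimate(s)[["min"]], numeric(1)),
    tm_max = vapply(panel$sequence, function(s) tmEstimate(s)[["max"]], numeric(1))
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePrimerTable
#' @export
readPrimerTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "sequence", "orientation")
  if (!all(need %in% names(p))) {
    stop("primer table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(p$anchor)) p$anchor <- NA_integer_
  p
}

#' Write panel primers as FASTA
#'
#' @param panel Panel data.frame.
#' @param path Output path.
#' @export
writePrimerFasta <- function(panel, path) {
  writeFasta(stats::setNames(panel$sequence, panel$name), path)
}
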