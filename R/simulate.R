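# Synthetic marker-gene families: Jukes-Cantor evolution along a known tree
# with degenerate primer footprints planted at known anchors, so primer
# detection, in-silico PCR, identity and tree inference can all be tested
# against exact truth.

.BASES <- c("A", "C", "G", "T")

.evolveChars <- function(chars, t) {
  if (t < 0) stop("branch length must be non-negative")
  if (t == 0) return(chars)
  p <- 0.75 * (1 - exp(-4 * t / 3))
  hit <- which(stats::runif(length(chars)) < p)
  if (length(hit)) {
    for (i in hit) {
      chars[i] <- sample(setdiff(.BASES, chars[i]), 1L)
    }
  }
  chars
}

#' Evolve a sequence under the Jukes-Cantor (JC69) model
#'
#' Each site independently substitutes to one of the three other bases with
#' probability p = (3/4)(1 - exp(-4t/3)), where t is the branch length in
#' expected substitutions per site. Uses the current RNG state; seed with
#' \code{set.seed} for reproducibility.
#'
#' @param parent A concrete A/C/G/T string.
#' @param branchLength Branch length t (>= 0).
#' @return The child sequence, same length.
#' @export
evolveJC69 <- function(parent, branchLength) {
  chars <- strsplit(toupper(as.character(parent)), "", fixed = TRUE)[[1L]]
  if (!all(chars %in% .BASES)) stop("parent must be a concrete A/C/G/T sequence")
  paste(.evolveChars(chars, branchLength), collapse = "")
}

#' Random tree for simulation
#'
#' A random rooted binary topology (\link[ape]{rtree}) with branch lengths
#' drawn uniformly from [minEdge, maxEdge] substitutions per site.
#'
#' @param nLeaves Number of leaves (default 8).
#' @param minEdge,maxEdge Branch-length bounds (defaults 0.02 and 0.15).
#' @return A \code{phylo}.
#' @export
randomMarkerTree <- function(nLeaves = 8L, minEdge = 0.02, maxEdge = 0.15) {
  ape::rtree(nLeaves, br = function(n) stats::runif(n, minEdge, maxEdge))
}

# Position-wise IUPAC union of two patterns anchored at their 5' ends; the
# longer pattern's overhang is kept as is.
.unionPattern <- function(a, b) {
  ba <- .encodeSeq(a); bb <- .encodeSeq(b)
  if (length(ba) < length(bb)) { tmp <- ba; ba <- bb; bb <- tmp }
  ba[seq_along(bb)] <- bitwOr(ba[seq_along(bb)], bb)
  .decodeBits(ba)
}

#' Default planted primer footprints
#'
#' The plus-strand footprints of the bsh screening panel at their reference
#' anchors: the A-1F footprint at position 1, the position-wise IUPAC union
#' of the two co-anchored forward primers (B-2F / E-3F) at 46, the reverse
#' complement of the C-1R / F-3R union at 448, and the reverse complement of
#' D-2R at 505. Planting the unions keeps every panel primer bindable within
#' the default mismatch budget while the footprints stay a single
#' non-overlapping set.
#'
#' @return A data.frame with columns name, start, pattern.
#' @export
defaultPlantedBlocks <- function() {
  p <- stats::setNames(.BSH_PANEL$sequence, .BSH_PANEL$name)
  data.frame(
    name = c("site_1F", "site_2F3F", "site_1R3R", "site_2R"),
    start = c(1L, 46L, 448L, 505L),
    pattern = c(
      p[["Bif-bshA-1F"]],
      .unionPattern(p[["Bif-bshB-2F"]], p[["Bif-bshE-3F"]]),
      revComp(.unionPattern(p[["Bif-bshC-1R"]], p[["Bif-bshF-3R"]])),
      revComp(p[["Bif-bshD-2R"]])
    ),
    stringsAsFactors = FALSE
  )
}

# One concrete expansion of an IUPAC pattern, each position sampled uniformly
# from the code's base set.
.samplePattern <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  vapply(chars, function(ch) {
    b <- .IUPAC_BASES[[ch]]
    if (length(b) == 1L) b else sample(b, 1L)
  }, character(1), USE.NAMES = FALSE)
}

# Flank-only indels for one leaf: each flank site starts an event with
# probability `rate`; half are deletions, half single insertions, lengths
# geometric (mean 2). Deletions are truncated so they never reach a
# footprint. Returns the edited char vector and the shifted anchor starts.
.applyIndels <- function(chars, rate, anchors, widths) {
  n <- length(chars)
  inFootprint <- logical(n)
  for (k in seq_along(anchors)) {
    inFootprint[anchors[k]:(anchors[k] + widths[k] - 1L)] <- TRUE
  }
  flank <- which(!inFootprint)
  starts <- flank[stats::runif(length(flank)) < rate]
  if (length(starts) == 0L) return(list(chars = chars, anchors = anchors))
  events <- data.frame(
    pos = starts,
    del = stats::runif(length(starts)) < 0.5,
    len = stats::rgeom(length(starts), 0.5) + 1L
  )
  # truncate deletions at the next footprint (or sequence end)
  for (i in which(events$del)) {
    p <- events$pos[i]
    nextStop <- suppressWarnings(min(c(which(inFootprint & seq_len(n) > p), n + 1L)))
    events$len[i] <- min(events$len[i], nextStop - p)
  }
  shift <- integer(length(anchors))
  for (i in seq_len(nrow(events))) {
    before <- events$pos[i] < anchors
    shift[before] <- shift[before] +
      if (events$del[i]) -events$len[i] else events$len[i]
  }
  for (i in order(events$pos, decreasing = TRUE)) {
    p <- events$pos[i]; l <- events$len[i]
    if (events$del[i]) {
      chars <- chars[-(p:(p + l - 1L))]
    } else {
      chars <- append(chars, sample(.BASES, l, replace = TRUE), after = p)
    }
  }
  list(chars = chars, anchors = anchors + shift)
}

#' Generate a synthetic marker-gene family with planted primer sites
#'
#' Evolves a random root sequence down \code{tree} under JC69, optionally
#' applies flank-only indels per leaf, then overwrites each planted-block
#' footprint in every leaf with an independently sampled concrete expansion
#' of the block's IUPAC pattern -- primer sites stay amplifiable while the
#' flanks diverge according to the tree. A truth record carries the tree, the
#' per-leaf footprint coordinates and the true pairwise path distances.
#'
#' @param tree A \code{phylo} with branch lengths in substitutions per site
#'   (default: \code{\link{randomMarkerTree}()}).
#' @param rootLength Root sequence length in bp (default 950, the scale of a
#'   bsh-type gene).
#' @param plantedBlocks data.frame with columns name, start, pattern
#'   (default \code{\link{defaultPlantedBlocks}()}); set to NULL to plant
#'   nothing (marker-negative templates).
#' @param indelRate Per-flank-site indel event probability (default 0; truth
#'   anchors shift accordingly when positive).
#' @param seed Optional integer seed.
#' @return A list with \code{templates} (DNAStringSet named by tip labels)
#'   and \code{truth} (list: tree, root, sites data.frame with per-leaf
#'   coordinates, distances = cophenetic path-length matrix).
#' @export
generateDataset <- function(tree = NULL, rootLength = 950L,
                            plantedBlocks = defaultPlantedBlocks(),
                            indelRate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tree)) tree <- randomMarkerTree()
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be non-negative")

  if (!is.null(plantedBlocks) && nrow(plantedBlocks) > 0L) {
    w <- nchar(plantedBlocks$pattern)
    s <- as.integer(plantedBlocks$start)
    e <- s + w - 1L
    if (any(s < 1L) || any(e > rootLength)) {
      stop("planted block outside the root sequence (rootLength = ", rootLength, ")")
    }
    o <- order(s)
    if (any(s[o][-1L] <= e[o][-length(o)])) {
      stop("planted blocks overlap (anchor collision)")
    }
  }

  root <- sample(.BASES, rootLength, replace = TRUE)
  nTip <- length(tree$tip.label)
  nodeSeq <- vector("list", nTip + tree$Nnode)
  rootNode <- nTip + 1L
  nodeSeq[[rootNode]] <- root
  # edges in preorder so a parent is always evolved before its children
  ord <- ape::reorder.phylo(tree, "cladewise")
  edges <- ord$edge
  lens <- ord$edge.length
  for (i in seq_len(nrow(edges))) {
    nodeSeq[[edges[i, 2L]]] <- .evolveChars(nodeSeq[[edges[i, 1L]]], lens[i])
  }

  sites <- NULL
  templates <- character(nTip)
  for (tip in seq_len(nTip)) {
    chars <- nodeSeq[[tip]]
    anchors <- if (is.null(plantedBlocks)) integer(0) else as.integer(plantedBlocks$start)
    widths <- if (is.null(plantedBlocks)) integer(0) else nchar(plantedBlocks$pattern)
    if (indelRate > 0 && length(chars) > 0L) {
      ed <- .applyIndels(chars, indelRate, anchors, widths)
      chars <- ed$chars
      anchors <- ed$anchors
    }
    if (length(anchors)) {
      for (k in seq_along(anchors)) {
        idx <- anchors[k]:(anchors[k] + widths[k] - 1L)
        chars[idx] <- .samplePattern(plantedBlocks$pattern[k])
      }
      sites <- rbind(sites, data.frame(
        leaf = tree$tip.label[tip],
        name = plantedBlocks$name,
        start = anchors,
        end = anchors + widths - 1L,
        pattern = plantedBlocks$pattern,
        stringsAsFactors = FALSE
      ))
    }
    templates[tip] <- paste(chars, collapse = "")
  }
  out <- Biostrings::DNAStringSet(templates)
  names(out) <- tree$tip.label
  list(
    templates = out,
    truth = list(
      tree = tree,
      root = paste(root, collapse = ""),
      sites = sites,
      distances = stats::cophenetic(tree)
    )
  )
}
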