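# Distance-based phylogeny: identity -> distance conversion, neighbor
# joining (ape::nj with negative-branch clamping), column-resampling
# bootstrap supports, and Newick I/O.

#' Convert a percent-identity matrix to evolutionary distances
#'
#' p = 1 - identity/100 (the p-distance). With \code{correction =
#' "jukes_cantor"}, d = -(3/4) ln(1 - 4p/3), the expected substitutions per
#' site under the one-parameter substitution model; undefined for p >= 0.75.
#'
#' @param idMat Symmetric percent-identity matrix (diagonal 100).
#' @param correction "none" (default) or "jukes_cantor".
#' @return A symmetric distance matrix with zero diagonal.
#' @export
toDistance <- function(idMat, correction = c("none", "jukes_cantor")) {
  correction <- match.arg(correction)
  idMat <- as.matrix(idMat)
  if (nrow(idMat) != ncol(idMat)) stop("identity matrix must be square")
  p <- 1 - idMat / 100
  if (any(p < -1e-9) || any(p > 1 + 1e-9)) stop("identities must lie in [0, 100]")
  d <- p
  if (correction == "jukes_cantor") {
    if (any(p >= 0.75)) {
      stop("Jukes-Cantor correction undefined for p-distance >= 0.75 (max here: ",
           round(max(p), 3), ")")
    }
    d <- -0.75 * log(1 - 4 * p / 3)
  }
  diag(d) <- 0
  (d + t(d)) / 2
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \link[ape]{nj}) on a labeled symmetric
#' distance matrix; the tree is unrooted and fully resolved. Negative branch
#' lengths, which NJ can produce on non-additive input, are clamped to zero
#' with a message.
#'
#' @param d Symmetric distance matrix (or \code{dist}) with at least 3 taxa.
#' @return An \link[ape]{ape} \code{phylo} object.
#' @export
njTree <- function(d) {
  .njClamp(d, quiet = FALSE)
}

.njClamp <- function(d, quiet = TRUE) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  tree <- ape::nj(stats::as.dist(d))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    if (!quiet) message(sum(neg), " negative branch length(s) clamped to 0")
    tree$edge.length[neg] <- 0
  }
  tree
}

# Pairwise p-distance between alignment rows; for each pair only columns
# where both rows are non-gap count.
.alnDistance <- function(m, correction = c("none", "jukes_cantor")) {
  correction <- match.arg(correction)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  gap <- m == "-"
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      use <- !gap[i, ] & !gap[j, ]
      if (!any(use)) stop("rows ", rownames(m)[i], " and ", rownames(m)[j],
                          " share no aligned columns")
      p <- mean(m[i, use] != m[j, use])
      if (correction == "jukes_cantor") {
        if (p >= 0.75) stop("Jukes-Cantor correction undefined for p >= 0.75")
        p <- -0.75 * log(1 - 4 * p / 3)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree with bootstrap supports from an alignment
#'
#' Builds the full-data NJ tree from row-wise p-distances (optionally
#' Jukes-Cantor corrected), then resamples alignment columns with replacement
#' \code{nReplicates} times, rebuilds the tree per replicate, and attaches to
#' each internal node of the full-data tree the percentage of replicate trees
#' containing the same leaf bipartition (stored in \code{node.label}).
#'
#' @param aln Alignment (any form accepted by \code{\link{columnProfiles}})
#'   with at least 3 rows.
#' @param nReplicates Bootstrap replicates (default 1000).
#' @param seed Optional integer seed for reproducible resampling.
#' @param correction Distance correction, "none" or "jukes_cantor".
#' @return A \code{phylo} tree whose \code{node.label} holds bootstrap
#'   percentages (the root label is empty).
#' @export
bootstrapSupports <- function(aln, nReplicates = 1000L, seed = NULL,
                              correction = c("none", "jukes_cantor")) {
  correction <- match.arg(correction)
  m <- .asAlnMatrix(aln)
  if (nrow(m) < 3L) stop("bootstrap needs an alignment with at least 3 rows")
  if (!is.null(seed)) set.seed(seed)
  full <- njTree(.alnDistance(m, correction))
  L <- ncol(m)
  reps <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    reps[[r]] <- .njClamp(.alnDistance(m[, cols, drop = FALSE], correction))
  }
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  supports <- 100 * counts / nReplicates
  lab <- ifelse(is.na(supports), "", format(supports, trim = TRUE))
  # the first internal node is the (arbitrary) root of the unrooted tree
  lab[1L] <- ""
  full$node.label <- lab
  full
}

#' Bootstrap support of a given clade
#'
#' Looks up, in a tree produced by \code{\link{bootstrapSupports}}, the
#' support of the bipartition separating \code{tips} from the remaining
#' leaves.
#'
#' @param tree A \code{phylo} with \code{node.label} supports.
#' @param tips Character vector of tip labels on one side of the bipartition.
#' @return The support percentage, or NA when no internal edge induces that
#'   bipartition.
#' @export
cladeSupport <- function(tree, tips) {
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  other <- setdiff(labels, tips)
  for (i in seq_along(pp)) {
    set <- labels[pp[[i]]]
    if (setequal(set, tips) || setequal(set, other)) {
      lab <- tree$node.label[i]
      return(if (is.null(lab) || !nzchar(lab)) NA_real_ else as.numeric(lab))
    }
  }
  NA_real_
}

#' Write / read trees in Newick format
#'
#' Branch lengths are written with 6 significant digits; bootstrap supports
#' travel as internal node labels. Reading prechecks parenthesis balance and
#' reports the character offset of the first imbalance.
#'
#' @param tree A \code{phylo}.
#' @param path File path.
#' @return \code{writeNewickTree} returns \code{path} invisibly;
#'   \code{readNewickTree} returns a \code{phylo}.
#' @export
writeNewickTree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' @rdname writeNewickTree
#' @export
readNewickTree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("malformed Newick: unmatched ')' at character ", i)
    }
  }
  if (depth != 0L) {
    stop("malformed Newick: ", depth, " unclosed '(' at end of input (length ",
         length(chars), ")")
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick: parser returned no tree")
  tree
}
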