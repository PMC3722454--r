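# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: expansion is plain recursion, site search scans
# concrete expansions window by window, and alignment scores come from
# enumerating the three column types at every step.

IUPAC_TABLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

randDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

randDegenerate <- function(n, pAmbig = 0.3) {
  letters15 <- names(IUPAC_TABLE)
  picks <- ifelse(runif(n) < pAmbig,
                  sample(letters15[5:15], n, replace = TRUE),
                  sample(letters15[1:4], n, replace = TRUE))
  paste(picks, collapse = "")
}

# all concrete expansions by plain recursion
oracleExpand <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  rec <- function(i) {
    if (i > length(chars)) return("")
    tails <- rec(i + 1L)
    unlist(lapply(IUPAC_TABLE[[chars[i]]], function(b) paste0(b, tails)))
  }
  rec(1L)
}

# brute-force binding sites: every window on both strands against every
# concrete expansion of the primer; a site exists when some expansion meets
# both the total and the 3'-window mismatch budget. Coordinates for the
# minus strand are computed on the reverse-complemented template and mapped
# back, independently of the implementation's arithmetic.
oracleRevComp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(seq, "", fixed = TRUE)[[1L]]]), collapse = "")
}

oracleSites <- function(template, primerSeq, maxMm = 2L, w3 = 3L, maxMm3 = 0L) {
  exps <- oracleExpand(primerSeq)
  k <- nchar(primerSeq)
  scanOne <- function(tmpl) {
    tchars <- strsplit(tmpl, "", fixed = TRUE)[[1L]]
    n <- length(tchars)
    if (n < k) return(integer(0))
    hits <- integer(0)
    for (s in seq_len(n - k + 1L)) {
      win <- tchars[s:(s + k - 1L)]
      for (e in exps) {
        echars <- strsplit(e, "", fixed = TRUE)[[1L]]
        mmv <- vapply(seq_len(k), function(j) {
          !(echars[j] %in% IUPAC_TABLE[[win[j]]])
        }, logical(1))
        if (sum(mmv) <= maxMm && sum(mmv[(k - w3 + 1L):k]) <= maxMm3) {
          hits <- c(hits, s)
          break
        }
      }
    }
    hits
  }
  n <- nchar(template)
  plus <- scanOne(template)
  minusOnRc <- scanOne(oracleRevComp(template))
  minus <- sort(n - (minusOnRc + k - 1L) + 1L)
  list(plus = plus, minus = minus)
}

# optimal end-to-end affine-gap score by enumerating, at each (i, j, state),
# the three possible next columns (cached so length-8 inputs stay fast)
oracleAlignScore <- function(a, b, match = 1, mismatch = -1,
                             gapOpen = 2, gapExtend = 1) {
  A <- strsplit(a, "", fixed = TRUE)[[1L]]
  B <- strsplit(b, "", fixed = TRUE)[[1L]]
  memo <- new.env(hash = TRUE)
  rec <- function(i, j, state) {
    key <- paste(i, j, state)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B)) {
      s <- if (A[i] == B[j]) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, 0L))
    }
    if (i <= length(A)) {
      pen <- gapExtend + if (state != 1L) gapOpen else 0
      best <- max(best, rec(i + 1L, j, 1L) - pen)
    }
    if (j <= length(B)) {
      pen <- gapExtend + if (state != 2L) gapOpen else 0
      best <- max(best, rec(i, j + 1L, 2L) - pen)
    }
    memo[[key]] <- best
    best
  }
  rec(1L, 1L, 0L)
}

# one concrete expansion of an IUPAC pattern, sampled per position
samplePattern <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  paste(vapply(chars, function(ch) {
    b <- IUPAC_TABLE[[ch]]
    if (length(b) == 1L) b else sample(b, 1L)
  }, character(1)), collapse = "")
}

# plant a concrete expansion of `pattern` at `at` (1-based) in `template`
plantAt <- function(template, pattern, at) {
  concrete <- samplePattern(pattern)
  paste0(substring(template, 1, at - 1L), concrete,
         substring(template, at + nchar(concrete), nchar(template)))
}

rfDist <- function(t1, t2) {
  as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)))
}

# 8-taxon alignment of two clades separated by `fixedDiff` planted fixed
# differences, with light within-clade JC noise
twoCladeAlignment <- function(seed, nPerClade = 4, len = 400, fixedDiff = 12,
                              within = 0.01) {
  set.seed(seed)
  root <- randDNA(len)
  ch <- strsplit(root, "", fixed = TRUE)[[1L]]
  pos <- sample(len, fixedDiff)
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1L]
  anc2 <- paste(ch, collapse = "")
  leaves <- c(
    setNames(vapply(seq_len(nPerClade), function(i) evolveJC69(root, within), ""),
             paste0("a", seq_len(nPerClade))),
    setNames(vapply(seq_len(nPerClade), function(i) evolveJC69(anc2, within), ""),
             paste0("b", seq_len(nPerClade)))
  )
  do.call(rbind, strsplit(leaves, "", fixed = TRUE))
}
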