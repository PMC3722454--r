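makeAln <- function(rows) do.call(rbind, strsplit(rows, "", fixed = TRUE))

test_that("column profiles agree with an independent per-column tally", {
  aln <- makeAln(c(a = "AAT", b = "ATT"))
  prof <- columnProfiles(aln)
  expect_identical(prof$consensus, c("A", "W", "T"))
  expect_identical(prof$isIdentical, c(TRUE, FALSE, TRUE))

  set.seed(404)
  m <- matrix(sample(c("A", "C", "G", "T", "-"), 4 * 30, replace = TRUE,
                     prob = c(0.22, 0.22, 0.22, 0.22, 0.12)),
              nrow = 4, dimnames = list(paste0("s", 1:4), NULL))
  prof <- columnProfiles(m)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    tab <- table(factor(col, levels = c("A", "C", "G", "T", "-")))
    expect_identical(prof$A[j], as.integer(tab[["A"]]))
    expect_identical(prof$C[j], as.integer(tab[["C"]]))
    expect_identical(prof$G[j], as.integer(tab[["G"]]))
    expect_identical(prof$T[j], as.integer(tab[["T"]]))
    expect_equal(prof$gapFraction[j], tab[["-"]] / 4)
    observed <- sort(unique(col[col != "-"]))
    if (length(observed)) {
      expect_setequal(iupacBases(prof$consensus[j]), observed)
    }
    expect_identical(prof$isIdentical[j],
                     length(observed) == 1L && tab[["-"]] == 0L)
  }
})

test_that("an alignment of identical gap-free rows is one full-span block", {
  set.seed(405)
  s <- randDNA(60)
  blocks <- findConservedBlocks(makeAln(c(a = s, b = s, c = s)), minLen = 17)
  expect_identical(nrow(blocks), 1L)
  expect_identical(blocks$start, 1L)
  expect_identical(blocks$end, 60L)
  expect_identical(blocks$referenceStart, 1L)
  expect_identical(blocks$consensus, s)
  expect_equal(blocks$degeneracy, 1)
  expect_equal(blocks$meanIdentity, 1)
})

test_that("planted conserved windows are recovered exactly in diverged backgrounds", {
  # star tree, long branches: background columns are almost never invariant
  star <- ape::stree(8, "star")
  star$edge.length <- rep(1.2, 8)
  planted <- data.frame(
    name = c("w1", "w2"), start = c(200L, 600L),
    pattern = c("ATGGCTAGCTAGGATCCTGA", "CCGGATATCGATCGGCTAAG")
  )
  for (rep in 1:20) {
    sim <- generateDataset(tree = star, rootLength = 800,
                           plantedBlocks = planted, seed = 7000 + rep)
    blocks <- findConservedBlocks(sim$templates, minLen = 17,
                                  maxBlockDegeneracy = 1)
    expect_identical(blocks$start, c(200L, 600L))
    expect_identical(blocks$end, c(219L, 619L))
    expect_identical(blocks$consensus, planted$pattern)
  }
})

test_that("blocks are invariant under row permutation and respect their constraints", {
  set.seed(406)
  sim <- generateDataset(seed = 77)
  m <- ampliPhy:::.asAlnMatrix(sim$templates)
  b1 <- findConservedBlocks(m, referenceId = rownames(m)[1])
  b2 <- findConservedBlocks(m[sample(nrow(m)), ], referenceId = rownames(m)[1])
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  # post-hoc re-check of the emitted constraints
  for (i in seq_len(nrow(b1))) {
    expect_gte(b1$end[i] - b1$start[i] + 1L, 17L)
    expect_lte(b1$degeneracy[i], 64)
    expect_equal(b1$degeneracy[i], degeneracy(b1$consensus[i]))
  }
})

test_that("minLen beyond the alignment length warns and returns nothing", {
  aln <- makeAln(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_warning(blocks <- findConservedBlocks(aln, minLen = 20), "exceeds")
  expect_identical(nrow(blocks), 0L)
  expect_error(findConservedBlocks(aln, minLen = 5), "at least 8")
})

test_that("blockToPrimer preserves consensus, orientation and degeneracy", {
  block <- S4Vectors::DataFrame(consensus = "ATGTGCACWGSYGTYCGTTT",
                                referenceStart = 1L)
  fwd <- blockToPrimer(block, "forward", "pF")
  expect_identical(primerSeq(fwd), "ATGTGCACWGSYGTYCGTTT")
  expect_equal(primerDegeneracy(fwd), 16)
  expect_identical(primerAnchor(fwd), 1L)

  rev <- blockToPrimer(block, "reverse", "pR")
  expect_identical(primerSeq(rev), revComp("ATGTGCACWGSYGTYCGTTT"))
  expect_equal(primerDegeneracy(rev), primerDegeneracy(fwd))

  wide <- S4Vectors::DataFrame(consensus = strrep("N", 8), referenceStart = 1L)
  expect_error(blockToPrimer(wide, "forward", "pX"), "cap")
})

test_that("Wallace Tm bounds equal the extremes over all expansions", {
  expect_equal(tmEstimate("AAAA"), c(min = 8, max = 8))
  expect_equal(tmEstimate("GGGG"), c(min = 16, max = 16))
  expect_equal(tmEstimate("AY"), c(min = 4, max = 6))

  wallace <- function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C"))
  }
  set.seed(407)
  for (i in 1:30) {
    x <- randDegenerate(sample(4:8, 1))
    tms <- vapply(oracleExpand(x), wallace, numeric(1))
    expect_equal(tmEstimate(x), c(min = min(tms), max = max(tms)))
  }
})

test_that("alignments are read from aligned FASTA and Clustal formats", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGTAC-TAC", ">s2", "ACGTACGAAC"), fa)
  a1 <- readAlignment(fa)
  expect_identical(dim(ampliPhy:::.asAlnMatrix(a1)), c(2L, 10L))

  aln <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "", "",
               "s1              ACGTACGTAC",
               "s2              ACGTACGAAC",
               "                *******.**"), aln)
  a2 <- readAlignment(aln)   # autodetected from the header line
  m <- ampliPhy:::.asAlnMatrix(a2)
  expect_identical(rownames(m), c("s1", "s2"))
  expect_identical(paste(m[1, ], collapse = ""), "ACGTACGTAC")
})

test_that("the packaged panel matches its published sequences and anchors", {
  panel <- bshPrimerPanel()
  expect_identical(nrow(panel), 6L)
  expect_identical(panel$sequence[panel$name == "Bif-bshA-1F"],
                   "ATGTGCACWGSYGTYCGTTT")
  expect_equal(panel$degeneracy[panel$name == "Bif-bshA-1F"], 16)
  expect_identical(panel$anchor, c(1L, 46L, 448L, 505L, 46L, 448L))
  # Tm windows should bracket a 55-60 C annealing program for the
  # sequencing pair
  a1f <- panel[panel$name == "Bif-bshA-1F", ]
  expect_lte(a1f$tmMin, 60)
  expect_gte(a1f$tmMax, 55)

  tmp <- withr::local_tempfile(fileext = ".tsv")
  writePrimerTable(panel, tmp)
  back <- readPrimerTable(tmp)
  expect_identical(back$name, panel$name)
  expect_identical(back$sequence, panel$sequence)
  expect_error(panelPrimer("nope"), "no primer named")
})
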