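test_that("an exact planted footprint is found at its 1-based position", {
  set.seed(501)
  primer <- panelPrimer("Bif-bshA-1F")
  tmpl <- plantAt(randDNA(400), primerSeq(primer), 101)
  sites <- findBindingSites(tmpl, primer)
  plus <- sites[BiocGenerics::strand(sites) == "+"]
  expect_identical(GenomicRanges::start(plus), 101L)
  expect_identical(GenomicRanges::end(plus), 120L)
  expect_identical(plus$mismatches, 0L)
  expect_identical(plus$threePrimeMismatches, 0L)
})

test_that("reverse-complementing the template mirrors sites and swaps strands", {
  set.seed(502)
  primer <- panelPrimer("Bif-bshD-2R")
  n <- 350
  tmpl <- plantAt(randDNA(n), revComp(primerSeq(primer)), 60)
  s1 <- findBindingSites(tmpl, primer)
  s2 <- findBindingSites(revComp(tmpl), primer)
  expect_identical(length(s1), length(s2))
  expect_setequal(
    paste(GenomicRanges::start(s1), BiocGenerics::strand(s1)),
    paste(n - GenomicRanges::end(s2) + 1L,
          c("+" = "-", "-" = "+")[as.character(BiocGenerics::strand(s2))])
  )
})

test_that("site search matches the exhaustive expansion-scan oracle", {
  set.seed(503)
  panel <- bshPrimerPanel()
  for (rep in 1:8) {
    tmpl <- randDNA(sample(300:700, 1))
    # plant a couple of degenerate footprints so hits actually occur
    nm <- sample(panel$name, 2)
    tmpl <- plantAt(tmpl, panel$sequence[panel$name == nm[1]], 40)
    tmpl <- plantAt(tmpl, revComp(panel$sequence[panel$name == nm[2]]), 200)
    for (p in nm) {
      primer <- panelPrimer(p)
      got <- findBindingSites(tmpl, primer)
      want <- oracleSites(tmpl, primerSeq(primer))
      expect_identical(
        GenomicRanges::start(got[BiocGenerics::strand(got) == "+"]),
        as.integer(want$plus)
      )
      expect_identical(
        GenomicRanges::start(got[BiocGenerics::strand(got) == "-"]),
        as.integer(want$minus)
      )
    }
  }
})

test_that("every reported site re-validates by direct per-position recount", {
  set.seed(504)
  primer <- panelPrimer("Bif-bshB-2F")
  tmpl <- plantAt(plantAt(randDNA(500), primerSeq(primer), 30),
                  revComp(primerSeq(primer)), 300)
  sites <- findBindingSites(tmpl, primer)
  expect_gt(length(sites), 0L)
  tchars <- strsplit(tmpl, "", fixed = TRUE)[[1L]]
  for (i in seq_along(sites)) {
    s <- GenomicRanges::start(sites)[i]
    e <- GenomicRanges::end(sites)[i]
    pat <- if (as.character(BiocGenerics::strand(sites))[i] == "+") {
      primerSeq(primer)
    } else {
      revComp(primerSeq(primer))
    }
    pchars <- strsplit(pat, "", fixed = TRUE)[[1L]]
    mm <- sum(!iupacMatch(tchars[s:e], pchars))
    expect_identical(sites$mismatches[i], as.integer(mm))
    expect_lte(mm, 2L)
  }
})

test_that("amplicons require both orientations and follow coordinate arithmetic", {
  set.seed(505)
  fwd <- panelPrimer("Bif-bshA-1F")
  rev <- panelPrimer("Bif-bshD-2R")

  # only a forward site: no product
  oneSided <- plantAt(randDNA(400), primerSeq(fwd), 50)
  expect_identical(length(predictAmplicons(oneSided, fwd, rev)), 0L)

  # 2 forward x 2 reverse sites in range: 4 products with exact lengths
  tmpl <- randDNA(1200)
  tmpl <- plantAt(tmpl, primerSeq(fwd), 10)
  tmpl <- plantAt(tmpl, primerSeq(fwd), 100)
  tmpl <- plantAt(tmpl, revComp(primerSeq(rev)), 600)
  tmpl <- plantAt(tmpl, revComp(primerSeq(rev)), 900)
  amp <- predictAmplicons(tmpl, fwd, rev)
  expect_identical(length(amp), 4L)
  fwdStarts <- c(10L, 100L)
  revEnds <- c(600L + 19L, 900L + 19L)
  wantLens <- sort(as.vector(outer(revEnds, fwdStarts, function(e, s) e - s + 1L)))
  expect_identical(sort(amp$productLength), wantLens)
  # product sequence is the inclusive template slice
  for (i in seq_along(amp)) {
    expect_identical(amp$sequence[i],
                     substring(tmpl, GenomicRanges::start(amp)[i],
                               GenomicRanges::end(amp)[i]))
  }
})

test_that("virtual gel collapses duplicate bands and flags negatives", {
  gr <- GenomicRanges::GRanges(
    seqnames = factor(c("t1", "t1", "t2"), levels = c("t1", "t2", "t3")),
    ranges = IRanges::IRanges(start = c(1, 1, 5), end = c(524, 524, 423)),
    productLength = c(524L, 524L, 419L)
  )
  gel <- virtualGel(gr, c("t1", "t2", "t3"))
  expect_identical(gel$bands, c("524", "419", ""))
  expect_identical(gel$positive, c(TRUE, TRUE, FALSE))
  expect_identical(gel$nBands, c(1L, 1L, 0L))
})
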