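test_that("identity-to-distance conversion follows p and Jukes-Cantor forms", {
  id <- matrix(c(100, 90, 90, 100), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(toDistance(id)["a", "b"], 0.1)
  expect_equal(toDistance(id, "jukes_cantor")["a", "b"],
               -0.75 * log(1 - 0.4 / 3))
  expect_true(all(diag(toDistance(id, "jukes_cantor")) == 0))

  far <- matrix(c(100, 20, 20, 100), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(toDistance(far, "jukes_cantor"), "0.75")

  # corrections agree to first order: |d_JC - p| <= p^2 for small p
  for (idpct in c(99.9, 99, 98, 96, 95)) {
    p <- 1 - idpct / 100
    m <- matrix(c(100, idpct, idpct, 100), 2,
                dimnames = list(c("a", "b"), c("a", "b")))
    expect_lte(abs(toDistance(m, "jukes_cantor")[1, 2] - p), p^2)
  }
})

test_that("three-taxon NJ reproduces the closed-form branch lengths", {
  d <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d["a", "b"] <- d["b", "a"] <- 0.3
  d["a", "c"] <- d["c", "a"] <- 0.5
  d["b", "c"] <- d["c", "b"] <- 0.6
  tr <- njTree(d)
  expect_identical(ape::Ntip(tr), 3L)
  want <- c(
    a = (0.3 + 0.5 - 0.6) / 2,
    b = (0.3 + 0.6 - 0.5) / 2,
    c = (0.5 + 0.6 - 0.3) / 2
  )
  tipEdge <- tr$edge[, 2] <= 3
  got <- setNames(tr$edge.length[tipEdge], tr$tip.label[tr$edge[tipEdge, 2]])
  expect_equal(got[names(want)], want)
  expect_error(njTree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers additive trees exactly, with clamped non-negative branches", {
  set.seed(701)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    true <- ape::rtree(n, br = function(k) runif(k, 0.05, 0.3))
    d <- stats::cophenetic(true)
    est <- njTree(d)
    expect_equal(rfDist(est, true), 0)
    expect_equal(sum(est$edge.length), sum(true$edge.length), tolerance = 1e-8)
  }
  # strongly non-additive input: lengths may clamp but never stay negative
  set.seed(702)
  for (i in 1:5) {
    n <- 6
    d <- matrix(runif(n * n, 0.1, 1), n, n,
                dimnames = list(paste0("t", 1:n), paste0("t", 1:n)))
    d <- (d + t(d)) / 2; diag(d) <- 0
    est <- suppressMessages(njTree(d))
    expect_true(all(est$edge.length >= 0))
  }
})

test_that("Newick round trips preserve topology, lengths and supports", {
  tmp <- withr::local_tempfile(fileext = ".nwk")
  t3 <- njTree(matrix(c(0, .2, .4, .2, 0, .5, .4, .5, 0), 3,
                      dimnames = list(c("a", "b", "c"), c("a", "b", "c"))))
  writeNewickTree(t3, tmp)
  back <- readNewickTree(tmp)
  expect_equal(rfDist(back, t3), 0)
  expect_equal(sort(back$edge.length), sort(t3$edge.length), tolerance = 1e-5)

  set.seed(703)
  for (i in 1:20) {
    tr <- ape::rtree(10)
    writeNewickTree(tr, tmp)
    expect_equal(rfDist(readNewickTree(tmp), tr), 0)
  }

  # supports ride along as internal node labels
  aln <- twoCladeAlignment(seed = 704)
  bt <- suppressMessages(bootstrapSupports(aln, nReplicates = 20, seed = 1))
  writeNewickTree(bt, tmp)
  back <- readNewickTree(tmp)
  expect_identical(back$node.label, bt$node.label)

  writeLines("((a:1,b:1:,c);", tmp)
  expect_error(readNewickTree(tmp), "unclosed")
  writeLines("(a:1,b:1));", tmp)
  expect_error(readNewickTree(tmp), "character 10")
})

test_that("bootstrap supports are reproducible and sensible at the extremes", {
  aln <- twoCladeAlignment(seed = 705)
  one <- suppressMessages(bootstrapSupports(aln, nReplicates = 1, seed = 9))
  sup <- suppressWarnings(as.numeric(one$node.label))
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))

  b1 <- suppressMessages(bootstrapSupports(aln, nReplicates = 50, seed = 11))
  b2 <- suppressMessages(bootstrapSupports(aln, nReplicates = 50, seed = 11))
  expect_identical(b1$node.label, b2$node.label)

  # clade supports do not depend on leaf input order at fixed seed
  perm <- sample(nrow(aln))
  b3 <- suppressMessages(bootstrapSupports(aln[perm, ], nReplicates = 50, seed = 11))
  expect_equal(cladeSupport(b3, paste0("a", 1:4)),
               cladeSupport(b1, paste0("a", 1:4)))
  expect_identical(cladeSupport(b1, c("a1", "a2", "a3")), NA_real_)
})
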