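# Preprocessing, banded alignment, 3' indel placement, LH-region filtering.

test_that("preprocessing replaces D, masks truncation flanks, rejects junk", {
  res <- preprocessSequence("ACDGT")
  expect_equal(res$clean, "AC-GT")
  expect_length(res$notes, 1L)

  res2 <- preprocessSequence("ACGT")
  expect_equal(res2$clean, "ACGT")
  expect_length(res2$notes, 0L)

  expect_error(preprocessSequence("ACG?"), "offset.*3")

  # bases adjacent to terminal gap runs become N
  res3 <- preprocessSequence("---ACGTACG")
  expect_equal(substring(res3$clean, 4, 4), "N")
  res4 <- preprocessSequence("ACGTACG--")
  expect_equal(substring(res4$clean, 7, 7), "N")
})

test_that("alignment of the reference to itself is empty and fully covered", {
  ref <- refSeq()
  h <- alignToRCRS(ref, ref)
  expect_equal(nrow(variants(h)), 0L)
  expect_equal(coveredRange(h), c(1L, 16569L))
  expect_length(unknownPositions(h), 0L)
})

test_that("single differences are recovered exactly", {
  ref <- refSeq()
  s <- ref; substring(s, 709, 709) <- "A"
  expect_equal(haplotypeTokens(alignToRCRS(s, ref)), "709A")

  # one base deleted inside the homopolymer context around 5747 -> 5752-
  s2 <- paste0(substring(ref, 1, 5746), substring(ref, 5748, nchar(ref)))
  expect_equal(haplotypeTokens(alignToRCRS(s2, ref)), "5752-")

  # heteroplasmy call becomes an ambiguity substitution, N an unknown position
  s3 <- ref; substring(s3, 3243, 3243) <- "R"; substring(s3, 5000, 5000) <- "N"
  h3 <- alignToRCRS(s3, ref)
  expect_equal(haplotypeTokens(h3), "3243R")
  expect_equal(unknownPositions(h3), 5000L)

  # with ambiguityAsUnknown, the ambiguity is masked instead
  h4 <- alignToRCRS(s3, ref, alignmentConfig(ambiguityAsUnknown = TRUE))
  expect_equal(nrow(variants(h4)), 0L)
  expect_setequal(unknownPositions(h4), c(3243L, 5000L))
})

test_that("truncation narrows the covered range without fake variants", {
  ref <- refSeq()
  s <- substring(ref, 41, nchar(ref) - 35)
  h <- alignToRCRS(s, ref)
  expect_equal(coveredRange(h), c(41L, 16569L - 35L))
  expect_equal(nrow(variants(h)), 0L)
})

test_that("mis-rotated or non-human input fails fast at the anchor stage", {
  ref <- refSeq()
  rotated <- paste0(substring(ref, 8001, nchar(ref)), substring(ref, 1, 8000))
  expect_error(alignToRCRS(rotated, ref), "rotat")
  withr::with_seed(9, {
    junk <- paste(sample(c("A", "C", "G", "T"), 16569, replace = TRUE), collapse = "")
    expect_error(alignToRCRS(junk, ref), "anchor")
  })
})

test_that("3' shift matches an exhaustive-placement oracle on random strings", {
  # oracle: the maximal position whose single-base edit reproduces the mutated
  # string, found by enumerating every placement
  delOracle <- function(chars, p) {
    mutated <- paste(chars[-p], collapse = "")
    max(which(vapply(seq_along(chars), function(q)
      paste(chars[-q], collapse = "") == mutated, logical(1))))
  }
  insOracle <- function(chars, p, b) {
    mutated <- paste(append(chars, b, after = p), collapse = "")
    max(which(vapply(seq_along(chars), function(q)
      paste(append(chars, b, after = q), collapse = "") == mutated, logical(1))))
  }
  withr::with_seed(202, {
    for (i in 1:60) {
      n <- sample(40:80, 1)
      # low-cardinality alphabet so homopolymers are frequent
      chars <- sample(c("A", "A", "C", "T"), n, replace = TRUE)
      ref <- paste(chars, collapse = "")
      p <- sample(2:(n - 2), 1)
      v <- shift3Prime(.variantRowForTest(p, "del"), ref)
      expect_equal(v$position, delOracle(chars, p))
      b <- sample(c("A", "C", "T"), 1)
      vi <- shift3Prime(.variantRowForTest(p, "ins", b, 1L), ref)
      expect_equal(vi$position, insOracle(chars, p, b))
    }
  })
})

test_that("3' shift is idempotent and leaves substitutions untouched", {
  ref <- refSeq()
  v <- parseVariants(c("5747-", "709A"))
  once <- shift3Prime(v, ref)
  expect_equal(shift3Prime(once, ref), once)
  expect_equal(once$position[once$kind == "sub"], 709L)
  # a deletion whose following base differs is unchanged
  v2 <- parseVariants("5746-")   # G followed by A
  expect_equal(shift3Prime(v2, ref)$position, 5746L)
})

test_that("reconstruction: applying an aligned haplotype reproduces the input", {
  ref <- refSeq()
  withr::with_seed(77, {
    for (i in 1:5) {
      s <- ref
      # random substitutions
      pos <- sample(setdiff(1000:16000, 5740:5760), 8)
      for (p in pos) {
        cur <- substring(s, p, p)
        substring(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
      }
      # one deletion and one insertion
      dp <- sample(2000:3000, 1)
      s <- paste0(substring(s, 1, dp - 1), substring(s, dp + 1, nchar(s)))
      ip <- sample(9000:10000, 1)
      s <- paste0(substring(s, 1, ip), "T", substring(s, ip + 1, nchar(s)))
      h <- alignToRCRS(s, ref)
      expect_equal(applyHaplotype(ref, h), s)
    }
  })
})

test_that("LH-region indels are dropped from motifs, substitutions kept", {
  h <- parseHaplotype("309- 315.1C 2361A 15826G")
  expect_equal(haplotypeTokens(dropLHIndels(h)), c("2361A", "15826G"))

  h2 <- parseHaplotype("2361A 15826G")
  expect_equal(haplotypeTokens(dropLHIndels(h2)), haplotypeTokens(h2))

  h3 <- parseHaplotype("16183- 16189C")
  expect_equal(haplotypeTokens(dropLHIndels(h3)), "16189C")
})

test_that("alignment of signature-realized genomes returns the signature set", {
  ref <- refSeq()
  tree <- randomTree(31L, 25L, ref)
  sigs <- fullSignatures(tree)
  withr::with_seed(5, {
    for (node in sample(setdiff(nodeNames(tree), rootName(tree)), 5)) {
      g <- realizeGenome(tree, node, ref, simConfigClean(), sampleId = node,
                         sigs = sigs)
      h <- alignToRCRS(g$seq, ref, sampleId = node)
      expect_equal(haplotypeTokens(h), sigs[[node]], label = node)
    }
  })
})

test_that("multi-record FASTA encoding logs per-record failures", {
  ref <- refSeq()
  s <- ref; substring(s, 709, 709) <- "A"
  fa <- withr::local_tempfile(fileext = ".fa")
  writeFasta(c(good = s, short = substring(ref, 1, 500)), fa)
  res <- encodeFasta(fa, ref)
  expect_named(res$haplotypes, "good")
  expect_equal(res$log$status, c("ok", "error"))
})
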