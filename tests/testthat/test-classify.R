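# Haplogroup estimation: scoring, classification, deviation bins, summaries.

test_that("scoring identities, ignores and heteroplasmy behave as specified", {
  tree <- fixtureTree()
  sig <- fullSignature(tree, "H24a3")

  q <- Haplotype("q", variants(sig))
  sc <- scoreNode(q, sig)
  expect_equal(sc$cost, 0)
  expect_equal(nrow(sc$private), 0L)
  expect_equal(nrow(sc$missing), 0L)

  # 16519 substitutions are ignored by default
  q2 <- Haplotype("q", rbind(variants(sig), parseVariants("16519C")))
  expect_equal(scoreNode(q2, sig)$cost, 0)

  # LH-region indels are ignored on both sides by default
  q3 <- Haplotype("q", rbind(variants(sig), parseVariants("315.1C")))
  expect_equal(scoreNode(q3, sig)$cost, 0)

  # a query ambiguity containing the expected allele satisfies the motif;
  # one containing only unexpected alleles leaves it missing
  sigTok <- haplotypeTokens(sig)
  hetOk <- sub("1555G", "1555R", sigTok, fixed = TRUE)   # R = A/G contains G
  expect_equal(scoreNode(Haplotype("q", hetOk), sig)$cost, 0)
  hetBad <- sub("1555G", "1555Y", sigTok, fixed = TRUE)  # Y = C/T misses G
  scBad <- scoreNode(Haplotype("q", hetBad), sig)
  expect_equal(formatVariants(scBad$missing), "1555G")
  expect_equal(formatVariants(scBad$private), "1555Y")

  # missing motif variants at unknown or uncovered positions do not count
  qMasked <- Haplotype("q", variants(sig)[-1, ],
                       unknownPositions = variants(sig)$position[1])
  expect_equal(scoreNode(qMasked, sig)$cost, 0)
})

test_that("scoring equals a brute-force set-algebra oracle on random cases", {
  # independent oracle on token sets with explicit ignore handling
  oracle <- function(qTok, sTok) {
    drop16519 <- function(x) x[!grepl("^16519[A-Z]", x)]
    dropLH <- function(x) {
      pos <- as.integer(sub("^([0-9]+).*", "\\1", x))
      indel <- grepl("-$|\\.", x)
      lh <- (pos >= 303 & pos <= 315) | (pos >= 515 & pos <= 524) |
            (pos >= 568 & pos <= 573) | (pos >= 16180 & pos <= 16194)
      x[!(indel & lh)]
    }
    qe <- dropLH(drop16519(qTok)); se <- dropLH(drop16519(sTok))
    list(cost = length(setdiff(qe, se)) + length(setdiff(se, qe)),
         private = sort(setdiff(qe, se)), missing = sort(setdiff(se, qe)))
  }
  pool <- c("709A", "1555G", "2626C", "6398T", "303-", "16519C", "455.1T",
            "5752-", "9305A", "12236A", "16189C", "315.1C", "8155A")
  withr::with_seed(404, {
    for (i in 1:40) {
      qTok <- sample(pool, sample(0:8, 1))
      sTok <- sample(pool, sample(0:8, 1))
      q <- Haplotype("q", parseVariants(qTok))
      sc <- scoreNode(q, sTok)
      ex <- oracle(qTok, sTok)
      expect_equal(sc$cost, ex$cost)
      expect_equal(sort(formatVariants(sc$private)), ex$private)
      expect_equal(sort(formatVariants(sc$missing)), ex$missing)
    }
  })
})

test_that("classification recovers fixture haplogroups and adds privates", {
  tree <- fixtureTree()
  q <- queryFromSignature(tree, "H24a3")
  r <- classifyHaplotype(q, tree)
  expect_equal(r@haplogroup, "H24a3")
  expect_equal(r@cost, 0)
  expect_equal(r@rootPath[1], "mt-MRCA")
  expect_equal(r@rootPath[length(r@rootPath)], "H24a3")

  extra <- parseVariants(c("5000A", "6000T", "7100C"))
  r2 <- classifyHaplotype(queryFromSignature(tree, "H24a3", extra), tree)
  expect_equal(r2@haplogroup, "H24a3")
  expect_equal(r2@cost, 3)
  expect_equal(nrow(r2@privateVariants), 3L)
  expect_equal(r2@deviation, "minimal")
})

test_that("classification agrees with a full-scan oracle on a random tree", {
  ref <- refSeq()
  tree <- randomTree(55L, 50L, ref)
  sigs <- fullSignatures(tree)
  depths <- nodeDepths(tree)
  w <- weightScheme()
  # independent argmin: per-node cost via scoreNode, same documented tie-break
  oracleAssign <- function(q) {
    costs <- vapply(names(sigs), function(nm) scoreNode(q, sigs[[nm]], w)$cost,
                    numeric(1))
    cand <- names(sigs)[costs == min(costs)]
    cand <- cand[order(-depths[cand], cand)]
    cand[1]
  }
  withr::with_seed(56, {
    nodes <- sample(setdiff(nodeNames(tree), rootName(tree)), 200, replace = TRUE)
    for (i in seq_along(nodes)) {
      nPriv <- sample(0:3, 1)
      extra <- if (nPriv > 0)
        parseVariants(paste0(sample(setdiff(2000:2900, 2361), nPriv), "A"))
        else emptyVariants()
      q <- Haplotype("q", rbind(parseVariants(sigs[[nodes[i]]]), extra))
      r <- classifyHaplotype(q, tree, w, sigs = sigs)
      expect_equal(r@haplogroup, oracleAssign(q), label = paste("case", i))
    }
  })
})

test_that("classification round-trips every node of a generated tree", {
  ref <- refSeq()
  tree <- randomTree(91L, 30L, ref)
  sigs <- fullSignatures(tree)
  for (nm in setdiff(nodeNames(tree), rootName(tree))) {
    q <- Haplotype(nm, parseVariants(sigs[[nm]]))
    r <- classifyHaplotype(q, tree, sigs = sigs)
    expect_equal(r@haplogroup, nm)
    expect_equal(r@cost, 0)
  }
})

test_that("cost is monotone in added non-ignored private variants", {
  tree <- fixtureTree()
  sigs <- fullSignatures(tree)
  q0 <- queryFromSignature(tree, "C1b")
  r0 <- classifyHaplotype(q0, tree, sigs = sigs)
  extras <- c("2500A", "2600T", "2700C", "2800G")
  prev <- r0@cost
  for (k in seq_along(extras)) {
    q <- queryFromSignature(tree, "C1b", parseVariants(extras[seq_len(k)]))
    r <- classifyHaplotype(q, tree, sigs = sigs)
    expect_gte(r@cost, prev)
    prev <- r@cost
  }
})

test_that("an uninformative profile is refused", {
  tree <- fixtureTree()
  q <- Haplotype("empty", emptyVariants(), 100L, 102L, 100:102)
  expect_error(classifyHaplotype(q, tree), "uninformative")
})

test_that("deviation bins partition the cost axis at 10/30/50", {
  expect_equal(deviationCategory(0), "minimal")
  expect_equal(deviationCategory(10), "minimal")
  expect_equal(deviationCategory(10.01), "moderate")
  expect_equal(deviationCategory(29.96), "moderate")
  expect_equal(deviationCategory(30), "moderate")
  expect_equal(deviationCategory(30.03), "substantial")
  expect_equal(deviationCategory(49.12), "substantial")
  expect_equal(deviationCategory(50), "substantial")
  expect_equal(deviationCategory(51.38), "extensive")
  expect_equal(deviationCategory(93.85), "extensive")
  expect_error(deviationCategory(-1), "nonnegative")
  # bins cover the axis without gaps
  withr::with_seed(8, {
    x <- runif(200, 0, 120)
    expect_true(all(deviationCategory(x) %in%
      c("minimal", "moderate", "substantial", "extensive")))
  })
})

test_that("cost summaries compute the documented arithmetic", {
  df <- data.frame(sample_id = c("a", "b", "c"), haplogroup = c("H3", "H3", "C1b"),
                   cost = c(1, 2, 9), n_private = c(1L, 2L, 9L),
                   deviation = deviationCategory(c(1, 2, 9)),
                   stringsAsFactors = FALSE)
  s <- summarizeCosts(df, fixtureTree())
  expect_equal(s$overall$mean_cost, 4)
  expect_equal(s$overall$median_cost, 2)
  expect_equal(s$byDeviation$n[s$byDeviation$group == "minimal"], 3L)
  expect_setequal(s$byMacro$group, c("H", "C"))

  one <- summarizeCosts(df[1, , drop = FALSE])
  expect_equal(one$overall$mean_cost, 1)
  expect_equal(one$overall$median_cost, 1)
})

test_that("weight overrides apply by token and by position", {
  tree <- fixtureTree()
  sig <- fullSignature(tree, "H24a3")
  q <- Haplotype("q", rbind(variants(sig), parseVariants(c("5000A", "6001T"))))
  w <- weightScheme(overrides = c("5000A" = 0.5, "6001" = 0.25))
  expect_equal(scoreNode(q, sig, w)$cost, 0.75)
})
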