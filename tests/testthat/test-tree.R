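# Haplogroup tree: signatures, nomenclature, integration, clustering, I/O.

test_that("full signatures accumulate, back-mutate and replay correctly", {
  tree <- haplogroupTree(c("mt-MRCA", "A", "B"), c(NA, "mt-MRCA", "A"),
                         list("", "195T 1000G", "T195C! 2000A"))
  expect_equal(nrow(variants(fullSignature(tree, "mt-MRCA"))), 0L)
  expect_equal(haplotypeTokens(fullSignature(tree, "A")), c("195T", "1000G"))
  # the back mutation removes the accumulated 195 variant
  expect_equal(haplotypeTokens(fullSignature(tree, "B")), c("1000G", "2000A"))

  # a later substitution replaces the earlier allele at that position
  tree2 <- haplogroupTree(c("mt-MRCA", "A", "B"), c(NA, "mt-MRCA", "A"),
                          list("", "1000G", "1000T"))
  expect_equal(haplotypeTokens(fullSignature(tree2, "B")), "1000T")

  # unmatched back mutation warns and is kept literally
  tree3 <- haplogroupTree(c("mt-MRCA", "A"), c(NA, "mt-MRCA"),
                          list("", "T195C!"))
  expect_warning(sig <- fullSignature(tree3, "A"), "no ancestral")
  expect_equal(haplotypeTokens(sig), "195C!")
})

test_that("full signatures equal a brute-force replay oracle on random trees", {
  # independent oracle: replay tokens as a position-keyed state map
  replayOracle <- function(tree, name) {
    state <- list()
    for (nm in rootPath(tree, name)) {
      v <- branchMotif(tree, nm)
      for (i in seq_len(nrow(v))) {
        key <- paste(v$position[i], v$kind[i], v$idx[i])
        if (v$kind[i] == "sub" && v$back[i] %% 2 == 1) {
          subKeys <- names(state)[grepl(paste0("^", v$position[i], " sub"), names(state))]
          if (length(subKeys)) { state[subKeys] <- NULL; next }
          state[[key]] <- v[i, ]
        } else if (v$kind[i] == "sub") {
          subKeys <- names(state)[grepl(paste0("^", v$position[i], " sub"), names(state))]
          state[subKeys] <- NULL
          row <- v[i, ]; row$back <- 0L
          state[[key]] <- row
        } else state[[key]] <- v[i, ]
      }
    }
    if (length(state) == 0) return(character(0))
    variantTokens(do.call(rbind, state))
  }
  ref <- refSeq()
  for (seed in c(3L, 14L)) {
    tree <- randomTree(seed, 30L, ref, backRate = 0.3)
    sigs <- fullSignatures(tree)
    for (nm in nodeNames(tree))
      expect_equal(sigs[[nm]], replayOracle(tree, nm), label = paste(seed, nm))
  }
})

test_that("fullSignatures agrees with per-node fullSignature", {
  tree <- fixtureTree()
  sigs <- fullSignatures(tree)
  for (nm in c("H24a3", "C1b", "L5a2a2a", "B4a1a1b"))
    expect_equal(sigs[[nm]], haplotypeTokens(fullSignature(tree, nm)))
})

test_that("next available names follow the letter/number alternation", {
  tree <- fixtureTree()
  expect_equal(nextAvailableName(tree, "W7"), "W7a")       # digit end, no kids
  expect_equal(nextAvailableName(tree, "T2h"), "T2h3")     # letter end, 1 and 2 taken
  expect_error(nextAvailableName(tree, "nope"), "unknown")

  # beyond z the letter sequence continues bijectively: aa, ab, ...
  kids <- paste0("W7", letters)
  t2 <- haplogroupTree(c("mt-MRCA", "W7", kids),
                       c(NA, "mt-MRCA", rep("W7", 26)),
                       c(list(""), as.list(paste0(100 + seq_len(27), "A"))))
  expect_equal(nextAvailableName(t2, "W7"), "W7aa")
})

test_that("subclade integration resolves asterisks and rejects per item", {
  tree <- fixtureTree()
  n0 <- nNodes(tree)
  additions <- data.frame(
    parent = c("W7", "T2h", "T2h", "nope", "H1", "H1"),
    motif = c("5000A", "6000G", "6000G", "7000T", "8000C", "9000C"),
    proposed = c("W7*", "T2h*", "T2h*", "X1*", "H1a", "H1x1"),
    stringsAsFactors = FALSE)
  res <- integrateSubclades(tree, additions)
  # W7* -> W7a, first T2h* -> T2h3; the duplicate-motif sibling is rejected;
  # unknown parent rejected; H1a collides with the existing node
  expect_equal(res$report$assigned[1:2], c("W7a", "T2h3"))
  expect_equal(res$report$status[3], "rejected: duplicate motif")
  expect_equal(res$report$status[4], "rejected: unknown parent")
  expect_equal(res$report$status[5], "rejected: name collision")
  expect_equal(res$report$status[6], "integrated")
  expect_equal(nNodes(res$tree), n0 + 3L)

  # an explicit rejection list blocks flagged proposals
  res2 <- integrateSubclades(tree, additions[1:2, ], reject = "W7*")
  expect_equal(res2$report$status, c("rejected: flagged", "integrated"))

  # empty additions leave the tree unchanged
  res3 <- integrateSubclades(tree, additions[0, ])
  expect_equal(nNodes(res3$tree), n0)
})

test_that("macrohaplogroup picks the deepest matching label", {
  tree <- fixtureTree()
  expect_equal(macrohaplogroup(tree, "B4a1a1b"), "R+16189")
  expect_equal(macrohaplogroup(tree, "H3"), "H")
  expect_equal(macrohaplogroup(tree, "L5a2a1a"), "L5")
  expect_equal(macrohaplogroup(tree, "C1b"), "C")
  expect_equal(macrohaplogroup(tree, "J1c1d"), "J")
})

test_that("first-level splits and stars follow the published grouping", {
  tree <- fixtureTree()
  c1b <- firstLevelSplit(tree, "C1b")
  expect_equal(c1b$label, "M8")
  expect_true(c1b$starred)          # M8 contains the C and CZ clades
  h1a <- firstLevelSplit(tree, "H1a")
  expect_equal(h1a$label, "H1")
  expect_false(h1a$starred)
  l0 <- firstLevelSplit(tree, "L0a2a2a")
  expect_equal(l0$label, "L0")      # macro fallback
})

test_that("lineages and phylopaths match the published worked examples", {
  tree <- fixtureTree()
  expect_equal(lineage(tree, "M7c1c3"), "M")
  expect_equal(lineage(tree, "I2"), "N")
  expect_equal(lineage(tree, "B4a1a1"), "R")
  expect_equal(lineage(tree, "L5a2a1a", subL = TRUE), "L5")
  expect_equal(lineage(tree, "L2a1b1a", subL = TRUE), "L2")

  expect_equal(phylopath(tree, "H3"), "L3-N-R-R0-HV-H-H3")
  expect_equal(phylopath(tree, "C1b"), "L3-M-M8-C-C1")
  expect_equal(phylopath(tree, "E1a1a1"), "L3-M-M9-E")
  expect_equal(phylopath(tree, "B4a1a1b"), "L3-N-R-R+16189-B4")
  expect_equal(phylopath(tree, "M7c1c3"), "L3-M-M7")
  expect_equal(phylopath(tree, "A2+ (64)"), "L3-N-A-A2")
  expect_equal(phylopath(tree, "L2a1b1a"), "L2")
  expect_equal(phylopath(tree, "L5a2a1a"), "L5")
})

test_that("macro labels are ancestors and lineage is phylopath-consistent", {
  tree <- fixtureTree()
  for (nm in setdiff(nodeNames(tree), rootName(tree))) {
    mac <- macrohaplogroup(tree, nm)
    path <- rootPath(tree, nm)
    expect_true(mac %in% path || startsWith(nm, substr(mac, 1, 1)))
    lin <- lineage(tree, nm)
    pp <- phylopath(tree, nm)
    if (lin == "L" && nzchar(pp)) expect_match(pp, "^L")
    if (lin %in% c("M", "N", "R") && nzchar(pp)) expect_match(pp, "^L3")
  }
})

test_that("tree JSON round-trips byte-stably and validates its schema", {
  tree <- fixtureTree()
  json1 <- writeTreeJSON(tree)
  back <- readTreeJSON(json1)
  expect_setequal(nodeNames(back), nodeNames(tree))
  expect_equal(writeTreeJSON(back), json1)    # byte-stable
  expect_equal(haplotypeTokens(fullSignature(back, "H24a3")),
               haplotypeTokens(fullSignature(tree, "H24a3")))
  expect_error(readTreeJSON('{"nodes": []}'), "schema")

  path <- withr::local_tempfile(fileext = ".json")
  writeTreeJSON(tree, path)
  expect_equal(writeTreeJSON(readTreeJSON(path)), json1)
})

test_that("node count after integration equals baseline plus accepted", {
  ref <- refSeq()
  tree <- randomTree(21L, 40L, ref)
  withr::with_seed(22, {
    parents <- sample(nodeNames(tree), 12, replace = TRUE)
    additions <- data.frame(parent = parents,
                            motif = paste0(sample(7000:8000, 12), "A"),
                            proposed = "*", stringsAsFactors = FALSE)
  })
  res <- integrateSubclades(tree, additions)
  accepted <- sum(res$report$status == "integrated")
  expect_equal(nNodes(res$tree), 40L + accepted)
})

test_that("newick export encodes the topology (ape as oracle)", {
  skip_if_not_installed("ape")
  # a branching-only tree (no unary chains), readable by ape
  tree <- haplogroupTree(c("mt-MRCA", "L0", "L1", "L0a", "L0b", "L1a", "L1b"),
                         c(NA, "mt-MRCA", "mt-MRCA", "L0", "L0", "L1", "L1"),
                         list("", "100A", "200C", "300G", "400T", "500A", "600C"))
  nwk <- writeNewick(tree)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("L0a", "L0b", "L1a", "L1b"))
  expect_equal(phy$Nnode, 3L)
  # names needing quoting are quoted
  t2 <- haplogroupTree(c("mt-MRCA", "A2+ (64)"), c(NA, "mt-MRCA"), list("", "64T"))
  expect_match(writeNewick(t2), "'A2\\+ \\(64\\)'")
  # motifs can ride along as comments
  expect_match(writeNewick(tree, comments = TRUE), "\\[&motif=100A\\]")
})

test_that("the flat full-signature JSON lists every node", {
  tree <- fixtureTree()
  flat <- jsonlite::fromJSON(writeSignaturesJSON(tree))
  expect_setequal(names(flat), nodeNames(tree))
  expect_equal(flat[["L5a2a"]],
               paste(haplotypeTokens(fullSignature(tree, "L5a2a")), collapse = " "))
})
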