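# Synthetic-data generator: random haplogroup trees, signature-realized
# mitogenomes with private variants and submitter-style noise, metadata, and
# truth tables, so the whole pipeline is testable without downloads.

#' Simulation configuration
#'
#' Defaults describe the data world the pipeline is built for: a
#' private-variant load of about 3 substitutions per sample (the typical load
#' of well-classified cohorts), occasional heteroplasmy calls, and the
#' submitter artifacts the preprocessing stage must absorb (N runs below the
#' QC threshold of 30, deletions written as `D`, truncated ends).
#'
#' @param nSamples cohort size.
#' @param privateRate Poisson mean of private substitutions per sample.
#' @param nRunRate Poisson mean of the number of N runs per sample.
#' @param nRunLength inclusive range of each N-run length.
#' @param ambiguityRate probability that a private variant is emitted as an
#'   IUPAC ambiguity (heteroplasmy) code instead of a plain base.
#' @param dCharRate probability that a sample carries a deletion written as
#'   `D` (a submitter artifact).
#' @param truncateProb probability of clipping a sequence end.
#' @param truncateMax maximal bases clipped per affected end.
#' @param pathogenicSpike `data.frame(variant, fraction)`: catalog variant
#'   tokens spiked into the given carrier fraction of samples.
#' @return a configuration list.
#' @export
simConfig <- function(nSamples = 100L, privateRate = 3, nRunRate = 0.5,
                      nRunLength = c(5L, 25L), ambiguityRate = 0.02,
                      dCharRate = 0.01, truncateProb = 0.02, truncateMax = 40L,
                      pathogenicSpike = NULL) {
  stopifnot(privateRate >= 0, nRunRate >= 0,
            ambiguityRate >= 0, ambiguityRate <= 1,
            dCharRate >= 0, dCharRate <= 1,
            truncateProb >= 0, truncateProb <= 1)
  list(nSamples = as.integer(nSamples), privateRate = privateRate,
       nRunRate = nRunRate, nRunLength = as.integer(nRunLength),
       ambiguityRate = ambiguityRate, dCharRate = dCharRate,
       truncateProb = truncateProb, truncateMax = as.integer(truncateMax),
       pathogenicSpike = pathogenicSpike)
}

#' Noise-free simulation configuration
#' @param ... overrides passed to [simConfig()].
#' @return a [simConfig()] with all noise channels off and zero privates.
#' @export
simConfigClean <- function(...) {
  cfg <- simConfig(privateRate = 0, nRunRate = 0, ambiguityRate = 0,
                   dCharRate = 0, truncateProb = 0)
  utils::modifyList(cfg, list(...))
}

# positions synthetic variants may use: outside LH regions and off 16519
.allowedPositions <- function(extraExclude = integer(0)) {
  pos <- seq_len(RCRS_LENGTH)
  pos[!.inRegions(pos, LH_REGIONS) & pos != 16519L & !pos %in% extraExclude]
}

.otherBase <- function(base) {
  vapply(base, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1),
         USE.NAMES = FALSE)
}

#' Generate a random haplogroup tree
#'
#' Node names follow the letter/number alternation of the nomenclature (root
#' children are single letters); each non-root node carries a non-empty motif
#' of substitutions at positions untouched on its ancestral path, with an
#' occasional back mutation reverting an ancestral variant. Reproducible per
#' seed; the caller's RNG stream is not disturbed.
#'
#' @param seed integer seed.
#' @param nNodes total node count including the root.
#' @param ref reference sequence string.
#' @param motifSizeDist function(n) returning n positive motif sizes.
#' @param backRate probability a node's motif starts with a back mutation.
#' @return a [HaplogroupTree-class].
#' @export
randomTree <- function(seed, nNodes, ref = loadReference(),
                       motifSizeDist = function(n) 1L + rpois(n, 1),
                       backRate = 0.04) {
  stopifnot(nNodes >= 1)
  withSeed(seed, .randomTreeImpl(nNodes, ref, motifSizeDist, backRate))
}

.randomTreeImpl <- function(nNodes, ref, motifSizeDist, backRate) {
  refChars <- strsplit(ref, "")[[1]]
  allowed <- .allowedPositions()
  nm <- character(nNodes); pa <- character(nNodes); mo <- vector("list", nNodes)
  usedPos <- vector("list", nNodes)   # positions varied on the root path
  accDerived <- vector("list", nNodes) # accumulated sub variants (pos -> derived)
  nm[1] <- "mt-MRCA"; pa[1] <- NA_character_; mo[[1]] <- emptyVariants()
  usedPos[[1]] <- integer(0); accDerived[[1]] <- character(0)
  childCount <- new.env(parent = emptyenv())
  for (i in seq_len(nNodes)[-1]) {
    p <- sample.int(i - 1L, 1L)
    parent <- nm[p]
    pa[i] <- parent
    k <- (get0(parent, envir = childCount, ifnotfound = 0L)) + 1L
    assign(parent, k, envir = childCount)
    nm[i] <- if (p == 1L) {
      paste0(toupper(.letterSuffix(k)))
    } else if (grepl("[0-9]$", parent)) {
      paste0(parent, .letterSuffix(k))
    } else {
      paste0(parent, k)
    }
    size <- max(1L, motifSizeDist(1))
    acc <- accDerived[[p]]
    vars <- emptyVariants()
    if (runif(1) < backRate && length(acc) > 0) {
      bp <- as.integer(sample(names(acc), 1))
      vars <- rbind(vars, .variantRow(bp, "sub", derived = refChars[bp], back = 1L))
      size <- size - 1L
    }
    if (size > 0) {
      free <- setdiff(allowed, usedPos[[p]])
      posv <- sample(free, size)
      vars <- rbind(vars, .variantRow(posv, "sub", derived = .otherBase(refChars[posv])))
    }
    mo[[i]] <- sortVariants(vars)
    newAcc <- acc
    for (r in seq_len(nrow(vars))) {
      pos <- as.character(vars$position[r])
      if (vars$back[r] %% 2L == 1L) newAcc <- newAcc[names(newAcc) != pos]
      else newAcc[pos] <- vars$derived[r]
    }
    accDerived[[i]] <- newAcc
    usedPos[[i]] <- union(usedPos[[p]], vars$position)
  }
  obj <- new("HaplogroupTree", nodeName = nm, nodeParent = pa,
             branchVariants = mo, macroLabels = MACRO_LABELS)
  validObject(obj)
  obj
}

#' Realize a mitogenome for a haplogroup
#'
#' The sequence is the reference edited by the node's full signature, plus
#' Poisson-sampled private substitutions at positions untouched by the
#' signature (and outside length-heteroplasmy regions and off 16519, so the
#' classification cost equals the private count under unit weights), plus the
#' configured noise: N runs, a deletion written as `D`, end truncation, and
#' pathogenic spikes. The truth row records everything injected.
#'
#' @param tree a [HaplogroupTree-class].
#' @param nodeName haplogroup to realize.
#' @param ref reference sequence string.
#' @param cfg a [simConfig()].
#' @param sampleId identifier for the record.
#' @param sigs optional precomputed [fullSignatures()].
#' @return `list(seq = <string>, truth = <one-row data.frame>)`.
#' @export
realizeGenome <- function(tree, nodeName, ref = loadReference(),
                          cfg = simConfig(), sampleId = nodeName, sigs = NULL) {
  sigTok <- if (is.null(sigs)) haplotypeTokens(fullSignature(tree, nodeName))
            else sigs[[nodeName]]
  sigVars <- parseVariants(sigTok)
  refChars <- strsplit(ref, "")[[1]]

  k <- rpois(1, cfg$privateRate)
  free <- setdiff(.allowedPositions(), sigVars$position)
  priv <- emptyVariants()
  if (k > 0) {
    posv <- sort(sample(free, k))
    der <- .otherBase(refChars[posv])
    amb <- runif(k) < cfg$ambiguityRate
    if (any(amb)) {   # heteroplasmy: ambiguity code covering ref + derived base
      der[amb] <- vapply(which(amb), function(j) {
        pair <- sort(c(refChars[posv[j]], der[j]))
        names(Filter(function(s) length(s) == 2 && all(s == pair), IUPAC_CODES))[1]
      }, character(1))
    }
    priv <- .variantRow(posv, "sub", derived = der)
  }

  nPriv <- nrow(priv)
  spiked <- character(0)
  if (!is.null(cfg$pathogenicSpike)) {
    for (r in seq_len(nrow(cfg$pathogenicSpike))) {
      if (runif(1) < cfg$pathogenicSpike$fraction[r]) {
        sv <- variants(parseHaplotype(cfg$pathogenicSpike$variant[r]))
        sv <- sv[!sv$position %in% c(sigVars$position, priv$position), , drop = FALSE]
        if (nrow(sv)) {
          priv <- rbind(priv, sv)
          spiked <- c(spiked, cfg$pathogenicSpike$variant[r])
        }
      }
    }
  }

  h <- Haplotype(sampleId, rbind(sigVars, priv))
  seq <- applyHaplotype(ref, h)

  # noise channels
  nRuns <- rpois(1, cfg$nRunRate)
  nPosAll <- integer(0)
  if (nRuns > 0) {
    for (r in seq_len(nRuns)) {
      len <- sample(seq(cfg$nRunLength[1], cfg$nRunLength[2]), 1)
      start <- sample.int(nchar(seq) - len, 1)
      substring(seq, start, start + len - 1L) <- strrep("N", len)
      nPosAll <- c(nPosAll, start:(start + len - 1L))
    }
  }
  dPos <- NA_integer_
  if (runif(1) < cfg$dCharRate) {
    dPos <- sample.int(nchar(seq), 1)
    substring(seq, dPos, dPos) <- "D"
  }
  trunc5 <- 0L; trunc3 <- 0L
  if (runif(1) < cfg$truncateProb) trunc5 <- sample.int(cfg$truncateMax, 1)
  if (runif(1) < cfg$truncateProb) trunc3 <- sample.int(cfg$truncateMax, 1)
  if (trunc5 + trunc3 > 0)
    seq <- substring(seq, 1L + trunc5, nchar(seq) - trunc3)

  truth <- data.frame(
    sample_id = sampleId, haplogroup = nodeName,
    n_private = nPriv,
    private = paste(variantTokens(priv), collapse = " "),
    n_n_positions = length(nPosAll), d_char_pos = dPos,
    trunc5 = trunc5, trunc3 = trunc3,
    spiked = paste(spiked, collapse = " "), stringsAsFactors = FALSE)
  list(seq = seq, truth = truth)
}

#' Simulate a cohort of mitogenomes with truth tables
#'
#' Samples haplogroups uniformly from the non-root nodes, realizes one genome
#' per sample ([realizeGenome()]), and fabricates raw metadata (geography and
#' technology annotations drawn from small realistic pools, including the
#' misspellings and multi-platform strings the normalizer must handle).
#'
#' @param tree a [HaplogroupTree-class].
#' @param seed integer seed (the only randomness source).
#' @param ref reference sequence string.
#' @param cfg a [simConfig()].
#' @return `list(sequences = <named character vector>, truth = <data.frame>,
#'   metadata = <data.frame>)`.
#' @export
simulateCohort <- function(tree, seed, ref = loadReference(), cfg = simConfig()) {
  withSeed(seed, {
    nodes <- setdiff(nodeNames(tree), rootName(tree))
    sigs <- fullSignatures(tree)
    picks <- sample(nodes, cfg$nSamples, replace = TRUE)
    geoPool <- c("Finland", "Finlnad", "Ireland", "Eire", "Austria", "China",
                 "India", "France", "French", "East-Africa", "")
    techPool <- c("Illumina", "Sanger", "IonTorrent", "454", "PacBio",
                  "Illumina;IonTorrent", "Sanger;Illumina", "")
    seqs <- character(cfg$nSamples); truths <- vector("list", cfg$nSamples)
    for (i in seq_len(cfg$nSamples)) {
      id <- sprintf("SYN%05d", i)
      rg <- realizeGenome(tree, picks[i], ref, cfg, sampleId = id, sigs = sigs)
      seqs[i] <- rg$seq; truths[[i]] <- rg$truth
    }
    names(seqs) <- sprintf("SYN%05d", seq_len(cfg$nSamples))
    meta <- data.frame(id = names(seqs),
                       geo_raw = sample(geoPool, cfg$nSamples, replace = TRUE),
                       tech_raw = sample(techPool, cfg$nSamples, replace = TRUE),
                       stringsAsFactors = FALSE)
    list(sequences = seqs, truth = do.call(rbind, truths), metadata = meta)
  })
}

#' Write a named character vector of sequences as FASTA
#'
#' @param sequences named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(sequences, path) {
  # write directly: sequences may carry '-'/'D' artifacts a DNAStringSet rejects
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", names(sequences)[i]), con)
    s <- sequences[[i]]
    starts <- seq(1L, nchar(s), by = 70L)
    writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
  }
  invisible(path)
}
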