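# Conversion of raw mitogenome sequences into phylogenetically aligned
# (3'-shifted) difference-coded haplotypes.

#' Default length-heteroplasmy-prone regions of the rCRS
#'
#' Poly-C / repeat stretches where indel placement is unstable and therefore
#' excluded from haplogroup motifs: 303-315, 515-524, 568-573, 16180-16194
#' (1-based, closed intervals).
#' @export
LH_REGIONS <- list(c(303L, 315L), c(515L, 524L), c(568L, 573L), c(16180L, 16194L))

.inRegions <- function(pos, regions) {
  hit <- rep(FALSE, length(pos))
  for (r in regions) hit <- hit | (pos >= r[1] & pos <= r[2])
  hit
}

#' Alignment configuration
#'
#' @param bandWidth maximal diagonal deviation of the banded aligner; must be
#'   at least the largest expected cumulative indel length (default 60).
#' @param gapOpen,gapExtend affine gap penalties (nonnegative).
#' @param match,mismatch,ambig match score, mismatch penalty (as a positive
#'   number) and score for IUPAC-compatible pairs.
#' @param lhRegions list of `c(start, end)` rCRS intervals regarded as
#'   length-heteroplasmy prone.
#' @param anchorK exact-match anchor k-mer length for the rotation check.
#' @param ambiguityAsUnknown record IUPAC ambiguity bases as unknown positions
#'   instead of ambiguity substitution variants (default `FALSE`: ambiguities
#'   become variants such as `3243R`; only `N` goes to unknown positions).
#' @return a configuration list.
#' @export
alignmentConfig <- function(bandWidth = 60L, gapOpen = 6L, gapExtend = 1L,
                            match = 2L, mismatch = 2L, ambig = 1L,
                            lhRegions = LH_REGIONS, anchorK = 31L,
                            ambiguityAsUnknown = FALSE) {
  stopifnot(bandWidth >= 1, gapOpen >= 0, gapExtend >= 0)
  for (r in lhRegions) stopifnot(r[1] >= 1, r[2] <= RCRS_LENGTH, r[1] <= r[2])
  list(bandWidth = as.integer(bandWidth), gapOpen = as.integer(gapOpen),
       gapExtend = as.integer(gapExtend), match = as.integer(match),
       mismatch = as.integer(mismatch), ambig = as.integer(ambig),
       lhRegions = lhRegions, anchorK = as.integer(anchorK),
       ambiguityAsUnknown = isTRUE(ambiguityAsUnknown))
}

#' Preprocess a raw mitogenome string
#'
#' Submitters frequently use `D` to denote a deletion although it is an IUPAC
#' ambiguity code; every `D`/`d` is therefore replaced by `-`. Bases
#' immediately flanking a terminal gap run (the footprint of a truncated FASTA
#' string) are set to `N`. One note is recorded per modification.
#'
#' @param raw nucleotide string (IUPAC codes, `-`, case-insensitive).
#' @return `list(clean = <string>, notes = <character vector>)`.
#' @export
preprocessSequence <- function(raw) {
  s <- toupper(raw)
  bad <- gregexpr("[^ACGTRYSWKMBDHVN-]", s)[[1]]
  if (bad[1] != -1)
    stop(sprintf("non-IUPAC symbol(s) %s at offset(s) %s",
                 paste(unique(substring(s, bad, bad)), collapse = ","),
                 paste(bad - 1L, collapse = ",")))
  notes <- character(0)
  dpos <- gregexpr("D", s, fixed = TRUE)[[1]]
  if (dpos[1] != -1) {
    notes <- c(notes, sprintf("replaced 'D' with '-' at offset %d", dpos - 1L))
    s <- gsub("D", "-", s, fixed = TRUE)
  }
  # terminal gap runs: mask the adjacent base as N
  lead <- regmatches(s, regexpr("^-+", s))
  if (length(lead)) {
    k <- nchar(lead) + 1L
    if (k <= nchar(s)) {
      substring(s, k, k) <- "N"
      notes <- c(notes, sprintf("base at offset %d flanked by leading gap run set to 'N'", k - 1L))
    }
  }
  trail <- regmatches(s, regexpr("-+$", s))
  if (length(trail)) {
    k <- nchar(s) - nchar(trail)
    if (k >= 1) {
      substring(s, k, k) <- "N"
      notes <- c(notes, sprintf("base at offset %d flanked by trailing gap run set to 'N'", k - 1L))
    }
  }
  list(clean = s, notes = notes)
}

#' Shift an indel to its 3'-most equivalent placement
#'
#' An indel inside a homopolymer (or matching-repeat) context has several
#' sequence-equivalent placements; the phylogenetic convention reports the
#' 3'-most one. A deletion reported at rCRS 5747, inside the A-run ending at
#' 5752, therefore normalizes to `5752-`. Substitutions are returned
#' unchanged; the operation is idempotent.
#'
#' @param v single-row variant table (or a [Haplotype-class] whose indels are
#'   all shifted).
#' @param ref reference sequence string.
#' @return the variant table with 3'-shifted positions.
#' @export
shift3Prime <- function(v, ref) {
  if (is(v, "Haplotype"))
    return(Haplotype(v@sampleId, shift3Prime(v@variants, ref),
                     v@coveredStart, v@coveredEnd, v@unknownPositions))
  if (nrow(v) == 0) return(v)
  chars <- strsplit(ref, "")[[1]]
  n <- length(chars)
  for (i in seq_len(nrow(v))) {
    p <- v$position[i]
    if (v$kind[i] == "del") {
      while (p < n && chars[p + 1L] == chars[p]) p <- p + 1L
    } else if (v$kind[i] == "ins") {
      b <- v$derived[i]
      while (p < n && chars[p + 1L] == b) p <- p + 1L
    }
    v$position[i] <- p
  }
  sortVariants(v)
}

# 3'-shift a multi-base deletion run [p, p+len-1]; returns the shifted start.
.shiftDeletionRun <- function(p, len, chars) {
  n <- length(chars)
  while (p + len <= n && chars[p + len] == chars[p]) p <- p + 1L
  p
}

# 3'-shift an insertion of the string `bases` placed after reference position p.
.shiftInsertionRun <- function(p, bases, chars) {
  n <- length(chars)
  while (p < n && chars[p + 1L] == bases[1]) {
    bases <- c(bases[-1], bases[1])
    p <- p + 1L
  }
  list(position = p, bases = bases)
}

#' Remove indels inside length-heteroplasmy-prone regions
#'
#' Indels whose (3'-shifted) position falls in a configured
#' length-heteroplasmy region are dropped from the haplotype; substitutions
#' are never touched. This is the convention that turns the motif
#' `"309- 315.1C 2361A 15826G"` into `"2361A 15826G"`.
#'
#' @param h a [Haplotype-class].
#' @param cfg an [alignmentConfig()] (its `lhRegions` are used).
#' @return the filtered [Haplotype-class].
#' @export
dropLHIndels <- function(h, cfg = alignmentConfig()) {
  v <- h@variants
  kill <- v$kind != "sub" & .inRegions(v$position, cfg$lhRegions)
  Haplotype(h@sampleId, v[!kill, , drop = FALSE],
            h@coveredStart, h@coveredEnd, h@unknownPositions)
}

# Locate the query in reference coordinates via exact k-mer anchors near both
# query ends; errors when no anchor hits (mis-rotated or non-human input).
.anchorWindow <- function(seq, ref, cfg) {
  k <- cfg$anchorK
  n <- nchar(seq)
  findAnchor <- function(offsets) {
    for (o in offsets) {
      if (o < 1 || o + k - 1L > n) next
      kmer <- substring(seq, o, o + k - 1L)
      if (grepl("[^ACGT]", kmer)) next
      hit <- regexpr(kmer, ref, fixed = TRUE)
      if (hit != -1) return(c(qry = o, ref = as.integer(hit)))
    }
    NULL
  }
  a <- findAnchor(seq(1L, min(400L, n - k + 1L), by = 7L))
  b <- findAnchor(seq(max(1L, n - k + 1L), max(1L, n - 400L), by = -7L))
  if (is.null(a) || is.null(b))
    stop("anchor failure: no exact k-mer anchor found near the sequence ends; ",
         "the sequence is likely mis-rotated, reverse-complemented or non-human")
  start <- a["ref"] - (a["qry"] - 1L)
  end <- b["ref"] + (n - b["qry"])
  # fail fast on mis-rotated input: a linearized rCRS-orientation genome must
  # start near reference position 1 and end near position 16569
  if (start > 700L || end < nchar(ref) - 700L)
    stop("anchor failure: sequence does not start/end near the reference ",
         "origin; it appears rotated relative to the rCRS linearization")
  c(start = max(1L, as.integer(start)), end = min(nchar(ref), as.integer(end)))
}

#' Align a mitogenome to the rCRS and difference-code it
#'
#' Anchors the (preprocessed) sequence by exact k-mer match, runs a banded
#' global alignment with affine gaps against the covered reference window, and
#' converts the alignment into a canonical [Haplotype-class]: substitutions for
#' base differences (IUPAC ambiguities become ambiguity variants such as
#' `3243R` unless `cfg$ambiguityAsUnknown`), per-position deletions and indexed
#' insertions, all indels placed at their 3'-most equivalent position, `N`
#' bases recorded as unknown positions, and the covered range reflecting any
#' truncation.
#'
#' @param seq preprocessed sequence string (see [preprocessSequence()]); any
#'   residual `-` characters are removed before alignment.
#' @param ref reference sequence string (defaults to the bundled synthetic
#'   rCRS stand-in).
#' @param cfg an [alignmentConfig()].
#' @param sampleId identifier for the resulting haplotype.
#' @return a [Haplotype-class].
#' @export
alignToRCRS <- function(seq, ref = loadReference(), cfg = alignmentConfig(),
                        sampleId = "") {
  s <- gsub("-", "", toupper(seq), fixed = TRUE)
  if (nchar(s) < 16000L || nchar(s) > 16700L)
    stop(sprintf("sequence length %d outside the accepted 16000..16700 range", nchar(s)))
  win <- .anchorWindow(s, ref, cfg)
  refwin <- substring(ref, win["start"], win["end"])
  if (abs(nchar(refwin) - nchar(s)) > cfg$bandWidth)
    stop("band overflow: length difference exceeds the band width; ",
         "increase bandWidth in alignmentConfig()")
  ops <- .bandedAlign(refwin, s, cfg$bandWidth, cfg$match, -cfg$mismatch,
                      cfg$ambig, cfg$gapOpen, cfg$gapExtend)
  .opsToHaplotype(ops, ref, s, offset = win[["start"]] - 1L, cfg = cfg,
                  sampleId = sampleId)
}

# Convert an alignment op matrix into a canonical haplotype.
.opsToHaplotype <- function(ops, ref, qry, offset, cfg, sampleId) {
  refChars <- strsplit(ref, "")[[1]]
  qryChars <- strsplit(qry, "")[[1]]
  op <- ops[, "op"]; ri <- ops[, "ref"]; qi <- ops[, "qry"]

  unknown <- integer(0)
  subs <- emptyVariants()
  aligned <- op == 0L
  if (any(aligned)) {
    rpos <- ri[aligned] + offset
    qc <- qryChars[qi[aligned]]
    rc <- refChars[rpos]
    isN <- qc == "N"
    unknown <- rpos[isN]
    if (cfg$ambiguityAsUnknown) {
      isAmb <- qc %in% AMBIGUITY_LETTERS
      unknown <- c(unknown, rpos[isAmb & !isN])
      diff <- qc != rc & !isN & !isAmb
    } else {
      diff <- qc != rc & !isN
    }
    if (any(diff)) subs <- .variantRow(rpos[diff], "sub", derived = qc[diff])
  }

  # group indel ops into runs and 3'-shift each run
  dels <- emptyVariants(); ins <- emptyVariants()
  runId <- cumsum(c(TRUE, diff(op) != 0 | diff(ri) > 1L))
  for (g in split(seq_along(op), runId)) {
    kind <- op[g[1]]
    if (kind == 1L) {                                    # deletion run
      p <- .shiftDeletionRun(ri[g[1]] + offset, length(g), refChars)
      dels <- rbind(dels, .variantRow(p + seq_along(g) - 1L, "del"))
    } else if (kind == 2L) {                             # insertion run
      sh <- .shiftInsertionRun(ri[g[1]] + offset, qryChars[qi[g]], refChars)
      if (sh$position < 1L)
        stop("query overhang before reference start cannot be represented")
      ins <- rbind(ins, .variantRow(rep(sh$position, length(g)), "ins",
                                    derived = sh$bases, idx = seq_along(g)))
    }
  }

  covered <- range(ri[op != 2L] + offset)
  vars <- rbind(subs, dels, ins)
  vars <- vars[vars$position >= covered[1] & vars$position <= covered[2] |
                 vars$kind == "ins", , drop = FALSE]
  Haplotype(sampleId, vars, covered[1], covered[2], unknown)
}

#' Encode every record of a FASTA file
#'
#' Applies [preprocessSequence()] and [alignToRCRS()] to each record.
#' Per-record failures are collected, not fatal.
#'
#' @param path FASTA file (multi-record, wrapped or unwrapped).
#' @param ref,cfg see [alignToRCRS()].
#' @return `list(haplotypes = <list>, log = <data.frame>)` where the log holds
#'   one row per record with its preprocessing notes or error message.
#' @export
encodeFasta <- function(path, ref = loadReference(), cfg = alignmentConfig()) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  haps <- list(); logs <- list()
  for (i in seq_along(set)) {
    res <- tryCatch({
      pp <- preprocessSequence(as.character(set[[i]]))
      h <- alignToRCRS(pp$clean, ref, cfg, sampleId = ids[i])
      list(h = h, note = paste(pp$notes, collapse = "; "), status = "ok")
    }, error = function(e) list(h = NULL, note = conditionMessage(e), status = "error"))
    if (!is.null(res$h)) haps[[ids[i]]] <- res$h
    logs[[i]] <- data.frame(sample_id = ids[i], status = res$status,
                            note = res$note, stringsAsFactors = FALSE)
  }
  list(haplotypes = haps, log = do.call(rbind, logs))
}
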