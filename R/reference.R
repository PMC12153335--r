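# Reference sequence handling.
#
# The package is built against the rCRS coordinate system (NC_012920.1,
# 16 569 bp). This build cannot redistribute the GenBank record, so it bundles
# a clearly labelled SYNTHETIC stand-in (inst/extdata/rCRS_synthetic.fasta)
# generated by syntheticRCRS(): seeded-random bases overwritten with the
# reference facts the difference-coding literature documents explicitly
# (reference bases carried by prefixed tokens such as G709A or A13105G!, the
# 303-315 poly-C stretch with 310T, the A homopolymer ending at 5752 that makes
# a deletion reported at 5747 normalize to 5752del, and the 16183 poly-A /
# poly-C context). Every exported function takes a `ref` argument, so the real
# NC_012920.1 FASTA can be substituted without code changes.

# documented reference facts encoded into the synthetic stand-in
.RCRS_FACTS <- c(
  `152` = "T", `195` = "T",
  `302` = "A", `303` = "C", `304` = "C", `305` = "C", `306` = "C", `307` = "C",
  `308` = "C", `309` = "C", `310` = "T", `311` = "C", `312` = "C", `313` = "C",
  `314` = "C", `315` = "C", `316` = "G",
  `455` = "T", `456` = "G", `464` = "A", `709` = "G", `750` = "A", `851` = "A",
  `1494` = "C", `1555` = "A", `1822` = "T", `2361` = "G", `3243` = "A",
  `3460` = "G", `5111` = "C", `5147` = "G", `5321` = "C", `5460` = "G",
  `5656` = "A", `5746` = "G",
  `5747` = "A", `5748` = "A", `5749` = "A", `5750` = "A", `5751` = "A",
  `5752` = "A", `5753` = "C",
  `6182` = "G", `6297` = "T", `7424` = "A", `8155` = "G", `8188` = "A",
  `8582` = "C", `9305` = "G", `9329` = "G", `11025` = "T", `11778` = "G",
  `11881` = "C", `12236` = "G", `13105` = "A", `13722` = "A", `14212` = "T",
  `14239` = "C", `14484` = "T", `14581` = "T", `14674` = "T", `14905` = "G",
  `14971` = "T", `15217` = "G", `15826` = "A", `15884` = "G",
  `16179` = "C", `16180` = "A", `16181` = "A", `16182` = "A", `16183` = "A",
  `16184` = "C", `16185` = "C", `16186` = "C", `16187` = "C", `16188` = "C",
  `16189` = "T", `16190` = "C", `16191` = "C", `16192` = "C", `16193` = "C",
  `16194` = "C", `16195` = "A",
  `16274` = "G", `16355` = "C", `16362` = "T", `16399` = "A", `16519` = "T"
)

#' Synthetic rCRS stand-in sequence
#'
#' Deterministic 16 569-bp sequence used in place of the rCRS (NC_012920.1),
#' which cannot be redistributed with this package. Bases at coordinates whose
#' reference allele or homopolymer context is documented in the
#' difference-coding literature carry that allele; all other bases are
#' seeded-random. Suitable for testing every coordinate-level operation of
#' the package; substitute the real record for production analyses.
#'
#' @return a single character string of length 16 569 (alphabet ACGT).
#' @export
syntheticRCRS <- function() {
  if (!is.null(.mitophylo_cache$rcrs)) return(.mitophylo_cache$rcrs)
  bases <- withSeed(1066L, sample(c("A", "C", "G", "T"), RCRS_LENGTH, replace = TRUE))
  bases[as.integer(names(.RCRS_FACTS))] <- unname(.RCRS_FACTS)
  seq <- paste(bases, collapse = "")
  .mitophylo_cache$rcrs <- seq
  seq
}

#' Load a reference sequence from FASTA
#'
#' @param path FASTA file; defaults to the bundled synthetic rCRS stand-in.
#' @return a character string; errors unless the record is exactly 16 569 bp
#'   over the alphabet A/C/G/T/N.
#' @export
loadReference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rCRS_synthetic.fasta", package = "mitophylo")
    if (!nzchar(path) || !file.exists(path)) return(syntheticRCRS())
  }
  set <- Biostrings::readDNAStringSet(path)
  seq <- toupper(as.character(set[[1]]))
  if (nchar(seq) != RCRS_LENGTH)
    stop(sprintf("reference must be %d bp, got %d", RCRS_LENGTH, nchar(seq)))
  if (grepl("[^ACGTN]", seq))
    stop("reference alphabet must be A/C/G/T/N")
  seq
}

#' Reconstruct a sequence from a reference and a haplotype
#'
#' Applies the haplotype's substitutions, deletions and insertions to `ref`,
#' masks `unknownPositions` as `N`, and clips to the covered range. This is the
#' inverse of [alignToRCRS()]: aligning the result recovers the haplotype.
#'
#' @param ref reference sequence string.
#' @param h a [Haplotype-class].
#' @param applyUnknown mask unknown positions as `N` (default `TRUE`).
#' @return the reconstructed sequence string.
#' @export
applyHaplotype <- function(ref, h, applyUnknown = TRUE) {
  stopifnot(is(h, "Haplotype"))
  chars <- strsplit(ref, "")[[1]]
  v <- h@variants
  subs <- v[v$kind == "sub", , drop = FALSE]
  if (nrow(subs)) chars[subs$position] <- subs$derived
  if (applyUnknown && length(h@unknownPositions))
    chars[h@unknownPositions] <- "N"
  keep <- seq(h@coveredStart, h@coveredEnd)
  dels <- v[v$kind == "del", , drop = FALSE]
  ins <- v[v$kind == "ins", , drop = FALSE]
  if (!nrow(dels) && !nrow(ins))                       # indel-free fast path
    return(paste(chars[keep], collapse = ""))
  drop <- rep(FALSE, length(chars))
  if (nrow(dels)) drop[dels$position] <- TRUE
  insAfter <- vector("list", length(chars))
  if (nrow(ins)) {
    ins <- ins[order(ins$position, ins$idx), , drop = FALSE]
    for (p in unique(ins$position))
      insAfter[[p]] <- ins$derived[ins$position == p]
  }
  pieces <- lapply(keep, function(i) {
    c(if (!drop[i]) chars[i], insAfter[[i]])
  })
  paste(unlist(pieces), collapse = "")
}
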