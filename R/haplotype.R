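# Haplotype: a difference-coded profile relative to the rCRS.

#' @title Haplotype: a difference-coded mtDNA profile
#'
#' @description An ordered set of variants relative to the rCRS together with
#' the covered coordinate range and the positions masked as unknown (no-call,
#' `N`). This is the "phylogenetically aligned haplotype" of forensic
#' reporting: all indels sit at their 3'-most equivalent placement.
#'
#' @slot sampleId sample identifier.
#' @slot variants canonical variant table (see [parseVariants()]).
#' @slot coveredStart,coveredEnd covered rCRS range (1-based, closed).
#' @slot unknownPositions rCRS coordinates treated as no-call.
#' @export
setClass("Haplotype",
  representation(sampleId = "character", variants = "data.frame",
                 coveredStart = "integer", coveredEnd = "integer",
                 unknownPositions = "integer"))

setValidity("Haplotype", function(object) {
  v <- object@variants
  msgs <- character(0)
  need <- c("position", "kind", "derived", "idx", "back", "ref_hint")
  if (!all(need %in% names(v))) return("variant table misses required columns")
  if (object@coveredStart < 1L || object@coveredEnd > RCRS_LENGTH ||
      object@coveredStart > object@coveredEnd)
    msgs <- c(msgs, "covered range must satisfy 1 <= start <= end <= 16569")
  if (nrow(v)) {
    if (any(v$position < object@coveredStart | v$position > object@coveredEnd))
      msgs <- c(msgs, "every variant position must lie within the covered range")
    if (anyDuplicated(variantKey(v)))
      msgs <- c(msgs, "no two variants may share (position, kind, insertion index)")
    if (any(v$kind == "del" & nzchar(v$derived)))
      msgs <- c(msgs, "deletions carry no derived allele")
    if (any(v$kind != "del" & nchar(v$derived) != 1L))
      msgs <- c(msgs, "substitutions and insertions carry one IUPAC symbol")
    if (any(v$kind == "ins" & v$idx < 1L) || any(v$kind != "ins" & v$idx != 0L))
      msgs <- c(msgs, "insertion index >= 1 iff the variant is an insertion")
    if (any(v$kind != "sub" & v$back > 0L))
      msgs <- c(msgs, "back mutations only occur on substitutions")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a [Haplotype-class] object
#'
#' @param sampleId sample identifier.
#' @param variants variant table or character vector of tokens.
#' @param coveredStart,coveredEnd covered rCRS range.
#' @param unknownPositions integer vector of no-call coordinates.
#' @return a [Haplotype-class] object with canonically sorted variants.
#' @export
Haplotype <- function(sampleId = "", variants = emptyVariants(),
                      coveredStart = 1L, coveredEnd = RCRS_LENGTH,
                      unknownPositions = integer(0)) {
  if (is.character(variants)) variants <- parseVariants(variants)
  variants <- sortVariants(uniqueVariants(variants))
  rownames(variants) <- NULL
  new("Haplotype", sampleId = as.character(sampleId), variants = variants,
      coveredStart = as.integer(coveredStart), coveredEnd = as.integer(coveredEnd),
      unknownPositions = sort(unique(as.integer(unknownPositions))))
}

#' @describeIn Haplotype-class sample identifier
#' @param object,x a [Haplotype-class]
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname Haplotype-class
#' @export
setMethod("sampleId", "Haplotype", function(object) object@sampleId)

#' @rdname Haplotype-class
#' @export
setGeneric("variants", function(object) standardGeneric("variants"))
#' @rdname Haplotype-class
#' @export
setMethod("variants", "Haplotype", function(object) object@variants)

#' @rdname Haplotype-class
#' @export
setGeneric("unknownPositions", function(object) standardGeneric("unknownPositions"))
#' @rdname Haplotype-class
#' @export
setMethod("unknownPositions", "Haplotype", function(object) object@unknownPositions)

#' @rdname Haplotype-class
#' @export
setGeneric("coveredRange", function(object) standardGeneric("coveredRange"))
#' @rdname Haplotype-class
#' @export
setMethod("coveredRange", "Haplotype",
          function(object) c(object@coveredStart, object@coveredEnd))

#' Canonical bare tokens of a haplotype
#' @param h a [Haplotype-class]
#' @return character vector of canonically sorted bare-style tokens
#' @export
haplotypeTokens <- function(h) variantTokens(h@variants)

setMethod("show", "Haplotype", function(object) {
  tok <- haplotypeTokens(object)
  cat(sprintf("Haplotype '%s' | range %d-%d | %d variant(s), %d unknown position(s)\n",
              object@sampleId, object@coveredStart, object@coveredEnd,
              nrow(object@variants), length(object@unknownPositions)))
  if (length(tok))
    cat(" ", paste(head(tok, 12), collapse = " "),
        if (length(tok) > 12) "..." else "", "\n")
})

#' Parse a whitespace-separated motif string into a haplotype
#'
#' Tokens are parsed with [parseVariants()], canonically sorted and
#' de-duplicated, so token order in the input does not matter.
#'
#' @param line motif string, e.g. `"2361A 15826G"` (may be empty).
#' @param sampleId sample identifier to attach.
#' @param permissive passed to [parseVariants()].
#' @return a [Haplotype-class].
#' @export
parseHaplotype <- function(line, sampleId = "", permissive = FALSE) {
  tokens <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  vars <- emptyVariants()
  for (i in seq_along(tokens)) {
    vars <- tryCatch(rbind(vars, .parseToken(tokens[i], permissive = permissive)),
      mitophylo_parse_error = function(e)
        stop(sprintf("token %d: %s", i, conditionMessage(e)), call. = FALSE))
  }
  Haplotype(sampleId, vars)
}

#' Read / write haplotypes in the tab-separated exchange format
#'
#' One sample per line: sample id, covered range (`"1-16569"`), space-separated
#' variant tokens (EMPOP-like). A fourth optional column lists unknown
#' positions as comma-separated coordinates.
#'
#' @param path file path.
#' @return `readHaplotypes`: a list of [Haplotype-class] objects.
#' @export
readHaplotypes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t")[[1]]
    if (length(f) < 2) stop("haplotype lines need at least id and range fields")
    rng <- as.integer(strsplit(f[2], "-")[[1]])
    h <- parseHaplotype(if (length(f) >= 3) f[3] else "", sampleId = f[1])
    unk <- if (length(f) >= 4 && nzchar(f[4]))
      as.integer(strsplit(f[4], ",")[[1]]) else integer(0)
    Haplotype(f[1], h@variants, rng[1], rng[2], unk)
  })
}

#' @rdname readHaplotypes
#' @param haplotypes list of [Haplotype-class] objects.
#' @return `writeHaplotypes`: `path`, invisibly.
#' @export
writeHaplotypes <- function(haplotypes, path) {
  lines <- vapply(haplotypes, function(h) {
    paste(h@sampleId, paste0(h@coveredStart, "-", h@coveredEnd),
          paste(haplotypeTokens(h), collapse = " "),
          paste(h@unknownPositions, collapse = ","), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
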