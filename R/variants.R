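# Variant model and the forensic difference-coded notation dialects.
#
# A variant is one difference from the rCRS. Internally variants are rows of a
# data.frame ("variant table") with columns:
#   position  integer, 1..16569 (rCRS coordinate, 1-based)
#   kind      "sub", "del" or "ins"
#   derived   single IUPAC symbol ("" for deletions)
#   idx       insertion index (the ".1" in "455.1T"); 0 for non-insertions
#   back      back-mutation count (trailing "!" = 1, "!!" = 2); substitutions only
#   ref_hint  leading reference base carried by the token ("" if absent)

#' rCRS genome length in base pairs
#' @export
RCRS_LENGTH <- 16569L

#' IUPAC nucleotide codes and the bases they stand for
#' @keywords internal
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_LETTERS <- names(IUPAC_CODES)
AMBIGUITY_LETTERS <- setdiff(IUPAC_LETTERS, c("A", "C", "G", "T"))

.variantRow <- function(position, kind, derived = "", idx = 0L, back = 0L,
                        ref_hint = "") {
  data.frame(position = as.integer(position), kind = kind, derived = derived,
             idx = as.integer(idx), back = as.integer(back),
             ref_hint = ref_hint, stringsAsFactors = FALSE)
}

#' An empty variant table
#' @return zero-row variant `data.frame`
#' @export
emptyVariants <- function() .variantRow(integer(0), character(0), character(0),
                                        integer(0), integer(0), character(0))

.parseError <- function(token, why) {
  stop(errorCondition(sprintf("malformed variant token '%s': %s", token, why),
                      class = c("mitophylo_parse_error", "error")))
}

.checkPosition <- function(pos, token) {
  if (is.na(pos) || pos < 1L || pos > RCRS_LENGTH)
    .parseError(token, sprintf("position %s outside 1..%d", pos, RCRS_LENGTH))
  pos
}

# Parse one token into a variant table (spans expand to several rows).
.parseToken <- function(token, permissive = FALSE) {
  tok <- trimws(token)
  if (!nzchar(tok)) .parseError(token, "empty token")

  # multi-position deletion span, e.g. "8281-8289d"
  m <- regmatches(tok, regexec("^([ACGTacgt]?)([0-9]+)-([0-9]+)(d|D|del|DEL|Del)$", tok))[[1]]
  if (length(m)) {
    from <- .checkPosition(as.integer(m[3]), tok)
    to <- .checkPosition(as.integer(m[4]), tok)
    if (to < from) .parseError(tok, "span end before start")
    return(.variantRow(from:to, "del", ref_hint = c(toupper(m[2]), rep("", to - from))))
  }

  # single deletion: "16183-", "16183del", "A16183d" (lowercase 'd' only;
  # uppercase 'D' is the IUPAC ambiguity code and parses as a substitution)
  m <- regmatches(tok, regexec("^([ACGTacgt]?)([0-9]+)(-|del|DEL|Del|d)$", tok))[[1]]
  if (length(m)) {
    pos <- .checkPosition(as.integer(m[3]), tok)
    return(.variantRow(pos, "del", ref_hint = toupper(m[2])))
  }

  # insertion: "455.1T"; multi-base forms like "960.1CC" expand to successive indices
  m <- regmatches(tok, regexec("^([ACGTacgt]?)([0-9]+)\\.([0-9]+)([A-Za-z]+)$", tok))[[1]]
  if (length(m)) {
    pos <- .checkPosition(as.integer(m[3]), tok)
    idx <- as.integer(m[4])
    if (is.na(idx) || idx < 1L) .parseError(tok, "insertion index must be >= 1")
    bases <- strsplit(m[5], "")[[1]]
    bases <- .normalizeDerived(bases, ref_hint = toupper(m[2]), token = tok,
                               permissive = permissive)
    return(.variantRow(rep(pos, length(bases)), "ins", derived = bases,
                       idx = idx + seq_along(bases) - 1L,
                       ref_hint = c(toupper(m[2]), rep("", length(bases) - 1L))))
  }

  # substitution: "709A", "G709A", "14484Y", "A13105G!", "C152T!!"
  m <- regmatches(tok, regexec("^([ACGTacgt]?)([0-9]+)([A-Za-z])(!{0,2})$", tok))[[1]]
  if (length(m)) {
    pos <- .checkPosition(as.integer(m[3]), tok)
    derived <- .normalizeDerived(m[4], ref_hint = toupper(m[2]), token = tok,
                                 permissive = permissive)
    return(.variantRow(pos, "sub", derived = derived, back = nchar(m[5]),
                       ref_hint = toupper(m[2])))
  }

  .parseError(tok, "does not match any variant notation dialect")
}

# Uppercase derived alleles; a bare lowercase letter after a leading reference
# base (e.g. "A16183c") is ambiguous between a base call and a deletion in the
# extended IUPAC convention, so it is rejected unless `permissive = TRUE`.
.normalizeDerived <- function(derived, ref_hint, token, permissive) {
  lower <- derived != toupper(derived)
  if (any(lower) && nzchar(ref_hint) && !permissive)
    .parseError(token, paste0(
      "lowercase derived allele after a leading reference base is ambiguous ",
      "(lowercase is reserved for extended IUPAC uncertainty); ",
      "use permissive = TRUE to read it as an uppercase base call"))
  derived <- toupper(derived)
  bad <- !derived %in% IUPAC_LETTERS
  if (any(bad)) .parseError(token, sprintf("'%s' is not an IUPAC symbol", derived[bad][1]))
  derived
}

#' Parse difference-coded variant tokens
#'
#' Accepts every dialect used in forensic mtDNA reporting: bare substitutions
#' (`"709A"`), reference-prefixed substitutions (`"G709A"`), IUPAC ambiguity
#' (heteroplasmy) calls (`"14484Y"`), back mutations (`"A13105G!"`, `"C152T!!"`),
#' insertions (`"455.1T"`), deletions (`"16183-"`, `"16183del"`, `"A16183d"`)
#' and multi-position deletion spans (`"8281-8289d"`, expanded per position).
#' Leading zeros in positions are tolerated (`"A0750G"`).
#'
#' @param tokens character vector of whitespace-free tokens.
#' @param permissive accept bare lowercase derived alleles after a leading
#'   reference base (e.g. `"A16183c"`) as uppercase base calls instead of
#'   rejecting them as ambiguous.
#' @return a variant table (`data.frame`), one row per variant, in input order.
#' @examples
#' parseVariants(c("455.1T", "G709A", "16183-", "14484Y"))
#' @export
parseVariants <- function(tokens, permissive = FALSE) {
  if (length(tokens) == 0) return(emptyVariants())
  do.call(rbind, lapply(tokens, .parseToken, permissive = permissive))
}

#' Format a variant table back into tokens
#'
#' The canonical output dialect is the bare style: `"709A"` for substitutions
#' (with trailing `"!"` per back-mutation count), `"16183-"` for deletions and
#' `"455.1T"` for insertions. The prefixed style prepends the rCRS base
#' (`"G709A"`), read from `ref` when supplied, else from the stored hint.
#'
#' @param v variant table.
#' @param style `"bare"` (default) or `"prefixed"`.
#' @param ref reference sequence string (required for prefixed style unless all
#'   rows carry a reference hint).
#' @return character vector of tokens.
#' @export
formatVariants <- function(v, style = c("bare", "prefixed"), ref = NULL) {
  style <- match.arg(style)
  if (nrow(v) == 0) return(character(0))
  bang <- strrep("!", v$back)
  core <- ifelse(v$kind == "del", paste0(v$position, "-"),
          ifelse(v$kind == "ins", paste0(v$position, ".", v$idx, v$derived),
                 paste0(v$position, v$derived, bang)))
  if (style == "bare") return(core)
  pref <- v$ref_hint
  if (!is.null(ref)) pref <- substring(ref, v$position, v$position)
  if (any(!nzchar(pref)))
    stop("prefixed style needs a reference sequence or stored reference hints")
  paste0(pref, core)
}

#' Canonical variant ordering
#'
#' Total, deterministic order by (position, kind rank, insertion index,
#' derived allele) with substitutions before deletions before insertions.
#'
#' @param v variant table.
#' @return the reordered variant table.
#' @export
sortVariants <- function(v) {
  if (nrow(v) <= 1) return(v)
  rank <- match(v$kind, c("sub", "del", "ins"))
  v[order(v$position, rank, v$idx, v$derived), , drop = FALSE]
}

# Identity key for matching variants across haplotypes: position/kind/index.
variantKey <- function(v) paste(v$position, v$kind, v$idx, sep = "/")

# Canonical bare tokens after sorting; the working currency of set operations.
variantTokens <- function(v) formatVariants(sortVariants(v), "bare")

# Drop duplicated tokens (same canonical rendering).
uniqueVariants <- function(v) {
  if (nrow(v) <= 1) return(v)
  v[!duplicated(formatVariants(v, "bare")), , drop = FALSE]
}
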