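# Pathogenic-variant screening and masking with a resolution audit.

#' @title PathogenicCatalog: named pathogenic variants
#'
#' @description A catalog of confirmed pathogenic mtDNA variants used for
#' screening and masking. Each entry has a label (`"Homo3"`, `"Hetero76"`), a
#' variant (one or, rarely, several tokens such as the paired deletion
#' `"9205- 9206-"`), and a mode: homoplasmic entries carry a plain base or a
#' deletion, heteroplasmic entries an IUPAC ambiguity code.
#'
#' @slot label entry labels.
#' @slot tokens list of canonical bare-token vectors, parallel to `label`.
#' @slot mode `"homoplasmic"` or `"heteroplasmic"`, parallel to `label`.
#' @export
setClass("PathogenicCatalog",
  representation(label = "character", tokens = "list", mode = "character"))

setValidity("PathogenicCatalog", function(object) {
  msgs <- character(0)
  if (length(object@tokens) != length(object@label) ||
      length(object@mode) != length(object@label))
    return("label, tokens and mode must be parallel")
  if (!all(object@mode %in% c("homoplasmic", "heteroplasmic")))
    msgs <- c(msgs, "mode must be homoplasmic or heteroplasmic")
  for (i in seq_along(object@label)) {
    v <- parseVariants(object@tokens[[i]])
    het <- object@mode[i] == "heteroplasmic"
    if (het && !all(v$derived %in% AMBIGUITY_LETTERS))
      msgs <- c(msgs, sprintf("heteroplasmic entry '%s' must use an IUPAC ambiguity code",
                              object@label[i]))
    if (!het && !all(v$derived %in% c("A", "C", "G", "T", "")))
      msgs <- c(msgs, sprintf("homoplasmic entry '%s' must use a plain base or deletion",
                              object@label[i]))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a [PathogenicCatalog-class]
#'
#' @param label entry labels.
#' @param variant variant strings (space-separated tokens for multi-variant
#'   entries).
#' @param mode `"homoplasmic"`/`"heteroplasmic"` per entry.
#' @return a validated [PathogenicCatalog-class].
#' @export
pathogenicCatalog <- function(label, variant, mode) {
  tokens <- lapply(variant, function(s) variantTokens(variants(parseHaplotype(s))))
  obj <- new("PathogenicCatalog", label = as.character(label), tokens = tokens,
             mode = as.character(mode))
  validObject(obj)
  obj
}

#' @rdname PathogenicCatalog-class
#' @param object a [PathogenicCatalog-class]
#' @export
setGeneric("catalogLabels", function(object) standardGeneric("catalogLabels"))
#' @rdname PathogenicCatalog-class
#' @export
setMethod("catalogLabels", "PathogenicCatalog", function(object) object@label)

setMethod("show", "PathogenicCatalog", function(object) {
  cat(sprintf("PathogenicCatalog | %d entries (%d homoplasmic, %d heteroplasmic)\n",
              length(object@label), sum(object@mode == "homoplasmic"),
              sum(object@mode == "heteroplasmic")))
})

#' Read a pathogenic catalog from TSV
#'
#' Expected columns: `label`, `variant`, `mode`. The bundled fixture
#' `system.file("extdata", "pathogenic_catalog.tsv", package = "mitophylo")`
#' transcribes the published confirmed-pathogenic screening list.
#'
#' @param path TSV file; defaults to the bundled fixture.
#' @return a [PathogenicCatalog-class].
#' @export
readPathogenicCatalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pathogenic_catalog.tsv", package = "mitophylo")
  df <- read.delim(path, stringsAsFactors = FALSE)
  pathogenicCatalog(df$label, df$variant, df$mode)
}

#' Screen a haplotype against the catalog
#'
#' A hit requires every token of an entry to match exactly by (position,
#' kind, derived allele): a homoplasmic `14484C` entry does not hit a
#' haplotype carrying the heteroplasmic `14484Y`, and vice versa. With
#' `permissive = TRUE` a heteroplasmic catalog code also hits a homoplasmic
#' call on any base of its IUPAC set (e.g. `3243R` hits `3243G`).
#'
#' @param h a [Haplotype-class].
#' @param catalog a [PathogenicCatalog-class].
#' @param permissive relax heteroplasmic matching as described.
#' @return `list(subjectId, hits = <labels>, isMpc)`; `isMpc` is `TRUE` for
#'   multi-pathogen-carrying profiles (two or more distinct hits).
#' @export
screenHaplotype <- function(h, catalog, permissive = FALSE) {
  tok <- haplotypeTokens(h)
  hits <- character(0)
  for (i in seq_along(catalog@label)) {
    entry <- catalog@tokens[[i]]
    ok <- all(entry %in% tok)
    if (!ok && permissive && catalog@mode[i] == "heteroplasmic") {
      ok <- all(vapply(entry, function(t) {
        v <- .parseToken(t)
        if (v$kind != "sub") return(t %in% tok)
        any(paste0(v$position, IUPAC_CODES[[v$derived]]) %in% tok) || t %in% tok
      }, logical(1)))
    }
    if (ok) hits <- c(hits, catalog@label[i])
  }
  list(subjectId = sampleId(h), hits = hits, isMpc = length(hits) >= 2)
}

#' Mask catalog variants out of a tree's branch motifs
#'
#' Removes every catalog variant from every branch-defining motif and audits
#' the impact on resolution: per affected haplogroup the removed variant(s)
#' and the remaining motif variants are listed; nodes whose motif becomes
#' empty and sibling pairs whose full signatures become identical are flagged
#' (either event would mean the masking degraded phylogenetic resolution).
#' Masking never alters non-catalog variants and is idempotent.
#'
#' @param tree a [HaplogroupTree-class].
#' @param catalog a [PathogenicCatalog-class].
#' @return `list(tree, audit, flags)`: the masked tree; an audit `data.frame`
#'   (`haplogroup`, `removed`, `remaining`); a flags `data.frame`
#'   (`haplogroup`, `flag`).
#' @export
maskMotifs <- function(tree, catalog) {
  catTok <- unique(unlist(catalog@tokens))
  motifs <- tree@branchVariants
  audit <- list(); flags <- list()
  for (i in seq_along(motifs)) {
    tok <- variantTokens(motifs[[i]])
    hit <- tok %in% catTok
    if (!any(hit)) next
    keep <- motifs[[i]][!formatVariants(motifs[[i]], "bare") %in% catTok, , drop = FALSE]
    audit[[length(audit) + 1L]] <- data.frame(
      haplogroup = tree@nodeName[i],
      removed = paste(tok[hit], collapse = " "),
      remaining = paste(variantTokens(keep), collapse = " "),
      stringsAsFactors = FALSE)
    if (nrow(keep) == 0)
      flags[[length(flags) + 1L]] <- data.frame(
        haplogroup = tree@nodeName[i], flag = "empty motif", stringsAsFactors = FALSE)
    motifs[[i]] <- keep
  }
  masked <- new("HaplogroupTree", nodeName = tree@nodeName,
                nodeParent = tree@nodeParent, branchVariants = motifs,
                macroLabels = tree@macroLabels)
  # resolution audit: identical full signatures among siblings
  sigs <- fullSignatures(masked)
  sigKey <- vapply(sigs, paste, character(1), collapse = " ")
  for (p in unique(tree@nodeParent[!is.na(tree@nodeParent)])) {
    kids <- masked@nodeName[!is.na(masked@nodeParent) & masked@nodeParent == p]
    if (length(kids) < 2) next
    dup <- kids[duplicated(sigKey[kids]) | duplicated(sigKey[kids], fromLast = TRUE)]
    for (k in dup)
      flags[[length(flags) + 1L]] <- data.frame(
        haplogroup = k, flag = "identical sibling signature", stringsAsFactors = FALSE)
  }
  emptyFlags <- data.frame(haplogroup = character(0), flag = character(0),
                           stringsAsFactors = FALSE)
  emptyAudit <- data.frame(haplogroup = character(0), removed = character(0),
                           remaining = character(0), stringsAsFactors = FALSE)
  list(tree = masked,
       audit = if (length(audit)) do.call(rbind, audit) else emptyAudit,
       flags = if (length(flags)) do.call(rbind, flags) else emptyFlags)
}

#' Screen a cohort and tabulate pathogenic-variant frequencies
#'
#' Per catalog entry the count of positive profiles and its percentage of the
#' cohort (rounded to two decimals, the reporting convention), sorted by
#' occurrence; plus the number and fraction of affected samples and the list
#' of multi-pathogen-carrying (mpc) profiles.
#'
#' @param haplotypes list of [Haplotype-class] objects.
#' @param catalog a [PathogenicCatalog-class].
#' @param permissive passed to [screenHaplotype()].
#' @return `list(frequency, affected, mpc)`.
#' @export
screenCohort <- function(haplotypes, catalog, permissive = FALSE) {
  stopifnot(length(haplotypes) > 0)
  hits <- lapply(haplotypes, screenHaplotype, catalog = catalog,
                 permissive = permissive)
  n <- length(haplotypes)
  perEntry <- vapply(catalog@label, function(lb)
    sum(vapply(hits, function(h) lb %in% h$hits, logical(1))), integer(1))
  freq <- data.frame(label = catalog@label, mode = catalog@mode,
                     variant = vapply(catalog@tokens, paste, character(1), collapse = " "),
                     positive = unname(perEntry),
                     occurrence = sprintf("%.2f%%", round(100 * perEntry / n, 2)),
                     stringsAsFactors = FALSE)
  freq <- freq[order(-freq$positive, freq$label), , drop = FALSE]
  rownames(freq) <- NULL
  nAffected <- sum(vapply(hits, function(h) length(h$hits) > 0, logical(1)))
  mpc <- do.call(rbind, lapply(hits[vapply(hits, `[[`, logical(1), "isMpc")],
    function(h) data.frame(sample_id = h$subjectId,
                           variants = paste(h$hits, collapse = " and "),
                           stringsAsFactors = FALSE)))
  if (is.null(mpc))
    mpc <- data.frame(sample_id = character(0), variants = character(0),
                      stringsAsFactors = FALSE)
  list(frequency = freq,
       affected = data.frame(n = nAffected,
                             fraction = sprintf("%.2f%%", round(100 * nAffected / n, 2)),
                             stringsAsFactors = FALSE),
       mpc = mpc)
}
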