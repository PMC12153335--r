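# Cost-based haplogroup estimation: score a query haplotype against every
# node's full signature; report the best node, its cost, private and missing
# variants, the root path and a deviation category.

#' Weight scheme for cost computation
#'
#' The cost of a candidate haplogroup is the weighted count of unexplained
#' differences: private variants (in the query but not the signature) plus
#' missing motif variants (in the signature but absent from the query at
#' covered, called positions). Defaults are unit weights, substitutions at
#' position 16519 ignored, and indels inside length-heteroplasmy regions
#' ignored on both sides.
#'
#' @param defaultWeight weight applied to any variant without an override.
#' @param overrides named numeric vector; names are bare variant tokens
#'   (`"16189C"`) or positions (`"152"`).
#' @param ignoredPositions substitutions at these positions never count.
#' @param ignoreLHIndels drop indels inside `lhRegions` from both sides.
#' @param lhRegions length-heteroplasmy intervals (default [LH_REGIONS]).
#' @return a weight-scheme list.
#' @export
weightScheme <- function(defaultWeight = 1, overrides = numeric(0),
                         ignoredPositions = 16519L, ignoreLHIndels = TRUE,
                         lhRegions = LH_REGIONS) {
  stopifnot(defaultWeight >= 0, all(overrides >= 0))
  list(defaultWeight = defaultWeight, overrides = overrides,
       ignoredPositions = as.integer(ignoredPositions),
       ignoreLHIndels = isTRUE(ignoreLHIndels), lhRegions = lhRegions)
}

.weightOf <- function(v, w) {
  if (nrow(v) == 0) return(numeric(0))
  tok <- formatVariants(v, "bare")
  out <- rep(w$defaultWeight, nrow(v))
  if (length(w$overrides)) {
    byTok <- w$overrides[tok]
    byPos <- w$overrides[as.character(v$position)]
    out <- ifelse(!is.na(byTok), byTok, ifelse(!is.na(byPos), byPos, out))
  }
  out
}

# drop ignored substitution positions and (optionally) LH-region indels
.effective <- function(v, w) {
  keep <- !(v$kind == "sub" & v$position %in% w$ignoredPositions)
  if (w$ignoreLHIndels)
    keep <- keep & !(v$kind != "sub" & .inRegions(v$position, w$lhRegions))
  v[keep, , drop = FALSE]
}

#' @title ClassificationResult: one sample's haplogroup estimate
#' @description Returned by [classifyHaplotype()].
#' @slot sampleId sample identifier.
#' @slot haplogroup assigned haplogroup name.
#' @slot cost weighted count of unexplained differences.
#' @slot privateVariants,missingVariants variant tables.
#' @slot rootPath names along root -> assigned node.
#' @slot deviation one of minimal/moderate/substantial/extensive.
#' @export
setClass("ClassificationResult",
  representation(sampleId = "character", haplogroup = "character",
                 cost = "numeric", privateVariants = "data.frame",
                 missingVariants = "data.frame", rootPath = "character",
                 deviation = "character"))

setMethod("show", "ClassificationResult", function(object) {
  cat(sprintf("'%s' -> %s | cost %.2f (%s) | %d private, %d missing\n",
              object@sampleId, object@haplogroup, object@cost, object@deviation,
              nrow(object@privateVariants), nrow(object@missingVariants)))
  if (nrow(object@privateVariants))
    cat("  private:", paste(formatVariants(object@privateVariants, "bare"), collapse = " "), "\n")
  if (nrow(object@missingVariants))
    cat("  missing:", paste(formatVariants(object@missingVariants, "bare"), collapse = " "), "\n")
})

#' Score a query haplotype against one signature
#'
#' `private` are query variants not explained by the signature, `missing` are
#' signature variants absent from the query at covered, called positions. An
#' ambiguity (heteroplasmy) call in the query whose IUPAC set contains the
#' expected signature allele satisfies the motif at zero cost; an ambiguity
#' containing only unexpected alleles leaves the signature variant missing and
#' the query variant private.
#'
#' @param query a [Haplotype-class].
#' @param signature a [Haplotype-class] (typically from [fullSignature()]) or
#'   a character vector of bare tokens.
#' @param w a [weightScheme()].
#' @return `list(cost, private, missing)` with variant tables.
#' @export
scoreNode <- function(query, signature, w = weightScheme()) {
  sig <- if (is(signature, "Haplotype")) signature@variants
         else if (is.data.frame(signature)) signature
         else parseVariants(signature)
  q <- .effective(query@variants, w)
  s <- .effective(sig, w)
  qKey <- variantKey(q); sKey <- variantKey(s)

  qMatched <- rep(FALSE, nrow(q)); sMatched <- rep(FALSE, nrow(s))
  hit <- match(sKey, qKey)
  for (i in which(!is.na(hit))) {
    j <- hit[i]
    qa <- q$derived[j]; sa <- s$derived[i]
    ok <- qa == sa ||
      (q$kind[j] != "del" && qa %in% AMBIGUITY_LETTERS && sa %in% IUPAC_CODES[[qa]])
    if (ok) { qMatched[j] <- TRUE; sMatched[i] <- TRUE }
  }
  private <- q[!qMatched, , drop = FALSE]
  missing <- s[!sMatched, , drop = FALSE]
  if (nrow(missing)) {
    callable <- missing$position >= query@coveredStart &
      missing$position <= query@coveredEnd &
      !missing$position %in% query@unknownPositions
    missing <- missing[callable, , drop = FALSE]
  }
  cost <- sum(.weightOf(private, w)) + sum(.weightOf(missing, w))
  list(cost = cost, private = private, missing = missing)
}

#' Deviation category of a cost value
#'
#' Bins partition the nonnegative axis: minimal `[0, 10]`, moderate
#' `(10, 30]`, substantial `(30, 50]`, extensive `(50, Inf)`.
#'
#' @param cost numeric vector of nonnegative costs.
#' @return character vector of categories.
#' @export
deviationCategory <- function(cost) {
  if (any(cost < 0)) stop("cost must be nonnegative")
  ifelse(cost <= 10, "minimal",
  ifelse(cost <= 30, "moderate",
  ifelse(cost <= 50, "substantial", "extensive")))
}

#' Estimate the haplogroup of a query haplotype
#'
#' Scores the query against every node's full signature (exhaustive scan) and
#' returns the minimum-cost node; ties break toward the deeper node, then the
#' lexicographically smaller name.
#'
#' @param query a [Haplotype-class].
#' @param tree a [HaplogroupTree-class].
#' @param w a [weightScheme()].
#' @param sigs optional precomputed [fullSignatures()] (named token list),
#'   reused across queries.
#' @return a [ClassificationResult-class].
#' @export
classifyHaplotype <- function(query, tree, w = weightScheme(), sigs = NULL) {
  span <- query@coveredEnd - query@coveredStart + 1L
  if (nrow(query@variants) == 0 && length(query@unknownPositions) >= span)
    stop("uninformative profile: no called variants and no covered positions")
  if (is.null(sigs)) sigs <- fullSignatures(tree)
  prep <- .prepareSignatures(sigs, w)
  depths <- nodeDepths(tree)

  qEff <- .effective(query@variants, w)
  qTok <- formatVariants(qEff, "bare")
  qKey <- variantKey(qEff)
  qW <- .weightOf(qEff, w)

  best <- NULL
  for (name in names(prep)) {
    sEff <- prep[[name]]
    cost <- .fastCost(qEff, qTok, qKey, qW, sEff, query, w)
    cand <- list(name = name, cost = cost, depth = depths[[name]])
    if (is.null(best) || cost < best$cost ||
        (cost == best$cost && (cand$depth > best$depth ||
          (cand$depth == best$depth && name < best$name))))
      best <- cand
  }
  sc <- scoreNode(query, prep[[best$name]], w)
  new("ClassificationResult", sampleId = query@sampleId, haplogroup = best$name,
      cost = sc$cost, privateVariants = sc$private, missingVariants = sc$missing,
      rootPath = rootPath(tree, best$name),
      deviation = deviationCategory(sc$cost))
}

# Parse signature token lists once and apply the ignore rules; the prepared
# list carries a marker attribute so repeated calls are free.
.prepareSignatures <- function(sigs, w) {
  if (isTRUE(attr(sigs, "prepared"))) return(sigs)
  out <- lapply(sigs, function(tok) .effective(parseVariants(tok), w))
  attr(out, "prepared") <- TRUE
  out
}

# Token-level cost; mirrors scoreNode but avoids rebuilding query structures.
.fastCost <- function(qEff, qTok, qKey, qW, sEff, query, w) {
  sKey <- variantKey(sEff)
  hit <- match(sKey, qKey)
  sMatched <- rep(FALSE, nrow(sEff)); qMatched <- rep(FALSE, nrow(qEff))
  for (i in which(!is.na(hit))) {
    j <- hit[i]
    qa <- qEff$derived[j]; sa <- sEff$derived[i]
    ok <- qa == sa ||
      (qEff$kind[j] != "del" && qa %in% AMBIGUITY_LETTERS && sa %in% IUPAC_CODES[[qa]])
    if (ok) { qMatched[j] <- TRUE; sMatched[i] <- TRUE }
  }
  miss <- sEff[!sMatched, , drop = FALSE]
  if (nrow(miss)) {
    callable <- miss$position >= query@coveredStart &
      miss$position <= query@coveredEnd &
      !miss$position %in% query@unknownPositions
    miss <- miss[callable, , drop = FALSE]
  }
  sum(qW[!qMatched]) + sum(.weightOf(miss, w))
}

#' Classify a batch of haplotypes
#'
#' @param queries list of [Haplotype-class] objects.
#' @param tree a [HaplogroupTree-class].
#' @param w a [weightScheme()].
#' @return a `data.frame` with one row per sample: `sample_id`, `haplogroup`,
#'   `cost`, `n_private`, `private`, `n_missing`, `missing`, `deviation`,
#'   `phylopath`.
#' @export
classifyCohort <- function(queries, tree, w = weightScheme()) {
  sigs <- .prepareSignatures(fullSignatures(tree), w)
  rows <- lapply(queries, function(q) {
    r <- classifyHaplotype(q, tree, w, sigs = sigs)
    data.frame(sample_id = r@sampleId, haplogroup = r@haplogroup, cost = r@cost,
               n_private = nrow(r@privateVariants),
               private = paste(formatVariants(r@privateVariants, "bare"), collapse = " "),
               n_missing = nrow(r@missingVariants),
               missing = paste(formatVariants(r@missingVariants, "bare"), collapse = " "),
               deviation = r@deviation,
               phylopath = phylopath(tree, r@haplogroup),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize costs and private-variant loads
#'
#' Overall and per-group mean/median/sd of cost and private-variant counts,
#' plus deviation-category counts, in the layout of cohort-level QC reporting.
#'
#' @param results `data.frame` from [classifyCohort()] (needs `cost`,
#'   `n_private`, `deviation`, and `haplogroup` for macro grouping).
#' @param tree optional [HaplogroupTree-class]; when given, a per-
#'   macrohaplogroup breakdown is included.
#' @return `list(overall, byDeviation, byMacro)` of `data.frame`s.
#' @export
summarizeCosts <- function(results, tree = NULL) {
  stopifnot(nrow(results) > 0)
  stat <- function(df, label) {
    data.frame(group = label, n = nrow(df),
               mean_cost = mean(df$cost), median_cost = median(df$cost),
               sd_cost = if (nrow(df) > 1) sd(df$cost) else NA_real_,
               mean_private = mean(df$n_private),
               median_private = median(df$n_private),
               sd_private = if (nrow(df) > 1) sd(df$n_private) else NA_real_,
               stringsAsFactors = FALSE)
  }
  overall <- stat(results, "overall")
  lev <- c("minimal", "moderate", "substantial", "extensive")
  byDev <- do.call(rbind, lapply(lev, function(l) {
    df <- results[results$deviation == l, , drop = FALSE]
    if (nrow(df) == 0)
      return(data.frame(group = l, n = 0L, mean_cost = NA_real_,
                        median_cost = NA_real_, sd_cost = NA_real_,
                        mean_private = NA_real_, median_private = NA_real_,
                        sd_private = NA_real_, stringsAsFactors = FALSE))
    stat(df, l)
  }))
  byMacro <- NULL
  if (!is.null(tree)) {
    mac <- vapply(results$haplogroup, function(h) macrohaplogroup(tree, h), character(1))
    byMacro <- do.call(rbind, lapply(sort(unique(mac)), function(m)
      stat(results[mac == m, , drop = FALSE], m)))
  }
  list(overall = overall, byDeviation = byDev, byMacro = byMacro)
}
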