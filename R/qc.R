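# Sample-level quality control: inclusion/exclusion criteria and the
# accounting report.

#' Quality-control configuration
#'
#' Criteria are strict inequalities: a sample with exactly 30 Ns or exactly
#' 16 519 bp is retained. The cost threshold appears in the literature both as
#' 500 (methods-level screen) and 100 (report-level accounting); the default
#' is 500 and the alternative is a plain argument, neither is hard-coded as
#' truth.
#'
#' @param maxUnknown maximal tolerated `N` count (exclude when above).
#' @param minLength minimal sequence length in called bases.
#' @param maxAmbiguous maximal tolerated count of non-ACGTN IUPAC symbols.
#' @param maxMissing maximal tolerated count of internal coverage gaps (`-`).
#' @param maxCost maximal tolerated classification cost.
#' @param blocklist sequence identifiers excluded a priori.
#' @param referenceIds identifiers of reference sequences (excluded).
#' @param excludeTaxa organism labels (non-Homo-sapiens subspecies) excluded.
#' @return a configuration list.
#' @export
qcConfig <- function(maxUnknown = 30L, minLength = 16519L, maxAmbiguous = 30L,
                     maxMissing = 50L, maxCost = 500, blocklist = character(0),
                     referenceIds = character(0), excludeTaxa = character(0)) {
  stopifnot(maxUnknown > 0, minLength > 0, maxAmbiguous > 0, maxCost > 0)
  list(maxUnknown = as.integer(maxUnknown), minLength = as.integer(minLength),
       maxAmbiguous = as.integer(maxAmbiguous), maxMissing = as.integer(maxMissing),
       maxCost = maxCost, blocklist = blocklist, referenceIds = referenceIds,
       excludeTaxa = excludeTaxa)
}

# fixed criterion order: attribution of multi-reason samples is reproducible
QC_CRITERIA <- c("blocklist", "unknown>30", "length<16519", "ambiguous>30",
                 "missing>50", "cost", "taxon", "reference")

.verdictRow <- function(id, reasons, counts) {
  data.frame(sample_id = id, included = length(reasons) == 0,
             reasons = paste(reasons, collapse = ";"),
             n_unknown = counts[["unknown"]], length = counts[["length"]],
             n_ambiguous = counts[["ambiguous"]], n_missing = counts[["missing"]],
             cost = counts[["cost"]], stringsAsFactors = FALSE)
}

#' Quality-control verdict for one sequence record
#'
#' Evaluates every criterion (no short-circuiting) so the verdict's reason
#' list is complete: blocklist membership, `N` count, called length, count of
#' ambiguous (non-ACGTN IUPAC) symbols, count of internal gap characters,
#' organism label, reference-sequence identifiers. Cost-based exclusion is a
#' separate step ([qcCost()]) because it needs a classification first.
#'
#' @param seq preprocessed sequence string (see [preprocessSequence()]).
#' @param id sequence identifier.
#' @param organism optional organism label from the metadata.
#' @param cfg a [qcConfig()].
#' @return a one-row verdict `data.frame` (`included`, semicolon-joined
#'   `reasons`, and the measured counts).
#' @export
qcSequence <- function(seq, id, organism = NA_character_, cfg = qcConfig()) {
  s <- toupper(seq)
  nUnknown <- lengths(regmatches(s, gregexpr("N", s, fixed = TRUE)))
  nMissing <- lengths(regmatches(s, gregexpr("-", s, fixed = TRUE)))
  nAmb <- lengths(regmatches(s, gregexpr("[RYSWKMBDHV]", s)))
  len <- nchar(s) - nMissing
  reasons <- character(0)
  if (id %in% cfg$blocklist) reasons <- c(reasons, "blocklist")
  if (nUnknown > cfg$maxUnknown) reasons <- c(reasons, "unknown>30")
  if (len < cfg$minLength) reasons <- c(reasons, "length<16519")
  if (nAmb > cfg$maxAmbiguous) reasons <- c(reasons, "ambiguous>30")
  if (nMissing > cfg$maxMissing) reasons <- c(reasons, "missing>50")
  if (!is.na(organism) && organism %in% cfg$excludeTaxa)
    reasons <- c(reasons, "taxon")
  if (id %in% cfg$referenceIds) reasons <- c(reasons, "reference")
  .verdictRow(id, reasons, list(unknown = nUnknown, length = len,
                                ambiguous = nAmb, missing = nMissing,
                                cost = NA_real_))
}

#' Cost-based quality-control verdict
#'
#' @param result a [ClassificationResult-class] (or a list with `sampleId`
#'   and `cost`).
#' @param cfg a [qcConfig()].
#' @return a one-row verdict `data.frame`; excluded iff `cost > maxCost`.
#' @export
qcCost <- function(result, cfg = qcConfig()) {
  cost <- if (is(result, "ClassificationResult")) result@cost else result$cost
  id <- if (is(result, "ClassificationResult")) result@sampleId else result$sampleId
  reasons <- if (cost > cfg$maxCost) "cost" else character(0)
  .verdictRow(id, reasons, list(unknown = NA_integer_, length = NA_integer_,
                                ambiguous = NA_integer_, missing = NA_integer_,
                                cost = cost))
}

#' Merge sequence-level and cost-level verdicts for the same sample
#'
#' @param seqVerdict,costVerdict one-row verdict `data.frame`s.
#' @return a merged one-row verdict with reasons in canonical criterion order.
#' @export
combineVerdicts <- function(seqVerdict, costVerdict) {
  reasons <- c(strsplit(seqVerdict$reasons, ";")[[1]],
               strsplit(costVerdict$reasons, ";")[[1]])
  reasons <- intersect(QC_CRITERIA, reasons)
  out <- seqVerdict
  out$cost <- costVerdict$cost
  out$reasons <- paste(reasons, collapse = ";")
  out$included <- length(reasons) == 0
  out
}

#' Quality-control accounting report
#'
#' Per-criterion exclusion counts plus the total excluded and retained. A
#' sample triggering several criteria is attributed to the FIRST one in the
#' fixed order blocklist, Ns, length, ambiguity, missing, cost, taxon,
#' reference, so the per-criterion counts sum exactly to the number excluded
#' (conservation: retained + excluded = batch size). The verdict rows still
#' list every triggered criterion.
#'
#' @param verdicts `data.frame` of verdict rows ([qcSequence()] /
#'   [combineVerdicts()]).
#' @return a `data.frame` with one row per criterion, a `Sum` row and a
#'   `Retained` row.
#' @export
qcReport <- function(verdicts) {
  stopifnot(nrow(verdicts) > 0)
  first <- vapply(strsplit(verdicts$reasons, ";"), function(r)
    if (length(r) == 0 || !nzchar(r[1])) NA_character_ else r[1], character(1))
  counts <- vapply(QC_CRITERIA, function(cr) sum(first == cr, na.rm = TRUE), integer(1))
  excluded <- sum(!verdicts$included)
  retained <- sum(verdicts$included)
  stopifnot(sum(counts) == excluded, retained + excluded == nrow(verdicts))
  rbind(
    data.frame(criterion = QC_CRITERIA, count = unname(counts), stringsAsFactors = FALSE),
    data.frame(criterion = "Sum", count = excluded, stringsAsFactors = FALSE),
    data.frame(criterion = "Retained", count = retained, stringsAsFactors = FALSE))
}
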