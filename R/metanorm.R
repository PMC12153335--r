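# Metadata normalization: geographic origin cleanup and sequencing-technology
# grouping.

#' Build an alias map for geographic normalization
#'
#' The map has three parts: misspelling/synonym corrections (raw label ->
#' canonical country, e.g. "Finlnad" -> "Finland", "Eire" -> "Ireland"),
#' nonspecific descriptors to drop (e.g. "East-Africa"), and the canonical
#' country list that valid values must come from. The bundled seed files are
#' editable TSVs; the full correction dictionary of any given study is a
#' replaceable input, not ground truth.
#'
#' @param correctionsPath TSV with columns `raw`, `canonical` (an empty
#'   canonical marks a nonspecific descriptor).
#' @param countriesPath text file with one canonical country per line.
#' @return `list(corrections, drop, countries)`.
#' @export
readAliasMap <- function(correctionsPath = NULL, countriesPath = NULL) {
  if (is.null(correctionsPath))
    correctionsPath <- system.file("extdata", "geo_aliases.tsv", package = "mitophylo")
  if (is.null(countriesPath))
    countriesPath <- system.file("extdata", "countries.txt", package = "mitophylo")
  df <- read.delim(correctionsPath, stringsAsFactors = FALSE)
  df$canonical[is.na(df$canonical)] <- ""
  countries <- readLines(countriesPath)
  countries <- countries[nzchar(trimws(countries))]
  list(corrections = setNames(df$canonical[nzchar(df$canonical)],
                              df$raw[nzchar(df$canonical)]),
       drop = df$raw[!nzchar(df$canonical)],
       countries = countries)
}

#' Normalize a geographic-origin label
#'
#' Exact alias hits map to their canonical country; listed nonspecific
#' descriptors, empty values and unmapped values resolve to `"unresolved"`
#' (unmapped values pass through only when already canonical). Normalization
#' is idempotent. Matching is case-insensitive on the raw side.
#'
#' @param raw character vector of raw geographic labels.
#' @param aliases an alias map from [readAliasMap()].
#' @return character vector of canonical countries or `"unresolved"`, with an
#'   attribute `"log"` listing the values that failed to resolve.
#' @export
normalizeGeography <- function(raw, aliases = readAliasMap()) {
  x <- trimws(raw)
  out <- character(length(x))
  lowCorr <- setNames(unname(aliases$corrections), tolower(names(aliases$corrections)))
  lowDrop <- tolower(aliases$drop)
  lowCty <- tolower(aliases$countries)
  unresolved <- character(0)
  for (i in seq_along(x)) {
    v <- x[i]; lv <- tolower(v)
    if (!nzchar(v) || is.na(v)) { out[i] <- "unresolved"; next }
    if (lv %in% names(lowCorr)) { out[i] <- lowCorr[[lv]]; next }
    if (lv %in% lowDrop) { out[i] <- "unresolved"; next }
    hit <- match(lv, lowCty)
    if (!is.na(hit)) { out[i] <- aliases$countries[hit]; next }
    out[i] <- "unresolved"
    unresolved <- c(unresolved, v)
  }
  attr(out, "log") <- unique(unresolved)
  out
}

# platform dictionary: raw spellings -> grouped category
.TECH_GROUPS <- list(
  "Illumina" = c("illumina", "hiseq", "miseq", "nextseq", "novaseq", "illumina hiseq",
                 "illumina miseq"),
  "Sanger" = c("sanger", "sanger dideoxy sequencing", "abi", "capillary"),
  "IonTorrent" = c("iontorrent", "ion torrent", "ion_torrent", "ion torrent pgm"),
  "Roche 454" = c("454", "roche 454", "roche454", "roche"),
  "Other" = c("pacbio", "pacific biosciences", "oxford nanopore", "nanopore",
              "oxford_nanopore", "helicos", "solid", "bgiseq", "complete genomics")
)

.techCategory <- function(platform) {
  lv <- tolower(trimws(platform))
  if (!nzchar(lv)) return("No data")
  for (cat in names(.TECH_GROUPS))
    if (lv %in% .TECH_GROUPS[[cat]]) return(cat)
  "No data"
}

#' Group a sequencing-technology annotation
#'
#' A single recognized platform maps to its category (Illumina, Sanger,
#' IonTorrent, Roche 454, or Other for long-read/minor platforms such as
#' PacBio and Oxford Nanopore). Samples sequenced with multiple technologies
#' (semicolon-separated, e.g. `"Illumina;IonTorrent"`) are grouped under the
#' first-listed platform's category and starred: `"Illumina*"`. Empty or
#' unrecognized annotations yield `"No data"`.
#'
#' @param raw character vector of raw technology annotations.
#' @return character vector of grouped categories.
#' @export
groupTechnology <- function(raw) {
  vapply(raw, function(v) {
    if (is.na(v) || !nzchar(trimws(v))) return("No data")
    parts <- strsplit(v, ";", fixed = TRUE)[[1]]
    cat <- .techCategory(parts[1])
    if (cat == "No data") return("No data")
    if (length(parts) > 1) paste0(cat, "*") else cat
  }, character(1), USE.NAMES = FALSE)
}

#' Tabulate grouped technology categories
#'
#' @param categories character vector from [groupTechnology()].
#' @return a `data.frame` of counts per category plus a `Sum` row; the counts
#'   always sum to the batch size.
#' @export
summarizeTechnology <- function(categories) {
  lev <- c("Illumina", "Illumina*", "Sanger", "Sanger*", "IonTorrent",
           "IonTorrent*", "Roche 454", "Roche 454*", "Other", "Other*", "No data")
  lev <- c(lev[lev %in% categories], setdiff(unique(categories), lev))
  counts <- vapply(lev, function(l) sum(categories == l), integer(1))
  rbind(data.frame(technology = lev, count = unname(counts), stringsAsFactors = FALSE),
        data.frame(technology = "Sum", count = length(categories), stringsAsFactors = FALSE))
}

#' Normalize a metadata table
#'
#' @param meta `data.frame` with columns `id`, `geo_raw`, `tech_raw`.
#' @param aliases alias map from [readAliasMap()].
#' @return the table with added `country` and `tech_category` columns.
#' @export
normalizeMetadata <- function(meta, aliases = readAliasMap()) {
  stopifnot(all(c("id", "geo_raw", "tech_raw") %in% names(meta)))
  meta$country <- as.character(normalizeGeography(meta$geo_raw, aliases))
  meta$tech_category <- groupTechnology(meta$tech_raw)
  meta
}
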