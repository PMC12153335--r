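# Tree exchange formats: hierarchical JSON {name, variants, children},
# flat full-signature JSON, and Newick (names only).

.treeToList <- function(tree, name) {
  kids <- childrenOf(tree, name)
  list(name = name,
       variants = as.list(variantTokens(branchMotif(tree, name))),
       children = lapply(kids, function(k) .treeToList(tree, k)))
}

#' Write / read the hierarchical tree JSON
#'
#' Canonical, byte-stable rendering: fixed key order (`name`, `variants`,
#' `children`), canonically sorted variant tokens, children in insertion
#' order. Reading validates the schema (each object must carry exactly those
#' keys with the right types).
#'
#' @param tree a [HaplogroupTree-class].
#' @param path output file; when `NULL` the JSON string is returned.
#' @return `writeTreeJSON`: the JSON string (invisibly when written to file).
#' @export
writeTreeJSON <- function(tree, path = NULL) {
  json <- jsonlite::toJSON(.treeToList(tree, rootName(tree)),
                           auto_unbox = TRUE, null = "list")
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(as.character(json))
}

.validateNodeList <- function(x, where = "root") {
  if (!is.list(x) || !all(c("name", "variants", "children") %in% names(x)))
    stop(sprintf("tree JSON schema violation at %s: need keys name/variants/children", where))
  if (!is.character(x$name) || length(x$name) != 1)
    stop(sprintf("tree JSON schema violation at %s: name must be a string", where))
  invisible(TRUE)
}

#' @rdname writeTreeJSON
#' @param input file path or JSON string.
#' @param macroLabels passed to [haplogroupTree()].
#' @return `readTreeJSON`: a [HaplogroupTree-class].
#' @export
readTreeJSON <- function(input, macroLabels = MACRO_LABELS) {
  isJson <- grepl("^\\s*[{]", input[1])
  txt <- if (!isJson && file.exists(input[1]))
    paste(readLines(input), collapse = "\n") else input
  x <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  names_ <- character(0); parents_ <- character(0); motifs_ <- list()
  walk <- function(node, parent) {
    .validateNodeList(node, where = if (is.na(parent)) "root" else parent)
    names_ <<- c(names_, node$name)
    parents_ <<- c(parents_, parent)
    tokens <- unlist(node$variants)
    motifs_[[length(motifs_) + 1L]] <<-
      if (length(tokens)) parseVariants(as.character(tokens)) else emptyVariants()
    for (ch in node$children) walk(ch, node$name)
  }
  walk(x, NA_character_)
  haplogroupTree(names_, parents_, motifs_, macroLabels = macroLabels)
}

#' Write the flat full-signature JSON export
#'
#' A single JSON object mapping every haplogroup name to its space-joined full
#' signature (all variants defining the haplogroup relative to the rCRS).
#'
#' @param tree a [HaplogroupTree-class].
#' @param path output file; when `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when written to file).
#' @export
writeSignaturesJSON <- function(tree, path = NULL) {
  sigs <- fullSignatures(tree)
  flat <- lapply(sigs, function(tok) paste(tok, collapse = " "))
  json <- as.character(jsonlite::toJSON(flat, auto_unbox = TRUE))
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

.newickLabel <- function(name) {
  if (grepl("[][ ():;,']", name))
    paste0("'", gsub("'", "''", name), "'")
  else name
}

#' Write the tree in Newick format
#'
#' Newick has no variant field, so only names are encoded; with
#' `comments = TRUE` each label is followed by a `[&motif=...]` comment
#' carrying the branch motif tokens.
#'
#' @param tree a [HaplogroupTree-class].
#' @param path output file; when `NULL` the Newick string is returned.
#' @param comments attach branch motifs as Newick comments.
#' @return the Newick string (invisibly when written to file).
#' @export
writeNewick <- function(tree, path = NULL, comments = FALSE) {
  render <- function(name) {
    kids <- childrenOf(tree, name)
    label <- .newickLabel(name)
    if (comments) {
      tok <- variantTokens(branchMotif(tree, name))
      if (length(tok)) label <- paste0(label, "[&motif=", paste(tok, collapse = " "), "]")
    }
    if (length(kids) == 0) return(label)
    paste0("(", paste(vapply(kids, render, character(1)), collapse = ","), ")", label)
  }
  nwk <- paste0(render(rootName(tree)), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}
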