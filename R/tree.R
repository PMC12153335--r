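# Haplogroup tree: named nodes carrying branch-defining motifs, rooted at the
# mt-MRCA; full signatures accumulate from the root down.

#' Default macrohaplogroup labels
#'
#' The 35 top-level clade labels used for macrohaplogroup clustering
#' (R+16189 is the clade often designated haplogroup B).
#' @export
MACRO_LABELS <- c("A", "C", "D", "E", "F", "G", "H", "HV", "I", "J", "K",
                  "L0", "L1", "L2", "L3", "L4", "L5", "L6", "L7",
                  "M", "N", "O", "P", "Q", "R", "R+16189", "R0",
                  "S", "T", "U", "V", "W", "X", "Y", "Z")

#' @title HaplogroupTree: the named mtDNA phylogeny
#'
#' @description Nodes are stored in insertion order; each node carries the
#' branch-defining motif (its own variants relative to the parent). The root
#' ("mt-MRCA") has an empty motif. Names are unique tree-wide.
#'
#' @slot nodeName character vector of node names (root first).
#' @slot nodeParent parent name per node (`NA` for the root).
#' @slot branchVariants list of variant tables, parallel to `nodeName`.
#' @slot macroLabels macrohaplogroup label set used by the clustering helpers.
#' @export
setClass("HaplogroupTree",
  representation(nodeName = "character", nodeParent = "character",
                 branchVariants = "list", macroLabels = "character"))

setValidity("HaplogroupTree", function(object) {
  nm <- object@nodeName; pa <- object@nodeParent
  msgs <- character(0)
  if (length(nm) == 0) return("tree needs at least a root node")
  if (anyDuplicated(nm)) msgs <- c(msgs, "node names must be unique tree-wide")
  roots <- which(is.na(pa))
  if (length(roots) != 1) msgs <- c(msgs, "exactly one root (parent NA) required")
  if (length(object@branchVariants) != length(nm))
    msgs <- c(msgs, "one branch motif per node required")
  known <- pa[!is.na(pa)] %in% nm
  if (!all(known)) msgs <- c(msgs, "every parent must be a node of the tree")
  if (length(roots) == 1 && nrow(object@branchVariants[[roots]]) > 0)
    msgs <- c(msgs, "the root carries an empty branch motif")
  # acyclicity: climbing from any node must reach the root
  if (length(msgs) == 0) {
    idx <- match(pa, nm)
    for (i in seq_along(nm)) {
      seen <- 0L; j <- i
      while (!is.na(idx[j])) {
        j <- idx[j]; seen <- seen + 1L
        if (seen > length(nm)) return("parent links contain a cycle")
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a [HaplogroupTree-class]
#'
#' @param names node names, root first.
#' @param parents parent name per node (`NA` for the root).
#' @param motifs list parallel to `names`: variant tables or motif strings
#'   (parsed with [parseVariants()]).
#' @param macroLabels macrohaplogroup label set (default [MACRO_LABELS]).
#' @param rootName convenience: when `names` is missing, builds a root-only tree.
#' @return a validated [HaplogroupTree-class].
#' @export
haplogroupTree <- function(names = "mt-MRCA", parents = NA_character_,
                           motifs = NULL, macroLabels = MACRO_LABELS,
                           rootName = "mt-MRCA") {
  if (is.null(motifs)) motifs <- rep(list(emptyVariants()), length(names))
  motifs <- lapply(motifs, function(m) {
    if (is.character(m))
      m <- if (length(m) == 1 && (grepl("[[:space:]]", m) || !nzchar(m)))
        variants(parseHaplotype(m)) else parseVariants(m)
    sortVariants(uniqueVariants(m))
  })
  obj <- new("HaplogroupTree", nodeName = as.character(names),
             nodeParent = as.character(parents), branchVariants = motifs,
             macroLabels = macroLabels)
  validObject(obj)
  obj
}

#' @rdname HaplogroupTree-class
#' @param object,tree a [HaplogroupTree-class]
#' @export
setGeneric("nNodes", function(object) standardGeneric("nNodes"))
#' @rdname HaplogroupTree-class
#' @export
setMethod("nNodes", "HaplogroupTree", function(object) length(object@nodeName))

#' @rdname HaplogroupTree-class
#' @export
setGeneric("nodeNames", function(object) standardGeneric("nodeNames"))
#' @rdname HaplogroupTree-class
#' @export
setMethod("nodeNames", "HaplogroupTree", function(object) object@nodeName)

#' @rdname HaplogroupTree-class
#' @export
setGeneric("rootName", function(object) standardGeneric("rootName"))
#' @rdname HaplogroupTree-class
#' @export
setMethod("rootName", "HaplogroupTree",
          function(object) object@nodeName[is.na(object@nodeParent)])

setMethod("show", "HaplogroupTree", function(object) {
  cat(sprintf("HaplogroupTree | %d node(s) | root '%s' | %d macro label(s)\n",
              nNodes(object), rootName(object), length(object@macroLabels)))
})

.nodeIndex <- function(tree, name) {
  i <- match(name, tree@nodeName)
  if (is.na(i)) stop(sprintf("unknown haplogroup '%s'", name))
  i
}

#' Children of a node, in insertion order
#' @param tree a [HaplogroupTree-class]; @param name node name.
#' @return character vector of child names.
#' @export
childrenOf <- function(tree, name) {
  .nodeIndex(tree, name)
  tree@nodeName[!is.na(tree@nodeParent) & tree@nodeParent == name]
}

#' Parent of a node (`NA` for the root)
#' @inheritParams childrenOf
#' @export
parentOf <- function(tree, name) tree@nodeParent[.nodeIndex(tree, name)]

#' Branch-defining motif of a node
#' @inheritParams childrenOf
#' @return variant table.
#' @export
branchMotif <- function(tree, name) tree@branchVariants[[.nodeIndex(tree, name)]]

#' Names along the root-to-node path
#' @inheritParams childrenOf
#' @return character vector, root first, `name` last.
#' @export
rootPath <- function(tree, name) {
  i <- .nodeIndex(tree, name)
  idx <- match(tree@nodeParent, tree@nodeName)
  path <- integer(0)
  while (!is.na(i)) { path <- c(i, path); i <- idx[i] }
  tree@nodeName[path]
}

#' Names of a node's subtree (node included)
#' @inheritParams childrenOf
#' @export
subtreeNames <- function(tree, name) {
  .nodeIndex(tree, name)
  out <- name; frontier <- name
  while (length(frontier)) {
    kids <- tree@nodeName[tree@nodeParent %in% frontier]
    out <- c(out, kids); frontier <- kids
  }
  out
}

# Apply one branch motif to an accumulated variant table (token replay).
# A back-mutation token with an odd "!" count removes the accumulated variant
# at its position; with no match it is kept literally (with a warning upstream).
# Substitutions replace an earlier substitution at the same position.
.accumulateMotif <- function(acc, motif, nodeName, warnUnmatched = TRUE) {
  for (i in seq_len(nrow(motif))) {
    row <- motif[i, , drop = FALSE]
    if (row$kind == "sub" && row$back %% 2L == 1L) {
      hit <- acc$position == row$position & acc$kind == "sub"
      if (any(hit)) { acc <- acc[!hit, , drop = FALSE]; next }
      if (warnUnmatched)
        warning(sprintf("back mutation '%s' at node '%s' has no ancestral variant; kept literally",
                        formatVariants(row, "bare"), nodeName), call. = FALSE)
      acc <- rbind(acc, row)
    } else if (row$kind == "sub") {
      row$back <- 0L                       # "!!" nets out to the derived state
      hit <- acc$position == row$position & acc$kind == "sub"
      acc <- rbind(acc[!hit, , drop = FALSE], row)
    } else {
      key <- variantKey(row)
      acc <- rbind(acc[variantKey(acc) != key, , drop = FALSE], row)
    }
  }
  acc
}

#' Full signature of a haplogroup
#'
#' Accumulates branch motifs along the root-to-node path: substitutions at an
#' already-variant position replace the earlier allele, and a back-mutation
#' token (trailing `!`) removes the previously accumulated variant at its
#' position (an unmatched back mutation is kept literally, with a warning).
#' A doubled `!!` nets out to the derived state.
#'
#' @param tree a [HaplogroupTree-class].
#' @param name haplogroup name.
#' @return a [Haplotype-class] whose `sampleId` is the haplogroup name.
#' @export
fullSignature <- function(tree, name) {
  path <- rootPath(tree, name)
  acc <- emptyVariants()
  for (nm in path)
    acc <- .accumulateMotif(acc, branchMotif(tree, nm), nm)
  Haplotype(name, acc)
}

#' All full signatures, as canonical token vectors
#'
#' One depth-first pass over the tree; considerably faster than calling
#' [fullSignature()] per node.
#'
#' @param tree a [HaplogroupTree-class].
#' @return named list: haplogroup name -> character vector of bare tokens.
#' @export
fullSignatures <- function(tree) {
  n <- nNodes(tree)
  accs <- vector("list", n)
  names(accs) <- tree@nodeName
  idx <- match(tree@nodeParent, tree@nodeName)
  # nodes are stored with parents before children only by convention; order a
  # traversal explicitly to be safe
  depth <- integer(n)
  for (i in seq_len(n)) {
    d <- 0L; j <- i
    while (!is.na(idx[j])) { j <- idx[j]; d <- d + 1L }
    depth[i] <- d
  }
  for (i in order(depth)) {
    base <- if (is.na(idx[i])) emptyVariants() else accs[[idx[i]]]
    accs[[i]] <- .accumulateMotif(base, tree@branchVariants[[i]],
                                  tree@nodeName[i], warnUnmatched = FALSE)
  }
  lapply(accs, variantTokens)
}

#' Node depths (root = 0)
#' @param tree a [HaplogroupTree-class].
#' @return named integer vector.
#' @export
nodeDepths <- function(tree) {
  idx <- match(tree@nodeParent, tree@nodeName)
  n <- nNodes(tree)
  depth <- integer(n)
  for (i in seq_len(n)) {
    d <- 0L; j <- i
    while (!is.na(idx[j])) { j <- idx[j]; d <- d + 1L }
    depth[i] <- d
  }
  setNames(depth, tree@nodeName)
}

# ---- nomenclature ----------------------------------------------------------

# bijective base-26 letter suffix: 1->a, 26->z, 27->aa, ...
.letterSuffix <- function(k) {
  out <- ""
  while (k > 0) {
    r <- (k - 1) %% 26
    out <- paste0(letters[r + 1], out)
    k <- (k - 1) %/% 26
  }
  out
}

#' Next available subclade name under Phylotree convention
#'
#' Letter and number levels alternate: a parent ending in a digit gets
#' lettered children (`a`, `b`, ..., `z`, `aa`, ...), a parent ending in a
#' letter gets numbered children (`1`, `2`, ...). The smallest suffix not used
#' by any existing node (tree-wide, names being unique) is returned: `W7` with
#' no subclades yields `W7a`; `T2h` with children `T2h1` and `T2h2` yields
#' `T2h3`.
#'
#' @param tree a [HaplogroupTree-class].
#' @param parent parent haplogroup name.
#' @param pending additional names to treat as taken (used during batch
#'   integration).
#' @return the resolved child name.
#' @export
nextAvailableName <- function(tree, parent, pending = character(0)) {
  .nodeIndex(tree, parent)
  taken <- c(tree@nodeName, pending)
  lettered <- grepl("[0-9]$", parent)
  k <- 1L
  repeat {
    cand <- paste0(parent, if (lettered) .letterSuffix(k) else k)
    if (!cand %in% taken) return(cand)
    k <- k + 1L
  }
}

#' Integrate proposed subclades, resolving asterisk nomenclature
#'
#' Each addition names a parent, a branch motif and a proposed name. Proposed
#' names containing `*` (the forensic-update convention for "new, unnamed
#' subclade") are resolved with [nextAvailableName()]. Items are rejected —
#' per item, processing continues — when the proposed name is on the explicit
#' rejection list, the parent is unknown, the resolved name collides, or the
#' motif duplicates an existing sibling's motif.
#'
#' @param tree a [HaplogroupTree-class].
#' @param additions `data.frame` with columns `parent`, `motif` (token string)
#'   and `proposed`.
#' @param reject character vector of proposed names to reject outright (e.g.
#'   entries flagged for excessive private variants).
#' @return `list(tree = <updated tree>, report = <data.frame>)`; the report has
#'   one row per addition with columns `proposed`, `assigned`, `parent`,
#'   `status` (the reassignment-list format).
#' @export
integrateSubclades <- function(tree, additions, reject = character(0)) {
  stopifnot(all(c("parent", "motif", "proposed") %in% names(additions)))
  nm <- tree@nodeName; pa <- tree@nodeParent; mo <- tree@branchVariants
  motifKey <- vapply(mo, function(v) paste(variantTokens(v), collapse = " "), character(1))
  rep_rows <- vector("list", nrow(additions))
  for (i in seq_len(nrow(additions))) {
    proposed <- additions$proposed[i]; parent <- additions$parent[i]
    status <- "integrated"; assigned <- NA_character_
    if (proposed %in% reject) {
      status <- "rejected: flagged"
    } else if (!parent %in% nm) {
      status <- "rejected: unknown parent"
    } else {
      vars <- tryCatch(variants(parseHaplotype(additions$motif[i])),
                       error = function(e) NULL)
      if (is.null(vars)) {
        status <- "rejected: unparseable motif"
      } else {
        key <- paste(variantTokens(vars), collapse = " ")
        sibs <- which(!is.na(pa) & pa == parent)
        if (any(motifKey[sibs] == key)) {
          status <- "rejected: duplicate motif"
        } else {
          assigned <- if (grepl("*", proposed, fixed = TRUE)) {
            lettered <- grepl("[0-9]$", parent)
            k <- 1L
            repeat {
              cand <- paste0(parent, if (lettered) .letterSuffix(k) else k)
              if (!cand %in% nm) break
              k <- k + 1L
            }
            cand
          } else proposed
          if (assigned %in% nm) {
            status <- "rejected: name collision"; assigned <- NA_character_
          } else {
            nm <- c(nm, assigned); pa <- c(pa, parent)
            mo <- c(mo, list(vars)); motifKey <- c(motifKey, key)
          }
        }
      }
    }
    rep_rows[[i]] <- data.frame(proposed = proposed, assigned = assigned,
                                parent = parent, status = status,
                                stringsAsFactors = FALSE)
  }
  out <- new("HaplogroupTree", nodeName = nm, nodeParent = pa,
             branchVariants = mo, macroLabels = tree@macroLabels)
  validObject(out)
  list(tree = out, report = do.call(rbind, rep_rows))
}

# ---- clustering ------------------------------------------------------------

# first-letter(s)+number pattern of first-level split labels, e.g. "M8", "H20"
.isSplitLabel <- function(x) grepl("^[A-Z]+[0-9]+$", x)

#' Macrohaplogroup of a node
#'
#' The nearest ancestor (including the node itself) whose name is a macro
#' label; walking from the node upward makes the deepest matching label win
#' (an H node reports H, not HV, R0 or R). Without any macro ancestor the
#' nearest L-sublabel context is reported (the root-adjacent L-label).
#'
#' @param tree a [HaplogroupTree-class].
#' @param name haplogroup name.
#' @return a macro label.
#' @export
macrohaplogroup <- function(tree, name) {
  path <- rev(rootPath(tree, name))       # node first
  hit <- path[path %in% tree@macroLabels]
  if (length(hit)) return(hit[1])
  lsub <- path[grepl("^L[0-7]", path)]
  if (length(lsub)) substr(lsub[1], 1, 2) else "L"
}

#' First-level split of a node
#'
#' Haplogroups are grouped by their first letter(s)+number label at the
#' shallowest depth below a macro label: `C1b` clusters under `M8` (the split
#' containing the C and CZ clades), `H1a` under `H1`. `starred` is `TRUE` when
#' the cluster's subtree contains nodes whose names do not extend the label
#' (e.g. `M8*` contains C and CZ). Falls back to the macrohaplogroup label
#' when no split label exists on the path.
#'
#' @inheritParams macrohaplogroup
#' @return `list(label = <character>, starred = <logical>)`.
#' @export
firstLevelSplit <- function(tree, name) {
  path <- rootPath(tree, name)            # root first
  cand <- path[.isSplitLabel(path) & !path %in% tree@macroLabels]
  label <- if (length(cand)) cand[1] else macrohaplogroup(tree, name)
  sub <- subtreeNames(tree, label)
  starred <- any(!startsWith(setdiff(sub, label), label))
  list(label = label, starred = starred)
}

#' Major lineage of a node
#'
#' `R` if the root path contains an R node, else `N`, else `M`, else `L`.
#' With `subL = TRUE`, L-lineage nodes report their L0..L7 sublabel.
#'
#' @inheritParams macrohaplogroup
#' @param subL report L0..L7 instead of plain `L` for L-lineage nodes.
#' @return one of `"L"` (`"L0"`..`"L7"`), `"M"`, `"N"`, `"R"`.
#' @export
lineage <- function(tree, name, subL = FALSE) {
  path <- rootPath(tree, name)
  if ("R" %in% path) return("R")
  if ("N" %in% path) return("N")
  if ("M" %in% path) return("M")
  if (subL) {
    mac <- macrohaplogroup(tree, name)
    if (grepl("^L[0-7]$", mac)) return(mac)
  }
  "L"
}

#' Phylogenetic placement string ("phylopath")
#'
#' Hyphen-joined cluster-level labels along the root-to-node path: every
#' ancestor (or the node itself) that is a macro label or matches the
#' first-letter(s)+number split pattern, e.g. `"L3-N-R-R0-HV-H-H3"` for H3 and
#' `"L3-M-M8-C-C1"` for C1b.
#'
#' @inheritParams macrohaplogroup
#' @return the phylopath string.
#' @export
phylopath <- function(tree, name) {
  path <- rootPath(tree, name)
  keep <- path[path %in% tree@macroLabels | .isSplitLabel(path)]
  paste(keep, collapse = "-")
}
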