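# Shared fixtures: built in code at test time.

refSeq <- function() loadReference()

# The published remaining-signature table used by the masking audit tests:
# per haplogroup the branch motif, the catalog variant it carries, and the
# expected remaining motif after masking. The T3 and X2p1 rows of the printed
# table list 11778A inside the remaining set although it is the removed
# variant of those rows; the expectation here follows the stated procedure
# (removal removes the variant), so those two rows are the printed cell minus
# the duplicated token.
maskAuditRows <- function() {
  rows <- list(
    list(hg = "H24a3", patho = "1555G",
         remaining = "2626C 6398T"),
    list(hg = "L5a2a2a", patho = "1555G",
         remaining = "464G 5321T 5460A 5746A 9966A 11182G 16274A 16399G"),
    list(hg = "J1d2b", patho = "11778A",
         remaining = "16311C 16362C 689C 9123A 14040A 14280G"),
    list(hg = "T3", patho = "11778A",
         remaining = "T195C! 1406C 1829G 4225G 11467G 13956G 13980A 15509G 16325C"),
    list(hg = "X2p1", patho = "11778A",
         remaining = "513A 4093G 8645G 9708C 16291T"),
    list(hg = "Q3b", patho = "14484C",
         remaining = "5460A 8454G 9254G A0750G 12684A 16249C 16362C"),
    list(hg = "M27b1", patho = "14674C",
         remaining = "64T 199C 236C 1598A 4775G 5788C 16145A 16223C"),
    list(hg = "J1c1d", patho = "14484Y",
         remaining = "16213A"))
  do.call(rbind, lapply(rows, function(r)
    data.frame(hg = r$hg, patho = r$patho, remaining = r$remaining,
               stringsAsFactors = FALSE)))
}

# Reference-derived fixture tree mirroring the published top-level topology:
# macrohaplogroup nodes, the worked-example clades, and the haplogroups of the
# masking audit with their published branch motifs. Other nodes carry small
# synthetic motifs so signatures stay distinct.
fixtureTree <- function() {
  edges <- list(
    # name              parent              motif
    c("L0",              "mt-MRCA",          "263G 1048T"),
    c("L0a",             "L0",               "5231A"),
    c("L0a2",            "L0a",              "8428C"),
    c("L0a2a",           "L0a2",             "9347G"),
    c("L0a2a2",          "L0a2a",            "10589A"),
    c("L0a2a2a",         "L0a2a2",           "12720C"),
    c("L1'2'3'4'5'6",    "mt-MRCA",          "7146G"),
    c("L1",              "L1'2'3'4'5'6",     "3666A"),
    c("L1c",             "L1",               "6071C"),
    c("L1c2",            "L1c",              "7055G"),
    c("L1c2a",           "L1c2",             "11654G"),
    c("L1c2a1",          "L1c2a",            "12810G"),
    c("L1c2a1a",         "L1c2a1",           "13485G"),
    c("L2'3'4'5'6",      "L1'2'3'4'5'6",     "4104G"),
    c("L2",              "L2'3'4'5'6",       "8206A"),
    c("L2a",             "L2",               "13803G"),
    c("L2a1",            "L2a",              "15784C"),
    c("L2a1b",           "L2a1",             "3918A"),
    c("L2a1b1",          "L2a1b",            "5581G"),
    c("L2a1b1a",         "L2a1b1",           "6722G"),
    c("L3'4'6",          "L2'3'4'5'6",       "9818C"),
    c("L4",              "L3'4'6",           "6915A"),
    c("L4b",             "L4",               "7861C"),
    c("L4b2",            "L4b",              "10373A"),
    c("L4b2a",           "L4b2",             "12416A"),
    c("L4b2a2",          "L4b2a",            "13722G"),
    c("L6",              "L3'4'6",           "14002G"),
    c("L6b",             "L6",               "14143T"),
    c("L5'7",            "L2'3'4'5'6",       "12236A"),
    c("L5",              "L5'7",             "8155A"),
    c("L5a",             "L5",               "9305A"),
    c("L5a2",            "L5a",              "10792G"),
    c("L5a2a",           "L5a2",             "2361A 15826G"),
    c("L5a2a1",          "L5a2a",            "3423C"),
    c("L5a2a1a",         "L5a2a1",           "4561C"),
    c("L5a2a2",          "L5a2a",            "7624A"),
    c("L5a2a2a",         "L5a2a2",
      "1555G 464G 5321T 5460A 5746A 9966A 11182G 16274A 16399G"),
    c("L7",              "L5'7",             "11884G"),
    c("L7a",             "L7",               "12616C"),
    c("L3",              "L3'4'6",           "769A 1018A"),
    c("M",               "L3",               "489C 10400T"),
    c("M5",              "M",                "1888A"),
    c("M27",             "M",                "2157C"),
    c("M27b",            "M27",              "3399C"),
    c("M27b1",           "M27b",
      "14674C 64T 199C 236C 1598A 4775G 5788C 16145A 16223C"),
    c("M7",              "M",                "9824C"),
    c("M7c",             "M7",               "4850T"),
    c("M7c1",            "M7c",              "11665T"),
    c("M7c1c",           "M7c1",             "12091C"),
    c("M7c1c3",          "M7c1c",            "12950G"),
    c("M8",              "M",                "4715G 8684T"),
    c("CZ",              "M8",               "9090C"),
    c("C",               "CZ",               "3552A 9545G"),
    c("C1",              "C",                "9722C"),
    c("C1b",             "C1",               "11151T"),
    c("M9",              "M",                "4491A"),
    c("E",               "M9",               "10834C"),
    c("E1a",             "E",                "6023A"),
    c("E1a1",            "E1a",              "7468C"),
    c("E1a1a",           "E1a1",             "13626G"),
    c("E1a1a1",          "E1a1a",            "14577C"),
    c("Q",               "M",                "5843G"),
    c("Q3",              "Q",                "12061C"),
    c("Q3b",             "Q3",
      "14484C 5460A 8454G 9254G A0750G 12684A 16249C 16362C"),
    c("G",               "M",                "7600A"),
    c("G2",              "G",                "8584A"),
    c("G2b",             "G2",               "10586A"),
    c("G2b1",            "G2b",              "12192T"),
    c("G2b1a",           "G2b1",             "13928C"),
    c("N",               "L3",               "8701G 15301A"),
    c("N1",              "N",                "10238C"),
    c("N1a",             "N1",               "1719A"),
    c("I",               "N1a",              "10034C"),
    c("I2",              "I",                "11065G"),
    c("I4",              "I",                "13780G"),
    c("I4a",             "I4",               "14582G"),
    c("W",               "N",                "1243C"),
    c("W7",              "W",                "9612A"),
    c("X",               "N",                "6221C"),
    c("X2",              "X",                "1438G"),
    c("X2p",             "X2",               "3447G"),
    c("X2p1",            "X2p",
      "11778A 513A 4093G 8645G 9708C 16291T"),
    c("A",               "N",                "4824G"),
    c("A2",              "A",                "8027A"),
    c("A2+ (64)",        "A2",               "64T"),
    c("R",               "N",                "12705T 16223T"),
    c("R0",              "R",                "73G"),
    c("HV",              "R0",               "14766T"),
    c("H",               "HV",               "2706G 7028T"),
    c("H1",              "H",                "3010A"),
    c("H1a",             "H1",               "6365C"),
    c("H3",              "H",                "6776C"),
    c("H24",             "H",                "6152C"),
    c("H24a",            "H24",              "7337A"),
    c("H24a3",           "H24a",             "1555G 2626C 6398T"),
    c("R+16189",         "R",                "16189C"),
    c("B4",              "R+16189",          "5465C"),
    c("B4a",             "B4",               "6620C"),
    c("B4a1",            "B4a",              "10676A"),
    c("B4a1a",           "B4a1",             "11708G"),
    c("B4a1a1",          "B4a1a",            "15746G"),
    c("B4a1a1b",         "B4a1a1",           "16217C"),
    c("U",               "R",                "11467G"),
    c("U2",              "U",                "1811G"),
    c("U2e",             "U2",               "3116T"),
    c("U2e1",            "U2e",              "5390G"),
    c("U2e1b",           "U2e1",             "7768G"),
    c("U5",              "U",                "3197C"),
    c("JT",              "R",                "4216C"),
    c("J",               "JT",               "10398G 13708A"),
    c("J1",              "J",                "462T"),
    c("J1c",             "J1",               "14798C"),
    c("J1c1",            "J1c",              "482C"),
    c("J1c1d",           "J1c1",             "14484Y 16213A"),
    c("J1d",             "J1",               "7963G"),
    c("J1d2",            "J1d",              "12373G"),
    c("J1d2b",           "J1d2",
      "11778A 16311C 16362C 689C 9123A 14040A 14280G"),
    c("T",               "JT",               "709A 1888A"),
    c("T2",              "T",                "11812G"),
    c("T2h",             "T2",               "4767G"),
    c("T2h1",            "T2h",              "5899C"),
    c("T2h2",            "T2h",              "8021C"),
    c("T3",              "T",
      "11778A T195C! 1406C 1829G 4225G 11467G 13956G 13980A 15509G 16325C"))
  nm <- c("mt-MRCA", vapply(edges, `[`, character(1), 1))
  pa <- c(NA_character_, vapply(edges, `[`, character(1), 2))
  mo <- c(list(""), lapply(edges, `[`, 3))
  haplogroupTree(nm, pa, mo)
}

table8Catalog <- function() {
  pathogenicCatalog(
    label = c("Homo3", "Homo28", "Homo34", "Homo36", "Hetero76"),
    variant = c("1555G", "11778A", "14484C", "14674C", "14484Y"),
    mode = c("homoplasmic", "homoplasmic", "homoplasmic", "homoplasmic",
             "heteroplasmic"))
}

# build a single test variant through the public parser
.variantRowForTest <- function(pos, kind, derived = "", idx = 0L) {
  if (kind == "del") parseVariants(paste0(pos, "-"))
  else if (kind == "ins") parseVariants(paste0(pos, ".", idx, derived))
  else parseVariants(paste0(pos, derived))
}

# a small random query haplotype: a node signature plus extra substitutions
queryFromSignature <- function(tree, node, extra = emptyVariants()) {
  sig <- fullSignature(tree, node)
  Haplotype(paste0("q_", node), rbind(variants(sig), extra))
}
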