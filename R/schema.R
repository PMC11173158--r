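# Feature schema: named group layout for node and edge feature vectors.

#' Standard amino acids
#'
#' The 20 standard residues in fixed alphabetical (three-letter code) order.
#' This order defines the columns of the one-hot block of the node schema.
#' @return Character vector of 20 three-letter codes.
#' @export
standard_aa <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}

# Meiler (2001) 7-dimensional physicochemical embedding per residue type:
# steric parameter, polarizability, volume, hydrophobicity, isoelectric
# point, helix probability, sheet probability.
.meiler_table <- function() {
  m <- rbind(
    ALA = c(1.28, 0.05, 1.00,  0.31, 6.11, 0.42, 0.23),
    ARG = c(2.34, 0.29, 6.13, -1.01, 10.74, 0.36, 0.25),
    ASN = c(1.60, 0.13, 2.95, -0.60, 6.52, 0.21, 0.22),
    ASP = c(1.60, 0.11, 2.78, -0.77, 2.95, 0.25, 0.20),
    CYS = c(1.77, 0.13, 2.43,  1.54, 6.35, 0.17, 0.41),
    GLN = c(1.56, 0.18, 3.95, -0.22, 5.65, 0.36, 0.25),
    GLU = c(1.56, 0.15, 3.78, -0.64, 3.09, 0.42, 0.21),
    GLY = c(0.00, 0.00, 0.00,  0.00, 6.07, 0.13, 0.15),
    HIS = c(2.99, 0.23, 4.66,  0.13, 7.69, 0.27, 0.30),
    ILE = c(4.19, 0.19, 4.00,  1.80, 6.04, 0.30, 0.45),
    LEU = c(2.59, 0.19, 4.00,  1.70, 6.04, 0.39, 0.31),
    LYS = c(1.89, 0.22, 4.77, -0.99, 9.99, 0.32, 0.27),
    MET = c(2.35, 0.22, 4.43,  1.23, 5.71, 0.38, 0.32),
    PHE = c(2.94, 0.29, 5.89,  1.79, 5.67, 0.30, 0.38),
    PRO = c(2.67, 0.00, 2.72,  0.72, 6.80, 0.13, 0.34),
    SER = c(1.31, 0.06, 1.60, -0.04, 5.70, 0.20, 0.28),
    THR = c(3.03, 0.11, 2.60,  0.26, 5.60, 0.21, 0.36),
    TRP = c(3.21, 0.41, 8.08,  2.25, 5.94, 0.32, 0.42),
    TYR = c(2.94, 0.30, 6.47,  0.96, 5.66, 0.25, 0.41),
    VAL = c(3.67, 0.14, 3.00,  1.22, 6.02, 0.27, 0.49))
  colnames(m) <- c("steric", "polarizability", "volume", "hydrophobicity",
                   "isoelectric", "helix_prob", "sheet_prob")
  m[standard_aa(), , drop = FALSE]
}

# Fixed accession list of 47 per-residue property scales drawn from the
# AAindex collection (hydrophobicity, polarity, volume, surface exposure,
# conformational propensities, ...).  The identity of each scale is part of
# the shipped schema contract; values are looked up in seqinr's aaindex data.
.expasy_accessions <- function() {
  c("KYTJ820101", "HOPT810101", "EISD840101", "GRAR740102", "ZIMJ680101",
    "ZIMJ680102", "ZIMJ680103", "ZIMJ680104", "ZIMJ680105", "CHOC760101",
    "CHOC760102", "CHOC760103", "JANJ780101", "JANJ780102", "JANJ780103",
    "BIGC670101", "CHAM820101", "CHAM820102", "DAYM780101", "FASG760101",
    "FASG760102", "FASG760103", "ROSG850101", "ROSG850102", "JOND750101",
    "MANP780101", "PONP800101", "PONP800102", "PONP800103", "PRAM900101",
    "WOLS870101", "WOLS870102", "WOLS870103", "OOBM770101", "KRIW790101",
    "LEVM760101", "RADA880101", "RADA880102", "ARGP820101", "BHAR880101",
    "BULH740101", "BULH740102", "CHAM810101", "CHAM830101", "COHE430101",
    "CHOP780201", "CHOP780202", "CHOP780203", "GUYH850101", "MIYS850101",
    "FAUJ880103")[1:47]
}

.pkg_cache <- new.env(parent = emptyenv())

# 20 x 47 matrix of property-scale values, rows in standard_aa() order.
.expasy_table <- function() {
  if (!is.null(.pkg_cache$expasy)) return(.pkg_cache$expasy)
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  aaindex <- env$aaindex
  acc <- vapply(aaindex, function(a) a$H, character(1))
  three_up <- toupper(standard_aa())
  cols <- lapply(.expasy_accessions(), function(h) {
    k <- which(acc == h)
    if (length(k) != 1L)
      stop("property scale ", h, " not found in aaindex")
    v <- aaindex[[k]]$I
    names(v) <- toupper(names(v))
    out <- v[three_up]
    if (any(is.na(out)))
      stop("property scale ", h, " has missing values")
    out
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(standard_aa(), .expasy_accessions())
  .pkg_cache$expasy <- m
  m
}

# Theoretical maximum accessible surface area per residue (A^2), used to
# turn the heuristic exposure estimate into ASA / relative ASA.
.max_asa <- function() {
  c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167, GLN = 225,
    GLU = 223, GLY = 104, HIS = 224, ILE = 197, LEU = 201, LYS = 236,
    MET = 224, PHE = 240, PRO = 159, SER = 155, THR = 172, TRP = 285,
    TYR = 263, VAL = 174)
}

# Eight secondary-structure classes; "C" is random coil.
.sse_classes <- function() c("H", "G", "I", "E", "B", "T", "S", "C")

#' Default node feature schema
#'
#' The node feature vector is the concatenation of named groups:
#' \describe{
#'   \item{position3d (3)}{C-alpha x, y, z in Angstrom.}
#'   \item{dssp_sse (8)}{One-hot secondary-structure class (H, G, I, E, B,
#'     T, S, C) including random coil.}
#'   \item{dssp_geom (4)}{Accessible surface area (A^2), phi (deg),
#'     psi (deg), relative ASA.}
#'   \item{meiler (7)}{Meiler physicochemical embedding of the residue type.}
#'   \item{expasy (47)}{Per-residue property scales (AAindex accessions).}
#'   \item{aa_onehot (20)}{One-hot residue identity.}
#' }
#' Group lengths sum to 89.  The schema is a validated object so an
#' alternative layout is a configuration change, not a code change.
#'
#' @return A `feature_schema` object (named list of group lengths with
#'   per-column names).
#' @export
default_node_schema <- function() {
  groups <- list(
    position3d = c("x", "y", "z"),
    dssp_sse   = paste0("sse_", .sse_classes()),
    dssp_geom  = c("asa", "phi", "psi", "rel_asa"),
    meiler     = paste0("meiler_", colnames(.meiler_table())),
    expasy     = paste0("expasy_", .expasy_accessions()),
    aa_onehot  = paste0("aa_", standard_aa()))
  new_feature_schema(groups, total = 89L)
}

#' Default edge feature schema
#'
#' Distance channel (C-alpha--C-alpha distance, Angstrom) followed by ten
#' bond-type channels, each holding the count of atom-level bonds of that
#' type condensed onto the residue pair.
#' @return A `feature_schema` object with 11 columns.
#' @export
default_edge_schema <- function() {
  groups <- list(
    distance = "distance",
    bonds = c("peptide", "disulfide", "hydrogen", "ionic", "aromatic",
              "aromatic_sulphur", "cation_pi", "hydrophobic", "vdw",
              "other_covalent"))
  new_feature_schema(groups, total = 11L)
}

new_feature_schema <- function(groups, total = NULL) {
  stopifnot(is.list(groups), length(groups) >= 1L, !is.null(names(groups)))
  lens <- vapply(groups, length, integer(1))
  if (!is.null(total) && sum(lens) != total)
    stop("schema group lengths sum to ", sum(lens), ", expected ", total)
  cols <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(cols)) stop("duplicate column names in schema")
  structure(list(groups = groups), class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  lens <- vapply(x$groups, length, integer(1))
  cat("feature schema:", sum(lens), "columns\n")
  for (g in names(x$groups))
    cat(sprintf("  %-12s %3d\n", g, lens[[g]]))
  invisible(x)
}

schema_ncol <- function(schema) {
  sum(vapply(schema$groups, length, integer(1)))
}

schema_colnames <- function(schema) {
  unlist(schema$groups, use.names = FALSE)
}

# Column index range (integer vector) of a named group.
schema_group_idx <- function(schema, group) {
  if (!group %in% names(schema$groups))
    stop("unknown schema group: ", group)
  lens <- vapply(schema$groups, length, integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  k <- match(group, names(schema$groups))
  seq.int(starts[k], ends[k])
}

# Drop one or more groups, returning the reduced schema.
schema_drop_groups <- function(schema, groups) {
  missing <- setdiff(groups, names(schema$groups))
  if (length(missing))
    stop("unknown or already removed schema group(s): ",
         paste(missing, collapse = ", "))
  new_feature_schema(schema$groups[setdiff(names(schema$groups), groups)])
}
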