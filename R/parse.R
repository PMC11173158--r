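# Structure parsing: PDB / mmCIF -> residue_set.

#' Construct a residue set
#'
#' Low-level constructor used by [parse_structure()] and the synthetic
#' complex generator.  A residue set holds the standard residues of a
#' (possibly multi-chain) structure with their atoms and one C-alpha
#' coordinate per residue.
#'
#' @param protein_id Identifier string.
#' @param residues data.frame with columns `chain`, `resno` (integer author
#'   numbering), `ins` (insertion code, "" if none), `aa` (three-letter
#'   code).
#' @param ca Numeric matrix, one row per residue, columns x/y/z (Angstrom).
#' @param atoms data.frame with columns `res_index` (1-based row of
#'   `residues`), `elety` (atom name), `elesy` (element symbol), `x`, `y`,
#'   `z`.
#' @return A `residue_set` object.
#' @export
residue_set <- function(protein_id, residues, ca, atoms) {
  stopifnot(is.data.frame(residues), nrow(residues) >= 1L,
            is.matrix(ca), nrow(ca) == nrow(residues), ncol(ca) == 3L,
            is.data.frame(atoms))
  if (any(!residues$aa %in% standard_aa()))
    stop("non-standard residue in residue_set")
  if (anyNA(ca)) stop("every residue needs exactly one C-alpha coordinate")
  for (ch in unique(residues$chain)) {
    idx <- which(residues$chain == ch)
    if (length(idx) == 0L) stop("empty chain ", ch)
    key <- order_key(residues$resno[idx], residues$ins[idx])
    if (any(diff(key) <= 0))
      stop("residue ordering not strictly increasing in chain ", ch)
  }
  rownames(ca) <- NULL
  structure(list(protein_id = protein_id,
                 residues = residues, ca = ca, atoms = atoms),
            class = "residue_set")
}

# Composite sort key: author residue number plus insertion-code rank.
order_key <- function(resno, ins) {
  ins_rank <- match(ifelse(ins == "" | is.na(ins), " ", ins),
                    c(" ", LETTERS, letters))
  resno * 100 + (ins_rank - 1)
}

#' @export
print.residue_set <- function(x, ...) {
  cat("residue_set", x$protein_id, "-", nrow(x$residues), "residues in",
      length(unique(x$residues$chain)), "chain(s)\n")
  invisible(x)
}

n_residues <- function(rs) nrow(rs$residues)

residue_keys <- function(rs) {
  paste0(rs$residues$chain, ":", rs$residues$resno,
         ifelse(rs$residues$ins == "", "", rs$residues$ins))
}

#' Parse a protein structure file
#'
#' Reads a PDB or mmCIF file and returns the standard amino-acid residues
#' as a [residue_set()].  Waters and other non-standard residues are
#' dropped; alternate locations are resolved to the highest occupancy
#' (ties broken by altloc letter order); hydrogens are discarded;
#' insertion codes are preserved in the residue ordering.  Residues
#' lacking a C-alpha atom and chains with no standard residues are
#' omitted with a warning.
#'
#' @param path Path to the structure file.
#' @param format "pdb" or "mmcif".
#' @return A `residue_set`.
#' @export
parse_structure <- function(path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, rm.alt = FALSE,
                                         verbose = FALSE)
    else bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("could not parse ", path, " as ", format,
                             ": ", conditionMessage(e)))
  at <- pdb$atom
  at$ins <- ifelse(is.na(at$insert) | at$insert == "", "", at$insert)
  at$chain[is.na(at$chain)] <- " "
  at <- at[at$resid %in% standard_aa(), , drop = FALSE]
  if (nrow(at) == 0L) stop("no standard residues in ", path)
  at <- at[is.na(at$elesy) | !at$elesy %in% c("H", "D"), , drop = FALSE]

  # altloc resolution: per (chain, resno, ins, atom name) keep the highest
  # occupancy, ties broken by altloc letter order
  at$alt[is.na(at$alt)] <- ""
  occ <- ifelse(is.na(at$o), 1, at$o)
  akey <- paste(at$chain, at$resno, at$ins, at$elety, sep = "\r")
  ord <- order(akey, -occ, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(akey[ord]), , drop = FALSE]

  # residue table in file chain order, (resno, insertion) order within chain
  rkey <- paste(at$chain, at$resno, at$ins, sep = "\r")
  first <- at[!duplicated(rkey), c("chain", "resno", "ins", "resid")]
  chains <- unique(at$chain)
  first <- first[order(match(first$chain, chains),
                       order_key(first$resno, first$ins)), , drop = FALSE]

  fkey <- paste(first$chain, first$resno, first$ins, sep = "\r")
  ca_rows <- at[at$elety == "CA", , drop = FALSE]
  ca_idx <- match(fkey, paste(ca_rows$chain, ca_rows$resno, ca_rows$ins,
                              sep = "\r"))
  if (anyNA(ca_idx)) {
    bad <- which(is.na(ca_idx))
    warning(length(bad), " residue(s) without C-alpha dropped")
    first <- first[-bad, , drop = FALSE]
    fkey <- fkey[-bad]
    ca_idx <- ca_idx[!is.na(ca_idx)]
  }
  if (nrow(first) == 0L) stop("no standard residues with C-alpha in ", path)
  dropped_chains <- setdiff(chains, unique(first$chain))
  if (length(dropped_chains))
    warning("chain(s) without standard residues omitted: ",
            paste(dropped_chains, collapse = ", "))

  residues <- data.frame(chain = first$chain, resno = first$resno,
                         ins = first$ins, aa = first$resid,
                         stringsAsFactors = FALSE)
  ca <- as.matrix(ca_rows[ca_idx, c("x", "y", "z")])
  res_index <- match(rkey, fkey)
  keep <- !is.na(res_index)
  atoms <- data.frame(res_index = res_index[keep], elety = at$elety[keep],
                      elesy = ifelse(is.na(at$elesy[keep]),
                                     substr(at$elety[keep], 1, 1),
                                     at$elesy[keep]),
                      x = at$x[keep], y = at$y[keep], z = at$z[keep],
                      stringsAsFactors = FALSE)
  pid <- sub("\\.(pdb|cif|ent)(\\.gz)?$", "", basename(path))
  residue_set(pid, residues, ca, atoms)
}

#' Write a residue set as a PDB file
#'
#' Emits standard ATOM records (PDB v3.3 fixed columns) for all atoms of
#' the residue set, with TER records between chains.  Round-trips through
#' [parse_structure()].
#'
#' @param rs A `residue_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(rs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (ch in unique(rs$residues$chain)) {
    ridx <- which(rs$residues$chain == ch)
    for (i in ridx) {
      rows <- which(rs$atoms$res_index == i)
      for (a in rows) {
        serial <- serial + 1L
        name <- rs$atoms$elety[a]
        # atom-name column convention: element right-aligned in cols 13-14
        name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name)
                    else sprintf("%-4s", name)
        writeLines(sprintf(
          "ATOM  %5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, name_fmt, rs$residues$aa[i],
          substr(ch, 1, 1), rs$residues$resno[i],
          ifelse(rs$residues$ins[i] == "", " ", rs$residues$ins[i]),
          rs$atoms$x[a], rs$atoms$y[a], rs$atoms$z[a], 1, 0,
          rs$atoms$elesy[a]), con)
      }
    }
    writeLines("TER", con)
  }
  writeLines("END", con)
  invisible(path)
}
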