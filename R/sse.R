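# Secondary-structure assignment and backbone geometry features.

# Dihedral angle (degrees, in (-180, 180]) defined by four points.
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Torsion-region classifier on (phi, psi); returns one of the 8 classes.
.classify_torsion <- function(phi, psi) {
  if (is.na(phi) || is.na(psi)) return("C")
  if (phi >= -100 && phi <= -30 && psi >= -80 && psi <= -5) return("H")
  if (phi >= -180 && phi <= -40 && (psi >= 90 || psi <= -150)) return("E")
  if (phi >= 30 && phi <= 90 && psi >= -20 && psi <= 60) return("T")
  "C"
}

# Backbone atom coordinate (3-vector) or NA for residue i.
.bb_atom <- function(rs, i, name) {
  k <- which(rs$atoms$res_index == i & rs$atoms$elety == name)
  if (length(k) == 0L) return(rep(NA_real_, 3))
  unlist(rs$atoms[k[1], c("x", "y", "z")], use.names = FALSE)
}

#' Assign secondary structure and backbone geometry features
#'
#' Gives every residue one of the 8 DSSP classes (H, G, I, E, B, T, S and
#' C for random coil) plus accessible surface area, phi, psi and relative
#' ASA.  The default `heuristic` backend classifies the backbone torsion
#' angles computed from N/CA/C atoms into canonical Ramachandran regions
#' and estimates solvent exposure from the C-alpha neighbour count; the
#' `precomputed` backend copies assignments verbatim from a classic
#' DSSP output file.
#'
#' Terminal residues (and residues lacking backbone atoms) carry the
#' sentinel phi = psi = 0 and class coil.
#'
#' @param rs A [residue_set()].
#' @param backend "heuristic" or "precomputed".
#' @param dssp_file Path to a DSSP output file (precomputed backend only).
#' @return data.frame with columns `sse`, `asa`, `phi`, `psi`, `rel_asa`,
#'   one row per residue of `rs`.
#' @export
assign_secondary_structure <- function(rs,
                                       backend = c("heuristic",
                                                   "precomputed"),
                                       dssp_file = NULL) {
  backend <- match.arg(backend)
  if (backend == "precomputed") {
    if (is.null(dssp_file)) stop("precomputed backend needs a dssp_file")
    return(.sse_from_dssp(rs, dssp_file))
  }
  n <- n_residues(rs)
  phi <- psi <- numeric(n)
  sse <- rep("C", n)
  for (ch in unique(rs$residues$chain)) {
    idx <- which(rs$residues$chain == ch)
    for (k in seq_along(idx)) {
      i <- idx[k]
      Ni <- .bb_atom(rs, i, "N"); CAi <- .bb_atom(rs, i, "CA")
      Ci <- .bb_atom(rs, i, "C")
      ph <- ps <- NA_real_
      if (k > 1) {
        Cprev <- .bb_atom(rs, idx[k - 1], "C")
        if (!anyNA(c(Cprev, Ni, CAi, Ci))) ph <- dihedral(Cprev, Ni, CAi, Ci)
      }
      if (k < length(idx)) {
        Nnext <- .bb_atom(rs, idx[k + 1], "N")
        if (!anyNA(c(Ni, CAi, Ci, Nnext))) ps <- dihedral(Ni, CAi, Ci, Nnext)
      }
      sse[i] <- if (is.na(ph) || is.na(ps)) "C" else .classify_torsion(ph, ps)
      phi[i] <- ifelse(is.na(ph), 0, ph)
      psi[i] <- ifelse(is.na(ps), 0, ps)
    }
  }
  # exposure proxy: residues with few C-alpha neighbours within 10 A are
  # treated as solvent exposed
  d <- as.matrix(stats::dist(rs$ca))
  ncount <- rowSums(d < 10) - 1L
  rel_asa <- pmin(1, pmax(0, 1 - ncount / 24))
  asa <- rel_asa * .max_asa()[rs$residues$aa]
  data.frame(sse = sse, asa = unname(asa), phi = phi, psi = psi,
             rel_asa = rel_asa, stringsAsFactors = FALSE)
}

# Classic DSSP column format: data lines follow the "  #  RESIDUE AA" header;
# residue number cols 6-10, insertion col 11, chain col 12, SS col 17,
# ACC cols 35-38, PHI cols 104-109, PSI cols 110-115.
.sse_from_dssp <- function(rs, dssp_file) {
  lines <- readLines(dssp_file)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) != 1L) stop("not a DSSP file: ", dssp_file)
  lines <- lines[(hdr + 1):length(lines)]
  lines <- lines[nchar(lines) >= 115]
  aa1 <- substr(lines, 14, 14)
  keep <- aa1 != "!"  # chain breaks
  lines <- lines[keep]
  chain <- trimws(substr(lines, 12, 12))
  resno <- as.integer(trimws(substr(lines, 6, 10)))
  ins <- trimws(substr(lines, 11, 11))
  ss <- substr(lines, 17, 17)
  ss[!ss %in% .sse_classes()] <- "C"
  acc <- as.numeric(trimws(substr(lines, 35, 38)))
  phi <- as.numeric(trimws(substr(lines, 104, 109)))
  psi <- as.numeric(trimws(substr(lines, 110, 115)))
  dkey <- paste0(chain, ":", resno, ins)
  m <- match(residue_keys(rs), dkey)
  if (anyNA(m)) {
    miss <- residue_keys(rs)[which(is.na(m))[1]]
    stop("DSSP file does not cover residue ", miss)
  }
  # DSSP's 360.0 marks undefined torsions
  phi[abs(phi) >= 360] <- 0
  psi[abs(psi) >= 360] <- 0
  rel <- pmin(1, acc[m] / .max_asa()[rs$residues$aa])
  data.frame(sse = ss[m], asa = acc[m], phi = phi[m], psi = psi[m],
             rel_asa = unname(rel), stringsAsFactors = FALSE)
}
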