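# Atom-level bond detection between residues.

#' Default bond-detection thresholds
#'
#' Distance cutoffs (Angstrom) for the ten bond/interaction types condensed
#' onto residue-pair edges.  Peptide bonds are assigned by chain adjacency;
#' the remaining rules are geometric and fully deterministic.
#'
#' @return Named list of cutoffs.
#' @export
default_bond_params <- function() {
  list(disulfide = 2.5,     # Cys SG--SG
       hydrogen = 3.5,      # N/O donor--acceptor pairs
       ionic = 4.0,         # charged-group atoms (Arg/Lys/His vs Asp/Glu)
       aromatic = 5.3,      # ring centroid -- ring centroid
       aromatic_sulphur = 5.3,  # ring centroid -- S (Cys SG, Met SD)
       cation_pi = 6.0,     # cation atom -- ring centroid
       hydrophobic = 5.0,   # apolar side-chain carbon pairs
       vdw_slack = 0.5,     # added to summed van der Waals radii
       other_covalent = 1.8,
       prefilter = 16.0)    # C-alpha prefilter radius for candidate pairs
}

.vdw_radius <- function(elem) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
  out <- r[elem]
  out[is.na(out)] <- 1.70
  unname(out)
}

.ring_atoms <- function(aa) {
  switch(aa,
         PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
         TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
         TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3",
                 "CH2"),
         HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
         NULL)
}

.cation_atoms <- function(aa) {
  switch(aa, LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
         HIS = c("ND1", "NE2"), NULL)
}

.anion_atoms <- function(aa) {
  switch(aa, ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), NULL)
}

.hydrophobic_res <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP",
                      "PRO", "TYR")
.backbone_names <- c("N", "CA", "C", "O", "OXT")

#' Detect atom-level bonds between residues
#'
#' Assigns peptide bonds to all chain-adjacent residue pairs and detects
#' non-covalent interactions (disulfide, hydrogen, ionic, aromatic,
#' aromatic-sulphur, cation-pi, hydrophobic, van der Waals, other-covalent)
#' by deterministic distance/chemistry rules.  Multiple atom-level bonds
#' between the same residue pair are all reported; [build_graph()] condenses
#' them into per-type counts on a single undirected edge.
#'
#' @param rs A [residue_set()].
#' @param params Cutoffs, see [default_bond_params()].
#' @return data.frame with columns `i`, `j` (residue indices, i < j),
#'   `type`, `atom_i`, `atom_j`.
#' @export
detect_bonds <- function(rs, params = default_bond_params()) {
  n <- n_residues(rs)
  out <- list()
  add <- function(i, j, type, ai, aj) {
    out[[length(out) + 1L]] <<- data.frame(
      i = min(i, j), j = max(i, j), type = type,
      atom_i = if (i < j) ai else aj, atom_j = if (i < j) aj else ai,
      stringsAsFactors = FALSE)
  }

  # peptide bonds: chain adjacency
  for (ch in unique(rs$residues$chain)) {
    idx <- which(rs$residues$chain == ch)
    if (length(idx) >= 2L)
      for (k in seq_len(length(idx) - 1L))
        add(idx[k], idx[k + 1L], "peptide", "C", "N")
  }
  if (n < 2L) return(.bond_df(out))

  # candidate pairs by C-alpha prefilter
  d <- as.matrix(stats::dist(rs$ca))
  cand <- which(upper.tri(d) & d < params$prefilter, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(.bond_df(out))

  res <- rs$residues
  atoms_by_res <- split(seq_len(nrow(rs$atoms)), rs$atoms$res_index)
  axyz <- as.matrix(rs$atoms[, c("x", "y", "z")])
  adjacent <- function(i, j) {
    res$chain[i] == res$chain[j] && abs(i - j) == 1L
  }
  centroid <- function(i) {
    ra <- .ring_atoms(res$aa[i])
    if (is.null(ra)) return(NULL)
    k <- atoms_by_res[[as.character(i)]]
    k <- k[rs$atoms$elety[k] %in% ra]
    if (length(k) < 3L) return(NULL)
    colMeans(axyz[k, , drop = FALSE])
  }

  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    adj <- adjacent(i, j)
    ai <- atoms_by_res[[as.character(i)]]
    aj <- atoms_by_res[[as.character(j)]]
    if (is.null(ai) || is.null(aj)) next
    ni <- rs$atoms$elety[ai]; nj <- rs$atoms$elety[aj]
    ei <- rs$atoms$elesy[ai]; ej <- rs$atoms$elesy[aj]
    dm <- sqrt(outer(rowSums(axyz[ai, , drop = FALSE]^2),
                     rowSums(axyz[aj, , drop = FALSE]^2), "+") -
               2 * axyz[ai, , drop = FALSE] %*% t(axyz[aj, , drop = FALSE]))
    used <- matrix(FALSE, length(ai), length(aj))

    # disulfide
    if (res$aa[i] == "CYS" && res$aa[j] == "CYS") {
      ki <- which(ni == "SG"); kj <- which(nj == "SG")
      if (length(ki) && length(kj) &&
          dm[ki[1], kj[1]] < params$disulfide) {
        add(i, j, "disulfide", "SG", "SG")
        used[ki[1], kj[1]] <- TRUE
      }
    }
    # other covalent links (non-peptide, non-disulfide)
    if (!adj) {
      hits <- which(dm < params$other_covalent & !used, arr.ind = TRUE)
      for (h in seq_len(nrow(hits))) {
        add(i, j, "other_covalent", ni[hits[h, 1]], nj[hits[h, 2]])
        used[hits[h, 1], hits[h, 2]] <- TRUE
      }
    }
    # hydrogen bonds: N/O -- N/O; for chain-adjacent pairs only contacts
    # involving a side-chain atom count (the backbone contact is the
    # peptide bond itself)
    di <- ei %in% c("N", "O"); dj <- ej %in% c("N", "O")
    if (any(di) && any(dj)) {
      hb <- outer(di, dj, "&") & dm < params$hydrogen & !used
      if (adj) hb <- hb & !outer(ni %in% .backbone_names,
                                 nj %in% .backbone_names, "&")
      hits <- which(hb, arr.ind = TRUE)
      for (h in seq_len(nrow(hits))) {
        add(i, j, "hydrogen", ni[hits[h, 1]], nj[hits[h, 2]])
        used[hits[h, 1], hits[h, 2]] <- TRUE
      }
    }
    # ionic (salt bridge)
    ion <- function(a, b, ka, kb) {
      hits <- which(outer(ka, kb, "&") & dm < params$ionic & !used,
                    arr.ind = TRUE)
      for (h in seq_len(nrow(hits))) {
        add(i, j, "ionic", ni[hits[h, 1]], nj[hits[h, 2]])
        used[hits[h, 1], hits[h, 2]] <<- TRUE
      }
    }
    ion(i, j, ni %in% .cation_atoms(res$aa[i]),
        nj %in% .anion_atoms(res$aa[j]))
    ion(i, j, ni %in% .anion_atoms(res$aa[i]),
        nj %in% .cation_atoms(res$aa[j]))

    # ring-centroid based interactions
    ci <- centroid(i); cj <- centroid(j)
    if (!is.null(ci) && !is.null(cj) &&
        sqrt(sum((ci - cj)^2)) < params$aromatic)
      add(i, j, "aromatic", "RING", "RING")
    sulph <- function(cen, kk, nn, swap) {
      if (is.null(cen) || !length(kk)) return()
      for (k in kk) {
        dd <- sqrt(sum((cen - axyz[k, ])^2))
        if (dd < params$aromatic_sulphur)
          if (swap) add(i, j, "aromatic_sulphur", nn, "RING")
          else add(i, j, "aromatic_sulphur", "RING", nn)
      }
    }
    s_j <- aj[nj %in% c("SG", "SD") & res$aa[j] %in% c("CYS", "MET")]
    s_i <- ai[ni %in% c("SG", "SD") & res$aa[i] %in% c("CYS", "MET")]
    if (!is.null(ci)) sulph(ci, s_j, "S", swap = FALSE)
    if (!is.null(cj)) sulph(cj, s_i, "S", swap = TRUE)
    cat_j <- aj[nj %in% .cation_atoms(res$aa[j])]
    cat_i <- ai[ni %in% .cation_atoms(res$aa[i])]
    if (!is.null(ci) && length(cat_j))
      for (k in cat_j)
        if (sqrt(sum((ci - axyz[k, ])^2)) < params$cation_pi)
          add(i, j, "cation_pi", "RING", rs$atoms$elety[k])
    if (!is.null(cj) && length(cat_i))
      for (k in cat_i)
        if (sqrt(sum((cj - axyz[k, ])^2)) < params$cation_pi)
          add(i, j, "cation_pi", rs$atoms$elety[k], "RING")

    # hydrophobic: apolar side-chain carbon pairs
    if (res$aa[i] %in% .hydrophobic_res && res$aa[j] %in% .hydrophobic_res) {
      hi <- ei == "C" & !ni %in% .backbone_names
      hj <- ej == "C" & !nj %in% .backbone_names
      hits <- which(outer(hi, hj, "&") & dm < params$hydrophobic,
                    arr.ind = TRUE)
      for (h in seq_len(nrow(hits)))
        add(i, j, "hydrophobic", ni[hits[h, 1]], nj[hits[h, 2]])
    }
    # van der Waals contacts (non-adjacent pairs, atoms not already bonded)
    if (!adj) {
      lim <- outer(.vdw_radius(ei), .vdw_radius(ej), "+") + params$vdw_slack
      hits <- which(dm < lim & !used, arr.ind = TRUE)
      for (h in seq_len(nrow(hits)))
        add(i, j, "vdw", ni[hits[h, 1]], nj[hits[h, 2]])
    }
  }
  .bond_df(out)
}

.bond_df <- function(out) {
  if (length(out) == 0L)
    return(data.frame(i = integer(), j = integer(), type = character(),
                      atom_i = character(), atom_j = character(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df[order(df$i, df$j, df$type, df$atom_i, df$atom_j), , drop = FALSE]
}
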