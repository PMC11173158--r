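# Structure parsing, secondary structure, bonds and graph construction.

test_that("parse_structure reads a minimal PDB and rejects water-only files", {
  f <- minimal_pdb(tempfile(fileext = ".pdb"))
  rs <- parse_structure(f, "pdb")
  expect_s3_class(rs, "residue_set")
  expect_equal(length(unique(rs$residues$chain)), 1L)
  expect_equal(nrow(rs$residues), 3L)
  expect_equal(rs$residues$aa, c("ALA", "GLY", "SER"))

  hoh <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "END"), hoh)
  expect_error(parse_structure(hoh, "pdb"), "no standard residues")
})

test_that("synthetic PDB writer round-trips through the parser", {
  cx <- generate_complex(synthetic_spec(seed = 3,
                                        residues_per_chain = c(30, 30)))
  f <- tempfile(fileext = ".pdb")
  write_pdb(cx$residue_set, f)
  rs <- parse_structure(f, "pdb")
  expect_equal(nrow(rs$residues), 60L)
  expect_equal(length(unique(rs$residues$chain)), 2L)
  expect_lt(max(abs(rs$ca - cx$residue_set$ca)), 1e-3)
})

test_that("altloc resolves to the highest occupancy", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      4  C   ALA A   1       3.000   1.000   0.000  1.00  0.00           C",
    "END"), f)
  rs <- parse_structure(f, "pdb")
  expect_equal(unname(rs$ca[1, 1]), 2.000)
})

test_that("torsion heuristic classifies canonical helix and strand", {
  sp <- synthetic_spec(seed = 5)
  hel <- generate_chain(12, sp, sse_plan = rep("H", 12))
  sse <- assign_secondary_structure(hel)
  expect_true(all(sse$sse[2:11] == "H"))
  # terminals: undefined torsions get the sentinel and coil
  expect_equal(sse$sse[c(1, 12)], c("C", "C"))
  expect_equal(sse$phi[1], 0)
  expect_equal(sse$psi[12], 0)
  str <- generate_chain(8, sp, sse_plan = rep("E", 8))
  expect_true(all(assign_secondary_structure(str)$sse[2:7] == "E"))
  # interior helix torsions near the canonical values
  expect_true(all(abs(sse$phi[2:11] + 60) < 20))
  expect_true(all(abs(sse$psi[2:11] + 45) < 20))
})

test_that("single-residue chains are coil with zero torsions", {
  rs <- residue_set("one",
                    data.frame(chain = "A", resno = 1L, ins = "",
                               aa = "ALA", stringsAsFactors = FALSE),
                    matrix(c(0, 0, 0), 1, 3),
                    data.frame(res_index = 1L, elety = "CA", elesy = "C",
                               x = 0, y = 0, z = 0,
                               stringsAsFactors = FALSE))
  sse <- assign_secondary_structure(rs)
  expect_equal(sse$sse, "C")
  expect_equal(sse$phi, 0)
  expect_equal(sse$psi, 0)
})

test_that("precomputed DSSP sidecar is copied verbatim and mismatches error", {
  f <- minimal_pdb(tempfile(fileext = ".pdb"))
  rs <- parse_structure(f, "pdb")
  dssp <- tempfile(fileext = ".dssp")
  hdr <- "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA"
  row <- function(i, aa, ss, acc, phi, psi) {
    line <- sprintf("%5d%5d %1s %1s  %1s", i, i, "A", aa, ss)
    sprintf("%-34s%4d%65s%6.1f%6.1f", line, acc, "", phi, psi)
  }
  writeLines(c(hdr, row(1, "A", "H", 100, -60, -45),
               row(2, "G", "E", 50, -120, 130),
               row(3, "S", " ", 80, 360, 360)), dssp)
  sse <- assign_secondary_structure(rs, backend = "precomputed",
                                    dssp_file = dssp)
  expect_equal(sse$sse, c("H", "E", "C"))
  expect_equal(sse$asa, c(100, 50, 80))
  expect_equal(sse$phi, c(-60, -120, 0))

  writeLines(c(hdr, row(1, "A", "H", 100, -60, -45)), dssp)
  expect_error(assign_secondary_structure(rs, backend = "precomputed",
                                          dssp_file = dssp),
               "does not cover residue A:2")
})

test_that("bond detection finds peptide, disulfide and ionic bonds", {
  f <- minimal_pdb(tempfile(fileext = ".pdb"))
  rs <- parse_structure(f, "pdb")
  b <- detect_bonds(rs)
  expect_equal(sum(b$type == "peptide"), 2L)

  # two cysteines with SG--SG at 2.05 A
  cys2 <- residue_set(
    "ss",
    data.frame(chain = c("A", "B"), resno = c(1L, 1L), ins = "",
               aa = "CYS", stringsAsFactors = FALSE),
    rbind(c(0, 0, 0), c(6, 0, 0)),
    data.frame(res_index = c(1L, 1L, 2L, 2L),
               elety = c("CA", "SG", "CA", "SG"),
               elesy = c("C", "S", "C", "S"),
               x = c(0, 1.975, 6, 4.025), y = 0, z = 0,
               stringsAsFactors = FALSE))
  b <- detect_bonds(cys2)
  expect_equal(sum(b$type == "disulfide"), 1L)

  # Lys NZ -- Asp OD1 at 3.5 A
  salt <- residue_set(
    "salt",
    data.frame(chain = c("A", "B"), resno = c(1L, 1L), ins = "",
               aa = c("LYS", "ASP"), stringsAsFactors = FALSE),
    rbind(c(0, 0, 0), c(8, 0, 0)),
    data.frame(res_index = c(1L, 1L, 2L, 2L),
               elety = c("CA", "NZ", "CA", "OD1"),
               elesy = c("C", "N", "C", "O"),
               x = c(0, 2.25, 8, 5.75), y = 0, z = 0,
               stringsAsFactors = FALSE))
  b <- detect_bonds(salt)
  expect_equal(sum(b$type == "ionic"), 1L)
})

test_that("graphs respect the shipped schema and condense bonds", {
  tc <- tiny_complex()
  g <- tc$graph
  expect_equal(ncol(g$X), 89L)
  expect_equal(ncol(g$E), 11L)
  # one-hot groups
  sse_cols <- ppiface:::schema_group_idx(g$node_schema, "dssp_sse")
  aa_cols <- ppiface:::schema_group_idx(g$node_schema, "aa_onehot")
  expect_true(all(abs(rowSums(g$X[, sse_cols]) - 1) < 1e-12))
  expect_true(all(abs(rowSums(g$X[, aa_cols]) - 1) < 1e-12))
  # undirected, no self loops, stored once
  expect_true(all(g$edges$i < g$edges$j))
  expect_false(anyDuplicated(paste(g$edges$i, g$edges$j)) > 0)
  # consecutive residues joined by a peptide-carrying edge
  for (ch in unique(g$nodes$chain)) {
    idx <- which(g$nodes$chain == ch)
    for (k in seq_len(length(idx) - 1L)) {
      e <- graph_edge_feature(g, idx[k], idx[k + 1L])
      expect_false(is.null(e))
      expect_gte(e[["peptide"]], 1)
    }
  }
  # bond condensation conserves counts
  bonds <- detect_bonds(tc$rs)
  expect_equal(sum(g$E[, -1]), nrow(bonds))
  # every edge has at least one non-zero bond channel
  expect_true(all(rowSums(g$E[, -1, drop = FALSE]) > 0))
  # distance channel equals the C-alpha distance
  d <- sqrt(rowSums((tc$rs$ca[g$edges$i, ] - tc$rs$ca[g$edges$j, ])^2))
  expect_lt(max(abs(g$E[, "distance"] - d)), 1e-6)
  # symmetric edge query
  e1 <- graph_edge_feature(g, g$edges$j[1], g$edges$i[1])
  expect_identical(e1, graph_edge_feature(g, g$edges$i[1], g$edges$j[1]))
})

test_that("graph construction is deterministic and containers round-trip", {
  tc <- tiny_complex()
  g2 <- build_graph(tc$rs, assign_secondary_structure(tc$rs),
                    detect_bonds(tc$rs))
  expect_identical(tc$graph$X, g2$X)
  expect_identical(tc$graph$E, g2$E)

  dir <- tempfile()
  write_graph(tc$graph, dir)
  g3 <- read_graph(dir)
  expect_equal(g3$protein_id, tc$graph$protein_id)
  expect_equal(g3$edges, tc$graph$edges)
  expect_lt(max(abs(g3$X - tc$graph$X)), 1e-9)
  expect_lt(max(abs(g3$E - tc$graph$E)), 1e-9)
  expect_equal(ncol(g3$X), 89L)
})

test_that("hand-chosen bond list is condensed into per-type counts", {
  rs <- three_chain_rs()
  bonds <- data.frame(
    i = c(1L, 1L, 1L, 1L), j = c(12L, 12L, 12L, 2L),
    type = c("hydrogen", "hydrogen", "ionic", "peptide"),
    atom_i = "X", atom_j = "Y", stringsAsFactors = FALSE)
  g <- build_graph(rs, assign_secondary_structure(rs), bonds)
  e <- graph_edge_feature(g, 1, 12)
  expect_equal(e[["hydrogen"]], 2)
  expect_equal(e[["ionic"]], 1)
  expect_equal(e[["peptide"]], 0)
})
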