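# Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

# A small two-chain complex with its graph, used by many tests.
tiny_complex <- function() {
  cached("tiny_complex", {
    cx <- generate_complex(synthetic_spec(seed = 12,
                                          residues_per_chain = c(25, 25)))
    rs <- cx$residue_set
    g <- build_graph(rs, assign_secondary_structure(rs), detect_bonds(rs))
    list(rs = rs, labels = cx$labels, graph = g)
  })
}

# Hand-built CA-only residue set: three straight parallel chains A, B, C
# spaced so A-B and B-C are in 8-A contact but A-C is not.
three_chain_rs <- function() {
  cached("three_chain_rs", {
    mk <- function(chain, y) {
      n <- 10L
      ca <- cbind(seq_len(n) * 3.8, rep(y, n), rep(0, n))
      list(res = data.frame(chain = chain, resno = seq_len(n), ins = "",
                            aa = rep("GLY", n), stringsAsFactors = FALSE),
           ca = ca)
    }
    parts <- list(mk("A", 0), mk("B", 6), mk("C", 12))
    residues <- do.call(rbind, lapply(parts, `[[`, "res"))
    ca <- do.call(rbind, lapply(parts, `[[`, "ca"))
    atoms <- data.frame(res_index = seq_len(nrow(residues)), elety = "CA",
                        elesy = "C", x = ca[, 1], y = ca[, 2], z = ca[, 3],
                        stringsAsFactors = FALSE)
    residue_set("abc", residues, ca, atoms)
  })
}

three_chain_graph <- function() {
  cached("three_chain_graph", {
    rs <- three_chain_rs()
    build_graph(rs, assign_secondary_structure(rs), detect_bonds(rs))
  })
}

# Minimal hand-written PDB text (3 residues, chain A).
minimal_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      5  CA  GLY A   2       4.093   2.770   0.100  1.00  0.00           C",
    "ATOM      6  C   GLY A   2       5.550   2.510   0.400  1.00  0.00           C",
    "ATOM      7  N   SER A   3       6.400   3.530   0.300  1.00  0.00           N",
    "ATOM      8  CA  SER A   3       7.840   3.400   0.500  1.00  0.00           C",
    "ATOM      9  C   SER A   3       8.500   4.760   0.700  1.00  0.00           C",
    "TER", "END")
  writeLines(lines, path)
  path
}

# PISA-style interface XML covering four residues of chain A.
fixture_pisa_xml <- function(path, deltas = c(0.00, -0.52, 0.31, 0.00)) {
  lines <- c(
    "<pisa_interfaces>",
    "  <interface>",
    "    <id>1</id>",
    unlist(lapply(seq_along(deltas), function(i) c(
      "    <residue>",
      sprintf("      <chain>A</chain><seqnum>%d</seqnum>", i),
      sprintf("      <solvenergy>%.2f</solvenergy>", deltas[i]),
      "    </residue>"))),
    "  </interface>",
    "</pisa_interfaces>")
  writeLines(lines, path)
  path
}

# Fast configuration for pipeline smoke tests.
fast_config <- function(...) {
  defaults <- list(state_dim = 8L, max_iter = 3L, wbal = 1,
                   net_s_hidden = 0L, net_o_hidden = 0L, epochs = 5L,
                   early_stopping_patience = 5L, seed = 1L)
  do.call(gnn_config, utils::modifyList(defaults, list(...)))
}

# Split a sample list by protein-level assignment.
split_parts <- function(samples, split) {
  pid <- vapply(samples, function(s) s$provenance$protein_id, character(1))
  list(train = samples[split[pid] == "train"],
       validation = samples[split[pid] == "validation"],
       test = samples[split[pid] == "test"])
}
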