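# Residue-level protein graphs with featurized nodes and edges.

#' Build a residue graph from a parsed structure
#'
#' Nodes are residues (one per C-alpha); node feature vectors follow the
#' 89-dimensional default schema (position, secondary structure, backbone
#' geometry, Meiler embedding, property scales, residue one-hot).  All
#' atom-level bonds between a residue pair are condensed onto one
#' undirected edge whose bond channels hold per-type counts and whose
#' distance channel is the C-alpha--C-alpha distance in Angstrom.
#'
#' @param rs A [residue_set()].
#' @param sse Output of [assign_secondary_structure()] on `rs`.
#' @param bonds Output of [detect_bonds()] on `rs`.
#' @param node_schema,edge_schema Feature schemas; defaults are the shipped
#'   89/11-dimensional contracts.
#' @return A `protein_graph` object.
#' @export
build_graph <- function(rs, sse = assign_secondary_structure(rs),
                        bonds = detect_bonds(rs),
                        node_schema = default_node_schema(),
                        edge_schema = default_edge_schema()) {
  n <- n_residues(rs)
  stopifnot(nrow(sse) == n)
  aa <- rs$residues$aa

  sse_onehot <- matrix(0, n, 8)
  sse_onehot[cbind(seq_len(n), match(sse$sse, .sse_classes()))] <- 1
  aa_onehot <- matrix(0, n, 20)
  aa_onehot[cbind(seq_len(n), match(aa, standard_aa()))] <- 1

  X <- cbind(rs$ca,
             sse_onehot,
             as.matrix(sse[, c("asa", "phi", "psi", "rel_asa")]),
             .meiler_table()[aa, , drop = FALSE],
             .expasy_table()[aa, , drop = FALSE],
             aa_onehot)
  dimnames(X) <- list(NULL, schema_colnames(node_schema))
  if (ncol(X) != schema_ncol(node_schema))
    stop("node feature matrix does not match schema")

  bond_types <- default_edge_schema()$groups$bonds
  if (nrow(bonds)) {
    pair_id <- paste(bonds$i, bonds$j, sep = "_")
    pairs <- unique(data.frame(i = bonds$i, j = bonds$j))
    pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
    rownames(pairs) <- NULL
    if (any(pairs$i == pairs$j)) stop("self-loop bond detected")
    E <- matrix(0, nrow(pairs), schema_ncol(edge_schema),
                dimnames = list(NULL, schema_colnames(edge_schema)))
    E[, "distance"] <- sqrt(rowSums((rs$ca[pairs$i, , drop = FALSE] -
                                     rs$ca[pairs$j, , drop = FALSE])^2))
    tab <- table(factor(pair_id, levels = paste(pairs$i, pairs$j, sep = "_")),
                 factor(bonds$type, levels = bond_types))
    E[, bond_types] <- as.matrix(tab)[, bond_types, drop = FALSE]
  } else {
    pairs <- data.frame(i = integer(), j = integer())
    E <- matrix(0, 0, schema_ncol(edge_schema),
                dimnames = list(NULL, schema_colnames(edge_schema)))
  }

  nodes <- data.frame(chain = rs$residues$chain, resno = rs$residues$resno,
                      ins = rs$residues$ins, aa = aa,
                      key = residue_keys(rs), stringsAsFactors = FALSE)
  structure(list(protein_id = rs$protein_id, nodes = nodes, X = X,
                 edges = pairs, E = E, node_schema = node_schema,
                 edge_schema = edge_schema),
            class = "protein_graph")
}

#' @export
print.protein_graph <- function(x, ...) {
  cat("protein_graph", x$protein_id, "-", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges,", ncol(x$X), "node /", ncol(x$E),
      "edge feature dims\n")
  invisible(x)
}

#' Query an edge feature vector
#'
#' Symmetric lookup: `graph_edge_feature(g, u, v)` and
#' `graph_edge_feature(g, v, u)` return the same vector, or NULL when the
#' nodes are not connected.
#' @param g A `protein_graph`.
#' @param u,v Node indices (1-based).
#' @return Named numeric vector of edge features, or NULL.
#' @export
graph_edge_feature <- function(g, u, v) {
  k <- which((g$edges$i == min(u, v)) & (g$edges$j == max(u, v)))
  if (length(k) == 0L) return(NULL)
  g$E[k[1], ]
}

#' Write a protein graph container
#'
#' Stores a graph as a small directory: a versioned JSON manifest with the
#' protein id, node table and schemas, plus flat TSV arrays for node
#' features, edge list and edge features.  Round-trips through
#' [read_graph()].
#'
#' @param g A `protein_graph`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_graph <- function(g, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    container_version = "1.0",
    protein_id = g$protein_id,
    n_nodes = nrow(g$nodes), n_edges = nrow(g$edges),
    node_schema = lapply(g$node_schema$groups, as.list),
    edge_schema = lapply(g$edge_schema$groups, as.list),
    nodes = g$nodes)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(g$X, file.path(dir, "node_features.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(cbind(g$edges, g$E), file.path(dir, "edges.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a protein graph container written by [write_graph()]
#' @param dir Container directory.
#' @return A `protein_graph`.
#' @export
read_graph <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  if (is.null(mf$container_version))
    stop("not a graph container: ", dir)
  node_schema <- new_feature_schema(as.list(mf$node_schema))
  edge_schema <- new_feature_schema(as.list(mf$edge_schema))
  X <- as.matrix(utils::read.table(file.path(dir, "node_features.tsv"),
                                   header = TRUE, sep = "\t",
                                   check.names = FALSE))
  ed <- utils::read.table(file.path(dir, "edges.tsv"), header = TRUE,
                          sep = "\t", check.names = FALSE)
  nodes <- as.data.frame(mf$nodes, stringsAsFactors = FALSE)
  nodes$ins[is.na(nodes$ins)] <- ""
  structure(list(protein_id = mf$protein_id, nodes = nodes, X = X,
                 edges = data.frame(i = as.integer(ed$i),
                                    j = as.integer(ed$j)),
                 E = as.matrix(ed[, -(1:2), drop = FALSE]),
                 node_schema = node_schema, edge_schema = edge_schema),
            class = "protein_graph")
}
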