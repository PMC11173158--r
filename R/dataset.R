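# Whole / Interface / Chain dataset views of labeled protein graphs.

new_dataset_sample <- function(variant, graph, labels, provenance) {
  stopifnot(variant %in% c("whole", "interface", "chain"),
            length(labels) == nrow(graph$nodes),
            all(labels %in% c(0L, 1L)))
  structure(list(variant = variant, graph = graph,
                 labels = as.integer(labels), provenance = provenance),
            class = "dataset_sample")
}

#' @export
print.dataset_sample <- function(x, ...) {
  cat("dataset_sample [", x$variant, "] ", x$provenance$protein_id, ": ",
      nrow(x$graph$nodes), " nodes, ", nrow(x$graph$edges), " edges, ",
      sum(x$labels), " positive\n", sep = "")
  invisible(x)
}

# Node-induced subgraph; optionally drop edges spanning two chains.
subset_graph <- function(g, node_idx, drop_interchain = FALSE) {
  map <- match(seq_len(nrow(g$nodes)), node_idx)
  keep <- !is.na(map[g$edges$i]) & !is.na(map[g$edges$j])
  if (drop_interchain)
    keep <- keep & g$nodes$chain[g$edges$i] == g$nodes$chain[g$edges$j]
  edges <- data.frame(i = map[g$edges$i[keep]], j = map[g$edges$j[keep]])
  nodes <- g$nodes[node_idx, , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(protein_id = g$protein_id,
                 nodes = nodes,
                 X = g$X[node_idx, , drop = FALSE],
                 edges = edges, E = g$E[keep, , drop = FALSE],
                 node_schema = g$node_schema, edge_schema = g$edge_schema),
            class = "protein_graph")
}

#' Whole-protein dataset sample
#'
#' The entire complex as one graph; labels are the superposition (element-
#' wise OR) of all per-interface residue sets.
#'
#' @param graph A `protein_graph` of the full complex.
#' @param labels An `interface_labels` object aligned to `graph`.
#' @return A `dataset_sample` with variant "whole".
#' @export
make_whole <- function(graph, labels) {
  lab <- integer(nrow(graph$nodes))
  for (iface in labels$interfaces) lab[iface$residues] <- 1L
  stopifnot(identical(lab, as.integer(labels$labels)))
  new_dataset_sample("whole", graph, lab,
                     list(protein_id = graph$protein_id,
                          chains = unique(graph$nodes$chain),
                          interface_id = NA_integer_))
}

#' Interface dataset samples (pairs of interacting chains)
#'
#' One sample per chain pair sharing at least one interface residue.  Each
#' sample keeps all residues of both chains (inter-chain edges included);
#' labels are re-derived from the interfaces involving exactly that pair,
#' so a chain repeated across pairs may carry different labels.
#'
#' @inheritParams make_whole
#' @return List of `dataset_sample`s with variant "interface" (possibly
#'   empty).
#' @export
enumerate_chain_pairs <- function(graph, labels) {
  chains <- unique(graph$nodes$chain)
  out <- list()
  if (length(chains) < 2L) return(out)
  for (a in seq_len(length(chains) - 1L)) {
    for (b in seq.int(a + 1L, length(chains))) {
      pair <- c(chains[a], chains[b])
      ifaces <- Filter(function(f) setequal(f$chains, pair),
                       labels$interfaces)
      pos <- sort(unique(unlist(lapply(ifaces, `[[`, "residues"))))
      if (length(pos) == 0L) next
      node_idx <- which(graph$nodes$chain %in% pair)
      sub <- subset_graph(graph, node_idx)
      lab <- integer(length(node_idx))
      lab[match(pos, node_idx)] <- 1L
      out[[length(out) + 1L]] <- new_dataset_sample(
        "interface", sub, lab,
        list(protein_id = graph$protein_id, chains = pair,
             interface_id = ifaces[[1]]$id))
    }
  }
  out
}

#' Chain dataset samples
#'
#' One sample per chain with all inter-chain edges removed; labels are the
#' whole-protein (superposed) labels restricted to the chain.
#'
#' @inheritParams make_whole
#' @return List of `dataset_sample`s with variant "chain".
#' @export
make_chains <- function(graph, labels) {
  whole <- integer(nrow(graph$nodes))
  for (iface in labels$interfaces) whole[iface$residues] <- 1L
  lapply(unique(graph$nodes$chain), function(ch) {
    node_idx <- which(graph$nodes$chain == ch)
    sub <- subset_graph(graph, node_idx, drop_interchain = TRUE)
    new_dataset_sample("chain", sub, whole[node_idx],
                       list(protein_id = graph$protein_id, chains = ch,
                            interface_id = NA_integer_))
  })
}

#' Protein-level train/validation/test split
#'
#' Deterministic for a fixed seed and applied at the protein level, so
#' every sample extracted from one protein inherits the same split in all
#' three dataset variants.  Sizes follow the largest-remainder rounding of
#' `fractions`.
#'
#' @param protein_ids Character vector of unique protein identifiers.
#' @param fractions Length-3 non-negative numeric (train, validation,
#'   test) summing to 1.
#' @param seed Integer seed.
#' @return Named character vector mapping protein id to
#'   "train"/"validation"/"test", with attributes `seed` and `fractions`.
#' @export
split_dataset <- function(protein_ids, fractions = c(0.8, 0.1, 0.1),
                          seed = 1L) {
  stopifnot(length(fractions) == 3L, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-9,
            !anyDuplicated(protein_ids))
  n <- length(protein_ids)
  n_classes <- sum(fractions > 0)
  if (n < n_classes)
    stop("fewer proteins (", n, ") than non-empty split classes (",
         n_classes, ")")
  # largest-remainder apportionment
  exact <- fractions * n
  sizes <- floor(exact)
  rem <- exact - sizes
  short <- n - sum(sizes)
  if (short > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(short)]
    sizes[give] <- sizes[give] + 1L
  }
  # guarantee at least one protein per non-empty class
  for (k in which(fractions > 0 & sizes == 0)) {
    donor <- which.max(sizes)
    sizes[donor] <- sizes[donor] - 1L
    sizes[k] <- 1L
  }
  # shuffle the sorted id set so the assignment depends only on the set
  # of ids and the seed, not on their input order
  perm <- with_local_seed(seed, sample.int(n))
  ord <- sort(protein_ids)[perm]
  assign <- rep(c("train", "validation", "test"), times = sizes)
  out <- stats::setNames(assign, ord)[protein_ids]
  names(out) <- protein_ids
  attr(out, "seed") <- seed
  attr(out, "fractions") <- fractions
  out
}

# Run expr under a temporary RNG state so callers' streams are untouched.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Dataset manifest
#'
#' Summarizes a list of samples as the tabular manifest written next to
#' graph containers: one row per sample with its variant, chains, split
#' and size statistics.
#'
#' @param samples List of `dataset_sample`s.
#' @param split Optional protein-level split from [split_dataset()].
#' @return data.frame with columns sample_id, protein_id, variant, chains,
#'   split, n_nodes, n_edges, n_positive.
#' @export
dataset_manifest <- function(samples, split = NULL) {
  rows <- lapply(seq_along(samples), function(k) {
    s <- samples[[k]]
    pid <- s$provenance$protein_id
    data.frame(
      sample_id = paste(pid, s$variant,
                        paste(s$provenance$chains, collapse = ""),
                        sep = "_"),
      protein_id = pid, variant = s$variant,
      chains = paste(s$provenance$chains, collapse = ","),
      split = if (is.null(split)) NA_character_ else unname(split[pid]),
      n_nodes = nrow(s$graph$nodes), n_edges = nrow(s$graph$edges),
      n_positive = sum(s$labels), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
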