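# Synthetic multi-chain pseudo-protein complexes with planted interfaces.
#
# Chains are built residue-by-residue from ideal backbone internal
# coordinates (NeRF chain extension) so that torsion angles, C-alpha
# spacing and hydrogen-bondable backbone geometry are realistic enough for
# the secondary-structure heuristic and the bond detector to find
# structure.  Chains are then docked so a cross-chain contact region
# exists; interface labels are geometric by construction.

#' Synthetic complex specification
#'
#' @param n_chains Number of chains (>= 1).
#' @param residues_per_chain Integer range (length-2) or scalar; chain
#'   lengths are drawn uniformly from it.
#' @param contact_cutoff Inter-chain C-alpha radius (Angstrom) defining
#'   interface labels; must exceed `ca_spacing`.
#' @param ca_spacing Successive C-alpha distance (Angstrom, default 3.8).
#' @param feature_signal Strength in [0, 1] of the planted correlation
#'   between interface membership and the designated node feature
#'   channels.
#' @param noise_sd Gaussian noise added to the designated channels.
#' @param seed Integer seed.
#' @param signal_channels Node schema column names carrying the planted
#'   signal (defaults to ASA-like and hydrophobicity-like channels).
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_chains = 2L, residues_per_chain = c(60L, 60L),
                           contact_cutoff = 8, ca_spacing = 3.8,
                           feature_signal = 0.8, noise_sd = 0.3,
                           seed = 7L,
                           signal_channels = c("asa", "rel_asa",
                                               "meiler_hydrophobicity",
                                               "expasy_KYTJ820101")) {
  if (length(residues_per_chain) == 1L)
    residues_per_chain <- rep(residues_per_chain, 2L)
  stopifnot(n_chains >= 1L, length(residues_per_chain) == 2L,
            residues_per_chain[1] >= 2L,
            residues_per_chain[1] <= residues_per_chain[2],
            contact_cutoff > ca_spacing,
            feature_signal >= 0, feature_signal <= 1, noise_sd >= 0)
  structure(list(n_chains = as.integer(n_chains),
                 residues_per_chain = as.integer(residues_per_chain),
                 contact_cutoff = contact_cutoff, ca_spacing = ca_spacing,
                 feature_signal = feature_signal, noise_sd = noise_sd,
                 seed = as.integer(seed),
                 signal_channels = signal_channels),
            class = "synthetic_spec")
}

# NeRF atom placement: new atom at bond length L from c, bond angle theta
# (deg) b-c-new, torsion chi (deg) a-b-c-new.
.place_atom <- function(a, b, c3, L, theta, chi) {
  theta <- theta * pi / 180; chi <- chi * pi / 180
  bc <- c3 - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(bc[2] * n[3] - bc[3] * n[2],
         bc[3] * n[1] - bc[1] * n[3],
         bc[1] * n[2] - bc[2] * n[1])
  d <- c(-L * cos(theta), -L * sin(theta) * cos(chi),
         -L * sin(theta) * sin(chi))
  c3 + d[1] * bc + d[2] * m + d[3] * n
}

# Canonical torsions with a little jitter; classes H / E / C.
.torsions_for <- function(cls) {
  switch(cls,
         H = c(phi = -60 + stats::rnorm(1, 0, 4),
               psi = -45 + stats::rnorm(1, 0, 4)),
         E = c(phi = -120 + stats::rnorm(1, 0, 6),
               psi = 130 + stats::rnorm(1, 0, 6)),
         C = c(phi = stats::runif(1, -150, -60),
               psi = stats::runif(1, 60, 170)))
}

# Random secondary-structure plan: helix / strand segments joined by coil.
.sse_plan <- function(n) {
  plan <- character(0)
  while (length(plan) < n) {
    type <- sample(c("H", "E", "C"), 1, prob = c(0.45, 0.25, 0.30))
    len <- switch(type, H = sample(8:14, 1), E = sample(4:8, 1),
                  C = sample(2:6, 1))
    plan <- c(plan, rep(type, len))
  }
  plan[seq_len(n)]
}

# Build one chain's backbone (N, CA, C, O) from a torsion plan; RNG is
# taken from the current stream.
.chain_backbone <- function(n, plan, scale = 1) {
  bl <- c(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231) * scale
  ang <- c(n_ca_c = 111.2, ca_c_n = 116.2, c_n_ca = 121.7)
  tor <- t(vapply(plan, .torsions_for, numeric(2)))
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(bl["n_ca"], 0, 0)
  C[1, ] <- CA[1, ] + bl["ca_c"] *
    c(cos(pi - ang["n_ca_c"] * pi / 180), sin(pi - ang["n_ca_c"] * pi / 180), 0)
  for (i in seq_len(n - 1L)) {
    N[i + 1, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], bl["c_n"],
                              ang["ca_c_n"], tor[i, "psi"])
    CA[i + 1, ] <- .place_atom(CA[i, ], C[i, ], N[i + 1, ], bl["n_ca"],
                               ang["c_n_ca"], 180)
    C[i + 1, ] <- .place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], bl["ca_c"],
                              ang["n_ca_c"], tor[i + 1, "phi"])
  }
  for (i in seq_len(n)) {
    psi <- if (i < n) tor[i, "psi"] else 180
    O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], bl["c_o"], 120.5,
                          psi + 180)
  }
  list(N = N, CA = CA, C = C, O = O, plan = plan)
}

.chain_to_residue_set <- function(bb, chain_id, protein_id) {
  n <- nrow(bb$CA)
  aa <- sample(standard_aa(), n, replace = TRUE)
  residues <- data.frame(chain = chain_id, resno = seq_len(n), ins = "",
                         aa = aa, stringsAsFactors = FALSE)
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(res_index = i, elety = c("N", "CA", "C", "O"),
               elesy = c("N", "C", "C", "O"),
               x = c(bb$N[i, 1], bb$CA[i, 1], bb$C[i, 1], bb$O[i, 1]),
               y = c(bb$N[i, 2], bb$CA[i, 2], bb$C[i, 2], bb$O[i, 2]),
               z = c(bb$N[i, 3], bb$CA[i, 3], bb$C[i, 3], bb$O[i, 3]),
               stringsAsFactors = FALSE)
  }))
  residue_set(protein_id, residues, bb$CA, atoms)
}

#' Generate a single chain backbone
#'
#' Builds an n-residue chain from ideal backbone geometry with segments of
#' canonical helix/strand torsions interleaved with coil.  Successive
#' C-alpha distances equal the spec's `ca_spacing` to within 0.01 A and
#' the trace is self-avoiding (bounded retries, then error).
#'
#' @param n Number of residues (>= 2).
#' @param spec A [synthetic_spec()]; its seed fixes the result.
#' @param sse_plan Optional character vector (length n, values "H", "E",
#'   "C") overriding the random segment plan.
#' @param chain_id Chain identifier.
#' @return A single-chain `residue_set` with attribute `sse_plan`.
#' @export
generate_chain <- function(n, spec = synthetic_spec(), sse_plan = NULL,
                           chain_id = "A") {
  stopifnot(n >= 2L)
  with_local_seed(spec$seed,
                  .generate_chain_impl(n, spec, sse_plan, chain_id,
                                       paste0("synth_", spec$seed)))
}

.generate_chain_impl <- function(n, spec, sse_plan, chain_id, protein_id,
                                 max_retry = 60L) {
  scale <- spec$ca_spacing / 3.8
  for (try in seq_len(max_retry)) {
    plan <- if (is.null(sse_plan)) .sse_plan(n) else sse_plan
    bb <- .chain_backbone(n, plan, scale)
    d <- as.matrix(stats::dist(bb$CA))
    nonadj <- abs(row(d) - col(d)) >= 2
    if (n < 3L || min(d[nonadj]) > 2.0) {
      rs <- .chain_to_residue_set(bb, chain_id, protein_id)
      attr(rs, "sse_plan") <- plan
      return(rs)
    }
  }
  stop("could not build a self-avoiding chain of length ", n,
       " after ", max_retry, " retries")
}

.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

.transform_rs <- function(rs, R, shift) {
  xyz <- as.matrix(rs$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, shift, "+")
  rs$atoms$x <- xyz[, 1]; rs$atoms$y <- xyz[, 2]; rs$atoms$z <- xyz[, 3]
  rs$ca <- sweep(rs$ca %*% t(R), 2, shift, "+")
  rs
}

.merge_rs <- function(rs_list, protein_id) {
  residues <- do.call(rbind, lapply(rs_list, `[[`, "residues"))
  ca <- do.call(rbind, lapply(rs_list, `[[`, "ca"))
  offset <- 0L
  atoms <- do.call(rbind, lapply(rs_list, function(r) {
    a <- r$atoms
    a$res_index <- a$res_index + offset
    offset <<- offset + nrow(r$residues)
    a
  }))
  residue_set(protein_id, residues, ca, atoms)
}

#' Generate a multi-chain complex with a planted interface
#'
#' Chains are generated independently, randomly rotated, and docked one at
#' a time so that the closest cross-chain C-alpha approach lies a little
#' inside the contact cutoff -- guaranteeing at least one contact region.
#' Labels come from [geometric_labeler()] at the spec's cutoff.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `residue_set`, `labels` (an `interface_labels`), and
#'   `sse_plans` (per-chain secondary-structure plans).
#' @export
generate_complex <- function(spec = synthetic_spec()) {
  with_local_seed(spec$seed, .generate_complex_impl(spec))
}

.generate_complex_impl <- function(spec) {
  pid <- paste0("synth_", spec$seed)
  len_range <- seq.int(spec$residues_per_chain[1],
                       spec$residues_per_chain[2])
  lens <- len_range[sample.int(length(len_range), spec$n_chains,
                               replace = TRUE)]
  chains <- lapply(seq_len(spec$n_chains), function(k) {
    .generate_chain_impl(lens[k], spec, NULL, LETTERS[k], pid)
  })
  # center each chain on its centroid
  chains <- lapply(chains, function(r)
    .transform_rs(r, diag(3), -colMeans(r$ca)))
  placed <- list(chains[[1]])
  if (spec$n_chains >= 2L) {
    target <- stats::runif(spec$n_chains - 1L, 3.9, 4.6)
    for (k in seq.int(2L, spec$n_chains)) {
      prev_ca <- do.call(rbind, lapply(placed, `[[`, "ca"))
      rot <- .random_rotation()
      cand <- .transform_rs(chains[[k]], rot, c(0, 0, 0))
      # anchor a random residue of the candidate onto a random residue of
      # the complex so the line search always starts from deep overlap
      anchor <- prev_ca[sample.int(nrow(prev_ca), 1L), ] -
        cand$ca[sample.int(nrow(cand$ca), 1L), ]
      cand <- .transform_rs(cand, diag(3), anchor)
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      mind <- function(t) {
        ca <- sweep(cand$ca, 2, t * u, "+")
        min(sqrt(pmax(outer(rowSums(ca^2), rowSums(prev_ca^2), "+") -
                      2 * ca %*% t(prev_ca), 0)))
      }
      lo <- 0; hi <- 400
      if (mind(hi) < target[k - 1]) stop("no contact achievable")
      t_star <- stats::uniroot(function(t) mind(t) - target[k - 1],
                               c(lo, hi), tol = 1e-4)$root
      placed[[k]] <- .transform_rs(cand, diag(3), t_star * u)
    }
  }
  rs <- .merge_rs(placed, pid)
  # random rigid motion: real structures come in arbitrary global frames,
  # so absolute coordinates must carry no information across complexes
  rs <- .transform_rs(rs, .random_rotation(), stats::runif(3, -150, 150))
  labels <- geometric_labeler(rs, spec$contact_cutoff)
  list(residue_set = rs, labels = labels,
       sse_plans = lapply(chains, attr, "sse_plan"))
}

# Overwrite the designated channels with label-correlated draws:
# value = feature_signal * label + N(0, noise_sd).
.inject_signal <- function(graph, labels, spec) {
  cols <- match(spec$signal_channels, colnames(graph$X))
  if (anyNA(cols))
    stop("unknown signal channel(s): ",
         paste(spec$signal_channels[is.na(cols)], collapse = ", "))
  n <- nrow(graph$X)
  for (cc in cols)
    graph$X[, cc] <- spec$feature_signal * labels +
      stats::rnorm(n, 0, spec$noise_sd)
  graph
}

#' Generate a corpus of labeled synthetic protein graphs
#'
#' Runs the full native pipeline (secondary structure, bond detection,
#' graph construction) on each generated complex, then plants the
#' label-correlated feature signal on the designated channels.  Per-seed
#' deterministic.
#'
#' @param n_proteins Number of complexes (>= 3).
#' @param spec A [synthetic_spec()]; per-protein seeds are derived from
#'   `spec$seed`.
#' @return List of per-protein entries, each with `graph`
#'   (`protein_graph`), `labels` (`interface_labels`), `residue_set` and
#'   `protein_id`; class `synthetic_corpus`.
#' @export
generate_corpus <- function(n_proteins, spec = synthetic_spec()) {
  stopifnot(n_proteins >= 3L)
  sub_seeds <- with_local_seed(spec$seed,
                               sample.int(.Machine$integer.max - 1L,
                                          n_proteins))
  corpus <- lapply(seq_len(n_proteins), function(k) {
    sp <- spec
    sp$seed <- sub_seeds[k]
    cx <- generate_complex(sp)
    rs <- cx$residue_set
    rs$protein_id <- sprintf("synth_%03d", k)
    g <- build_graph(rs, assign_secondary_structure(rs), detect_bonds(rs))
    g <- with_local_seed(sub_seeds[k] %% 1000000L + 1L,
                         .inject_signal(g, cx$labels$labels, sp))
    list(protein_id = rs$protein_id, graph = g, labels = cx$labels,
         residue_set = rs)
  })
  structure(corpus, class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  nn <- vapply(x, function(p) nrow(p$graph$nodes), integer(1))
  pos <- vapply(x, function(p) sum(p$labels$labels), integer(1))
  cat("synthetic_corpus:", length(x), "complexes,",
      sum(nn), "residues,",
      sprintf("%.1f%% interface", 100 * sum(pos) / sum(nn)), "\n")
  invisible(x)
}

#' Materialize dataset variants from a synthetic corpus
#'
#' @param corpus A `synthetic_corpus` from [generate_corpus()].
#' @param variant "whole", "interface" or "chain".
#' @return List of `dataset_sample`s.
#' @export
corpus_samples <- function(corpus, variant = c("whole", "interface",
                                               "chain")) {
  variant <- match.arg(variant)
  out <- lapply(corpus, function(p) {
    switch(variant,
           whole = list(make_whole(p$graph, p$labels)),
           interface = enumerate_chain_pairs(p$graph, p$labels),
           chain = make_chains(p$graph, p$labels))
  })
  unlist(out, recursive = FALSE)
}
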