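# Whole / Interface / Chain dataset views and protein-level splits.

test_that("whole sample keeps everything and superposes labels", {
  tc <- tiny_complex()
  s <- make_whole(tc$graph, tc$labels)
  expect_equal(s$variant, "whole")
  expect_equal(nrow(s$graph$nodes), nrow(tc$graph$nodes))
  expect_equal(nrow(s$graph$edges), nrow(tc$graph$edges))
  union <- integer(nrow(tc$graph$nodes))
  for (f in tc$labels$interfaces) union[f$residues] <- 1L
  expect_equal(s$labels, union)
})

test_that("a single-chain protein has an all-zero whole sample and no pairs", {
  ch <- generate_chain(20, synthetic_spec(seed = 9))
  g <- build_graph(ch, assign_secondary_structure(ch), detect_bonds(ch))
  lab <- geometric_labeler(ch, 8)
  s <- make_whole(g, lab)
  expect_true(all(s$labels == 0L))
  expect_equal(length(enumerate_chain_pairs(g, lab)), 0L)
})

test_that("chain pairs: contacting pairs become samples, shared chains repeat", {
  rs <- three_chain_rs()          # A-B and B-C contact, A-C apart
  g <- three_chain_graph()
  lab <- geometric_labeler(rs, 8)
  pairs <- enumerate_chain_pairs(g, lab)
  expect_equal(length(pairs), 2L)
  pair_chains <- lapply(pairs, function(s) sort(s$provenance$chains))
  expect_true(any(vapply(pair_chains, identical, logical(1), c("A", "B"))))
  expect_true(any(vapply(pair_chains, identical, logical(1), c("B", "C"))))
  # chain B appears in both samples
  expect_true(all(vapply(pairs, function(s)
    "B" %in% s$graph$nodes$chain, logical(1))))
  # every interface sample spans exactly two chains and has a positive
  for (s in pairs) {
    expect_equal(length(unique(s$graph$nodes$chain)), 2L)
    expect_gte(sum(s$labels), 1L)
  }
})

test_that("OR of pair labels over pairs containing a chain equals its whole slice", {
  rs <- three_chain_rs()
  g <- three_chain_graph()
  lab <- geometric_labeler(rs, 8)
  whole <- make_whole(g, lab)
  pairs <- enumerate_chain_pairs(g, lab)
  for (ch in c("A", "B", "C")) {
    acc <- integer(sum(g$nodes$chain == ch))
    keys <- g$nodes$key[g$nodes$chain == ch]
    for (s in pairs) {
      if (!ch %in% s$provenance$chains) next
      m <- match(s$graph$nodes$key, keys)
      acc[m[!is.na(m)]] <- pmax(acc[m[!is.na(m)]],
                                s$labels[!is.na(m)])
    }
    expect_equal(acc, whole$labels[g$nodes$chain == ch])
  }
})

test_that("chain samples drop inter-chain edges and restrict whole labels", {
  rs <- three_chain_rs()
  g <- three_chain_graph()
  lab <- geometric_labeler(rs, 8)
  whole <- make_whole(g, lab)
  chains <- make_chains(g, lab)
  expect_equal(length(chains), 3L)
  total_nodes <- 0L
  for (s in chains) {
    expect_equal(length(unique(s$graph$nodes$chain)), 1L)
    expect_true(all(s$graph$nodes$chain[s$graph$edges$i] ==
                    s$graph$nodes$chain[s$graph$edges$j]))
    ch <- s$provenance$chains
    expect_equal(s$labels, whole$labels[g$nodes$chain == ch])
    total_nodes <- total_nodes + nrow(s$graph$nodes)
  }
  expect_equal(total_nodes, nrow(g$nodes))
})

test_that("split is deterministic, exact for round fractions, protein-level", {
  ids <- sprintf("p%02d", 1:10)
  sp <- split_dataset(ids, c(0.8, 0.1, 0.1), seed = 42)
  expect_equal(unname(table(sp)[c("train", "validation", "test")]),
               c(8L, 1L, 1L), ignore_attr = TRUE)
  sp2 <- split_dataset(ids, c(0.8, 0.1, 0.1), seed = 42)
  expect_identical(sp, sp2)
  expect_false(identical(unname(sp),
                         unname(split_dataset(ids, c(0.8, 0.1, 0.1),
                                              seed = 43))))
  expect_error(split_dataset(c("a", "b"), c(0.8, 0.1, 0.1), 1),
               "fewer proteins")
})

test_that("split depends only on the id set and seed, not input order", {
  ids <- sprintf("p%02d", 1:12)
  sp1 <- split_dataset(ids, c(0.7, 0.2, 0.1), seed = 5)
  perm <- rev(ids)
  sp2 <- split_dataset(perm, c(0.7, 0.2, 0.1), seed = 5)
  expect_identical(sp1[ids], sp2[ids])
})

test_that("all samples of a protein inherit its split in every variant", {
  corpus <- generate_corpus(6, synthetic_spec(seed = 11,
                                              residues_per_chain = c(15, 20)))
  ids <- vapply(corpus, `[[`, character(1), "protein_id")
  split <- split_dataset(ids, c(0.5, 0.25, 0.25), seed = 2)
  for (variant in c("whole", "interface", "chain")) {
    samples <- corpus_samples(corpus, variant)
    for (s in samples) {
      expect_true(s$provenance$protein_id %in% ids)
      expect_true(unname(split[s$provenance$protein_id]) %in%
                  c("train", "validation", "test"))
    }
    parts <- split_parts(samples, split)
    got <- unlist(lapply(parts, function(p)
      unique(vapply(p, function(s) s$provenance$protein_id, character(1)))))
    expect_false(anyDuplicated(got) > 0)
  }
})

test_that("node accounting: chain samples partition the whole sample", {
  corpus <- generate_corpus(4, synthetic_spec(seed = 13, n_chains = 3,
                                              residues_per_chain = c(15, 20)))
  for (p in corpus) {
    whole <- make_whole(p$graph, p$labels)
    chains <- make_chains(p$graph, p$labels)
    expect_equal(sum(vapply(chains, function(s) nrow(s$graph$nodes),
                            integer(1))),
                 nrow(whole$graph$nodes))
  }
})

test_that("dataset manifest summarizes counts per sample", {
  tc <- tiny_complex()
  samples <- c(list(make_whole(tc$graph, tc$labels)),
               enumerate_chain_pairs(tc$graph, tc$labels),
               make_chains(tc$graph, tc$labels))
  mf <- dataset_manifest(samples)
  expect_equal(nrow(mf), length(samples))
  expect_true(all(c("whole", "interface", "chain") %in% mf$variant))
  expect_equal(mf$n_nodes[1], nrow(tc$graph$nodes))
  expect_equal(mf$n_positive[1], sum(tc$labels$labels))
})
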