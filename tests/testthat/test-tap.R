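test_that("collapse_isoforms merges suffixed identifiers and sums counts", {
  ev <- make_evidence(list(
    list("r1", "pepA", "P1-1", 3),
    list("r1", "pepA", "P1-2", 2),
    list("r1", "pepB", "P2", 4)))
  out <- collapse_isoforms(ev)
  expect_equal(nrow(out), 2)
  expect_equal(out$spectral_count[out$protein_ids == "P1"], 5)
  expect_equal(out$spectral_count[out$protein_ids == "P2"], 4)

  # no suffixes: identity
  ev2 <- make_evidence(list(list("r1", "pepA", "P1", 3),
                            list("r1", "pepB", "P2;P3", 1)))
  expect_equal(collapse_isoforms(ev2)$spectral_count, ev2$spectral_count)
  expect_setequal(collapse_isoforms(ev2)$protein_ids, c("P1", "P2;P3"))

  # mixed table: output protein set equals suffix-stripped input set
  ev3 <- make_evidence(list(list("r1", "p1", "Q1-2;Q2", 1),
                            list("r2", "p2", "Q3-10", 2),
                            list("r1", "p3", "HLA-DRB1", 5)))
  got <- unique(unlist(strsplit(collapse_isoforms(ev3)$protein_ids, ";")))
  # only a trailing <delim><digits> suffix is an isoform tag
  expect_setequal(got, c("Q1", "Q2", "Q3", "HLA-DRB1"))
  # custom delimiter leaves "-" identifiers alone
  got2 <- unique(unlist(strsplit(collapse_isoforms(ev3, "_")$protein_ids,
                                 ";")))
  expect_true("HLA-DRB1" %in% got2)
})

test_that("group_proteins discards proteins without specific peptides", {
  # P1 peptides {a, b}, P2 peptides {b}: P2 has no specific peptide
  ev <- make_evidence(list(list("r1", "a", "P1", 5),
                           list("r1", "b", "P1;P2", 3)))
  g <- group_proteins(ev, min_peptides = 1)
  expect_equal(g$group_id, "P1")
  expect_equal(g$total_spectral_count, 8)

  # disjoint specific peptides: both retained as separate groups
  ev2 <- make_evidence(list(list("r1", "a", "P1", 5),
                            list("r1", "b", "P2", 9)))
  g2 <- group_proteins(ev2, min_peptides = 1)
  expect_setequal(g2$group_id, c("P1", "P2"))
  # sorted by total count descending
  expect_equal(g2$group_id[1], "P2")

  # identical peptide sets merge into one group, smallest member names it
  ev3 <- make_evidence(list(list("r1", "a", "P9;P2", 5),
                            list("r1", "b", "P9;P2", 1)))
  g3 <- group_proteins(ev3)
  expect_equal(g3$group_id, "P2")
  expect_equal(g3$members, "P2;P9")
  expect_equal(g3$n_peptides, 2)

  # min_peptides threshold drops thin groups
  expect_equal(nrow(group_proteins(ev2, min_peptides = 2)), 0)
  expect_equal(nrow(group_proteins(make_evidence(list()))), 0)
})

test_that("grouping is idempotent and order-invariant", {
  set.seed(11)
  rows <- list()
  for (i in 1:12) {
    prot <- paste0("P", sample(1:6, sample(1:2, 1)))
    rows[[i]] <- list(paste0("r", sample(1:2, 1)), paste0("pep", i),
                      paste(prot, collapse = ";"), sample(1:9, 1))
  }
  ev <- make_evidence(rows)
  g1 <- group_proteins(ev, min_peptides = 1)
  # permutation invariance
  g2 <- group_proteins(ev[sample(nrow(ev)), ], min_peptides = 1)
  expect_equal(g1, g2)
  # idempotence: re-express groups as evidence and regroup
  ev2 <- do.call(rbind, lapply(seq_len(nrow(g1)), function(i) {
    peps <- strsplit(g1$specific_peptides[i], ";")[[1]]
    make_evidence(lapply(peps, function(p)
      list("r1", p, g1$members[i], 1)))
  }))
  g3 <- group_proteins(ev2, min_peptides = 1)
  expect_setequal(g3$group_id, g1$group_id)
  expect_equal(g3$members[order(g3$group_id)],
               g1$members[order(g1$group_id)])
})

test_that("subtract_background removes the control union by identity", {
  bait <- group_proteins(make_evidence(list(
    list("r1", "a", "EGFR", 5), list("r1", "b", "GRB2", 3),
    list("r1", "c", "HSPX", 2))), min_peptides = 1)
  ctrl <- group_proteins(make_evidence(list(
    list("c1", "c", "HSPX", 9), list("c1", "d", "KRT1", 4))),
    min_peptides = 1)
  out <- subtract_background(bait, ctrl)
  expect_setequal(out$group_id, c("EGFR", "GRB2"))
  # empty control union: identity
  empty <- group_proteins(make_evidence(list()))
  expect_equal(subtract_background(bait, empty), bait)
})

test_that("build_network constructs bait-prey edges and drops self-edges", {
  # 2 baits sharing 1 prey -> 3 nodes, 2 edges
  g1 <- group_proteins(make_evidence(list(list("r", "a", "X", 4))),
                       min_peptides = 1)
  net <- build_network(list(B1 = g1, B2 = g1))
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$nodes$role[net$nodes$protein %in% c("B1", "B2")],
                  "bait")
  expect_equal(net$nodes$role[net$nodes$protein == "X"], "prey")
  expect_true(all(net$edges$evidence == "TAP"))

  # bait retrieving only itself -> 1 node, 0 edges
  self <- group_proteins(make_evidence(list(list("r", "a", "B1", 7))),
                         min_peptides = 1)
  net2 <- build_network(list(B1 = self))
  expect_equal(nrow(net2$nodes), 1)
  expect_equal(nrow(net2$edges), 0)

  # duplicated bait entries (two cell lines) sum support
  net3 <- build_network(list(g1, g1), baits = c("B1", "B1"))
  expect_equal(nrow(net3$edges), 1)
  expect_equal(net3$edges$support, 8)
})

test_that("annotation_filter selects annotated nodes in network order", {
  net <- interactome(data.frame(protein = c("A", "B", "C"),
                                role = c("bait", "prey", "prey")))
  ann <- data.frame(protein = c("A", "B", "C", "C"),
                    category = c("MAPK", "MAPK", "cell cycle", "apoptosis"))
  expect_equal(annotation_filter(net, ann, "MAPK"), c("A", "B"))
  expect_equal(annotation_filter(net, ann, c("MAPK", "apoptosis")),
               c("A", "B", "C"))
  expect_equal(annotation_filter(net, ann, character()), character())
  expect_warning(out <- annotation_filter(net, ann, "ERB"), "unknown")
  expect_equal(out, character())
})

test_that("tap_pipeline recovers the planted interactome", {
  cfg <- sim_config(seed = 5, n_baits = 4, n_prey_per_bait = 10,
                    n_background = 15, shared_peptide_fraction = 0.2)
  sim <- simulate_tap(cfg)
  res <- tap_pipeline(sim$evidence, sim$manifest)
  net <- res$network
  # subtraction safety: no control-set protein survives
  expect_length(intersect(net$nodes$protein, sim$truth$true_background), 0)
  # shared-only prey are discarded by grouping, everything else recovered
  expected <- sim$truth$true_edges
  expected <- expected[!expected$prey %in% sim$truth$shared_only_prey, ]
  got <- paste(net$edges$from, net$edges$to)
  expect_setequal(got, paste(expected$bait, expected$prey))
  # 20% of 10 prey per bait lack specific peptides
  expect_equal(length(sim$truth$shared_only_prey), 4 * 2)
  # row-order invariance of the full assembly
  ev2 <- sim$evidence[rev(seq_len(nrow(sim$evidence))), ]
  net2 <- tap_pipeline(ev2, sim$manifest)$network
  expect_equal(net2, net)
})
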