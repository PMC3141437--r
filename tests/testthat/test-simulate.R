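test_that("Yule trees are deterministic, binary and correctly sized", {
  t1 <- simulateTree(58, 1, seed = 5)
  t2 <- simulateTree(58, 1, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(ape::Ntip(t1), 58L)
  expect_equal(t1$Nnode, 57L)
  expect_true(ape::is.binary.phylo(t1))
  expect_false(identical(ape::write.tree(simulateTree(58, 1, seed = 6)),
                         ape::write.tree(t1)))
  t0 <- simulateTree(2, 1, seed = 1)
  expect_equal(ape::Ntip(t0), 2L)
  expect_true(all(t0$edge.length > 0))
  expect_error(simulateTree(1), ">= 2")
})

test_that("degenerate gain/loss settings are exact", {
  tree <- simulateTree(8, 1, seed = 2)
  cfg1 <- simulationConfig(n_tips = 8, n_families = 50, p0 = 1,
                           gain_rate = 0, loss_rate = 0, dup_rate = 0,
                           seed = 3)
  gc1 <- simulateGeneContent(tree, cfg1)
  expect_true(all(gc1$counts == 1L))
  expect_true(all(gc1$truth$root_presence))

  cfg0 <- simulationConfig(n_tips = 8, n_families = 50, p0 = 0,
                           gain_rate = 0, loss_rate = 0, seed = 3)
  expect_true(all(simulateGeneContent(tree, cfg0)$counts == 0L))
})

test_that("tip presence frequencies match the analytic two-state chain", {
  tree <- simulateTree(8, 1, seed = 7)
  cfg <- simulationConfig(n_tips = 8, n_families = 500, p0 = 0.5,
                          gain_rate = 0.1, loss_rate = 0.1, dup_rate = 0,
                          seed = 13)
  gc <- simulateGeneContent(tree, cfg)
  depth <- ape::node.depth.edgelength(tree)[seq_len(8)]
  for (s in seq_len(8)) {
    tp <- gainLossTransition(depth[s], 0.1, 0.1)
    p_analytic <- cfg$p0 * tp[1, "from1"] + (1 - cfg$p0) * tp[1, "from0"]
    p_emp <- mean(gc$counts[, tree$tip.label[s]] > 0)
    se <- sqrt(p_analytic * (1 - p_analytic) / cfg$n_families)
    expect_lt(abs(p_emp - p_analytic), 3 * se + 1e-9)
  }
})

test_that("Brownian simulation has the exact degenerate and moment behaviour", {
  tree <- readTree(text = "(A:1,B:1);")
  expect_equal(unname(simulateContinuous(tree, 0, rootValue = 3,
                                         seed = 1)[1:2]), c(3, 3))
  diffs <- vapply(1:2000, function(s) {
    v <- simulateContinuous(tree, 1, 0, seed = s)
    v[["A"]] - v[["B"]]
  }, 0)
  # tip difference ~ Normal(0, 2); var of sample variance ~ 2*4/(n-1)
  expect_lt(abs(var(diffs) - 2), 3 * sqrt(2 * 4 / 1999))
  expect_identical(simulateContinuous(tree, 1, 0, seed = 9),
                   simulateContinuous(tree, 1, 0, seed = 9))
  expect_error(simulateContinuous(tree, -1), "non-negative")
})

test_that("pseudogenization moves the target tip's copies as a binomial", {
  tree <- simulateTree(6, 1, seed = 4)
  base <- simulationConfig(n_tips = 6, n_families = 300, dup_rate = 0.5,
                           pseudo_target = tree$tip.label[1],
                           pseudo_fraction = 0, seed = 21)
  gc <- simulateGeneContent(tree, base)
  m0 <- simulateGenomeMetadata(tree, gc$counts, base)
  expect_true(all(m0$pseudo == 0L))
  expect_true(all(m0$genomes$pseudogene_bp == 0))

  full <- base; full$pseudo_fraction <- 1
  m1 <- simulateGenomeMetadata(tree, gc$counts, full)
  expect_true(all(m1$functional[, tree$tip.label[1]] == 0L))

  frac <- base; frac$pseudo_fraction <- 0.64
  m2 <- simulateGenomeMetadata(tree, gc$counts, frac)
  n_copies <- sum(gc$counts[, tree$tip.label[1]])
  n_pseudo <- sum(m2$pseudo[, tree$tip.label[1]])
  expect_lt(abs(n_pseudo - 0.64 * n_copies),
            3 * sqrt(n_copies * 0.64 * 0.36))
  # partition invariant holds exactly
  g <- m2$genomes
  expect_true(all(g$coding_bp + g$noncoding_bp + g$pseudogene_bp ==
                    g$genome_size_bp))
  bad <- base; bad$pseudo_target <- "nosuchtip"; bad$pseudo_fraction <- 0.5
  expect_error(simulateGenomeMetadata(tree, gc$counts, bad), "target")
})

test_that("emitted files re-parse to the in-memory objects exactly", {
  dir <- withr::local_tempdir()
  d <- simulateDataset(simulationConfig(n_tips = 10, n_families = 60,
                                        seed = 17), dir = dir)
  groups <- readOrthoGroups(file.path(dir, "groups.txt"))
  genomes <- readGenomeTable(file.path(dir, "genomes.tsv"))
  pg <- readPseudogenes(file.path(dir, "pseudogenes.tsv"))
  x <- buildOrthologSet(groups, genomes, pg)
  expect_identical(functionalCounts(x), functionalCounts(d$orthoset))
  expect_identical(pseudoCounts(x), pseudoCounts(d$orthoset))
  expect_identical(genomes$finished, genomeData(d$orthoset)$finished)
  tr <- readTree(file.path(dir, "tree.nwk"))
  expect_setequal(tr$tip.label, d$tree$tip.label)
  expect_true(file.exists(file.path(dir, "truth.json")))

  d2 <- simulateDataset(simulationConfig(n_tips = 10, n_families = 60,
                                         seed = 17))
  expect_identical(functionalCounts(d2$orthoset),
                   functionalCounts(d$orthoset))
})

test_that("phenotypes and clade labels are consistent with the tree", {
  tree <- simulateTree(12, 1, seed = 8)
  ph <- simulatePhenotypes(tree, seed = 3)
  expect_equal(rownames(ph$tips), tree$tip.label)
  expect_identical(ph$tips,
                   simulatePhenotypes(tree, seed = 3)$tips)
  cl <- assignClades(tree)
  expect_setequal(names(cl), tree$tip.label)
  expect_equal(sort(unique(unname(cl))), c("clade1", "clade2"))
  # clade1 is the larger basal subtree
  expect_gte(sum(cl == "clade1"), sum(cl == "clade2"))
})

test_that("clade-specific edge rates scale contrast variance", {
  tree <- ape::stree(8, "balanced")
  tree$edge.length <- rep(1, nrow(tree$edge))
  cl <- setNames(rep(c("clade1", "clade2"), each = 4), tree$tip.label)
  rates <- cladeEdgeRates(tree, cl, c(clade1 = 4, clade2 = 1))
  # terminal edges of clade1 tips carry rate 4
  term <- tree$edge[, 2] <= 8
  tip_rate <- rates[term][order(tree$edge[term, 2])]
  expect_equal(unname(tip_rate), rep(c(4, 1), each = 4))
})
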