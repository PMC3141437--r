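test_that("core definition behaves at the k boundary", {
  # 5 genomes, 3 finished; one group absent from one finished genome
  fc <- matrix(1L, 3, 5, dimnames = list(paste0("g", 1:3), paste0("s", 1:5)))
  fc[2, 1] <- 0L   # s1 is finished
  fc[3, 4] <- 0L   # s4 is a draft
  x <- make_oset(fc, finished = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(coreGroups(computeCore(x, 0L, draftWildcard = TRUE)),
               c("g1", "g3"))
  expect_equal(coreGroups(computeCore(x, 1L, draftWildcard = TRUE)),
               c("g1", "g2", "g3"))
  # without the draft wildcard the draft absence excludes g3
  expect_equal(coreGroups(computeCore(x, 0L, draftWildcard = FALSE)), "g1")
  expect_equal(coreMissingFinished(computeCore(x, 1L, TRUE))$g2, "s1")
  expect_error(computeCore(x, 4L), "finished")
})

test_that("a matrix with no absences puts every group in the strict core", {
  x <- make_oset(matrix(1L, 4, 3, dimnames = list(paste0("g", 1:4),
                                                  paste0("s", 1:3))))
  expect_equal(coreGroups(computeCore(x, 0L)), paste0("g", 1:4))
})

test_that("pseudogene-only presence is retained but annotated", {
  fc <- matrix(1L, 2, 3, dimnames = list(c("g1", "g2"), c("A", "B", "C")))
  pc <- fc; pc[] <- 0L
  fc["g1", "B"] <- 0L; pc["g1", "B"] <- 1L
  x <- make_oset(fc, pc)
  res <- computeCore(x, 0L, presenceMode = "any_copy")
  expect_true("g1" %in% coreGroups(res))
  expect_equal(coreFunctionalLoss(res)$g1, "B")
  # functional_only mode drops it
  expect_false("g1" %in% coreGroups(computeCore(x, 0L,
                                                presenceMode = "functional_only")))
})

test_that("core computation matches the brute-force scan for k = 0..3", {
  for (seed in 1:8) {
    x <- random_oset(200, 10, seed)
    for (k in 0:3) {
      expect_equal(coreGroups(computeCore(x, k, TRUE, "any_copy")),
                   bf_core(x, k, TRUE, "any_copy"))
      expect_equal(coreGroups(computeCore(x, k, FALSE, "functional_only")),
                   bf_core(x, k, FALSE, "functional_only"))
      expect_equal(coreGroups(computeCore(x, k, TRUE, "any_copy",
                                          singleCopy = TRUE)),
                   bf_core(x, k, TRUE, "any_copy", single = TRUE))
    }
  }
})

test_that("core sets are nested: strict within RCF within RCF1..RCF3", {
  for (seed in 11:20) {
    x <- random_oset(120, 8, seed)
    strict <- coreGroups(computeCore(x, 0L, FALSE))
    prev <- coreGroups(computeCore(x, 0L, TRUE))
    expect_true(all(strict %in% prev))
    for (k in 1:3) {
      cur <- coreGroups(computeCore(x, k, TRUE))
      expect_true(all(prev %in% cur))
      prev <- cur
    }
    expect_true(all(coreGroups(computeCore(x, 1L, TRUE, singleCopy = TRUE))
                    %in% coreGroups(computeCore(x, 1L, TRUE))))
  }
})

test_that("planted phenotype signatures are recovered exactly", {
  set.seed(42)
  ng <- 60; ns <- 10
  flag <- c(rep(TRUE, 4), rep(FALSE, 6))
  fc <- matrix(rbinom(ng * ns, 2, 0.6), ng, ns,
               dimnames = list(sprintf("g%02d", 1:ng), paste0("s", 1:ns)))
  planted <- paste0("g", sprintf("%02d", 1:7))
  fc[1:7, ] <- 0L
  fc[1:7, flag] <- 1L
  # make sure no unplanted group mimics the pattern
  fc[-(1:7), 5] <- pmax(fc[-(1:7), 5], 1L)  # s5 is flag-negative
  x <- make_oset(fc, finished = rep(TRUE, ns),
                 flags = data.frame(filamentous = flag))
  sig <- phenotypeSignature(x, "filamentous", mode = "all_positive")
  expect_setequal(sig$group_id, planted)
  expect_error(phenotypeSignature(x, "nosuchflag"), "flag")
})

test_that("signature modes nest and pseudo-only positives are reported", {
  fc <- matrix(0L, 2, 4, dimnames = list(c("g1", "g2"),
                                         c("P1", "P2", "N1", "N2")))
  pc <- fc
  fc[, c("P1", "P2")] <- 1L
  fc["g2", "P2"] <- 0L; pc["g2", "P2"] <- 1L  # pseudogenized in a positive
  flag <- c(TRUE, TRUE, FALSE, FALSE)
  x <- make_oset(fc, pc, finished = c(TRUE, FALSE, TRUE, TRUE),
                 flags = data.frame(heterocystous = flag))
  sig <- phenotypeSignature(x, "heterocystous", mode = "finished_positive")
  expect_setequal(sig$group_id, c("g1", "g2"))
  expect_equal(sig$pseudo_only[sig$group_id == "g2"], "P2")
  all_pos <- phenotypeSignature(x, "heterocystous", mode = "all_positive")
  expect_true(all(all_pos$group_id %in% sig$group_id))
})

test_that("a fully positive flag reduces the signature to the functional core", {
  for (seed in 3:5) {
    x <- random_oset(100, 6, seed)
    gd <- genomeData(x)
    y <- make_oset(functionalCounts(x), pseudoCounts(x),
                   finished = gd$finished,
                   flags = data.frame(diazotroph = rep(TRUE, 6)))
    sig <- phenotypeSignature(y, "diazotroph", mode = "all_positive",
                              presenceMode = "functional_only")
    core <- coreGroups(computeCore(y, 0L, FALSE, "functional_only"))
    expect_setequal(sig$group_id, core)
  }
})

test_that("clade signatures match brute force and exclude outgroups", {
  set.seed(9)
  clade <- c("clade1", "clade1", "clade1", "clade2", "clade2", "outgroup")
  for (seed in 1:5) {
    x0 <- random_oset(150, 6, seed)
    x <- make_oset(functionalCounts(x0), pseudoCounts(x0),
                   finished = genomeData(x0)$finished, clade = clade)
    got <- cladeSignature(x, "clade1", "clade2")
    cn <- copyNumbers(x, "any_copy")
    fin <- genomeData(x)$finished
    want <- groupIds(x)[vapply(seq_len(nrow(cn)), function(g)
      all(cn[g, clade == "clade1" & fin] > 0) &&
        all(cn[g, clade == "clade2"] == 0), NA)]
    expect_equal(got, want)
  }
  expect_error(cladeSignature(make_oset(matrix(1L, 1, 2, dimnames =
    list("g1", c("A", "B")))), "clade1", "clade2"), "clade")
})

test_that("per-genome missing orthologs distinguish absent from pseudogenized", {
  fc <- matrix(1L, 3, 4, dimnames = list(paste0("g", 1:3),
                                         c("NoAzSim", "B", "C", "D")))
  pc <- fc; pc[] <- 0L
  fc["g1", "NoAzSim"] <- 0L; pc["g1", "NoAzSim"] <- 1L
  fc["g2", "NoAzSim"] <- 0L
  x <- make_oset(fc, pc)
  res <- missingInGenome(x, "NoAzSim")
  expect_equal(res$group_id, c("g1", "g2"))
  expect_equal(res$status, c("pseudogenized", "absent"))
  expect_equal(nrow(missingInGenome(x, "B")), 0L)
  expect_error(missingInGenome(x, "Z"), "unknown")

  for (seed in 6:9) {
    y <- random_oset(120, 7, seed)
    fcy <- functionalCounts(y)
    for (g in genomeIds(y)[1:2]) {
      got <- missingInGenome(y, g)$group_id
      others <- setdiff(genomeIds(y), g)
      want <- groupIds(y)[fcy[, g] == 0 &
                            apply(fcy[, others, drop = FALSE] > 0, 1, all)]
      expect_equal(got, want)
    }
  }
})
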