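test_that("Fitch reconstruction handles the textbook cases", {
  tr <- readTree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  rec <- fitchStates(tr, c(A = 1, B = 1, C = 0, D = 0))
  expect_equal(reconstructionCost(rec), 1)
  expect_setequal(rootState(rec), c("0", "1"))

  rec1 <- fitchStates(tr, c(A = 1, B = 1, C = 1, D = 1))
  expect_equal(reconstructionCost(rec1), 0)
  expect_true(all(vapply(nodeStates(rec1), identical, NA, "1")))
  expect_false(any(equivocalBranches(rec1)))
  expect_error(fitchStates(tr, c(A = 1, B = 1, C = 0)), "D")
})

test_that("Fitch cost and root set match exhaustive enumeration", {
  n_ok <- 0L
  for (seed in 1:40) {
    nt <- sample(4:7, 1)
    tr <- random_binary_tree(nt, seed)
    states <- setNames(sample(0:1, nt, replace = TRUE), tr$tip.label)
    if (length(unique(states)) == 1L) next
    rec <- fitchStates(tr, states)
    bf <- bf_fitch(tr, states)
    expect_equal(reconstructionCost(rec), bf$cost)
    expect_equal(sort(rootState(rec)), bf$root)
    n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 25L)
})

test_that("Fitch change count is invariant under re-rooting", {
  for (seed in 1:10) {
    tr <- random_binary_tree(8, seed)
    set.seed(seed)
    states <- setNames(sample(0:1, 8, replace = TRUE), tr$tip.label)
    if (length(unique(states)) == 1L) next
    c0 <- reconstructionCost(fitchStates(tr, states))
    for (tip in sample(tr$tip.label, 2)) {
      tr2 <- ape::root(ape::unroot(tr), outgroup = tip, resolve.root = TRUE)
      expect_equal(reconstructionCost(fitchStates(tr2, states)), c0)
    }
  }
})

test_that("vectorised binary Fitch agrees with the general implementation", {
  d <- simulateDataset(simulationConfig(n_tips = 10, n_families = 60,
                                        seed = 23))
  pres <- presenceMatrix(d$orthoset, "any_copy")
  ri <- rootContentInterval(d$orthoset, d$tree)
  for (g in sample(groupIds(d$orthoset), 15)) {
    st <- setNames(as.integer(pres[g, ]), colnames(pres))
    rec <- fitchStates(d$tree, st)
    want <- if (setequal(rootState(rec), "1")) "sure"
            else if (setequal(rootState(rec), c("0", "1"))) "ambiguous"
            else "absent"
    got <- if (g %in% ri$sure) "sure"
           else if (g %in% ri$ambiguous) "ambiguous" else "absent"
    expect_equal(got, want)
    expect_equal(unname(ri$changes[g]), reconstructionCost(rec))
  }
})

test_that("root content interval counts sure and ambiguous groups", {
  tr <- readTree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  fc <- rbind(everywhere = c(1L, 1L, 1L, 1L),
              single_tip = c(1L, 0L, 0L, 0L),
              split = c(1L, 1L, 0L, 0L))
  colnames(fc) <- c("A", "B", "C", "D")
  x <- make_oset(fc)
  ri <- rootContentInterval(x, tr)
  expect_equal(ri$min_genes, 1L)
  expect_equal(ri$max_genes, 2L)
  expect_equal(ri$sure, "everywhere")
  expect_equal(ri$ambiguous, "split")
  bad <- make_oset(matrix(1L, 1, 2, dimnames = list("g", c("A", "Z"))))
  expect_error(rootContentInterval(bad, tr), "tip")
})

test_that("linear-cost Sankoff handles exact cases and matches enumeration", {
  tr <- readTree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  rec2 <- sankoffLinear(tr, c(A = 2, B = 2, C = 2, D = 2))
  expect_equal(reconstructionCost(rec2), 0)
  expect_equal(rootState(rec2), 2L)

  tr2 <- readTree(text = "(A:1,B:1);")
  rec04 <- sankoffLinear(tr2, c(A = 0, B = 4))
  expect_equal(reconstructionCost(rec04), 4)
  expect_equal(sort(rootState(rec04)), 0:4)

  for (seed in 1:25) {
    nt <- sample(4:6, 1)
    tr <- random_binary_tree(nt, seed + 100)
    copies <- setNames(sample(0:3, nt, replace = TRUE), tr$tip.label)
    rec <- sankoffLinear(tr, copies, maxState = 3)
    bf <- bf_sankoff(tr, copies, max_state = 3)
    expect_equal(reconstructionCost(rec), bf$cost)
    expect_equal(sort(rootState(rec)), bf$root)
  }
  expect_error(sankoffLinear(tr2, c(A = -1, B = 2)), "negative")
})

test_that("copy-number root interval sums per-group root ranges", {
  tr <- readTree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  fc <- rbind(g1 = c(2L, 2L, 2L, 2L), g2 = c(0L, 0L, 4L, 4L))
  colnames(fc) <- c("A", "B", "C", "D")
  ci <- copyNumberRootInterval(make_oset(fc), tr)
  expect_equal(unname(ci$rootRange["g1", ]), c(2, 2))
  expect_equal(unname(ci$rootRange["g2", ]), c(0, 4))
  expect_equal(ci$min_copies, 2)
  expect_equal(ci$max_copies, 6)
})

test_that("squared-change parsimony solves the closed-form cases", {
  star <- readTree(text = "(A:1,B:1,C:1);")
  rec <- squaredChange(star, c(A = 2, B = 4, C = 6))
  expect_equal(rootState(rec), 4)

  two <- readTree(text = "(A:1,B:1);")
  expect_equal(rootState(squaredChange(two, c(A = 2, B = 4))), 3)
  # weighted two-tip root is the inverse-branch-length weighted mean (the
  # GLS/Brownian root estimate)
  twow <- readTree(text = "(A:1,B:3);")
  expect_equal(rootState(squaredChange(twow, c(A = 0, B = 4),
                                       weighted = TRUE)),
               (0 / 1 + 4 / 3) / (1 / 1 + 1 / 3))
  zero <- readTree(text = "(A:0,B:1);")
  expect_error(squaredChange(zero, c(A = 1, B = 2), weighted = TRUE),
               "branch")
})

test_that("squared-change values match a generic convex optimizer", {
  for (seed in 1:10) {
    tr <- random_binary_tree(8, seed + 300)
    vals <- setNames(rnorm(8, 50, 10), tr$tip.label)
    for (weighted in c(FALSE, TRUE)) {
      rec <- squaredChange(tr, vals, weighted = weighted)
      w <- if (weighted) tr$edge.length else rep(1, nrow(tr$edge))
      obj <- function(z) {
        full <- c(vals[tr$tip.label], z)
        sum((full[tr$edge[, 1]] - full[tr$edge[, 2]])^2 / w)
      }
      opt <- optim(rep(mean(vals), tr$Nnode), obj, method = "BFGS",
                   control = list(reltol = 1e-14, maxit = 2000))
      expect_equal(nodeValues(rec)[9:15], opt$par, tolerance = 1e-5,
                   ignore_attr = TRUE)
      expect_lte(reconstructionCost(rec), opt$value + 1e-8)
      # local optimality: random perturbations never improve the objective
      for (r in 1:20) {
        pert <- nodeValues(rec)[9:15] + rnorm(7, 0, 0.5)
        expect_gte(obj(pert), reconstructionCost(rec) - 1e-10)
      }
    }
  }
})

test_that("ancestral gene-count recovery improves as the BM rate shrinks", {
  tree <- simulateTree(32, 1, seed = 12)
  root_val <- 4300
  err <- vapply(c(4, 0.25), function(s2) {
    e <- vapply(1:30, function(r) {
      v <- simulateContinuous(tree, s2 * 1e4, root_val, seed = 7000 + r)
      tips <- setNames(v[seq_len(32)], tree$tip.label)
      abs(rootState(squaredChange(tree, tips)) - root_val)
    }, 0)
    mean(e)
  }, 0)
  expect_lt(err[2], err[1])
})
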