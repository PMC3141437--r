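# Fixture builders and independent brute-force oracles used across tests.

make_oset <- function(fc, pc = NULL, finished = NULL, clade = NULL,
                      flags = NULL) {
  if (is.null(finished)) finished <- rep(TRUE, ncol(fc))
  gd <- data.frame(finished = finished,
                   row.names = colnames(fc), stringsAsFactors = FALSE)
  if (!is.null(clade)) gd$clade <- clade
  if (!is.null(flags)) gd <- cbind(gd, flags)
  OrthologSet(fc, pc, genomeData = gd)
}

random_oset <- function(ngroups, ngenomes, seed, p_zero = 0.3,
                        p_pseudo = 0.15) {
  set.seed(seed)
  fc <- matrix(rpois(ngroups * ngenomes, 1.2), ngroups, ngenomes)
  fc[runif(length(fc)) < p_zero] <- 0L
  pc <- matrix(rbinom(ngroups * ngenomes, 1L, p_pseudo), ngroups, ngenomes)
  dimnames(fc) <- dimnames(pc) <-
    list(sprintf("g%03d", seq_len(ngroups)), sprintf("s%02d", seq_len(ngenomes)))
  n_fix <- min(4L, ngenomes)  # enough finished genomes for k up to 3
  finished <- c(rep(TRUE, n_fix), runif(ngenomes - n_fix) < 0.7)
  make_oset(fc, pc, finished = finished)
}

# Exhaustive per-group scan for (relaxed) core membership
bf_core <- function(x, k, wildcard, mode, single = FALSE) {
  cn <- copyNumbers(x, mode)
  fc <- functionalCounts(x)
  fin <- genomeData(x)$finished
  keep <- vapply(seq_len(nrow(cn)), function(g) {
    pres <- cn[g, ] > 0
    ok <- sum(!pres[fin]) <= k
    if (!wildcard) ok <- ok && all(pres[!fin])
    if (single) ok <- ok && all(fc[g, pres] == 1)
    ok
  }, NA)
  groupIds(x)[keep]
}

# Exhaustive Fitch: minimise changes over all internal-node assignments
bf_fitch <- function(tree, tip_states) {
  nt <- ape::Ntip(tree)
  states <- sort(unique(as.character(tip_states)))
  obs <- as.character(tip_states[tree$tip.label])
  nint <- tree$Nnode
  grid <- do.call(expand.grid, c(rep(list(states), nint),
                                 stringsAsFactors = FALSE))
  best <- Inf; root_states <- character()
  root <- nt + 1L
  for (i in seq_len(nrow(grid))) {
    assign_all <- c(obs, unlist(grid[i, ], use.names = FALSE))
    chg <- sum(assign_all[tree$edge[, 1L]] != assign_all[tree$edge[, 2L]])
    if (chg < best) { best <- chg; root_states <- assign_all[root] }
    else if (chg == best) root_states <- union(root_states, assign_all[root])
  }
  list(cost = best, root = sort(root_states))
}

# Exhaustive Sankoff with |i-j| costs
bf_sankoff <- function(tree, tip_copies, max_state) {
  nt <- ape::Ntip(tree)
  obs <- as.integer(tip_copies[tree$tip.label])
  nint <- tree$Nnode
  grid <- do.call(expand.grid, rep(list(0:max_state), nint))
  best <- Inf; root_states <- integer()
  root <- nt + 1L
  for (i in seq_len(nrow(grid))) {
    assign_all <- c(obs, as.integer(grid[i, ]))
    cost <- sum(abs(assign_all[tree$edge[, 1L]] - assign_all[tree$edge[, 2L]]))
    if (cost < best) { best <- cost; root_states <- assign_all[root] }
    else if (cost == best) root_states <- union(root_states, assign_all[root])
  }
  list(cost = best, root = sort(root_states))
}

random_binary_tree <- function(ntips, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntips)
  tr$edge.length <- tr$edge.length + 0.05  # keep lengths strictly positive
  tr
}
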