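## Tree helpers over ape "phylo" objects --------------------------------------

.children_list <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge)))
    ch[[tree$edge[i, 1L]]] <- c(ch[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  ch
}

.postorder_internal <- function(tree) {
  # internal nodes in child-before-parent order: sort by last occurrence in
  # the postorder edge list (a node's final child edge closes its subtree)
  ids <- reorder(tree, "postorder")$edge[, 1L]
  rev(unique(rev(ids)))
}

.root_node <- function(tree) ape::Ntip(tree) + 1L

## Discrete parsimony ----------------------------------------------------------

#' Fitch parsimony ancestral state reconstruction
#'
#' Bottom-up Fitch pass (set intersection where non-empty, else union, the
#' union counting one change) followed by a top-down refinement that narrows
#' every node to the states attainable in at least one most-parsimonious
#' reconstruction. Polytomies are handled by iterated pairwise
#' intersection/union in child order. A branch is flagged equivocal when the
#' reconstruction at either endpoint is ambiguous (more than one attainable
#' state), the situation drawn as bi-coloured branches on trait maps.
#'
#' @param tree rooted ape \code{phylo}
#' @param tipStates vector of discrete states named by tip label (any finite
#'   alphabet; factors and integers allowed)
#' @return an \linkS4class{AncestralReconstruction} (method "fitch"); the
#'   \code{states} slot is indexed by ape node number, \code{cost} is the
#'   minimum change count
#' @export
fitchStates <- function(tree, tipStates) {
  nt <- ape::Ntip(tree)
  if (!all(tree$tip.label %in% names(tipStates)))
    stop("tip(s) missing a state: ",
         paste(setdiff(tree$tip.label, names(tipStates)), collapse = ", "))
  obs <- as.character(tipStates[tree$tip.label])
  if (anyNA(obs)) stop("NA tip state")
  alph <- sort(unique(obs))
  k <- length(alph)
  ch <- .children_list(tree)
  n_node <- nt + tree$Nnode

  # Fitch down-pass on state sets (logical masks over the alphabet)
  down <- matrix(FALSE, n_node, k)
  down[cbind(seq_len(nt), match(obs, alph))] <- TRUE
  cost <- 0L
  for (v in .postorder_internal(tree)) {
    s <- down[ch[[v]][1L], ]
    for (c2 in ch[[v]][-1L]) {
      i <- s & down[c2, ]
      if (any(i)) s <- i
      else { s <- s | down[c2, ]; cost <- cost + 1L }
    }
    down[v, ] <- s
  }

  # Unit-cost Sankoff pass for exact MPR state sets
  C <- matrix(Inf, n_node, k)
  C[cbind(seq_len(nt), match(obs, alph))] <- 0
  for (v in .postorder_internal(tree)) {
    # per child the contribution for state s is min(C_c(s), min_t C_c(t)+1)
    contrib <- vapply(ch[[v]], function(cc)
      pmin(C[cc, ], min(C[cc, ]) + 1), numeric(k))
    C[v, ] <- rowSums(matrix(contrib, nrow = k))
  }
  allowed <- matrix(FALSE, n_node, k)
  root <- .root_node(tree)
  allowed[root, ] <- C[root, ] == min(C[root, ])
  edges <- reorder(tree, "postorder")$edge
  for (i in rev(seq_len(nrow(edges)))) {  # preorder: parent before child
    p <- edges[i, 1L]; v <- edges[i, 2L]
    if (v <= nt) { allowed[v, ] <- C[v, ] == 0; next }
    ok <- rep(FALSE, k)
    for (s in which(allowed[p, ])) {
      val <- C[v, ] + (seq_len(k) != s)
      ok <- ok | val == min(val)
    }
    allowed[v, ] <- ok
  }
  states <- lapply(seq_len(n_node), function(v) alph[allowed[v, ]])
  equiv <- vapply(seq_len(nrow(tree$edge)), function(i)
    sum(allowed[tree$edge[i, 1L], ]) > 1L ||
      sum(allowed[tree$edge[i, 2L], ]) > 1L, NA)
  new("AncestralReconstruction", method = "fitch", tree = tree,
      states = states, values = numeric(), cost = as.numeric(cost),
      equivocal = equiv)
}

#' Binary-presence Fitch root sets for every group at once
#'
#' Vectorised Fitch down-pass over all ortholog groups of a matrix using
#' 2-bit state-set codes (1 = absent only, 2 = present only, 3 = ambiguous).
#' Internal workhorse of \code{\link{rootContentInterval}}.
#'
#' @param tree rooted ape \code{phylo} whose tips are genome ids
#' @param presence logical matrix groups x genomes
#' @return list with \code{rootCode} (integer per group) and \code{changes}
#'   (Fitch change count per group)
#' @keywords internal
.fitch_binary_all <- function(tree, presence) {
  nt <- ape::Ntip(tree)
  stopifnot(all(tree$tip.label %in% colnames(presence)))
  ng <- nrow(presence)
  n_node <- nt + tree$Nnode
  code <- matrix(0L, ng, n_node)
  code[, seq_len(nt)] <- ifelse(presence[, tree$tip.label, drop = FALSE],
                                2L, 1L)
  changes <- integer(ng)
  ch <- .children_list(tree)
  for (v in .postorder_internal(tree)) {
    s <- code[, ch[[v]][1L]]
    for (c2 in ch[[v]][-1L]) {
      i <- bitwAnd(s, code[, c2])
      u <- bitwOr(s, code[, c2])
      is_union <- i == 0L
      changes <- changes + is_union
      s <- ifelse(is_union, u, i)
    }
    code[, v] <- s
  }
  list(rootCode = code[, .root_node(tree)], changes = changes)
}

#' Ancestral gene-content interval at the root
#'
#' Runs binary Fitch parsimony on the presence/absence of every ortholog
#' group and counts, at the root (the MRCA of the sampled genomes), the
#' groups surely present (root set \{present\}) and those ambiguously
#' present (root set \{absent, present\}). The interval [min, max] counts
#' sure groups only in the minimum and adds ambiguous groups for the
#' maximum.
#'
#' @param x an \linkS4class{OrthologSet}
#' @param tree rooted ape \code{phylo}; tip labels must be genome ids of
#'   \code{x}
#' @param presenceMode "any_copy" (default) or "functional_only"
#' @return list with \code{min_genes}, \code{max_genes}, \code{sure}
#'   (group ids surely present at the root), \code{ambiguous} (group ids
#'   ambiguously present), \code{changes} (named per-group change counts)
#' @export
rootContentInterval <- function(x, tree,
                                presenceMode = c("any_copy",
                                                 "functional_only")) {
  presenceMode <- .check_mode(presenceMode)
  if (!all(tree$tip.label %in% genomeIds(x)))
    stop("tree tip(s) absent from the ortholog matrix: ",
         paste(setdiff(tree$tip.label, genomeIds(x)), collapse = ", "))
  pres <- presenceMatrix(x, presenceMode)
  fit <- .fitch_binary_all(tree, pres)
  sure <- groupIds(x)[fit$rootCode == 2L]
  amb <- groupIds(x)[fit$rootCode == 3L]
  list(min_genes = length(sure), max_genes = length(sure) + length(amb),
       sure = sure, ambiguous = amb,
       changes = stats::setNames(fit$changes, groupIds(x)))
}

#' Sankoff parsimony with linear copy-number costs
#'
#' Dynamic-programming (Sankoff) reconstruction over the state alphabet
#' 0..\code{maxState} with cost |i - j| per parent/child state change —
#' the natural cost for gene copy numbers, where gaining or losing one copy
#' costs one step. Reports the exact set of states attainable at every node
#' in at least one minimum-cost reconstruction.
#'
#' @param tree rooted ape \code{phylo}
#' @param tipCopies non-negative integer copy numbers named by tip label
#' @param maxState top of the state alphabet; defaults to the observed
#'   maximum (states beyond it cannot appear in an optimal reconstruction
#'   under linear costs)
#' @return an \linkS4class{AncestralReconstruction} (method "sankoff");
#'   \code{states} holds integer state vectors per node, \code{cost} the
#'   minimum total linear cost
#' @export
sankoffLinear <- function(tree, tipCopies, maxState = NULL) {
  nt <- ape::Ntip(tree)
  if (!all(tree$tip.label %in% names(tipCopies)))
    stop("tip(s) missing a copy number")
  obs <- as.integer(tipCopies[tree$tip.label])
  if (any(obs < 0)) stop("negative copy number")
  if (is.null(maxState)) maxState <- max(obs)
  if (any(obs > maxState)) stop("tip copy number exceeds maxState")
  alph <- 0:maxState
  k <- length(alph)
  ch <- .children_list(tree)
  n_node <- nt + tree$Nnode
  costmat <- abs(outer(alph, alph, "-"))
  C <- matrix(Inf, n_node, k)
  C[cbind(seq_len(nt), obs + 1L)] <- 0
  for (v in .postorder_internal(tree)) {
    acc <- numeric(k)
    for (cc in ch[[v]])
      acc <- acc + apply(costmat + rep(C[cc, ], each = k), 1L, min)
    C[v, ] <- acc
  }
  allowed <- matrix(FALSE, n_node, k)
  root <- .root_node(tree)
  allowed[root, ] <- C[root, ] == min(C[root, ])
  edges <- reorder(tree, "postorder")$edge
  for (i in rev(seq_len(nrow(edges)))) {
    p <- edges[i, 1L]; v <- edges[i, 2L]
    if (v <= nt) { allowed[v, ] <- C[v, ] == 0; next }
    ok <- rep(FALSE, k)
    for (s in which(allowed[p, ])) {
      val <- C[v, ] + costmat[s, ]
      ok <- ok | val == min(val)
    }
    allowed[v, ] <- ok
  }
  states <- lapply(seq_len(n_node), function(v) alph[allowed[v, ]])
  equiv <- vapply(seq_len(nrow(tree$edge)), function(i)
    sum(allowed[tree$edge[i, 1L], ]) > 1L ||
      sum(allowed[tree$edge[i, 2L], ]) > 1L, NA)
  new("AncestralReconstruction", method = "sankoff", tree = tree,
      states = states, values = numeric(),
      cost = min(C[root, ]), equivocal = equiv)
}

#' Copy-number-based ancestral gene-content interval
#'
#' Runs \code{\link{sankoffLinear}} per ortholog group on copy numbers and
#' sums, over groups, the smallest and largest root states attainable in a
#' minimum-cost reconstruction, yielding a gene-copy interval for the MRCA.
#'
#' @inheritParams rootContentInterval
#' @return list with \code{min_copies}, \code{max_copies} and a per-group
#'   matrix \code{rootRange} (columns min, max)
#' @export
copyNumberRootInterval <- function(x, tree,
                                   presenceMode = c("any_copy",
                                                    "functional_only")) {
  presenceMode <- .check_mode(presenceMode)
  if (!all(tree$tip.label %in% genomeIds(x)))
    stop("tree tip(s) absent from the ortholog matrix")
  cn <- copyNumbers(x, presenceMode)[, tree$tip.label, drop = FALSE]
  rng <- t(apply(cn, 1L, function(row) {
    rec <- sankoffLinear(tree, row)
    root_states <- rec@states[[.root_node(tree)]]
    c(min(root_states), max(root_states))
  }))
  colnames(rng) <- c("min", "max")
  list(min_copies = sum(rng[, "min"]), max_copies = sum(rng[, "max"]),
       rootRange = rng)
}

## Continuous parsimony --------------------------------------------------------

#' Squared-change parsimony for continuous characters
#'
#' Reconstructs internal-node values minimising the sum over branches of
#' (parent - child)^2 / w, with w = 1 (unweighted, default) or w = branch
#' length (weighted). The objective is strictly convex, so the solution is
#' the unique zero of the gradient — obtained exactly by solving the sparse
#' linear system (tree Laplacian restricted to internal nodes).
#'
#' @param tree rooted ape \code{phylo}
#' @param tipValues numeric values named by tip label
#' @param weighted divide each squared change by the branch length
#' @return an \linkS4class{AncestralReconstruction} (method
#'   "squared_change"); \code{values} holds one value per ape node number
#'   (tips keep their observations), \code{cost} the minimised objective
#' @export
squaredChange <- function(tree, tipValues, weighted = FALSE) {
  nt <- ape::Ntip(tree)
  if (!all(tree$tip.label %in% names(tipValues)))
    stop("tip(s) missing a value: ",
         paste(setdiff(tree$tip.label, names(tipValues)), collapse = ", "))
  obs <- as.numeric(tipValues[tree$tip.label])
  if (anyNA(obs)) stop("NA tip value")
  n_node <- nt + tree$Nnode
  w <- if (weighted) {
    if (is.null(tree$edge.length)) stop("weighted mode needs branch lengths")
    if (any(tree$edge.length <= 0)) {
      bad <- which(tree$edge.length <= 0)[1L]
      stop(sprintf("zero-length branch %d -> %d cannot be weighted",
                   tree$edge[bad, 1L], tree$edge[bad, 2L]))
    }
    tree$edge.length
  } else rep(1, nrow(tree$edge))
  int <- (nt + 1L):n_node
  idx <- function(v) v - nt
  A <- matrix(0, tree$Nnode, tree$Nnode)
  b <- numeric(tree$Nnode)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]; v <- tree$edge[i, 2L]; wi <- 1 / w[i]
    A[idx(p), idx(p)] <- A[idx(p), idx(p)] + wi
    if (v > nt) {
      A[idx(v), idx(v)] <- A[idx(v), idx(v)] + wi
      A[idx(p), idx(v)] <- A[idx(p), idx(v)] - wi
      A[idx(v), idx(p)] <- A[idx(v), idx(p)] - wi
    } else {
      b[idx(p)] <- b[idx(p)] + obs[v] * wi
    }
  }
  vals <- numeric(n_node)
  vals[seq_len(nt)] <- obs
  vals[int] <- solve(A, b)
  cost <- sum((vals[tree$edge[, 1L]] - vals[tree$edge[, 2L]])^2 / w)
  new("AncestralReconstruction", method = "squared_change", tree = tree,
      states = list(), values = vals, cost = cost,
      equivocal = rep(FALSE, nrow(tree$edge)))
}

## Accessors -------------------------------------------------------------------

#' @describeIn fitchStates per-node state sets (discrete methods), indexed
#'   by ape node number
#' @param object an AncestralReconstruction
#' @export
nodeStates <- function(object) object@states

#' @describeIn fitchStates per-node values (continuous method)
#' @export
nodeValues <- function(object) object@values

#' @describeIn fitchStates total reconstruction cost
#' @export
reconstructionCost <- function(object) object@cost

#' @describeIn fitchStates logical per-edge equivocality flags (ape edge
#'   order)
#' @export
equivocalBranches <- function(object) object@equivocal

#' @describeIn fitchStates value or state set at the root (MRCA)
#' @export
rootState <- function(object) {
  root <- .root_node(object@tree)
  if (object@method == "squared_change") object@values[root]
  else object@states[[root]]
}

#' @export
setMethod("show", "AncestralReconstruction", function(object) {
  cat(sprintf("AncestralReconstruction (%s): %d tips, cost = %.6g\n",
              object@method, ape::Ntip(object@tree), object@cost))
  rs <- rootState(object)
  cat("  root:", paste(format(rs), collapse = " "), "\n")
  if (length(object@equivocal) && any(object@equivocal))
    cat(sprintf("  %d equivocal branches\n", sum(object@equivocal)))
})
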