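#' Simulation configuration
#'
#' Bundles the parameters of the synthetic dataset generator with defaults
#' emulating a 58-genome collection: a Yule tree with two basal clades,
#' ortholog families evolving by gain/loss with terminal-branch duplication,
#' genome nucleotide partitions derived from gene counts, binary phenotypes
#' evolving on the tree, and one heavily pseudogenized tip (an eroding
#' obligate-symbiont-like genome, 64% of its paralogous copies
#' pseudogenized).
#'
#' @param n_tips number of genomes
#' @param birth_rate Yule speciation rate (per unit time)
#' @param n_families number of ortholog families simulated
#' @param p0 root presence probability per family
#' @param gain_rate,loss_rate per-branch-length rates of the two-state
#'   presence chain
#' @param dup_rate linear birth rate of extra copies on terminal branches
#'   (in-paralogs)
#' @param gene_length_bp mean coding length per gene copy
#' @param noncoding_mean,noncoding_dispersion mean and Beta dispersion of
#'   the per-genome non-coding fraction
#' @param bm_sigma2 Brownian-motion rate for the continuous trait
#' @param phenotype_gain,phenotype_loss rates of the binary phenotype chain
#' @param pseudo_target tip id whose functional copies are pseudogenized
#'   (NULL for none)
#' @param pseudo_fraction fraction pseudogenized at the target tip
#' @param draft_fraction fraction of genomes marked unfinished
#' @param cog_error per-gene probability that the COG best hit is corrupted
#' @param seed master seed
#' @return a list of class \code{simulationConfig}
#' @export
simulationConfig <- function(n_tips = 58L, birth_rate = 1,
                             n_families = 2000L, p0 = 0.3,
                             gain_rate = 0.1, loss_rate = 0.15,
                             dup_rate = 0.3, gene_length_bp = 1000,
                             noncoding_mean = 0.15,
                             noncoding_dispersion = 50,
                             bm_sigma2 = 1,
                             phenotype_gain = 0.1, phenotype_loss = 0.1,
                             pseudo_target = "t1", pseudo_fraction = 0.64,
                             draft_fraction = 1/3, cog_error = 0.1,
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_tips >= 2, cfg$birth_rate > 0,
            cfg$p0 >= 0, cfg$p0 <= 1,
            cfg$gain_rate >= 0, cfg$loss_rate >= 0, cfg$dup_rate >= 0,
            cfg$pseudo_fraction >= 0, cfg$pseudo_fraction <= 1,
            cfg$bm_sigma2 >= 0)
  class(cfg) <- "simulationConfig"
  cfg
}

#' Simulate a Yule tree
#'
#' Pure-birth tree with branch lengths, deterministic given the seed.
#'
#' @param nTips number of tips (>= 2)
#' @param birthRate speciation rate
#' @param seed integer seed
#' @return rooted binary ape \code{phylo} with tips t1..tn
#' @export
simulateTree <- function(nTips, birthRate = 1, seed = 1L) {
  if (nTips < 2) stop("nTips must be >= 2")
  set.seed(as.integer(seed))
  ape::rphylo(nTips, birth = birthRate, death = 0)
}

#' Two-state transition probabilities of the gain/loss chain
#'
#' P(present at branch end | start state) for a continuous-time chain with
#' gain rate lambda and loss rate mu over branch length t. Closed form used
#' both by the simulator and as the analytic oracle in tests.
#'
#' @param t branch length(s)
#' @param gain,loss chain rates
#' @return matrix with columns \code{from0} (gain probability) and
#'   \code{from1} (retention probability)
#' @export
gainLossTransition <- function(t, gain, loss) {
  r <- gain + loss
  if (r == 0) return(cbind(from0 = rep(0, length(t)),
                           from1 = rep(1, length(t))))
  pi1 <- gain / r
  e <- exp(-r * t)
  cbind(from0 = pi1 * (1 - e), from1 = pi1 + (1 - pi1) * e)
}

#' Simulate ortholog family gain/loss and duplication on a tree
#'
#' Each family evolves presence/absence independently along the tree by a
#' continuous-time two-state chain (gain rate \code{gain_rate}, loss rate
#' \code{loss_rate}) from a Bernoulli(\code{p0}) root draw. Lineages
#' present at a tip accrue extra in-paralog copies by a linear birth process
#' at rate \code{dup_rate} acting on the terminal branch (internal nodes
#' carry single copies), so all simulated paralogs are recent, tip-specific
#' duplicates.
#'
#' @param tree rooted ape \code{phylo} with branch lengths
#' @param config a \code{\link{simulationConfig}}
#' @return list: \code{counts} (integer family x tip functional copy
#'   matrix), \code{truth} (root presence, full node x family presence
#'   matrix with ape node indexing, true root gene count, config echo)
#' @export
simulateGeneContent <- function(tree, config) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  set.seed(as.integer(config$seed) + 101L)
  nf <- config$n_families
  nt <- ape::Ntip(tree)
  n_node <- nt + tree$Nnode
  pres <- matrix(NA, nf, n_node)
  pres[, .root_node(tree)] <- stats::runif(nf) < config$p0
  edges <- reorder(tree, "postorder")
  eo <- rev(seq_len(nrow(edges$edge)))  # preorder: parent before child
  for (i in eo) {
    p <- edges$edge[i, 1L]; v <- edges$edge[i, 2L]
    tp <- gainLossTransition(edges$edge.length[i],
                             config$gain_rate, config$loss_rate)
    prob <- ifelse(pres[, p], tp[1L, "from1"], tp[1L, "from0"])
    pres[, v] <- stats::runif(nf) < prob
  }
  counts <- matrix(0L, nf, nt,
                   dimnames = list(sprintf("fam%04d", seq_len(nf)),
                                   tree$tip.label))
  term_len <- stats::setNames(numeric(nt), seq_len(nt))
  term_len[as.character(tree$edge[tree$edge[, 2L] <= nt, 2L])] <-
    tree$edge.length[tree$edge[, 2L] <= nt]
  for (s in seq_len(nt)) {
    on <- which(pres[, s])
    if (!length(on)) next
    # pure-birth from one copy over time t: copies ~ 1 + Geom(e^{-delta t})
    psurv <- exp(-config$dup_rate * term_len[as.character(s)])
    counts[on, s] <- 1L + stats::rgeom(length(on), psurv)
  }
  list(counts = counts,
       truth = list(
         root_presence = pres[, .root_node(tree)],
         node_presence = pres,
         true_root_genes = sum(pres[, .root_node(tree)]),
         config = config))
}

#' Simulate binary phenotypes on a tree
#'
#' Independent two-state chains (same machinery as the gene gain/loss
#' process) for each named phenotype flag, from an all-absent root.
#'
#' @param tree rooted ape \code{phylo}
#' @param flags character vector of flag names
#' @param gain,loss chain rates
#' @param seed integer seed
#' @return list: \code{tips} logical tip x flag matrix, \code{nodes} full
#'   node x flag truth matrix
#' @export
simulatePhenotypes <- function(tree, flags = .PHENOTYPE_FLAGS,
                               gain = 0.1, loss = 0.1, seed = 1L) {
  set.seed(as.integer(seed) + 202L)
  nt <- ape::Ntip(tree)
  n_node <- nt + tree$Nnode
  states <- matrix(NA, n_node, length(flags),
                   dimnames = list(NULL, flags))
  states[.root_node(tree), ] <- FALSE
  edges <- reorder(tree, "postorder")
  for (i in rev(seq_len(nrow(edges$edge)))) {
    p <- edges$edge[i, 1L]; v <- edges$edge[i, 2L]
    tp <- gainLossTransition(edges$edge.length[i], gain, loss)
    prob <- ifelse(states[p, ], tp[1L, "from1"], tp[1L, "from0"])
    states[v, ] <- stats::runif(length(flags)) < prob
  }
  tips <- states[seq_len(nt), , drop = FALSE]
  rownames(tips) <- tree$tip.label
  list(tips = tips, nodes = states)
}

#' Simulate Brownian motion on a tree
#'
#' value(child) ~ Normal(value(parent), sigma2 * branch length), recorded at
#' every node. \code{sigma2} may be a scalar or a per-edge vector (ape edge
#' order), which is how clade-specific rates are simulated.
#'
#' @param tree rooted ape \code{phylo} with branch lengths
#' @param sigma2 Brownian rate, scalar or per-edge
#' @param rootValue value at the root
#' @param seed integer seed
#' @return numeric vector of node values indexed by ape node number (tips
#'   first, named by tip label where applicable)
#' @export
simulateContinuous <- function(tree, sigma2 = 1, rootValue = 0, seed = 1L) {
  if (any(sigma2 < 0)) stop("sigma2 must be non-negative")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  set.seed(as.integer(seed) + 303L)
  nt <- ape::Ntip(tree)
  n_node <- nt + tree$Nnode
  if (length(sigma2) == 1L) sigma2 <- rep(sigma2, nrow(tree$edge))
  stopifnot(length(sigma2) == nrow(tree$edge))
  vals <- numeric(n_node)
  vals[.root_node(tree)] <- rootValue
  edges <- reorder(tree, "postorder")
  # map per-edge sigma2 (given in tree$edge order) onto postorder
  s2 <- sigma2[match(paste(edges$edge[, 1L], edges$edge[, 2L]),
                     paste(tree$edge[, 1L], tree$edge[, 2L]))]
  for (i in rev(seq_len(nrow(edges$edge)))) {
    p <- edges$edge[i, 1L]; v <- edges$edge[i, 2L]
    vals[v] <- vals[p] +
      stats::rnorm(1L, 0, sqrt(s2[i] * edges$edge.length[i]))
  }
  names(vals)[seq_len(nt)] <- tree$tip.label
  vals
}

#' Per-edge Brownian rates from clade labels
#'
#' Assigns each edge the rate of the clade its child subtree lies in; edges
#' not fully inside a labelled clade (the basal edges) get \code{baseRate}.
#'
#' @param tree rooted ape \code{phylo}
#' @param clades clade labels named by tip label
#' @param rates named numeric, e.g. c(clade1 = 4, clade2 = 1)
#' @param baseRate rate for edges outside any single clade
#' @return numeric vector in ape edge order, usable as \code{sigma2} in
#'   \code{\link{simulateContinuous}}
#' @export
cladeEdgeRates <- function(tree, clades, rates, baseRate = mean(rates)) {
  nt <- ape::Ntip(tree)
  node_clade <- character(nt + tree$Nnode)
  node_clade[seq_len(nt)] <- as.character(clades[tree$tip.label])
  ch <- .children_list(tree)
  for (v in .postorder_internal(tree)) {
    cl <- unique(node_clade[ch[[v]]])
    node_clade[v] <- if (length(cl) == 1L) cl else "mixed"
  }
  vapply(seq_len(nrow(tree$edge)), function(i) {
    cl <- node_clade[tree$edge[i, 2L]]
    if (cl %in% names(rates)) rates[[cl]] else baseRate
  }, 0)
}

#' Clade labels from the basal split of a tree
#'
#' Tips descending from the root's first child become \code{clade1}, the
#' rest \code{clade2}; the larger subtree is always clade1 (the study's
#' convention of calling the big heterogeneous clade first).
#'
#' @param tree rooted ape \code{phylo}
#' @return character vector of clade labels named by tip label
#' @export
assignClades <- function(tree) {
  ch <- .children_list(tree)[[.root_node(tree)]]
  desc <- lapply(ch, function(v) {
    if (v <= ape::Ntip(tree)) tree$tip.label[v]
    else ape::extract.clade(tree, v)$tip.label
  })
  desc <- desc[order(-lengths(desc))]
  cl <- stats::setNames(rep("clade2", ape::Ntip(tree)), tree$tip.label)
  cl[desc[[1L]]] <- "clade1"
  cl
}

#' Simulate genome metadata and pseudogenization
#'
#' Derives the per-genome nucleotide partition from the simulated gene
#' counts: coding bp = functional copies x gene length with multiplicative
#' lognormal noise; the non-coding fraction is drawn per tip from a Beta
#' distribution; pseudogenization converts each functional copy of the
#' target tip to a pseudogene independently with probability
#' \code{pseudo_fraction}, moving its nucleotides into the pseudogene
#' partition. The partition always sums exactly to the genome size.
#'
#' @param tree rooted ape \code{phylo}
#' @param counts functional copy matrix from
#'   \code{\link{simulateGeneContent}}
#' @param config a \code{\link{simulationConfig}}
#' @return list: \code{genomes} (metadata data.frame), \code{functional}
#'   and \code{pseudo} (updated copy matrices), \code{phenotypes} (tip
#'   truth), \code{pseudo_genes} (ids of pseudogenized copies)
#' @export
simulateGenomeMetadata <- function(tree, counts, config) {
  set.seed(as.integer(config$seed) + 404L)
  nt <- ape::Ntip(tree)
  tips <- tree$tip.label
  functional <- counts
  pseudo <- counts
  pseudo[] <- 0L
  if (!is.null(config$pseudo_target) && config$pseudo_fraction > 0) {
    if (!config$pseudo_target %in% tips)
      stop("pseudogenization target tip not in tree: ", config$pseudo_target)
    s <- config$pseudo_target
    pseudo[, s] <- stats::rbinom(nrow(counts), counts[, s],
                                 config$pseudo_fraction)
    functional[, s] <- counts[, s] - pseudo[, s]
  }
  L <- config$gene_length_bp
  fn_count <- colSums(functional)
  ps_count <- colSums(pseudo)
  coding <- round(fn_count * L * stats::rlnorm(nt, 0, 0.05))
  pseudobp <- round(ps_count * L * stats::rlnorm(nt, 0, 0.05))
  m <- config$noncoding_mean; phi <- config$noncoding_dispersion
  fnc <- stats::rbeta(nt, m * phi, (1 - m) * phi)
  noncoding <- round(coding * fnc / (1 - fnc))
  ph <- simulatePhenotypes(tree, gain = config$phenotype_gain,
                           loss = config$phenotype_loss,
                           seed = config$seed)
  finished <- stats::runif(nt) >= config$draft_fraction
  clades <- assignClades(tree)
  genomes <- data.frame(
    name = paste("Synthetic genome", tips),
    finished = finished,
    clade = unname(clades[tips]),
    genome_size_bp = coding + noncoding + pseudobp,
    coding_bp = coding, noncoding_bp = noncoding, pseudogene_bp = pseudobp,
    gene_count = fn_count,
    ph$tips[tips, , drop = FALSE],
    habitat = sample(c("marine", "freshwater", "terrestrial", "hot_spring"),
                     nt, replace = TRUE),
    row.names = tips, stringsAsFactors = FALSE)
  list(genomes = genomes, functional = functional, pseudo = pseudo,
       phenotypes = ph$tips)
}

#' Simulate a per-gene COG best-hit table
#'
#' Each family gets a true COG category; each gene's best hit reproduces it
#' with probability 1 - \code{cog_error}, and is otherwise corrupted to a
#' random other category or dropped — exercising the majority-assignment
#' rule.
#'
#' @param groups membership data.frame (\code{group_id}, \code{gene_id})
#' @param config a \code{\link{simulationConfig}}
#' @return list: \code{hits} (data.frame gene_id/category/evalue),
#'   \code{true_categories} (named by group id)
#' @export
simulateCogHits <- function(groups, config) {
  set.seed(as.integer(config$seed) + 505L)
  cats <- strsplit("JKLDOMNPTCGEFHIQRSUV", "")[[1]]
  fams <- unique(groups$group_id)
  true_cat <- stats::setNames(sample(cats, length(fams), replace = TRUE),
                              fams)
  n <- nrow(groups)
  hit <- true_cat[groups$group_id]
  u <- stats::runif(n)
  corrupt <- u < config$cog_error
  drop <- u < config$cog_error / 2           # half the corruptions: no hit
  hit[corrupt] <- vapply(hit[corrupt], function(cc)
    sample(setdiff(cats, cc), 1L), "")
  hit[drop] <- NA_character_
  hits <- data.frame(gene_id = groups$gene_id,
                     category = unname(hit),
                     evalue = signif(stats::runif(n, 1e-40, 0.009), 3),
                     stringsAsFactors = FALSE)
  hits$evalue[is.na(hits$category)] <- 1
  hits$category[is.na(hits$category)] <- "-"
  list(hits = hits, true_categories = true_cat)
}

#' Generate and write a complete synthetic dataset
#'
#' Runs the full generator (tree, gene content, metadata/pseudogenization,
#' phenotypes, COG hits) and, when \code{dir} is given, writes the standard
#' input files: \code{groups.txt}, \code{genomes.tsv},
#' \code{pseudogenes.tsv}, \code{tree.nwk}, \code{coghits.tsv} and
#' \code{truth.json}. Re-parsing the files reproduces the in-memory objects
#' exactly. Gene ids are \code{<family>_<tip>_<copy>}.
#'
#' @param config a \code{\link{simulationConfig}}
#' @param dir output directory (NULL: nothing written)
#' @return (invisibly) list with \code{tree}, \code{groups},
#'   \code{genomes}, \code{pseudogenes}, \code{coghits}, \code{orthoset}
#'   (the assembled \linkS4class{OrthologSet}) and \code{truth}
#' @export
simulateDataset <- function(config = simulationConfig(), dir = NULL) {
  tree <- simulateTree(config$n_tips, config$birth_rate, config$seed)
  gc <- simulateGeneContent(tree, config)
  meta <- simulateGenomeMetadata(tree, gc$counts, config)
  tips <- tree$tip.label
  mk_members <- function(mat, tag) {
    idx <- which(mat > 0L, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    n <- mat[idx]
    fam <- rep(rownames(mat)[idx[, 1L]], n)
    tip <- rep(colnames(mat)[idx[, 2L]], n)
    data.frame(group_id = fam, genome_id = tip,
               gene_id = sprintf("%s_%s_%s%d", fam, tip, tag, sequence(n)),
               stringsAsFactors = FALSE)
  }
  groups <- rbind(mk_members(meta$functional, "c"),
                  mk_members(meta$pseudo, "p"))
  groups <- groups[order(match(groups$group_id, rownames(gc$counts)),
                         match(groups$genome_id, tips)), ]
  rownames(groups) <- NULL
  pseudogenes <- groups$gene_id[grepl("_p\\d+$", groups$gene_id)]
  cog <- simulateCogHits(groups, config)
  oset <- buildOrthologSet(groups, meta$genomes, pseudogenes)
  truth <- list(
    config = unclass(config),
    root_presence = unname(gc$truth$root_presence),
    true_root_genes = gc$truth$true_root_genes,
    phenotype_nodes = NULL,
    true_categories = as.list(cog$true_categories))
  out <- list(tree = tree, groups = groups, genomes = meta$genomes,
              pseudogenes = pseudogenes, coghits = cog$hits,
              orthoset = oset, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeOrthoGroups(groups, file.path(dir, "groups.txt"))
    writeGenomeTable(meta$genomes, file.path(dir, "genomes.tsv"))
    writeLines(pseudogenes, file.path(dir, "pseudogenes.tsv"))
    writeTree(tree, file.path(dir, "tree.nwk"))
    utils::write.table(cog$hits, file.path(dir, "coghits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
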