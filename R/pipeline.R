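.stage_log <- function(stage, t0) {
  message(sprintf("[pancestor] %-22s %7.2fs", stage,
                  as.numeric(proc.time()[3L]) - t0))
}

.pipeline_defaults <- list(
  pseudogenes = NULL, coghits = NULL, seed = 1L,
  chisq_replicates = 2000L, pseudogene_mode = "merge_noncoding",
  core_presence_mode = "any_copy", out = NULL)

#' Run the full pan-genome analysis pipeline
#'
#' Executes every stage on one dataset: input parsing and matrix
#' construction; strict/relaxed core sets and phenotype/clade signatures;
#' paralog profiling and COG functional distribution; the Monte-Carlo
#' composition test; ancestral reconstruction of gene content (presence and
#' copy-number based) and of genome size and gene count; and independent
#' contrasts with the clade rate test and through-origin regression of
#' paralog-copy contrasts on genome-size contrasts within clade1.
#'
#' @param config a named list or path to a YAML file with keys:
#'   \code{groups}, \code{genomes}, \code{tree} (required file paths),
#'   \code{pseudogenes}, \code{coghits} (optional paths), \code{seed},
#'   \code{chisq_replicates}, \code{pseudogene_mode},
#'   \code{core_presence_mode}, \code{out} (optional output directory for
#'   per-stage TSVs and \code{report.json})
#' @return (invisibly) the report as a nested list; identical inputs and
#'   seed give a bit-identical report
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.pipeline_defaults, config)
  for (key in c("groups", "genomes", "tree"))
    if (is.null(cfg[[key]]))
      stop("pipeline config is missing required key: ", key)
  for (key in c("groups", "genomes", "tree", "pseudogenes", "coghits"))
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("pipeline config: input file not found: ", cfg[[key]])
  t0 <- as.numeric(proc.time()[3L])
  in_files <- unlist(cfg[c("groups", "genomes", "tree", "pseudogenes",
                           "coghits")])
  report <- list(fingerprint = list(
    inputs = as.list(tools::md5sum(in_files)), seed = cfg$seed))

  run_stage <- function(stage, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
    .stage_log(stage, t0)
    res
  }

  ## data_model
  dm <- run_stage("data_model", {
    groups <- readOrthoGroups(cfg$groups)
    genomes <- readGenomeTable(cfg$genomes)
    pg <- if (!is.null(cfg$pseudogenes)) readPseudogenes(cfg$pseudogenes)
    tree <- readTree(cfg$tree)
    if (!all(tree$tip.label %in% rownames(genomes)))
      stop("tree tips missing from the genome table")
    list(x = buildOrthologSet(groups, genomes, pg), tree = tree,
         groups = groups)
  })
  x <- dm$x; tree <- dm$tree

  ## core_sets
  core <- run_stage("core_sets", {
    pm <- cfg$core_presence_mode
    sizes <- c(
      strict = length(coreGroups(computeCore(x, 0L, FALSE, pm))),
      RCF = length(coreGroups(computeCore(x, 0L, TRUE, pm))),
      RCF1 = length(coreGroups(computeCore(x, 1L, TRUE, pm))),
      RCF2 = length(coreGroups(computeCore(x, 2L, TRUE, pm))),
      RCF3 = length(coreGroups(computeCore(x, 3L, TRUE, pm))))
    flags <- intersect(.PHENOTYPE_FLAGS, colnames(genomeData(x)))
    sig <- lapply(stats::setNames(flags, flags), function(fl)
      nrow(phenotypeSignature(x, fl)))
    clades <- genomeData(x)$clade
    csig <- if (all(c("clade1", "clade2") %in% clades))
      list(clade1_excl = length(cladeSignature(x, "clade1", "clade2")),
           clade2_excl = length(cladeSignature(x, "clade2", "clade1")))
    fin <- genomeIds(x)[genomeData(x)$finished]
    n_with_missing <- sum(vapply(fin, function(g)
      nrow(missingInGenome(x, g)) > 0L, NA))
    list(core_sizes = as.list(sizes), signature_sizes = sig,
         clade_signatures = csig,
         finished_genomes_with_missing = n_with_missing)
  })

  ## paralog_profile
  paralogs <- run_stage("paralog_profile", {
    ps <- paralogStats(x)
    res <- list(
      total_paralogous_groups = sum(rowSums(copyNumbers(x) >= 2L) > 0L),
      max_total_copies = max(ps$total_paralog_copies),
      stats = ps)
    if (!is.null(cfg$coghits)) {
      hits <- readCogHits(cfg$coghits)
      cm <- cogAssignments(dm$groups, hits)
      res$cog_assigned <- sum(!is.na(cm))
      res$distribution <- functionalDistribution(x, cm)
    }
    res
  })

  ## genome_composition
  comp <- run_stage("genome_composition", {
    tab <- compositionTable(genomeData(x), cfg$pseudogene_mode)
    ct <- noncodingChisq(tab, B = cfg$chisq_replicates, seed = cfg$seed)
    list(statistic = testStatistic(ct), p = testPValue(ct),
         B = cfg$chisq_replicates,
         bias = as.list(stats::setNames(biasCalls(ct), genomeIds(x))))
  })

  ## ancestral_reconstruction
  anc <- run_stage("ancestral_reconstruction", {
    ri <- rootContentInterval(x, tree)
    ci <- copyNumberRootInterval(x, tree)
    gd <- genomeData(x)
    size_rec <- squaredChange(
      tree, stats::setNames(gd$genome_size_bp, rownames(gd)))
    gene_rec <- squaredChange(
      tree, stats::setNames(gd$gene_count, rownames(gd)))
    list(root_genes_min = ri$min_genes, root_genes_max = ri$max_genes,
         root_copies_min = ci$min_copies, root_copies_max = ci$max_copies,
         root_genome_size_bp = rootState(size_rec),
         root_gene_count = rootState(gene_rec))
  })

  ## independent_contrasts
  contr <- run_stage("independent_contrasts", {
    gd <- genomeData(x)
    clades <- stats::setNames(gd$clade, rownames(gd))
    ps <- paralogStats(x)
    size_c <- picContrasts(
      tree, stats::setNames(gd$genome_size_bp, rownames(gd)), clades)
    par_c <- picContrasts(
      tree, stats::setNames(ps$total_paralog_copies, ps$genome_id), clades)
    res <- list(n_contrasts = nrow(size_c))
    if (all(c("clade1", "clade2") %in% size_c$clade)) {
      rt_size <- cladeRateTest(size_c)
      rt_par <- cladeRateTest(par_c)
      res$rate_test <- list(
        genome_size = list(W = rt_size$statistic, p = rt_size$p),
        paralog_copies = list(W = rt_par$statistic, p = rt_par$p))
    }
    in1 <- size_c$clade == "clade1"
    if (sum(in1) >= 3) {
      or <- originRegression(size_c$standardized[in1],
                             par_c$standardized[in1])
      res$regression <- list(slope = or$slope, r = or$r, p = or$p,
                             n = or$n)
    }
    res$tables <- list(size = size_c, paralog = par_c)
    res
  })

  report <- c(report, list(
    core = core, paralogs = paralogs[setdiff(names(paralogs),
                                             c("stats", "distribution"))],
    composition = comp, ancestral = anc,
    contrasts = contr[setdiff(names(contr), "tables")]))

  if (!is.null(cfg$out)) {
    dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
    wtsv <- function(df, name)
      utils::write.table(df, file.path(cfg$out, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    wtsv(paralogs$stats, "paralog_stats.tsv")
    if (!is.null(paralogs$distribution))
      utils::write.table(cbind(genome_id = rownames(paralogs$distribution),
                               as.data.frame(paralogs$distribution)),
                         file.path(cfg$out, "cog_distribution.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    wtsv(contr$tables$size, "contrasts_genome_size.tsv")
    wtsv(contr$tables$paralog, "contrasts_paralog_copies.tsv")
    jsonlite::write_json(report, file.path(cfg$out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
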