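#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
NULL

.PHENOTYPE_FLAGS <- c("filamentous", "heterocystous", "diazotroph", "plant_symbiont")
.CLADE_LEVELS <- c("clade1", "clade2", "outgroup", "unassigned")

#' OrthologSet: ortholog-by-genome copy counts with genome metadata
#'
#' The central container of the package: an ortholog group x genome matrix of
#' gene copy counts, split into functional copies and pseudogene copies, with
#' per-genome metadata (assembly status, clade label, nucleotide partition,
#' phenotype flags) carried as column data. Extends
#' \linkS4class{SummarizedExperiment} with assays \code{"functional"} and
#' \code{"pseudo"}.
#'
#' Column data must contain at least \code{finished} (logical) and
#' \code{clade} (one of \code{clade1}, \code{clade2}, \code{outgroup},
#' \code{unassigned}). When the nucleotide partition columns
#' \code{genome_size_bp}, \code{coding_bp}, \code{noncoding_bp},
#' \code{pseudogene_bp} are present, the partition must sum exactly:
#' coding + non-coding + pseudogene = genome size.
#'
#' @aliases OrthologSet-class
#' @exportClass OrthologSet
setClass("OrthologSet", contains = "SummarizedExperiment")

setValidity("OrthologSet", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("functional", "pseudo") %in% an))
    return("assays 'functional' and 'pseudo' are required")
  fc <- SummarizedExperiment::assay(object, "functional")
  pc <- SummarizedExperiment::assay(object, "pseudo")
  if (any(fc < 0) || any(pc < 0))
    msg <- c(msg, "copy counts must be non-negative")
  if (any(fc != round(fc)) || any(pc != round(pc)))
    msg <- c(msg, "copy counts must be integers")
  cd <- SummarizedExperiment::colData(object)
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "genome ids (column names) must be present and unique")
  if (!"finished" %in% colnames(cd))
    msg <- c(msg, "colData must contain a logical 'finished' column")
  if ("clade" %in% colnames(cd) &&
      !all(cd$clade %in% .CLADE_LEVELS))
    msg <- c(msg, sprintf("clade labels must be one of: %s",
                          paste(.CLADE_LEVELS, collapse = ", ")))
  part <- c("genome_size_bp", "coding_bp", "noncoding_bp", "pseudogene_bp")
  if (all(part %in% colnames(cd))) {
    bad <- which(cd$coding_bp + cd$noncoding_bp + cd$pseudogene_bp !=
                   cd$genome_size_bp)
    if (length(bad))
      msg <- c(msg, sprintf(
        "nucleotide partition does not sum to genome size for: %s",
        paste(rownames(cd)[bad], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Core-set computation result
#'
#' Holds the group ids making up a (relaxed) core set together with, for each
#' member group, the finished genomes lacking it and the genomes where it is
#' present only as a pseudogene (functional loss).
#'
#' @slot spec list echoing the core specification (k_missing_finished,
#'   draft_wildcard, presence_mode, single_copy)
#' @slot groups character vector of member group ids
#' @slot missingFinished named list: per member group, ids of finished
#'   genomes in which it is absent
#' @slot functionalLoss named list: per member group, ids of genomes where
#'   only pseudogene copies remain
#' @exportClass CoreResult
setClass("CoreResult", representation(
  spec = "list", groups = "character",
  missingFinished = "list", functionalLoss = "list"))

setValidity("CoreResult", function(object) {
  k <- object@spec$k_missing_finished
  if (!is.null(k) && length(object@missingFinished) &&
      any(lengths(object@missingFinished) > k))
    return("a member group lacks more finished genomes than the core specification allows")
  TRUE
})

#' Monte-Carlo chi-squared composition test result
#'
#' @slot table observed contingency table (rows: nucleotide classes,
#'   columns: genomes)
#' @slot statistic Pearson chi-squared statistic
#' @slot B number of Monte-Carlo replicates
#' @slot p Monte-Carlo p-value, add-one convention (never below 1/(B+1))
#' @slot residuals signed Pearson residuals for the non-coding row
#' @slot bias per-genome bias call: "coding", "noncoding" or "none"
#' @exportClass CompositionTest
setClass("CompositionTest", representation(
  table = "matrix", statistic = "numeric", B = "integer",
  p = "numeric", residuals = "numeric", bias = "character"))

setValidity("CompositionTest", function(object) {
  if (object@p < 1 / (object@B + 1) - 1e-12)
    return("Monte-Carlo p-value below the attainable minimum 1/(B+1)")
  if (any(object@bias == "noncoding" & object@residuals <= 0) ||
      any(object@bias == "coding" & object@residuals >= 0))
    return("bias call direction contradicts residual sign")
  TRUE
})

#' Ancestral character reconstruction on a rooted tree
#'
#' Result of Fitch parsimony, Sankoff parsimony with linear costs, or
#' squared-change parsimony. Discrete reconstructions carry per-node state
#' sets (states attainable in at least one most-parsimonious reconstruction)
#' and a per-branch equivocality flag; continuous reconstructions carry one
#' value per node.
#'
#' @slot method "fitch", "sankoff" or "squared_change"
#' @slot tree the ape \code{phylo} the reconstruction was computed on
#' @slot states list of state vectors per node (discrete; empty otherwise),
#'   indexed by ape node number
#' @slot values numeric node values (continuous; length 0 otherwise)
#' @slot cost total cost: change count (Fitch), weighted linear cost
#'   (Sankoff) or sum of squared changes
#' @slot equivocal logical per edge (ape edge order): ambiguity on the branch
#' @exportClass AncestralReconstruction
setClass("AncestralReconstruction", representation(
  method = "character", tree = "ANY", states = "list",
  values = "numeric", cost = "numeric", equivocal = "logical"))
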