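#' Compute a strict or relaxed core ortholog set
#'
#' A group belongs to the core iff the number of \emph{finished} genomes in
#' which it is absent (under \code{presenceMode}) is at most
#' \code{kMissingFinished}, and — unless \code{draftWildcard} — it is
#' additionally present in every draft genome. With \code{singleCopy} a group
#' must further have exactly one functional copy in every genome where it is
#' present.
#'
#' The strict core is \code{kMissingFinished = 0, draftWildcard = FALSE};
#' the relaxed core over finished genomes ("RCF") sets
#' \code{draftWildcard = TRUE}, and RCF1..RCF3 additionally allow absence
#' from 1..3 finished genomes. Pseudogene-only presence in a genome does not
#' exclude a group under the default \code{any_copy} mode, but is annotated
#' as a functional loss.
#'
#' @param x an \linkS4class{OrthologSet}
#' @param kMissingFinished number of finished genomes allowed to lack a
#'   core group (0 for the strict core)
#' @param draftWildcard when TRUE, draft (unfinished) genomes are wildcards:
#'   presence and absence both allowed
#' @param presenceMode "any_copy" (default: a pseudogene still counts as
#'   presence) or "functional_only"
#' @param singleCopy restrict to groups with exactly one functional copy in
#'   every genome where present
#' @return a \linkS4class{CoreResult}
#' @export
computeCore <- function(x, kMissingFinished = 0L, draftWildcard = FALSE,
                        presenceMode = c("any_copy", "functional_only"),
                        singleCopy = FALSE) {
  presenceMode <- .check_mode(presenceMode)
  gd <- genomeData(x)
  finished <- gd$finished
  if (kMissingFinished > sum(finished))
    stop("kMissingFinished exceeds the number of finished genomes")
  pres <- presenceMatrix(x, presenceMode)
  n_missing_fin <- rowSums(!pres[, finished, drop = FALSE])
  keep <- n_missing_fin <= kMissingFinished
  if (!draftWildcard && any(!finished))
    keep <- keep & rowSums(!pres[, !finished, drop = FALSE]) == 0L
  if (singleCopy) {
    fc <- functionalCounts(x)
    keep <- keep & rowSums(pres & fc != 1L) == 0L
  }
  ids <- groupIds(x)[keep]
  fin_ids <- genomeIds(x)[finished]
  missing_fin <- lapply(which(keep), function(g)
    fin_ids[!pres[g, finished]])
  fc <- functionalCounts(x)
  pc <- pseudoCounts(x)
  loss <- lapply(which(keep), function(g)
    genomeIds(x)[fc[g, ] == 0L & pc[g, ] > 0L])
  names(missing_fin) <- names(loss) <- ids
  new("CoreResult",
      spec = list(k_missing_finished = as.integer(kMissingFinished),
                  draft_wildcard = draftWildcard,
                  presence_mode = presenceMode, single_copy = singleCopy),
      groups = ids, missingFinished = missing_fin, functionalLoss = loss)
}

#' @describeIn computeCore group ids of the core members
#' @param object a CoreResult
#' @export
coreGroups <- function(object) object@groups

#' @describeIn computeCore per-group finished genomes lacking the ortholog
#' @export
coreMissingFinished <- function(object) object@missingFinished

#' @describeIn computeCore per-group genomes retaining only pseudogene copies
#' @export
coreFunctionalLoss <- function(object) object@functionalLoss

#' @export
setMethod("show", "CoreResult", function(object) {
  s <- object@spec
  cat(sprintf(
    "CoreResult: %d groups (k_missing_finished=%d, draft_wildcard=%s, %s%s)\n",
    length(object@groups), s$k_missing_finished, s$draft_wildcard,
    s$presence_mode, if (s$single_copy) ", single-copy" else ""))
  nl <- sum(lengths(object@functionalLoss) > 0)
  if (nl) cat(sprintf("  %d groups carry pseudogene-only copies somewhere\n", nl))
})

#' Phenotype-exclusive ortholog signature
#'
#' Groups present in the required flag-positive genomes and entirely absent
#' (no functional or pseudogene copy) from every flag-negative genome,
#' regardless of assembly status. With \code{mode = "finished_positive"}
#' presence is required only in finished positive genomes (drafts may lack
#' the group); \code{"all_positive"} requires presence in every positive
#' genome. Positive-side presence counts pseudogene copies
#' (\code{presenceMode = "any_copy"}); positive genomes where the group
#' survives only as a pseudogene are reported in the \code{pseudo_only}
#' column.
#'
#' @param x an \linkS4class{OrthologSet}
#' @param flag a phenotype flag column of the genome table, e.g.
#'   "heterocystous"
#' @param mode "finished_positive" or "all_positive"
#' @param presenceMode presence evaluation on the positive side
#' @return data.frame with columns \code{group_id} and \code{pseudo_only}
#'   (comma-separated positive genomes with pseudogene-only presence)
#' @export
phenotypeSignature <- function(x, flag,
                               mode = c("finished_positive", "all_positive"),
                               presenceMode = c("any_copy", "functional_only")) {
  mode <- match.arg(mode)
  presenceMode <- .check_mode(presenceMode)
  gd <- genomeData(x)
  if (!flag %in% colnames(gd))
    stop("unknown phenotype flag: ", flag)
  pos <- which(gd[[flag]])
  neg <- which(!gd[[flag]])
  req <- if (mode == "finished_positive") intersect(pos, which(gd$finished))
         else pos
  pres <- presenceMatrix(x, presenceMode)
  any_pres <- presenceMatrix(x, "any_copy")
  keep <- rowSums(!pres[, req, drop = FALSE]) == 0L &
    rowSums(any_pres[, neg, drop = FALSE]) == 0L
  fc <- functionalCounts(x)
  pc <- pseudoCounts(x)
  ids <- groupIds(x)[keep]
  ponly <- vapply(which(keep), function(g) {
    p <- pos[fc[g, pos] == 0L & pc[g, pos] > 0L]
    paste(genomeIds(x)[p], collapse = ",")
  }, "")
  data.frame(group_id = ids, pseudo_only = ponly, stringsAsFactors = FALSE)
}

#' Clade-exclusive ortholog signature
#'
#' Groups present in all finished genomes of \code{cladeA} and entirely
#' absent from every genome of \code{cladeB}. Genomes labelled
#' \code{outgroup} or \code{unassigned} are ignored. The symmetric call
#' yields the reverse signature.
#'
#' @param x an \linkS4class{OrthologSet}
#' @param cladeA,cladeB clade labels from the genome table
#' @param presenceMode presence evaluation in cladeA (default any_copy)
#' @return character vector of group ids
#' @export
cladeSignature <- function(x, cladeA = "clade1", cladeB = "clade2",
                           presenceMode = c("any_copy", "functional_only")) {
  presenceMode <- .check_mode(presenceMode)
  gd <- genomeData(x)
  for (cl in c(cladeA, cladeB))
    if (!cl %in% gd$clade)
      stop("clade label absent from genome table: ", cl)
  a_fin <- which(gd$clade == cladeA & gd$finished)
  b_all <- which(gd$clade == cladeB)
  pres <- presenceMatrix(x, presenceMode)
  any_pres <- presenceMatrix(x, "any_copy")
  keep <- rowSums(!pres[, a_fin, drop = FALSE]) == 0L &
    rowSums(any_pres[, b_all, drop = FALSE]) == 0L
  groupIds(x)[keep]
}

#' Orthologs missing from one genome but present in all others
#'
#' Groups with zero functional copies in \code{genome} (either fully absent
#' or surviving only as pseudogenes — the two cases are distinguished) while
#' every other genome retains at least one functional copy.
#'
#' @param x an \linkS4class{OrthologSet}
#' @param genome a genome id
#' @return data.frame with columns \code{group_id} and \code{status}
#'   ("absent" or "pseudogenized")
#' @export
missingInGenome <- function(x, genome) {
  if (!genome %in% genomeIds(x)) stop("unknown genome: ", genome)
  fc <- functionalCounts(x)
  pc <- pseudoCounts(x)
  others <- setdiff(genomeIds(x), genome)
  keep <- fc[, genome] == 0L &
    rowSums(fc[, others, drop = FALSE] == 0L) == 0L
  data.frame(
    group_id = groupIds(x)[keep],
    status = as.character(ifelse(pc[keep, genome] > 0L,
                                 "pseudogenized", "absent")),
    stringsAsFactors = FALSE)
}
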