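#' Construct an OrthologSet
#'
#' @param functional integer matrix of functional copy counts, rows = ortholog
#'   groups, columns = genomes; dimnames required
#' @param pseudo integer matrix of pseudogene copy counts, same dims
#' @param genomeData data.frame or DataFrame of per-genome metadata, one row
#'   per column of the count matrices, rownames = genome ids. Must contain a
#'   logical \code{finished} column; \code{clade} defaults to "unassigned".
#' @return an \linkS4class{OrthologSet}
#' @export
#' @examples
#' fc <- matrix(c(1L, 1L, 0L, 2L), 2, 2,
#'              dimnames = list(c("G1", "G2"), c("A", "B")))
#' gd <- data.frame(finished = c(TRUE, TRUE), row.names = c("A", "B"))
#' OrthologSet(fc, genomeData = gd)
OrthologSet <- function(functional, pseudo = NULL, genomeData) {
  functional <- as.matrix(functional)
  if (is.null(pseudo)) {
    pseudo <- functional
    pseudo[] <- 0L
  }
  pseudo <- as.matrix(pseudo)
  storage.mode(functional) <- "integer"
  storage.mode(pseudo) <- "integer"
  gd <- S4Vectors::DataFrame(genomeData)
  if (is.null(rownames(gd)) && !is.null(colnames(functional)))
    rownames(gd) <- colnames(functional)
  if (!"clade" %in% colnames(gd))
    gd$clade <- "unassigned"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(functional = functional, pseudo = pseudo), colData = gd)
  new("OrthologSet", se)
}

#' @describeIn OrthologSet functional copy-count matrix
#' @param x an OrthologSet
#' @export
functionalCounts <- function(x) SummarizedExperiment::assay(x, "functional")

#' @describeIn OrthologSet pseudogene copy-count matrix
#' @export
pseudoCounts <- function(x) SummarizedExperiment::assay(x, "pseudo")

#' @describeIn OrthologSet genome metadata (colData) as a data.frame
#' @export
genomeData <- function(x) as.data.frame(SummarizedExperiment::colData(x))

#' @describeIn OrthologSet ortholog group ids
#' @export
groupIds <- function(x) rownames(x)

#' @describeIn OrthologSet genome ids
#' @export
genomeIds <- function(x) colnames(x)

.check_mode <- function(mode)
  match.arg(mode, c("any_copy", "functional_only"))

#' Copy-number matrix under a presence mode
#'
#' \code{any_copy} counts functional plus pseudogene copies (a pseudogene is
#' presence without function); \code{functional_only} counts functional
#' copies alone.
#'
#' @param x an OrthologSet
#' @param mode "any_copy" or "functional_only"
#' @return integer matrix, groups x genomes
#' @export
copyNumbers <- function(x, mode = c("any_copy", "functional_only")) {
  mode <- .check_mode(mode)
  if (mode == "any_copy") functionalCounts(x) + pseudoCounts(x)
  else functionalCounts(x)
}

#' Presence/absence matrix under a presence mode
#'
#' @inheritParams copyNumbers
#' @return logical matrix, groups x genomes
#' @export
presenceMatrix <- function(x, mode = c("any_copy", "functional_only"))
  copyNumbers(x, mode) > 0L

#' @export
setMethod("show", "OrthologSet", function(object) {
  cat(sprintf("OrthologSet: %d ortholog groups x %d genomes\n",
              nrow(object), ncol(object)))
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("  finished genomes: %d | total functional copies: %d | pseudogene copies: %d\n",
              sum(cd$finished),
              sum(functionalCounts(object)), sum(pseudoCounts(object))))
  if ("clade" %in% colnames(cd))
    cat("  clades:", paste(sprintf("%s=%d", names(table(cd$clade)),
                                   table(cd$clade)), collapse = " "), "\n")
})

#' Build an OrthologSet from parsed inputs
#'
#' Assembles the group x genome copy matrices from a tidy membership table,
#' a genome metadata table and an optional pseudogene list. Members whose
#' gene id appears in \code{pseudogenes} are counted as pseudogene copies;
#' all others as functional copies. Genomes without members of a group get
#' zero counts.
#'
#' @param groups data.frame with columns \code{group_id}, \code{genome_id},
#'   \code{gene_id} (one row per member), as returned by
#'   \code{\link{readOrthoGroups}}
#' @param genomes data.frame of genome metadata with a \code{id} column (or
#'   rownames), as returned by \code{\link{readGenomeTable}}
#' @param pseudogenes character vector of pseudogene gene ids (optional)
#' @return an \linkS4class{OrthologSet}
#' @export
buildOrthologSet <- function(groups, genomes, pseudogenes = NULL) {
  stopifnot(all(c("group_id", "genome_id", "gene_id") %in% colnames(groups)))
  if ("id" %in% colnames(genomes)) {
    rownames(genomes) <- genomes$id
    genomes$id <- NULL
  }
  gids <- rownames(genomes)
  unknown <- setdiff(unique(groups$genome_id), gids)
  if (length(unknown))
    stop("ortholog group members reference genomes absent from the genome ",
         "table: ", paste(unknown, collapse = ", "))
  grp <- factor(groups$group_id, levels = unique(groups$group_id))
  gen <- factor(groups$genome_id, levels = gids)
  is_pseudo <- groups$gene_id %in% pseudogenes
  fc <- table(grp[!is_pseudo], gen[!is_pseudo])
  pc <- table(grp[is_pseudo], gen[is_pseudo])
  to_mat <- function(tb) {
    m <- matrix(0L, nlevels(grp), nlevels(gen),
                dimnames = list(levels(grp), levels(gen)))
    if (nrow(tb)) m[rownames(tb), colnames(tb)] <- as.integer(tb)
    m
  }
  OrthologSet(to_mat(fc), to_mat(pc), genomeData = genomes)
}
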