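#' Read an OrthoMCL-style groups file
#'
#' Each non-empty line is \code{"groupId: taxon|gene taxon|gene ..."} with
#' whitespace-separated members; each member token is split at its first
#' \code{"|"} into (genome id, gene id).
#'
#' @param path file path
#' @return data.frame with columns \code{group_id}, \code{genome_id},
#'   \code{gene_id}, one row per member, groups in file order
#' @export
readOrthoGroups <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) & !grepl("^\\s*#", lines)
  out <- vector("list", sum(keep))
  j <- 0L
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    line <- lines[i]
    m <- regexpr(":", line, fixed = TRUE)
    if (m < 0)
      stop(sprintf("groups file parse error at line %d: missing ':'", i))
    gid <- trimws(substr(line, 1L, m - 1L))
    if (!nzchar(gid))
      stop(sprintf("groups file parse error at line %d: empty group id", i))
    rest <- trimws(substring(line, m + 1L))
    members <- strsplit(rest, "\\s+")[[1]]
    members <- members[nzchar(members)]
    if (!length(members))
      stop(sprintf("groups file parse error at line %d: group without members", i))
    bar <- regexpr("|", members, fixed = TRUE)
    if (any(bar < 0))
      stop(sprintf("groups file parse error at line %d: member without '|'", i))
    j <- j + 1L
    out[[j]] <- data.frame(
      group_id = gid,
      genome_id = substr(members, 1L, bar - 1L),
      gene_id = substring(members, bar + 1L),
      stringsAsFactors = FALSE)
    if (anyDuplicated(paste(out[[j]]$genome_id, out[[j]]$gene_id)))
      stop(sprintf("groups file parse error at line %d: duplicate member", i))
  }
  res <- do.call(rbind, out[seq_len(j)])
  if (is.null(res))
    res <- data.frame(group_id = character(), genome_id = character(),
                      gene_id = character(), stringsAsFactors = FALSE)
  res
}

#' Write an OrthoMCL-style groups file
#'
#' @param groups membership data.frame as from \code{\link{readOrthoGroups}}
#' @param path output path
#' @export
writeOrthoGroups <- function(groups, path) {
  sp <- split(paste0(groups$genome_id, "|", groups$gene_id),
              factor(groups$group_id, levels = unique(groups$group_id)))
  writeLines(paste0(names(sp), ": ", vapply(sp, paste, "", collapse = " ")),
             path)
  invisible(path)
}

.as_bool <- function(x) {
  if (is.logical(x)) return(x)
  x <- as.character(x)
  if (!all(is.na(x) | x %in% c("0", "1", "TRUE", "FALSE")))
    stop("boolean column must be encoded 0/1")
  out <- x %in% c("1", "TRUE")
  out[is.na(x)] <- NA
  out
}

#' Read a genome metadata table
#'
#' Tab-delimited, UTF-8, header line, \code{#} comment lines ignored.
#' Expected columns: \code{id}, \code{name}, \code{finished} (0/1),
#' \code{clade}, \code{genome_size_bp}, \code{coding_bp}, \code{noncoding_bp},
#' \code{pseudogene_bp}, \code{gene_count}, phenotype flag columns
#' (\code{filamentous}, \code{heterocystous}, \code{diazotroph},
#' \code{plant_symbiont}; 0/1) and \code{habitat}. The nucleotide partition
#' must sum exactly to genome size and ids must be unique.
#'
#' @param path file path
#' @return data.frame with rownames = genome ids, flags as logicals
#' @export
readGenomeTable <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!"id" %in% colnames(df)) stop("genome table lacks an 'id' column")
  if (anyDuplicated(df$id))
    stop("duplicate genome ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  for (col in intersect(c("finished", .PHENOTYPE_FLAGS), colnames(df)))
    df[[col]] <- .as_bool(df[[col]])
  part <- c("genome_size_bp", "coding_bp", "noncoding_bp", "pseudogene_bp")
  if (all(part %in% colnames(df))) {
    bad <- which(df$coding_bp + df$noncoding_bp + df$pseudogene_bp !=
                   df$genome_size_bp)
    if (length(bad))
      stop("coding + noncoding + pseudogene bp do not sum to genome size ",
           "for genome(s): ", paste(df$id[bad], collapse = ", "))
  }
  if ("clade" %in% colnames(df) && !all(df$clade %in% .CLADE_LEVELS))
    stop("unknown clade label(s): ",
         paste(setdiff(df$clade, .CLADE_LEVELS), collapse = ", "))
  rownames(df) <- df$id
  df$id <- NULL
  df
}

#' Write a genome metadata table
#'
#' @param genomes data.frame as from \code{\link{readGenomeTable}}
#' @param path output path
#' @export
writeGenomeTable <- function(genomes, path) {
  df <- genomes
  for (col in intersect(c("finished", .PHENOTYPE_FLAGS), colnames(df)))
    df[[col]] <- as.integer(df[[col]])
  df <- cbind(id = rownames(genomes), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pseudogene list
#'
#' One gene id per line; an optional second tab-separated column carries the
#' genome id (ignored for matrix construction). \code{#} comments allowed.
#'
#' @param path file path
#' @return character vector of gene ids
#' @export
readPseudogenes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  vapply(strsplit(lines, "\t"), `[`, "", 1L)
}

#' Read a per-protein COG best-hit table
#'
#' Tab-delimited with header: \code{gene_id}, \code{category} (single COG
#' letter, or empty/\code{-} for no hit), \code{evalue}, and optionally
#' \code{cog} (the COG identifier, used for the transposase carve-out).
#'
#' @param path file path
#' @return data.frame with one row per gene id
#' @export
readCogHits <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "category", "evalue") %in% colnames(df)))
  if (anyDuplicated(df$gene_id))
    stop("COG hit table has multiple rows for gene id(s): ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  if (any(df$evalue < 0)) stop("negative e-value in COG hit table")
  df$category[df$category %in% c("", "-", "none")] <- NA_character_
  df
}

#' Read a rooted phylogeny in Newick format
#'
#' Thin validated wrapper over \code{ape::read.tree}: requires unique tip
#' labels and non-negative branch lengths; polytomies are preserved.
#'
#' @param file path to a Newick file (or NULL when \code{text} is given)
#' @param text Newick string
#' @return an ape \code{phylo}
#' @export
readTree <- function(file = NULL, text = NULL) {
  tr <- if (is.null(text)) ape::read.tree(file) else ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick tree")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch lengths")
  tr
}

#' Write a phylogeny in Newick format
#'
#' @param tree an ape \code{phylo}
#' @param path output path
#' @export
writeTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
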