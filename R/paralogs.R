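#' Per-genome in-paralog statistics
#'
#' A group is paralogous in a genome when its copy count there (under
#' \code{presenceMode}) is at least 2. For each genome the summary reports
#' the number of such groups, their proportion, the total number of
#' paralogous gene copies, the mean copies per paralogous group, and the
#' pseudogene share among those copies.
#'
#' The proportion's denominator defaults to the number of groups with at
#' least one copy in that genome; \code{denominator = "matrix"} uses the
#' total number of groups in the matrix instead.
#'
#' @param x an \linkS4class{OrthologSet}
#' @param presenceMode "any_copy" (default) or "functional_only"
#' @param denominator "genome" or "matrix"
#' @return data.frame, one row per genome: \code{genome_id},
#'   \code{n_groups}, \code{n_paralog_groups}, \code{prop_paralog_groups},
#'   \code{total_paralog_copies}, \code{mean_copies}, \code{pseudo_share}
#' @export
paralogStats <- function(x, presenceMode = c("any_copy", "functional_only"),
                         denominator = c("genome", "matrix")) {
  presenceMode <- .check_mode(presenceMode)
  denominator <- match.arg(denominator)
  cn <- copyNumbers(x, presenceMode)
  fc <- functionalCounts(x)
  pc <- pseudoCounts(x)
  par <- cn >= 2L
  n_present <- colSums(cn >= 1L)
  n_par <- colSums(par)
  denom <- if (denominator == "genome") n_present else rep(nrow(x), ncol(x))
  total <- colSums(cn * par)
  pseudo_in_par <- colSums(pc * par)
  all_in_par <- colSums((fc + pc) * par)
  data.frame(
    genome_id = genomeIds(x),
    n_groups = n_present,
    n_paralog_groups = n_par,
    prop_paralog_groups = ifelse(denom > 0, n_par / denom, 0),
    total_paralog_copies = total,
    mean_copies = ifelse(n_par > 0, total / n_par, NA_real_),
    pseudo_share = ifelse(all_in_par > 0, pseudo_in_par / all_in_par,
                          NA_real_),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Majority-rule COG category assignment for one ortholog group
#'
#' Implements the plurality rule used for group-level functional annotation:
#' member hits at or above the e-value cut-off are discarded; members
#' without a passing hit count as a pseudo-category "none". If the plurality
#' category is a real COG it is assigned; if "none" is the plurality, the
#' most abundant real COG (if any) is assigned instead; otherwise no
#' category. Ties among equally abundant real COGs are broken
#' lexicographically.
#'
#' @param categories character vector of per-member best-hit categories
#'   (NA for no passing hit)
#' @return single COG category letter, or NA
#' @export
assignCog <- function(categories) {
  categories[is.na(categories)] <- ".none"
  counts <- sort(table(categories), decreasing = TRUE)
  real <- counts[names(counts) != ".none"]
  if (!length(real)) return(NA_character_)
  m <- max(counts)
  top_real <- names(real)[real == m]
  if (length(top_real)) return(sort(top_real)[1L])
  # "none" is the strict plurality: fall back to the most abundant real COG
  sort(names(real)[real == max(real)])[1L]
}

#' COG category assignment for every ortholog group
#'
#' Applies \code{\link{assignCog}} group-wise after discarding hits with
#' e-value >= \code{evalueCutoff}.
#'
#' @param groups membership data.frame (\code{group_id}, \code{genome_id},
#'   \code{gene_id}) as from \code{\link{readOrthoGroups}}
#' @param hits COG best-hit table from \code{\link{readCogHits}}
#' @param evalueCutoff hits at or above this e-value are discarded (0.01,
#'   the conventional RPS-BLAST cut-off)
#' @return named character vector: group id -> category letter or NA
#' @export
cogAssignments <- function(groups, hits, evalueCutoff = 0.01) {
  ok <- hits[!is.na(hits$category) & hits$evalue < evalueCutoff, ]
  cat_of <- stats::setNames(ok$category, ok$gene_id)
  member_cat <- unname(cat_of[groups$gene_id])
  vapply(split(member_cat,
               factor(groups$group_id, levels = unique(groups$group_id))),
         assignCog, "")
}

#' Genome-by-COG-category functional distribution
#'
#' For each genome, the proportion of its gene copies whose group carries
#' each COG category; groups without an assigned category fall into an
#' \code{unassigned} bin, so each row sums to 1. Pseudogene copies are
#' excluded by default. When \code{transposaseGroups} is given, those groups
#' (a transposase subset of category L) are additionally reported in a
#' subcolumn \code{"t"} while remaining counted inside L.
#'
#' @param x an \linkS4class{OrthologSet}
#' @param cogMap named vector group id -> category, as from
#'   \code{\link{cogAssignments}}; must cover every group of \code{x}
#' @param excludePseudogenes drop pseudogene copies from the tally (default)
#' @param transposaseGroups optional character vector of group ids
#' @return numeric matrix genomes x categories (plus \code{unassigned} and
#'   optionally \code{t})
#' @export
functionalDistribution <- function(x, cogMap, excludePseudogenes = TRUE,
                                   transposaseGroups = NULL) {
  if (!all(groupIds(x) %in% names(cogMap)))
    stop("cogMap does not cover every group in the matrix")
  cats <- cogMap[groupIds(x)]
  counts <- if (excludePseudogenes) functionalCounts(x)
            else functionalCounts(x) + pseudoCounts(x)
  lev <- sort(unique(stats::na.omit(unname(cats))))
  f <- factor(ifelse(is.na(cats), "unassigned", cats),
              levels = c(lev, "unassigned"))
  tot <- rowsum(counts, f, reorder = FALSE)  # category x genome
  denom <- colSums(tot)
  if (any(denom == 0))
    stop("genome(s) with no counted gene copies: ",
         paste(genomeIds(x)[denom == 0], collapse = ", "))
  out <- t(tot) / denom
  if (!is.null(transposaseGroups)) {
    tg <- groupIds(x) %in% transposaseGroups
    out <- cbind(out, t = colSums(counts[tg, , drop = FALSE]) / denom)
  }
  out
}
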