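#' Felsenstein's phylogenetically independent contrasts
#'
#' Standard post-order algorithm on a binary rooted tree with strictly
#' positive branch lengths. At each internal node with daughters carrying
#' working values (x_a, x_b) and corrected branch lengths (v_a, v_b):
#' the raw contrast is x_a - x_b with standard deviation sqrt(v_a + v_b);
#' the node's working value is the inverse-variance weighted mean and its
#' own branch length is incremented by v_a v_b / (v_a + v_b). Under
#' Brownian motion the standardized contrasts are i.i.d. Normal(0, sigma^2).
#'
#' When clade labels are supplied, each contrast is assigned a clade iff
#' every descendant tip of its node carries that label; contrasts spanning
#' clades or touching outgroup/unassigned tips are labelled "excluded"
#' (the between-clade basal contrast is therefore never tested).
#'
#' @param tree binary rooted ape \code{phylo} with positive branch lengths
#' @param tipValues numeric values named by tip label
#' @param clades optional clade labels named by tip label
#' @return data.frame, one row per internal node: \code{node} (ape node
#'   number), \code{raw}, \code{sd}, \code{standardized}, and \code{clade}
#'   when labels were given
#' @export
picContrasts <- function(tree, tipValues, clades = NULL) {
  nt <- ape::Ntip(tree)
  if (!ape::is.rooted(tree) || !ape::is.binary.phylo(tree))
    stop("tree has polytomies; resolve them (e.g. ape::multi2di) before ",
         "computing contrasts")
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0))
    stop("contrasts need strictly positive branch lengths")
  if (!all(tree$tip.label %in% names(tipValues)))
    stop("tip(s) missing a value")
  x <- numeric(nt + tree$Nnode)
  x[seq_len(nt)] <- as.numeric(tipValues[tree$tip.label])
  # corrected length of the edge above each node
  v <- numeric(nt + tree$Nnode)
  v[tree$edge[, 2L]] <- tree$edge.length
  ch <- .children_list(tree)
  ord <- .postorder_internal(tree)
  out <- data.frame(node = ord, raw = NA_real_, sd = NA_real_)
  for (i in seq_along(ord)) {
    node <- ord[i]
    a <- ch[[node]][1L]; b <- ch[[node]][2L]
    out$raw[i] <- x[a] - x[b]
    out$sd[i] <- sqrt(v[a] + v[b])
    x[node] <- (x[a] / v[a] + x[b] / v[b]) / (1 / v[a] + 1 / v[b])
    v[node] <- v[node] + v[a] * v[b] / (v[a] + v[b])
  }
  out$standardized <- out$raw / out$sd
  if (!is.null(clades)) {
    tip_clade <- as.character(clades[tree$tip.label])
    node_clade <- character(nt + tree$Nnode)
    node_clade[seq_len(nt)] <- tip_clade
    for (node in ord) {
      cl <- unique(node_clade[ch[[node]]])
      node_clade[node] <-
        if (length(cl) == 1L && cl %in% c("clade1", "clade2")) cl
        else "excluded"
    }
    out$clade <- node_clade[out$node]
  }
  out
}

#' Wilcoxon rank-sum test of contrast magnitudes between clades
#'
#' Two-sample two-tailed Wilcoxon rank-sum test on the absolute values of
#' standardized contrasts of one clade versus the other — a test of equal
#' evolutionary rates under Brownian motion, since contrast magnitudes scale
#' with the square root of the rate. Contrasts labelled "excluded" (the
#' basal between-clade contrast and outgroup-spanning contrasts) are
#' dropped. The exact null distribution is enumerated when both groups have
#' at most 12 contrasts and no ties; otherwise the normal approximation
#' with tie and continuity corrections is used.
#'
#' @param contrasts contrast table from \code{\link{picContrasts}} with a
#'   \code{clade} column
#' @param clade1,clade2 labels of the two groups
#' @return list: \code{statistic} (rank-sum W), \code{p} (two-tailed),
#'   \code{n1}, \code{n2}, \code{method} ("exact" or "normal")
#' @export
cladeRateTest <- function(contrasts, clade1 = "clade1", clade2 = "clade2") {
  g1 <- abs(contrasts$standardized[contrasts$clade == clade1])
  g2 <- abs(contrasts$standardized[contrasts$clade == clade2])
  if (!length(g1) || !length(g2))
    stop("no contrasts in one of the clades after exclusions")
  ties <- anyDuplicated(c(g1, g2)) > 0L
  exact <- length(g1) <= 12L && length(g2) <= 12L && !ties
  wt <- stats::wilcox.test(g1, g2, alternative = "two.sided",
                           exact = exact, correct = TRUE)
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n1 = length(g1), n2 = length(g2),
       method = if (exact) "exact" else "normal")
}

#' Regression through the origin of paired contrasts
#'
#' Positivizes the pairs (whenever x < 0, both signs are flipped), then fits
#' the no-intercept regression slope = sum(xy)/sum(x^2) with correlation
#' r = sum(xy)/sqrt(sum(x^2) sum(y^2)) and a two-tailed p-value from
#' t = r sqrt((n-1)/(1-r^2)) on n-1 degrees of freedom (the through-origin
#' convention: one parameter estimated, no intercept).
#'
#' @param x,y paired standardized contrasts from the same internal nodes
#' @return list: \code{slope}, \code{r}, \code{p}, \code{n}
#' @export
originRegression <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 paired contrasts")
  flip <- x < 0
  x[flip] <- -x[flip]
  y[flip] <- -y[flip]
  sxx <- sum(x^2)
  if (sxx == 0) stop("all x contrasts are zero")
  sxy <- sum(x * y)
  syy <- sum(y^2)
  r <- if (syy == 0) 0 else sxy / sqrt(sxx * syy)
  p <- if (1 - r^2 < .Machine$double.eps) 0
       else 2 * stats::pt(-abs(r * sqrt((n - 1) / (1 - r^2))), df = n - 1)
  list(slope = sxy / sxx, r = r, p = p, n = n)
}
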