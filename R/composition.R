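#' Genome nucleotide-composition table
#'
#' Builds the nucleotide-class x genome contingency table underlying the
#' composition bias test. Pseudogene nucleotides merge into the non-coding
#' row by default (a pseudogene region no longer codes), can be kept as a
#' separate third row, or merged into the coding row.
#'
#' @param genomes genome metadata data.frame with columns \code{coding_bp},
#'   \code{noncoding_bp}, \code{pseudogene_bp}
#' @param pseudogeneMode "merge_noncoding" (default), "separate" or
#'   "merge_coding"
#' @return integer matrix with rows \code{coding}, \code{noncoding} (and
#'   \code{pseudogene} when separate), columns = genomes
#' @export
compositionTable <- function(genomes,
                             pseudogeneMode = c("merge_noncoding", "separate",
                                                "merge_coding")) {
  pseudogeneMode <- match.arg(pseudogeneMode)
  cb <- genomes$coding_bp
  nb <- genomes$noncoding_bp
  pb <- genomes$pseudogene_bp
  tab <- switch(pseudogeneMode,
    merge_noncoding = rbind(coding = cb, noncoding = nb + pb),
    separate = rbind(coding = cb, noncoding = nb, pseudogene = pb),
    merge_coding = rbind(coding = cb + pb, noncoding = nb))
  colnames(tab) <- rownames(genomes)
  storage.mode(tab) <- "double"  # bp totals can exceed .Machine$integer.max
  tab
}

#' Monte-Carlo Pearson chi-squared test for composition bias
#'
#' Tests whether non-coding nucleotides are unequally distributed across
#' genomes. The Pearson statistic sum((O-E)^2/E) is computed from the
#' observed table with expectations from the row/column margins; the null
#' distribution is sampled by multinomial resampling of the table total with
#' cell probabilities E/total (independence of nucleotide class and genome),
#' and the p-value uses the add-one convention
#' p = (1 + #\{replicate >= observed\}) / (B + 1), so p >= 1/(B+1).
#' Per-genome Pearson residuals (O-E)/sqrt(E) of the non-coding row give a
#' bias call: "noncoding" above +\code{residualThreshold}, "coding" below
#' -\code{residualThreshold}, else "none".
#'
#' @param table contingency table from \code{\link{compositionTable}} (the
#'   last row is taken as the non-coding row)
#' @param B number of Monte-Carlo replicates (2000 gives a minimum
#'   attainable p of 1/2001, i.e. < 0.001)
#' @param seed integer seed for the resampling
#' @param residualThreshold bias-call threshold on the Pearson residual
#' @return a \linkS4class{CompositionTest}
#' @export
noncodingChisq <- function(table, B = 2000L, seed = 1L,
                           residualThreshold = 2) {
  if (B < 1) stop("B must be >= 1")
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs <= 0) || any(cs <= 0)) stop("zero row or column margin")
  n <- sum(table)
  E <- outer(rs, cs) / n
  stat <- sum((table - E)^2 / E)
  probs <- as.vector(E) / n
  set.seed(as.integer(seed))
  ge <- 0L
  for (b in seq_len(B)) {
    sim <- matrix(stats::rmultinom(1L, n, probs), nrow(table))
    Eb <- outer(rowSums(sim), colSums(sim)) / n
    if (any(Eb == 0)) { ge <- ge + 1L; next }  # degenerate draw: conservative
    if (sum((sim - Eb)^2 / Eb) >= stat) ge <- ge + 1L
  }
  p <- (1 + ge) / (B + 1)
  resid <- (table[nrow(table), ] - E[nrow(table), ]) / sqrt(E[nrow(table), ])
  bias <- ifelse(resid > residualThreshold, "noncoding",
                 ifelse(resid < -residualThreshold, "coding", "none"))
  new("CompositionTest", table = table, statistic = stat, B = as.integer(B),
      p = p, residuals = resid, bias = as.character(bias))
}

#' @describeIn noncodingChisq chi-squared statistic
#' @param object a CompositionTest
#' @export
testStatistic <- function(object) object@statistic

#' @describeIn noncodingChisq Monte-Carlo p-value
#' @export
testPValue <- function(object) object@p

#' @describeIn noncodingChisq per-genome non-coding Pearson residuals
#' @export
testResiduals <- function(object) object@residuals

#' @describeIn noncodingChisq per-genome bias calls
#' @export
biasCalls <- function(object) object@bias

#' @export
setMethod("show", "CompositionTest", function(object) {
  cat(sprintf(
    "Monte-Carlo Pearson chi-squared composition test\n  X-squared = %.4g, B = %d replicates, p = %.4g\n",
    object@statistic, object@B, object@p))
  tb <- table(factor(object@bias, levels = c("coding", "noncoding", "none")))
  cat(sprintf("  bias calls: coding=%d noncoding=%d none=%d\n",
              tb["coding"], tb["noncoding"], tb["none"]))
})
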