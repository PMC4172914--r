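checkCounts <- function(nf, n, Nf, N) {
  nf <- assertCount(nf, "nf"); n <- assertCount(n, "n")
  Nf <- assertCount(Nf, "Nf"); N <- assertCount(N, "N")
  if (any(n > N) || any(Nf > N) || any(nf > pmin(n, Nf)) ||
      any(nf < pmax(0L, n + Nf - N)))
    stop("inconsistent 2x2 counts: need nf <= min(n, Nf), n <= N, Nf <= N")
  list(nf = nf, n = n, Nf = Nf, N = N)
}

#' One-sided Fisher over-representation p-value
#'
#' Probability that a hypergeometric draw of `n` genes from a universe of
#' `N` genes containing `Nf` genes of interest yields at least the observed
#' `nf` genes of interest: `P(X >= nf)`, the upper tail of
#' `Hypergeometric(N, Nf, n)`. This is the one-sided Fisher exact test for
#' over-representation of a category. Vectorized over the counts.
#'
#' @param nf genes of interest inside the category.
#' @param n category size.
#' @param Nf genes of interest in the universe.
#' @param N universe size.
#' @return p-value(s) in (0, 1].
#' @examples
#' fisherEnrichment(3, 5, 10, 100)
#' fisherEnrichment(0, 5, 10, 100)  # upper tail from zero is 1
#' @export
fisherEnrichment <- function(nf, n, Nf, N) {
  cc <- checkCounts(nf, n, Nf, N)
  stats::phyper(cc$nf - 1L, cc$Nf, cc$N - cc$Nf, cc$n, lower.tail = FALSE)
}

#' Pearson chi-square p-value for a 2x2 enrichment table
#'
#' Pearson's chi-square statistic (1 df, no continuity correction) on the
#' table `[[nf, n - nf], [Nf - nf, N - n - Nf + nf]]` with its upper-tail
#' p-value. When any expected cell count is zero the test is undefined and
#' the p-value is reported as 1 with attribute `undefined = TRUE`.
#'
#' @inheritParams fisherEnrichment
#' @return p-value(s) in (0, 1], with attributes `statistic` and
#'   `undefined` (logical vectors).
#' @examples
#' chi2Enrichment(3, 5, 10, 100)
#' @export
chi2Enrichment <- function(nf, n, Nf, N) {
  cc <- checkCounts(nf, n, Nf, N)
  nf <- as.numeric(cc$nf); n <- as.numeric(cc$n)
  Nf <- as.numeric(cc$Nf); N <- as.numeric(cc$N)
  # expected counts from the margins (row: in/out category, col: DE or not)
  e11 <- n * Nf / N; e12 <- n * (N - Nf) / N
  e21 <- (N - n) * Nf / N; e22 <- (N - n) * (N - Nf) / N
  undefined <- e11 == 0 | e12 == 0 | e21 == 0 | e22 == 0
  o11 <- nf; o12 <- n - nf; o21 <- Nf - nf; o22 <- N - n - Nf + nf
  stat <- (o11 - e11)^2 / e11 + (o12 - e12)^2 / e12 +
    (o21 - e21)^2 / e21 + (o22 - e22)^2 / e22
  stat[undefined] <- NA_real_
  p <- ifelse(undefined, 1, stats::pchisq(stat, df = 1, lower.tail = FALSE))
  structure(p, statistic = stat, undefined = undefined)
}

#' Enrichment ratio Re
#'
#' The in-category proportion of genes of interest over the background
#' proportion: `Re = (nf/n) / (Nf/N)`. `Re > 1` exactly when the category
#' contains more genes of interest than the universe-wide rate predicts.
#'
#' @inheritParams fisherEnrichment
#' @return ratio(s) >= 0.
#' @examples
#' enrichmentRatio(5, 10, 50, 1000)  # 0.5 / 0.05 = 10
#' @export
enrichmentRatio <- function(nf, n, Nf, N) {
  cc <- checkCounts(nf, n, Nf, N)
  if (any(cc$n == 0L) || any(cc$Nf == 0L) || any(cc$N == 0L))
    stop("enrichment ratio undefined: n, Nf and N must be positive")
  (as.numeric(cc$nf) / cc$n) / (as.numeric(cc$Nf) / cc$N)
}

#' Run-level empirical FDR from paired Fisher and chi-square p-values
#'
#' `FDR = 1 - Nk/T`, where `Nk` is the number of categories whose Fisher
#' exact p falls strictly below their chi-square p and `T` is the number of
#' categories tested. The two tests agree in ranking when the signal is
#' strong (the exact tail is then the smaller), so a run in which few
#' categories satisfy `p_fisher < p_chi2` is judged unreliable as a whole;
#' the formula yields one scalar per run, not a per-category quantity.
#'
#' @param rows data.frame with columns `p_fisher` and `p_chi2`.
#' @return list with `Nk`, `T`, `empirical_fdr`.
#' @examples
#' empiricalFdr(data.frame(p_fisher = c(.001, .2), p_chi2 = c(.003, .1)))
#' @export
empiricalFdr <- function(rows) {
  if (!NROW(rows)) stop("no enrichment rows; empirical FDR undefined")
  stopifnot(all(c("p_fisher", "p_chi2") %in% names(rows)))
  Nk <- sum(rows$p_fisher < rows$p_chi2)  # strict: ties do not count
  T <- nrow(rows)
  list(Nk = Nk, T = T, empirical_fdr = 1 - Nk / T)
}

#' Over-representation analysis of differential-miRNA target genes
#'
#' Maps the differential miRNAs to their predicted target genes, intersects
#' with the gene universe, and tests every gene set of size
#' `minTermSize..maxTermSize` for over-representation with the one-sided
#' Fisher exact test and the Pearson chi-square test. Each row carries the
#' counts (`nf`, `n`, `Nf`, `N`), both p-values, the enrichment ratio
#' `Re`, and a reference BH q-value on the Fisher p-values; the run-level
#' empirical FDR `1 - Nk/T` is computed across all tested rows and a term
#' is flagged significant when `p_fisher < pThreshold` and the run's
#' empirical FDR is below `fdrThreshold`. Defaults are the GO thresholds
#' p < 0.001 and FDR < 0.05; pathway runs conventionally use p < 0.05.
#'
#' @param deMirnas character vector of differential miRNA ids.
#' @param targetMap data.frame (`mirna`, `gene`) of predicted targets.
#' @param geneSets a [GeneSetList-class].
#' @param universe gene universe; default all genes in the collection.
#' @param pThreshold Fisher-p significance threshold.
#' @param fdrThreshold run-level empirical-FDR threshold.
#' @param minTermSize,maxTermSize bounds on tested category size (after
#'   intersection with the universe).
#' @return An [EnrichmentResult-class]; rows sorted by Fisher p.
#' @examples
#' sim <- simulateCtPanel(panelConfig(nFeatures = 60, nUp = 6, nDown = 2,
#'                                    seed = 2))
#' ann <- simulateAnnotations(rownames(sim$panel), sim$truth$de$mirna_id,
#'                            nGenes = 500, nTerms = 40, seed = 2)
#' res <- runEnrichment(sim$truth$de$mirna_id, ann$targetMap, ann$geneSets)
#' res
#' @export
runEnrichment <- function(deMirnas, targetMap, geneSets,
                          universe = NULL,
                          pThreshold = 0.001, fdrThreshold = 0.05,
                          minTermSize = 3L, maxTermSize = 500L) {
  stopifnot(is(geneSets, "GeneSetList"))
  if (is.null(universe))
    universe <- unique(unlist(geneSets@sets, use.names = FALSE))
  universe <- unique(as.character(universe))
  de_genes <- unique(targetMap$gene[targetMap$mirna %in% deMirnas])
  de_genes <- intersect(de_genes, universe)
  N <- length(universe)
  Nf <- length(de_genes)

  empty <- function() new("EnrichmentResult",
    table = data.frame(term_id = character(0), description = character(0),
                       nf = integer(0), n = integer(0), Nf = integer(0),
                       N = integer(0), p_fisher = numeric(0),
                       p_chi2 = numeric(0), re = numeric(0),
                       q_fisher = numeric(0), significant = logical(0)),
    Nk = 0L, T = 0L, empiricalFdr = NA_real_,
    namespace = geneSets@namespace,
    pThreshold = pThreshold, fdrThreshold = fdrThreshold)

  if (Nf == 0L) {
    warning("no differential target gene maps into the universe; ",
            "empty enrichment result")
    return(empty())
  }
  sets_u <- lapply(geneSets@sets, intersect, universe)
  n <- lengths(sets_u)
  keep <- n >= minTermSize & n <= maxTermSize
  if (!any(keep)) return(empty())
  sets_u <- sets_u[keep]
  n <- n[keep]
  nf <- vapply(sets_u, function(g) length(intersect(g, de_genes)),
               integer(1))
  p_f <- fisherEnrichment(nf, n, Nf, N)
  p_c <- as.numeric(chi2Enrichment(nf, n, Nf, N))
  re <- enrichmentRatio(nf, n, Nf, N)
  fdr <- empiricalFdr(data.frame(p_fisher = p_f, p_chi2 = p_c))
  tab <- data.frame(
    term_id = names(sets_u),
    description = unname(geneSets@descriptions[names(sets_u)]),
    nf = as.integer(nf), n = as.integer(n),
    Nf = as.integer(Nf), N = as.integer(N),
    p_fisher = p_f, p_chi2 = p_c, re = re,
    q_fisher = bhAdjust(p_f),
    significant = p_f < pThreshold & fdr$empirical_fdr < fdrThreshold,
    stringsAsFactors = FALSE, row.names = NULL
  )
  tab <- tab[order(tab$p_fisher, tab$term_id), , drop = FALSE]
  rownames(tab) <- NULL
  new("EnrichmentResult", table = tab,
      Nk = as.integer(fdr$Nk), T = as.integer(fdr$T),
      empiricalFdr = fdr$empirical_fdr,
      namespace = geneSets@namespace,
      pThreshold = pThreshold, fdrThreshold = fdrThreshold)
}

#' @describeIn runEnrichment per-term result table of an
#'   [EnrichmentResult-class].
#' @param x an [EnrichmentResult-class].
#' @export
setMethod("enrichmentTable", "EnrichmentResult", function(x) x@table)

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult (", object@namespace, "): ", object@T,
      " terms tested\n", sep = "")
  cat(sprintf("  empirical FDR = 1 - %d/%d = %.4f; %d significant (p < %g, FDR < %g)\n",
              object@Nk, object@T,
              if (object@T) object@empiricalFdr else NA,
              sum(object@table$significant), object@pThreshold,
              object@fdrThreshold))
  if (nrow(object@table))
    print(utils::head(object@table[, c("term_id", "nf", "n", "p_fisher",
                                       "re", "significant")], 5))
})

#' Write an enrichment result as TSV
#' @param x an [EnrichmentResult-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeEnrichment <- function(x, path) {
  stopifnot(is(x, "EnrichmentResult"))
  tab <- x@table
  tab$empirical_fdr <- rep(if (x@T) x@empiricalFdr else NA_real_,
                           nrow(tab))
  writeTsv(tab, path)
}
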