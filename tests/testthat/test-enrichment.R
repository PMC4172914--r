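test_that("Fisher upper tail matches the combinatorial sum and fisher.test", {
  expect_equal(fisherEnrichment(0, 5, 10, 100), 1)
  expect_equal(fisherEnrichment(10, 100, 10, 100), 1)  # category = universe
  expect_equal(fisherEnrichment(3, 5, 10, 100),
               bruteFisher(3, 5, 10, 100), tolerance = 1e-12)
  # cross-check against the reference exact test
  ft <- fisher.test(matrix(c(3, 2, 7, 88), 2), alternative = "greater")
  expect_equal(fisherEnrichment(3, 5, 10, 100), ft$p.value,
               tolerance = 1e-10)
  expect_error(fisherEnrichment(6, 5, 10, 100), "inconsistent")
  expect_error(fisherEnrichment(3, 5, 10, -1), "count")
})

test_that("chi-square statistic equals the four-cell arithmetic", {
  p <- chi2Enrichment(3, 5, 10, 100)
  O <- c(3, 2, 7, 88)
  E <- c(5 * 10, 5 * 90, 95 * 10, 95 * 90) / 100
  stat <- sum((O - E)^2 / E)
  expect_equal(attr(p, "statistic")[1], stat)
  expect_equal(as.numeric(p), pchisq(stat, 1, lower.tail = FALSE))
  # agrees with the standard implementation, no continuity correction
  ct <- suppressWarnings(chisq.test(matrix(O, 2, byrow = TRUE),
                                    correct = FALSE))
  expect_equal(as.numeric(p), ct$p.value)
  # proportions equal across margins -> statistic 0, p = 1
  p0 <- chi2Enrichment(2, 10, 20, 100)
  expect_equal(attr(p0, "statistic")[1], 0)
  expect_equal(as.numeric(p0), 1)
  # empty category: undefined, flagged p = 1
  pe <- chi2Enrichment(0, 0, 10, 100)
  expect_equal(as.numeric(pe), 1)
  expect_true(attr(pe, "undefined")[1])
})

test_that("enrichment ratio is the proportion ratio", {
  expect_equal(enrichmentRatio(5, 10, 50, 1000), 10)
  expect_equal(enrichmentRatio(2, 10, 20, 100), 1)  # background rate
  expect_equal(enrichmentRatio(0, 10, 20, 100), 0)
  expect_error(enrichmentRatio(0, 0, 20, 100), "positive")
  # Re > 1 iff the in-category proportion beats the background
  set.seed(3)
  pick <- function(v) v[sample.int(length(v), 1)]
  for (i in 1:50) {
    N <- pick(20:200); Nf <- pick(1:N); n <- pick(1:N)
    nf <- pick(max(0, n + Nf - N):min(n, Nf))
    re <- enrichmentRatio(nf, n, Nf, N)
    expect_equal(re > 1, nf / n > Nf / N)
  }
})

test_that("empirical FDR counts strict Fisher-vs-chi2 wins", {
  rows <- data.frame(p_fisher = c(.01, .5, .02, .03),
                     p_chi2 = c(.02, .4, .03, .05))
  # comparisons: TRUE, FALSE, TRUE, TRUE -> 1 - 3/4
  expect_equal(empiricalFdr(rows)$empirical_fdr, 0.25)
  all_win <- data.frame(p_fisher = c(.1, .2), p_chi2 = c(.2, .3))
  expect_equal(empiricalFdr(all_win)$empirical_fdr, 0)
  none <- data.frame(p_fisher = c(.2, .3), p_chi2 = c(.2, .1))  # tie fails
  expect_equal(empiricalFdr(none)$empirical_fdr, 1)
  expect_error(empiricalFdr(data.frame()), "undefined")
  # invariant under row order
  perm <- rows[c(3, 1, 4, 2), ]
  expect_equal(empiricalFdr(perm)$empirical_fdr,
               empiricalFdr(rows)$empirical_fdr)
})

test_that("runEnrichment assembles counts, flags and ordering correctly", {
  tm <- data.frame(mirna = c("m1", "m1", "m2", "m2"),
                   gene = c("g1", "g2", "g3", "g4"))
  gsl <- geneSetList(list(
    hit = c("g1", "g2", "g3", "g5"),
    background = paste0("g", 5:14),
    tiny = "g1"  # below minTermSize, excluded
  ))
  res <- runEnrichment(c("m1", "m2"), tm, gsl,
                       universe = paste0("g", 1:20),
                       pThreshold = 0.05, fdrThreshold = 1)
  tab <- enrichmentTable(res)
  expect_false("tiny" %in% tab$term_id)
  hit <- tab[tab$term_id == "hit", ]
  expect_equal(hit$nf, 3L)  # g1, g2, g3
  expect_equal(hit$n, 4L)
  expect_equal(hit$Nf, 4L)
  expect_equal(hit$N, 20L)
  expect_equal(hit$re, (3 / 4) / (4 / 20))
  expect_equal(hit$p_fisher, bruteFisher(3, 4, 4, 20), tolerance = 1e-12)
  expect_equal(tab$p_fisher, sort(tab$p_fisher))
  expect_equal(res@T, 2L)
  # DE targets disjoint from the universe -> warning + empty result
  expect_warning(
    empty <- runEnrichment("m9", tm, gsl, universe = paste0("g", 1:20)),
    "no differential target gene")
  expect_equal(nrow(enrichmentTable(empty)), 0L)
  # a universe gene in no term changes N only
  res2 <- runEnrichment(c("m1", "m2"), tm, gsl,
                        universe = c(paste0("g", 1:20), "orphan"),
                        pThreshold = 0.05, fdrThreshold = 1)
  tab2 <- enrichmentTable(res2)
  expect_equal(tab2[tab2$term_id == "hit", c("nf", "n")],
               hit[, c("nf", "n")], ignore_attr = TRUE)
  expect_equal(tab2$N[1], 21L)
})

test_that("GMT round-trips and matches the fgsea reader", {
  gsl <- geneSetList(list(a = c("g1", "g2"), b = c("g2", "g3", "g4")),
                     descriptions = c(a = "first", b = "second"))
  path <- tempfile(fileext = ".gmt")
  writeGmt(gsl, path)
  back <- readGmt(path)
  expect_identical(geneSets(back), geneSets(gsl))
  expect_identical(back@descriptions, gsl@descriptions)
  skip_if_not_installed("fgsea")
  expect_identical(fgsea::gmtPathways(path),
                   geneSets(gsl))
})

test_that("run-level flags honour the GO thresholds", {
  # one overwhelmingly enriched term among weak ones
  sim <- simulateCtPanel(panelConfig(seed = 41))
  ann <- simulateAnnotations(rownames(sim$panel), sim$truth$de$mirna_id,
                             nGenes = 1500, nTerms = 60,
                             nPlantedTerms = 1, enrichmentFactor = 12,
                             seed = 41)
  res <- runEnrichment(sim$truth$de$mirna_id, ann$targetMap, ann$geneSets)
  expect_equal(res@pThreshold, 0.001)
  expect_equal(res@fdrThreshold, 0.05)
  tab <- enrichmentTable(res)
  sig <- tab$significant
  if (res@empiricalFdr < 0.05) {
    expect_identical(sig, tab$p_fisher < 0.001)
  } else {
    expect_false(any(sig))
  }
})
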