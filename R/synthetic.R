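#' Configure the synthetic TaqMan-style panel generator
#'
#' Builds a validated [PanelConfig-class]. The defaults emulate a rodent
#' miRNA low-density array study: 365 miRNA assays plus the endogenous snRNA
#' controls U44 and U48, two groups ("newborn", "adult") of three biological
#' replicates, per-feature variances drawn from the inverse-gamma family the
#' RVM test assumes, and a planted differential set of 16 up-regulated
#' features (fold change 17 to 602) and 2 down-regulated features (fold
#' change 1/28 to 1/14).
#'
#' @param nFeatures number of non-control miRNA assays.
#' @param controlIds endogenous-control assay names.
#' @param nPerGroup biological replicates per group.
#' @param groupNames two group labels; the first is the reference.
#' @param baselineCtRange interval of per-feature mean CT values (cycles).
#' @param varianceHyperA,varianceHyperB shape and scale of the gamma prior
#'   on precision 1/sigma^2; feature variances are inverse-gamma. With the
#'   defaults (a = 2, b = 1) the prior mean variance is 1 cycle^2, i.e. a
#'   replicate SD of about one cycle.
#' @param nUp,nDown counts of planted up/down differential features.
#' @param upLog2fcRange,downLog2fcRange log2-fold-change intervals for the
#'   planted effects (up positive, down negative).
#' @param undetectedCtProb probability a well reads "Undetermined" (missing).
#' @param seed integer seed.
#' @return A [PanelConfig-class].
#' @examples
#' cfg <- panelConfig(seed = 7)
#' cfg
#' @export
panelConfig <- function(nFeatures = 365L,
                        controlIds = c("U44", "U48"),
                        nPerGroup = 3L,
                        groupNames = c("newborn", "adult"),
                        baselineCtRange = c(18, 35),
                        varianceHyperA = 2,
                        varianceHyperB = 1,
                        nUp = 16L,
                        nDown = 2L,
                        upLog2fcRange = c(log2(17), log2(602)),
                        downLog2fcRange = c(-log2(28), -log2(14)),
                        undetectedCtProb = 0,
                        seed = 1L) {
  new("PanelConfig",
      nFeatures = as.integer(nFeatures),
      controlIds = as.character(controlIds),
      nPerGroup = as.integer(nPerGroup),
      groupNames = as.character(groupNames),
      baselineCtRange = as.numeric(baselineCtRange),
      varianceHyperA = as.numeric(varianceHyperA),
      varianceHyperB = as.numeric(varianceHyperB),
      nUp = as.integer(nUp),
      nDown = as.integer(nDown),
      upLog2fcRange = as.numeric(upLog2fcRange),
      downLog2fcRange = as.numeric(downLog2fcRange),
      undetectedCtProb = as.numeric(undetectedCtProb),
      seed = as.integer(seed))
}

setMethod("show", "PanelConfig", function(object) {
  cat("PanelConfig:", object@nFeatures, "assays +",
      length(object@controlIds), "controls;",
      object@nPerGroup, "x", object@nPerGroup, "samples (",
      paste(object@groupNames, collapse = " vs "), ")\n")
  cat(sprintf("  variance prior: 1/sigma^2 ~ Gamma(a=%g, scale b=%g)\n",
              object@varianceHyperA, object@varianceHyperB))
  cat(sprintf("  planted: %d up in [%.1f, %.1f] log2FC, %d down in [%.1f, %.1f]; seed %d\n",
              object@nUp, object@upLog2fcRange[1], object@upLog2fcRange[2],
              object@nDown, object@downLog2fcRange[1],
              object@downLog2fcRange[2], object@seed))
})

#' Simulate a CT panel with planted differential expression
#'
#' Generates a [CtPanel-class] of raw CT values plus the ground truth needed
#' for recovery testing. Per feature, a baseline mean CT is drawn uniformly
#' from `baselineCtRange` and a variance from the inverse-gamma prior
#' (`1/sigma^2 ~ Gamma(varianceHyperA, scale = varianceHyperB)`); wells are
#' `Normal(mean, sigma)` truncated above at cycle 40 (the instrument's last
#' cycle). Planted features have the second group's mean CT shifted by
#' minus the planted log2 effect — one PCR cycle is one log2 unit, and a
#' lower CT means higher expression — so the realized log2 fold change of
#' the second group over the first equals the planted effect up to sampling
#' noise. Control assays never receive a group shift and carry a small
#' fixed technical variance (SD 0.1 cycles) rather than a draw from the
#' biological prior — endogenous controls are chosen for their stability,
#' and noisy controls would leak a shared shift into every normalized
#' feature of a sample. With probability
#' `undetectedCtProb` a well is recorded as `NA` ("Undetermined").
#'
#' @param config a [PanelConfig-class] from [panelConfig()].
#' @return A list with elements `panel` (a [CtPanel-class]) and `truth`, a
#'   list with `de` (data.frame `mirna_id`, `log2fc`, `direction`),
#'   `trueVariances` (named per-feature variances), `baselines`, and the
#'   generating `config`.
#' @examples
#' sim <- simulateCtPanel(panelConfig(nFeatures = 30, nUp = 3, nDown = 1,
#'                                    seed = 42))
#' sim$panel
#' sim$truth$de
#' @export
simulateCtPanel <- function(config) {
  stopifnot(is(config, "PanelConfig"))
  validObject(config)
  withSeed(config@seed, {
    n <- config@nFeatures
    ids <- sprintf("rno-miR-sim-%03d", seq_len(n))
    all_ids <- c(ids, config@controlIds)
    n_all <- length(all_ids)
    samples <- paste0(rep(config@groupNames, each = config@nPerGroup),
                      "_", rep(seq_len(config@nPerGroup), 2))
    group <- rep(config@groupNames, each = config@nPerGroup)

    # Feature baselines; controls are abundant snRNAs, kept in the low-CT
    # (high-abundance) fifth of the baseline range.
    baselines <- stats::runif(n, config@baselineCtRange[1],
                              config@baselineCtRange[2])
    ctrl_hi <- config@baselineCtRange[1] +
      0.2 * diff(config@baselineCtRange)
    baselines <- c(baselines,
                   stats::runif(length(config@controlIds),
                                config@baselineCtRange[1], ctrl_hi))
    names(baselines) <- all_ids

    variances <- 1 / stats::rgamma(n_all, shape = config@varianceHyperA,
                                   scale = config@varianceHyperB)
    # controls are picked for stability: technical-scale noise only, so
    # normalization does not inject a shared biological-scale shift
    variances[seq(n + 1L, n_all)] <- 0.01
    names(variances) <- all_ids

    de_idx <- sample.int(n, config@nUp + config@nDown)
    effects <- numeric(0)
    if (config@nUp > 0)
      effects <- stats::runif(config@nUp, config@upLog2fcRange[1],
                              config@upLog2fcRange[2])
    if (config@nDown > 0)
      effects <- c(effects,
                   stats::runif(config@nDown, config@downLog2fcRange[1],
                                config@downLog2fcRange[2]))
    shift <- numeric(n_all)
    shift[de_idx] <- -effects  # second group only; -1 cycle = 2-fold up

    mean_mat <- matrix(baselines, nrow = n_all, ncol = length(samples))
    second <- group == config@groupNames[2]
    mean_mat[, second] <- mean_mat[, second] + shift

    ct <- mean_mat + matrix(stats::rnorm(n_all * length(samples),
                                         sd = rep(sqrt(variances),
                                                  length(samples))),
                            nrow = n_all)
    ct <- pmin(ct, 40)
    if (config@undetectedCtProb > 0) {
      drop <- matrix(stats::runif(length(ct)) < config@undetectedCtProb,
                     nrow = n_all)
      ct[drop] <- NA_real_
    }
    dimnames(ct) <- list(all_ids, samples)

    panel <- CtPanel(ct, group = group, controlIds = config@controlIds)
    de <- data.frame(
      mirna_id = ids[de_idx],
      log2fc = if (length(de_idx)) effects else numeric(0),
      direction = rep(c("up", "down"), c(config@nUp, config@nDown)),
      stringsAsFactors = FALSE
    )
    list(panel = panel,
         truth = list(de = de, trueVariances = variances,
                      baselines = baselines, config = config))
  })
}

#' Simulate miRNA target maps and gene-set annotations with planted signal
#'
#' Generates the two annotation resources the downstream stages need: a
#' miRNA-to-target-gene map (emulating a sequence-based target database) and
#' a flat gene-set collection (GO terms or pathways, GMT-serializable).
#' A chosen number of "planted" terms over-sample their members from the
#' pooled targets of the differential miRNAs, so that over-representation
#' analysis has known positive signal: inside a planted term, a gene from
#' the differential-target pool is `enrichmentFactor` times as likely to be
#' drawn as a background gene.
#'
#' @param mirnaIds all miRNA ids in the panel.
#' @param deIds ids of the (planted) differential miRNAs.
#' @param nGenes size of the gene universe.
#' @param nTerms number of gene sets to generate.
#' @param targetMapDensity mean number of target genes per miRNA.
#' @param termSizeRange interval of gene-set sizes.
#' @param nPlantedTerms number of over-represented ("enriched") terms.
#' @param enrichmentFactor sampling-weight ratio of differential-target
#'   genes over background genes inside planted terms.
#' @param namespace `"GO"` or `"pathway"`.
#' @param seed integer seed.
#' @return A list with `targetMap` (data.frame `mirna`, `gene`),
#'   `geneSets` (a [GeneSetList-class]), and `plantedTerms` (character).
#' @examples
#' sim <- simulateCtPanel(panelConfig(nFeatures = 40, nUp = 4, nDown = 2,
#'                                    seed = 3))
#' ann <- simulateAnnotations(rownames(sim$panel), sim$truth$de$mirna_id,
#'                            nGenes = 300, nTerms = 20, seed = 3)
#' head(ann$targetMap)
#' ann$geneSets
#' @export
simulateAnnotations <- function(mirnaIds, deIds,
                                nGenes = 2000L, nTerms = 200L,
                                targetMapDensity = 30,
                                termSizeRange = c(10L, 100L),
                                nPlantedTerms = 2L,
                                enrichmentFactor = 10,
                                namespace = c("GO", "pathway"),
                                seed = 1L) {
  namespace <- match.arg(namespace)
  mirnaIds <- setdiff(unique(as.character(mirnaIds)), character(0))
  if (!length(mirnaIds)) stop("miRNA universe is empty")
  if (nGenes < 1L) stop("nGenes must be positive")
  if (nTerms < 0L) stop("nTerms must be nonnegative")
  withSeed(seed, {
    genes <- sprintf("gene%04d", seq_len(nGenes))
    sizes <- pmax(1L, stats::rpois(length(mirnaIds), targetMapDensity))
    sizes <- pmin(sizes, nGenes)
    target_map <- data.frame(
      mirna = rep(mirnaIds, sizes),
      gene = unlist(lapply(sizes, function(k) sample(genes, k))),
      stringsAsFactors = FALSE
    )

    sets <- list()
    planted <- character(0)
    if (nTerms > 0L) {
      prefix <- if (namespace == "GO") "GO:SIM" else "path_sim"
      term_ids <- sprintf("%s%04d", prefix, seq_len(nTerms))
      de_pool <- unique(target_map$gene[target_map$mirna %in% deIds])
      n_planted <- min(nPlantedTerms, nTerms)
      planted <- term_ids[seq_len(n_planted)]
      w_planted <- ifelse(genes %in% de_pool, enrichmentFactor, 1)
      term_sizes <- sample(seq(termSizeRange[1], termSizeRange[2]),
                           nTerms, replace = TRUE)
      term_sizes <- pmin(term_sizes, nGenes)
      sets <- lapply(seq_len(nTerms), function(i) {
        if (i <= n_planted && length(de_pool))
          sample(genes, term_sizes[i], prob = w_planted)
        else
          sample(genes, term_sizes[i])
      })
      names(sets) <- term_ids
    }
    desc <- sprintf("simulated %s term%s", namespace,
                    ifelse(names(sets) %in% planted, " (planted enrichment)",
                           ""))
    names(desc) <- names(sets)
    gsl <- new("GeneSetList", sets = sets,
               descriptions = if (length(sets)) desc else
                 stats::setNames(character(0), character(0)),
               namespace = namespace)
    list(targetMap = target_map, geneSets = gsl, plantedTerms = planted)
  })
}

#' Read and write miRNA target maps
#'
#' A target map is a two-column TSV (`mirna` TAB `gene`), one row per
#' predicted miRNA-target interaction.
#'
#' @param path file path.
#' @param targetMap data.frame with columns `mirna` and `gene`.
#' @return `readTargetMap` returns the data.frame; `writeTargetMap`
#'   invisibly returns `path`.
#' @export
readTargetMap <- function(path) {
  tm <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna", "gene") %in% names(tm)))
    stop("target map needs columns 'mirna' and 'gene': ", path)
  tm
}

#' @rdname readTargetMap
#' @export
writeTargetMap <- function(targetMap, path) {
  writeTsv(targetMap[, c("mirna", "gene")], path)
}
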