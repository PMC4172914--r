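#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData
NULL

#' Panel configuration for the synthetic CT generator
#'
#' Describes a TaqMan-style low-density miRNA array experiment: how many
#' assays the panel carries, which assays are endogenous controls, the group
#' design, the CT baseline range, the inverse-gamma variance prior shared by
#' all features (the same prior the RVM test assumes), and the planted
#' differential-expression regime.
#'
#' Defaults emulate a rodent miRNA panel profiled in two groups of three
#' animals: 365 miRNA assays plus the snRNA controls U44 and U48, with 16
#' planted up-regulated features (fold changes between 17 and 602) and 2
#' planted down-regulated features (fold changes between 1/28 and 1/14).
#'
#' @slot nFeatures number of non-control miRNA assays.
#' @slot controlIds names of the endogenous-control assays.
#' @slot nPerGroup biological replicates per group (>= 2).
#' @slot groupNames labels of the two groups; the first is the reference.
#' @slot baselineCtRange interval from which per-feature mean CT values are
#'   drawn (cycles).
#' @slot varianceHyperA,varianceHyperB shape and scale of the gamma prior on
#'   feature precision 1/sigma^2 (so sigma^2 is inverse-gamma).
#' @slot nUp,nDown counts of planted up/down differential features.
#' @slot upLog2fcRange,downLog2fcRange intervals (log2 fold change) for
#'   planted effects; up positive, down negative.
#' @slot undetectedCtProb probability that a well reads "Undetermined" and is
#'   recorded as missing.
#' @slot seed integer seed making generation reproducible.
#'
#' @seealso [panelConfig()] for the user-facing constructor,
#'   [simulateCtPanel()] for the generator.
#' @exportClass PanelConfig
setClass("PanelConfig",
  representation(
    nFeatures = "integer",
    controlIds = "character",
    nPerGroup = "integer",
    groupNames = "character",
    baselineCtRange = "numeric",
    varianceHyperA = "numeric",
    varianceHyperB = "numeric",
    nUp = "integer",
    nDown = "integer",
    upLog2fcRange = "numeric",
    downLog2fcRange = "numeric",
    undetectedCtProb = "numeric",
    seed = "integer"
  )
)

setValidity("PanelConfig", function(object) {
  msg <- character()
  if (object@nFeatures < 1L)
    msg <- c(msg, "nFeatures must be >= 1")
  if (length(object@controlIds) < 1L || anyDuplicated(object@controlIds))
    msg <- c(msg, "controlIds must be a nonempty set of unique names")
  if (object@nPerGroup < 2L)
    msg <- c(msg, "nPerGroup must be >= 2 (within-group variance must be estimable)")
  if (length(object@groupNames) != 2L || anyDuplicated(object@groupNames))
    msg <- c(msg, "groupNames must be two distinct labels")
  if (object@nUp + object@nDown > object@nFeatures)
    msg <- c(msg, "nUp + nDown must not exceed nFeatures")
  if (object@varianceHyperA <= 0 || object@varianceHyperB <= 0)
    msg <- c(msg, "variance hyperparameters must be positive")
  ranges <- list(
    baselineCtRange = object@baselineCtRange,
    upLog2fcRange = object@upLog2fcRange,
    downLog2fcRange = object@downLog2fcRange
  )
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
      msg <- c(msg, sprintf("%s must be an ordered finite interval", nm))
  }
  if (length(object@upLog2fcRange) == 2L && object@upLog2fcRange[1] <= 0 &&
      object@nUp > 0L)
    msg <- c(msg, "upLog2fcRange must be positive (up effects raise expression)")
  if (length(object@downLog2fcRange) == 2L && object@downLog2fcRange[2] >= 0 &&
      object@nDown > 0L)
    msg <- c(msg, "downLog2fcRange must be negative")
  if (object@undetectedCtProb < 0 || object@undetectedCtProb > 1)
    msg <- c(msg, "undetectedCtProb must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' CT matrix container
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding raw cycle-threshold
#' (CT) values from a qPCR array: one row per assay (miRNA or endogenous
#' control), one column per sample. `colData(x)$group` carries the two-group
#' design; `rowData(x)$isControl` flags the endogenous-control assays used
#' for delta-CT normalization.
#'
#' @seealso [CtPanel()], [deltaCt()]
#' @exportClass CtPanel
setClass("CtPanel", contains = "SummarizedExperiment")

setValidity("CtPanel", function(object) {
  msg <- character()
  if (!"ct" %in% names(assays(object)))
    msg <- c(msg, "assay 'ct' is required")
  cd <- colData(object)
  if (!"group" %in% names(cd)) {
    msg <- c(msg, "colData column 'group' is required")
  } else {
    g <- as.character(cd$group)
    if (anyNA(g))
      msg <- c(msg, "every sample must have a group")
    tab <- table(g)
    if (length(tab) != 2L)
      msg <- c(msg, "exactly two groups are required")
    else if (any(tab < 2L))
      msg <- c(msg, "both groups need >= 2 samples")
  }
  rd <- rowData(object)
  if (!"isControl" %in% names(rd))
    msg <- c(msg, "rowData column 'isControl' is required")
  else if (!any(rd$isControl))
    msg <- c(msg, "at least one endogenous-control assay is required")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "unique assay rownames are required")
  if (length(msg)) msg else TRUE
})

#' Control-normalized delta-CT container
#'
#' A [SummarizedExperiment::SummarizedExperiment] of delta-CT values
#' (CT minus the per-sample mean control CT), with control rows removed.
#' The per-sample control means are kept in `metadata(x)$controlMeans`.
#'
#' @seealso [deltaCt()], [foldChanges()], [rvmTest()]
#' @exportClass DeltaCtPanel
setClass("DeltaCtPanel", contains = "SummarizedExperiment")

setValidity("DeltaCtPanel", function(object) {
  msg <- character()
  if (!"delta_ct" %in% names(assays(object)))
    msg <- c(msg, "assay 'delta_ct' is required")
  if (!"group" %in% names(colData(object)))
    msg <- c(msg, "colData column 'group' is required")
  rd <- rowData(object)
  if ("isControl" %in% names(rd) && any(rd$isControl))
    msg <- c(msg, "control rows must be dropped from a DeltaCtPanel")
  if (is.null(metadata(object)$controlMeans))
    msg <- c(msg, "metadata 'controlMeans' is required")
  if (length(msg)) msg else TRUE
})

#' Fitted random variance model hyperparameters
#'
#' The RVM assumes each feature's true variance sigma^2 is drawn from an
#' inverse-gamma prior: 1/sigma^2 ~ Gamma(shape a, scale b). Under that
#' prior the observed residual variances satisfy s^2 * a * b ~ F(m, 2a)
#' where m is the residual degrees of freedom, which is the marginal
#' likelihood this fit maximizes.
#'
#' @slot a,b maximum-likelihood hyperparameters (positive when converged).
#' @slot converged whether the optimizer reported convergence.
#' @slot loglik log-likelihood at the optimum.
#' @slot nFeaturesUsed number of positive-variance features used.
#'
#' @seealso [fitRvm()], [rvmTest()]
#' @exportClass RvmFit
setClass("RvmFit",
  representation(
    a = "numeric",
    b = "numeric",
    converged = "logical",
    loglik = "numeric",
    nFeaturesUsed = "integer"
  )
)

setValidity("RvmFit", function(object) {
  msg <- character()
  if (object@converged && (object@a <= 0 || object@b <= 0))
    msg <- c(msg, "a and b must be positive when converged")
  if (!is.finite(object@loglik))
    msg <- c(msg, "loglik must be finite")
  if (length(msg)) msg else TRUE
})

#' Flat gene-set collection
#'
#' A named list of gene sets (GO terms or pathways) with one-line
#' descriptions, as read from or written to GMT. Annotations are taken as
#' given and flat; no ontology-graph propagation is performed.
#'
#' @slot sets named list of character vectors (term id -> member genes).
#' @slot descriptions named character vector, parallel to `sets`.
#' @slot namespace `"GO"` or `"pathway"`.
#'
#' @seealso [geneSetList()], [readGmt()], [writeGmt()], [runEnrichment()]
#' @exportClass GeneSetList
setClass("GeneSetList",
  representation(
    sets = "list",
    descriptions = "character",
    namespace = "character"
  )
)

setValidity("GeneSetList", function(object) {
  msg <- character()
  if (length(object@sets)) {
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
      msg <- c(msg, "term ids must be unique and named")
    if (any(lengths(object@sets) == 0L))
      msg <- c(msg, "gene sets must be nonempty")
    if (!identical(names(object@sets), names(object@descriptions)))
      msg <- c(msg, "descriptions must parallel sets")
  }
  if (length(object@namespace) != 1L ||
      !object@namespace %in% c("GO", "pathway"))
    msg <- c(msg, "namespace must be 'GO' or 'pathway'")
  if (length(msg)) msg else TRUE
})

#' Over-representation analysis result
#'
#' One row per tested term with the 2x2 counts (`nf`, `n`, `Nf`, `N`),
#' one-sided Fisher and Pearson chi-square p-values, the enrichment ratio
#' `Re = (nf/n)/(Nf/N)`, a reference BH q-value, and the significance flag.
#' The run-level empirical FDR is the scalar `1 - Nk/T`, where `Nk` counts
#' terms whose Fisher p falls strictly below their chi-square p among the
#' `T` terms tested.
#'
#' @slot table data.frame of per-term rows, sorted by Fisher p.
#' @slot Nk,T integer counts entering the empirical FDR.
#' @slot empiricalFdr the scalar `1 - Nk/T`.
#' @slot namespace annotation namespace the run used.
#' @slot pThreshold,fdrThreshold thresholds behind the `significant` flag.
#'
#' @seealso [runEnrichment()], [empiricalFdr()]
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
  representation(
    table = "data.frame",
    Nk = "integer",
    T = "integer",
    empiricalFdr = "numeric",
    namespace = "character",
    pThreshold = "numeric",
    fdrThreshold = "numeric"
  )
)

setValidity("EnrichmentResult", function(object) {
  msg <- character()
  if (object@Nk < 0L || object@T < 0L || object@Nk > object@T)
    msg <- c(msg, "0 <= Nk <= T is required")
  if (object@T > 0L &&
      (object@empiricalFdr < 0 || object@empiricalFdr > 1))
    msg <- c(msg, "empiricalFdr must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Bipartite regulatory network
#'
#' A two-layer graph with miRNAs on the left and genes or GO terms on the
#' right; edges only cross layers. Left nodes carry the miRNA's direction
#' and weight |log2 fold change|; edge weights depend on the network kind
#' (see [mirnaGeneNetwork()] and [mirnaGoNetwork()]). Degree — the incident
#' edge count — is the centrality used for hub ranking: the key miRNAs and
#' genes are the nodes of largest degree.
#'
#' @slot leftNodes data.frame (id, direction, weight) of miRNA nodes.
#' @slot rightNodes data.frame (id, type) of gene or term nodes.
#' @slot edges data.frame (from, to, weight); `from` left, `to` right.
#' @slot kind `"mirna-gene"` or `"mirna-go"`.
#'
#' @seealso [rankHubs()], [degrees()], [asIgraph()]
#' @exportClass BipartiteNetwork
setClass("BipartiteNetwork",
  representation(
    leftNodes = "data.frame",
    rightNodes = "data.frame",
    edges = "data.frame",
    kind = "character"
  )
)

setValidity("BipartiteNetwork", function(object) {
  msg <- character()
  if (anyDuplicated(object@leftNodes$id) || anyDuplicated(object@rightNodes$id))
    msg <- c(msg, "node ids must be unique within a layer")
  if (length(intersect(object@leftNodes$id, object@rightNodes$id)))
    msg <- c(msg, "left and right node ids must be disjoint")
  e <- object@edges
  if (nrow(e)) {
    if (!all(e$from %in% object@leftNodes$id))
      msg <- c(msg, "every edge source must be a left (miRNA) node")
    if (!all(e$to %in% object@rightNodes$id))
      msg <- c(msg, "every edge target must be a right node")
    if (anyDuplicated(paste(e$from, e$to)))
      msg <- c(msg, "parallel edges are not allowed")
  }
  if (!object@kind %in% c("mirna-gene", "mirna-go"))
    msg <- c(msg, "kind must be 'mirna-gene' or 'mirna-go'")
  if (length(msg)) msg else TRUE
})
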