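#' Delta-CT normalization against endogenous controls
#'
#' Normalizes each sample's CT values against its endogenous-control
#' assays: `dCT(feature, sample) = CT(feature, sample) - mean(control CTs
#' of that sample)`, using the finite control values only. Averaging CT
#' values of the controls equals taking the geometric mean of their
#' expression levels, the standard multi-reference normalization. Control
#' rows are dropped from the output; the per-sample control means are kept
#' in `metadata()$controlMeans`.
#'
#' Subtracting a per-sample constant makes dCT invariant to sample-wide
#' shifts in amplification efficiency or input amount: adding a constant to
#' every CT of a sample leaves its dCT values unchanged.
#'
#' @param x a [CtPanel-class].
#' @param ... unused.
#' @return A [DeltaCtPanel-class].
#' @examples
#' ct <- rbind("miR-a" = c(25, 26, 24, 21, 20, 22),
#'             U44 = c(20, 21, 19, 20, 19, 21),
#'             U48 = c(22, 21, 21, 20, 21, 19))
#' colnames(ct) <- paste0("s", 1:6)
#' panel <- CtPanel(ct, rep(c("newborn", "adult"), each = 3),
#'                  c("U44", "U48"))
#' deltaCtValues(deltaCt(panel))
#' @rdname deltaCt
#' @export
setMethod("deltaCt", "CtPanel", function(x, ...) {
  ctrl <- ctValues(x)[rowData(x)$isControl, , drop = FALSE]
  ctrl_mean <- colMeans(ctrl, na.rm = TRUE)
  dead <- !is.finite(ctrl_mean)
  if (any(dead))
    stop("sample(s) with no detected control assay: ",
         paste(colnames(x)[dead], collapse = ", "))
  keep <- !rowData(x)$isControl
  dct <- sweep(ctValues(x)[keep, , drop = FALSE], 2, ctrl_mean)
  se <- SummarizedExperiment(
    assays = list(delta_ct = dct),
    colData = colData(x),
    rowData = rowData(x)[keep, , drop = FALSE]
  )
  metadata(se)$controlMeans <- ctrl_mean
  new("DeltaCtPanel", se)
})

#' Drop features with too many undetected wells
#'
#' A feature missing in more than `maxMissingFrac` of the samples of either
#' group is excluded (its group mean would rest on too few wells); the
#' dropped assay ids are attached as `attr(result, "droppedFeatures")` and
#' reported via `message()`.
#'
#' @param x a [DeltaCtPanel-class].
#' @param maxMissingFrac largest tolerated within-group missing fraction.
#' @return The filtered [DeltaCtPanel-class].
#' @export
filterDetected <- function(x, maxMissingFrac = 0.5) {
  stopifnot(is(x, "DeltaCtPanel"))
  g <- as.character(groupLabels(x))
  bad <- rep(FALSE, nrow(x))
  for (grp in unique(g)) {
    sub <- deltaCtValues(x)[, g == grp, drop = FALSE]
    bad <- bad | rowMeans(is.na(sub)) > maxMissingFrac
  }
  if (any(bad))
    message(sum(bad), " feature(s) dropped for missingness: ",
            paste(utils::head(rownames(x)[bad], 5), collapse = ", "),
            if (sum(bad) > 5) ", ..." else "")
  out <- x[!bad, ]
  attr(out, "droppedFeatures") <- rownames(x)[bad]
  out
}

#' Per-feature 2^-ddCT fold changes between groups
#'
#' Computes, per feature, `ddCT = mean dCT(comparison) - mean dCT(reference)`
#' over the available (non-missing) samples of each group, and the fold
#' change `2^-ddCT` of the comparison group over the reference. Because a
#' lower CT means higher abundance, a comparison group expressed k-fold
#' above the reference shows ddCT = -log2(k) and fold change k. Swapping
#' the two groups maps every fold change to its reciprocal.
#'
#' @param x a [DeltaCtPanel-class].
#' @param reference,comparison group labels; the fold change is
#'   comparison over reference.
#' @return data.frame with columns `mirna_id`, `delta_delta_ct`,
#'   `fold_change` (one row per feature, input order).
#' @examples
#' sim <- simulateCtPanel(panelConfig(nFeatures = 20, nUp = 2, nDown = 1,
#'                                    seed = 5))
#' fc <- foldChanges(deltaCt(sim$panel), "newborn", "adult")
#' head(fc)
#' @export
foldChanges <- function(x, reference, comparison) {
  stopifnot(is(x, "DeltaCtPanel"))
  g <- as.character(groupLabels(x))
  for (nm in c(reference, comparison))
    if (!nm %in% g) stop("unknown group: ", nm)
  dct <- deltaCtValues(x)
  m_ref <- rowMeans(dct[, g == reference, drop = FALSE], na.rm = TRUE)
  m_cmp <- rowMeans(dct[, g == comparison, drop = FALSE], na.rm = TRUE)
  ddct <- m_cmp - m_ref
  data.frame(
    mirna_id = rownames(dct),
    delta_delta_ct = ddct,
    fold_change = 2^(-ddct),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
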