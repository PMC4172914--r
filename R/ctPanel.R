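#' Construct a CtPanel from a CT matrix
#'
#' @param ct numeric matrix of cycle-threshold values, assays in rows
#'   (unique rownames required), samples in columns. `NA` marks undetected
#'   ("Undetermined") wells.
#' @param group character or factor of length `ncol(ct)` assigning each
#'   sample to one of exactly two groups.
#' @param controlIds assay names to treat as endogenous controls (e.g.
#'   `c("U44", "U48")`); must be present in `rownames(ct)`.
#'
#' @return A [CtPanel-class] object.
#'
#' @examples
#' ct <- matrix(rnorm(24, 25, 1), nrow = 4,
#'              dimnames = list(c("miR-a", "miR-b", "U44", "U48"),
#'                              paste0("s", 1:6)))
#' panel <- CtPanel(ct, group = rep(c("newborn", "adult"), each = 3),
#'                  controlIds = c("U44", "U48"))
#' panel
#' @export
CtPanel <- function(ct, group, controlIds) {
  ct <- as.matrix(ct)
  if (is.null(rownames(ct)))
    stop("ct must have assay rownames")
  missing_ctrl <- setdiff(controlIds, rownames(ct))
  if (length(missing_ctrl))
    stop("control assays not present in ct: ",
         paste(missing_ctrl, collapse = ", "))
  if (length(group) != ncol(ct))
    stop("group must have one label per sample column")
  if (is.null(colnames(ct)))
    colnames(ct) <- paste0("sample", seq_len(ncol(ct)))
  se <- SummarizedExperiment(
    assays = list(ct = ct),
    colData = DataFrame(group = factor(group), row.names = colnames(ct)),
    rowData = DataFrame(isControl = rownames(ct) %in% controlIds,
                        row.names = rownames(ct))
  )
  new("CtPanel", se)
}

#' Accessors for CT and delta-CT containers
#'
#' `ctValues()` / `deltaCtValues()` return the value matrix, `groupLabels()`
#' the per-sample group factor, and `controlIds()` the endogenous-control
#' assay names.
#'
#' @param x a [CtPanel-class] or [DeltaCtPanel-class].
#' @return A matrix, factor, or character vector as described.
#' @name ctValues
#' @aliases deltaCtValues groupLabels controlIds
NULL

#' @rdname ctValues
#' @export
setMethod("ctValues", "CtPanel", function(x) assay(x, "ct"))

#' @rdname ctValues
#' @export
setMethod("deltaCtValues", "DeltaCtPanel", function(x) assay(x, "delta_ct"))

#' @rdname ctValues
#' @export
setMethod("groupLabels", "SummarizedExperiment",
          function(x) colData(x)$group)

#' @rdname ctValues
#' @export
setMethod("controlIds", "CtPanel",
          function(x) rownames(x)[rowData(x)$isControl])

setMethod("show", "CtPanel", function(object) {
  tab <- table(groupLabels(object))
  cat("CtPanel:", sum(!rowData(object)$isControl), "assays,",
      sum(rowData(object)$isControl), "controls,",
      ncol(object), "samples\n")
  cat("  groups:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  cat("  controls:", paste(controlIds(object), collapse = ", "), "\n")
  n_na <- sum(is.na(ctValues(object)))
  if (n_na) cat("  undetected wells:", n_na, "\n")
})

setMethod("show", "DeltaCtPanel", function(object) {
  tab <- table(groupLabels(object))
  cat("DeltaCtPanel:", nrow(object), "assays,", ncol(object), "samples\n")
  cat("  groups:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
})

#' Read and write CT panels as TSV
#'
#' The on-disk layout is two plain TSV files: the CT matrix (first column
#' `assay_id`, remaining columns one per sample) and a sample sheet with
#' columns `sample_id` and `group`. Control assays are named at read time.
#'
#' @param ctFile path to the CT matrix TSV.
#' @param groupFile path to the sample->group TSV.
#' @param controlIds endogenous-control assay names.
#' @param x a [CtPanel-class] to write.
#' @param dir output directory for `writeCtPanel` (created if needed).
#' @param prefix file-name prefix for the two TSVs.
#' @return `readCtPanel` returns a [CtPanel-class]; `writeCtPanel`
#'   invisibly returns the paths written.
#' @export
readCtPanel <- function(ctFile, groupFile, controlIds) {
  ct_df <- utils::read.delim(ctFile, check.names = FALSE,
                             stringsAsFactors = FALSE)
  ct <- as.matrix(ct_df[, -1, drop = FALSE])
  rownames(ct) <- ct_df[[1]]
  groups <- utils::read.delim(groupFile, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(groups)))
    stop("group file needs columns sample_id and group")
  idx <- match(colnames(ct), groups$sample_id)
  if (anyNA(idx))
    stop("samples missing from group file: ",
         paste(colnames(ct)[is.na(idx)], collapse = ", "))
  CtPanel(ct, group = groups$group[idx], controlIds = controlIds)
}

#' @rdname readCtPanel
#' @export
writeCtPanel <- function(x, dir, prefix = "ct_panel") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ct_path <- file.path(dir, paste0(prefix, "_matrix.tsv"))
  grp_path <- file.path(dir, paste0(prefix, "_samples.tsv"))
  writeTsv(data.frame(assay_id = rownames(x), ctValues(x),
                      check.names = FALSE), ct_path)
  writeTsv(data.frame(sample_id = colnames(x),
                      group = as.character(groupLabels(x))), grp_path)
  invisible(c(ct = ct_path, groups = grp_path))
}
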