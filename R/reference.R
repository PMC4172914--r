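#' Published reference fold-change table
#'
#' Loads the packaged reference table of 18 differentially expressed miRNAs
#' from a TaqMan rodent-panel comparison of adult versus newborn rat
#' cochlear sensory epithelium: 16 miRNAs up-regulated in the mature
#' cochlea (fold changes about 17 to 600) and 2 down-regulated members of
#' the miR-29 family. Each record carries the miRNA id, the 2^-ddCT fold
#' change of adult over newborn, the direction ("style"), and the mature
#' miRNA sequence. The raw CT data behind this table were never deposited,
#' so the package uses it as the entry point for enrichment and network
#' analysis of the published result (see [runReferenceMode()]).
#'
#' @return data.frame with columns `mirna_id`, `fold_change`, `style`,
#'   `sequence`; fold changes as printed, to all decimal places.
#' @examples
#' ref <- referenceFoldChanges()
#' nrow(ref)            # 18
#' table(ref$style)     # 16 up, 2 down
#' @export
referenceFoldChanges <- function() {
  path <- system.file("extdata", "cochlea_mirna_fold_changes.tsv",
                      package = "mirArrayDE")
  if (!nzchar(path) || !file.exists(path))
    stop("packaged reference fold-change fixture not found: ",
         "inst/extdata/cochlea_mirna_fold_changes.tsv")
  ref <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("mirna_id", "fold_change", "style", "sequence")
  if (!all(needed %in% names(ref)) || nrow(ref) != 18L)
    stop("reference fixture is corrupt: ", path)
  bad <- ref$fold_change <= 0 | ((ref$fold_change > 1) != (ref$style == "up"))
  if (any(bad))
    stop("reference fixture violates the direction rule: ", path)
  ref
}
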