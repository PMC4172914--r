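#' Assemble a validated pipeline run configuration
#'
#' Collects file paths, group orientation, thresholds and the seed into a
#' single validated list, optionally starting from a YAML file; arguments
#' override YAML entries. File paths are checked at construction.
#'
#' @param yaml optional path to a YAML configuration file whose keys match
#'   the argument names below.
#' @param ctFile,groupFile CT matrix and sample-sheet TSVs (see
#'   [readCtPanel()]).
#' @param controlIds endogenous-control assay names.
#' @param targetMapFile miRNA->gene TSV ([readTargetMap()]).
#' @param goGmtFile,pathwayGmtFile optional GMT files; each enables the
#'   corresponding enrichment + network stage.
#' @param reference,comparison group labels; fold changes are comparison
#'   over reference.
#' @param pDe,fcDe differential-selection thresholds ([selectDifferential()]).
#' @param pGo,fdrGo GO-enrichment thresholds.
#' @param pPathway,fdrPathway pathway-enrichment thresholds.
#' @param seed integer seed recorded in the manifest.
#' @param outdir output directory.
#' @return A named list of class `"mirArrayRunConfig"`.
#' @export
runConfig <- function(yaml = NULL,
                      ctFile = NULL, groupFile = NULL,
                      controlIds = c("U44", "U48"),
                      targetMapFile = NULL,
                      goGmtFile = NULL, pathwayGmtFile = NULL,
                      reference = "newborn", comparison = "adult",
                      pDe = 0.05, fcDe = 2,
                      pGo = 0.001, fdrGo = 0.05,
                      pPathway = 0.05, fdrPathway = 0.05,
                      seed = 1L, outdir = "mirArrayDE_out") {
  cfg <- as.list(environment())
  cfg$yaml <- NULL
  if (!is.null(yaml)) {
    y <- yaml::read_yaml(yaml)
    unknown <- setdiff(names(y), names(cfg))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    given <- names(as.list(match.call()))  # explicit args win over YAML
    for (k in setdiff(names(y), given)) cfg[[k]] <- y[[k]]
  }
  for (k in c("ctFile", "groupFile", "targetMapFile")) {
    if (is.null(cfg[[k]])) stop("config requires ", k)
    if (!file.exists(cfg[[k]])) stop(k, " does not exist: ", cfg[[k]])
  }
  for (k in c("goGmtFile", "pathwayGmtFile"))
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      stop(k, " does not exist: ", cfg[[k]])
  for (k in c("pDe", "pGo", "fdrGo", "pPathway", "fdrPathway"))
    if (cfg[[k]] <= 0 || cfg[[k]] > 1)
      stop(k, " must lie in (0, 1]")
  if (cfg$fcDe < 1) stop("fcDe must be >= 1")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "mirArrayRunConfig"
  cfg
}

configHash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  hashable <- unclass(cfg)
  # hash file contents, not paths, so the hash moves with the data
  for (k in c("ctFile", "groupFile", "targetMapFile", "goGmtFile",
              "pathwayGmtFile"))
    if (!is.null(hashable[[k]]) && file.exists(hashable[[k]]))
      hashable[[paste0(k, "_md5")]] <-
        unname(tools::md5sum(hashable[[k]]))
  writeLines(jsonlite::toJSON(hashable[order(names(hashable))],
                              auto_unbox = TRUE, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

stageLog <- function(stage, ...) message("[", stage, "] ", ...)

enrichStage <- function(de, target_map, gmt_file, namespace, p, fdr,
                        outdir, tag) {
  gsl <- readGmt(gmt_file, namespace = namespace)
  out <- list()
  for (dir in c("up", "down")) {
    ids <- de$mirna_id[de$direction == dir]
    label <- paste0(tag, "_", dir)
    if (!length(ids)) {
      stageLog("enrich", label, ": no ", dir, "-regulated miRNAs, skipped")
      next
    }
    res <- withCallingHandlers(
      runEnrichment(ids, target_map, gsl, pThreshold = p,
                    fdrThreshold = fdr),
      warning = function(w) {
        stageLog("enrich", label, ": ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    writeEnrichment(res, file.path(outdir,
                                   paste0("enrichment_", label, ".tsv")))
    stageLog("enrich", label, ": ", res@T, " terms tested, ",
             sum(res@table$significant), " significant, empirical FDR ",
             signif(res@empiricalFdr, 4))
    out[[dir]] <- res
  }
  attr(out, "geneSets") <- gsl
  out
}

#' Run the full analysis pipeline
#'
#' Executes, in order: CT input -> delta-CT normalization ->
#' missingness filter -> fold changes (2^-ddCT) -> RVM t-test + BH ->
#' differential selection -> GO/pathway over-representation (up- and
#' down-regulated miRNA target sets analyzed separately) -> miRNA-gene
#' and miRNA-GO networks with hub ranking. Every stage writes its table
#' under `outdir` and logs its feature counts; a JSON manifest records the
#' configuration, its hash, the seed, and summary counts so a run can be
#' audited and reproduced.
#'
#' @param config a list from [runConfig()] (or a YAML path handed to it).
#' @return Invisibly, a list with the differential table, the enrichment
#'   results, the networks, and the manifest.
#' @seealso [runReferenceMode()] for the published-table entry point.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- runConfig(yaml = config)
  stopifnot(inherits(config, "mirArrayRunConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  panel <- readCtPanel(config$ctFile, config$groupFile, config$controlIds)
  stageLog("input", nrow(panel), " assays (",
           sum(rowData(panel)$isControl), " controls), ",
           ncol(panel), " samples")

  dct <- deltaCt(panel)
  dct <- suppressMessages(filterDetected(dct))
  dropped <- attr(dct, "droppedFeatures")
  stageLog("normalize", nrow(dct), " features after delta-CT (",
           length(dropped), " dropped for missingness)")

  fc <- foldChanges(dct, config$reference, config$comparison)
  tt <- rvmTest(dct, reference = config$reference,
                comparison = config$comparison)
  res <- merge(fc, tt, by = "mirna_id", sort = FALSE)
  res$q_value <- bhAdjust(res$p_value)
  res <- res[order(res$p_value, res$mirna_id), ]
  writeTsv(res[, c("mirna_id", "delta_delta_ct", "fold_change", "t", "df",
                   "p_value", "q_value")],
           file.path(config$outdir, "all_features.tsv"))

  de <- selectDifferential(res, config$pDe, config$fcDe)
  stageLog("differential", nrow(de), " differential features (",
           sum(de$direction == "up"), " up, ",
           sum(de$direction == "down"), " down) at p < ", config$pDe,
           ", |FC| >= ", config$fcDe)
  de_out <- de[, c("mirna_id", "fold_change", "direction", "t", "df",
                   "p_value", "q_value")]
  names(de_out)[3] <- "style"
  writeTsv(de_out, file.path(config$outdir, "differential_mirnas.tsv"))

  target_map <- readTargetMap(config$targetMapFile)
  go <- pathway <- NULL
  go_sets <- NULL
  if (!is.null(config$goGmtFile)) {
    go <- enrichStage(de, target_map, config$goGmtFile, "GO",
                      config$pGo, config$fdrGo, config$outdir, "go")
    go_sets <- attr(go, "geneSets")
  }
  if (!is.null(config$pathwayGmtFile))
    pathway <- enrichStage(de, target_map, config$pathwayGmtFile,
                           "pathway", config$pPathway, config$fdrPathway,
                           config$outdir, "pathway")

  networks <- list()
  if (nrow(de)) {
    gene_net <- withCallingHandlers(
      mirnaGeneNetwork(de, target_map),
      warning = function(w) {
        stageLog("network", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    writeEdgeList(gene_net,
                  file.path(config$outdir, "mirna_gene_edges.tsv"))
    writeNodeTable(gene_net,
                   file.path(config$outdir, "mirna_gene_nodes.tsv"))
    writeGraphML(gene_net,
                 file.path(config$outdir, "mirna_gene_network.graphml"))
    stageLog("network", "miRNA-gene: ", nrow(gene_net@edges), " edges")
    networks$gene <- gene_net
    if (!is.null(go) && length(go)) {
      sig_terms <- unique(unlist(lapply(go, function(r)
        r@table$term_id[r@table$significant])))
      go_net <- suppressWarnings(
        mirnaGoNetwork(de, target_map, sig_terms, go_sets))
      writeEdgeList(go_net,
                    file.path(config$outdir, "mirna_go_edges.tsv"))
      writeNodeTable(go_net,
                     file.path(config$outdir, "mirna_go_nodes.tsv"))
      writeGraphML(go_net,
                   file.path(config$outdir, "mirna_go_network.graphml"))
      stageLog("network", "miRNA-GO: ", nrow(go_net@edges), " edges")
      networks$go <- go_net
    }
  }

  manifest <- list(
    package = "mirArrayDE",
    version = as.character(utils::packageVersion("mirArrayDE")),
    mode = "pipeline",
    config = unclass(config),
    config_hash = configHash(config),
    seed = config$seed,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    counts = list(
      assays_in = nrow(panel),
      features_tested = nrow(dct),
      dropped_missing = length(dropped),
      differential = nrow(de),
      up = sum(de$direction == "up"),
      down = sum(de$direction == "down")
    )
  )
  jsonlite::write_json(manifest,
                       file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(list(differential = de, allFeatures = res, go = go,
                 pathway = pathway, networks = networks,
                 manifest = manifest))
}

#' Analyze the published reference fold-change table
#'
#' The raw CT data behind the published 18-miRNA result were never
#' deposited, so normalization and testing cannot be re-run; this mode
#' feeds the printed fold changes and directions (see
#' [referenceFoldChanges()]) straight into the enrichment and network
#' stages against user-supplied (or simulated) target maps and gene sets.
#'
#' @param outdir output directory.
#' @param targetMap data.frame (`mirna`, `gene`), or `NULL` to skip the
#'   annotation-dependent stages.
#' @param geneSets a [GeneSetList-class], or `NULL` to skip enrichment
#'   and the miRNA-GO network.
#' @param pThreshold,fdrThreshold enrichment thresholds (GO defaults).
#' @return Invisibly, a list with the reference table, enrichment results
#'   (up/down), the networks, and the manifest.
#' @export
runReferenceMode <- function(outdir, targetMap = NULL, geneSets = NULL,
                             pThreshold = 0.001, fdrThreshold = 0.05) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ref <- referenceFoldChanges()
  de <- data.frame(mirna_id = ref$mirna_id, fold_change = ref$fold_change,
                   direction = ref$style, stringsAsFactors = FALSE)
  de <- de[order(-abs(log2(de$fold_change))), ]
  writeTsv(ref, file.path(outdir, "reference_mirnas.tsv"))
  stageLog("reference", nrow(de), " published miRNAs (",
           sum(de$direction == "up"), " up, ",
           sum(de$direction == "down"), " down); top: ",
           de$mirna_id[1], " (FC ", de$fold_change[1], ")")

  enrich <- list()
  networks <- list()
  if (!is.null(targetMap)) {
    if (!is.null(geneSets)) {
      for (dir in c("up", "down")) {
        ids <- de$mirna_id[de$direction == dir]
        res <- suppressWarnings(
          runEnrichment(ids, targetMap, geneSets,
                        pThreshold = pThreshold,
                        fdrThreshold = fdrThreshold))
        writeEnrichment(res, file.path(outdir,
          paste0("enrichment_reference_", dir, ".tsv")))
        enrich[[dir]] <- res
      }
    }
    gene_net <- suppressWarnings(mirnaGeneNetwork(de, targetMap))
    writeEdgeList(gene_net, file.path(outdir, "mirna_gene_edges.tsv"))
    writeNodeTable(gene_net, file.path(outdir, "mirna_gene_nodes.tsv"))
    networks$gene <- gene_net
    if (length(enrich)) {
      sig_terms <- unique(unlist(lapply(enrich, function(r)
        r@table$term_id[r@table$significant])))
      go_net <- suppressWarnings(
        mirnaGoNetwork(de, targetMap, sig_terms, geneSets))
      writeEdgeList(go_net, file.path(outdir, "mirna_go_edges.tsv"))
      writeNodeTable(go_net, file.path(outdir, "mirna_go_nodes.tsv"))
      networks$go <- go_net
    }
  }
  manifest <- list(
    package = "mirArrayDE",
    version = as.character(utils::packageVersion("mirArrayDE")),
    mode = "reference",
    counts = list(
      mirnas = nrow(de),
      up = sum(de$direction == "up"),
      down = sum(de$direction == "down")
    ),
    top_up = de$mirna_id[which.max(de$fold_change)],
    max_fold_change = max(de$fold_change),
    min_fold_change = min(de$fold_change),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(reference = ref, differential = de, enrichment = enrich,
                 networks = networks, manifest = manifest))
}

#' Simulate a study-like data set to disk
#'
#' Convenience wrapper writing everything [runPipeline()] needs: the CT
#' matrix and sample sheet, the target map, one GO-style GMT, and a YAML
#' config plus JSON ground truth. Defaults emulate the 365-assay rodent
#' panel study design with 16 strong up- and 2 strong down-regulated
#' miRNAs.
#'
#' @param dir output directory.
#' @param config a [PanelConfig-class]; default [panelConfig()].
#' @param nGenes,nTerms annotation sizes (see [simulateAnnotations()]).
#' @return Invisibly, the [runConfig()] list pointing at the written files.
#' @export
simulateStudy <- function(dir, config = panelConfig(),
                          nGenes = 2000L, nTerms = 200L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulateCtPanel(config)
  paths <- writeCtPanel(sim$panel, dir)
  ann <- simulateAnnotations(
    rownames(sim$panel)[!rowData(sim$panel)$isControl],
    sim$truth$de$mirna_id,
    nGenes = nGenes, nTerms = nTerms, seed = config@seed)
  tm_path <- file.path(dir, "target_map.tsv")
  writeTargetMap(ann$targetMap, tm_path)
  gmt_path <- file.path(dir, "gene_sets.gmt")
  writeGmt(ann$geneSets, gmt_path)
  truth <- list(
    de = sim$truth$de,
    planted_terms = ann$plantedTerms,
    seed = config@seed
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  cfg <- runConfig(
    ctFile = unname(paths["ct"]), groupFile = unname(paths["groups"]),
    controlIds = config@controlIds, targetMapFile = tm_path,
    goGmtFile = gmt_path,
    reference = config@groupNames[1], comparison = config@groupNames[2],
    seed = config@seed, outdir = file.path(dir, "results"))
  yaml::write_yaml(lapply(unclass(cfg), function(x)
    if (is.null(x)) NULL else x), file.path(dir, "config.yaml"))
  invisible(cfg)
}
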