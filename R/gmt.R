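#' Build, read and write flat gene-set collections (GMT)
#'
#' GMT is the tab-delimited gene-set exchange format: one line per set,
#' `term_id TAB description TAB gene1 TAB gene2 ...`.
#'
#' @param sets named list of character vectors (term id -> genes).
#' @param descriptions optional named character vector of one-line
#'   descriptions; defaults to the term ids.
#' @param namespace `"GO"` or `"pathway"`.
#' @param x a [GeneSetList-class].
#' @param path file path.
#' @return `geneSetList` and `readGmt` return a [GeneSetList-class];
#'   `writeGmt` invisibly returns `path`.
#' @examples
#' gsl <- geneSetList(list(termA = c("g1", "g2"), termB = c("g2", "g3")))
#' tmp <- tempfile(fileext = ".gmt")
#' writeGmt(gsl, tmp)
#' readGmt(tmp)
#' @export
geneSetList <- function(sets, descriptions = NULL,
                        namespace = c("GO", "pathway")) {
  namespace <- match.arg(namespace)
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(descriptions))
    descriptions <- stats::setNames(names(sets), names(sets))
  descriptions <- as.character(descriptions)[match(names(sets),
                                                   names(descriptions))]
  names(descriptions) <- names(sets)
  new("GeneSetList", sets = sets, descriptions = descriptions,
      namespace = namespace)
}

#' @rdname geneSetList
#' @export
readGmt <- function(path, namespace = c("GO", "pathway")) {
  namespace <- match.arg(namespace)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3L
  if (any(short))
    stop("malformed GMT (need id, description, >=1 gene) at line ",
         which(short)[1], ": ", path)
  ids <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  names(desc) <- ids
  new("GeneSetList", sets = sets, descriptions = desc, namespace = namespace)
}

#' @rdname geneSetList
#' @export
writeGmt <- function(x, path) {
  stopifnot(is(x, "GeneSetList"))
  lines <- vapply(names(x@sets), function(id) {
    paste(c(id, x@descriptions[[id]], x@sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
setMethod("length", "GeneSetList", function(x) length(x@sets))

#' @export
setMethod("names", "GeneSetList", function(x) names(x@sets))

#' Extract the gene sets as a plain named list
#' @param x a [GeneSetList-class]
#' @return named list of character vectors.
#' @export
geneSets <- function(x) x@sets

setMethod("show", "GeneSetList", function(object) {
  cat("GeneSetList (", object@namespace, "): ", length(object@sets),
      " sets, ", length(unique(unlist(object@sets))), " genes\n", sep = "")
  if (length(object@sets)) {
    sz <- lengths(object@sets)
    cat("  set sizes: ", min(sz), "-", max(sz),
        " (median ", stats::median(sz), ")\n", sep = "")
  }
})
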