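newBipartite <- function(left, right, edges, kind) {
  if (nrow(edges)) {
    # isolated right nodes never arise (edges define them); drop isolated
    # miRNAs too so every retained node participates in the network
    left <- left[left$id %in% edges$from, , drop = FALSE]
    right <- right[right$id %in% edges$to, , drop = FALSE]
  } else {
    left <- left[0, , drop = FALSE]
    right <- right[0, , drop = FALSE]
  }
  rownames(left) <- rownames(right) <- rownames(edges) <- NULL
  new("BipartiteNetwork", leftNodes = left, rightNodes = right,
      edges = edges, kind = kind)
}

deFrame <- function(deResults) {
  stopifnot(all(c("mirna_id", "fold_change") %in% names(deResults)))
  direction <- if ("direction" %in% names(deResults)) deResults$direction
  else ifelse(deResults$fold_change > 1, "up", "down")
  data.frame(id = deResults$mirna_id,
             direction = direction,
             weight = abs(log2(deResults$fold_change)),
             stringsAsFactors = FALSE)
}

#' Build the miRNA-gene regulatory network
#'
#' A bipartite graph with one node per differential miRNA and one per
#' targeted gene; the edge (m, g) exists iff g is a predicted target of m.
#' The adjacency entry a_mg — the edge weight — is the miRNA's
#' differential-expression weight |log2 fold change|, so that up- and
#' down-regulated miRNAs contribute on the same scale (direction is kept
#' as a node attribute). Genes carry no expression weight of their own
#' (miRNA arrays measure no mRNA).
#'
#' @param deResults data.frame of differential miRNAs with `mirna_id`,
#'   `fold_change`, and optionally `direction`.
#' @param targetMap data.frame (`mirna`, `gene`).
#' @return A [BipartiteNetwork-class] (possibly empty, with a warning, if
#'   no differential miRNA has targets).
#' @examples
#' de <- data.frame(mirna_id = c("m1", "m2"), fold_change = c(8, 0.25))
#' tm <- data.frame(mirna = c("m1", "m1", "m2"),
#'                  gene = c("g1", "g2", "g1"))
#' net <- mirnaGeneNetwork(de, tm)
#' degrees(net)
#' @export
mirnaGeneNetwork <- function(deResults, targetMap) {
  if (!NROW(deResults)) stop("deResults is empty")
  left <- deFrame(deResults)
  tm <- unique(targetMap[targetMap$mirna %in% left$id,
                         c("mirna", "gene")])
  if (!nrow(tm))
    warning("no differential miRNA has targets in the map; empty network")
  edges <- data.frame(
    from = tm$mirna,
    to = tm$gene,
    weight = left$weight[match(tm$mirna, left$id)],
    stringsAsFactors = FALSE
  )
  right <- data.frame(id = unique(tm$gene),
                      type = rep("gene", length(unique(tm$gene))),
                      stringsAsFactors = FALSE)
  newBipartite(left, right, edges, "mirna-gene")
}

#' Build the miRNA-GO (or miRNA-pathway) network
#'
#' Connects each differential miRNA to every significant term with which
#' it shares at least one gene: the edge (m, term) exists iff some gene is
#' both a predicted target of m and annotated to the term. The edge weight
#' is the number of shared genes scaled by the miRNA's |log2 fold change|.
#'
#' @inheritParams mirnaGeneNetwork
#' @param significantTerms term ids to include — typically the significant
#'   rows of an [EnrichmentResult-class], or the result itself.
#' @param geneSets the [GeneSetList-class] the terms come from.
#' @return A [BipartiteNetwork-class].
#' @export
mirnaGoNetwork <- function(deResults, targetMap, significantTerms,
                           geneSets) {
  if (!NROW(deResults)) stop("deResults is empty")
  stopifnot(is(geneSets, "GeneSetList"))
  if (is(significantTerms, "EnrichmentResult")) {
    tab <- enrichmentTable(significantTerms)
    significantTerms <- tab$term_id[tab$significant]
  }
  significantTerms <- intersect(as.character(significantTerms),
                                names(geneSets@sets))
  left <- deFrame(deResults)
  tm <- unique(targetMap[targetMap$mirna %in% left$id,
                         c("mirna", "gene")])
  targets_of <- split(tm$gene, tm$mirna)
  rows <- list()
  for (m in names(targets_of)) {
    for (term in significantTerms) {
      shared <- length(intersect(targets_of[[m]],
                                 geneSets@sets[[term]]))
      if (shared > 0)
        rows[[length(rows) + 1L]] <- data.frame(
          from = m, to = term, shared = shared,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    if (length(significantTerms) && nrow(tm))
      warning("no target gene of a differential miRNA is annotated to a ",
              "significant term; empty network")
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
    return(newBipartite(left, data.frame(id = character(0),
                                         type = character(0)),
                        edges, "mirna-go"))
  }
  e <- do.call(rbind, rows)
  edges <- data.frame(
    from = e$from,
    to = e$to,
    weight = e$shared * left$weight[match(e$from, left$id)],
    stringsAsFactors = FALSE
  )
  right <- data.frame(id = unique(e$to), type = "go_term",
                      stringsAsFactors = FALSE)
  newBipartite(left, right, edges, "mirna-go")
}

#' Node degrees of a bipartite network
#'
#' `degrees()` counts incident edges per node; `weightedDegrees()` sums
#' incident edge weights. Both satisfy the bipartite handshake identity:
#' the left degrees and the right degrees each sum to the number of edges.
#'
#' @param x a [BipartiteNetwork-class].
#' @param side `"both"` (default), `"left"` (miRNAs) or `"right"`.
#' @return named numeric/integer vector of degrees.
#' @name degrees
NULL

bipartiteDegrees <- function(x, side, weighted) {
  side <- match.arg(side, c("both", "left", "right"))
  ids <- switch(side,
    left = x@leftNodes$id,
    right = x@rightNodes$id,
    both = c(x@leftNodes$id, x@rightNodes$id))
  w <- if (weighted) x@edges$weight else rep(1L, nrow(x@edges))
  inc <- c(stats::setNames(rep(0, length(ids)), ids))
  if (nrow(x@edges)) {
    tal <- tapply(c(w, w), c(x@edges$from, x@edges$to), sum)
    hit <- intersect(names(tal), ids)
    inc[hit] <- tal[hit]
  }
  if (!weighted) storage.mode(inc) <- "integer"
  inc
}

#' @rdname degrees
#' @export
setMethod("degrees", "BipartiteNetwork", function(x, side = c("both",
    "left", "right")) {
  bipartiteDegrees(x, match.arg(side), weighted = FALSE)
})

#' @rdname degrees
#' @export
setMethod("weightedDegrees", "BipartiteNetwork", function(x,
    side = c("both", "left", "right")) {
  bipartiteDegrees(x, match.arg(side), weighted = TRUE)
})

#' Rank hub nodes by degree
#'
#' The key miRNAs and genes (or terms) of a regulatory network are the
#' nodes of largest degree. Ranking uses the unweighted degree — the
#' number of partners — with ties broken lexicographically by node id;
#' the weighted degree is carried along for reference.
#'
#' @param x a [BipartiteNetwork-class].
#' @param topK how many nodes to return (default all).
#' @param side rank `"both"` layers together (default), or one layer.
#' @return data.frame (`id`, `type`, `degree`, `weighted_degree`) in
#'   nonincreasing degree order.
#' @examples
#' de <- data.frame(mirna_id = c("m1", "m2", "m3"),
#'                  fold_change = c(4, 8, 16))
#' tm <- data.frame(mirna = c("m1", "m2", "m3"), gene = "hub_gene")
#' rankHubs(mirnaGeneNetwork(de, tm))
#' @export
rankHubs <- function(x, topK = Inf, side = c("both", "left", "right")) {
  stopifnot(is(x, "BipartiteNetwork"))
  side <- match.arg(side)
  if (!is.numeric(topK) || length(topK) != 1L || topK < 1)
    stop("topK must be a positive number")
  d <- degrees(x, side)
  wd <- weightedDegrees(x, side)
  if (!length(d))
    return(data.frame(id = character(0), type = character(0),
                      degree = integer(0), weighted_degree = numeric(0),
                      stringsAsFactors = FALSE))
  type <- c(stats::setNames(rep("mirna", nrow(x@leftNodes)),
                            x@leftNodes$id),
            stats::setNames(x@rightNodes$type, x@rightNodes$id))
  out <- data.frame(id = names(d), type = unname(type[names(d)]),
                    degree = unname(d),
                    weighted_degree = unname(wd[names(d)]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$id), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, topK)
}

#' Convert a bipartite network to igraph
#'
#' @param x a [BipartiteNetwork-class].
#' @param ... unused.
#' @return an [igraph::igraph] object with vertex attributes `type`
#'   (logical bipartite flag), `layer`, `direction`, and edge `weight`.
#' @rdname asIgraph
#' @export
setMethod("asIgraph", "BipartiteNetwork", function(x, ...) {
  vertices <- data.frame(
    name = c(x@leftNodes$id, x@rightNodes$id),
    type = c(rep(FALSE, nrow(x@leftNodes)), rep(TRUE, nrow(x@rightNodes))),
    layer = c(rep("mirna", nrow(x@leftNodes)), x@rightNodes$type),
    direction = c(x@leftNodes$direction,
                  rep(NA_character_, nrow(x@rightNodes))),
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(x@edges, directed = FALSE,
                                vertices = vertices)
})

setMethod("show", "BipartiteNetwork", function(object) {
  cat("BipartiteNetwork (", object@kind, "): ",
      nrow(object@leftNodes), " miRNAs, ", nrow(object@rightNodes),
      " ", if (object@kind == "mirna-gene") "genes" else "terms",
      ", ", nrow(object@edges), " edges\n", sep = "")
  if (nrow(object@edges)) {
    top <- rankHubs(object, topK = 3)
    cat("  top hubs:",
        paste(sprintf("%s (deg %d)", top$id, top$degree), collapse = ", "),
        "\n")
  }
})

#' Export a bipartite network
#'
#' `writeEdgeList` writes a TSV (`source`, `target`, `weight`,
#' `source_type`, `target_type`); `writeNodeTable` a node attribute TSV
#' (`id`, `type`, `direction`, `degree`, `weighted_degree`);
#' `writeGraphML` a GraphML file via igraph.
#'
#' @param x a [BipartiteNetwork-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeEdgeList <- function(x, path) {
  stopifnot(is(x, "BipartiteNetwork"))
  type <- stats::setNames(x@rightNodes$type, x@rightNodes$id)
  writeTsv(data.frame(
    source = x@edges$from,
    target = x@edges$to,
    weight = x@edges$weight,
    source_type = rep("mirna", nrow(x@edges)),
    target_type = unname(type[x@edges$to]),
    stringsAsFactors = FALSE
  ), path)
}

#' @rdname writeEdgeList
#' @export
writeNodeTable <- function(x, path) {
  stopifnot(is(x, "BipartiteNetwork"))
  hubs <- rankHubs(x)
  dir <- stats::setNames(x@leftNodes$direction, x@leftNodes$id)
  hubs$direction <- unname(dir[hubs$id])
  writeTsv(hubs[, c("id", "type", "direction", "degree",
                    "weighted_degree")], path)
}

#' @rdname writeEdgeList
#' @export
writeGraphML <- function(x, path) {
  g <- asIgraph(x)
  # GraphML needs NA-free attributes
  igraph::V(g)$direction <- ifelse(is.na(igraph::V(g)$direction), "",
                                   igraph::V(g)$direction)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
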