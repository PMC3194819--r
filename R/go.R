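#' GO term overrepresentation of a gene set (hypergeometric test)
#'
#' For each annotated term, the upper-tail hypergeometric probability of
#' observing at least the overlap between the term's members and the DE set
#' within the background universe, with Benjamini-Hochberg adjustment across
#' terms and a significance flag at the requested FDR.
#'
#' @param de_genes Character vector of differentially expressed genes.
#' @param annotation Tibble with columns `gene`, `term`.
#' @param background Character vector of background genes; defaults to all
#'   annotated genes. `de_genes` must be a subset.
#' @param fdr Adjusted-p threshold for the `significant` flag (default 0.05).
#' @return Tibble with `term`, `term_size`, `overlap`, `p_value`, `p_adjust`,
#'   `significant`, ordered by p-value.
#' @examples
#' ann <- tibble::tibble(gene = c("a", "b", "c", "d"),
#'                       term = c("T1", "T1", "T2", "T2"))
#' enrich_go(c("a", "b"), ann)
#' @export
enrich_go <- function(de_genes, annotation, background = NULL, fdr = 0.05) {
  stopifnot(is.data.frame(annotation),
            all(c("gene", "term") %in% names(annotation)))
  if (!length(de_genes)) stop("empty DE set", call. = FALSE)
  background <- unique(background %||% annotation$gene)
  if (!all(de_genes %in% background)) {
    # mirrors the array workflow: only annotated genes enter the enrichment
    warning(sum(!de_genes %in% background),
            " DE gene(s) outside the background dropped")
    de_genes <- intersect(de_genes, background)
    if (!length(de_genes)) stop("no DE genes in the background", call. = FALSE)
  }
  ann <- annotation[annotation$gene %in% background, ]
  de <- unique(de_genes)
  N <- length(background); n <- length(de)
  res <- ann |>
    dplyr::distinct(.data$gene, .data$term) |>
    dplyr::group_by(term = .data$term) |>
    dplyr::summarise(term_size = dplyr::n(),
                     overlap = sum(.data$gene %in% de), .groups = "drop") |>
    dplyr::mutate(
      p_value = phyper(.data$overlap - 1, .data$term_size,
                       N - .data$term_size, n, lower.tail = FALSE),
      p_adjust = p.adjust(.data$p_value, method = "BH"),
      significant = .data$p_adjust <= fdr
    ) |>
    dplyr::arrange(.data$p_value)
  res
}

#' Theme proximity network over significant GO terms
#'
#' Each significant theme gets an expression profile: the per-sample mean of
#' its DE member genes. Theme proximity is the Spearman correlation between
#' theme profiles in this transcriptional expression space; edges are kept at
#' or above `threshold`, and transcriptional modules are either the connected
#' components of the thresholded graph (default) or average-linkage clusters
#' of the proximity matrix cut at height `1 - threshold`.
#'
#' @param enrichment Result of [enrich_go()] (only rows with
#'   `significant == TRUE` are used unless `terms` is given).
#' @param x Expression matrix (genes x samples).
#' @param annotation Tibble `gene`, `term`.
#' @param de_genes DE gene set defining theme membership.
#' @param threshold Minimum proximity for an edge (default 0.5).
#' @param modules `"components"` or `"clustering"`.
#' @param terms Optional explicit character vector of theme ids.
#' @return An object of class `theme_network` with `themes` (tibble `term`,
#'   `module`, `n_genes`), `edges` (tibble `from`, `to`, `proximity`,
#'   `intra_module`), and the full `proximity` matrix.
#' @export
theme_proximity <- function(enrichment, x, annotation, de_genes,
                            threshold = 0.5,
                            modules = c("components", "clustering"),
                            terms = NULL) {
  modules <- match.arg(modules)
  stopifnot(is.matrix(x))
  terms <- terms %||% enrichment$term[enrichment$significant]
  if (length(terms) < 2) stop("need at least 2 significant themes", call. = FALSE)
  members <- lapply(terms, function(t) {
    g <- intersect(annotation$gene[annotation$term == t], de_genes)
    intersect(g, rownames(x))
  })
  names(members) <- terms
  empty <- lengths(members) == 0
  if (any(empty)) {
    warning("themes with no DE members excluded: ",
            paste(terms[empty], collapse = ", "))
    terms <- terms[!empty]; members <- members[!empty]
  }
  if (length(terms) < 2) stop("fewer than 2 themes with DE members", call. = FALSE)
  profiles <- t(vapply(members, function(g) colMeans(x[g, , drop = FALSE]),
                       numeric(ncol(x))))
  prox <- suppressWarnings(cor(t(profiles), method = "spearman"))
  dimnames(prox) <- list(terms, terms)

  ut <- upper.tri(prox)
  keep <- !is.na(prox[ut]) & prox[ut] >= threshold
  edges <- tibble::tibble(from = terms[row(prox)[ut][keep]],
                          to = terms[col(prox)[ut][keep]],
                          proximity = prox[ut][keep])
  if (modules == "components") {
    g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                       directed = FALSE,
                                       vertices = data.frame(name = sort(terms)))
    comp <- igraph::components(g)$membership
    module <- comp[terms]
  } else {
    d <- as.dist(1 - prox)
    hc <- hclust(d, method = "average")
    module <- stats::cutree(hc, h = 1 - threshold)[terms]
  }
  # renumber modules by first appearance over sorted term ids so the
  # partition is invariant to input order
  first <- tapply(seq_along(sort(terms)), module[sort(terms)], min)
  relabel <- setNames(rank(first), names(first))
  module <- as.integer(relabel[as.character(module)])
  names(module) <- terms

  themes <- tibble::tibble(term = terms, module = module,
                           n_genes = lengths(members))
  edges$intra_module <- module[edges$from] == module[edges$to]
  structure(list(themes = themes, edges = edges, proximity = prox,
                 threshold = threshold, modules = modules),
            class = "theme_network")
}

#' @export
print.theme_network <- function(x, ...) {
  cat(sprintf("theme proximity network: %d themes, %d edges, %d module(s)\n",
              nrow(x$themes), nrow(x$edges), max(x$themes$module)))
  invisible(x)
}

#' Export a theme proximity network as GraphML (module as node attribute)
#'
#' @param network A `theme_network`.
#' @param path Output path.
#' @export
export_theme_network <- function(network, path) {
  stopifnot(inherits(network, "theme_network"))
  vs <- data.frame(name = network$themes$term, module = network$themes$module)
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = vs)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
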