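#' Spearman correlation matrix between gene expression profiles
#'
#' Link strength between each pair of genes is Spearman's rank correlation
#' (midranks for ties) of their expression profiles across the chosen
#' samples. Genes with constant profiles have undefined correlations; their
#' entries are returned as NA with a warning and are excluded from any
#' thresholded network.
#'
#' @param x Expression matrix (genes x samples).
#' @param genes Optional character vector restricting the genes (e.g. the DE
#'   set).
#' @param samples Optional character or integer vector restricting the
#'   samples (e.g. the FS samples only).
#' @return Symmetric matrix of Spearman rho with unit diagonal.
#' @export
spearman_matrix <- function(x, genes = NULL, samples = NULL) {
  stopifnot(is.matrix(x))
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  if (!is.null(samples)) x <- x[, samples, drop = FALSE]
  if (ncol(x) < 3) stop("need at least 3 samples", call. = FALSE)
  if (nrow(x) < 2) stop("need at least 2 genes", call. = FALSE)
  const <- apply(x, 1, function(v) length(unique(v)) == 1)
  rho <- suppressWarnings(cor(t(x), method = "spearman"))
  if (any(const)) {
    warning(sum(const), " constant gene profile(s): correlations undefined (NA)")
    rho[const, ] <- NA; rho[, const] <- NA
  }
  diag(rho) <- 1
  rho
}

#' Threshold a correlation matrix into a co-expression network
#'
#' An edge joins two genes when their coefficient falls inside `[lo, hi]`
#' (the coefficient is the signed rho by default, or `|rho|` with
#' `absolute = TRUE`). The study's defaults are `[0.85, 1]` for the FS
#' network and `[0.14, 0.70]` for the NFS network; both networks share the
#' same node set (every gene of the matrix, isolated or not).
#'
#' @param rho Symmetric correlation matrix (e.g. from [spearman_matrix()]).
#' @param lo,hi Threshold interval, `0 <= lo <= hi <= 1`.
#' @param absolute Threshold on `|rho|` instead of signed rho.
#' @return An object of class `coexpr_network` with `nodes`, `edges`
#'   (tibble `from`, `to`, `rho`), the interval, and `n_candidate_pairs`
#'   (pairs with defined rho).
#' @export
threshold_network <- function(rho, lo, hi, absolute = FALSE) {
  stopifnot(is.matrix(rho), nrow(rho) == ncol(rho))
  if (lo > hi) stop("lo must not exceed hi", call. = FALSE)
  genes <- rownames(rho) %||% as.character(seq_len(nrow(rho)))
  ut <- upper.tri(rho)
  pair_i <- row(rho)[ut]; pair_j <- col(rho)[ut]
  val <- rho[ut]
  defined <- !is.na(val)
  coefv <- if (absolute) abs(val) else val
  keep <- defined & coefv >= lo & coefv <= hi
  edges <- tibble::tibble(from = genes[pair_i[keep]],
                          to = genes[pair_j[keep]],
                          rho = val[keep])
  structure(list(nodes = genes, edges = edges, lo = lo, hi = hi,
                 absolute = absolute,
                 n_candidate_pairs = sum(defined)),
            class = "coexpr_network")
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat(sprintf("co-expression network: %d nodes, %d edges (coefficient in [%g, %g]%s)\n",
              length(x$nodes), nrow(x$edges), x$lo, x$hi,
              if (x$absolute) ", absolute" else ""))
  invisible(x)
}

#' Rank genes by network degree (hub table)
#'
#' Hubs are the genes with the highest number of gene-gene links. Degrees are
#' counted over the network's edges; ranking is by descending degree with
#' lexicographic gene-id tie-break.
#'
#' @param network A `coexpr_network`.
#' @return Tibble with `gene`, `degree`, `rank`.
#' @export
hub_degrees <- function(network) {
  stopifnot(inherits(network, "coexpr_network"))
  deg <- setNames(rep(0L, length(network$nodes)), network$nodes)
  if (nrow(network$edges)) {
    t1 <- table(network$edges$from); t2 <- table(network$edges$to)
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
    deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
  }
  tibble::tibble(gene = names(deg), degree = as.integer(deg)) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$gene) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Histogram of gene-gene link strengths
#'
#' Counts candidate gene pairs per `|rho|` bin (default width 0.1 over
#' [0, 1]); bins are right-closed and the lowest bin includes 0, so the
#' counts sum to the number of pairs with defined correlation.
#'
#' @param rho Correlation matrix.
#' @param width Bin width (default 0.1).
#' @param group Optional label stored in a `group` column (handy when
#'   combining FS and NFS histograms for plotting).
#' @return Tibble with `bin_lo`, `bin_hi`, `count` (and `group` if given).
#' @export
link_histogram <- function(rho, width = 0.1, group = NULL) {
  stopifnot(is.matrix(rho))
  val <- abs(rho[upper.tri(rho)])
  val <- val[!is.na(val)]
  breaks <- seq(0, 1, by = width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  cnt <- table(cut(val, breaks = breaks, include.lowest = TRUE))
  out <- tibble::tibble(bin_lo = breaks[-length(breaks)],
                        bin_hi = breaks[-1],
                        count = as.integer(cnt))
  if (!is.null(group)) out$group <- group
  out
}

#' Export a co-expression network for Cytoscape
#'
#' `"sif"` writes the simple interaction format (`gene co gene` lines, one
#' per edge; isolated nodes as singleton lines). `"graphml"` writes GraphML
#' with a `degree` node attribute and a `rho` edge attribute (round-trips
#' through [read_network_graphml()]).
#'
#' @param network A `coexpr_network`.
#' @param path Output path.
#' @param format `"sif"` or `"graphml"`.
#' @export
export_network <- function(network, path, format = c("sif", "graphml")) {
  stopifnot(inherits(network, "coexpr_network"))
  format <- match.arg(format)
  if (format == "sif") {
    lines <- character(0)
    if (nrow(network$edges)) {
      lines <- sprintf("%s co %s", network$edges$from, network$edges$to)
    }
    isolated <- setdiff(network$nodes,
                        unique(c(network$edges$from, network$edges$to)))
    writeLines(c(lines, isolated), path)
  } else {
    g <- as_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert a co-expression network to an igraph graph
#'
#' @param network A `coexpr_network`.
#' @return An igraph object with `degree` vertex attribute and `rho` edge
#'   attribute.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "coexpr_network"))
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = data.frame(name = network$nodes))
  igraph::V(g)$degree <- igraph::degree(g)
  g
}

#' Read back a GraphML network written by [export_network()]
#'
#' @param path GraphML file.
#' @return A `coexpr_network` (threshold interval set to the observed rho
#'   range).
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  ed <- igraph::as_data_frame(g, what = "edges")
  edges <- tibble::tibble(from = ed$from, to = ed$to,
                          rho = if ("rho" %in% names(ed)) ed$rho else NA_real_)
  nodes <- igraph::V(g)$name
  structure(list(nodes = nodes, edges = edges,
                 lo = if (nrow(edges)) min(edges$rho) else 0,
                 hi = if (nrow(edges)) max(edges$rho) else 1,
                 absolute = FALSE,
                 n_candidate_pairs = choose(length(nodes), 2)),
            class = "coexpr_network")
}
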