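#' Filter probes by flag count
#'
#' One-color array spots carry quality flags (low intensity, saturation,
#' control spots, ...). A gene is kept only when it was flagged on at most
#' `max_flags` arrays.
#'
#' @param x Expression matrix (genes x samples).
#' @param flags Integer vector, number of arrays on which each gene's spot was
#'   flagged; same length/order as `rownames(x)`.
#' @param max_flags Maximum tolerated flag count (default 1).
#' @return The filtered matrix.
#' @export
filter_flags <- function(x, flags, max_flags = 1) {
  stopifnot(is.matrix(x), length(flags) == nrow(x))
  keep <- flags <= max_flags
  if (!any(keep)) stop("all genes removed by the flag filter", call. = FALSE)
  x[keep, , drop = FALSE]
}

#' Loess (lowess) normalization against a median pseudo-sample
#'
#' One-color loess normalization: the reference profile is the gene-wise
#' median across samples; for each sample a lowess curve of
#' `M = sample - reference` against `A = (sample + reference)/2` is fitted and
#' subtracted, removing intensity-dependent bias while preserving rank order
#' up to the smooth correction.
#'
#' @param x Log2 expression matrix (genes x samples), >= 2 samples.
#' @param span Lowess smoother span (default 0.4).
#' @return Normalized matrix of the same shape.
#' @export
normalize_lowess <- function(x, span = 0.4) {
  stopifnot(is.matrix(x), ncol(x) >= 2)
  if (any(apply(x, 2, sd) == 0)) {
    stop("constant sample: loess normalization undefined", call. = FALSE)
  }
  ref <- apply(x, 1, median)
  out <- x
  for (j in seq_len(ncol(x))) {
    m <- x[, j] - ref
    a <- (x[, j] + ref) / 2
    fit <- stats::lowess(a, m, f = span)
    corr <- stats::approx(fit$x, fit$y, xout = a, rule = 2, ties = mean)$y
    out[, j] <- x[, j] - corr
  }
  out
}

#' Select the SAM exchangeability (fudge) factor s0
#'
#' s0 is the percentile of the per-gene standard errors that minimizes the
#' coefficient of variation of the d statistic's spread across standard-error
#' windows: genes are binned into quantile windows of `s`, the median absolute
#' deviation of `d = r / (s + s0)` is computed per window, and the candidate
#' (percentiles 0, 5, ..., 100 of `s`) with the smallest CV of those MADs
#' wins. With fewer than 10 genes the median of `s` is used.
#'
#' @param r Per-gene numerators (group mean differences).
#' @param s Per-gene pooled standard errors.
#' @param n_windows Number of standard-error windows (default 10).
#' @return The chosen s0 (scalar).
#' @export
choose_s0 <- function(r, s, n_windows = 10) {
  stopifnot(length(r) == length(s))
  if (all(s == 0)) stop("all standard errors are zero", call. = FALSE)
  if (length(s) < 10) return(median(s))
  cand <- quantile(s, seq(0, 1, by = 0.05), names = FALSE)
  win <- cut(rank(s, ties.method = "first"), breaks = n_windows, labels = FALSE)
  cv <- vapply(cand, function(s0) {
    d <- r / (s + s0)
    mads <- tapply(d, win, stats::mad)
    mads <- mads[is.finite(mads)]
    if (mean(mads) == 0) return(Inf)
    sd(mads) / mean(mads)
  }, numeric(1))
  if (all(!is.finite(cv))) return(median(s))
  cand[which.min(cv)]
}

sam_d_stats <- function(x, g1, g2, s0 = NULL) {
  n1 <- length(g1); n2 <- length(g2)
  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, g2, drop = FALSE])
  ss1 <- rowSums((x[, g1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, g2, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  r <- m1 - m2
  if (is.null(s0)) s0 <- choose_s0(r, s)
  d <- r / (s + s0)
  d[!is.finite(d)] <- 0  # zero difference over zero spread
  list(d = d, r = r, s = s, s0 = s0)
}

# permutation group-1 index sets: exhaustive when C(n, n1) <= cap, else
# `n_sampled` uniform draws under the current RNG state
sam_permutations <- function(n, n1, cap = 10000, n_sampled = 200) {
  if (choose(n, n1) <= cap) {
    perms <- combn(n, n1)
    list(idx = perms, exhaustive = TRUE)
  } else {
    idx <- replicate(n_sampled, sort(sample.int(n, n1)))
    list(idx = idx, exhaustive = FALSE)
  }
}

# cutoffs for a given delta from the sorted observed d and the expected order
# statistics dbar: genes above cutup / below cutlow are called
sam_cutoffs <- function(d_sorted, dbar, delta) {
  up <- d_sorted >= 0 & (d_sorted - dbar) >= delta
  lo <- d_sorted <= 0 & (dbar - d_sorted) >= delta
  list(cutup = if (any(up)) min(d_sorted[up]) else Inf,
       cutlow = if (any(lo)) max(d_sorted[lo]) else -Inf)
}

#' Two-class (unpaired) Significance Analysis of Microarrays
#'
#' The SAM procedure for finding genes whose expression differs between two
#' groups: a moderated t-like statistic `d = (mean_1 - mean_2) / (s + s0)`
#' with pooled standard error `s` and fudge factor `s0`, compared against
#' expected order statistics from label permutations. For each candidate
#' threshold delta the false discovery rate is estimated as the average
#' number of permuted genes beyond the delta cutoffs divided by the observed
#' call count (capped at 1); the reported delta is the smallest with
#' estimated FDR at or below `target_fdr`, and each gene's q-value is the
#' smallest estimated FDR over the deltas at which it is called. The average
#' is the default because the median permuted count degenerates to zero
#' whenever fewer than half the permutations reach the cutoffs, which lets
#' single spurious genes through; `fdr_estimator = "median"` restores the
#' median variant.
#'
#' Permutations are exhaustive group relabellings when `choose(n, n1)` is at
#' most `exhaustive_cap`, otherwise `n_perm` seeded uniform draws.
#'
#' @param x Log2 expression matrix (genes x samples).
#' @param groups Character vector (length `ncol(x)`) with exactly two distinct
#'   labels.
#' @param contrast Length-2 character vector naming the comparison as
#'   (numerator, denominator); default compares `"FS"` minus `"NFS"` when
#'   present, otherwise the two labels in sorted order.
#' @param target_fdr Target false discovery rate (default 0.05).
#' @param s0 Optional fixed fudge factor; chosen by [choose_s0()] when NULL.
#' @param n_perm Number of sampled permutations when exhaustive enumeration is
#'   infeasible.
#' @param exhaustive_cap Largest permutation count enumerated exhaustively.
#' @param seed Integer seed for sampled permutations.
#' @return An object of class `sam_fit`; see [tidy.sam_fit()] and
#'   [glance.sam_fit()].
#' @examples
#' sim <- generate_expression(expression_spec(n_genes = 60, n_de = 5, seed = 3))
#' fit <- sam_two_class(sim$expression, sim$groups$group, seed = 3)
#' glance(fit)
#' @export
#' @param fdr_estimator Summary of the permuted call counts: `"mean"`
#'   (default) or `"median"`.
sam_two_class <- function(x, groups, contrast = NULL, target_fdr = 0.05,
                          s0 = NULL, n_perm = 200, exhaustive_cap = 10000,
                          seed = 1, fdr_estimator = c("mean", "median")) {
  fdr_estimator <- match.arg(fdr_estimator)
  fdr_summary <- if (fdr_estimator == "mean") mean else median
  stopifnot(is.matrix(x), length(groups) == ncol(x))
  if (target_fdr <= 0 || target_fdr >= 1) {
    stop("target_fdr must be in (0, 1)", call. = FALSE)
  }
  labs <- unique(groups)
  if (length(labs) != 2) stop("exactly two groups required", call. = FALSE)
  if (is.null(contrast)) {
    contrast <- if (all(c("FS", "NFS") %in% labs)) c("FS", "NFS") else sort(labs)
  }
  g1 <- which(groups == contrast[1]); g2 <- which(groups == contrast[2])
  if (length(g1) < 2 || length(g2) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  check_seed(seed)
  obs <- sam_d_stats(x, g1, g2, s0)
  p <- nrow(x); n <- ncol(x)

  perms <- sam_permutations(n, length(g1), cap = exhaustive_cap,
                            n_sampled = n_perm)
  idx <- perms$idx
  B <- ncol(idx)
  # permuted d for every relabelling, with the observed s0 held fixed
  P1 <- matrix(0, n, B); P1[cbind(as.vector(idx), rep(seq_len(B), each = nrow(idx)))] <- 1
  n1 <- length(g1); n2 <- length(g2)
  X <- x; X2 <- x^2
  S1 <- X %*% P1; Q1 <- X2 %*% P1
  tot <- rowSums(X); tot2 <- rowSums(X2)
  M1 <- S1 / n1; M2 <- (tot - S1) / n2
  SS1 <- Q1 - n1 * M1^2
  SS2 <- (tot2 - Q1) - n2 * M2^2
  Sp <- sqrt((1 / n1 + 1 / n2) * (SS1 + SS2) / (n1 + n2 - 2))
  Dperm <- (M1 - M2) / (Sp + obs$s0)
  Dperm[!is.finite(Dperm)] <- 0
  Dperm_sorted <- apply(Dperm, 2, sort)           # p x B
  if (!is.matrix(Dperm_sorted)) Dperm_sorted <- matrix(Dperm_sorted, nrow = p)
  dbar <- rowMeans(Dperm_sorted)

  ord <- order(obs$d)
  d_sorted <- obs$d[ord]
  res <- d_sorted - dbar
  deltas <- sort(unique(c(0, abs(res))))

  n_called <- integer(length(deltas))
  fdr <- numeric(length(deltas))
  called_mat <- matrix(FALSE, p, length(deltas))  # in sorted-gene order
  tDperm <- t(Dperm_sorted)                       # B x p
  # numerical guard: the observed labelling is itself a permutation whose d
  # values sit exactly at the cutoffs; count within round-off of the cutoff
  eps <- 1e-8 * (1 + max(abs(d_sorted)))
  for (k in seq_along(deltas)) {
    cuts <- sam_cutoffs(d_sorted, dbar, deltas[k])
    called <- d_sorted >= cuts$cutup | d_sorted <= cuts$cutlow
    called_mat[, k] <- called
    n_called[k] <- sum(called)
    if (n_called[k] == 0) { fdr[k] <- 0; next }
    perm_counts <- rowSums(tDperm >= cuts$cutup - eps) +
      rowSums(tDperm <= cuts$cutlow + eps)
    fdr[k] <- min(1, fdr_summary(perm_counts) / n_called[k])
  }

  ok <- which(fdr <= target_fdr)
  delta_star <- if (length(ok)) deltas[min(ok)] else Inf
  sel <- if (is.finite(delta_star)) {
    called_mat[, which(deltas == delta_star)]
  } else rep(FALSE, p)

  # q-value: smallest estimated FDR over deltas at which the gene is called
  qs <- rep(1, p)
  for (k in seq_along(deltas)) {
    idxk <- called_mat[, k]
    qs[idxk] <- pmin(qs[idxk], fdr[k])
  }

  genes <- rownames(x) %||% as.character(seq_len(p))
  tab <- tibble::tibble(
    gene = genes[ord],
    d = unname(d_sorted),
    dbar = unname(dbar),
    fold = unname(2^(obs$r[ord])),
    q = qs,
    called = sel
  ) |>
    dplyr::arrange(dplyr::desc(abs(.data$d)))

  structure(list(
    table = tab, delta = delta_star, s0 = obs$s0,
    fdr_at_delta = if (is.finite(delta_star)) fdr[which(deltas == delta_star)] else NA_real_,
    target_fdr = target_fdr, contrast = contrast,
    n_perm = B, exhaustive = perms$exhaustive,
    delta_grid = tibble::tibble(delta = deltas, n_called = n_called, fdr = fdr)
  ), class = "sam_fit")
}

#' @export
print.sam_fit <- function(x, ...) {
  cat("SAM two-class fit (", x$contrast[1], " vs ", x$contrast[2], ")\n", sep = "")
  cat(sprintf("  s0 = %.4g, delta = %.4g, estimated FDR at delta = %.3g\n",
              x$s0, x$delta, x$fdr_at_delta))
  cat(sprintf("  %d genes called (target FDR %.2g), %s permutations (n = %d)\n",
              sum(x$table$called), x$target_fdr,
              if (x$exhaustive) "exhaustive" else "sampled", x$n_perm))
  invisible(x)
}

#' Select differentially expressed genes from a SAM fit
#'
#' Applies the study's selection rule: q-value at or below the target FDR and
#' linear fold change at or above `min_fold` in the stated direction
#' (up-regulated in the contrast's first group by default). The fold gate is
#' inclusive (`fold >= min_fold`).
#'
#' @param sam A `sam_fit`.
#' @param min_fold Minimum linear fold change (default 3).
#' @param fdr Maximum q-value; defaults to the fit's target FDR.
#' @param direction `"up"` (numerator group), `"down"`, or `"both"`.
#' @return Character vector of gene ids (possibly empty).
#' @export
select_de <- function(sam, min_fold = 3, fdr = sam$target_fdr,
                      direction = c("up", "down", "both")) {
  stopifnot(inherits(sam, "sam_fit"), min_fold >= 1)
  direction <- match.arg(direction)
  tab <- sam$table
  keep <- tab$q <= fdr & switch(direction,
    up = tab$fold >= min_fold,
    down = tab$fold <= 1 / min_fold,
    both = pmax(tab$fold, 1 / tab$fold) >= min_fold)
  tab$gene[keep]
}

#' Hierarchical clustering of expression profiles (Pearson, complete linkage)
#'
#' Distance between gene profiles is `1 - Pearson r`; merges use complete
#' linkage. Genes with zero-variance profiles get the maximal distance (2) to
#' every other gene, with a warning. Input rows are ordered lexicographically
#' by gene id first so the dendrogram is invariant to input gene order.
#'
#' @param x Expression matrix restricted to the genes of interest (>= 2 rows).
#' @return An object of class `hclust`.
#' @export
cluster_expression <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  x <- x[order(rownames(x) %||% seq_len(nrow(x))), , drop = FALSE]
  sds <- apply(x, 1, sd)
  cc <- suppressWarnings(cor(t(x)))
  if (any(sds == 0)) {
    warning("zero-variance profile(s): distance set to 2")
    cc[sds == 0, ] <- -1
    cc[, sds == 0] <- -1
  }
  diag(cc) <- 1
  hclust(as.dist(1 - cc), method = "complete")
}

#' Export a dendrogram in Newick format
#'
#' @param hc An `hclust` object (e.g. from [cluster_expression()]).
#' @param path Output path.
#' @export
dendrogram_newick <- function(hc, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the 'ape' package is required for Newick export", call. = FALSE)
  }
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
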