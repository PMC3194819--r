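#' Turn a fitted object into a tidy per-observation tibble
#'
#' @param x A fitted object (`sam_fit`, `coexpr_network`, `texture_cv`,
#'   `standard_curve`, ...).
#' @param ... Passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model summary
#'
#' @param x A fitted object.
#' @param ... Passed to methods.
#' @return A one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @describeIn tidy per-gene SAM table (`gene`, `d`, `dbar`, `fold`, `q`,
#'   `called`), ordered by `|d|`.
#' @export
tidy.sam_fit <- function(x, ...) x$table

#' @describeIn glance SAM fit summary: `s0`, `delta`, `fdr_at_delta`,
#'   `n_called`, permutation count.
#' @export
glance.sam_fit <- function(x, ...) {
  tibble::tibble(s0 = x$s0, delta = x$delta, fdr_at_delta = x$fdr_at_delta,
                 target_fdr = x$target_fdr, n_called = sum(x$table$called),
                 n_perm = x$n_perm, exhaustive = x$exhaustive)
}

#' @describeIn tidy network edge list (`from`, `to`, `rho`).
#' @export
tidy.coexpr_network <- function(x, ...) x$edges

#' @describeIn glance network summary: node, edge and candidate-pair counts
#'   and the threshold interval.
#' @export
glance.coexpr_network <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$nodes), n_edges = nrow(x$edges),
                 n_candidate_pairs = x$n_candidate_pairs,
                 lo = x$lo, hi = x$hi, absolute = x$absolute)
}

#' @describeIn tidy per-fold cross-validation metrics.
#' @export
tidy.texture_cv <- function(x, ...) x$folds

#' @describeIn glance pooled and fold-mean cross-validation metrics.
#' @export
glance.texture_cv <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, kappa = x$kappa, auc = x$auc,
                 mean_fold_accuracy = x$mean_fold_accuracy,
                 mean_fold_kappa = x$mean_fold_kappa,
                 k = x$k, n = sum(x$confusion))
}

#' @describeIn glance standard-curve parameters.
#' @export
glance.standard_curve <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, efficiency = x$efficiency, n = x$n)
}
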