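#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10(quantity) over a dilution series.
#' The amplification efficiency is `10^(-1/slope)`; a perfect assay doubles
#' per cycle (efficiency 2, slope -3.32).
#'
#' @param quantity Known standard quantities (> 0, at least 3 distinct).
#' @param ct Measured Ct values (replicates may be pre-averaged or given
#'   per-replicate with repeated quantities).
#' @return Object of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`.
#' @examples
#' q <- 10^-(0:4)
#' fit_standard_curve(q, 35 + 3.3219 * log10(1 / q))
#' @export
fit_standard_curve <- function(quantity, ct) {
  stopifnot(length(quantity) == length(ct))
  if (any(quantity <= 0)) stop("standard quantities must be positive", call. = FALSE)
  if (length(unique(quantity)) < 3) {
    stop("need at least 3 distinct dilution points", call. = FALSE)
  }
  fit <- lm(ct ~ log10(quantity))
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    stop("standard curve slope must be negative", call. = FALSE)
  }
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((ct - mean(ct))^2)
  structure(list(
    slope = slope,
    intercept = unname(coef(fit)[1]),
    r_squared = r2,
    efficiency = 10^(-1 / slope),
    n = length(ct)
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve: slope %.4f, intercept %.2f, R^2 %.4f, efficiency %.3f\n",
              x$slope, x$intercept, x$r_squared, x$efficiency))
  invisible(x)
}

# invert the curve: quantity from Ct
curve_quantity <- function(curve, ct) 10^((ct - curve$intercept) / curve$slope)

#' Relative expression by the standard-curve method
#'
#' Ct values (triplicates averaged per sample and gene) are inverted through
#' each gene's standard curve to relative quantities, normalized by the
#' reference gene's quantity in the same sample, and summarized as the fold
#' change of FS versus NFS group means per target gene. Samples lacking a
#' reference measurement are excluded with a warning.
#'
#' @param measurements Tibble with columns `sample`, `gene`, `group`, `ct`
#'   (one row per replicate; standards excluded or flagged via an
#'   `is_standard` column).
#' @param curves Named list of `standard_curve` objects, one per gene
#'   (including the reference gene).
#' @param reference Reference gene name (default `"GAPDH"`).
#' @param groups Length-2 character vector: (numerator, denominator) of the
#'   fold change; default `c("FS", "NFS")`.
#' @return List with `samples` (per-sample normalized quantities) and
#'   `fold_changes` (tibble `gene`, `mean_num`, `mean_den`, `fold_change`).
#' @export
relative_expression <- function(measurements, curves, reference = "GAPDH",
                                groups = c("FS", "NFS")) {
  stopifnot(is.data.frame(measurements),
            all(c("sample", "gene", "group", "ct") %in% names(measurements)))
  if ("is_standard" %in% names(measurements)) {
    measurements <- measurements[!measurements$is_standard, ]
  }
  targets <- setdiff(unique(measurements$gene), reference)
  missing_curves <- setdiff(c(targets, reference), names(curves))
  if (length(missing_curves)) {
    stop("no standard curve for: ", paste(missing_curves, collapse = ", "),
         call. = FALSE)
  }
  mean_ct <- measurements |>
    dplyr::group_by(sample = .data$sample, gene = .data$gene,
                    group = .data$group) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
  mean_ct$quantity <- vapply(seq_len(nrow(mean_ct)), function(i) {
    curve_quantity(curves[[mean_ct$gene[i]]], mean_ct$ct[i])
  }, numeric(1))
  ref <- mean_ct[mean_ct$gene == reference,
                 c("sample", "quantity")]
  names(ref)[2] <- "ref_quantity"
  tab <- mean_ct[mean_ct$gene != reference, ] |>
    dplyr::left_join(ref, by = "sample")
  if (any(is.na(tab$ref_quantity))) {
    dropped <- unique(tab$sample[is.na(tab$ref_quantity)])
    warning("samples without reference measurement excluded: ",
            paste(dropped, collapse = ", "))
    tab <- tab[!is.na(tab$ref_quantity), ]
  }
  tab$normalized <- tab$quantity / tab$ref_quantity
  fc <- tab |>
    dplyr::group_by(gene = .data$gene) |>
    dplyr::summarise(
      mean_num = mean(.data$normalized[.data$group == groups[1]]),
      mean_den = mean(.data$normalized[.data$group == groups[2]]),
      .groups = "drop") |>
    dplyr::mutate(fold_change = .data$mean_num / .data$mean_den)
  if (any(!is.finite(fc$fold_change))) {
    stop("a group has no usable samples for some gene", call. = FALSE)
  }
  list(samples = tab, fold_changes = fc)
}

#' Fit standard curves for every gene in a qPCR table
#'
#' Convenience wrapper: fits [fit_standard_curve()] per gene on the
#' `is_standard` rows of a table such as the one produced by
#' [generate_qpcr()], averaging replicate Ct values per dilution point.
#'
#' @param qpcr Tibble with `gene`, `ct`, `quantity`, `is_standard`.
#' @return Named list of `standard_curve` objects.
#' @export
fit_standard_curves <- function(qpcr) {
  std <- qpcr[qpcr$is_standard, ]
  if (!nrow(std)) stop("no standard rows", call. = FALSE)
  pts <- std |>
    dplyr::group_by(gene = .data$gene, quantity = .data$quantity) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
  out <- lapply(split(pts, pts$gene), function(d) {
    fit_standard_curve(d$quantity, d$ct)
  })
  out
}
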