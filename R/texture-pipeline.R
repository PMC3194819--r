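# coefficient operator of the windowed Haar transform: rows = coefficients,
# columns = window pixels (column-major); linear, so features for all windows
# come from one matrix product
haar_window_operator <- function(win, levels = 2) {
  basis <- diag(win * win)
  first <- haar_dwt2(matrix(0, win, win), levels)
  bands <- c(unlist(lapply(seq_len(levels), function(l)
    paste0("l", l, "_", c("dv", "dh", "dd")))), "approx")
  sizes <- c(unlist(lapply(seq_len(levels), function(l)
    rep(length(first$detail[[l]][[1]]), 3))), length(first$approx))
  op <- matrix(0, sum(sizes), win * win)
  for (px in seq_len(win * win)) {
    w <- matrix(basis[, px], win, win)
    dw <- haar_dwt2(w, levels)
    vec <- c(unlist(lapply(seq_len(levels), function(l)
      c(dw$detail[[l]]$dv, dw$detail[[l]]$dh, dw$detail[[l]]$dd))), dw$approx)
    op[, px] <- vec
  }
  band_id <- rep(bands, sizes)
  list(op = op, band_id = band_id)
}

window_stack <- function(image, rows, cols, win) {
  half <- (win - 1) / 2
  nr <- nrow(image)
  offsets <- as.vector(outer(-half:half, (-half:half) * nr, `+`))
  centers <- (cols - 1) * nr + rows
  out <- matrix(0, length(centers), win * win)
  for (k in seq_along(offsets)) out[, k] <- image[centers + offsets[k]]
  out
}

#' Extract the per-pixel texture feature table of an image
#'
#' For every labelled in-mask pixel whose sliding window fits inside the
#' image, computes the full texture bank over the `window x window`
#' neighbourhood: co-occurrence, run-length, first-order, Haar wavelet,
#' fractal, Markov-random-field and Gabor features (150 columns with the
#' defaults; see the package overview). Border pixels without a full window
#' are skipped.
#'
#' @param image Preprocessed numeric matrix (see [preprocess_image()]).
#' @param mask Logical matrix of eligible pixels (default: all).
#' @param labels Integer matrix of per-pixel class labels (0 = unlabelled);
#'   when NULL every in-mask pixel is used with label NA.
#' @param window Sliding-window side (odd, default 9).
#' @param levels Gray levels for co-occurrence/run-length quantization
#'   (default 64; a 16-level reduction of the run-length family is always
#'   included).
#' @param distances Co-occurrence displacement distances (angle-averaged
#'   features; default 1:4).
#' @param unaveraged_distances Distances for which per-angle co-occurrence
#'   features are kept (default 1:2).
#' @param gabor_frequencies,gabor_orientations,gabor_size,gabor_sigma Gabor
#'   bank configuration (see [gabor_bank()]).
#' @param image_id Identifier stored in the `image` provenance column.
#' @return Tibble: `image`, `row`, `col`, `label`, then the feature columns.
#' @export
extract_features <- function(image, mask = NULL, labels = NULL, window = 9,
                             levels = 64, distances = 1:4,
                             unaveraged_distances = 1:2,
                             gabor_frequencies = c(0.15, 0.25, 0.35),
                             gabor_orientations = c(0, 45, 90, 135),
                             gabor_size = 7, gabor_sigma = 2,
                             image_id = "img") {
  stopifnot(is.matrix(image), window %% 2 == 1, window >= 3)
  mask <- mask %||% matrix(TRUE, nrow(image), ncol(image))
  half <- (window - 1) / 2
  eligible <- mask
  if (!is.null(labels)) eligible <- eligible & labels > 0
  rowi <- row(image); coli <- col(image)
  fits <- rowi > half & rowi <= nrow(image) - half &
    coli > half & coli <= ncol(image) - half
  sel <- which(eligible & fits)
  if (!length(sel)) stop("no eligible pixels", call. = FALSE)
  rows <- rowi[sel]; cols <- coli[sel]

  q64 <- quantize_image(image, levels = levels, mask = mask)
  q16 <- quantize_image(image, levels = 16, mask = mask)

  feats <- list()

  # -- co-occurrence
  raw <- cpp_glcm_stack(q64, rows, cols, window, as.integer(distances))
  for (d in seq_along(distances)) {
    block <- raw[, (d - 1) * 24 + seq_len(24), drop = FALSE]
    for (f in seq_along(glcm_feature_names)) {
      avg <- rowMeans(block[, f + 6 * (0:3), drop = FALSE])
      feats[[paste0("glcm_d", distances[d], "_", glcm_feature_names[f])]] <- avg
    }
  }
  for (d in which(distances %in% unaveraged_distances)) {
    block <- raw[, (d - 1) * 24 + seq_len(24), drop = FALSE]
    for (a in 1:4) {
      for (f in seq_along(glcm_feature_names)) {
        feats[[paste0("glcm_d", distances[d], "_a", texture_angles[a], "_",
                      glcm_feature_names[f])]] <- block[, (a - 1) * 6 + f]
      }
    }
  }

  # -- run length (full levels: direction-averaged + per direction;
  #    16-level reduction: direction-averaged)
  raw64 <- cpp_rlm_stack(q64, rows, cols, window, as.integer(levels))
  raw16 <- cpp_rlm_stack(q16, rows, cols, window, 16L)
  for (f in seq_along(rlm_feature_names)) {
    feats[[paste0("rlm_", rlm_feature_names[f])]] <-
      rowMeans(raw64[, f + 5 * (0:3), drop = FALSE])
  }
  for (f in seq_along(rlm_feature_names)) {
    feats[[paste0("rlm_q16_", rlm_feature_names[f])]] <-
      rowMeans(raw16[, f + 5 * (0:3), drop = FALSE])
  }
  for (a in 1:4) {
    for (f in seq_along(rlm_feature_names)) {
      feats[[paste0("rlm_a", texture_angles[a], "_", rlm_feature_names[f])]] <-
        raw64[, (a - 1) * 5 + f]
    }
  }

  # -- first order
  W <- window_stack(image, rows, cols, window)
  feats[["fo_mean"]] <- rowMeans(W)
  feats[["fo_var"]] <- rowMeans(W^2) - rowMeans(W)^2
  Wq <- window_stack(q64, rows, cols, window)
  npx <- window^2
  ent <- rep(0, length(sel))
  for (g in 0:(levels - 1)) {
    p <- rowSums(Wq == g) / npx
    nz <- p > 0
    ent[nz] <- ent[nz] - p[nz] * log2(p[nz])
  }
  feats[["fo_entropy"]] <- ent

  # -- wavelet (linear operator applied to the window stack)
  hop <- haar_window_operator(window, levels = 2)
  coefs <- W %*% t(hop$op)
  for (b in unique(hop$band_id)) {
    cb <- coefs[, hop$band_id == b, drop = FALSE]
    feats[[paste0("wav_", b, "_meanabs")]] <- rowMeans(abs(cb))
    feats[[paste0("wav_", b, "_energy")]] <- rowSums(cb^2)
  }

  # -- fractal
  sizes <- c(2L, 3L, 4L)
  cnt <- cpp_dbc_counts(image, rows, cols, window, sizes, 64L)
  xs <- log(window %/% sizes)
  xc <- xs - mean(xs)
  ys <- log(cnt)
  slope <- (ys %*% xc) / sum(xc^2)
  feats[["fd"]] <- as.numeric(slope)
  feats[["fd_intercept"]] <- rowMeans(ys) - as.numeric(slope) * mean(xs)

  # -- Markov random field (order 2)
  mrf <- cpp_mrf_stack(image, rows, cols, window, 2L)
  mrf_names <- c("mrf_theta_h", "mrf_theta_v", "mrf_theta_d1", "mrf_theta_d2",
                 "mrf_sigma2")
  for (k in seq_along(mrf_names)) feats[[mrf_names[k]]] <- mrf[, k]

  # -- Gabor: whole-image convolution, then window statistics of the
  #    response over the valid positions (equals the per-window definition
  #    at every retained pixel)
  bank <- gabor_bank(gabor_frequencies, gabor_orientations, gabor_size,
                     gabor_sigma)
  m <- window - gabor_size + 1
  box <- matrix(1 / m^2, m, m)
  centers <- (cols - 1) * nrow(image) + rows
  for (nm in names(bank)) {
    R <- conv2_same(image, bank[[nm]])
    mabs <- conv2_same(abs(R), box)
    msq <- conv2_same(R^2, box)
    mr <- conv2_same(R, box)
    feats[[paste0("gabor_", nm, "_meanabs")]] <- mabs[centers]
    feats[[paste0("gabor_", nm, "_sd")]] <-
      sqrt(pmax(msq[centers] - mr[centers]^2, 0))
  }

  lab <- if (is.null(labels)) NA_integer_ else labels[sel]
  dplyr::bind_cols(
    tibble::tibble(image = image_id, row = rows, col = cols, label = lab),
    tibble::as_tibble(feats))
}

#' Equalize class sizes by downsampling
#'
#' Majority classes are downsampled uniformly at random (seeded) to the
#' minority class count, avoiding classification bias from unequal class
#' frequencies.
#'
#' @param features Feature tibble with a label column.
#' @param seed Integer seed.
#' @param label_col Label column name (default `"label"`).
#' @return Balanced tibble.
#' @export
balance_classes <- function(features, seed = 1, label_col = "label") {
  stopifnot(is.data.frame(features), label_col %in% names(features))
  counts <- table(features[[label_col]])
  if (length(counts) < 2) stop("need at least 2 classes", call. = FALSE)
  if (any(counts == 0)) stop("a class has no rows", call. = FALSE)
  n_min <- min(counts)
  check_seed(seed)
  idx <- unlist(lapply(names(counts), function(cl) {
    rows <- which(features[[label_col]] == cl)
    if (length(rows) > n_min) sort(sample(rows, n_min)) else rows
  }))
  features[sort(idx), ]
}

#' Cohen's kappa of a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with `p_o` the
#' observed accuracy and `p_e` the expected agreement under independent
#' marginals. Values above zero indicate agreement beyond chance.
#'
#' @param confusion Square matrix of counts (rows = truth, columns =
#'   predicted).
#' @return Kappa (scalar).
#' @examples
#' cohen_kappa(matrix(c(45, 15, 5, 35), 2))  # 0.6
#' @export
cohen_kappa <- function(confusion) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion))
  n <- sum(confusion)
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (pe == 1) return(ifelse(po == 1, 1, 0))
  (po - pe) / (1 - pe)
}

#' Random-forest k-fold cross-validated pixel classification
#'
#' Stratified k-fold cross-validation of a random forest on a texture feature
#' table. Rows are shuffled (seeded) and assigned to folds within each class;
#' in each turn the forest is trained on k-1 folds and tested on the held-out
#' fold. Both the pooled out-of-fold metrics (confusion matrix, accuracy,
#' Cohen's kappa, ROC AUC for binary tasks) and the per-fold means are
#' reported.
#'
#' @param features Feature tibble from [extract_features()] (provenance
#'   columns `image`, `row`, `col` are dropped automatically).
#' @param k Number of folds (default 10).
#' @param seed Integer seed for fold assignment and forest training.
#' @param num_trees Trees per forest (default 100).
#' @param label_col Label column name.
#' @return Object of class `texture_cv`: confusion matrix, overall and
#'   per-fold metrics, and the out-of-fold predictions. See
#'   [tidy.texture_cv()] / [glance.texture_cv()].
#' @export
crossval_classify <- function(features, k = 10, seed = 1, num_trees = 100,
                              label_col = "label") {
  stopifnot(is.data.frame(features), label_col %in% names(features))
  y <- factor(features[[label_col]])
  if (nlevels(y) < 2) stop("need at least 2 classes", call. = FALSE)
  if (nrow(features) < k) stop("fewer rows than folds", call. = FALSE)
  if (any(table(y) < k)) {
    stop("a class has fewer rows than folds: folds cannot be stratified",
         call. = FALSE)
  }
  x <- features[, setdiff(names(features),
                          c(label_col, "image", "row", "col")), drop = FALSE]
  x <- as.data.frame(x)
  check_seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    rows <- which(y == cl)
    rows <- sample(rows)                       # data randomization
    fold[rows] <- rep_len(seq_len(k), length(rows))
  }
  lev <- levels(y)
  pred <- factor(rep(lev[1], length(y)), levels = lev)
  prob <- matrix(NA_real_, length(y), nlevels(y),
                 dimnames = list(NULL, lev))
  fold_rows <- list()
  for (f in seq_len(k)) {
    test <- fold == f
    fit <- ranger::ranger(x = x[!test, , drop = FALSE], y = y[!test],
                          num.trees = num_trees, probability = TRUE,
                          seed = seed + f, num.threads = 1)
    p <- predict(fit, x[test, , drop = FALSE], num.threads = 1)$predictions
    prob[test, ] <- p
    pred[test] <- lev[max.col(p, ties.method = "first")]
    cm_f <- table(truth = y[test], predicted = pred[test])
    fold_rows[[f]] <- tibble::tibble(
      fold = f, n = sum(test),
      accuracy = sum(diag(cm_f)) / sum(cm_f),
      kappa = cohen_kappa(unclass(cm_f)))
  }
  cm <- unclass(table(truth = y, predicted = pred))
  folds <- dplyr::bind_rows(fold_rows)
  auc <- NA_real_
  if (nlevels(y) == 2) {
    roc <- pROC::roc(response = y, predictor = prob[, 2], levels = lev,
                     direction = "<", quiet = TRUE)
    auc <- as.numeric(pROC::auc(roc))
  }
  structure(list(
    confusion = cm,
    accuracy = sum(diag(cm)) / sum(cm),
    kappa = cohen_kappa(cm),
    auc = auc,
    per_class_accuracy = diag(cm) / rowSums(cm),
    folds = folds,
    mean_fold_accuracy = mean(folds$accuracy),
    mean_fold_kappa = mean(folds$kappa),
    oof = tibble::tibble(truth = y, predicted = pred,
                         prob = if (nlevels(y) == 2) prob[, 2] else NA_real_),
    k = k, num_trees = num_trees, seed = seed
  ), class = "texture_cv")
}

#' @export
print.texture_cv <- function(x, ...) {
  cat(sprintf("%d-fold random-forest cross-validation (%d trees)\n",
              x$k, x$num_trees))
  cat(sprintf("  pooled accuracy %.3f, kappa %.3f%s\n", x$accuracy, x$kappa,
              if (is.finite(x$auc)) sprintf(", AUC %.3f", x$auc) else ""))
  cat(sprintf("  per-fold mean accuracy %.3f, kappa %.3f\n",
              x$mean_fold_accuracy, x$mean_fold_kappa))
  print(x$confusion)
  invisible(x)
}
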