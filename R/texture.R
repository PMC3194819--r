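#' @section Texture feature bank:
#' The default per-pixel bank totals exactly 150 features computed over a
#' 9x9 sliding window: 72 co-occurrence (6 Haralick-style features x 4
#' distances angle-averaged, plus per-angle variants at distances 1-2), 30
#' run-length (5 features angle-averaged at 64 and 16 gray levels, plus
#' per-direction variants), 3 first-order statistics, 14 Haar wavelet subband
#' statistics, 2 fractal (differential box counting slope and intercept), 5
#' Markov-random-field parameters, and 24 Gabor filter response statistics
#' (3 frequencies x 4 orientations x 2 statistics).
#' @name texture-bank
NULL

# ---- preprocessing -----------------------------------------------------

swap_sort <- function(lst, a, b) {
  lo <- pmin(lst[[a]], lst[[b]]); hi <- pmax(lst[[a]], lst[[b]])
  lst[[a]] <- lo; lst[[b]] <- hi
  lst
}

#' 3x3 median filter
#'
#' Noise filter used in image preprocessing; reflect padding at the borders,
#' computed with a median-of-9 sorting network (fully vectorized).
#'
#' @param x Numeric matrix.
#' @return Filtered matrix of the same shape.
#' @export
median_filter <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  xp <- x[c(2, seq_len(nr), nr - 1), c(2, seq_len(nc), nc - 1)]
  p <- vector("list", 9)
  k <- 1
  for (dr in 0:2) for (dc in 0:2) {
    p[[k]] <- xp[dr + seq_len(nr), dc + seq_len(nc)]
    k <- k + 1
  }
  for (s in list(c(2, 3), c(5, 6), c(8, 9), c(1, 2), c(4, 5), c(7, 8),
                 c(2, 3), c(5, 6), c(8, 9), c(1, 4), c(6, 9), c(5, 8),
                 c(4, 7), c(2, 5), c(3, 6), c(5, 8), c(5, 3), c(7, 5),
                 c(5, 3))) {
    p <- swap_sort(p, s[1], s[2])
  }
  p[[5]]
}

#' Otsu threshold of a set of intensities
#'
#' Maximizes the between-class variance over a binned histogram; used to
#' separate image background from foreground tissue.
#'
#' @param values Numeric vector of intensities.
#' @param n_bins Histogram bins (default 256).
#' @return Threshold value; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(values, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Preprocess a grayscale image for texture analysis
#'
#' Noise filtering (3x3 median, reflect padding), background segmentation
#' (Otsu threshold on the filtered intensities within the region of
#' interest), and intensity normalization (in-mask values rescaled to zero
#' mean, unit variance). The whole image is normalized with the in-mask
#' statistics so sliding windows near the mask boundary stay defined.
#'
#' @param image Numeric matrix of intensities (any finite scale).
#' @param roi Optional logical matrix restricting the analysis region.
#' @param segment Apply the Otsu background split (default TRUE); when FALSE
#'   the mask is the ROI itself.
#' @param filter Apply the median filter (default TRUE).
#' @return List with `image` (normalized matrix) and `mask` (logical
#'   foreground matrix).
#' @export
preprocess_image <- function(image, roi = NULL, segment = TRUE, filter = TRUE) {
  stopifnot(is.matrix(image))
  if (any(!is.finite(image))) stop("image has non-finite intensities", call. = FALSE)
  roi <- roi %||% matrix(TRUE, nrow(image), ncol(image))
  stopifnot(dim(roi)[1] == nrow(image), dim(roi)[2] == ncol(image))
  img <- if (filter) median_filter(image) else image
  if (segment) {
    thr <- otsu_threshold(img[roi])
    mask <- roi & img > thr
  } else {
    mask <- roi
  }
  if (!any(mask)) stop("empty foreground after segmentation", call. = FALSE)
  mu <- mean(img[mask]); sigma <- sd(img[mask])
  if (!is.finite(sigma) || sigma == 0) {
    stop("constant foreground: intensity normalization degenerate", call. = FALSE)
  }
  list(image = (img - mu) / sigma, mask = mask)
}

#' Quantize an image to discrete gray levels
#'
#' Equal-width binning of the in-mask intensity range into `levels` gray
#' levels, 0-based. Idempotent at fixed `levels`.
#'
#' @param image Numeric matrix.
#' @param levels Number of gray levels (>= 2; default 64).
#' @param mask Optional logical matrix; the bin range is taken from in-mask
#'   values (out-of-mask pixels are clamped into range).
#' @return Integer matrix with values in `0:(levels - 1)`.
#' @export
quantize_image <- function(image, levels = 64, mask = NULL) {
  stopifnot(is.matrix(image))
  if (levels < 2) stop("levels must be at least 2", call. = FALSE)
  vals <- if (is.null(mask)) image else image[mask]
  lo <- min(vals); hi <- max(vals)
  if (hi == lo) return(matrix(0L, nrow(image), ncol(image)))
  q <- floor((pmin(pmax(image, lo), hi) - lo) / (hi - lo) * levels)
  q[q >= levels] <- levels - 1L
  matrix(as.integer(q), nrow(image), ncol(image))
}

# ---- per-window feature families ---------------------------------------

texture_angles <- c(0L, 45L, 90L, 135L)
glcm_feature_names <- c("energy", "contrast", "correlation", "homogeneity",
                        "entropy", "dissimilarity")
rlm_feature_names <- c("sre", "lre", "gln", "rln", "rp")

check_window <- function(window) {
  stopifnot(is.matrix(window), nrow(window) == ncol(window),
            nrow(window) %% 2 == 1)
  nrow(window)
}

#' Gray-level co-occurrence (Haralick-style) features of one window
#'
#' Builds the symmetric normalized co-occurrence matrix for each requested
#' displacement distance and the four standard angles (0, 45, 90, 135
#' degrees) and returns energy, contrast, correlation, homogeneity, entropy
#' and dissimilarity, plus the angle-averaged row per distance.
#'
#' @param window Integer-valued square matrix (odd side), already quantized.
#' @param distances Integer vector of displacement distances (default 1).
#' @return Tibble with columns `distance`, `angle` (degrees, or `"mean"`),
#'   and the six features.
#' @export
glcm_features <- function(window, distances = 1) {
  win <- check_window(window)
  if (any(distances >= win)) stop("distance must be smaller than the window",
                                  call. = FALSE)
  q <- matrix(as.integer(window), win, win)
  ctr <- as.integer((win + 1) / 2)
  raw <- cpp_glcm_stack(q, ctr, ctr, win, as.integer(distances))
  out <- list()
  for (d in seq_along(distances)) {
    block <- matrix(raw[1, (d - 1) * 24 + seq_len(24)], nrow = 4, byrow = TRUE)
    colnames(block) <- glcm_feature_names
    out[[length(out) + 1]] <- tibble::tibble(
      distance = distances[d],
      angle = as.character(texture_angles)) |>
      dplyr::bind_cols(tibble::as_tibble(block))
    out[[length(out) + 1]] <- dplyr::bind_cols(
      tibble::tibble(distance = distances[d], angle = "mean"),
      tibble::as_tibble(t(colMeans(block))))
  }
  dplyr::bind_rows(out)
}

#' Gray-level run-length features of one window
#'
#' Run-length matrices in the four standard directions; features are
#' short-run emphasis (`sre`), long-run emphasis (`lre`), gray-level
#' non-uniformity (`gln`), run-length non-uniformity (`rln`) and run
#' percentage (`rp`), plus the direction-averaged row.
#'
#' @param window Integer-valued square matrix (odd side), quantized.
#' @param levels Number of gray levels (defaults to `max(window) + 1`).
#' @return Tibble with `direction` (degrees or `"mean"`) and the features.
#' @export
rlm_features <- function(window, levels = NULL) {
  win <- check_window(window)
  levels <- levels %||% (max(window) + 1L)
  q <- matrix(as.integer(window), win, win)
  ctr <- as.integer((win + 1) / 2)
  raw <- cpp_rlm_stack(q, ctr, ctr, win, as.integer(levels))
  block <- matrix(raw[1, ], nrow = 4, byrow = TRUE)
  colnames(block) <- rlm_feature_names
  dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(direction = as.character(texture_angles)),
                     tibble::as_tibble(block)),
    dplyr::bind_cols(tibble::tibble(direction = "mean"),
                     tibble::as_tibble(t(colMeans(block)))))
}

# one level of the 2-D Haar transform; odd dimensions get symmetric
# (edge-replicate) padding
haar_step <- function(m) {
  if (nrow(m) %% 2 == 1) m <- rbind(m, m[nrow(m), , drop = FALSE])
  if (ncol(m) %% 2 == 1) m <- cbind(m, m[, ncol(m), drop = FALSE])
  ro <- seq(1, nrow(m), by = 2); re <- ro + 1
  lo_v <- (m[ro, , drop = FALSE] + m[re, , drop = FALSE]) / sqrt(2)
  hi_v <- (m[ro, , drop = FALSE] - m[re, , drop = FALSE]) / sqrt(2)
  co <- seq(1, ncol(m), by = 2); ce <- co + 1
  list(
    ll = (lo_v[, co, drop = FALSE] + lo_v[, ce, drop = FALSE]) / sqrt(2),
    dh = (lo_v[, co, drop = FALSE] - lo_v[, ce, drop = FALSE]) / sqrt(2),
    dv = (hi_v[, co, drop = FALSE] + hi_v[, ce, drop = FALSE]) / sqrt(2),
    dd = (hi_v[, co, drop = FALSE] - hi_v[, ce, drop = FALSE]) / sqrt(2))
}

#' Two-dimensional discrete Haar wavelet transform
#'
#' @param x Numeric matrix.
#' @param levels Decomposition depth (default 2).
#' @return List with `detail` (per level: `dv` vertical, `dh` horizontal,
#'   `dd` diagonal detail) and `approx` (final approximation).
#' @export
haar_dwt2 <- function(x, levels = 2) {
  stopifnot(is.matrix(x), levels >= 1)
  detail <- vector("list", levels)
  cur <- x
  for (l in seq_len(levels)) {
    st <- haar_step(cur)
    detail[[l]] <- st[c("dv", "dh", "dd")]
    cur <- st$ll
  }
  list(detail = detail, approx = cur)
}

#' Haar wavelet subband statistics of one window
#'
#' Mean absolute coefficient and energy (sum of squares) per detail subband
#' over `levels` decomposition levels, plus the approximation statistics.
#'
#' @param window Numeric square matrix.
#' @param levels Decomposition depth (default 2).
#' @return Named numeric vector (length `6 * levels + 2`).
#' @export
wavelet_features <- function(window, levels = 2) {
  dw <- haar_dwt2(window, levels)
  out <- c()
  for (l in seq_len(levels)) {
    for (b in c("dv", "dh", "dd")) {
      coefs <- dw$detail[[l]][[b]]
      out[paste0("wav_l", l, "_", b, "_meanabs")] <- mean(abs(coefs))
      out[paste0("wav_l", l, "_", b, "_energy")] <- sum(coefs^2)
    }
  }
  out["wav_approx_meanabs"] <- mean(abs(dw$approx))
  out["wav_approx_energy"] <- sum(dw$approx^2)
  out
}

#' Fractal dimension of an intensity surface (differential box counting)
#'
#' Box counts at grid sizes `sizes` are regressed (log-log, least squares)
#' against the per-side box count; the slope is the fractal dimension (2 for
#' a flat surface, up to 3 for a maximally rough one). Intensities are
#' rescaled to the window's own range, so the estimate is invariant to
#' additive offsets.
#'
#' @param window Numeric square matrix (side >= 8).
#' @param sizes Box sizes (default 2, 3, 4).
#' @param levels Intensity levels of the rescaled surface (default 64).
#' @return Named vector `c(fd, intercept)`.
#' @export
fractal_dimension <- function(window, sizes = c(2L, 3L, 4L), levels = 64) {
  win <- nrow(window)
  stopifnot(is.matrix(window), win == ncol(window), win >= 8)
  if (win %% 2 == 0) {
    # even windows: replicate the last row/column so the centred kernel applies
    window <- rbind(cbind(window, window[, win]),
                    c(window[win, ], window[win, win]))
    win <- win + 1L
  }
  sizes <- as.integer(sizes[sizes <= win %/% 2])
  if (length(sizes) <= 2) stop("need more than 2 box-count scales", call. = FALSE)
  ctr <- as.integer((win + 1) / 2)
  cnt <- cpp_dbc_counts(window, ctr, ctr, win, sizes, as.integer(levels))
  g <- win %/% sizes
  xs <- log(g)
  ys <- log(as.numeric(cnt))
  fit <- lm(ys ~ xs)
  c(fd = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
}

#' Gauss-Markov random field parameters of one window
#'
#' Least-squares regression of each interior pixel on its symmetric neighbour
#' sums: horizontal and vertical for order 1, plus the two diagonals for
#' order 2, with an intercept; the residual variance is returned as an
#' additional feature. Near-singular designs (constant windows, perfect
#' stripes) are ridge-stabilized, yielding near-zero parameters for the
#' degenerate directions.
#'
#' @param window Numeric square matrix (odd side >= 3).
#' @param order Neighbourhood order, 1 or 2 (default 1).
#' @return Named vector: `theta_h`, `theta_v` (order 1; plus `theta_d1`,
#'   `theta_d2` for order 2) and `sigma2`.
#' @export
mrf_features <- function(window, order = 1) {
  win <- check_window(window)
  ctr <- as.integer((win + 1) / 2)
  raw <- cpp_mrf_stack(window, ctr, ctr, win, as.integer(order))
  nm <- if (order >= 2) c("theta_h", "theta_v", "theta_d1", "theta_d2", "sigma2")
        else c("theta_h", "theta_v", "sigma2")
  out <- setNames(raw[1, ], nm)
  attr(out, "degenerate") <- length(unique(as.vector(window))) == 1
  out
}

#' Build a zero-DC Gabor filter bank
#'
#' @param frequencies Spatial frequencies in cycles/pixel.
#' @param orientations Orientations in degrees.
#' @param size Kernel side (odd, default 7).
#' @param sigma Gaussian envelope standard deviation (default 2).
#' @return Named list of kernels (`f<freq>_o<deg>`), each with zero mean.
#' @export
gabor_bank <- function(frequencies = c(0.15, 0.25, 0.35),
                       orientations = c(0, 45, 90, 135),
                       size = 7, sigma = 2) {
  stopifnot(size %% 2 == 1)
  half <- (size - 1) / 2
  rowg <- matrix(-half:half, size, size)
  colg <- t(rowg)
  bank <- list()
  for (f in frequencies) {
    for (o in orientations) {
      th <- o * pi / 180
      xp <- colg * cos(th) + rowg * sin(th)
      k <- exp(-(rowg^2 + colg^2) / (2 * sigma^2)) * cos(2 * pi * f * xp)
      k <- k - mean(k)
      bank[[sprintf("f%g_o%g", f, o)]] <- k
    }
  }
  bank
}

#' Gabor filter response statistics of one window
#'
#' Convolves the window with each bank filter (valid positions only) and
#' returns the mean magnitude and the standard deviation of the response per
#' filter. A constant window yields zero responses (zero-DC bank).
#'
#' @param window Numeric square matrix, side larger than the kernel.
#' @param frequencies,orientations,size,sigma Passed to [gabor_bank()].
#' @return Named vector `gabor_<filter>_meanabs` / `gabor_<filter>_sd`.
#' @export
gabor_features <- function(window, frequencies = c(0.15, 0.25, 0.35),
                           orientations = c(0, 45, 90, 135),
                           size = 7, sigma = 2) {
  win <- nrow(window)
  stopifnot(is.matrix(window), win == ncol(window), win > size)
  bank <- gabor_bank(frequencies, orientations, size, sigma)
  m <- win - size + 1
  out <- c()
  for (nm in names(bank)) {
    k <- bank[[nm]]
    resp <- matrix(0, m, m)
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        resp[i, j] <- sum(window[i:(i + size - 1), j:(j + size - 1)] * k)
      }
    }
    out[paste0("gabor_", nm, "_meanabs")] <- mean(abs(resp))
    out[paste0("gabor_", nm, "_sd")] <- sqrt(mean(resp^2) - mean(resp)^2)
  }
  out
}

# 2-D convolution, 'same' output, via FFT with zero padding; kernels here
# are symmetric so convolution equals correlation
conv2_same <- function(x, k) {
  nr <- nrow(x); nc <- ncol(x); ks <- nrow(k); half <- (ks - 1) / 2
  pr <- nr + ks - 1; pc <- nc + ks - 1
  xp <- matrix(0, pr, pc); xp[seq_len(nr), seq_len(nc)] <- x
  kp <- matrix(0, pr, pc); kp[seq_len(ks), seq_len(ks)] <- k
  full <- Re(fft(fft(xp) * fft(kp), inverse = TRUE)) / (pr * pc)
  full[half + seq_len(nr), half + seq_len(nc)]
}
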