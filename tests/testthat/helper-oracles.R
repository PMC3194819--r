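# Independent brute-force oracles used to validate the implementations.
# These are written as literal translations of the definitions (plain loops,
# no shared code with the package internals).

# midranks computed from first principles, then the Pearson product-moment
# formula written out by hand
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  rx <- midrank(x); ry <- midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (den == 0) return(NA_real_)
  num / den
}

# SAM brute force: plain-loop d statistics, explicit permutation list, the
# procedure's stated call rule and q-value definition
oracle_sam_d <- function(x, g1, g2, s0) {
  apply(x, 1, function(v) {
    a <- v[g1]; b <- v[g2]
    se <- sqrt((1 / length(a) + 1 / length(b)) *
               (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
               (length(a) + length(b) - 2))
    (mean(a) - mean(b)) / (se + s0)
  })
}

oracle_sam_q <- function(x, groups, contrast, s0) {
  g1 <- which(groups == contrast[1]); g2 <- which(groups == contrast[2])
  n <- ncol(x); n1 <- length(g1)
  perms <- combn(n, n1)
  d_obs <- oracle_sam_d(x, g1, g2, s0)
  ds <- sort(d_obs)
  perm_sorted <- sapply(seq_len(ncol(perms)), function(b) {
    p1 <- perms[, b]; p2 <- setdiff(seq_len(n), p1)
    sort(oracle_sam_d(x, p1, p2, s0))
  })
  dbar <- rowMeans(perm_sorted)
  deltas <- sort(unique(c(0, abs(ds - dbar))))
  p <- nrow(x)
  q <- rep(1, p)
  for (delta in deltas) {
    up_ok <- which(ds >= 0 & (ds - dbar) >= delta)
    lo_ok <- which(ds <= 0 & (dbar - ds) >= delta)
    cutup <- if (length(up_ok)) min(ds[up_ok]) else Inf
    cutlow <- if (length(lo_ok)) max(ds[lo_ok]) else -Inf
    called <- d_obs >= cutup | d_obs <= cutlow
    if (!any(called)) next
    false_counts <- vapply(seq_len(ncol(perms)), function(b) {
      sum(perm_sorted[, b] >= cutup) + sum(perm_sorted[, b] <= cutlow)
    }, numeric(1))
    fdr <- min(1, mean(false_counts) / sum(called))
    q[called] <- pmin(q[called], fdr)
  }
  names(q) <- rownames(x)
  q
}

# literal dense-matrix GLCM; angle in degrees
oracle_glcm <- function(window, dist, angle) {
  offs <- list("0" = c(0, 1), "45" = c(-1, 1), "90" = c(-1, 0),
               "135" = c(-1, -1))[[as.character(angle)]] * dist
  L <- max(window) + 1
  P <- matrix(0, L, L)
  for (r in seq_len(nrow(window))) {
    for (c in seq_len(ncol(window))) {
      r2 <- r + offs[1]; c2 <- c + offs[2]
      if (r2 < 1 || r2 > nrow(window) || c2 < 1 || c2 > ncol(window)) next
      i <- window[r, c] + 1; j <- window[r2, c2] + 1
      P[i, j] <- P[i, j] + 1
      P[j, i] <- P[j, i] + 1
    }
  }
  P <- P / sum(P)
  iv <- matrix(0:(L - 1), L, L)
  jv <- t(iv)
  mu <- sum(P * iv)
  va <- sum(P * iv^2) - mu^2
  pos <- P > 0
  c(energy = sum(P^2),
    contrast = sum(P * (iv - jv)^2),
    correlation = if (va > 1e-12) (sum(P * iv * jv) - mu^2) / va else 0,
    homogeneity = sum(P / (1 + (iv - jv)^2)),
    entropy = -sum(P[pos] * log2(P[pos])),
    dissimilarity = sum(P * abs(iv - jv)))
}

# literal run-length features via rle over extracted lines
oracle_rlm <- function(window, angle) {
  n <- nrow(window)
  lines <- switch(as.character(angle),
    "0" = lapply(seq_len(n), function(r) window[r, ]),
    "90" = lapply(seq_len(n), function(c) window[, c]),
    "45" = lapply(seq(2, 2 * n), function(s) {  # walk direction (-1, +1)
      r <- pmin(s - 1, n):max(1, s - n)
      c <- s - r
      window[cbind(r, c)]
    }),
    "135" = lapply(seq(-(n - 1), n - 1), function(dlt) {  # walk (-1, -1)
      r <- if (dlt >= 0) (n):(1 + dlt) else (n + dlt):1
      c <- r - dlt
      window[cbind(r, c)]
    }))
  runs <- do.call(rbind, lapply(lines, function(v) {
    r <- rle(v); cbind(gray = r$values, len = r$lengths)
  }))
  nr <- nrow(runs)
  gl <- table(runs[, "gray"])
  ln <- table(runs[, "len"])
  c(sre = sum(1 / runs[, "len"]^2) / nr,
    lre = sum(runs[, "len"]^2) / nr,
    gln = sum(gl^2) / nr,
    rln = sum(ln^2) / nr,
    rp = nr / length(window))
}

# literal 2-level Haar with edge replication, written recursively
oracle_haar_features <- function(window, levels = 2) {
  haar1d <- function(v) {
    if (length(v) %% 2 == 1) v <- c(v, v[length(v)])
    lo <- hi <- numeric(length(v) / 2)
    for (k in seq_along(lo)) {
      lo[k] <- (v[2 * k - 1] + v[2 * k]) / sqrt(2)
      hi[k] <- (v[2 * k - 1] - v[2 * k]) / sqrt(2)
    }
    list(lo = lo, hi = hi)
  }
  decomp <- function(m) {
    nr <- nrow(m)
    lo_rows <- NULL; hi_rows <- NULL
    for (c in seq_len(ncol(m))) {
      s <- haar1d(m[, c])
      lo_rows <- cbind(lo_rows, s$lo); hi_rows <- cbind(hi_rows, s$hi)
    }
    ll <- lh <- hl <- hh <- NULL
    for (r in seq_len(nrow(lo_rows))) {
      s <- haar1d(lo_rows[r, ]); ll <- rbind(ll, s$lo); lh <- rbind(lh, s$hi)
    }
    for (r in seq_len(nrow(hi_rows))) {
      s <- haar1d(hi_rows[r, ]); hl <- rbind(hl, s$lo); hh <- rbind(hh, s$hi)
    }
    list(ll = ll, dv = hl, dh = lh, dd = hh)
  }
  out <- c()
  cur <- window
  for (l in seq_len(levels)) {
    d <- decomp(cur)
    for (b in c("dv", "dh", "dd")) {
      out[paste0("wav_l", l, "_", b, "_meanabs")] <- mean(abs(d[[b]]))
      out[paste0("wav_l", l, "_", b, "_energy")] <- sum(d[[b]]^2)
    }
    cur <- d$ll
  }
  out["wav_approx_meanabs"] <- mean(abs(cur))
  out["wav_approx_energy"] <- sum(cur^2)
  out
}

# exact upper-tail hypergeometric by enumerating every DE-set draw from the
# background
oracle_hyper_p <- function(background, term_genes, de_size, k_obs) {
  subsets <- combn(length(background), de_size)
  hits <- 0
  for (b in seq_len(ncol(subsets))) {
    overlap <- sum(background[subsets[, b]] %in% term_genes)
    if (overlap >= k_obs) hits <- hits + 1
  }
  hits / ncol(subsets)
}

# stationary Gauss-Markov random field on a torus via its spectral density
simulate_gmrf <- function(n, theta, sigma = 1, seed = 1) {
  set.seed(seed)
  w1 <- 2 * pi * (0:(n - 1)) / n
  W1 <- matrix(w1, n, n)          # row frequency
  W2 <- t(W1)                     # column frequency
  denom <- 1 - 2 * theta[1] * cos(W2) - 2 * theta[2] * cos(W1) -
    2 * theta[3] * cos(W1 + W2) - 2 * theta[4] * cos(W1 - W2)
  stopifnot(all(denom > 0))
  S <- sigma^2 / denom
  z <- matrix(rnorm(n * n), n, n)
  Re(fft(fft(z) * sqrt(S), inverse = TRUE)) / (n * n)
}

rand_window <- function(win = 9, levels = 8) {
  matrix(sample.int(levels, win * win, replace = TRUE) - 1L, win, win)
}
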