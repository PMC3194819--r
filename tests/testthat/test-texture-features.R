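checkerboard <- function(n = 9) {
  matrix(as.integer((row(diag(n)) + col(diag(n))) %% 2), n, n)
}

test_that("preprocessing is affine invariant and denoises salt-and-pepper", {
  tex <- generate_texture(texture_spec(height = 60, width = 60, border = 8,
                                       seed = 2))
  p1 <- preprocess_image(tex$image)
  p2 <- preprocess_image(tex$image + 0.3)
  expect_equal(p1$image, p2$image, tolerance = 1e-12)
  expect_identical(p1$mask, p2$mask)
  expect_error(preprocess_image(matrix(1, 10, 10)), "constant|foreground")
  expect_error(preprocess_image(matrix(c(1, NA), 4, 4)), "finite")
  # salt-and-pepper corruption: median filter halves the MSE to the clean image
  clean <- generate_texture(texture_spec(
    height = 64, width = 64,
    classes = data.frame(class = 1:2, frequency = 0.15, orientation = c(0, 90),
                         contrast = 0.6, noise_sd = 0), seed = 3))$image
  set.seed(9)
  corrupt <- clean
  idx <- sample(length(corrupt), round(0.05 * length(corrupt)))
  corrupt[idx] <- sample(c(0, 1), length(idx), replace = TRUE)
  filtered <- median_filter(corrupt)
  expect_lt(mean((filtered - clean)^2), 0.5 * mean((corrupt - clean)^2))
})

test_that("quantization bins equally, caps range and is idempotent", {
  two <- matrix(c(0.2, 0.8), 4, 4)
  expect_setequal(unique(as.vector(quantize_image(two, 2))), c(0L, 1L))
  ramp <- matrix(seq(0, 1, length.out = 64), 8, 8)
  q4 <- quantize_image(ramp, 4)
  expect_true(all(abs(tabulate(as.vector(q4) + 1, 4) - 16) <= 1))
  q64 <- quantize_image(ramp, 64)
  expect_identical(quantize_image(q64 + 0, 64), q64)
  expect_error(quantize_image(ramp, 1), "levels")
  expect_true(all(quantize_image(matrix(5, 3, 3), 8) == 0L))
})

test_that("co-occurrence features match closed forms and the literal oracle", {
  const <- matrix(3L, 9, 9)
  g <- glcm_features(const)
  gm <- g[g$angle == "mean" & g$distance == 1, ]
  expect_equal(gm$energy, 1)
  expect_equal(gm$contrast, 0)
  expect_equal(gm$entropy, 0)
  expect_equal(gm$homogeneity, 1)
  cb <- checkerboard(9)
  g0 <- glcm_features(cb)
  h <- g0[g0$angle == "0" & g0$distance == 1, ]
  expect_equal(h$contrast, 1)  # every horizontal pair differs by one level
  expect_equal(h$energy, 0.5)
  set.seed(21)
  for (rep in 1:100) {
    w <- rand_window(9, sample(c(4, 8, 16), 1))
    d <- sample(1:3, 1)
    got <- glcm_features(w, distances = d)
    for (a in c("0", "45", "90", "135")) {
      expect_equal(unlist(got[got$angle == a, -(1:2)]),
                   oracle_glcm(w, d, as.integer(a)), tolerance = 1e-10,
                   ignore_attr = TRUE)
    }
  }
})

test_that("run-length features match direct enumeration", {
  const <- matrix(2L, 9, 9)
  r <- rlm_features(const)
  h <- r[r$direction == "0", ]
  expect_equal(h$rp, 9 / 81)    # nine runs of length nine
  expect_equal(h$lre, 81)
  cb <- checkerboard(9)
  rc <- rlm_features(cb)
  expect_equal(rc$sre[rc$direction == "0"], 1)  # all 81 runs have length 1
  expect_equal(rc$rp[rc$direction == "0"], 1)
  set.seed(22)
  for (rep in 1:100) {
    w <- rand_window(9, sample(c(3, 6), 1))
    got <- rlm_features(w)
    for (a in c("0", "45", "90", "135")) {
      expect_equal(unlist(got[got$direction == a, -1]),
                   oracle_rlm(w, as.integer(a)), tolerance = 1e-10,
                   ignore_attr = TRUE)
    }
  }
})

test_that("wavelet subband statistics match a literal Haar transform", {
  const <- matrix(4, 9, 9)
  wf <- wavelet_features(const)
  detail <- wf[grepl("_d[vhd]_", names(wf))]
  expect_true(all(detail == 0))
  # horizontal step edge excites the vertical detail band
  step <- matrix(0, 8, 8); step[2:8, ] <- 1  # edge off the dyadic boundary
  sf <- wavelet_features(step)
  expect_gt(sf["wav_l1_dv_energy"] + sf["wav_l2_dv_energy"],
            sf["wav_l1_dh_energy"] + sf["wav_l2_dh_energy"])
  # Parseval at even sizes (orthonormal transform)
  set.seed(31)
  w8 <- matrix(rnorm(64), 8, 8)
  f8 <- wavelet_features(w8)
  expect_equal(sum(f8[grepl("_energy$", names(f8)) &
                      !grepl("approx", names(f8))]) + f8[["wav_approx_energy"]],
               sum(w8^2), tolerance = 1e-10)
  for (rep in 1:50) {
    w <- matrix(rnorm(81), 9, 9)
    expect_equal(wavelet_features(w), oracle_haar_features(w),
                 tolerance = 1e-10)
  }
})

test_that("fractal dimension is 2 for flat surfaces and offset invariant", {
  expect_equal(unname(fractal_dimension(matrix(7.5, 9, 9))["fd"]), 2,
               tolerance = 1e-12)
  set.seed(41)
  w <- matrix(runif(81), 9, 9)
  fd <- unname(fractal_dimension(w)["fd"])
  expect_gt(fd, 2)
  expect_lte(fd, 3.2)  # rough surfaces head towards (2, 3]
  expect_equal(fractal_dimension(w + 10), fractal_dimension(w),
               tolerance = 1e-10)
  expect_error(fractal_dimension(matrix(1, 4, 4)), "scales|>= 8")
})

test_that("Markov random field parameters recover a known field", {
  const <- mrf_features(matrix(1, 9, 9), order = 2)
  expect_true(attr(const, "degenerate"))
  expect_equal(unname(const), rep(0, 5), ignore_attr = TRUE)
  theta <- c(0.15, 0.1, 0.05, 0.05)
  f <- simulate_gmrf(129, theta, seed = 4)
  est <- mrf_features(f, order = 2)
  expect_equal(unname(est[1:4]), theta, tolerance = 0.05)
  # horizontal bands: left/right neighbours equal the pixel exactly, so the
  # horizontal parameter dominates the vertical one
  bands <- outer(rep(c(0, 0, 1, 1), length.out = 9), rep(1, 9))
  set.seed(5)
  est1 <- mrf_features(bands + matrix(rnorm(81, sd = 0.01), 9), order = 1)
  expect_gt(abs(est1["theta_h"]), abs(est1["theta_v"]))
})

test_that("Gabor responses are zero-DC, frequency tuned and rotate cleanly", {
  g <- gabor_features(matrix(3, 9, 9))
  expect_true(all(abs(g) < 1e-10))
  # grating matched to one bank filter maximizes that filter's response
  grid <- outer(rep(1, 32), 1:32)
  grating <- sin(2 * pi * 0.25 * grid)  # vertical stripes, frequency 0.25
  gf <- gabor_features(grating[1:9, 1:9],
                       frequencies = c(0.15, 0.25, 0.35))
  means <- gf[grepl("meanabs", names(gf))]
  expect_equal(names(which.max(means)), "gabor_f0.25_o0_meanabs")
  # rotating the window by 90 degrees permutes the orientation features
  w <- generate_texture(texture_spec(height = 9, width = 9, seed = 6))$image
  a <- gabor_features(w)
  b <- gabor_features(t(w)[, 9:1])  # 90-degree rotation
  for (f in c(0.15, 0.25, 0.35)) {
    expect_equal(unname(a[sprintf("gabor_f%g_o0_meanabs", f)]),
                 unname(b[sprintf("gabor_f%g_o90_meanabs", f)]),
                 tolerance = 1e-8)
  }
})
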