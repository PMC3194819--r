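make_expr <- function(values, genes = NULL) {
  m <- matrix(values, nrow = length(values) / 6, byrow = TRUE)
  rownames(m) <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("flag filtering keeps genes with at most one flagged array", {
  x <- matrix(rnorm(10), 5, 2, dimnames = list(letters[1:5], c("s1", "s2")))
  kept <- filter_flags(x, flags = c(0, 1, 1, 2, 3))
  expect_equal(rownames(kept), c("a", "b", "c"))
  expect_error(filter_flags(x, flags = rep(5, 5)), "all genes")
})

test_that("loess normalization is a no-op on identical samples and removes offsets", {
  set.seed(1)
  base <- rnorm(300, 8, 2)
  x <- cbind(s1 = base, s2 = base, s3 = base)
  expect_equal(normalize_lowess(x), x, tolerance = 1e-10)
  # constant offset on one sample is removed
  x2 <- cbind(s1 = base, s2 = base + 0.8, s3 = base)
  n2 <- normalize_lowess(x2)
  expect_lt(abs(mean(n2[, 2] - base)), 0.05)
  # monotone nonlinear distortion: MA-trend flattened
  x3 <- cbind(s1 = base, s2 = base + 0.05 * (base - 8)^2, s3 = base)
  n3 <- normalize_lowess(x3)
  m <- n3[, 2] - base; a <- (n3[, 2] + base) / 2
  expect_lt(abs(coef(lm(m ~ a))[2]), 0.03)
  expect_error(normalize_lowess(cbind(rep(1, 5), rnorm(5))), "constant")
})

test_that("the d statistic matches its closed form", {
  x <- make_expr(c(1, 2, 3, 7, 8, 9,
                   4, 4, 4, 4, 4, 4))
  groups <- rep(c("FS", "NFS"), each = 3)
  fit <- sam_two_class(x, groups, s0 = 0, seed = 1)
  tab <- tidy(fit)
  # pooled SE = sqrt((1/3 + 1/3) * ((2 + 2)/4)) = sqrt(2/3)
  expect_equal(tab$d[tab$gene == "g01"], -6 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(tab$d[tab$gene == "g02"], 0)
  expect_equal(tab$fold[tab$gene == "g01"], 2^-6)
})

test_that("q-values match the exhaustive-permutation brute-force oracle", {
  for (n1 in c(3, 4)) {
    set.seed(n1 * 10)
    n <- 2 * n1
    p <- 30
    x <- matrix(rnorm(p * n), p, n,
                dimnames = list(sprintf("g%02d", 1:p), sprintf("s%d", 1:n)))
    x[1:4, 1:n1] <- x[1:4, 1:n1] + 2.5
    groups <- rep(c("FS", "NFS"), each = n1)
    fit <- sam_two_class(x, groups, s0 = 0.2, seed = 1)
    expect_true(fit$exhaustive)
    expect_equal(fit$n_perm, choose(n, n1))
    q_oracle <- oracle_sam_q(x, groups, c("FS", "NFS"), s0 = 0.2)
    got <- setNames(fit$table$q, fit$table$gene)[names(q_oracle)]
    expect_equal(got, q_oracle, tolerance = 1e-12)
  }
})

test_that("s0 selection stabilizes d across standard-error windows", {
  # all-equal standard errors: every percentile is that value
  expect_equal(choose_s0(rnorm(100), rep(0.7, 100)), 0.7)
  # tiny inputs fall back to the median
  expect_equal(choose_s0(1:5, c(1, 2, 3, 4, 5)), 3)
  expect_error(choose_s0(1:20, rep(0, 20)), "zero")
  # two-scale standard errors: the chosen s0 beats s0 = 0 on the
  # window-CV criterion evaluated independently
  set.seed(3)
  s <- c(runif(150, 0.01, 0.05), runif(150, 0.5, 1))
  r <- rnorm(300, 0, s + 0.3)
  s0 <- choose_s0(r, s)
  cv_at <- function(s0v) {
    d <- r / (s + s0v)
    win <- cut(rank(s, ties.method = "first"), 10, labels = FALSE)
    mads <- tapply(d, win, mad)
    sd(mads) / mean(mads)
  }
  expect_lt(cv_at(s0), cv_at(0))
})

test_that("a null experiment keeps the realized FDR near the target", {
  set.seed(11)
  fdrs <- replicate(30, {
    sim <- generate_expression(expression_spec(
      n_genes = 200, n_de = 0, n_hub_blocks = 0, block_size = 0,
      seed = sample.int(1e6, 1)))
    fit <- sam_two_class(sim$expression, sim$groups$group, n_perm = 100,
                         seed = sample.int(1e6, 1))
    n_called <- sum(fit$table$called)
    n_called / max(1, n_called)  # every call is false under the null
  })
  expect_lte(median(fdrs), 0.05 + 0.05)
})

test_that("fold gate is inclusive at the boundary and monotone", {
  tab <- tibble::tibble(
    gene = c("a", "b", "c", "d"),
    d = c(5, 5, 5, -5), dbar = 0,
    fold = c(2.9, 3.0, 6, 0.2), q = c(0.01, 0.01, 0.2, 0.01),
    called = TRUE)
  fit <- structure(list(table = tab, target_fdr = 0.05), class = "sam_fit")
  expect_equal(select_de(fit), "b")                      # 2.9 out, 3.0 in
  expect_equal(select_de(fit, min_fold = 1), c("a", "b"))
  expect_equal(select_de(fit, min_fold = 1, direction = "down"), "d")
  # raising min_fold never adds genes
  sets <- lapply(c(1, 2, 3, 5), function(mf) select_de(fit, min_fold = mf))
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("planted fourfold genes are recovered at 5% FDR", {
  sim <- generate_expression(expression_spec(seed = 11))  # 50 of 1000 at 4x
  fit <- sam_two_class(sim$expression, sim$groups$group, seed = 11)
  de <- select_de(fit, min_fold = 3)
  expect_gte(mean(sim$truth$de_genes %in% de), 0.9)
})

test_that("hierarchical clustering follows 1 - r with complete linkage", {
  prof <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4),
                c = c(4, 3, 2, 1), d = c(1, 3, 2, 4))
  hc <- cluster_expression(prof)
  # duplicated profiles merge at height 0
  expect_equal(min(hc$height), 0)
  # anti-correlated pair sits at distance 2
  cc <- cor(t(prof))
  expect_equal(1 - cc["a", "c"], 2)
  # merge heights equal hand-computed complete linkage on 1 - r
  d <- 1 - cc
  expect_equal(max(hc$height), max(d))
  # gene-order permutation leaves heights unchanged
  hc2 <- cluster_expression(prof[c(3, 1, 4, 2), ])
  expect_equal(hc$height, hc2$height)
  expect_warning(cluster_expression(rbind(a = rep(1, 4), prof)), "zero-variance")
})
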