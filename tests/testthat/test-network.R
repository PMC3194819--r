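test_that("Spearman matrix equals the rank-then-Pearson oracle, ties included", {
  set.seed(5)
  for (rep in 1:30) {
    n <- sample(3:8, 1)
    x <- rbind(a = sample(1:4, n, replace = TRUE) + 0,
               b = sample(1:4, n, replace = TRUE) + 0,
               c = rnorm(n))
    colnames(x) <- sprintf("s%d", 1:n)
    skip_degenerate <- any(apply(x, 1, function(v) length(unique(v)) == 1))
    if (skip_degenerate) next
    rho <- spearman_matrix(x)
    for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
      expect_equal(rho[pair[1], pair[2]],
                   oracle_spearman(x[pair[1], ], x[pair[2], ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("monotone and tied profiles give the expected rho", {
  x <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(6, 4, 2))
  colnames(x) <- c("s1", "s2", "s3")
  rho <- spearman_matrix(x)
  expect_equal(rho["a", "b"], 1)
  expect_equal(rho["a", "c"], -1)
  y <- rbind(a = c(1, 2, 2, 4), b = c(1, 3, 3, 5))
  colnames(y) <- sprintf("s%d", 1:4)
  expect_equal(spearman_matrix(y)["a", "b"], 1)  # midranks align exactly
  z <- rbind(a = c(1, 1, 1), b = c(1, 2, 3))
  colnames(z) <- c("s1", "s2", "s3")
  expect_warning(rz <- spearman_matrix(z), "constant")
  expect_true(is.na(rz["a", "b"]))
})

toy_rho <- function() {
  rho <- diag(3)
  rho[1, 2] <- rho[2, 1] <- 0.9
  rho[1, 3] <- rho[3, 1] <- 0.5
  rho[2, 3] <- rho[3, 2] <- 0.2
  dimnames(rho) <- list(c("a", "b", "c"), c("a", "b", "c"))
  rho
}

test_that("threshold intervals gate edges as stated", {
  rho <- toy_rho()
  expect_equal(nrow(threshold_network(rho, 0.85, 1)$edges), 1)   # FS interval
  expect_equal(nrow(threshold_network(rho, 0.14, 0.70)$edges), 2)  # NFS band
  full <- threshold_network(rho, 0, 1, absolute = TRUE)
  expect_equal(nrow(full$edges), 3)
  expect_error(threshold_network(rho, 0.9, 0.1), "lo")
  # widening the interval never removes edges
  e1 <- threshold_network(rho, 0.3, 0.7)$edges
  e2 <- threshold_network(rho, 0.1, 0.95)$edges
  expect_true(all(paste(e1$from, e1$to) %in% paste(e2$from, e2$to)))
})

test_that("degrees and ranks follow the edge list", {
  # star: hub correlated with 9 leaves, leaves mutually uncorrelated
  n <- 10
  rho <- diag(n)
  rho[1, 2:n] <- rho[2:n, 1] <- 0.95
  dimnames(rho) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  net <- threshold_network(rho, 0.85, 1)
  hubs <- hub_degrees(net)
  expect_equal(hubs$degree[hubs$gene == "g01"], 9)
  expect_equal(sort(unique(hubs$degree[hubs$gene != "g01"])), 1)
  expect_equal(hubs$rank, 1:10)
  # degree sum = 2 x edges
  expect_equal(sum(hubs$degree), 2 * nrow(net$edges))
  empty <- threshold_network(toy_rho(), 0.99, 1)
  expect_equal(sum(hub_degrees(empty)$degree), 0)
})

test_that("link histogram bins are right-closed and conserve pair counts", {
  rho <- diag(4)
  rho[upper.tri(rho)] <- rho[lower.tri(rho)] <- 0.95
  h <- link_histogram(rho)
  expect_equal(sum(h$count), choose(4, 2))
  expect_equal(h$count[h$bin_lo == 0.9], choose(4, 2))
  # right-closed: a value exactly at an edge falls in the lower bin
  rho2 <- diag(3)
  rho2[upper.tri(rho2)] <- rho2[lower.tri(rho2)] <- 0.2
  h2 <- link_histogram(rho2)
  expect_equal(h2$count[h2$bin_lo == 0.1], 3)
  # approximately uniform rho spreads evenly over bins
  set.seed(8)
  n <- 80
  vals <- matrix(0, n, n)
  vals[upper.tri(vals)] <- runif(choose(n, 2))
  vals <- vals + t(vals); diag(vals) <- 1
  h3 <- link_histogram(vals)
  expect_equal(sum(h3$count), choose(n, 2))
  expect_true(all(abs(h3$count - choose(n, 2) / 10) < 5 * sqrt(choose(n, 2) / 10)))
})

test_that("planted hub blocks occupy the top degrees of the FS network", {
  hits <- sapply(1:10, function(s) {
    sim <- generate_expression(expression_spec(n_genes = 200, n_fs = 50,
                                               n_nfs = 4, n_de = 50,
                                               block_size = 10, seed = s))
    fs <- sim$groups$sample[sim$groups$group == "FS"]
    rho <- spearman_matrix(sim$expression, genes = sim$truth$de_genes,
                           samples = fs)
    net <- threshold_network(rho, 0.85, 1)
    hubs <- hub_degrees(net)
    all(sim$truth$hub_genes %in% hubs$gene[1:10])
  })
  expect_gte(mean(hits), 0.9)
})

test_that("exports round-trip and follow the SIF dialect", {
  rho <- toy_rho()
  net <- threshold_network(rho, 0.85, 1)
  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  lines <- readLines(sif)
  expect_equal(lines[1], "a co b")
  expect_true("c" %in% lines)  # isolated node listed as a singleton
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  back <- read_network_graphml(gml)
  expect_setequal(back$nodes, net$nodes)
  expect_equal(nrow(back$edges), nrow(net$edges))
  expect_equal(sort(back$edges$rho), sort(net$edges$rho))
  expect_error(export_network(net, tempfile(), "xlsx"), "format|arg")
})
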