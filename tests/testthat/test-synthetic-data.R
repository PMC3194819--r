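test_that("expression generator honors its dimension contract and seed", {
  sim <- generate_expression(expression_spec(n_genes = 100, n_fs = 6,
                                             n_nfs = 12, n_de = 10,
                                             block_size = 5, seed = 1))
  expect_equal(dim(sim$expression), c(100, 18))
  expect_equal(sum(sim$groups$group == "FS"), 6)
  expect_length(sim$truth$de_genes, 10)
  expect_true(all(sim$truth$hub_genes %in% sim$truth$de_genes))
  sim2 <- generate_expression(expression_spec(n_genes = 100, n_fs = 6,
                                              n_nfs = 12, n_de = 10,
                                              block_size = 5, seed = 1))
  expect_identical(sim$expression, sim2$expression)
  expect_error(expression_spec(n_genes = 10, n_de = 20), "n_de")
  expect_error(expression_spec(fold = 0.5), "fold")
  expect_error(expression_spec(n_de = 5, block_size = 10), "hub-block")
})

test_that("noise-free generation recovers the planted fold exactly", {
  # hub-block genes included: the centred latent factor must leave the
  # planted group-mean difference untouched
  spec <- expression_spec(n_genes = 50, n_de = 10, fold = 3, noise_sd = 0,
                          n_hub_blocks = 1, block_size = 5, seed = 2)
  sim <- generate_expression(spec)
  fs <- sim$groups$sample[sim$groups$group == "FS"]
  nfs <- sim$groups$sample[sim$groups$group == "NFS"]
  lfc <- rowMeans(sim$expression[, fs]) - rowMeans(sim$expression[, nfs])
  expect_equal(unname(2^lfc[sim$truth$de_genes]), rep(3, 10), tolerance = 1e-12)
  others <- setdiff(rownames(sim$expression), sim$truth$de_genes)
  expect_equal(unname(2^lfc[others]), rep(1, 40), tolerance = 1e-12)
})

test_that("hub blocks reach high within-block Spearman correlation", {
  # Monte-Carlo check of the latent-factor model at large sample count
  rhos <- sapply(1:5, function(s) {
    sim <- generate_expression(expression_spec(n_genes = 60, n_fs = 50,
                                               n_nfs = 4, n_de = 12,
                                               block_size = 10, seed = s))
    fs <- sim$groups$sample[sim$groups$group == "FS"]
    rho <- spearman_matrix(sim$expression, genes = sim$truth$hub_genes,
                           samples = fs)
    mean(rho[upper.tri(rho)])
  })
  expect_true(all(rhos > 0.85))
})

test_that("texture generator produces the stated classes deterministically", {
  tex <- generate_texture(texture_spec(height = 128, width = 128, seed = 3))
  expect_setequal(unique(as.vector(tex$labels)), c(1L, 2L))
  expect_true(all(is.finite(tex$image)))
  expect_true(all(tex$image >= 0 & tex$image <= 1))
  tex2 <- generate_texture(texture_spec(height = 128, width = 128, seed = 3))
  expect_identical(tex$image, tex2$image)
  # zero contrast and zero noise collapse to a constant image
  flat <- generate_texture(texture_spec(
    height = 16, width = 16,
    classes = data.frame(class = 1:2, frequency = 0.2, orientation = c(0, 90),
                         contrast = 0, noise_sd = 0), seed = 1))
  expect_equal(unique(as.vector(flat$image)), 0.5)
  expect_error(texture_spec(height = 1, width = 8), "height")
})

test_that("annotation generator plants covered terms and is seed-stable", {
  genes <- sprintf("g%03d", 1:60)
  de <- genes[1:20]
  ann <- generate_annotation(genes, n_terms = 10, genes_per_term = 8,
                             planted_terms = 2, de_genes = de, seed = 4)
  for (t in ann$planted_term_ids) {
    members <- ann$annotation$gene[ann$annotation$term == t]
    expect_equal(sum(members %in% de), 8)  # fully covered by the DE set
  }
  ann2 <- generate_annotation(genes, n_terms = 10, genes_per_term = 8,
                              planted_terms = 2, de_genes = de, seed = 4)
  expect_identical(ann$annotation, ann2$annotation)
  expect_error(generate_annotation(genes, genes_per_term = 100), "exceeds")
})

test_that("unplanted term overlaps follow the hypergeometric law", {
  # chi-square goodness of fit of overlap counts across many seeds
  genes <- sprintf("g%03d", 1:40)
  de <- genes[1:10]
  K <- 8
  overlaps <- sapply(1:300, function(s) {
    ann <- generate_annotation(genes, n_terms = 1, genes_per_term = K,
                               planted_terms = 0, seed = s)
    sum(ann$annotation$gene %in% de)
  })
  probs <- dhyper(0:K, length(de), length(genes) - length(de), K)
  obs <- tabulate(overlaps + 1, K + 1)
  # pool tail cells with small expectation
  keep <- probs * 300 >= 5
  obs_p <- c(obs[keep], sum(obs[!keep]))
  exp_p <- c(probs[keep], sum(probs[!keep])) * 300
  chi2 <- sum((obs_p - exp_p)^2 / exp_p)
  expect_lt(chi2, qchisq(0.999, df = length(obs_p) - 1))
})

test_that("qPCR generator spaces perfect-efficiency dilutions by 3.32 cycles", {
  q <- tibble::tibble(sample = "s1", gene = "NELL1", group = "FS", quantity = 1)
  tab <- generate_qpcr(q, efficiency = 2, noise_sd = 0, seed = 1)
  std <- tab[tab$is_standard & tab$replicate == 1, ]
  spacing <- diff(std$ct[order(-std$quantity)])
  expect_equal(spacing, rep(1 / log10(2), length(spacing)), tolerance = 1e-10)
  tab2 <- generate_qpcr(q, efficiency = 2, noise_sd = 0, seed = 99)
  expect_equal(tab$ct, tab2$ct)  # noise-free: seed-independent
  tabn <- generate_qpcr(q, noise_sd = 0.2, seed = 5)
  tabn2 <- generate_qpcr(q, noise_sd = 0.2, seed = 5)
  expect_identical(tabn, tabn2)
  expect_error(generate_qpcr(dplyr::mutate(q, quantity = -1)), "positive")
  expect_error(generate_qpcr(q, efficiency = 2.5), "efficiency")
})

test_that("expression and annotation writers round-trip", {
  sim <- generate_expression(expression_spec(n_genes = 20, n_de = 2,
                                             n_hub_blocks = 0, seed = 6))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(sim$expression, f)
  back <- read_expression_matrix(f)
  expect_equal(back, sim$expression, tolerance = 1e-12)
  ann <- generate_annotation(rownames(sim$expression), n_terms = 3,
                             genes_per_term = 4, seed = 1)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_annotation(ann$annotation, f2)
  expect_equal(read_annotation(f2), ann$annotation)
})
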