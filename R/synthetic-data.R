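#' Specification for a synthetic two-group expression matrix
#'
#' Describes a log2-scale expression experiment emulating a one-color
#' microarray comparison of FS (febrile-seizure) versus NFS patients:
#' a set of planted differentially expressed (DE) genes up-regulated in FS by
#' a fixed linear fold change, and one or more "hub blocks" of DE genes that
#' share an additive latent factor within the FS samples only, so that their
#' pairwise Spearman correlation is high in the FS co-expression network while
#' the NFS network stays in a lower correlation regime.
#'
#' Defaults mirror the study conditions: 6 FS and 12 NFS samples, planted
#' up-regulation at 4-fold (comfortably past the 3-fold selection gate), and
#' a residual log2 noise standard deviation of 0.5, a typical residual spread
#' for array data.
#'
#' @param n_genes Total number of genes.
#' @param n_fs,n_nfs Samples per group.
#' @param n_de Number of planted DE genes (up-regulated in FS).
#' @param fold Linear-scale fold change (>= 1) planted in the DE genes.
#' @param n_hub_blocks Number of correlated hub blocks.
#' @param block_size Genes per hub block; block genes are drawn from the
#'   planted DE set.
#' @param noise_sd Log2-scale residual standard deviation.
#' @param hub_strength Loading of the shared latent factor added to block
#'   genes in FS samples (log2 units per unit factor).
#' @param seed Integer seed; identical seeds give identical matrices.
#' @return A list of class `expression_spec`.
#' @export
expression_spec <- function(n_genes = 1000, n_fs = 6, n_nfs = 12, n_de = 50,
                            fold = 4, n_hub_blocks = 1, block_size = 10,
                            noise_sd = 0.5, hub_strength = 2, seed = 1) {
  stopifnot(n_genes >= 1, n_fs >= 2, n_nfs >= 2, n_de >= 0, noise_sd >= 0,
            n_hub_blocks >= 0, block_size >= 0, hub_strength >= 0)
  if (fold < 1) stop("fold must be >= 1 (linear scale)", call. = FALSE)
  if (n_de > n_genes) stop("n_de must not exceed n_genes", call. = FALSE)
  if (n_hub_blocks * block_size > n_de) {
    stop("hub-block genes are drawn from the planted DE set: ",
         "n_hub_blocks * block_size must not exceed n_de", call. = FALSE)
  }
  structure(list(n_genes = n_genes, n_fs = n_fs, n_nfs = n_nfs, n_de = n_de,
                 fold = fold, n_hub_blocks = n_hub_blocks,
                 block_size = block_size, noise_sd = noise_sd,
                 hub_strength = hub_strength, seed = seed),
            class = "expression_spec")
}

#' Generate a synthetic two-group expression matrix with known ground truth
#'
#' Draws a log2-scale genes-by-samples matrix according to an
#' [expression_spec()]: per-gene baselines, independent Gaussian noise,
#' a planted `log2(fold)` mean shift in FS samples for the DE genes, and a
#' shared per-sample latent factor added to each hub block's genes within the
#' FS samples.
#'
#' @param spec An [expression_spec()].
#' @return A list with components `expression` (numeric matrix, genes x
#'   samples), `groups` (tibble with `sample`, `group`), and `truth` (list
#'   with `de_genes`, `hub_genes`, `hub_blocks`).
#' @examples
#' sim <- generate_expression(expression_spec(n_genes = 100, seed = 42))
#' dim(sim$expression)
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "expression_spec"))
  check_seed(spec$seed)
  p <- spec$n_genes
  n <- spec$n_fs + spec$n_nfs
  genes <- sprintf("g%04d", seq_len(p))
  samples <- c(sprintf("FS%02d", seq_len(spec$n_fs)),
               sprintf("NFS%02d", seq_len(spec$n_nfs)))
  group <- rep(c("FS", "NFS"), c(spec$n_fs, spec$n_nfs))

  baseline <- rnorm(p, mean = 8, sd = 1.5)
  x <- matrix(rnorm(p * n, sd = spec$noise_sd), p, n) + baseline
  de_idx <- if (spec$n_de > 0) sort(sample.int(p, spec$n_de)) else integer(0)
  if (length(de_idx)) {
    x[de_idx, group == "FS"] <- x[de_idx, group == "FS"] + log2(spec$fold)
  }
  hub_blocks <- list()
  if (spec$n_hub_blocks > 0 && spec$block_size > 0) {
    pool <- de_idx
    for (b in seq_len(spec$n_hub_blocks)) {
      blk <- pool[seq_len(spec$block_size)]
      pool <- setdiff(pool, blk)
      # centred across the FS samples: the factor induces co-variation
      # without disturbing the planted group-mean difference
      f <- rnorm(spec$n_fs)
      f <- f - mean(f)
      x[blk, group == "FS"] <- x[blk, group == "FS"] +
        spec$hub_strength * matrix(f, length(blk), spec$n_fs, byrow = TRUE)
      hub_blocks[[b]] <- genes[blk]
    }
  }
  dimnames(x) <- list(genes, samples)
  list(
    expression = x,
    groups = tibble::tibble(sample = samples, group = group),
    truth = list(de_genes = genes[de_idx],
                 hub_genes = unlist(hub_blocks) %||% character(0),
                 hub_blocks = hub_blocks)
  )
}

#' Specification for a synthetic two-class texture image
#'
#' Each class region is an oriented sinusoidal grating plus Gaussian noise;
#' the classes differ in second-order statistics (orientation, spatial
#' frequency, contrast) while sharing the same mean intensity, which is the
#' regime a texture (rather than intensity) classifier must resolve. A dark
#' border emulates the image background that the preprocessing stage
#' segments away.
#'
#' @param height,width Texture region size in pixels.
#' @param classes Data frame with one row per class and columns `frequency`
#'   (cycles/pixel), `orientation` (degrees), `contrast` (peak-to-peak, in
#'   [0,1]) and `noise_sd`.
#' @param layout `"vsplit"` (left/right halves) or `"hsplit"`.
#' @param border Width in pixels of the dark background frame around the
#'   texture (intensity ~0.02).
#' @param seed Integer seed.
#' @return A list of class `texture_spec`.
#' @export
texture_spec <- function(height = 128, width = 128,
                         classes = data.frame(
                           class = c(1L, 2L),
                           frequency = c(0.2, 0.2),
                           orientation = c(0, 90),
                           contrast = c(0.5, 0.5),
                           noise_sd = c(0.05, 0.05)),
                         layout = c("vsplit", "hsplit"),
                         border = 0, seed = 1) {
  layout <- match.arg(layout)
  stopifnot(height >= 2, width >= 2, nrow(classes) == 2, border >= 0,
            all(classes$contrast >= 0), all(classes$noise_sd >= 0))
  structure(list(height = height, width = width, classes = classes,
                 layout = layout, border = border, seed = seed),
            class = "texture_spec")
}

#' Generate a synthetic two-class texture image with per-pixel labels
#'
#' @param spec A [texture_spec()].
#' @return A list with `image` (numeric matrix in [0,1], including any dark
#'   border), `labels` (integer matrix, 0 = background/unlabelled, 1/2 =
#'   class), and `mask` (logical matrix marking the texture region).
#' @examples
#' tex <- generate_texture(texture_spec(height = 32, width = 32, seed = 7))
#' table(tex$labels)
#' @export
generate_texture <- function(spec) {
  stopifnot(inherits(spec, "texture_spec"))
  check_seed(spec$seed)
  h <- spec$height; w <- spec$width
  lab <- matrix(0L, h, w)
  if (spec$layout == "vsplit") {
    half <- floor(w / 2)
    if (half < 1 || w - half < 1) stop("zero-area class region", call. = FALSE)
    lab[, seq_len(half)] <- 1L
    lab[, (half + 1):w] <- 2L
  } else {
    half <- floor(h / 2)
    if (half < 1 || h - half < 1) stop("zero-area class region", call. = FALSE)
    lab[seq_len(half), ] <- 1L
    lab[(half + 1):h, ] <- 2L
  }
  rowg <- matrix(seq_len(h), h, w)
  colg <- matrix(seq_len(w), h, w, byrow = TRUE)
  img <- matrix(0.5, h, w)
  for (k in seq_len(nrow(spec$classes))) {
    cl <- spec$classes[k, ]
    sel <- lab == cl$class
    theta <- cl$orientation * pi / 180
    phase <- 2 * pi * cl$frequency * (colg * cos(theta) + rowg * sin(theta))
    img[sel] <- 0.5 + cl$contrast / 2 * sin(phase[sel]) +
      rnorm(sum(sel), sd = cl$noise_sd)
  }
  img <- pmin(pmax(img, 0), 1)
  if (spec$border > 0) {
    b <- spec$border
    full <- matrix(0.02, h + 2 * b, w + 2 * b)
    full[b + seq_len(h), b + seq_len(w)] <- pmin(pmax(img, 0.15), 1)
    labf <- matrix(0L, h + 2 * b, w + 2 * b)
    labf[b + seq_len(h), b + seq_len(w)] <- lab
    img <- full; lab <- labf
  }
  list(image = img, labels = lab, mask = lab > 0L)
}

#' Generate a synthetic gene-to-GO-term annotation with planted enriched terms
#'
#' The first `planted_terms` terms draw their member genes from the supplied
#' DE set (so they are strongly overrepresented among DE genes); all other
#' terms draw members uniformly from the full gene universe.
#'
#' @param genes Character vector of gene ids (the annotation universe).
#' @param n_terms Number of GO terms.
#' @param genes_per_term Members per term.
#' @param planted_terms Number of terms planted inside the DE set.
#' @param de_genes Character vector of DE gene ids (required when
#'   `planted_terms > 0`).
#' @param seed Integer seed.
#' @return A list with `annotation` (tibble `gene`, `term`) and
#'   `planted_term_ids`.
#' @export
generate_annotation <- function(genes, n_terms = 50, genes_per_term = 10,
                                planted_terms = 0, de_genes = character(0),
                                seed = 1) {
  stopifnot(length(genes) >= 1, n_terms >= 1, planted_terms >= 0,
            planted_terms <= n_terms)
  if (genes_per_term > length(genes)) {
    stop("genes_per_term exceeds the number of genes", call. = FALSE)
  }
  if (planted_terms > 0 && !length(de_genes)) {
    stop("planted terms require a non-empty de_genes set", call. = FALSE)
  }
  check_seed(seed)
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  members <- lapply(seq_len(n_terms), function(t) {
    if (t <= planted_terms) {
      pool <- intersect(de_genes, genes)
      m <- sample(pool, min(genes_per_term, length(pool)))
      if (length(m) < genes_per_term) {
        m <- c(m, sample(setdiff(genes, m), genes_per_term - length(m)))
      }
      m
    } else {
      sample(genes, genes_per_term)
    }
  })
  ann <- tibble::tibble(
    gene = unlist(members),
    term = rep(terms, vapply(members, length, integer(1)))
  )
  list(annotation = ann,
       planted_term_ids = if (planted_terms > 0) terms[seq_len(planted_terms)]
                          else character(0))
}

#' Generate synthetic qPCR Ct measurements with a dilution standard series
#'
#' Ct values follow the standard-curve model
#' `Ct = intercept - log10(quantity) / log10(efficiency) + noise`,
#' so a perfect-efficiency (2) assay spaces 10-fold dilutions by
#' 1/log10(2) = 3.32 cycles. For every gene a dilution series of standards is
#' emitted alongside the unknown samples, each measured in `replicates`
#' technical replicates.
#'
#' @param quantities Tibble with columns `sample`, `gene`, `group`, and
#'   `quantity` (true relative quantity, > 0) for the unknowns.
#' @param efficiency Amplification efficiency per cycle, in (1, 2].
#' @param intercept Ct at quantity 1.
#' @param noise_sd Standard deviation of Ct noise.
#' @param n_standards Number of dilution points per gene.
#' @param dilution Fold dilution between consecutive standards.
#' @param replicates Technical replicates per measurement.
#' @param seed Integer seed.
#' @return Tibble with columns `sample`, `gene`, `group`, `replicate`, `ct`,
#'   `quantity` (known for standards, NA for unknowns) and `is_standard`.
#' @examples
#' q <- tibble::tibble(sample = c("s1", "s2"), gene = "NELL1",
#'                     group = c("FS", "NFS"), quantity = c(3, 1))
#' generate_qpcr(q, noise_sd = 0, seed = 1)
#' @export
generate_qpcr <- function(quantities, efficiency = 2, intercept = 35,
                          noise_sd = 0.1, n_standards = 5, dilution = 10,
                          replicates = 3, seed = 1) {
  stopifnot(is.data.frame(quantities),
            all(c("sample", "gene", "group", "quantity") %in% names(quantities)))
  if (efficiency <= 1 || efficiency > 2) {
    stop("efficiency must be in (1, 2]", call. = FALSE)
  }
  if (any(quantities$quantity <= 0)) {
    stop("quantities must be positive", call. = FALSE)
  }
  check_seed(seed)
  ct_of <- function(q) intercept - log10(q) / log10(efficiency)
  std_q <- dilution^(-(seq_len(n_standards) - 1))
  rows <- list()
  for (g in unique(quantities$gene)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      sample = rep(sprintf("std_%s_%d", g, seq_len(n_standards)),
                   each = replicates),
      gene = g, group = "standard",
      replicate = rep(seq_len(replicates), n_standards),
      ct = rep(ct_of(std_q), each = replicates) +
        rnorm(n_standards * replicates, sd = noise_sd),
      quantity = rep(std_q, each = replicates),
      is_standard = TRUE)
  }
  rows[[length(rows) + 1]] <- tibble::tibble(
    sample = rep(quantities$sample, each = replicates),
    gene = rep(quantities$gene, each = replicates),
    group = rep(quantities$group, each = replicates),
    replicate = rep(seq_len(replicates), nrow(quantities)),
    ct = rep(ct_of(quantities$quantity), each = replicates) +
      rnorm(nrow(quantities) * replicates, sd = noise_sd),
    quantity = NA_real_,
    is_standard = FALSE)
  dplyr::bind_rows(rows)
}

#' Write an expression matrix as tab-delimited text
#'
#' Genes in rows (first column `gene`), one column per sample.
#' @param x Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-delimited expression matrix written by [write_expression_matrix()]
#' @param path Input path.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write sample group labels as a two-column CSV (`sample`, `group`)
#' @param groups Tibble with `sample` and `group`.
#' @param path Output path.
#' @export
write_group_labels <- function(groups, path) {
  utils::write.csv(groups[, c("sample", "group")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a gene-to-term annotation as two-column TSV (`gene`, `term`)
#' @param annotation Tibble with `gene` and `term`.
#' @param path Output path.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation[, c("gene", "term")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column gene-to-term annotation TSV
#' @param path Input path.
#' @return Tibble with `gene` and `term`.
#' @export
read_annotation <- function(path) {
  tibble::as_tibble(utils::read.delim(path, colClasses = "character"))
}
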