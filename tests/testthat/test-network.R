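# helper: co-expression fixture with two planted blocks of correlated genes
block_counts <- function(seed = 1, n_per_block = 12, n_noise = 16, n_t = 20,
                         n_n = 20, tumor_shift_block1 = 2) {
  withr::with_seed(seed, {
    n_g <- 2 * n_per_block + n_noise
    n_s <- n_t + n_n
    # co-expression latents act in all samples; only block 1 gets a tumor
    # mean shift, so only block 1 is tumor-specific. Six stable highly
    # expressed filler genes dominate the library so CPM scaling does not
    # induce spurious correlation among the noise genes.
    lat1 <- rnorm(n_s); lat2 <- rnorm(n_s)
    logmu <- matrix(runif(n_g, 5, 9), n_g, n_s)
    idx1 <- 1:n_per_block
    idx2 <- n_per_block + 1:n_per_block
    tum <- 1:n_t
    logmu[idx1, ] <- logmu[idx1, ] +
      matrix(1.5 * lat1, n_per_block, n_s, byrow = TRUE)
    logmu[idx1, tum] <- logmu[idx1, tum] + tumor_shift_block1
    logmu[idx2, ] <- logmu[idx2, ] +
      matrix(1.5 * lat2, n_per_block, n_s, byrow = TRUE)
    logmu <- rbind(logmu, matrix(13, 6, n_s))
    counts <- matrix(rnbinom(length(logmu), mu = 2^logmu, size = 20),
                     n_g + 6,
                     dimnames = list(sprintf("G%03d", seq_len(n_g + 6)),
                                     sprintf("S%03d", 1:n_s)))
    samples <- mk_samples(colnames(counts),
                          condition = rep(c("tumor", "normal"), c(n_t, n_n)))
    list(counts = counts, samples = samples, block1 = rownames(counts)[idx1],
         block2 = rownames(counts)[idx2])
  })
}

test_that("correlated blocks are recovered as modules, shifted blocks as tumor-specific", {
  fx <- block_counts(seed = 2)
  mod <- build_coexpression_modules(fx$counts, fx$samples, tau = 0.6,
                                    min_size = 10, cut_height = 0.3)
  expect_length(mod$modules, 2L)
  memb <- mod$membership$module_id[match(c(fx$block1, fx$block2),
                                         mod$membership$gene_id)]
  m1 <- memb[seq_along(fx$block1)]
  m2 <- memb[-seq_along(fx$block1)]
  # each block lands intact in one module, and the blocks are not mixed
  expect_length(unique(m1), 1L)
  expect_length(unique(m2), 1L)
  expect_true(unique(m1) > 0 && unique(m2) > 0)
  expect_false(unique(m1) == unique(m2))
  expect_true(unique(m1) %in% mod$tumor_specific)   # up-shifted in tumor
  expect_false(unique(m2) %in% mod$tumor_specific)  # identical across conditions
})

test_that("independent noise yields no modules of the minimum size", {
  withr::with_seed(5, {
    counts <- matrix(rnbinom(50 * 30, mu = 200, size = 10), 50,
                     dimnames = list(sprintf("G%02d", 1:50), sprintf("S%02d", 1:30)))
  })
  samples <- mk_samples(colnames(counts),
                        condition = rep(c("tumor", "normal"), c(15, 15)))
  mod <- build_coexpression_modules(counts, samples, tau = 0.6, min_size = 10)
  expect_length(mod$modules, 0L)
})

test_that("directed networks follow the substrate-product and PPI-cutoff rules", {
  rx <- tibble::tibble(
    reaction_id = c("r1", "r2"), enzyme_gene = c("A", "B"),
    substrates = list("m1", "m2"), products = list("m2", "m3")
  )
  net <- build_directed_net(rx, "metabolic")
  expect_equal(net$edges, tibble::tibble(from = "A", to = "B"))
  rx_disjoint <- tibble::tibble(
    reaction_id = c("r1", "r2"), enzyme_gene = c("A", "B"),
    substrates = list("m1", "m3"), products = list("m2", "m4")
  )
  expect_equal(nrow(build_directed_net(rx_disjoint, "metabolic")$edges), 0L)

  ppi <- tibble::tibble(gene_a = c("A", "A"), gene_b = c("B", "C"),
                        weight = c(0.7, 0.3))
  pnet <- build_directed_net(ppi, "ppi")
  expect_setequal(paste(pnet$edges$from, pnet$edges$to),
                  c("A B", "B A"))
})

test_that("score_a matches brute-force AUC and formula evaluation on random instances", {
  for (i in 1:50) {
    fx <- block_counts(seed = 100 + i, n_per_block = 6, n_noise = 6,
                       n_t = 10, n_n = 10)
    mod <- build_coexpression_modules(fx$counts, fx$samples, tau = 0.5,
                                      min_size = 4, cut_height = 0.4)
    genes <- rownames(fx$counts)
    withr::with_seed(200 + i, {
      edges <- tibble::tibble(
        from = sample(genes, 30, replace = TRUE),
        to = sample(genes, 30, replace = TRUE)
      )
    })
    edges <- dplyr::distinct(dplyr::filter(edges, .data$from != .data$to))
    net <- structure(list(edges = edges, nodes = genes, source = "metabolic"),
                     class = "directed_net")
    sc <- score_importance(net, mod, fx$counts, fx$samples)

    # independent oracle: all-pairs AUC with ties at 1/2, direct formula
    ts_genes <- unlist(mod$modules[mod$tumor_specific], use.names = FALSE)
    n_all <- length(mod$network_genes)
    n_in <- length(intersect(ts_genes, mod$network_genes))
    for (j in seq_len(nrow(sc))) {
      a <- sc$gene_id[j]
      nb <- unique(edges$to[edges$from == a])
      non_nb <- setdiff(mod$network_genes, c(nb, a))
      pos <- mod$cor_abs[a, intersect(nb, colnames(mod$cor_abs))]
      neg <- mod$cor_abs[a, non_nb]
      wins <- 0
      for (p in pos) for (q in neg) {
        wins <- wins + (p > q) + 0.5 * (p == q)
      }
      auc <- if (length(pos) && length(neg)) wins / (length(pos) * length(neg)) else 0.5
      c_in <- length(intersect(nb, ts_genes))
      expected <- if (c_in == 0 || n_in == 0) -Inf else
        abs(auc - 0.5) * log2((c_in / length(nb)) / (n_in / n_all))
      expect_equal(sc$auc[j], auc, tolerance = 1e-12)
      expect_equal(sc$score_a[j], expected, tolerance = 1e-12)
    }
  }
})

test_that("score_a annihilates at auc = 0.5 and at no enrichment", {
  expect_equal(abs(0.5 - 0.5) * log2((4 / 8) / (100 / 1000)), 0)
  expect_equal(abs(0.8 - 0.5) * log2((10 / 100) / (100 / 1000)), 0)
  expect_equal(abs(0.8 - 0.5) * log2((4 / 8) / (100 / 1000)),
               0.3 * log2(5), tolerance = 1e-12)
  expect_equal(0.3 * log2(5), 0.69658, tolerance = 1e-4)
})

test_that("auc is invariant under negating a gene's expression", {
  fx <- block_counts(seed = 31, n_per_block = 6, n_noise = 6, n_t = 10, n_n = 10)
  mod <- build_coexpression_modules(fx$counts, fx$samples, tau = 0.5,
                                    min_size = 4, cut_height = 0.4)
  # |r| is symmetric under sign flips, so the modules' correlation matrix
  # (the auc input) is unchanged when an expression vector is negated
  expr <- methorigin:::log2_cpm(fx$counts)[, fx$samples$condition == "tumor"]
  a <- rownames(expr)[1]
  flipped <- expr
  flipped[a, ] <- -flipped[a, ]
  expect_equal(abs(cor(t(flipped)))[a, ], mod$cor_abs[a, ], tolerance = 1e-10)
})

test_that("epi-driver calls follow the three-way intersection and are monotone", {
  de <- tibble::tibble(gene_id = c("A", "B", "C"), log2fc = c(3, 3, 0),
                       p = 0, q = 0, significant = c(TRUE, TRUE, FALSE))
  sm <- tibble::tibble(gene_id = c("A", "C"), key_gene = c(TRUE, TRUE))
  calls <- call_epidrivers(de, sm, NULL, assoc_genes = c("A", "B"))
  expect_true(calls$epi_driver[calls$gene_id == "A"])
  expect_false(calls$epi_driver[calls$gene_id == "B"])  # not key in any net
  expect_false(calls$epi_driver[calls$gene_id == "C"])  # not DE
  empty <- call_epidrivers(de[0, ], sm, NULL, assoc_genes = "A")
  expect_equal(sum(empty$epi_driver), 0L)

  # monotone: enlarging any flag set never removes an existing driver
  base_drv <- calls$gene_id[calls$epi_driver]
  grown <- call_epidrivers(de, dplyr::bind_rows(sm, tibble::tibble(gene_id = "B", key_gene = TRUE)),
                           NULL, assoc_genes = c("A", "B"))
  expect_true(all(base_drv %in% grown$gene_id[grown$epi_driver]))
})

test_that("overlap significance equals the hypergeometric tail", {
  u <- sprintf("g%02d", 1:10)
  full <- overlap_significance(u[1:5], u[1:5], u)
  expect_equal(full$p, 1 / choose(10, 5), tolerance = 1e-12)
  disjoint <- overlap_significance(u[1:5], u[6:10], u)
  expect_equal(disjoint$p, 1)
  empty <- overlap_significance(character(), u[1:5], u)
  expect_equal(empty$overlap, 0L)
  expect_equal(empty$p, 1)
  expect_error(overlap_significance("a", "b", character()), "universe")
  pw <- pairwise_overlap(list(x = u[1:5], y = u[1:5], z = u[6:10]), u)
  expect_equal(nrow(pw), 3L)
  expect_true(all(pw$q >= pw$p))
})
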