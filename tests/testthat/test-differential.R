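test_that("BH adjustment matches the hand step-up and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.04), 0.04)
  p <- runif(50)
  ord <- sample(50)
  expect_equal(bh_adjust(p)[ord], bh_adjust(p[ord]))
  expect_true(all(bh_adjust(p) >= p & bh_adjust(p) <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("rank-sum p is exact on the complete-separation fixture", {
  withr::with_seed(1, {
    x <- 0.9 + runif(10, -0.01, 0.01)
    y <- 0.2 + runif(10, -0.01, 0.01)
  })
  rs <- methorigin:::rank_sum_test(x, y)
  expect_equal(rs$method, "exact")
  expect_equal(rs$p, 2 / choose(20, 10))
})

test_that("rank-sum agrees with wilcox.test and its own normal approximation", {
  withr::with_seed(7, {
    for (i in 1:20) {
      x <- rnorm(8)
      y <- rnorm(8, 0.5)
      exact <- methorigin:::rank_sum_test(x, y, exact_max = 25)
      ref <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))
      expect_equal(exact$p, ref$p.value, tolerance = 1e-12)
    }
    # exact path vs tie-corrected normal approximation stay within 0.01
    dmax <- 0
    for (i in 1:100) {
      x <- rnorm(8); y <- rnorm(8, sample(c(0, 1), 1))
      pe <- methorigin:::rank_sum_test(x, y, exact_max = 25)$p
      pa <- methorigin:::rank_sum_test(x, y, exact_max = 0)$p
      dmax <- max(dmax, abs(pe - pa))
    }
    expect_lte(dmax, 0.01)
  })
})

test_that("differential methylation applies the joint q and delta-beta gate", {
  samples <- mk_samples(sprintf("S%02d", 1:20),
                        condition = rep(c("tumor", "normal"), each = 10))
  withr::with_seed(3, {
    beta <- rbind(
      flat = rep(0.5, 20),                                    # identical
      big = c(rep(0.9, 10), rep(0.2, 10)) + runif(20, 0, 1e-3),  # separated
      small = c(rep(0.50, 10), rep(0.35, 10)) + runif(20, 0, 1e-3) # q small, gate fails
    )
  })
  colnames(beta) <- samples$sample_id
  dm <- diff_methylation(beta, samples)
  expect_equal(dm$p[dm$probe_id == "flat"], 1)
  expect_false(dm$significant[dm$probe_id == "flat"])
  big <- dm[dm$probe_id == "big", ]
  expect_true(big$significant)
  expect_equal(big$direction, "hyper")
  expect_equal(big$delta_beta, 0.7, tolerance = 0.01)
  small <- dm[dm$probe_id == "small", ]
  expect_lt(small$q, 0.05)
  expect_false(small$significant)  # |delta beta| = 0.15 < 0.2
  expect_true(all(dm$q >= dm$p))
})

test_that("group relabeling that preserves membership leaves results unchanged", {
  b <- simulate_bundle(small_cfg(seed = 4, missing_rate = 0,
                                 n_high_missing_probes = 0))
  dm1 <- diff_methylation(b$beta, b$samples)
  perm <- order(b$samples$condition, b$samples$sample_id)
  dm2 <- diff_methylation(b$beta[, b$samples$sample_id[perm]], b$samples[perm, ])
  expect_equal(dm1, dm2)
})

test_that("differential expression handles degenerate genes and identical groups", {
  samples <- mk_samples(sprintf("S%02d", 1:8),
                        condition = rep(c("tumor", "normal"), each = 4))
  # identical per-group library sizes, so CPM comparisons are direct
  counts <- rbind(
    same = rep(c(5, 10, 15, 20), 2),
    zero = rep(0, 8),
    up = c(800, 900, 850, 950, 10, 12, 9, 11),
    filler = c(9195, 9090, 9135, 9030, 9985, 9978, 9976, 9969)
  )
  colnames(counts) <- samples$sample_id
  de <- diff_expression(counts, samples)
  expect_equal(de$log2fc[de$gene_id == "same"], 0, tolerance = 1e-6)
  expect_false(de$significant[de$gene_id == "same"])
  expect_equal(de$log2fc[de$gene_id == "zero"], 0)
  expect_equal(de$p[de$gene_id == "zero"], 1)
  expect_true(de$significant[de$gene_id == "up"])
})

test_that("a planted 8-fold change is detected in nearly every replicate", {
  withr::with_seed(11, {
    hits <- 0
    n_rep <- 200
    for (r in seq_len(n_rep)) {
      n_genes <- 50
      base <- runif(n_genes, 4, 9)
      mu <- outer(2^base, rep(1, 20))
      mu[1, 1:10] <- mu[1, 1:10] * 8  # planted log2fc = 3 in tumor
      counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / 0.1), n_genes,
                       dimnames = list(sprintf("G%02d", 1:n_genes), sprintf("S%02d", 1:20)))
      samples <- mk_samples(colnames(counts),
                            condition = rep(c("tumor", "normal"), each = 10))
      de <- diff_expression(counts, samples)
      hits <- hits + de$significant[1]
    }
    expect_gte(hits / n_rep, 0.95)
  })
})
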