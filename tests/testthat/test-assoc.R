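test_that("region windows follow the stated strand-aware arithmetic", {
  genes <- tibble::tibble(
    gene_id = c("Gp", "Gm"), chrom = "chr1", strand = c("+", "-"),
    tss = c(10000, 5000), tes = c(20000, 1000)
  )
  man <- mk_manifest(sprintf("cg%02d", 1:7),
                     pos = c(9200, 11400, 13000, 5800, 4200, 3000, 60000))
  asn <- annotate_regions(man, genes)
  get <- function(p) asn[asn$probe_id == p, ]
  expect_equal(get("cg01")$region, "upstream_1500")    # 800 bp 5' of + TSS
  expect_equal(get("cg01")$gene_id, "Gp")
  expect_equal(get("cg02")$region, "downstream_1500")
  expect_equal(get("cg03")$region, "gene_body")
  expect_equal(get("cg04")$region, "upstream_1500")    # 800 bp 5' on - strand
  expect_equal(get("cg04")$gene_id, "Gm")
  expect_equal(get("cg05")$region, "downstream_1500")  # 800 bp 3' on - strand
  expect_equal(get("cg06")$region, "gene_body")        # within - gene span
  expect_equal(get("cg07")$region, "igr")
  expect_true(is.na(get("cg07")$gene_id))
  # boundary: the TSS base itself is downstream, not upstream
  man2 <- mk_manifest("cgT", pos = 10000)
  expect_equal(annotate_regions(man2, genes)$region[1], "downstream_1500")
})

test_that("every gene-window probe gets exactly one region per gene, igr is exclusive", {
  sim <- simulate_manifest_genes(small_cfg(seed = 9))
  asn <- annotate_regions(sim$manifest, sim$genes)
  per_pair <- dplyr::count(asn, .data$probe_id, .data$gene_id)
  expect_true(all(per_pair$n == 1))
  igr_probes <- asn$probe_id[asn$region == "igr"]
  expect_true(all(is.na(asn$gene_id[asn$region == "igr"])))
  expect_false(any(igr_probes %in% asn$probe_id[asn$region != "igr"]))
})

test_that("a noiseless affine relation is recovered essentially exactly", {
  n <- 30
  samples <- mk_samples(sprintf("S%02d", 1:n), condition = "tumor")
  # integer counts with a constant library size, beta defined so that
  # log2(CPM+1) is exactly affine in beta: beta = (log2(c+1) - 6) / 6
  c1 <- seq(100, 3000, length.out = n)
  counts <- rbind(g1 = c1, filler = 1e6 - c1)
  colnames(counts) <- samples$sample_id
  beta <- mk_beta(matrix((log2(c1 + 1) - 6) / 6, 1, n), probes = "cg001")
  colnames(beta) <- samples$sample_id
  asn <- tibble::tibble(probe_id = "cg001", gene_id = "g1", region = "gene_body")
  fa <- fit_association(beta, counts, samples, asn, model = "plain")
  expect_equal(fa$assoc$beta_coef, 6, tolerance = 1e-9)
  expect_lt(fa$assoc$p, 1e-12)
  expect_equal(fa$assoc$sign, "+")
})

test_that("zero-variance probes are skipped with a reason", {
  n <- 10
  samples <- mk_samples(sprintf("S%02d", 1:n), condition = "tumor")
  beta <- mk_beta(rbind(rep(0.5, n), runif(n)), probes = c("cgA", "cgB"))
  colnames(beta) <- samples$sample_id
  counts <- matrix(rpois(2 * n, 100), 2, n,
                   dimnames = list(c("g1", "g2"), samples$sample_id))
  asn <- tibble::tibble(probe_id = c("cgA", "cgB"), gene_id = c("g1", "g2"),
                        region = "gene_body")
  fa <- fit_association(beta, counts, samples, asn, model = "plain")
  expect_equal(fa$skipped$probe_id, "cgA")
  expect_equal(fa$skipped$reason, "zero beta variance")
  expect_equal(fa$assoc$probe_id, "cgB")
})

test_that("cancer-type correction removes confound-only associations", {
  cfg <- small_cfg(seed = 21, n_classes = 2, n_pairs_per_class = 20,
                   n_genes = 80, n_probes = 200, confound_fraction = 0.5,
                   missing_rate = 0)
  b <- simulate_bundle(cfg)
  asn <- annotate_regions(b$manifest, b$genes)
  plain <- fit_association(b$beta, b$counts, b$samples, asn, model = "plain")
  corr <- fit_association(b$beta, b$counts, b$samples, asn, model = "type_corrected")
  conf <- b$truth$confounded_genes
  plain_sig <- plain$genes$associated[match(conf, plain$genes$gene_id)]
  corr_sig <- corr$genes$associated[match(conf, corr$genes$gene_id)]
  expect_gte(mean(plain_sig, na.rm = TRUE), 0.9)
  expect_gte(mean(!corr_sig, na.rm = TRUE), 0.9)
  expect_lt(sum(corr$genes$associated), sum(plain$genes$associated))
})

test_that("sign tallies track planted promoter and gene-body coupling directions", {
  b <- simulate_bundle(small_cfg(seed = 6, missing_rate = 0,
                                 n_pairs_per_class = 20))
  asn <- annotate_regions(b$manifest, b$genes)
  fa <- fit_association(b$beta, b$counts, b$samples, asn, model = "type_corrected")
  cp <- b$truth$coupled_pairs
  got <- dplyr::inner_join(cp, fa$assoc, by = c("probe_id", "gene_id"))
  expect_equal(got$sign.y, got$sign.x)
  gl <- fa$genes[match(b$truth$planted_epidriver_genes, fa$genes$gene_id), ]
  expect_true(all(gl$associated))
  expect_gte(sum(gl$n_neg), 1)  # promoter couplings surface as negative
  expect_gte(sum(gl$n_pos), 1)  # gene-body couplings as positive
})

test_that("the identity permutation reproduces the observed count and seeds are stable", {
  b <- simulate_bundle(small_cfg(seed = 8, missing_rate = 0))
  asn <- annotate_regions(b$manifest, b$genes)
  ident <- permutation_null(b$beta, b$counts, b$samples, asn, n_perm = 3,
                            seed = 1, permute = function(n, i) seq_len(n))
  expect_equal(attr(ident, "null_counts"),
               rep(ident$observed_significant_genes, 3))
  expect_equal(ident$null_sd, 0)
  p1 <- permutation_null(b$beta, b$counts, b$samples, asn, n_perm = 10, seed = 5)
  p2 <- permutation_null(b$beta, b$counts, b$samples, asn, n_perm = 10, seed = 5)
  expect_identical(p1, p2)
  expect_false(identical(
    attr(p1, "null_counts"),
    attr(permutation_null(b$beta, b$counts, b$samples, asn, n_perm = 10, seed = 6),
         "null_counts")) && p1$null_sd > 0)
})
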