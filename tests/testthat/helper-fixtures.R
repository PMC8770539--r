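# Shared fixture builders. Everything is generated in code at test time.

# A small but complete simulation configuration for module-level tests.
small_cfg <- function(seed = 1, ...) {
  args <- modifyList(
    list(n_classes = 3, n_pairs_per_class = 8, n_probes = 150, n_genes = 60,
         n_planted_epidrivers = 2, n_partners_per_driver = 4,
         n_planted_markers_per_class = 1, confound_fraction = 0.1,
         seed = seed),
    list(...)
  )
  do.call(sim_config, args)
}

# Hand-built beta matrix with ids.
mk_beta <- function(values, probes = sprintf("cg%03d", seq_len(nrow(values))),
                    samples = sprintf("S%02d", seq_len(ncol(values)))) {
  matrix(values, nrow = length(probes), dimnames = list(probes, samples))
}

# Minimal manifest for hand-built probes (all autosomal, unflagged, unless
# overridden).
mk_manifest <- function(probes, chrom = "chr1", pos = NULL,
                        snp = FALSE, multimap = FALSE) {
  tibble::tibble(
    probe_id = probes,
    chrom = rep_len(chrom, length(probes)),
    pos = if (is.null(pos)) seq(1e4, by = 1000, length.out = length(probes)) else pos,
    island_relation = "OpenSea",
    snp_flag = rep_len(snp, length(probes)),
    multimap_flag = rep_len(multimap, length(probes))
  )
}

# Sample sheet for a flat tumor/normal or multi-class design.
mk_samples <- function(ids, class_label = "C1", condition = "tumor",
                       cohort = NA_character_) {
  tibble::tibble(
    sample_id = ids,
    class_label = rep_len(class_label, length(ids)),
    condition = rep_len(condition, length(ids)),
    pair_id = NA_character_,
    cohort = rep_len(cohort, length(ids))
  )
}

# Write a complete, well-formed tiny text bundle to a temp dir; returns paths.
write_tiny_bundle_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                                    beta_extra_sample = FALSE) {
  beta <- tibble::tibble(
    probe_id = c("cg001", "cg002", "cg003"),
    S1 = c(0.1, 0.5, 0.9), S2 = c(0.2, 0.6, 0.8),
    S3 = c(0.3, NA, 0.7), S4 = c(0.4, 0.5, 0.6)
  )
  if (beta_extra_sample) beta$S9 <- c(0.5, 0.5, 0.5)
  counts <- tibble::tibble(
    gene_id = c("G1", "G2"),
    S1 = c(10, 0), S2 = c(20, 1), S3 = c(30, 2), S4 = c(40, 3)
  )
  manifest <- tibble::tibble(
    probe_id = c("cg001", "cg002", "cg003"),
    chrom = "chr1", pos = c(1000, 2000, 3000),
    island_relation = c("Island", "N_Shore", "OpenSea"),
    snp_flag = FALSE, multimap_flag = FALSE
  )
  genes <- tibble::tibble(
    gene_id = c("G1", "G2"), chrom = "chr1", strand = c("+", "-"),
    tss = c(500, 9000), tes = c(4000, 5000)
  )
  samples <- tibble::tibble(
    sample_id = paste0("S", 1:4), class_label = c("A", "A", "B", "B"),
    condition = c("tumor", "normal", "tumor", "normal"),
    pair_id = c("p1", "p1", "p2", "p2"), cohort = NA_character_
  )
  reactions <- tibble::tibble(
    reaction_id = c("r1", "r2"), enzyme_gene = c("G1", "G2"),
    substrates = c("m1", "m2"), products = c("m2", "m3")
  )
  ppi <- tibble::tibble(gene_a = "G1", gene_b = "G2", weight = 0.7)

  paths <- list(
    beta = file.path(dir, "beta.tsv"), counts = file.path(dir, "counts.tsv"),
    manifest = file.path(dir, "manifest.csv"), genes = file.path(dir, "genes.tsv"),
    samples = file.path(dir, "samples.tsv"),
    reactions = file.path(dir, "reactions.tsv"), ppi = file.path(dir, "ppi.tsv")
  )
  readr::write_tsv(beta, paths$beta, na = "NA")
  readr::write_tsv(counts, paths$counts)
  readr::write_csv(manifest, paths$manifest)
  readr::write_tsv(genes, paths$genes)
  readr::write_tsv(samples, paths$samples)
  readr::write_tsv(reactions, paths$reactions)
  readr::write_tsv(ppi, paths$ppi)
  paths
}

# Naive O(n^3) complete-linkage agglomeration: returns the partition after
# cutting at k clusters, as a membership vector. Independent oracle for
# cluster_heatmap ordering.
naive_complete_linkage <- function(mat, k) {
  n <- nrow(mat)
  d <- as.matrix(dist(mat))
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    clusters[[best[3]]] <- c(clusters[[best[3]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  out <- integer(n)
  for (i in seq_along(clusters)) out[clusters[[i]]] <- i
  out
}
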