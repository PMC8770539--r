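#' Simulation configuration for synthetic multi-omics bundles
#'
#' Builds and validates the configuration of the synthetic-data generator.
#' The generator emulates a pan-cancer paired tumor/normal design: beta
#' values in \[0, 1\] with missingness, planted epi-driver genes whose
#' expression is coupled to nearby CpG methylation (promoter couplings
#' negative, gene-body couplings positive), planted tissue-specific marker
#' CpGs, class-level confounding present in both omics, and toy metabolic
#' and protein-interaction networks in which the planted drivers are
#' upstream hubs.
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: 5 tumor classes with 40 tumor/normal pairs each, 1,000 probes,
#' 500 genes, 6 planted markers in total (2 for the first class, 1 for each
#' other class — the six-CpG panel analog), coupling strength 0.7, a 0.3
#' tumor-normal beta shift on coupled probes, marker displacement 0.4 about
#' the 0.5 background, beta noise SD 0.05 and negative-binomial dispersion
#' 0.2.
#'
#' @param n_classes Number of tumor classes (tissues).
#' @param n_pairs_per_class Tumor/normal pairs per class.
#' @param n_probes,n_genes Universe sizes.
#' @param n_planted_epidrivers Number of planted epi-driver genes.
#' @param n_partners_per_driver Downstream co-expressed partner genes per
#'   driver (these form the tumor-specific modules and the drivers'
#'   out-neighborhoods).
#' @param n_planted_markers_per_class Scalar or vector (recycled across
#'   classes) of planted tissue-specific marker CpGs per class.
#' @param coupling_r Target absolute correlation between a coupled probe's
#'   beta and its gene's log-expression in tumor samples, in (0, 1).
#' @param delta_beta_effect Mean tumor-normal beta shift on coupled probes,
#'   in (0, 1).
#' @param marker_separation Displacement of a marker's own-class tumor mean
#'   above (and the remaining classes below) the 0.5 background, so the
#'   between-class gap is `2 * marker_separation`.
#' @param noise_sd_beta Beta-scale noise SD (applied on the logit scale via
#'   the delta method, clipped to \[0.001, 0.999\]).
#' @param nb_dispersion Negative-binomial dispersion of the count noise.
#' @param confound_fraction Fraction of genes given class-level mean shifts
#'   in both omics with no within-class coupling.
#' @param tumor_expr_shift log2 expression shift of planted drivers in
#'   tumor samples (must clear the |log2FC| > 2 differential gate).
#' @param marker_presence_rate For classes carrying several markers: the
#'   fraction of own-class tumor samples in which each marker is present
#'   (partial penetrance; the class's markers back each other up).
#' @param het_single_presence_rate Marker presence rate of the first
#'   single-marker class, modelling a heterogeneous carcinoma whose
#'   marker-silent tumors share the unmethylated signature with
#'   marker-silent samples of the multi-marker classes.
#' @param missing_rate Fraction of beta entries set missing at random.
#' @param n_high_missing_probes Probes forced above 50% missingness.
#' @param seed Integer seed; identical configurations produce bit-identical
#'   bundles.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_classes = 5,
                       n_pairs_per_class = 40,
                       n_probes = 1000,
                       n_genes = 500,
                       n_planted_epidrivers = 10,
                       n_partners_per_driver = 12,
                       n_planted_markers_per_class = c(2, 1, 1, 1, 1),
                       coupling_r = 0.7,
                       delta_beta_effect = 0.3,
                       marker_separation = 0.4,
                       noise_sd_beta = 0.05,
                       nb_dispersion = 0.2,
                       confound_fraction = 0.1,
                       tumor_expr_shift = 3,
                       marker_presence_rate = 0.85,
                       het_single_presence_rate = 0.7,
                       missing_rate = 0.02,
                       n_high_missing_probes = 5,
                       seed = 1) {
  cfg <- list(
    n_classes = as.integer(n_classes),
    n_pairs_per_class = as.integer(n_pairs_per_class),
    n_probes = as.integer(n_probes),
    n_genes = as.integer(n_genes),
    n_planted_epidrivers = as.integer(n_planted_epidrivers),
    n_partners_per_driver = as.integer(n_partners_per_driver),
    n_planted_markers_per_class =
      as.integer(rep_len(n_planted_markers_per_class, n_classes)),
    coupling_r = coupling_r,
    delta_beta_effect = delta_beta_effect,
    marker_separation = marker_separation,
    noise_sd_beta = noise_sd_beta,
    nb_dispersion = nb_dispersion,
    confound_fraction = confound_fraction,
    tumor_expr_shift = tumor_expr_shift,
    marker_presence_rate = marker_presence_rate,
    het_single_presence_rate = het_single_presence_rate,
    missing_rate = missing_rate,
    n_high_missing_probes = as.integer(n_high_missing_probes),
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(
      n_classes >= 1, n_pairs_per_class >= 1, n_probes >= 1, n_genes >= 2,
      n_planted_epidrivers >= 1, n_partners_per_driver >= 1,
      all(n_planted_markers_per_class >= 1),
      coupling_r > 0, coupling_r < 1,
      delta_beta_effect > 0, delta_beta_effect < 1,
      marker_separation > 0, marker_separation < 0.5,
      noise_sd_beta > 0, nb_dispersion >= 0,
      confound_fraction >= 0, confound_fraction <= 1,
      marker_presence_rate > 0, marker_presence_rate <= 1,
      het_single_presence_rate > 0, het_single_presence_rate <= 1,
      missing_rate >= 0, missing_rate <= 1
    )
  })
  n_conf <- round(cfg$confound_fraction * cfg$n_genes)
  need_genes <- cfg$n_planted_epidrivers * (1 + cfg$n_partners_per_driver) + n_conf
  if (need_genes > cfg$n_genes) {
    stop(sprintf("n_genes too small: need at least %d for drivers, partners and confounded genes",
                 need_genes), call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

class_labels <- function(cfg) sprintf("C%d", seq_len(cfg$n_classes))

# Strand-aware probe position relative to a gene's TSS.
pos_from_tss <- function(gene, offset) {
  # offset > 0 is 3' of the TSS, offset < 0 is 5' of the TSS
  if (gene$strand == "+") gene$tss + offset else gene$tss - offset
}

#' Generate a probe manifest and gene model with region ground truth
#'
#' Places genes on four autosomes (alternating strand), then positions
#' probes deliberately in all four region categories (upstream window,
#' downstream window, gene body, intergenic) on both strands, and includes
#' chrX/chrY, SNP-flagged and multi-mapping probes to exercise the quality
#' filters. Also fixes the planted assignments (epi-driver genes with their
#' coupled promoter/body probes, downstream partner genes, class-specific
#' marker probes, confounded genes).
#'
#' @param cfg A [sim_config()].
#' @return List with `manifest`, `genes`, and a `truth` list carrying
#'   planted assignments plus a `region_truth` tibble of intended
#'   (probe, gene, region) labels.
#' @export
simulate_manifest_genes <- function(cfg) {
  withr::with_seed(derive_seed(cfg$seed, 1), {
    n_genes <- cfg$n_genes
    chroms <- paste0("chr", 1:4)
    gene_chrom <- chroms[(seq_len(n_genes) - 1) %% 4 + 1]
    idx_within <- ave(seq_len(n_genes), gene_chrom, FUN = seq_along)
    start <- 1e5 + (idx_within - 1) * 5e4
    span <- 8000
    strand <- ifelse(seq_len(n_genes) %% 2 == 1, "+", "-")
    genes <- tibble::tibble(
      gene_id = sprintf("G%04d", seq_len(n_genes)),
      chrom = gene_chrom,
      strand = strand,
      tss = ifelse(strand == "+", start, start + span),
      tes = ifelse(strand == "+", start + span, start)
    )

    # planted assignments
    drivers <- sort(sample(genes$gene_id, cfg$n_planted_epidrivers))
    pool <- setdiff(genes$gene_id, drivers)
    partners <- list()
    for (d in drivers) {
      partners[[d]] <- sort(sample(pool, cfg$n_partners_per_driver))
      pool <- setdiff(pool, partners[[d]])
    }
    n_conf <- min(round(cfg$confound_fraction * cfg$n_genes), length(pool))
    confounded <- sort(sample(pool, n_conf))
    pool <- setdiff(pool, confounded)

    gene_row <- function(g) genes[match(g, genes$gene_id), ]
    rows <- list()
    add <- function(chrom, pos, gene_id, region, role,
                    snp = FALSE, multimap = FALSE) {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        chrom = chrom, pos = as.numeric(pos), gene_id = gene_id,
        region = region, role = role, snp_flag = snp, multimap_flag = multimap
      )
    }

    # coupled probes of each planted driver: promoter (negative sign) and
    # gene body (positive sign)
    for (d in drivers) {
      g <- gene_row(d)
      add(g$chrom, pos_from_tss(g, -800), d, "upstream_1500", paste0("coupled_prom:", d))
      add(g$chrom, pos_from_tss(g, 3000), d, "gene_body", paste0("coupled_body:", d))
    }

    # tissue-specific marker probes, hosted in driver gene bodies
    labels <- class_labels(cfg)
    marker_class <- rep(labels, times = cfg$n_planted_markers_per_class)
    for (k in seq_along(marker_class)) {
      d <- drivers[(k - 1) %% length(drivers) + 1]
      g <- gene_row(d)
      add(g$chrom, pos_from_tss(g, 5000 + 13 * k), d, "gene_body",
          paste0("marker:", marker_class[k]))
    }

    # confounded genes carry one body probe each
    for (cg in confounded) {
      g <- gene_row(cg)
      add(g$chrom, pos_from_tss(g, 4000), cg, "gene_body", paste0("confounded:", cg))
    }

    # guarantee every region category on both strands
    cover_plus <- gene_row(genes$gene_id[genes$strand == "+"][1])
    cover_minus <- gene_row(genes$gene_id[genes$strand == "-"][1])
    for (g in list(cover_plus, cover_minus)) {
      add(g$chrom, pos_from_tss(g, -500), g$gene_id, "upstream_1500", "coverage")
      add(g$chrom, pos_from_tss(g, 700), g$gene_id, "downstream_1500", "coverage")
      add(g$chrom, pos_from_tss(g, 3500), g$gene_id, "gene_body", "coverage")
    }

    # filter-exercising probes
    for (i in 1:4) add("chrX", 1e6 + i * 1000, NA, "igr", "xy")
    for (i in 1:2) add("chrY", 1e6 + i * 1000, NA, "igr", "xy")
    for (i in 1:4) add("chr1", 9e6 + i * 1000, NA, "igr", "snp", snp = TRUE)
    for (i in 1:4) add("chr2", 9e6 + i * 1000, NA, "igr", "multimap", multimap = TRUE)
    for (i in seq_len(cfg$n_high_missing_probes)) {
      add("chr3", 9.5e6 + i * 1000, NA, "igr", "high_missing")
    }

    placed <- dplyr::bind_rows(rows)
    n_left <- cfg$n_probes - nrow(placed)
    if (n_left < 0) {
      stop(sprintf("n_probes too small: need at least %d to cover all planted probes and region categories",
                   nrow(placed)), call. = FALSE)
    }
    if (n_left > 0) {
      n_body <- floor(0.4 * n_left)
      if (n_body > 0) {
        gsel <- sample(genes$gene_id, n_body, replace = TRUE)
        for (i in seq_len(n_body)) {
          g <- gene_row(gsel[i])
          add(g$chrom, pos_from_tss(g, sample(1600:7900, 1)), gsel[i],
              "gene_body", "noise_body")
        }
      }
      for (i in seq_len(n_left - n_body)) {
        add(chroms[(i - 1) %% 4 + 1], 2e7 + i * 500, NA, "igr", "noise_igr")
      }
      placed <- dplyr::bind_rows(rows)
    }

    placed$probe_id <- sprintf("cg%05d", seq_len(nrow(placed)))
    placed$island_relation <- island_vocabulary[(seq_len(nrow(placed)) - 1) %% 6 + 1]

    manifest <- placed |>
      dplyr::select("probe_id", "chrom", "pos", "island_relation",
                    "snp_flag", "multimap_flag")
    region_truth <- placed |>
      dplyr::select("probe_id", "gene_id", "region", "role")

    marker_probes <- placed |>
      dplyr::filter(startsWith(.data$role, "marker:")) |>
      dplyr::transmute(probe_id = .data$probe_id,
                       class_label = sub("^marker:", "", .data$role),
                       gene_id = .data$gene_id)
    coupled_pairs <- placed |>
      dplyr::filter(startsWith(.data$role, "coupled_")) |>
      dplyr::transmute(probe_id = .data$probe_id, gene_id = .data$gene_id,
                       region = .data$region,
                       sign = ifelse(startsWith(.data$role, "coupled_prom"), "-", "+"))
    confounded_probes <- placed |>
      dplyr::filter(startsWith(.data$role, "confounded:")) |>
      dplyr::select("probe_id", "gene_id")

    truth <- list(
      planted_epidriver_genes = drivers,
      partners = partners,
      planted_marker_probes = split(marker_probes$probe_id, marker_probes$class_label),
      marker_probes = marker_probes,
      coupled_pairs = coupled_pairs,
      confounded_genes = confounded,
      confounded_probes = confounded_probes,
      high_missing_probes = placed$probe_id[placed$role == "high_missing"],
      region_truth = region_truth
    )
    list(manifest = manifest, genes = genes, truth = truth)
  })
}

#' Generate toy metabolic reactions and a PPI edge list
#'
#' Planted epi-driver genes are made upstream hubs: each driver's reaction
#' products feed the reactions of all of its partner genes (and the first
#' partners form a downstream chain of length >= 3), so the derived
#' directed metabolic network contains an edge from the driver to every
#' partner. Non-planted genes receive sparse random out-edges. The PPI list
#' mirrors the same hub structure with high-confidence weights, plus a
#' handful of sub-threshold (< 0.4) edges that the network builder must
#' discard.
#'
#' @param cfg A [sim_config()].
#' @param sim Output of [simulate_manifest_genes()].
#' @return List with `reactions` (tibble with list-columns) and `ppi`
#'   (undirected weighted edge tibble).
#' @export
simulate_networks <- function(cfg, sim) {
  withr::with_seed(derive_seed(cfg$seed, 2), {
    genes <- sim$genes$gene_id
    truth <- sim$truth
    drivers <- truth$planted_epidriver_genes

    edges <- list()
    for (d in drivers) {
      p <- truth$partners[[d]]
      edges[[length(edges) + 1L]] <- tibble::tibble(from = d, to = p)
      if (length(p) >= 2) {
        chain_len <- min(length(p) - 1, 4)
        edges[[length(edges) + 1L]] <-
          tibble::tibble(from = p[seq_len(chain_len)], to = p[seq_len(chain_len) + 1])
      }
    }
    nondrivers <- setdiff(genes, drivers)
    for (g in nondrivers) {
      to <- sample(setdiff(genes, g), 3)
      edges[[length(edges) + 1L]] <- tibble::tibble(from = g, to = to)
    }
    edges <- dplyr::distinct(dplyr::bind_rows(edges))

    # encode each directed edge through a dedicated shared metabolite
    reactions <- dplyr::bind_rows(
      tibble::tibble(
        reaction_id = sprintf("rx_out_%05d", seq_len(nrow(edges))),
        enzyme_gene = edges$from,
        substrates = lapply(edges$from, function(g) paste0("m_src_", g)),
        products = lapply(seq_len(nrow(edges)), function(i) sprintf("m_e%05d", i))
      ),
      tibble::tibble(
        reaction_id = sprintf("rx_in_%05d", seq_len(nrow(edges))),
        enzyme_gene = edges$to,
        substrates = lapply(seq_len(nrow(edges)), function(i) sprintf("m_e%05d", i)),
        products = lapply(seq_len(nrow(edges)), function(i) sprintf("m_snk%05d", i))
      )
    )

    ppi <- list()
    for (d in drivers) {
      ppi[[length(ppi) + 1L]] <- tibble::tibble(
        gene_a = d, gene_b = truth$partners[[d]], weight = 0.8
      )
    }
    for (g in nondrivers) {
      ppi[[length(ppi) + 1L]] <- tibble::tibble(
        gene_a = g, gene_b = sample(setdiff(genes, g), 1),
        weight = round(runif(1, 0.45, 0.95), 3)
      )
    }
    low_a <- sample(genes, 10, replace = TRUE)
    low_b <- sample(genes, 10, replace = TRUE)
    keep <- low_a != low_b
    ppi[[length(ppi) + 1L]] <- tibble::tibble(
      gene_a = low_a[keep], gene_b = low_b[keep],
      weight = round(runif(sum(keep), 0.05, 0.35), 3)
    )
    ppi <- dplyr::bind_rows(ppi) |>
      dplyr::mutate(lo = pmin(.data$gene_a, .data$gene_b),
                    hi = pmax(.data$gene_a, .data$gene_b)) |>
      dplyr::distinct(.data$lo, .data$hi, .keep_all = TRUE) |>
      dplyr::select("gene_a", "gene_b", "weight")

    list(reactions = reactions, ppi = ppi)
  })
}

#' Generate the paired tumor/normal cohort (beta, counts, sample sheet)
#'
#' Draws beta values with logit-normal noise (clipped to \[0.001, 0.999\]),
#' shifts coupled probes by `delta_beta_effect` in tumor (promoter probes
#' hypo-, body probes hyper-methylated), couples each driver's probes to
#' its expression through a shared per-sample latent factor calibrated (with
#' bounded retries) so the achieved tumor |correlation| reaches
#' `coupling_r - 0.05`, separates marker probes across classes, plants
#' class-level confounding in both omics, draws counts with
#' negative-binomial overdispersion and a per-sample scale factor, and
#' finally masks ~`missing_rate` of beta entries plus a few probes above
#' 50% missingness.
#'
#' @param cfg A [sim_config()].
#' @param sim Output of [simulate_manifest_genes()].
#' @return List with `beta`, `counts`, `samples` and the completed `truth`.
#' @export
simulate_cohort <- function(cfg, sim) {
  withr::with_seed(derive_seed(cfg$seed, 3), {
    truth <- sim$truth
    labels <- class_labels(cfg)
    pairs_grid <- tidyr::expand_grid(class_label = labels,
                                     pair = seq_len(cfg$n_pairs_per_class))
    samples <- tidyr::expand_grid(pairs_grid, condition = c("tumor", "normal")) |>
      dplyr::mutate(
        sample_id = sprintf("%s_%s%03d", .data$class_label,
                            ifelse(.data$condition == "tumor", "T", "N"), .data$pair),
        pair_id = sprintf("%s_P%03d", .data$class_label, .data$pair),
        cohort = NA_character_
      ) |>
      dplyr::select("sample_id", "class_label", "condition", "pair_id", "cohort")
    n_s <- nrow(samples)
    is_tumor <- samples$condition == "tumor"
    cls <- samples$class_label

    genes <- sim$genes$gene_id
    n_g <- length(genes)
    probes <- sim$manifest$probe_id
    n_p <- length(probes)
    drivers <- truth$planted_epidriver_genes

    # ---- expression mean structure (log2 scale) ----
    base_g <- runif(n_g, 3, 10)
    logmu <- matrix(base_g, n_g, n_s, dimnames = list(genes, samples$sample_id))

    # class-level confounding, aligned across both omics
    conf_beta_off <- matrix(0, length(truth$confounded_genes), cfg$n_classes,
                            dimnames = list(truth$confounded_genes, labels))
    if (length(truth$confounded_genes) && cfg$n_classes >= 2) {
      levels_off <- seq(-0.15, 0.15, length.out = cfg$n_classes)
      for (g in truth$confounded_genes) {
        conf_beta_off[g, ] <- sample(levels_off)
        logmu[g, ] <- logmu[g, ] + 10 * conf_beta_off[g, cls]
      }
    }

    # tumor shifts: drivers strongly differential; partner modules shift
    # moderately, alternating up/down so the library composition stays
    # near-neutral and planted fold changes survive CPM scaling
    logmu[drivers, is_tumor] <- logmu[drivers, is_tumor] + cfg$tumor_expr_shift
    for (i in seq_along(drivers)) {
      shift <- if (i %% 2 == 1) 1.2 else -1.2
      logmu[truth$partners[[drivers[i]]], is_tumor] <-
        logmu[truth$partners[[drivers[i]]], is_tumor] + shift
    }

    # shared latent factors (one per driver, tumor samples)
    n_t <- sum(is_tumor)
    u <- matrix(rnorm(length(drivers) * n_t), length(drivers), n_t,
                dimnames = list(drivers, samples$sample_id[is_tumor]))

    sd_expr <- (1 / log(2)) * sqrt(cfg$nb_dispersion + 0.02)
    ct <- min(0.95, cfg$coupling_r + 0.05)
    gamma0 <- sd_expr * sqrt(ct / (1 - ct))
    w_mod <- sd_expr * sqrt(0.85 / 0.15)

    for (i in seq_along(drivers)) {
      d <- drivers[i]
      logmu[d, is_tumor] <- logmu[d, is_tumor] + gamma0 * u[i, ]
      logmu[truth$partners[[d]], is_tumor] <-
        sweep(logmu[truth$partners[[d]], is_tumor, drop = FALSE], 2, w_mod * u[i, ], "+")
    }

    sf <- exp(rnorm(n_s, 0, 0.2))
    draw_counts <- function(lm2) {
      # cap the mean so runaway retry inflation cannot overflow rnbinom
      mu <- pmin(sweep(2^lm2, 2, sf, "*"), 1e9)
      if (cfg$nb_dispersion < 1e-8) {
        matrix(stats::rpois(length(mu), mu), nrow(mu), dimnames = dimnames(mu))
      } else {
        matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
               nrow(mu), dimnames = dimnames(mu))
      }
    }
    counts <- draw_counts(logmu)

    # ---- methylation mean structure ----
    mu_p <- runif(n_p, 0.15, 0.85)
    names(mu_p) <- probes
    mu_mat <- matrix(mu_p, n_p, n_s, dimnames = list(probes, samples$sample_id))

    # Marker probes. Most single-marker classes are clean one-hot (own
    # tumor samples high, everything else low). Intratumoral marker
    # heterogeneity (partial penetrance) is planted in two places: classes
    # carrying several markers have each marker present in only
    # `marker_presence_rate` of own samples (their markers back each
    # other up), and the first single-marker class is a heterogeneous
    # carcinoma whose marker is present in `het_single_presence_rate` of
    # own samples. Marker-silent tumors are a real feature of
    # tissue-of-origin panels; without them every class signature would be
    # recoverable by elimination and a backup marker could never add
    # accuracy.
    mk <- truth$marker_probes
    if (nrow(mk)) {
      mu_mat[mk$probe_id, ] <- 0.5 - cfg$marker_separation
      tab <- table(mk$class_label)
      multi <- names(which(tab >= 2))
      het_single <- sort(names(which(tab == 1)))[1]
      presence <- matrix(TRUE, nrow(mk), n_s,
                         dimnames = list(mk$probe_id, samples$sample_id))
      # silences are exact counts, and within a multi-marker class each
      # silent tumor is silent for exactly one of the class's markers
      # (disjoint), so the markers genuinely back each other up
      for (cl_m in unique(mk$class_label)) {
        rows <- which(mk$class_label == cl_m)
        own <- which(is_tumor & cls == cl_m)
        q <- if (cl_m %in% multi) {
          1 - cfg$marker_presence_rate
        } else if (identical(cl_m, het_single)) {
          1 - cfg$het_single_presence_rate
        } else 0
        n_silent_each <- round(q * length(own))
        if (n_silent_each > 0 && n_silent_each * length(rows) <= length(own)) {
          silent_all <- sample(own, n_silent_each * length(rows))
          for (r in seq_along(rows)) {
            idx <- silent_all[seq_len(n_silent_each) + (r - 1) * n_silent_each]
            presence[rows[r], idx] <- FALSE
          }
        }
        for (r in rows) {
          on <- own[presence[r, own]]
          mu_mat[mk$probe_id[r], on] <- 0.5 + cfg$marker_separation
        }
      }
      truth$marker_presence <- presence
    }

    cp <- truth$coupled_pairs
    prom <- cp$probe_id[cp$sign == "-"]
    body <- cp$probe_id[cp$sign == "+"]
    mu_mat[prom, ] <- 0.55
    mu_mat[body, ] <- 0.45
    mu_mat[prom, is_tumor] <- pmax(0.05, 0.55 - cfg$delta_beta_effect)
    mu_mat[body, is_tumor] <- pmin(0.95, 0.45 + cfg$delta_beta_effect)

    if (nrow(truth$confounded_probes)) {
      for (j in seq_len(nrow(truth$confounded_probes))) {
        pr <- truth$confounded_probes$probe_id[j]
        g <- truth$confounded_probes$gene_id[j]
        mu_mat[pr, ] <- 0.5 + conf_beta_off[g, cls]
      }
    }

    mu_sd <- pmin(pmax(mu_p, 0.1), 0.9)
    sd_logit <- cfg$noise_sd_beta / (mu_sd * (1 - mu_sd))
    sd_logit[match(c(prom, body, mk$probe_id, truth$confounded_probes$probe_id), probes)] <-
      cfg$noise_sd_beta / 0.2

    draw_beta_row <- function(p_idx, extra_logit = 0) {
      lm <- qlogis(pmin(pmax(mu_mat[p_idx, ], 0.02), 0.98)) + extra_logit
      pmin(pmax(plogis(lm + rnorm(n_s, 0, sd_logit[p_idx])), 0.001), 0.999)
    }

    sd_l_coupled <- cfg$noise_sd_beta / 0.2
    alpha0 <- sd_l_coupled * sqrt(ct / (1 - ct))

    beta <- matrix(NA_real_, n_p, n_s, dimnames = list(probes, samples$sample_id))
    coupled_idx <- match(cp$probe_id, probes)
    for (p_idx in seq_len(n_p)) {
      if (p_idx %in% coupled_idx) next
      beta[p_idx, ] <- draw_beta_row(p_idx)
    }

    # couple each driver's promoter/body probes to its expression through
    # the shared latent, with bounded retries to hit the target correlation
    for (i in seq_along(drivers)) {
      d <- drivers[i]
      pr_p <- cp$probe_id[cp$gene_id == d & cp$sign == "-"]
      pr_b <- cp$probe_id[cp$gene_id == d & cp$sign == "+"]
      scale <- 1
      ok <- FALSE
      for (try in 1:20) {
        # loadings are physiologically capped: a probe cannot swing by
        # more than ~6 logit units, a gene by more than ~4 log2 units
        a_eff <- min(alpha0 * scale, 6)
        g_eff <- min(gamma0 * scale, 4)
        extra <- numeric(n_s)
        extra[is_tumor] <- a_eff * u[i, ]
        beta[pr_p, ] <- draw_beta_row(match(pr_p, probes), -extra)
        beta[pr_b, ] <- draw_beta_row(match(pr_b, probes), extra)
        lm_d <- logmu[d, ]
        lm_d[is_tumor] <- lm_d[is_tumor] + (g_eff - gamma0) * u[i, ]
        counts[d, ] <- draw_counts(matrix(lm_d, 1, dimnames = list(d, samples$sample_id)))
        e <- log2(counts[d, is_tumor] + 1)
        r_p <- suppressWarnings(cor(beta[pr_p, is_tumor], e))
        r_b <- suppressWarnings(cor(beta[pr_b, is_tumor], e))
        if (!is.na(r_p) && !is.na(r_b) &&
            r_p <= -(cfg$coupling_r - 0.05) && r_b >= (cfg$coupling_r - 0.05)) {
          ok <- TRUE
          break
        }
        scale <- scale * 1.35
      }
      if (!ok) {
        stop(sprintf("coupling infeasible for gene %s: could not reach |r| >= %.2f within bounded retries",
                     d, cfg$coupling_r - 0.05), call. = FALSE)
      }
    }

    # missingness: MCAR plus dedicated high-missing probes
    if (cfg$missing_rate > 0) {
      mask <- runif(length(beta)) < cfg$missing_rate
      beta[mask] <- NA_real_
    }
    for (pr in truth$high_missing_probes) {
      beta[pr, sample(n_s, ceiling(0.6 * n_s))] <- NA_real_
    }

    storage.mode(counts) <- "double"
    truth$conf_beta_offsets <- conf_beta_off
    list(beta = beta, counts = counts, samples = samples, truth = truth)
  })
}

#' Generate a complete synthetic input bundle with ground truth
#'
#' Runs [simulate_manifest_genes()], [simulate_networks()] and
#' [simulate_cohort()] under seeds derived from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return An `omics_bundle`-like list with the additional elements `truth`
#'   and `config`.
#' @export
simulate_bundle <- function(cfg = sim_config()) {
  sim <- simulate_manifest_genes(cfg)
  nets <- simulate_networks(cfg, sim)
  coh <- simulate_cohort(cfg, sim)
  structure(
    list(beta = coh$beta, counts = coh$counts, manifest = sim$manifest,
         genes = sim$genes, samples = coh$samples,
         reactions = nets$reactions, ppi = nets$ppi,
         report = tibble::tibble(file = character(), issue = character(),
                                 id = character()),
         truth = coh$truth, config = cfg),
    class = c("sim_bundle", "omics_bundle")
  )
}

#' Write a synthetic bundle to a directory of plain-text files
#'
#' Emits `beta.tsv`, `counts.tsv`, `manifest.csv`, `genes.tsv`,
#' `samples.tsv`, `reactions.tsv`, `ppi.tsv` and `truth.json`, in the same
#' formats [read_bundle()] consumes.
#'
#' @param bundle A [simulate_bundle()] result.
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  mat_tbl <- function(m, id) {
    tibble::as_tibble(m, rownames = id)
  }
  readr::write_tsv(mat_tbl(bundle$beta, "probe_id"), p("beta.tsv"), na = "NA")
  readr::write_tsv(mat_tbl(bundle$counts, "gene_id"), p("counts.tsv"), na = "NA")
  readr::write_csv(bundle$manifest, p("manifest.csv"))
  readr::write_tsv(bundle$genes, p("genes.tsv"))
  readr::write_tsv(bundle$samples, p("samples.tsv"), na = "NA")
  write_table(bundle$reactions, p("reactions.tsv"), "tsv")
  readr::write_tsv(bundle$ppi, p("ppi.tsv"))
  if (!is.null(bundle$truth)) {
    tr <- bundle$truth
    tr$conf_beta_offsets <- NULL
    jsonlite::write_json(tr, p("truth.json"), dataframe = "rows", na = "null",
                         auto_unbox = FALSE, digits = NA)
  }
  invisible(c(beta = p("beta.tsv"), counts = p("counts.tsv"),
              manifest = p("manifest.csv"), genes = p("genes.tsv"),
              samples = p("samples.tsv"), reactions = p("reactions.tsv"),
              ppi = p("ppi.tsv")))
}
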