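#' Annotate CpG probes to strand-aware gene region windows
#'
#' Each probe is assigned, per gene on the same chromosome, to one of the
#' region windows: `upstream_1500` (1-1500 bp 5' of the TSS; the TSS base
#' itself is excluded), `downstream_1500` (0-1500 bp 3' of the TSS,
#' including the TSS base), or `gene_body` (between TSS and TES but beyond
#' the downstream window). Windows are disjoint within a gene, so the
#' precedence upstream > downstream > gene_body is implied by the
#' arithmetic. A probe may map to several genes; a probe falling in no
#' gene window yields a single intergenic (`igr`) record with `gene_id`
#' `NA`. Coordinates are 1-based.
#'
#' @param manifest Probe manifest tibble.
#' @param genes Gene model tibble.
#' @return Tibble with columns `probe_id`, `gene_id`, `region`.
#' @export
annotate_regions <- function(manifest, genes) {
  pr <- dplyr::select(manifest, "probe_id", "chrom", "pos")
  gn <- dplyr::select(genes, "gene_id", "chrom", "strand", "tss", "tes")
  hits <- dplyr::inner_join(pr, gn, by = "chrom", relationship = "many-to-many") |>
    dplyr::mutate(
      offset = ifelse(.data$strand == "+", .data$pos - .data$tss,
                      .data$tss - .data$pos),
      len = abs(.data$tes - .data$tss),
      region = dplyr::case_when(
        .data$offset >= -1500 & .data$offset <= -1 ~ "upstream_1500",
        .data$offset >= 0 & .data$offset <= 1500 ~ "downstream_1500",
        .data$offset > 1500 & .data$offset <= .data$len ~ "gene_body",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::filter(!is.na(.data$region)) |>
    dplyr::distinct(.data$probe_id, .data$gene_id, .keep_all = TRUE) |>
    dplyr::select("probe_id", "gene_id", "region")
  igr <- tibble::tibble(
    probe_id = setdiff(manifest$probe_id, hits$probe_id),
    gene_id = NA_character_,
    region = "igr"
  )
  dplyr::bind_rows(hits, igr) |>
    dplyr::arrange(match(.data$probe_id, manifest$probe_id))
}

# Row-wise OLS of Y on X with an optional categorical covariate, via
# within-group centring (Frisch-Waugh). Returns slope, t, p and df of the
# methylation slope.
assoc_rowwise <- function(X, Y, class = NULL) {
  n <- ncol(X)
  if (is.null(class) || length(unique(class)) < 2) {
    Xc <- X - rowMeans(X)
    Yc <- Y - rowMeans(Y)
    df <- n - 2
  } else {
    f <- factor(class)
    Xc <- X
    Yc <- Y
    for (lv in levels(f)) {
      idx <- which(f == lv)
      Xc[, idx] <- X[, idx, drop = FALSE] - rowMeans(X[, idx, drop = FALSE])
      Yc[, idx] <- Y[, idx, drop = FALSE] - rowMeans(Y[, idx, drop = FALSE])
    }
    df <- n - 2 - (nlevels(f) - 1)
  }
  sxx <- rowSums(Xc^2)
  syy <- rowSums(Yc^2)
  sxy <- rowSums(Xc * Yc)
  slope <- sxy / sxx
  r2 <- pmin(1, (sxy^2) / (sxx * syy))
  tstat <- sign(sxy) * sqrt(df * r2 / pmax(1 - r2, 0))
  p <- 2 * pt(-abs(tstat), df)
  p[is.infinite(tstat)] <- 0
  const_y <- syy == 0
  slope[const_y] <- 0
  p[const_y] <- 1
  tibble::tibble(beta_coef = unname(slope), t = unname(tstat), p = unname(p),
                 df = df, zero_var_x = unname(sxx == 0))
}

#' Linear-model association between CpG methylation and gene expression
#'
#' For every (probe, gene, region) assignment, fits an ordinary
#' least-squares regression of `log2(CPM + 1)` expression on beta over
#' tumor samples, optionally with the cancer class as a categorical
#' covariate (`model = "type_corrected"`). The p-value comes from the
#' methylation slope's t-statistic; BH runs within each (region, model)
#' family. Probes with zero beta variance are skipped and itemised.
#'
#' @param beta Complete probes x samples beta matrix.
#' @param counts Genes x samples count matrix.
#' @param samples Sample sheet.
#' @param assignments Region assignments ([annotate_regions()]).
#' @param model `"plain"` or `"type_corrected"`.
#' @param q_cut Significance cut for the gene-level flag (default 0.05).
#' @return List of class `meth_assoc` with `assoc` (per-CpG tibble:
#'   `probe_id`, `gene_id`, `region`, `beta_coef`, `p`, `q`, `sign`,
#'   `model`), `genes` (per-gene tibble with `n_cpg`, `n_sig`, `n_pos`,
#'   `n_neg`, `associated`) and `skipped` (tibble of skipped records with
#'   reasons).
#' @export
fit_association <- function(beta, counts, samples, assignments,
                            model = c("type_corrected", "plain"),
                            q_cut = 0.05) {
  model <- match.arg(model)
  samples <- dplyr::filter(samples, .data$condition == "tumor")
  samp <- intersect(intersect(colnames(beta), colnames(counts)), samples$sample_id)
  if (length(samp) < 3) stop("need at least 3 tumor samples with both omics", call. = FALSE)
  cls <- samples$class_label[match(samp, samples$sample_id)]

  asn <- assignments |>
    dplyr::filter(.data$region != "igr",
                  .data$probe_id %in% rownames(beta),
                  .data$gene_id %in% rownames(counts))
  if (!nrow(asn)) stop("no probe-gene assignments overlap the matrices", call. = FALSE)
  expr <- log2_cpm(counts[, samp, drop = FALSE])
  X <- beta[asn$probe_id, samp, drop = FALSE]
  Y <- expr[asn$gene_id, , drop = FALSE]

  st <- assoc_rowwise(X, Y, class = if (model == "type_corrected") cls else NULL)
  res <- dplyr::bind_cols(asn, st)
  skipped <- res |>
    dplyr::filter(.data$zero_var_x) |>
    dplyr::transmute(.data$probe_id, .data$gene_id, .data$region,
                     reason = "zero beta variance")
  res <- res |>
    dplyr::filter(!.data$zero_var_x) |>
    dplyr::group_by(.data$region) |>
    dplyr::mutate(q = bh_adjust(.data$p)) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      .data$probe_id, .data$gene_id, .data$region,
      .data$beta_coef, .data$p, .data$q,
      sign = ifelse(.data$beta_coef < 0, "-", "+"),
      model = model
    )
  genes <- res |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_cpg = dplyr::n(),
      n_sig = sum(.data$q < q_cut),
      n_pos = sum(.data$q < q_cut & .data$sign == "+"),
      n_neg = sum(.data$q < q_cut & .data$sign == "-"),
      associated = .data$n_sig > 0,
      .groups = "drop"
    )
  structure(list(assoc = res, genes = genes, skipped = skipped, model = model),
            class = "meth_assoc")
}

#' @export
print.meth_assoc <- function(x, ...) {
  cat(sprintf("<meth_assoc:%s> %d CpG-gene records, %d associated gene(s), %d skipped\n",
              x$model, nrow(x$assoc), sum(x$genes$associated), nrow(x$skipped)))
  invisible(x)
}

#' Permutation null for gene-level methylation-expression association
#'
#' The window-mean variant: per (gene, region window), the methylation
#' profile is the mean beta over the gene's probes assigned to that
#' window. Averaging within windows (rather than across the whole gene)
#' matters because promoter and gene-body methylation couple to expression
#' with opposite signs and would cancel in a pooled mean. Each permutation
#' shuffles the sample-column assignment of that methylation matrix
#' (expression and class labels stay fixed), refits the
#' cancer-type-corrected model per row, applies BH across rows, and counts
#' genes with at least one significant window. The observed count uses the
#' identity assignment.
#'
#' @param beta,counts,samples,assignments As in [fit_association()].
#' @param n_perm Number of shuffles (default 1000).
#' @param seed Integer seed for the shuffles.
#' @param q_cut Significance cut (default 0.05).
#' @param permute Optional test hook: `function(n, iter)` returning a
#'   permutation of `seq_len(n)`; defaults to a uniform random shuffle.
#' @return One-row tibble with `n_perm`, `observed_significant_genes`,
#'   `null_mean`, `null_sd`; the per-iteration counts are attached as the
#'   attribute `null_counts`.
#' @export
permutation_null <- function(beta, counts, samples, assignments,
                             n_perm = 1000, seed = 1, q_cut = 0.05,
                             permute = NULL) {
  stopifnot(n_perm >= 1)
  samples <- dplyr::filter(samples, .data$condition == "tumor")
  samp <- intersect(intersect(colnames(beta), colnames(counts)), samples$sample_id)
  cls <- samples$class_label[match(samp, samples$sample_id)]
  asn <- assignments |>
    dplyr::filter(.data$region != "igr",
                  .data$probe_id %in% rownames(beta),
                  .data$gene_id %in% rownames(counts))
  windows <- dplyr::distinct(asn, .data$gene_id, .data$region)
  B <- beta[, samp, drop = FALSE]
  M <- do.call(rbind, lapply(seq_len(nrow(windows)), function(i) {
    pr <- asn$probe_id[asn$gene_id == windows$gene_id[i] &
                       asn$region == windows$region[i]]
    colMeans(B[pr, , drop = FALSE])
  }))
  keep <- apply(M, 1, function(v) var(v) > 0)
  M <- M[keep, , drop = FALSE]
  windows <- windows[keep, ]
  expr <- log2_cpm(counts[, samp, drop = FALSE])
  Y <- expr[windows$gene_id, , drop = FALSE]
  cls_use <- if (length(unique(cls)) >= 2) cls else NULL

  count_sig <- function(Mx) {
    st <- assoc_rowwise(Mx, Y, class = cls_use)
    ok <- !st$zero_var_x
    q <- rep(NA_real_, nrow(Mx))
    q[ok] <- bh_adjust(st$p[ok])
    length(unique(windows$gene_id[!is.na(q) & q < q_cut]))
  }
  observed <- count_sig(M)
  null_counts <- withr::with_seed(derive_seed(seed, 7), {
    vapply(seq_len(n_perm), function(i) {
      idx <- if (is.null(permute)) sample(ncol(M)) else permute(ncol(M), i)
      count_sig(M[, idx, drop = FALSE])
    }, numeric(1))
  })
  out <- tibble::tibble(
    n_perm = as.integer(n_perm),
    observed_significant_genes = observed,
    null_mean = mean(null_counts),
    null_sd = if (n_perm > 1) sd(null_counts) else 0
  )
  attr(out, "null_counts") <- null_counts
  out
}
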