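#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment; a thin, validating
#' wrapper around [stats::p.adjust()]. Output preserves length and order,
#' each adjusted value lies in \[p, 1\], and adjusted values are monotone
#' in the ranks of the input.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  assert_probs(p)
  p.adjust(p, method = "BH")
}

#' Differential methylation by rank-sum test and delta-beta gate
#'
#' Per probe, a two-sided Mann-Whitney U (Wilcoxon rank-sum) test between
#' the two contrast groups plus the tumor-minus-normal mean beta difference.
#' The null is enumerated exactly when there are no ties and both groups
#' are small; otherwise a tie-corrected normal approximation with
#' continuity correction is used. BH adjustment is applied across all
#' probes in the call, and a probe is significant when `q < 0.05` and
#' `|delta_beta| > 0.2`.
#'
#' @param beta Complete (post-imputation) probes x samples beta matrix.
#' @param samples Sample sheet tibble covering the columns of `beta`.
#' @param group_by Column of `samples` defining the contrast (default
#'   `"condition"`).
#' @param contrast Length-2 character vector `c(case, reference)`; default
#'   `c("tumor", "normal")` so `delta_beta > 0` means hypermethylated in
#'   tumor.
#' @return Tibble with columns `probe_id`, `delta_beta`, `p`, `q`,
#'   `significant`, `direction`.
#' @export
diff_methylation <- function(beta, samples, group_by = "condition",
                             contrast = c("tumor", "normal")) {
  if (anyNA(beta)) stop("beta must be complete; run knn_impute() first", call. = FALSE)
  samples <- samples[match(colnames(beta), samples$sample_id), ]
  g <- samples[[group_by]]
  case <- colnames(beta)[g == contrast[1]]
  ref <- colnames(beta)[g == contrast[2]]
  if (length(case) < 2 || length(ref) < 2) {
    stop("both contrast groups need at least 2 samples", call. = FALSE)
  }
  res <- apply(beta, 1, function(v) {
    rank_sum_test(v[case], v[ref])$p
  })
  delta <- rowMeans(beta[, case, drop = FALSE]) - rowMeans(beta[, ref, drop = FALSE])
  q <- bh_adjust(res)
  tibble::tibble(
    probe_id = rownames(beta),
    delta_beta = unname(delta),
    p = unname(res),
    q = q,
    significant = unname(q < 0.05 & abs(delta) > 0.2),
    direction = unname(ifelse(delta > 0, "hyper", "hypo"))
  )
}

#' Differential expression by moderated t-test on log2 CPM
#'
#' Counts are scaled to counts-per-million per sample and transformed to
#' `log2(CPM + 1)`. Each gene is tested with a two-sample t-statistic whose
#' pooled variance is shrunk halfway toward the mean pooled variance of all
#' genes (weight 0.5), a light empirical-Bayes moderation that stabilises
#' small-sample variance estimates. The log2 fold-change is the group mean
#' difference on the transformed scale; BH adjustment runs across genes,
#' and significance requires `q < 0.05` and `|log2fc| > 2`. Genes with zero
#' counts throughout are reported with `log2fc = 0, p = 1`.
#'
#' @param counts Genes x samples count matrix.
#' @param samples Sample sheet tibble covering the columns of `counts`.
#' @param group_by Column of `samples` defining the contrast.
#' @param contrast Length-2 character vector `c(case, reference)`.
#' @return Tibble with columns `gene_id`, `log2fc`, `p`, `q`, `significant`.
#' @export
diff_expression <- function(counts, samples, group_by = "condition",
                            contrast = c("tumor", "normal")) {
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  g <- samples[[group_by]]
  case <- g == contrast[1]
  ref <- g == contrast[2]
  if (sum(case) < 2 || sum(ref) < 2) {
    stop("both contrast groups need at least 2 samples", call. = FALSE)
  }
  expr <- log2_cpm(counts)
  a <- expr[, case, drop = FALSE]
  b <- expr[, ref, drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  pooled <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  shrunk <- 0.5 * pooled + 0.5 * mean(pooled)
  lfc <- m1 - m2
  tstat <- lfc / sqrt(shrunk * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  p <- 2 * pt(-abs(tstat), df)
  p[!is.finite(tstat)] <- 1
  zero <- rowSums(counts[, case | ref, drop = FALSE]) == 0
  lfc[zero] <- 0
  p[zero] <- 1
  q <- bh_adjust(p)
  tibble::tibble(
    gene_id = rownames(counts),
    log2fc = unname(lfc),
    p = unname(p),
    q = q,
    significant = q < 0.05 & abs(lfc) > 2
  )
}
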