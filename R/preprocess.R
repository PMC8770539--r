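#' Filter invalid or ambiguous CpG probes
#'
#' Removes probes on chromosomes X and Y, SNP-overlapping probes,
#' multi-mapping probes, and probes with strictly more than 50% missing
#' values. Each removed probe is attributed to the first matching rule in
#' the order XY > SNP > multimap > missing, so the report counts are
#' deterministic and sum (with `kept`) to the input probe count. The order
#' of the remaining probes is preserved.
#'
#' @param beta Probes x samples beta matrix (may contain `NA`).
#' @param manifest Probe manifest tibble ([read_probe_manifest()]); every
#'   probe in `beta` must be present.
#' @return List with `beta` (filtered matrix) and `report` (one-row tibble
#'   with `removed_xy`, `removed_snp`, `removed_multimap`,
#'   `removed_missing`, `kept`).
#' @export
filter_probes <- function(beta, manifest) {
  absent <- setdiff(rownames(beta), manifest$probe_id)
  if (length(absent)) {
    stop("probes absent from manifest: ", paste(head(absent, 5), collapse = ", "),
         call. = FALSE)
  }
  m <- manifest[match(rownames(beta), manifest$probe_id), ]
  miss_frac <- rowMeans(is.na(beta))
  xy <- m$chrom %in% c("chrX", "chrY", "X", "Y")
  snp <- !xy & m$snp_flag
  multi <- !xy & !snp & m$multimap_flag
  miss <- !xy & !snp & !multi & miss_frac > 0.5
  keep <- !(xy | snp | multi | miss)
  list(
    beta = beta[keep, , drop = FALSE],
    report = tibble::tibble(
      removed_xy = sum(xy), removed_snp = sum(snp),
      removed_multimap = sum(multi), removed_missing = sum(miss),
      kept = sum(keep)
    )
  )
}

#' K-nearest-neighbour imputation of missing beta values
#'
#' For a missing cell (probe p, sample s), the k probes nearest to p by
#' Euclidean distance over pairwise-complete samples (scaled to the number
#' of shared samples) that are observed in sample s are averaged. Observed
#' entries are never altered, and imputed values stay within \[0, 1\]
#' because they are means of beta values.
#'
#' @param beta Probes x samples beta matrix after [filter_probes()] (no
#'   probe above 50% missing).
#' @param k Number of neighbouring probes to average (default 10).
#' @return A complete beta matrix.
#' @export
knn_impute <- function(beta, k = 10) {
  stopifnot(k >= 1)
  if (!anyNA(beta)) return(beta)
  if (any(colSums(!is.na(beta)) == 0)) {
    bad <- colnames(beta)[colSums(!is.na(beta)) == 0][1]
    stop("sample with all values missing: ", bad, call. = FALSE)
  }
  obs <- !is.na(beta)
  z <- beta
  z[!obs] <- 0
  w <- obs * 1
  # pairwise-complete squared Euclidean distances via cross-products:
  # sum over shared samples of (z_i - z_j)^2, scaled by the shared count
  q <- z^2
  cross <- tcrossprod(z)
  qw <- tcrossprod(q, w)
  n_shared <- tcrossprod(w)
  d2 <- (qw + t(qw) - 2 * cross) / n_shared
  d2[n_shared == 0] <- Inf
  d2 <- pmax(d2, 0)
  diag(d2) <- Inf

  out <- beta
  probe_ids <- rownames(beta)
  for (i in which(rowSums(!obs) > 0)) {
    dist_i <- d2[i, ]
    ord <- order(dist_i, probe_ids)
    for (s in which(!obs[i, ])) {
      cand <- ord[obs[ord, s] & is.finite(dist_i[ord])]
      if (!length(cand)) {
        out[i, s] <- mean(beta[i, ], na.rm = TRUE)
        next
      }
      nb <- cand[seq_len(min(k, length(cand)))]
      out[i, s] <- mean(beta[nb, s])
    }
  }
  out
}
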