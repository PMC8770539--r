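#' One-vs-rest tissue-specificity filter for CpG candidates
#'
#' Per (probe, class): a Welch two-sample t-test of the class's tumor
#' samples against all other tumor samples, BH-adjusted across probes
#' within the class. The dispersion gate uses the pooled standard
#' deviation of the probe's beta across all tumor samples (high
#' between-class spread implies high pooled SD). A candidate passes when
#' `ovr_q < 0.05` and `sd > 0.2`.
#'
#' @param beta Complete probes x samples beta matrix.
#' @param samples Sample sheet; only tumor samples enter the test.
#' @param candidates Character vector of candidate probe ids (typically
#'   probes of epi-driver genes); default all probes in `beta`.
#' @param sd_scope `"pooled"` (default) or `"class"` — whether the SD gate
#'   uses all tumor samples or only the class's own.
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @return Tibble with columns `probe_id`, `class_label`, `ovr_p`,
#'   `ovr_q`, `sd`, `passes`.
#' @export
ovr_specific_filter <- function(beta, samples, candidates = rownames(beta),
                                sd_scope = c("pooled", "class"),
                                adjust = c("BH", "bonferroni")) {
  sd_scope <- match.arg(sd_scope)
  adjust <- match.arg(adjust)
  tum <- tumor_samples(samples)
  tum <- tum[tum$sample_id %in% colnames(beta), ]
  if (length(unique(tum$class_label)) < 2) {
    stop("need at least 2 tumor classes", call. = FALSE)
  }
  candidates <- intersect(candidates, rownames(beta))
  if (!length(candidates)) stop("no candidate probes present in beta", call. = FALSE)
  B <- beta[candidates, tum$sample_id, drop = FALSE]
  pooled_sd <- apply(B, 1, sd)

  classes <- sort(unique(tum$class_label))
  res <- purrr::map_dfr(classes, function(cl) {
    own <- tum$sample_id[tum$class_label == cl]
    rest <- tum$sample_id[tum$class_label != cl]
    if (length(own) < 3) {
      warning("class ", cl, " has fewer than 3 tumor samples; skipped")
      return(NULL)
    }
    wt <- welch_rows(B[, own, drop = FALSE], B[, rest, drop = FALSE])
    sd_val <- if (sd_scope == "pooled") pooled_sd else
      apply(B[, own, drop = FALSE], 1, sd)
    q <- if (adjust == "BH") bh_adjust(wt$p) else pmin(1, wt$p * length(wt$p))
    tibble::tibble(
      probe_id = candidates, class_label = cl,
      ovr_p = wt$p, ovr_q = q, sd = unname(sd_val),
      passes = q < 0.05 & sd_val > 0.2
    )
  })
  res
}

#' Rank passing probes by gradient-boosted Shapley attribution
#'
#' Fits a multiclass gradient-boosted tree ensemble (xgboost, fixed seed
#' and depth/rounds) on the training tumor samples and computes exact
#' per-sample, per-class tree-Shapley attributions; a probe's importance
#' is the mean absolute attribution over samples and classes. Ties are
#' broken by probe id.
#'
#' @param beta Complete probes x samples beta matrix restricted (by
#'   `probes`) to filter-passing candidates.
#' @param samples Sample sheet; tumor samples (of the `"train"` cohort if
#'   cohorts are assigned) are used.
#' @param probes Probes to rank (default all rows of `beta`).
#' @param nrounds,max_depth,eta Booster configuration (defaults 200, 3,
#'   0.1).
#' @param seed Integer seed.
#' @return A `marker_ranking` object: tibble with `probe_id`, `rank`,
#'   `importance` in non-increasing order.
#' @export
shapley_rank <- function(beta, samples, probes = rownames(beta),
                         nrounds = 200, max_depth = 3, eta = 0.1, seed = 1) {
  tum <- tumor_samples(samples)
  if (any(!is.na(tum$cohort))) tum <- dplyr::filter(tum, .data$cohort == "train")
  tum <- tum[tum$sample_id %in% colnames(beta), ]
  classes <- sort(unique(tum$class_label))
  if (length(classes) < 2) stop("need at least 2 tumor classes", call. = FALSE)
  probes <- intersect(probes, rownames(beta))
  if (!length(probes)) stop("no passing probes to rank", call. = FALSE)

  X <- t(beta[probes, tum$sample_id, drop = FALSE])
  y <- match(tum$class_label, classes) - 1L
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  params <- list(objective = "multi:softprob", num_class = length(classes),
                 max_depth = max_depth, eta = eta, nthread = 1,
                 seed = derive_seed(seed, 11))
  fit <- withr::with_seed(derive_seed(seed, 11), {
    xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                       verbose = 0)
  })
  contrib <- predict(fit, dtrain, predcontrib = TRUE)
  # samples x classes x (features, intercept) for multiclass; drop the
  # intercept column and average |attribution| over samples and classes
  if (length(dim(contrib)) == 3) {
    imp <- apply(abs(contrib[, , seq_along(probes), drop = FALSE]), 3, mean)
  } else {
    imp <- colMeans(abs(contrib[, seq_along(probes), drop = FALSE]))
  }
  names(imp) <- probes
  ord <- order(-imp, probes)
  out <- tibble::tibble(
    probe_id = probes[ord],
    rank = seq_along(probes),
    importance = unname(imp[ord])
  )
  class(out) <- c("marker_ranking", class(out))
  out
}

#' Cross-validated accuracy of nested top-k marker panels
#'
#' For k = 1..K (K capped by `max_k`), measures the 10-fold
#' cross-validated accuracy of a random forest trained on the top-k ranked
#' probes, on training tumor samples. Folds are stratified by class and
#' shared across k so that increments reflect the added probe, not fold
#' noise.
#'
#' @param beta Complete probes x samples beta matrix.
#' @param samples Sample sheet (training tumor samples are used).
#' @param ranking A `marker_ranking` from [shapley_rank()].
#' @param max_k Largest panel size evaluated (default: all ranked probes).
#' @param n_folds Number of CV folds (default 10).
#' @param n_trees Trees in each forest (default 100).
#' @param seed Integer seed.
#' @return Tibble with `k` and `cumulative_accuracy`.
#' @export
panel_accuracy_curve <- function(beta, samples, ranking,
                                 max_k = nrow(ranking), n_folds = 10,
                                 n_trees = 100, seed = 1) {
  tum <- tumor_samples(samples)
  if (any(!is.na(tum$cohort))) tum <- dplyr::filter(tum, .data$cohort == "train")
  tum <- tum[tum$sample_id %in% colnames(beta), ]
  y <- factor(tum$class_label)
  K <- min(max_k, nrow(ranking))
  folds <- withr::with_seed(derive_seed(seed, 12), {
    unsplit(lapply(split(seq_along(y), y), function(idx) {
      sample(rep_len(seq_len(n_folds), length(idx)))
    }), y)
  })
  X_full <- t(beta[ranking$probe_id[seq_len(K)], tum$sample_id, drop = FALSE])
  acc <- vapply(seq_len(K), function(k) {
    X <- X_full[, seq_len(k), drop = FALSE]
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      if (!any(!tr)) next
      fit <- withr::with_seed(derive_seed(seed, 13L + f), {
        randomForest::randomForest(X[tr, , drop = FALSE], y[tr], ntree = n_trees)
      })
      pred[!tr] <- predict(fit, X[!tr, , drop = FALSE])
    }
    mean(pred == y, na.rm = TRUE)
  }, numeric(1))
  tibble::tibble(k = seq_len(K), cumulative_accuracy = acc)
}

#' Plateau rule for panel size selection
#'
#' Given the cumulative accuracy sequence over nested panels, returns the
#' smallest k whose next `m` increments each improve accuracy by less than
#' `eps`; if the rule never fires, returns `K` (the full sequence length).
#'
#' @param cumulative_accuracy Numeric vector, accuracy at k = 1..K.
#' @param eps Improvement floor (> 0; default 0.005).
#' @param m Patience: number of consecutive sub-`eps` increments required
#'   (default 2).
#' @return Selected panel size `k`.
#' @export
select_plateau_k <- function(cumulative_accuracy, eps = 0.005, m = 2) {
  stopifnot(length(cumulative_accuracy) >= 1, eps > 0, m >= 1)
  K <- length(cumulative_accuracy)
  inc <- diff(cumulative_accuracy)
  for (k in seq_len(max(0L, K - m))) {
    nxt <- inc[k:(k + m - 1)]
    if (all(nxt < eps)) return(k)
  }
  K
}

#' Two-stage marker panel selection
#'
#' Convenience wrapper chaining [ovr_specific_filter()], [shapley_rank()],
#' [panel_accuracy_curve()] and [select_plateau_k()].
#'
#' @param beta,samples As above.
#' @param candidates Candidate probe ids (typically epi-driver probes).
#' @param eps,m Plateau parameters.
#' @param max_k Largest panel size evaluated.
#' @param seed Integer seed.
#' @return List of class `marker_panel` with `candidates` (filter table),
#'   `ranking`, `curve`, `selected_k` and `panel` (selected probe ids).
#' @export
select_markers <- function(beta, samples, candidates = rownames(beta),
                           eps = 0.005, m = 2, max_k = 25, seed = 1) {
  cand <- ovr_specific_filter(beta, samples, candidates)
  passing <- unique(cand$probe_id[cand$passes])
  if (!length(passing)) stop("no probes pass the one-vs-rest filter", call. = FALSE)
  ranking <- shapley_rank(beta, samples, probes = passing, seed = seed)
  curve <- panel_accuracy_curve(beta, samples, ranking, max_k = max_k, seed = seed)
  k <- select_plateau_k(curve$cumulative_accuracy, eps = eps, m = m)
  structure(
    list(candidates = cand, ranking = ranking, curve = curve,
         selected_k = k, panel = ranking$probe_id[seq_len(k)]),
    class = "marker_panel"
  )
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("<marker_panel> %d candidate(s) passing, selected k = %d\n",
              length(unique(x$candidates$probe_id[x$candidates$passes])),
              x$selected_k))
  cat("  panel:", paste(x$panel, collapse = ", "), "\n")
  invisible(x)
}
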