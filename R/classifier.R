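#' Stratified 7:3 cohort split
#'
#' Fills the `cohort` column of the sample sheet with `train`/`test`,
#' stratified per class at the given ratio with rounding toward training.
#' Matched tumor/normal pairs are treated as one unit and never split
#' across cohorts. Samples whose cohort is already set (e.g. `external`)
#' are left untouched.
#'
#' @param samples Sample sheet tibble.
#' @param ratio Training fraction (default 0.7).
#' @param seed Integer seed; the assignment is deterministic under it.
#' @return The sample sheet with `cohort` filled.
#' @export
split_cohort <- function(samples, ratio = 0.7, seed = 1) {
  fill <- is.na(samples$cohort)
  units <- samples[fill, ] |>
    dplyr::mutate(unit = ifelse(is.na(.data$pair_id),
                                paste0("sample:", .data$sample_id),
                                paste0("pair:", .data$pair_id)))
  per_class <- units |>
    dplyr::filter(.data$condition == "tumor") |>
    dplyr::count(.data$class_label)
  if (any(per_class$n < 4)) {
    stop("class with fewer than 4 tumor samples: ",
         paste(per_class$class_label[per_class$n < 4], collapse = ", "),
         call. = FALSE)
  }
  assign <- withr::with_seed(derive_seed(seed, 21), {
    units |>
      dplyr::distinct(.data$unit, .data$class_label) |>
      dplyr::group_by(.data$class_label) |>
      dplyr::group_modify(function(df, key) {
        idx <- sample(nrow(df))
        n_train <- ceiling(ratio * nrow(df))
        df$cohort_new <- "test"
        df$cohort_new[idx[seq_len(n_train)]] <- "train"
        df
      }) |>
      dplyr::ungroup()
  })
  units <- dplyr::left_join(units, assign[, c("unit", "cohort_new")], by = "unit")
  samples$cohort[fill] <- units$cohort_new
  samples
}

#' Under-sample the rest classes to balance a one-vs-rest task
#'
#' Keeps every positive-class sample and draws rest-class samples without
#' replacement to match the positive count, allocated as evenly as
#' possible across the rest classes (remainder slots assigned by a seeded
#' draw). When the rest pool is smaller than the positive count, all rest
#' samples are kept with a warning.
#'
#' @param samples Tibble with `sample_id` and `class_label` (the
#'   one-vs-rest view, e.g. training tumor samples).
#' @param positive_class The class treated as positive.
#' @param seed Integer seed.
#' @return Character vector of selected sample ids (positives first).
#' @export
undersample_balance <- function(samples, positive_class, seed = 1) {
  pos <- samples$sample_id[samples$class_label == positive_class]
  if (!length(pos)) stop("positive class is empty", call. = FALSE)
  rest <- samples[samples$class_label != positive_class, ]
  if (nrow(rest) <= length(pos)) {
    if (nrow(rest) < length(pos)) {
      warning("rest pool smaller than positive count; keeping all rest samples")
    }
    return(c(pos, rest$sample_id))
  }
  withr::with_seed(derive_seed(seed, 22), {
    rest_classes <- sort(unique(rest$class_label))
    base <- length(pos) %/% length(rest_classes)
    quota <- setNames(rep(base, length(rest_classes)), rest_classes)
    rem <- length(pos) - base * length(rest_classes)
    if (rem > 0) {
      bump <- sample(rest_classes, rem)
      quota[bump] <- quota[bump] + 1
    }
    picked <- unlist(lapply(rest_classes, function(cl) {
      ids <- rest$sample_id[rest$class_label == cl]
      sample(ids, min(quota[[cl]], length(ids)))
    }), use.names = FALSE)
    c(pos, picked)
  })
}

#' Train the under-sampled one-vs-rest origin forest
#'
#' For each class: balances the training tumor samples with
#' [undersample_balance()], grid-searches the number of trees (10-100) and
#' the splitting criterion (gini, entropy) by out-of-bag score (ties go to
#' fewer trees, then gini), fits the final binary forest, and records
#' 10-fold cross-validated accuracy and AUC on the balanced set.
#'
#' @param beta Complete probes x samples beta matrix containing the panel.
#' @param samples Sample sheet with cohorts assigned ([split_cohort()]).
#' @param panel Ordered marker probe ids.
#' @param grid List with `n_trees` (vector within 10-100) and `criterion`
#'   (subset of `c("gini", "entropy")`).
#' @param n_folds Cross-validation folds (default 10).
#' @param seed Integer seed.
#' @return An `origin_model`: list with the panel, per-class forests and
#'   chosen hyperparameters, class prevalences, fold-level CV metrics and
#'   training metadata.
#' @export
train_ovr_forest <- function(beta, samples, panel,
                             grid = list(n_trees = seq(10, 100, by = 10),
                                         criterion = c("gini", "entropy")),
                             n_folds = 10, seed = 1) {
  missing_probes <- setdiff(panel, rownames(beta))
  if (length(missing_probes)) {
    stop("panel probes missing from beta: ",
         paste(missing_probes, collapse = ", "), call. = FALSE)
  }
  tum <- tumor_samples(samples)
  if (any(!is.na(tum$cohort))) tum <- dplyr::filter(tum, .data$cohort == "train")
  tum <- tum[tum$sample_id %in% colnames(beta), ]
  classes <- sort(unique(tum$class_label))
  X_all <- t(beta[panel, tum$sample_id, drop = FALSE])

  forests <- list()
  chosen <- list()
  cv <- list()
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    ids <- undersample_balance(tum[, c("sample_id", "class_label")], cl,
                               seed = derive_seed(seed, 30L + ci))
    X <- X_all[ids, , drop = FALSE]
    y <- factor(ifelse(tum$class_label[match(ids, tum$sample_id)] == cl,
                       "pos", "rest"), levels = c("rest", "pos"))

    # grid search: fit the largest forest once per criterion, score OOB on
    # nested tree subsets
    cand <- tidyr::expand_grid(criterion = grid$criterion, n_trees = sort(grid$n_trees))
    fits <- lapply(unique(cand$criterion), function(cr) {
      cart_forest(X, y, n_trees = max(grid$n_trees), criterion = cr,
                  seed = derive_seed(seed, 40L + ci))
    })
    names(fits) <- unique(cand$criterion)
    cand$oob <- purrr::map2_dbl(cand$criterion, cand$n_trees, function(cr, t) {
      oob_accuracy(fits[[cr]], X, y, n_trees = t)
    })
    ord <- order(-cand$oob, cand$n_trees,
                 match(cand$criterion, c("gini", "entropy")))
    best <- cand[ord[1], ]
    final <- fits[[best$criterion]]
    final$trees <- final$trees[seq_len(best$n_trees)]

    folds <- withr::with_seed(derive_seed(seed, 50L + ci), {
      unsplit(lapply(split(seq_along(y), y), function(idx) {
        sample(rep_len(seq_len(min(n_folds, length(idx))), length(idx)))
      }), y)
    })
    for (f in sort(unique(folds))) {
      tr <- folds != f
      fit_f <- cart_forest(X[tr, , drop = FALSE], y[tr],
                           n_trees = best$n_trees, criterion = best$criterion,
                           seed = derive_seed(seed, 60L + ci * 10L + f))
      pr <- predict_cart_forest(fit_f, X[!tr, , drop = FALSE])[, "pos"]
      truth <- y[!tr]
      cv[[length(cv) + 1L]] <- tibble::tibble(
        class_label = cl, fold = f,
        accuracy = mean((pr >= 0.5) == (truth == "pos")),
        auc = auc_rank(pr[truth == "pos"], pr[truth == "rest"])
      )
    }
    forests[[cl]] <- final
    chosen[[cl]] <- tibble::tibble(class_label = cl, n_trees = best$n_trees,
                                   criterion = best$criterion, oob_score = best$oob,
                                   n_balanced = length(ids))
  }
  structure(
    list(version = 1L, panel = panel, classes = classes, forests = forests,
         chosen = dplyr::bind_rows(chosen),
         prevalence = table(tum$class_label),
         cv = dplyr::bind_rows(cv),
         seed = as.integer(seed), grid = grid),
    class = "origin_model"
  )
}

#' @export
print.origin_model <- function(x, ...) {
  cat(sprintf("<origin_model v%d> %d classes, panel of %d probes\n",
              x$version, length(x$classes), length(x$panel)))
  print(x$chosen)
  invisible(x)
}

#' Predict the tissue of origin of new samples
#'
#' Per-class probability is the class's binary forest positive probability
#' renormalised across classes to sum to one; the label is the argmax,
#' with ties broken toward the class with larger training prevalence, then
#' lexicographically. All panel probes must be present and complete — no
#' silent imputation.
#'
#' @param model An `origin_model`.
#' @param beta Probes x samples beta matrix of the new samples.
#' @return Tibble with `sample_id`, `predicted_class` and one probability
#'   column per class.
#' @export
predict_origin <- function(model, beta) {
  missing_probes <- setdiff(model$panel, rownames(beta))
  if (length(missing_probes)) {
    stop("panel probes missing from beta: ",
         paste(missing_probes, collapse = ", "), call. = FALSE)
  }
  X <- t(beta[model$panel, , drop = FALSE])
  if (anyNA(X)) stop("beta contains missing values for panel probes", call. = FALSE)
  raw <- vapply(model$classes, function(cl) {
    predict_cart_forest(model$forests[[cl]], X)[, "pos"]
  }, numeric(nrow(X)))
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1, dimnames = list(NULL, model$classes))
  tot <- rowSums(raw)
  probs <- raw / ifelse(tot > 0, tot, 1)
  probs[tot == 0, ] <- 1 / length(model$classes)
  prev <- as.numeric(model$prevalence[model$classes])
  prev[is.na(prev)] <- 0
  pick <- apply(probs, 1, function(p) {
    model$classes[order(-p, -prev, model$classes)[1]]
  })
  out <- tibble::as_tibble(probs)
  names(out) <- paste0("prob_", model$classes)
  dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(X), predicted_class = unname(pick)),
    out
  )
}

#' Evaluate an origin model on a held-out cohort
#'
#' Computes per-class one-vs-rest AUC (rank statistic), per-class OVR
#' accuracy and overall argmax accuracy on the requested cohort, with 95%
#' confidence intervals from stratified bootstrap resampling of the test
#' samples (`estimate +- 1.96 * bootstrap SE`, clipped to \[0, 1\]).
#' Fold-level cross-validation metrics recorded at training time ride
#' along in `folds`.
#'
#' @param model An `origin_model`.
#' @param beta Complete probes x samples beta matrix.
#' @param samples Sample sheet; rows with `cohort == cohort_name` and
#'   `condition == "tumor"` form the evaluation set.
#' @param cohort_name Cohort to evaluate (default `"test"`).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return A `classifier_report`: list with `per_class`, `overall`,
#'   `confusion` (rows = true classes), `predictions` and `folds`.
#' @export
evaluate_origin <- function(model, beta, samples, cohort_name = "test",
                            n_boot = 1000, seed = 1) {
  ev <- tumor_samples(samples, cohort = cohort_name)
  ev <- ev[ev$sample_id %in% colnames(beta), ]
  if (!nrow(ev)) stop("no tumor samples in cohort '", cohort_name, "'", call. = FALSE)
  extra <- setdiff(unique(ev$class_label), model$classes)
  if (length(extra)) {
    warning("test class(es) absent from model skipped: ",
            paste(extra, collapse = ", "))
    ev <- ev[!ev$class_label %in% extra, ]
  }
  pred <- predict_origin(model, beta[, ev$sample_id, drop = FALSE])
  truth <- ev$class_label
  probs <- as.matrix(pred[, paste0("prob_", model$classes)])

  metric_set <- function(idx) {
    tr <- truth[idx]
    pc <- pred$predicted_class[idx]
    pb <- probs[idx, , drop = FALSE]
    per <- vapply(model$classes, function(cl) {
      pos <- tr == cl
      c(auc = auc_rank(pb[pos, paste0("prob_", cl)], pb[!pos, paste0("prob_", cl)]),
        acc = mean((pc == cl) == pos))
    }, numeric(2))
    list(per = per, overall = mean(pc == tr))
  }
  obs <- metric_set(seq_along(truth))
  boots <- withr::with_seed(derive_seed(seed, 70), {
    idx_by_class <- split(seq_along(truth), truth)
    lapply(seq_len(n_boot), function(b) {
      idx <- unlist(lapply(idx_by_class, function(ix) sample(ix, length(ix),
                                                             replace = TRUE)))
      metric_set(idx)
    })
  })
  boot_auc <- sapply(boots, function(b) b$per["auc", ])
  boot_acc <- sapply(boots, function(b) b$per["acc", ])
  if (is.null(dim(boot_auc))) {
    boot_auc <- matrix(boot_auc, nrow = 1, dimnames = list(model$classes))
    boot_acc <- matrix(boot_acc, nrow = 1, dimnames = list(model$classes))
  }
  boot_overall <- vapply(boots, function(b) b$overall, numeric(1))
  ci <- function(est, draws) {
    se <- sd(draws)
    c(lo = max(0, est - 1.96 * se), hi = min(1, est + 1.96 * se))
  }
  per_class <- purrr::map_dfr(seq_along(model$classes), function(i) {
    cl <- model$classes[i]
    a_ci <- ci(obs$per["auc", i], boot_auc[i, ])
    c_ci <- ci(obs$per["acc", i], boot_acc[i, ])
    tibble::tibble(
      class_label = cl, n_test = sum(truth == cl),
      accuracy = obs$per["acc", i], accuracy_lo = c_ci["lo"], accuracy_hi = c_ci["hi"],
      auc = obs$per["auc", i], auc_lo = a_ci["lo"], auc_hi = a_ci["hi"]
    )
  })
  o_ci <- ci(obs$overall, boot_overall)
  confusion <- table(factor(truth, levels = model$classes),
                     factor(pred$predicted_class, levels = model$classes))
  structure(
    list(per_class = per_class,
         overall = tibble::tibble(accuracy = obs$overall,
                                  accuracy_lo = o_ci["lo"], accuracy_hi = o_ci["hi"],
                                  n_test = length(truth)),
         confusion = confusion, predictions = pred, folds = model$cv,
         cohort = cohort_name),
    class = "classifier_report"
  )
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report:%s> overall accuracy %.3f [%.3f, %.3f] (n=%d)\n",
              x$cohort, x$overall$accuracy, x$overall$accuracy_lo,
              x$overall$accuracy_hi, x$overall$n_test))
  print(x$per_class)
  invisible(x)
}

#' Serialise / reload an origin model
#'
#' The model is written as a versioned R serialisation (uncompressed, so
#' identical models produce identical bytes).
#'
#' @param model An `origin_model`.
#' @param path Destination file.
#' @return `path` invisibly.
#' @export
write_origin_model <- function(model, path) {
  stopifnot(inherits(model, "origin_model"))
  saveRDS(model, path, compress = FALSE)
  invisible(path)
}

#' @rdname write_origin_model
#' @export
read_origin_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "origin_model") || is.null(model$version)) {
    stop("not a serialised origin_model", call. = FALSE)
  }
  model
}
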