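# linearly separable two-class beta fixture over a 4-probe panel
separable_fixture <- function(seed = 1, n_per_class = 40) {
  withr::with_seed(seed, {
    cls <- rep(c("A", "B"), each = n_per_class)
    n_s <- length(cls)
    beta <- matrix(0.2, 4, n_s,
                   dimnames = list(sprintf("cg%02d", 1:4), sprintf("S%03d", 1:n_s)))
    beta[1:2, cls == "A"] <- 0.8
    beta[3:4, cls == "B"] <- 0.8
    beta <- pmin(pmax(beta + rnorm(length(beta), 0, 0.05), 0.001), 0.999)
    samples <- mk_samples(colnames(beta), class_label = cls, condition = "tumor")
    list(beta = beta, samples = samples)
  })
}

test_that("the stratified split honours the ratio, rounding and pair integrity", {
  s100 <- mk_samples(sprintf("S%03d", 1:100), class_label = "A", condition = "tumor")
  out <- split_cohort(s100, ratio = 0.7, seed = 1)
  expect_equal(sum(out$cohort == "train"), 70)
  expect_equal(sum(out$cohort == "test"), 30)

  s11 <- mk_samples(sprintf("S%02d", 1:11), class_label = "A", condition = "tumor")
  out11 <- split_cohort(s11, ratio = 0.7, seed = 1)
  expect_equal(sum(out11$cohort == "train"), 8)  # ceiling(7.7), toward train

  expect_identical(split_cohort(s100, seed = 7), split_cohort(s100, seed = 7))

  b <- simulate_bundle(small_cfg(seed = 2))
  sp <- split_cohort(b$samples, seed = 3)
  per_pair <- tapply(sp$cohort, sp$pair_id, function(x) length(unique(x)))
  expect_true(all(per_pair == 1))

  tiny <- mk_samples(sprintf("S%d", 1:3), class_label = "A", condition = "tumor")
  expect_error(split_cohort(tiny), "fewer than 4")
})

test_that("under-sampling balances the rest classes evenly and deterministically", {
  sm <- tibble::tibble(
    sample_id = sprintf("S%03d", 1:330),
    class_label = c(rep("P", 30), rep(sprintf("R%02d", 1:10), each = 30))
  )
  ids <- undersample_balance(sm, "P", seed = 1)
  expect_length(ids, 60)
  picked <- table(sm$class_label[match(setdiff(ids, sm$sample_id[1:30]), sm$sample_id)])
  expect_true(all(picked == 3))
  expect_identical(undersample_balance(sm, "P", seed = 4),
                   undersample_balance(sm, "P", seed = 4))

  small <- tibble::tibble(sample_id = sprintf("S%d", 1:17),
                          class_label = c(rep("P", 10), rep("R", 7)))
  expect_warning(ids2 <- undersample_balance(small, "P", seed = 1), "rest pool")
  expect_length(ids2, 17)
})

test_that("a separable fixture trains to high held-out accuracy within the stated grid", {
  fx <- separable_fixture(seed = 5)
  sam <- split_cohort(fx$samples, ratio = 0.7, seed = 5)
  model <- train_ovr_forest(fx$beta, sam, panel = rownames(fx$beta), seed = 5)
  expect_true(all(model$chosen$n_trees >= 10 & model$chosen$n_trees <= 100))
  expect_true(all(model$chosen$criterion %in% c("gini", "entropy")))
  rep <- evaluate_origin(model, fx$beta, sam, n_boot = 100, seed = 5)
  expect_gte(rep$overall$accuracy, 0.95)
  expect_true(all(rep$per_class$auc >= 0.95))
  expect_equal(as.numeric(rowSums(rep$confusion)),
               as.numeric(table(sam$class_label[sam$cohort == "test" &
                                                sam$condition == "tumor"])[model$classes]))
  # tidy/glance accessors
  expect_equal(nrow(tidy(model)), 2L)
  expect_equal(glance(rep)$accuracy, rep$overall$accuracy)
})

test_that("shuffled labels give chance-level cross-validated AUC", {
  aucs <- vapply(1:5, function(seed) {
    fx <- separable_fixture(seed = 50 + seed)
    withr::with_seed(seed, {
      fx$samples$class_label <- sample(fx$samples$class_label)
    })
    sam <- split_cohort(fx$samples, ratio = 0.7, seed = seed)
    model <- train_ovr_forest(fx$beta, sam, panel = rownames(fx$beta),
                              grid = list(n_trees = c(50), criterion = "gini"),
                              seed = seed)
    mean(model$cv$auc)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("origin probabilities renormalise, break ties deterministically, and guard inputs", {
  fx <- separable_fixture(seed = 9)
  sam <- split_cohort(fx$samples, ratio = 0.7, seed = 9)
  model <- train_ovr_forest(fx$beta, sam, panel = rownames(fx$beta), seed = 9)
  pred <- predict_origin(model, fx$beta)
  probs <- as.matrix(pred[, paste0("prob_", model$classes)])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-9))
  expect_error(predict_origin(model, fx$beta[-1, , drop = FALSE]), "cg01")
  expect_error(train_ovr_forest(fx$beta[-1, , drop = FALSE], sam,
                                panel = rownames(fx$beta)), "cg01")
  nab <- fx$beta
  nab[1, 1] <- NA
  expect_error(predict_origin(model, nab), "missing values")
})

test_that("a fixed seed reproduces the model and report bit-exactly, and models reload", {
  fx <- separable_fixture(seed = 3)
  sam <- split_cohort(fx$samples, ratio = 0.7, seed = 3)
  m1 <- train_ovr_forest(fx$beta, sam, panel = rownames(fx$beta), seed = 3)
  m2 <- train_ovr_forest(fx$beta, sam, panel = rownames(fx$beta), seed = 3)
  expect_identical(serialize(m1, NULL), serialize(m2, NULL))
  r1 <- evaluate_origin(m1, fx$beta, sam, n_boot = 50, seed = 3)
  r2 <- evaluate_origin(m2, fx$beta, sam, n_boot = 50, seed = 3)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))

  path <- withr::local_tempfile(fileext = ".rds")
  write_origin_model(m1, path)
  m3 <- read_origin_model(path)
  expect_identical(serialize(m1, NULL), serialize(m3, NULL))
  pred1 <- predict_origin(m1, fx$beta)
  pred3 <- predict_origin(m3, fx$beta)
  expect_identical(pred1, pred3)
})

test_that("the rank AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(8, {
    for (i in 1:10) {
      y <- rbinom(40, 1, 0.5)
      if (length(unique(y)) < 2) next
      s <- rnorm(40, y)
      mine <- methorigin:::auc_rank(s[y == 1], s[y == 0])
      ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                            direction = "<")))
      expect_equal(mine, ref, tolerance = 1e-12)
    }
  })
})
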