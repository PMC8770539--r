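# 5-class tumor-only beta fixture with planted class-specific markers and
# pure-noise probes
marker_fixture <- function(seed = 1, n_per_class = 20, n_noise = 50,
                           own = 0.9, other = 0.1, sd = 0.05) {
  withr::with_seed(seed, {
    classes <- paste0("K", 1:5)
    cls <- rep(classes, each = n_per_class)
    n_s <- length(cls)
    planted <- sprintf("mk_%s", classes)
    beta <- matrix(rnorm(n_noise * n_s, rep(runif(n_noise, 0.3, 0.7), n_s), sd),
                   n_noise, n_s, dimnames = list(sprintf("noise%02d", 1:n_noise), NULL))
    mk <- matrix(other, length(planted), n_s, dimnames = list(planted, NULL))
    for (i in seq_along(classes)) mk[i, cls == classes[i]] <- own
    mk <- mk + rnorm(length(mk), 0, sd)
    beta <- pmin(pmax(rbind(mk, beta), 0.001), 0.999)
    colnames(beta) <- sprintf("S%03d", 1:n_s)
    samples <- mk_samples(colnames(beta), class_label = cls, condition = "tumor")
    list(beta = beta, samples = samples, planted = planted, classes = classes)
  })
}

test_that("the one-vs-rest filter passes planted markers and rejects flat or low-sd probes", {
  fx <- marker_fixture(seed = 2)
  res <- ovr_specific_filter(fx$beta, fx$samples)
  for (i in seq_along(fx$classes)) {
    row <- res[res$probe_id == fx$planted[i] & res$class_label == fx$classes[i], ]
    expect_true(row$passes)
    expect_gt(row$sd, 0.2)   # pooled sd of a 0.9-vs-0.1 marker is ~0.33
  }
  noise_rows <- res[grepl("^noise", res$probe_id), ]
  expect_gte(mean(!noise_rows$passes), 0.99)
})

test_that("a strong mean gap still fails when the pooled sd stays at or below 0.2", {
  withr::with_seed(4, {
    cls <- rep(paste0("K", 1:5), each = 30)
    beta <- matrix(0.45, 1, length(cls), dimnames = list("cgX", sprintf("S%03d", seq_along(cls))))
    beta[1, cls == "K1"] <- 0.55
    beta <- beta + rnorm(length(beta), 0, 0.02)
  })
  samples <- mk_samples(colnames(beta), class_label = cls, condition = "tumor")
  res <- ovr_specific_filter(beta, samples)
  k1 <- res[res$class_label == "K1", ]
  expect_lt(k1$ovr_q, 0.05)  # highly significant mean gap
  expect_lte(k1$sd, 0.2)
  expect_false(k1$passes)    # rejected on the sd gate alone
})

test_that("a perfectly separating probe tops the Shapley ranking", {
  hits <- 0
  for (seed in 1:5) {
    fx <- marker_fixture(seed = seed)
    # keep one planted marker plus all noise probes
    probes <- c(fx$planted[1], grep("^noise", rownames(fx$beta), value = TRUE))
    rk <- shapley_rank(fx$beta, fx$samples, probes = probes, nrounds = 50,
                       seed = seed)
    hits <- hits + (rk$probe_id[1] == fx$planted[1])
  }
  expect_gte(hits, 4)
})

test_that("all-noise inputs produce no dominant importance", {
  ok <- 0
  for (seed in 1:5) {
    fx <- marker_fixture(seed = 10 + seed)
    probes <- grep("^noise", rownames(fx$beta), value = TRUE)
    rk <- shapley_rank(fx$beta, fx$samples, probes = probes, nrounds = 50,
                       seed = seed)
    ok <- ok + (max(rk$importance) < 10 * median(rk$importance))
  }
  expect_gte(ok, 4)
})

test_that("duplicating an informative probe keeps both copies above the noise", {
  fx <- marker_fixture(seed = 3)
  beta <- fx$beta
  dup <- beta[fx$planted[1], , drop = FALSE]
  rownames(dup) <- "mk_copy"
  beta2 <- rbind(beta, dup)
  probes1 <- c(fx$planted[1], grep("^noise", rownames(beta), value = TRUE))
  probes2 <- c(probes1, "mk_copy")
  rk1 <- shapley_rank(beta, fx$samples, probes = probes1, nrounds = 50, seed = 3)
  rk2 <- shapley_rank(beta2, fx$samples, probes = probes2, nrounds = 50, seed = 3)
  single <- rk1$importance[rk1$probe_id == fx$planted[1]]
  pair <- sum(rk2$importance[rk2$probe_id %in% c(fx$planted[1], "mk_copy")])
  expect_gte(pair, single * 0.9)
  # boosted trees route all splits through one of two identical columns,
  # so the pair's credit may concentrate on a single copy; the best copy
  # must stay clear of the noise
  max_noise <- max(rk2$importance[grepl("^noise", rk2$probe_id)])
  expect_gt(max(rk2$importance[rk2$probe_id %in% c(fx$planted[1], "mk_copy")]),
            max_noise)
})

test_that("importance rankings are stable across seeds on the planted fixture", {
  fx <- marker_fixture(seed = 6)
  probes <- rownames(fx$beta)
  rk1 <- shapley_rank(fx$beta, fx$samples, probes = probes, nrounds = 50, seed = 1)
  rk2 <- shapley_rank(fx$beta, fx$samples, probes = probes, nrounds = 50, seed = 2)
  m <- match(rk1$probe_id, rk2$probe_id)
  expect_gte(cor(rk1$rank, seq_along(m)[m], method = "spearman"), 0.8)
})

test_that("the plateau rule reproduces the hand-traced stopping decisions", {
  expect_equal(select_plateau_k(c(0.60, 0.80, 0.90, 0.95, 0.954, 0.955),
                                eps = 0.005, m = 2), 4)
  expect_equal(select_plateau_k(seq(0.5, 0.95, by = 0.05), eps = 0.005, m = 2),
               10)  # strictly improving: rule never fires, returns K
  expect_equal(select_plateau_k(c(0.9), eps = 0.01, m = 1), 1)
  expect_error(select_plateau_k(numeric(), 0.01, 1))
})

test_that("selected k is non-increasing in the improvement floor", {
  withr::with_seed(9, {
    for (i in 1:20) {
      acc <- cummax(runif(12))
      ks <- vapply(c(0.001, 0.005, 0.02, 0.1), function(e) {
        select_plateau_k(acc, eps = e, m = 2)
      }, numeric(1))
      expect_true(all(diff(ks) <= 0))
    }
  })
})
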