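# Bagged CART forest built on rpart.
#
# The origin classifier's hyperparameter grid spans both the Gini and the
# entropy (information) splitting criteria, so the forest is built on
# rpart, which exposes both. Each tree sees a bootstrap sample of the
# rows and, by default, every feature: with small marker panels a random
# feature subspace is actively harmful, because trees blinded to a
# class's own marker see that class's positives as unmethylated
# everywhere and claim the shared all-low signature for their class.
# Ensemble diversity comes from the bootstrap; `mtry` remains available
# for wide inputs. Out-of-bag (OOB) votes provide the OOB score used for
# the grid search.

cart_forest <- function(x, y, n_trees = 100, criterion = c("gini", "entropy"),
                        mtry = NULL, seed = 1) {
  criterion <- match.arg(criterion)
  x <- as.data.frame(x)
  y <- factor(y)
  n <- nrow(x)
  p <- ncol(x)
  mtry <- mtry %||% p
  split_name <- if (criterion == "gini") "gini" else "information"
  # trees grow to single-observation leaves: a class pattern carried by
  # one in-bag example (a backup-marker-silent tumor) must still be
  # learnable, and Laplace smoothing plus margin-centred thresholds keep
  # small leaves from becoming overconfident or noise-shaped
  ctrl <- rpart::rpart.control(cp = 0, minsplit = 2, minbucket = 1,
                               maxdepth = 30, xval = 0, maxcompete = 0,
                               maxsurrogate = 0)
  trees <- withr::with_seed(seed, {
    lapply(seq_len(n_trees), function(i) {
      boot <- sample.int(n, n, replace = TRUE)
      feats <- sort(sample.int(p, mtry))
      df <- x[boot, feats, drop = FALSE]
      df$.y <- y[boot]
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          parms = list(split = split_name), control = ctrl)
      fit <- centre_split_gaps(fit, df)
      fit$call <- NULL
      fit$where <- NULL
      attr(fit$terms, ".Environment") <- baseenv()
      list(fit = fit, feats = feats, oob = setdiff(seq_len(n), unique(boot)))
    })
  })
  structure(list(trees = trees, levels = levels(y), criterion = criterion,
                 mtry = mtry, n = n, feature_names = colnames(x)),
            class = "cart_forest")
}

# Robustly margin-centre the continuous split thresholds of a fitted
# tree. rpart puts a cutpoint immediately next to a boundary observation;
# when the two sides of a node are separated by a wide empirical margin
# (background-low versus fully methylated marker values), a single
# aberrant observation — typically an imputed cell sitting at ~0.2
# between the levels — drags the threshold to the imputation level, and
# every future value in the margin then generalises to the wrong side.
# The adjusted threshold sits at the midpoint of the node's margin, with
# one straggler per side ignored when the side has at least six
# observations. The in-bag partition is unchanged except possibly for
# the ignored stragglers.
centre_split_gaps <- function(fit, df) {
  if (nrow(fit$frame) == 1L || is.null(fit$splits)) return(fit)
  frame <- fit$frame
  splits <- fit$splits
  nn <- as.integer(rownames(frame))
  nonleaf <- which(frame$var != "<leaf>")
  node_rows <- list("1" = seq_len(nrow(df)))
  for (i in seq_along(nonleaf)) {
    fi <- nonleaf[i]
    rows <- node_rows[[as.character(nn[fi])]]
    v <- as.character(frame$var[fi])
    cut <- splits[i, "index"]
    vals <- df[rows, v]
    below <- sort(vals[vals < cut], decreasing = TRUE)
    above <- sort(vals[vals >= cut])
    if (length(below) && length(above)) {
      lo <- if (length(below) >= 6) below[2] else below[1]
      hi <- if (length(above) >= 6) above[2] else above[1]
      if (hi > lo) splits[i, "index"] <- (lo + hi) / 2
    }
    goleft <- if (splits[i, "ncat"] < 0) vals < cut else vals >= cut
    node_rows[[as.character(2L * nn[fi])]] <- rows[goleft]
    node_rows[[as.character(2L * nn[fi] + 1L)]] <- rows[!goleft]
  }
  fit$splits <- splits
  fit
}

# Per-tree class probabilities with Laplace smoothing of the leaf counts:
# prob = (n_class + 1) / (n_leaf + K). Trees are grown to small pure
# leaves, so raw leaf proportions collapse to hard 0/1 votes; smoothing
# makes low-support leaves (e.g. the genuinely ambiguous unmethylated
# signature shared by marker-silent tumors of two classes) contribute
# graded probabilities instead.
tree_probs <- function(fit, newx, levels) {
  k <- length(levels)
  if (nrow(fit$frame) == 1L) {
    # stump: every sample lands in the root
    yv2 <- fit$frame$yval2
    counts <- matrix(as.numeric(yv2[1, 1 + seq_len(k)]), nrow(newx), k,
                     byrow = TRUE)
  } else {
    one <- nrow(newx) == 1L
    if (one) newx <- newx[c(1L, 1L), , drop = FALSE]  # predict.rpart drops dims
    m <- predict(fit, newdata = newx, type = "matrix")
    if (one) m <- m[1L, , drop = FALSE]
    counts <- m[, 1 + seq_len(k), drop = FALSE]
  }
  sm <- (counts + 1) / (rowSums(counts) + k)
  colnames(sm) <- attr(fit, "ylevels")
  sm
}

predict_cart_forest <- function(forest, newx, n_trees = length(forest$trees)) {
  newx <- as.data.frame(newx)
  k <- length(forest$levels)
  acc <- matrix(0, nrow(newx), k, dimnames = list(rownames(newx), forest$levels))
  use <- forest$trees[seq_len(min(n_trees, length(forest$trees)))]
  for (tr in use) {
    pr <- tree_probs(tr$fit, newx, forest$levels)
    acc[, colnames(pr)] <- acc[, colnames(pr), drop = FALSE] + pr
  }
  acc / length(use)
}

# OOB class-probability votes using the first n_trees trees.
oob_probs <- function(forest, x, n_trees = length(forest$trees)) {
  x <- as.data.frame(x)
  k <- length(forest$levels)
  acc <- matrix(0, nrow(x), k, dimnames = list(NULL, forest$levels))
  cnt <- numeric(nrow(x))
  for (tr in forest$trees[seq_len(min(n_trees, length(forest$trees)))]) {
    if (!length(tr$oob)) next
    pr <- tree_probs(tr$fit, x[tr$oob, , drop = FALSE], forest$levels)
    acc[tr$oob, colnames(pr)] <- acc[tr$oob, colnames(pr), drop = FALSE] + pr
    cnt[tr$oob] <- cnt[tr$oob] + 1
  }
  acc[cnt > 0, ] <- acc[cnt > 0, , drop = FALSE] / cnt[cnt > 0]
  list(probs = acc, voted = cnt > 0)
}

oob_accuracy <- function(forest, x, y, n_trees = length(forest$trees)) {
  ov <- oob_probs(forest, x, n_trees)
  if (!any(ov$voted)) return(NA_real_)
  pred <- forest$levels[max.col(ov$probs[ov$voted, , drop = FALSE], ties.method = "first")]
  mean(pred == as.character(y)[ov$voted])
}
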