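# small synthetic cohort feature table with controllable group separation
toy_cohort <- function(delta = 0, n_per_group = 6, trials = 5, sd = 1,
                       seed = 1, p_features = 3) {
  with_seed(seed, {
    ids <- sprintf("S%02d", seq_len(2 * n_per_group))
    calibre <- rep(c("high", "low"), each = n_per_group)
    rows <- expand.grid(participant = ids, trial = seq_len(trials),
                        stringsAsFactors = FALSE)
    rows$calibre <- calibre[match(rows$participant, ids)]
    X <- matrix(stats::rnorm(nrow(rows) * p_features, sd = sd), nrow(rows))
    X[rows$calibre == "high", ] <- X[rows$calibre == "high", ] + delta
    colnames(X) <- paste0("f", seq_len(p_features))
    d <- data.frame(rows[c("participant", "calibre", "trial")], X)
    d$calibre <- factor(d$calibre, levels = c("low", "high"))
    d
  })
}

test_that("1-D k-means calibre split matches the exhaustive oracle", {
  x <- c(a = 2, b = 3, c = 4, d = 20, e = 22, f = 24)
  lab <- kmeans_calibre(x)
  expect_equal(as.character(lab[c("a", "b", "c")]), rep("low", 3))
  expect_equal(as.character(lab[c("d", "e", "f")]), rep("high", 3))
  # two values: singletons, larger one high
  lab2 <- kmeans_calibre(c(p = 1, q = 10))
  expect_equal(as.character(lab2), c("low", "high"))
  expect_error(kmeans_calibre(c(3, 3, 3)), "degenerate")
  # random instances against brute-force enumeration over all 2-partitions
  set.seed(91)
  for (i in 1:20) {
    y <- stats::rnorm(7, sd = 5)
    lab <- kmeans_calibre(y)
    wss <- function(g) sum((y[g] - mean(y[g]))^2)
    best <- Inf
    for (m in 1:(2^7 - 2)) {
      g <- as.logical(bitwAnd(m, 2^(0:6)))
      if (any(g) && any(!g)) best <- min(best, wss(g) + wss(!g))
    }
    got <- wss(lab == "high") + wss(lab == "low")
    expect_equal(got, best, tolerance = 1e-9)
  }
})

test_that("Friedman statistic reproduces hand-computed rank tables", {
  # one treatment higher in all 5 blocks: chi2 = 5, p = 0.0253
  tab <- cbind(low = c(1, 2, 3, 4, 5), high = c(2, 3, 4, 5, 6))
  res <- friedman_test(tab)
  expect_equal(res$chi2, 5)
  expect_equal(res$p, stats::pchisq(5, 1, lower.tail = FALSE))
  expect_equal(round(res$p, 2), 0.03)
  # higher in 4 of 5 blocks: chi2 = 1.8
  tab2 <- cbind(c(1, 2, 3, 4, 6), c(2, 3, 4, 5, 5))
  res2 <- friedman_test(tab2)
  expect_equal(res2$chi2, 1.8)
  expect_equal(res2$p, stats::pchisq(1.8, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # identical treatments: fully tied table
  res3 <- friedman_test(cbind(1:5, 1:5))
  expect_equal(res3$chi2, 0)
  expect_equal(res3$p, 1)
})

test_that("Friedman statistic agrees with stats::friedman.test on untied tables", {
  set.seed(92)
  for (i in 1:20) {
    k <- sample(2:4, 1); n <- sample(4:8, 1)
    tab <- matrix(stats::rnorm(n * k), n, k)
    ours <- friedman_test(tab)
    ref <- stats::friedman.test(tab)
    expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("feature selection keeps canonical order and respects alpha", {
  co <- generate_cohort(seed = 3, signals = FALSE)
  sel <- select_features(co$features)
  expect_true(all(sel$selected %in% feature_names()))
  expect_equal(sel$selected,
               feature_names()[feature_names() %in% sel$selected])
  expect_length(select_features(co$features, alpha = 0)$selected, 0)
  expect_equal(names(sel$p), feature_names())
})

test_that("fold schemes are balanced, duplicate-free and seed-deterministic", {
  ids <- sprintf("P%02d", 1:12)
  for (seed in c(1, 7, 123)) {
    sch <- build_fold_scheme(ids, seed = seed)
    expect_length(sch, 12)
    expect_true(all(lengths(sch) == 3))
    expect_true(all(vapply(sch, anyDuplicated, integer(1)) == 0))
    counts <- table(unlist(sch))
    expect_true(all(counts == 3))
  }
  expect_identical(build_fold_scheme(ids, seed = 5),
                   build_fold_scheme(ids, seed = 5))
  expect_error(build_fold_scheme(ids[1:5], seed = 1), "balance infeasible")
})

test_that("pairs of participants co-occur in folds with uniform frequency", {
  ids <- sprintf("P%02d", 1:12)
  counts <- matrix(0, 12, 12, dimnames = list(ids, ids))
  for (seed in 1:400) {
    sch <- build_fold_scheme(ids, seed = seed)
    for (f in sch) for (a in f) for (b in f) if (a != b)
      counts[a, b] <- counts[a, b] + 1
  }
  off <- counts[upper.tri(counts)]
  # expected pairs per seed: 12 folds x 3 pairs / 66 = 6/11
  expect_equal(mean(off) / 400, 6 / 11, tolerance = 0.05)
  expect_gt(min(off) / 400, 6 / 11 * 0.6)
  expect_lt(max(off) / 400, 6 / 11 * 1.4)
})

test_that("KNN: memorized point, separated clusters, and null accuracy", {
  set.seed(93)
  train <- matrix(stats::rnorm(60), 30)
  labels <- rep(c("high", "low"), 15)
  expect_equal(knn_classify(train, labels, train[3, , drop = FALSE], k = 1),
               labels[3])
  # well-separated clusters: perfect for every odd k
  sep <- toy_cohort(delta = 8, sd = 1, seed = 94)
  X <- as.matrix(sep[paste0("f", 1:3)])
  tr_idx <- sep$trial <= 3
  for (k in c(1, 3, 7, 15)) {
    pred <- knn_classify(X[tr_idx, ], sep$calibre[tr_idx], X[!tr_idx, ], k)
    expect_equal(mean(pred == as.character(sep$calibre[!tr_idx])), 1)
  }
  # uninformative features: accuracy near chance over repeats
  accs <- replicate(40, {
    null <- toy_cohort(delta = 0, seed = sample.int(1e6, 1))
    Xn <- as.matrix(null[paste0("f", 1:3)])
    idx <- null$trial <= 3
    pred <- knn_classify(Xn[idx, ], null$calibre[idx], Xn[!idx, ], 5)
    mean(pred == as.character(null$calibre[!idx]))
  })
  expect_equal(mean(accs), 0.5, tolerance = 0.08)
})

test_that("KNN handles zero-variance features and k bounds", {
  train <- cbind(c(0, 0, 1, 1), c(5, 5, 5, 5))
  labels <- c("low", "low", "high", "high")
  expect_warning(pred <- knn_classify(train, labels, train, 1),
                 "zero-variance")
  expect_equal(pred, labels)
  expect_error(suppressWarnings(knn_classify(train, labels, train, 9)),
               "k out of range")
})

test_that("cross-validation metrics: identities, separable and shuffled cohorts", {
  # per-repeat metric identities on a fabricated confusion
  m <- skatekin:::.confusion_metrics(rep(c("high", "low"), each = 15),
                                     rep(c("high", "low"), each = 15))
  expect_equal(unname(m), c(100, 100, 100, 100))
  sep <- toy_cohort(delta = 8, n_per_group = 6, seed = 95)
  sch <- build_fold_scheme(unique(sep$participant), seed = 1)
  res <- cross_validate(sep, sch, paste0("f", 1:3), ks = c(1, 5, 9))
  expect_equal(res$accuracy, rep(100, 3))
  expect_equal(res$sensitivity, rep(100, 3))
  expect_equal(res$specificity, rep(100, 3))
  expect_equal(res$precision, rep(100, 3))
  # deterministic given (data, seed)
  res2 <- cross_validate(sep, build_fold_scheme(unique(sep$participant), 1),
                         paste0("f", 1:3), ks = c(1, 5, 9))
  expect_identical(res, res2)
})

test_that("separability is monotone in the injected effect size at k = 1", {
  accs <- vapply(c(0, 1, 2, 4, 8), function(delta) {
    d <- toy_cohort(delta = delta, seed = 96)
    sch <- build_fold_scheme(unique(d$participant), seed = 2)
    cross_validate(d, sch, paste0("f", 1:3), ks = 1)$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= -1e-9))
})

test_that("PCA embedding: orthonormal loadings, eigen oracle, reconstruction", {
  co <- generate_cohort(seed = 4, signals = FALSE)
  emb <- pca_embed(co$features, n_components = 3)
  L <- emb$loadings
  expect_equal(crossprod(L), diag(3), tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(diff(emb$explained_variance) <= 1e-12))
  # first loading parallel to the leading eigenvector of the correlation matrix
  X <- as.matrix(co$features[feature_names()])
  ev <- eigen(stats::cor(X))$vectors[, 1]
  v <- L[, 1]
  expect_equal(abs(sum(ev * v)), 1, tolerance = 1e-6)
  # full reconstruction equals the z-scored table
  full <- pca_embed(co$features, n_components = 12)
  Z <- scale(X)
  expect_equal(full$scores %*% t(full$loadings), Z, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(pca_embed(co$features, n_components = 13), "rank")
})

test_that("the classification stage is deterministic given data and seed", {
  co <- generate_cohort(seed = 6, signals = FALSE)
  r1 <- run_classification(co$features, pca = "all12", seed = 11)
  r2 <- run_classification(co$features, pca = "all12", seed = 11)
  expect_identical(r1$metrics, r2$metrics)
  expect_equal(nrow(r1$metrics), 15)
})
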