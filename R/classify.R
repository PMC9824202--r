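# Calibre clustering, Friedman-test feature selection, balanced subject-wise
# KNN cross-validation (k = 1..15) and the PCA feature-space variant.

#' Calibre labels by 1-D k-means on skating experience
#'
#' Exact two-cluster k-means on years of experience: for sorted 1-D data an
#' optimal 2-means partition is a split of the sorted order, so all n-1
#' splits are enumerated and the one minimizing within-cluster sum of squares
#' is returned. The cluster with the higher mean is labelled `"high"`.
#'
#' @param experience_years Named numeric vector, one value per participant.
#' @return Factor (`"low"`/`"high"`) named by participant.
#' @export
kmeans_calibre <- function(experience_years) {
  x <- experience_years
  if (length(x) < 2 || length(unique(x)) < 2)
    stop("degenerate clustering: need >= 2 distinct experience values",
         call. = FALSE)
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  wss <- vapply(seq_len(n - 1), function(s) {
    sum((xs[1:s] - mean(xs[1:s]))^2) + sum((xs[(s + 1):n] - mean(xs[(s + 1):n]))^2)
  }, numeric(1))
  s <- which.min(wss)
  lab <- rep("low", n)
  lab[(s + 1):n] <- "high"            # sorted ascending: upper split = higher mean
  out <- factor(lab[order(ord)], levels = c("low", "high"))
  names(out) <- names(x)
  out
}

#' Friedman rank test over a block x treatment table
#'
#' Rank-based repeated-measures comparison: within each block the treatment
#' cells are ranked (midranks on ties), and the tie-corrected chi-square
#' statistic (Conover's form) is referred to a chi-square distribution with
#' k - 1 degrees of freedom. Implemented directly because the feature
#' selection uses the two-treatment case (the two calibre groups) with five
#' trial blocks, where the discrete null matters. A fully tied table gives
#' `chi2 = 0`, `p = 1`.
#'
#' @param x Numeric matrix, blocks in rows, treatments in columns.
#' @return List with `chi2`, `df` and `p`.
#' @export
friedman_test <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2)
    stop("need at least 2 blocks and 2 treatments", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite cells", call. = FALSE)
  r <- t(apply(x, 1, rank))          # midranks on ties
  Rj <- colSums(r)
  A <- sum(r^2)
  C <- n * k * (k + 1)^2 / 4
  num <- (k - 1) * (sum(Rj^2) - n^2 * k * (k + 1)^2 / 4)
  den <- A - C
  chi2 <- if (den <= .Machine$double.eps * A) 0 else num / den
  list(chi2 = chi2, df = k - 1,
       p = if (chi2 == 0) 1 else stats::pchisq(chi2, df = k - 1, lower.tail = FALSE))
}

#' Per-feature Friedman test between calibre groups
#'
#' Builds the block x treatment table for one feature — blocks are the trial
#' indices, treatments the two calibre groups, each cell the group mean of
#' the feature in that trial — and applies [friedman_test].
#'
#' @param data Cohort feature table: data frame with columns `participant`,
#'   `calibre` (`"low"`/`"high"`), `trial` and the feature columns.
#' @param feature Feature column name.
#' @return List with `chi2`, `df`, `p` and the `table` used.
#' @export
friedman_feature_test <- function(data, feature) {
  stopifnot(feature %in% names(data),
            all(c("participant", "calibre", "trial") %in% names(data)))
  tab <- tapply(data[[feature]], list(data$trial, data$calibre), mean)
  tab <- tab[, c("low", "high"), drop = FALSE]
  if (any(is.na(tab)))
    stop("every trial block needs both calibre groups", call. = FALSE)
  res <- friedman_test(tab)
  res$table <- tab
  res
}

#' Friedman feature selection
#'
#' Runs [friedman_feature_test] for every feature and keeps those with
#' p <= `alpha`, preserving the canonical feature order.
#'
#' @inheritParams friedman_feature_test
#' @param features Feature columns to test (default the canonical twelve).
#' @param alpha Selection level.
#' @return List with `selected` (character), and `p` / `chi2` named vectors.
#' @export
select_features <- function(data, features = feature_names(), alpha = 0.05) {
  res <- lapply(features, function(f) friedman_feature_test(data, f))
  p <- vapply(res, `[[`, numeric(1), "p")
  chi2 <- vapply(res, `[[`, numeric(1), "chi2")
  names(p) <- names(chi2) <- features
  list(selected = features[p <= alpha], p = p, chi2 = chi2, alpha = alpha)
}

#' Balanced subject-wise fold scheme
#'
#' Random assignment of participants to `n_folds` test sets of `test_size`
#' participants each, such that every participant appears in a test set
#' exactly `n_folds * test_size / n` times and never twice in the same fold.
#' Built by shuffling the multiset of participant appearances into folds and
#' repairing within-fold duplicates by random swaps with other folds.
#'
#' @param participants Vector of participant ids.
#' @param seed Integer seed (all randomness in the scheme flows from it).
#' @param n_folds Number of repeats.
#' @param test_size Test-set size per repeat.
#' @return Object of class `fold_scheme`: list of `n_folds` test-id vectors,
#'   with attribute `appearances`.
#' @export
build_fold_scheme <- function(participants, seed, n_folds = 12, test_size = 3) {
  n <- length(participants)
  total <- n_folds * test_size
  if (total %% n != 0)
    stop("balance infeasible: n_folds * test_size must be a multiple of n",
         call. = FALSE)
  appearances <- total %/% n
  if (test_size > n) stop("test_size exceeds participant count", call. = FALSE)
  with_seed(seed, {
    slots <- sample(rep(seq_len(n), appearances))
    folds <- matrix(slots, nrow = n_folds, byrow = TRUE)
    repeat {
      dup <- which(apply(folds, 1, anyDuplicated) > 0)
      if (length(dup) == 0) break
      f <- dup[1]
      j <- anyDuplicated(folds[f, ])
      done <- FALSE
      for (g in sample(setdiff(seq_len(n_folds), f))) {
        for (jj in sample(test_size)) {
          a <- folds[f, j]; b <- folds[g, jj]
          if (!(b %in% folds[f, ]) && !(a %in% folds[g, -jj])) {
            folds[f, j] <- b; folds[g, jj] <- a
            done <- TRUE; break
          }
        }
        if (done) break
      }
      if (!done) stop("fold repair failed", call. = FALSE)  # not reachable for balanced designs
    }
    out <- lapply(seq_len(n_folds), function(i) participants[folds[i, ]])
    structure(out, class = "fold_scheme", appearances = appearances)
  })
}

#' K-nearest-neighbour classification
#'
#' Features are z-scored with training-set statistics (zero-variance training
#' features are dropped with a warning); test rows are assigned the majority
#' label among the `k` Euclidean-nearest training rows, ties going to the
#' label of the single nearest neighbour.
#'
#' @param train Numeric matrix of training feature rows.
#' @param labels Factor/character labels for `train` rows.
#' @param test Numeric matrix of rows to classify.
#' @param k Number of neighbours, `1 <= k <= nrow(train)`.
#' @return Character vector of predicted labels.
#' @export
knn_classify <- function(train, labels, test, k) {
  train <- as.matrix(train); test <- as.matrix(test)
  labels <- as.character(labels)
  stopifnot(nrow(train) == length(labels), ncol(train) == ncol(test))
  if (k < 1 || k > nrow(train)) stop("k out of range", call. = FALSE)
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  keep <- sd > 0
  if (!all(keep)) {
    warning(sprintf("knn_classify: dropping %d zero-variance feature(s)",
                    sum(!keep)), call. = FALSE)
    if (!any(keep)) stop("no informative features left", call. = FALSE)
  }
  zt <- sweep(sweep(train[, keep, drop = FALSE], 2, mu[keep]), 2, sd[keep], "/")
  zs <- sweep(sweep(test[, keep, drop = FALSE], 2, mu[keep]), 2, sd[keep], "/")
  apply(zs, 1, function(row) {
    d2 <- colSums((t(zt) - row)^2)
    nn <- order(d2)[seq_len(k)]
    votes <- table(labels[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) top else labels[nn[1]]
  })
}

.confusion_metrics <- function(truth, pred, positive = "high") {
  tp <- sum(truth == positive & pred == positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  c(sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    accuracy = 100 * (tp + tn) / (tp + tn + fp + fn),
    precision = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_)
}

#' Subject-wise cross-validated KNN metrics
#'
#' For each repeat of the fold scheme, all trials of the test participants
#' are classified individually by a KNN trained on the remaining
#' participants' trials, for every `k`; sensitivity, specificity, accuracy
#' and precision (positive class `"high"`) are computed per repeat and
#' averaged over repeats. A metric undefined in a repeat (no positive or no
#' negative test trials, or no positive prediction for precision) is excluded
#' from its average.
#'
#' @param data Cohort feature table (see [friedman_feature_test]).
#' @param scheme A [build_fold_scheme] result.
#' @param features Character vector of feature columns, or a numeric matrix
#'   of precomputed scores with one row per row of `data` (PCA variant).
#' @param ks Neighbour counts to evaluate.
#' @param positive Positive class.
#' @return Data frame with columns `k`, `sensitivity`, `specificity`,
#'   `accuracy`, `precision` (percent), one row per `k`.
#' @export
cross_validate <- function(data, scheme, features, ks = 1:15,
                           positive = "high") {
  stopifnot(inherits(scheme, "fold_scheme"))
  X <- if (is.character(features)) as.matrix(data[, features, drop = FALSE])
       else as.matrix(features)
  stopifnot(nrow(X) == nrow(data))
  truth_all <- as.character(data$calibre)
  res <- array(NA_real_, c(length(scheme), length(ks), 4))
  for (r in seq_along(scheme)) {
    test_idx <- data$participant %in% scheme[[r]]
    tr <- X[!test_idx, , drop = FALSE]
    te <- X[test_idx, , drop = FALSE]
    lab <- truth_all[!test_idx]
    truth <- truth_all[test_idx]
    for (ki in seq_along(ks)) {
      pred <- knn_classify(tr, lab, te, ks[ki])
      res[r, ki, ] <- .confusion_metrics(truth, pred, positive)
    }
  }
  out <- data.frame(k = ks,
                    sensitivity = colMeans(res[, , 1, drop = FALSE], na.rm = TRUE)[, 1],
                    specificity = colMeans(res[, , 2, drop = FALSE], na.rm = TRUE)[, 1],
                    accuracy = colMeans(res[, , 3, drop = FALSE], na.rm = TRUE)[, 1],
                    precision = colMeans(res[, , 4, drop = FALSE], na.rm = TRUE)[, 1])
  rownames(out) <- NULL
  out
}

#' Principal-component feature space
#'
#' PCA (via [stats::prcomp]) of the z-scored feature table; the leading
#' `n_components` scores form the alternative KNN feature space. Loadings are
#' orthonormal and ordered by decreasing explained variance.
#'
#' @param data Cohort feature table.
#' @param features Feature columns to embed (all twelve by default; pass the
#'   selected three for the reduced variant).
#' @param n_components Number of components kept.
#' @return List with `scores` (n x n_components), `loadings`,
#'   `explained_variance` (proportions) and the fitted `prcomp` object.
#' @export
pca_embed <- function(data, features = feature_names(), n_components = 3) {
  X <- as.matrix(data[, features, drop = FALSE])
  fit <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  if (n_components > ncol(fit$rotation))
    stop("n_components exceeds the rank of the feature table", call. = FALSE)
  list(scores = fit$x[, seq_len(n_components), drop = FALSE],
       loadings = fit$rotation[, seq_len(n_components), drop = FALSE],
       explained_variance = fit$sdev^2 / sum(fit$sdev^2),
       fit = fit)
}
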