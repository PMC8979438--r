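# Group statistics (rank tests, Spearman correlations), per-feature
# ROC/AUC between phenotype pairs, and random-forest classification with
# repeated stratified cross-validation and permutation importance.

#' Rank-based comparison of a feature between two phenotype groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test for independent
#' samples, with group means reported alongside. The signed-rank variant
#' is available for genuinely paired inputs of equal length. A feature
#' constant across both groups yields p = 1 with a flag.
#'
#' @param ft a \linkS4class{FeatureTable}.
#' @param feature feature column name.
#' @param groups character vector of two phenotype labels.
#' @param alpha significance level for the flag (default 0.01).
#' @param paired use the signed-rank test for paired samples.
#' @return one-row data.frame: feature, group1, group2, mean1, mean2,
#'   statistic, p_value, significant, degenerate.
#' @export
groupCompare <- function(ft, feature, groups, alpha = 0.01,
                         paired = FALSE) {
  stopifnot(length(groups) == 2L)
  vals <- featureValues(ft)[[feature]]
  if (is.null(vals)) stopf("feature '%s' not in table", feature)
  ph <- mutationInfo(ft)$phenotype
  x <- vals[ph == groups[1]]
  y <- vals[ph == groups[2]]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3L || length(y) < 3L)
    stopf("need at least 3 observations per group (have %d and %d)",
          length(x), length(y))
  degenerate <- (max(c(x, y)) - min(c(x, y))) < 1e-12
  if (degenerate) {
    stat <- NA_real_; p <- 1
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided", paired = paired))
    stat <- unname(wt$statistic); p <- wt$p.value
  }
  data.frame(feature = feature, group1 = groups[1], group2 = groups[2],
             mean1 = mean(x), mean2 = mean(y), statistic = stat,
             p_value = p, significant = !degenerate & p < alpha,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Pairwise Spearman correlations between features
#'
#' Rank correlation with average ranks for ties, pairwise-complete
#' observations; an all-tied column gives NA against everything else.
#'
#' @param ft a \linkS4class{FeatureTable} (or plain numeric data.frame).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearmanMatrix <- function(ft) {
  df <- if (methods::is(ft, "FeatureTable")) featureValues(ft) else ft
  suppressWarnings(
    m <- stats::cor(as.matrix(df), method = "spearman",
                    use = "pairwise.complete.obs"))
  diag(m) <- 1
  m
}

#' ROC curve and AUC of one feature for a class pair
#'
#' AUC is the concordance probability P(score_pos > score_neg) + 0.5
#' P(tie), computed from ranks. The raw orientation is reported (no
#' forcing of AUC >= 0.5); the flipped value is attached so either
#' convention can be read off.
#'
#' @param ft a \linkS4class{FeatureTable}.
#' @param feature feature column name (used as the score).
#' @param positive,negative phenotype labels of the two classes.
#' @return list: auc, auc_flipped, n_pos, n_neg, roc (data.frame with
#'   threshold, tpr, fpr).
#' @export
rocAuc <- function(ft, feature, positive, negative) {
  vals <- featureValues(ft)[[feature]]
  if (is.null(vals)) stopf("feature '%s' not in table", feature)
  ph <- mutationInfo(ft)$phenotype
  pos <- vals[ph == positive]; neg <- vals[ph == negative]
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  if (!length(pos) || !length(neg))
    stopf("empty class: %d positive, %d negative", length(pos), length(neg))
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  thr <- sort(unique(c(pos, neg)), decreasing = TRUE)
  roc <- data.frame(
    threshold = c(Inf, thr),
    tpr = c(0, vapply(thr, function(t) mean(pos >= t), numeric(1))),
    fpr = c(0, vapply(thr, function(t) mean(neg >= t), numeric(1))))
  list(auc = auc, auc_flipped = 1 - auc, n_pos = length(pos),
       n_neg = length(neg), roc = roc)
}

# stratified fold assignment: within each class, shuffle then deal out
# fold labels round-robin
.stratifiedFolds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Random-forest phenotype classification with repeated CV
#'
#' Repeated stratified k-fold cross-validation (default 10-fold x 5
#' repeats) of a random forest (500 trees, sqrt-features per split).
#' Feature importance is the mean decrease in out-of-fold accuracy when
#' that feature is permuted in the held-out fold. Fully reproducible
#' under the seed.
#'
#' @param ft a \linkS4class{FeatureTable}.
#' @param features feature column names to use (default all).
#' @param folds,repeats CV scheme (defaults 10 and 5). The fold count is
#'   reduced with a warning when a class has fewer rows than folds.
#' @param trees forest size (default 500).
#' @param nPerm permutation draws per feature and fold when estimating
#'   importance (default 5; averaging reduces estimator noise on small
#'   held-out folds).
#' @param seed integer seed (mandatory for reporting).
#' @return list: accuracy (mean), accuracy_sd (over repeats), importance
#'   (named, mean decrease accuracy, sorted), confusion (table),
#'   per_repeat (numeric), features, seed, folds, repeats.
#' @export
rfClassify <- function(ft, features = names(featureValues(ft)),
                       folds = 10L, repeats = 5L, trees = 500L,
                       nPerm = 5L, seed = 1L) {
  df <- featureValues(ft)[, features, drop = FALSE]
  y <- factor(mutationInfo(ft)$phenotype, levels = PHENOTYPE_LEVELS)
  y <- droplevels(y)
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]; y <- y[keep]
  minClass <- min(table(y))
  if (minClass < folds) {
    folds <- max(2L, as.integer(minClass))
    warnf("smallest class has %d rows; reducing folds to %d", minClass,
          folds)
  }
  set.seed(childSeed(seed, "rf-cv"))
  p <- length(features)
  accRep <- numeric(repeats)
  impAcc <- matrix(0, 0, p, dimnames = list(NULL, features))
  confusion <- table(truth = y, pred = y)
  confusion[] <- 0L
  for (rep_i in seq_len(repeats)) {
    foldOf <- .stratifiedFolds(as.character(y), folds)
    nOk <- 0L; nTot <- 0L
    for (f in seq_len(folds)) {
      test <- which(foldOf == f)
      fit <- randomForest::randomForest(
        x = df[-test, , drop = FALSE], y = y[-test], ntree = trees,
        mtry = max(1L, floor(sqrt(p))))
      pred <- stats::predict(fit, df[test, , drop = FALSE])
      nOk <- nOk + sum(pred == y[test]); nTot <- nTot + length(test)
      confusion <- confusion + table(truth = y[test], pred = pred)
      baseAcc <- mean(pred == y[test])
      dec <- vapply(features, function(feat) {
        mean(vapply(seq_len(nPerm), function(b) {
          perm <- df[test, , drop = FALSE]
          perm[[feat]] <- perm[[feat]][sample.int(nrow(perm))]
          baseAcc - mean(stats::predict(fit, perm) == y[test])
        }, numeric(1)))
      }, numeric(1))
      impAcc <- rbind(impAcc, dec)
    }
    accRep[rep_i] <- nOk / nTot
  }
  importance <- sort(colMeans(impAcc), decreasing = TRUE)
  list(accuracy = mean(accRep), accuracy_sd = stats::sd(accRep),
       importance = importance, confusion = confusion,
       per_repeat = accRep, features = features, seed = seed,
       folds = folds, repeats = repeats)
}

#' Top-k features by permutation importance
#'
#' Ties are broken by the original column order; k beyond the feature
#' count is capped with a warning.
#'
#' @param report result of \code{\link{rfClassify}}.
#' @param k number of features to keep.
#' @return character vector of feature names.
#' @export
selectTopK <- function(report, k) {
  imp <- report$importance
  if (k > length(imp)) {
    warnf("k = %d exceeds %d features; returning all", k, length(imp))
    k <- length(imp)
  }
  # stable tie-break: order by -importance, then original column position
  pos <- match(names(imp), report$features)
  names(imp)[order(-imp, pos)][seq_len(k)]
}
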