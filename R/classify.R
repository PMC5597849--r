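# AUC via the rank (Mann-Whitney) formulation; ties count 0.5
.auc_rank <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.as_labels <- function(grp) as.integer(grp == "case")

# samples x features design matrix from a features x samples abundance matrix
.design <- function(features) {
  X <- t(as.matrix(features))
  storage.mode(X) <- "double"
  X
}

#' Random-forest variable importance ranking
#'
#' Trains a seeded random forest (CART/Gini, bootstrap, `mtry =
#' floor(sqrt(p))`) and ranks features by permutation-based mean
#' decrease in out-of-bag accuracy, descending, ties broken by feature
#' id.
#'
#' @param features Features x samples abundance matrix.
#' @param cohort Cohort table with case/control groups (>= 5 samples per
#'   group).
#' @param n_trees Number of trees (the field convention is 10 000;
#'   desk-scale runs use 500).
#' @param seed Forest seed.
#' @return A data.frame (feature, importance) in ranked order.
#' @export
rf_importance <- function(features, cohort, n_trees = 10000L, seed = 1L) {
  grp <- .match_groups(features, cohort)
  if (length(unique(grp)) < 2L) stop("labels contain a single class")
  if (min(table(grp)) < 5L) stop("need at least 5 samples per group")
  X <- .design(features)
  fit <- .rf_cpp(X, .as_labels(grp), as.integer(n_trees), -1L,
                 derive_seed(seed, "rf-imp"), NULL, TRUE)
  res <- data.frame(feature = rownames(features), importance = fit$importance,
                    stringsAsFactors = FALSE)
  res[order(-res$importance, res$feature), , drop = FALSE]
}

# repeated stratified K-fold CV scores for a fixed feature set; returns
# pooled out-of-fold probability scores (samples x repeats) and labels
.cv_scores <- function(X, lab, cv_folds, cv_repeats, n_trees, seed) {
  n <- nrow(X)
  scores <- matrix(NA_real_, n, cv_repeats)
  for (r in seq_len(cv_repeats)) {
    set.seed(derive_seed(seed, paste0("cv", r)))
    fold <- integer(n)
    for (cls in unique(lab)) {
      idx <- which(lab == cls)
      fold[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
    }
    for (k in seq_len(cv_folds)) {
      test <- fold == k
      if (length(unique(lab[!test])) < 2L) stop("fold with a single class")
      fit <- .rf_cpp(X[!test, , drop = FALSE], lab[!test],
                     as.integer(n_trees), -1L,
                     derive_seed(seed, sprintf("cv%d.fold%d", r, k)),
                     X[test, , drop = FALSE], FALSE)
      scores[test, r] <- fit$test_prob
    }
  }
  scores
}

#' Cross-validated AUC over importance-ranked feature subsets
#'
#' For each subset size `k`, retrains the forest on the top-`k` features
#' of the ranking with repeated stratified cross-validation and scores
#' the pooled out-of-fold probabilities by AUC. The ranking is computed
#' once on the full data unless supplied, which optimistically biases
#' the curve (flagged in the result).
#'
#' @param features Features x samples abundance matrix.
#' @param cohort Cohort table.
#' @param ranking Character vector of feature ids in importance order;
#'   computed by [rf_importance()] when `NULL`.
#' @param sizes Strictly increasing subset sizes; defaults to
#'   `1..10, 15, 20, 30, 40, ...` capped at the number of features.
#' @param cv_folds,cv_repeats Stratified CV scheme (default 5-fold, 10
#'   repeats).
#' @param n_trees Trees per forest.
#' @param seed Master seed for ranking, folds and forests.
#' @return A data.frame (size, auc) with attributes `best_size` (argmax,
#'   smallest on ties), `best_auc`, `best_scores` (pooled out-of-fold
#'   scores of the best model), `labels`, `ranking`, and
#'   `ranking_bias_note`.
#' @export
subset_auc_curve <- function(features, cohort, ranking = NULL, sizes = NULL,
                             cv_folds = 5L, cv_repeats = 10L, n_trees = 500L,
                             seed = 1L) {
  grp <- .match_groups(features, cohort)
  lab <- .as_labels(grp)
  p <- nrow(features)
  if (is.null(ranking)) {
    ranking <- rf_importance(features, cohort, n_trees = n_trees,
                             seed = derive_seed(seed, "ranking"))$feature
  }
  if (is.null(sizes)) {
    base <- c(1:10, 15, 20, 30, 40, 60, 80, 120, 160, 240, 320)
    sizes <- sort(unique(c(base[base <= p], p)))
  }
  if (any(sizes > p)) stop("subset sizes exceed the number of features")
  if (any(diff(sizes) <= 0)) stop("sizes must be strictly increasing")
  X <- .design(features)
  aucs <- numeric(length(sizes))
  all_scores <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    cols <- match(ranking[seq_len(sizes[i])], colnames(X))
    sc <- .cv_scores(X[, cols, drop = FALSE], lab, cv_folds, cv_repeats,
                     n_trees, seed)
    all_scores[[i]] <- rowMeans(sc)
    aucs[i] <- .auc_rank(as.vector(sc), rep(lab, times = ncol(sc)))
  }
  out <- data.frame(size = sizes, auc = aucs)
  best <- which.max(aucs)
  attr(out, "best_size") <- sizes[best]
  attr(out, "best_auc") <- aucs[best]
  attr(out, "best_scores") <- setNames(all_scores[[best]], colnames(features))
  attr(out, "labels") <- setNames(lab, colnames(features))
  attr(out, "ranking") <- ranking
  attr(out, "ranking_bias_note") <-
    "feature ranking computed on the full data; the curve is optimistically biased"
  out
}

#' AUC with bootstrap confidence interval and ROC points
#'
#' AUC by the rank (Mann-Whitney) formulation with a percentile
#' bootstrap CI over stratified resamples of the (score, label) pairs,
#' plus the ROC step curve.
#'
#' @param scores Numeric classifier scores (higher = more case-like).
#' @param labels 0/1 labels (or `"case"`/`"control"`).
#' @param n_boot Bootstrap replicates (the field convention is 10 000).
#' @param seed Bootstrap seed.
#' @param conf Confidence level.
#' @return `list(auc, ci_low, ci_high, roc)` where `roc` is a data.frame
#'   (threshold, fpr, tpr).
#' @export
roc_auc_ci <- function(scores, labels, n_boot = 10000L, seed = 1L,
                       conf = 0.95) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.integer(as.character(labels) == "case")
  }
  auc <- .auc_rank(scores, labels)
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  set.seed(derive_seed(seed, "boot"))
  bauc <- vapply(seq_len(n_boot), function(b) {
    i <- c(sample(pos, length(pos), replace = TRUE),
           sample(neg, length(neg), replace = TRUE))
    .auc_rank(scores[i], labels[i])
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(bauc, c(alpha, 1 - alpha), type = 7))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(scores[neg] >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(scores[pos] >= t), numeric(1)))
  list(auc = auc, ci_low = ci[1L], ci_high = ci[2L], roc = roc)
}

#' Compare classifiers with and without a clinical covariate
#'
#' Fits three cross-validated models -- covariate alone, features alone,
#' features plus covariate -- and reports their pooled out-of-fold AUCs
#' with bootstrap CIs side by side.
#'
#' @param features Features x samples abundance matrix.
#' @param cohort Cohort table containing the covariate column.
#' @param covariate Cohort column name (default `"pbmi"`).
#' @param cv_folds,cv_repeats,n_trees,seed As in [subset_auc_curve()].
#' @param n_boot Bootstrap replicates for the CIs.
#' @return A data.frame (model, auc, ci_low, ci_high) for the three
#'   models, with per-model pooled scores in `attr(, "scores")`.
#' @export
classify_with_covariate <- function(features, cohort, covariate = "pbmi",
                                    cv_folds = 5L, cv_repeats = 10L,
                                    n_trees = 500L, n_boot = 1000L, seed = 1L) {
  grp <- .match_groups(features, cohort)
  lab <- .as_labels(grp)
  cov <- cohort[[covariate]][match(colnames(features), cohort$sample_id)]
  if (is.null(cov) || all(is.na(cov))) stop("covariate missing: ", covariate)
  X <- .design(features)
  Xc <- matrix(cov, ncol = 1L, dimnames = list(rownames(X), covariate))
  designs <- list(covariate = Xc, features = X, combined = cbind(X, Xc))
  rows <- list(); scores <- list()
  for (nm in names(designs)) {
    sc <- rowMeans(.cv_scores(designs[[nm]], lab, cv_folds, cv_repeats,
                              n_trees, derive_seed(seed, nm)))
    ci <- roc_auc_ci(sc, lab, n_boot = n_boot, seed = derive_seed(seed, paste0(nm, "-ci")))
    rows[[nm]] <- data.frame(model = nm, auc = ci$auc, ci_low = ci$ci_low,
                             ci_high = ci$ci_high, stringsAsFactors = FALSE)
    scores[[nm]] <- sc
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "scores") <- scores
  out
}
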