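#' ROC curve and AUC
#'
#' Builds the ROC curve over the distinct score thresholds and computes the
#' area under it by the trapezoidal rule. With ties counted half, this area
#' equals the Mann-Whitney concordance probability: the probability that a
#' randomly chosen positive receives a higher score than a randomly chosen
#' negative.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels 0/1 labels; both classes must be present.
#' @return `lncass_roc`: list with `thresholds`, `fpr`, `tpr`, `auc`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC is undefined with a single class present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # cumulative counts at each distinct threshold (classify score >= t as +)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l)[keep]; fp <- cumsum(1 - l)[keep]
  tpr <- c(0, tp / n_pos); fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, s[keep]), fpr = fpr, tpr = tpr, auc = auc),
            class = "lncass_roc")
}

#' Pairwise-concordance AUC (Mann-Whitney)
#'
#' Independent route to the AUC: the rank-based Mann-Whitney statistic,
#' equal to the mean over all (positive, negative) pairs of
#' `[s_pos > s_neg] + 0.5 [s_pos == s_neg]`.
#'
#' @inheritParams roc_auc
#' @return AUC in `[0, 1]`.
#' @export
auc_concordance <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC is undefined with a single class present")
  r <- rank(scores)   # midranks handle ties as 1/2
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Mean absolute error
#'
#' @param estimates,truth Equal-length numeric vectors.
#' @return Mean of `|estimates - truth|`.
#' @export
mae <- function(estimates, truth) {
  if (length(estimates) != length(truth))
    stop("estimates and truth must have equal length")
  mean(abs(estimates - truth))
}

#' Sparsity-recovery AUC
#'
#' How well the magnitudes of estimated coefficients separate truly
#' non-zero from truly zero parameters: the AUC of `|beta_hat|` against the
#' labels `beta_true != 0`.
#'
#' @param beta_hat Estimated coefficients.
#' @param beta_true True coefficients; must contain both zero and non-zero
#'   entries.
#' @return AUC in `[0, 1]`.
#' @export
sparsity_recovery_auc <- function(beta_hat, beta_true) {
  if (length(beta_hat) != length(beta_true))
    stop("beta_hat and beta_true must have equal length")
  lab <- as.numeric(beta_true != 0)
  if (all(lab == 1) || all(lab == 0))
    stop("beta_true must contain both zero and non-zero entries")
  roc_auc(abs(beta_hat), lab)$auc
}

#' Cross-validation plan
#'
#' @param scheme `"kfold"` or `"loocv"`.
#' @param folds Number of folds (ignored for loocv).
#' @param repeats Number of independent repetitions (kfold only).
#' @param class_balance If `TRUE` (with loocv on a binomial dataset), each
#'   fold's training set randomly drops one observation of the class
#'   opposite to the held-out one, so class proportions are identical
#'   across folds.
#' @param seed Integer seed controlling fold assignment and balancing.
#' @return `lncass_cv_plan`.
#' @export
cv_plan <- function(scheme = c("kfold", "loocv"), folds = 10, repeats = 1,
                    class_balance = FALSE, seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(folds >= 2, repeats >= 1)
  structure(list(scheme = scheme, folds = as.integer(folds),
                 repeats = as.integer(repeats),
                 class_balance = isTRUE(class_balance), seed = as.integer(seed)),
            class = "lncass_cv_plan")
}

# stratified fold assignment for one repetition
.assign_folds <- function(y, k, stratify) {
  n <- length(y)
  fold <- integer(n)
  if (stratify) {
    for (cls in unique(y)) {
      ii <- which(y == cls)
      fold[ii] <- sample(rep_len(seq_len(k), length(ii)))
    }
  } else {
    fold <- sample(rep_len(seq_len(k), n))
  }
  fold
}

#' Run cross-validation
#'
#' Scores every observation exactly once per repeat with a model never
#' trained on it. k-fold splits are stratified by class for binomial data.
#' Under class-balanced LOOCV, the training set of each fold additionally
#' drops one randomly chosen observation of the class opposite the held-out
#' one (seeded per fold).
#'
#' @param data `lncass_dataset`.
#' @param plan `lncass_cv_plan`.
#' @param fit Function `(train_data) -> function(X_new) -> scores`, i.e. a
#'   trainer returning a predictor.
#' @return List with `scores` (data frame: `observation`, `rep`, `fold`,
#'   `score`, `label`), `auc_pooled` (over all held-out scores, per repeat
#'   averaged — see `auc_by_repeat`), and `auc_by_repeat`.
#' @export
run_cv <- function(data, plan, fit) {
  stopifnot(inherits(data, "lncass_dataset"), inherits(plan, "lncass_cv_plan"),
            is.function(fit))
  n <- data$n
  y <- data$y
  k <- if (plan$scheme == "loocv") n else plan$folds
  if (k > n) stop("more folds than observations")
  reps <- if (plan$scheme == "loocv") 1L else plan$repeats
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    set.seed(plan$seed + 1000L * r)
    fold <- if (plan$scheme == "loocv") seq_len(n)
            else .assign_folds(y, k, stratify = data$family == "binomial")
    rows <- vector("list", k)
    for (f in seq_len(k)) {
      test_idx <- which(fold == f)
      train_idx <- setdiff(seq_len(n), test_idx)
      if (plan$class_balance && plan$scheme == "loocv" &&
          data$family == "binomial") {
        held_cls <- y[test_idx]
        opp <- train_idx[y[train_idx] != held_cls]
        if (length(opp)) {
          set.seed(plan$seed + 7L * f)
          train_idx <- setdiff(train_idx, sample(opp, 1))
        }
      }
      train <- regression_dataset(data$X[train_idx, , drop = FALSE],
                                  y[train_idx], family = data$family,
                                  predictor_names = data$predictor_names)
      predict_fn <- fit(train)
      sc <- predict_fn(data$X[test_idx, , drop = FALSE])
      rows[[f]] <- data.frame(observation = test_idx, rep = r, fold = f,
                              score = as.numeric(sc), label = y[test_idx])
    }
    out[[r]] <- do.call(rbind, rows)
  }
  scores <- do.call(rbind, out)
  auc_by_repeat <- vapply(seq_len(reps), function(r) {
    sub <- scores[scores$rep == r, ]
    roc_auc(sub$score, sub$label)$auc
  }, numeric(1))
  list(scores = scores, auc_pooled = roc_auc(scores$score, scores$label)$auc,
       auc_by_repeat = auc_by_repeat, auc_mean = mean(auc_by_repeat))
}
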