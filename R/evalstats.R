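#' Classical one-way analysis of variance
#'
#' Equal-variance one-way ANOVA:
#' `F = (SSB / (k - 1)) / (SSW / (N - k))` with the p value from the F
#' distribution.  Delegated to [stats::oneway.test()] with
#' `var.equal = TRUE` (identical to the `aov` F test).
#'
#' @param groups List of numeric vectors (>= 2 groups of >= 2 values).
#' @param feature Optional feature name carried into the result.
#' @return List with `feature`, `means`, `sds`, `ns`, `F`, `df`, `p`.
#' @export
one_way_anova <- function(groups, feature = NA_character_) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("every group needs >= 2 members")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ft <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(feature = feature,
       means = vapply(groups, mean, double(1)),
       sds = vapply(groups, stats::sd, double(1)),
       ns = lengths(groups),
       F = unname(ft$statistic),
       df = unname(ft$parameter),
       p = unname(ft$p.value))
}

#' Pearson product-moment correlation with its t-test p value
#'
#' @param x,y Numeric vectors of equal length (>= 3) with nonzero
#'   variance.
#' @return List with `r` and `p` (two-sided, n - 2 df).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Confusion matrix, accuracy and misclassification count
#'
#' @param truth,predicted Integer label vectors (0..3) of equal length.
#' @param n_classes Number of classes.
#' @return List with `confusion` (rows = truth, cols = predicted),
#'   `accuracy` and `misclassified`.
#' @export
confusion_and_accuracy <- function(truth, predicted, n_classes = 4L) {
  if (length(truth) != length(predicted)) stop("length mismatch")
  lv <- 0:(n_classes - 1)
  if (!all(truth %in% lv) || !all(predicted %in% lv))
    stop("labels must lie in 0..", n_classes - 1)
  confusion <- table(factor(truth, levels = lv),
                     factor(predicted, levels = lv))
  confusion <- unclass(as.matrix(confusion))
  dimnames(confusion) <- list(truth = emotion_levels()[lv + 1],
                              predicted = emotion_levels()[lv + 1])
  acc <- sum(diag(confusion)) / length(truth)
  list(confusion = confusion, accuracy = acc,
       misclassified = as.integer(length(truth) - sum(diag(confusion))))
}

# Midrank (Mann-Whitney) AUC of scores for positives vs negatives;
# equivalent to trapezoidal integration of the ROC curve with midrank tie
# handling.
auc_midrank <- function(scores, positive) {
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' One-vs-rest ROC AUC for a multiclass score matrix
#'
#' Per class, the AUC of that class's score column against the
#' one-vs-rest binarized truth, computed by the midrank (Mann-Whitney)
#' method; the macro AUC is the unweighted mean over classes present in
#' the truth vector.  A class absent from the truth gets `NA` and is
#' excluded from the macro average.
#'
#' @param truth Integer labels 0..(ncol(scores) - 1).
#' @param scores Numeric n x k score matrix.
#' @return List with `per_class` (named numeric) and `macro`.
#' @export
roc_auc_ovr <- function(truth, scores) {
  scores <- as.matrix(scores)
  if (length(truth) != nrow(scores)) stop("length mismatch")
  k <- ncol(scores)
  per <- vapply(seq_len(k), function(j)
    auc_midrank(scores[, j], truth == (j - 1L)), double(1))
  names(per) <- emotion_levels()[seq_len(k)]
  list(per_class = per, macro = mean(per, na.rm = TRUE))
}

# --- comparator baselines ----------------------------------------------

# One-vs-rest Gaussian-kernel SVM: one binary machine per class, scored
# by its decision value.  Kernel scale s corresponds to gamma = 1/s^2.
svm_ovr_scores <- function(x_train, y_train, x_test, kernel_scale = 2.5,
                           n_classes = 4L) {
  gam <- 1 / kernel_scale^2
  sc <- matrix(NA_real_, nrow(x_test), n_classes)
  for (j in seq_len(n_classes)) {
    yy <- factor(ifelse(y_train == (j - 1L), "pos", "neg"),
                 levels = c("neg", "pos"))
    if (length(unique(yy)) < 2) {   # class absent from this training fold
      sc[, j] <- -Inf
      next
    }
    fit <- e1071::svm(x_train, yy, kernel = "radial", gamma = gam,
                      cost = 1, scale = FALSE, probability = FALSE)
    dv <- attr(stats::predict(fit, x_test, decision.values = TRUE),
               "decision.values")
    # orient the decision value toward the positive class
    sgn <- if (grepl("^pos", colnames(dv)[1])) 1 else -1
    sc[, j] <- sgn * dv[, 1]
  }
  sc
}

# RUSBoost: SAMME-style boosting of shallow rpart trees, each fitted on a
# class-balanced random undersample of the training data.  (No R package
# in the environment provides RUSBoost; the boosting loop is written here
# and the weak learner is delegated to rpart.)
rusboost_scores <- function(x_train, y_train, x_test, n_learners = 20L,
                            max_splits = 30L, n_classes = 4L,
                            seed = NULL) {
  df_tr <- data.frame(x_train)
  df_te <- data.frame(x_test)
  names(df_te) <- names(df_tr)
  yf <- factor(y_train, levels = 0:(n_classes - 1))
  n <- length(y_train)
  w <- rep(1 / n, n)
  agg <- matrix(0, nrow(x_test), n_classes)
  with_seed(seed, {
    for (m in seq_len(n_learners)) {
      # random undersampling: equal draws per class, weight-proportional
      tab <- table(yf)
      n_min <- min(tab[tab > 0])
      idx <- unlist(lapply(levels(yf), function(cl) {
        pool <- which(yf == cl)
        if (length(pool) == 0) return(integer(0))
        sample(pool, min(n_min, length(pool)), replace = FALSE,
               prob = w[pool] / sum(w[pool]))
      }))
      fit <- rpart::rpart(y ~ ., data = cbind(df_tr[idx, , drop = FALSE],
                                              y = yf[idx]),
                          method = "class",
                          control = rpart::rpart.control(
                            maxdepth = max(1L, floor(log2(max_splits + 1))),
                            cp = 0, minsplit = 2, xval = 0))
      pred_tr <- stats::predict(fit, df_tr, type = "class")
      err <- sum(w * (pred_tr != yf)) / sum(w)
      if (err >= 1 - 1 / n_classes || err <= 0) {
        alpha <- if (err <= 0) 3 else 0.01
      } else {
        alpha <- log((1 - err) / err) + log(n_classes - 1)
      }
      w <- w * exp(alpha * (pred_tr != yf))
      w <- w / sum(w)
      pred_te <- stats::predict(fit, df_te, type = "class")
      agg <- agg + alpha *
        (matrix(0:(n_classes - 1), nrow(x_test), n_classes,
                byrow = TRUE) == as.integer(as.character(pred_te)))
    }
  })
  agg
}

#' Comparator baselines under shared cross-validation folds
#'
#' Evaluates (i) a one-vs-rest Gaussian-kernel support-vector classifier
#' (kernel scale 2.5) and (ii) a RUSBoost ensemble of decision trees
#' (20 learners, at most 30 splits each) under exactly the folds used for
#' the convolutional network, reporting the same metrics.
#'
#' @param x Feature matrix.
#' @param y Integer labels 0..3.
#' @param folds Integer fold assignment (1..k), e.g. from a prior
#'   [cv_odcnn()] run, so all models share folds.
#' @param seed Seed for the undersampling draws.
#' @return Named list of `emotion_cv_report` objects
#'   (`svm`, `rusboost`).
#' @export
run_comparators <- function(x, y, folds, seed = 1L) {
  x <- as.matrix(x); y <- as.integer(y)
  k <- max(folds)
  n <- nrow(x)
  sc_svm <- matrix(NA_real_, n, 4L)
  sc_rus <- matrix(NA_real_, n, 4L)
  for (f in seq_len(k)) {
    te <- folds == f
    sc_svm[te, ] <- svm_ovr_scores(x[!te, , drop = FALSE], y[!te],
                                   x[te, , drop = FALSE])
    sc_rus[te, ] <- rusboost_scores(x[!te, , drop = FALSE], y[!te],
                                    x[te, , drop = FALSE],
                                    seed = derive_seed(seed, 900L + f))
  }
  mk_report <- function(name, scores) {
    predicted <- as.integer(max.col(scores, ties.method = "first") - 1L)
    ca <- confusion_and_accuracy(y, predicted)
    auc <- roc_auc_ovr(y, scores)
    structure(list(model = name, accuracy = ca$accuracy,
                   confusion = ca$confusion,
                   misclassified = ca$misclassified,
                   per_class_auc = auc$per_class, macro_auc = auc$macro,
                   scores = scores, predicted = predicted, folds = folds,
                   loss_curves = NULL),
              class = "emotion_cv_report")
  }
  list(svm = mk_report("Gaussian SVM (one-vs-rest)", sc_svm),
       rusboost = mk_report("RUSBoosted trees", sc_rus))
}

#' Reproduce the per-feature ANOVA table on a generated dataset
#'
#' Runs [one_way_anova()] across the four emotion groups for each of the
#' seven modeled features.
#'
#' @param records Data frame of employee records.
#' @return Data frame with feature, F and p columns plus per-class means.
#' @export
anova_table <- function(records) {
  feats <- emotion_features_modeled()
  rows <- lapply(feats, function(f) {
    groups <- split(records[[f]],
                    factor(records$emotion, levels = emotion_levels()))
    a <- one_way_anova(groups, feature = f)
    data.frame(feature = f, F = a$F, p = a$p,
               t(stats::setNames(a$means, paste0("mean_", names(a$means)))))
  })
  do.call(rbind, rows)
}

#' Per-class Pearson correlation table on a generated dataset
#'
#' @param records Data frame of employee records.
#' @return Data frame with emotion, the feature pair, r and p.
#' @export
correlation_table <- function(records) {
  feats <- emotion_features_modeled()
  pairs <- utils::combn(feats, 2)
  rows <- list()
  for (em in emotion_levels()) {
    sub <- records[records$emotion == em, , drop = FALSE]
    if (nrow(sub) < 3) next
    for (j in seq_len(ncol(pairs))) {
      pr <- pearson_r(sub[[pairs[1, j]]], sub[[pairs[2, j]]])
      rows[[length(rows) + 1]] <-
        data.frame(emotion = em, var1 = pairs[1, j], var2 = pairs[2, j],
                   r = pr$r, p = pr$p)
    }
  }
  do.call(rbind, rows)
}
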