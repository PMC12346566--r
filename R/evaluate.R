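# Evaluation protocols: per-class classification reports, Wilson intervals,
# Cohen's kappa with bootstrap CIs, subject-grouped cross-validation with a
# hard leakage audit, SNR robustness sweeps, and the ablation harness.

#' Per-class classification report
#'
#' Precision, recall, F1, and support per class plus macro and weighted
#' average rows. Classes absent from both vectors keep zero support.
#'
#' @param actual,predicted Character vectors of equal length.
#' @param classes Class vocabulary (default: union of observed values).
#' @return Data frame with one row per class plus `macro avg` and
#'   `weighted avg`; attribute `"accuracy"` holds the overall accuracy.
#' @export
classification_report <- function(actual, predicted,
                                  classes = sort(unique(c(actual, predicted)),
                                                 method = "radix")) {
  stopifnot(length(actual) == length(predicted))
  tp <- fp <- fn <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    tp[cl] <- sum(actual == cl & predicted == cl)
    fp[cl] <- sum(actual != cl & predicted == cl)
    fn[cl] <- sum(actual == cl & predicted != cl)
  }
  support <- tp + fn
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  # averages over classes with support (a vocabulary class can be absent
  # from a finite test draw)
  has <- support > 0
  rep_ <- data.frame(
    class = c(classes, "macro avg", "weighted avg"),
    precision = c(precision, mean(precision[has]),
                  sum(precision * support) / sum(support)),
    recall = c(recall, mean(recall[has]), sum(recall * support) / sum(support)),
    f1 = c(f1, mean(f1[has]), sum(f1 * support) / sum(support)),
    support = c(support, sum(support), sum(support)),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(rep_, "accuracy") <- mean(actual == predicted)
  rep_
}

#' Confusion matrix over a fixed class vocabulary
#' @param actual,predicted Character vectors.
#' @param classes Class vocabulary.
#' @return Integer matrix, rows = actual, columns = predicted.
#' @export
confusion_matrix <- function(actual, predicted,
                             classes = sort(unique(c(actual, predicted)),
                                            method = "radix")) {
  table(factor(actual, classes), factor(predicted, classes))
}

#' Wilson score interval for a proportion
#'
#' @param correct Number of successes.
#' @param total Number of trials (> 0).
#' @param conf Confidence level (default 0.95).
#' @return Named vector `c(lower, upper)`, clipped to `[0, 1]`.
#' @export
accuracy_ci <- function(correct, total, conf = 0.95) {
  if (total <= 0) stop("accuracy_ci: total must be positive")
  if (correct < 0 || correct > total) stop("accuracy_ci: correct out of range")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- correct / total
  denom <- 1 + z^2 / total
  center <- (p + z^2 / (2 * total)) / denom
  half <- z * sqrt(p * (1 - p) / total + z^2 / (4 * total^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Cohen's kappa with a percentile-bootstrap confidence interval
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with chance agreement from the marginal
#' label distributions. With `p_e = 1` (both raters constant and equal) kappa
#' is undefined and returned as `NA`.
#'
#' @param a,b Label sequences of equal length.
#' @param ci_bootstrap Bootstrap resamples for the 95% CI (0 = point
#'   estimate only).
#' @param seed Integer seed for the bootstrap.
#' @return List with `kappa`, `p_o`, `p_e`, and (if bootstrapped) `ci`.
#' @export
cohens_kappa <- function(a, b, ci_bootstrap = 0, seed = 0) {
  if (length(a) != length(b)) stop("cohens_kappa: length mismatch")
  k_of <- function(x, y) {
    lev <- union(x, y)
    p_o <- mean(x == y)
    pa <- table(factor(x, lev)) / length(x)
    pb <- table(factor(y, lev)) / length(y)
    p_e <- sum(pa * pb)
    if (1 - p_e < 1e-12) return(c(NA_real_, p_o, p_e))
    c((p_o - p_e) / (1 - p_e), p_o, p_e)
  }
  est <- k_of(a, b)
  out <- list(kappa = est[1], p_o = est[2], p_e = est[3])
  if (ci_bootstrap > 0) {
    ks <- with_seed(seed, vapply(seq_len(ci_bootstrap), function(i) {
      ix <- sample(length(a), replace = TRUE)
      k_of(a[ix], b[ix])[1]
    }, 0))
    out$ci <- stats::quantile(ks, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  out
}

# Hard leakage audit: no training clip may originate from a held-out
# subject. Violation is an error, never a warning.
.audit_leakage <- function(train_source_subjects, held_out_subjects) {
  leaked <- intersect(unique(train_source_subjects), held_out_subjects)
  if (length(leaked) > 0) {
    stop("leakage violation: training data derived from held-out subject(s) ",
         paste(leaked, collapse = ", "))
  }
  invisible(TRUE)
}

#' Leave-one-subject-out protocol
#'
#' One fold per subject; the held-out subject's clips (and anything derived
#' from them, per `source_subjects`) are fully excluded from training. The
#' trainer is called fresh per fold, so weights re-initialize every time. A
#' training clip tracing back to a held-out subject aborts the protocol.
#'
#' @param features List of per-clip feature objects.
#' @param labels,subjects Character vectors aligned with `features`.
#' @param trainer `function(features, labels, seed) -> model`.
#' @param predict_fun `function(model, features) -> character labels`.
#' @param source_subjects Originating subject per clip (defaults to
#'   `subjects`; differs for augmented clips).
#' @param seed Integer base seed (per-fold seeds derive from it).
#' @return List with `per_fold` (data frame: subject, n, correct), `pooled`
#'   classification report, `accuracy`, and `ci` (Wilson 95%).
#' @export
loso_protocol <- function(features, labels, subjects, trainer, predict_fun,
                          source_subjects = subjects, seed = 0) {
  stopifnot(length(features) == length(labels),
            length(labels) == length(subjects),
            length(source_subjects) == length(subjects))
  subj_set <- unique(subjects)
  all_actual <- character(0); all_pred <- character(0)
  per_fold <- data.frame(subject = character(0), n = integer(0),
                         correct = integer(0))
  for (fi in seq_along(subj_set)) {
    s <- subj_set[fi]
    test_i <- subjects == s
    train_i <- !test_i
    .audit_leakage(source_subjects[train_i], s)
    model <- trainer(features[train_i], labels[train_i], seed + fi)
    pred <- predict_fun(model, features[test_i])
    all_actual <- c(all_actual, labels[test_i])
    all_pred <- c(all_pred, pred)
    per_fold <- rbind(per_fold, data.frame(
      subject = s, n = sum(test_i),
      correct = sum(pred == labels[test_i])))
  }
  acc <- mean(all_pred == all_actual)
  list(per_fold = per_fold,
       pooled = classification_report(all_actual, all_pred),
       accuracy = acc,
       ci = accuracy_ci(sum(all_pred == all_actual), length(all_actual)))
}

#' Subject-grouped stratified k-fold protocol
#'
#' Subjects (never clips) are dealt to folds; within each class, subject
#' groups are distributed round-robin so fold class proportions track the
#' global ones.
#'
#' @inheritParams loso_protocol
#' @param k Number of folds (>= 2).
#' @return List with `pooled` report, `accuracy`, `ci`, and `fold_of`
#'   (named subject -> fold map).
#' @export
kfold_protocol <- function(features, labels, subjects, trainer, predict_fun,
                           k = 10, source_subjects = subjects, seed = 0) {
  if (k < 2) stop("kfold_protocol: k must be >= 2")
  subj_class <- tapply(labels, subjects, function(x) x[1])[unique(subjects)]
  if (k > length(subj_class)) {
    stop("kfold_protocol: k exceeds the number of subject groups")
  }
  fold_of <- with_seed(seed, {
    fo <- integer(0)
    counter <- 0L
    for (cl in sample(unique(subj_class))) {
      ss <- sample(names(subj_class)[subj_class == cl])
      f <- ((counter + seq_along(ss) - 1L) %% k) + 1L
      counter <- counter + length(ss)
      fo[ss] <- f
    }
    fo
  })
  all_actual <- character(0); all_pred <- character(0)
  for (fi in seq_len(k)) {
    held <- names(fold_of)[fold_of == fi]
    test_i <- subjects %in% held
    if (!any(test_i)) next
    .audit_leakage(source_subjects[!test_i], held)
    model <- trainer(features[!test_i], labels[!test_i], seed + fi)
    pred <- predict_fun(model, features[test_i])
    all_actual <- c(all_actual, labels[test_i])
    all_pred <- c(all_pred, pred)
  }
  list(pooled = classification_report(all_actual, all_pred),
       accuracy = mean(all_pred == all_actual),
       ci = accuracy_ci(sum(all_pred == all_actual), length(all_actual)),
       fold_of = fold_of)
}

#' SNR robustness sweep
#'
#' Corrupts each clean test clip with white noise at every SNR on the grid
#' (fresh seeds per clip), re-featurizes, re-classifies, and tabulates
#' accuracy plus macro-average sensitivity and specificity.
#'
#' @param model A trained diagnoser.
#' @param clips List of clean test [audio_clip()]s with labels.
#' @param featurize `function(clip) -> mfcc_matrix` matching the model input.
#' @param snr_grid SNRs in dB (default 5, 10, 15, 20).
#' @param seed Integer seed.
#' @return Data frame with `snr_db`, `accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
noise_sweep <- function(model, clips, featurize, snr_grid = c(5, 10, 15, 20),
                        seed = 0) {
  labels <- vapply(clips, `[[`, "", "label")
  rows <- lapply(seq_along(snr_grid), function(gi) {
    noisy <- lapply(seq_along(clips), function(i) {
      inject_noise(clips[[i]], snr_grid[gi], seed = seed * 1000L + gi * 101L + i)
    })
    feats <- lapply(noisy, featurize)
    pred <- predict_diagnoser(model, feats)$labels
    cm <- confusion_matrix(labels, pred, classes = unique(labels))
    sens <- mean(diag(cm) / pmax(rowSums(cm), 1))
    spec <- mean(vapply(seq_len(nrow(cm)), function(ci) {
      tn <- sum(cm[-ci, -ci]); fp <- sum(cm[-ci, ci])
      tn / max(tn + fp, 1)
    }, 0))
    data.frame(snr_db = snr_grid[gi], accuracy = mean(pred == labels),
               sensitivity = sens, specificity = spec)
  })
  do.call(rbind, rows)
}

#' Ablation harness over architecture variants
#'
#' Trains each registered variant (`full`, `no_attention`, `cnn_only`) on the
#' same subject-level split across the given seeds and reports mean accuracy
#' and delta versus the full model. The registry documents (without running)
#' two further variants from the source architecture family: a joint
#' diagnosis+prescription head and a transformer encoder, both of which
#' require paired audio-prescription data that this artifact does not
#' contain.
#'
#' @param features,labels,subjects Aligned per-clip data.
#' @param config Base [diagnoser_config()] (its `variant` field is
#'   overridden).
#' @param variants Variant names to run.
#' @param seeds Integer vector of training seeds.
#' @param test_fraction Held-out subject share.
#' @param seed Split seed.
#' @return Data frame with `variant`, `mean_accuracy`, `delta_vs_full`.
#' @export
ablation_harness <- function(features, labels, subjects,
                             config = diagnoser_config(),
                             variants = c("full", "no_attention", "cnn_only"),
                             seeds = 0:2, test_fraction = 0.2, seed = 0) {
  known <- c("full", "no_attention", "cnn_only")
  bad <- setdiff(variants, known)
  if (length(bad) > 0) stop("unknown variant(s): ", paste(bad, collapse = ", "))
  split <- subject_holdout(subjects, test_fraction, seed)
  res <- lapply(variants, function(v) {
    cfg <- config
    cfg$variant <- v
    accs <- vapply(seeds, function(s) {
      mod <- train_diagnoser(features[split$train], labels[split$train],
                             cfg, seed = s)
      pred <- predict_diagnoser(mod, features[split$test])$labels
      mean(pred == labels[split$test])
    }, 0)
    data.frame(variant = v, mean_accuracy = mean(accs))
  })
  out <- do.call(rbind, res)
  full_acc <- out$mean_accuracy[out$variant == "full"]
  out$delta_vs_full <- if (length(full_acc) == 1) {
    out$mean_accuracy - full_acc
  } else NA_real_
  out
}

#' Subject-level holdout split
#'
#' Splits subjects (stratified by their class) into train/test, returning
#' clip index vectors; clips of one subject never straddle the split.
#'
#' @param subjects Character vector, one entry per clip.
#' @param test_fraction Held-out share of subjects per class.
#' @param seed Integer seed.
#' @param labels Optional per-clip labels for stratification (defaults to
#'   unstratified).
#' @return List with logical-index vectors `train` and `test`.
#' @export
subject_holdout <- function(subjects, test_fraction = 0.2, seed = 0,
                            labels = NULL) {
  subj <- unique(subjects)
  groups <- if (is.null(labels)) {
    list(subj)
  } else {
    cls <- tapply(labels, subjects, function(x) x[1])[subj]
    split(subj, factor(cls, levels = unique(cls)))       # locale-stable
  }
  held <- with_seed(seed, unlist(lapply(groups, function(ss) {
    k <- max(1L, round(length(ss) * test_fraction))
    sample(ss, k)
  }), use.names = FALSE))
  list(train = !(subjects %in% held), test = subjects %in% held)
}

#' One-vs-rest AUC per class plus macro AUC
#'
#' @param actual Character labels.
#' @param probs Probability matrix with class columns.
#' @return Named vector of per-class AUCs with a `macro` entry (unweighted
#'   mean over classes present in `actual`).
#' @export
per_class_auc <- function(actual, probs) {
  classes <- colnames(probs)
  aucs <- vapply(classes, function(cl) {
    y <- as.integer(actual == cl)
    if (length(unique(y)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(y, probs[, cl], quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, 0)
  c(aucs, macro = mean(aucs, na.rm = TRUE))
}
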