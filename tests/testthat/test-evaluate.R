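test_that("classification reports are self-consistent", {
  set.seed(21)
  classes <- c("a", "b", "c")
  actual <- sample(classes, 200, replace = TRUE)
  predicted <- ifelse(runif(200) < 0.7, actual, sample(classes, 200, TRUE))
  rep_ <- classification_report(actual, predicted, classes)
  cm <- confusion_matrix(actual, predicted, classes)
  # accuracy = trace / total
  expect_equal(attr(rep_, "accuracy"), sum(diag(cm)) / sum(cm))
  # confusion row sums equal class supports
  expect_equal(as.vector(rowSums(cm)),
               rep_$support[seq_along(classes)])
  per <- rep_[seq_along(classes), ]
  # macro F1 = unweighted mean; weighted F1 = support-weighted mean
  expect_equal(rep_$f1[rep_$class == "macro avg"], mean(per$f1))
  expect_equal(rep_$f1[rep_$class == "weighted avg"],
               sum(per$f1 * per$support) / sum(per$support))
})

test_that("Wilson intervals match the closed form and clip to [0, 1]", {
  for (x in c(0, 1, 5, 9, 10)) {
    got <- accuracy_ci(x, 10)
    expect_equal(unname(got), pmin(1, pmax(0, oracle_wilson(x, 10))),
                 tolerance = 1e-12, label = paste("x =", x))
  }
  lo <- accuracy_ci(0, 10)
  expect_equal(lo[["lower"]], 0)
  expect_lt(lo[["upper"]], 0.35)
  expect_equal(accuracy_ci(10, 10)[["upper"]], 1)
  expect_error(accuracy_ci(1, 0), "positive")
})

test_that("Cohen's kappa matches enumeration on all small 2x2 tables", {
  expect_equal(cohens_kappa(letters[1:5], letters[1:5])$kappa, 1)
  # chance-level toy: p_o = p_e = 0.5
  expect_equal(cohens_kappa(c("A", "A", "B", "B"), c("A", "B", "A", "B"))$kappa, 0)
  # balanced perfect disagreement
  expect_equal(cohens_kappa(c("A", "B", "A", "B"), c("B", "A", "B", "A"))$kappa, -1)
  expect_error(cohens_kappa(c("A", "B"), c("A")), "length mismatch")
  # both raters constant and equal: undefined
  expect_true(is.na(cohens_kappa(c("A", "A"), c("A", "A"))$kappa))

  # exhaustive sweep of 2x2 tables with total <= 12 against the oracle
  for (n11 in 0:4) for (n12 in 0:4) for (n21 in 0:4) {
    for (n22 in 0:(12 - n11 - n12 - n21)) {
      if (n11 + n12 + n21 + n22 == 0) next
      a <- c(rep("X", n11 + n12), rep("Y", n21 + n22))
      b <- c(rep("X", n11), rep("Y", n12), rep("X", n21), rep("Y", n22))
      want <- oracle_kappa(a, b)
      got <- cohens_kappa(a, b)$kappa
      if (is.nan(want) || is.infinite(want)) {
        expect_true(is.na(got))
      } else {
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  }
})

test_that("kappa agrees with the independent caret implementation", {
  skip_if_not_installed("caret")
  set.seed(4)
  a <- sample(c("p", "q", "r"), 60, replace = TRUE)
  b <- ifelse(runif(60) < 0.6, a, sample(c("p", "q", "r"), 60, TRUE))
  cm <- caret::confusionMatrix(factor(b, c("p", "q", "r")),
                               factor(a, c("p", "q", "r")))
  expect_equal(cohens_kappa(a, b)$kappa,
               unname(cm$overall["Kappa"]), tolerance = 1e-10)
})

test_that("bootstrap kappa CI brackets the point estimate", {
  set.seed(5)
  a <- sample(c("A", "B"), 80, replace = TRUE)
  b <- ifelse(runif(80) < 0.8, a, sample(c("A", "B"), 80, TRUE))
  k <- cohens_kappa(a, b, ci_bootstrap = 300, seed = 1)
  expect_lte(k$ci[1], k$kappa)
  expect_gte(k$ci[2], k$kappa)
})

# a deterministic majority-class "trainer" keeps protocol tests instant
majority_trainer <- function(features, labels, seed) {
  names(sort(table(labels), decreasing = TRUE))[1]
}
majority_predict <- function(model, features) rep(model, length(features))

test_that("LOSO builds one fold per subject and audits augmentation leakage", {
  feats <- as.list(1:6)
  labels <- c("a", "a", "b", "b", "a", "b")
  subjects <- c("s1", "s1", "s2", "s2", "s3", "s3")
  res <- loso_protocol(feats, labels, subjects, majority_trainer,
                       majority_predict)
  expect_equal(nrow(res$per_fold), 3)           # 3 subjects -> 3 folds
  expect_setequal(res$per_fold$subject, c("s1", "s2", "s3"))
  expect_equal(sum(res$per_fold$n), 6)
  expect_true(all(res$ci >= 0 & res$ci <= 1))

  # an augmented clip tracing to a held-out subject aborts the protocol
  source_subjects <- c("s1", "s2", "s2", "s2", "s3", "s3")  # clip 1 leaked
  expect_error(
    loso_protocol(feats, labels, subjects, majority_trainer,
                  majority_predict, source_subjects = source_subjects),
    "leakage")
})

test_that("grouped k-fold tests each subject exactly once, stratified", {
  feats <- as.list(1:8)
  labels <- rep(c("a", "b"), each = 4)
  subjects <- c("s1", "s1", "s2", "s2", "s3", "s3", "s4", "s4")
  res <- kfold_protocol(feats, labels, subjects, majority_trainer,
                        majority_predict, k = 2)
  expect_equal(sum(res$pooled$support[res$pooled$class == "macro avg"]), 8)
  # each fold holds one subject of each class: proportions within 1 sample
  tab <- table(res$fold_of, c(s1 = "a", s2 = "a", s3 = "b", s4 = "b")[names(res$fold_of)])
  expect_true(all(abs(tab - 1) <= 1))
  expect_named(res$pooled, c("class", "precision", "recall", "f1", "support"))
  expect_error(kfold_protocol(feats, labels, subjects, majority_trainer,
                              majority_predict, k = 10), "exceeds")
})

test_that("subject holdout never straddles a subject across the split", {
  subs <- rep(sprintf("s%02d", 1:10), each = 3)
  sp <- subject_holdout(subs, 0.3, seed = 2)
  expect_length(intersect(unique(subs[sp$train]), unique(subs[sp$test])), 0)
  expect_equal(sp$train, !sp$test)
})

test_that("one-vs-rest AUC is 1 under perfect separation", {
  actual <- c("a", "a", "b", "b")
  probs <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.2, 0.8), c(0.1, 0.9))
  colnames(probs) <- c("a", "b")
  auc <- per_class_auc(actual, probs)
  expect_equal(unname(auc[c("a", "b", "macro")]), c(1, 1, 1))
})

test_that("the ablation registry rejects unknown variants", {
  expect_error(ablation_harness(list(), character(0), character(0),
                                variants = "transformer"), "unknown variant")
})
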