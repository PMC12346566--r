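# Explainability: attention traces for the acoustic diagnoser and
# model-agnostic feature attribution for the prescription recommender.

#' Extract the attention trace for one clip
#'
#' The softmax attention weights over the pooled time axis from the forward
#' pass, paired with the predicted class.
#'
#' @param model A trained diagnoser (full variant).
#' @param m An [mfcc_matrix()] shaped for the model.
#' @return An `attention_trace`: list with `alpha` (nonnegative, sums to 1),
#'   `predicted`, `frame_hop_s` (`NA` unless supplied later for plotting).
#' @export
attention_trace <- function(model, m) {
  if (is.na(model$best_epoch)) stop("attention_trace: model is untrained")
  if (model$config$variant == "cnn_only") {
    stop("attention_trace: the cnn_only variant has no attention layer")
  }
  pr <- predict_diagnoser(model, m)
  structure(list(alpha = pr$alpha, predicted = pr$label),
            class = "attention_trace")
}

#' Write an attention trace as CSV
#' @param trace An [attention_trace()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_attention_trace <- function(trace, path) {
  utils::write.csv(data.frame(step = seq_along(trace$alpha),
                              alpha = trace$alpha), path, row.names = FALSE)
  invisible(path)
}

#' Plot an attention trace as a heat strip
#' @param trace An [attention_trace()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
plot_attention_trace <- function(trace, path) {
  grDevices::png(path, width = 800, height = 160)
  on.exit(grDevices::dev.off())
  graphics::image(matrix(trace$alpha, ncol = 1), axes = FALSE,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  main = paste("attention -", trace$predicted))
  invisible(path)
}

.rx_patient_features <- c("age", "sex", "smoking", "diagnosis",
                          "comedication", "renal_impaired",
                          "hepatic_impaired", "eGFR", "weight")

# probability the model assigns to drug `d` for each row
.drug_prob <- function(model, rows, d) {
  fm <- .rx_feature_matrix(rows, model$age_center, model$age_scale)
  P <- stats::predict(model$forest, data = fm$X, num.threads = 1)$predictions
  drugs <- vapply(strsplit(colnames(P), " | ", fixed = TRUE), `[[`, "", 1)
  rowSums(P[, drugs == d, drop = FALSE])
}

#' Feature attribution for the recommender's drug output
#'
#' Two model-agnostic methods over the raw patient fields.
#' `"permutation"` (default, global): each feature column is permuted across
#' the evaluation rows (seeded) and its importance is the label-flip rate of
#' the predicted drug -- a feature the generating rules never consult scores
#' about zero. `"kernel"` (local): exact Shapley values for the probability
#' of each row's predicted drug, computed by full coalition enumeration with
#' feature absence marginalized over the background rows; the attributions of
#' a row sum to `f(x) - mean(f(background))` by construction.
#'
#' @param model A [train_recommender()] model.
#' @param background Background rows (kernel method; kept small).
#' @param eval_rows Rows to explain.
#' @param method `"permutation"` or `"kernel"`.
#' @param seed Integer seed.
#' @param features Patient fields to attribute over.
#' @return An `attribution_report`: list with `global` (data frame sorted by
#'   mean absolute attribution), `local` (kernel method: matrix of signed
#'   attributions, rows = eval rows), `method`.
#' @export
feature_attribution <- function(model, background, eval_rows,
                                method = c("permutation", "kernel"),
                                seed = 0,
                                features = .rx_patient_features) {
  method <- match.arg(method)
  missing_f <- setdiff(features, names(eval_rows))
  if (length(missing_f) > 0) {
    stop("feature mismatch: eval rows lack ", paste(missing_f, collapse = ", "))
  }
  if (method == "permutation") {
    base_pred <- predict_recommender(model, eval_rows)$drug
    imp <- with_seed(seed, vapply(features, function(fc) {
      perm <- eval_rows
      perm[[fc]] <- perm[[fc]][sample(nrow(perm))]
      mean(predict_recommender(model, perm)$drug != base_pred)
    }, 0))
    glob <- data.frame(feature = features, importance = imp,
                       row.names = NULL)[order(-imp), ]
    return(structure(list(global = glob, local = NULL,
                          method = "permutation"), class = "attribution_report"))
  }

  if (nrow(background) == 0) stop("kernel attribution needs background rows")
  p <- length(features)
  if (p > 14) stop("kernel attribution enumerates coalitions; use <= 14 features")
  base_pred <- predict_recommender(model, eval_rows)$drug
  masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p)))
  colnames(masks) <- features
  fact <- factorial(0:p)
  local <- matrix(0, nrow(eval_rows), p, dimnames = list(NULL, features))
  for (ri in seq_len(nrow(eval_rows))) {
    x <- eval_rows[ri, , drop = FALSE]
    d <- base_pred[ri]
    # v(S): average model output with features outside S drawn from background
    v <- vapply(seq_len(nrow(masks)), function(mi) {
      S <- masks[mi, ]
      hyb <- background
      for (fc in features[S]) hyb[[fc]] <- rep(x[[fc]], nrow(background))
      mean(.drug_prob(model, hyb, d))
    }, 0)
    sizes <- rowSums(masks)
    for (j in seq_len(p)) {
      without_j <- which(!masks[, j])
      for (mi in without_j) {
        s <- sizes[mi]
        w <- fact[s + 1] * fact[p - s] / fact[p + 1]   # |S|!(p-|S|-1)!/p!
        mj <- mi + 2^(j - 1)                           # S with j added
        local[ri, j] <- local[ri, j] + w * (v[mj] - v[mi])
      }
    }
  }
  imp <- colMeans(abs(local))
  glob <- data.frame(feature = features, importance = imp,
                     row.names = NULL)[order(-imp), ]
  structure(list(global = glob, local = local, method = "kernel"),
            class = "attribution_report")
}

#' Plot one case's signed attributions (force-style bar chart)
#' @param report A kernel-method [feature_attribution()] report.
#' @param case Row index into the report's `local` matrix.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
plot_attribution_case <- function(report, case, path) {
  if (is.null(report$local)) stop("per-case plots need kernel attributions")
  phi <- sort(report$local[case, ])
  grDevices::png(path, width = 640, height = 360)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(4, 9, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::barplot(phi, horiz = TRUE, las = 1,
                    col = ifelse(phi >= 0, "#d73027", "#4575b4"),
                    xlab = "contribution to predicted-drug probability")
  invisible(path)
}

#' Write an attribution report (global ranking) as CSV
#' @param report An [feature_attribution()] report.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_attribution_report <- function(report, path) {
  utils::write.csv(report$global, path, row.names = FALSE)
  invisible(path)
}
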