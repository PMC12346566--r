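# Literature-derived disease-to-biomarker map and simulated molecular vector
# fusion. Twenty distinct protein/cytokine/gene markers cover the eight
# classes; synthetic intensity vectors are driven by the acoustic model's
# predicted posterior (never the true label, which would leak the answer into
# the fused channel).

#' The 20-marker vocabulary, in canonical order
#' @return Character vector of marker names.
#' @export
marker_vocabulary <- function() {
  c("MMP-9", "ELANE", "TGF-b", "CRP", "PCT", "IL-6", "IFN-a", "CXCL10",
    "TLR3", "IL-1b", "TNF-a", "SP-D", "POSTN", "IL-5", "YKL-40",
    "fibrinogen", "CC16", "IL-8", "G-CSF", "MUC5AC")
}

#' Build the disease-to-biomarker association map
#'
#' Each non-healthy class carries its literature-motivated marker triple:
#' bronchiectasis (MMP-9, ELANE, TGF-b: airway remodeling), pneumonia (CRP,
#' PCT, IL-6: acute bacterial/viral infection), URTI (IFN-a, CXCL10, TLR3:
#' antiviral signalling), LRTI (IL-1b, TNF-a, SP-D: lower-airway
#' inflammation), asthma (POSTN, IL-5, YKL-40: eosinophilic), COPD (IL-6,
#' fibrinogen, CC16: chronic systemic inflammation; IL-6 shared with
#' pneumonia), bronchiolitis (IL-8, G-CSF, MUC5AC: RSV-triggered). Healthy
#' maps to baseline levels only.
#'
#' Association magnitudes are not quantified in the literature consensus, so
#' a single elevation weight applies to every listed marker; both it and the
#' baseline are overridable.
#'
#' @param weight Elevation weight in `(0, 1]` for listed markers (default 0.8).
#' @param baseline Baseline intensity for all markers (default 0.1).
#' @return A `biomarker_map`: list with `vocabulary`, `baseline`, and
#'   `weights` (8 x 20 matrix, class x marker).
#' @export
build_marker_map <- function(weight = 0.8, baseline = 0.1) {
  stopifnot(weight > 0, weight <= 1, baseline >= 0, baseline < 1)
  vocab <- marker_vocabulary()
  assoc <- list(
    asthma         = c("POSTN", "IL-5", "YKL-40"),
    bronchiectasis = c("MMP-9", "ELANE", "TGF-b"),
    bronchiolitis  = c("IL-8", "G-CSF", "MUC5AC"),
    COPD           = c("IL-6", "fibrinogen", "CC16"),
    healthy        = character(0),
    LRTI           = c("IL-1b", "TNF-a", "SP-D"),
    pneumonia      = c("CRP", "PCT", "IL-6"),
    URTI           = c("IFN-a", "CXCL10", "TLR3")
  )
  W <- matrix(0, length(assoc), length(vocab),
              dimnames = list(names(assoc), vocab))
  for (cls in names(assoc)) W[cls, assoc[[cls]]] <- weight
  structure(list(vocabulary = vocab, baseline = baseline, weights = W),
            class = "biomarker_map")
}

#' Simulate a molecular intensity vector from a diagnostic posterior
#'
#' Marker intensity is `baseline + sum_d posterior_d * weight_{d,marker}`
#' plus Gaussian noise, clipped to `[0, 1]` -- elevation proportional to the
#' disease likelihood under the acoustic model.
#'
#' @param posterior Probability vector over the 8 classes (codec order),
#'   summing to 1.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @param map A [build_marker_map()].
#' @return A named numeric vector of 20 intensities in `[0, 1]`.
#' @export
simulate_vector <- function(posterior, noise_sd = 0.05, seed = 0,
                            map = build_marker_map()) {
  if (length(posterior) != nrow(map$weights) || any(posterior < 0) ||
      abs(sum(posterior) - 1) > 1e-6) {
    stop("simulate_vector: posterior must be a probability vector over the ",
         nrow(map$weights), " classes")
  }
  if (noise_sd < 0) stop("simulate_vector: noise_sd must be >= 0")
  mu <- map$baseline + as.numeric(posterior %*% map$weights)
  x <- if (noise_sd > 0) {
    with_seed(seed, mu + stats::rnorm(length(mu), 0, noise_sd))
  } else mu
  stats::setNames(pmin(1, pmax(0, x)), map$vocabulary)
}

#' Train a fusion head on concatenated audio-latent and molecular features
#'
#' A softmax regression head (fit with Adam on cross-entropy) over
#' `[audio_latent, molecular_vector]`, i.e. fusion at the diagnoser's
#' penultimate layer.
#'
#' @param latents Numeric matrix, one row per sample (penultimate
#'   activations).
#' @param molecular Numeric matrix, one row per sample (20 columns).
#' @param labels Character diagnosis labels.
#' @param epochs,lr,batch_size Optimization settings.
#' @param seed Integer seed.
#' @return A `fusion_head`: list with `W`, `b`, `codec`, and the input split
#'   sizes.
#' @export
train_fusion_head <- function(latents, molecular, labels, epochs = 150,
                              lr = 0.01, batch_size = 32, seed = 0) {
  stopifnot(nrow(latents) == nrow(molecular),
            nrow(latents) == length(labels))
  enc <- encode_labels(labels)
  X <- cbind(latents, molecular)
  K <- ncol(enc$onehot)
  with_seed(seed * 31L + 7L, {
    params <- list(W = .glorot(ncol(X), K), b = numeric(K))
    opt <- adam_init(params)
    for (ep in seq_len(epochs)) {
      ord <- sample(nrow(X))
      for (b0 in seq(1, length(ord), by = batch_size)) {
        bi <- ord[b0:min(b0 + batch_size - 1L, length(ord))]
        Z <- sweep(X[bi, , drop = FALSE] %*% params$W, 2, params$b, `+`)
        sx <- softmax_xent(Z, enc$onehot[bi, , drop = FALSE])
        grads <- list(W = crossprod(X[bi, , drop = FALSE], sx$dlogits),
                      b = colSums(sx$dlogits))
        up <- adam_update(params, grads, opt, lr = lr)
        params <- up$params
        opt <- up$state
      }
    }
    structure(list(W = params$W, b = params$b, codec = enc$codec,
                   n_latent = ncol(latents), n_molecular = ncol(molecular)),
              class = "fusion_head")
  })
}

#' Classify from fused audio-latent and molecular features
#'
#' @param audio_latent Penultimate-layer vector (or matrix, one row per
#'   sample).
#' @param mol Molecular vector (or matrix) from [simulate_vector()].
#' @param fusion_head A [train_fusion_head()] model.
#' @return List with `labels` and `probs` (rows sum to 1).
#' @export
fuse_and_classify <- function(audio_latent, mol, fusion_head) {
  if (is.vector(audio_latent)) audio_latent <- matrix(audio_latent, 1)
  if (is.vector(mol)) mol <- matrix(mol, 1)
  if (ncol(audio_latent) != fusion_head$n_latent ||
      ncol(mol) != fusion_head$n_molecular) {
    stop("fuse_and_classify: feature dimensions do not match the fusion head")
  }
  X <- cbind(audio_latent, mol)
  P <- softmax_rows(sweep(X %*% fusion_head$W, 2, fusion_head$b, `+`))
  list(labels = decode_labels(fusion_head$codec, P), probs = P)
}

#' Write the marker map as an editable YAML knowledge file
#' @param map A [build_marker_map()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_marker_map <- function(map, path) {
  per_disease <- apply(map$weights, 1, function(w) as.list(w[w > 0]),
                       simplify = FALSE)
  yaml::write_yaml(list(vocabulary = map$vocabulary, baseline = map$baseline,
                        diseases = per_disease), path)
  invisible(path)
}

#' Read a marker map written by [write_marker_map()]
#' @param path YAML path.
#' @return A `biomarker_map`.
#' @export
read_marker_map <- function(path) {
  y <- yaml::read_yaml(path)
  vocab <- unlist(y$vocabulary)
  W <- matrix(0, length(y$diseases), length(vocab),
              dimnames = list(names(y$diseases), vocab))
  for (cls in names(y$diseases)) {
    for (mk in names(y$diseases[[cls]])) W[cls, mk] <- y$diseases[[cls]][[mk]]
  }
  structure(list(vocabulary = vocab, baseline = y$baseline, weights = W),
            class = "biomarker_map")
}
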