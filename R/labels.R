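#' The eight diagnosis classes
#'
#' Fixed case-insensitive lexicographic order; the fitted ordering of the
#' original label encoder is not recoverable, so a deterministic convention is
#' used throughout.
#'
#' @return Character vector of the eight class names, in codec order.
#' @export
diagnosis_classes <- function() {
  c("asthma", "bronchiectasis", "bronchiolitis", "COPD",
    "healthy", "LRTI", "pneumonia", "URTI")
}

#' Build the label codec
#'
#' A bijective map between the eight class names and indices 1..8.
#'
#' @return A `label_codec`: list with `classes`, `to_index`, `to_name`.
#' @export
label_codec <- function() {
  classes <- diagnosis_classes()
  to_index <- stats::setNames(seq_along(classes), classes)
  structure(list(classes = classes, to_index = to_index), class = "label_codec")
}

#' Encode diagnosis labels as one-hot rows
#'
#' @param labels Character vector of class names.
#' @return List with `codec` (a [label_codec()]) and `onehot`
#'   (length(labels) x 8 matrix, each row summing to 1).
#' @export
encode_labels <- function(labels) {
  codec <- label_codec()
  idx <- codec$to_index[labels]
  if (any(is.na(idx))) {
    bad <- unique(labels[is.na(idx)])
    stop("unknown diagnosis label(s): ", paste(bad, collapse = ", "))
  }
  onehot <- matrix(0, nrow = length(labels), ncol = length(codec$classes),
                   dimnames = list(NULL, codec$classes))
  onehot[cbind(seq_along(idx), idx)] <- 1
  list(codec = codec, onehot = onehot)
}

#' Decode class indices (or one-hot rows) back to names
#'
#' @param codec A [label_codec()].
#' @param x Integer indices, or a one-hot / probability matrix (row argmax taken).
#' @return Character vector of class names.
#' @export
decode_labels <- function(codec, x) {
  if (is.matrix(x)) x <- apply(x, 1, which.max)
  codec$classes[as.integer(x)]
}
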