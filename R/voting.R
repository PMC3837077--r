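#' Per-classifier, per-class vote-weight matrix
#'
#' Row m, column j holds the weight of classifier m's vote for label j.  At
#' decode time classifier m's vote for its output label `op(t,m)` carries
#' weight `V[m, op] * F_m`, where `F_m` is the classifier's cross-validated
#' F-measure; a class nobody votes for scores zero.
#'
#' @param V numeric matrix, one row per classifier, one column per label;
#'   entries must be non-negative.
#' @param classifiers character vector of classifier identifiers (rows).
#' @param labels character vector: the label alphabet (columns), `"O"` last.
#' @return An object of class `weight_matrix` (numeric matrix with dimnames).
#' @export
weight_matrix <- function(V, classifiers = rownames(V), labels = colnames(V)) {
  V <- as.matrix(V)
  stopifnot(is.numeric(V), all(V >= 0))
  if (is.null(classifiers)) classifiers <- paste0("C", seq_len(nrow(V)))
  if (is.null(labels)) stop("label alphabet required")
  stopifnot(length(classifiers) == nrow(V), length(labels) == ncol(V))
  dimnames(V) <- list(classifiers, labels)
  class(V) <- c("weight_matrix", "matrix", "array")
  V
}

#' Combined per-class vote scores for one token
#'
#' For a token where classifier m outputs label `op(m)`, the combined score of
#' class c is the sum over classifiers that voted c of `V[m, c] * F_m`.
#'
#' @param token_outputs character vector of length N: each classifier's output
#'   label for the token.
#' @param weights a [weight_matrix()] (N x O).
#' @param classifier_F numeric vector of length N: each classifier's overall
#'   F-measure (scale-invariant: percent or fraction both work).
#' @return named numeric vector of length O: the score of every label.
#' @export
combined_scores <- function(token_outputs, weights, classifier_F) {
  labels <- colnames(weights)
  stopifnot(length(token_outputs) == nrow(weights),
            length(classifier_F) == nrow(weights))
  idx <- match(token_outputs, labels)
  if (anyNA(idx)) {
    stop("output label outside the alphabet: ",
         token_outputs[which(is.na(idx))[1L]])
  }
  scores <- stats::setNames(numeric(length(labels)), labels)
  w <- weights[cbind(seq_len(nrow(weights)), idx)] * classifier_F
  for (m in seq_along(idx)) scores[idx[m]] <- scores[idx[m]] + w[m]
  scores
}

# Core vectorized decoder.  `outputs` is a T x N integer matrix of label
# indices into `labels`; returns an integer vector of decoded label indices.
#
# Tie rule: the alphabet keeps "O" last; among tied positive maxima the
# earliest alphabet label wins, and a token whose every class scores zero (no
# effective vote) decodes to "O" so that zero-information ties never invent
# entities.
decode_outputs <- function(outputs, V, classifier_F) {
  n_tok <- nrow(outputs)
  n_lab <- ncol(V)
  scores <- matrix(0, n_tok, n_lab)
  for (m in seq_len(ncol(outputs))) {
    op <- outputs[, m]
    at <- cbind(seq_len(n_tok), op)
    scores[at] <- scores[at] + V[m, op] * classifier_F[m]
  }
  dec <- max.col(scores, ties.method = "first")
  o_idx <- n_lab  # "O" is last by construction
  zero <- scores[cbind(seq_len(n_tok), dec)] <= 0
  dec[zero] <- o_idx
  dec
}

#' Weighted-vote joint decoding
#'
#' Assigns each token the label with the maximum combined score
#' ([combined_scores()]) independently per token; boundary conflicts between
#' classifiers are resolved implicitly by the per-token argmax.  See
#' `decode_outputs` tie rule in the package vignette: ties among positive
#' scores break to the earliest label in the alphabet (entity labels sorted,
#' `"O"` last); all-zero score rows decode to `"O"`.
#'
#' @param outputs character matrix (tokens x classifiers) of predicted labels,
#'   or a `prediction_matrix` (see [build_model_bank()]), in which case all
#'   held-out tokens are decoded.
#' @param weights a [weight_matrix()].
#' @param classifier_F numeric vector of per-classifier F-measures; taken from
#'   the prediction matrix when `outputs` is one.
#' @return character vector of decoded labels, one per token.
#' @export
weighted_vote_decode <- function(outputs, weights, classifier_F = NULL) {
  labels <- colnames(weights)
  if (inherits(outputs, "prediction_matrix")) {
    if (is.null(classifier_F)) classifier_F <- outputs$classifier_F
    stopifnot(identical(outputs$labels, labels))
    idx_mat <- outputs$outputs
  } else {
    stopifnot(!is.null(classifier_F))
    idx_mat <- matrix(match(outputs, labels), nrow(outputs), ncol(outputs))
    if (anyNA(idx_mat)) stop("output label outside the alphabet")
  }
  if (ncol(idx_mat) != nrow(weights)) {
    stop(sprintf("weight matrix has %d rows but there are %d classifiers",
                 nrow(weights), ncol(idx_mat)))
  }
  labels[decode_outputs(idx_mat, unclass(weights), classifier_F)]
}

#' Write / read a weight matrix as plain text
#'
#' Tab-separated matrix with a header row of labels and a leading column of
#' classifier identifiers; round-trips exactly at full double precision.
#'
#' @param weights a [weight_matrix()].
#' @param path file path.
#' @return `write_weight_matrix` invisibly returns `path`;
#'   `read_weight_matrix` returns a [weight_matrix()].
#' @export
write_weight_matrix <- function(weights, path) {
  header <- paste(c("classifier", colnames(weights)), collapse = "\t")
  rows <- vapply(seq_len(nrow(weights)), function(i) {
    paste(c(rownames(weights)[i], sprintf("%.17g", weights[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_weight_matrix
#' @export
read_weight_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  labels <- header[-1L]
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  V <- t(vapply(body, function(f) as.numeric(f[-1L]), numeric(length(labels))))
  weight_matrix(V, classifiers = vapply(body, `[`, character(1L), 1L),
                labels = labels)
}
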