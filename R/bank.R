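# ---- backend registry -------------------------------------------------------
#
# A backend is any learner exposing
#   fit(corpus, template, resources)            -> opaque fitted state
#   predict(state, corpus, template, resources) -> character labels, one per
#                                                  token of `corpus`
# The ensemble machinery never looks inside the state.  Two reference
# backends ship with the package: a dependency-free memorizing baseline and a
# multinomial naive-Bayes feature-bag labeler with greedy left-to-right
# decoding (feature-sensitive, so template variations yield genuinely
# different classifiers).

.backends <- new.env(parent = emptyenv())

#' Register a sequence-labeling backend
#'
#' @param name backend identifier used in [labeler_spec()].
#' @param fit function `(corpus, template, resources)` returning fitted state.
#' @param predict function `(state, corpus, template, resources)` returning a
#'   character vector of labels aligned with `corpus$tokens`.
#' @return invisibly, `name`.
#' @export
register_backend <- function(name, fit, predict) {
  stopifnot(is.character(name), is.function(fit), is.function(predict))
  assign(name, list(fit = fit, predict = predict), envir = .backends)
  invisible(name)
}

get_backend <- function(name) {
  if (!exists(name, envir = .backends, inherits = FALSE)) {
    stop("unknown backend: ", name, " (registered: ",
         paste(ls(.backends), collapse = ", "), ")")
  }
  get(name, envir = .backends)
}

#' Base labeler specification
#'
#' @param learner registered backend name (see [register_backend()]).
#' @param template a [feature_template()].
#' @param hyperparameters backend-specific named list.
#' @param id optional identifier; defaults to `learner` plus a template digest.
#' @return An object of class `labeler_spec`.
#' @export
labeler_spec <- function(learner, template = feature_template(),
                         hyperparameters = list(), id = NULL) {
  get_backend(learner)  # must be registered
  if (is.null(id)) id <- paste0(learner, "-", content_key(template))
  structure(list(learner = learner, template = template,
                 hyperparameters = hyperparameters, id = id),
            class = "labeler_spec")
}

# ---- memorizing baseline ----------------------------------------------------

fit_memorize <- function(corpus, template, resources) {
  tok <- corpus$tokens
  if (nrow(tok) == 0L) return(list(map = character()))
  tb <- table(tok$surface, factor(tok$label, levels = corpus$label_alphabet))
  # most frequent training label per surface; ties to the earliest alphabet
  # label ("O" last) for determinism
  map <- colnames(tb)[max.col(tb, ties.method = "first")]
  names(map) <- rownames(tb)
  list(map = map)
}

predict_memorize <- function(state, corpus, template, resources) {
  lab <- state$map[corpus$tokens$surface]
  lab[is.na(lab)] <- "O"
  unname(lab)
}

# ---- naive-Bayes feature-bag labeler ---------------------------------------

fit_nb <- function(corpus, template, resources, alpha = 1) {
  tok <- corpus$tokens
  labels <- corpus$label_alphabet
  bags <- extract_feature_bags(corpus, template, resources, mode = "train")
  y <- factor(tok$label, levels = labels)
  feat <- unlist(bags, use.names = FALSE)
  feat_y <- rep(y, lengths(bags))
  counts <- table(feat, feat_y)            # features x labels
  vocab <- rownames(counts)
  tot <- colSums(counts)
  loglik <- log(sweep(counts + alpha, 2L, tot + alpha * (length(vocab) + 1L), "/"))
  unseen <- log(alpha / (tot + alpha * (length(vocab) + 1L)))
  ll <- new.env(parent = emptyenv(), size = length(vocab))
  for (i in seq_along(vocab)) assign(vocab[i], loglik[i, ], envir = ll)
  prior <- log((table(y) + 1) / (length(y) + length(labels)))
  list(labels = labels, loglik = ll, unseen = unseen,
       prior = as.numeric(prior))
}

predict_nb <- function(state, corpus, template, resources) {
  tok <- corpus$tokens
  labels <- state$labels
  out <- character(nrow(tok))
  i <- 1L
  for (s in seq_len(n_sentences(corpus))) {
    sent <- tok[tok$sentence == s, , drop = FALSE]
    prev <- character()
    for (p in seq_len(nrow(sent))) {
      bag <- feature_bag(extract_features(sent, p, template, resources,
                                          previous_tags = prev))
      scores <- state$prior
      for (f in bag) {
        v <- get0(f, envir = state$loglik, inherits = FALSE)
        scores <- scores + (if (is.null(v)) state$unseen else v)
      }
      lab <- labels[which.max(scores)]
      out[i] <- lab
      prev <- c(prev, lab)
      i <- i + 1L
    }
  }
  out
}

register_backend("memorize", fit_memorize, predict_memorize)
register_backend("nb", fit_nb, predict_nb)

# ---- folds ------------------------------------------------------------------

#' Sentence-level cross-validation folds
#'
#' Partitions the corpus's sentences into `k` near-equal folds (sizes differ
#' by at most one), deterministically for a fixed seed.  The fold unit is the
#' sentence: sequence labelers need intact sentences.
#'
#' @param corpus a [bio_corpus()].
#' @param k number of folds (>= 2).
#' @param rng_seed integer seed.
#' @return list of `k` integer vectors of sentence indices (sorted within
#'   fold), disjoint and covering the corpus.
#' @export
make_folds <- function(corpus, k = 5L, rng_seed = 1L) {
  ns <- n_sentences(corpus)
  stopifnot(k >= 2L)
  if (k > ns) stop(sprintf("k = %d exceeds sentence count %d", k, ns))
  perm <- with_seed(rng_seed, sample.int(ns))
  sizes <- rep(ns %/% k, k) + (seq_len(k) <= ns %% k)
  idx <- split(perm, rep(seq_len(k), times = sizes))
  unname(lapply(idx, sort))
}

# ---- training and prediction ------------------------------------------------

#' Cross-validated training and prediction for one labeler
#'
#' For each fold, trains the backend on the complementary sentences (with
#' resources rebuilt on that training portion only) and predicts the held-out
#' sentences.  The labeler's overall F-measure `F_m` is the strict-match F
#' over the concatenated held-out predictions, on the percent scale.
#'
#' @param spec a [labeler_spec()].
#' @param corpus a labelled [bio_corpus()].
#' @param folds fold list from [make_folds()].
#' @param rng_seed integer seed (drives training-time feature randomization).
#' @return list with `predictions` (character vector aligned with the corpus
#'   tokens), `F_m` (percent), `report` (the [strict_match_scores()] report)
#'   and `fold_of_sentence` (integer vector).
#' @export
train_and_predict <- function(spec, corpus, folds, rng_seed = 1L) {
  backend <- get_backend(spec$learner)
  ns <- n_sentences(corpus)
  fold_of <- integer(ns)
  for (f in seq_along(folds)) fold_of[folds[[f]]] <- f
  pred <- character(nrow(corpus$tokens))
  with_seed(rng_seed, {
    for (f in seq_along(folds)) {
      held <- folds[[f]]
      train <- subset_sentences(corpus, setdiff(seq_len(ns), held))
      test <- subset_sentences(corpus, held)
      res <- tryCatch({
        resources <- build_resources(train, spec$template)
        state <- backend$fit(train, spec$template, resources)
        backend$predict(state, test, spec$template, resources)
      }, error = function(e) {
        stop(sprintf("backend '%s' (spec %s) failed on fold %d: %s",
                     spec$learner, spec$id, f, conditionMessage(e)),
             call. = FALSE)
      })
      pred[corpus$tokens$sentence %in% held] <- res
    }
  })
  report <- strict_match_scores(corpus, pred)
  list(predictions = pred, F_m = unname(report$overall["f"]),
       report = report, fold_of_sentence = fold_of)
}

# ---- prediction matrix ------------------------------------------------------

new_prediction_matrix <- function(tokens, outputs, labels, classifier_F,
                                  classifier_names, folds) {
  stopifnot(nrow(outputs) == nrow(tokens),
            ncol(outputs) == length(classifier_F),
            length(classifier_names) == length(classifier_F),
            all(outputs >= 1L), all(outputs <= length(labels)))
  structure(list(tokens = tokens, outputs = outputs, labels = labels,
                 classifier_F = classifier_F,
                 classifier_names = classifier_names, folds = folds),
            class = "prediction_matrix")
}

#' @export
print.prediction_matrix <- function(x, ...) {
  cat(sprintf("<prediction_matrix> %d tokens x %d classifiers, %d folds\n",
              nrow(x$outputs), ncol(x$outputs), length(x$folds)))
  cat(sprintf("  labels: %s\n", paste(x$labels, collapse = ", ")))
  cat(sprintf("  F_m: %s\n", paste(sprintf("%s=%.2f", x$classifier_names,
                                           x$classifier_F), collapse = ", ")))
  invisible(x)
}

#' Build a model bank
#'
#' Trains every labeler spec on identical cross-validation folds and
#' assembles the per-token prediction matrix `op(t, m)` together with each
#' classifier's F-measure `F_m` — the inputs the weighted-vote ensemble and
#' its GA optimizer operate on.
#'
#' @param corpus a labelled [bio_corpus()].
#' @param specs list of [labeler_spec()] objects with distinct ids.
#' @param k number of folds.
#' @param rng_seed integer seed (folds and training-time randomization).
#' @param cache_dir optional directory; when given, the assembled bank is
#'   cached on disk keyed by (corpus, specs, k, seed) and rebuilt only on a
#'   key miss.
#' @return A `prediction_matrix`.
#' @export
build_model_bank <- function(corpus, specs, k = 5L, rng_seed = 1L,
                             cache_dir = NULL) {
  stopifnot(length(specs) >= 1L)
  ids <- vapply(specs, function(s) s$id, character(1L))
  if (anyDuplicated(ids)) stop("duplicate labeler spec ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  key <- NULL
  if (!is.null(cache_dir)) {
    key <- content_key(list(corpus$tokens, lapply(specs, unclass), k, rng_seed))
    cache_file <- file.path(cache_dir, paste0("bank-", key, ".rds"))
    if (file.exists(cache_file)) return(readRDS(cache_file))
  }
  folds <- make_folds(corpus, k, rng_seed)
  fits <- lapply(seq_along(specs), function(m) {
    train_and_predict(specs[[m]], corpus, folds, rng_seed = rng_seed + m)
  })
  tok <- corpus$tokens
  fold_of <- fits[[1L]]$fold_of_sentence
  tokens <- data.frame(sentence = tok$sentence,
                       position = stats::ave(seq_len(nrow(tok)), tok$sentence,
                                             FUN = seq_along) - 1L,
                       fold = fold_of[tok$sentence],
                       gold = tok$label,
                       stringsAsFactors = FALSE)
  outputs <- vapply(fits, function(f) match(f$predictions, corpus$label_alphabet),
                    integer(nrow(tok)))
  if (anyNA(outputs)) stop("backend produced a label outside the alphabet")
  bank <- new_prediction_matrix(
    tokens, matrix(outputs, nrow = nrow(tok)), corpus$label_alphabet,
    vapply(fits, function(f) f$F_m, numeric(1L)), ids, folds)
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(bank, cache_file)
  }
  bank
}
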