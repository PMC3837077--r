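# Filler/trigger/entity word material for the corpus generator.  The
# generator emulates the corpus properties the ensemble is sensitive to —
# multi-token mentions, orthographically marked entity tokens, trigger
# contexts — not linguistically realistic text.
.synth_triggers <- c("binds", "activates", "inhibits", "encodes",
                     "phosphorylates", "regulates")

#' Synthetic-corpus configuration
#'
#' @param n_sentences number of sentences.
#' @param sentence_len integer min/max sentence length in tokens.
#' @param entity_types entity type names.
#' @param entity_density expected entity mentions per sentence (Poisson).
#' @param entity_len integer min/max mention length in tokens (1-4).
#' @param orth_signal probability that an entity token carries an
#'   orthographic mark (capital/digit/hyphen pattern).
#' @param trigger_prob probability that a trigger verb immediately precedes
#'   a mention.
#' @param filler_vocab,entity_vocab vocabulary sizes (filler words; marked
#'   and plain entity words per type).
#' @param rng_seed integer seed.
#' @return An object of class `corpus_gen_config`.
#' @export
corpus_gen_config <- function(n_sentences = 100L, sentence_len = c(6L, 12L),
                              entity_types = c("protein", "dna"),
                              entity_density = 1.0, entity_len = c(1L, 3L),
                              orth_signal = 0.8, trigger_prob = 0.3,
                              filler_vocab = 150L, entity_vocab = 25L,
                              rng_seed = 1L) {
  stopifnot(n_sentences >= 1L, length(sentence_len) == 2L,
            sentence_len[1L] >= 1L, sentence_len[2L] >= sentence_len[1L],
            length(entity_types) >= 1L,
            entity_density >= 0, entity_len[1L] >= 1L,
            entity_len[2L] >= entity_len[1L], entity_len[2L] <= 4L,
            orth_signal >= 0, orth_signal <= 1,
            trigger_prob >= 0, trigger_prob <= 1)
  structure(list(n_sentences = as.integer(n_sentences),
                 sentence_len = as.integer(sentence_len),
                 entity_types = entity_types,
                 entity_density = entity_density,
                 entity_len = as.integer(entity_len),
                 orth_signal = orth_signal,
                 trigger_prob = trigger_prob,
                 filler_vocab = as.integer(filler_vocab),
                 entity_vocab = as.integer(entity_vocab),
                 rng_seed = as.integer(rng_seed)),
            class = "corpus_gen_config")
}

# orthographically marked surface: caps/digit/hyphen hybrids ("IL-2" style)
.marked_surface <- function(n, type_tag) {
  caps <- replicate(n, paste(sample(LETTERS, sample(2:3, 1L)), collapse = ""))
  num <- sample(1:99, n, replace = TRUE)
  sep <- sample(c("-", ""), n, replace = TRUE, prob = c(0.6, 0.4))
  paste0(type_tag, caps, sep, num)
}

#' Generate a synthetic BIO corpus
#'
#' Sentences of filler tokens interleaved with entity mentions labelled in
#' BIO.  Entity surfaces come from per-type dictionaries; a configurable
#' fraction carries capital/digit/hyphen orthographic marks; trigger verbs
#' are placed immediately before mentions at the configured rate.  PoS-like
#' (`NN`/`NNP`/`VBZ`/`DT`) and chunk-like (`B-NP`/`I-NP`/`O`) auxiliary
#' columns are emitted.  Deterministic per seed.
#'
#' @param config a [corpus_gen_config()].
#' @return A labelled [bio_corpus()] with `word`, `pos`, `chunk`, `label`
#'   columns.
#' @export
generate_corpus <- function(config) {
  with_seed(config$rng_seed, {
    types <- config$entity_types
    dict <- lapply(seq_along(types), function(k) {
      tag <- toupper(substr(types[k], 1L, 1L))
      list(marked = unique(.marked_surface(config$entity_vocab, tag)),
           plain = paste0(substr(types[k], 1L, 3L),
                          "gene", seq_len(config$entity_vocab)))
    })
    names(dict) <- types
    fillers <- c(.stop_words,
                 paste0("word", seq_len(config$filler_vocab)))
    rows <- vector("list", config$n_sentences)
    for (s in seq_len(config$n_sentences)) {
      L <- sample(config$sentence_len[1L]:config$sentence_len[2L], 1L)
      n_ent <- stats::rpois(1L, config$entity_density)
      lens <- integer(0)
      if (n_ent > 0L) {
        lens <- sample(config$entity_len[1L]:config$entity_len[2L], n_ent,
                       replace = TRUE)
        while (length(lens) && sum(lens) > L - 1L) lens <- lens[-length(lens)]
      }
      n_ent <- length(lens)
      n_fill <- L - sum(lens)
      # item layout: entities interleaved among fillers
      items <- sample(c(rep(0L, n_fill), seq_len(n_ent)))
      surface <- character(); pos <- character(); chunk <- character()
      label <- character()
      for (it in items) {
        if (it == 0L) {
          surface <- c(surface, sample(fillers, 1L))
          pos <- c(pos, sample(c("NN", "DT", "JJ"), 1L))
          chunk <- c(chunk, "O"); label <- c(label, "O")
        } else {
          tp <- sample(types, 1L)
          ln <- lens[it]
          if (stats::runif(1L) < config$trigger_prob && length(label) &&
              label[length(label)] == "O") {
            surface[length(surface)] <- sample(.synth_triggers, 1L)
            pos[length(pos)] <- "VBZ"
          }
          marked <- stats::runif(ln) < config$orth_signal
          toks <- ifelse(marked,
                         sample(dict[[tp]]$marked, ln, replace = TRUE),
                         sample(dict[[tp]]$plain, ln, replace = TRUE))
          surface <- c(surface, toks)
          pos <- c(pos, rep("NNP", ln))
          chunk <- c(chunk, "B-NP", rep("I-NP", ln - 1L))
          label <- c(label, paste0("B-", tp),
                     rep(paste0("I-", tp), max(0L, ln - 1L)))
        }
      }
      rows[[s]] <- data.frame(sentence = s, surface = surface, pos = pos,
                              chunk = chunk, label = label,
                              stringsAsFactors = FALSE)
    }
    bio_corpus(do.call(rbind, rows),
               columns = c("word", "pos", "chunk", "label"))
  })
}

#' Per-class reliability profile of a simulated classifier
#'
#' For every label j, `a(j)` is the probability that the simulated classifier
#' reproduces the gold label; errors follow the confusion rule.  Names in
#' `accuracy` may be full labels (`"B-protein"`) or bare entity types
#' (`"protein"`, applying to both `B-` and `I-`).
#'
#' @param default accuracy for labels without an override.
#' @param accuracy named numeric vector of per-label/per-type overrides.
#' @param confusion `"uniform"` (errors drawn uniformly over the other
#'   labels) or `"boundary_jitter"` (errors flip the B-/I- role of entity
#'   labels and promote `O` to a random `B-` label, stressing the strict
#'   boundary criterion).
#' @return An object of class `reliability_profile`.
#' @export
reliability_profile <- function(default = 0.8, accuracy = c(),
                                confusion = c("uniform", "boundary_jitter")) {
  confusion <- match.arg(confusion)
  stopifnot(default >= 0, default <= 1,
            length(accuracy) == 0L || !is.null(names(accuracy)),
            all(accuracy >= 0), all(accuracy <= 1))
  structure(list(default = default, accuracy = accuracy,
                 confusion = confusion),
            class = "reliability_profile")
}

profile_accuracy <- function(profile, labels) {
  a <- rep(profile$default, length(labels))
  names(a) <- labels
  for (nm in names(profile$accuracy)) {
    hit <- if (nm %in% labels) nm else {
      labels[label_type(labels) == nm]
    }
    if (length(hit) == 0L) stop("profile override matches no label: ", nm)
    a[hit] <- profile$accuracy[[nm]]
  }
  a
}

#' Simulate a bank of classifier outputs
#'
#' Stands in for trained classifiers so the ensemble optimizer can be studied
#' in isolation: for each token with gold label j, classifier m emits j with
#' probability `a(m, j)` and otherwise an error drawn by the profile's
#' confusion rule.  Corruption is per-token, so simulated outputs can break
#' BIO validity exactly as real taggers do.  Each classifier's `F_m` is the
#' strict-match F of its simulated outputs.
#'
#' @param corpus a labelled [bio_corpus()].
#' @param profiles list of [reliability_profile()] objects (one classifier
#'   each).
#' @param k fold count (ignored when `folds` given).
#' @param folds optional fold list from [make_folds()].
#' @param rng_seed integer seed.
#' @return A `prediction_matrix`.
#' @export
simulate_classifier_outputs <- function(corpus, profiles, k = 5L,
                                        folds = NULL, rng_seed = 1L) {
  stopifnot(length(profiles) >= 1L)
  if (is.null(folds)) folds <- make_folds(corpus, k, rng_seed)
  tok <- corpus$tokens
  labels <- corpus$label_alphabet
  gold_idx <- match(tok$label, labels)
  n <- nrow(tok)
  n_lab <- length(labels)
  b_labels <- which(label_role(labels) == "B")
  outputs <- matrix(0L, n, length(profiles))
  F_m <- numeric(length(profiles))
  with_seed(rng_seed, {
    for (m in seq_along(profiles)) {
      prof <- profiles[[m]]
      acc <- profile_accuracy(prof, labels)
      correct <- stats::runif(n) < acc[gold_idx]
      out <- gold_idx
      err <- which(!correct)
      if (length(err)) {
        if (prof$confusion == "uniform") {
          shift <- sample.int(n_lab - 1L, length(err), replace = TRUE)
          out[err] <- ((gold_idx[err] - 1L + shift) %% n_lab) + 1L
        } else {
          for (i in err) {
            g <- labels[gold_idx[i]]
            out[i] <- if (g == "O") {
              if (length(b_labels)) sample(b_labels, 1L) else gold_idx[i]
            } else {
              flipped <- paste0(if (label_role(g) == "B") "I-" else "B-",
                                label_type(g))
              match(flipped, labels)
            }
          }
        }
      }
      outputs[, m] <- out
      F_m[m] <- unname(strict_match_scores(corpus, labels[out])$overall["f"])
    }
  })
  fold_of <- integer(n_sentences(corpus))
  for (f in seq_along(folds)) fold_of[folds[[f]]] <- f
  tokens <- data.frame(sentence = tok$sentence,
                       position = stats::ave(seq_len(n), tok$sentence,
                                             FUN = seq_along) - 1L,
                       fold = fold_of[tok$sentence],
                       gold = tok$label,
                       stringsAsFactors = FALSE)
  new_prediction_matrix(tokens, outputs, labels, F_m,
                        paste0("sim", seq_along(profiles)), folds)
}
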