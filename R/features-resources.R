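#' Declarative feature template
#'
#' Describes which feature families a base labeler uses and with what
#' windows.  Varying templates across labelers is what makes the members of a
#' model bank genuinely different classifiers.
#'
#' @param context_window integer radius (0-3) for context features, either a
#'   single value or a named vector with entries `word`, `pos`, `chunk`.
#' @param ngram_order maximum n for left-to-right context n-grams (1 or 2).
#' @param affix_len maximum prefix/suffix length (0-4); 0 disables affixes.
#' @param dynamic_depth number of preceding output tags used (0-3).
#' @param flags named logical vector switching feature families on/off;
#'   unnamed families default to `TRUE`.  Recognized names: `length`,
#'   `infrequent`, `normalization`, `word_shape`, `word_class`,
#'   `orthographic`, `head_noun`, `trigger`, `informative_words`,
#'   `content_words`, `unknown_token`, `dynamic_ne`.
#' @return An object of class `feature_template`.
#' @export
feature_template <- function(context_window = 2L, ngram_order = 2L,
                             affix_len = 3L, dynamic_depth = 1L,
                             flags = c()) {
  fam <- c("length", "infrequent", "normalization", "word_shape",
           "word_class", "orthographic", "head_noun", "trigger",
           "informative_words", "content_words", "unknown_token",
           "dynamic_ne")
  full <- stats::setNames(rep(TRUE, length(fam)), fam)
  if (length(flags)) {
    stopifnot(!is.null(names(flags)), all(names(flags) %in% fam))
    full[names(flags)] <- as.logical(flags)
  }
  if (length(context_window) == 1L && is.null(names(context_window))) {
    context_window <- c(word = context_window, pos = context_window,
                        chunk = context_window)
  }
  cw <- stats::setNames(rep(0L, 3L), c("word", "pos", "chunk"))
  cw[names(context_window)] <- as.integer(context_window)
  stopifnot(all(cw >= 0L & cw <= 3L),
            ngram_order %in% 1:2,
            affix_len >= 0L, affix_len <= 4L,
            dynamic_depth >= 0L, dynamic_depth <= 3L)
  structure(list(context_window = cw,
                 ngram_order = as.integer(ngram_order),
                 affix_len = as.integer(affix_len),
                 dynamic_depth = as.integer(dynamic_depth),
                 flags = full),
            class = "feature_template")
}

#' Exclusivity weight of a word for entity mentions
#'
#' `NEweight(w)` measures how exclusively `w` occurs inside entity mentions:
#' the count of occurrences of `w` inside entity spans divided by its total
#' count in the training data.  Lies in \[0, 1\] and is monotone in the
#' inside count.
#'
#' @param word token surface (unused in the arithmetic; kept for clarity at
#'   call sites).
#' @param inside_count occurrences of the word inside entity spans.
#' @param total_count total occurrences in the training data (> 0).
#' @return numeric in \[0, 1\].
#' @export
ne_weight <- function(word, inside_count, total_count) {
  stopifnot(total_count > 0, inside_count >= 0, total_count >= inside_count)
  inside_count / total_count
}

# candidate filter for informative words: drop digits/numbers/symbols
.is_wordlike <- function(w) grepl("[A-Za-z]", w) & !grepl("^[0-9.,;:%()/+-]+$", w)

#' Informative-word lists
#'
#' Builds the five informative-word classes from a labelled training corpus.
#' Candidates are the words occurring inside multiword entity mentions, minus
#' digit/number/symbol tokens; words with fewer than two occurrences inside
#' entities are dropped; survivors are binned by [ne_weight()] into five
#' equal-width classes over (0, 1]: (0, .2], (.2, .4], (.4, .6], (.6, .8],
#' (.8, 1].
#'
#' @param corpus a labelled [bio_corpus()].
#' @param min_inside minimum inside-entity occurrence count (default 2).
#' @return list with `lists` (list of five character vectors) and `weights`
#'   (named numeric vector of NEweights for all candidate words).
#' @export
build_informative_word_lists <- function(corpus, min_inside = 2L) {
  tok <- corpus$tokens
  empty <- list(lists = rep(list(character()), 5L),
                weights = stats::setNames(numeric(), character()))
  if (nrow(tok) == 0L) return(empty)
  ch <- extract_chunks_multi(tok$sentence, tok$label)
  if (nrow(ch) == 0L) return(empty)
  inside <- label_role(tok$label) != "O"
  multi <- ch[ch$end > ch$start, , drop = FALSE]
  if (nrow(multi) == 0L) return(empty)
  pos <- stats::ave(seq_len(nrow(tok)), tok$sentence, FUN = seq_along) - 1L
  in_multi <- rep(FALSE, nrow(tok))
  for (i in seq_len(nrow(multi))) {
    in_multi <- in_multi | (tok$sentence == multi$sentence[i] &
                            pos >= multi$start[i] & pos <= multi$end[i])
  }
  cand <- unique(tok$surface[in_multi])
  cand <- cand[.is_wordlike(cand)]
  if (length(cand) == 0L) return(empty)
  inside_counts <- vapply(cand, function(w) sum(tok$surface == w & inside), 0L)
  total_counts <- vapply(cand, function(w) sum(tok$surface == w), 0L)
  keep <- inside_counts >= min_inside
  weights <- stats::setNames(inside_counts / total_counts, cand)
  cand <- cand[keep]
  lists <- lapply(seq_len(5L), function(b) {
    lo <- (b - 1L) / 5; hi <- b / 5
    sort(cand[weights[cand] > lo & weights[cand] <= hi])
  })
  list(lists = lists, weights = weights)
}

#' Content-word vocabulary from entity contexts
#'
#' Collects all unigrams within `window` tokens of every entity-labelled
#' token (crossing sentence boundaries), lower-cases them, removes stop
#' words, numbers, punctuation and special symbols, and returns the 10 most
#' frequent survivors (ties broken lexicographically).  Fewer than 10
#' survivors are returned as-is with a warning.
#'
#' @param corpus a labelled [bio_corpus()].
#' @param window context radius in tokens (default 3).
#' @return character vector of at most 10 words, most frequent first.
#' @export
extract_content_word_vocab <- function(corpus, window = 3L) {
  tok <- corpus$tokens
  ent <- which(label_role(tok$label) != "O")
  if (length(ent) == 0L) {
    warning("no entity-labelled tokens; content-word vocabulary is empty")
    return(character())
  }
  n <- nrow(tok)
  # count each context occurrence, not each unique position
  words <- tolower(unlist(lapply(ent, function(i) {
    tok$surface[setdiff(max(1L, i - window):min(n, i + window), i)]
  })))
  words <- words[.is_wordlike(words) & !(words %in% .stop_words)]
  if (length(words) == 0L) {
    warning("all entity-context words filtered; content-word vocabulary is empty")
    return(character())
  }
  counts <- table(words)
  ord <- order(-as.integer(counts), names(counts))
  vocab <- names(counts)[ord]
  if (length(vocab) < 10L) {
    warning(sprintf("only %d content words survive filtering (10 requested)",
                    length(vocab)))
    return(vocab)
  }
  vocab[seq_len(10L)]
}

#' Build all corpus-derived feature resources
#'
#' Populates the lookup tables the token-level features draw on: training
#' word frequencies, the five informative-word lists, head-noun unigrams and
#' bigrams (the final one/two tokens of entity mentions with at least
#' `min_freq` occurrences), trigger words (tokens immediately preceding
#' entity mentions with at least `min_freq` occurrences), the content-word
#' vocabulary, the seen-word vocabulary, and the length/infrequency
#' thresholds (5 characters, 10 occurrences).
#'
#' @param corpus a labelled training [bio_corpus()].
#' @param template a [feature_template()] (controls the content-word window).
#' @param min_freq minimum occurrence count for head nouns and triggers.
#' @param content_window radius for [extract_content_word_vocab()].
#' @return An object of class `feature_resources`.
#' @export
build_resources <- function(corpus, template = feature_template(),
                            min_freq = 2L, content_window = 3L) {
  tok <- corpus$tokens
  word_counts <- if (nrow(tok)) table(tok$surface) else table(character())
  ch <- extract_chunks_multi(tok$sentence, tok$label)
  pos <- if (nrow(tok)) stats::ave(seq_len(nrow(tok)), tok$sentence,
                                   FUN = seq_along) - 1L else integer()
  row_of <- function(sent, p) which(tok$sentence == sent & pos == p)
  head_uni <- character(); head_bi <- character(); trig <- character()
  if (nrow(ch)) {
    head_uni <- vapply(seq_len(nrow(ch)), function(i) {
      tok$surface[row_of(ch$sentence[i], ch$end[i])]
    }, character(1L))
    bi_ok <- ch$end > ch$start
    head_bi <- vapply(which(bi_ok), function(i) {
      paste(tok$surface[row_of(ch$sentence[i], ch$end[i] - 1L)],
            tok$surface[row_of(ch$sentence[i], ch$end[i])])
    }, character(1L))
    pre_ok <- ch$start > 0L
    trig <- vapply(which(pre_ok), function(i) {
      tok$surface[row_of(ch$sentence[i], ch$start[i] - 1L)]
    }, character(1L))
  }
  keep_freq <- function(x) {
    if (length(x) == 0L) return(character())
    tb <- table(x)
    sort(names(tb)[tb >= min_freq])
  }
  inf <- build_informative_word_lists(corpus)
  content <- withCallingHandlers(
    extract_content_word_vocab(corpus, window = content_window),
    warning = function(w) invokeRestart("muffleWarning"))
  structure(list(
    word_counts = word_counts,
    informative_lists = inf$lists,
    ne_weights = inf$weights,
    head_nouns = list(unigrams = keep_freq(head_uni),
                      bigrams = keep_freq(head_bi)),
    trigger_words = keep_freq(trig),
    content_vocab = content,
    seen_vocab = unique(tok$surface),
    content_window = as.integer(content_window),
    length_threshold = 5L,
    infrequent_threshold = 10L),
    class = "feature_resources")
}
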