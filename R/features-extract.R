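#' Extract features for one token
#'
#' Assembles the feature families switched on in the template for the token
#' at `position` of `sentence`.  Out-of-sentence context positions yield the
#' boundary placeholders `<s>` / `</s>`.  The extractor only ever looks at
#' `previous_tags` (never the gold label of the current or a future token),
#' so decoding-time extraction is causally valid.
#'
#' @param sentence data frame of one sentence's tokens (columns `surface`,
#'   optionally `pos` and `chunk`).
#' @param position 1-based token index within the sentence.
#' @param template a [feature_template()].
#' @param resources a `feature_resources` object from [build_resources()].
#' @param previous_tags labels already assigned to the preceding tokens of
#'   the sentence (training: gold; decoding: predictions); shorter histories
#'   are padded with `<s>`.
#' @param unknown_bit value of the unknown-token feature.  `NULL` (the
#'   default, for test/decode time) means "surface not in the training
#'   vocabulary"; at training time callers pass a Bernoulli(0.5) bit drawn
#'   from the seeded run RNG, fixed per token occurrence.
#' @return named character vector mapping feature names to values (binary
#'   features have value `"1"`).
#' @export
extract_features <- function(sentence, position, template, resources,
                             previous_tags = character(),
                             unknown_bit = NULL) {
  stopifnot(position >= 1L, position <= nrow(sentence))
  fl <- template$flags
  need_res <- any(fl[c("infrequent", "head_noun", "trigger",
                       "informative_words", "content_words", "unknown_token")])
  if (need_res && is.null(resources)) {
    stop("feature template requires corpus resources but none were supplied")
  }
  n <- nrow(sentence)
  at <- function(col, i) {
    if (i < 1L) "<s>" else if (i > n) "</s>" else sentence[[col]][i]
  }
  surf <- sentence$surface[position]
  out <- character(); nm <- character()
  add <- function(name, value = "1") {
    out[[length(out) + 1L]] <<- value
    nm[[length(nm) + 1L]] <<- name
  }

  # context words and their left-to-right n-grams
  r <- template$context_window[["word"]]
  for (off in -r:r) add(sprintf("w[%d]", off), at("surface", position + off))
  if (template$ngram_order >= 2L && r >= 1L) {
    for (off in -r:(r - 1L)) {
      add(sprintf("w[%d..%d]", off, off + 1L),
          paste(at("surface", position + off),
                at("surface", position + off + 1L), sep = "|"))
    }
  }
  if (!is.null(sentence$pos)) {
    rp <- template$context_window[["pos"]]
    for (off in -rp:rp) add(sprintf("p[%d]", off), at("pos", position + off))
  }
  if (!is.null(sentence$chunk)) {
    rc <- template$context_window[["chunk"]]
    for (off in -rc:rc) add(sprintf("c[%d]", off), at("chunk", position + off))
  }

  if (template$affix_len > 0L) {
    for (k in seq_len(min(template$affix_len, nchar(surf)))) {
      add(sprintf("pre[%d]", k), substr(surf, 1L, k))
      add(sprintf("suf[%d]", k), substr(surf, nchar(surf) - k + 1L, nchar(surf)))
    }
  }
  len_thr <- if (is.null(resources)) 5L else resources$length_threshold
  if (fl[["length"]] && nchar(surf) > len_thr) add("len>5")
  if (fl[["infrequent"]]) {
    cnt <- resources$word_counts[surf]
    if (is.na(cnt) || cnt < resources$infrequent_threshold) add("infreq")
  }
  if (fl[["normalization"]]) add("stem", word_stem(surf))
  if (fl[["word_shape"]]) add("shape", word_shape(surf))
  if (fl[["word_class"]]) add("wc", word_class(surf))
  if (fl[["orthographic"]]) {
    flags <- orthographic_flags(surf)
    for (cat in names(flags)[flags == 1L]) add(paste0("ortho:", cat))
  }
  if (fl[["head_noun"]]) {
    if (surf %in% resources$head_nouns$unigrams) add("hn")
    prev <- at("surface", position - 1L)
    nxt <- at("surface", position + 1L)
    if (paste(prev, surf) %in% resources$head_nouns$bigrams) add("hn_bi_prev")
    if (paste(surf, nxt) %in% resources$head_nouns$bigrams) add("hn_bi_next")
  }
  if (fl[["trigger"]] && surf %in% resources$trigger_words) add("trig")
  if (fl[["informative_words"]]) {
    for (k in seq_along(resources$informative_lists)) {
      if (surf %in% resources$informative_lists[[k]]) add(sprintf("inf[%d]", k))
    }
  }
  if (fl[["content_words"]] && length(resources$content_vocab)) {
    win <- max(1L, position - resources$content_window):
           min(n, position + resources$content_window)
    ctx <- tolower(sentence$surface[setdiff(win, position)])
    hit <- which(resources$content_vocab %in% ctx)
    for (k in hit) add(sprintf("cw[%d]", k))
  }
  if (fl[["unknown_token"]]) {
    bit <- if (is.null(unknown_bit)) !(surf %in% resources$seen_vocab)
           else as.logical(unknown_bit)
    if (bit) add("unk")
  }
  if (fl[["dynamic_ne"]] && template$dynamic_depth > 0L) {
    hist <- c(rep("<s>", template$dynamic_depth), previous_tags)
    hist <- hist[(length(hist) - template$dynamic_depth + 1L):length(hist)]
    d <- template$dynamic_depth
    for (k in seq_len(d)) {
      add(sprintf("t[-%d..-1]", k),
          paste(hist[(d - k + 1L):d], collapse = "|"))
    }
  }
  stats::setNames(out, nm)
}

# Feature bag for the learners: "name=value" strings, one per feature.
feature_bag <- function(feats) paste(names(feats), feats, sep = "=")

# Batch extraction over a whole corpus.  mode "train" uses gold labels as the
# tag history (and draws the training-time unknown-token bits from the
# current RNG state, one per token); mode "predict" is driven by the caller
# supplying predicted previous tags per token via a callback-free greedy loop
# in the backend, so this path only handles depth-0 templates.
extract_feature_bags <- function(corpus, template, resources,
                                 mode = c("train", "predict")) {
  mode <- match.arg(mode)
  tok <- corpus$tokens
  n <- nrow(tok)
  bags <- vector("list", n)
  unk_bits <- if (mode == "train" && template$flags[["unknown_token"]]) {
    stats::runif(n) < 0.5
  } else NULL
  i <- 1L
  for (s in seq_len(n_sentences(corpus))) {
    sent <- tok[tok$sentence == s, , drop = FALSE]
    prev <- character()
    for (p in seq_len(nrow(sent))) {
      bags[[i]] <- feature_bag(extract_features(
        sent, p, template, resources,
        previous_tags = prev,
        unknown_bit = if (is.null(unk_bits)) NULL else unk_bits[i]))
      if (mode == "train") prev <- c(prev, sent$label[p])
      i <- i + 1L
    }
  }
  bags
}
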