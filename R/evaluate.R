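#' Extract entity chunks from a BIO label sequence
#'
#' A chunk is a maximal labelled span: it starts at a `B-X` token, or at an
#' `I-X` token not preceded by a `B-X`/`I-X` of the same type (orphan rule,
#' conlleval-compatible), and extends through following `I-X` tokens of the
#' same type.  Token indices are 0-based; spans are closed intervals.
#'
#' @param labels character vector of BIO labels for one sentence.
#' @param orphan_starts_chunk if `FALSE`, orphan `I-X` tokens are ignored
#'   instead of starting a chunk.
#' @return data frame with columns `start`, `end` (0-based, inclusive) and
#'   `type`.
#' @export
extract_chunks <- function(labels, orphan_starts_chunk = TRUE) {
  ch <- extract_chunks_multi(rep(1L, length(labels)), labels, orphan_starts_chunk)
  ch[, c("start", "end", "type"), drop = FALSE]
}

# Vectorized chunker over a whole corpus: `sentence` is an integer vector
# aligned with `labels`.  Returns sentence/start/end/type.
extract_chunks_multi <- function(sentence, labels, orphan_starts_chunk = TRUE) {
  n <- length(labels)
  empty <- data.frame(sentence = integer(), start = integer(), end = integer(),
                      type = character(), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  role <- label_role(labels)
  type <- label_type(labels)
  ent <- role != "O"
  if (!any(ent)) return(empty)
  prev_same <- c(FALSE, sentence[-1L] == sentence[-n])
  prev_role <- c("O", role[-n])
  prev_type <- c("", type[-n])
  continues <- role == "I" & prev_same & prev_role != "O" & prev_type == type
  start_flag <- ent & !continues
  if (!orphan_starts_chunk) {
    # an orphan I and its continuation run are dropped entirely
    keep <- logical(n)
    run_ok <- FALSE
    for (i in seq_len(n)) {        # rare path; only used when flag flipped
      if (start_flag[i]) run_ok <- role[i] == "B"
      keep[i] <- ent[i] && run_ok
    }
    ent <- keep
    start_flag <- start_flag & ent
    continues <- ent & !start_flag
  }
  pos <- stats::ave(seq_len(n), sentence, FUN = seq_along) - 1L
  chunk_id <- cumsum(start_flag)
  chunk_id[!ent] <- NA_integer_
  idx <- which(ent)
  cid <- chunk_id[idx]
  first <- !duplicated(cid)
  starts <- pos[idx][first]
  sent <- sentence[idx][first]
  typ <- type[idx][first]
  ends <- tapply(pos[idx], cid, max)
  data.frame(sentence = sent, start = starts,
             end = as.integer(ends[as.character(cid[first])]),
             type = typ, stringsAsFactors = FALSE)
}

#' Strict-boundary chunk-level scoring
#'
#' JNLPBA-style strict matching: a predicted entity counts as correct if and
#' only if its left boundary, right boundary and type all equal a gold
#' chunk's.  Recall is correct/gold chunks, precision is correct/predicted
#' chunks, and F is their harmonic mean; all on the percent scale.
#'
#' @param gold a [bio_corpus()] (or a data frame of tokens with `sentence` and
#'   `label` columns) holding the gold labels.
#' @param predicted character vector of predicted labels aligned 1:1 with the
#'   gold tokens.
#' @return An object of class `eval_report`: list with `overall` (named vector
#'   `recall`, `precision`, `f`), `by_class` (data frame per entity type), and
#'   `counts` (`gold`, `predicted`, `correct`).
#' @export
strict_match_scores <- function(gold, predicted) {
  tok <- if (inherits(gold, "bio_corpus")) gold$tokens else gold
  if (length(predicted) != nrow(tok)) {
    stop(sprintf("predicted labels (%d) not aligned with gold tokens (%d)",
                 length(predicted), nrow(tok)))
  }
  gch <- extract_chunks_multi(tok$sentence, tok$label)
  pch <- extract_chunks_multi(tok$sentence, predicted)
  gkey <- paste(gch$sentence, gch$start, gch$end, gch$type)
  pkey <- paste(pch$sentence, pch$start, pch$end, pch$type)
  correct <- sum(pkey %in% gkey)
  types <- sort(unique(c(gch$type, pch$type)))
  by_class <- do.call(rbind, lapply(types, function(tp) {
    g <- sum(gch$type == tp); p <- sum(pch$type == tp)
    cr <- sum(pkey %in% gkey & pch$type == tp)
    data.frame(type = tp, gold = g, predicted = p, correct = cr,
               recall = pct_ratio(cr, g), precision = pct_ratio(cr, p),
               f = f_measure(pct_ratio(cr, g), pct_ratio(cr, p)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(by_class)) {
    by_class <- data.frame(type = character(), gold = integer(),
                           predicted = integer(), correct = integer(),
                           recall = numeric(), precision = numeric(),
                           f = numeric(), stringsAsFactors = FALSE)
  }
  r <- pct_ratio(correct, nrow(gch))
  p <- pct_ratio(correct, nrow(pch))
  structure(
    list(overall = c(recall = r, precision = p, f = f_measure(r, p)),
         by_class = by_class,
         counts = c(gold = nrow(gch), predicted = nrow(pch), correct = correct)),
    class = "eval_report")
}

pct_ratio <- function(num, den) if (den > 0) 100 * num / den else 0

f_measure <- function(r, p) if (r + p > 0) 2 * r * p / (r + p) else 0

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("strict-match scores: R=%.2f P=%.2f F=%.2f  (gold=%d pred=%d correct=%d)\n",
              x$overall["recall"], x$overall["precision"], x$overall["f"],
              x$counts["gold"], x$counts["predicted"], x$counts["correct"]))
  if (nrow(x$by_class)) {
    for (i in seq_len(nrow(x$by_class))) {
      b <- x$by_class[i, ]
      cat(sprintf("  %-12s R=%6.2f P=%6.2f F=%6.2f (gold=%d pred=%d correct=%d)\n",
                  b$type, b$recall, b$precision, b$f, b$gold, b$predicted, b$correct))
    }
  }
  invisible(x)
}
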