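#' BIO-labelled corpora
#'
#' A `bio_corpus` holds a pre-tokenized corpus in the token-per-line column
#' convention used by the JNLPBA/GENIA shared-task data: every token carries a
#' surface form, optional part-of-speech and chunk columns, and a BIO label
#' (`O`, `B-<type>` or `I-<type>`).  Internally tokens live in a single
#' data frame with a sentence index, which keeps whole-corpus operations
#' vectorized.
#'
#' @param tokens data frame with columns `sentence` (integer, 1-based,
#'   contiguous), `surface`, `label`, and optionally `pos` and `chunk`.
#' @param columns character vector of the column roles present
#'   (subset of `c("word", "pos", "chunk", "label")`).
#'
#' @return An object of class `bio_corpus`: a list with elements `tokens`
#'   (the data frame), `entity_types` (character) and `label_alphabet`
#'   (character, B-/I- labels sorted, `"O"` last).
#' @export
bio_corpus <- function(tokens, columns = c("word", "label")) {
  stopifnot(is.data.frame(tokens))
  if (nrow(tokens) > 0L) {
    stopifnot(all(c("sentence", "surface", "label") %in% names(tokens)))
    if (any(!nzchar(tokens$surface))) stop("token surfaces must be non-empty")
    bad <- which(!is_bio_label(tokens$label))
    if (length(bad)) {
      stop(sprintf("label at token %d does not match the BIO pattern: '%s'",
                   bad[1L], tokens$label[bad[1L]]))
    }
    tokens$sentence <- as.integer(tokens$sentence)
    # renumber sentences contiguously in order of first appearance
    tokens$sentence <- match(tokens$sentence, unique(tokens$sentence))
  } else {
    tokens <- data.frame(sentence = integer(), surface = character(),
                         label = character(), stringsAsFactors = FALSE)
  }
  types <- sort(unique(label_type(tokens$label)))
  types <- types[nzchar(types)]
  # alphabet collected from the data: observed B-/I- labels sorted, "O" last
  observed <- sort(unique(tokens$label[tokens$label != "O"]))
  structure(
    list(tokens = tokens,
         entity_types = types,
         label_alphabet = c(observed, "O")),
    columns = columns,
    class = "bio_corpus")
}

#' @export
print.bio_corpus <- function(x, ...) {
  cat(sprintf("<bio_corpus> %d sentences, %d tokens\n",
              n_sentences(x), nrow(x$tokens)))
  cat("  entity types:",
      if (length(x$entity_types)) paste(x$entity_types, collapse = ", ") else "(none)",
      "\n")
  cat("  columns:", paste(attr(x, "columns"), collapse = ", "), "\n")
  invisible(x)
}

#' Number of sentences in a corpus
#' @param corpus a [bio_corpus()].
#' @return integer count.
#' @export
n_sentences <- function(corpus) {
  if (nrow(corpus$tokens) == 0L) 0L else max(corpus$tokens$sentence)
}

#' Extract one sentence as a data frame of tokens
#' @param corpus a [bio_corpus()].
#' @param i sentence index (1-based).
#' @return data frame of the sentence's tokens.
#' @export
sentence_tokens <- function(corpus, i) {
  corpus$tokens[corpus$tokens$sentence == i, , drop = FALSE]
}

# Subset a corpus to a set of sentence indices, renumbering contiguously but
# preserving the given order.
subset_sentences <- function(corpus, idx) {
  tok <- corpus$tokens
  pieces <- tok[tok$sentence %in% idx, , drop = FALSE]
  pieces <- pieces[order(match(pieces$sentence, idx)), , drop = FALSE]
  pieces$sentence <- match(pieces$sentence, idx)
  rownames(pieces) <- NULL
  bio_corpus(pieces, columns = attr(corpus, "columns"))
}

#' Read a CoNLL-style BIO corpus
#'
#' Reads a token-per-line file with whitespace-separated columns and blank
#' lines as sentence separators.  Column roles are declared by the caller so a
#' single reader covers JNLPBA-style (word pos chunk label), two-column
#' (word label) and intermediate layouts.
#'
#' @param path file path.
#' @param columns character vector naming the role of each column in order;
#'   must contain `"word"` and `"label"`, may contain `"pos"` and `"chunk"`.
#' @return A [bio_corpus()].  The validation report of
#'   [validate_bio_corpus()] is attached as attribute `"validation"`.
#' @export
read_bio_corpus <- function(path, columns = c("word", "label")) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(all(c("word", "label") %in% columns))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  blank <- !nzchar(trimws(lines))
  keep <- !blank
  if (!any(keep)) {
    corp <- bio_corpus(data.frame(sentence = integer(), surface = character(),
                                  label = character(), stringsAsFactors = FALSE),
                       columns = columns)
    attr(corp, "validation") <- validate_bio_corpus(corp)
    return(corp)
  }
  # sentence id: count of preceding blank-line boundaries with content after
  sent_id <- cumsum(c(TRUE, blank[-length(blank)]))[keep]
  sent_id <- match(sent_id, unique(sent_id))
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  short <- which(nf < length(columns))
  if (length(short)) {
    stop(sprintf("line %d has %d column(s); %d declared",
                 which(keep)[short[1L]], nf[short[1L]], length(columns)))
  }
  mat <- t(vapply(fields, function(f) f[seq_along(columns)], character(length(columns))))
  tok <- data.frame(sentence = sent_id,
                    surface = mat[, match("word", columns)],
                    label = mat[, match("label", columns)],
                    stringsAsFactors = FALSE)
  if ("pos" %in% columns) tok$pos <- mat[, match("pos", columns)]
  if ("chunk" %in% columns) tok$chunk <- mat[, match("chunk", columns)]
  tok <- tok[, c("sentence", "surface", intersect(c("pos", "chunk"),
                                                  names(tok)), "label")]
  corp <- bio_corpus(tok, columns = columns)
  attr(corp, "validation") <- validate_bio_corpus(corp)
  corp
}

#' Validate BIO label structure
#'
#' Malformed BIO (an `I-X` token with no preceding `B-X`/`I-X` of the same
#' type) is legal input — real taggers produce it — so it is preserved on read
#' and merely reported here.  The evaluator treats an orphan `I-X` as a chunk
#' start.
#'
#' @param corpus a [bio_corpus()].
#' @return data frame with one row per orphan `I-` token
#'   (`sentence`, `position`, `label`).
#' @export
validate_bio_corpus <- function(corpus) {
  tok <- corpus$tokens
  if (nrow(tok) == 0L) {
    return(data.frame(sentence = integer(), position = integer(),
                      label = character(), stringsAsFactors = FALSE))
  }
  role <- label_role(tok$label)
  type <- label_type(tok$label)
  n <- nrow(tok)
  prev_same_sent <- c(FALSE, tok$sentence[-1L] == tok$sentence[-n])
  prev_role <- c("O", role[-n])
  prev_type <- c("", type[-n])
  orphan <- role == "I" &
    (!prev_same_sent | prev_role == "O" | prev_type != type)
  pos <- stats::ave(seq_len(n), tok$sentence, FUN = seq_along) - 1L
  data.frame(sentence = tok$sentence[orphan],
             position = pos[orphan],
             label = tok$label[orphan],
             stringsAsFactors = FALSE)
}

#' Write a corpus in CoNLL-style column format
#'
#' Emits only the columns present in the corpus (word first, label last),
#' whitespace separated, one blank line between sentences.  Reading the file
#' back with the same column declaration reproduces the corpus exactly.
#'
#' @param corpus a [bio_corpus()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_bio_corpus <- function(corpus, path) {
  tok <- corpus$tokens
  cols <- attr(corpus, "columns")
  parts <- list()
  for (role in cols) {
    parts[[role]] <- switch(role,
      word = tok$surface, pos = tok$pos, chunk = tok$chunk, label = tok$label)
  }
  if (nrow(tok) == 0L) {
    writeLines(character(), path, useBytes = TRUE)
    return(invisible(path))
  }
  body <- do.call(paste, parts)
  # insert blank lines at sentence boundaries
  out <- character(0)
  split_body <- split(body, tok$sentence)
  out <- unlist(lapply(split_body, function(s) c(s, "")), use.names = FALSE)
  out <- out[-length(out)]
  writeLines(enc2utf8(out), path, useBytes = TRUE)
  invisible(path)
}
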