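#' Convert a GENETAG-style corpus to BIO
#'
#' GENETAG annotates gene mentions by replacing the token's part-of-speech tag
#' with `NEWGENE` (overlapping mentions: `NEWGENE1`); all other tokens carry an
#' ordinary PoS tag.  Conversion follows the standard preprocessing for this
#' data: every `NEWGENE1` is first rewritten to `NEWGENE`, maximal runs of
#' `NEWGENE` tokens become `B-NEWGENE`, `I-NEWGENE`, ... in BIO, each gene
#' token is assigned the proper-noun PoS `NNP`, and non-gene tokens keep their
#' PoS and are labelled `O`.
#'
#' @param path path to a two-column file: `word tag`, blank line between
#'   sentences, where `tag` is `NEWGENE`, `NEWGENE1`, or a PoS tag.
#' @param gene_tags tags marking gene tokens (default `NEWGENE`/`NEWGENE1`).
#' @return A [bio_corpus()] with `word`, `pos` and `label` columns and entity
#'   type `NEWGENE`.
#' @export
convert_genetag <- function(path, gene_tags = c("NEWGENE", "NEWGENE1")) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  blank <- !nzchar(trimws(lines))
  keep <- !blank
  if (!any(keep)) return(bio_corpus(data.frame(sentence = integer(),
                                               surface = character(),
                                               label = character()),
                                    columns = c("word", "pos", "label")))
  sent_id <- cumsum(c(TRUE, blank[-length(blank)]))[keep]
  sent_id <- match(sent_id, unique(sent_id))
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop(sprintf("line %d has fewer than 2 columns", which(keep)[which(nf < 2L)[1L]]))
  }
  surface <- vapply(fields, `[`, character(1L), 1L)
  tag <- vapply(fields, `[`, character(1L), 2L)
  if (any(!nzchar(tag))) stop("empty tag value encountered")
  tag[tag == "NEWGENE1"] <- "NEWGENE"
  is_gene <- tag %in% gene_tags
  n <- length(surface)
  run_start <- is_gene &
    c(TRUE, !is_gene[-n] | sent_id[-1L] != sent_id[-n])
  label <- rep("O", n)
  label[is_gene] <- ifelse(run_start[is_gene], "B-NEWGENE", "I-NEWGENE")
  pos <- ifelse(is_gene, "NNP", tag)
  bio_corpus(data.frame(sentence = sent_id, surface = surface, pos = pos,
                        label = label, stringsAsFactors = FALSE),
             columns = c("word", "pos", "label"))
}

#' Restrict a corpus to a subset of entity types
#'
#' The cross-corpus experiments harmonize annotation schemes by keeping only
#' the entity classes shared between corpora: every `B-`/`I-` label whose type
#' is not in `keep_types` becomes `O`; kept labels are untouched and the label
#' alphabet is recomputed.
#'
#' @param corpus a [bio_corpus()].
#' @param keep_types character vector of entity type names to retain; must be
#'   a subset of `corpus$entity_types`.
#' @return A [bio_corpus()] over the reduced label alphabet.
#' @export
remap_labels <- function(corpus, keep_types) {
  unknown <- setdiff(keep_types, corpus$entity_types)
  if (length(unknown)) {
    stop("unknown entity type(s): ", paste(unknown, collapse = ", "))
  }
  tok <- corpus$tokens
  drop <- label_type(tok$label) != "" & !(label_type(tok$label) %in% keep_types)
  tok$label[drop] <- "O"
  bio_corpus(tok, columns = attr(corpus, "columns"))
}

#' Rename entity types
#'
#' Explicit harmonization step used before merging corpora annotated under
#' different type vocabularies (e.g. GENETAG's `NEWGENE` vs GENIA's
#' `protein`).
#'
#' @param corpus a [bio_corpus()].
#' @param rename named character vector, `old_type = "new_type"` pairs.
#' @return A [bio_corpus()] with relabelled types.
#' @export
rename_entity_types <- function(corpus, rename) {
  if (length(rename) == 0L) return(corpus)
  stopifnot(!is.null(names(rename)))
  tok <- corpus$tokens
  type <- label_type(tok$label)
  hit <- type %in% names(rename)
  tok$label[hit] <- paste0(substr(tok$label[hit], 1L, 2L), rename[type[hit]])
  bio_corpus(tok, columns = attr(corpus, "columns"))
}

#' Concatenate corpora
#'
#' Sentences are concatenated in the given order; the label alphabet is the
#' union.  Entity type vocabularies must already be harmonized — pass
#' `rename` to apply [rename_entity_types()] to every input first.
#'
#' @param corpora list of [bio_corpus()] objects (at least one).
#' @param rename optional named character vector of type renames applied to
#'   every input corpus before merging.
#' @return A [bio_corpus()].  Columns present are the intersection of the
#'   inputs' columns.
#' @export
merge_corpora <- function(corpora, rename = NULL) {
  stopifnot(length(corpora) >= 1L)
  if (!is.null(rename)) corpora <- lapply(corpora, rename_entity_types, rename = rename)
  cols <- Reduce(intersect, lapply(corpora, attr, "columns"))
  want <- c("sentence", "surface",
            if ("pos" %in% cols) "pos",
            if ("chunk" %in% cols) "chunk",
            "label")
  offset <- 0L
  pieces <- lapply(corpora, function(cc) {
    if (nrow(cc$tokens) == 0L) return(NULL)
    tok <- cc$tokens[, want, drop = FALSE]
    tok$sentence <- tok$sentence + offset
    offset <<- offset + n_sentences(cc)
    tok
  })
  pieces <- Filter(Negate(is.null), pieces)
  if (length(pieces) == 0L) {
    return(bio_corpus(data.frame(sentence = integer(), surface = character(),
                                 label = character(), stringsAsFactors = FALSE),
                      columns = cols))
  }
  bio_corpus(do.call(rbind, pieces), columns = cols)
}

#' Drop sentences with no entity mention
#'
#' The combined cross-corpus training sets are heavily imbalanced; removing
#' sentences that contain no gene/protein mention (all-`O` sentences) makes
#' the positive/negative example ratio more compatible.  Keeps exactly the
#' sentences with at least one non-`O` label, in the original order;
#' idempotent.
#'
#' @param corpus a [bio_corpus()].
#' @return A [bio_corpus()] containing only entity-bearing sentences.
#' @export
remove_noninformative_sentences <- function(corpus) {
  tok <- corpus$tokens
  if (nrow(tok) == 0L) return(corpus)
  has_ne <- tapply(tok$label != "O", tok$sentence, any)
  keep <- as.integer(names(has_ne))[has_ne]
  subset_sentences(corpus, sort(keep))
}
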