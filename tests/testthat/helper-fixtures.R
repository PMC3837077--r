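# Fixture builders: all corpora are constructed in code.

# Build a corpus from per-sentence label strings; surfaces default to
# "tokN" but can be supplied in parallel.
toy_corpus <- function(label_sentences, word_sentences = NULL,
                       columns = c("word", "label")) {
  rows <- list()
  for (s in seq_along(label_sentences)) {
    labs <- strsplit(label_sentences[[s]], "\\s+")[[1L]]
    words <- if (is.null(word_sentences)) {
      paste0("tok", seq_along(labs))
    } else {
      strsplit(word_sentences[[s]], "\\s+")[[1L]]
    }
    rows[[s]] <- data.frame(sentence = s, surface = words, label = labs,
                            stringsAsFactors = FALSE)
  }
  bio_corpus(do.call(rbind, rows), columns = columns)
}

write_corpus_file <- function(lines) {
  path <- tempfile(fileext = ".bio")
  writeLines(lines, path)
  path
}

# Random BIO label sequence (possibly malformed, as real taggers emit).
random_labels <- function(n, types = c("protein", "dna", "rna")) {
  alphabet <- c("O", paste0("B-", types), paste0("I-", types))
  sample(alphabet, n, replace = TRUE,
         prob = c(0.5, rep(0.5 / (2 * length(types)), 2 * length(types))))
}

# Complementary two-classifier bank over single-token entities: classifier 1
# perfect on protein and coin-flip on dna, classifier 2 the reverse.  Used by
# the GA recovery and dominance checks.
complementary_bank <- function(n_sentences = 300L, corpus_seed = 42L,
                               sim_seed = 7L, k = 5L) {
  corp <- generate_corpus(corpus_gen_config(
    n_sentences = n_sentences, entity_types = c("protein", "dna"),
    entity_len = c(1L, 1L), entity_density = 1.2, rng_seed = corpus_seed))
  profiles <- list(reliability_profile(1.0, c(dna = 0.5)),
                   reliability_profile(1.0, c(protein = 0.5)))
  simulate_classifier_outputs(corp, profiles, k = k, rng_seed = sim_seed)
}

# Heterogeneous five-classifier bank over two entity types.
five_classifier_bank <- function(corpus_seed = 11L, sim_seed = 5L,
                                 n_sentences = 250L, k = 5L) {
  corp <- generate_corpus(corpus_gen_config(
    n_sentences = n_sentences, entity_types = c("protein", "dna"),
    entity_density = 1.2, entity_len = c(1L, 2L), rng_seed = corpus_seed))
  profiles <- list(
    reliability_profile(0.88, c(protein = 0.96, dna = 0.55)),
    reliability_profile(0.88, c(protein = 0.55, dna = 0.96)),
    reliability_profile(0.85, c(protein = 0.80, dna = 0.80)),
    reliability_profile(0.80, c(protein = 0.90, dna = 0.65, O = 0.92)),
    reliability_profile(0.75, c(protein = 0.60, dna = 0.90, O = 0.95)))
  simulate_classifier_outputs(corp, profiles, k = k, rng_seed = sim_seed)
}
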