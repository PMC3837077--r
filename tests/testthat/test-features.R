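test_that("word shape and word class follow their normalization rules", {
  expect_equal(word_shape(c("IL", "IL-2", "IL-88")), c("AA", "AA-0", "AA-0"))
  expect_equal(word_shape("p53kinase2026"), "a0aaaaaa0")
  expect_equal(word_class(c("IL23R", "mRNA", "A")), c("AOA", "aA", "A"))
  expect_error(word_shape(""), "empty")
  expect_error(word_class(""), "empty")
  # idempotent on their own output alphabet, never lengthening
  set.seed(41)
  words <- replicate(50, paste(sample(c(LETTERS, letters, 0:9, "-", "."),
                                      sample(1:12, 1), replace = TRUE),
                               collapse = ""))
  expect_equal(word_shape(word_shape(words)), word_shape(words))
  expect_true(all(nchar(word_shape(words)) <= nchar(words)))
  expect_true(all(nchar(word_class(words)) <= nchar(words)))
})

test_that("orthographic categories fire on their canonical examples", {
  fires <- function(w, cat) orthographic_flags(w)[cat] == 1L
  examples <- list(
    InitCap = "Src", AllCaps = "EBNA", InCap = "mAb",
    CapMixAlpha = "NFkappaB", DigitOnly = "123", DigitSpecial = "12-3",
    DigitAlpha = "2A", AlphaDigitAlpha = "IL23R", Hyphen = "-",
    CapLowAlpha = "Ras", CapsAndDigits = "32Dc13", RomanNumeral = "II",
    StopWord = "at", ATGCSeq = "CCGCCC", AlphaDigit = "p50",
    DigitCommaDigit = "1,28", GreekLetter = "alpha", LowMixAlpha = "mRNA")
  for (cat in names(examples)) {
    expect_true(fires(examples[[cat]], cat),
                label = sprintf("%s fires on %s", cat, examples[[cat]]))
  }
  more <- list(AllCaps = "LMP", CapMixAlpha = "EpoR", ATGCSeq = "ATAGAT",
               AlphaDigit = "p65", GreekLetter = "beta", LowMixAlpha = "mAb",
               RomanNumeral = "I", StopWord = "in", CapLowAlpha = "Epo")
  for (cat in names(more)) expect_true(fires(more[[cat]], cat))
  # a number with a comma is not DigitOnly
  expect_equal(unname(orthographic_flags("1,28")["DigitOnly"]), 0L)
  # categories are indicators over the full fixed category set
  expect_equal(length(orthographic_flags("x")), 18L)
  expect_true(all(orthographic_flags("Abc-12") %in% 0:1))
})

test_that("NEweight is the inside/total ratio with its range and monotonicity", {
  expect_equal(ne_weight("factor", 3, 4), 0.75)
  expect_equal(ne_weight("of", 0, 7), 0)
  expect_equal(ne_weight("kinase", 5, 5), 1)
  expect_error(ne_weight("x", 1, 0))
  expect_error(ne_weight("x", 5, 3))
  for (total in c(4, 9)) {
    w <- vapply(0:total, function(k) ne_weight("w", k, total), numeric(1))
    expect_true(all(diff(w) > 0))
    expect_true(all(w >= 0 & w <= 1))
  }
})

test_that("informative-word lists apply the count cutoff and weight binning", {
  # "alpha" occurs twice inside multiword mentions (weight 1); "rare" once
  # (cut); "factor" twice inside out of four total (weight 0.5)
  corp <- toy_corpus(
    list("B-p I-p O O", "B-p I-p O O", "O O O O", "O O O O"),
    list("alpha factor binds cell", "alpha factor was here",
         "factor factor rare good", "rare stuff here too"))
  # make "rare" appear once inside a multiword NE
  corp$tokens$label[corp$tokens$surface == "rare" &
                    corp$tokens$sentence == 3][1] <- "I-p"
  corp <- bio_corpus(corp$tokens, attr(corp, "columns"))
  inf <- build_informative_word_lists(corp)
  expect_false("rare" %in% unlist(inf$lists))     # inside count 1 < 2
  expect_true("alpha" %in% inf$lists[[5]])        # weight 1 -> bin (0.8, 1]
  expect_true("factor" %in% inf$lists[[3]])       # weight 0.5 -> bin (0.4, .6]
  expect_equal(unname(inf$weights["factor"]), 0.5)
  # no multiword mentions -> five empty lists
  single <- toy_corpus(list("B-p O"), list("p53 binds"))
  expect_equal(lengths(build_informative_word_lists(single)$lists),
               rep(0L, 5))
  # equal-width binning puts one word per bin on a constructed spread
  spread <- toy_corpus(
    rep(list("B-p I-p"), 10),
    c(rep("w10 w30", 1), rep("w50 w70", 1), rep("w90 w10", 1),
      rep("w30 w50", 1), rep("w70 w90", 1),
      "f1 w10", "f2 w30", "f3 w50", "f4 w70", "f5 w90"))
  # engineered weights by adding outside occurrences
  extra <- data.frame(sentence = 11,
                      surface = c(rep("w10", 27), rep("w30", 7),
                                  rep("w50", 3), rep("w70", 1)),
                      label = "O")
  spread <- bio_corpus(rbind(spread$tokens, extra), attr(spread, "columns"))
  inf2 <- build_informative_word_lists(spread)
  expect_equal(unname(inf2$weights[c("w10", "w30", "w50", "w70", "w90")]),
               c(0.1, 0.3, 0.5, 0.75, 1.0))
  expect_true("w10" %in% inf2$lists[[1]])
  expect_true("w30" %in% inf2$lists[[2]])
  expect_true("w50" %in% inf2$lists[[3]])
  expect_true("w70" %in% inf2$lists[[4]])
  expect_true("w90" %in% inf2$lists[[5]])
})

test_that("content-word vocabulary counts entity contexts with filtering and tie order", {
  labels <- c(rep(list("O B-p O O"), 12), list("O O O O"))
  words <- c(sprintf("factor P%d factor cell", 1:12), list("the of at in"))
  corp <- toy_corpus(labels, words)
  vocab <- suppressWarnings(extract_content_word_vocab(corp, window = 3))
  expect_equal(vocab[1], "factor")     # 12 entity contexts, max count
  expect_false(any(c("and", "of", "the") %in% vocab))  # stopwords removed
  expect_warning(extract_content_word_vocab(corp), "only")
  # no entities -> empty vocabulary with a warning
  expect_warning(v0 <- extract_content_word_vocab(
    toy_corpus(list("O O O")), 3), "empty")
  expect_equal(v0, character())
})

test_that("resources collect head nouns, triggers, vocabulary and thresholds", {
  corp <- toy_corpus(
    list("O B-p I-p I-p I-p O", "O B-p I-p I-p I-p O",
         "O O B-p O O O", "O O B-p O O O"),
    list("the NF-kappa B transcription factor binds",
         "a GATA-1 like transcription factor acts",
         "it binds p53 strongly in vivo",
         "protein binds p53 weakly in vitro"))
  res <- build_resources(corp, min_freq = 2)
  expect_true("transcription factor" %in% res$head_nouns$bigrams)
  expect_true("factor" %in% res$head_nouns$unigrams)
  expect_true("binds" %in% res$trigger_words)       # precedes 2 mentions
  expect_false("the" %in% res$trigger_words)        # precedes only 1
  expect_equal(res$length_threshold, 5L)
  expect_equal(res$infrequent_threshold, 10L)
  expect_true(all(c("binds", "p53") %in% res$seen_vocab))
  # empty corpus -> empty resources
  res0 <- build_resources(toy_corpus(list("O")), min_freq = 2)
  expect_equal(length(res0$head_nouns$unigrams), 0L)
  expect_equal(length(res0$trigger_words), 0L)
})

test_that("token feature extraction emits exactly the enabled families", {
  corp <- toy_corpus(list("O B-p O"), list("binds interleukin strongly"))
  res <- build_resources(corp)
  sent <- corp$tokens
  tmpl <- feature_template(context_window = 2, affix_len = 3,
                           dynamic_depth = 2)
  f <- extract_features(sent, 2, tmpl, res, previous_tags = "O")
  # context window with boundary placeholders
  expect_equal(unname(f["w[-2]"]), "<s>")
  expect_equal(unname(f["w[0]"]), "interleukin")
  expect_equal(unname(f["w[1]"]), "strongly")
  expect_equal(unname(f["w[0..1]"]), "interleukin|strongly")
  # affixes of the current word only
  expect_equal(unname(f[c("pre[1]", "pre[2]", "pre[3]")]), c("i", "in", "int"))
  expect_equal(unname(f[c("suf[1]", "suf[2]", "suf[3]")]), c("n", "in", "kin"))
  # length 11 > 5 threshold fires; word is seen, so no unknown flag
  expect_true("len>5" %in% names(f))
  expect_false("unk" %in% names(f))
  expect_equal(unname(f["shape"]), "aaaaaaaaaaa")
  expect_true("t[-1..-1]" %in% names(f))
  expect_equal(unname(f["t[-2..-1]"]), "<s>|O")
  # families switched off disappear
  bare <- feature_template(context_window = 0, affix_len = 0,
                           dynamic_depth = 0,
                           flags = c(length = FALSE, orthographic = FALSE,
                                     normalization = FALSE, word_shape = FALSE,
                                     word_class = FALSE, content_words = FALSE,
                                     infrequent = FALSE, head_noun = FALSE,
                                     trigger = FALSE,
                                     informative_words = FALSE,
                                     unknown_token = FALSE))
  fb <- extract_features(sent, 2, bare, res)
  expect_equal(names(fb), "w[0]")
})

test_that("unknown-token feature distinguishes seen from unseen at test time", {
  corp <- toy_corpus(list("O O"), list("seen also"))
  res <- build_resources(corp)
  tmpl <- feature_template(context_window = 0, affix_len = 0,
                           dynamic_depth = 0)
  novel <- data.frame(sentence = 1, surface = "novelword", label = "O")
  expect_true("unk" %in%
    names(extract_features(novel, 1, tmpl, res)))
  known <- data.frame(sentence = 1, surface = "seen", label = "O")
  expect_false("unk" %in%
    names(extract_features(known, 1, tmpl, res)))
  # training-time bit is caller-supplied (drawn from the seeded run RNG)
  expect_true("unk" %in%
    names(extract_features(known, 1, tmpl, res, unknown_bit = TRUE)))
})

test_that("feature extraction is deterministic and causally valid", {
  corp <- generate_corpus(corpus_gen_config(n_sentences = 6, rng_seed = 2))
  res <- build_resources(corp)
  tmpl <- feature_template()
  sent <- sentence_tokens(corp, 3)
  a <- extract_features(sent, 2, tmpl, res, previous_tags = c("O"))
  b <- extract_features(sent, 2, tmpl, res, previous_tags = c("O"))
  expect_identical(a, b)
  # changing the gold label of the current token must not change features
  sent2 <- sent
  sent2$label[2] <- if (sent$label[2] == "O") "B-protein" else "O"
  sent2$label[min(3, nrow(sent))] <- "B-dna"
  c_ <- extract_features(sent2, 2, tmpl, res, previous_tags = c("O"))
  expect_identical(a, c_)
})
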