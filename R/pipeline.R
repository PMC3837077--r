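#' End-to-end ensemble pipeline
#'
#' Runs the full workflow: build the cross-validated model bank on the
#' training corpus, search vote weights with the GA, retrain every base
#' labeler on the complete training corpus, decode the test corpus by
#' weighted voting (using the CV-derived weights and `F_m`), and score the
#' ensemble and every individual classifier with strict matching.
#'
#' @param train_corpus labelled training [bio_corpus()].
#' @param test_corpus labelled test [bio_corpus()] over the same entity
#'   types.
#' @param specs list of [labeler_spec()] objects.
#' @param config a [ga_config()] (`folds` and `rng_seed` drive the whole
#'   run).
#' @param injected optional seed chromosomes passed to [run_ga()].
#' @param cache_dir optional bank cache directory.
#' @return An object of class `ner_pipeline_result`: list with `solution`
#'   (the [run_ga()] fit), `ensemble_report`, `individual_reports` (named
#'   list), `test_predictions` (character matrix tokens x classifiers) and
#'   `ensemble_labels`.
#' @export
run_pipeline <- function(train_corpus, test_corpus, specs,
                         config = ga_config(), injected = NULL,
                         cache_dir = NULL) {
  if (!setequal(train_corpus$entity_types, test_corpus$entity_types)) {
    stop("pipeline: train and test corpora carry different entity types")
  }
  bank <- tryCatch(
    build_model_bank(train_corpus, specs, k = config$folds,
                     rng_seed = config$rng_seed, cache_dir = cache_dir),
    error = function(e) stop("pipeline stage 'bank': ", conditionMessage(e),
                             call. = FALSE))
  solution <- tryCatch(run_ga(bank, config, injected = injected),
                       error = function(e) stop("pipeline stage 'optimize': ",
                                                conditionMessage(e),
                                                call. = FALSE))
  labels <- train_corpus$label_alphabet
  test_pred <- with_seed(config$rng_seed + 104729L, {
    vapply(seq_along(specs), function(m) {
      spec <- specs[[m]]
      backend <- get_backend(spec$learner)
      resources <- build_resources(train_corpus, spec$template)
      state <- backend$fit(train_corpus, spec$template, resources)
      backend$predict(state, test_corpus, spec$template, resources)
    }, character(nrow(test_corpus$tokens)))
  })
  test_pred <- matrix(test_pred, nrow = nrow(test_corpus$tokens),
                      dimnames = list(NULL, solution$classifier_names))
  bad <- !(test_pred %in% labels)
  if (any(bad)) test_pred[bad] <- "O"  # labels unseen in training decode to O
  ens <- tryCatch(
    weighted_vote_decode(test_pred, solution$weights, solution$classifier_F),
    error = function(e) stop("pipeline stage 'decode': ", conditionMessage(e),
                             call. = FALSE))
  individual <- lapply(seq_along(specs), function(m) {
    strict_match_scores(test_corpus, test_pred[, m])
  })
  names(individual) <- solution$classifier_names
  structure(list(solution = solution,
                 ensemble_report = strict_match_scores(test_corpus, ens),
                 individual_reports = individual,
                 test_predictions = test_pred,
                 ensemble_labels = ens,
                 seed = config$rng_seed),
            class = "ner_pipeline_result")
}

#' @export
print.ner_pipeline_result <- function(x, ...) {
  cat("End-to-end weighted-vote ensemble run\n")
  cat(sprintf("  CV fitness of best weights: %.2f\n", x$solution$fitness))
  cat("  test-set scores:\n")
  ind_f <- vapply(x$individual_reports, function(r) r$overall["f"], numeric(1L))
  for (nm in names(x$individual_reports)) {
    cat(sprintf("    %-28s F=%6.2f\n", nm,
                x$individual_reports[[nm]]$overall["f"]))
  }
  cat(sprintf("    %-28s F=%6.2f (best individual %+.2f)\n", "ensemble",
              x$ensemble_report$overall["f"],
              x$ensemble_report$overall["f"] - max(ind_f)))
  invisible(x)
}
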