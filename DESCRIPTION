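Package: nervote
Title: Genetic-Algorithm Weighted-Vote Classifier Ensembles for Biomedical Named-Entity Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building weighted-vote classifier ensembles for
    biomedical named-entity recognition on BIO-labelled corpora. A real-coded
    genetic algorithm with roulette-wheel selection, single-point crossover,
    adaptive crossover/mutation probabilities and Laplacian mutation searches
    per-classifier, per-class vote weights that maximize cross-validated
    strict-match F-measure. Includes CoNLL-style corpus reading, writing and
    cross-corpus annotation harmonization (label remapping, GENETAG
    conversion, corpus merging, non-informative sentence removal), a suite of
    orthographic, contextual and corpus-derived token features, a pluggable
    model bank of base sequence labelers, JNLPBA-style strict-boundary chunk
    evaluation, and synthetic corpus/classifier simulators for controlled
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
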