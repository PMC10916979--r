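Package: fluprop
Title: Word-Property Analysis of Verbal Fluency for Dementia Research
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for psycholinguistic word-property analysis of verbal
    fluency tasks in clinical neuropsychology. Scores transcripts for valid
    responses, looks up per-word frequency, semantic granularity (hypernym
    taxonomy depth), phonological neighborhood, length, familiarity and
    imageability, and summarises each property with seven distributional
    statistics per participant. Provides mixed analysis-of-covariance group
    comparisons with Tukey post-hocs and effect sizes, an iterated stratified
    cross-validated logistic-regression classifier with feature importances,
    Spearman/partial correlation batteries with false-discovery-rate control,
    beta-band phase-locking-value EEG connectivity with cluster-based
    permutation tests, and synthetic cohort/lexicon/EEG generators with
    plantable disease-like effects for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    igraph,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
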