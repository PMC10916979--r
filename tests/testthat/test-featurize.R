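test_that("distributional statistics match direct moment formulas", {
  got <- distributional_features(c(1, 2, 3))
  expect_equal(unname(got["mean"]), 2)
  expect_equal(unname(got["median"]), 2)
  expect_equal(unname(got["sd"]), 1)
  expect_equal(unname(got["min"]), 1)
  expect_equal(unname(got["max"]), 3)
  expect_equal(unname(got["skewness"]), 0)
  expect_equal(unname(got["kurtosis"]), -1.5)

  set.seed(5)
  for (n in c(3, 5, 17, 100)) {
    x <- rnorm(n, sd = runif(1, 0.5, 4))
    expect_equal(distributional_features(x), brute_moments(x), tolerance = 1e-12)
  }
})

test_that("degenerate sequences yield missing statistics, not errors", {
  const <- distributional_features(c(5, 5, 5))
  expect_equal(unname(const["sd"]), 0)
  expect_true(is.na(const["skewness"]) && is.na(const["kurtosis"]))
  expect_true(all(is.na(distributional_features(numeric(0)))))
  one <- distributional_features(7)
  expect_equal(unname(one["mean"]), 7)
  expect_true(is.na(one["sd"]))
})

test_that("outlier trimming removes values beyond k group SDs", {
  v <- c(1, 1, 1, 1, 100)
  keep <- trim_outliers(v, rep("g", 5), k = 3)
  expect_equal(keep, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_true(all(trim_outliers(rep(4, 6), rep("g", 6), k = 3)))
  expect_true(all(trim_outliers(v, rep("g", 5), k = Inf)))
  # per-group: the outlier is only an outlier within its own group
  keep2 <- trim_outliers(c(1, 1, 1, 1, 100, 100, 100, 100, 100),
                         c(rep("a", 4), rep("b", 5)), k = 3)
  expect_true(all(keep2))
})

make_tiny_study <- function() {
  lex <- toy_lexicon(
    form = c("oso", "lobo", "puma", "gato", "vaca"),
    phonemes = c("o s o", "l o b o", "p u m a", "g a t o", "b a k a"),
    log_freq_pm = c(1.1, 0.9, 0.5, 1.6, 1.2),
    familiarity = c(5, 4.5, 3.5, 6.5, 6),
    imageability = c(6, 6, 5.5, 6.5, 6.2))
  tax <- taxonomy(
    edges = data.frame(child = c("animal", "oso", "lobo", "puma", "gato", "vaca"),
                       parent = c("entity", rep("animal", 5))),
    senses = data.frame(form = c("oso", "lobo", "puma", "gato", "vaca"),
                        node = c("oso", "lobo", "puma", "gato", "vaca")))
  rows <- rbind(
    data.frame(participant_id = "p1", task = "phonemic", position = 1:3,
               word = c("puma", "perro", "oso")),
    data.frame(participant_id = "p1", task = "semantic", position = 1:4,
               word = c("gato", "vaca", "gato", "lobo")),
    data.frame(participant_id = "p2", task = "phonemic", position = 1:2,
               word = c("vaca", "oso")),
    data.frame(participant_id = "p2", task = "semantic", position = 1:2,
               word = c("lobo", "<unk>")))
  resp <- flag_validity(fluprop:::as_responses(rows))
  list(lex = lex, tax = tax, resp = resp,
       pts = toy_participants(c("p1", "p2"), group = c("AD", "HC")))
}

test_that("feature matrix has exactly 42 property columns with coherent metadata", {
  st <- make_tiny_study()
  fm <- build_feature_matrix(st$resp, st$pts, st$lex, st$tax)
  info <- attr(fm, "column_info")
  expect_equal(sum(info$kind == "property"), 42)
  expect_equal(length(unique(info$statistic[info$kind == "property"])), 7)
  expect_equal(length(unique(info$property[info$kind == "property"])), 6)
  expect_equal(nrow(fm), 2)

  per_task <- build_feature_matrix(st$resp, st$pts, st$lex, st$tax,
                                   task_mode = "per_task")
  it <- attr(per_task, "column_info")
  for (task in c("phonemic", "semantic")) {
    expect_equal(sum(it$kind == "property" & it$task == task), 42)
  }
})

test_that("feature cells agree with hand-assembled summaries and modes behave", {
  st <- make_tiny_study()
  fm <- build_feature_matrix(st$resp, st$pts, st$lex, st$tax, task_mode = "per_task")
  # p1 semantic frequencies: gato, vaca, gato(rep, still counted in all_responses), lobo
  expect_equal(fm["p1", "frequency_mean_semantic"],
               mean(c(1.6, 1.2, 1.6, 0.9)))
  # valid counts: repetition excluded
  expect_equal(fm["p1", "valid_count_semantic"], 3)
  # unintelligible is excluded from properties even in all_responses mode
  expect_equal(fm["p2", "frequency_mean_semantic"], 0.9)

  vo <- build_feature_matrix(st$resp, st$pts, st$lex, st$tax,
                             mode = "valid_only", task_mode = "per_task")
  expect_equal(vo["p1", "frequency_mean_semantic"], mean(c(1.6, 1.2, 0.9)))

  # out-of-lexicon word ('perro') drops from p1 phonemic means
  expect_equal(fm["p1", "frequency_mean_phonemic"], mean(c(0.5, 1.1)))
  expect_equal(attr(fm, "missing_counts")["p1", "frequency"], 1L)
})

test_that("valid_only equals all_responses on cohorts without invalid words", {
  sim <- simulate_fluency(cohort_spec(n = c(AD = 6, HC = 6), lexicon_size = 200,
                                      invalid_rate = 0, unintelligible_rate = 0,
                                      seed = 31))
  a <- build_feature_matrix(sim$responses, sim$participants, sim$lexicon, sim$taxonomy,
                            mode = "all_responses")
  b <- build_feature_matrix(sim$responses, sim$participants, sim$lexicon, sim$taxonomy,
                            mode = "valid_only")
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
})

test_that("featurization is deterministic and column counts hold in every mode", {
  sim <- simulate_fluency(cohort_spec(n = c(AD = 5, HC = 5), lexicon_size = 150,
                                      seed = 8))
  for (mode in c("all_responses", "valid_only", "valid_outlier_trimmed")) {
    fm <- build_feature_matrix(sim$responses, sim$participants, sim$lexicon,
                               sim$taxonomy, mode = mode)
    info <- attr(fm, "column_info")
    expect_equal(sum(info$kind == "property"), 42)
    fm2 <- build_feature_matrix(sim$responses, sim$participants, sim$lexicon,
                                sim$taxonomy, mode = mode)
    expect_identical(as.data.frame(fm), as.data.frame(fm2))
  }
  # sd >= 0 and min <= median <= max wherever present
  fm <- build_feature_matrix(sim$responses, sim$participants, sim$lexicon, sim$taxonomy)
  info <- attr(fm, "column_info")
  for (p in property_names()) {
    sdc <- fm[[paste0(p, "_sd")]]
    expect_true(all(sdc >= 0, na.rm = TRUE))
    ok <- stats::complete.cases(fm[[paste0(p, "_min")]], fm[[paste0(p, "_median")]],
                                fm[[paste0(p, "_max")]])
    expect_true(all(fm[[paste0(p, "_min")]][ok] <= fm[[paste0(p, "_median")]][ok] &
                      fm[[paste0(p, "_median")]][ok] <= fm[[paste0(p, "_max")]][ok]))
  }
})

test_that("feature matrices round-trip through TSV with sidecar metadata", {
  st <- make_tiny_study()
  fm <- build_feature_matrix(st$resp, st$pts, st$lex, st$tax)
  f <- tempfile(fileext = ".tsv")
  write_features(fm, f)
  back <- read.delim(f, check.names = FALSE)
  expect_equal(back$participant_id, rownames(fm))
  expect_equal(back[["frequency_mean"]], unname(fm[["frequency_mean"]]))
  meta <- jsonlite::read_json(paste0(f, ".meta.json"), simplifyVector = TRUE)
  expect_equal(nrow(meta), ncol(fm))
})

test_that("empty cohorts error", {
  st <- make_tiny_study()
  empty <- st$pts[0, , drop = FALSE]
  class(empty) <- class(st$pts)
  expect_error(build_feature_matrix(st$resp, empty, st$lex, st$tax), "empty cohort")
})
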