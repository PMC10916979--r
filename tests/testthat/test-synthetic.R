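test_that("generators are pure functions of spec and seed", {
  spec <- cohort_spec(n = c(AD = 5, HC = 5), lexicon_size = 120, seed = 50)
  a <- make_lexicon(spec); b <- make_lexicon(spec)
  expect_identical(as.data.frame(a$lexicon), as.data.frame(b$lexicon))
  expect_identical(a$taxonomy$edges, b$taxonomy$edges)
  ca <- make_cohort(spec, a$lexicon, a$taxonomy)
  cb <- make_cohort(spec, b$lexicon, b$taxonomy)
  expect_identical(ca$transcripts, cb$transcripts)
  expect_identical(as.data.frame(ca$participants), as.data.frame(cb$participants))

  spec2 <- cohort_spec(n = c(AD = 5, HC = 5), lexicon_size = 120, seed = 51)
  expect_false(identical(as.data.frame(make_lexicon(spec2)$lexicon),
                         as.data.frame(a$lexicon)))
})

test_that("spec validation rejects impossible settings", {
  expect_error(cohort_spec(n = c(AD = 5, HC = 5), lexicon_size = 50), "seed")
  expect_error(cohort_spec(n = c(AD = 1, HC = 5), seed = 1), ">= 2")
  bad_R <- rbind(c(1, 0.99, -0.99), c(0.99, 1, 0.99), c(-0.99, 0.99, 1))
  expect_error(cohort_spec(n = c(AD = 5, HC = 5), property_correlation = bad_R,
                           seed = 1), "positive semi-definite")
  expect_error(cohort_spec(n = c(AD = 5, HC = 5), seed = 1,
                           effects = list(AD = list(sparkle = c(phonemic = 1,
                                                                semantic = 1)))),
               "unknown properties")
  expect_error(eeg_spec(seed = 1, n_channels = 8, cluster_channels = 1:10),
               "subset")
  expect_error(eeg_spec(seed = 1, duration_s = 1.5), "2 segments")
})

test_that("planted lexicon correlations are recovered in large samples", {
  spec <- cohort_spec(n = c(AD = 2, HC = 2), lexicon_size = 5000,
                      missing_rate = 0, seed = 60)
  lx <- make_lexicon(spec)
  lex <- lx$lexicon
  expect_equal(cor(lex$log_freq_pm, lex$familiarity), 0.6, tolerance = 0.05)
  expect_equal(cor(lex$log_freq_pm, lex$imageability), 0.3, tolerance = 0.05)
  expect_true(all(lex$familiarity >= 1 & lex$familiarity <= 7))
})

test_that("generated taxonomies are valid rooted DAGs with word senses", {
  spec <- cohort_spec(n = c(AD = 2, HC = 2), lexicon_size = 300, seed = 61)
  lx <- make_lexicon(spec)
  tax <- lx$taxonomy
  # constructor already guarantees reachability; check depth consistency
  expect_true(all(tax$depth[tax$edges$child] == tax$depth[tax$edges$parent] + 1))
  expect_equal(tax$depth[["entity"]], 0L)
  expect_true(all(lx$lexicon$form %in% names(tax$senses)))
})

test_that("generated study passes every loader validation via file round-trip", {
  sim <- simulate_fluency(cohort_spec(n = c(AD = 4, bvFTD = 4, HC = 4),
                                      lexicon_size = 150, seed = 62))
  dir <- tempfile("study")
  write_study(sim, dir)
  loaded <- load_transcripts(file.path(dir, "transcripts.tsv"),
                             file.path(dir, "metadata.tsv"))
  lex <- load_lexicon(file.path(dir, "lexicon.tsv"))
  tax <- load_taxonomy(file.path(dir, "taxonomy_edges.tsv"),
                       file.path(dir, "taxonomy_senses.tsv"))
  inv <- readLines(file.path(dir, "invalid_words.txt"))
  resp <- flag_validity(loaded$responses, invalid_words = inv)
  expect_equal(nrow(resp), nrow(sim$responses))
  expect_equal(as.data.frame(lex)$form, as.data.frame(sim$lexicon)$form)
  fm <- build_feature_matrix(resp, loaded$participants, lex, tax)
  expect_equal(sum(attr(fm, "column_info")$kind == "property"), 42)
})

test_that("null cohorts carry no group structure in word properties", {
  spec <- cohort_spec(n = c(AD = 20, HC = 20),
                      effects = list(AD = list()), count_deficit = c(AD = 0),
                      lexicon_size = 400, seed = 63)
  sim <- simulate_fluency(spec)
  fm <- build_feature_matrix(sim$responses, sim$participants, sim$lexicon,
                             sim$taxonomy, task_mode = "per_task")
  df <- cbind(as.data.frame(sim$participants), as.data.frame(fm))
  anc <- mixed_ancova(df, c("frequency_mean_phonemic", "frequency_mean_semantic"))
  expect_gt(anc$terms$p[anc$terms$term == "group"], 0.01)
})

test_that("planted frequency shifts move the group mean in the right direction", {
  spec <- cohort_spec(n = c(AD = 25, HC = 25),
                      effects = list(AD = list(frequency = c(phonemic = 1.2,
                                                             semantic = 1.2))),
                      count_deficit = c(AD = 0), lexicon_size = 400,
                      invalid_rate = 0, unintelligible_rate = 0, seed = 64)
  sim <- simulate_fluency(spec)
  fm <- build_feature_matrix(sim$responses, sim$participants, sim$lexicon,
                             sim$taxonomy)
  ad <- fm$frequency_mean[sim$participants$group == "AD"]
  hc <- fm$frequency_mean[sim$participants$group == "HC"]
  expect_gt(mean(ad), mean(hc))
  expect_gt(cohen_d(ad, hc), 0.5)
})

test_that("severity couples IFS to planted word-property shifts", {
  spec <- cohort_spec(n = c(AD = 30, HC = 30), lexicon_size = 400, seed = 65)
  sim <- simulate_fluency(spec)
  pts <- sim$participants
  pat <- pts[pts$group == "AD", ]
  expect_lt(cor(pat$severity, pat$ifs), -0.3)
  expect_lt(mean(pat$ifs), mean(pts$ifs[pts$group == "HC"]))
})

test_that("EEG generator plants monotone coupling and group reduction", {
  base <- eeg_spec(n_channels = 8, n_per_group = c(3, 3), sampling_rate = 256,
                   duration_s = 6, cluster_channels = 1:4, seed = 70)
  ee <- make_eeg(base)
  expect_length(ee$affected, 3)
  expect_s3_class(ee$affected[[1]], "fluprop_eeg")

  in_cluster <- function(m) mean(m[1:4, 1:4][upper.tri(diag(4))])
  plv_a <- mean(vapply(ee$affected, function(s) in_cluster(plv_matrix(s)), numeric(1)))
  plv_c <- mean(vapply(ee$control, function(s) in_cluster(plv_matrix(s)), numeric(1)))
  expect_gt(plv_c, plv_a) # reduced coupling in the affected group

  # zero coupling everywhere -> off-diagonal PLV near the null level
  null_spec <- eeg_spec(n_channels = 6, n_per_group = c(2, 2), sampling_rate = 256,
                        duration_s = 6, base_coupling = 0, cluster_channels = 1:2,
                        cluster_coupling = 0, cluster_reduction = 0, seed = 71)
  en <- make_eeg(null_spec)
  p0 <- plv_matrix(en$control[[1]])
  expect_lt(mean(p0[upper.tri(p0)]), 0.45)

  # stronger coupling -> higher PLV
  hi <- eeg_spec(n_channels = 6, n_per_group = c(2, 2), sampling_rate = 256,
                 duration_s = 6, cluster_channels = 1:6, cluster_coupling = 0.9,
                 cluster_reduction = 0, base_coupling = 0, seed = 72)
  lo <- eeg_spec(n_channels = 6, n_per_group = c(2, 2), sampling_rate = 256,
                 duration_s = 6, cluster_channels = 1:6, cluster_coupling = 0.3,
                 cluster_reduction = 0, base_coupling = 0, seed = 72)
  p_hi <- plv_matrix(make_eeg(hi)$control[[1]])
  p_lo <- plv_matrix(make_eeg(lo)$control[[1]])
  expect_gt(mean(p_hi[upper.tri(p_hi)]), mean(p_lo[upper.tri(p_lo)]))
})
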