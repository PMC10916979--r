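#' Specification of a synthetic fluency cohort
#'
#' Bundles every parameter of the cohort generator: group sizes, plantable
#' group effects on word properties (in units of the control group's
#' between-participant SD of the per-task property mean, with per-task
#' selectivity), valid-count deficits, covariate distributions matched to a
#' typical three-group dementia cohort, severity-linked cognitive scores,
#' and the lexicon/taxonomy shape. Defaults emulate the disease structure the
#' pipeline is designed to detect: an AD-like group producing fewer,
#' higher-frequency, lower-granularity words, with a higher phonological
#' neighborhood in the semantic task only, and a bvFTD-like group with
#' reduced counts but unaltered word properties.
#'
#' @param n named integer vector of group sizes.
#' @param effects per-group list of property effect sizes; each entry is a
#'   named list \code{property = c(phonemic = e1, semantic = e2)}.
#' @param count_mean,count_sd per-task mean and SD of the control group's
#'   response counts.
#' @param count_deficit per-patient-group mean reduction in response counts
#'   (scaled by each participant's severity).
#' @param covariates per-group age/education means and SDs and female
#'   fraction.
#' @param cognition per-group MoCA and IFS means and SDs.
#' @param severity_sd SD of the patients' latent severity (mean 1).
#' @param ifs_link,moca_link correlation between latent severity and the
#'   cognitive scores within patient groups.
#' @param invalid_rate,unintelligible_rate per-response injection rates.
#' @param missing_rate per-cell deletion rate of lexicon property values.
#' @param lexicon_size,zipf_exponent vocabulary size and Zipf rank-frequency
#'   exponent.
#' @param property_correlation 3x3 correlation matrix coupling log frequency,
#'   familiarity and imageability.
#' @param taxonomy_nodes number of taxonomy concept nodes.
#' @param seed mandatory RNG seed.
#' @return a \code{fluprop_cohort_spec} list.
#' @export
cohort_spec <- function(n = c(AD = 32, bvFTD = 32, HC = 27),
                        effects = list(
                          AD = list(frequency = c(phonemic = 0.8, semantic = 0.8),
                                    granularity = c(phonemic = -0.6, semantic = -0.6),
                                    neighborhood = c(phonemic = 0, semantic = 0.8)),
                          bvFTD = list()),
                        count_mean = c(phonemic = 14, semantic = 19),
                        count_sd = 4,
                        count_deficit = c(AD = 6, bvFTD = 4.5),
                        covariates = list(
                          AD = list(age = c(75.75, 5.63), education = c(11.63, 4.20), sex_f = 18 / 32),
                          bvFTD = list(age = c(68.87, 7.81), education = c(13.20, 5.01), sex_f = 17 / 32),
                          HC = list(age = c(72.30, 7.34), education = c(13.59, 3.78), sex_f = 19 / 27)),
                        cognition = list(
                          AD = list(moca = c(15.41, 4.98), ifs = c(14.41, 4.96)),
                          bvFTD = list(moca = c(17.92, 7.61), ifs = c(15.66, 7.37)),
                          HC = list(moca = c(25.70, 3.27), ifs = c(21.43, 3.06))),
                        severity_sd = 0.3, ifs_link = 0.7, moca_link = 0.7,
                        invalid_rate = 0.08, unintelligible_rate = 0.01,
                        missing_rate = 0.05,
                        lexicon_size = 2000, zipf_exponent = 1,
                        property_correlation = rbind(c(1, 0.6, 0.3),
                                                     c(0.6, 1, 0.4),
                                                     c(0.3, 0.4, 1)),
                        taxonomy_nodes = NULL, seed) {
  if (missing(seed)) stop("cohort_spec: seed is mandatory")
  if (any(n < 2)) stop("group sizes must be >= 2")
  ev <- eigen(property_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8)) stop("property correlation matrix is not positive semi-definite")
  known <- property_names()
  for (g in names(effects)) {
    bad <- setdiff(names(effects[[g]]), known)
    if (length(bad)) stop("effects reference unknown properties: ",
                          paste(bad, collapse = ", "))
  }
  if (is.null(taxonomy_nodes)) taxonomy_nodes <- max(60L, lexicon_size %/% 3L)
  structure(list(n = n, effects = effects, count_mean = count_mean,
                 count_sd = count_sd, count_deficit = count_deficit,
                 covariates = covariates, cognition = cognition,
                 severity_sd = severity_sd, ifs_link = ifs_link,
                 moca_link = moca_link, invalid_rate = invalid_rate,
                 unintelligible_rate = unintelligible_rate,
                 missing_rate = missing_rate, lexicon_size = lexicon_size,
                 zipf_exponent = zipf_exponent,
                 property_correlation = property_correlation,
                 taxonomy_nodes = taxonomy_nodes, seed = as.integer(seed)),
            class = "fluprop_cohort_spec")
}

.phoneme_inventory <- c("a", "e", "i", "o", "u",
                        "p", "t", "k", "b", "d", "g", "f", "s", "x", "m",
                        "n", "l", "r", "w", "y")

#' Generate a synthetic lexicon and hypernym taxonomy
#'
#' Words get random phoneme sequences (consonant/vowel alternating, lengths
#' 2-9), Zipf rank-frequency log10 frequencies per million, and familiarity
#' and imageability ratings linearly coupled to standardized log frequency
#' with the spec's correlation matrix (so their sample Pearson correlations
#' match it), clipped to the 1-7 rating scale. The taxonomy is a random
#' rooted tree (uniform attachment, hence log-depth profiles) with every
#' word given one sense and a tenth of them two. Property values are then
#' deleted completely at random at \code{missing_rate} to exercise
#' missing-data policies downstream. Fully reproducible from the spec seed.
#'
#' @param spec a \code{fluprop_cohort_spec}.
#' @return list with \code{lexicon} (a \code{fluprop_lexicon}) and
#'   \code{taxonomy} (a \code{fluprop_taxonomy}).
#' @export
make_lexicon <- function(spec) {
  stopifnot(inherits(spec, "fluprop_cohort_spec"))
  set.seed(spec$seed)
  V <- spec$lexicon_size
  vowels <- .phoneme_inventory[1:5]
  cons <- .phoneme_inventory[-(1:5)]
  gen_word <- function() {
    L <- sample(2:9, 1, prob = c(2, 6, 10, 10, 7, 4, 2, 1))
    start_v <- runif(1) < 0.3
    ph <- vapply(seq_len(L), function(i) {
      if ((i %% 2 == 1) != start_v) sample(cons, 1) else sample(vowels, 1)
    }, character(1))
    ph
  }
  seqs <- list(); forms <- character(0)
  while (length(forms) < V) {
    ph <- gen_word()
    f <- paste(ph, collapse = "")
    if (!f %in% forms) {
      forms <- c(forms, f)
      seqs[[length(seqs) + 1L]] <- ph
    }
  }
  rank <- sample.int(V)
  H <- sum(seq_len(V)^(-spec$zipf_exponent))
  freq_pm <- 1e6 * rank^(-spec$zipf_exponent) / H
  log_freq <- log10(freq_pm)
  zf <- as.numeric(scale(log_freq))
  R <- spec$property_correlation
  A <- R[2:3, 1]
  Cov <- R[2:3, 2:3] - A %*% t(A)
  U <- chol(Cov)
  lat <- outer(zf, A) + matrix(rnorm(2 * V), V, 2) %*% U
  clamp7 <- function(v) pmin(pmax(v, 1), 7)
  familiarity <- clamp7(4 + 1.1 * lat[, 1])
  imageability <- clamp7(4 + 1.1 * lat[, 2])

  df <- data.frame(form = forms,
                   phonemes = vapply(seqs, paste, character(1), collapse = " "),
                   log_freq_pm = log_freq, familiarity = familiarity,
                   imageability = imageability, stringsAsFactors = FALSE)
  for (col in c("log_freq_pm", "familiarity", "imageability")) {
    drop <- runif(V) < spec$missing_rate
    df[[col]][drop] <- NA
  }

  # random rooted taxonomy: uniform attachment, node 1 = root
  nt <- spec$taxonomy_nodes
  nodes <- c("entity", sprintf("n%04d", seq_len(nt - 1)))
  parent <- vapply(2:nt, function(i) nodes[sample.int(i - 1, 1)], character(1))
  edges <- data.frame(child = nodes[-1], parent = parent, stringsAsFactors = FALSE)
  sense_node <- sample(nodes[-1], V, replace = TRUE)
  senses <- data.frame(form = forms, node = sense_node, stringsAsFactors = FALSE)
  extra <- runif(V) < 0.1
  if (any(extra)) {
    senses <- rbind(senses, data.frame(
      form = forms[extra],
      node = sample(nodes[-1], sum(extra), replace = TRUE),
      stringsAsFactors = FALSE))
  }
  tax <- taxonomy(edges, senses, root = "entity")
  lex <- .as_lexicon(df)
  attr(lex, "freq_pm_true") <- freq_pm[match(lex$form, forms)]
  list(lexicon = lex, taxonomy = tax)
}

# pi-weighted exponential-tilt calibration: find beta so that the expected
# sampled property value shifts by `target` from its null expectation
.calibrate_tilt <- function(z, pi_w, target) {
  if (target == 0) return(0)
  m <- function(beta) {
    w <- pi_w * exp(beta * z)
    sum(w * z) / sum(w)
  }
  uniroot(function(b) m(b) - m(0) - target, interval = c(-50, 50),
          extendInt = "yes", tol = 1e-8)$root
}

#' Generate fluency transcripts and metadata for a synthetic cohort
#'
#' Each participant draws a latent severity (patients: mean 1, SD
#' \code{severity_sd}; controls: 0) that (i) reduces response counts by the
#' group's deficit, (ii) tilts word sampling towards the group's planted
#' property profile, and (iii) drives MoCA/IFS scores with the configured
#' link. Words are drawn without replacement with probability proportional
#' to corpus frequency times an exponential tilt
#' \eqn{\exp(sev_i \sum_p \beta_p z_p(w))}; each \eqn{\beta_p} is calibrated
#' by exact exponential-tilt inversion on the lexicon so that the planted
#' shift of the per-participant property mean equals the spec's effect size
#' in control-SD units (\eqn{\sigma_w/\sqrt{k}} for k-word lists). Invalid
#' responses (repetitions, digit tokens, listed proper names) and
#' unintelligible markers are injected at the configured rates.
#'
#' @param spec a \code{fluprop_cohort_spec}.
#' @param lexicon,taxonomy from \code{\link{make_lexicon}}.
#' @param seed RNG seed; defaults to \code{spec$seed + 1} so lexicon and
#'   cohort draws come from distinct streams.
#' @return list with \code{transcripts} (long data frame), \code{participants}
#'   (a \code{fluprop_participants} with \code{moca}, \code{ifs},
#'   \code{severity}), and \code{invalid_words} (the listed-invalid pool).
#' @export
make_cohort <- function(spec, lexicon, taxonomy, seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "fluprop_cohort_spec"),
            inherits(lexicon, "fluprop_lexicon"))
  set.seed(seed)
  ptab <- .property_table(lexicon, taxonomy)
  # complete-value copy for the sampling model (mean-impute; the generator
  # may use ground truth the analyst does not see)
  zt <- ptab[property_names()]
  for (p in names(zt)) {
    v <- zt[[p]]; v[is.na(v)] <- mean(v, na.rm = TRUE); zt[[p]] <- v
  }
  pi_w <- attr(lexicon, "freq_pm_true")
  if (is.null(pi_w)) pi_w <- 10^ifelse(is.na(lexicon$log_freq_pm), 0, lexicon$log_freq_pm)
  pi_w <- pi_w / sum(pi_w)

  mu_pi <- vapply(zt, function(v) sum(pi_w * v), numeric(1))
  sd_pi <- vapply(names(zt), function(p) {
    sqrt(sum(pi_w * (zt[[p]] - mu_pi[p])^2))
  }, numeric(1))
  zmat <- as.matrix(zt)
  zmat <- sweep(sweep(zmat, 2, mu_pi, "-"), 2, sd_pi, "/")

  tasks <- c("phonemic", "semantic")
  # per group x task: tilt coefficients beta_p
  beta <- list()
  for (g in names(spec$effects)) {
    beta[[g]] <- lapply(tasks, function(t) {
      b <- setNames(numeric(ncol(zmat)), colnames(zmat))
      for (p in names(spec$effects[[g]])) {
        e <- spec$effects[[g]][[p]][[t]]
        if (is.null(e) || is.na(e) || e == 0) next
        sigma_null <- 1 / sqrt(spec$count_mean[[t]]) # z-scale participant-mean SD
        b[p] <- .calibrate_tilt(zmat[, p], pi_w, e * sigma_null)
      }
      b
    })
    names(beta[[g]]) <- tasks
  }

  invalid_pool <- c("pedro", "paco", "paloma", "paris", "pirulo", "panchito")
  rows <- list(); meta <- list()
  for (g in names(spec$n)) {
    cv <- spec$covariates[[g]]; cg <- spec$cognition[[g]]
    for (i in seq_len(spec$n[[g]])) {
      id <- sprintf("%s%03d", g, i)
      sev <- if (g == "HC") 0 else max(0.2, min(2, rnorm(1, 1, spec$severity_sd)))
      zs <- if (g == "HC") 0 else (sev - 1) / spec$severity_sd
      mk_score <- function(ms, link) {
        if (g == "HC") rnorm(1, ms[1], ms[2])
        else ms[1] - ms[2] * (link * zs + sqrt(1 - link^2) * rnorm(1))
      }
      ifs <- max(0, min(30, mk_score(cg$ifs, spec$ifs_link)))
      moca <- as.integer(round(max(0, min(30, mk_score(cg$moca, spec$moca_link)))))
      meta[[id]] <- data.frame(
        participant_id = id, group = g,
        sex = if (runif(1) < cv$sex_f) "F" else "M",
        age = round(max(40, rnorm(1, cv$age[1], cv$age[2])), 1),
        education = round(max(3, rnorm(1, cv$education[1], cv$education[2])), 1),
        handedness = if (runif(1) < 0.92) "R" else "L",
        moca = moca, ifs = round(ifs, 1), severity = sev,
        stringsAsFactors = FALSE)
      deficit <- if (g %in% names(spec$count_deficit)) spec$count_deficit[[g]] * sev else 0
      for (t in tasks) {
        k <- round(rnorm(1, spec$count_mean[[t]] - deficit, spec$count_sd))
        k <- max(3, min(k, nrow(lexicon) - 1))
        b <- if (g %in% names(beta)) beta[[g]][[t]] else NULL
        w <- if (is.null(b) || all(b == 0) || sev == 0) pi_w else
          pi_w * exp(sev * drop(zmat %*% b))
        words <- sample(lexicon$form, k, prob = w)
        # invalid / unintelligible injection
        for (j in seq_along(words)) {
          u <- runif(1)
          if (u < spec$unintelligible_rate) {
            words[j] <- "<unk>"
          } else if (u < spec$unintelligible_rate + spec$invalid_rate) {
            type <- sample(c("repetition", "digit", "listed"), 1)
            if (type == "repetition" && j > 1) {
              words[j] <- words[sample.int(j - 1, 1)]
            } else if (type == "digit") {
              words[j] <- as.character(sample(10:99, 1))
            } else {
              words[j] <- sample(invalid_pool, 1)
            }
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = id, task = t, position = seq_along(words),
          word = words, stringsAsFactors = FALSE)
      }
    }
  }
  transcripts <- do.call(rbind, rows)
  rownames(transcripts) <- NULL
  participants <- as_participants(do.call(rbind, meta))
  rownames(participants) <- NULL
  list(transcripts = transcripts, participants = participants,
       invalid_words = invalid_pool)
}

#' Simulate a complete fluency study
#'
#' Convenience wrapper: generates lexicon + taxonomy + cohort from one spec
#' and returns validity-flagged responses ready for featurization.
#'
#' @param spec a \code{fluprop_cohort_spec}.
#' @return list with \code{responses}, \code{participants}, \code{lexicon},
#'   \code{taxonomy}, \code{invalid_words}.
#' @export
simulate_fluency <- function(spec) {
  lx <- make_lexicon(spec)
  co <- make_cohort(spec, lx$lexicon, lx$taxonomy)
  resp <- flag_validity(as_responses(co$transcripts),
                        invalid_words = co$invalid_words)
  list(responses = resp, participants = co$participants,
       lexicon = lx$lexicon, taxonomy = lx$taxonomy,
       invalid_words = co$invalid_words)
}

#' Write a simulated study to the package's file formats
#'
#' Emits \code{lexicon.tsv}, \code{taxonomy_edges.tsv},
#' \code{taxonomy_senses.tsv}, \code{transcripts.tsv}, \code{metadata.tsv}
#' and \code{invalid_words.txt} under \code{dir}, in the formats the loaders
#' read back.
#'
#' @param sim result of \code{\link{simulate_fluency}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE, na = "")
  lex <- as.data.frame(sim$lexicon)[, c("form", "phonemes", "log_freq_pm",
                                        "familiarity", "imageability")]
  wt(lex, "lexicon.tsv")
  wt(sim$taxonomy$edges, "taxonomy_edges.tsv")
  senses <- data.frame(
    form = rep(names(sim$taxonomy$senses), lengths(sim$taxonomy$senses)),
    node = unlist(sim$taxonomy$senses), stringsAsFactors = FALSE)
  wt(senses, "taxonomy_senses.tsv")
  tr <- as.data.frame(sim$responses)[, c("participant_id", "task", "position", "raw")]
  names(tr)[4] <- "word"
  wt(tr, "transcripts.tsv")
  md <- as.data.frame(sim$participants)
  md$severity <- NULL
  wt(md, "metadata.tsv")
  writeLines(sim$invalid_words, file.path(dir, "invalid_words.txt"))
  invisible(dir)
}

#' Specification of a synthetic resting-state EEG experiment
#'
#' Parameters of the oscillatory sensor-signal generator: all channels share
#' a weak band-limited global source; a planted sensor cluster additionally
#' shares a stronger cluster source whose mixing is reduced in the affected
#' group, producing the hypoconnected cluster the permutation test should
#' recover.
#'
#' @param n_channels number of sensors.
#' @param n_per_group subjects in the affected and control groups.
#' @param sampling_rate Hz.
#' @param duration_s recording length per subject in seconds (>= 2 segments).
#' @param band frequency band of the shared sources (Hz).
#' @param base_coupling global source mixing coefficient (all channels).
#' @param cluster_channels indices of the planted cluster's sensors.
#' @param cluster_coupling cluster source mixing in the control group.
#' @param cluster_reduction fractional reduction of cluster mixing in the
#'   affected group (0 = none, 1 = fully removed).
#' @param noise_sd per-channel independent noise SD.
#' @param segment_ms segment length for PLV analysis.
#' @param seed mandatory RNG seed.
#' @return a \code{fluprop_eeg_spec} list.
#' @export
eeg_spec <- function(n_channels = 128, n_per_group = c(affected = 16, control = 14),
                     sampling_rate = 1024, duration_s = 60, band = c(13, 30),
                     base_coupling = 0.25, cluster_channels = 1:10,
                     cluster_coupling = 0.8, cluster_reduction = 0.5,
                     noise_sd = 1, segment_ms = 1000, seed) {
  if (missing(seed)) stop("eeg_spec: seed is mandatory")
  if (any(cluster_channels > n_channels)) {
    stop("cluster channels must be a subset of the channels")
  }
  if (duration_s * 1000 < 2 * segment_ms) stop("duration must cover at least 2 segments")
  structure(list(n_channels = n_channels, n_per_group = n_per_group,
                 sampling_rate = sampling_rate, duration_s = duration_s,
                 band = band, base_coupling = base_coupling,
                 cluster_channels = cluster_channels,
                 cluster_coupling = cluster_coupling,
                 cluster_reduction = cluster_reduction, noise_sd = noise_sd,
                 segment_ms = segment_ms, seed = as.integer(seed)),
            class = "fluprop_eeg_spec")
}

.bandlimited_noise <- function(n, fs, band) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  signal::filtfilt(bf, rnorm(n))
}

#' Generate segmented EEG for two groups with a planted hypoconnected cluster
#'
#' @param spec a \code{fluprop_eeg_spec}.
#' @return list with \code{affected} and \code{control}, each a list of
#'   \code{fluprop_eeg} objects (band-filtered, segmented).
#' @export
make_eeg <- function(spec) {
  stopifnot(inherits(spec, "fluprop_eeg_spec"))
  set.seed(spec$seed)
  fs <- spec$sampling_rate
  n_t <- round(spec$duration_s * fs)
  chans <- paste0("ch", seq_len(spec$n_channels))
  gen_subject <- function(cluster_mix) {
    g <- .bandlimited_noise(n_t, fs, spec$band)
    s <- .bandlimited_noise(n_t, fs, spec$band)
    x <- matrix(rnorm(spec$n_channels * n_t, sd = spec$noise_sd),
                nrow = spec$n_channels)
    # normalize sources to the noise scale so coupling coefficients are
    # comparable across bands
    g <- g / sd(g); s <- s / sd(s)
    x <- x + spec$base_coupling * matrix(g, spec$n_channels, n_t, byrow = TRUE)
    x[spec$cluster_channels, ] <- x[spec$cluster_channels, ] +
      cluster_mix * matrix(s, length(spec$cluster_channels), n_t, byrow = TRUE)
    rownames(x) <- chans
    bandpass_and_segment(x, fs, band = spec$band, segment_ms = spec$segment_ms)
  }
  affected <- lapply(seq_len(spec$n_per_group[[1]]), function(i) {
    gen_subject(spec$cluster_coupling * (1 - spec$cluster_reduction))
  })
  control <- lapply(seq_len(spec$n_per_group[[2]]), function(i) {
    gen_subject(spec$cluster_coupling)
  })
  list(affected = affected, control = control)
}
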