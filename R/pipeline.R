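#' Build a pipeline configuration
#'
#' A configuration either points at input files (transcripts, metadata,
#' lexicon, taxonomy, invalid-word list) or embeds a simulation spec, and
#' fixes every analysis choice: group pairs, featurization mode, classifier
#' settings, correlation batteries and the root seed all stage seeds derive
#' from.
#'
#' @param paths named list of input paths (\code{transcripts},
#'   \code{metadata}, \code{lexicon}, \code{taxonomy_edges},
#'   \code{taxonomy_senses}, optionally \code{invalid_words}); or \code{NULL}
#'   when \code{simulate} is given.
#' @param simulate optional \code{fluprop_cohort_spec} to generate inputs.
#' @param pairs list of group pairs to compare.
#' @param mode featurization trimming variant.
#' @param classifier list of classifier settings (folds, iterations, knn_k).
#' @param seed root seed.
#' @param out_dir output directory.
#' @return a \code{fluprop_config} list.
#' @export
pipeline_config <- function(paths = NULL, simulate = NULL,
                            pairs = list(c("AD", "HC"), c("bvFTD", "HC")),
                            mode = "all_responses",
                            classifier = list(folds = 5, iterations = 1000, knn_k = 5),
                            seed = 1, out_dir = "fluprop_out") {
  if (is.null(paths) && is.null(simulate)) {
    stop("config error: either input paths or a simulation spec is required")
  }
  if (!is.null(paths)) {
    need <- c("transcripts", "metadata", "lexicon", "taxonomy_edges", "taxonomy_senses")
    miss <- setdiff(need, names(paths))
    if (length(miss)) stop("config error: missing path(s): ", paste(miss, collapse = ", "))
  }
  structure(list(paths = paths, simulate = simulate, pairs = pairs,
                 mode = mode, classifier = classifier, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "fluprop_config")
}

#' Read a pipeline configuration from YAML
#'
#' File keys mirror \code{\link{pipeline_config}} arguments; a
#' \code{simulate} block is passed to \code{\link{cohort_spec}} (group sizes
#' under \code{n}).
#'
#' @param path YAML file.
#' @return a \code{fluprop_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate)) {
    args <- y$simulate
    # YAML 1.1 parses a bare `n` key as boolean FALSE; map it back
    names(args)[names(args) %in% c("FALSE", "no")] <- "n"
    if (!is.null(args$n)) args$n <- unlist(args$n)
    sim <- do.call(cohort_spec, args)
  }
  pipeline_config(paths = y$paths, simulate = sim,
                  pairs = if (is.null(y$pairs)) list(c("AD", "HC"), c("bvFTD", "HC")) else y$pairs,
                  mode = if (is.null(y$mode)) "all_responses" else y$mode,
                  classifier = if (is.null(y$classifier))
                    list(folds = 5, iterations = 1000, knn_k = 5) else y$classifier,
                  seed = if (is.null(y$seed)) 1L else y$seed,
                  out_dir = if (is.null(y$out_dir)) "fluprop_out" else y$out_dir)
}

#' Run the full behavioral analysis pipeline
#'
#' Executes corpus loading (or simulation), featurization, group-level mixed
#' ANCOVAs, subject-level classification and IFS correlation batteries for
#' every configured group pair, writing per-stage TSV/JSON outputs plus a
#' run manifest (settings, seed, package version) into the output directory.
#' All stage seeds derive from the root seed, so reruns with the same
#' configuration are deterministic.
#'
#' @param config a \code{fluprop_config}.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "fluprop_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simulate)) {
    sim <- simulate_fluency(config$simulate)
  } else {
    p <- config$paths
    for (f in unlist(p)) if (!file.exists(f)) stop("config error: missing input file ", f)
    loaded <- load_transcripts(p$transcripts, p$metadata)
    inv <- if (!is.null(p$invalid_words)) readLines(p$invalid_words) else character(0)
    sim <- list(responses = flag_validity(loaded$responses, invalid_words = inv),
                participants = loaded$participants,
                lexicon = load_lexicon(p$lexicon),
                taxonomy = load_taxonomy(p$taxonomy_edges, p$taxonomy_senses),
                invalid_words = inv)
  }

  feats_pooled <- build_feature_matrix(sim$responses, sim$participants,
                                       sim$lexicon, sim$taxonomy,
                                       mode = config$mode, task_mode = "pooled")
  feats_task <- build_feature_matrix(sim$responses, sim$participants,
                                     sim$lexicon, sim$taxonomy,
                                     mode = config$mode, task_mode = "per_task")
  write_features(feats_pooled, file.path(out, "features_pooled.tsv"))
  write_features(feats_task, file.path(out, "features_per_task.tsv"))

  results <- list(features = feats_pooled, features_per_task = feats_task)
  anc_rows <- list(); cls <- list(); cors <- list()
  for (k in seq_along(config$pairs)) {
    pair <- config$pairs[[k]]
    tag <- paste(pair, collapse = "_")
    anc <- ancova_battery(feats_task, sim$participants, pair = pair)
    for (nm in names(anc)) {
      a <- anc[[nm]]
      if (inherits(a, "error")) next
      tt <- a$terms; tt$outcome <- nm; tt$pair <- tag
      anc_rows[[paste(tag, nm)]] <- tt
    }
    lab_rows <- sim$participants$group %in% pair
    cls[[tag]] <- feature_set_battery(
      feats_pooled[sim$participants$participant_id[lab_rows], , drop = FALSE],
      sim$participants$group[lab_rows],
      folds = config$classifier$folds,
      iterations = config$classifier$iterations,
      knn_k = config$classifier$knn_k,
      seed = config$seed + 100L + k)
    pooled <- cbind(sim$participants,
                    as.data.frame(feats_task)[sim$participants$participant_id, ,
                                              drop = FALSE])
    pooled <- collapse_pair(pooled, patient = setdiff(pair, "HC")[1])
    measures <- c("valid_count_phonemic", "valid_count_semantic",
                  as.vector(outer(property_names(),
                                  c("mean_phonemic", "mean_semantic"), paste, sep = "_")))
    cors[[tag]] <- correlation_battery(pooled, measures, "ifs", method = "spearman")
  }
  anc_tab <- do.call(rbind, anc_rows)
  write.table(anc_tab, file.path(out, "ancova.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (tag in names(cls)) {
    jsonlite::write_json(
      lapply(cls[[tag]], function(r) r[c("feature_set", "auc_mean", "auc_sd",
                                         "accuracy_mean", "accuracy_sd")]),
      file.path(out, paste0("classifier_", tag, ".json")), auto_unbox = TRUE,
      digits = NA)
    imp <- cls[[tag]]$all$importances
    write.table(data.frame(feature = names(imp), importance = imp),
                file.path(out, paste0("importances_", tag, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cor_tab <- do.call(rbind, Map(function(d, tag) {
    if (nrow(d)) d$pair <- tag
    d
  }, cors, names(cors)))
  write.table(cor_tab, file.path(out, "correlations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "fluprop",
    version = as.character(utils::packageVersion("fluprop")),
    seed = config$seed, mode = config$mode, pairs = config$pairs,
    classifier = config$classifier,
    simulated = !is.null(config$simulate),
    n_participants = nrow(sim$participants))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  results$ancova <- anc_tab
  results$classifiers <- cls
  results$correlations <- cor_tab
  invisible(results)
}
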