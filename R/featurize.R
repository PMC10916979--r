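#' Seven distributional statistics of a value sequence
#'
#' Summarises a sequence of per-word property values with the seven
#' distributional features used throughout the package: mean, median,
#' standard deviation (n - 1 denominator), minimum, maximum, moment skewness
#' (g1 = m3 / m2^1.5) and excess kurtosis (g2 = m4 / m2^2 - 3), both
#' bias-uncorrected. Skewness and kurtosis are missing when n < 3 or the
#' sequence is constant; all seven are missing for an empty sequence.
#'
#' @param values numeric vector with missing values already removed.
#' @return named numeric vector of length 7.
#' @export
distributional_features <- function(values) {
  stats_names <- c("mean", "median", "sd", "min", "max", "skewness", "kurtosis")
  out <- setNames(rep(NA_real_, 7L), stats_names)
  x <- as.numeric(values)
  n <- length(x)
  if (n == 0) return(out)
  out["mean"] <- mean(x)
  out["median"] <- median(x)
  out["min"] <- min(x)
  out["max"] <- max(x)
  if (n >= 2) out["sd"] <- sd(x)
  m2 <- mean((x - mean(x))^2)
  if (n >= 3 && m2 > 0) {
    out["skewness"] <- mean((x - mean(x))^3) / m2^1.5
    out["kurtosis"] <- mean((x - mean(x))^4) / m2^2 - 3
  }
  out
}

#' Names of the seven distributional statistics
#' @return character vector in canonical order.
#' @export
statistic_names <- function() {
  c("mean", "median", "sd", "min", "max", "skewness", "kurtosis")
}

#' Remove word-level outliers within groups
#'
#' Drops word-level property values lying beyond \code{k} standard
#' deviations from the mean of the participant's group. Mean and SD are
#' computed leaving the candidate value out, so a single gross outlier
#' cannot mask itself by inflating the group SD; with \code{k = Inf}
#' nothing is removed.
#'
#' @param values numeric vector of word-level values.
#' @param group group label per value.
#' @param k SD multiplier (default 3; \code{Inf} keeps everything).
#' @return logical vector, \code{TRUE} for values to keep.
#' @export
trim_outliers <- function(values, group, k = 3) {
  keep <- rep(TRUE, length(values))
  if (is.infinite(k)) return(keep)
  for (g in unique(group)) {
    i <- which(group == g & !is.na(values))
    n <- length(i)
    if (n < 3) next
    v <- values[i]
    s1 <- sum(v); s2 <- sum(v^2)
    m_loo <- (s1 - v) / (n - 1)
    var_loo <- pmax(0, (s2 - v^2 - (n - 1) * m_loo^2) / (n - 2))
    dev <- abs(v - m_loo)
    keep[i] <- ifelse(var_loo > 0, dev <= k * sqrt(var_loo), dev == 0)
  }
  keep
}

#' Build the participant-by-feature word-property matrix
#'
#' Resolves every response to its six word properties, then summarises each
#' property per participant with the seven distributional statistics,
#' yielding the 42 property-derived feature columns (6 properties x 7
#' statistics) plus the valid-response counts per task. Per-word missing
#' values are ignored within each summary; a property with no resolvable
#' values for a participant yields missing cells. Unintelligible responses
#' are always excluded.
#'
#' Task handling: by default both tasks' responses are pooled per property
#' before summarisation (42 property columns total); with
#' \code{task_mode = "per_task"} each task is summarised separately (42 per
#' task). Trimming modes mirror the primary analysis and its robustness
#' replications: \code{all_responses} keeps valid and invalid (intelligible)
#' words, \code{valid_only} drops invalid words, and
#' \code{valid_outlier_trimmed} additionally drops word-level values beyond
#' \code{k_sd} SDs of the participant's group (per property x task x group).
#'
#' @param responses flagged \code{fluprop_responses}.
#' @param participants \code{fluprop_participants} (defines rows and groups).
#' @param lexicon a \code{fluprop_lexicon}.
#' @param taxonomy a \code{fluprop_taxonomy}.
#' @param mode trimming variant.
#' @param task_mode \code{"pooled"} or \code{"per_task"}.
#' @param k_sd SD multiplier for outlier trimming.
#' @return a \code{fluprop_features} data frame: one row per participant,
#'   columns \code{valid_count_phonemic}, \code{valid_count_semantic} and the
#'   property-statistic features; attribute \code{column_info} describes each
#'   column (kind, property, statistic, task) and attribute
#'   \code{missing_counts} records per-participant counts of unresolved
#'   word-property values (for data-comparability checks).
#' @export
build_feature_matrix <- function(responses, participants, lexicon, taxonomy,
                                 mode = c("all_responses", "valid_only",
                                          "valid_outlier_trimmed"),
                                 task_mode = c("pooled", "per_task"),
                                 k_sd = 3) {
  mode <- match.arg(mode)
  task_mode <- match.arg(task_mode)
  stopifnot(inherits(responses, "fluprop_responses"),
            inherits(participants, "fluprop_participants"))
  if (nrow(participants) == 0) stop("empty cohort")
  if (any(is.na(responses$valid))) stop("validity not flagged; run flag_validity() first")

  props <- property_names()
  stats_n <- statistic_names()
  ids <- participants$participant_id

  r <- responses[is.na(responses$invalid_reason) |
                   responses$invalid_reason != "unintelligible", , drop = FALSE]
  if (mode != "all_responses") r <- r[r$valid, , drop = FALSE]

  ptab <- .property_table(lexicon, taxonomy)
  idx <- match(r$normalized, ptab$form)
  wordvals <- ptab[idx, props, drop = FALSE]
  # out-of-lexicon, in-taxonomy forms still resolve granularity
  miss_form <- is.na(idx)
  if (any(miss_form)) {
    in_tax <- r$normalized[miss_form] %in% names(taxonomy$senses)
    if (any(in_tax)) {
      wf <- which(miss_form)[in_tax]
      wordvals$granularity[wf] <- vapply(
        r$normalized[wf],
        function(f) as.integer(min(taxonomy$depth[taxonomy$senses[[f]]])),
        integer(1))
    }
  }

  grp <- participants$group[match(r$participant_id, participants$participant_id)]
  if (mode == "valid_outlier_trimmed") {
    for (p in props) {
      keep <- rep(TRUE, nrow(r))
      for (task in c("phonemic", "semantic")) {
        sel <- r$task == task
        keep[sel] <- trim_outliers(wordvals[[p]][sel], grp[sel], k = k_sd)
      }
      wordvals[[p]][!keep] <- NA
    }
  }

  task_of <- if (task_mode == "pooled") rep("pooled", nrow(r)) else r$task
  tasks <- if (task_mode == "pooled") "pooled" else c("phonemic", "semantic")

  cols <- expand.grid(statistic = stats_n, property = props, task = tasks,
                      stringsAsFactors = FALSE)[, c("property", "statistic", "task")]
  colname <- function(p, s, t) {
    if (t == "pooled") paste(p, s, sep = "_") else paste(p, s, t, sep = "_")
  }
  feat <- matrix(NA_real_, nrow = length(ids), ncol = nrow(cols),
                 dimnames = list(ids, mapply(colname, cols$property,
                                             cols$statistic, cols$task)))
  miss_counts <- matrix(0L, nrow = length(ids), ncol = length(props),
                        dimnames = list(ids, props))
  pid_f <- factor(r$participant_id, levels = ids)
  for (t in tasks) {
    sel_t <- task_of == t
    for (p in props) {
      v <- wordvals[[p]]
      by_id <- split(v[sel_t], pid_f[sel_t])
      summ <- vapply(ids, function(id) {
        x <- by_id[[id]]
        distributional_features(x[!is.na(x)])
      }, numeric(7))
      for (s in stats_n) {
        feat[, colname(p, s, t)] <- summ[s, ]
      }
      if (t == tasks[1] || task_mode == "per_task") {
        nmiss <- vapply(ids, function(id) sum(is.na(by_id[[id]])), integer(1))
        miss_counts[, p] <- miss_counts[, p] + nmiss
      }
    }
  }

  vc <- .valid_count_table(responses, participants)
  out <- data.frame(valid_count_phonemic = vc$phonemic,
                    valid_count_semantic = vc$semantic,
                    feat, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- ids
  info <- rbind(
    data.frame(column = c("valid_count_phonemic", "valid_count_semantic"),
               kind = "valid_count", property = NA_character_,
               statistic = NA_character_, task = c("phonemic", "semantic"),
               stringsAsFactors = FALSE),
    data.frame(column = colnames(feat), kind = "property",
               property = cols$property, statistic = cols$statistic,
               task = cols$task, stringsAsFactors = FALSE)
  )
  structure(out, column_info = info, missing_counts = miss_counts,
            mode = mode, task_mode = task_mode,
            class = c("fluprop_features", "data.frame"))
}

#' @export
print.fluprop_features <- function(x, ...) {
  info <- attr(x, "column_info")
  cat(sprintf("<fluprop_features> %d participants x %d columns (%d property-derived; mode %s, tasks %s)\n",
              nrow(x), ncol(x), sum(info$kind == "property"),
              attr(x, "mode"), attr(x, "task_mode")))
  invisible(x)
}

#' Write a feature matrix and its column metadata
#'
#' Serialises the matrix to wide TSV (missing cells as empty fields) and the
#' column metadata to a JSON sidecar next to it.
#'
#' @param features a \code{fluprop_features}.
#' @param path output TSV path; the sidecar is \code{<path>.meta.json}.
#' @return \code{path}, invisibly.
#' @export
write_features <- function(features, path) {
  df <- data.frame(participant_id = rownames(features),
                   as.data.frame(features), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  jsonlite::write_json(attr(features, "column_info"),
                       paste0(path, ".meta.json"), dataframe = "rows")
  invisible(path)
}
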