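#' Two-by-two mixed ANCOVA (group x task) with covariates
#'
#' Compares an outcome measured under both fluency tasks between two groups,
#' with group as between-subjects factor, task as within-subject factor, and
#' additive between-subject covariates (canonically sex, age and education;
#' no covariate x factor interactions). Reports F, degrees of freedom, p,
#' partial eta squared (SS_effect / (SS_effect + SS_error), computed from the
#' sums of squares, not back-derived from F) and the stratum mean-square
#' error for the terms \code{group}, \code{task} and \code{group:task}.
#'
#' The design is decomposed exactly into its two strata: between-subject
#' effects are tested on subject task-means (Type III, via model comparison
#' against the covariate-only model), and within-subject effects on task
#' differences, where additive between-subject covariates cancel. Sex (and
#' group) use sum-to-zero contrasts. Participants missing any model variable
#' are dropped listwise and counted.
#'
#' @param data data frame with one row per participant containing the group
#'   column, covariates, and the outcome under both tasks.
#' @param outcome_cols length-2 character: columns holding the outcome for
#'   the phonemic and semantic task (order = task order).
#' @param group_col name of the two-level group column.
#' @param covariates covariate column names (character covariates are
#'   sum-contrast coded; numeric ones enter linearly). May be empty.
#' @return a \code{fluprop_ancova} object: data frame of terms with columns
#'   \code{term, F, df1, df2, p, eta_p_sq, mse}, plus attributes \code{n_used}
#'   and \code{n_dropped}.
#' @export
mixed_ancova <- function(data, outcome_cols, group_col = "group",
                         covariates = c("sex", "age", "education")) {
  stopifnot(length(outcome_cols) == 2, all(outcome_cols %in% names(data)),
            group_col %in% names(data), all(covariates %in% names(data)))
  used <- data[, c(group_col, covariates, outcome_cols), drop = FALSE]
  cc <- complete.cases(used)
  n_dropped <- sum(!cc)
  used <- used[cc, , drop = FALSE]
  g <- factor(used[[group_col]])
  if (nlevels(g) != 2) stop("group column must have exactly two levels, got ",
                            nlevels(g))
  if (any(table(g) < 3)) stop("fewer than 3 participants in a group")
  y1 <- used[[outcome_cols[1]]]
  y2 <- used[[outcome_cols[2]]]
  if (sd(c(y1, y2)) == 0) stop("outcome is constant")
  n <- length(y1)

  # design pieces: sum-coded group, covariates (factors sum-coded)
  Xg <- matrix(ifelse(g == levels(g)[1], 1, -1), ncol = 1)
  Xc <- NULL
  for (cv in covariates) {
    v <- used[[cv]]
    if (is.numeric(v)) {
      Xc <- cbind(Xc, v)
    } else {
      f <- factor(v)
      C <- stats::contr.sum(nlevels(f))
      Xc <- cbind(Xc, C[as.integer(f), , drop = FALSE])
    }
  }
  one <- matrix(1, n, 1)

  rss <- function(X, y) {
    fit <- lm.fit(X, y)
    sum(fit$residuals^2)
  }

  # between stratum: subject task-means (conventional SS scale = 2 * mean-scale)
  m <- (y1 + y2) / 2
  Xb_full <- cbind(one, Xg, Xc)
  if (qr(Xb_full)$rank < ncol(Xb_full)) stop("between-subject design is rank deficient")
  rss_f <- rss(Xb_full, m)
  rss_g <- rss(cbind(one, Xc), m)
  df_eb <- n - ncol(Xb_full)
  if (df_eb <= 0) stop("not enough participants for the covariate model")
  ss_group <- 2 * (rss_g - rss_f)
  ss_err_b <- 2 * rss_f
  F_group <- (ss_group / 1) / (ss_err_b / df_eb)

  # within stratum: task differences (conventional SS scale = difference / 2)
  d <- y2 - y1
  Xw_full <- cbind(one, Xg)
  rss_wf <- rss(Xw_full, d)
  rss_task <- rss(Xg, d)      # drop intercept -> task main effect
  rss_int <- rss(one, d)      # drop group term -> interaction
  df_ew <- n - 2
  ss_task <- (rss_task - rss_wf) / 2
  ss_gt <- (rss_int - rss_wf) / 2
  ss_err_w <- rss_wf / 2
  F_task <- ss_task / (ss_err_w / df_ew)
  F_gt <- ss_gt / (ss_err_w / df_ew)

  res <- data.frame(
    term = c("group", "task", "group:task"),
    F = c(F_group, F_task, F_gt),
    df1 = 1L,
    df2 = c(df_eb, df_ew, df_ew),
    p = c(pf_upper(F_group, 1, df_eb), pf_upper(F_task, 1, df_ew),
          pf_upper(F_gt, 1, df_ew)),
    eta_p_sq = c(ss_group / (ss_group + ss_err_b),
                 ss_task / (ss_task + ss_err_w),
                 ss_gt / (ss_gt + ss_err_w)),
    mse = c(ss_err_b / df_eb, ss_err_w / df_ew, ss_err_w / df_ew),
    stringsAsFactors = FALSE
  )
  structure(list(terms = res, groups = levels(g), covariates = covariates,
                 outcome = outcome_cols, n_used = n, n_dropped = n_dropped),
            class = "fluprop_ancova")
}

pf_upper <- function(f, df1, df2) stats::pf(f, df1, df2, lower.tail = FALSE)

#' @export
print.fluprop_ancova <- function(x, ...) {
  cat(sprintf("Mixed ANCOVA: %s vs %s on (%s, %s); covariates: %s\n",
              x$groups[1], x$groups[2], x$outcome[1], x$outcome[2],
              if (length(x$covariates)) paste(x$covariates, collapse = ", ") else "none"))
  cat(sprintf("n = %d (%d dropped listwise)\n", x$n_used, x$n_dropped))
  tt <- x$terms
  tt$F <- round(tt$F, 2); tt$p <- signif(tt$p, 3)
  tt$eta_p_sq <- round(tt$eta_p_sq, 3); tt$mse <- round(tt$mse, 2)
  print(tt, row.names = FALSE)
  invisible(x)
}

#' Tukey HSD post-hoc contrasts over group-by-task cells
#'
#' All pairwise contrasts between the four group x task cells, with
#' studentized-range-adjusted p-values (Tukey-Kramer, via one-way decomposition
#' of the cell samples) and Cohen's d on a pooled-SD denominator. Cell
#' dependence across tasks is ignored by this classical procedure.
#'
#' @param y numeric outcome values (long format, one row per observation).
#' @param cell factor (or coercible) identifying the cell of each value.
#' @return data frame with \code{contrast, diff, p_tukey, cohen_d}.
#' @export
tukey_posthoc <- function(y, cell) {
  cell <- factor(cell)
  if (any(grepl("-", levels(cell), fixed = TRUE))) {
    stop("cell labels must not contain '-' (used as the contrast separator)")
  }
  if (any(table(cell) < 2)) stop("degenerate cells: every cell needs >= 2 values")
  keep <- !is.na(y)
  y <- y[keep]; cell <- droplevels(cell[keep])
  fit <- aov(y ~ cell)
  tk <- TukeyHSD(fit)$cell
  cons <- rownames(tk)
  d <- vapply(cons, function(cn) {
    ab <- strsplit(cn, "-", fixed = TRUE)[[1]]
    cohen_d(y[cell == ab[1]], y[cell == ab[2]])
  }, numeric(1))
  data.frame(contrast = cons, diff = tk[, "diff"], p_tukey = tk[, "p adj"],
             cohen_d = d, row.names = NULL, stringsAsFactors = FALSE)
}

#' Cohen's d (pooled-SD standardized mean difference)
#'
#' @param a,b numeric samples.
#' @return (mean(a) - mean(b)) / pooled SD.
#' @export
cohen_d <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  sp <- sqrt(((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2))
  if (sp == 0) return(0)
  (mean(a) - mean(b)) / sp
}

#' Partial eta squared from sums of squares
#'
#' @param ss_effect effect sum of squares.
#' @param ss_error error sum of squares of the effect's stratum.
#' @return SS_effect / (SS_effect + SS_error).
#' @export
eta_squared_partial <- function(ss_effect, ss_error) {
  if (ss_error <= 0) stop("zero or negative error sum of squares")
  ss_effect / (ss_effect + ss_error)
}

#' Run mixed ANCOVAs over feature-matrix outcomes
#'
#' Convenience wrapper applying \code{\link{mixed_ancova}} to valid counts
#' and each per-task property mean in a per-task feature matrix, for one
#' group pair.
#'
#' @param features a \code{fluprop_features} built with
#'   \code{task_mode = "per_task"}.
#' @param participants \code{fluprop_participants}.
#' @param pair character length-2: the two groups to compare.
#' @param covariates covariate columns in \code{participants}.
#' @param statistic which per-task statistic to analyse (default mean).
#' @return named list of \code{fluprop_ancova}, one per outcome
#'   (\code{valid_count} and the six properties).
#' @export
ancova_battery <- function(features, participants, pair = c("AD", "HC"),
                           covariates = c("sex", "age", "education"),
                           statistic = "mean") {
  stopifnot(attr(features, "task_mode") == "per_task")
  df <- cbind(participants, as.data.frame(features)[participants$participant_id, ,
                                                    drop = FALSE])
  df <- df[df$group %in% pair, , drop = FALSE]
  out <- list()
  out$valid_count <- mixed_ancova(df,
                                  c("valid_count_phonemic", "valid_count_semantic"),
                                  covariates = covariates)
  for (p in property_names()) {
    cols <- paste(p, statistic, c("phonemic", "semantic"), sep = "_")
    out[[p]] <- tryCatch(mixed_ancova(df, cols, covariates = covariates),
                         error = function(e) e)
  }
  out
}
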