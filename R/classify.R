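# --- preprocessing fitted on training folds only -----------------------------

fit_minmax <- function(x) {
  lo <- apply(x, 2, function(v) suppressWarnings(min(v, na.rm = TRUE)))
  hi <- apply(x, 2, function(v) suppressWarnings(max(v, na.rm = TRUE)))
  lo[!is.finite(lo)] <- 0; hi[!is.finite(hi)] <- 0
  list(lo = lo, range = ifelse(hi > lo, hi - lo, 1))
}

apply_minmax <- function(sc, x, clip = FALSE) {
  z <- sweep(sweep(x, 2, sc$lo, "-"), 2, sc$range, "/")
  if (clip) z <- pmin(pmax(z, 0), 1)
  z
}

# nan-Euclidean distance over mutually observed coordinates, rescaled by the
# fraction observed (sklearn convention)
.nan_euclid <- function(row, train) {
  diffs <- sweep(train, 2, row, "-")
  sq <- diffs^2
  obs <- !is.na(sq)
  n_obs <- rowSums(obs)
  sq[!obs] <- 0
  d2 <- rowSums(sq) * ncol(train) / pmax(n_obs, 1)
  d2[n_obs == 0] <- Inf
  sqrt(d2)
}

#' K-nearest-neighbor imputation fitted on a training matrix
#'
#' Imputes missing cells of \code{x} from the \code{k} nearest training rows
#' (uniform weights) under the nan-Euclidean distance computed over mutually
#' observed coordinates. Only training rows observed in the target column are
#' candidates; if none exist the training column mean of observed values is
#' used (and 0 if the column is entirely missing in training). Observed cells
#' are returned untouched.
#'
#' @param train numeric training matrix (defines the neighbor pool).
#' @param x matrix to impute (may be \code{train} itself).
#' @param k number of neighbors.
#' @return \code{x} with missing cells filled in.
#' @export
knn_impute <- function(train, x, k = 5) {
  if (!anyNA(x)) return(x)
  col_means <- apply(train, 2, function(v) {
    m <- mean(v, na.rm = TRUE); if (is.nan(m)) 0 else m
  })
  self <- identical(dim(train), dim(x)) && isTRUE(all.equal(train, x))
  for (i in which(rowSums(is.na(x)) > 0)) {
    row <- x[i, ]
    miss <- which(is.na(row))
    d <- .nan_euclid(row, train)
    if (self) d[i] <- Inf
    for (j in miss) {
      cand <- which(!is.na(train[, j]) & is.finite(d))
      if (length(cand) == 0) { x[i, j] <- col_means[j]; next }
      nb <- cand[order(d[cand], cand)][seq_len(min(k, length(cand)))]
      x[i, j] <- mean(train[nb, j])
    }
  }
  x
}

# --- scoring ------------------------------------------------------------------

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation; ties share ranks.
#'
#' @param scores numeric classifier scores.
#' @param labels logical or 0/1; \code{TRUE}/1 = positive class.
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

.stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- sample(idx) # random order
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

.fit_logistic <- function(x, y) {
  # L2-penalized logistic with the pinned defaults: penalty strength C = 1
  # (glmnet lambda = 1/n), intercept fitted and unpenalized, no internal
  # standardization (features are already min-max scaled).
  n <- nrow(x)
  fit <- withCallingHandlers(
    glmnet::glmnet(x, factor(y, levels = c(FALSE, TRUE)),
                   family = "binomial", alpha = 0, lambda = 1 / n,
                   standardize = FALSE, thresh = 1e-10, maxit = 1000L),
    warning = function(w) {
      # advisory emitted for small training classes; expected at fold sizes
      if (grepl("fewer than 8", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  list(beta = as.numeric(fit$beta[, 1]), a0 = as.numeric(fit$a0[1]))
}

.predict_logistic <- function(model, x) {
  eta <- drop(x %*% model$beta) + model$a0
  1 / (1 + exp(-eta))
}

#' Iterated stratified cross-validated logistic classification
#'
#' Discriminates two groups from a feature matrix with the iterated
#' cross-validation harness used for subject-level classification: per
#' iteration a fresh random stratified 5-fold partition (label proportions
#' preserved); per fold, a min-max scaler and a K-nearest-neighbor imputer
#' (uniform weights, K = 5) are fitted on the training folds only and applied
#' to the test fold (test values clipped to [0, 1]); an L2 logistic model
#' (C = 1, fitted intercept) is trained and out-of-fold probabilities pooled
#' within the iteration give that iteration's AUC and accuracy (decision
#' boundary 0.5). The report aggregates mean and SD over iterations, mean
#' absolute coefficients over all fold models (feature importances), and each
#' subject's output score averaged over iterations.
#'
#' @param features numeric matrix or \code{fluprop_features} (rows =
#'   participants).
#' @param labels two-level factor/character of group membership, aligned with
#'   rows; the first level sorts as reference, the second is the positive class.
#' @param feature_cols optional character vector restricting the columns used.
#' @param folds number of CV folds.
#' @param iterations number of random repartitions.
#' @param knn_k imputer neighborhood size.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return a \code{fluprop_classifier_report}.
#' @export
run_classifier <- function(features, labels, feature_cols = NULL,
                           folds = 5, iterations = 1000, knn_k = 5, seed = 1) {
  x <- as.matrix(as.data.frame(features))
  if (!is.null(feature_cols)) x <- x[, feature_cols, drop = FALSE]
  storage.mode(x) <- "double"
  lab <- factor(labels)
  if (nlevels(lab) != 2) stop("labels must have exactly two levels")
  y <- lab == levels(lab)[2]
  if (min(table(y)) < folds) stop("need at least `folds` participants per class")
  n <- length(y)
  set.seed(seed)

  auc_it <- acc_it <- numeric(iterations)
  score_sum <- numeric(n)
  imp_sum <- numeric(ncol(x)); imp_n <- 0L
  for (it in seq_len(iterations)) {
    repeat {
      fold <- .stratified_folds(y, folds)
      if (all(vapply(seq_len(folds),
                     function(f) length(unique(y[fold != f])) == 2, logical(1)))) break
      message("resampling partition: a class was absent from a training split")
    }
    scores <- numeric(n)
    for (f in seq_len(folds)) {
      tr <- fold != f; te <- !tr
      sc <- fit_minmax(x[tr, , drop = FALSE])
      xtr <- apply_minmax(sc, x[tr, , drop = FALSE])
      xte <- apply_minmax(sc, x[te, , drop = FALSE], clip = TRUE)
      xtr_i <- knn_impute(xtr, xtr, k = knn_k)
      xte_i <- knn_impute(xtr, xte, k = knn_k)
      mod <- .fit_logistic(xtr_i, y[tr])
      scores[te] <- .predict_logistic(mod, xte_i)
      imp_sum <- imp_sum + abs(mod$beta); imp_n <- imp_n + 1L
    }
    auc_it[it] <- auc_score(scores, y)
    acc_it[it] <- mean((scores > 0.5) == y)
    score_sum <- score_sum + scores
  }
  structure(list(
    feature_set = if (is.null(feature_cols)) "all" else
      paste(feature_cols, collapse = ","),
    positive_class = levels(lab)[2],
    auc_mean = mean(auc_it), auc_sd = sd(auc_it),
    accuracy_mean = mean(acc_it), accuracy_sd = sd(acc_it),
    importances = setNames(imp_sum / imp_n, colnames(x)),
    subject_scores = setNames(score_sum / iterations, rownames(x)),
    n_iterations = iterations, n_folds = folds, knn_k = knn_k, seed = seed
  ), class = "fluprop_classifier_report")
}

#' @export
print.fluprop_classifier_report <- function(x, ...) {
  cat(sprintf("<classifier report> positive = %s; %d-fold CV x %d iterations\n",
              x$positive_class, x$n_folds, x$n_iterations))
  cat(sprintf("AUC = %.3f +/- %.3f; accuracy = %.3f +/- %.3f\n",
              x$auc_mean, x$auc_sd, x$accuracy_mean, x$accuracy_sd))
  top <- sort(x$importances, decreasing = TRUE)
  cat("top features:", paste(names(head(top, 5)), collapse = ", "), "\n")
  invisible(x)
}

#' One classifier per word property plus the all-features classifier
#'
#' Runs \code{\link{run_classifier}} once per property (its 7 distributional
#' features) and once on all property-derived features combined (42 with
#' pooled tasks), giving a radar-plot-ready AUC table.
#'
#' @param features a \code{fluprop_features}.
#' @param labels group labels aligned with rows.
#' @param ... passed to \code{\link{run_classifier}} (folds, iterations,
#'   knn_k, seed).
#' @return named list of \code{fluprop_classifier_report} (six properties +
#'   \code{"all"}), with an \code{auc_table} attribute.
#' @export
feature_set_battery <- function(features, labels, ...) {
  info <- attr(features, "column_info")
  if (is.null(info)) stop("features must be a fluprop_features with column_info")
  prop_cols <- info$column[info$kind == "property"]
  out <- list()
  for (p in property_names()) {
    cols <- info$column[info$kind == "property" & info$property == p]
    out[[p]] <- run_classifier(features, labels, feature_cols = cols, ...)
  }
  out$all <- run_classifier(features, labels, feature_cols = prop_cols, ...)
  auc <- data.frame(feature_set = names(out),
                    auc_mean = vapply(out, `[[`, numeric(1), "auc_mean"),
                    auc_sd = vapply(out, `[[`, numeric(1), "auc_sd"),
                    row.names = NULL)
  attr(out, "auc_table") <- auc
  out
}
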