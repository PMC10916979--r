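#' Correlation battery with FDR control
#'
#' Correlates each measure with each target over the supplied sample (for
#' brain/behavior analyses the caller collapses one patient group with the
#' healthy controls first; see \code{\link{collapse_pair}}). The method is
#' either fixed (\code{"spearman"} for executive-score batteries,
#' \code{"pearson"}) or chosen per pair (\code{"auto"}): Pearson only when
#' Shapiro-Wilk keeps normality for \emph{both} variables at alpha = 0.05,
#' Spearman otherwise. p-values are Benjamini-Hochberg adjusted within the
#' battery (one battery = one call). Pairs with fewer than 4 complete
#' observations are skipped with a message.
#'
#' @param data data frame holding measures and targets per participant.
#' @param measures character vector of measure column names.
#' @param targets character vector of target column names.
#' @param method \code{"spearman"}, \code{"pearson"} or \code{"auto"}.
#' @return data frame of class \code{fluprop_correlations} with columns
#'   \code{x, y, method, rho, p, p_fdr, n}.
#' @export
correlation_battery <- function(data, measures, targets,
                                method = c("spearman", "auto", "pearson")) {
  method <- match.arg(method)
  stopifnot(all(measures %in% names(data)), all(targets %in% names(data)))
  rows <- list()
  for (mx in measures) {
    for (ty in targets) {
      x <- data[[mx]]; y <- data[[ty]]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 4) {
        message(sprintf("skipping %s ~ %s: only %d complete pairs", mx, ty, sum(ok)))
        next
      }
      use <- method
      if (method == "auto") {
        norm_x <- shapiro.test(x[ok])$p.value >= 0.05
        norm_y <- shapiro.test(y[ok])$p.value >= 0.05
        use <- if (norm_x && norm_y) "pearson" else "spearman"
      }
      ct <- suppressWarnings(cor.test(x[ok], y[ok], method = use, exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        x = mx, y = ty, method = use, rho = unname(ct$estimate),
        p = ct$p.value, n = sum(ok), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(x = character(0), y = character(0), method = character(0),
                      rho = numeric(0), p = numeric(0), p_fdr = numeric(0),
                      n = integer(0))
  } else {
    out <- do.call(rbind, rows)
    out$p_fdr <- p.adjust(out$p, method = "BH")
    out <- out[, c("x", "y", "method", "rho", "p", "p_fdr", "n")]
  }
  structure(out, class = c("fluprop_correlations", "data.frame"))
}

#' Collapse one patient group with healthy controls
#'
#' Subsets a participant-level data frame to one patient group plus the
#' control group, the pooling used to widen variance before brain/behavior
#' correlations.
#'
#' @param data data frame with a \code{group} column.
#' @param patient patient group label.
#' @param control control group label.
#' @return the pooled subset.
#' @export
collapse_pair <- function(data, patient = "AD", control = "HC") {
  data[data$group %in% c(patient, control), , drop = FALSE]
}

#' Partial correlation controlling for nuisance variables
#'
#' Correlates the residuals of \code{x} and \code{y} after linear removal of
#' the control variables; for the Spearman variant all variables are rank
#' transformed first.
#'
#' @param x,y numeric vectors.
#' @param controls data frame or matrix of control variables.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return one-row data frame \code{method, rho, p, n, controls}.
#' @export
partial_correlation <- function(x, y, controls, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  controls <- as.data.frame(controls)
  ok <- !is.na(x) & !is.na(y) & complete.cases(controls)
  x <- x[ok]; y <- y[ok]
  cm <- as.matrix(data.frame(lapply(controls[ok, , drop = FALSE], as.numeric)))
  n <- length(x)
  k <- ncol(cm)
  if (n < k + 4) stop("too few complete observations for partial correlation")
  if (method == "spearman") {
    x <- rank(x); y <- rank(y); cm <- apply(cm, 2, rank)
  }
  X <- cbind(1, cm)
  if (qr(X)$rank < ncol(X)) stop("collinear control variables")
  rx <- lm.fit(X, x)$residuals
  ry <- lm.fit(X, y)$residuals
  if (sd(rx) < 1e-10 * max(1, sd(x)) || sd(ry) < 1e-10 * max(1, sd(y))) {
    stop("degenerate partial correlation: a variable is fully explained by the controls")
  }
  rho <- cor(rx, ry)
  df <- n - 2 - k
  tval <- rho * sqrt(df / (1 - rho^2))
  p <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  data.frame(method = paste0("partial-", method), rho = rho, p = p, n = n,
             controls = paste(colnames(controls), collapse = ","),
             stringsAsFactors = FALSE)
}
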