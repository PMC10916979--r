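# zero-phase frequency-domain band-pass: unit gain inside the band,
# raised-cosine roll-off over `transition` Hz on either side
.fft_bandpass <- function(ch, fs, band, transition = 2) {
  n <- length(ch)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f) # two-sided symmetric frequency axis
  mask <- numeric(n)
  lo <- band[1]; hi <- band[2]
  mask[f >= lo & f <= hi] <- 1
  up <- f > lo - transition & f < lo
  mask[up] <- 0.5 * (1 + cos(pi * (lo - f[up]) / transition))
  dn <- f > hi & f < hi + transition
  mask[dn] <- 0.5 * (1 + cos(pi * (f[dn] - hi) / transition))
  Re(fft(fft(ch) * mask, inverse = TRUE)) / n
}

#' Band-pass filter and segment a multichannel recording
#'
#' Applies a zero-phase band-pass to every channel and cuts the result into
#' non-overlapping fixed-length segments (canonically 1000 ms), dropping the
#' trailing remainder. The default filter is an acausal frequency-domain
#' mask with unit passband gain and raised-cosine transitions: it adds no
#' start-up transient, so in-band periodic components pass exactly (which
#' the phase-locking analytics rely on); a forward-backward Butterworth of
#' modest order is available as an alternative.
#'
#' @param x numeric matrix, channels x time samples; rownames are channel
#'   labels.
#' @param sampling_rate sampling rate in Hz.
#' @param band length-2 numeric, band edges in Hz (default the beta band,
#'   13-30 Hz). Must lie below the Nyquist frequency.
#' @param segment_ms segment length in milliseconds.
#' @param filter_type \code{"fft"} (zero-phase frequency-domain mask) or
#'   \code{"butterworth"} (zero-phase forward-backward IIR).
#' @param order Butterworth order (per pass); ignored for \code{"fft"}.
#' @param transition roll-off width in Hz for the \code{"fft"} filter.
#' @return a \code{fluprop_eeg} object holding a channels x samples x
#'   segments array plus metadata.
#' @export
bandpass_and_segment <- function(x, sampling_rate, band = c(13, 30),
                                 segment_ms = 1000,
                                 filter_type = c("fft", "butterworth"),
                                 order = 4, transition = 2) {
  filter_type <- match.arg(filter_type)
  x <- as.matrix(x)
  nyq <- sampling_rate / 2
  if (band[2] >= nyq) stop("band upper edge must be below the Nyquist frequency")
  if (band[1] <= 0 || band[1] >= band[2]) stop("invalid band")
  spt <- floor(segment_ms / 1000 * sampling_rate)
  if (ncol(x) < spt) stop("recording shorter than one segment")
  if (filter_type == "fft") {
    filt <- t(apply(x, 1, .fft_bandpass, fs = sampling_rate, band = band,
                    transition = transition))
  } else {
    bf <- signal::butter(order, band / nyq, type = "pass")
    filt <- t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
  }
  n_seg <- floor(ncol(x) / spt)
  seg <- array(NA_real_, dim = c(nrow(x), spt, n_seg))
  for (s in seq_len(n_seg)) {
    seg[, , s] <- filt[, ((s - 1) * spt + 1):(s * spt), drop = FALSE]
  }
  ch_names <- rownames(x)
  if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(nrow(x)))
  structure(list(segments = seg, channels = ch_names,
                 sampling_rate = sampling_rate, segment_ms = segment_ms,
                 band = band),
            class = "fluprop_eeg")
}

#' @export
print.fluprop_eeg <- function(x, ...) {
  d <- dim(x$segments)
  cat(sprintf("<fluprop_eeg> %d channels x %d samples x %d segments @ %g Hz, band %g-%g Hz\n",
              d[1], d[2], d[3], x$sampling_rate, x$band[1], x$band[2]))
  invisible(x)
}

# analytic signal via the FFT half-spectrum method
.analytic <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Phase-locking value connectivity matrix
#'
#' For each segment, instantaneous phases are taken from the analytic signal
#' of every channel; for each channel pair the PLV is the modulus of the
#' time-averaged complex exponential of the phase difference. Values are
#' averaged over segments. PLV ranges from 0 (no phase relation) to 1
#' (perfectly locked phases); it depends only on phases, so it is invariant
#' to amplitude rescaling. The first and last \code{edge_ms} of each
#' segment's phase series are excluded to suppress filter/Hilbert edge
#' effects. Channels with zero variance in any segment get missing pairs
#' with a warning.
#'
#' @param seg a \code{fluprop_eeg}.
#' @param edge_ms samples to discard at either end of each segment (ms).
#' @return channels x channels symmetric matrix of class
#'   \code{fluprop_connectivity} with unit diagonal; attributes \code{band}
#'   and \code{n_segments}.
#' @export
plv_matrix <- function(seg, edge_ms = 100) {
  stopifnot(inherits(seg, "fluprop_eeg"))
  d <- dim(seg$segments)
  n_ch <- d[1]; spt <- d[2]; n_seg <- d[3]
  drop_n <- floor(edge_ms / 1000 * seg$sampling_rate)
  keep <- seq.int(drop_n + 1, spt - drop_n)
  if (length(keep) < 2) stop("edge exclusion leaves no samples")
  acc <- matrix(0, n_ch, n_ch)
  bad <- logical(n_ch)
  for (s in seq_len(n_seg)) {
    sl <- seg$segments[, , s, drop = FALSE]
    dim(sl) <- d[1:2]
    sds <- apply(sl, 1, sd)
    bad <- bad | sds == 0
    E <- matrix(0+0i, nrow = length(keep), ncol = n_ch)
    for (ch in seq_len(n_ch)) {
      a <- .analytic(sl[ch, ])[keep]
      ph <- Arg(a)
      E[, ch] <- exp(1i * ph)
    }
    acc <- acc + Mod(t(Conj(E)) %*% E) / length(keep)
  }
  plv <- acc / n_seg
  diag(plv) <- 1
  if (any(bad)) {
    warning("zero-variance channel(s): ",
            paste(seg$channels[bad], collapse = ", "), "; their pairs set missing")
    plv[bad, ] <- NA_real_; plv[, bad] <- NA_real_
    diag(plv)[bad] <- NA_real_
  }
  dimnames(plv) <- list(seg$channels, seg$channels)
  structure(plv, band = seg$band, n_segments = n_seg,
            class = c("fluprop_connectivity", "matrix", "array"))
}

#' @export
print.fluprop_connectivity <- function(x, ...) {
  b <- attr(x, "band")
  cat(sprintf("<fluprop_connectivity> %d channels, band %g-%g Hz, %d segments; mean off-diagonal PLV %.3f\n",
              nrow(x), b[1], b[2], attr(x, "n_segments"),
              mean(x[upper.tri(x)], na.rm = TRUE)))
  invisible(x)
}

.edge_index <- function(n_ch) which(upper.tri(matrix(0, n_ch, n_ch)), arr.ind = TRUE)

.edge_t <- function(va, vb, welch = FALSE) {
  # va, vb: subjects x edges matrices of one group each
  n1 <- nrow(va); n2 <- nrow(vb)
  m1 <- colMeans(va); m2 <- colMeans(vb)
  s1 <- (colSums(va^2) - n1 * m1^2) / (n1 - 1)
  s2 <- (colSums(vb^2) - n2 * m2^2) / (n2 - 1)
  if (welch) {
    se <- sqrt(s1 / n1 + s2 / n2)
    df <- (s1 / n1 + s2 / n2)^2 /
      ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  }
  list(t = (m1 - m2) / se, df = df)
}

.edge_clusters <- function(supra_edges, n_ch) {
  # connected components of the sensor graph induced by supra-threshold edges;
  # cluster statistic = edge count
  if (nrow(supra_edges) == 0) return(list())
  g <- igraph::graph_from_edgelist(cbind(as.character(supra_edges[, 1]),
                                         as.character(supra_edges[, 2])),
                                   directed = FALSE)
  memb <- igraph::components(g)$membership
  comp_of_edge <- memb[as.character(supra_edges[, 1])]
  split(seq_len(nrow(supra_edges)), comp_of_edge)
}

#' Cluster-based permutation test on connectivity matrices
#'
#' Compares two groups of subject-level connectivity matrices. Each edge
#' (channel pair) gets a two-sample two-tailed t-test; edges significant at
#' \code{p_con} form a graph on the sensors whose connected components are
#' the clusters, scored by their number of connections. Group labels are
#' then permuted \code{n_perm} times and the null distribution of the
#' maximum cluster size is accumulated; each observed cluster's p-value is
#' the proportion of permutations (with the (count + 1) / (n_perm + 1)
#' convention, so p is never exactly 0) whose maximum statistic reaches the
#' cluster's size. Controls the family-wise error across clusters.
#'
#' @param group_a,group_b lists of \code{fluprop_connectivity} (or plain
#'   symmetric matrices) with matching channel sets.
#' @param p_con edge-level two-tailed threshold.
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @param var_type \code{"pooled"} (classical t) or \code{"welch"}.
#' @return a \code{fluprop_clustertest}: edge table, clusters (channel pairs,
#'   size, p), null max-size distribution.
#' @export
cluster_permutation_test <- function(group_a, group_b, p_con = 0.05,
                                     n_perm = 1000, seed = 1,
                                     var_type = c("pooled", "welch")) {
  var_type <- match.arg(var_type)
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("need at least 2 subjects per group")
  }
  chans <- rownames(group_a[[1]])
  if (is.null(chans)) chans <- paste0("ch", seq_len(nrow(group_a[[1]])))
  all_m <- c(group_a, group_b)
  for (m in all_m) {
    if (!is.null(rownames(m)) && !identical(rownames(m), chans)) {
      stop("channel sets differ between subjects")
    }
    if (nrow(m) != length(chans)) stop("channel sets differ between subjects")
  }
  n_ch <- length(chans)
  ei <- .edge_index(n_ch)
  vec <- t(vapply(all_m, function(m) as.matrix(m)[ei], numeric(nrow(ei))))
  n1 <- length(group_a); n2 <- length(group_b); n <- n1 + n2
  welch <- var_type == "welch"

  score <- function(rows_a) {
    tt <- .edge_t(vec[rows_a, , drop = FALSE], vec[-rows_a, , drop = FALSE],
                  welch = welch)
    crit <- qt(1 - p_con / 2, tt$df)
    which(abs(tt$t) > crit)
  }

  obs_t <- .edge_t(vec[seq_len(n1), , drop = FALSE],
                   vec[-seq_len(n1), , drop = FALSE], welch = welch)
  supra <- which(abs(obs_t$t) > qt(1 - p_con / 2, obs_t$df))
  obs_edges <- cbind(chans[ei[supra, 1]], chans[ei[supra, 2]])
  comp <- .edge_clusters(obs_edges, n_ch)
  sizes <- lengths(comp)

  set.seed(seed)
  null_max <- integer(n_perm)
  for (p in seq_len(n_perm)) {
    rows_a <- sample.int(n, n1)
    sup_p <- score(rows_a)
    if (length(sup_p) == 0) { null_max[p] <- 0L; next }
    ep <- cbind(chans[ei[sup_p, 1]], chans[ei[sup_p, 2]])
    cl <- .edge_clusters(ep, n_ch)
    null_max[p] <- max(lengths(cl))
  }

  clusters <- lapply(seq_along(comp), function(k) {
    rows <- comp[[k]]
    list(channels = sort(unique(c(obs_edges[rows, 1], obs_edges[rows, 2]))),
         edges = data.frame(a = obs_edges[rows, 1], b = obs_edges[rows, 2],
                            t = obs_t$t[supra][rows], stringsAsFactors = FALSE),
         size = length(rows),
         p = (sum(null_max >= length(rows)) + 1) / (n_perm + 1))
  })
  ord <- order(vapply(clusters, `[[`, integer(1), "size"), decreasing = TRUE)
  structure(list(channels = chans,
                 edge_t = obs_t$t, edge_df = obs_t$df, edge_index = ei,
                 p_con = p_con, var_type = var_type,
                 clusters = clusters[ord], null_max = null_max,
                 n_perm = n_perm, seed = seed),
            class = "fluprop_clustertest")
}

#' @export
print.fluprop_clustertest <- function(x, ...) {
  cat(sprintf("<cluster permutation test> %d channels, %d permutations (%s t)\n",
              length(x$channels), x$n_perm, x$var_type))
  if (!length(x$clusters)) {
    cat("no supra-threshold edges\n")
  } else {
    for (k in seq_along(x$clusters)) {
      cl <- x$clusters[[k]]
      cat(sprintf("cluster %d: %d edges over %d sensors, p = %.4g\n",
                  k, cl$size, length(cl$channels), cl$p))
    }
  }
  invisible(x)
}

#' Per-subject mean connectivity over a cluster's edges
#'
#' @param matrices list of subject connectivity matrices.
#' @param cluster a cluster entry from \code{\link{cluster_permutation_test}}
#'   (a list with an \code{edges} data frame) or a two-column data frame of
#'   channel pairs.
#' @return numeric vector, one mean PLV per subject.
#' @export
cluster_mean_connectivity <- function(matrices, cluster) {
  edges <- if (is.list(cluster) && !is.null(cluster$edges)) cluster$edges else cluster
  if (NROW(edges) == 0) stop("empty cluster")
  vapply(matrices, function(m) {
    mean(mapply(function(a, b) m[a, b], as.character(edges[[1]]),
                as.character(edges[[2]])))
  }, numeric(1))
}
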