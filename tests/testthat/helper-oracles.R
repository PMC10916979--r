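# Independent brute-force oracles and tiny fixture builders shared by the suite.

# exact one-edit (substitution/insertion/deletion) relation on token vectors
edit1 <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la == lb) {
    sum(a != b) == 1
  } else if (abs(la - lb) == 1) {
    long <- if (la > lb) a else b
    short <- if (la > lb) b else a
    for (drop in seq_along(long)) {
      if (identical(long[-drop], short)) return(TRUE)
    }
    FALSE
  } else {
    FALSE
  }
}

brute_neighbors <- function(phoneme_strings) {
  toks <- strsplit(phoneme_strings, " ", fixed = TRUE)
  vapply(seq_along(toks), function(i) {
    sum(vapply(seq_along(toks)[-i], function(j) edit1(toks[[i]], toks[[j]]),
               logical(1)))
  }, integer(1))
}

# direct moment formulas
brute_moments <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m4 <- sum((x - m)^4) / n
  s <- sort(x)
  med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  c(mean = m, median = med, sd = sqrt(sum((x - m)^2) / (n - 1)),
    min = min(x), max = max(x),
    skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}

# Benjamini-Hochberg step-up, straight from the definition
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# shortest path length to root by iterative relaxation over the edge list
brute_depth <- function(edges, root) {
  nodes <- unique(c(edges$child, edges$parent, root))
  d <- setNames(rep(Inf, length(nodes)), nodes)
  d[root] <- 0
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      ch <- edges$child[k]; pa <- edges$parent[k]
      if (d[pa] + 1 < d[ch]) { d[ch] <- d[pa] + 1; changed <- TRUE }
    }
    if (!changed) break
  }
  d
}

# build a fluprop_lexicon from explicit columns
toy_lexicon <- function(form, phonemes = NA, log_freq_pm = NA,
                        familiarity = NA, imageability = NA) {
  df <- data.frame(form = form, phonemes = phonemes, log_freq_pm = log_freq_pm,
                   familiarity = familiarity, imageability = imageability,
                   stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  suppressMessages(load_lexicon(f))
}

chain_taxonomy <- function() {
  taxonomy(
    edges = data.frame(child = c("animal", "dog", "bulldog"),
                       parent = c("entity", "animal", "dog")),
    senses = data.frame(form = c("animal", "dog", "bulldog"),
                        node = c("animal", "dog", "bulldog")))
}

# small responses object from per-participant word lists
toy_responses <- function(words_by_pt, task = "semantic") {
  rows <- do.call(rbind, lapply(names(words_by_pt), function(id) {
    w <- words_by_pt[[id]]
    if (length(w) == 0) return(NULL)
    data.frame(participant_id = id, task = task, position = seq_along(w),
               word = w, stringsAsFactors = FALSE)
  }))
  fluprop:::as_responses(rows)
}

toy_participants <- function(ids, group = "HC") {
  fluprop:::as_participants(data.frame(
    participant_id = ids, group = group, sex = rep_len(c("F", "M"), length(ids)),
    age = seq(60, by = 1, length.out = length(ids)),
    education = rep(12, length(ids)), stringsAsFactors = FALSE))
}

# random taxonomy for property checks
random_taxonomy <- function(n_nodes, seed) {
  set.seed(seed)
  nodes <- c("entity", sprintf("n%03d", seq_len(n_nodes - 1)))
  parent <- vapply(2:n_nodes, function(i) nodes[sample.int(i - 1, 1)], character(1))
  edges <- data.frame(child = nodes[-1], parent = parent, stringsAsFactors = FALSE)
  senses <- data.frame(form = nodes[-1], node = nodes[-1], stringsAsFactors = FALSE)
  taxonomy(edges, senses)
}
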