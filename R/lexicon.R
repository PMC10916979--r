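#' Normalize a word form for lexicon lookup
#'
#' Lowercases, trims surrounding whitespace and strips the Spanish accent
#' marks that dominate transcript/lexicon mismatches. The original form is
#' left untouched wherever the package stores raw responses.
#'
#' @param x character vector of word forms.
#' @return character vector of normalized lookup keys.
#' @export
normalize_form <- function(x) {
  x <- tolower(trimws(as.character(x)))
  chartr("áéíóúüñ", "aeiouun", x)
}

# Map phoneme symbols (space-separated in the input) to one character each so
# sequences become plain strings and neighbor hashing stays O(V * L).
.encode_phonemes <- function(phoneme_strings) {
  toks <- strsplit(phoneme_strings, "[[:space:]]+")
  toks <- lapply(toks, function(t) t[nzchar(t)])
  symbols <- unique(unlist(toks))
  pool <- c(intToUtf8(33:126, multiple = TRUE), intToUtf8(161:1500, multiple = TRUE))
  if (length(symbols) > length(pool)) stop("phoneme inventory too large to encode")
  key <- setNames(pool[seq_along(symbols)], symbols)
  enc <- vapply(toks, function(t) {
    if (length(t) == 0) NA_character_ else paste(key[t], collapse = "")
  }, character(1))
  list(encoded = enc, key = key, lengths = lengths(toks))
}

# Neighborhood counts for every sequence at once. Two sequences are neighbors
# iff they differ by exactly one substitution, insertion or deletion.
# Substitutions: sequences sharing a position-wildcarded key differ only at
# that position (or are identical). Insertions/deletions: hash each
# sequence's distinct single-deletion strings.
.neighborhood_all <- function(enc) {
  ok <- !is.na(enc) & nzchar(enc)
  out <- rep(NA_integer_, length(enc))
  if (!any(ok)) return(out)
  s <- enc[ok]
  L <- nchar(s)
  # word count per distinct sequence
  cnt <- table(s)
  mult <- as.integer(cnt[s]) # words sharing this exact sequence (incl. self)

  wc_keys <- character(0); wc_val <- integer(0)
  del_of <- vector("list", length(s)) # distinct deletion strings per word
  for (p in seq_len(max(L))) {
    has <- L >= p
    k <- paste0(substr(s[has], 1, p - 1), "\x01", substring(s[has], p + 1))
    wc_keys <- c(wc_keys, k)
    wc_val <- c(wc_val, rep(1L, sum(has)))
    d <- paste0(substr(s[has], 1, p - 1), substring(s[has], p + 1))
    idx <- which(has)
    for (j in seq_along(idx)) del_of[[idx[j]]] <- c(del_of[[idx[j]]], d[j])
  }
  wc_tab <- rowsum(wc_val, wc_keys)
  wc_count <- setNames(as.integer(wc_tab[, 1]), rownames(wc_tab))

  del_of <- lapply(del_of, unique)
  # words whose single-deletion set contains a given string
  all_del <- unlist(del_of)
  del_mult <- rep(1L, length(all_del))
  dd <- rowsum(del_mult, all_del)
  del_count <- setNames(as.integer(dd[, 1]), rownames(dd))
  seq_count <- setNames(as.integer(cnt), names(cnt))

  res <- integer(length(s))
  for (i in seq_along(s)) {
    li <- L[i]
    keys <- paste0(substr(rep(s[i], li), 1, seq_len(li) - 1), "\x01",
                   substring(rep(s[i], li), seq_len(li) + 1))
    sub_n <- sum(wc_count[keys]) - li * mult[i]
    ins_n <- del_count[s[i]]
    if (is.na(ins_n)) ins_n <- 0L
    ds <- del_of[[i]]
    del_n <- sum(seq_count[ds], na.rm = TRUE)
    res[i] <- as.integer(sub_n + ins_n + del_n)
  }
  out[ok] <- res
  out
}

.as_lexicon <- function(df) {
  stopifnot(is.data.frame(df), "form" %in% names(df))
  for (col in c("phonemes", "log_freq_pm", "familiarity", "imageability")) {
    if (!col %in% names(df)) df[[col]] <- NA
  }
  df$form <- normalize_form(df$form)
  if (any(!nzchar(df$form))) stop("lexicon contains empty word forms")
  dup <- duplicated(df$form)
  if (any(dup)) {
    warning(sprintf("lexicon: %d duplicated form(s) collapsed to first occurrence (e.g. '%s')",
                    sum(dup), df$form[dup][1]))
    df <- df[!dup, , drop = FALSE]
  }
  df$phonemes <- as.character(df$phonemes)
  df$phonemes[!is.na(df$phonemes) & !nzchar(trimws(df$phonemes))] <- NA
  for (col in c("log_freq_pm", "familiarity", "imageability")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  for (col in c("familiarity", "imageability")) {
    bad <- !is.na(df[[col]]) & (df[[col]] < 1 | df[[col]] > 7)
    if (any(bad)) stop(sprintf("%s outside [1, 7] for %d entries", col, sum(bad)))
  }
  # neighborhood basis: phoneme sequence when present, else graphemes
  no_ph <- is.na(df$phonemes)
  basis <- df$phonemes
  if (any(no_ph)) {
    message(sprintf("lexicon: %d entries lack phonemes; neighborhood/length fall back to graphemes",
                    sum(no_ph)))
    basis[no_ph] <- vapply(strsplit(df$form[no_ph], ""), paste, character(1), collapse = " ")
  }
  encd <- .encode_phonemes(basis)
  df$length <- ifelse(is.na(basis), NA_integer_, encd$lengths)
  df$neighborhood <- .neighborhood_all(encd$encoded)
  rownames(df) <- NULL
  structure(df[, c("form", "phonemes", "log_freq_pm", "familiarity",
                   "imageability", "length", "neighborhood")],
            encoded = encd$encoded,
            class = c("fluprop_lexicon", "data.frame"))
}

#' Load a psycholinguistic lexicon from delimited text
#'
#' Reads a UTF-8 TSV/CSV with columns \code{form}, \code{phonemes}
#' (space-separated symbols), \code{log_freq_pm} (log10 frequency per
#' million), \code{familiarity} and \code{imageability} (both on 1--7 rating
#' scales). Column names in the file can be remapped through \code{dialect}
#' so database exports (e.g. EsPal-style tables) load without editing.
#' Duplicate forms collapse to the first occurrence with a warning; absent
#' columns yield missing values. Phoneme length and phonological neighborhood
#' are precomputed for every entry on load.
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   \code{c(form = "word", log_freq_pm = "log_frq")}.
#' @param sep field separator; defaults to tab for \code{.tsv} files and
#'   comma for \code{.csv}.
#' @return a \code{fluprop_lexicon} data frame, one row per unique form.
#' @export
load_lexicon <- function(path, dialect = NULL, sep = NULL) {
  if (!file.exists(path)) stop("cannot read lexicon file: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""), fileEncoding = "UTF-8")
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      if (dialect[[canon]] %in% names(df)) {
        names(df)[names(df) == dialect[[canon]]] <- canon
      }
    }
  }
  if (!"form" %in% names(df)) stop("lexicon file has no 'form' column")
  .as_lexicon(df)
}

#' @export
print.fluprop_lexicon <- function(x, ...) {
  cat(sprintf("<fluprop_lexicon> %d entries; %d with phonemes, %d with frequency\n",
              nrow(x), sum(!is.na(x$phonemes)), sum(!is.na(x$log_freq_pm))))
  print(head(as.data.frame(x), 4))
  invisible(x)
}

#' Construct a hypernym taxonomy
#'
#' A taxonomy is a rooted acyclic graph of concept nodes with child-to-parent
#' (hyponym-to-hypernym) edges, plus a sense map from word forms to nodes.
#' Every node must reach the root (canonically \code{"entity"}). Node depths
#' (shortest hypernym-path length in edges to the root) are computed on
#' construction.
#'
#' @param edges data frame with columns \code{child}, \code{parent}.
#' @param senses data frame with columns \code{form}, \code{node}; a form may
#'   map to several nodes (polysemy).
#' @param root root node identifier.
#' @return a \code{fluprop_taxonomy} object.
#' @export
taxonomy <- function(edges, senses, root = "entity") {
  stopifnot(all(c("child", "parent") %in% names(edges)),
            all(c("form", "node") %in% names(senses)))
  edges$child <- as.character(edges$child)
  edges$parent <- as.character(edges$parent)
  nodes <- unique(c(edges$child, edges$parent, root))
  g <- igraph::graph_from_edgelist(as.matrix(edges[, c("child", "parent")]), directed = TRUE)
  missing_nodes <- setdiff(nodes, igraph::V(g)$name)
  if (length(missing_nodes)) g <- igraph::add_vertices(g, length(missing_nodes), name = missing_nodes)
  d <- igraph::distances(g, v = nodes, to = root, mode = "out")[, 1]
  if (any(!is.finite(d))) {
    stop("taxonomy: ", sum(!is.finite(d)), " node(s) cannot reach root '", root, "'")
  }
  senses$form <- normalize_form(senses$form)
  senses$node <- as.character(senses$node)
  unknown <- setdiff(senses$node, nodes)
  if (length(unknown)) stop("taxonomy: senses refer to unknown nodes: ",
                            paste(head(unknown, 5), collapse = ", "))
  depth <- setNames(as.integer(d), nodes)
  structure(list(nodes = nodes, edges = edges, root = root,
                 depth = depth, senses = split(senses$node, senses$form)),
            class = "fluprop_taxonomy")
}

#' Load a taxonomy from edge-list and sense files
#'
#' @param edges_path two-column delimited file \code{child<TAB>parent}.
#' @param senses_path two-column delimited file \code{form<TAB>node}.
#' @param root root node identifier.
#' @inherit taxonomy return
#' @export
load_taxonomy <- function(edges_path, senses_path, root = "entity") {
  ed <- read.delim(edges_path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  se <- read.delim(senses_path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  taxonomy(ed, se, root = root)
}

#' @export
print.fluprop_taxonomy <- function(x, ...) {
  cat(sprintf("<fluprop_taxonomy> %d nodes (root '%s', max depth %d), %d word senses\n",
              length(x$nodes), x$root, max(x$depth), length(x$senses)))
  invisible(x)
}

#' Semantic granularity of a word
#'
#' Granularity quantifies conceptual specificity as the number of edges on
#' the shortest hypernym path from a word's node to the taxonomy root
#' (\code{"entity"}): direct children of the root score 1, more specific
#' concepts score higher. Polysemous forms take the minimum over their
#' senses; forms with no sense return \code{NA}.
#'
#' @param form word form (normalized internally).
#' @param taxonomy a \code{fluprop_taxonomy}.
#' @param senses how to resolve polysemy: minimum depth (default), maximum,
#'   or the first listed sense.
#' @return non-negative integer depth, or \code{NA} if the form is unknown.
#' @export
granularity <- function(form, taxonomy, senses = c("min", "max", "first")) {
  senses <- match.arg(senses)
  stopifnot(inherits(taxonomy, "fluprop_taxonomy"))
  nd <- taxonomy$senses[[normalize_form(form)]]
  if (is.null(nd)) return(NA_integer_)
  d <- taxonomy$depth[nd]
  as.integer(switch(senses, min = min(d), max = max(d), first = d[1]))
}

#' Phonological neighborhood size of a lexicon word
#'
#' Counts lexicon entries (excluding the word itself) whose phoneme sequence
#' differs from the target's by exactly one substitution, insertion or
#' deletion (no transpositions). Entries without a phoneme sequence are
#' compared on graphemes (announced once at lexicon construction).
#'
#' @param form word form; must be present in the lexicon.
#' @param lexicon a \code{fluprop_lexicon}.
#' @return non-negative integer count, or \code{NA} when the form is absent
#'   or has no sequence.
#' @export
phonological_neighborhood <- function(form, lexicon) {
  stopifnot(inherits(lexicon, "fluprop_lexicon"))
  i <- match(normalize_form(form), lexicon$form)
  if (is.na(i)) return(NA_integer_)
  lexicon$neighborhood[i]
}

#' Assemble the six word properties for one form
#'
#' Looks up frequency, familiarity and imageability in the lexicon, phoneme
#' length and phonological neighborhood from the lexicon's sequences, and
#' granularity from the taxonomy. Any unavailable value is missing
#' per-property (an out-of-lexicon word that is in the taxonomy still gets a
#' granularity). Never errors on arbitrary strings.
#'
#' @param form word form.
#' @param lexicon a \code{fluprop_lexicon}.
#' @param taxonomy a \code{fluprop_taxonomy}.
#' @return one-row data frame with columns \code{frequency}, \code{granularity},
#'   \code{neighborhood}, \code{length}, \code{familiarity}, \code{imageability}.
#' @export
word_properties <- function(form, lexicon, taxonomy) {
  key <- normalize_form(form)
  i <- match(key, lexicon$form)
  data.frame(
    form = key,
    frequency = if (is.na(i)) NA_real_ else lexicon$log_freq_pm[i],
    granularity = granularity(key, taxonomy),
    neighborhood = if (is.na(i)) NA_integer_ else lexicon$neighborhood[i],
    length = if (is.na(i)) NA_integer_ else lexicon$length[i],
    familiarity = if (is.na(i)) NA_real_ else lexicon$familiarity[i],
    imageability = if (is.na(i)) NA_real_ else lexicon$imageability[i],
    stringsAsFactors = FALSE
  )
}

# Full word -> six-property table for a lexicon (featurization fast path).
.property_table <- function(lexicon, taxonomy) {
  gran <- rep(NA_integer_, nrow(lexicon))
  hit <- lexicon$form %in% names(taxonomy$senses)
  gran[hit] <- vapply(lexicon$form[hit],
                      function(f) as.integer(min(taxonomy$depth[taxonomy$senses[[f]]])),
                      integer(1))
  data.frame(form = lexicon$form,
             frequency = lexicon$log_freq_pm,
             granularity = gran,
             neighborhood = lexicon$neighborhood,
             length = lexicon$length,
             familiarity = lexicon$familiarity,
             imageability = lexicon$imageability,
             stringsAsFactors = FALSE)
}

#' Names of the six word properties
#' @return character vector of property names in canonical order.
#' @export
property_names <- function() {
  c("frequency", "granularity", "neighborhood", "length", "familiarity", "imageability")
}
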