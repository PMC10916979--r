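#' Load fluency transcripts and participant metadata
#'
#' Transcripts are long-format delimited text with columns
#' \code{participant_id}, \code{task} (\code{phonemic} or \code{semantic}),
#' \code{position} (1-based utterance index) and \code{word}. Metadata mirrors
#' the usual cohort table: \code{participant_id}, \code{group} (one of
#' \code{AD}, \code{bvFTD}, \code{HC}), \code{sex}, \code{age},
#' \code{education}, and optionally \code{handedness}, \code{moca},
#' \code{ifs}. Every transcript participant must appear in the metadata.
#'
#' @param path transcript file (TSV).
#' @param metadata_path participant metadata file (TSV).
#' @return list with \code{responses} (a \code{fluprop_responses} data frame,
#'   validity unset) and \code{participants} (a \code{fluprop_participants}
#'   data frame).
#' @export
load_transcripts <- function(path, metadata_path) {
  tr <- read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                   na.strings = c("NA"))
  md <- read.delim(metadata_path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("participant_id", "task", "position", "word")
  if (!all(need %in% names(tr))) {
    stop("transcript file must have columns: ", paste(need, collapse = ", "))
  }
  list(responses = as_responses(tr), participants = as_participants(md, tr))
}

as_participants <- function(md, tr = NULL) {
  need <- c("participant_id", "group", "sex", "age", "education")
  if (!all(need %in% names(md))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  md$participant_id <- as.character(md$participant_id)
  if (anyDuplicated(md$participant_id)) stop("duplicate participant ids in metadata")
  bad_grp <- setdiff(unique(md$group), c("AD", "bvFTD", "HC"))
  if (length(bad_grp)) stop("unknown group label(s): ", paste(bad_grp, collapse = ", "))
  if (any(md$age < 0, na.rm = TRUE) || any(md$education < 0, na.rm = TRUE)) {
    stop("age and education must be non-negative")
  }
  if (!is.null(tr)) {
    orphan <- setdiff(unique(as.character(tr$participant_id)), md$participant_id)
    if (length(orphan)) {
      stop("transcript participants missing from metadata: ",
           paste(orphan, collapse = ", "))
    }
  }
  structure(md, class = c("fluprop_participants", "data.frame"))
}

as_responses <- function(tr) {
  tr$participant_id <- as.character(tr$participant_id)
  bad_task <- setdiff(unique(tr$task), c("phonemic", "semantic"))
  if (length(bad_task)) stop("unknown task label(s): ", paste(bad_task, collapse = ", "))
  tr <- tr[order(tr$participant_id, tr$task, tr$position), , drop = FALSE]
  key <- interaction(tr$participant_id, tr$task, drop = TRUE)
  ok <- tapply(tr$position, key, function(p) identical(as.integer(p), seq_along(p)))
  if (any(!ok)) {
    stop("positions are not consecutive from 1 within participant x task for: ",
         paste(names(ok)[!ok][1:min(3, sum(!ok))], collapse = ", "))
  }
  out <- data.frame(participant_id = tr$participant_id, task = tr$task,
                    position = as.integer(tr$position),
                    raw = as.character(tr$word),
                    normalized = normalize_form(tr$word),
                    valid = NA, invalid_reason = NA_character_,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("fluprop_responses", "data.frame"))
}

#' @export
print.fluprop_responses <- function(x, ...) {
  cat(sprintf("<fluprop_responses> %d responses, %d participants; validity %s\n",
              nrow(x), length(unique(x$participant_id)),
              if (all(is.na(x$valid))) "unset" else
                sprintf("flagged (%d invalid)", sum(!x$valid, na.rm = TRUE))))
  print(head(as.data.frame(x), 4))
  invisible(x)
}

#' Flag response validity
#'
#' Applies the standard fluency scoring rules: exact normalized duplicates
#' after the first occurrence are repetitions; tokens containing digits are
#' rule violations; tokens on a user-supplied invalid list (proper names,
#' same-family/morphological variants -- judgments that are adjudicated by
#' examiners, not automated here) are listed-invalid; unintelligible markers
#' are flagged and excluded from all downstream word-property analysis.
#' Re-flagging already-flagged responses recomputes from scratch, so the
#' operation is idempotent.
#'
#' @param responses a \code{fluprop_responses} data frame.
#' @param invalid_words character vector of study-specific invalid tokens
#'   (compared on normalized forms).
#' @param unintelligible_markers tokens marking unintelligible speech.
#' @return the responses with \code{valid} and \code{invalid_reason} set.
#' @export
flag_validity <- function(responses, invalid_words = character(0),
                          unintelligible_markers = c("<unk>", "xxx", "???")) {
  stopifnot(inherits(responses, "fluprop_responses"))
  invalid_words <- normalize_form(invalid_words)
  reason <- rep(NA_character_, nrow(responses))
  unint <- responses$normalized %in% normalize_form(unintelligible_markers)
  digits <- grepl("[0-9]", responses$normalized)
  listed <- responses$normalized %in% invalid_words
  ord <- order(responses$participant_id, responses$task, responses$position)
  responses <- responses[ord, , drop = FALSE]
  unint <- unint[ord]; digits <- digits[ord]; listed <- listed[ord]
  key <- interaction(responses$participant_id, responses$task, drop = TRUE)
  rep_flag <- as.logical(ave(responses$normalized, key,
                             FUN = function(z) duplicated(z)))
  # precedence: unintelligible > digits > listed > repetition
  reason[rep_flag] <- "repetition"
  reason[listed] <- "listed_invalid"
  reason[digits] <- "rule_violation"
  reason[unint] <- "unintelligible"
  responses$invalid_reason <- reason
  responses$valid <- is.na(reason)
  responses
}

#' Count valid responses for one participant and task
#'
#' The standard fluency score: the number of responses complying with task
#' instructions.
#'
#' @param responses flagged \code{fluprop_responses}.
#' @param participant_id participant identifier.
#' @param task \code{"phonemic"} or \code{"semantic"}.
#' @return non-negative integer count.
#' @export
valid_count <- function(responses, participant_id, task) {
  stopifnot(inherits(responses, "fluprop_responses"))
  if (any(is.na(responses$valid))) stop("validity not flagged; run flag_validity() first")
  sel <- responses$participant_id == participant_id & responses$task == task
  if (!any(responses$participant_id == participant_id)) {
    stop("unknown participant: ", participant_id)
  }
  sum(responses$valid[sel])
}

# valid counts for all participant x task pairs (participants define rows; a
# missing task list counts 0)
.valid_count_table <- function(responses, participants) {
  ids <- participants$participant_id
  out <- data.frame(participant_id = ids,
                    phonemic = 0L, semantic = 0L, stringsAsFactors = FALSE)
  for (task in c("phonemic", "semantic")) {
    v <- tapply(responses$valid[responses$task == task],
                responses$participant_id[responses$task == task], sum)
    out[[task]] <- ifelse(ids %in% names(v), as.integer(v[ids]), 0L)
  }
  out
}
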