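# Corpus I/O, tokenization and sentence segmentation.
#
# A corpus is a directory of UTF-8 .txt files (one letter per file) plus a
# metadata CSV with columns id, date, period and optionally addressee,
# source. In memory a corpus is a data.frame with one row per letter.

#' Construct a single letter record
#'
#' @param id Letter identifier (unique within a corpus).
#' @param text Raw letter text (UTF-8); must be non-empty after stripping
#'   whitespace.
#' @param date Letter date, `Date` or ISO-8601 string; may be `NA`.
#' @param period Period label (e.g. `"acute_mania"`).
#' @param addressee,source Optional provenance strings.
#' @return One-row data.frame with columns id, text, date, period,
#'   addressee, source.
#' @export
letter_record <- function(id, text, date = NA, period, addressee = NA,
                          source = NA) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) stop("letter '", id, "': text is empty")
  date <- if (is.na(date[1L])) as.Date(NA) else as.Date(date)
  data.frame(id = id, text = text, date = date, period = period,
             addressee = as.character(addressee),
             source = as.character(source),
             stringsAsFactors = FALSE)
}

#' Load a letter corpus from disk
#'
#' Reads one `.txt` file per metadata row and returns letters sorted by date
#' then id. Every metadata row must match exactly one file named `<id>.txt`.
#'
#' @param directory Directory containing the letter files.
#' @param metadata Path to a CSV with header `id,date,period` (optionally
#'   `addressee,source`).
#' @param periods Optional character vector of admissible period labels; if
#'   given, any other label is an error.
#' @return data.frame with columns id, text, date, period, addressee, source,
#'   sorted by date then id.
#' @export
load_corpus <- function(directory, metadata, periods = NULL) {
  if (!dir.exists(directory)) stop("corpus directory not found: ", directory)
  meta <- utils::read.csv(metadata, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("id", "date", "period")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(meta$id))
    stop("duplicate letter id(s) in metadata: ",
         paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "))
  dates <- as.Date(meta$date, format = "%Y-%m-%d")
  bad <- !is.na(meta$date) & nzchar(meta$date) & is.na(dates)
  if (any(bad))
    stop("unparseable date for id(s): ", paste(meta$id[bad], collapse = ", "))
  if (!is.null(periods)) {
    unknown <- setdiff(unique(meta$period), periods)
    if (length(unknown))
      stop("period label(s) not in configuration: ",
           paste(unknown, collapse = ", "))
  }
  paths <- file.path(directory, paste0(meta$id, ".txt"))
  absent <- !file.exists(paths)
  if (any(absent))
    stop("no letter file for id(s): ", paste(meta$id[absent], collapse = ", "))
  texts <- vapply(paths, function(p)
    paste(readLines(p, encoding = "UTF-8", warn = FALSE), collapse = "\n"),
    character(1L))
  empty <- !nzchar(trimws(texts))
  if (any(empty))
    stop("empty letter file for id(s): ", paste(meta$id[empty], collapse = ", "))
  out <- data.frame(id = meta$id, text = unname(texts), date = dates,
                    period = meta$period,
                    addressee = if ("addressee" %in% names(meta)) meta$addressee else NA_character_,
                    source = if ("source" %in% names(meta)) meta$source else NA_character_,
                    stringsAsFactors = FALSE)
  out[order(out$date, out$id), , drop = FALSE]
}

#' Write a corpus to disk
#'
#' Inverse of [load_corpus()]: one `.txt` file per letter plus
#' `metadata.csv`. `load_corpus(write_corpus(x))` is the identity on
#' (id, text, date, period).
#'
#' @param corpus data.frame as returned by [load_corpus()].
#' @param directory Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_corpus <- function(corpus, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(corpus))) {
    writeLines(corpus$text[i], file.path(directory, paste0(corpus$id[i], ".txt")),
               useBytes = TRUE)
  }
  meta <- corpus[, c("id", "date", "period", "addressee", "source")]
  meta$date <- format(meta$date, "%Y-%m-%d")
  utils::write.csv(meta, file.path(directory, "metadata.csv"),
                   row.names = FALSE, na = "")
  invisible(directory)
}

# Word tokens: alphanumeric runs, optionally joined by internal apostrophes
# or hyphens ("Pitt's", "to-morrow" are single tokens). Punctuation is never
# a word token; numerals are.
.token_regex <- "[[:alnum:]]+(?:['’-][[:alnum:]]+)*"

#' Tokenize text into word tokens
#'
#' Splits on whitespace and punctuation. Apostrophe-internal forms and
#' hyphenated words are single tokens; numerals count as word tokens;
#' punctuation marks are excluded.
#'
#' @param text Non-empty character scalar.
#' @return List with `tokens` (case-preserving) and `tokens_fold`
#'   (case-folded, for all lexical type counts).
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) stop("cannot tokenize empty text")
  m <- regmatches(text, gregexpr(.token_regex, text, perl = TRUE))[[1L]]
  list(tokens = m, tokens_fold = tolower(m))
}

#' Segment text into sentences as token index ranges
#'
#' The modern dialect treats `.`, `!` and `?` as sentence-terminal; the
#' historical dialect additionally treats `;` and `:` as sentence-terminal
#' (period-era orthography used them to mark sentence boundaries). Trailing
#' material without a terminator forms a final sentence. Ranges are 0-based
#' and half-open over the token sequence and partition it exactly.
#'
#' @param text Non-empty character scalar.
#' @param dialect `"modern"` (default) or `"historical"`.
#' @return data.frame with integer columns `start`, `end` (0-based,
#'   half-open token indices).
#' @export
segment_sentences <- function(text, dialect = c("modern", "historical")) {
  dialect <- match.arg(dialect)
  term <- if (dialect == "modern") "[.!?]+" else "[.!?;:]+"
  pieces <- strsplit(text, term, perl = TRUE)[[1L]]
  counts <- vapply(pieces, function(p) {
    if (!nzchar(trimws(p))) return(0L)
    length(regmatches(p, gregexpr(.token_regex, p, perl = TRUE))[[1L]])
  }, integer(1L), USE.NAMES = FALSE)
  counts <- counts[counts > 0L]
  if (!length(counts)) stop("text contains no word tokens")
  ends <- cumsum(counts)
  data.frame(start = c(0L, ends[-length(ends)]), end = ends)
}

#' Tokenize and segment one letter
#'
#' @param letter One-row data.frame (see [letter_record()]) or a character
#'   scalar of text (then `id` must be given).
#' @param dialect Sentence-segmentation dialect, see [segment_sentences()].
#' @param id Letter id when `letter` is raw text.
#' @return Object of class `tokenized_letter`: list with `letter_id`,
#'   `tokens`, `tokens_fold`, `sentences` (0-based half-open ranges) and
#'   `pos` (NA until [pos_tag()] is applied).
#' @export
tokenize_letter <- function(letter, dialect = c("modern", "historical"),
                            id = NULL) {
  dialect <- match.arg(dialect)
  if (is.data.frame(letter)) {
    id <- letter$id[1L]
    text <- letter$text[1L]
  } else {
    text <- letter
    if (is.null(id)) id <- "letter"
  }
  tk <- tokenize(text)
  sent <- segment_sentences(text, dialect)
  stopifnot(sum(sent$end - sent$start) == length(tk$tokens))
  structure(list(letter_id = id, tokens = tk$tokens,
                 tokens_fold = tk$tokens_fold, sentences = sent,
                 pos = rep(NA_character_, length(tk$tokens))),
            class = "tokenized_letter")
}

#' @export
print.tokenized_letter <- function(x, ...) {
  cat("<tokenized_letter>", x$letter_id, "-", length(x$tokens), "tokens,",
      nrow(x$sentences), "sentences\n")
  invisible(x)
}

#' Export tokenized letters as JSON lines
#'
#' One JSON object per line per letter, for debugging and audit.
#'
#' @param tokenized List of `tokenized_letter` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tokenized_jsonl <- function(tokenized, path) {
  lines <- vapply(tokenized, function(tl) {
    jsonlite::toJSON(list(letter_id = tl$letter_id, tokens = tl$tokens,
                          sentences = tl$sentences, pos = tl$pos),
                     auto_unbox = TRUE)
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
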