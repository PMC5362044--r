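# Textual features: lexical variation, vocabulary richness and
# information-theoretic measures, computed per letter over case-folded word
# tokens. Length-sensitive measures (LogTTR, HL, PHL) are computed as mean
# segmental statistics over consecutive non-overlapping 10-word blocks, with
# a trailing partial block discarded.

.LEXICAL_TAGS <- c("NOUN", "VERB", "ADJ", "ADV")

#' Lexical variation profile (LV, NV, ADJV, MODV, ADVV, CVV, VV)
#'
#' Ratios of word-type counts within the lexical (content-word) classes to
#' the number of lexical words. Types are counted over case-folded tokens.
#'
#' * `LV`  = lexical word types / lexical words
#' * `NV`  = noun types / lexical words
#' * `ADJV` = adjective types / lexical words
#' * `ADVV` = adverb types / lexical words
#' * `MODV` = (adjective types + adverb types) / lexical words
#' * `VV`  = lexical verb types / lexical words
#' * `CVV` = lexical verb types / sqrt(2 x verb tokens)
#'
#' With zero verb tokens, `VV` and `CVV` are defined as 0.
#'
#' @param tokens_fold Case-folded word tokens.
#' @param pos Coarse POS tags (one per token).
#' @return Named numeric vector with the seven ratios.
#' @export
lexical_variation_profile <- function(tokens_fold, pos) {
  stopifnot(length(tokens_fold) == length(pos))
  lex <- pos %in% .LEXICAL_TAGS
  n_lex <- sum(lex)
  if (n_lex == 0L) stop("no lexical words")
  types_of <- function(keep) length(unique(tokens_fold[keep]))
  n_verb_tok <- sum(pos == "VERB")
  verb_types <- types_of(pos == "VERB")
  adj_types <- types_of(pos == "ADJ")
  adv_types <- types_of(pos == "ADV")
  c(LV = types_of(lex) / n_lex,
    NV = types_of(pos == "NOUN") / n_lex,
    ADJV = adj_types / n_lex,
    MODV = (adj_types + adv_types) / n_lex,
    ADVV = adv_types / n_lex,
    CVV = if (n_verb_tok == 0L) 0 else verb_types / sqrt(2 * n_verb_tok),
    VV = if (n_verb_tok == 0L) 0 else verb_types / n_lex)
}

#' Mean of a block statistic over sequential 10-word segments
#'
#' Applies `block_fn` to consecutive non-overlapping blocks of
#' `block_size` tokens, discards a trailing partial block, and returns the
#' arithmetic mean. This removes the document-length sensitivity of
#' type/token-style statistics.
#'
#' @param tokens Token vector (case-folded for lexical statistics).
#' @param block_fn Function taking a block of tokens and returning a scalar.
#' @param block_size Tokens per block (default 10).
#' @return Mean of the per-block values.
#' @export
segmental_mean <- function(tokens, block_fn, block_size = 10L) {
  n_blocks <- length(tokens) %/% block_size
  if (n_blocks < 1L) stop("letter shorter than one block")
  vals <- vapply(seq_len(n_blocks), function(b) {
    block <- tokens[((b - 1L) * block_size + 1L):(b * block_size)]
    as.numeric(block_fn(block))
  }, numeric(1L))
  mean(vals)
}

#' Bilogarithmic type/token ratio of one block
#'
#' `log10(types) / log10(tokens)` for a block of at least 2 tokens. The
#' letter-level feature (MS LogTTR) is the segmental mean of this statistic
#' over 10-word blocks.
#'
#' @param block Token block (length >= 2).
#' @return Ratio in (0, 1].
#' @export
log_ttr <- function(block) {
  stopifnot(length(block) >= 2L)
  log10(length(unique(block))) / log10(length(block))
}

#' Mean segmental bilogarithmic type/token ratio
#' @param tokens_fold Case-folded tokens (>= 10).
#' @return MS LogTTR.
#' @export
ms_log_ttr <- function(tokens_fold) segmental_mean(tokens_fold, log_ttr)

#' Hapax statistics: HL, PHL and DL/V
#'
#' * `HL`: segmental mean over 10-word blocks of the number of tokens
#'   occurring exactly once within the block (hapax legomena).
#' * `PHL`: segmental mean of the number of adjacent token bigrams occurring
#'   exactly once within the block (pair hapax legomena; at most 9 per
#'   10-word block).
#' * `DL_V`: dis legomena over vocabulary — types occurring exactly twice in
#'   the whole letter, divided by the number of word types V.
#'
#' @param tokens_fold Case-folded tokens (>= 10 for HL/PHL).
#' @return Named numeric vector `HL`, `PHL`, `DL_V`.
#' @export
hapax_profile <- function(tokens_fold) {
  hl_block <- function(block) sum(table(block) == 1L)
  phl_block <- function(block) {
    bi <- paste(block[-length(block)], block[-1L])
    sum(table(bi) == 1L)
  }
  c(HL = segmental_mean(tokens_fold, hl_block),
    PHL = segmental_mean(tokens_fold, phl_block),
    DL_V = dis_legomena_ratio(tokens_fold))
}

#' Dis legomena over vocabulary
#'
#' Count of word types occurring exactly twice in the whole letter, divided
#' by the number of word types V. Unlike HL/PHL this is a whole-letter
#' statistic and needs no minimum length.
#'
#' @param tokens_fold Case-folded tokens (>= 1).
#' @return Ratio in \[0, 1\].
#' @export
dis_legomena_ratio <- function(tokens_fold) {
  stopifnot(length(tokens_fold) >= 1L)
  tab <- table(tokens_fold)
  sum(tab == 2L) / length(tab)
}

#' Brunet's vocabulary-richness index W
#'
#' `W = N^(V^-0.165)` with N word tokens and V word types. Lower values
#' indicate a richer vocabulary (more distinct word types at a given
#' length); W is close to length-invariant for natural text.
#'
#' @param n_tokens Word-token count N (>= 1).
#' @param n_types Word-type count V (1 <= V <= N).
#' @return Brunet's W (> 0).
#' @export
brunets_w <- function(n_tokens, n_types) {
  stopifnot(n_tokens >= 1, n_types >= 1)
  if (n_types > n_tokens) stop("type count exceeds token count")
  n_tokens^(n_types^(-0.165))
}

#' Simpson's lexical diversity index D
#'
#' The probability that two word tokens drawn at random from the letter
#' without replacement are the same type:
#' `D = sum_i n_i (n_i - 1) / (N (N - 1))`. Higher D means more repetition.
#'
#' @param tokens_fold Case-folded tokens (>= 2).
#' @return D in \[0, 1\].
#' @export
simpsons_d <- function(tokens_fold) {
  n <- length(tokens_fold)
  if (n < 2L) stop("Simpson's D requires at least 2 tokens")
  cnt <- as.numeric(table(tokens_fold))
  sum(cnt * (cnt - 1)) / (n * (n - 1))
}

#' Normalized Shannon entropy of the word-type distribution
#'
#' `H = -sum_i p_i log2 p_i / log2 V`, i.e. word entropy divided by its
#' maximum for the observed vocabulary of V types, so H lies in \[0, 1\];
#' a single-type letter has H = 0 by convention.
#'
#' @param tokens_fold Case-folded tokens (>= 1).
#' @return H in \[0, 1\].
#' @export
shannon_entropy <- function(tokens_fold) {
  stopifnot(length(tokens_fold) >= 1L)
  p <- as.numeric(table(tokens_fold)) / length(tokens_fold)
  if (length(p) == 1L) return(0)
  -sum(p * log2(p)) / log2(length(p))
}

#' zlib compression ratio of the letter text
#'
#' DEFLATE-compressed byte length of the UTF-8 encoded text divided by its
#' raw byte length, at zlib's standard compression level 6 (the default of
#' both R's `memCompress` and zlib). Lower values mean more redundant,
#' repetitive text.
#'
#' @param text Non-empty character scalar.
#' @return CR > 0.
#' @export
compression_ratio <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) stop("cannot compress empty text")
  raw_bytes <- charToRaw(enc2utf8(text))
  length(memCompress(raw_bytes, type = "gzip")) / length(raw_bytes)
}

#' Full textual profile (features 15-29) for one tagged letter
#'
#' @param tokenized A `tokenized_letter` with `pos` filled.
#' @param text The raw letter text (for the compression ratio).
#' @return Named numeric vector: LV, LogTTR, NV, ADJV, MODV, ADVV, CVV, VV,
#'   W, HL, PHL, D, DL_V, H, CR.
#' @export
textual_profile <- function(tokenized, text) {
  stopifnot(inherits(tokenized, "tokenized_letter"), !anyNA(tokenized$pos))
  tf <- tokenized$tokens_fold
  lv <- lexical_variation_profile(tf, tokenized$pos)
  hx <- hapax_profile(tf)
  out <- c(lv["LV"], LogTTR = ms_log_ttr(tf),
           lv[c("NV", "ADJV", "MODV", "ADVV", "CVV", "VV")],
           W = brunets_w(length(tf), length(unique(tf))),
           hx[c("HL", "PHL")], D = simpsons_d(tf), hx["DL_V"],
           H = shannon_entropy(tf), CR = compression_ratio(text))
  names(out) <- c("LV", "LogTTR", "NV", "ADJV", "MODV", "ADVV", "CVV", "VV",
                  "W", "HL", "PHL", "D", "DL_V", "H", "CR")
  out
}
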