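# Coarse part-of-speech tagging.
#
# The feature extractors only need the coarse tag set {NOUN, VERB, ADJ,
# ADV, OTHER}. Tags come either from a backend tagger or — for synthetic
# corpora — from ground truth supplied with the letter, which bypasses any
# backend. The built-in backend is a deterministic rule/lexicon tagger:
# closed-class function words map to OTHER, small open-class lexicons and
# suffix rules cover verbs, adjectives and adverbs, and the default tag is
# NOUN. It is intentionally simple and fully documented here; any other
# backend can be plugged in as a function(tokens) -> coarse tags.

.FUNCTION_WORDS <- c(
  "the", "a", "an", "this", "that", "these", "those", "some", "any", "no",
  "every", "each", "either", "neither", "both", "all", "such",
  "i", "you", "he", "she", "it", "we", "they", "me", "him", "her", "us",
  "them", "my", "your", "his", "its", "our", "their", "mine", "yours",
  "hers", "ours", "theirs", "myself", "yourself", "himself", "herself",
  "itself", "ourselves", "themselves", "who", "whom", "whose", "which",
  "what", "where", "when", "why", "how",
  "and", "but", "or", "nor", "for", "yet", "so", "if", "though", "although",
  "because", "while", "whereas", "unless", "until", "till", "since", "as",
  "than", "that", "whether", "lest",
  "of", "in", "on", "at", "to", "from", "by", "with", "without", "upon",
  "into", "onto", "over", "under", "above", "below", "between", "among",
  "through", "during", "before", "after", "against", "towards", "toward",
  "about", "concerning", "respecting", "per", "via", "within",
  "not", "there", "here", "then", "also", "too", "only", "just", "even",
  "o", "oh", "mr", "mrs", "sir", "madam", "lord", "lady", "dr", "st",
  "is", "am", "are", "was", "were", "be", "been", "being",
  "have", "has", "had", "having", "do", "does", "did", "doing", "done",
  "shall", "will", "should", "would", "may", "might", "must", "can",
  "could", "ought")

.VERB_LEMMAS <- c(
  "write", "wrote", "written", "receive", "send", "sent", "give", "gave",
  "given", "take", "took", "taken", "make", "made", "go", "went", "gone",
  "come", "came", "see", "saw", "seen", "know", "knew", "known", "think",
  "thought", "say", "said", "tell", "told", "find", "found", "believe",
  "desire", "wish", "hope", "trust", "remain", "appear", "seem", "approve",
  "consider", "propose", "intend", "expect", "order", "command", "direct",
  "acquaint", "inform", "express", "return", "attend", "continue", "prevent",
  "require", "answer", "agree", "consent", "judge", "examine", "read",
  "hear", "heard", "feel", "felt", "keep", "kept", "let", "put", "set",
  "bring", "brought", "leave", "left", "meet", "met", "speak", "spoke",
  "spoken", "stand", "stood", "understand", "understood")

.ADJ_WORDS <- c(
  "good", "great", "small", "little", "large", "long", "short", "high",
  "low", "new", "old", "young", "early", "late", "own", "same", "other",
  "last", "first", "next", "few", "many", "much", "more", "most", "less",
  "least", "best", "better", "worse", "worst", "true", "false", "right",
  "wrong", "happy", "glad", "sorry", "necessary", "proper", "present",
  "former", "royal", "able", "strong", "weak", "certain", "sure", "clear",
  "fit", "ready", "willing", "angry", "full", "whole", "private", "public")

.ADV_WORDS <- c(
  "very", "well", "soon", "now", "never", "always", "often", "again",
  "once", "twice", "rather", "quite", "almost", "already", "perhaps",
  "indeed", "therefore", "however", "thus", "hence", "moreover", "besides",
  "yesterday", "today", "tomorrow", "forthwith", "hereafter")

#' Built-in rule-based coarse POS tagger
#'
#' Deterministic lexicon + suffix tagger over the coarse tag set
#' \{NOUN, VERB, ADJ, ADV, OTHER\}: closed-class function words (articles,
#' pronouns, prepositions, conjunctions, auxiliaries) are OTHER; `-ly`
#' forms and a small adverb lexicon are ADV; common adjectives and
#' adjectival suffixes (`-ous`, `-ful`, `-ive`, `-able`, `-ible`, `-less`,
#' `-ish`) are ADJ; a verb lexicon, its `-s`/`-ed`/`-ing` inflections and
#' `-ize`/`-ise` stems are VERB; everything else — the open noun class —
#' is NOUN. Case-insensitive; numerals are OTHER.
#'
#' @param tokens Character vector of word tokens.
#' @return Character vector of coarse tags, same length as `tokens`.
#' @export
rule_tagger <- function(tokens) {
  w <- tolower(tokens)
  n <- length(w)
  tag <- rep("NOUN", n)
  tag[grepl("^[0-9]", w)] <- "OTHER"
  verb_forms <- unique(c(.VERB_LEMMAS,
                         paste0(.VERB_LEMMAS, "s"),
                         paste0(.VERB_LEMMAS, "ed"),
                         paste0(.VERB_LEMMAS, "d"),
                         paste0(.VERB_LEMMAS, "ing"),
                         paste0(sub("e$", "", .VERB_LEMMAS), "ing")))
  tag[w %in% verb_forms] <- "VERB"
  tag[grepl("(ize|ise|izes|ises|ized|ised|izing|ising)$", w)] <- "VERB"
  tag[w %in% .ADJ_WORDS |
        grepl("(ous|ful|ive|able|ible|less)$", w) |
        (grepl("ish$", w) & nchar(w) > 5L)] <- "ADJ"
  tag[w %in% .ADV_WORDS | (grepl("ly$", w) & nchar(w) > 3L)] <- "ADV"
  tag[w %in% .FUNCTION_WORDS] <- "OTHER"
  tag
}

#' Assign coarse POS tags to a tokenized letter
#'
#' Fills the `pos` slot with one tag per token. When `tags` is supplied
#' (the synthetic ground-truth path) the backend is bypassed and the tags
#' are passed through unchanged after validation.
#'
#' @param tokenized A `tokenized_letter`.
#' @param backend `"rules"` for the built-in [rule_tagger()], `"none"` to
#'   require ground-truth tags, or a function `tokens -> tags`.
#' @param tags Optional ground-truth tags (one per token).
#' @return The `tokenized_letter` with `pos` filled.
#' @export
pos_tag <- function(tokenized, backend = "rules", tags = NULL) {
  stopifnot(inherits(tokenized, "tokenized_letter"))
  n <- length(tokenized$tokens)
  if (!is.null(tags)) {
    if (length(tags) != n)
      stop("ground-truth tags length ", length(tags), " != ", n, " tokens")
    if (!all(tags %in% POS_TAGS))
      stop("unknown tag(s): ", paste(setdiff(tags, POS_TAGS), collapse = ", "))
    tokenized$pos <- tags
    return(tokenized)
  }
  tagger <- if (is.function(backend)) backend
  else if (identical(backend, "rules")) rule_tagger
  else if (identical(backend, "none"))
    stop("no tagging backend configured; supply ground-truth tags ",
         "(tags =) as the synthetic path does")
  else stop("unknown backend: ", backend)
  out <- tagger(tokenized$tokens)
  if (length(out) != n || !all(out %in% POS_TAGS))
    stop("backend returned invalid tags")
  tokenized$pos <- out
  tokenized
}
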