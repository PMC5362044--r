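# Syntactic complexity: production-unit counts and the 14 ratio features.
#
# Production units follow the standard second-language syntactic-complexity
# definitions: a clause is a structure with at least a subject and a finite
# verb; a T-unit is a main clause plus all attached or embedded subordinate
# material; a complex T-unit contains a dependent clause; a coordinate
# phrase is a phrase immediately before a coordinating conjunction; a
# complex nominal is a word sequence denoting a single concept (modified
# noun, nominal clause, gerund/infinitive subject). Counts come either from
# ground truth (the synthetic path) or from bracketed constituency trees
# supplied by an external parser; the tree-pattern queries live in
# parsetree.R.

#' Construct validated production-unit counts for one letter
#'
#' @param words,sentences,clauses,dependent_clauses,t_units,complex_t_units,coordinate_phrases,complex_nominals,verb_phrases
#'   Non-negative integer counts. `sentences >= 1`, `t_units >= 1`,
#'   `complex_t_units <= t_units`, `dependent_clauses <= clauses`.
#' @return Named list of class `parse_counts`.
#' @export
parse_counts <- function(words, sentences, clauses, dependent_clauses,
                         t_units, complex_t_units, coordinate_phrases,
                         complex_nominals, verb_phrases) {
  x <- list(words = words, sentences = sentences, clauses = clauses,
            dependent_clauses = dependent_clauses, t_units = t_units,
            complex_t_units = complex_t_units,
            coordinate_phrases = coordinate_phrases,
            complex_nominals = complex_nominals, verb_phrases = verb_phrases)
  v <- unlist(x)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  if (x$sentences < 1L) stop("sentences must be >= 1")
  if (x$t_units < 1L) stop("t_units must be >= 1")
  if (x$complex_t_units > x$t_units) stop("complex_t_units > t_units")
  if (x$dependent_clauses > x$clauses) stop("dependent_clauses > clauses")
  structure(lapply(x, as.integer), class = "parse_counts")
}

#' The 14 syntactic-complexity ratios from production-unit counts
#'
#' Computes, in canonical order: MLC = words/clauses, MLS = words/sentences,
#' MLT = words/T-units, C_S = clauses/sentences, C_T = clauses/T-units,
#' CT_T = complex T-units/T-units, DC_C = dependent clauses/clauses,
#' DC_T = dependent clauses/T-units, CP_C = coordinate phrases/clauses,
#' CP_T = coordinate phrases/T-units, T_S = T-units/sentences,
#' CN_C = complex nominals/clauses, CN_T = complex nominals/T-units,
#' VP_T = verb phrases/T-units. A zero denominator yields 0 with a warning
#' (degenerate letter).
#'
#' @param counts A `parse_counts` object.
#' @return Named numeric vector of the 14 ratios.
#' @export
syntactic_ratios <- function(counts) {
  stopifnot(inherits(counts, "parse_counts"))
  safe <- function(num, den) {
    if (den == 0L) {
      warning("zero denominator in syntactic ratio; reporting 0", call. = FALSE)
      return(0)
    }
    num / den
  }
  with(counts, c(
    MLC = safe(words, clauses),
    MLS = safe(words, sentences),
    MLT = safe(words, t_units),
    C_S = safe(clauses, sentences),
    C_T = safe(clauses, t_units),
    CT_T = safe(complex_t_units, t_units),
    DC_C = safe(dependent_clauses, clauses),
    DC_T = safe(dependent_clauses, t_units),
    CP_C = safe(coordinate_phrases, clauses),
    CP_T = safe(coordinate_phrases, t_units),
    T_S = safe(t_units, sentences),
    CN_C = safe(complex_nominals, clauses),
    CN_T = safe(complex_nominals, t_units),
    VP_T = safe(verb_phrases, t_units)))
}

#' Production-unit counts for one letter
#'
#' Dispatches between the two supported sources: ground-truth counts
#' (synthetic corpora; passed through unchanged after validation) and
#' bracketed constituency trees from an external parser, counted with the
#' tree patterns of [count_trees()]. An unparseable sentence (tree `NULL`)
#' contributes only to the word and sentence totals.
#'
#' @param tokenized A `tokenized_letter` (for word/sentence totals).
#' @param trees Optional list of Penn-bracketed tree strings (or parsed
#'   trees), one per sentence; `NULL` entries mark parser failures.
#' @param ground_truth Optional `parse_counts` to pass through.
#' @return A `parse_counts`.
#' @export
letter_parse_counts <- function(tokenized, trees = NULL, ground_truth = NULL) {
  if (!is.null(ground_truth)) {
    stopifnot(inherits(ground_truth, "parse_counts"))
    return(ground_truth)
  }
  if (is.null(trees))
    stop("no parser backend output; supply trees or ground_truth counts")
  counted <- count_trees(trees)
  parse_counts(words = length(tokenized$tokens),
               sentences = nrow(tokenized$sentences),
               clauses = counted$clauses,
               dependent_clauses = counted$dependent_clauses,
               t_units = max(1L, counted$t_units),
               complex_t_units = counted$complex_t_units,
               coordinate_phrases = counted$coordinate_phrases,
               complex_nominals = counted$complex_nominals,
               verb_phrases = counted$verb_phrases)
}
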