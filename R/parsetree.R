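# Penn-bracketed constituency trees and production-unit tree patterns.
#
# The parser itself is external; only the counting patterns are part of
# this package. A tree is a nested list: list(label = "NP", children =
# list(...)) for internal nodes and list(label = "NN", token = "king") for
# preterminals.
#
# Pattern definitions (applied per sentence tree):
#   clause           S / SINV / SQ node that dominates a finite verb
#                    (VBD, VBP, VBZ, MD) among the verbs of its own VP
#                    spine, plus finite subordinate clauses under SBAR —
#                    i.e. a subject + finite-verb structure
#   dependent clause clause dominated by an SBAR (cannot stand alone)
#   T-unit           topmost clause, with coordinated main clauses at the
#                    top level each counting as one T-unit
#   complex T-unit   T-unit dominating at least one dependent clause
#   coordinate phrase NP/VP/ADJP/ADVP node whose immediately following
#                    sibling is a coordinating conjunction (CC)
#   complex nominal  NP containing pre/post-modification (adjective, PP,
#                    relative SBAR, possessive) or more than one nominal
#                    head; plus nominal clauses (SBAR-subject) and
#                    gerund/infinitive subjects
#   verb phrase      VP node (finite or non-finite)

#' Parse one Penn-bracketed tree string
#'
#' @param s Bracketed tree, e.g.
#'   `"(S (NP (DT the) (NN king)) (VP (VBD wrote)))"`.
#' @return Nested-list tree.
#' @export
read_penn_tree <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  toks <- regmatches(s, gregexpr("\\(|\\)|[^()\\s]+", s, perl = TRUE))[[1L]]
  i <- 0L
  nxt <- function() { i <<- i + 1L; toks[i] }
  parse_node <- function() {
    t <- nxt()
    if (t != "(") stop("malformed tree near token ", i)
    label <- nxt()
    t <- nxt()
    if (t != "(" && t != ")") {
      # preterminal: (TAG token)
      close <- nxt()
      if (close != ")") stop("malformed preterminal near token ", i)
      return(list(label = label, token = t))
    }
    children <- list()
    while (t == "(") {
      i <<- i - 1L
      children[[length(children) + 1L]] <- parse_node()
      t <- nxt()
    }
    if (t != ")") stop("unbalanced tree")
    list(label = label, children = children)
  }
  node <- parse_node()
  if (i != length(toks)) stop("trailing material after tree")
  # strip a ROOT/TOP wrapper
  if (node$label %in% c("ROOT", "TOP") && length(node$children) == 1L)
    node <- node$children[[1L]]
  node
}

.is_leaf <- function(node) !is.null(node$token)
.kids <- function(node) if (.is_leaf(node)) list() else node$children

.CLAUSE_LABELS <- c("S", "SINV", "SQ")
.FINITE_VERB <- c("VBD", "VBP", "VBZ", "MD")
.PHRASE_LABELS <- c("NP", "VP", "ADJP", "ADVP")

# does this node dominate a finite verb without descending into a nested
# clause (so each clause is credited with its own finite verb)?
.has_own_finite_verb <- function(node) {
  if (.is_leaf(node)) return(node$label %in% .FINITE_VERB)
  for (ch in .kids(node)) {
    if (!.is_leaf(ch) && ch$label %in% c(.CLAUSE_LABELS, "SBAR")) next
    if (.has_own_finite_verb(ch)) return(TRUE)
  }
  FALSE
}

.walk <- function(node, fn, parent = NULL) {
  fn(node, parent)
  for (ch in .kids(node)) .walk(ch, fn, node)
  invisible(NULL)
}

#' Count production units in a list of sentence trees
#'
#' @param trees List of bracketed tree strings or parsed trees; `NULL`
#'   entries (unparseable sentences) are skipped.
#' @return List with counts `clauses`, `dependent_clauses`, `t_units`,
#'   `complex_t_units`, `coordinate_phrases`, `complex_nominals`,
#'   `verb_phrases`.
#' @export
count_trees <- function(trees) {
  tot <- list(clauses = 0L, dependent_clauses = 0L, t_units = 0L,
              complex_t_units = 0L, coordinate_phrases = 0L,
              complex_nominals = 0L, verb_phrases = 0L)
  for (tr in trees) {
    if (is.null(tr)) next
    if (is.character(tr)) tr <- read_penn_tree(tr)
    one <- .count_one_tree(tr)
    for (k in names(tot)) tot[[k]] <- tot[[k]] + one[[k]]
  }
  tot
}

.count_one_tree <- function(root) {
  clauses <- 0L; dep_clauses <- 0L; coord_phrases <- 0L
  complex_nominals <- 0L; verb_phrases <- 0L
  clause_nodes <- list()

  .walk(root, function(node, parent) {
    if (.is_leaf(node)) return(invisible(NULL))
    lab <- node$label
    if (lab %in% .CLAUSE_LABELS && .has_own_finite_verb(node)) {
      clauses <<- clauses + 1L
      under_sbar <- !is.null(parent) && parent$label == "SBAR"
      if (under_sbar) dep_clauses <<- dep_clauses + 1L
      clause_nodes[[length(clause_nodes) + 1L]] <<- node
    }
    if (lab == "VP") verb_phrases <<- verb_phrases + 1L
    if (lab == "NP" && .is_complex_nominal(node))
      complex_nominals <<- complex_nominals + 1L
    # coordinate phrases: phrase siblings immediately followed by a CC
    ks <- .kids(node)
    if (length(ks) >= 2L) {
      for (j in seq_len(length(ks) - 1L)) {
        a <- ks[[j]]; b <- ks[[j + 1L]]
        if (!.is_leaf(a) && a$label %in% .PHRASE_LABELS &&
            .is_leaf(b) && b$label == "CC")
          coord_phrases <<- coord_phrases + 1L
      }
    }
    invisible(NULL)
  })

  # T-units: top-level coordinated main clauses each count once; a single
  # main clause is one T-unit. Dependent (SBAR) clauses never open one.
  top <- root
  t_roots <- list()
  if (top$label %in% .CLAUSE_LABELS) {
    ks <- .kids(top)
    sub_s <- Filter(function(ch) !.is_leaf(ch) && ch$label %in% .CLAUSE_LABELS,
                    ks)
    has_cc <- any(vapply(ks, function(ch) .is_leaf(ch) && ch$label == "CC",
                         logical(1L)))
    if (length(sub_s) >= 2L && has_cc) t_roots <- sub_s else t_roots <- list(top)
  } else {
    t_roots <- list(top)
  }
  t_units <- length(t_roots)
  complex_t <- sum(vapply(t_roots, .dominates_dependent_clause, logical(1L)))

  list(clauses = clauses, dependent_clauses = dep_clauses,
       t_units = t_units, complex_t_units = as.integer(complex_t),
       coordinate_phrases = coord_phrases,
       complex_nominals = complex_nominals, verb_phrases = verb_phrases)
}

.dominates_dependent_clause <- function(node) {
  found <- FALSE
  .walk(node, function(nd, parent) {
    if (!found && !.is_leaf(nd) && nd$label %in% .CLAUSE_LABELS &&
        !is.null(parent) && parent$label == "SBAR" &&
        .has_own_finite_verb(nd))
      found <<- TRUE
  })
  found
}

# An NP is a complex nominal when it carries modification beyond a bare
# determiner + single nominal head: an adjective (JJ*), a PP or SBAR
# post-modifier, a possessive, a nested NP, or multiple nominal heads.
.is_complex_nominal <- function(node) {
  ks <- .kids(node)
  labs <- vapply(ks, function(ch) ch$label, character(1L))
  if (any(grepl("^JJ", labs))) return(TRUE)
  if (any(labs %in% c("PP", "SBAR", "POS", "NP", "VP"))) return(TRUE)
  if (sum(grepl("^NN", labs)) >= 2L) return(TRUE)
  FALSE
}
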