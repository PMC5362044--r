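# Synthetic letter-corpus generator.
#
# Emulates two-class letter corpora with the statistical structure the
# pipeline assumes: a Zipf vocabulary with a fixed coarse POS tag per
# vocabulary item, local repetitiveness (each token copies one of the
# previous 10 tokens with probability rho — the mechanism that drives
# Simpson's D up and entropy/compression ratio down), and clause/sentence
# assembly with controllable coordination (kappa) and subordination
# (sigma) rates from which ground-truth parse counts are accumulated. The
# generated prose is pseudo-English (pronounceable nonsense words); it
# carries ground-truth tags and counts so no tagger or parser is needed.

#' Parameters for synthetic letter generation
#'
#' @param n_letters Number of letters.
#' @param words_per_letter_mean Mean letter length in word tokens (letter
#'   lengths are rounded lognormal around this mean, sdlog 0.3, floored at
#'   20).
#' @param vocab_size Number of vocabulary types.
#' @param zipf_s Zipf exponent (> 0) of the vocabulary frequency law.
#' @param repeat_prob rho in \[0, 1): probability that a token copies a
#'   uniformly chosen token from the previous 10 tokens instead of a fresh
#'   Zipf draw.
#' @param pos_mix Named proportions over NOUN, VERB, ADJ, ADV, OTHER
#'   (sum 1) from which each vocabulary item's fixed tag is drawn.
#' @param clauses_per_sentence lambda_c > 0: sentences have
#'   Poisson(lambda_c) + 1 clauses.
#' @param coord_rate kappa in \[0, 1\]: probability a clause contributes a
#'   coordinate phrase.
#' @param subord_rate sigma in \[0, 1\]: probability a non-initial clause is
#'   a dependent clause.
#' @param period Period label attached to generated letters.
#' @return Validated list of class `synthetic_params`.
#' @export
synthetic_params <- function(n_letters = 30L,
                             words_per_letter_mean = 100,
                             vocab_size = 2000L,
                             zipf_s = 1.05,
                             repeat_prob = 0.05,
                             pos_mix = c(NOUN = 0.25, VERB = 0.15,
                                         ADJ = 0.08, ADV = 0.05,
                                         OTHER = 0.47),
                             clauses_per_sentence = 4,
                             coord_rate = 0.2,
                             subord_rate = 0.25,
                             period = "period") {
  stopifnot(n_letters >= 1L, words_per_letter_mean >= 20,
            vocab_size >= 2L, zipf_s > 0,
            repeat_prob >= 0, repeat_prob < 1,
            clauses_per_sentence > 0,
            coord_rate >= 0, coord_rate <= 1,
            subord_rate >= 0, subord_rate <= 1)
  if (!setequal(names(pos_mix), POS_TAGS))
    stop("pos_mix must name exactly NOUN, VERB, ADJ, ADV, OTHER")
  if (abs(sum(pos_mix) - 1) > 1e-9) stop("pos_mix must sum to 1")
  structure(list(n_letters = as.integer(n_letters),
                 words_per_letter_mean = words_per_letter_mean,
                 vocab_size = as.integer(vocab_size), zipf_s = zipf_s,
                 repeat_prob = repeat_prob, pos_mix = pos_mix[POS_TAGS],
                 clauses_per_sentence = clauses_per_sentence,
                 coord_rate = coord_rate, subord_rate = subord_rate,
                 period = period),
            class = "synthetic_params")
}

# pronounceable pseudo-word for vocabulary rank i (deterministic)
.pseudo_word <- function(i) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
            "v", "w", "z", "th", "st", "br", "cl", "gr")
  vow <- c("a", "e", "i", "o", "u")
  i <- i - 1L
  syll <- character(0)
  repeat {
    syll <- c(syll, paste0(cons[(i %% 20L) + 1L], vow[((i %/% 20L) %% 5L) + 1L]))
    i <- i %/% 100L
    if (i == 0L) break
    i <- i - 1L
  }
  paste(rev(syll), collapse = "")
}

.make_vocab <- function(params) {
  v <- params$vocab_size
  words <- vapply(seq_len(v), .pseudo_word, character(1L))
  # ranks collide for > 100 syllable combinations; disambiguate by suffix
  dup <- duplicated(words)
  words[dup] <- paste0(words[dup], seq_len(sum(dup)))
  prob <- (seq_len(v))^(-params$zipf_s)
  pos <- sample(POS_TAGS, v, replace = TRUE, prob = params$pos_mix)
  list(words = words, prob = prob / sum(prob), pos = pos)
}

# one letter's token stream with the copy-from-recent-window process
.draw_tokens <- function(n, vocab, rho) {
  idx <- integer(n)
  fresh <- sample.int(length(vocab$words), n, replace = TRUE,
                      prob = vocab$prob)
  copy <- stats::runif(n) < rho
  for (i in seq_len(n)) {
    if (i > 1L && copy[i]) {
      win <- idx[max(1L, i - 10L):(i - 1L)]
      idx[i] <- win[sample.int(length(win), 1L)]
    } else {
      idx[i] <- fresh[i]
    }
  }
  idx
}

#' Generate one synthetic letter with ground truth
#'
#' Draws the content-token stream (Zipf + recent-window repetition),
#' assembles it into clauses and sentences, inserts a coordinating
#' conjunction token for each coordinate phrase, and accumulates
#' ground-truth parse counts from the same construction choices. Called
#' inside an already-seeded RNG context; use
#' [generate_comparison_corpus()] for a seeded corpus.
#'
#' @param params A `synthetic_params`.
#' @param vocab Vocabulary from the corpus context (internal).
#' @param id Letter id.
#' @param date Letter date.
#' @return List: `letter` (one-row data.frame), `tokens`, `tags`
#'   (ground-truth coarse POS, one per token), `counts` (`parse_counts`).
#' @export
generate_letter <- function(params, vocab = NULL, id = "L1",
                            date = as.Date("1788-10-01")) {
  if (is.null(vocab)) vocab <- .make_vocab(params)
  m <- params$words_per_letter_mean
  sdlog <- 0.3
  len <- max(20L, round(stats::rlnorm(1L, log(m) - sdlog^2 / 2, sdlog)))
  content <- .draw_tokens(len, vocab, params$repeat_prob)

  tokens <- character(0); tags <- character(0)
  sent_strings <- character(0)
  clauses <- 0L; dep_clauses <- 0L; t_units <- 0L; complex_t <- 0L
  coord <- 0L; nominals <- 0L; verb_phrases <- 0L
  n_sentences <- 0L
  pos_in <- 1L
  conj <- c("and", "but", "or")
  while (pos_in <= len) {
    n_cl <- stats::rpois(1L, params$clauses_per_sentence) + 1L
    sent_tokens <- character(0); sent_tags <- character(0)
    clause_strings <- character(0)
    tu_has_dep <- FALSE
    sent_t_units <- 0L
    for (ci in seq_len(n_cl)) {
      if (pos_in > len) break
      cl_len <- min(stats::rpois(1L, 6L) + 3L, len - pos_in + 1L)
      idxs <- content[pos_in:(pos_in + cl_len - 1L)]
      pos_in <- pos_in + cl_len
      w <- vocab$words[idxs]; tg <- vocab$pos[idxs]
      # coordinate phrase: conjunction inserted inside the clause
      if (stats::runif(1L) < params$coord_rate && cl_len >= 2L) {
        at <- sample.int(cl_len - 1L, 1L)
        w <- append(w, conj[sample.int(3L, 1L)], after = at)
        tg <- append(tg, "OTHER", after = at)
        coord <- coord + 1L
      }
      is_dep <- ci > 1L && stats::runif(1L) < params$subord_rate
      if (ci == 1L || !is_dep) {
        # new T-unit: close bookkeeping of the previous one
        if (sent_t_units > 0L && tu_has_dep) complex_t <- complex_t + 1L
        sent_t_units <- sent_t_units + 1L
        tu_has_dep <- FALSE
      } else {
        dep_clauses <- dep_clauses + 1L
        tu_has_dep <- TRUE
      }
      clauses <- clauses + 1L
      nominals <- nominals + stats::rpois(1L, 0.7)
      verb_phrases <- verb_phrases + 1L + stats::rbinom(1L, 1L, 0.25)
      sent_tokens <- c(sent_tokens, w); sent_tags <- c(sent_tags, tg)
      clause_strings <- c(clause_strings, paste(w, collapse = " "))
    }
    if (!length(sent_tokens)) break
    if (tu_has_dep) complex_t <- complex_t + 1L
    t_units <- t_units + sent_t_units
    n_sentences <- n_sentences + 1L
    tokens <- c(tokens, sent_tokens); tags <- c(tags, sent_tags)
    sent_strings <- c(sent_strings,
                      paste0(paste(clause_strings, collapse = ", "), "."))
  }
  text <- paste(sent_strings, collapse = " ")
  counts <- parse_counts(words = length(tokens), sentences = n_sentences,
                         clauses = clauses, dependent_clauses = dep_clauses,
                         t_units = max(1L, t_units),
                         complex_t_units = complex_t,
                         coordinate_phrases = coord,
                         complex_nominals = nominals,
                         verb_phrases = verb_phrases)
  list(letter = letter_record(id, text, date, params$period),
       tokens = tokens, tags = tags, counts = counts)
}

#' Generate a two-period comparison corpus with ground truth
#'
#' Generates the two labeled letter sets (one `synthetic_params` each) with
#' dates assigned as consecutive days within disjoint ranges, so
#' chronological epoch splitting works. When `directory` is given, the
#' corpus is written to disk ([write_corpus()]) together with
#' `ground_truth.json` (per-letter tags and parse counts).
#'
#' @param params_a,params_b Parameters for the two periods (their `period`
#'   labels must differ).
#' @param seed Integer seed; the whole corpus is a deterministic function
#'   of (params, seed).
#' @param directory Optional output directory.
#' @param start_a,start_b First letter dates of each period.
#' @return List of class `synthetic_corpus`: `corpus` (data.frame of
#'   letters), `tags` (named list), `counts` (named list of
#'   `parse_counts`), `params`, `seed`.
#' @export
generate_comparison_corpus <- function(params_a, params_b, seed = 1L,
                                       directory = NULL,
                                       start_a = as.Date("1788-04-01"),
                                       start_b = as.Date("1788-10-01")) {
  stopifnot(inherits(params_a, "synthetic_params"),
            inherits(params_b, "synthetic_params"))
  if (identical(params_a$period, params_b$period))
    stop("the two periods must have distinct labels")
  # One writer, one vocabulary: the vocabulary (words, Zipf weights, POS
  # assignment) is a deterministic function of (vocabulary params, seed),
  # so two periods with equal params share it exactly and differ only
  # through the style process (rho, kappa, sigma, lengths).
  vocab_seed <- (seed %% 1000000L) + 777L
  vocab_a <- withr::with_seed(vocab_seed, .make_vocab(params_a))
  vocab_b <- withr::with_seed(vocab_seed, .make_vocab(params_b))
  out <- withr::with_seed(seed, {
    res <- list()
    for (side in list(list(p = params_a, start = start_a, tag = "a",
                           vocab = vocab_a),
                      list(p = params_b, start = start_b, tag = "b",
                           vocab = vocab_b))) {
      vocab <- side$vocab
      for (i in seq_len(side$p$n_letters)) {
        id <- sprintf("%s%03d", toupper(side$tag), i)
        res[[id]] <- generate_letter(side$p, vocab, id = id,
                                     date = side$start + (i - 1L))
      }
    }
    res
  })
  corpus <- do.call(rbind, lapply(out, `[[`, "letter"))
  rownames(corpus) <- NULL
  tags <- lapply(out, `[[`, "tags")
  counts <- lapply(out, `[[`, "counts")
  result <- structure(list(corpus = corpus, tags = tags, counts = counts,
                           params = list(a = params_a, b = params_b),
                           seed = seed),
                      class = "synthetic_corpus")
  if (!is.null(directory)) {
    write_corpus(corpus, directory)
    gt <- lapply(names(out), function(id)
      list(tags = tags[[id]], counts = unclass(counts[[id]])))
    names(gt) <- names(out)
    jsonlite::write_json(gt, file.path(directory, "ground_truth.json"),
                         auto_unbox = TRUE)
  }
  result
}

#' Load ground-truth tags and parse counts written beside a synthetic corpus
#'
#' Reads the `ground_truth.json` emitted by [generate_comparison_corpus()]
#' so a corpus reloaded from disk with [load_corpus()] can be analyzed with
#' its ground-truth tags and counts.
#'
#' @param path Path to `ground_truth.json`.
#' @return List with named lists `tags` and `counts` (by letter id).
#' @export
load_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path)
  tags <- lapply(raw, function(x) vapply(x$tags, identity, character(1L)))
  counts <- lapply(raw, function(x) do.call(parse_counts, x$counts))
  list(tags = tags, counts = counts)
}

#' Study-condition presets for the six two-period comparisons
#'
#' Class sizes and mean letter lengths follow the study corpus: A
#' (pre-mania 21 letters x 129.1 words vs acute mania 31 x 152.4), B (acute
#' mania vs post-mania 37 x 73.3), C (acute mania vs healthy/no stressors
#' 47 x 85.1), D (acute mania vs healthy/political stressors 42 x 127), E
#' (healthy spring-summer 20 x 57.2 vs healthy autumn-winter 47 x 85.1), F
#' (healthy autumn-winter vs healthy spring-summer 11 x 101). Manic-period
#' letters use the repetitive, coordination-heavy style (rho = 0.35,
#' kappa = 0.35, sigma = 0.18); healthy periods use rho = 0.05,
#' kappa = 0.2, sigma = 0.25 — a repetition contrast of delta-rho = 0.3 for
#' A-D and identical style parameters (a null contrast) for E and F.
#'
#' @param preset One of `"A"`..`"F"`.
#' @return List with `params_a`, `params_b` ready for
#'   [generate_comparison_corpus()].
#' @export
comparison_preset <- function(preset = c("A", "B", "C", "D", "E", "F")) {
  preset <- match.arg(preset)
  healthy <- function(n, len, label)
    synthetic_params(n_letters = n, words_per_letter_mean = len,
                     repeat_prob = 0.05, coord_rate = 0.2,
                     subord_rate = 0.25, period = label)
  manic <- function(n, len, label)
    synthetic_params(n_letters = n, words_per_letter_mean = len,
                     repeat_prob = 0.35, coord_rate = 0.35,
                     subord_rate = 0.18, period = label)
  switch(preset,
    A = list(params_a = healthy(21L, 129.1, "pre_mania"),
             params_b = manic(31L, 152.4, "acute_mania")),
    B = list(params_a = manic(31L, 152.4, "acute_mania"),
             params_b = healthy(37L, 73.3, "post_mania")),
    C = list(params_a = manic(31L, 152.4, "acute_mania"),
             params_b = healthy(47L, 85.1, "healthy_no_stress")),
    D = list(params_a = manic(31L, 152.4, "acute_mania"),
             params_b = healthy(42L, 127, "healthy_stress")),
    E = list(params_a = healthy(20L, 57.2, "healthy_spring_summer"),
             params_b = healthy(47L, 85.1, "healthy_autumn_winter")),
    F = list(params_a = healthy(47L, 85.1, "healthy_autumn_winter"),
             params_b = healthy(11L, 101, "healthy_spring_summer")))
}
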