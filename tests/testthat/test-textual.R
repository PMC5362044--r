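test_that("lexical variation ratios match hand-evaluated values", {
  toks <- c("king", "wrote", "letter", "king", "angry")
  tags <- c("NOUN", "VERB", "NOUN", "NOUN", "ADJ")
  p <- lexical_variation_profile(toks, tags)
  expect_equal(unname(p["LV"]), 0.8)
  expect_equal(unname(p["NV"]), 0.4)
  expect_equal(unname(p["VV"]), 0.2)
  expect_equal(unname(p["ADJV"]), 0.2)
  expect_equal(unname(p["ADVV"]), 0)
  expect_equal(unname(p["MODV"]), 0.2)
  expect_equal(unname(p["CVV"]), 1 / sqrt(2), tolerance = 1e-12)
})

test_that("lexical variation degenerate cases follow the contracts", {
  # all tokens distinct nouns
  p <- lexical_variation_profile(letters[1:5], rep("NOUN", 5))
  expect_equal(unname(p[c("LV", "NV")]), c(1, 1))
  # zero verbs: CVV and VV are 0
  expect_equal(unname(p[c("CVV", "VV")]), c(0, 0))
  # one verb repeated n times
  n <- 4L
  q <- lexical_variation_profile(rep("go", n), rep("VERB", n))
  expect_equal(unname(q["VV"]), 1 / n)
  expect_equal(unname(q["CVV"]), 1 / sqrt(2 * n))
  expect_error(lexical_variation_profile(c("the", "of"), c("OTHER", "OTHER")),
               "no lexical words")
})

test_that("segmental mean applies the 10-word block truncation rule", {
  # 20 tokens: first block all distinct, second block 5 types of 10
  toks <- c(letters[1:10], rep(c("x", "y", "z", "w", "v"), 2))
  expect_equal(segmental_mean(toks, function(b) length(unique(b))), 7.5)
  # 25 tokens: exactly 2 blocks used, trailing 5 discarded
  toks25 <- c(toks, c("q", "q", "q", "q", "q"))
  expect_equal(segmental_mean(toks25, function(b) length(unique(b))), 7.5)
  expect_equal(segmental_mean(letters[1:20], function(b) 3.5), 3.5)
  expect_error(segmental_mean(letters[1:9], length), "shorter than one block")
})

test_that("bilogarithmic TTR matches its formula and decreases with repetition", {
  expect_equal(log_ttr(letters[1:10]), 1.0)
  block <- rep(c("a", "b", "c", "d", "e"), 2)
  expect_equal(log_ttr(block), log10(5) / log10(10), tolerance = 1e-12)
  # replacing one token by a duplicate of another strictly lowers the value
  for (i in 1:9) {
    b <- letters[1:10]
    b[i] <- b[10]
    expect_lt(log_ttr(b), 1.0)
  }
  expect_equal(ms_log_ttr(c(letters[1:10], block)),
               mean(c(1, log10(5) / log10(10))), tolerance = 1e-12)
})

test_that("hapax statistics match hand counts", {
  block <- c("a", "b", "c", "a", "d", "e", "f", "g", "h", "i")
  hp <- hapax_profile(block)
  expect_equal(unname(hp["HL"]), 8)           # all but the two a's
  # all-distinct block: HL 10, PHL 9 (maximum)
  hp2 <- hapax_profile(letters[1:10])
  expect_equal(unname(hp2["HL"]), 10)
  expect_equal(unname(hp2["PHL"]), 9)
  # dis legomena over vocabulary on "a a b b c"
  expect_equal(dis_legomena_ratio(c("a", "a", "b", "b", "c")), 2 / 3)
  expect_equal(unname(hapax_profile(c("a", "a", "b", "b", "c",
                                      "c", "c", "d", "e", "f"))["DL_V"]),
               2 / 6)
})

test_that("Brunet's W matches direct evaluation and its monotonicity", {
  expect_equal(brunets_w(1, 1), 1.0)
  expect_equal(brunets_w(100, 100), 100^(100^-0.165), tolerance = 1e-12)
  expect_equal(brunets_w(100, 100), 8.617, tolerance = 1e-3)
  expect_equal(brunets_w(150, 90), 10.856, tolerance = 1e-3)
  expect_error(brunets_w(10, 11), "exceeds")
  # at fixed N, W increases as V decreases (poorer vocabulary)
  w <- vapply(100:1, function(v) brunets_w(100, v), numeric(1))
  expect_true(all(diff(w) > 0))
})

test_that("Simpson's D equals the brute-force pair probability", {
  expect_equal(simpsons_d(rep("a", 5)), 1.0)
  expect_equal(simpsons_d(letters[1:6]), 0.0)
  expect_equal(simpsons_d(c("a", "a", "a", "b")), 0.5)
  # brute force over all ordered token pairs, 20 seeded random texts
  withr::with_seed(42, {
    for (r in 1:20) {
      toks <- sample(letters[1:5], 12, replace = TRUE)
      pairs <- outer(toks, toks, "==")
      diag(pairs) <- NA
      expect_equal(simpsons_d(toks), mean(pairs, na.rm = TRUE),
                   tolerance = 1e-12)
    }
  })
  expect_error(simpsons_d("a"), "at least 2")
})

test_that("normalized entropy spans [0,1] with the stated endpoints", {
  expect_equal(shannon_entropy(rep("a", 7)), 0)
  expect_equal(shannon_entropy(rep(letters[1:4], 3)), 1.0)
  expect_equal(shannon_entropy(c("a", "a", "a", "b")),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)), tolerance = 1e-12)
  expect_equal(shannon_entropy(c("a", "a", "a", "b")), 0.8113, tolerance = 1e-4)
})

test_that("compression ratio reflects redundancy and is deterministic", {
  rep_text <- paste(rep("ab", 500), collapse = "")
  rand_text <- withr::with_seed(1, paste(sample(letters, 1000, replace = TRUE),
                                         collapse = ""))
  expect_lt(compression_ratio(rep_text), compression_ratio(rand_text))
  expect_identical(compression_ratio(rand_text), compression_ratio(rand_text))
  expect_error(compression_ratio(""), "empty")
  # self-concatenation never increases the ratio (50 seeded synthetic letters)
  p <- synthetic_params(n_letters = 50L, words_per_letter_mean = 60,
                        period = "x")
  corp <- generate_comparison_corpus(
    p, synthetic_params(n_letters = 1L, period = "y"), seed = 5)
  texts <- corp$corpus$text[corp$corpus$period == "x"]
  expect_length(texts, 50L)
  for (tx in texts) {
    expect_lte(compression_ratio(paste0(tx, tx)), compression_ratio(tx))
  }
})

test_that("the full textual profile is finite and correctly bounded", {
  tl <- toy_tagged_letter()
  prof <- textual_profile(tl, paste(tl$tokens, collapse = " "))
  expect_named(prof, c("LV", "LogTTR", "NV", "ADJV", "MODV", "ADVV", "CVV",
                       "VV", "W", "HL", "PHL", "D", "DL_V", "H", "CR"))
  expect_true(all(is.finite(prof)))
  expect_true(all(prof[c("LV", "LogTTR", "D", "H")] >= 0 &
                    prof[c("LV", "LogTTR", "D", "H")] <= 1))
  expect_true(prof["HL"] >= 0 && prof["HL"] <= 10)
  expect_gt(prof["W"], 0)
})
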