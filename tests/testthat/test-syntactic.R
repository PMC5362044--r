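test_that("the 14 syntactic ratios match hand arithmetic", {
  pc <- parse_counts(words = 20, sentences = 2, clauses = 4,
                     dependent_clauses = 2, t_units = 2, complex_t_units = 2,
                     coordinate_phrases = 1, complex_nominals = 3,
                     verb_phrases = 4)
  r <- syntactic_ratios(pc)
  expect_equal(r, c(MLC = 5, MLS = 10, MLT = 10, C_S = 2, C_T = 2, CT_T = 1,
                    DC_C = 0.5, DC_T = 1, CP_C = 0.25, CP_T = 0.5, T_S = 1,
                    CN_C = 0.75, CN_T = 1.5, VP_T = 2))
})

test_that("a minimal one-clause sentence yields the degenerate ratio set", {
  pc <- parse_counts(words = 5, sentences = 1, clauses = 1,
                     dependent_clauses = 0, t_units = 1, complex_t_units = 0,
                     coordinate_phrases = 0, complex_nominals = 0,
                     verb_phrases = 1)
  r <- syntactic_ratios(pc)
  expect_equal(unname(r[c("MLC", "MLS", "MLT")]), c(5, 5, 5))
  expect_equal(unname(r[c("C_S", "C_T", "T_S", "VP_T")]), c(1, 1, 1, 1))
  expect_equal(unname(r[c("CT_T", "DC_C", "DC_T", "CP_C", "CP_T",
                          "CN_C", "CN_T")]), rep(0, 7))
})

test_that("ratios are homogeneous of degree zero in the counts", {
  base <- list(words = 20, sentences = 2, clauses = 4, dependent_clauses = 2,
               t_units = 2, complex_t_units = 2, coordinate_phrases = 1,
               complex_nominals = 3, verb_phrases = 4)
  r1 <- syntactic_ratios(do.call(parse_counts, base))
  r3 <- syntactic_ratios(do.call(parse_counts, lapply(base, `*`, 3L)))
  expect_equal(r1, r3)
})

test_that("length identities MLS = MLC x C/S and MLT = MLC x C/T hold", {
  withr::with_seed(9, {
    for (i in 1:20) {
      pc <- parse_counts(words = sample(20:200, 1), sentences = sample(1:9, 1),
                         clauses = sample(5:15, 1), dependent_clauses = 2,
                         t_units = sample(2:5, 1), complex_t_units = 1,
                         coordinate_phrases = sample(0:4, 1),
                         complex_nominals = sample(0:9, 1),
                         verb_phrases = sample(1:9, 1))
      r <- syntactic_ratios(pc)
      expect_equal(unname(r["MLS"]), unname(r["MLC"] * r["C_S"]),
                   tolerance = 1e-12)
      expect_equal(unname(r["MLT"]), unname(r["MLC"] * r["C_T"]),
                   tolerance = 1e-12)
    }
  })
})

test_that("count validation enforces the declared invariants", {
  expect_error(parse_counts(10, 1, 2, 3, 1, 0, 0, 0, 1), "dependent_clauses")
  expect_error(parse_counts(10, 1, 2, 0, 1, 2, 0, 0, 1), "complex_t_units")
  expect_error(parse_counts(10, 0, 2, 0, 1, 0, 0, 0, 1), "sentences")
  expect_error(parse_counts(10, 1, 2, 0, 0, 0, 0, 0, 1), "t_units")
  expect_error(parse_counts(-1, 1, 2, 0, 1, 0, 0, 0, 1), "non-negative")
})

test_that("zero denominators report 0 with a warning", {
  pc <- parse_counts(words = 5, sentences = 1, clauses = 0,
                     dependent_clauses = 0, t_units = 1, complex_t_units = 0,
                     coordinate_phrases = 0, complex_nominals = 0,
                     verb_phrases = 1)
  w <- testthat::capture_warnings(r <- syntactic_ratios(pc))
  expect_true(any(grepl("zero denominator", w)))
  expect_equal(unname(r["MLC"]), 0)
})

test_that("tree-pattern counting matches manual production-unit analysis", {
  # coordinated main clauses: 1 sentence, 2 T-units, 2 clauses
  tree <- paste0("(ROOT (S (S (NP (DT The) (NN king)) (VP (VBD wrote)))",
                 " (CC and)",
                 " (S (NP (DT the) (NN minister)) (VP (VBD replied)))",
                 " (. .)))")
  tl <- tokenize_letter("The king wrote and the minister replied.", id = "f1")
  pc <- letter_parse_counts(tl, trees = list(tree))
  expect_equal(pc$sentences, 1L)
  expect_equal(pc$t_units, 2L)
  expect_equal(pc$clauses, 2L)
  expect_equal(pc$coordinate_phrases, 0L)   # clause, not phrase, coordination
  expect_equal(pc$verb_phrases, 2L)
  expect_equal(pc$dependent_clauses, 0L)

  # subordination: one T-unit containing a dependent clause
  tree2 <- paste0("(ROOT (S (NP (DT The) (NN king)) (VP (VBD said)",
                  " (SBAR (IN that) (S (NP (DT the) (NN fleet))",
                  " (VP (VBD sailed))))) (. .)))")
  tl2 <- tokenize_letter("The king said that the fleet sailed.", id = "f2")
  pc2 <- letter_parse_counts(tl2, trees = list(tree2))
  expect_equal(pc2$clauses, 2L)
  expect_equal(pc2$dependent_clauses, 1L)
  expect_equal(pc2$t_units, 1L)
  expect_equal(pc2$complex_t_units, 1L)

  # phrase coordination: NP before CC is a coordinate phrase
  tree3 <- paste0("(ROOT (S (NP (NP (DT the) (NN army)) (CC and)",
                  " (NP (DT the) (NN navy))) (VP (VBD marched)) (. .)))")
  tl3 <- tokenize_letter("The army and the navy marched.", id = "f3")
  pc3 <- letter_parse_counts(tl3, trees = list(tree3))
  expect_equal(pc3$coordinate_phrases, 1L)
  expect_equal(pc3$t_units, 1L)
  # the coordinated NP is a complex nominal (nested NPs)
  expect_gte(pc3$complex_nominals, 1L)

  # determinism and the ground-truth bypass
  expect_identical(letter_parse_counts(tl, trees = list(tree)),
                   letter_parse_counts(tl, trees = list(tree)))
  gt <- parse_counts(10, 1, 2, 1, 1, 1, 0, 2, 2)
  expect_identical(letter_parse_counts(tl, ground_truth = gt), gt)
  # unparseable sentences (NULL trees) contribute words/sentences only
  pc_null <- letter_parse_counts(tl, trees = list(NULL))
  expect_equal(pc_null$words, 7L)
  expect_equal(pc_null$clauses, 0L)
  expect_error(letter_parse_counts(tl), "backend")
})
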