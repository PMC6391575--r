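test_that("matched-slot score is the scaled inside-mention probability", {
  st <- slot_statistics(
    data.frame(symbol = c("A", "B", "C", "D"),
               freq_m = c(37L, 0L, 30L, 3L),
               freq_n = c(0L, 5L, 30L, 1L), stringsAsFactors = FALSE),
    data.frame(symbol = character(), freq_m = integer(), freq_n = integer(),
               stringsAsFactors = FALSE))
  expect_identical(match_score(st, "A"), 100)   # mention-exclusive
  expect_identical(match_score(st, "B"), 0)
  expect_identical(match_score(st, "C"), 50)
  expect_equal(match_score(st, "D"), 75)
  expect_identical(match_score(st, "Unseen"), 50)  # lambda / 2 fallback
})

test_that("insertion penalty follows the inverse-entropy branches", {
  st <- toy_stats()
  # P_nonMiRNA = 0: free insertion
  expect_identical(insertion_penalty(st, "Let", "slot"), 0)
  expect_identical(insertion_penalty(st, "Suffix", "slot"), 0)
  # P_miRNA = 0: forbidden insertion
  expect_identical(insertion_penalty(st, "(", "word"), Inf)
  # maximum entropy: H = 1, penalty 1
  st2 <- slot_statistics(
    data.frame(symbol = "E", freq_m = 30L, freq_n = 30L,
               stringsAsFactors = FALSE),
    data.frame(symbol = "w", freq_m = 5L, freq_n = 5L,
               stringsAsFactors = FALSE))
  expect_equal(insertion_penalty(st2, "E", "slot"), 1)
  expect_equal(insertion_penalty(st2, "w", "word"), 1)
  # symmetry in (P_m, P_n)
  sym <- slot_statistics(
    data.frame(symbol = c("p25", "p75"), freq_m = c(1L, 3L),
               freq_n = c(3L, 1L), stringsAsFactors = FALSE),
    data.frame(symbol = character(), freq_m = integer(), freq_n = integer(),
               stringsAsFactors = FALSE))
  expect_equal(insertion_penalty(sym, "p25", "slot"),
               insertion_penalty(sym, "p75", "slot"))
  expect_identical(insertion_penalty(st, "nevereverseen", "word"),
                   st$unseen_insertion)
})

test_that("deletion penalty is the negative log mention probability", {
  st <- slot_statistics(
    data.frame(symbol = c("X", "H", "Q", "Z"),
               freq_m = c(10L, 5L, 1L, 0L),
               freq_n = c(0L, 5L, 3L, 4L), stringsAsFactors = FALSE),
    data.frame(symbol = character(), freq_m = integer(), freq_n = integer(),
               stringsAsFactors = FALSE))
  expect_identical(deletion_penalty(st, "X"), 0)   # P = 1
  expect_equal(deletion_penalty(st, "H"), 1)       # P = 0.5
  expect_equal(deletion_penalty(st, "Q"), 2)       # P = 0.25
  expect_identical(deletion_penalty(st, "Z"), Inf)
})

test_that("the candidate score is additive over M, I and D", {
  st <- toy_stats()
  expect_equal(sequence_score(list(M = c("Let", "Suffix"), I = NULL,
                                   D = character()), st), 200)
  expect_identical(sequence_score(list(M = character(), I = NULL,
                                       D = character()), st), 0)
  # one 100-gain match, one penalty-1 insertion, one penalty-2 deletion
  st3 <- slot_statistics(
    data.frame(symbol = c("A", "E", "Q"),
               freq_m = c(5L, 30L, 1L), freq_n = c(0L, 30L, 3L),
               stringsAsFactors = FALSE),
    data.frame(symbol = character(), freq_m = integer(), freq_n = integer(),
               stringsAsFactors = FALSE))
  expect_equal(sequence_score(list(
    M = "A",
    I = data.frame(symbol = "E", kind = "slot", stringsAsFactors = FALSE),
    D = "Q"), st3), 97)
  # any infinite penalty rejects
  expect_identical(sequence_score(list(M = "Let", I = "(", D = character()),
                                  st), -Inf)
})

test_that("moving matches to deletions or growing insertions lowers the score", {
  st <- toy_stats()
  finite_slots <- c("Species", "Precursor", "miRNA", "Order", "Conj")
  set.seed(9)
  for (rep in 1:25) {
    M <- sample(finite_slots, sample(1:4, 1), replace = TRUE)
    D <- sample(finite_slots, sample(0:2, 1), replace = TRUE)
    base <- sequence_score(list(M = M, I = NULL, D = D), st)
    k <- sample(seq_along(M), 1)
    moved <- sequence_score(list(M = M[-k], I = NULL, D = c(D, M[k])), st)
    expect_true(moved < base)
    grown <- sequence_score(list(
      M = M, I = data.frame(symbol = ",", kind = "word",
                            stringsAsFactors = FALSE), D = D), st)
    expect_true(grown < base)
  }
})

test_that("cluster thresholds follow the core/optional decomposition", {
  st <- toy_stats()
  # single mention-exclusive core slot, nothing else
  cl <- spba:::make_cluster(spba:::new_principle("Let"), list())
  expect_equal(cluster_threshold(cl, st), 100)
  # adding a non-core slot to the dominant subtracts its deletion penalty
  st4 <- slot_statistics(
    data.frame(symbol = c("X", "Q"), freq_m = c(10L, 1L),
               freq_n = c(0L, 3L), stringsAsFactors = FALSE),
    data.frame(symbol = character(), freq_m = integer(), freq_n = integer(),
               stringsAsFactors = FALSE))
  dom <- spba:::new_principle(c("X", "Q"))
  sub <- spba:::new_principle("X")
  cl2 <- spba:::make_cluster(dom, list(sub))
  th <- cluster_threshold(cl2, st4)
  # core {X} scores 100; deleting Q costs 2; optional Q at P=0.5 with a
  # finite insertion penalty lowers it further under the default sign
  expect_true(th < 100 - 2 + 1e-9)
  expect_equal(cluster_threshold(cl2, st4, insertion_sign = 1) -
                 cluster_threshold(cl2, st4, insertion_sign = -1),
               2 * 0.5 * insertion_penalty(st4, "Q", "slot"))
})

test_that("trained cluster thresholds equal an independent recomputation", {
  fx <- shared_fixture()
  model <- fx$model
  st <- model$stats
  for (cl in model$clusters) {
    expected <- sum(vapply(cl$core_slots,
                           function(s) match_score(st, s), numeric(1)))
    for (s in cl$dominant$slots)
      if (!(s %in% cl$core_slots))
        expected <- expected - deletion_penalty(st, s)
    for (s in cl$optional_slots) {
      pen <- insertion_penalty(st, s, "slot")
      if (is.finite(pen)) expected <- expected - cl$optional_probs[[s]] * pen
    }
    for (w in names(cl$nonslot_probs)) {
      pen <- insertion_penalty(st, w, "word")
      if (is.finite(pen)) expected <- expected - cl$nonslot_probs[[w]] * pen
    }
    expect_equal(cl$threshold, expected)
  }
})

test_that("statistics estimation counts inside and outside occurrences", {
  st <- estimate_slot_statistics(toy_corpus(), default_slot_scheme())
  # every suffix occurrence in the toy corpus is inside a mention
  suf <- st$slots[st$slots$symbol == "Hairpin", ]
  expect_identical(suf$freq_n, 0L)
  expect_identical(match_score(st, "Hairpin"), 100)
  # 'and' occurs once, outside mentions
  conj <- st$slots[st$slots$symbol == "Conj", ]
  expect_identical(conj$freq_m, 0L)
  expect_identical(conj$freq_n, 1L)
  # symbols absent from the corpus are absent from the tables
  expect_false("zzz" %in% st$words$symbol)
  expect_error(estimate_slot_statistics(spba_corpus(list()),
                                        default_slot_scheme()), "empty")
})
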