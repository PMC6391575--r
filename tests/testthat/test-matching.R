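test_that("alignment reproduces the documented decompositions", {
  st <- toy_stats()
  sc <- default_slot_scheme()
  al <- align_window(label_slots(tokenize("miR-16-2"), sc),
                     c("Species", "miRNA", "Order", "Order"), st)
  expect_identical(al$M$slot, c("miRNA", "Order", "Order"))
  expect_identical(al$M$text, c("miR", "16", "2"))
  expect_identical(al$I$symbol, c("-", "-"))
  expect_identical(al$D$slot, "Species")

  al <- align_window(label_slots(tokenize("pre-miR-149"), sc),
                     c("Precursor", "miRNA", "Order", "Order"), st)
  expect_identical(al$M$slot, c("Precursor", "miRNA", "Order"))
  expect_identical(sort(al$I$symbol), c("-", "-"))
  expect_identical(al$D$slot, "Order")
})

test_that("alignment invariants hold: |M| + |D| = principle length, score recomputes", {
  st <- toy_stats()
  sc <- default_slot_scheme()
  cases <- list(
    list(txt = "hsa-miR-181b", pr = c("Species", "miRNA", "Order")),
    list(txt = "miR-21, 221 and 128a",
         pr = c("Precursor", "Species", "miRNA", "Order", "Conj", "Order",
                "Suffix")),
    list(txt = "pre-miR-149", pr = c("miRNA", "Order")),
    list(txt = "micro RNA-66b", pr = c("miRNA", "Order")))
  for (cs in cases) {
    al <- align_window(label_slots(tokenize(cs$txt), sc), cs$pr, st)
    expect_identical(nrow(al$M) + nrow(al$D), length(cs$pr))
    expect_true(all(diff(al$M$token) > 0))
    expect_equal(al$score, sequence_score(al, st))
  }
})

test_that("an empty principle inserts every token", {
  st <- toy_stats()
  lab <- make_labeled(c("-", ","), list(character(), character()))
  al <- align_window(lab, character(), st)
  expect_identical(nrow(al$M), 0L)
  expect_identical(nrow(al$D), 0L)
  expect_identical(nrow(al$I), 2L)
})

test_that("a multi-token indicator matches as one slot occurrence", {
  st <- toy_stats()
  sc <- default_slot_scheme()
  al <- align_window(label_slots(tokenize("micro RNA-21"), sc),
                     c("miRNA", "Order"), st)
  expect_identical(al$M$slot, c("miRNA", "Order"))
  expect_identical(al$M$text[1], "micro RNA")
  expect_identical(nrow(al$I), 1L)   # just the hyphen
})

test_that("the DP aligner equals exhaustive enumeration on random cases", {
  st <- toy_stats()
  slot_pool <- c("Species", "Precursor", "miRNA", "Order", "Conj", "Suffix",
                 "Let")
  word_pool <- c("-", ",", "this", "unknownword")
  set.seed(77)
  for (rep in 1:120) {
    n <- sample(1:8, 1); m <- sample(1:5, 1)
    labels <- lapply(seq_len(n), function(i) {
      k <- sample(0:2, 1)
      if (k == 0) character() else sample(slot_pool, k)
    })
    texts <- vapply(seq_len(n), function(i)
      if (length(labels[[i]])) paste0("t", i) else sample(word_pool, 1),
      character(1))
    pr <- sample(slot_pool, m, replace = TRUE)
    lab <- make_labeled(texts, labels)
    al <- align_window(lab, pr, st)
    expect_equal(al$score, enum_align_score(texts, labels, pr, st),
                 tolerance = 1e-9)
  }
})

test_that("recognition accepts grammar mentions and respects thresholds", {
  fx <- shared_fixture()
  model <- fx$model
  sent <- "expression of hsa-miR-181b in cells."
  lab <- label_slots(tokenize(sent), model$scheme)
  found <- recognize_mentions(lab, model$clusters, model$stats)
  expect_identical(nrow(found), 1L)
  expect_identical(found$surface, "hsa-miR-181b")
  expect_true(found$accepted)
  expect_true(found$score >= found$threshold)
})

test_that("a bare anaphoric indicator is generated but filtered out", {
  fx <- shared_fixture()
  model <- fx$model
  sent <- "aberrant expression of this miR confers a growth advantage"
  lab <- label_slots(tokenize(sent), model$scheme)
  expect_identical(
    nrow(recognize_mentions(lab, model$clusters, model$stats)), 0L)
  cand <- recognize_mentions(lab, model$clusters, model$stats,
                             keep_rejected = TRUE)
  expect_identical(nrow(cand), 1L)
  expect_false(cand$accepted)
  expect_true(cand$score < cand$threshold)
})

test_that("sentences without an anchor slot yield no mentions", {
  fx <- shared_fixture()
  lab <- label_slots(tokenize("the expression of 21 genes in hsa cells"),
                     fx$model$scheme)
  expect_identical(
    nrow(recognize_mentions(lab, fx$model$clusters, fx$model$stats)), 0L)
})

test_that("extending a mention with matched slots never lowers its score", {
  fx <- shared_fixture()
  model <- fx$model
  st <- model$stats
  sc <- model$scheme
  pr <- c("Species", "miRNA", "Order")
  short <- align_window(label_slots(tokenize("miR-21"), sc), pr, st)
  long <- align_window(label_slots(tokenize("hsa-miR-21"), sc), pr, st)
  expect_true(long$score >= short$score)
})
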