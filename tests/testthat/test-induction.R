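test_that("candidate principles mirror the gold mention decompositions", {
  pr <- extract_principles(toy_corpus(), default_slot_scheme())
  keys <- vapply(pr, spba:::principle_key, character(1))
  expect_true("Species miRNA Order" %in% keys)        # hsa-miR-181b
  expect_true("Precursor miRNA Order" %in% keys)      # pre-miR-149
  expect_true("Species miRNA Order Order" %in% keys)  # cel-miR-16-2
  expect_true("miRNA Order Hairpin" %in% keys)        # miR-485-5p
  # hyphens inside mentions are recorded as non-slot words
  p <- pr[[match("Species miRNA Order", keys)]]
  expect_identical(p$nonslot_counts[["-"]], 1L)
})

test_that("identical slot sequences merge with summed support", {
  doc <- new_document("d", "x hsa-miR-21 y hsa-miR-22 z.",
                      data.frame(start = c(2L, 15L), end = c(12L, 25L),
                                 surface = c("hsa-miR-21", "hsa-miR-22"),
                                 accessions = c("", ""),
                                 stringsAsFactors = FALSE))
  pr <- extract_principles(spba_corpus(list(doc)), default_slot_scheme())
  expect_length(pr, 1L)
  expect_identical(pr[[1]]$support, 2L)
  expect_identical(pr[[1]]$nonslot_counts[["-"]], 2L)
})

test_that("misaligned and label-free annotations are skipped with warnings", {
  doc <- new_document("d", "abc miR-21 and plainwords here.",
                      data.frame(start = c(2L, 15L), end = c(8L, 25L),
                                 surface = c("", ""), accessions = c("", ""),
                                 stringsAsFactors = FALSE))
  w <- capture_warnings(
    pr <- extract_principles(spba_corpus(list(doc)), default_slot_scheme()))
  expect_true(any(grepl("token boundaries", w)))
  expect_true(any(grepl("labeled token", w)))
  expect_length(pr, 0L)
})

test_that("domination follows the per-operation edit limits", {
  dom <- c("Precursor", "Species", "miRNA", "Order", "Conj", "Order",
           "Suffix")
  expect_true(dominates(dom, c("Species", "miRNA", "Order", "Order"),
                        ids_criteria(3, 0, 0)))
  expect_true(dominates(dom, c("Precursor", "miRNA", "Order", "Order"),
                        ids_criteria(3, 0, 0)))
  expect_true(dominates(dom, c("miRNA", "Order", "Suffix"),
                        ids_criteria(4, 0, 0)))
  expect_true(dominates(dom, dom, ids_criteria(0, 0, 0)))
  expect_false(dominates(c("miRNA"), c("Species", "miRNA", "Order", "Order"),
                         ids_criteria(1, 0, 0)))
  expect_true(dominates(c("miRNA"), c("Species", "miRNA", "Order", "Order"),
                        ids_criteria(0, 3, 0)))
  expect_true(dominates(c("A", "B"), c("A", "C"), ids_criteria(0, 0, 1)))
  expect_false(dominates(c("A", "B"), c("A", "C"), ids_criteria(0, 0, 0)))
})

test_that("the documented cluster emerges from its four principles", {
  dom <- spba:::new_principle(
    c("Precursor", "Species", "miRNA", "Order", "Conj", "Order", "Suffix"))
  others <- list(
    spba:::new_principle(c("Species", "miRNA", "Order", "Order")),
    spba:::new_principle(c("Precursor", "miRNA", "Order", "Order")),
    spba:::new_principle(c("miRNA", "Order", "Suffix")))
  graph <- build_domination_graph(c(list(dom), others), ids_criteria(4, 0, 0))
  clusters <- greedy_dominating_set(graph)
  expect_length(clusters, 1L)
  expect_identical(clusters[[1]]$dominant$slots, dom$slots)
  expect_identical(clusters[[1]]$core_slots, c("Order", "miRNA"))
  expect_setequal(clusters[[1]]$optional_slots,
                  c("Precursor", "Species", "Conj", "Suffix"))
})

test_that("degenerate graphs cluster as expected", {
  expect_identical(greedy_dominating_set(
    structure(list(principles = list(), edges = list()),
              class = "spba_domgraph")), list())
  # no edges: every principle its own cluster
  pr <- lapply(c("A", "B", "C"), spba:::new_principle)
  g <- structure(list(principles = pr,
                      edges = list(integer(), integer(), integer())),
                 class = "spba_domgraph")
  expect_length(greedy_dominating_set(g), 3L)
  # star: one dominator covers everything
  g$edges <- list(2:3, integer(), integer())
  cl <- greedy_dominating_set(g)
  expect_length(cl, 1L)
  expect_identical(cl[[1]]$dominant$slots, "A")
})

test_that("every principle stays covered by some cluster", {
  set.seed(42)
  for (rep in 1:10) {
    g <- random_domgraph(sample(3:9, 1))
    clusters <- greedy_dominating_set(g)
    covered <- unique(unlist(lapply(clusters, function(cl)
      c(spba:::principle_key(cl$dominant),
        vapply(cl$dominated, spba:::principle_key, character(1))))))
    all_keys <- vapply(g$principles, spba:::principle_key, character(1))
    expect_setequal(covered, all_keys)
  }
})

test_that("training twice on the same corpus gives identical clusters", {
  fx <- generate_corpus(fixture_config(n_documents = 15, seed = 7))
  m1 <- spba_train(fx$corpus)
  m2 <- spba_train(fx$corpus)
  expect_identical(lapply(m1$clusters, `[[`, "dominant"),
                   lapply(m2$clusters, `[[`, "dominant"))
  expect_identical(vapply(m1$clusters, `[[`, numeric(1), "threshold"),
                   vapply(m2$clusters, `[[`, numeric(1), "threshold"))
})
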