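test_that("the family table parser follows the documented column rules", {
  lex <- read_family_file(toy_family_path())
  accs <- vapply(lex$entries, `[[`, character(1), "accession")
  names_of <- function(acc) lex$entries[[match(acc, accs)]]$names
  # accession/id pairing
  expect_true("mir-1255" %in% names_of("RF00994"))
  # slash expansion in the description
  expect_true(all(c("mir-103", "mir-107") %in% names_of("RF00129")))
  # previous-name cells: "\N" contributes nothing, real ones are split
  expect_true(all(c("mir555", "mir_555") %in% names_of("RF90001")))
  n994 <- names_of("RF00994")
  expect_false(any(grepl("\\\\N", unlist(lapply(lex$entries, `[[`,
                                                "names")))))
  # hyphen/underscore -> space variants are added
  expect_true("mir 1255" %in% n994)
  expect_true("mir 555" %in% names_of("RF90001"))
})

test_that("malformed family lines are skipped with warnings", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("RF00001\tmir-9\t\\N\tmir-9 family\ta\tb\tc\td\te\tf\t\\N",
               "short\tline",
               "BAD42\tmir-8\t\\N\tx\ta\tb\tc\td\te\tf\t\\N"), p)
  w <- capture_warnings(lex <- read_family_file(p))
  expect_true(all(grepl("skipped", w)))
  expect_length(w, 2L)
  expect_length(lex$entries, 1L)
  expect_identical(lex$entries[[1]]$accession, "RF00001")
  expect_error(read_family_file(file.path(tempdir(), "missing.txt")),
               "not found")
})

test_that("the slot index reaches every entry and rebuilds identically", {
  fx <- shared_fixture()
  model <- fx$model
  lex <- read_family_file(toy_family_path())
  idx <- build_slot_index(lex, model$scheme, model$clusters, model$stats)
  indexed <- sort(unique(unlist(mget(ls(idx$keys), envir = idx$keys))))
  expect_setequal(indexed,
                  vapply(lex$entries, `[[`, character(1), "accession"))
  idx2 <- build_slot_index(lex, model$scheme, model$clusters, model$stats)
  expect_identical(sort(ls(idx$keys)), sort(ls(idx2$keys)))
  # an Order value maps to its family
  expect_true("RF00994" %in% idx$keys[[paste("Order", "1255", sep = "\r")]])
  # empty lexicon -> empty index
  empty <- structure(list(entries = list()), class = "spba_lexicon")
  e_idx <- build_slot_index(empty, model$scheme, model$clusters, model$stats)
  expect_length(ls(e_idx$keys), 0L)
})

test_that("mentions ground to the right accessions", {
  fx <- shared_fixture()
  model <- fx$model
  lex <- read_family_file(toy_family_path())
  idx <- build_slot_index(lex, model$scheme, model$clusters, model$stats)
  # exact name
  expect_identical(top_accessions(
    normalize_mention("hsa-miR-1255", idx, model$stats)), "RF00994")
  # slash mention grounded to both families
  nm <- normalize_mention("miR-1/133a", idx, model$stats)
  expect_setequal(top_accessions(nm), c("RF00103", "RF00446"))
  expect_identical(length(unique(nm$group)), 2L)
  # value absent from the lexicon: unnormalized
  expect_identical(nrow(normalize_mention("miR-9999", idx, model$stats)), 0L)
  # raw-token fallback name
  expect_identical(top_accessions(
    normalize_mention("mir555", idx, model$stats)), "RF90001")
})

test_that("indexed top-1 equals brute-force scoring over the whole lexicon", {
  model <- shared_fixture()$model
  # a small corpus keeps the lexicon well under 200 entries
  small <- generate_corpus(fixture_config(n_documents = 30, seed = 505))
  p <- withr::local_tempfile(fileext = ".txt")
  write_family_file(small$family, p)
  lex <- read_family_file(p)
  expect_lte(length(lex$entries), 200L)
  idx <- build_slot_index(lex, model$scheme, model$clusters, model$stats)
  gold <- corpus_annotations(small$corpus)
  plain <- gold[!grepl(";", gold$accessions) &
                  !grepl(",| and ", gold$surface), ]
  set.seed(5)
  pick <- plain[sample(nrow(plain), min(15, nrow(plain))), ]
  for (i in seq_len(nrow(pick))) {
    nm <- normalize_mention(pick$surface[i], idx, model$stats)
    if (!nrow(nm)) next
    bf <- brute_force_top1(pick$surface[i], lex, model$scheme, model$stats)
    expect_identical(nm$accession[1], bf$accession,
                     label = paste("mention", pick$surface[i]))
  }
})

test_that("unambiguous gold names normalize with full top-1 accuracy", {
  model <- shared_fixture()$model
  small <- generate_corpus(fixture_config(n_documents = 30, seed = 506))
  p <- withr::local_tempfile(fileext = ".txt")
  write_family_file(small$family, p)
  lex <- read_family_file(p)
  idx <- build_slot_index(lex, model$scheme, model$clusters, model$stats)
  gold <- corpus_annotations(small$corpus)
  plain <- gold[!grepl(";", gold$accessions), ]
  hits <- vapply(seq_len(nrow(plain)), function(i) {
    nm <- normalize_mention(plain$surface[i], idx, model$stats)
    nrow(nm) > 0 && identical(top_accessions(nm), plain$accessions[i])
  }, logical(1))
  expect_identical(mean(hits), 1)
})

test_that("ambiguity statistics match hand counts", {
  mk <- function(...) structure(list(entries = list(...)),
                                class = "spba_lexicon")
  # 2 entries, 3 unique names, one name shared
  lex <- mk(list(accession = "RF00001", names = c("a", "shared")),
            list(accession = "RF00002", names = c("b", "shared")))
  rep <- ambiguity_report(lex)
  expect_equal(rep$ids_per_name, 4 / 3)
  expect_equal(rep$names_per_id, 2)
  expect_identical(rep$english_fraction, 0)
  # disjoint single names
  lex2 <- mk(list(accession = "RF00001", names = "a"),
             list(accession = "RF00002", names = "b"))
  expect_equal(ambiguity_report(lex2)$ids_per_name, 1)
  expect_equal(ambiguity_report(lex2, english_words = c("a", "zz"))
               $english_fraction, 0.5)
})
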