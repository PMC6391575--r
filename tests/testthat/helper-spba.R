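# Shared builders for the test suite. Everything is generated in code; the
# only on-disk fixture is the bundled synthetic toy family file.

toy_family_path <- function() {
  system.file("extdata", "toy_family_synthetic.txt", package = "spba")
}

# hand-set statistics with easy round numbers for scoring/alignment tests
toy_stats <- function(lambda = 100) {
  slots <- data.frame(
    symbol = c("Species", "Precursor", "miRNA", "Let", "Order", "Conj",
               "Suffix", "Hairpin", "Prefix"),
    freq_m = c(18L, 10L, 40L, 8L, 60L, 4L, 12L, 12L, 28L),
    freq_n = c(2L,  2L,  2L,  0L, 4L,  12L, 0L,  0L,  4L),
    stringsAsFactors = FALSE)
  words <- data.frame(
    symbol = c("-", ",", "(", ")", "this"),
    freq_m = c(50L, 10L, 0L, 0L, 0L),
    freq_n = c(10L, 90L, 30L, 30L, 40L),
    stringsAsFactors = FALSE)
  slot_statistics(slots, words, lambda = lambda)
}

# a labeled sequence built directly from token texts and label sets,
# bypassing the tokenizer (offsets are synthesized)
make_labeled <- function(texts, labels) {
  stopifnot(length(texts) == length(labels))
  n <- length(texts)
  ends <- cumsum(nchar(texts) + 1L)
  tokens <- data.frame(text = texts,
                       start = c(0L, head(ends, -1L)),
                       end = ends - 1L,
                       stringsAsFactors = FALSE)
  structure(list(tokens = tokens, labels = labels,
                 runs = data.frame(from = integer(), to = integer(),
                                   slot = character(),
                                   stringsAsFactors = FALSE),
                 text = paste(texts, collapse = " ")),
            class = "spba_labeled")
}

# a tiny two-document corpus with hand-placed gold spans
toy_corpus <- function() {
  t1 <- "expression of hsa-miR-181b and pre-miR-149 in cells."
  t2 <- "levels of cel-miR-16-2 increased while miR-485-5p decreased."
  a1 <- data.frame(start = c(14L, 31L), end = c(26L, 42L),
                   surface = c("hsa-miR-181b", "pre-miR-149"),
                   accessions = c("RF10001", "RF10002"),
                   stringsAsFactors = FALSE)
  a2 <- data.frame(start = c(10L, 39L), end = c(22L, 49L),
                   surface = c("cel-miR-16-2", "miR-485-5p"),
                   accessions = c("RF10003", "RF10004"),
                   stringsAsFactors = FALSE)
  spba_corpus(list(new_document("d1", t1, a1), new_document("d2", t2, a2)))
}

# one trained model on a seeded synthetic corpus, shared across test files
shared_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      train <- generate_corpus(fixture_config(n_documents = 100, seed = 101))
      cache <<- list(train = train, model = spba_train(train$corpus))
    }
    cache
  }
})

# maximum Eq-1 score over all monotone alignments, by explicit enumeration
# of matched index pairs (independent of the DP implementation)
enum_align_score <- function(texts, labels, slots, stats) {
  n <- length(texts); m <- length(slots)
  ins <- vapply(seq_len(n), function(i) {
    if (length(labels[[i]]))
      min(vapply(labels[[i]],
                 function(s) insertion_penalty(stats, s, "slot"), numeric(1)))
    else insertion_penalty(stats, texts[i], "word")
  }, numeric(1))
  del <- vapply(slots, function(s) deletion_penalty(stats, s), numeric(1))
  gain <- vapply(slots, function(s) match_score(stats, s), numeric(1))
  ok <- function(ti, si) slots[si] %in% labels[[ti]]
  best <- -sum(ins) - sum(del)          # the all-insert/all-delete alignment
  if (is.nan(best)) best <- -Inf
  for (k in seq_len(min(n, m))) {
    tok_sets <- utils::combn(n, k, simplify = FALSE)
    slot_sets <- utils::combn(m, k, simplify = FALSE)
    for (ts in tok_sets) for (ss in slot_sets) {
      if (!all(mapply(ok, ts, ss))) next
      sc <- sum(gain[ss]) - sum(ins[-ts]) - sum(del[-ss])
      if (is.nan(sc)) sc <- -Inf
      if (sc > best) best <- sc
    }
  }
  best
}

# exact minimum dominating set size by exhaustive search (test oracle only)
exact_min_domset_size <- function(edges) {
  n <- length(edges)
  cover_of <- lapply(seq_len(n), function(v) unique(c(v, edges[[v]])))
  for (k in seq_len(n)) {
    for (comb in utils::combn(n, k, simplify = FALSE)) {
      if (length(unique(unlist(cover_of[comb]))) == n) return(k)
    }
  }
  n
}

random_domgraph <- function(n, p_edge = 0.25) {
  pr <- lapply(seq_len(n), function(i)
    spba:::new_principle(paste0("S", i), support = sample(1:5, 1)))
  edges <- lapply(seq_len(n), function(i) {
    out <- which(stats::runif(n) < p_edge)
    setdiff(out, i)
  })
  structure(list(principles = pr, edges = edges,
                 criteria = ids_criteria()),
            class = "spba_domgraph")
}

# brute-force normalization: score the mention against every entry's every
# name, no index involved
brute_force_top1 <- function(mention, lexicon, scheme, stats) {
  scores <- vapply(lexicon$entries, function(e)
    max(vapply(e$names, function(nm)
      mention_name_score(mention, nm, scheme, stats), numeric(1))),
    numeric(1))
  accs <- vapply(lexicon$entries, `[[`, character(1), "accession")
  ord <- order(-scores, accs)
  list(accession = accs[ord[1]], score = scores[ord[1]])
}
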