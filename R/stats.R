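#' Construct a slot statistics object
#'
#' Usually produced by [estimate_slot_statistics()]; the constructor is
#' exported so that statistics can also be built programmatically (tests,
#' worked examples).
#'
#' @param slots Data frame with columns `symbol`, `freq_m`, `freq_n`: per
#'   slot, its occurrence counts inside and outside gold miRNA mentions.
#' @param words Same layout for unlabeled words (the "non-slot" symbols such
#'   as "-" and ",").
#' @param lambda Scale constant of the matched-slot score; the matched score
#'   of a slot occurring exclusively inside mentions is exactly `lambda`.
#' @param unseen_match Matched score used for a slot absent from the
#'   statistics (default `lambda / 2`: an unseen slot neither accepts nor
#'   rejects on its own).
#' @param unseen_insertion Insertion penalty used for a symbol absent from
#'   the statistics.
#' @param pseudocount Additive smoothing applied to both frequencies
#'   (default 0, i.e. none).
#' @return An object of class `spba_stats`.
#' @export
slot_statistics <- function(slots, words, lambda = 100,
                            unseen_match = lambda / 2,
                            unseen_insertion = 30, pseudocount = 0) {
  stopifnot(lambda > 0, pseudocount >= 0)
  for (df in list(slots, words)) {
    stopifnot(all(c("symbol", "freq_m", "freq_n") %in% names(df)),
              all(df$freq_m >= 0), all(df$freq_n >= 0))
  }
  structure(list(slots = slots, words = words, lambda = lambda,
                 unseen_match = unseen_match,
                 unseen_insertion = unseen_insertion,
                 pseudocount = pseudocount),
            class = "spba_stats")
}

#' @export
print.spba_stats <- function(x, ...) {
  cat("<spba_stats> lambda=", x$lambda, "; ", nrow(x$slots), " slots, ",
      nrow(x$words), " non-slot words\n", sep = "")
  invisible(x)
}

#' Estimate per-slot corpus statistics
#'
#' Counts, for every slot label and every unlabeled word, its occurrences
#' inside gold mention spans (`freq_m`) and outside them (`freq_n`) over the
#' whole training corpus. A token carrying several labels (e.g. a child slot
#' and its parent) counts once for each. These frequencies drive the matched
#' score, the insertion penalty and the deletion penalty.
#'
#' @inheritParams extract_principles
#' @inheritParams slot_statistics
#' @return An `spba_stats` object.
#' @export
estimate_slot_statistics <- function(corpus, scheme, lambda = 100,
                                     unseen_match = lambda / 2,
                                     unseen_insertion = 30,
                                     pseudocount = 0) {
  if (!length(corpus$documents)) stop("empty corpus: no documents")
  slot_m <- list(); slot_n <- list(); word_m <- list(); word_n <- list()
  bump <- function(env, key) {
    env[[key]] <- (env[[key]] %||% 0L) + 1L
    env
  }
  for (doc in corpus$documents) {
    labeled <- label_slots(tokenize(doc$text), scheme)
    toks <- labeled$tokens
    anns <- doc$annotations
    inside <- rep(FALSE, nrow(toks))
    for (a in seq_len(nrow(anns)))
      inside <- inside | (toks$start >= anns$start[a] &
                          toks$end <= anns$end[a])
    for (i in seq_len(nrow(toks))) {
      labs <- labeled$labels[[i]]
      if (length(labs)) {
        for (s in labs) {
          if (inside[i]) slot_m <- bump(slot_m, s)
          else slot_n <- bump(slot_n, s)
        }
      } else {
        w <- casefold_term(toks$text[i])
        if (inside[i]) word_m <- bump(word_m, w)
        else word_n <- bump(word_n, w)
      }
    }
  }
  tab <- function(m, n) {
    syms <- sort(union(names(m), names(n)))
    data.frame(symbol = syms,
               freq_m = vapply(syms, function(s) m[[s]] %||% 0L, integer(1)),
               freq_n = vapply(syms, function(s) n[[s]] %||% 0L, integer(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  slot_statistics(tab(slot_m, slot_n), tab(word_m, word_n), lambda = lambda,
                  unseen_match = unseen_match,
                  unseen_insertion = unseen_insertion,
                  pseudocount = pseudocount)
}

stats_row <- function(stats, symbol, kind = c("slot", "word")) {
  kind <- match.arg(kind)
  df <- if (kind == "slot") stats$slots else stats$words
  i <- match(symbol, df$symbol)
  if (is.na(i)) return(NULL)
  fm <- df$freq_m[i] + stats$pseudocount
  fn <- df$freq_n[i] + stats$pseudocount
  if (fm + fn <= 0) return(NULL)
  list(fm = fm, fn = fn, p_m = fm / (fm + fn), p_n = fn / (fm + fn))
}

#' Matched-slot score
#'
#' `lambda * freq_m / (freq_m + freq_n)`: the probability that an occurrence
#' of the slot lies inside a miRNA mention, scaled to `[0, lambda]`. A slot
#' occurring exclusively inside mentions scores exactly `lambda`.
#'
#' @param stats An `spba_stats` object.
#' @param slot Slot identifier.
#' @return A score in `[0, lambda]`; `stats$unseen_match` for unseen slots.
#' @export
match_score <- function(stats, slot) {
  r <- stats_row(stats, slot, "slot")
  if (is.null(r)) return(stats$unseen_match)
  stats$lambda * r$p_m
}

#' Insertion penalty of a symbol
#'
#' The inverse entropy `1 / H` of the symbol's inside/outside distribution,
#' with `H = -(p_m log2 p_m + p_n log2 p_n)`: a non-negative cost subtracted
#' from the alignment score for every inserted symbol. Boundary cases: a
#' symbol never seen outside mentions inserts for free (penalty 0); a symbol
#' never seen inside mentions cannot be inserted (penalty `Inf`, rejecting
#' the candidate).
#'
#' @param stats An `spba_stats` object.
#' @param symbol A slot identifier (`kind = "slot"`) or a literal word
#'   (`kind = "word"`).
#' @param kind Whether the symbol is a slot or a non-slot word.
#' @return A non-negative penalty, possibly `Inf`;
#'   `stats$unseen_insertion` for unseen symbols.
#' @export
insertion_penalty <- function(stats, symbol, kind = c("slot", "word")) {
  r <- stats_row(stats, symbol, match.arg(kind))
  if (is.null(r)) return(stats$unseen_insertion)
  if (r$p_n == 0) return(0)
  if (r$p_m == 0) return(Inf)
  h <- -(r$p_m * log2(r$p_m) + r$p_n * log2(r$p_n))
  1 / h
}

#' Deletion penalty of a slot
#'
#' `-log2` of the slot's probability of belonging to a miRNA mention (the
#' matched score normalized by `lambda`): deleting a mention-exclusive slot
#' is free, deleting a slot that never occurs in mentions is forbidden
#' (penalty `Inf`).
#'
#' @inheritParams match_score
#' @return A non-negative penalty, possibly `Inf`.
#' @export
deletion_penalty <- function(stats, slot) {
  m <- match_score(stats, slot)
  if (m <= 0) return(Inf)
  -log2(m / stats$lambda)
}

as_insertion_df <- function(I) {
  if (is.null(I)) return(data.frame(symbol = character(), kind = character(),
                                    stringsAsFactors = FALSE))
  if (is.data.frame(I)) return(I)
  # a bare character vector is interpreted as non-slot words
  data.frame(symbol = as.character(I), kind = "word", stringsAsFactors = FALSE)
}

#' Total score of an alignment
#'
#' The candidate score: the sum of matched-slot scores minus the insertion
#' penalties of all inserted symbols minus the deletion penalties of all
#' deleted slots. Any infinite penalty rejects the candidate (`-Inf`).
#'
#' @param alignment Either an `spba_alignment` from [align_window()], or a
#'   list with elements `M` (character vector of matched slots), `I`
#'   (data frame with columns `symbol`, `kind`, or a character vector of
#'   words) and `D` (character vector of deleted slots).
#' @param stats An `spba_stats` object.
#' @return The score (possibly `-Inf`).
#' @export
sequence_score <- function(alignment, stats) {
  M <- alignment$M
  if (is.data.frame(M)) M <- M$slot
  D <- alignment$D
  if (is.data.frame(D)) D <- D$slot
  I <- as_insertion_df(alignment$I)
  total <- 0
  for (s in M) total <- total + match_score(stats, s)
  for (k in seq_len(nrow(I))) {
    pen <- insertion_penalty(stats, I$symbol[k], I$kind[k])
    if (!is.finite(pen)) return(-Inf)
    total <- total - pen
  }
  for (s in D) {
    pen <- deletion_penalty(stats, s)
    if (!is.finite(pen)) return(-Inf)
    total <- total - pen
  }
  total
}

#' Acceptance threshold of a principle cluster
#'
#' The threshold against which candidate scores are compared: the summed
#' matched scores of the cluster's core slots, minus the deletion penalties
#' of the dominant's non-core slot positions, adjusted by the expected
#' insertion penalties of the optional slots and of the non-slot words
#' weighted by their occurrence probabilities in the cluster's source
#' mentions. A candidate is accepted iff its score is at least the
#' threshold.
#'
#' @param cluster An `spba_cluster` from [greedy_dominating_set()].
#' @param stats An `spba_stats` object.
#' @param insertion_sign Sign applied to the two expected-insertion terms:
#'   `-1` (default) treats insertion scores as penalties lowering the
#'   threshold, `+1` adds them instead.
#' @return The threshold (numeric scalar).
#' @export
cluster_threshold <- function(cluster, stats, insertion_sign = -1) {
  stopifnot(insertion_sign %in% c(-1, 1))
  th <- 0
  for (s in cluster$core_slots) th <- th + match_score(stats, s)
  for (s in principle_slots(cluster$dominant)) {
    if (!(s %in% cluster$core_slots)) th <- th - deletion_penalty(stats, s)
  }
  for (s in cluster$optional_slots) {
    pen <- insertion_penalty(stats, s, "slot")
    if (is.finite(pen))
      th <- th + insertion_sign * cluster$optional_probs[[s]] * pen
  }
  for (w in names(cluster$nonslot_probs)) {
    pen <- insertion_penalty(stats, w, "word")
    if (is.finite(pen))
      th <- th + insertion_sign * cluster$nonslot_probs[[w]] * pen
  }
  th
}
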