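#' Split text into sentences
#'
#' A rule splitter: a sentence ends at a run of `.`, `!` or `?` followed by
#' whitespace (or end of text). Offsets are 0-based, half-open into the
#' original text, so `substr(text, start + 1, end)` recovers each sentence.
#'
#' @param text A single string.
#' @return A data frame with columns `text`, `start`, `end`; zero rows for
#'   empty input.
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (!nzchar(trimws(text))) return(empty)
  m <- gregexpr("[.!?]+(\\s+|$)", text, perl = TRUE)[[1]]
  starts <- integer(); ends <- integer()
  pos <- 1L
  if (m[1] != -1L) {
    lens <- attr(m, "match.length")
    for (k in seq_along(m)) {
      punct <- regmatches(text, list(m))[[1]][k]
      punct_len <- nchar(sub("\\s+$", "", punct))
      send <- m[k] + punct_len - 1L      # 1-based inclusive end
      if (send >= pos) {
        sstart <- pos
        while (sstart <= send && grepl("^\\s$", substr(text, sstart, sstart)))
          sstart <- sstart + 1L
        if (sstart <= send) { starts <- c(starts, sstart); ends <- c(ends, send) }
      }
      pos <- m[k] + lens[k]
    }
  }
  if (pos <= nchar(text) && nzchar(trimws(substr(text, pos, nchar(text))))) {
    sstart <- pos
    while (grepl("^\\s$", substr(text, sstart, sstart))) sstart <- sstart + 1L
    send <- nchar(text)
    while (grepl("^\\s$", substr(text, send, send))) send <- send - 1L
    starts <- c(starts, sstart); ends <- c(ends, send)
  }
  if (!length(starts)) return(empty)
  data.frame(text = substring(text, starts, ends),
             start = starts - 1L, end = ends,
             stringsAsFactors = FALSE)
}

#' Tokenize a sentence
#'
#' Splits on whitespace, then splits off each of `-`, `,`, `/`, `(`, `)` as a
#' single-character token; every other maximal run of characters is one
#' token. This convention makes hyphenated miRNA names decompose as e.g.
#' `"miR-16-2"` -> `miR`, `-`, `16`, `-`, `2`. Offsets are 0-based half-open.
#'
#' @param sentence A single string.
#' @return A data frame with columns `text`, `start`, `end` and the source
#'   string attached as attribute `"source"`.
#' @export
tokenize <- function(sentence) {
  stopifnot(is.character(sentence), length(sentence) == 1L)
  if (!nzchar(sentence)) {
    out <- data.frame(text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "source") <- sentence
    return(out)
  }
  m <- gregexpr("[^\\s,/()-]+|[-,/()]", sentence, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    out <- data.frame(text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  } else {
    lens <- attr(m, "match.length")
    out <- data.frame(text = substring(sentence, m, m + lens - 1L),
                      start = as.integer(m) - 1L,
                      end = as.integer(m) + lens - 1L,
                      stringsAsFactors = FALSE)
  }
  attr(out, "source") <- sentence
  out
}

#' Label tokens with slots
#'
#' Each token receives every slot whose terms or open-class pattern match it
#' (including ancestor slots, by generalization). Closed-class terms spanning
#' several tokens (e.g. "micro rna") are matched greedily longest-first and
#' label all covered tokens; the covered run is remembered so that alignment
#' and principle extraction can treat it as a single slot occurrence.
#'
#' @param tokens A token data frame from [tokenize()].
#' @param scheme An `spba_scheme`.
#' @return An object of class `spba_labeled`: a list with `tokens`, `labels`
#'   (one character vector per token), `runs` (data frame of multi-token term
#'   matches with columns `from`, `to`, `slot`) and `text` (the source
#'   string, when known).
#' @export
label_slots <- function(tokens, scheme) {
  n <- nrow(tokens)
  labels <- rep(list(character()), n)
  runs <- data.frame(from = integer(), to = integer(), slot = character(),
                     stringsAsFactors = FALSE)
  folded <- casefold_term(tokens$text)
  # multi-token closed-class terms, longest first
  mw <- list()
  for (s in scheme$slots) {
    for (tm in s$terms[grepl(" ", s$terms, fixed = TRUE)]) {
      mw[[length(mw) + 1L]] <- list(slot = s$name,
                                    words = strsplit(tm, " ", fixed = TRUE)[[1]])
    }
  }
  if (length(mw)) {
    mw <- mw[order(-vapply(mw, function(x) length(x$words), integer(1)))]
    covered <- rep(FALSE, n)
    i <- 1L
    while (i <= n) {
      hit <- FALSE
      for (term in mw) {
        k <- length(term$words)
        if (i + k - 1L <= n && !any(covered[i:(i + k - 1L)]) &&
            all(folded[i:(i + k - 1L)] == term$words)) {
          lab <- c(term$slot, slot_ancestors(scheme, term$slot))
          for (j in i:(i + k - 1L))
            labels[[j]] <- union(labels[[j]], lab)
          covered[i:(i + k - 1L)] <- TRUE
          runs <- rbind(runs, data.frame(from = i, to = i + k - 1L,
                                         slot = term$slot,
                                         stringsAsFactors = FALSE))
          i <- i + k
          hit <- TRUE
          break
        }
      }
      if (!hit) i <- i + 1L
    }
  }
  # single-token terms and open-class patterns
  for (i in seq_len(n))
    labels[[i]] <- sort(union(labels[[i]], lookup_term(scheme, folded[i])))
  structure(list(tokens = tokens, labels = labels, runs = runs,
                 text = attr(tokens, "source")),
            class = "spba_labeled")
}

#' @export
print.spba_labeled <- function(x, ...) {
  cat("<spba_labeled> ", nrow(x$tokens), " tokens\n", sep = "")
  for (i in seq_len(nrow(x$tokens))) {
    lab <- if (length(x$labels[[i]])) paste(x$labels[[i]], collapse = ",")
           else "-"
    cat(sprintf("  %2d %-12s %s\n", i, x$tokens$text[i], lab))
  }
  invisible(x)
}

# the single most specific label of a token, used when one slot per token is
# needed (principle extraction, normalization); NA when unlabeled
primary_label <- function(labels, scheme) {
  if (!length(labels)) return(NA_character_)
  d <- vapply(labels, function(s) slot_depth(scheme, s), integer(1))
  cand <- sort(labels[d == max(d)])
  cand[1]
}

# subset a labeled sequence to token indices idx (kept contiguous)
labeled_window <- function(labeled, idx) {
  runs <- labeled$runs
  if (nrow(runs))
    runs <- runs[runs$from >= min(idx) & runs$to <= max(idx), , drop = FALSE]
  shift <- min(idx) - 1L
  if (nrow(runs)) { runs$from <- runs$from - shift; runs$to <- runs$to - shift }
  structure(list(tokens = labeled$tokens[idx, , drop = FALSE],
                 labels = labeled$labels[idx],
                 runs = runs, text = labeled$text),
            class = "spba_labeled")
}
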