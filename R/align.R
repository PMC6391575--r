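#' Align a labeled token window against a principle
#'
#' Dynamic programming over (token index, slot index) with three moves:
#' match a token to the next principle slot when the slot is among the
#' token's labels (gaining the slot's matched score), insert a token
#' (subtracting its insertion penalty: the cheapest of its slot labels when
#' labeled, the word penalty otherwise), or delete a principle slot
#' (subtracting its deletion penalty). A multi-token term run (e.g.
#' "micro rna") matches or inserts as a single unit. The alignment with the
#' maximum total score is returned; ties break by fewer insertions, then
#' fewer deletions, then leftmost matches.
#'
#' @param window An `spba_labeled` sequence (see [label_slots()]).
#' @param principle An `spba_principle` or character vector of slots.
#' @param stats An `spba_stats` object.
#' @return An object of class `spba_alignment`: list with `principle`, `M`
#'   (data frame `token`, `slot`, `text`, `gain`), `I` (data frame `token`,
#'   `symbol`, `kind`, `penalty`), `D` (data frame `pos`, `slot`,
#'   `penalty`) and `score`. `|M| + |D|` always equals the principle length.
#' @export
align_window <- function(window, principle, stats) {
  slots <- principle_slots(principle)
  n <- nrow(window$tokens)
  m <- length(slots)
  labs <- window$labels
  texts <- casefold_term(window$tokens$text)

  # per-token insertion cost and reported symbol
  ins_cost <- numeric(n); ins_sym <- character(n); ins_kind <- character(n)
  for (i in seq_len(n)) {
    if (length(labs[[i]])) {
      pens <- vapply(labs[[i]], function(s) insertion_penalty(stats, s, "slot"),
                     numeric(1))
      k <- which.min(pens)
      ins_cost[i] <- pens[k]; ins_sym[i] <- labs[[i]][k]; ins_kind[i] <- "slot"
    } else {
      ins_cost[i] <- insertion_penalty(stats, texts[i], "word")
      ins_sym[i] <- texts[i]; ins_kind[i] <- "word"
    }
  }
  del_cost <- vapply(slots, function(s) deletion_penalty(stats, s), numeric(1))
  gain <- vapply(slots, function(s) match_score(stats, s), numeric(1))

  # complete multi-token runs ending at token i: run_from[i] = start index
  run_from <- rep(NA_integer_, n); run_slot <- rep(NA_character_, n)
  if (nrow(window$runs)) {
    for (r in seq_len(nrow(window$runs))) {
      to <- window$runs$to[r]
      if (window$runs$from[r] >= 1L && to <= n && window$runs$to[r] - window$runs$from[r] >= 1L) {
        run_from[to] <- window$runs$from[r]
        run_slot[to] <- window$runs$slot[r]
      }
    }
  }

  NEG <- -Inf
  sc <- matrix(NEG, n + 1L, m + 1L)
  ni <- matrix(0L, n + 1L, m + 1L)   # insertions used
  nd <- matrix(0L, n + 1L, m + 1L)   # deletions used
  mv <- matrix("", n + 1L, m + 1L)   # move leading into the cell
  sc[1, 1] <- 0

  better <- function(s1, i1, d1, s2, i2, d2) {
    # is candidate 1 strictly preferable to incumbent 2?
    if (s1 > s2 + 1e-9) return(TRUE)
    if (s1 < s2 - 1e-9) return(FALSE)
    if (i1 != i2) return(i1 < i2)
    d1 < d2
  }

  for (i in 0:n) for (j in 0:m) {
    if (i == 0 && j == 0) next
    bs <- NEG; bi <- 0L; bd <- 0L; bm <- ""
    consider <- function(ps, pi, pd, move, delta, dins = 0L, ddel = 0L) {
      s <- ps + delta
      if (!is.finite(s)) s <- NEG
      if (bm == "" || better(s, pi + dins, pd + ddel, bs, bi, bd)) {
        bs <<- s; bi <<- pi + dins; bd <<- pd + ddel; bm <<- move
      }
    }
    # run match / run insert (multi-token unit ending at token i)
    if (i >= 1L && !is.na(run_from[i])) {
      rf <- run_from[i]
      rlabs <- unique(c(run_slot[i], slot_ancestors_cached(window, run_slot[i])))
      if (j >= 1L && slots[j] %in% rlabs && sc[rf, j] > NEG)
        consider(sc[rf, j], ni[rf, j], nd[rf, j], "RM", gain[j])
      if (sc[rf, j + 1L] > NEG) {
        rpen <- insertion_penalty(stats, run_slot[i], "slot")
        consider(sc[rf, j + 1L], ni[rf, j + 1L], nd[rf, j + 1L], "RI",
                 -rpen, dins = 1L)
      }
    }
    if (i >= 1L && j >= 1L && slots[j] %in% labs[[i]] && sc[i, j] > NEG)
      consider(sc[i, j], ni[i, j], nd[i, j], "M", gain[j])
    if (j >= 1L && sc[i + 1L, j] > NEG)
      consider(sc[i + 1L, j], ni[i + 1L, j], nd[i + 1L, j], "D",
               -del_cost[j], ddel = 1L)
    if (i >= 1L && sc[i, j + 1L] > NEG)
      consider(sc[i, j + 1L], ni[i, j + 1L], nd[i, j + 1L], "I",
               -ins_cost[i], dins = 1L)
    sc[i + 1L, j + 1L] <- bs; ni[i + 1L, j + 1L] <- bi
    nd[i + 1L, j + 1L] <- bd; mv[i + 1L, j + 1L] <- bm
  }

  # backtrack
  M <- data.frame(token = integer(), from = integer(), slot = character(),
                  text = character(), gain = numeric(),
                  stringsAsFactors = FALSE)
  I <- data.frame(token = integer(), from = integer(), symbol = character(),
                  kind = character(), penalty = numeric(),
                  stringsAsFactors = FALSE)
  D <- data.frame(pos = integer(), slot = character(), penalty = numeric(),
                  stringsAsFactors = FALSE)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    move <- mv[i + 1L, j + 1L]
    if (move == "M") {
      M <- rbind(M, data.frame(token = i, from = i, slot = slots[j],
                               text = window$tokens$text[i], gain = gain[j],
                               stringsAsFactors = FALSE))
      i <- i - 1L; j <- j - 1L
    } else if (move == "RM") {
      M <- rbind(M, data.frame(token = i, from = run_from[i], slot = slots[j],
                               text = paste(window$tokens$text[run_from[i]:i],
                                            collapse = " "),
                               gain = gain[j], stringsAsFactors = FALSE))
      i <- run_from[i] - 1L; j <- j - 1L
    } else if (move == "RI") {
      I <- rbind(I, data.frame(token = i, from = run_from[i],
                               symbol = run_slot[i], kind = "slot",
                               penalty = insertion_penalty(stats, run_slot[i],
                                                           "slot"),
                               stringsAsFactors = FALSE))
      i <- run_from[i] - 1L
    } else if (move == "D") {
      D <- rbind(D, data.frame(pos = j, slot = slots[j],
                               penalty = del_cost[j], stringsAsFactors = FALSE))
      j <- j - 1L
    } else if (move == "I") {
      I <- rbind(I, data.frame(token = i, from = i, symbol = ins_sym[i],
                               kind = ins_kind[i], penalty = ins_cost[i],
                               stringsAsFactors = FALSE))
      i <- i - 1L
    } else {
      # unreachable state (score -Inf throughout): everything deleted/inserted
      if (j > 0L) {
        D <- rbind(D, data.frame(pos = j, slot = slots[j],
                                 penalty = del_cost[j],
                                 stringsAsFactors = FALSE))
        j <- j - 1L
      } else {
        I <- rbind(I, data.frame(token = i, from = i, symbol = ins_sym[i],
                                 kind = ins_kind[i], penalty = ins_cost[i],
                                 stringsAsFactors = FALSE))
        i <- i - 1L
      }
    }
  }
  M <- M[order(M$token), , drop = FALSE]; rownames(M) <- NULL
  I <- I[order(I$token), , drop = FALSE]; rownames(I) <- NULL
  D <- D[order(D$pos), , drop = FALSE]; rownames(D) <- NULL
  score <- sc[n + 1L, m + 1L]
  if (!is.finite(score)) score <- -Inf
  structure(list(principle = slots, M = M, I = I, D = D, score = score),
            class = "spba_alignment")
}

# ancestors of a run slot; labels of the run tokens already include them,
# so read them off the first run token
slot_ancestors_cached <- function(window, slot) {
  for (i in seq_along(window$labels)) {
    if (slot %in% window$labels[[i]]) return(window$labels[[i]])
  }
  slot
}

#' @export
print.spba_alignment <- function(x, ...) {
  cat("<spba_alignment> vs [", paste(x$principle, collapse = "]["),
      "]  score=", format(round(x$score, 3)), "\n", sep = "")
  if (nrow(x$M))
    cat("  M:", paste(sprintf("%s->%s", x$M$text, x$M$slot), collapse = ", "),
        "\n")
  if (nrow(x$I))
    cat("  I:", paste(x$I$symbol, collapse = ", "), "\n")
  if (nrow(x$D))
    cat("  D:", paste(x$D$slot, collapse = ", "), "\n")
  invisible(x)
}

#' Recognize miRNA mentions in a labeled sentence
#'
#' Candidate windows are anchored on tokens labeled with the miRNA indicator
#' slot (or its descendants such as `Let`); each window extends left and
#' right from its anchor, up to `window_limit` tokens each way, while tokens
#' are slot-labeled or are non-slot symbols previously seen inside mentions.
#' Every window is aligned against every cluster dominant; leading and
#' trailing insertions are trimmed from the span (their penalties returned
#' to the score); the best-scoring alignment per anchor is kept and emitted
#' iff its score reaches the cluster's threshold. Overlapping accepted
#' mentions are merged keeping the higher score.
#'
#' @param labeled An `spba_labeled` sentence.
#' @param clusters List of `spba_cluster` objects carrying thresholds.
#' @param stats An `spba_stats` object.
#' @param window_limit Maximum extension (tokens) on each side of the anchor.
#' @param keep_rejected Also return the best-scoring rejected candidate of
#'   each anchor that produced no accepted mention (with `accepted = FALSE`).
#' @param anchor_slots Slot labels that seed candidate windows.
#' @return A data frame of mentions: `start`, `end`, `surface`, `score`,
#'   `threshold`, `principle`, `accepted`. Offsets are 0-based half-open
#'   into the sentence.
#' @export
recognize_mentions <- function(labeled, clusters, stats, window_limit = 20L,
                               keep_rejected = FALSE,
                               anchor_slots = c("miRNA", "Let")) {
  toks <- labeled$tokens
  n <- nrow(toks)
  out <- data.frame(start = integer(), end = integer(), surface = character(),
                    score = numeric(), threshold = numeric(),
                    principle = character(), accepted = logical(),
                    stringsAsFactors = FALSE)
  if (!n || !length(clusters)) return(out)
  known_nons <- stats$words$symbol[stats$words$freq_m > 0]
  extendable <- vapply(seq_len(n), function(i)
    length(labeled$labels[[i]]) > 0 ||
      casefold_term(toks$text[i]) %in% known_nons, logical(1))
  anchors <- which(vapply(labeled$labels, function(l)
    any(anchor_slots %in% l), logical(1)))
  # one anchor per multi-token indicator run
  if (nrow(labeled$runs)) {
    drop <- unlist(lapply(seq_len(nrow(labeled$runs)), function(r)
      seq(labeled$runs$from[r] + 1L, length.out = labeled$runs$to[r] -
            labeled$runs$from[r])))
    anchors <- setdiff(anchors, drop)
  }
  for (a in anchors) {
    l <- a
    while (l > 1L && a - (l - 1L) <= window_limit && extendable[l - 1L])
      l <- l - 1L
    r <- a
    while (r < n && (r + 1L) - a <= window_limit && extendable[r + 1L])
      r <- r + 1L
    win <- labeled_window(labeled, l:r)
    best <- NULL
    best_rej <- NULL
    for (cl in clusters) {
      al <- align_window(win, cl$dominant, stats)
      al <- trim_alignment(al)
      if (is.nan(al$score)) al$score <- sequence_score(al, stats)
      if (!nrow(al$M)) next
      tstart <- win$tokens$start[min(c(al$M$from, al$I$from))]
      tend <- win$tokens$end[max(c(al$M$token, al$I$token))]
      rec <- list(start = tstart, end = tend, score = al$score,
                  threshold = cl$threshold,
                  principle = paste(al$principle, collapse = " "))
      if (is.finite(al$score) && al$score >= cl$threshold) {
        if (is.null(best) || al$score > best$score) best <- rec
      } else if (is.null(best_rej) || al$score > best_rej$score) {
        best_rej <- rec
      }
    }
    rec <- best %||% (if (keep_rejected) best_rej else NULL)
    if (!is.null(rec)) {
      surface <- if (!is.null(labeled$text))
        substr(labeled$text, rec$start + 1L, rec$end) else ""
      out <- rbind(out, data.frame(start = rec$start, end = rec$end,
                                   surface = surface, score = rec$score,
                                   threshold = rec$threshold,
                                   principle = rec$principle,
                                   accepted = !is.null(best),
                                   stringsAsFactors = FALSE))
    }
  }
  if (!nrow(out)) return(out)
  # merge overlaps among accepted mentions, higher score wins
  out <- out[order(-out$accepted, -out$score, out$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(out))) {
      if (i != j && keep[j] &&
          out$start[j] < out$end[i] && out$start[i] < out$end[j])
        keep[j] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# drop leading/trailing inserted tokens from an alignment, refunding their
# penalties; the reported span then starts and ends on matched material
trim_alignment <- function(al) {
  if (nrow(al$I) && nrow(al$M)) {
    lo <- min(al$M$from); hi <- max(al$M$token)
    edge <- al$I$token < lo | al$I$from > hi
    if (any(edge)) {
      al$score <- al$score + sum(al$I$penalty[edge])
      al$I <- al$I[!edge, , drop = FALSE]
    }
  }
  al
}
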