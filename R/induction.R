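#' Edit limits for the domination relation
#'
#' A principle `p` dominates a principle `q` when `q` can be derived from `p`
#' by at most `max_deletions` slot deletions, `max_insertions` insertions and
#' `max_substitutions` substitutions (order preserved). The defaults let a
#' dominant drop slots to yield a dominated principle but never the reverse.
#'
#' @param max_deletions,max_insertions,max_substitutions Non-negative
#'   integer limits on each edit operation.
#' @return A list of class `spba_ids_criteria`.
#' @export
ids_criteria <- function(max_deletions = 3L, max_insertions = 0L,
                         max_substitutions = 0L) {
  stopifnot(max_deletions >= 0, max_insertions >= 0, max_substitutions >= 0)
  structure(list(max_deletions = as.integer(max_deletions),
                 max_insertions = as.integer(max_insertions),
                 max_substitutions = as.integer(max_substitutions)),
            class = "spba_ids_criteria")
}

new_principle <- function(slots, support = 1L, nonslot_counts = integer()) {
  stopifnot(length(slots) >= 1L)
  structure(list(slots = as.character(slots), support = as.integer(support),
                 nonslot_counts = nonslot_counts),
            class = "spba_principle")
}

principle_slots <- function(p) {
  if (inherits(p, "spba_principle")) p$slots else as.character(p)
}

principle_key <- function(p) paste(principle_slots(p), collapse = " ")

#' @export
print.spba_principle <- function(x, ...) {
  cat("<spba_principle> [", paste(x$slots, collapse = "]["),
      "] support=", x$support, "\n", sep = "")
  invisible(x)
}

#' Extract candidate principles from an annotated corpus
#'
#' For each gold mention, tokens inside the span are labeled with the scheme;
#' unlabeled tokens are considered insertions and dropped, and the ordered
#' sequence of the remaining slot labels (one, most specific, label per
#' token; multi-token term runs collapse to one occurrence) is a candidate
#' principle. Identical sequences are merged with summed support. The
#' unlabeled words seen inside each mention are tallied so that principle
#' clusters can later estimate their expected insertions.
#'
#' @param corpus An `spba_corpus` (see [read_corpus()] / [generate_corpus()]).
#' @param scheme An `spba_scheme`.
#' @return A list of `spba_principle` objects. Annotations whose span does
#'   not align to token boundaries, or that contain no labeled token, are
#'   skipped with a warning.
#' @export
extract_principles <- function(corpus, scheme) {
  acc <- list()
  for (doc in corpus$documents) {
    labeled <- label_slots(tokenize(doc$text), scheme)
    toks <- labeled$tokens
    anns <- doc$annotations
    for (a in seq_len(nrow(anns))) {
      s <- anns$start[a]; e <- anns$end[a]
      idx <- which(toks$start >= s & toks$end <= e)
      if (!length(idx) || !any(toks$start[idx] == s) ||
          !any(toks$end[idx] == e)) {
        warning("annotation [", s, ",", e, ") in document '", doc$doc_id,
                "' does not align to token boundaries; skipped")
        next
      }
      seq_slots <- character()
      nons <- character()
      i <- 1L
      while (i <= length(idx)) {
        ti <- idx[i]
        lab <- primary_label(labeled$labels[[ti]], scheme)
        if (is.na(lab)) {
          nons <- c(nons, casefold_term(toks$text[ti]))
          i <- i + 1L
          next
        }
        seq_slots <- c(seq_slots, lab)
        # a multi-token term run is one slot occurrence
        run <- labeled$runs[labeled$runs$from <= ti & labeled$runs$to >= ti, ,
                            drop = FALSE]
        i <- if (nrow(run)) i + (run$to[1] - ti + 1L) else i + 1L
      }
      if (!length(seq_slots)) {
        warning("annotation '", anns$surface[a], "' in document '",
                doc$doc_id, "' contains no labeled token; skipped")
        next
      }
      key <- paste(seq_slots, collapse = " ")
      nons <- unique(nons)
      if (is.null(acc[[key]])) {
        cnt <- setNames(rep(1L, length(nons)), nons)
        acc[[key]] <- new_principle(seq_slots, 1L, cnt)
      } else {
        p <- acc[[key]]
        p$support <- p$support + 1L
        for (w in nons) {
          prev <- p$nonslot_counts[w]
          p$nonslot_counts[w] <- if (is.na(prev)) 1L else prev + 1L
        }
        acc[[key]] <- p
      }
    }
  }
  unname(acc)
}

#' Does one principle dominate another?
#'
#' Computed by slot-level edit distance with per-operation limits: `p`
#' dominates `q` iff `q` is derivable from `p` within the limits in
#' `criteria`. A principle always dominates itself (zero edits).
#'
#' @param p,q Principles (`spba_principle` or character vectors of slots).
#' @param criteria An [ids_criteria()] object.
#' @return `TRUE` or `FALSE`.
#' @export
dominates <- function(p, q, criteria = ids_criteria()) {
  ps <- principle_slots(p); qs <- principle_slots(q)
  n <- length(ps); m <- length(qs)
  lim <- c(criteria$max_deletions, criteria$max_insertions,
           criteria$max_substitutions)
  # pareto[[i]][[j]]: minimal (del, ins, sub) triples turning ps[i..n] into
  # qs[j..m]; suffix DP keeps the whole frontier since limits are per-op
  pareto <- vector("list", n + 1L)
  for (i in seq_len(n + 1L)) pareto[[i]] <- vector("list", m + 1L)
  prune <- function(v) {
    if (length(v) <= 1L) return(v)
    keep <- rep(TRUE, length(v))
    for (a in seq_along(v)) for (b in seq_along(v)) {
      if (a != b && keep[a] && keep[b] && all(v[[b]] <= v[[a]]) &&
          any(v[[b]] < v[[a]])) keep[a] <- FALSE
    }
    unique(v[keep])
  }
  pareto[[n + 1L]][[m + 1L]] <- list(c(0L, 0L, 0L))
  for (j in m:1) if (m >= 1L)
    pareto[[n + 1L]][[j]] <- list(c(0L, m - j + 1L, 0L))
  for (i in n:1) if (n >= 1L)
    pareto[[i]][[m + 1L]] <- list(c(n - i + 1L, 0L, 0L))
  if (n >= 1L) for (i in n:1) {
    if (m >= 1L) for (j in m:1) {
      opts <- list()
      for (v in pareto[[i + 1L]][[j + 1L]]) {
        opts[[length(opts) + 1L]] <-
          if (ps[i] == qs[j]) v else v + c(0L, 0L, 1L)
      }
      for (v in pareto[[i + 1L]][[j]])
        opts[[length(opts) + 1L]] <- v + c(1L, 0L, 0L)
      for (v in pareto[[i]][[j + 1L]])
        opts[[length(opts) + 1L]] <- v + c(0L, 1L, 0L)
      pareto[[i]][[j]] <- prune(opts)
    }
  }
  any(vapply(pareto[[1L]][[1L]], function(v) all(v <= lim), logical(1)))
}

#' Build the domination graph over candidate principles
#'
#' A directed graph whose vertices are the candidate principles and whose
#' edges point from dominator to dominated, as decided by [dominates()].
#'
#' @param principles A list of principles.
#' @param criteria An [ids_criteria()] object.
#' @return A list of class `spba_domgraph` with elements `principles` and
#'   `edges` (integer out-neighbor lists, no self-edges).
#' @export
build_domination_graph <- function(principles, criteria = ids_criteria()) {
  n <- length(principles)
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    out <- integer()
    for (j in seq_len(n)) {
      if (i != j && dominates(principles[[i]], principles[[j]], criteria))
        out <- c(out, j)
    }
    edges[[i]] <- out
  }
  structure(list(principles = principles, edges = edges,
                 criteria = criteria),
            class = "spba_domgraph")
}

#' Summarize principles into clusters via a greedy dominating set
#'
#' Repeatedly selects the vertex covering the most not-yet-covered vertices
#' (itself plus its out-neighbors) until every principle is covered; each
#' selected vertex becomes a cluster dominant and all its out-neighbors its
#' dominated principles (a principle dominated by two dominants belongs to
#' both clusters). Ties break by coverage, then support, then slot-sequence
#' length, then lexicographically, making the result deterministic. Each
#' cluster records its core slots (present in every member), optional slots
#' (present in some members) with their occurrence probabilities, and the
#' unlabeled ("non-slot") words observed inside the members' source mentions
#' with theirs.
#'
#' @param graph An `spba_domgraph`.
#' @return A list of clusters (class `spba_cluster`); empty for an empty
#'   graph.
#' @export
greedy_dominating_set <- function(graph) {
  pr <- graph$principles
  n <- length(pr)
  if (!n) return(list())
  covered <- rep(FALSE, n)
  selected <- integer()
  support <- vapply(pr, function(p) p$support %||% 1L, integer(1))
  len <- vapply(pr, function(p) length(principle_slots(p)), integer(1))
  keys <- vapply(pr, principle_key, character(1))
  while (!all(covered)) {
    gain <- vapply(seq_len(n), function(v)
      sum(!covered[unique(c(v, graph$edges[[v]]))]), integer(1))
    ord <- order(-gain, -support, -len, keys)
    best <- ord[1]
    selected <- c(selected, best)
    covered[unique(c(best, graph$edges[[best]]))] <- TRUE
  }
  lapply(selected, function(v) {
    members <- pr[unique(c(v, graph$edges[[v]]))]
    make_cluster(pr[[v]], members[-1L])
  })
}

make_cluster <- function(dominant, dominated) {
  members <- c(list(dominant), dominated)
  slot_sets <- lapply(members, function(p) unique(principle_slots(p)))
  core <- Reduce(intersect, slot_sets)
  allslots <- Reduce(union, slot_sets)
  optional <- setdiff(allslots, core)
  supp <- vapply(members, function(p) p$support %||% 1L, integer(1))
  total <- sum(supp)
  opt_p <- vapply(optional, function(s)
    sum(supp[vapply(slot_sets, function(ss) s %in% ss, logical(1))]) / total,
    numeric(1))
  nons <- list()
  for (k in seq_along(members)) {
    cnt <- members[[k]]$nonslot_counts
    for (w in names(cnt)) nons[[w]] <- (nons[[w]] %||% 0L) + cnt[[w]]
  }
  nons_p <- if (length(nons))
    setNames(vapply(nons, function(x) min(1, x / total), numeric(1)),
             names(nons)) else setNames(numeric(), character())
  structure(list(dominant = dominant, dominated = dominated,
                 core_slots = sort(core), optional_slots = sort(optional),
                 optional_probs = opt_p[sort(optional)],
                 nonslot_probs = nons_p[sort(names(nons_p))],
                 threshold = NA_real_),
            class = "spba_cluster")
}

#' @export
print.spba_cluster <- function(x, ...) {
  cat("<spba_cluster> dominant [", paste(x$dominant$slots, collapse = "]["),
      "]\n  ", length(x$dominated), " dominated; core: ",
      paste(x$core_slots, collapse = ", "), "\n", sep = "")
  if (!is.na(x$threshold))
    cat("  threshold: ", format(round(x$threshold, 3)), "\n", sep = "")
  invisible(x)
}
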