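#' Compile a normalization lexicon from an Rfam family table dump
#'
#' Reads the tab-separated `family.txt` dump and compiles one normalization
#' entry per family: the accession (column 1, `RF` + 5 digits), the family
#' id (column 2, e.g. "mir-1255"), miRNA-style names pulled from the
#' description (column 4) — slash patterns such as "mir-103/107" expand to
#' one name per alternative — and the previous names (column 11,
#' comma/whitespace separated; the literal `\N` contributes nothing). All
#' names are case-folded, and for every name containing `-` or `_` the
#' variant with those characters replaced by a space is added.
#'
#' @param path Path to the tab-separated family file (at least 11 columns).
#' @param columns Named integer vector re-pointing the `accession`, `id`,
#'   `description` and `previous` columns (1-based) for other dump layouts.
#' @return An object of class `spba_lexicon`: a list of entries, each with
#'   `accession` and `names`. Malformed lines are skipped with a warning.
#' @export
read_family_file <- function(path,
                             columns = c(accession = 1L, id = 2L,
                                         description = 4L, previous = 11L)) {
  if (!file.exists(path)) stop("family file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  entries <- list()
  need <- max(columns)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < need) {
      warning("family file line ", i, ": expected at least ", need,
              " tab-separated fields, got ", length(fields), "; skipped")
      next
    }
    acc <- trimws(fields[columns[["accession"]]])
    if (!grepl("^RF[0-9]{5}$", acc)) {
      warning("family file line ", i, ": malformed accession '", acc,
              "'; skipped")
      next
    }
    names_ <- casefold_term(fields[columns[["id"]]])
    names_ <- names_[nzchar(names_)]
    names_ <- c(names_, description_names(fields[columns[["description"]]]))
    prev <- trimws(fields[columns[["previous"]]])
    if (nzchar(prev) && prev != "\\N") {
      pn <- casefold_term(strsplit(prev, "[,;]\\s*|\\s+")[[1]])
      names_ <- c(names_, pn[nzchar(pn)])
    }
    names_ <- unique(names_)
    variants <- gsub("[-_]", " ", names_)
    names_ <- unique(c(names_, variants[variants != names_]))
    if (!length(names_)) {
      warning("family file line ", i, ": no usable names; skipped")
      next
    }
    entries[[length(entries) + 1L]] <- list(accession = acc, names = names_)
  }
  structure(list(entries = entries), class = "spba_lexicon")
}

# pull miRNA-style names out of a free-text description, expanding slash
# alternatives ("mir-103/107" -> mir-103, mir-107; "mir-29a/b" -> mir-29a,
# mir-29b)
description_names <- function(desc) {
  desc <- casefold_term(desc)
  pat <- "\\b(?:mir|let|lin|lsy)[-_]?[0-9]+[a-z]{0,2}[0-9]?(?:/[0-9a-z]+(?:-[0-9]+)?)*\\b"
  hits <- regmatches(desc, gregexpr(pat, desc, perl = TRUE))[[1]]
  out <- character()
  for (h in hits) {
    parts <- strsplit(h, "/", fixed = TRUE)[[1]]
    base <- parts[1]
    out <- c(out, base)
    for (alt in parts[-1]) {
      if (grepl("^[0-9]", alt)) {
        # numeric alternative: swap the whole order group
        out <- c(out, sub("[0-9]+[a-z]{0,2}[0-9]?([^0-9]*)$",
                          paste0(alt, "\\1"), base))
      } else {
        # letter variant: swap the trailing letters of the order group
        out <- c(out, sub("(?<=[0-9])[a-z]{0,2}[0-9]?$", alt, base,
                          perl = TRUE))
      }
    }
  }
  unique(out)
}

# leading digits of a numbering value ("133a" -> "133"); NA when the value
# does not start with a digit
order_stem <- function(x) {
  x <- casefold_term(x)
  ifelse(grepl("^[0-9]", x), sub("^([0-9]+).*$", "\\1", x), NA_character_)
}

#' @export
print.spba_lexicon <- function(x, ...) {
  cat("<spba_lexicon> ", length(x$entries), " families, ",
      length(unique(unlist(lapply(x$entries, `[[`, "names")))),
      " distinct names\n", sep = "")
  invisible(x)
}

#' Build a slot-value index over a normalization lexicon
#'
#' Every lexicon name is tokenized, slot-labeled and aligned against the
#' model's cluster dominants; each matched (slot, token value) pair maps to
#' the entry's accession, so a recognized mention can retrieve its candidate
#' families through the values of its own matched slots. Names matching no
#' principle fall back to indexing by their raw token values.
#'
#' @param lexicon An `spba_lexicon` from [read_family_file()].
#' @param scheme An `spba_scheme`.
#' @param clusters List of `spba_cluster` objects (from a trained model).
#' @param stats An `spba_stats` object.
#' @return An object of class `spba_slot_index` carrying the key map, the
#'   per-accession name decompositions, the scheme and the lexicon.
#' @export
build_slot_index <- function(lexicon, scheme, clusters, stats) {
  is_open <- function(slot) !is.na(scheme$slots[[slot]]$pattern)
  keys <- new.env(parent = emptyenv())
  decomp <- list()
  add_key <- function(slot, value, acc) {
    k <- paste(slot, casefold_term(value), sep = "\r")
    keys[[k]] <- union(keys[[k]] %||% character(), acc)
  }
  for (entry in lexicon$entries) {
    acc <- entry$accession
    decomp[[acc]] <- decomp[[acc]] %||% list()
    for (nm in entry$names) {
      labeled <- label_slots(tokenize(nm), scheme)
      prim <- vapply(seq_along(labeled$labels), function(i)
        primary_label(labeled$labels[[i]], scheme), character(1))
      decomp[[acc]][[length(decomp[[acc]]) + 1L]] <-
        list(texts = casefold_term(labeled$tokens$text), slots = prim)
      matched <- FALSE
      for (cl in clusters) {
        al <- align_window(labeled, cl$dominant, stats)
        if (nrow(al$M)) {
          matched <- TRUE
          for (r in seq_len(nrow(al$M))) {
            add_key(al$M$slot[r], al$M$text[r], acc)
            # letter variants of a numbering value index under the digit
            # stem too, so "133a" can reach a family named "mir-133"
            if (is_open(al$M$slot[r])) {
              stem <- order_stem(al$M$text[r])
              if (!is.na(stem) && stem != casefold_term(al$M$text[r]))
                add_key(al$M$slot[r], stem, acc)
            }
          }
        }
      }
      if (!matched) {
        for (tx in labeled$tokens$text) add_key("*", tx, acc)
      }
    }
  }
  structure(list(keys = keys, decomp = decomp, scheme = scheme,
                 clusters = clusters, lexicon = lexicon),
            class = "spba_slot_index")
}

#' @export
print.spba_slot_index <- function(x, ...) {
  cat("<spba_slot_index> ", length(ls(x$keys)), " keys over ",
      length(x$decomp), " accessions\n", sep = "")
  invisible(x)
}

#' Score a mention against one lexicon name
#'
#' Token-level alignment between the mention and the name: tokens match when
#' their case-folded texts are equal (gaining the matched score of the
#' token's slot, or nothing for unlabeled symbols such as "-"); unmatched
#' mention tokens cost their insertion penalty, unmatched name tokens the
#' deletion penalty of their slot (or the word insertion penalty when
#' unlabeled). This is the scoring rule both the indexed and the brute-force
#' normalization paths share.
#'
#' @param mention Mention surface string (or character vector of tokens).
#' @param name Lexicon name string (or character vector of tokens).
#' @param scheme An `spba_scheme`.
#' @param stats An `spba_stats` object.
#' @return A numeric score (higher is a better grounding).
#' @export
mention_name_score <- function(mention, name, scheme, stats) {
  tok <- function(x) {
    if (length(x) > 1L) return(casefold_term(x))
    casefold_term(tokenize(x)$text)
  }
  a <- tok(mention); b <- tok(name)
  pa <- vapply(a, function(t) primary_label(lookup_term(scheme, t), scheme),
               character(1))
  pb <- vapply(b, function(t) primary_label(lookup_term(scheme, t), scheme),
               character(1))
  n <- length(a); m <- length(b)
  skip_a <- vapply(seq_len(n), function(i) {
    p <- if (is.na(pa[i])) insertion_penalty(stats, a[i], "word")
         else insertion_penalty(stats, pa[i], "slot")
    if (is.finite(p)) p else stats$unseen_insertion
  }, numeric(1))
  skip_b <- vapply(seq_len(m), function(j) {
    p <- if (is.na(pb[j])) insertion_penalty(stats, b[j], "word")
         else deletion_penalty(stats, pb[j])
    if (is.finite(p)) p else stats$unseen_insertion
  }, numeric(1))
  gain <- vapply(seq_len(m), function(j)
    if (is.na(pb[j])) 0 else match_score(stats, pb[j]), numeric(1))
  open_b <- vapply(seq_len(m), function(j)
    !is.na(pb[j]) && !is.na(scheme$slots[[pb[j]]]$pattern), logical(1))
  dp <- matrix(0, n + 1L, m + 1L)
  for (i in 0:n) for (j in 0:m) {
    if (i == 0 && j == 0) next
    best <- -Inf
    if (i >= 1 && j >= 1) {
      if (a[i] == b[j]) {
        best <- max(best, dp[i, j] + gain[j])
      } else if (open_b[j] && !is.na(pa[i]) && pa[i] == pb[j] &&
                 !is.na(order_stem(a[i])) &&
                 identical(order_stem(a[i]), order_stem(b[j]))) {
        # letter variant of the same numbering stem: half credit, so an
        # exact value still outranks it
        best <- max(best, dp[i, j] + gain[j] / 2)
      }
    }
    if (i >= 1) best <- max(best, dp[i, j + 1L] - skip_a[i])
    if (j >= 1) best <- max(best, dp[i + 1L, j] - skip_b[j])
    dp[i + 1L, j + 1L] <- best
  }
  dp[n + 1L, m + 1L]
}

#' Normalize a recognized mention to Rfam accessions
#'
#' The mention is tokenized and slot-labeled; conjunction or slash mentions
#' with several order groups (e.g. "miR-1/133a") are split into sub-mentions
#' that share the indicator tokens and are normalized independently.
#' Candidate accessions are retrieved from the slot index through the
#' mention's labeled token values, scored with [mention_name_score()]
#' against each candidate's best name, and returned sorted by score
#' (descending), ties broken by ascending accession.
#'
#' @param mention Mention surface string.
#' @param index An `spba_slot_index`.
#' @param stats An `spba_stats` object.
#' @return A data frame with columns `group`, `accession`, `score`; zero
#'   rows when no candidate is found (the mention stays unnormalized).
#' @export
normalize_mention <- function(mention, index, stats) {
  scheme <- index$scheme
  labeled <- label_slots(tokenize(as.character(mention)), scheme)
  toks <- casefold_term(labeled$tokens$text)
  prim <- vapply(seq_along(labeled$labels), function(i)
    primary_label(labeled$labels[[i]], scheme), character(1))
  out <- data.frame(group = integer(), accession = character(),
                    score = numeric(), stringsAsFactors = FALSE)
  if (!length(toks)) return(out)
  # split into order groups at separators (slash, comma, conjunction)
  sep <- toks %in% c("/", ",") | (!is.na(prim) & prim == "Conj")
  grp <- cumsum(sep)
  grp[sep] <- NA
  segs <- split(seq_along(toks), grp)
  ind_idx <- which(vapply(labeled$labels, function(l) "miRNA" %in% l,
                          logical(1)))
  sub_mentions <- list()
  for (k in seq_along(segs)) {
    idx <- segs[[k]]
    if (k == 1L) sub_mentions[[k]] <- toks[idx]
    else {
      if (!any(!is.na(prim[idx]) & prim[idx] == "Order")) next
      sub_mentions[[length(sub_mentions) + 1L]] <-
        c(toks[ind_idx[ind_idx <= max(segs[[1]])]], toks[idx])
    }
  }
  sub_mentions <- Filter(length, sub_mentions)
  for (g in seq_along(sub_mentions)) {
    sub <- sub_mentions[[g]]
    prim_sub <- vapply(sub, function(t)
      primary_label(lookup_term(scheme, t), scheme), character(1))
    open_sub <- vapply(seq_along(sub), function(i)
      !is.na(prim_sub[i]) && !is.na(scheme$slots[[prim_sub[i]]]$pattern),
      logical(1))
    token_keys <- function(i, valued_only) {
      p <- prim_sub[i]
      keys <- character()
      if (!is.na(p)) {
        keys <- paste(p, sub[i], sep = "\r")
        if (open_sub[i]) {
          stem <- order_stem(sub[i])
          if (!is.na(stem)) keys <- c(keys, paste(p, stem, sep = "\r"))
        }
      }
      if (!valued_only) keys <- c(keys, paste("*", sub[i], sep = "\r"))
      keys
    }
    cand <- character()
    if (any(open_sub)) {
      # value-bearing slots (the numbering) discriminate between families:
      # only they nominate candidates, so a value absent from the lexicon
      # leaves the mention unnormalized instead of tying every family
      for (i in which(open_sub))
        for (k in token_keys(i, TRUE))
          cand <- union(cand, index$keys[[k]] %||% character())
    } else {
      for (i in seq_along(sub))
        for (k in token_keys(i, FALSE))
          cand <- union(cand, index$keys[[k]] %||% character())
    }
    if (!length(cand)) next
    scores <- vapply(cand, function(acc) {
      max(vapply(index$decomp[[acc]], function(d)
        mention_name_score(sub, d$texts, scheme, stats), numeric(1)))
    }, numeric(1))
    ord <- order(-scores, cand)
    out <- rbind(out, data.frame(group = g, accession = cand[ord],
                                 score = scores[ord],
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Top accessions of a normalization result
#'
#' For each sub-mention group, the accession(s) with the highest score; the
#' union over groups is the predicted accession set of the mention.
#'
#' @param norm A data frame from [normalize_mention()].
#' @return Character vector of accessions (sorted, unique).
#' @export
top_accessions <- function(norm) {
  if (!nrow(norm)) return(character())
  out <- character()
  for (g in unique(norm$group)) {
    sub <- norm[norm$group == g, , drop = FALSE]
    out <- c(out, sub$accession[sub$score >= max(sub$score) - 1e-9])
  }
  sort(unique(out))
}

#' Ambiguity statistics of a normalization lexicon
#'
#' Over the compiled name variants: the mean number of accessions a name is
#' associated with, the mean number of names an accession is linked to, and
#' the fraction of names that are also ordinary English words (given a word
#' list).
#'
#' @param lexicon An `spba_lexicon`.
#' @param english_words Character vector of English words (case-folded
#'   internally); empty by default, giving an English-ambiguity of 0.
#' @return A list with `ids_per_name`, `names_per_id`, `english_fraction`,
#'   `n_names`, `n_ids`.
#' @export
ambiguity_report <- function(lexicon, english_words = character()) {
  pairs <- do.call(rbind, lapply(lexicon$entries, function(e)
    data.frame(name = e$names, accession = e$accession,
               stringsAsFactors = FALSE)))
  if (is.null(pairs) || !nrow(pairs))
    return(list(ids_per_name = NA_real_, names_per_id = NA_real_,
                english_fraction = 0, n_names = 0L, n_ids = 0L))
  pairs <- unique(pairs)
  per_name <- tapply(pairs$accession, pairs$name,
                     function(x) length(unique(x)))
  per_id <- tapply(pairs$name, pairs$accession,
                   function(x) length(unique(x)))
  ew <- casefold_term(english_words)
  nms <- unique(pairs$name)
  list(ids_per_name = mean(per_name),
       names_per_id = mean(per_id),
       english_fraction = if (length(ew)) mean(nms %in% ew) else 0,
       n_names = length(nms),
       n_ids = length(unique(pairs$accession)))
}
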