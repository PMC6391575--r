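#' Configuration of the synthetic corpus generator
#'
#' The generator emulates the statistical structure the recognizer assumes:
#' sentences embedding mentions drawn from the slot grammar
#' `[Precursor]? [Species]? [indicator] [Order] ([Conj|,] [Order])*
#' [Suffix]?`, joined with `-` separators, surrounded by filler words into
#' which slot-term "decoys" are injected at the configured noise rate so
#' that slots and symbols also occur outside mentions.
#'
#' @param n_documents Number of documents.
#' @param seed Random seed fixing all randomness end-to-end.
#' @param noise_rate Probability that a filler word position is replaced by
#'   a decoy (a species/precursor/conjunction term, punctuation symbol,
#'   bare indicator or bare numbering string). Hairpin suffix and `Let`
#'   terms are never decoys, so those slots stay mention-exclusive.
#' @param mention_dist Named probability vector over the number of mentions
#'   per sentence.
#' @param sentences_per_doc Integer vector the per-document sentence count
#'   is drawn from.
#' @param p_precursor,p_species,p_suffix Probabilities that a mention
#'   carries the corresponding optional part.
#' @param conj_weights Named probability vector over the number of extra
#'   order groups in a conjunction/list mention (`"0"` = plain mention).
#' @return A list of class `spba_fixture_config`.
#' @export
fixture_config <- function(n_documents = 40L, seed = 1L, noise_rate = 0.05,
                           mention_dist = c("0" = 0.3, "1" = 0.5, "2" = 0.2),
                           sentences_per_doc = 1:4,
                           p_precursor = 0.15, p_species = 0.5,
                           p_suffix = 0.25,
                           conj_weights = c("0" = 0.75, "1" = 0.15,
                                            "2" = 0.07, "3" = 0.03)) {
  stopifnot(noise_rate >= 0, noise_rate <= 1,
            abs(sum(mention_dist) - 1) < 1e-8,
            abs(sum(conj_weights) - 1) < 1e-8,
            p_precursor >= 0, p_precursor <= 1,
            p_species >= 0, p_species <= 1,
            p_suffix >= 0, p_suffix <= 1)
  structure(list(n_documents = as.integer(n_documents),
                 seed = as.integer(seed), noise_rate = noise_rate,
                 mention_dist = mention_dist,
                 sentences_per_doc = as.integer(sentences_per_doc),
                 p_precursor = p_precursor, p_species = p_species,
                 p_suffix = p_suffix, conj_weights = conj_weights),
            class = "spba_fixture_config")
}

fixture_fillers <- c(
  "expression", "of", "the", "levels", "in", "cells", "was", "were",
  "significantly", "increased", "decreased", "regulated", "by", "targets",
  "signaling", "pathway", "tumor", "tissue", "samples", "analysis",
  "showed", "that", "compared", "with", "control", "patients", "observed",
  "study", "results", "suggest")

fixture_decoys <- data.frame(
  term = c("hsa", "cel", "pre", "and", "or", "-", ",", "(", ")", "mir",
           "ORDER"),
  weight = c(0.12, 0.08, 0.08, 0.20, 0.05, 0.10, 0.12, 0.05, 0.05, 0.05,
             0.10),
  stringsAsFactors = FALSE)

sample_order <- function() {
  ord <- as.character(sample(1:499, 1))
  if (runif(1) < 0.35) ord <- paste0(ord, sample(letters[1:3], 1))
  ord
}

sample_mention <- function(config) {
  ind <- sample(c("miR", "mir", "let", "microRNA", "micro RNA"), 1,
                prob = c(0.50, 0.15, 0.15, 0.12, 0.08))
  is_let <- ind == "let"
  base <- if (is_let) "let" else "mir"
  order1 <- if (is_let) paste0("7", sample(letters[1:7], 1)) else
    sample_order()
  parts <- character()
  if (!is_let && runif(1) < config$p_precursor) parts <- c(parts, "pre-")
  if (!is_let && runif(1) < config$p_species)
    parts <- c(parts, paste0(sample(c("hsa", "cel"), 1), "-"))
  surface <- paste0(paste(parts, collapse = ""), ind, "-", order1)
  ids <- paste0(base, "-", order1)
  n_extra <- as.integer(sample(names(config$conj_weights), 1,
                               prob = config$conj_weights))
  if (n_extra > 0) {
    for (k in seq_len(n_extra)) {
      ord <- if (is_let) paste0("7", sample(letters[1:7], 1)) else
        sample_order()
      # multi-miRNA mentions are joined with commas, a final conjunction,
      # or a slash ("mir-1/133a" style); each id is annotated on the span
      u <- runif(1)
      if (u < 0.15) {
        joiner <- "/"; hyph <- ""
      } else {
        joiner <- if (k == n_extra && u > 0.7) " and " else ", "
        hyph <- if (runif(1) < 0.3) "-" else ""
      }
      surface <- paste0(surface, joiner, hyph, ord)
      ids <- c(ids, paste0(base, "-", ord))
    }
  }
  if (runif(1) < config$p_suffix)
    surface <- paste0(surface, "-", sample(c("3p", "5p"), 1))
  list(surface = surface, ids = unique(casefold_term(ids)))
}

#' Generate a synthetic annotated corpus with a matched toy family file
#'
#' Produces documents whose sentences embed grammar-generated miRNA
#' mentions with gold spans and gold accessions, a toy Rfam-layout family
#' table containing exactly the generated families, and a manifest of the
#' expected counts. Regenerating with the same config is byte-identical.
#'
#' @param config An [fixture_config()] object.
#' @return A list of class `spba_fixture` with elements `corpus`
#'   (`spba_corpus`), `family` (data frame, 11 tab-separable columns),
#'   `manifest` (list of counts) and `config`.
#' @seealso [write_fixture()]
#' @export
generate_corpus <- function(config = fixture_config()) {
  stopifnot(inherits(config, "spba_fixture_config"))
  if (config$n_documents < 1L) stop("at least one document is required")
  withr::with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  all_ids <- character()
  n_mentions <- 0L
  n_sentences <- 0L
  docs <- vector("list", config$n_documents)
  for (d in seq_len(config$n_documents)) {
    doc_id <- sprintf("doc%03d", d)
    text <- ""
    ann <- data.frame(start = integer(), end = integer(),
                      surface = character(), accessions = character(),
                      stringsAsFactors = FALSE)
    n_sent <- sample(config$sentences_per_doc, 1)
    for (s in seq_len(n_sent)) {
      n_sentences <- n_sentences + 1L
      n_m <- as.integer(sample(names(config$mention_dist), 1,
                               prob = config$mention_dist))
      n_fill <- sample(5:9, 1)
      words <- sample(fixture_fillers, n_fill, replace = TRUE)
      # mentions go between filler words, never sentence-final
      slots_avail <- seq_len(n_fill - 1L)
      n_m <- min(n_m, length(slots_avail))
      pos <- sort(sample(slots_avail, n_m))
      # decoys never replace the words flanking a mention: a slot term
      # directly abutting a mention would be absorbed into the gold span
      # by any consistent annotation, so such text/gold combinations are
      # artifacts the generator does not produce
      protected <- unique(c(pos, pos + 1L))
      for (w in setdiff(seq_len(n_fill), protected)) {
        if (runif(1) < config$noise_rate) {
          decoy <- sample(fixture_decoys$term, 1,
                          prob = fixture_decoys$weight)
          if (decoy == "ORDER") decoy <- sample_order()
          words[w] <- decoy
        }
      }
      mention_at <- vector("list", n_m)
      for (k in seq_len(n_m)) {
        m <- sample_mention(config)
        mention_at[[k]] <- m
        all_ids <- c(all_ids, m$ids)
        n_mentions <- n_mentions + 1L
      }
      if (nzchar(text)) text <- paste0(text, " ")
      sent_rows <- list()
      for (w in seq_len(n_fill)) {
        if (w > 1L) text <- paste0(text, " ")
        text <- paste0(text, words[w])
        if (n_m > 0L && w %in% pos) {
          m <- mention_at[[which(pos == w)]]
          text <- paste0(text, " ")
          start <- nchar(text)
          text <- paste0(text, m$surface)
          sent_rows[[length(sent_rows) + 1L]] <- data.frame(
            start = start, end = nchar(text), surface = m$surface,
            accessions = paste(m$ids, collapse = ";"),
            stringsAsFactors = FALSE)
        }
      }
      text <- paste0(text, ".")
      if (length(sent_rows)) ann <- rbind(ann, do.call(rbind, sent_rows))
    }
    docs[[d]] <- new_document(doc_id, text, ann)
  }
  # assign accessions to the generated family ids
  ids <- sort(unique(all_ids))
  acc <- setNames(sprintf("RF%05d", seq_along(ids)), ids)
  for (d in seq_along(docs)) {
    a <- docs[[d]]$annotations
    if (nrow(a)) {
      a$accessions <- vapply(a$accessions, function(x) {
        paste(unname(acc[strsplit(x, ";", fixed = TRUE)[[1]]]),
              collapse = ";")
      }, character(1))
      docs[[d]]$annotations <- a
    }
  }
  family <- make_family_table(ids, acc)
  manifest <- list(n_documents = config$n_documents,
                   n_sentences = n_sentences,
                   n_mentions = n_mentions,
                   n_unique_ids = length(ids),
                   seed = config$seed,
                   noise_rate = config$noise_rate)
  structure(list(corpus = spba_corpus(docs), family = family,
                 manifest = manifest, config = config),
            class = "spba_fixture")
}

make_family_table <- function(ids, acc) {
  n <- length(ids)
  prev <- rep("\\N", n)
  # every fifth family gets a hyphen-free previous name, exercising the
  # raw-token fallback of the slot index
  alt <- seq_len(n) %% 5L == 0L
  prev[alt] <- gsub("-", "", ids[alt])
  data.frame(
    rfam_acc = unname(acc[ids]),
    rfam_id = ids,
    auto_wiki = "\\N",
    description = paste(ids, "microRNA precursor family"),
    author = "synthetic",
    seed_source = "synthetic",
    gathering_cutoff = "50.00",
    trusted_cutoff = "50.10",
    noise_cutoff = "49.90",
    comment = "synthetic fixture family",
    previous_id = prev,
    stringsAsFactors = FALSE)
}

#' @export
print.spba_fixture <- function(x, ...) {
  cat("<spba_fixture> ", x$manifest$n_documents, " documents, ",
      x$manifest$n_mentions, " mentions, ", x$manifest$n_unique_ids,
      " families (seed ", x$manifest$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a fixture to disk
#'
#' Emits `corpus.txt`/`corpus.ann` (standoff corpus), `family.txt`
#' (tab-separated family table in the Rfam dump layout) and
#' `manifest.json`.
#'
#' @param fixture An `spba_fixture` from [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_corpus(fixture$corpus, file.path(dir, "corpus.txt"))
  write_family_file(fixture$family, file.path(dir, "family.txt"))
  jsonlite::write_json(fixture$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_fixture
#' @param family Family table data frame (11 columns).
#' @param path Output path for the tab-separated family file.
#' @export
write_family_file <- function(family, path) {
  utils::write.table(family, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
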