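#' Train a principle-based miRNA recognizer
#'
#' Runs the full training pipeline: candidate principles are extracted from
#' the gold mentions, the domination graph is built under the edit-limit
#' criteria and summarized into clusters by the greedy dominating-set
#' approximation, per-slot corpus statistics are estimated, and every
#' cluster receives its acceptance threshold.
#'
#' @param corpus An `spba_corpus` with gold mention annotations.
#' @param scheme An `spba_scheme` (default: the bundled scheme).
#' @param criteria An [ids_criteria()] object.
#' @param lambda Scale constant of the matched-slot score.
#' @param insertion_sign Sign of the expected-insertion terms in the cluster
#'   threshold (see [cluster_threshold()]).
#' @param window_limit Window extension limit stored with the model and used
#'   by [spba_annotate()].
#' @param ... Passed to [estimate_slot_statistics()] (`unseen_match`,
#'   `unseen_insertion`, `pseudocount`).
#' @return An object of class `spba_model`.
#' @export
spba_train <- function(corpus, scheme = default_slot_scheme(),
                       criteria = ids_criteria(), lambda = 100,
                       insertion_sign = -1, window_limit = 20L, ...) {
  principles <- extract_principles(corpus, scheme)
  if (!length(principles))
    stop("no candidate principles could be extracted from the corpus")
  graph <- build_domination_graph(principles, criteria)
  clusters <- greedy_dominating_set(graph)
  stats <- estimate_slot_statistics(corpus, scheme, lambda = lambda, ...)
  for (k in seq_along(clusters))
    clusters[[k]]$threshold <- cluster_threshold(clusters[[k]], stats,
                                                 insertion_sign)
  structure(list(scheme = scheme, stats = stats, clusters = clusters,
                 criteria = criteria, insertion_sign = insertion_sign,
                 window_limit = as.integer(window_limit),
                 version = as.character(utils::packageVersion("spba"))),
            class = "spba_model")
}

#' @export
print.spba_model <- function(x, ...) {
  cat("<spba_model> ", length(x$clusters), " principle cluster(s), lambda=",
      x$stats$lambda, "\n", sep = "")
  for (cl in x$clusters)
    cat(sprintf("  [%s]  support=%d  threshold=%.3f\n",
                paste(cl$dominant$slots, collapse = "]["),
                cl$dominant$support, cl$threshold))
  invisible(x)
}

#' Write a trained model to a JSON file
#'
#' The file is self-contained: scheme, statistics, clusters with thresholds
#' and a version stamp. `read_spba_model()` restores an equivalent model.
#'
#' @param model An `spba_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spba_model <- function(model, path) {
  ser_principle <- function(p) list(slots = p$slots, support = p$support,
                                    nonslot_counts = as.list(p$nonslot_counts))
  obj <- list(
    version = model$version,
    insertion_sign = model$insertion_sign,
    window_limit = model$window_limit,
    criteria = unclass(model$criteria),
    scheme = list(version = model$scheme$version,
                  slots = lapply(model$scheme$slots, unclass)),
    stats = list(slots = model$stats$slots, words = model$stats$words,
                 lambda = model$stats$lambda,
                 unseen_match = model$stats$unseen_match,
                 unseen_insertion = model$stats$unseen_insertion,
                 pseudocount = model$stats$pseudocount),
    clusters = lapply(model$clusters, function(cl) list(
      dominant = ser_principle(cl$dominant),
      dominated = lapply(cl$dominated, ser_principle),
      core_slots = cl$core_slots,
      optional_slots = cl$optional_slots,
      optional_probs = as.list(cl$optional_probs),
      nonslot_probs = as.list(cl$nonslot_probs),
      threshold = cl$threshold))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a trained model from a JSON file
#'
#' @param path Path to a model file written by [write_spba_model()].
#' @return An `spba_model`.
#' @export
read_spba_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  deser_principle <- function(p) {
    cnt <- unlist(p$nonslot_counts) %||% integer()
    if (is.null(p$nonslot_counts) || !length(p$nonslot_counts))
      cnt <- setNames(integer(), character())
    new_principle(unlist(p$slots), p$support, cnt)
  }
  scheme <- spba_scheme(lapply(obj$scheme$slots, function(s)
    slot_def(s$name, parent = s$parent %||% NA_character_,
             terms = unlist(s$terms) %||% character(),
             pattern = s$pattern %||% NA_character_)),
    version = obj$scheme$version)
  as_df <- function(x) data.frame(
    symbol = vapply(x, function(r) r$symbol, character(1)),
    freq_m = vapply(x, function(r) as.integer(r$freq_m), integer(1)),
    freq_n = vapply(x, function(r) as.integer(r$freq_n), integer(1)),
    stringsAsFactors = FALSE)
  empty_df <- data.frame(symbol = character(), freq_m = integer(),
                         freq_n = integer(), stringsAsFactors = FALSE)
  stats <- slot_statistics(
    if (length(obj$stats$slots)) as_df(obj$stats$slots) else empty_df,
    if (length(obj$stats$words)) as_df(obj$stats$words) else empty_df,
    lambda = obj$stats$lambda, unseen_match = obj$stats$unseen_match,
    unseen_insertion = obj$stats$unseen_insertion,
    pseudocount = obj$stats$pseudocount)
  clusters <- lapply(obj$clusters, function(cl) {
    out <- make_cluster(deser_principle(cl$dominant),
                        lapply(cl$dominated, deser_principle))
    out$threshold <- cl$threshold
    out
  })
  structure(list(scheme = scheme, stats = stats, clusters = clusters,
                 criteria = do.call(ids_criteria, obj$criteria),
                 insertion_sign = obj$insertion_sign,
                 window_limit = as.integer(obj$window_limit),
                 version = obj$version),
            class = "spba_model")
}

#' Annotate text or a corpus with a trained model
#'
#' Splits the input into sentences, tokenizes, labels slots, recognizes
#' mentions against the model's principle clusters, and (when a slot index
#' is supplied) normalizes each accepted mention to Rfam family accessions.
#'
#' @param model An `spba_model`.
#' @param text A single string to annotate (alternative to `corpus`).
#' @param corpus An `spba_corpus` whose documents are annotated (gold
#'   annotations, if any, are ignored).
#' @param doc_id Document id used with `text` input.
#' @param index Optional `spba_slot_index` from [build_slot_index()]; when
#'   supplied, an `accessions` column is filled with the top-scoring
#'   accession per mention sub-part, `;`-separated.
#' @param keep_rejected Passed to [recognize_mentions()].
#' @return A data frame of annotations: `doc_id`, `start`, `end`,
#'   `surface`, `accessions`, `score`, `principle`, `accepted`.
#' @export
spba_annotate <- function(model, text = NULL, corpus = NULL,
                          doc_id = "doc1", index = NULL,
                          keep_rejected = FALSE) {
  if (is.null(text) && is.null(corpus))
    stop("supply either `text` or `corpus`")
  docs <- if (!is.null(corpus)) corpus$documents
          else list(list(doc_id = doc_id, text = text))
  rows <- list()
  for (doc in docs) {
    sents <- split_sentences(doc$text)
    for (k in seq_len(nrow(sents))) {
      labeled <- label_slots(tokenize(sents$text[k]), model$scheme)
      found <- recognize_mentions(labeled, model$clusters, model$stats,
                                  window_limit = model$window_limit,
                                  keep_rejected = keep_rejected)
      if (!nrow(found)) next
      found$start <- found$start + sents$start[k]
      found$end <- found$end + sents$start[k]
      found$doc_id <- doc$doc_id
      rows[[length(rows) + 1L]] <- found
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), end = integer(), surface = character(),
               score = numeric(), threshold = numeric(),
               principle = character(), accepted = logical(),
               doc_id = character(), stringsAsFactors = FALSE)
  out$accessions <- rep("", nrow(out))
  if (!is.null(index) && nrow(out)) {
    for (i in seq_len(nrow(out))) {
      if (!out$accepted[i]) next
      nm <- normalize_mention(out$surface[i], index, model$stats)
      out$accessions[i] <- paste(top_accessions(nm), collapse = ";")
    }
  }
  out[, c("doc_id", "start", "end", "surface", "accessions", "score",
          "principle", "accepted")]
}
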