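#' Strict-span micro-averaged evaluation
#'
#' A predicted annotation is a true positive iff its `(doc_id, start, end)`
#' exactly equal a gold annotation's (strict matching); in normalization
#' mode the predicted and gold accession sets must additionally share at
#' least one accession. Precision, recall and F1 are micro-averaged over
#' all documents; a per-document breakdown is included.
#'
#' @param pred,gold Annotation data frames (`doc_id`, `start`, `end`,
#'   `surface`, optionally `accessions`), e.g. from [spba_annotate()] and
#'   [corpus_annotations()].
#' @param mode `"recognition"` or `"normalization"`.
#' @return An object of class `spba_eval`: list with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`, `mode` and `by_document`.
#' @export
evaluate_annotations <- function(pred, gold,
                                 mode = c("recognition", "normalization")) {
  mode <- match.arg(mode)
  key <- function(df) paste(df$doc_id, df$start, df$end, sep = "\r")
  accs <- function(x) {
    if (is.null(x)) return(character())
    strsplit(x %||% "", ";", fixed = TRUE)[[1]]
  }
  pred <- pred[!duplicated(key(pred)), , drop = FALSE]
  gold <- gold[!duplicated(key(gold)), , drop = FALSE]
  pk <- key(pred); gk <- key(gold)
  hit <- logical(nrow(pred))
  for (i in seq_len(nrow(pred))) {
    j <- match(pk[i], gk)
    if (is.na(j)) next
    if (mode == "recognition") {
      hit[i] <- TRUE
    } else {
      pa <- accs(pred$accessions[i]); ga <- accs(gold$accessions[j])
      hit[i] <- length(intersect(pa, ga)) > 0
    }
  }
  gold_hit <- gk %in% pk[hit]
  docs <- sort(unique(c(pred$doc_id, gold$doc_id)))
  by_doc <- do.call(rbind, lapply(docs, function(d) {
    tp <- sum(hit & pred$doc_id == d)
    fp <- sum(!hit & pred$doc_id == d)
    fn <- sum(!gold_hit & gold$doc_id == d)
    data.frame(doc_id = d, tp = tp, fp = fp, fn = fn,
               stringsAsFactors = FALSE)
  }))
  tp <- sum(hit); fp <- sum(!hit); fn <- sum(!gold_hit)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = p, recall = r,
                 f1 = f, mode = mode,
                 by_document = by_doc %||% data.frame()),
            class = "spba_eval")
}

#' @export
print.spba_eval <- function(x, ...) {
  cat("<spba_eval> mode: ", x$mode, " (strict span, micro-averaged)\n",
      sep = "")
  cat(sprintf("  TP=%d FP=%d FN=%d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  P=%.3f R=%.3f F=%.3f\n", x$precision, x$recall, x$f1))
  invisible(x)
}
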