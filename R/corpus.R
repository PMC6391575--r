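#' Annotated corpora
#'
#' An `spba_corpus` is a list of documents, each with a `doc_id`, its raw
#' `text`, and a data frame of gold `annotations` (`start`, `end`,
#' `surface`, `accessions`; offsets 0-based half-open into the text,
#' accessions `;`-separated, possibly empty for recognition-only corpora).
#'
#' @param documents List of documents (see [new_document()]).
#' @return An object of class `spba_corpus`.
#' @export
spba_corpus <- function(documents) {
  structure(list(documents = documents), class = "spba_corpus")
}

#' @rdname spba_corpus
#' @param doc_id Document identifier.
#' @param text Document text.
#' @param annotations Annotation data frame (defaults to none).
#' @export
new_document <- function(doc_id, text, annotations = NULL) {
  if (is.null(annotations))
    annotations <- data.frame(start = integer(), end = integer(),
                              surface = character(), accessions = character(),
                              stringsAsFactors = FALSE)
  if (is.null(annotations$accessions))
    annotations$accessions <- rep("", nrow(annotations))
  list(doc_id = as.character(doc_id), text = as.character(text),
       annotations = annotations)
}

#' @export
print.spba_corpus <- function(x, ...) {
  n_ann <- sum(vapply(x$documents, function(d) nrow(d$annotations),
                      integer(1)))
  cat("<spba_corpus> ", length(x$documents), " document(s), ", n_ann,
      " gold annotation(s)\n", sep = "")
  invisible(x)
}

#' Flatten a corpus' gold annotations into one data frame
#'
#' @param corpus An `spba_corpus`.
#' @return Data frame with `doc_id`, `start`, `end`, `surface`,
#'   `accessions`.
#' @export
corpus_annotations <- function(corpus) {
  rows <- lapply(corpus$documents, function(d) {
    if (!nrow(d$annotations)) return(NULL)
    cbind(data.frame(doc_id = d$doc_id, stringsAsFactors = FALSE),
          d$annotations)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out))
    out <- data.frame(doc_id = character(), start = integer(),
                      end = integer(), surface = character(),
                      accessions = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

validate_annotations <- function(doc_id, text, ann) {
  keep <- rep(TRUE, nrow(ann))
  for (i in seq_len(nrow(ann))) {
    if (is.na(ann$start[i]) || is.na(ann$end[i]) ||
        ann$start[i] < 0 || ann$end[i] > nchar(text) ||
        ann$start[i] >= ann$end[i]) {
      warning("document '", doc_id, "': annotation with invalid span [",
              ann$start[i], ",", ann$end[i], "); dropped")
      keep[i] <- FALSE
      next
    }
    got <- substr(text, ann$start[i] + 1L, ann$end[i])
    if (nzchar(ann$surface[i]) && got != ann$surface[i]) {
      warning("document '", doc_id, "': surface '", ann$surface[i],
              "' does not match text at [", ann$start[i], ",", ann$end[i],
              ") ('", got, "'); dropped")
      keep[i] <- FALSE
    }
  }
  ann[keep, , drop = FALSE]
}

#' Read an annotated corpus
#'
#' Standoff format: `<path>` is a `.txt` file with one document per line,
#' `doc_id<TAB>text`; annotations live in the sibling `.ann` file, one per
#' line, `doc_id<TAB>start<TAB>end<TAB>surface<TAB>accessions` (accessions
#' `;`-separated, optional; offsets 0-based half-open). BioC format:
#' `<path>` is a BioC XML collection whose passage annotations carry
#' `type = miRNA` and optional `Rfam` infons.
#'
#' @param path Path to the `.txt` (standoff) or `.xml` (BioC) file.
#' @param format `"standoff"` or `"bioc"`.
#' @return An `spba_corpus`. Annotations with invalid offsets are dropped
#'   with a warning.
#' @export
read_corpus <- function(path, format = c("standoff", "bioc")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path)
  if (format == "bioc") return(read_bioc(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  docs <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) stop("malformed document line: ", substr(ln, 1, 60))
    docs[[parts[1]]] <- new_document(parts[1],
                                     paste(parts[-1], collapse = "\t"))
  }
  ann_path <- sub("\\.txt$", ".ann", path)
  if (ann_path != path && file.exists(ann_path)) {
    ann <- read_annotations(ann_path)
    for (i in seq_len(nrow(ann))) {
      id <- ann$doc_id[i]
      if (is.null(docs[[id]])) {
        warning("annotation for unknown document '", id, "'; dropped")
        next
      }
      docs[[id]]$annotations <- rbind(
        docs[[id]]$annotations,
        ann[i, c("start", "end", "surface", "accessions"), drop = FALSE])
    }
    for (id in names(docs))
      docs[[id]]$annotations <- validate_annotations(
        id, docs[[id]]$text, docs[[id]]$annotations)
  }
  spba_corpus(unname(docs))
}

#' Write an annotated corpus in the standoff format
#'
#' @param corpus An `spba_corpus`.
#' @param path Path to the output `.txt` file; annotations go to the
#'   sibling `.ann` file.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  writeLines(vapply(corpus$documents, function(d)
    paste(d$doc_id, d$text, sep = "\t"), character(1)), path)
  write_annotations(corpus_annotations(corpus),
                    sub("\\.txt$", ".ann", path))
  invisible(path)
}

#' Read / write standoff annotation files
#'
#' One annotation per line:
#' `doc_id<TAB>start<TAB>end<TAB>surface<TAB>accessions[<TAB>score<TAB>principle]`.
#'
#' @param path File path.
#' @return For `read_annotations`, a data frame with at least `doc_id`,
#'   `start`, `end`, `surface`, `accessions`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(ln) {
    p <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(p) < 4L) stop("malformed annotation line: ", substr(ln, 1, 60))
    data.frame(doc_id = p[1], start = as.integer(p[2]), end = as.integer(p[3]),
               surface = p[4],
               accessions = if (length(p) >= 5L) p[5] else "",
               score = if (length(p) >= 6L) as.numeric(p[6]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(doc_id = character(), start = integer(),
                      end = integer(), surface = character(),
                      accessions = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  out
}

#' @rdname read_annotations
#' @param ann Annotation data frame.
#' @export
write_annotations <- function(ann, path) {
  lines <- vapply(seq_len(nrow(ann)), function(i) {
    base <- paste(ann$doc_id[i], ann$start[i], ann$end[i], ann$surface[i],
                  ann$accessions[i] %||% "", sep = "\t")
    if (!is.null(ann$score) && !is.na(ann$score[i]))
      base <- paste(base, format(round(ann$score[i], 3)),
                    ann$principle[i] %||% "", sep = "\t")
    base
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

read_bioc <- function(path) {
  xml <- xml2::read_xml(path)
  docs <- lapply(xml2::xml_find_all(xml, ".//document"), function(dnode) {
    id <- xml2::xml_text(xml2::xml_find_first(dnode, "./id"))
    passages <- xml2::xml_find_all(dnode, "./passage")
    text <- ""
    rows <- list()
    for (pnode in passages) {
      off <- as.integer(xml2::xml_text(xml2::xml_find_first(pnode,
                                                            "./offset")))
      ptext <- xml2::xml_text(xml2::xml_find_first(pnode, "./text"))
      if (is.na(off)) off <- nchar(text)
      if (nchar(text) < off) text <- paste0(text,
                                            strrep(" ", off - nchar(text)))
      text <- paste0(substr(text, 1, off), ptext)
      for (anode in xml2::xml_find_all(pnode, "./annotation")) {
        loc <- xml2::xml_find_first(anode, "./location")
        astart <- as.integer(xml2::xml_attr(loc, "offset"))
        alen <- as.integer(xml2::xml_attr(loc, "length"))
        surf <- xml2::xml_text(xml2::xml_find_first(anode, "./text"))
        rfam <- xml2::xml_text(xml2::xml_find_first(
          anode, "./infon[@key='Rfam']"))
        rows[[length(rows) + 1L]] <- data.frame(
          start = astart, end = astart + alen, surface = surf,
          accessions = if (is.na(rfam)) "" else rfam,
          stringsAsFactors = FALSE)
      }
    }
    ann <- do.call(rbind, rows)
    if (is.null(ann)) ann <- NULL
    d <- new_document(id, text, ann)
    d$annotations <- validate_annotations(id, text, d$annotations)
    d
  })
  spba_corpus(docs)
}

#' Write a corpus (with annotations) as BioC XML
#'
#' One passage per document; annotations carry `type = miRNA` and, when
#' present, an `Rfam` infon with the `;`-separated accessions.
#'
#' @param corpus An `spba_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bioc <- function(corpus, path) {
  root <- xml2::xml_new_root("collection")
  xml2::xml_add_child(root, "source", "spba")
  for (d in corpus$documents) {
    dnode <- xml2::xml_add_child(root, "document")
    xml2::xml_add_child(dnode, "id", d$doc_id)
    pnode <- xml2::xml_add_child(dnode, "passage")
    xml2::xml_add_child(pnode, "offset", "0")
    xml2::xml_add_child(pnode, "text", d$text)
    ann <- d$annotations
    for (i in seq_len(nrow(ann))) {
      anode <- xml2::xml_add_child(pnode, "annotation",
                                   id = as.character(i))
      inf <- xml2::xml_add_child(anode, "infon", "miRNA")
      xml2::xml_set_attr(inf, "key", "type")
      if (nzchar(ann$accessions[i] %||% "")) {
        rf <- xml2::xml_add_child(anode, "infon", ann$accessions[i])
        xml2::xml_set_attr(rf, "key", "Rfam")
      }
      loc <- xml2::xml_add_child(anode, "location")
      xml2::xml_set_attr(loc, "offset", as.character(ann$start[i]))
      xml2::xml_set_attr(loc, "length",
                         as.character(ann$end[i] - ann$start[i]))
      xml2::xml_add_child(anode, "text", ann$surface[i])
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}
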