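#' Slot schemes: the hierarchical lexical knowledge behind principles
#'
#' A slot scheme defines the named lexical categories ("slots") out of which
#' miRNA mention principles are built: closed-class slots hold literal term
#' lists (e.g. `Species` holding "hsa" and "cel"), open-class slots hold a
#' recognizer pattern (e.g. `Order`, the numbering part of a miRNA name), and
#' slots may be organized hierarchically so that a token labeled with a child
#' slot is also reportable under its parent (e.g. `Hairpin` "3p"/"5p" terms
#' generalize to `Suffix`).
#'
#' @param slots A list of slot definitions created with [slot_def()].
#' @param version Free-text version stamp.
#' @return An object of class `spba_scheme`.
#' @seealso [read_slot_scheme()], [default_slot_scheme()], [lookup_term()]
#' @export
#' @examples
#' sc <- spba_scheme(list(
#'   slot_def("miRNA", terms = c("mir", "let")),
#'   slot_def("Order", pattern = "^[0-9]{1,4}[a-z]{0,2}[0-9]?$")
#' ))
#' lookup_term(sc, "miR")
spba_scheme <- function(slots, version = "1") {
  names(slots) <- vapply(slots, `[[`, character(1), "name")
  scheme <- structure(list(slots = slots, version = as.character(version)),
                      class = "spba_scheme")
  validate_scheme(scheme)
  scheme
}

#' Define a single slot
#'
#' @param name Slot identifier (unique within a scheme).
#' @param parent Optional parent slot identifier (generalization).
#' @param terms Character vector of literal terms (closed class); stored
#'   case-folded and de-duplicated. Terms may contain spaces, in which case
#'   they match a run of tokens.
#' @param pattern Optional regular expression making the slot open class:
#'   a token matches the slot when the case-folded token matches the pattern.
#' @return A list of class `spba_slot_def`.
#' @export
slot_def <- function(name, parent = NA_character_, terms = character(),
                     pattern = NA_character_) {
  terms <- unique(casefold_term(as.character(terms)))
  if (any(!nzchar(terms)))
    stop("slot '", name, "': empty term after case-folding")
  structure(list(name = as.character(name), parent = as.character(parent),
                 terms = terms, pattern = as.character(pattern)),
            class = "spba_slot_def")
}

validate_scheme <- function(scheme) {
  slots <- scheme$slots
  nms <- names(slots)
  if (anyDuplicated(nms))
    stop("duplicate slot name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  parents <- vapply(slots, `[[`, character(1), "parent")
  bad <- parents[!is.na(parents) & !(parents %in% nms)]
  if (length(bad))
    stop("dangling parent reference(s): ", paste(unique(bad), collapse = ", "))
  # acyclicity: walk each parent chain
  for (nm in nms) {
    seen <- character()
    cur <- nm
    while (!is.na(slots[[cur]]$parent)) {
      if (cur %in% seen) stop("slot hierarchy contains a cycle at '", nm, "'")
      seen <- c(seen, cur)
      cur <- slots[[cur]]$parent
    }
  }
  # a slot must be matchable or be a pure generalization node with children
  has_child <- nms %in% parents
  for (i in seq_along(slots)) {
    s <- slots[[i]]
    if (!length(s$terms) && is.na(s$pattern) && !has_child[i])
      stop("slot '", s$name,
           "' has no terms, no pattern and no child slots")
  }
  invisible(scheme)
}

#' @export
print.spba_scheme <- function(x, ...) {
  cat("<spba_scheme> version ", x$version, ", ", length(x$slots),
      " slots\n", sep = "")
  for (s in x$slots) {
    kind <- if (!is.na(s$pattern)) paste0("open /", s$pattern, "/")
            else paste0(length(s$terms), " terms")
    par <- if (is.na(s$parent)) "" else paste0(" < ", s$parent)
    cat("  ", s$name, par, ": ", kind, "\n", sep = "")
  }
  invisible(x)
}

#' Ancestors of a slot (nearest first)
#' @param scheme An `spba_scheme`.
#' @param slot Slot identifier.
#' @return Character vector of ancestor slot names, possibly empty.
#' @export
slot_ancestors <- function(scheme, slot) {
  out <- character()
  cur <- scheme$slots[[slot]]
  while (!is.null(cur) && !is.na(cur$parent)) {
    out <- c(out, cur$parent)
    cur <- scheme$slots[[cur$parent]]
  }
  out
}

slot_depth <- function(scheme, slot) length(slot_ancestors(scheme, slot))

#' Look up the slots matching a token
#'
#' Returns every slot whose own term list (or open-class pattern) matches the
#' case-folded token, together with all ancestors of those slots, so that a
#' token carrying a child label is also retrievable via the parent label.
#'
#' @param scheme An `spba_scheme`.
#' @param token_text A single token string.
#' @return Character vector of slot identifiers (empty when nothing matches).
#' @export
lookup_term <- function(scheme, token_text) {
  tok <- casefold_term(token_text)
  hits <- character()
  for (s in scheme$slots) {
    ok <- tok %in% s$terms ||
      (!is.na(s$pattern) && nzchar(tok) && grepl(s$pattern, tok, perl = TRUE))
    if (ok) hits <- c(hits, s$name, slot_ancestors(scheme, s$name))
  }
  sort(unique(hits))
}

#' Read a slot scheme from its plain-text format
#'
#' The format is one slot per block: a header line
#' `SLOT <name> [PARENT <name>] [OPEN <regex>]`, followed by indented lines
#' holding one term each. Lines starting with `#` and blank lines are
#' ignored; an optional `VERSION <text>` line sets the scheme version.
#'
#' @param path Path to the scheme file.
#' @return An `spba_scheme`.
#' @export
read_slot_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  slots <- list()
  version <- "1"
  cur <- NULL
  flush <- function() {
    if (!is.null(cur)) slots[[length(slots) + 1L]] <<- do.call(slot_def, cur)
    cur <<- NULL
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || grepl("^\\s*#", ln)) next
    if (grepl("^VERSION\\s+", ln)) {
      version <- trimws(sub("^VERSION\\s+", "", ln))
    } else if (grepl("^SLOT\\s+", ln)) {
      flush()
      rest <- trimws(sub("^SLOT\\s+", "", ln))
      words <- strsplit(rest, "\\s+")[[1]]
      cur <- list(name = words[1], terms = character())
      j <- 2L
      while (j < length(words) + 1L && j <= length(words)) {
        key <- words[j]
        if (key == "PARENT") {
          if (j == length(words))
            stop("line ", i, ": PARENT without a value")
          cur$parent <- words[j + 1L]; j <- j + 2L
        } else if (key == "OPEN") {
          if (j == length(words))
            stop("line ", i, ": OPEN without a pattern")
          cur$pattern <- paste(words[(j + 1L):length(words)], collapse = " ")
          j <- length(words) + 1L
        } else stop("line ", i, ": unexpected token '", key, "'")
      }
    } else if (grepl("^\\s+", ln)) {
      if (is.null(cur)) stop("line ", i, ": term line before any SLOT header")
      cur$terms <- c(cur$terms, trimws(ln))
    } else {
      stop("line ", i, ": cannot parse '", ln, "'")
    }
  }
  flush()
  if (!length(slots)) stop("scheme file defines no slots: ", path)
  spba_scheme(slots, version = version)
}

#' Write a slot scheme to its plain-text format
#'
#' `read_slot_scheme(write_slot_scheme(x, path))` reproduces `x`.
#'
#' @param scheme An `spba_scheme`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_slot_scheme <- function(scheme, path) {
  validate_scheme(scheme)
  out <- c(paste("VERSION", scheme$version))
  for (s in scheme$slots) {
    hdr <- paste("SLOT", s$name)
    if (!is.na(s$parent)) hdr <- paste(hdr, "PARENT", s$parent)
    if (!is.na(s$pattern)) hdr <- paste(hdr, "OPEN", s$pattern)
    out <- c(out, hdr, paste0("  ", s$terms))
  }
  ok <- tryCatch({ writeLines(out, path); TRUE },
                 error = function(e) stop("cannot write scheme: ",
                                          conditionMessage(e)))
  invisible(path)
}

#' The bundled default slot scheme
#'
#' Covers the slots a miRNA mention is built from: a `Prefix` generalization
#' over `Precursor` ("pre", "pri") and `Species` ("hsa", "cel"); the `miRNA`
#' indicator slot ("mir", "mirna", "microrna", "micro rna", "lsy") with a
#' `Let` child ("let", "lin") for the lethal-7/lin-4 precursor families; the
#' open-class `Order` slot matching numbering strings such as "21", "181b" or
#' "16a1"; `Conj` for conjunctions inside list mentions; and `Suffix`
#' generalizing the `Hairpin` arm terms "3p"/"5p".
#'
#' @return An `spba_scheme`.
#' @export
default_slot_scheme <- function() {
  path <- system.file("extdata", "default_scheme.txt", package = "spba")
  if (!nzchar(path))
    path <- file.path("inst", "extdata", "default_scheme.txt")
  read_slot_scheme(path)
}
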