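#' @title Standoff (.txt/.a1/.a2) reading and writing
#' @description The BioNLP Shared Task standoff format: a document is a raw
#'   `.txt` file plus tab-separated annotation records — `T` entities and
#'   triggers, `E` events, `R` relations, `M` modifiers and `*  Equiv`
#'   equivalence lines — with document-scoped character offsets. The `.a1`
#'   file holds given entities, the `.a2` file everything predicted.
#' @name st-io
NULL

#' Construct a standoff document
#'
#' @param id Document identifier.
#' @param text Document text.
#' @param entities Tibble `id`, `type`, `start`, `end`, `text`, `given`.
#' @param events Tibble `id`, `type`, `trigger`, list-column `args` of
#'   tibbles `role`, `target` (targets are `T` or `E` ids; role names carry
#'   the standoff numbering, e.g. `Theme2`).
#' @param relations Tibble `id`, `type`, list-column `args` as above.
#' @param modifiers Tibble `id`, `kind`, `target`.
#' @param equivs List of character vectors of `T` ids.
#' @return An `st_document`.
#' @export
st_document <- function(id, text,
                        entities = NULL, events = NULL, relations = NULL,
                        modifiers = NULL, equivs = list()) {
  if (is.null(entities)) {
    entities <- fast_tbl(id = character(), type = character(),
                               start = integer(), end = integer(),
                               text = character(), given = logical())
  }
  if (is.null(events)) {
    events <- fast_tbl(id = character(), type = character(),
                             trigger = character(), args = list())
  }
  if (is.null(relations)) {
    relations <- fast_tbl(id = character(), type = character(),
                                args = list())
  }
  if (is.null(modifiers)) {
    modifiers <- fast_tbl(id = character(), kind = character(),
                                target = character())
  }
  structure(list(id = as.character(id), text = text,
                 entities = tibble::as_tibble(entities),
                 events = tibble::as_tibble(events),
                 relations = tibble::as_tibble(relations),
                 modifiers = tibble::as_tibble(modifiers),
                 equivs = equivs),
            class = "st_document")
}

#' @export
print.st_document <- function(x, ...) {
  cat(sprintf("<st_document %s> %d entities, %d events, %d relations, %d modifiers, %d equiv groups\n",
              x$id, nrow(x$entities), nrow(x$events), nrow(x$relations),
              nrow(x$modifiers), length(x$equivs)))
  invisible(x)
}

st_parse_error <- function(file, lineno, line, why) {
  stop(sprintf("malformed standoff line (%s:%d): %s [%s]", file, lineno, why,
               line), call. = FALSE)
}

parse_arg_pairs <- function(txt) {
  if (!length(txt) || !nzchar(txt)) return(empty_role_args())
  pieces <- strsplit(trimws(txt), "\\s+")[[1]]
  parts <- strsplit(pieces, ":", fixed = TRUE)
  fast_tbl(role = vapply(parts, `[`, character(1), 1),
                 target = vapply(parts, `[`, character(1), 2))
}

empty_role_args <- function() {
  fast_tbl(role = character(), target = character())
}

parse_st_lines <- function(lines, file, given, acc) {
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (!nzchar(ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    id <- f[1]
    if (startsWith(id, "T")) {
      if (length(f) < 3) st_parse_error(file, k, ln, "entity line needs 3 fields")
      m <- regmatches(f[2], regexec("^(.*\\S) (\\d+) (\\d+)$", f[2]))[[1]]
      if (!length(m)) st_parse_error(file, k, ln, "cannot parse 'TYPE start end'")
      acc$entities[[length(acc$entities) + 1]] <- fast_tbl(
        id = id, type = m[2], start = as.integer(m[3]), end = as.integer(m[4]),
        text = f[3], given = given)
    } else if (startsWith(id, "E")) {
      if (length(f) < 2) st_parse_error(file, k, ln, "event line needs 2 fields")
      args <- parse_arg_pairs(f[2])
      if (!nrow(args)) st_parse_error(file, k, ln, "event line has no trigger")
      acc$events[[length(acc$events) + 1]] <- fast_tbl(
        id = id, type = args$role[1], trigger = args$target[1],
        args = list(args[-1, , drop = FALSE]))
    } else if (startsWith(id, "R")) {
      if (length(f) < 2) st_parse_error(file, k, ln, "relation line needs 2 fields")
      pieces <- strsplit(trimws(f[2]), "\\s+")[[1]]
      if (length(pieces) < 2) st_parse_error(file, k, ln, "relation needs arguments")
      acc$relations[[length(acc$relations) + 1]] <- fast_tbl(
        id = id, type = pieces[1],
        args = list(parse_arg_pairs(paste(pieces[-1], collapse = " "))))
    } else if (startsWith(id, "M")) {
      if (length(f) < 2) st_parse_error(file, k, ln, "modifier line needs 2 fields")
      pieces <- strsplit(trimws(f[2]), "\\s+")[[1]]
      if (length(pieces) != 2) st_parse_error(file, k, ln, "modifier needs 'Kind Eid'")
      acc$modifiers[[length(acc$modifiers) + 1]] <- fast_tbl(
        id = id, kind = pieces[1], target = pieces[2])
    } else if (id == "*") {
      pieces <- strsplit(trimws(f[2]), "\\s+")[[1]]
      if (length(pieces) < 3 || pieces[1] != "Equiv") {
        st_parse_error(file, k, ln, "expected '* Equiv T T ...'")
      }
      acc$equivs[[length(acc$equivs) + 1]] <- pieces[-1]
    } else {
      st_parse_error(file, k, ln, "unknown record kind")
    }
  }
  acc
}

as_st_lines <- function(x) {
  if (length(x) == 1 && grepl("\n", x, fixed = TRUE)) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(x)
  }
}

#' Read a standoff document
#'
#' Parses the `.txt`/`.a1`/`.a2` triplet of one document. Every record
#' becomes exactly one row; entity offsets are verified against the text.
#'
#' @param txt Document text (single string) or path when `from_files = TRUE`.
#' @param a1,a2 Character vectors of standoff lines (or a single
#'   newline-joined string, or file paths with `from_files = TRUE`). `NULL`
#'   is treated as empty.
#' @param id Document id; defaults to `"doc"` (or the txt file stem).
#' @param from_files Read the three arguments as file paths.
#' @return An [st_document()].
#' @export
read_st_document <- function(txt, a1 = NULL, a2 = NULL, id = NULL,
                             from_files = FALSE) {
  if (from_files) {
    if (is.null(id)) id <- sub("\\.txt$", "", basename(txt))
    txt <- paste(readLines(txt, warn = FALSE), collapse = "\n")
    a1 <- if (!is.null(a1) && file.exists(a1)) readLines(a1, warn = FALSE) else character()
    a2 <- if (!is.null(a2) && file.exists(a2)) readLines(a2, warn = FALSE) else character()
  }
  if (is.null(id)) id <- "doc"
  acc <- list(entities = list(), events = list(), relations = list(),
              modifiers = list(), equivs = list())
  acc <- parse_st_lines(as_st_lines(a1 %||% character()), ".a1", TRUE, acc)
  acc <- parse_st_lines(as_st_lines(a2 %||% character()), ".a2", FALSE, acc)
  ent <- if (length(acc$entities)) dplyr::bind_rows(acc$entities) else NULL
  doc <- st_document(
    id, txt,
    entities = ent,
    events = if (length(acc$events)) dplyr::bind_rows(acc$events) else NULL,
    relations = if (length(acc$relations)) dplyr::bind_rows(acc$relations) else NULL,
    modifiers = if (length(acc$modifiers)) dplyr::bind_rows(acc$modifiers) else NULL,
    equivs = acc$equivs)
  e <- doc$entities
  if (nrow(e)) {
    slice <- substring(txt, e$start + 1L, e$end)
    bad <- which(slice != e$text)
    if (length(bad)) {
      stop(sprintf("entity %s text '%s' does not match document slice '%s'",
                   e$id[bad[1]], e$text[bad[1]], slice[bad[1]]), call. = FALSE)
    }
  }
  doc
}

st_referenced_ids <- function(d) {
  c(unlist(lapply(d$events$args, function(a) a$target)),
    d$events$trigger,
    unlist(lapply(d$relations$args, function(a) a$target)),
    d$modifiers$target, unlist(d$equivs))
}

st_check_references <- function(d) {
  known <- c(d$entities$id, d$events$id, d$relations$id)
  miss <- setdiff(st_referenced_ids(d), known)
  if (length(miss)) {
    stop(sprintf("document '%s' has dangling references: %s", d$id,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# deterministic renumbering: T by (start, end, type) with given entities
# first; E in topological order (arguments before referencing events);
# R and M last
st_id_map <- function(d) {
  e <- d$entities
  ord <- order(!e$given, e$start, e$end, e$type)
  map <- stats::setNames(paste0("T", seq_len(nrow(e))), e$id[ord])
  ev <- d$events
  if (nrow(ev)) {
    deps <- lapply(ev$args, function(a) intersect(a$target, ev$id))
    names(deps) <- ev$id
    ordered <- character(); pending <- ev$id
    while (length(pending)) {
      ready <- pending[vapply(deps[pending], function(x)
        all(x %in% ordered), logical(1))]
      if (!length(ready)) ready <- pending  # cycle guard; should not happen
      ordered <- c(ordered, ready)
      pending <- setdiff(pending, ready)
    }
    map <- c(map, stats::setNames(paste0("E", seq_along(ordered)), ordered))
  }
  if (nrow(d$relations)) {
    map <- c(map, stats::setNames(paste0("R", seq_len(nrow(d$relations))),
                                  d$relations$id))
  }
  if (nrow(d$modifiers)) {
    map <- c(map, stats::setNames(paste0("M", seq_len(nrow(d$modifiers))),
                                  d$modifiers$id))
  }
  map
}

#' Write a standoff document
#'
#' Emits the `.a1`/`.a2` line vectors for a document, renumbering ids
#' deterministically: `T` records ordered by (given, start, end, type), `E`
#' records topologically (arguments before the events that reference them),
#' `R`/`M` records last. Reading the output back recovers the document up to
#' id renumbering.
#'
#' @param d An [st_document()]; referential integrity is checked first.
#' @return List with character vectors `a1` and `a2` (and `txt`, the text).
#' @export
write_st_document <- function(d) {
  st_check_references(d)
  map <- st_id_map(d)
  e <- d$entities
  ent_lines <- function(rows) {
    rows <- rows[order(rows$start, rows$end, rows$type), , drop = FALSE]
    sprintf("%s\t%s %d %d\t%s", map[rows$id], rows$type, rows$start,
            rows$end, rows$text)
  }
  a1 <- character()
  if (any(e$given)) a1 <- ent_lines(e[e$given, , drop = FALSE])
  for (g in d$equivs) {
    a1 <- c(a1, paste0("*\tEquiv ", paste(map[g], collapse = " ")))
  }
  a2 <- character()
  if (any(!e$given)) a2 <- ent_lines(e[!e$given, , drop = FALSE])
  ev <- d$events
  if (nrow(ev)) {
    new_ids <- map[ev$id]
    ord <- order(as.integer(substring(new_ids, 2)))
    for (i in ord) {
      args <- ev$args[[i]]
      arg_txt <- if (nrow(args)) {
        paste0(" ", paste(sprintf("%s:%s", args$role, map[args$target]),
                          collapse = " "))
      } else ""
      a2 <- c(a2, sprintf("%s\t%s:%s%s", new_ids[i], ev$type[i],
                          map[ev$trigger[i]], arg_txt))
    }
  }
  rl <- d$relations
  for (i in seq_len(nrow(rl))) {
    args <- rl$args[[i]]
    a2 <- c(a2, sprintf("%s\t%s %s", map[rl$id[i]], rl$type[i],
                        paste(sprintf("%s:%s", args$role, map[args$target]),
                              collapse = " ")))
  }
  md <- d$modifiers
  for (i in seq_len(nrow(md))) {
    a2 <- c(a2, sprintf("%s\t%s %s", map[md$id[i]], md$kind[i],
                        map[md$target[i]]))
  }
  list(txt = d$text, a1 = a1, a2 = a2)
}

#' Write / read a standoff corpus directory
#'
#' One `.txt`/`.a1`/`.a2` triplet per document, named by document id.
#'
#' @param docs List of [st_document()]s.
#' @param dir Directory path.
#' @return `write_st_directory`: the directory, invisibly.
#'   `read_st_directory`: list of `st_document`s.
#' @export
write_st_directory <- function(docs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in docs) {
    out <- write_st_document(d)
    writeLines(out$txt, file.path(dir, paste0(d$id, ".txt")))
    writeLines(out$a1, file.path(dir, paste0(d$id, ".a1")))
    writeLines(out$a2, file.path(dir, paste0(d$id, ".a2")))
  }
  invisible(dir)
}

#' @rdname write_st_directory
#' @export
read_st_directory <- function(dir) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  lapply(txts, function(tx) {
    stem <- sub("\\.txt$", "", tx)
    read_st_document(tx, paste0(stem, ".a1"), paste0(stem, ".a2"),
                     from_files = TRUE)
  })
}

# role numbering: standoff uses Theme, Theme2, ... for repeated roles
role_base <- function(role) sub("(?<=\\D)\\d+$", "", role, perl = TRUE)

role_suffix <- function(role) {
  out <- rep(NA_integer_, length(role))
  hit <- regexpr("(?<=\\D)\\d+$", role, perl = TRUE)
  has <- hit > 0
  out[has] <- as.integer(substring(role[has], hit[has]))
  out
}
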