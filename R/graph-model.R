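#' @title Interaction-graph data model
#' @description Constructors and accessors for the unified graph
#'   representation: sentences carrying tokens, dependencies, entity nodes and
#'   interaction edges; documents grouping sentences; corpora grouping
#'   documents. All annotation layers are tibbles so they compose with dplyr.
#' @name graph-model
NULL

#' Empty annotation-layer tables
#'
#' Column-typed empty tibbles for each per-sentence annotation layer. Useful
#' when constructing sentences programmatically.
#'
#' @return A zero-row tibble with the layer's columns.
#' @keywords internal
#' @name empty-layers
NULL

# quosure-free tibble construction for hot paths (row-per-record loops)
fast_tbl <- function(...) {
  x <- list(...)
  tibble::new_tibble(x, nrow = if (length(x)) length(x[[1]]) else 0L)
}

#' @rdname empty-layers
#' @export
empty_tokens <- function() {
  fast_tbl(id = character(), text = character(), pos = character(),
                 start = integer(), end = integer())
}

#' @rdname empty-layers
#' @export
empty_dependencies <- function() {
  fast_tbl(type = character(), governor = character(),
                 dependent = character())
}

#' @rdname empty-layers
#' @export
empty_entities <- function() {
  fast_tbl(id = character(), type = character(), start = integer(),
                 end = integer(), text = character(), head = character(),
                 given = logical(), event = logical(),
                 negation = logical(), speculation = logical())
}

#' @rdname empty-layers
#' @export
empty_interactions <- function() {
  fast_tbl(id = character(), type = character(), source = character(),
                 target = character(), directed = logical(),
                 event = logical(), given = logical(),
                 site_of = character(), source_role = character(),
                 target_role = character(), cross_sentence = logical())
}

#' @rdname empty-layers
#' @export
empty_events <- function() {
  fast_tbl(id = character(), trigger = character(),
                 args = list())
}

# one event's argument list: interaction id plus, when the argument points at
# another event (not just its trigger node), that event's membership id
empty_event_args <- function() {
  fast_tbl(interaction = character(), target_event = character())
}

complete_layer <- function(x, template) {
  if (is.data.frame(x) && identical(names(x), names(template))) {
    return(if (tibble::is_tibble(x)) x else tibble::as_tibble(x))
  }
  x <- tibble::as_tibble(x)
  for (col in setdiff(names(template), names(x))) {
    proto <- template[[col]]
    x[[col]] <- if (is.logical(proto)) {
      if (col %in% c("given", "event", "negation", "speculation",
                     "directed", "cross_sentence")) {
        rep(col == "directed", nrow(x))
      } else rep(FALSE, nrow(x))
    } else if (is.integer(proto)) rep(NA_integer_, nrow(x))
    else rep(NA_character_, nrow(x))
  }
  # unknown columns (e.g. preserved foreign XML attributes) ride along
  x[c(names(template), setdiff(names(x), names(template)))]
}

#' Construct a sentence graph
#'
#' Binds the annotation layers of one sentence into a `sentence_graph`
#' object. Offsets in all layers are 0-based, half-open and sentence-scoped;
#' `offset` records where the sentence starts in its document so conversion
#' to document-scoped standoff offsets is a plain shift.
#'
#' @param id Sentence identifier, unique within the document.
#' @param text Sentence text.
#' @param tokens,dependencies,entities,interactions,events Annotation layers;
#'   missing columns are filled with defaults (`given`/`event`/modifier flags
#'   `FALSE`, `directed` `TRUE`).
#' @param offset Integer start of the sentence in the document text.
#' @return A `sentence_graph` object.
#' @export
#' @examples
#' s <- sentence_graph("s1", "BMP-6 binds ALK2.",
#'   tokens = tibble::tibble(
#'     id = c("t1", "t2", "t3", "t4"),
#'     text = c("BMP-6", "binds", "ALK2", "."),
#'     pos = c("NN", "VBZ", "NN", "."),
#'     start = c(0L, 6L, 12L, 16L), end = c(5L, 11L, 16L, 17L)))
sentence_graph <- function(id, text,
                           tokens = empty_tokens(),
                           dependencies = empty_dependencies(),
                           entities = empty_entities(),
                           interactions = empty_interactions(),
                           events = empty_events(),
                           offset = 0L) {
  structure(list(
    id = as.character(id), text = text,
    tokens = complete_layer(tokens, empty_tokens()),
    dependencies = complete_layer(dependencies, empty_dependencies()),
    entities = complete_layer(entities, empty_entities()),
    interactions = complete_layer(interactions, empty_interactions()),
    events = {
      ev <- tibble::as_tibble(events)
      if (!"args" %in% names(ev)) ev$args <- list()
      ev
    },
    offset = as.integer(offset)
  ), class = "sentence_graph")
}

#' Construct a document
#'
#' @param id Document identifier.
#' @param text Full document text; sentence offsets index into it.
#' @param sentences List of [sentence_graph()] objects whose offsets tile the
#'   document.
#' @param equivs List of character vectors of entity-node ids forming
#'   given equivalence groups.
#' @return An `ig_document` object.
#' @export
ig_document <- function(id, text, sentences = list(), equivs = list()) {
  structure(list(id = as.character(id), text = text,
                 sentences = sentences, equivs = equivs),
            class = "ig_document")
}

#' Construct a corpus
#'
#' @param documents List of [ig_document()] objects with unique ids.
#' @param set Partition label, e.g. `"train"`, `"devel"` or `"test"`.
#' @return An `ig_corpus` object.
#' @export
ig_corpus <- function(documents = list(), set = "train") {
  ids <- vapply(documents, function(d) d$id, character(1))
  names(documents) <- ids
  structure(list(documents = documents, set = set), class = "ig_corpus")
}

#' @export
print.sentence_graph <- function(x, ...) {
  cat(sprintf("<sentence_graph %s> %s\n", x$id, x$text))
  cat(sprintf("  %d tokens, %d dependencies, %d entities, %d interactions, %d events\n",
              nrow(x$tokens), nrow(x$dependencies), nrow(x$entities),
              nrow(x$interactions), nrow(x$events)))
  invisible(x)
}

#' @export
print.ig_document <- function(x, ...) {
  cat(sprintf("<ig_document %s> %d sentences, %d chars\n",
              x$id, length(x$sentences), nchar(x$text)))
  invisible(x)
}

#' @export
print.ig_corpus <- function(x, ...) {
  cat(sprintf("<ig_corpus '%s'> %d documents, %d sentences\n",
              x$set, length(x$documents),
              sum(vapply(x$documents, function(d) length(d$sentences), integer(1)))))
  invisible(x)
}

corpus_sentences <- function(corpus) {
  unlist(lapply(corpus$documents, function(d) d$sentences), recursive = FALSE)
}

# entity lookup across a whole document (cross-sentence interactions point at
# entities in sibling sentences, so ids are resolved document-wide)
document_entities <- function(doc) {
  ents <- lapply(doc$sentences, function(s) {
    e <- s$entities
    e$sentence <- rep(s$id, nrow(e))
    e
  })
  dplyr::bind_rows(ents)
}

#' Resolve the syntactic head token of a character span
#'
#' Each entity node is bound to a single token, the syntactic head of its
#' span. Among tokens overlapping the span, the head is the token none of
#' whose governors lies inside the span (a parse root qualifies); if several
#' qualify the rightmost is taken, and if none does (a dependency cycle
#' within the span) the rightmost overlapping token is taken.
#'
#' @param start,end 0-based half-open character interval in sentence text.
#' @param sentence A [sentence_graph()].
#' @return The id of the head token.
#' @export
#' @examples
#' toks <- tibble::tibble(id = c("t1", "t2"), text = c("protein", "kinase"),
#'   pos = c("NN", "NN"), start = c(0L, 8L), end = c(7L, 14L))
#' deps <- tibble::tibble(type = "nn", governor = "t2", dependent = "t1")
#' s <- sentence_graph("s1", "protein kinase", tokens = toks, dependencies = deps)
#' resolve_head_token(0, 14, s)  # "t2"
resolve_head_token <- function(start, end, sentence) {
  tok <- sentence$tokens
  inside <- tok$start < end & tok$end > start
  if (!any(inside)) {
    stop(sprintf("span [%d,%d) of sentence '%s' overlaps no token",
                 as.integer(start), as.integer(end), sentence$id),
         call. = FALSE)
  }
  ids <- tok$id[inside]
  dep <- sentence$dependencies
  governed_inside <- vapply(ids, function(tid) {
    gov <- dep$governor[dep$dependent == tid]
    any(gov %in% ids)
  }, logical(1))
  cand <- ids[!governed_inside]
  if (!length(cand)) cand <- ids
  # rightmost by token start offset
  starts <- tok$start[match(cand, tok$id)]
  cand[which.max(starts)]
}

#' Validate a graph object
#'
#' Structural check of the graph invariants: token and entity offsets within
#' bounds, token text matching the sentence slice, unique ids, dependency
#' endpoints existing, interaction endpoints resolving (document-wide for
#' edges flagged `cross_sentence`), `site_of` references naming a sibling
#' edge with the same source node, and event memberships referencing
#' existing interactions. Reporting only: never throws.
#'
#' @param x A `sentence_graph`, `ig_document` or `ig_corpus`.
#' @return A tibble with columns `where`, `kind`, `message`; zero rows iff
#'   all invariants hold.
#' @export
validate_graph <- function(x) {
  UseMethod("validate_graph")
}

finding <- function(where, kind, message) {
  tibble::tibble(where = where, kind = kind, message = message)
}

#' @export
validate_graph.sentence_graph <- function(x) {
  validate_sentence_impl(x, extra_entity_ids = character())
}

validate_sentence_impl <- function(x, extra_entity_ids) {
  out <- list()
  n <- nchar(x$text)
  tok <- x$tokens
  if (anyDuplicated(tok$id)) {
    out[[length(out) + 1]] <- finding(x$id, "duplicate_id", "duplicate token ids")
  }
  bad <- which(tok$start < 0 | tok$end > n | tok$start >= tok$end)
  for (i in bad) {
    out[[length(out) + 1]] <- finding(
      x$id, "offset", sprintf("token %s has offsets [%d,%d) outside [0,%d)",
                              tok$id[i], tok$start[i], tok$end[i], n))
  }
  ok <- setdiff(seq_len(nrow(tok)), bad)
  mism <- ok[substring(x$text, tok$start[ok] + 1L, tok$end[ok]) != tok$text[ok]]
  for (i in mism) {
    out[[length(out) + 1]] <- finding(
      x$id, "offset", sprintf("token %s text does not match sentence slice", tok$id[i]))
  }
  dep <- x$dependencies
  bad_dep <- which(!(dep$governor %in% tok$id) | !(dep$dependent %in% tok$id) |
                     dep$governor == dep$dependent)
  for (i in bad_dep) {
    out[[length(out) + 1]] <- finding(
      x$id, "dependency", sprintf("dependency %s(%s,%s) has invalid endpoints",
                                  dep$type[i], dep$governor[i], dep$dependent[i]))
  }
  ent <- x$entities
  if (anyDuplicated(ent$id)) {
    out[[length(out) + 1]] <- finding(x$id, "duplicate_id", "duplicate entity ids")
  }
  for (i in which(ent$start < 0 | ent$end > n | ent$start >= ent$end)) {
    out[[length(out) + 1]] <- finding(
      x$id, "offset", sprintf("entity %s offsets out of bounds", ent$id[i]))
  }
  for (i in which(!(ent$head %in% tok$id))) {
    out[[length(out) + 1]] <- finding(
      x$id, "head", sprintf("entity %s head token '%s' missing", ent$id[i], ent$head[i]))
  }
  itr <- x$interactions
  if (nrow(itr)) {
    known <- c(ent$id, extra_entity_ids)
    if (anyDuplicated(itr$id)) {
      out[[length(out) + 1]] <- finding(x$id, "duplicate_id", "duplicate interaction ids")
    }
    for (i in which(!(itr$source %in% ent$id))) {
      out[[length(out) + 1]] <- finding(
        x$id, "dangling_endpoint",
        sprintf("interaction %s source '%s' missing", itr$id[i], itr$source[i]))
    }
    for (i in seq_len(nrow(itr))) {
      pool <- if (isTRUE(itr$cross_sentence[i])) known else ent$id
      if (!(itr$target[i] %in% pool)) {
        out[[length(out) + 1]] <- finding(
          x$id, "dangling_endpoint",
          sprintf("interaction %s target '%s' missing", itr$id[i], itr$target[i]))
      }
    }
    for (i in which(!is.na(itr$site_of))) {
      j <- match(itr$site_of[i], itr$id)
      if (is.na(j)) {
        out[[length(out) + 1]] <- finding(
          x$id, "site_of",
          sprintf("interaction %s siteOf names unknown edge '%s'",
                  itr$id[i], itr$site_of[i]))
      } else if (itr$source[j] != itr$source[i]) {
        out[[length(out) + 1]] <- finding(
          x$id, "site_of",
          sprintf("interaction %s siteOf edge '%s' has a different source node",
                  itr$id[i], itr$site_of[i]))
      }
    }
  }
  ev <- x$events
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      if (!(ev$trigger[i] %in% ent$id)) {
        out[[length(out) + 1]] <- finding(
          x$id, "event", sprintf("event %s trigger '%s' missing", ev$id[i], ev$trigger[i]))
      }
      args <- ev$args[[i]]
      if (nrow(args)) {
        miss <- setdiff(args$interaction, itr$id)
        for (m in miss) {
          out[[length(out) + 1]] <- finding(
            x$id, "event", sprintf("event %s references unknown interaction '%s'",
                                   ev$id[i], m))
        }
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out) else finding(character(), character(), character())
}

#' @export
validate_graph.ig_document <- function(x) {
  all_ids <- unlist(lapply(x$sentences, function(s) s$entities$id))
  out <- lapply(x$sentences, validate_sentence_impl, extra_entity_ids = all_ids)
  # sentence offsets must tile the document without overlap
  offs <- vapply(x$sentences, function(s) s$offset, integer(1))
  lens <- vapply(x$sentences, function(s) nchar(s$text), integer(1))
  if (length(offs) > 1) {
    o <- order(offs)
    ends <- offs[o] + lens[o]
    if (any(offs[o][-1] < ends[-length(ends)])) {
      out[[length(out) + 1]] <- finding(x$id, "offset", "sentence spans overlap")
    }
  }
  for (s in x$sentences) {
    if (s$offset + nchar(s$text) > nchar(x$text) ||
        substring(x$text, s$offset + 1L, s$offset + nchar(s$text)) != s$text) {
      out[[length(out) + 1]] <- finding(
        s$id, "offset", "sentence text does not match document slice")
    }
  }
  for (g in x$equivs) {
    if (!all(g %in% all_ids)) {
      out[[length(out) + 1]] <- finding(
        x$id, "equiv", "equivalence group references unknown entity")
    }
  }
  dplyr::bind_rows(out)
}

#' @export
validate_graph.ig_corpus <- function(x) {
  ids <- vapply(x$documents, function(d) d$id, character(1))
  out <- lapply(x$documents, validate_graph)
  if (anyDuplicated(ids)) {
    out[[length(out) + 1]] <- finding("corpus", "duplicate_id", "duplicate document ids")
  }
  dplyr::bind_rows(out)
}
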