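#' @title Interaction XML reading and writing
#' @description The corpus-level XML serialization of the interaction graph:
#'   `corpus > document > sentence` elements carrying `entity`,
#'   `interaction` and `event` annotation plus embedded `token` and
#'   `dependency` parses. Character offsets are 0-based half-open
#'   (`charOffset="start-end"`). Boolean attributes are written as
#'   `True`/`False` and omitted at their defaults; attributes the package
#'   does not know are preserved verbatim through a round trip.
#' @name ixml
NULL

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub('"', "&quot;", x, fixed = TRUE)
  # keep whitespace intact through XML attribute-value normalization
  x <- gsub("\n", "&#10;", x, fixed = TRUE)
  gsub("\t", "&#9;", x, fixed = TRUE)
}

attr_str <- function(...) {
  kv <- c(...)
  kv <- kv[!is.na(kv)]
  if (!length(kv)) return("")
  paste0(" ", paste(sprintf('%s="%s"', names(kv), xml_escape(unname(kv))),
                    collapse = " "))
}

flag_attr <- function(name, value, default) {
  if (isTRUE(value) == default) stats::setNames(character(), character())
  else stats::setNames(if (isTRUE(value)) "True" else "False", name)
}

extra_attrs <- function(layer, i) {
  if (!"extra" %in% names(layer)) return(character())
  ex <- layer$extra[[i]]
  if (is.null(ex) || !length(ex)) character() else ex
}

#' Write a corpus as Interaction XML
#'
#' @param corpus An [ig_corpus()].
#' @param path Optional file path; when `NULL` the XML is returned as a
#'   single string.
#' @return The XML string (invisibly when written to a file).
#' @export
write_interaction_xml <- function(corpus, path = NULL) {
  out <- character()
  emit <- function(x) out[[length(out) + 1L]] <<- x
  emit('<?xml version="1.0" encoding="UTF-8"?>')
  emit(sprintf('<corpus%s>', attr_str(c(set = corpus$set))))
  for (doc in corpus$documents) {
    emit(sprintf('  <document%s>', attr_str(c(id = doc$id,
                                              text = doc$text))))
    for (s in doc$sentences) {
      emit(sprintf('    <sentence%s>', attr_str(c(
        id = s$id, text = s$text,
        charOffset = sprintf("%d-%d", s$offset, s$offset + nchar(s$text))))))
      e <- s$entities
      for (i in seq_len(nrow(e))) {
        emit(sprintf('      <entity%s/>', attr_str(
          c(id = e$id[i], type = e$type[i],
            charOffset = sprintf("%d-%d", e$start[i], e$end[i]),
            text = e$text[i], headToken = e$head[i]),
          flag_attr("given", e$given[i], FALSE),
          flag_attr("event", e$event[i], FALSE),
          flag_attr("negation", e$negation[i], FALSE),
          flag_attr("speculation", e$speculation[i], FALSE),
          extra_attrs(e, i))))
      }
      itr <- s$interactions
      for (i in seq_len(nrow(itr))) {
        emit(sprintf('      <interaction%s/>', attr_str(
          c(id = itr$id[i], type = itr$type[i], e1 = itr$source[i],
            e2 = itr$target[i]),
          flag_attr("directed", itr$directed[i], TRUE),
          flag_attr("event", itr$event[i], FALSE),
          flag_attr("given", itr$given[i], FALSE),
          c(siteOf = itr$site_of[i], sourceRole = itr$source_role[i],
            targetRole = itr$target_role[i]),
          flag_attr("crossSentence", itr$cross_sentence[i], FALSE),
          extra_attrs(itr, i))))
      }
      ev <- s$events
      for (i in seq_len(nrow(ev))) {
        args <- ev$args[[i]]
        if (is.null(args) || !nrow(args)) {
          emit(sprintf('      <event%s/>', attr_str(
            c(id = ev$id[i], trigger = ev$trigger[i]))))
        } else {
          emit(sprintf('      <event%s>', attr_str(
            c(id = ev$id[i], trigger = ev$trigger[i]))))
          for (j in seq_len(nrow(args))) {
            emit(sprintf('        <arg%s/>', attr_str(
              c(interaction = args$interaction[j],
                targetEvent = args$target_event[j]))))
          }
          emit('      </event>')
        }
      }
      tok <- s$tokens
      if (nrow(tok)) {
        emit('      <tokenization>')
        for (i in seq_len(nrow(tok))) {
          emit(sprintf('        <token%s/>', attr_str(
            c(id = tok$id[i], text = tok$text[i], POS = tok$pos[i],
              charOffset = sprintf("%d-%d", tok$start[i], tok$end[i])))))
        }
        emit('      </tokenization>')
      }
      dep <- s$dependencies
      if (nrow(dep)) {
        emit('      <parse>')
        for (i in seq_len(nrow(dep))) {
          emit(sprintf('        <dependency%s/>', attr_str(
            c(type = dep$type[i], t1 = dep$governor[i], t2 = dep$dependent[i]))))
        }
        emit('      </parse>')
      }
      emit('    </sentence>')
    }
    for (g in doc$equivs) {
      emit(sprintf('    <equiv%s/>', attr_str(c(members = paste(g, collapse = " ")))))
    }
    emit('  </document>')
  }
  emit('</corpus>')
  xml <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(xml, path, sep = "")
    return(invisible(xml))
  }
  xml
}

parse_offset <- function(x) {
  p <- strsplit(x, "-", fixed = TRUE)[[1]]
  c(as.integer(p[1]), as.integer(p[2]))
}

read_flag <- function(attrs, name, default) {
  v <- attrs[[name]]
  if (is.null(v) || is.na(v)) default else identical(v, "True")
}

known_attrs <- list(
  entity = c("id", "type", "charOffset", "text", "headToken", "given",
             "event", "negation", "speculation"),
  interaction = c("id", "type", "e1", "e2", "directed", "event", "given",
                  "siteOf", "sourceRole", "targetRole", "crossSentence"))

#' Read an Interaction XML corpus
#'
#' @param x File path or XML string.
#' @return An [ig_corpus()].
#' @export
read_interaction_xml <- function(x) {
  root <- xml2::read_xml(x)
  docs <- lapply(xml2::xml_find_all(root, "./document"), function(dnode) {
    dat <- xml2::xml_attrs(dnode)
    sentences <- lapply(xml2::xml_find_all(dnode, "./sentence"), function(snode) {
      sat <- xml2::xml_attrs(snode)
      off <- parse_offset(sat[["charOffset"]])
      grab <- function(xpath) xml2::xml_find_all(snode, xpath)
      ent_nodes <- grab("./entity")
      entities <- if (length(ent_nodes)) {
        rows <- lapply(ent_nodes, function(en) {
          a <- as.list(xml2::xml_attrs(en))
          eo <- parse_offset(a$charOffset)
          extra <- a[setdiff(names(a), known_attrs$entity)]
          tibble::tibble(id = a$id, type = a$type, start = eo[1], end = eo[2],
                         text = a$text %||% "", head = a$headToken %||% NA_character_,
                         given = read_flag(a, "given", FALSE),
                         event = read_flag(a, "event", FALSE),
                         negation = read_flag(a, "negation", FALSE),
                         speculation = read_flag(a, "speculation", FALSE),
                         extra = list(unlist(extra) %||% character()))
        })
        dplyr::bind_rows(rows)
      } else empty_entities()
      itr_nodes <- grab("./interaction")
      interactions <- if (length(itr_nodes)) {
        rows <- lapply(itr_nodes, function(en) {
          a <- as.list(xml2::xml_attrs(en))
          extra <- a[setdiff(names(a), known_attrs$interaction)]
          tibble::tibble(id = a$id, type = a$type, source = a$e1, target = a$e2,
                         directed = read_flag(a, "directed", TRUE),
                         event = read_flag(a, "event", FALSE),
                         given = read_flag(a, "given", FALSE),
                         site_of = a$siteOf %||% NA_character_,
                         source_role = a$sourceRole %||% NA_character_,
                         target_role = a$targetRole %||% NA_character_,
                         cross_sentence = read_flag(a, "crossSentence", FALSE),
                         extra = list(unlist(extra) %||% character()))
        })
        dplyr::bind_rows(rows)
      } else empty_interactions()
      ev_nodes <- grab("./event")
      events <- if (length(ev_nodes)) {
        rows <- lapply(ev_nodes, function(en) {
          a <- as.list(xml2::xml_attrs(en))
          argn <- xml2::xml_find_all(en, "./arg")
          args <- if (length(argn)) {
            dplyr::bind_rows(lapply(argn, function(an) {
              aa <- as.list(xml2::xml_attrs(an))
              tibble::tibble(interaction = aa$interaction,
                             target_event = aa$targetEvent %||% NA_character_)
            }))
          } else empty_event_args()
          tibble::tibble(id = a$id, trigger = a$trigger, args = list(args))
        })
        dplyr::bind_rows(rows)
      } else empty_events()
      tok_nodes <- grab("./tokenization/token")
      tokens <- if (length(tok_nodes)) {
        dplyr::bind_rows(lapply(tok_nodes, function(tn) {
          a <- as.list(xml2::xml_attrs(tn))
          to <- parse_offset(a$charOffset)
          tibble::tibble(id = a$id, text = a$text, pos = a$POS,
                         start = to[1], end = to[2])
        }))
      } else empty_tokens()
      dep_nodes <- grab("./parse/dependency")
      dependencies <- if (length(dep_nodes)) {
        dplyr::bind_rows(lapply(dep_nodes, function(dn) {
          a <- as.list(xml2::xml_attrs(dn))
          tibble::tibble(type = a$type, governor = a$t1, dependent = a$t2)
        }))
      } else empty_dependencies()
      sentence_graph(sat[["id"]], sat[["text"]], tokens = tokens,
                     dependencies = dependencies, entities = entities,
                     interactions = interactions, events = events,
                     offset = off[1])
    })
    equivs <- lapply(xml2::xml_find_all(dnode, "./equiv"), function(en) {
      strsplit(xml2::xml_attr(en, "members"), " ", fixed = TRUE)[[1]]
    })
    ig_document(dat[["id"]], dat[["text"]], sentences, equivs = equivs)
  })
  set <- xml2::xml_attr(root, "set")
  ig_corpus(docs, set = if (is.na(set)) "train" else set)
}
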