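#' @title Annotation scheme induction and structural validity
#' @description The annotation scheme is the induced rule set of a corpus:
#'   entity, event, relation, modifier and prediction-target definitions with
#'   per-role and overall argument-count limits. It drives candidate
#'   filtering in the edge and unmerging steps and structural validation of
#'   output events.
#' @name scheme
NULL

arg_constraint <- function(role, min, max, targets, site_primary = character()) {
  tibble::tibble(role = role, min = as.integer(min), max = as.integer(max),
                 targets = list(sort(unique(targets))),
                 site_primary = list(sort(unique(site_primary))))
}

#' Construct an annotation scheme
#'
#' Normally produced by [learn_scheme()]; the constructor is exported so
#' schemes (e.g. for the synthetic generator) can be written down directly.
#'
#' @param entity_types Character vector of entity (non-event) node types.
#' @param events Tibble with columns `type`, `overall_min`, `overall_max` and
#'   a list-column `arguments` of per-role constraint tibbles
#'   (`role`, `min`, `max`, `targets`, `site_primary`).
#' @param relations Tibble with columns `type`, `directed`, `end1_role`,
#'   `end2_role` and list-columns `end1_types`, `end2_types`.
#' @param modifiers Named list mapping modifier kind (`negation`,
#'   `speculation`) to the character vector of node types it may attach to.
#' @param targets List with character vectors `entities` and `interactions`:
#'   the node and edge types that are prediction targets (not given).
#' @return An `annotation_scheme` object.
#' @export
annotation_scheme <- function(entity_types = character(),
                              events = NULL,
                              relations = NULL,
                              modifiers = list(negation = character(),
                                               speculation = character()),
                              targets = list(entities = character(),
                                             interactions = character())) {
  if (is.null(events)) {
    events <- tibble::tibble(type = character(), overall_min = integer(),
                             overall_max = integer(), arguments = list())
  }
  if (is.null(relations)) {
    relations <- tibble::tibble(type = character(), directed = logical(),
                                end1_role = character(), end2_role = character(),
                                end1_types = list(), end2_types = list())
  }
  events <- events[order(events$type), , drop = FALSE]
  relations <- relations[order(relations$type), , drop = FALSE]
  relations$end1_types <- lapply(relations$end1_types, function(x) sort(unique(x)))
  relations$end2_types <- lapply(relations$end2_types, function(x) sort(unique(x)))
  s <- structure(list(
    entity_types = sort(unique(entity_types)),
    events = tibble::as_tibble(events),
    relations = tibble::as_tibble(relations),
    modifiers = list(negation = sort(unique(modifiers$negation %||% character())),
                     speculation = sort(unique(modifiers$speculation %||% character()))),
    targets = list(entities = sort(unique(targets$entities %||% character())),
                   interactions = sort(unique(targets$interactions %||% character())))
  ), class = "annotation_scheme")
  s$edge_rules <- build_edge_rules(s)
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# flat enumeration of licensed (edge type, source type, target type) triples,
# the lookup table behind is_valid_edge
build_edge_rules <- function(s) {
  rows <- list()
  for (i in seq_len(nrow(s$events))) {
    trig <- s$events$type[i]
    args <- s$events$arguments[[i]]
    for (j in seq_len(nrow(args))) {
      tg <- args$targets[[j]]
      if (length(tg)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          type = args$role[j], source_type = trig, target_type = tg)
      }
    }
  }
  for (i in seq_len(nrow(s$relations))) {
    r <- s$relations[i, ]
    e1 <- r$end1_types[[1]]; e2 <- r$end2_types[[1]]
    if (length(e1) && length(e2)) {
      grid <- expand.grid(source_type = e1, target_type = e2,
                          stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- tibble::tibble(
        type = r$type, source_type = grid$source_type,
        target_type = grid$target_type)
      if (!r$directed) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          type = r$type, source_type = grid$target_type,
          target_type = grid$source_type)
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(type = character(), source_type = character(),
                          target_type = character()))
  }
  dplyr::distinct(dplyr::bind_rows(rows))
}

#' Event types defined by a scheme
#'
#' @param s An [annotation_scheme()].
#' @return Character vector of event type names.
#' @export
event_types <- function(s) s$events$type

#' @export
print.annotation_scheme <- function(x, ...) {
  cat(serialize_scheme(x))
  invisible(x)
}

#' Learn the annotation scheme of a corpus
#'
#' Deterministic, rule-based induction of the five definition kinds from a
#' fully annotated corpus (conventionally the union of the train and devel
#' partitions). A node type is an entity if it never carries the event flag
#' and never has outgoing event-argument edges; otherwise it is an event
#' type. Per-role and overall argument-count limits are the observed extremes
#' over event instances; Site-like roles record the primary-argument roles
#' observed through `siteOf`; relations record observed endpoint type sets,
#' end roles and directedness; modifier targets are the node types observed
#' negated or speculated; prediction targets are the node and edge types
#' observed without the given flag.
#'
#' @param corpus An `ig_corpus`, `ig_document`, or list of either (all are
#'   pooled).
#' @return An [annotation_scheme()].
#' @export
learn_scheme <- function(corpus) {
  sentences <- gather_sentences(corpus)
  if (!length(sentences) ||
      !any(vapply(sentences, function(s) nrow(s$entities) > 0, logical(1)))) {
    warning("corpus has no annotation; returning an empty scheme", call. = FALSE)
    return(annotation_scheme())
  }

  node_flag <- new.env(parent = emptyenv())   # type -> has event flag
  node_out  <- new.env(parent = emptyenv())   # type -> has outgoing event edge
  node_given_only <- new.env(parent = emptyenv())
  mod_neg <- character(); mod_spec <- character()
  target_nodes <- character(); target_edges <- character()
  rel_rows <- list()
  instances <- list()                          # per event instance records

  for (s in sentences) {
    ent <- s$entities
    itr <- s$interactions
    for (i in seq_len(nrow(ent))) {
      ty <- ent$type[i]
      if (isTRUE(ent$event[i])) assign(ty, TRUE, envir = node_flag)
      if (!isTRUE(ent$given[i])) target_nodes <- c(target_nodes, ty)
      if (isTRUE(ent$negation[i])) mod_neg <- c(mod_neg, ty)
      if (isTRUE(ent$speculation[i])) mod_spec <- c(mod_spec, ty)
    }
    if (nrow(itr)) {
      src_type <- ent$type[match(itr$source, ent$id)]
      for (i in which(itr$event)) assign(src_type[i], TRUE, envir = node_out)
      target_edges <- c(target_edges, itr$type[!itr$given])
    }
  }
  all_types <- sort(unique(unlist(lapply(sentences, function(s) s$entities$type))))
  is_event_type <- vapply(all_types, function(ty) {
    isTRUE(mget(ty, envir = node_flag, ifnotfound = FALSE)[[1]]) ||
      isTRUE(mget(ty, envir = node_out, ifnotfound = FALSE)[[1]])
  }, logical(1))
  ev_types <- all_types[is_event_type]
  ent_types <- all_types[!is_event_type]

  # event instances: one per event membership, with per-role counts,
  # target types and siteOf-derived primary roles
  docs <- gather_documents(corpus)
  for (doc in docs) {
    doc_ents <- document_entities(doc)
    for (s in doc$sentences) {
      ev <- s$events
      if (!nrow(ev)) next
      itr <- s$interactions
      ent <- s$entities
      trig_type <- ent$type[match(ev$trigger, ent$id)]
      for (i in seq_len(nrow(ev))) {
        args <- ev$args[[i]]
        if (is.null(args) || !nrow(args)) {
          instances[[length(instances) + 1]] <- list(
            type = trig_type[i], roles = character(), targets = character(),
            primaries = character())
          next
        }
        k <- match(args$interaction, itr$id)
        roles <- itr$type[k]
        tgt_ids <- itr$target[k]
        tgt_types <- ent$type[match(tgt_ids, ent$id)]
        miss <- is.na(tgt_types)
        if (any(miss)) {
          tgt_types[miss] <- doc_ents$type[match(tgt_ids[miss], doc_ents$id)]
        }
        prim <- rep(NA_character_, length(k))
        has_site <- !is.na(itr$site_of[k])
        if (any(has_site)) {
          prim[has_site] <- itr$type[match(itr$site_of[k][has_site], itr$id)]
        }
        instances[[length(instances) + 1]] <- list(
          type = trig_type[i], roles = roles, targets = tgt_types,
          primaries = prim)
      }
    }
  }

  events <- build_event_definitions(ev_types, instances)
  relations <- build_relation_definitions(sentences, ev_types)
  annotation_scheme(
    entity_types = ent_types,
    events = events,
    relations = relations,
    modifiers = list(negation = sort(unique(mod_neg)),
                     speculation = sort(unique(mod_spec))),
    targets = list(entities = sort(unique(target_nodes)),
                   interactions = sort(unique(target_edges)))
  )
}

build_event_definitions <- function(ev_types, instances) {
  rows <- lapply(sort(ev_types), function(ty) {
    inst <- Filter(function(x) identical(x$type, ty), instances)
    if (!length(inst)) {
      return(tibble::tibble(type = ty, overall_min = 0L, overall_max = 0L,
                            arguments = list(arg_constraint(character(),
                                                            integer(), integer(),
                                                            character())[0, ])))
    }
    roles <- sort(unique(unlist(lapply(inst, function(x) x$roles))))
    totals <- vapply(inst, function(x) length(x$roles), integer(1))
    args <- lapply(roles, function(ro) {
      counts <- vapply(inst, function(x) sum(x$roles == ro), integer(1))
      tg <- unlist(lapply(inst, function(x) x$targets[x$roles == ro]))
      pr <- unlist(lapply(inst, function(x) x$primaries[x$roles == ro]))
      arg_constraint(ro, min(counts), max(counts), tg[!is.na(tg)],
                     pr[!is.na(pr)])
    })
    args <- if (length(args)) dplyr::bind_rows(args) else
      arg_constraint(character(), integer(), integer(), character())[0, ]
    tibble::tibble(type = ty, overall_min = min(totals),
                   overall_max = max(totals), arguments = list(args))
  })
  if (!length(rows)) {
    return(tibble::tibble(type = character(), overall_min = integer(),
                          overall_max = integer(), arguments = list()))
  }
  dplyr::bind_rows(rows)
}

build_relation_definitions <- function(sentences, ev_types) {
  rows <- list()
  for (s in sentences) {
    itr <- s$interactions
    if (!nrow(itr)) next
    rel <- itr[!itr$event, , drop = FALSE]
    if (!nrow(rel)) next
    ent <- s$entities
    rows[[length(rows) + 1]] <- tibble::tibble(
      type = rel$type, directed = rel$directed,
      end1_role = rel$source_role, end2_role = rel$target_role,
      end1 = ent$type[match(rel$source, ent$id)],
      end2 = ent$type[match(rel$target, ent$id)])
  }
  if (!length(rows)) {
    return(tibble::tibble(type = character(), directed = logical(),
                          end1_role = character(), end2_role = character(),
                          end1_types = list(), end2_types = list()))
  }
  obs <- dplyr::bind_rows(rows)
  out <- lapply(sort(unique(obs$type)), function(ty) {
    o <- obs[obs$type == ty, ]
    directed <- all(o$directed)
    e1 <- o$end1; e2 <- o$end2
    if (!directed) { e1 <- c(o$end1, o$end2); e2 <- c(o$end2, o$end1) }
    r1 <- o$end1_role[!is.na(o$end1_role)]
    r2 <- o$end2_role[!is.na(o$end2_role)]
    tibble::tibble(type = ty, directed = directed,
                   end1_role = if (length(r1)) r1[1] else "Arg1",
                   end2_role = if (length(r2)) r2[1] else "Arg2",
                   end1_types = list(sort(unique(e1[!is.na(e1)]))),
                   end2_types = list(sort(unique(e2[!is.na(e2)]))))
  })
  dplyr::bind_rows(out)
}

gather_documents <- function(corpus) {
  if (inherits(corpus, "ig_document")) return(list(corpus))
  if (inherits(corpus, "ig_corpus")) return(unname(corpus$documents))
  if (is.list(corpus)) return(unlist(lapply(corpus, gather_documents),
                                     recursive = FALSE))
  stop("expected an ig_corpus, ig_document or list of them", call. = FALSE)
}

gather_sentences <- function(corpus) {
  unlist(lapply(gather_documents(corpus), function(d) d$sentences),
         recursive = FALSE)
}

#' Can an edge of this type exist between these node types?
#'
#' True iff some event definition licenses `edge_type` as an argument role
#' from a trigger of `source_type` to a target of `target_type`, or some
#' relation definition licenses it between the two (respecting direction for
#' directed relations). With `edge_type = NULL`, answers whether any edge
#' type is licensed for the pair — the filter used in edge example
#' generation.
#'
#' @param scheme An [annotation_scheme()].
#' @param source_type,target_type Node type strings.
#' @param edge_type Edge type string, or `NULL` for "any".
#' @return Logical scalar.
#' @export
is_valid_edge <- function(scheme, source_type, target_type, edge_type = NULL) {
  er <- scheme$edge_rules
  hit <- er$source_type == source_type & er$target_type == target_type
  if (!is.null(edge_type)) hit <- hit & er$type == edge_type
  any(hit)
}

# all edge types licensed between a pair of node types
valid_edge_types <- function(scheme, source_type, target_type) {
  er <- scheme$edge_rules
  sort(unique(er$type[er$source_type == source_type &
                        er$target_type == target_type]))
}

#' Is an argument multiset a structurally valid event?
#'
#' Checks a candidate event (trigger type plus argument multiset) against the
#' scheme: every role licensed with a licensed target type, per-role counts
#' within their `[min,max]`, total count within the overall `[min,max]`, and
#' for Site-like roles a primary-argument role drawn from the licensed set.
#'
#' @param scheme An [annotation_scheme()].
#' @param trigger_type Event type string.
#' @param args Tibble (or data.frame) with columns `role`, `target_type` and
#'   optionally `site_primary_role` (NA where not applicable). Zero-row input
#'   tests the zero-argument event.
#' @return Logical scalar.
#' @export
is_valid_event_structure <- function(scheme, trigger_type, args) {
  i <- match(trigger_type, scheme$events$type)
  if (is.na(i)) return(FALSE)
  def <- scheme$events[i, ]
  cons <- def$arguments[[1]]
  if (is.null(args) || !nrow(args)) {
    return(def$overall_min == 0L && all(cons$min == 0L))
  }
  if (!"site_primary_role" %in% names(args)) {
    args$site_primary_role <- NA_character_
  }
  n <- nrow(args)
  if (n < def$overall_min || n > def$overall_max) return(FALSE)
  if (!all(args$role %in% cons$role)) return(FALSE)
  for (j in seq_len(nrow(cons))) {
    ro <- cons$role[j]
    k <- which(args$role == ro)
    if (length(k) < cons$min[j] || length(k) > cons$max[j]) return(FALSE)
    if (length(k)) {
      if (!all(args$target_type[k] %in% cons$targets[[j]])) return(FALSE)
      sp <- cons$site_primary[[j]]
      if (length(sp)) {
        pr <- args$site_primary_role[k]
        if (any(is.na(pr)) || !all(pr %in% sp)) return(FALSE)
      }
    }
  }
  TRUE
}

#' Serialize / parse an annotation scheme
#'
#' The text layout mirrors the scheme's tabular presentation: one row per
#' definition, tab-separated fields, roles separated by `" / "`, type lists
#' comma-separated, Site primary roles in braces. The round trip is lossless
#' and the file is what gets embedded in a trained model bundle.
#'
#' @param scheme An [annotation_scheme()].
#' @return `serialize_scheme`: a single string. `parse_scheme`: the scheme.
#' @export
serialize_scheme <- function(scheme) {
  lines <- c("# annotation scheme v1")
  for (ty in scheme$entity_types) lines <- c(lines, paste0("ENTITY\t", ty))
  for (i in seq_len(nrow(scheme$events))) {
    e <- scheme$events[i, ]
    args <- e$arguments[[1]]
    parts <- vapply(seq_len(nrow(args)), function(j) {
      sp <- args$site_primary[[j]]
      braces <- if (length(sp)) paste0(" {", paste(sp, collapse = ","), "}") else ""
      sprintf("%s%s [%d,%d] %s", args$role[j], braces, args$min[j], args$max[j],
              paste(args$targets[[j]], collapse = ", "))
    }, character(1))
    lines <- c(lines, sprintf("EVENT\t%s [%d,%d]\t%s", e$type,
                              e$overall_min, e$overall_max,
                              paste(parts, collapse = " / ")))
  }
  for (i in seq_len(nrow(scheme$relations))) {
    r <- scheme$relations[i, ]
    lines <- c(lines, sprintf(
      "RELATION\t%s, %s\t%s(%s) / %s(%s)", r$type,
      if (r$directed) "directed" else "undirected",
      r$end1_role, paste(r$end1_types[[1]], collapse = ", "),
      r$end2_role, paste(r$end2_types[[1]], collapse = ", ")))
  }
  for (kind in c("negation", "speculation")) {
    if (length(scheme$modifiers[[kind]])) {
      lines <- c(lines, sprintf("MODIFIER\t%s\t%s", kind,
                                paste(scheme$modifiers[[kind]], collapse = ", ")))
    }
  }
  if (length(scheme$targets$entities)) {
    lines <- c(lines, sprintf("TARGET\tENTITY\t%s",
                              paste(scheme$targets$entities, collapse = ", ")))
  }
  if (length(scheme$targets$interactions)) {
    lines <- c(lines, sprintf("TARGET\tINTERACTION\t%s",
                              paste(scheme$targets$interactions, collapse = ", ")))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

split_list <- function(x) {
  x <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  sort(x[nzchar(x)])
}

#' @rdname serialize_scheme
#' @param text Scheme text produced by `serialize_scheme`.
#' @export
parse_scheme <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  ent <- character(); ev_rows <- list(); rel_rows <- list()
  mods <- list(negation = character(), speculation = character())
  targets <- list(entities = character(), interactions = character())
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    kind <- f[1]
    if (kind == "ENTITY") {
      ent <- c(ent, f[2])
    } else if (kind == "EVENT") {
      m <- regmatches(f[2], regexec("^(.*) \\[(\\d+),(\\d+)\\]$", f[2]))[[1]]
      args_txt <- if (length(f) >= 3 && nzchar(f[3])) {
        strsplit(f[3], " / ", fixed = TRUE)[[1]]
      } else character()
      args <- lapply(args_txt, function(a) {
        am <- regmatches(a, regexec(
          "^(\\S+?)(?: \\{([^}]*)\\})? \\[(\\d+),(\\d+)\\] (.*)$", a))[[1]]
        arg_constraint(am[2], as.integer(am[4]), as.integer(am[5]),
                       split_list(am[6]),
                       if (nzchar(am[3])) split_list(am[3]) else character())
      })
      args <- if (length(args)) dplyr::bind_rows(args) else
        arg_constraint(character(), integer(), integer(), character())[0, ]
      ev_rows[[length(ev_rows) + 1]] <- tibble::tibble(
        type = m[2], overall_min = as.integer(m[3]),
        overall_max = as.integer(m[4]), arguments = list(args))
    } else if (kind == "RELATION") {
      hm <- regmatches(f[2], regexec("^(.*), (directed|undirected)$", f[2]))[[1]]
      em <- regmatches(f[3], regexec(
        "^(\\S+)\\(([^)]*)\\) / (\\S+)\\(([^)]*)\\)$", f[3]))[[1]]
      rel_rows[[length(rel_rows) + 1]] <- tibble::tibble(
        type = hm[2], directed = hm[3] == "directed",
        end1_role = em[2], end2_role = em[4],
        end1_types = list(split_list(em[3])),
        end2_types = list(split_list(em[5])))
    } else if (kind == "MODIFIER") {
      mods[[f[2]]] <- split_list(f[3])
    } else if (kind == "TARGET") {
      if (f[2] == "ENTITY") targets$entities <- split_list(f[3])
      else targets$interactions <- split_list(f[3])
    }
  }
  annotation_scheme(
    entity_types = ent,
    events = if (length(ev_rows)) dplyr::bind_rows(ev_rows) else NULL,
    relations = if (length(rel_rows)) dplyr::bind_rows(rel_rows) else NULL,
    modifiers = mods, targets = targets)
}

#' @export
tidy.annotation_scheme <- function(x, ...) {
  rows <- list()
  if (length(x$entity_types)) {
    rows[[1]] <- tibble::tibble(kind = "entity", type = x$entity_types,
                                role = NA_character_, min = NA_integer_,
                                max = NA_integer_, targets = list(NULL))
  }
  for (i in seq_len(nrow(x$events))) {
    e <- x$events[i, ]
    args <- e$arguments[[1]]
    rows[[length(rows) + 1]] <- tibble::tibble(
      kind = "event", type = e$type, role = NA_character_,
      min = e$overall_min, max = e$overall_max, targets = list(NULL))
    if (nrow(args)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        kind = "argument", type = e$type, role = args$role,
        min = args$min, max = args$max, targets = args$targets)
    }
  }
  for (i in seq_len(nrow(x$relations))) {
    r <- x$relations[i, ]
    rows[[length(rows) + 1]] <- tibble::tibble(
      kind = "relation", type = r$type,
      role = paste(r$end1_role, r$end2_role, sep = "/"),
      min = NA_integer_, max = NA_integer_,
      targets = list(union(r$end1_types[[1]], r$end2_types[[1]])))
  }
  dplyr::bind_rows(rows)
}
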