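#' @title Conversion between standoff documents and interaction graphs
#' @description Events are represented indirectly in the graph: the trigger
#'   word is a node and every argument is a directed edge out of it, so a
#'   single event is a trigger node plus a set of outgoing edges. Conversion
#'   from standoff expands equivalence groups into individual events, unifies
#'   Site arguments (Site edges attach to the trigger, a SiteParent relation
#'   links the site entity to its protein, and `siteOf` names the primary
#'   argument's edge), and records event memberships so the merged graph can
#'   be pulled apart again. Conversion back applies the Site discard rules
#'   and removes duplicate events recursively.
#' @name convert
NULL

# locate the sentence whose span contains a document offset
sentence_index_of <- function(offset, sent_offsets, sent_lens) {
  i <- which(offset >= sent_offsets & offset < sent_offsets + sent_lens)
  if (!length(i)) NA_integer_ else i[1]
}

# pair each Site-like argument of one standoff event with its primary
# argument, by role-suffix match first (Site2 pairs with Theme2), then by
# uniqueness; returns the primary row index (NA when unresolvable)
pair_site_primaries <- function(roles, site_role = "Site") {
  base <- role_base(roles)
  suffix <- role_suffix(roles)
  suffix[is.na(suffix)] <- 1L
  is_site <- base == site_role
  out <- rep(NA_integer_, length(roles))
  for (i in which(is_site)) {
    cand <- which(!is_site & suffix == suffix[i])
    if (length(cand) > 1) {
      th <- cand[base[cand] == "Theme"]
      cand <- if (length(th)) th else cand
    }
    if (!length(cand) && sum(!is_site) == 1) cand <- which(!is_site)
    if (length(cand)) out[i] <- cand[1]
  }
  out
}

#' Convert a standoff document to an interaction graph
#'
#' Builds a document graph from a standoff document and its per-sentence
#' parses. Event triggers become entity nodes with the event flag; every
#' argument becomes a directed edge from the trigger node; Site arguments
#' additionally produce a SiteParent edge from the site entity to its
#' protein and carry `siteOf` naming the primary argument's edge;
#' equivalence groups are expanded into individual event copies; relations
#' with an event-trigger endpoint are skipped with a logged warning; head
#' tokens are assigned with [resolve_head_token()]. Arguments whose target
#' lies in another sentence are kept but flagged `cross_sentence`.
#'
#' @param d An [st_document()].
#' @param parses List with one element per sentence, each a list with
#'   `offset` (0-based document offset), `text`, `tokens` and
#'   `dependencies` (sentence-scoped, see [empty_tokens()]).
#' @return An [ig_document()]; skipped-annotation messages are kept in its
#'   `log` field.
#' @export
st_to_graph <- function(d, parses) {
  sent_offsets <- vapply(parses, function(p) as.integer(p$offset), integer(1))
  sent_lens <- vapply(parses, function(p) nchar(p$text), integer(1))
  sids <- paste0(d$id, ".s", seq_along(parses))
  sentences <- lapply(seq_along(parses), function(i) {
    sentence_graph(sids[i], parses[[i]]$text,
                   tokens = parses[[i]]$tokens,
                   dependencies = parses[[i]]$dependencies %||% empty_dependencies(),
                   offset = sent_offsets[i])
  })
  log <- character()

  e <- d$entities
  ent_sentence <- integer(nrow(e))
  node_ids <- character(nrow(e))
  counters <- integer(length(parses))
  ent_rows <- vector("list", length(parses))
  trigger_of <- unique(d$events$trigger)
  negated <- unique(d$events$trigger[d$events$id %in%
                                       d$modifiers$target[tolower(d$modifiers$kind) == "negation"]])
  speculated <- unique(d$events$trigger[d$events$id %in%
                                          d$modifiers$target[tolower(d$modifiers$kind) == "speculation"]])
  for (i in seq_len(nrow(e))) {
    si <- sentence_index_of(e$start[i], sent_offsets, sent_lens)
    if (is.na(si)) {
      stop(sprintf("entity %s of document '%s' lies outside every sentence",
                   e$id[i], d$id), call. = FALSE)
    }
    counters[si] <- counters[si] + 1L
    node_ids[i] <- paste0(sids[si], ".e", counters[si])
    ent_sentence[i] <- si
  }
  for (si in seq_along(parses)) {
    k <- which(ent_sentence == si)
    if (!length(k)) { ent_rows[[si]] <- empty_entities(); next }
    starts <- e$start[k] - sent_offsets[si]
    ends <- e$end[k] - sent_offsets[si]
    heads <- vapply(seq_along(k), function(j) {
      resolve_head_token(starts[j], ends[j], sentences[[si]])
    }, character(1))
    ent_rows[[si]] <- fast_tbl(
      id = node_ids[k], type = e$type[k], start = starts, end = ends,
      text = e$text[k], head = heads, given = e$given[k],
      event = e$id[k] %in% trigger_of,
      negation = e$id[k] %in% negated,
      speculation = e$id[k] %in% speculated)
  }
  node_of <- stats::setNames(node_ids, e$id)
  sentence_of_node <- stats::setNames(ent_sentence, node_ids)

  # equivalence groups over entity nodes
  equivs <- lapply(d$equivs, function(g) unname(node_of[g]))
  member_alternatives <- new.env(parent = emptyenv())
  for (g in equivs) for (m in g) assign(m, g, envir = member_alternatives)
  alts_of <- function(node) {
    got <- mget(node, envir = member_alternatives, ifnotfound = list(NULL))[[1]]
    if (is.null(got)) node else got
  }

  # expand events children-first so event-valued arguments expand recursively
  ev <- d$events
  expanded <- list()           # original E id -> list of instance records
  inst_count <- 0L
  order_ids <- topo_event_order(ev)
  for (eid in order_ids) {
    i <- match(eid, ev$id)
    args <- ev$args[[i]]
    trig_node <- node_of[[ev$trigger[i]]]
    if (!nrow(args)) {
      inst_count <- inst_count + 1L
      expanded[[eid]] <- list(list(uid = inst_count, type = ev$type[i],
                                   trigger = trig_node,
                                   args = NULL))
      next
    }
    alternatives <- lapply(seq_len(nrow(args)), function(j) {
      tgt <- args$target[j]
      if (tgt %in% ev$id) {
        lapply(expanded[[tgt]] %||% list(), function(inst)
          list(node = inst$trigger, event_uid = inst$uid))
      } else {
        lapply(alts_of(node_of[[tgt]]), function(nd)
          list(node = nd, event_uid = NA_integer_))
      }
    })
    if (any(lengths(alternatives) == 0)) {
      log <- c(log, sprintf("event %s dropped: argument target unavailable", eid))
      expanded[[eid]] <- list()
      next
    }
    idx <- expand.grid(lapply(alternatives, seq_along))
    insts <- lapply(seq_len(nrow(idx)), function(r) {
      picks <- lapply(seq_along(alternatives), function(j)
        alternatives[[j]][[idx[r, j]]])
      inst_count <<- inst_count + 1L
      list(uid = inst_count, type = ev$type[i], trigger = trig_node,
           args = fast_tbl(
             role = args$role,
             node = vapply(picks, function(p) p$node, character(1)),
             event_uid = vapply(picks, function(p) p$event_uid, integer(1))))
    })
    inst_count <- insts[[length(insts)]]$uid
    expanded[[eid]] <- insts
  }

  # materialise interactions (deduplicated by source/target/type) and
  # event memberships, plus SiteParent edges and siteOf references
  itr_key <- new.env(parent = emptyenv())  # "src|tgt|type" -> edge id
  itr_rows <- lapply(seq_along(parses), function(i) list())
  itr_counters <- integer(length(parses))
  site_of_pending <- list()                # edge id -> primary edge id
  add_edge <- function(src, tgt, type, event_flag, src_role = NA_character_,
                       tgt_role = NA_character_) {
    key <- paste(src, tgt, type, sep = "|")
    found <- mget(key, envir = itr_key, ifnotfound = list(NULL))[[1]]
    if (!is.null(found)) return(found)
    si <- sentence_of_node[[src]]
    itr_counters[si] <<- itr_counters[si] + 1L
    id <- paste0(sids[si], ".i", itr_counters[si])
    itr_rows[[si]][[length(itr_rows[[si]]) + 1L]] <<- fast_tbl(
      id = id, type = type, source = src, target = tgt, directed = TRUE,
      event = event_flag, given = FALSE, site_of = NA_character_,
      source_role = src_role, target_role = tgt_role,
      cross_sentence = sentence_of_node[[src]] != sentence_of_node[[tgt]])
    assign(key, id, envir = itr_key)
    id
  }
  memberships <- lapply(seq_along(parses), function(i) list())
  uid_to_mid <- character(inst_count + 1000L)
  mem_counters <- integer(length(parses))
  for (eid in order_ids) {
    for (inst in expanded[[eid]]) {
      si <- sentence_of_node[[inst$trigger]]
      mem_counters[si] <- mem_counters[si] + 1L
      mid <- paste0(sids[si], ".ev", mem_counters[si])
      uid_to_mid[inst$uid] <- mid
      if (is.null(inst$args)) {
        memberships[[si]][[length(memberships[[si]]) + 1L]] <- fast_tbl(
          id = mid, trigger = inst$trigger, args = list(empty_event_args()))
        next
      }
      a <- inst$args
      edge_ids <- vapply(seq_len(nrow(a)), function(j) {
        add_edge(inst$trigger, a$node[j], role_base(a$role[j]), TRUE)
      }, character(1))
      prim <- pair_site_primaries(a$role)
      for (j in which(!is.na(prim))) {
        site_of_pending[[edge_ids[j]]] <- edge_ids[prim[j]]
        # SiteParent: site entity -> its protein (when the primary targets
        # a plain entity node)
        pj <- prim[j]
        if (is.na(a$event_uid[pj])) {
          add_edge(a$node[j], a$node[pj], "SiteParent", FALSE, "Arg1", "Arg2")
        }
      }
      memberships[[si]][[length(memberships[[si]]) + 1L]] <- fast_tbl(
        id = mid, trigger = inst$trigger,
        args = list(fast_tbl(
          interaction = edge_ids,
          target_event = ifelse(is.na(a$event_uid), NA_character_,
                                uid_to_mid[pmax(a$event_uid, 1L)]))))
    }
  }

  # binary relations; those touching an event trigger node (or an event id)
  # cannot be represented distinctly from the event itself, so are skipped
  trigger_nodes <- unname(node_of[trigger_of])
  for (i in seq_len(nrow(d$relations))) {
    args <- d$relations$args[[i]]
    rid <- d$relations$id[i]
    rtype <- d$relations$type[i]
    if (nrow(args) != 2) {
      log <- c(log, sprintf("relation %s skipped: not binary", rid))
      next
    }
    if (any(startsWith(args$target, "E"))) {
      log <- c(log, sprintf("relation %s (%s) skipped: event endpoint", rid, rtype))
      next
    }
    nds <- unname(node_of[args$target])
    if (any(nds %in% trigger_nodes)) {
      log <- c(log, sprintf("relation %s (%s) skipped: event-trigger endpoint",
                            rid, rtype))
      next
    }
    add_edge(nds[1], nds[2], rtype, FALSE, args$role[1], args$role[2])
  }

  for (si in seq_along(parses)) {
    itr <- if (length(itr_rows[[si]])) dplyr::bind_rows(itr_rows[[si]]) else
      empty_interactions()
    if (nrow(itr) && length(site_of_pending)) {
      hit <- intersect(itr$id, names(site_of_pending))
      itr$site_of[match(hit, itr$id)] <- unlist(site_of_pending[hit])
    }
    sentences[[si]]$entities <- ent_rows[[si]]
    sentences[[si]]$interactions <- itr
    sentences[[si]]$events <- if (length(memberships[[si]])) {
      dplyr::bind_rows(memberships[[si]])
    } else empty_events()
  }
  doc <- ig_document(d$id, d$text, sentences, equivs = equivs)
  doc$log <- log
  if (length(log)) {
    for (msg in log) warning(sprintf("[%s] %s", d$id, msg), call. = FALSE)
  }
  doc
}

topo_event_order <- function(ev) {
  if (!nrow(ev)) return(character())
  deps <- lapply(ev$args, function(a)
    if (is.null(a) || !nrow(a)) character() else intersect(a$target, ev$id))
  names(deps) <- ev$id
  ordered <- character(); pending <- ev$id
  while (length(pending)) {
    ready <- pending[vapply(deps[pending], function(x)
      all(x %in% ordered), logical(1))]
    if (!length(ready)) {
      stop("event annotation contains a reference cycle", call. = FALSE)
    }
    ordered <- c(ordered, ready)
    pending <- setdiff(pending, ready)
  }
  ordered
}

#' Retrieve the conversion log of a document
#'
#' Messages about annotation skipped or repaired while converting (e.g.
#' relations with event-trigger endpoints).
#'
#' @param doc An [ig_document()] produced by [st_to_graph()].
#' @return Character vector (possibly empty).
#' @export
conversion_log <- function(doc) doc$log %||% character()

# site-like roles per the scheme (roles observed with a primary argument)
scheme_site_roles <- function(scheme) {
  if (is.null(scheme)) return("Site")
  roles <- unlist(lapply(scheme$events$arguments, function(a)
    a$role[lengths(a$site_primary) > 0]))
  unique(c(roles, character()))
}

#' Convert an interaction graph back to a standoff document
#'
#' Enumerates each trigger node's event memberships into `E` records,
#' re-attaching Site edges to their primary argument (via `siteOf` for gold
#' annotation, via SiteParent linkage for predictions, taking the primary
#' whose target protein occurs first in document order, exactly once),
#' discarding a Site when its primary argument already has one, collapsing
#' equivalence-expanded copies back onto the group representative, removing
#' events made identical by these operations recursively until none remain,
#' and removing events that reference removed events. Unreferenced non-given
#' entities are not emitted.
#'
#' @param doc An [ig_document()].
#' @param scheme Optional [annotation_scheme()], used to identify Site-like
#'   roles; without it, edges named `Site` or carrying `siteOf` are treated
#'   as sites.
#' @return An [st_document()].
#' @export
graph_to_st <- function(doc, scheme = NULL) {
  site_roles <- scheme_site_roles(scheme)
  ents <- document_entities(doc)
  sent_off <- stats::setNames(
    vapply(doc$sentences, function(s) s$offset, integer(1)),
    vapply(doc$sentences, function(s) s$id, character(1)))
  ent_tbl <- fast_tbl(
    id = ents$id, type = ents$type,
    start = ents$start + unname(sent_off[ents$sentence]),
    end = ents$end + unname(sent_off[ents$sentence]),
    text = ents$text, given = ents$given)
  doc_order <- stats::setNames(rank(ent_tbl$start, ties.method = "first"),
                               ent_tbl$id)

  itr_all <- dplyr::bind_rows(lapply(doc$sentences, function(s) s$interactions))
  mem_all <- dplyr::bind_rows(lapply(doc$sentences, function(s) s$events))
  node_events <- split(mem_all$id, mem_all$trigger)
  site_parents <- itr_all[itr_all$type == "SiteParent", , drop = FALSE]

  # order memberships children-first (an argument's target events precede it)
  mem_deps <- lapply(mem_all$args, function(a) {
    if (is.null(a) || !nrow(a)) return(character())
    k <- match(a$interaction, itr_all$id)
    tgt_nodes <- itr_all$target[k]
    explicit <- a$target_event[!is.na(a$target_event)]
    implicit <- unlist(node_events[tgt_nodes[is.na(a$target_event)]])
    c(explicit, implicit)
  })
  names(mem_deps) <- mem_all$id
  ordered <- character(); pending <- mem_all$id
  while (length(pending)) {
    ready <- pending[vapply(mem_deps[pending], function(x)
      !any(x %in% pending), logical(1))]
    if (!length(ready)) stop("event memberships form a cycle", call. = FALSE)
    ordered <- c(ordered, ready)
    pending <- setdiff(pending, ready)
  }

  # build standoff events; memberships with event-valued arguments lacking an
  # explicit target event are duplicated over the target trigger's events
  st_events <- list()                       # st event id -> record
  mem_to_st <- list()                       # membership id -> st event ids
  ev_n <- 0L
  for (mid in ordered) {
    i <- match(mid, mem_all$id)
    trig <- mem_all$trigger[i]
    ttype <- ents$type[match(trig, ents$id)]
    a <- mem_all$args[[i]]
    if (is.null(a) || !nrow(a)) {
      ev_n <- ev_n + 1L
      sid <- paste0("se", ev_n)
      st_events[[sid]] <- list(id = sid, type = ttype, trigger = trig,
                               roles = character(), targets = character(),
                               site_of = integer())
      mem_to_st[[mid]] <- sid
      next
    }
    k <- match(a$interaction, itr_all$id)
    roles <- itr_all$type[k]
    tgt_nodes <- itr_all$target[k]
    tgt_event_flag <- ents$event[match(tgt_nodes, ents$id)]
    # per-argument alternatives: entity target, explicit child event, or all
    # events of the target trigger
    alternatives <- lapply(seq_along(k), function(j) {
      if (!is.na(a$target_event[j])) {
        # gold annotation names the child event explicitly
        lapply(mem_to_st[[a$target_event[j]]] %||% character(),
               function(x) list(ev = x))
      } else if (isTRUE(tgt_event_flag[j]) && !(roles[j] %in% site_roles)) {
        # predicted case: duplicate over every event of the target trigger;
        # empty when the trigger ended up with no events (argument dangles)
        sts <- unlist(lapply(node_events[[tgt_nodes[j]]] %||% character(),
                             function(m) mem_to_st[[m]]))
        lapply(sts %||% character(), function(x) list(ev = x))
      } else {
        list(list(node = tgt_nodes[j]))
      }
    })
    if (any(lengths(alternatives) == 0)) next  # referenced event was removed
    idx <- expand.grid(lapply(alternatives, seq_along))
    for (r in seq_len(nrow(idx))) {
      picks <- lapply(seq_along(alternatives), function(j)
        alternatives[[j]][[idx[r, j]]])
      targets <- vapply(picks, function(p) p$ev %||% p$node, character(1))
      is_ev <- vapply(picks, function(p) !is.null(p$ev), logical(1))
      rec <- resolve_event_sites(roles, targets, is_ev, itr_all, k,
                                 site_roles, site_parents, doc_order)
      if (is.null(rec)) next
      ev_n <- ev_n + 1L
      sid <- paste0("se", ev_n)
      st_events[[sid]] <- c(list(id = sid, type = ttype, trigger = trig), rec)
      mem_to_st[[mid]] <- c(mem_to_st[[mid]], sid)
    }
  }

  # collapse equivalence-expanded copies onto group representatives, then
  # remove duplicates recursively (re-pointing references to the survivor)
  rep_map <- character()
  for (g in doc$equivs) if (length(g) > 1) {
    rep_map[g[-1]] <- g[1]
  }
  if (length(rep_map)) {
    for (sid in names(st_events)) {
      tg <- st_events[[sid]]$targets
      hit <- tg %in% names(rep_map)
      if (any(hit)) st_events[[sid]]$targets[hit] <- rep_map[tg[hit]]
    }
  }
  st_events <- dedupe_events_fixpoint(st_events)

  st_events_tbl <- build_st_event_rows(st_events, site_roles)

  # relations (non-event, non-SiteParent edges plus SiteParent itself)
  rel <- itr_all[!itr_all$event, , drop = FALSE]
  relations <- NULL
  if (nrow(rel)) {
    relations <- fast_tbl(
      id = paste0("sr", seq_len(nrow(rel))), type = rel$type,
      args = lapply(seq_len(nrow(rel)), function(i) fast_tbl(
        role = c(rel$source_role[i] %||% "Arg1", rel$target_role[i] %||% "Arg2"),
        target = c(rel$source[i], rel$target[i]))))
    relations$args <- lapply(relations$args, function(a) {
      a$role[is.na(a$role)] <- c("Arg1", "Arg2")[seq_len(sum(is.na(a$role)))]
      a
    })
  }

  # modifiers: every surviving event on a flagged trigger
  mods <- list()
  neg_nodes <- ents$id[ents$negation]
  spec_nodes <- ents$id[ents$speculation]
  m_n <- 0L
  for (sid in names(st_events)) {
    trig <- st_events[[sid]]$trigger
    if (trig %in% neg_nodes) {
      m_n <- m_n + 1L
      mods[[length(mods) + 1]] <- fast_tbl(id = paste0("sm", m_n),
                                                 kind = "Negation", target = sid)
    }
    if (trig %in% spec_nodes) {
      m_n <- m_n + 1L
      mods[[length(mods) + 1]] <- fast_tbl(id = paste0("sm", m_n),
                                                 kind = "Speculation", target = sid)
    }
  }

  # keep given entities, and non-given entities referenced by the output
  referenced <- unique(c(
    unlist(lapply(st_events, function(x) c(x$trigger, x$targets))),
    if (!is.null(relations)) unlist(lapply(relations$args, function(a) a$target)),
    unlist(doc$equivs)))
  keep <- ent_tbl$given | ent_tbl$id %in% referenced
  ent_keep <- ent_tbl[keep, , drop = FALSE]

  st_document(doc$id, doc$text,
              entities = ent_keep,
              events = st_events_tbl,
              relations = relations,
              modifiers = if (length(mods)) dplyr::bind_rows(mods) else NULL,
              equivs = Filter(length, lapply(doc$equivs, function(g)
                g[g %in% ent_keep$id])))
}

# attach site arguments to primaries inside one candidate event; returns
# NULL when the event collapses entirely, else roles/targets/site_of vectors
resolve_event_sites <- function(roles, targets, is_ev, itr_all, k, site_roles,
                                site_parents, doc_order) {
  is_site <- roles %in% site_roles | !is.na(itr_all$site_of[k])
  prim_idx <- rep(NA_integer_, length(roles))
  for (j in which(is_site)) {
    so <- itr_all$site_of[k[j]]
    if (!is.na(so)) {
      hit <- which(itr_all$id[k] == so & !is_site)
      if (length(hit)) prim_idx[j] <- hit[1]
    } else {
      # predicted case: follow SiteParent from the site entity to its
      # protein(s); attach to the primary whose protein is first in
      # document order
      site_node <- itr_all$target[k[j]]
      parents <- site_parents$target[site_parents$source == site_node]
      cand <- which(!is_site & !is_ev & targets %in% parents)
      if (length(cand)) {
        prim_idx[j] <- cand[order(doc_order[targets[cand]])][1]
      }
    }
  }
  # a primary argument keeps at most one site; a site maps to at most one
  # primary (guaranteed by prim_idx being single-valued)
  drop <- rep(FALSE, length(roles))
  seen_primary <- integer()
  for (j in which(is_site)) {
    if (is.na(prim_idx[j]) || prim_idx[j] %in% seen_primary) {
      drop[j] <- TRUE
    } else {
      seen_primary <- c(seen_primary, prim_idx[j])
    }
  }
  keep <- !drop
  if (!any(keep)) return(NULL)
  list(roles = roles[keep], targets = targets[keep],
       site_of = match(prim_idx[keep], which(keep)),
       is_site = is_site[keep])
}

event_signature <- function(x) {
  a <- order(x$roles, x$targets)
  paste(x$type, x$trigger,
        paste(x$roles[a], x$targets[a], sep = ":", collapse = ","),
        sep = "|")
}

# recursively remove duplicate events, re-pointing references at the
# survivor; terminates because the event count strictly decreases
dedupe_events_fixpoint <- function(st_events) {
  repeat {
    sigs <- vapply(st_events, event_signature, character(1))
    dup <- duplicated(sigs)
    if (!any(dup)) return(st_events)
    survivor <- stats::setNames(names(st_events)[match(sigs, sigs)],
                                names(st_events))
    removed <- names(st_events)[dup]
    st_events <- st_events[!dup]
    for (sid in names(st_events)) {
      tg <- st_events[[sid]]$targets
      hit <- tg %in% removed
      if (any(hit)) st_events[[sid]]$targets[hit] <- survivor[tg[hit]]
    }
  }
}

# order events topologically and emit standoff role numbering
# (Theme, Theme2, ...; each Site follows its primary with a matching suffix)
build_st_event_rows <- function(st_events, site_roles) {
  if (!length(st_events)) {
    return(fast_tbl(id = character(), type = character(),
                          trigger = character(), args = list()))
  }
  rows <- lapply(names(st_events), function(sid) {
    x <- st_events[[sid]]
    if (!length(x$roles)) {
      return(fast_tbl(id = sid, type = x$type, trigger = x$trigger,
                            args = list(empty_role_args())))
    }
    is_site <- if (!is.null(x$is_site)) x$is_site else
      (x$roles %in% site_roles)
    prim <- x$site_of %||% rep(NA_integer_, length(x$roles))
    prim_order <- which(!is_site)
    counts <- integer()
    out_roles <- character(); out_targets <- character()
    suffix_of <- integer(length(x$roles))
    for (j in prim_order) {
      base <- x$roles[j]
      counts[base] <- (if (is.na(counts[base])) 0L else counts[base]) + 1L
      suffix_of[j] <- counts[base]
      out_roles <- c(out_roles,
                     if (counts[base] == 1L) base else paste0(base, counts[base]))
      out_targets <- c(out_targets, x$targets[j])
      sites_here <- which(is_site & !is.na(prim) & prim == j)
      for (sj in sites_here) {
        out_roles <- c(out_roles, if (counts[base] == 1L) x$roles[sj] else
          paste0(x$roles[sj], counts[base]))
        out_targets <- c(out_targets, x$targets[sj])
      }
    }
    # sites without resolvable primaries were discarded upstream
    fast_tbl(id = sid, type = x$type, trigger = x$trigger,
                   args = list(fast_tbl(role = out_roles,
                                              target = out_targets)))
  })
  dplyr::bind_rows(rows)
}
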