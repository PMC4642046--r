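#' @title Sentence realization for the synthetic generator
#' @description Turns event plans into templated subject-verb-object token
#'   sequences with projective dependency parses, entity nodes, interaction
#'   edges and event memberships. Not natural language: the point is that
#'   parses are constructible without an external parser while exercising
#'   every structural phenomenon the pipeline must handle.
#' @name synthetic-realize
#' @keywords internal
NULL

new_sentence_builder <- function() {
  sb <- new.env(parent = emptyenv())
  sb$words <- character(); sb$pos <- character()
  sb$deps <- list(); sb$ents <- list(); sb$instances <- list()
  sb$relations <- list(); sb$equiv_pairs <- list()
  sb
}

sb_token <- function(sb, word, pos) {
  sb$words <- c(sb$words, word); sb$pos <- c(sb$pos, pos)
  length(sb$words)
}

sb_dep <- function(sb, type, gov, dep) {
  sb$deps[[length(sb$deps) + 1]] <- list(type = type, gov = gov, dep = dep)
}

sb_entity <- function(sb, type, tok, given, event = FALSE, negation = FALSE,
                      speculation = FALSE) {
  sb$ents[[length(sb$ents) + 1]] <- list(type = type, tok = tok, given = given,
                                         event = event, negation = negation,
                                         speculation = speculation)
  length(sb$ents)
}

entity_word <- function(gen, type) {
  # a small cycling name pool per type, so lexical features generalize
  # across mentions instead of memorizing one-off strings
  gen$word_n <- gen$word_n + 1L
  prefix <- switch(type, Protein = "Pr", Entity = "Ser", Chemical = "Ch",
                   substr(type, 1, 2))
  pool <- switch(type, Protein = 10L, Entity = 5L, 4L)
  paste0(prefix, (gen$word_n - 1L) %% pool + 1L)
}

emit_entity <- function(sb, gen, ep) {
  tok <- sb_token(sb, entity_word(gen, ep$type), "NN")
  idx <- sb_entity(sb, ep$type, tok, ep$given)
  alts <- idx
  if (isTRUE(ep$alias)) {
    or_tok <- sb_token(sb, "or", "CC")
    alias_tok <- sb_token(sb, entity_word(gen, ep$type), "NN")
    sb_dep(sb, "conj_or", tok, alias_tok)
    alias_idx <- sb_entity(sb, ep$type, alias_tok, ep$given)
    sb$equiv_pairs[[length(sb$equiv_pairs) + 1]] <- c(idx, alias_idx)
    alts <- c(idx, alias_idx)
    gen$manifest[["equiv_groups"]] <- gen$manifest[["equiv_groups"]] + 1L
  }
  list(main = idx, alts = alts, tok = tok)
}

# realize one trigger group (one trigger, >= 1 events); returns the trigger
# token index and the instance indices created
emit_event_group <- function(sb, gen, p, depth = 0) {
  all_args <- p$events
  flat <- list()   # realized argument handles, per event, per arg
  # classify by surface position
  classify <- function(a) {
    if (isTRUE(a$is_site)) "site"
    else if (a$role == "Cause" && identical(a$target$kind, "entity")) "subj"
    else "obj"
  }
  realized <- lapply(all_args, function(args) vector("list", length(args)))
  # subjects
  subj_refs <- list()
  for (e in seq_along(all_args)) {
    for (j in seq_along(all_args[[e]])) {
      a <- all_args[[e]][[j]]
      if (classify(a) == "subj") {
        if (identical(a$target$kind, "cross")) {
          tok <- sb_token(sb, "it", "PRP")
          realized[[e]][[j]] <- list(kind = "cross", node = a$target$node,
                                     tok = tok)
        } else {
          h <- emit_entity(sb, gen, a$target)
          realized[[e]][[j]] <- c(list(kind = "ent"), h)
        }
        subj_refs[[length(subj_refs) + 1]] <- realized[[e]][[j]]$tok
      }
    }
  }
  if (isTRUE(p$speculation)) {
    spec_tok <- sb_token(sb, "possibly", "RB")
  } else spec_tok <- NULL
  if (isTRUE(p$negation)) {
    neg_tok <- sb_token(sb, "not", "RB")
  } else neg_tok <- NULL
  trig_tok <- sb_token(sb, trigger_word_for(p$type), trigger_pos_for(p$type))
  if (!is.null(spec_tok)) sb_dep(sb, "advmod", trig_tok, spec_tok)
  if (!is.null(neg_tok)) sb_dep(sb, "neg", trig_tok, neg_tok)
  for (tk in subj_refs) sb_dep(sb, "nsubj", trig_tok, tk)
  # objects
  obj_heads <- integer()
  for (e in seq_along(all_args)) {
    for (j in seq_along(all_args[[e]])) {
      a <- all_args[[e]][[j]]
      if (classify(a) != "obj") next
      if (length(obj_heads)) {
        and_tok <- sb_token(sb, "and", "CC")
        sb_dep(sb, "cc", obj_heads[1], and_tok)
      }
      if (identical(a$target$kind, "cross")) {
        tok <- sb_token(sb, "it", "PRP")
        realized[[e]][[j]] <- list(kind = "cross", node = a$target$node,
                                   tok = tok)
        head_tok <- tok
      } else if (identical(a$target$kind, "entity")) {
        h <- emit_entity(sb, gen, a$target)
        realized[[e]][[j]] <- c(list(kind = "ent"), h)
        head_tok <- h$tok
      } else {
        child <- emit_event_group(sb, gen, a$target, depth + 1)
        realized[[e]][[j]] <- list(kind = "inst", inst = child$instances[1],
                                   tok = child$trig_tok)
        head_tok <- child$trig_tok
        gen$manifest[["nested_events"]] <- gen$manifest[["nested_events"]] + 1L
      }
      if (!length(obj_heads)) sb_dep(sb, "dobj", trig_tok, head_tok)
      else sb_dep(sb, "conj_and", obj_heads[1], head_tok)
      obj_heads <- c(obj_heads, head_tok)
    }
  }
  # sites
  for (e in seq_along(all_args)) {
    for (j in seq_along(all_args[[e]])) {
      a <- all_args[[e]][[j]]
      if (classify(a) != "site") next
      sb_token(sb, "at", "IN")
      h <- emit_entity(sb, gen, a$target)
      realized[[e]][[j]] <- c(list(kind = "ent"), h)
      sb_dep(sb, "prep_at", trig_tok, h$tok)
      gen$manifest[["site_args"]] <- gen$manifest[["site_args"]] + 1L
    }
  }
  trig_ent <- sb_entity(sb, p$type, trig_tok, FALSE, event = TRUE,
                        negation = isTRUE(p$negation),
                        speculation = isTRUE(p$speculation))
  if (isTRUE(p$negation)) {
    gen$manifest[["negations"]] <- gen$manifest[["negations"]] + 1L
  }
  if (isTRUE(p$speculation)) {
    gen$manifest[["speculations"]] <- gen$manifest[["speculations"]] + 1L
  }
  inst_idx <- integer()
  for (e in seq_along(all_args)) {
    args <- lapply(seq_along(all_args[[e]]), function(j) {
      a <- all_args[[e]][[j]]
      r <- realized[[e]][[j]]
      list(role = a$role, kind = r$kind,
           ref = switch(r$kind, ent = r$main, inst = r$inst, cross = r$node),
           alts = if (r$kind == "ent") r$alts else NULL,
           is_site = isTRUE(a$is_site), primary = a$primary)
    })
    sb$instances[[length(sb$instances) + 1]] <- list(type = p$type,
                                                     trigger = trig_ent,
                                                     args = args)
    inst_idx <- c(inst_idx, length(sb$instances))
    gen$manifest[["events"]] <- gen$manifest[["events"]] + 1L
  }
  if (length(all_args) > 1) {
    gen$manifest[["shared_triggers"]] <- gen$manifest[["shared_triggers"]] + 1L
  }
  list(trig_tok = trig_tok, trig_ent = trig_ent, instances = inst_idx)
}

# assemble a sentence_graph (plus registry info) from realized content
finish_sentence <- function(sb, gen, sid) {
  n <- length(sb$words)
  ends <- cumsum(nchar(sb$words) + 1L) - 1L
  starts <- c(0L, utils::head(ends, -1) + 1L)
  text <- paste(sb$words, collapse = " ")
  tok_ids <- paste0("t", seq_len(n))
  tokens <- fast_tbl(id = tok_ids, text = sb$words, pos = sb$pos,
                           start = starts, end = starts + nchar(sb$words))
  deps <- if (length(sb$deps)) {
    fast_tbl(
      type = vapply(sb$deps, `[[`, character(1), "type"),
      governor = tok_ids[vapply(sb$deps, `[[`, numeric(1), "gov")],
      dependent = tok_ids[vapply(sb$deps, `[[`, numeric(1), "dep")])
  } else empty_dependencies()
  ents <- sb$ents
  ent_ids <- paste0(sid, ".e", seq_along(ents))
  entities <- if (length(ents)) {
    fast_tbl(
      id = ent_ids,
      type = vapply(ents, `[[`, character(1), "type"),
      start = starts[vapply(ents, `[[`, numeric(1), "tok")],
      end = starts[vapply(ents, `[[`, numeric(1), "tok")] +
        nchar(sb$words[vapply(ents, `[[`, numeric(1), "tok")]),
      text = sb$words[vapply(ents, `[[`, numeric(1), "tok")],
      head = tok_ids[vapply(ents, `[[`, numeric(1), "tok")],
      given = vapply(ents, `[[`, logical(1), "given"),
      event = vapply(ents, `[[`, logical(1), "event"),
      negation = vapply(ents, `[[`, logical(1), "negation"),
      speculation = vapply(ents, `[[`, logical(1), "speculation"))
  } else empty_entities()

  edge_env <- new.env(parent = emptyenv())
  edge_rows <- list()
  site_pending <- list()
  add_edge <- function(src, tgt, type, event_flag, src_role = NA_character_,
                       tgt_role = NA_character_, cross = FALSE) {
    key <- paste(src, tgt, type, sep = "|")
    found <- mget(key, envir = edge_env, ifnotfound = list(NULL))[[1]]
    if (!is.null(found)) return(found)
    id <- paste0(sid, ".i", length(edge_rows) + 1L)
    edge_rows[[length(edge_rows) + 1L]] <<- fast_tbl(
      id = id, type = type, source = src, target = tgt, directed = TRUE,
      event = event_flag, given = FALSE, site_of = NA_character_,
      source_role = src_role, target_role = tgt_role, cross_sentence = cross)
    assign(key, id, envir = edge_env)
    id
  }
  inst_memberships <- vector("list", length(sb$instances))
  mem_rows <- list()
  for (i in seq_along(sb$instances)) {
    inst <- sb$instances[[i]]
    args <- inst$args
    trig_node <- ent_ids[inst$trigger]
    if (!length(args)) {
      mid <- paste0(sid, ".ev", length(mem_rows) + 1L)
      mem_rows[[length(mem_rows) + 1L]] <- fast_tbl(
        id = mid, trigger = trig_node, args = list(empty_event_args()))
      inst_memberships[[i]] <- mid
      next
    }
    alternatives <- lapply(args, function(a) {
      switch(a$kind,
             ent = lapply(a$alts, function(k)
               list(node = ent_ids[k], mem = NA_character_, cross = FALSE)),
             inst = lapply(inst_memberships[[a$ref]], function(m)
               list(node = NULL, mem = m, cross = FALSE)),
             cross = list(list(node = a$ref, mem = NA_character_,
                               cross = TRUE)))
    })
    idx <- expand.grid(lapply(alternatives, seq_along))
    mids <- character()
    for (r in seq_len(nrow(idx))) {
      picks <- lapply(seq_along(alternatives), function(j)
        alternatives[[j]][[idx[r, j]]])
      edge_ids <- character(length(args))
      tgt_event <- rep(NA_character_, length(args))
      for (j in seq_along(args)) {
        p <- picks[[j]]
        if (!is.na(p$mem)) {
          # target is a child event: edge points at its trigger node
          tgt_node <- mem_rows[[match(p$mem,
                                      vapply(mem_rows, function(x) x$id,
                                             character(1)))]]$trigger
          tgt_event[j] <- p$mem
        } else tgt_node <- p$node
        edge_ids[j] <- add_edge(trig_node, tgt_node, args[[j]]$role, TRUE,
                                cross = isTRUE(p$cross))
        if (isTRUE(p$cross) && r == 1L) {
          gen$manifest[["cross_sentence_events"]] <-
            gen$manifest[["cross_sentence_events"]] + 1L
        }
      }
      for (j in seq_along(args)) {
        a <- args[[j]]
        if (a$is_site && !is.na(a$primary)) {
          prim_edge <- edge_ids[a$primary]
          site_pending[[edge_ids[j]]] <- prim_edge
          prim_pick <- picks[[a$primary]]
          if (is.na(prim_pick$mem) && !isTRUE(prim_pick$cross)) {
            add_edge(picks[[j]]$node, prim_pick$node, "SiteParent", FALSE,
                     "Arg1", "Arg2")
          }
        }
      }
      mid <- paste0(sid, ".ev", length(mem_rows) + 1L)
      mem_rows[[length(mem_rows) + 1L]] <- fast_tbl(
        id = mid, trigger = trig_node,
        args = list(fast_tbl(interaction = edge_ids,
                                   target_event = tgt_event)))
      mids <- c(mids, mid)
    }
    inst_memberships[[i]] <- mids
  }
  for (rl in sb$relations) {
    add_edge(ent_ids[rl$e1], ent_ids[rl$e2], rl$type, FALSE,
             rl$end1_role, rl$end2_role)
    gen$manifest[["relations"]] <- gen$manifest[["relations"]] + 1L
  }
  interactions <- if (length(edge_rows)) dplyr::bind_rows(edge_rows) else
    empty_interactions()
  if (nrow(interactions) && length(site_pending)) {
    hit <- intersect(interactions$id, names(site_pending))
    interactions$site_of[match(hit, interactions$id)] <-
      unlist(site_pending[hit])
  }
  s <- sentence_graph(sid, text, tokens = tokens, dependencies = deps,
                      entities = entities, interactions = interactions,
                      events = if (length(mem_rows)) dplyr::bind_rows(mem_rows)
                      else empty_events())
  equivs <- lapply(sb$equiv_pairs, function(pr) ent_ids[pr])
  list(sentence = s, equivs = equivs,
       registry = entities[!entities$event, c("id", "type"), drop = FALSE])
}

realize_sentence <- function(plans, sid, gen) {
  sb <- new_sentence_builder()
  prev_trig <- NULL
  for (p in plans) {
    if (identical(p$kind, "mention")) {
      emit_entity(sb, gen, p$entity)
      next
    }
    if (identical(p$kind, "relation")) {
      h1 <- emit_entity(sb, gen, p$e1)
      sb_token(sb, "with", "IN")
      h2 <- emit_entity(sb, gen, p$e2)
      sb_dep(sb, "prep_with", h1$tok, h2$tok)
      sb$relations[[length(sb$relations) + 1]] <- list(
        type = p$type, e1 = h1$main, e2 = h2$main,
        end1_role = p$end1_role, end2_role = p$end2_role)
      next
    }
    if (!is.null(prev_trig)) {
      and_tok <- sb_token(sb, "and", "CC")
      sb_dep(sb, "cc", prev_trig, and_tok)
    }
    g <- emit_event_group(sb, gen, p)
    if (!is.null(prev_trig)) sb_dep(sb, "conj_and", prev_trig, g$trig_tok)
    prev_trig <- g$trig_tok
  }
  dot <- sb_token(sb, ".", ".")
  anchor <- if (!is.null(prev_trig)) prev_trig else 1L
  if (length(sb$words) > 1) sb_dep(sb, "punct", anchor, dot)
  finish_sentence(sb, gen, sid)
}
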