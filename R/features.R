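#' @title Sparse feature extraction for the four classification steps
#' @description Classifiable examples carry sparse binary feature sets named
#'   by convention: `txt_`/`POS_` token features, `stem_`/`dt_`/`tt_`
#'   subtoken features (stem, character duplets, triplets), `linear_k_`
#'   signed-offset context, `dist_d_` dependency context within bounded
#'   distance, shortest-path features (`dep_Forward_`/`dep_Reverse_` steps,
#'   `tok_FF..` position-coded path tokens, `tokenPath_` whole-path
#'   signatures, `ngram_` label n-grams), `argRole_` and `trg_` prefixes for
#'   unmerging, and `t1HOut_`/`spec_` features for modifier detection.
#' @name features
NULL

#' Default speculation word list
#'
#' A small curated set of speculation-related words used by the modifier
#' detector; pass your own vector to [build_modifier_examples()] to replace
#' it.
#'
#' @return Character vector.
#' @export
speculation_words <- function() {
  c("may", "might", "suggest", "suggests", "suggesting", "possibly",
    "potentially", "appear", "appears", "likely", "putative", "probably",
    "hypothesize", "hypothesized", "unclear", "whether", "could", "propose")
}

merged_class <- function(types) {
  if (!length(types)) "neg" else paste(sort(unique(types)), collapse = "---")
}

split_merged_class <- function(cls) {
  if (identical(cls, "neg")) character() else
    strsplit(cls, "---", fixed = TRUE)[[1]]
}

# light suffix-stripping stemmer (longest listed suffix, stem >= 3 chars)
stem_word <- function(w) {
  w <- tolower(w)
  suffixes <- c("ational", "ization", "ations", "ingly", "ation", "ments",
                "ness", "ment", "ions", "ing", "ion", "ies", "ed", "es",
                "ly", "s")
  for (sfx in suffixes) {
    if (endsWith(w, sfx) && nchar(w) - nchar(sfx) >= 3) {
      return(substr(w, 1, nchar(w) - nchar(sfx)))
    }
  }
  w
}

char_ngrams <- function(w, n) {
  w <- tolower(w)
  if (nchar(w) < n) return(character())
  unique(vapply(seq_len(nchar(w) - n + 1L), function(i)
    substr(w, i, i + n - 1L), character(1)))
}

# undirected adjacency of the dependency graph: list token id -> tibble of
# (neighbour, label, direction out/in)
dep_adjacency <- function(sentence) {
  dep <- sentence$dependencies
  adj <- stats::setNames(vector("list", nrow(sentence$tokens)),
                         sentence$tokens$id)
  for (i in seq_len(nrow(dep))) {
    g <- dep$governor[i]; d <- dep$dependent[i]; ty <- dep$type[i]
    adj[[g]] <- rbind(adj[[g]], data.frame(to = d, label = ty, dir = "out",
                                           stringsAsFactors = FALSE))
    adj[[d]] <- rbind(adj[[d]], data.frame(to = g, label = ty, dir = "in",
                                           stringsAsFactors = FALSE))
  }
  adj
}

#' Shortest undirected dependency path between two tokens
#'
#' Minimal-length path in the undirected view of the sentence's dependency
#' graph; among equally short paths the one with the lexicographically
#' smallest dependency-label sequence is returned (deterministic tie-break).
#'
#' @param t1,t2 Token ids.
#' @param sentence A [sentence_graph()].
#' @return `NULL` when the tokens are disconnected, else a list with
#'   `tokens` (token ids, `t1` first), `labels` (dependency labels per step)
#'   and `dirs` (`"F"` when the step follows governor-to-dependent
#'   direction, `"R"` otherwise). `t1 == t2` yields an empty path.
#' @export
shortest_undirected_path <- function(t1, t2, sentence) {
  if (identical(t1, t2)) {
    return(list(tokens = t1, labels = character(), dirs = character()))
  }
  dep <- sentence$dependencies
  if (!nrow(dep)) return(NULL)
  verts <- sentence$tokens$id
  g <- igraph::graph_from_data_frame(
    data.frame(from = dep$governor, to = dep$dependent,
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = verts))
  sp <- suppressWarnings(igraph::all_shortest_paths(g, from = t1, to = t2))
  paths <- sp$vpaths %||% sp$res
  if (!length(paths)) return(NULL)
  decode <- function(vp) {
    toks <- igraph::as_ids(vp)
    labels <- character(length(toks) - 1L)
    dirs <- character(length(toks) - 1L)
    for (k in seq_len(length(toks) - 1L)) {
      a <- toks[k]; b <- toks[k + 1L]
      fwd <- which(dep$governor == a & dep$dependent == b)
      if (length(fwd)) {
        labels[k] <- sort(dep$type[fwd])[1]; dirs[k] <- "F"
      } else {
        rev <- which(dep$governor == b & dep$dependent == a)
        labels[k] <- sort(dep$type[rev])[1]; dirs[k] <- "R"
      }
    }
    list(tokens = toks, labels = labels, dirs = dirs)
  }
  decoded <- lapply(paths, decode)
  keys <- vapply(decoded, function(p) paste(p$labels, collapse = "\r"),
                 character(1))
  decoded[[order(keys)[1]]]
}

# context features shared by the entity-style builders
entity_token_features <- function(sentence, tok_id, adj = NULL,
                                  linear_window = 3L, dep_depth = 3L) {
  tok <- sentence$tokens
  i <- match(tok_id, tok$id)
  f <- c(paste0("txt_", tok$text[i]), paste0("POS_", tok$pos[i]),
         paste0("stem_", stem_word(tok$text[i])),
         paste0("dt_", char_ngrams(tok$text[i], 2L)),
         paste0("tt_", char_ngrams(tok$text[i], 3L)))
  for (k in setdiff(seq(-linear_window, linear_window), 0L)) {
    j <- i + k
    if (j >= 1 && j <= nrow(tok)) {
      f <- c(f, sprintf("linear_%d_txt_%s", k, tok$text[j]),
             sprintf("linear_%d_POS_%s", k, tok$pos[j]))
    }
  }
  if (is.null(adj)) adj <- dep_adjacency(sentence)
  given_head <- sentence$entities$head[sentence$entities$given]
  given_type <- sentence$entities$type[sentence$entities$given]
  # breadth-first dependency context with label-chain features
  dist <- stats::setNames(rep(NA_integer_, nrow(tok)), tok$id)
  chain <- stats::setNames(rep(NA_character_, nrow(tok)), tok$id)
  dist[tok_id] <- 0L; chain[tok_id] <- ""
  frontier <- tok_id
  d <- 0L
  while (length(frontier) && d < dep_depth) {
    d <- d + 1L
    nxt <- character()
    for (u in frontier) {
      nb <- adj[[u]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        v <- nb$to[r]
        if (!is.na(dist[v])) next
        dist[v] <- d
        step <- paste0(if (nb$dir[r] == "out") "frw_" else "rev_", nb$label[r])
        chain[v] <- paste0(chain[u], "-", step)
        j <- match(v, tok$id)
        f <- c(f, sprintf("dist_%d_txt_%s", d, tok$text[j]),
               sprintf("dist_%d_POS_%s", d, tok$pos[j]),
               sprintf("chain_dist_dist_%d%s", d, chain[v]))
        hit <- which(given_head == v)
        if (length(hit)) {
          f <- c(f, sprintf("dist_%d_annType_%s", d,
                            unique(given_type[hit])))
        }
        nxt <- c(nxt, v)
      }
    }
    frontier <- nxt
  }
  # head-out dependencies (token as governor)
  dep <- sentence$dependencies
  out <- which(dep$governor == tok_id)
  for (r in out) {
    j <- match(dep$dependent[r], tok$id)
    f <- c(f, paste0("t1HOut_", dep$type[r]),
           sprintf("t1HOut_%s_%s", dep$type[r], tok$pos[j]),
           paste0("t1HOut_", tok$text[j]))
    if (dep$dependent[r] %in% given_head) {
      f <- c(f, sprintf("t1HOut_%s_NAMED_ENT", dep$type[r]))
    }
  }
  unique(f)
}

sentence_level_features <- function(sentence) {
  unique(c(paste0("bow_", sentence$tokens$text),
           paste0("hasType_", unique(sentence$entities$type[sentence$entities$given]))))
}

example_tbl <- function(id, step, gold, features, anchor) {
  tibble::tibble(id = id, step = step, gold = gold, features = features,
                 anchor = anchor)
}

empty_examples <- function() {
  example_tbl(character(), character(), character(), list(), list())
}

#' Build entity-step examples
#'
#' One classifiable example per token that is not part of a given entity;
#' the gold class is the node type, merged with `---` when several non-given
#' nodes share the head token, or `"neg"`.
#'
#' @param sentence A [sentence_graph()].
#' @param scheme An [annotation_scheme()] (carried for interface symmetry;
#'   entity examples are not filtered by it).
#' @param labeled Attach gold classes (requires gold annotation).
#' @return Tibble of examples (`id`, `step`, `gold`, `features`, `anchor`).
#' @export
build_entity_examples <- function(sentence, scheme, labeled = TRUE) {
  tok <- sentence$tokens
  if (!nrow(tok)) return(empty_examples())
  ent <- sentence$entities
  given <- ent[ent$given, , drop = FALSE]
  covered <- rep(FALSE, nrow(tok))
  for (i in seq_len(nrow(given))) {
    covered <- covered | (tok$start < given$end[i] & tok$end > given$start[i])
  }
  keep <- which(!covered)
  if (!length(keep)) return(empty_examples())
  adj <- dep_adjacency(sentence)
  sent_f <- sentence_level_features(sentence)
  rows <- lapply(keep, function(i) {
    tid <- tok$id[i]
    gold <- if (labeled) {
      merged_class(ent$type[!ent$given & ent$head == tid])
    } else NA_character_
    example_tbl(paste0(sentence$id, ".ent.", tid), "entity", gold,
                list(unique(c(entity_token_features(sentence, tid, adj),
                              sent_f))),
                list(list(sentence = sentence$id, token = tid)))
  })
  dplyr::bind_rows(rows)
}

undirected_only_pair <- function(scheme, ta, tb) {
  er <- scheme$edge_rules
  types <- er$type[er$source_type == ta & er$target_type == tb]
  if (!length(types)) return(FALSE)
  und <- scheme$relations$type[!scheme$relations$directed]
  all(types %in% und)
}

# candidate ordered node pairs under the scheme filter: every pair licensed
# for at least one edge type, with undirected-only pairs generated once
edge_candidate_pairs <- function(entities, scheme, filter = TRUE) {
  n <- nrow(entities)
  if (n < 2) return(NULL)
  idx <- expand.grid(a = seq_len(n), b = seq_len(n))
  idx <- idx[idx$a != idx$b, , drop = FALSE]
  if (!filter) return(idx)
  keep <- vapply(seq_len(nrow(idx)), function(r) {
    ta <- entities$type[idx$a[r]]; tb <- entities$type[idx$b[r]]
    if (!is_valid_edge(scheme, ta, tb)) return(FALSE)
    if (undirected_only_pair(scheme, ta, tb)) {
      # one example per unordered pair: keep the document-order orientation
      return(entities$start[idx$a[r]] <= entities$start[idx$b[r]])
    }
    TRUE
  }, logical(1))
  idx[keep, , drop = FALSE]
}

edge_pair_features <- function(sentence, e1, e2, adj) {
  ent <- sentence$entities
  tok <- sentence$tokens
  i1 <- match(e1, ent$id); i2 <- match(e2, ent$id)
  t1 <- ent$head[i1]; t2 <- ent$head[i2]
  endpoint <- function(prefix, i) {
    j <- match(ent$head[i], tok$id)
    c(sprintf("%s_annType_%s", prefix, ent$type[i]),
      sprintf("%s_txt_%s", prefix, tok$text[j]),
      sprintf("%s_POS_%s", prefix, tok$pos[j]),
      sprintf("%s_stem_%s", prefix, stem_word(tok$text[j])))
  }
  f <- c(endpoint("e1", i1), endpoint("e2", i2))
  path <- shortest_undirected_path(t1, t2, sentence)
  if (is.null(path)) return(unique(c(f, "noPath")))
  if (!length(path$labels)) return(unique(c(f, "sameHead")))
  f <- c(f, sprintf("pathLength_%d", min(length(path$labels), 9L)))
  f <- c(f, sprintf("dep_%s_%s", ifelse(path$dirs == "F", "Forward", "Reverse"),
                    path$labels))
  prefix <- vapply(seq_along(path$dirs), function(k)
    paste(path$dirs[seq_len(k)], collapse = ""), character(1))
  mids <- seq_along(path$tokens)[-c(1, length(path$tokens))]
  for (k in mids) {
    j <- match(path$tokens[k], tok$id)
    f <- c(f, sprintf("tok_%stxt_%s", prefix[k - 1L], tok$text[j]),
           sprintf("tok_%sPOS_%s", prefix[k - 1L], tok$pos[j]),
           sprintf("txt_%s", tok$text[j]),
           sprintf("POS_%s", tok$pos[j]))
  }
  node_label <- vapply(path$tokens, function(tid) {
    hit <- which(ent$head == tid)
    if (length(hit)) ent$type[hit[1]] else tok$pos[match(tid, tok$id)]
  }, character(1))
  node_label[1] <- "e1"; node_label[length(node_label)] <- "e2"
  f <- c(f, paste0("tokenPath_", paste(node_label, collapse = "_")))
  steps <- sprintf("%s_%s", tolower(path$dirs), path$labels)
  for (n in 2:4) {
    if (length(steps) >= n) {
      f <- c(f, vapply(seq_len(length(steps) - n + 1L), function(k)
        paste0("ngram_", paste(steps[k:(k + n - 1L)], collapse = "-")),
        character(1)))
    }
  }
  unique(f)
}

#' Build edge-step examples
#'
#' One classifiable example per candidate node pair; candidates are exactly
#' the pairs between which the scheme licenses at least one edge type, which
#' removes most pairs that could only ever be negative. The gold class is
#' the edge type (merged for overlapping parallel edges) or `"neg"`.
#'
#' @param sentence A [sentence_graph()].
#' @param scheme An [annotation_scheme()].
#' @param entities Node table to pair (defaults to the sentence's entities;
#'   predicted nodes can be supplied during inference).
#' @param labeled Attach gold classes from the sentence's interactions.
#' @param filter Apply the scheme filter (disable to measure its effect).
#' @return Tibble of examples.
#' @export
build_edge_examples <- function(sentence, scheme,
                                entities = sentence$entities,
                                labeled = TRUE, filter = TRUE) {
  ent <- entities
  if (nrow(ent) < 2) return(empty_examples())
  idx <- edge_candidate_pairs(ent, scheme, filter = filter)
  if (is.null(idx) || !nrow(idx)) return(empty_examples())
  adj <- dep_adjacency(sentence)
  sent_f <- sentence_level_features(sentence)
  itr <- sentence$interactions
  itr <- itr[!itr$cross_sentence, , drop = FALSE]
  und <- scheme$relations$type[!scheme$relations$directed]
  rows <- lapply(seq_len(nrow(idx)), function(r) {
    a <- ent$id[idx$a[r]]; b <- ent$id[idx$b[r]]
    gold <- if (labeled) {
      hit <- itr$type[itr$source == a & itr$target == b]
      back <- itr$type[itr$source == b & itr$target == a & itr$type %in% und]
      merged_class(c(hit, back))
    } else NA_character_
    example_tbl(paste0(sentence$id, ".edge.", a, ".", b), "edge", gold,
                list(unique(c(edge_pair_features(sentence, a, b, adj), sent_f))),
                list(list(sentence = sentence$id, source = a, target = b)))
  })
  dplyr::bind_rows(rows)
}

#' Scheme-filter statistics for edge example generation
#'
#' Counts, over a corpus, the edge examples a brute-force all-pairs
#' generator would build, how many of them the scheme filter removes (all
#' removable examples are negatives), and the positive examples among the
#' kept candidates.
#'
#' @param corpus An `ig_corpus` (or document/list).
#' @param scheme An [annotation_scheme()].
#' @return One-row tibble: `total_examples`, `filtered_out`, `kept`,
#'   `positives`, `negatives_kept`.
#' @export
edge_filter_stats <- function(corpus, scheme) {
  tot <- 0L; kept <- 0L; pos <- 0L
  for (s in gather_sentences(corpus)) {
    all_ex <- build_edge_examples(s, scheme, filter = FALSE)
    flt <- build_edge_examples(s, scheme, filter = TRUE)
    tot <- tot + nrow(all_ex)
    kept <- kept + nrow(flt)
    pos <- pos + sum(flt$gold != "neg")
  }
  tibble::tibble(total_examples = tot, filtered_out = tot - kept,
                 kept = kept, positives = pos, negatives_kept = kept - pos)
}

# outgoing argument edges of a trigger node usable in events (licensed as a
# role of the trigger's type; intra-sentence only)
trigger_argument_edges <- function(sentence, node_id, scheme) {
  itr <- sentence$interactions
  ent <- sentence$entities
  ttype <- ent$type[match(node_id, ent$id)]
  i <- match(ttype, scheme$events$type)
  if (is.na(i)) return(itr[0, , drop = FALSE])
  roles <- scheme$events$arguments[[i]]$role
  out <- itr[itr$source == node_id & !itr$cross_sentence &
               itr$type %in% roles, , drop = FALSE]
  out[order(out$id), , drop = FALSE]
}

# argument view of an edge subset, resolving each Site edge's primary
# argument within the subset (siteOf first, then SiteParent linkage)
subset_arg_view <- function(edges, sentence, scheme, doc_entities = NULL) {
  ent <- sentence$entities
  site_roles <- scheme_site_roles(scheme)
  ttypes <- ent$type[match(edges$target, ent$id)]
  if (any(is.na(ttypes)) && !is.null(doc_entities)) {
    miss <- is.na(ttypes)
    ttypes[miss] <- doc_entities$type[match(edges$target[miss],
                                            doc_entities$id)]
  }
  prim_role <- rep(NA_character_, nrow(edges))
  is_site <- edges$type %in% site_roles
  if (any(is_site)) {
    sp <- sentence$interactions[sentence$interactions$type == "SiteParent", ,
                                drop = FALSE]
    for (j in which(is_site)) {
      so <- edges$site_of[j]
      if (!is.na(so) && so %in% edges$id) {
        prim_role[j] <- edges$type[match(so, edges$id)]
      } else {
        parents <- sp$target[sp$source == edges$target[j]]
        hit <- which(!is_site & edges$target %in% parents)
        if (length(hit)) prim_role[j] <- edges$type[hit[1]]
      }
    }
  }
  tibble::tibble(role = edges$type, target_type = ttypes,
                 site_primary_role = prim_role)
}

#' Enumerate valid argument subsets of a trigger node
#'
#' Every subset of the trigger's outgoing argument edges that forms a
#' structurally valid event under the scheme (the unmerging candidate set).
#' The empty subset is included when the event type admits zero arguments.
#'
#' @param sentence A [sentence_graph()].
#' @param node_id Trigger entity-node id.
#' @param scheme An [annotation_scheme()].
#' @param max_subsets Cap on enumerated subsets; beyond it the
#'   highest-priority edges (by id order) are kept and a warning is issued.
#' @return List of character vectors of interaction ids (each sorted).
#' @export
enumerate_event_candidates <- function(sentence, node_id, scheme,
                                       max_subsets = 1024L) {
  ent <- sentence$entities
  ttype <- ent$type[match(node_id, ent$id)]
  edges <- trigger_argument_edges(sentence, node_id, scheme)
  n <- nrow(edges)
  if (2^n > max_subsets) {
    keep_n <- floor(log2(max_subsets))
    warning(sprintf("trigger %s has %d argument edges; capping enumeration to the first %d edges",
                    node_id, n, keep_n), call. = FALSE)
    edges <- edges[seq_len(keep_n), , drop = FALSE]
    n <- keep_n
  }
  out <- list()
  for (mask in seq_len(2^n) - 1L) {
    pick <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    sub <- edges[pick, , drop = FALSE]
    view <- subset_arg_view(sub, sentence, scheme)
    if (is_valid_event_structure(scheme, ttype, view)) {
      out[[length(out) + 1]] <- sort(sub$id)
    }
  }
  out
}

unmerging_features <- function(sentence, node_id, edge_ids, scheme, adj) {
  ent <- sentence$entities
  tok <- sentence$tokens
  itr <- sentence$interactions
  trig_tok <- ent$head[match(node_id, ent$id)]
  f <- paste0("trg_", entity_token_features(sentence, trig_tok, adj))
  span_toks <- match(trig_tok, tok$id)
  for (eid in edge_ids) {
    k <- match(eid, itr$id)
    role <- itr$type[k]
    tgt <- itr$target[k]
    ti <- match(tgt, ent$id)
    if (is.na(ti)) next
    tgt_tok <- ent$head[ti]
    j <- match(tgt_tok, tok$id)
    span_toks <- c(span_toks, j)
    pf <- paste0("arg", role, "_")
    f <- c(f, sprintf("%sannType_%s", pf, ent$type[ti]),
           sprintf("%stxt_%s", pf, tok$text[j]),
           sprintf("%sPOS_%s", pf, tok$pos[j]))
    path <- shortest_undirected_path(trig_tok, tgt_tok, sentence)
    if (is.null(path)) {
      f <- c(f, paste0(pf, "noPath"))
    } else if (length(path$labels)) {
      f <- c(f, sprintf("%sdep_%s_%s", pf,
                        ifelse(path$dirs == "F", "Forward", "Reverse"),
                        path$labels))
    }
  }
  # argument-count features: subsets differing only in how many edges of a
  # role they include would otherwise be indistinguishable
  roles <- itr$type[match(edge_ids, itr$id)]
  f <- c(f, sprintf("numArgs_%d", length(edge_ids)),
         sprintf("num%s_%d", names(table(roles)), as.integer(table(roles))))
  lo <- min(span_toks); hi <- max(span_toks)
  f <- c(f, paste0("bow_", tok$text[lo:hi]))
  span_ids <- tok$id[lo:hi]
  dep <- sentence$dependencies
  outside <- !(dep$governor %in% span_ids) | !(dep$dependent %in% span_ids)
  f <- c(f, paste0("context_dep_", dep$type[outside]))
  unique(f)
}

#' Build unmerging-step examples
#'
#' One classifiable example per trigger node per structurally valid subset
#' of its outgoing argument edges; the gold class is `"pos"` iff the subset
#' equals the argument set of one gold event on that trigger.
#'
#' @inheritParams enumerate_event_candidates
#' @param labeled Attach gold classes from the sentence's event memberships.
#' @return Tibble of examples; each anchor holds the trigger node id and the
#'   subset of interaction ids.
#' @export
build_unmerging_examples <- function(sentence, scheme, labeled = TRUE,
                                     max_subsets = 1024L) {
  ent <- sentence$entities
  triggers <- ent$id[ent$type %in% scheme$events$type & !ent$given]
  triggers <- c(triggers, ent$id[ent$type %in% scheme$events$type & ent$given])
  if (!length(triggers)) return(empty_examples())
  adj <- dep_adjacency(sentence)
  gold_sets <- lapply(seq_len(nrow(sentence$events)), function(i) {
    a <- sentence$events$args[[i]]
    sort(a$interaction)
  })
  gold_trig <- sentence$events$trigger
  rows <- list()
  for (nd in triggers) {
    cands <- enumerate_event_candidates(sentence, nd, scheme,
                                        max_subsets = max_subsets)
    for (ci in seq_along(cands)) {
      sub <- cands[[ci]]
      gold <- if (labeled) {
        hit <- any(vapply(seq_along(gold_sets), function(g)
          gold_trig[g] == nd && identical(gold_sets[[g]], sub), logical(1)))
        if (hit) "pos" else "neg"
      } else NA_character_
      rows[[length(rows) + 1]] <- example_tbl(
        paste0(sentence$id, ".unm.", nd, ".", ci), "unmerging", gold,
        list(unmerging_features(sentence, nd, sub, scheme, adj)),
        list(list(sentence = sentence$id, trigger = nd, edges = sub)))
    }
  }
  if (!length(rows)) return(empty_examples())
  dplyr::bind_rows(rows)
}

#' Build modifier-step examples
#'
#' One example per trigger node of a modifier-capable type (per the
#' scheme); the gold class is `none`, `negation`, `speculation` or
#' `negation---speculation`. Features are trigger-style features plus
#' matches against a speculation word list and head-out dependency
#' features.
#'
#' @param sentence A [sentence_graph()].
#' @param scheme An [annotation_scheme()].
#' @param labeled Attach gold classes from the trigger's modifier flags.
#' @param spec_words Speculation word list; see [speculation_words()].
#' @return Tibble of examples.
#' @export
build_modifier_examples <- function(sentence, scheme, labeled = TRUE,
                                    spec_words = speculation_words()) {
  capable <- union(scheme$modifiers$negation, scheme$modifiers$speculation)
  ent <- sentence$entities
  triggers <- ent$id[ent$type %in% capable]
  if (!length(triggers)) return(empty_examples())
  adj <- dep_adjacency(sentence)
  sent_f <- sentence_level_features(sentence)
  spec_hits <- paste0("spec_word_",
                      intersect(tolower(sentence$tokens$text), spec_words))
  rows <- lapply(triggers, function(nd) {
    i <- match(nd, ent$id)
    gold <- if (labeled) {
      kinds <- c(if (ent$negation[i]) "negation",
                 if (ent$speculation[i]) "speculation")
      if (!length(kinds)) "none" else paste(kinds, collapse = "---")
    } else NA_character_
    example_tbl(paste0(sentence$id, ".mod.", nd), "modifier", gold,
                list(unique(c(entity_token_features(sentence, ent$head[i], adj),
                              sent_f, spec_hits))),
                list(list(sentence = sentence$id, trigger = nd)))
  })
  dplyr::bind_rows(rows)
}

#' Feature space: frozen name-to-column mapping
#'
#' Built from training examples and frozen; names unseen at training map to
#' no column at prediction time (they are ignored, never appended).
#'
#' @param examples Tibble of examples (list-column `features`).
#' @return A `feature_space` object.
#' @export
feature_space <- function(examples) {
  nms <- sort(unique(unlist(examples$features)))
  structure(list(names = nms), class = "feature_space")
}

#' @export
print.feature_space <- function(x, ...) {
  cat(sprintf("<feature_space> %d features\n", length(x$names)))
  invisible(x)
}

#' Sparse design matrix for a set of examples
#'
#' @param examples Tibble of examples.
#' @param space A [feature_space()].
#' @return A `dgCMatrix` with one row per example.
#' @export
examples_to_matrix <- function(examples, space) {
  n <- nrow(examples)
  ii <- integer(); jj <- integer()
  for (r in seq_len(n)) {
    j <- match(examples$features[[r]], space$names)
    j <- j[!is.na(j)]
    ii <- c(ii, rep(r, length(j)))
    jj <- c(jj, j)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                       dims = c(n, length(space$names)),
                       dimnames = list(examples$id, space$names))
}

#' Export examples in sparse text form
#'
#' `label qid:<sentence> index:value ...` lines for use with external
#' trainers, plus a sidecar mapping of feature names to column indices.
#'
#' @param examples Tibble of examples.
#' @param space A [feature_space()].
#' @param path Output file; the feature map is written to `<path>.features`.
#' @param class_map Optional named integer vector mapping class labels to
#'   integers (built from the data when omitted).
#' @return `path`, invisibly.
#' @export
write_examples_sparse <- function(examples, space, path, class_map = NULL) {
  if (is.null(class_map)) {
    lv <- sort(unique(examples$gold))
    class_map <- stats::setNames(seq_along(lv), lv)
  }
  lines <- vapply(seq_len(nrow(examples)), function(r) {
    j <- sort(match(examples$features[[r]], space$names))
    j <- j[!is.na(j)]
    paste(c(class_map[[examples$gold[r]]],
            paste0("qid:", examples$anchor[[r]]$sentence %||% "0"),
            sprintf("%d:1", j)), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  writeLines(sprintf("%d\t%s", seq_along(space$names), space$names),
             paste0(path, ".features"))
  invisible(path)
}

#' Feature group of a feature name
#'
#' Maps feature names to the reporting groups used in importance summaries:
#' token, subtoken, linear, dependencies, sentence, entity, path, ngrams,
#' args, trigger, bow, context, spec.
#'
#' @param names Character vector of feature names.
#' @return Character vector of group labels.
#' @export
feature_group <- function(names) {
  grp <- function(nm) {
    if (startsWith(nm, "trg_")) return("trigger")
    if (startsWith(nm, "arg")) return("args")
    if (startsWith(nm, "context_")) return("context")
    if (startsWith(nm, "bow_")) return("bow")
    if (startsWith(nm, "spec_word_")) return("spec")
    if (startsWith(nm, "e1_") || startsWith(nm, "e2_")) return("entity")
    if (startsWith(nm, "ngram_")) return("ngrams")
    if (startsWith(nm, "dep_") || startsWith(nm, "tok_") ||
        startsWith(nm, "tokenPath_") || startsWith(nm, "pathLength") ||
        nm %in% c("noPath", "sameHead")) return("path")
    if (startsWith(nm, "linear_")) return("linear")
    if (startsWith(nm, "dist_") || startsWith(nm, "chain_") ||
        startsWith(nm, "t1HOut_")) return("dependencies")
    if (startsWith(nm, "stem_") || startsWith(nm, "dt_") ||
        startsWith(nm, "tt_")) return("subtoken")
    if (startsWith(nm, "hasType_")) return("sentence")
    if (startsWith(nm, "txt_") || startsWith(nm, "POS_")) return("token")
    "other"
  }
  vapply(names, grp, character(1), USE.NAMES = FALSE)
}
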