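# Hand-built fixtures and independent brute-force oracles used across the
# suite. Everything is constructed in code; nothing is read from disk.

# a small parsed sentence: "PrA phosphorylates PrB at SerC ."
tiny_sentence <- function() {
  toks <- tibble::tibble(
    id = paste0("t", 1:6),
    text = c("PrA", "phosphorylates", "PrB", "at", "SerC", "."),
    pos = c("NN", "VBZ", "NN", "IN", "NN", "."),
    start = c(0L, 4L, 19L, 23L, 26L, 31L),
    end = c(3L, 18L, 22L, 25L, 30L, 32L))
  deps <- tibble::tibble(
    type = c("nsubj", "dobj", "prep_at", "punct"),
    governor = c("t2", "t2", "t2", "t2"),
    dependent = c("t1", "t3", "t5", "t6"))
  sentence_graph("s1", "PrA phosphorylates PrB at SerC .",
                 tokens = toks, dependencies = deps)
}

# demo scheme restricted so every phenomenon is surface-determined (no
# multi-site events, used where perfect separability is asserted)
separable_scheme <- function() {
  s <- demo_scheme()
  i <- match("Binding", s$events$type)
  args <- s$events$arguments[[i]]
  s$events$arguments[[i]] <- args[args$role != "Site", , drop = FALSE]
  s$events$overall_max[i] <- 2L
  annotation_scheme(s$entity_types, s$events, s$relations, s$modifiers,
                    s$targets)
}

gen_corpus <- function(n = 10, seed = 1, ...) {
  generate_corpus(generator_spec(n_documents = n, seed = seed, ...))
}

roundtrip_st <- function(st_doc, parses, scheme) {
  out <- write_st_document(st_doc)
  d2 <- read_st_document(out$txt, out$a1, out$a2, id = st_doc$id)
  gd <- suppressWarnings(st_to_graph(d2, parses))
  graph_to_st(gd, scheme)
}

# independent breadth-first enumeration of all shortest undirected paths
# (the oracle for the igraph-backed implementation)
bf_all_shortest_paths <- function(t1, t2, sentence) {
  dep <- sentence$dependencies
  nbr <- function(u) {
    fwd <- which(dep$governor == u)
    rev <- which(dep$dependent == u)
    data.frame(to = c(dep$dependent[fwd], dep$governor[rev]),
               lab = c(dep$type[fwd], dep$type[rev]),
               dir = c(rep("F", length(fwd)), rep("R", length(rev))),
               stringsAsFactors = FALSE)
  }
  if (identical(t1, t2)) return(list(list(tokens = t1, labels = character())))
  paths <- list(list(tokens = t1, labels = character(), dirs = character()))
  found <- list()
  depth <- 0L
  # plain breadth-first simple-path enumeration; stops at the first depth
  # that reaches the target, so exactly the shortest paths are returned
  while (!length(found) && length(paths) && depth < nrow(sentence$tokens)) {
    depth <- depth + 1L
    nxt <- list()
    for (p in paths) {
      u <- p$tokens[length(p$tokens)]
      nb <- nbr(u)
      for (r in seq_len(nrow(nb))) {
        v <- nb$to[r]
        if (v %in% p$tokens) next
        q <- list(tokens = c(p$tokens, v),
                  labels = c(p$labels, nb$lab[r]),
                  dirs = c(p$dirs, nb$dir[r]))
        if (v == t2) found[[length(found) + 1]] <- q
        else nxt[[length(nxt) + 1]] <- q
      }
    }
    paths <- nxt
  }
  found
}

# brute-force edge-candidate oracle: all ordered pairs minus scheme-invalid
# ones, with undirected-only pairs kept once (document order)
bf_edge_candidates <- function(entities, scheme) {
  n <- nrow(entities)
  out <- list()
  und <- scheme$relations$type[!scheme$relations$directed]
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    ta <- entities$type[a]; tb <- entities$type[b]
    types <- Filter(function(ty) is_valid_edge(scheme, ta, tb, ty),
                    unique(scheme$edge_rules$type))
    if (!length(types)) next
    if (all(types %in% und) && entities$start[a] > entities$start[b]) next
    out[[length(out) + 1]] <- c(entities$id[a], entities$id[b])
  }
  out
}

# brute-force unmerging oracle: full power set of the trigger's argument
# edges filtered by structural validity
bf_unmerging_subsets <- function(sentence, node_id, scheme) {
  itr <- sentence$interactions
  ent <- sentence$entities
  ttype <- ent$type[match(node_id, ent$id)]
  i <- match(ttype, scheme$events$type)
  if (is.na(i)) return(list())
  roles <- scheme$events$arguments[[i]]$role
  edges <- itr[itr$source == node_id & !itr$cross_sentence &
                 itr$type %in% roles, , drop = FALSE]
  edges <- edges[order(edges$id), , drop = FALSE]
  n <- nrow(edges)
  site_roles <- "Site"
  out <- list()
  for (mask in seq_len(2^n) - 1L) {
    pick <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    sub <- edges[pick, , drop = FALSE]
    # independent validity check: count every role, resolve site primaries
    view <- tibble::tibble(role = sub$type,
                           target_type = ent$type[match(sub$target, ent$id)],
                           site_primary_role = NA_character_)
    sp <- itr[itr$type == "SiteParent", , drop = FALSE]
    for (j in seq_len(nrow(sub))) {
      if (!is.na(sub$site_of[j]) && sub$site_of[j] %in% sub$id) {
        view$site_primary_role[j] <- sub$type[match(sub$site_of[j], sub$id)]
      } else if (sub$type[j] %in% site_roles) {
        parents <- sp$target[sp$source == sub$target[j]]
        hit <- which(!(sub$type %in% site_roles) & sub$target %in% parents)
        if (length(hit)) view$site_primary_role[j] <- sub$type[hit[1]]
      }
    }
    if (is_valid_event_structure(scheme, ttype, view)) {
      out[[length(out) + 1]] <- sort(sub$id)
    }
  }
  out
}

canon_subsets <- function(x) {
  sort(vapply(x, function(s) paste(s, collapse = ","), character(1)))
}

# fill a partial entity table to the full layer shape
complete_layer2 <- function(ent) {
  s <- sentence_graph("tmp", "x", entities = ent,
                      tokens = tibble::tibble(id = "t1", text = "x",
                                              pos = "NN", start = 0L,
                                              end = 1L))
  s$entities
}
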