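#' @title Corpus generation and controlled perturbation
#' @name generate
NULL

empty_manifest <- function() {
  c(documents = 0L, sentences = 0L, events = 0L, nested_events = 0L,
    shared_triggers = 0L, equiv_groups = 0L, cross_sentence_events = 0L,
    negations = 0L, speculations = 0L, site_args = 0L, relations = 0L)
}

# can a second, minimal event be added on the same trigger with a distinct
# entity target? (the shared-trigger phenomenon)
shareable_type <- function(scheme, type) {
  i <- match(type, scheme$events$type)
  cons <- scheme$events$arguments[[i]]
  if (!nrow(cons)) return(FALSE)
  ev_ty <- event_types(scheme)
  all(vapply(seq_len(nrow(cons)), function(j) {
    cons$min[j] == 0 || length(setdiff(cons$targets[[j]], ev_ty)) > 0
  }, logical(1))) && sum(cons$min) >= 1
}

mark_equiv_candidate <- function(plan, scheme) {
  given <- scheme_given_types(scheme)
  args <- plan$events[[1]]
  prim_taken <- unlist(lapply(args, function(a) a$primary))
  for (j in seq_along(args)) {
    a <- args[[j]]
    if (!a$is_site && identical(a$target$kind, "entity") &&
        a$target$given && !(j %in% prim_taken)) {
      plan$events[[1]][[j]]$target$alias <- TRUE
      return(plan)
    }
  }
  plan
}

mark_cross_candidate <- function(plan, registry) {
  args <- plan$events[[1]]
  prim_taken <- unlist(lapply(args, function(a) a$primary))
  for (j in seq_along(args)) {
    a <- args[[j]]
    if (!a$is_site && identical(a$target$kind, "entity") &&
        !isTRUE(a$target$alias) && !(j %in% prim_taken)) {
      hit <- which(registry$type == a$target$type)
      if (!length(hit)) next
      plan$events[[1]][[j]]$target <- list(kind = "cross",
                                           node = registry$id[hit[1]],
                                           type = a$target$type)
      return(plan)
    }
  }
  plan
}

#' Generate a synthetic gold-annotated corpus
#'
#' Deterministic given the spec's seed. Emits the graph corpus, the matched
#' standoff documents, the per-sentence parses required by [st_to_graph()],
#' and a manifest of realized structural phenomena (self-audited counts).
#'
#' @param spec A [generator_spec()].
#' @return List with elements `corpus` ([ig_corpus()]), `st_documents` (list
#'   of [st_document()]), `parses` (per document, the parse list for
#'   [st_to_graph()]), `manifest` (named integer vector), and `scheme` (the
#'   generating scheme).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  scheme <- spec$scheme
  ev_ty <- event_types(scheme)
  if (!length(ev_ty)) {
    stop("generator specification error: scheme defines no event types",
         call. = FALSE)
  }
  nestable <- any(vapply(seq_len(nrow(scheme$events)), function(i) {
    any(unlist(scheme$events$arguments[[i]]$targets) %in% ev_ty)
  }, logical(1)))
  if (spec$nesting_rate > 0 && !spec$saturate && !nestable) {
    stop("generator specification error: nesting requested but no event type takes event-valued arguments",
         call. = FALSE)
  }
  set.seed(spec$seed)
  gen <- new.env(parent = emptyenv())
  gen$manifest <- empty_manifest()
  gen$word_n <- 0L

  sat_plans <- if (spec$saturate) saturation_plans(scheme) else NULL
  n_docs <- if (spec$saturate) {
    ceiling(length(sat_plans) / spec$sentences_per_document)
  } else spec$n_documents
  sat_i <- 0L

  documents <- vector("list", n_docs)
  parses_per_doc <- vector("list", n_docs)
  topables <- ev_ty
  for (di in seq_len(n_docs)) {
    did <- paste0("d", di)
    registry <- tibble::tibble(id = character(), type = character())
    sentences <- list()
    equivs <- list()
    for (si in seq_len(spec$sentences_per_document)) {
      if (spec$saturate) {
        sat_i <- sat_i + 1L
        if (sat_i > length(sat_plans)) break
        plans <- sat_plans[sat_i]
      } else {
        n_ev <- sample2(spec$events_per_sentence)
        plans <- lapply(seq_len(n_ev), function(k) {
          plan_event_random(scheme, sample2(topables), spec, 0)
        })
        for (k in seq_along(plans)) {
          ty <- plans[[k]]$type
          if (ty %in% scheme$modifiers$negation &&
              stats::runif(1) < spec$negation_rate) {
            plans[[k]]$negation <- TRUE
          }
          if (ty %in% scheme$modifiers$speculation &&
              stats::runif(1) < spec$speculation_rate) {
            plans[[k]]$speculation <- TRUE
          }
          if (shareable_type(scheme, ty) &&
              stats::runif(1) < spec$shared_trigger_rate) {
            second <- plan_event_minimal(scheme, ty)
            plans[[k]]$events <- c(plans[[k]]$events, second$events)
          }
          if (stats::runif(1) < spec$equiv_rate) {
            plans[[k]] <- mark_equiv_candidate(plans[[k]], scheme)
          }
          if (si > 1 && nrow(registry) &&
              stats::runif(1) < spec$cross_sentence_rate) {
            plans[[k]] <- mark_cross_candidate(plans[[k]], registry)
          }
        }
      }
      sid <- paste0(did, ".s", si)
      out <- realize_sentence(plans, sid, gen)
      sentences[[length(sentences) + 1]] <- out$sentence
      equivs <- c(equivs, out$equivs)
      registry <- dplyr::bind_rows(registry, out$registry)
      gen$manifest[["sentences"]] <- gen$manifest[["sentences"]] + 1L
    }
    # document text: sentences joined by a single space
    off <- 0L
    for (k in seq_along(sentences)) {
      sentences[[k]]$offset <- off
      off <- off + nchar(sentences[[k]]$text) + 1L
    }
    text <- paste(vapply(sentences, function(s) s$text, character(1)),
                  collapse = " ")
    documents[[di]] <- ig_document(did, text, sentences, equivs = equivs)
    parses_per_doc[[di]] <- lapply(sentences, function(s) {
      list(offset = s$offset, text = s$text, tokens = s$tokens,
           dependencies = s$dependencies)
    })
    gen$manifest[["documents"]] <- gen$manifest[["documents"]] + 1L
  }
  documents <- Filter(function(d) length(d$sentences) > 0, documents)
  corpus <- ig_corpus(documents, set = "train")
  st_documents <- lapply(documents, graph_to_st, scheme = scheme)
  list(corpus = corpus, st_documents = st_documents,
       parses = parses_per_doc[seq_along(documents)],
       manifest = gen$manifest, scheme = scheme)
}

#' Inject controlled errors into standoff documents
#'
#' Produces a predicted-like copy of gold standoff documents with stated
#' counts of structural errors, for exercising the evaluator and the repair
#' rules. Supported operations: `retype_event` (event type swapped),
#' `invalid_role` (an argument's role renamed to an unlicensed one),
#' `drop_argument` (a required argument removed), `extra_argument` (an
#' argument duplicated beyond its role maximum), `duplicate_event` (an event
#' copied under a new id), `extra_siteparent` (an additional SiteParent
#' relation linking an existing site entity to a second protein).
#'
#' @param st_docs List of [st_document()]s (gold).
#' @param errors Named integer vector/list of operation counts; omitted
#'   operations default to zero. All zero returns the input unchanged.
#' @param scheme The [annotation_scheme()] (used to pick unlicensed values).
#' @return List with `documents` (perturbed copies) and `applied` (tibble of
#'   the operations actually applied).
#' @export
perturb_predictions <- function(st_docs, errors = list(), scheme = demo_scheme()) {
  want <- empty_errors()
  for (nm in names(errors)) {
    if (!nm %in% names(want)) {
      stop(sprintf("unknown perturbation '%s'", nm), call. = FALSE)
    }
    want[[nm]] <- as.integer(errors[[nm]])
  }
  applied <- list()
  note <- function(doc, op, detail) {
    applied[[length(applied) + 1]] <<- tibble::tibble(document = doc, op = op,
                                                      detail = detail)
  }
  ev_ty <- event_types(scheme)
  out <- lapply(st_docs, function(d) {
    ev <- d$events
    i <- 1L
    while (i <= nrow(ev)) {
      if (want[["retype_event"]] > 0 && length(ev_ty) > 1) {
        other <- setdiff(ev_ty, ev$type[i])[1]
        note(d$id, "retype_event", sprintf("%s: %s -> %s", ev$id[i],
                                           ev$type[i], other))
        ev$type[i] <- other
        want[["retype_event"]] <<- want[["retype_event"]] - 1L
      } else if (want[["invalid_role"]] > 0 && nrow(ev$args[[i]]) >= 1) {
        a <- ev$args[[i]]
        note(d$id, "invalid_role", sprintf("%s: %s -> BogusRole", ev$id[i],
                                           a$role[1]))
        a$role[1] <- "BogusRole"
        ev$args[[i]] <- a
        want[["invalid_role"]] <<- want[["invalid_role"]] - 1L
      } else if (want[["drop_argument"]] > 0 && nrow(ev$args[[i]]) >= 1) {
        a <- ev$args[[i]]
        note(d$id, "drop_argument", sprintf("%s: %s", ev$id[i], a$role[1]))
        ev$args[[i]] <- a[-1, , drop = FALSE]
        want[["drop_argument"]] <<- want[["drop_argument"]] - 1L
      } else if (want[["extra_argument"]] > 0 && nrow(ev$args[[i]]) >= 1) {
        a <- ev$args[[i]]
        extra <- a[1, , drop = FALSE]
        extra$role <- paste0(role_base(extra$role),
                             sum(role_base(a$role) == role_base(extra$role)) + 1L)
        note(d$id, "extra_argument", sprintf("%s: +%s", ev$id[i], extra$role))
        ev$args[[i]] <- dplyr::bind_rows(a, extra)
        want[["extra_argument"]] <<- want[["extra_argument"]] - 1L
      } else if (want[["duplicate_event"]] > 0) {
        dup <- ev[i, , drop = FALSE]
        dup$id <- paste0(dup$id, "dup")
        note(d$id, "duplicate_event", sprintf("%s duplicated", ev$id[i]))
        ev <- dplyr::bind_rows(ev, dup)
        want[["duplicate_event"]] <<- want[["duplicate_event"]] - 1L
      }
      i <- i + 1L
    }
    d$events <- ev
    if (want[["extra_siteparent"]] > 0) {
      sites <- d$entities$id[d$entities$type == "Entity"]
      prots <- d$entities$id[d$entities$type == "Protein"]
      if (length(sites) && length(prots) >= 2) {
        existing <- unlist(lapply(d$relations$args, function(a) a$target))
        new_prot <- setdiff(prots, existing)
        if (length(new_prot)) {
          d$relations <- dplyr::bind_rows(d$relations, tibble::tibble(
            id = paste0("Rsp", nrow(d$relations) + 1L), type = "SiteParent",
            args = list(tibble::tibble(role = c("Arg1", "Arg2"),
                                       target = c(sites[1], new_prot[1])))))
          note(d$id, "extra_siteparent",
               sprintf("%s -> %s", sites[1], new_prot[1]))
          want[["extra_siteparent"]] <<- want[["extra_siteparent"]] - 1L
        }
      }
    }
    d
  })
  list(documents = out,
       applied = if (length(applied)) dplyr::bind_rows(applied) else
         tibble::tibble(document = character(), op = character(),
                        detail = character()))
}

empty_errors <- function() {
  c(retype_event = 0L, invalid_role = 0L, drop_argument = 0L,
    extra_argument = 0L, duplicate_event = 0L, extra_siteparent = 0L)
}
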