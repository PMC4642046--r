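#' @title Synthetic gold-annotated corpora
#' @description Template-based generation of small, fully annotated event
#'   corpora with controllable structure: nested events, shared triggers,
#'   Site/SiteParent structures, equivalence groups, negation/speculation
#'   modifiers and (optionally) cross-sentence arguments. Sentences are
#'   subject-verb-object realizations with simple projective dependency
#'   parses, so every pipeline component is testable without external data.
#'   A saturation mode realizes every constraint boundary of the generating
#'   scheme at least once, which makes the scheme exactly recoverable by
#'   [learn_scheme()].
#' @name synthetic
NULL

#' A small GENIA-flavoured demonstration scheme
#'
#' Protein is a given entity; Entity is a predicted site span; four event
#' types exercise required/optional arguments, multiple Themes, Sites with
#' Theme as primary, and event-valued (nested) arguments; SiteParent links
#' site entities to their proteins; negation and speculation attach to all
#' event types.
#'
#' @return An [annotation_scheme()].
#' @export
demo_scheme <- function() {
  ev <- dplyr::bind_rows(
    tibble::tibble(type = "Gene_expression", overall_min = 1L, overall_max = 1L,
                   arguments = list(arg_constraint("Theme", 1, 1, "Protein"))),
    tibble::tibble(type = "Phosphorylation", overall_min = 1L, overall_max = 3L,
                   arguments = list(dplyr::bind_rows(
                     arg_constraint("Cause", 0, 1, "Protein"),
                     arg_constraint("Site", 0, 1, "Entity", "Theme"),
                     arg_constraint("Theme", 1, 1, "Protein")))),
    tibble::tibble(type = "Binding", overall_min = 1L, overall_max = 4L,
                   arguments = list(dplyr::bind_rows(
                     arg_constraint("Site", 0, 2, "Entity", "Theme"),
                     arg_constraint("Theme", 1, 2, "Protein")))),
    tibble::tibble(type = "Regulation", overall_min = 1L, overall_max = 2L,
                   arguments = list(dplyr::bind_rows(
                     arg_constraint("Cause", 0, 1, "Protein"),
                     arg_constraint("Theme", 1, 1,
                                    c("Protein", "Gene_expression",
                                      "Phosphorylation", "Binding",
                                      "Regulation"))))))
  rel <- tibble::tibble(type = "SiteParent", directed = TRUE,
                        end1_role = "Arg1", end2_role = "Arg2",
                        end1_types = list("Entity"), end2_types = list("Protein"))
  annotation_scheme(
    entity_types = c("Entity", "Protein"),
    events = ev, relations = rel,
    modifiers = list(
      negation = c("Binding", "Gene_expression", "Phosphorylation", "Regulation"),
      speculation = c("Binding", "Gene_expression", "Phosphorylation", "Regulation")),
    targets = list(
      entities = c("Binding", "Entity", "Gene_expression", "Phosphorylation",
                   "Regulation"),
      interactions = c("Cause", "Site", "SiteParent", "Theme")))
}

# per-type surface realizations for the demo scheme; unknown types fall back
# to a synthetic verb
demo_trigger_words <- c(
  Gene_expression = "expression", Phosphorylation = "phosphorylates",
  Binding = "binds", Regulation = "regulates")
demo_trigger_pos <- c(
  Gene_expression = "NN", Phosphorylation = "VBZ", Binding = "VBZ",
  Regulation = "VBZ")

trigger_word_for <- function(type) {
  if (type %in% names(demo_trigger_words)) demo_trigger_words[[type]]
  else paste0("x", tolower(gsub("[^A-Za-z]", "", type)))
}
trigger_pos_for <- function(type) {
  if (type %in% names(demo_trigger_pos)) demo_trigger_pos[[type]] else "VBZ"
}

#' A random annotation scheme for recovery experiments
#'
#' Draws a scheme with 2--4 event types over a small entity inventory:
#' required Theme arguments (max 1--2), optional Cause arguments, optional
#' Site arguments (primary role Theme, target Entity, with a SiteParent
#' relation), occasional zero-argument event types, event-valued Theme
#' targets, random modifier target sets, and an optional directed
#' Association relation between given entity types.
#'
#' @param seed Integer seed; the draw is fully determined by it.
#' @return An [annotation_scheme()].
#' @export
random_scheme <- function(seed) {
  set.seed(seed)
  ents <- "Protein"
  if (stats::runif(1) < 0.5) ents <- c(ents, "Chemical")
  n_ev <- sample(2:4, 1)
  ev_names <- paste0("Ev", LETTERS[seq_len(n_ev)])
  use_site <- logical(n_ev)
  zero_arg <- stats::runif(n_ev) < 0.2
  zero_arg[1] <- FALSE   # keep at least one event with arguments
  rows <- list()
  for (i in seq_len(n_ev)) {
    ty <- ev_names[i]
    if (zero_arg[i]) {
      rows[[i]] <- tibble::tibble(
        type = ty, overall_min = 0L, overall_max = 0L,
        arguments = list(arg_constraint(character(), integer(), integer(),
                                        character())[0, ]))
      next
    }
    theme_max <- sample(1:2, 1)
    theme_targets <- unique(c("Protein",
                              if (stats::runif(1) < 0.4 && i > 1)
                                sample(ev_names[seq_len(i - 1)], 1)))
    args <- arg_constraint("Theme", 1, theme_max, theme_targets)
    if (stats::runif(1) < 0.6) {
      args <- dplyr::bind_rows(
        arg_constraint("Cause", 0, 1, sample(ents, 1)), args)
    }
    if (stats::runif(1) < 0.4) {
      use_site[i] <- TRUE
      args <- dplyr::bind_rows(
        args, arg_constraint("Site", 0, 1, "Entity", "Theme"))
    }
    args <- args[order(args$role), , drop = FALSE]
    rows[[i]] <- tibble::tibble(type = ty, overall_min = sum(args$min),
                                overall_max = sum(args$max),
                                arguments = list(args))
  }
  if (any(use_site)) ents <- c(ents, "Entity")
  rel <- NULL
  if (any(use_site)) {
    rel <- tibble::tibble(type = "SiteParent", directed = TRUE,
                          end1_role = "Arg1", end2_role = "Arg2",
                          end1_types = list("Entity"),
                          end2_types = list("Protein"))
  }
  if (stats::runif(1) < 0.4 && length(setdiff(ents, "Entity")) >= 1) {
    given_ents <- setdiff(ents, "Entity")
    assoc <- tibble::tibble(type = "Association", directed = TRUE,
                            end1_role = "Arg1", end2_role = "Arg2",
                            end1_types = list(given_ents),
                            end2_types = list(given_ents[length(given_ents)]))
    rel <- if (is.null(rel)) assoc else dplyr::bind_rows(rel, assoc)
  }
  pick_targets <- function() {
    n <- sample(0:length(ev_names), 1)
    if (n == 0) character() else sort(sample(ev_names, n))
  }
  annotation_scheme(
    entity_types = sort(ents),
    events = dplyr::bind_rows(rows),
    relations = rel,
    modifiers = list(negation = pick_targets(), speculation = pick_targets()),
    targets = list(
      entities = sort(c(ev_names, intersect("Entity", ents))),
      interactions = sort(unique(c(
        unlist(lapply(rows, function(r) r$arguments[[1]]$role)),
        if (!is.null(rel)) rel$type)))))
}

#' Generator settings for a synthetic corpus
#'
#' The defaults are the package's reference study conditions: small
#' multi-sentence documents over [demo_scheme()] with moderate rates of
#' nesting, shared triggers, Sites, equivalence groups and modifiers, and no
#' cross-sentence arguments (so an all-oracle run can reconstruct every
#' event).
#'
#' @param scheme Generating [annotation_scheme()].
#' @param n_documents,sentences_per_document Corpus size.
#' @param events_per_sentence Vector of candidate counts sampled per sentence.
#' @param nesting_rate Probability an event-capable argument slot nests a
#'   child event.
#' @param shared_trigger_rate Probability a top-level event receives a second
#'   event on the same trigger.
#' @param equiv_rate Probability a suitable argument protein receives an
#'   equivalent alias mention.
#' @param site_rate Probability an optional Site argument slot is filled.
#' @param optional_rate Probability any other optional argument slot is filled.
#' @param cross_sentence_rate Probability a top-level event's first required
#'   argument is retargeted to an entity of a preceding sentence.
#' @param negation_rate,speculation_rate Per-trigger modifier probabilities
#'   (applied only to types the scheme licenses).
#' @param seed Integer seed; generation is fully determined by it.
#' @param saturate When `TRUE`, ignore the rates and deterministically
#'   realize every constraint boundary of the scheme at least once.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(scheme = demo_scheme(), n_documents = 10,
                           sentences_per_document = 2,
                           events_per_sentence = c(1, 2),
                           nesting_rate = 0.25, shared_trigger_rate = 0.15,
                           equiv_rate = 0.1, site_rate = 0.3,
                           optional_rate = 0.35, cross_sentence_rate = 0,
                           negation_rate = 0.1, speculation_rate = 0.1,
                           seed = 1, saturate = FALSE) {
  rates <- c(nesting_rate = nesting_rate,
             shared_trigger_rate = shared_trigger_rate,
             equiv_rate = equiv_rate, site_rate = site_rate,
             optional_rate = optional_rate,
             cross_sentence_rate = cross_sentence_rate,
             negation_rate = negation_rate, speculation_rate = speculation_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("generator rates must lie in [0,1]", call. = FALSE)
  }
  structure(list(scheme = scheme, n_documents = n_documents,
                 sentences_per_document = sentences_per_document,
                 events_per_sentence = events_per_sentence,
                 nesting_rate = nesting_rate,
                 shared_trigger_rate = shared_trigger_rate,
                 equiv_rate = equiv_rate, site_rate = site_rate,
                 optional_rate = optional_rate,
                 cross_sentence_rate = cross_sentence_rate,
                 negation_rate = negation_rate,
                 speculation_rate = speculation_rate,
                 seed = seed, saturate = saturate),
            class = "generator_spec")
}

# ---- plan construction ----------------------------------------------------
# an event plan:   list(type, events = list(arg lists), negation, speculation)
# an arg:          list(role, target (entity plan / event plan / cross ref),
#                       is_site, primary = index of primary arg in same list)
# an entity plan:  list(kind = "entity", type, given, alias = TRUE/FALSE)
# a cross ref:     list(kind = "cross", node, type)

scheme_given_types <- function(scheme) {
  setdiff(scheme$entity_types, scheme$targets$entities)
}

plan_entity <- function(type, given) {
  list(kind = "entity", type = type, given = given, alias = FALSE)
}

plan_event_random <- function(scheme, type, spec, depth) {
  def <- scheme$events[match(type, scheme$events$type), ]
  cons <- def$arguments[[1]]
  args <- list()
  budget <- def$overall_max
  ev_ty <- event_types(scheme)
  # non-site roles first so sites can point at a realized primary
  ord <- order(lengths(cons$site_primary) > 0, cons$role)
  for (j in ord) {
    ro <- cons$role[j]
    is_site <- length(cons$site_primary[[j]]) > 0
    p_fill <- if (is_site) spec$site_rate else spec$optional_rate
    extra <- sum(stats::runif(max(cons$max[j] - cons$min[j], 0)) < p_fill)
    count <- min(cons$min[j] + extra, budget - sum(cons$min[cons$role != ro]))
    count <- max(count, cons$min[j])
    for (k in seq_len(count)) {
      if (is_site) {
        prim_roles <- cons$site_primary[[j]]
        prim_idx <- which(vapply(args, function(a)
          a$role %in% prim_roles && identical(a$target$kind, "entity") &&
            is.na(a$primary), logical(1)))
        prim_idx <- setdiff(prim_idx,
                            unlist(lapply(args, function(a) a$primary)))
        if (!length(prim_idx)) next
        args[[length(args) + 1]] <- list(
          role = ro, target = plan_entity(sample(cons$targets[[j]], 1), FALSE),
          is_site = TRUE, primary = prim_idx[1])
      } else {
        tgts <- cons$targets[[j]]
        ev_tgts <- intersect(tgts, ev_ty)
        ent_tgts <- setdiff(tgts, ev_ty)
        nest <- length(ev_tgts) > 0 && depth < 2 &&
          (length(ent_tgts) == 0 || stats::runif(1) < spec$nesting_rate)
        target <- if (nest) {
          plan_event_random(scheme, sample2(ev_tgts), spec, depth + 1)
        } else {
          ty <- sample2(ent_tgts)
          plan_entity(ty, ty %in% scheme_given_types(scheme))
        }
        args[[length(args) + 1]] <- list(role = ro, target = target,
                                         is_site = FALSE, primary = NA_integer_)
      }
    }
  }
  list(type = type, events = list(args), negation = FALSE, speculation = FALSE)
}

sample2 <- function(x) if (length(x) == 1) x else sample(x, 1)

# minimal valid instance of an event type (required roles only, entity
# targets preferred, nested children at their own minimum)
plan_event_minimal <- function(scheme, type, depth = 0) {
  def <- scheme$events[match(type, scheme$events$type), ]
  cons <- def$arguments[[1]]
  args <- list()
  ev_ty <- event_types(scheme)
  for (j in seq_len(nrow(cons))) {
    for (k in seq_len(cons$min[j])) {
      tgts <- cons$targets[[j]]
      ent_tgts <- setdiff(tgts, ev_ty)
      target <- if (length(ent_tgts)) {
        plan_entity(ent_tgts[1], ent_tgts[1] %in% scheme_given_types(scheme))
      } else {
        plan_event_minimal(scheme, tgts[1], depth + 1)
      }
      args[[length(args) + 1]] <- list(role = cons$role[j], target = target,
                                       is_site = FALSE, primary = NA_integer_)
    }
  }
  list(type = type, events = list(args), negation = FALSE, speculation = FALSE)
}

# saturation: the plans that realize every boundary of the scheme
saturation_plans <- function(scheme) {
  plans <- list()
  ev_ty <- event_types(scheme)
  given <- scheme_given_types(scheme)
  mk_entity <- function(ty) plan_entity(ty, ty %in% given)
  mk_target <- function(ty, depth = 0) {
    if (ty %in% ev_ty) plan_event_minimal(scheme, ty, depth + 1) else mk_entity(ty)
  }
  for (i in seq_len(nrow(scheme$events))) {
    ty <- scheme$events$type[i]
    cons <- scheme$events$arguments[[i]]
    # all-minimum instance (also realizes zero-argument events)
    plans[[length(plans) + 1]] <- plan_event_minimal(scheme, ty)
    if (!nrow(cons)) next
    # all-maximum instance, avoiding sites (added separately with explicit
    # primaries) when their primary would be missing
    args <- list()
    site_prim_roles <- unique(unlist(cons$site_primary))
    for (j in seq_len(nrow(cons))) {
      if (length(cons$site_primary[[j]])) next
      tgts <- cons$targets[[j]]
      if (cons$role[j] %in% site_prim_roles) {
        # a site will want this argument as its primary, which requires an
        # entity-valued target
        ent_tg <- setdiff(tgts, ev_ty)
        if (length(ent_tg)) tgts <- ent_tg
      }
      for (k in seq_len(cons$max[j])) {
        args[[length(args) + 1]] <- list(
          role = cons$role[j], target = mk_target(tgts[1]),
          is_site = FALSE, primary = NA_integer_)
      }
    }
    for (j in which(lengths(cons$site_primary) > 0)) {
      for (k in seq_len(cons$max[j])) {
        prim_roles <- cons$site_primary[[j]]
        prim_idx <- which(vapply(args, function(a)
          a$role %in% prim_roles && identical(a$target$kind, "entity"),
          logical(1)))
        taken <- unlist(lapply(args, function(a) a$primary))
        prim_idx <- setdiff(prim_idx, taken)
        if (!length(prim_idx)) break
        args[[length(args) + 1]] <- list(
          role = cons$role[j], target = mk_entity(cons$targets[[j]][1]),
          is_site = TRUE, primary = prim_idx[1])
      }
    }
    if (length(args)) {
      plans[[length(plans) + 1]] <- list(type = ty, events = list(args),
                                         negation = FALSE, speculation = FALSE)
    }
    # per-role target-type coverage
    for (j in seq_len(nrow(cons))) {
      is_site <- length(cons$site_primary[[j]]) > 0
      for (tg in cons$targets[[j]]) {
        base <- plan_event_minimal(scheme, ty)
        args <- base$events[[1]]
        if (is_site) {
          prim_roles <- cons$site_primary[[j]]
          prim_idx <- which(vapply(args, function(a)
            a$role %in% prim_roles && identical(a$target$kind, "entity"),
            logical(1)))
          if (!length(prim_idx)) next
          args[[length(args) + 1]] <- list(role = cons$role[j],
                                           target = mk_entity(tg),
                                           is_site = TRUE,
                                           primary = prim_idx[1])
        } else {
          hit <- which(vapply(args, function(a) a$role == cons$role[j],
                              logical(1)))
          slot <- list(role = cons$role[j], target = mk_target(tg),
                       is_site = FALSE, primary = NA_integer_)
          if (length(hit)) args[[hit[1]]] <- slot
          else if (length(args) + 1 <= scheme$events$overall_max[i]) {
            args[[length(args) + 1]] <- slot
          } else next
        }
        base$events[[1]] <- args
        plans[[length(plans) + 1]] <- base
      }
      # site primary-role coverage beyond the first listed primary
      if (is_site && length(cons$site_primary[[j]]) > 1) {
        for (pr in cons$site_primary[[j]][-1]) {
          base <- plan_event_minimal(scheme, ty)
          args <- base$events[[1]]
          prim_idx <- which(vapply(args, function(a)
            a$role == pr && identical(a$target$kind, "entity"), logical(1)))
          if (!length(prim_idx)) {
            # primary role is optional: add one entity-valued occurrence
            pj <- match(pr, cons$role)
            ent_tg <- setdiff(cons$targets[[pj]], ev_ty)
            if (!length(ent_tg)) next
            args[[length(args) + 1]] <- list(role = pr,
                                             target = mk_entity(ent_tg[1]),
                                             is_site = FALSE,
                                             primary = NA_integer_)
            prim_idx <- length(args)
          }
          args[[length(args) + 1]] <- list(role = cons$role[j],
                                           target = mk_entity(cons$targets[[j]][1]),
                                           is_site = TRUE,
                                           primary = prim_idx[1])
          base$events[[1]] <- args
          plans[[length(plans) + 1]] <- base
        }
      }
    }
  }
  # modifier coverage
  for (kind in c("negation", "speculation")) {
    for (ty in intersect(scheme$modifiers[[kind]], ev_ty)) {
      p <- plan_event_minimal(scheme, ty)
      p[[kind]] <- TRUE
      plans[[length(plans) + 1]] <- p
    }
  }
  # standalone mention per entity type (so pure entities are observed)
  for (ty in scheme$entity_types) {
    plans[[length(plans) + 1]] <- list(kind = "mention",
                                       entity = mk_entity(ty))
  }
  # relation coverage (SiteParent arises with the sites above)
  for (i in seq_len(nrow(scheme$relations))) {
    r <- scheme$relations[i, ]
    if (r$type == "SiteParent") next
    e1s <- r$end1_types[[1]]; e2s <- r$end2_types[[1]]
    combos <- unique(rbind(
      data.frame(a = e1s, b = e2s[1], stringsAsFactors = FALSE),
      data.frame(a = e1s[1], b = e2s, stringsAsFactors = FALSE)))
    for (k in seq_len(nrow(combos))) {
      plans[[length(plans) + 1]] <- list(
        kind = "relation", type = r$type,
        end1_role = r$end1_role, end2_role = r$end2_role,
        e1 = mk_entity(combos$a[k]), e2 = mk_entity(combos$b[k]))
    }
  }
  plans
}
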