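#' @title Content-based comparison of standoff documents
#' @description Standoff ids are arbitrary, so documents are compared on
#'   content signatures: entities by (type, span), events by their recursive
#'   structure, and — because equivalence groups are expanded into
#'   individual events on load and collapsed again on write — event sets are
#'   compared after expansion over equivalence members.
#' @name compare
NULL

st_entity_sig <- function(d) {
  e <- d$entities
  sort(sprintf("%s|%d|%d|%s", e$type, e$start, e$end,
               ifelse(e$given, "g", "p")))
}

#' Recursive event signatures of a standoff document
#'
#' One content signature per event — type, trigger span, and recursively
#' signed arguments with roles — expanded over equivalence groups. Two
#' documents annotate the same events iff their signature sets are equal;
#' the event-level evaluator matches on exactly these.
#'
#' @param d An [st_document()].
#' @param expand_equivs Expand arguments over equivalence-group members.
#' @return Sorted character vector of signatures.
#' @export
st_event_sigs <- function(d, expand_equivs = TRUE) {
  ev <- d$events
  if (!nrow(ev)) return(character())
  e <- d$entities
  ent_sig <- stats::setNames(sprintf("%s@%d-%d", e$type, e$start, e$end), e$id)
  alts <- stats::setNames(as.list(e$id), e$id)
  if (expand_equivs) {
    for (g in d$equivs) for (m in g) alts[[m]] <- g
  }
  sigs <- list()   # event id -> character vector of expanded signatures
  for (eid in topo_event_order(ev)) {
    i <- match(eid, ev$id)
    args <- ev$args[[i]]
    trig_sig <- ent_sig[[ev$trigger[i]]]
    if (is.null(args) || !nrow(args)) {
      sigs[[eid]] <- sprintf("%s(%s)", ev$type[i], trig_sig)
      next
    }
    base <- role_base(args$role)
    alt_per_arg <- lapply(seq_len(nrow(args)), function(j) {
      tgt <- args$target[j]
      if (tgt %in% ev$id) sigs[[tgt]] %||% character()
      else unname(ent_sig[unlist(alts[[tgt]])])
    })
    if (any(lengths(alt_per_arg) == 0)) { sigs[[eid]] <- character(); next }
    idx <- expand.grid(lapply(alt_per_arg, seq_along))
    sigs[[eid]] <- vapply(seq_len(nrow(idx)), function(r) {
      parts <- vapply(seq_along(alt_per_arg), function(j)
        paste0(base[j], ":", alt_per_arg[[j]][[idx[r, j]]]), character(1))
      sprintf("%s(%s)[%s]", ev$type[i], trig_sig,
              paste(sort(parts), collapse = ","))
    }, character(1))
  }
  sort(unique(unlist(sigs[ev$id])))
}

st_relation_sigs <- function(d) {
  rl <- d$relations
  if (!nrow(rl)) return(character())
  e <- d$entities
  ent_sig <- stats::setNames(sprintf("%s@%d-%d", e$type, e$start, e$end), e$id)
  sort(vapply(seq_len(nrow(rl)), function(i) {
    a <- rl$args[[i]]
    sprintf("%s[%s]", rl$type[i],
            paste(a$role, unname(ent_sig[a$target]), sep = ":", collapse = ","))
  }, character(1)))
}

st_modifier_sigs <- function(d) {
  md <- d$modifiers
  if (!nrow(md)) return(character())
  # modifier signature: kind + trigger-level anchor (type and span of the
  # modified event's trigger)
  ev <- d$events
  e <- d$entities
  ent_sig <- stats::setNames(sprintf("%s@%d-%d", e$type, e$start, e$end), e$id)
  trig <- stats::setNames(ev$trigger, ev$id)
  ty <- stats::setNames(ev$type, ev$id)
  sort(sprintf("%s|%s(%s)", tolower(md$kind), ty[md$target],
               ent_sig[trig[md$target]]))
}

#' Are two standoff documents equivalent up to id renumbering?
#'
#' Compares text, entity signatures, expanded event signatures (equivalence
#' groups expanded on both sides, so load-time expansion followed by
#' write-time collapsing is an identity on this surface), relation
#' signatures, and modifier signatures.
#'
#' @param a,b [st_document()]s.
#' @return Logical scalar.
#' @export
st_documents_equivalent <- function(a, b) {
  identical(a$text, b$text) &&
    identical(st_entity_sig(a), st_entity_sig(b)) &&
    identical(st_event_sigs(a), st_event_sigs(b)) &&
    identical(st_relation_sigs(a), st_relation_sigs(b)) &&
    identical(st_modifier_sigs(a), st_modifier_sigs(b))
}

#' Which events of a document are reachable within sentence boundaries?
#'
#' The pipeline builds classification examples only inside sentences, so
#' events with a cross-sentence argument — or resting on such an event —
#' cannot be extracted. Their count gives the closed-form performance
#' ceiling of an all-oracle run.
#'
#' @param doc An [ig_document()].
#' @return Tibble with columns `event` (membership id) and `reachable`.
#' @export
reachable_events <- function(doc) {
  itr_all <- dplyr::bind_rows(lapply(doc$sentences, function(s) s$interactions))
  mem_all <- dplyr::bind_rows(lapply(doc$sentences, function(s) s$events))
  if (!nrow(mem_all)) {
    return(tibble::tibble(event = character(), reachable = logical()))
  }
  reach <- stats::setNames(rep(NA, nrow(mem_all)), mem_all$id)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(mem_all))) {
      mid <- mem_all$id[i]
      if (!is.na(reach[[mid]])) next
      a <- mem_all$args[[i]]
      if (is.null(a) || !nrow(a)) { reach[[mid]] <- TRUE; changed <- TRUE; next }
      k <- match(a$interaction, itr_all$id)
      if (any(itr_all$cross_sentence[k])) {
        reach[[mid]] <- FALSE; changed <- TRUE; next
      }
      kids <- a$target_event[!is.na(a$target_event)]
      if (!length(kids)) { reach[[mid]] <- TRUE; changed <- TRUE; next }
      vals <- reach[kids]
      if (any(!vals, na.rm = TRUE)) { reach[[mid]] <- FALSE; changed <- TRUE }
      else if (!any(is.na(vals))) { reach[[mid]] <- TRUE; changed <- TRUE }
    }
    if (!changed) break
  }
  reach[is.na(reach)] <- FALSE   # cycles cannot be emitted
  tibble::tibble(event = mem_all$id, reachable = unname(reach[mem_all$id]))
}
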