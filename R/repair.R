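#' @title Deterministic repair of structurally invalid events
#' @description Mirrors the consistent manual procedure used to satisfy a
#'   strict structural validator without inspecting the offending text: an
#'   invalid argument is renamed to a missing required role when both
#'   conditions hold, otherwise removed; an event that cannot be repaired is
#'   removed; and events pointing to removed events are removed recursively.
#' @name repair
NULL

# argument view of one standoff event against a scheme: base roles, target
# types, and site primary roles via suffix pairing
st_event_arg_view <- function(args, type_of) {
  if (is.null(args) || !nrow(args)) {
    return(fast_tbl(role = character(), target_type = character(),
                          site_primary_role = character()))
  }
  base <- role_base(args$role)
  prim <- pair_site_primaries(args$role)
  fast_tbl(
    role = base,
    target_type = unname(type_of[args$target]),
    site_primary_role = ifelse(is.na(prim), NA_character_, base[prim]))
}

st_type_map <- function(d) {
  c(stats::setNames(d$entities$type, d$entities$id),
    stats::setNames(d$events$type, d$events$id))
}

st_event_valid <- function(scheme, ev_type, view) {
  ev_type %in% scheme$events$type &&
    !any(is.na(view$target_type)) &&
    is_valid_event_structure(scheme, ev_type, view)
}

# indices of arguments that make the event invalid: unknown role, unlicensed
# target type, occurrences beyond the role maximum, or a Site-like argument
# with a missing/unlicensed primary role
invalid_arg_indices <- function(scheme, ev_type, view) {
  i <- match(ev_type, scheme$events$type)
  if (is.na(i)) return(seq_len(nrow(view)))
  cons <- scheme$events$arguments[[i]]
  bad <- logical(nrow(view))
  for (j in seq_len(nrow(view))) {
    cj <- match(view$role[j], cons$role)
    if (is.na(cj)) { bad[j] <- TRUE; next }
    if (is.na(view$target_type[j]) ||
        !(view$target_type[j] %in% cons$targets[[cj]])) { bad[j] <- TRUE; next }
    sp <- cons$site_primary[[cj]]
    if (length(sp)) {
      pr <- view$site_primary_role[j]
      if (is.na(pr) || !(pr %in% sp)) bad[j] <- TRUE
    }
  }
  # occurrences beyond the per-role maximum (later ones are the extras)
  for (cj in seq_len(nrow(cons))) {
    k <- which(view$role == cons$role[cj] & !bad)
    if (length(k) > cons$max[cj]) bad[k[-seq_len(cons$max[cj])]] <- TRUE
  }
  which(bad)
}

missing_required_roles <- function(scheme, ev_type, view) {
  i <- match(ev_type, scheme$events$type)
  if (is.na(i)) return(character())
  cons <- scheme$events$arguments[[i]]
  counts <- vapply(cons$role, function(r) sum(view$role == r), integer(1))
  sort(cons$role[counts < cons$min])
}

renumber_roles <- function(args) {
  if (!nrow(args)) return(args)
  base <- role_base(args$role)
  counts <- integer()
  args$role <- vapply(seq_along(base), function(j) {
    b <- base[j]
    counts[b] <<- (if (is.na(counts[b])) 0L else counts[b]) + 1L
    if (counts[b] == 1L) b else paste0(b, counts[b])
  }, character(1))
  args
}

#' Validate a standoff document against a scheme and repair it
#'
#' Applies, per invalid event and in order: (1) if exactly one argument is
#' invalid and a required argument is missing, rename the invalid argument's
#' role to the missing one; (2) otherwise remove the invalid arguments;
#' (3) if the event is still invalid, remove it. Finally events referencing
#' removed events are removed, recursively. The result always validates
#' cleanly against the scheme.
#'
#' @param d An [st_document()].
#' @param scheme An [annotation_scheme()].
#' @return List with elements `document` (the repaired [st_document()]) and
#'   `log` (tibble `event`, `action`, `detail`; zero rows iff `d` was
#'   already valid).
#' @export
validate_and_repair <- function(d, scheme) {
  log <- list()
  note <- function(event, action, detail) {
    log[[length(log) + 1]] <<- fast_tbl(event = event, action = action,
                                              detail = detail)
  }
  ev <- d$events
  removed <- character()
  if (nrow(ev)) {
    type_of <- st_type_map(d)
    keep <- rep(TRUE, nrow(ev))
    for (i in seq_len(nrow(ev))) {
      ety <- ev$type[i]
      if (!(ety %in% scheme$events$type)) {
        keep[i] <- FALSE
        note(ev$id[i], "remove_event", sprintf("unknown event type '%s'", ety))
        next
      }
      args <- ev$args[[i]]
      view <- st_event_arg_view(args, type_of)
      if (st_event_valid(scheme, ety, view)) next
      bad <- invalid_arg_indices(scheme, ety, view)
      miss <- missing_required_roles(scheme, ety, view)
      if (length(bad) == 1 && length(miss) >= 1) {
        old <- view$role[bad]
        args$role[bad] <- miss[1]
        note(ev$id[i], "rename_argument",
             sprintf("'%s' -> '%s'", old, miss[1]))
        args <- renumber_roles(args)
        view <- st_event_arg_view(args, type_of)
        bad <- invalid_arg_indices(scheme, ety, view)
      }
      if (length(bad) && !st_event_valid(scheme, ety, view)) {
        note(ev$id[i], "remove_argument",
             paste(args$role[bad], collapse = ", "))
        args <- renumber_roles(args[-bad, , drop = FALSE])
        view <- st_event_arg_view(args, type_of)
      }
      if (!st_event_valid(scheme, ety, view)) {
        keep[i] <- FALSE
        note(ev$id[i], "remove_event", "not repairable")
      } else {
        ev$args[[i]] <- args
      }
    }
    removed <- ev$id[!keep]
    ev <- ev[keep, , drop = FALSE]
    # recursive removal of events pointing at removed events
    repeat {
      if (!nrow(ev)) break
      refs_removed <- vapply(ev$args, function(a)
        any(a$target %in% removed), logical(1))
      if (!any(refs_removed)) break
      for (i in which(refs_removed)) {
        note(ev$id[i], "remove_event", "references a removed event")
      }
      removed <- c(removed, ev$id[refs_removed])
      ev <- ev[!refs_removed, , drop = FALSE]
    }
  }
  md <- d$modifiers
  if (nrow(md)) {
    gone <- md$target %in% removed
    for (i in which(gone)) {
      note(md$id[i], "remove_modifier", "its event was removed")
    }
    md <- md[!gone, , drop = FALSE]
  }
  out <- d
  out$events <- ev
  out$modifiers <- md
  list(document = out,
       log = if (length(log)) dplyr::bind_rows(log) else
         fast_tbl(event = character(), action = character(),
                        detail = character()))
}

#' Is a standoff document structurally valid under a scheme?
#'
#' Convenience wrapper: `TRUE` iff [validate_and_repair()] would leave the
#' document untouched.
#'
#' @inheritParams validate_and_repair
#' @return Logical scalar.
#' @export
st_is_valid <- function(d, scheme) {
  nrow(validate_and_repair(d, scheme)$log) == 0
}
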