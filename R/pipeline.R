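#' @title The event extraction pipeline
#' @description Orchestrates the step sequence entity detection → recall
#'   adjustment → edge detection → unmerging → modifier detection over
#'   interaction-graph corpora, with training, prediction, micro-averaged
#'   evaluation and component ablation against the always-correct oracle.
#'   Downstream steps are trained on gold upstream annotation; at prediction
#'   time each step consumes the previous step's output.
#' @name pipeline
NULL

pipeline_steps <- c("entity", "edge", "unmerging", "modifier")

#' Pipeline configuration
#'
#' @param adapter Trainable [classifier_adapter()] used for every step.
#' @param lambda Default regularization for non-tuned steps.
#' @param lambda_grid Regularization grid for step-level tuning (log scale).
#' @param beta_grid Recall-adjustment grid for the entity step.
#' @param objective `"event"` tunes the entity step and beta against
#'   end-to-end event F on the development set; `"step"` against entity-step
#'   micro-F.
#' @param max_subsets Cap on unmerging subset enumeration per trigger.
#' @param seed Integer seed for all stochastic components.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(adapter = adapter_glmnet(),
                            lambda = 1e-3,
                            lambda_grid = 10^seq(-3, 0),
                            beta_grid = c(0.4, 0.6, 0.8, 1),
                            objective = c("event", "step"),
                            max_subsets = 1024L,
                            seed = 1L) {
  structure(list(adapter = adapter, lambda = lambda,
                 lambda_grid = lambda_grid, beta_grid = beta_grid,
                 objective = match.arg(objective),
                 max_subsets = max_subsets, seed = as.integer(seed)),
            class = "pipeline_config")
}

build_step_examples <- function(corpus, scheme, step, max_subsets = 1024L) {
  rows <- lapply(gather_sentences(corpus), function(s) {
    switch(step,
           entity = build_entity_examples(s, scheme),
           edge = build_edge_examples(s, scheme),
           unmerging = build_unmerging_examples(s, scheme,
                                                max_subsets = max_subsets),
           modifier = build_modifier_examples(s, scheme))
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) empty_examples() else out
}

#' Train the full pipeline
#'
#' Learns the annotation scheme from the union of the training and
#' development corpora, builds gold examples per step, trains each step's
#' classifier (step-level grid search on development micro-F), then tunes
#' the entity step's regularization jointly with the recall-adjustment
#' parameter against the configured objective.
#'
#' @param train,devel [ig_corpus()] objects with gold annotation.
#' @param config A [pipeline_config()].
#' @return An `event_pipeline` bundle: scheme, per-step models, `beta` and
#'   the tuning log.
#' @export
train_pipeline <- function(train, devel, config = pipeline_config()) {
  if (!length(devel$documents)) {
    stop("tuning requires a non-empty development corpus", call. = FALSE)
  }
  scheme <- learn_scheme(list(train, devel))
  tr_ex <- lapply(stats::setNames(pipeline_steps, pipeline_steps),
                  function(st) build_step_examples(train, scheme, st,
                                                   config$max_subsets))
  dv_ex <- lapply(stats::setNames(pipeline_steps, pipeline_steps),
                  function(st) build_step_examples(devel, scheme, st,
                                                   config$max_subsets))
  grid <- lapply(config$lambda_grid, function(l) list(lambda = l))
  neg_of <- c(entity = "neg", edge = "neg", unmerging = "neg",
              modifier = "none")
  models <- list()
  tuning <- list()
  for (st in c("edge", "unmerging", "modifier")) {
    if (!nrow(tr_ex[[st]])) {
      models[[st]] <- NULL
      next
    }
    tn <- tune_parameters(config$adapter, tr_ex[[st]], dv_ex[[st]],
                          param_grid = grid, betas = 1,
                          neg_class = neg_of[[st]], seed = config$seed)
    models[[st]] <- tn$model
    tuning[[st]] <- tn$results
  }
  # entity step: regularization and beta tuned together against the
  # configured objective
  ent_space <- feature_space(tr_ex$entity)
  if (config$objective == "step") {
    tn <- tune_parameters(config$adapter, tr_ex$entity, dv_ex$entity,
                          param_grid = grid, betas = config$beta_grid,
                          neg_class = "neg", seed = config$seed)
    models$entity <- tn$model
    beta <- tn$best_beta
    tuning$entity <- tn$results
  } else {
    gold_st <- lapply(devel$documents, graph_to_st, scheme = scheme)
    rows <- list(); best <- NULL
    for (pi in seq_along(grid)) {
      model <- train_classifier(config$adapter, tr_ex$entity,
                                params = grid[[pi]], space = ent_space,
                                seed = config$seed)
      for (beta in config$beta_grid) {
        cand <- structure(list(scheme = scheme,
                               models = c(models, list(entity = model)),
                               beta = beta, config = config),
                          class = "event_pipeline")
        pred <- predict_corpus(devel, cand)
        sc <- glance(evaluate_micro_f(pred$st_documents, gold_st))$f
        rows[[length(rows) + 1]] <- tibble::tibble(
          param_index = pi, beta = beta, reg = grid[[pi]]$lambda, score = sc)
        if (is.null(best) || sc > best$score ||
            (sc == best$score && beta > best$beta) ||
            (sc == best$score && beta == best$beta &&
               grid[[pi]]$lambda < best$reg)) {
          best <- list(score = sc, beta = beta, reg = grid[[pi]]$lambda,
                       model = model)
        }
      }
    }
    models$entity <- best$model
    beta <- best$beta
    tuning$entity <- dplyr::bind_rows(rows)
  }
  structure(list(scheme = scheme, models = models, beta = beta,
                 config = config, tuning = tuning),
            class = "event_pipeline")
}

#' @export
print.event_pipeline <- function(x, ...) {
  cat(sprintf("<event_pipeline> %d event types, beta = %.2f, steps: %s\n",
              nrow(x$scheme$events), x$beta,
              paste(names(x$models), collapse = ", ")))
  invisible(x)
}

#' @export
glance.event_pipeline <- function(x, ...) {
  tibble::tibble(
    event_types = nrow(x$scheme$events),
    entity_types = length(x$scheme$entity_types),
    relation_types = nrow(x$scheme$relations),
    beta = x$beta,
    features_entity = length(x$models$entity$space$names %||% character()),
    features_edge = length(x$models$edge$space$names %||% character()))
}

#' Persist / restore a trained pipeline bundle
#'
#' The bundle directory holds the scheme as readable text alongside the
#' serialized models and tuning log.
#'
#' @param bundle An `event_pipeline`.
#' @param dir Bundle directory.
#' @return `save_bundle`: `dir` invisibly. `load_bundle`: the bundle.
#' @export
save_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(serialize_scheme(bundle$scheme), file.path(dir, "scheme.txt"),
             sep = "")
  saveRDS(bundle, file.path(dir, "bundle.rds"))
  invisible(dir)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(dir) {
  readRDS(file.path(dir, "bundle.rds"))
}

# ---- prediction -----------------------------------------------------------

# matching predicted graph elements to gold, for oracle labelling: nodes by
# (head token, type), edges by mapped endpoints and type
match_nodes_to_gold <- function(entities, gold) {
  key <- function(e) paste(e$head, e$type, sep = "|")
  gold_ids <- stats::setNames(gold$id, key(gold))
  stats::setNames(unname(gold_ids[key(entities)]), entities$id)
}

label_entity_examples <- function(examples, gold_sentence) {
  ent <- gold_sentence$entities
  examples$gold <- vapply(examples$anchor, function(a) {
    merged_class(ent$type[!ent$given & ent$head == a$token])
  }, character(1))
  examples
}

label_edge_examples <- function(examples, work_sentence, gold_sentence,
                                scheme) {
  node_map <- match_nodes_to_gold(work_sentence$entities,
                                  gold_sentence$entities)
  itr <- gold_sentence$interactions
  itr <- itr[!itr$cross_sentence, , drop = FALSE]
  und <- scheme$relations$type[!scheme$relations$directed]
  examples$gold <- vapply(examples$anchor, function(a) {
    ga <- node_map[[a$source]]; gb <- node_map[[a$target]]
    if (is.na(ga) || is.na(gb)) return("neg")
    hit <- itr$type[itr$source == ga & itr$target == gb]
    back <- itr$type[itr$source == gb & itr$target == ga & itr$type %in% und]
    merged_class(c(hit, back))
  }, character(1))
  examples
}

label_unmerging_examples <- function(examples, work_sentence, gold_sentence) {
  node_map <- match_nodes_to_gold(work_sentence$entities,
                                  gold_sentence$entities)
  witr <- work_sentence$interactions
  gitr <- gold_sentence$interactions
  edge_map <- stats::setNames(rep(NA_character_, nrow(witr)), witr$id)
  for (i in seq_len(nrow(witr))) {
    gs <- node_map[[witr$source[i]]]; gt <- node_map[[witr$target[i]]]
    if (is.na(gs) || is.na(gt)) next
    hit <- gitr$id[gitr$source == gs & gitr$target == gt &
                     gitr$type == witr$type[i]]
    if (length(hit)) edge_map[[witr$id[i]]] <- hit[1]
  }
  gold_sets <- lapply(seq_len(nrow(gold_sentence$events)), function(i)
    sort(gold_sentence$events$args[[i]]$interaction))
  gold_trig <- gold_sentence$events$trigger
  examples$gold <- vapply(examples$anchor, function(a) {
    gt <- node_map[[a$trigger]]
    if (is.na(gt)) return("neg")
    mapped <- edge_map[a$edges]
    if (anyNA(mapped) && length(a$edges)) return("neg")
    mapped <- sort(unname(mapped))
    hit <- any(vapply(seq_along(gold_sets), function(g)
      gold_trig[g] == gt && identical(gold_sets[[g]], mapped), logical(1)))
    if (hit) "pos" else "neg"
  }, character(1))
  examples
}

label_modifier_examples <- function(examples, work_sentence, gold_sentence) {
  node_map <- match_nodes_to_gold(work_sentence$entities,
                                  gold_sentence$entities)
  gent <- gold_sentence$entities
  examples$gold <- vapply(examples$anchor, function(a) {
    gt <- node_map[[a$trigger]]
    if (is.na(gt)) return("none")
    i <- match(gt, gent$id)
    kinds <- c(if (gent$negation[i]) "negation",
               if (gent$speculation[i]) "speculation")
    if (!length(kinds)) "none" else paste(kinds, collapse = "---")
  }, character(1))
  examples
}

step_predictions <- function(step, examples, bundle, oracle_steps) {
  if (step %in% oracle_steps) return(oracle_classify(examples))
  model <- bundle$models[[step]]
  if (is.null(model)) {
    neg <- if (step == "modifier") "none" else "neg"
    return(tibble::tibble(id = examples$id, pred = rep(neg, nrow(examples)),
                          scores = rep(list(stats::setNames(1, neg)),
                                       nrow(examples))))
  }
  predict_classifier(model, examples)
}

predict_sentence <- function(gold_sentence, bundle, oracle_steps,
                             counters) {
  scheme <- bundle$scheme
  s <- gold_sentence
  work <- sentence_graph(s$id, s$text, tokens = s$tokens,
                         dependencies = s$dependencies,
                         entities = s$entities[s$entities$given, , drop = FALSE],
                         offset = s$offset)
  # entity step + recall adjustment -----------------------------------------
  ex <- build_entity_examples(work, scheme, labeled = FALSE)
  if (nrow(ex)) {
    ex <- label_entity_examples(ex, s)
    preds <- step_predictions("entity", ex, bundle, oracle_steps)
    if (!("entity" %in% oracle_steps)) {
      preds <- adjust_recall(preds, bundle$beta, neg_class = "neg")
    }
    pos <- which(preds$pred != "neg")
    if (length(pos)) {
      tok <- work$tokens
      new_rows <- list()
      for (r in pos) {
        a <- ex$anchor[[r]]
        ti <- match(a$token, tok$id)
        for (ty in split_merged_class(preds$pred[r])) {
          counters$pe <- counters$pe + 1L
          new_rows[[length(new_rows) + 1]] <- tibble::tibble(
            id = paste0(s$id, ".p", counters$pe), type = ty,
            start = tok$start[ti], end = tok$end[ti], text = tok$text[ti],
            head = a$token, given = FALSE,
            event = ty %in% scheme$events$type,
            negation = FALSE, speculation = FALSE)
        }
      }
      work$entities <- dplyr::bind_rows(work$entities,
                                        dplyr::bind_rows(new_rows))
    }
  }
  # edge step ----------------------------------------------------------------
  ex <- build_edge_examples(work, scheme, labeled = FALSE)
  if (nrow(ex)) {
    ex <- label_edge_examples(ex, work, s, scheme)
    preds <- step_predictions("edge", ex, bundle, oracle_steps)
    pos <- which(preds$pred != "neg")
    if (length(pos)) {
      ent_types <- stats::setNames(work$entities$type, work$entities$id)
      rel_def <- bundle$scheme$relations
      new_rows <- list()
      for (r in pos) {
        a <- ex$anchor[[r]]
        for (ty in split_merged_class(preds$pred[r])) {
          counters$pi <- counters$pi + 1L
          ri <- match(ty, rel_def$type)
          is_rel <- !is.na(ri)
          new_rows[[length(new_rows) + 1]] <- tibble::tibble(
            id = paste0(s$id, ".pi", counters$pi), type = ty,
            source = a$source, target = a$target,
            directed = if (is_rel) rel_def$directed[ri] else TRUE,
            event = !is_rel, given = FALSE, site_of = NA_character_,
            source_role = if (is_rel) rel_def$end1_role[ri] else NA_character_,
            target_role = if (is_rel) rel_def$end2_role[ri] else NA_character_,
            cross_sentence = FALSE)
        }
      }
      work$interactions <- dplyr::bind_rows(work$interactions,
                                            dplyr::bind_rows(new_rows))
    }
  }
  # unmerging step -----------------------------------------------------------
  ex <- build_unmerging_examples(work, scheme, labeled = FALSE,
                                 max_subsets = bundle$config$max_subsets %||% 1024L)
  kept_memberships <- empty_events()
  if (nrow(ex)) {
    ex <- label_unmerging_examples(ex, work, s)
    preds <- step_predictions("unmerging", ex, bundle, oracle_steps)
    pos <- which(preds$pred == "pos")
    if (length(pos)) {
      rows <- lapply(pos, function(r) {
        a <- ex$anchor[[r]]
        counters$ev <- counters$ev + 1L
        tibble::tibble(id = paste0(s$id, ".pev", counters$ev),
                       trigger = a$trigger,
                       args = list(tibble::tibble(
                         interaction = a$edges,
                         target_event = rep(NA_character_,
                                            length(a$edges)))))
      })
      kept_memberships <- dplyr::bind_rows(rows)
    }
  }
  work$events <- kept_memberships
  # drop argument edges not used by any event, and predicted triggers left
  # without events (their dangling edges go with them)
  used_edges <- unique(unlist(lapply(kept_memberships$args,
                                     function(a) a$interaction)))
  itr <- work$interactions
  keep_itr <- !itr$event | itr$id %in% used_edges
  itr <- itr[keep_itr, , drop = FALSE]
  ent <- work$entities
  live_triggers <- unique(kept_memberships$trigger)
  keep_ent <- ent$given | !ent$event | ent$id %in% live_triggers
  # referenced non-event predicted entities stay only when an edge uses them
  referenced <- unique(c(itr$source, itr$target))
  keep_ent <- keep_ent & (ent$given | ent$id %in% c(referenced, live_triggers))
  ent <- ent[keep_ent, , drop = FALSE]
  itr <- itr[itr$source %in% ent$id & itr$target %in% ent$id, , drop = FALSE]
  work$entities <- ent
  work$interactions <- itr
  drop_args <- vapply(seq_len(nrow(work$events)), function(i)
    !all(work$events$args[[i]]$interaction %in% itr$id), logical(1))
  if (any(drop_args)) work$events <- work$events[!drop_args, , drop = FALSE]
  # modifier step ------------------------------------------------------------
  ex <- build_modifier_examples(work, scheme, labeled = FALSE)
  if (nrow(ex) && nrow(work$events)) {
    ex <- ex[vapply(ex$anchor, function(a)
      a$trigger %in% work$events$trigger, logical(1)), , drop = FALSE]
  } else {
    ex <- empty_examples()
  }
  if (nrow(ex)) {
    ex <- label_modifier_examples(ex, work, s)
    preds <- step_predictions("modifier", ex, bundle, oracle_steps)
    for (r in which(preds$pred != "none")) {
      a <- ex$anchor[[r]]
      i <- match(a$trigger, work$entities$id)
      kinds <- split_merged_class(preds$pred[r])
      if ("negation" %in% kinds) work$entities$negation[i] <- TRUE
      if ("speculation" %in% kinds) work$entities$speculation[i] <- TRUE
    }
  }
  work
}

#' Predict a corpus with a trained pipeline
#'
#' Applies the entity, recall-adjustment, edge, unmerging and modifier
#' steps to each sentence (starting from the given annotation only), then
#' converts each document back to the standoff format. Steps named in
#' `oracle_steps` are replaced by the always-correct classifier, which reads
#' the gold annotation carried by the input corpus.
#'
#' @param corpus An [ig_corpus()]; gold annotation is used only for oracle
#'   steps and ignored otherwise.
#' @param bundle An `event_pipeline` from [train_pipeline()] (for all-oracle
#'   runs, [oracle_bundle()] suffices).
#' @param oracle_steps Subset of
#'   `c("entity", "edge", "unmerging", "modifier")`.
#' @return List with `documents` (predicted [ig_document()]s) and
#'   `st_documents` (predicted [st_document()]s).
#' @export
predict_corpus <- function(corpus, bundle, oracle_steps = character()) {
  bad <- setdiff(oracle_steps, pipeline_steps)
  if (length(bad)) {
    stop(sprintf("unknown pipeline step(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  counters <- new.env(parent = emptyenv())
  docs <- lapply(corpus$documents, function(doc) {
    counters$pe <- 0L; counters$pi <- 0L; counters$ev <- 0L
    sentences <- lapply(doc$sentences, predict_sentence, bundle = bundle,
                        oracle_steps = oracle_steps, counters = counters)
    out <- ig_document(doc$id, doc$text, sentences, equivs = list())
    out
  })
  st_docs <- lapply(docs, graph_to_st, scheme = bundle$scheme)
  list(documents = docs, st_documents = st_docs)
}

#' An all-oracle pipeline bundle
#'
#' A bundle without trained models, for ablation baselines and ceiling
#' measurements: every step must then be named in `oracle_steps`.
#'
#' @param scheme An [annotation_scheme()].
#' @param max_subsets Unmerging enumeration cap.
#' @return An `event_pipeline`.
#' @export
oracle_bundle <- function(scheme, max_subsets = 1024L) {
  structure(list(scheme = scheme, models = list(), beta = 1,
                 config = list(max_subsets = max_subsets), tuning = list()),
            class = "event_pipeline")
}

# ---- evaluation -----------------------------------------------------------

#' Micro-averaged F-score evaluation
#'
#' Event-level mode (lists of [st_document()]s): events match on type,
#' trigger span and recursively matched arguments with roles (a child
#' mismatch fails the parent); equivalence groups are expanded before
#' matching. Example-level mode (two character vectors of classes):
#' micro-averaged over the positive classes. Percentages are reported to
#' two decimals.
#'
#' @param pred,gold Lists of [st_document()]s, or character class vectors.
#' @param neg_class Negative class label (example-level mode).
#' @return An `event_eval` object; see [tidy.event_eval()] and
#'   [glance.event_eval()].
#' @export
evaluate_micro_f <- function(pred, gold, neg_class = "neg") {
  if (is.character(pred)) {
    m <- example_micro_f(pred, gold, neg_class = neg_class)
    return(structure(list(
      mode = "example",
      per_class = tibble::tibble(class = "all-positive",
                                 matched = m$tp, spurious = m$fp,
                                 missed = m$fn),
      matched = m$tp, spurious = m$fp, missed = m$fn), class = "event_eval"))
  }
  if (inherits(pred, "st_document")) pred <- list(pred)
  if (inherits(gold, "st_document")) gold <- list(gold)
  per_doc <- lapply(seq_along(gold), function(i) {
    ps <- if (i <= length(pred)) st_event_sigs(pred[[i]]) else character()
    gs <- st_event_sigs(gold[[i]])
    tibble::tibble(sig = union(ps, gs),
                   in_pred = union(ps, gs) %in% ps,
                   in_gold = union(ps, gs) %in% gs)
  })
  all <- dplyr::bind_rows(per_doc)
  all$class <- sub("\\(.*$", "", all$sig)
  per_class <- dplyr::summarise(
    dplyr::group_by(all, .data$class),
    matched = sum(.data$in_pred & .data$in_gold),
    spurious = sum(.data$in_pred & !.data$in_gold),
    missed = sum(!.data$in_pred & .data$in_gold), .groups = "drop")
  structure(list(mode = "event", per_class = per_class,
                 matched = sum(per_class$matched),
                 spurious = sum(per_class$spurious),
                 missed = sum(per_class$missed)),
            class = "event_eval")
}

prf <- function(matched, spurious, missed) {
  p <- if (matched + spurious == 0) 0 else matched / (matched + spurious)
  r <- if (matched + missed == 0) 0 else matched / (matched + missed)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = round(100 * p, 2), recall = round(100 * r, 2),
    f = round(100 * f, 2))
}

#' @export
print.event_eval <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<event_eval %s> P %.2f / R %.2f / F %.2f (matched %d, spurious %d, missed %d)\n",
              x$mode, g$precision, g$recall, g$f, x$matched, x$spurious,
              x$missed))
  invisible(x)
}

#' Per-class precision/recall/F of an evaluation
#'
#' @param x An `event_eval`.
#' @param ... Unused.
#' @return Tibble with one row per class plus counts.
#' @export
tidy.event_eval <- function(x, ...) {
  pc <- x$per_class
  m <- t(vapply(seq_len(nrow(pc)), function(i)
    prf(pc$matched[i], pc$spurious[i], pc$missed[i]), numeric(3)))
  dplyr::bind_cols(pc, tibble::as_tibble(m))
}

#' Micro-averaged summary row of an evaluation
#'
#' @param x An `event_eval`.
#' @param ... Unused.
#' @return One-row tibble: counts and micro precision/recall/F percentages.
#' @export
glance.event_eval <- function(x, ...) {
  m <- prf(x$matched, x$spurious, x$missed)
  tibble::tibble(matched = x$matched, spurious = x$spurious,
                 missed = x$missed, precision = m[["precision"]],
                 recall = m[["recall"]], f = m[["f"]])
}

#' Bar chart of per-class F-scores
#'
#' @param object An `event_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.event_eval <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$f)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "F-score (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Component ablation with the always-correct classifier
#'
#' Re-runs prediction with named pipeline steps replaced by the oracle and
#' evaluates each run at event level against gold; the default rows mirror
#' the classic ablation layout (None, each single step, Entity+Edge, All).
#'
#' @param corpus Gold [ig_corpus()].
#' @param bundle An `event_pipeline`.
#' @param rows Named list of `oracle_steps` vectors, one per ablation row.
#' @return Tibble with one row per ablation setting of class `ablation_table`.
#' @export
ablate_components <- function(corpus, bundle,
                              rows = list(
                                None = character(),
                                Entity = "entity",
                                Edge = "edge",
                                Unmerging = "unmerging",
                                `Entity+Edge` = c("entity", "edge"),
                                All = c("entity", "edge", "unmerging",
                                        "modifier"))) {
  gold_st <- lapply(corpus$documents, graph_to_st, scheme = bundle$scheme)
  out <- lapply(names(rows), function(nm) {
    pred <- predict_corpus(corpus, bundle, oracle_steps = rows[[nm]])
    g <- glance(evaluate_micro_f(pred$st_documents, gold_st))
    dplyr::bind_cols(tibble::tibble(
      setting = nm, oracle_steps = paste(rows[[nm]], collapse = "+")), g)
  })
  structure(dplyr::bind_rows(out),
            class = c("ablation_table", class(tibble::tibble())))
}
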