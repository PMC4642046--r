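#' @title GraphViz dot export of sentence annotation
#' @description Renders a sentence's dependency parse and semantic
#'   annotation as a dot-language graph description for debugging: one node
#'   per token (text and part of speech), arcs for dependencies, boxes for
#'   entity nodes attached to their head tokens, and labelled arrows for
#'   interaction edges. Rendering to an image is left to an external dot
#'   processor; the contract here ends at valid, deterministic dot text.
#' @name visualize
NULL

dot_quote <- function(x) {
  paste0('"', gsub('"', '\\\\"', x), '"')
}

#' Rendering options for [to_dot()]
#'
#' @param show_parse,show_annotation Layer toggles; at least one must be on.
#' @param rankdir Graph direction (`"LR"` or `"TB"`).
#' @param colors Named fill colors for element kinds.
#' @return A `render_options` list.
#' @export
render_options <- function(show_parse = TRUE, show_annotation = TRUE,
                           rankdir = "LR",
                           colors = c(token = "white", given = "lightblue",
                                      event = "lightsalmon",
                                      entity = "lightyellow")) {
  if (!show_parse && !show_annotation) {
    stop("at least one of the parse and annotation layers must be enabled",
         call. = FALSE)
  }
  structure(list(show_parse = show_parse, show_annotation = show_annotation,
                 rankdir = rankdir, colors = colors),
            class = "render_options")
}

#' Render a sentence as dot text
#'
#' @param sentence A [sentence_graph()].
#' @param opts A [render_options()].
#' @return A single string of valid dot syntax; identical input yields
#'   identical text.
#' @export
to_dot <- function(sentence, opts = render_options()) {
  out <- c("digraph sentence {",
           sprintf("  rankdir=%s;", opts$rankdir),
           "  node [fontname=\"Helvetica\"];")
  tok <- sentence$tokens
  if (!nrow(tok)) {
    out <- c(out,
             sprintf("  empty [label=%s shape=plaintext];",
                     dot_quote(sprintf("(empty sentence %s)", sentence$id))),
             "}")
    return(paste0(paste(out, collapse = "\n"), "\n"))
  }
  for (i in seq_len(nrow(tok))) {
    out <- c(out, sprintf(
      "  %s [label=%s shape=ellipse style=filled fillcolor=%s];",
      dot_quote(tok$id[i]),
      dot_quote(sprintf("%s\\n%s", tok$text[i], tok$pos[i])),
      dot_quote(opts$colors[["token"]])))
  }
  # invisible chain keeps tokens in sentence order
  if (nrow(tok) > 1) {
    out <- c(out, sprintf("  %s [style=invis weight=100];",
                          paste(vapply(tok$id, dot_quote, character(1)),
                                collapse = " -> ")))
  }
  if (opts$show_parse) {
    dep <- sentence$dependencies
    for (i in seq_len(nrow(dep))) {
      out <- c(out, sprintf("  %s -> %s [label=%s color=gray40];",
                            dot_quote(dep$governor[i]),
                            dot_quote(dep$dependent[i]),
                            dot_quote(dep$type[i])))
    }
  }
  if (opts$show_annotation) {
    ent <- sentence$entities
    for (i in seq_len(nrow(ent))) {
      fill <- if (ent$event[i]) "event" else if (ent$given[i]) "given" else "entity"
      mods <- c(if (ent$negation[i]) "neg", if (ent$speculation[i]) "spec")
      label <- paste0(ent$type[i],
                      if (length(mods)) paste0(" [", paste(mods, collapse = ","), "]"))
      out <- c(out, sprintf("  %s [label=%s shape=box style=filled fillcolor=%s];",
                            dot_quote(ent$id[i]), dot_quote(label),
                            dot_quote(opts$colors[[fill]])),
               sprintf("  %s -> %s [style=dotted arrowhead=none];",
                       dot_quote(ent$id[i]), dot_quote(ent$head[i])))
    }
    itr <- sentence$interactions
    for (i in seq_len(nrow(itr))) {
      extra <- if (!is.na(itr$site_of[i])) " color=purple" else
        if (!itr$event[i]) " color=darkgreen" else ""
      tgt <- itr$target[i]
      if (!(tgt %in% ent$id)) next  # cross-sentence target lives elsewhere
      out <- c(out, sprintf("  %s -> %s [label=%s penwidth=1.5%s];",
                            dot_quote(itr$source[i]), dot_quote(tgt),
                            dot_quote(itr$type[i]), extra))
    }
  }
  out <- c(out, "}")
  paste0(paste(out, collapse = "\n"), "\n")
}
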