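#' Compile a schema into a decoding grammar
#'
#' Builds the context-free grammar of the template linearization language in a
#' form suitable for incremental one-token-lookahead parsing during decoding.
#' Terminal classes are the start tag and end tag of every template/slot name,
#' a free-text terminal covering every vocabulary token that is neither a
#' special tag nor EOS (the permissive decoding-phase definition of the
#' free-text non-terminal, which only has to avoid matches of `[start:` and
#' `[end:`), and EOS. The grammar accepts exactly the linearizations of
#' schema-conforming instances: grouped repetition of fillers, slots in
#' canonical order, at least one free-text token per textual filler. By
#' construction (distinct per-name tags, grouped canonical repetition) the
#' compiled grammar is deterministic under one-token lookahead, so no
#' backtracking is ever needed.
#'
#' @param schema A `template_schema`.
#' @param vocab A `vocabulary` containing both tags of every schema name.
#' @return An object of class `decoding_grammar`.
#' @export
build_decoding_grammar <- function(schema, vocab) {
  validate_schema(schema)
  check_vocab_covers(vocab, schema)
  names_all <- sort_c(unique(c(names(schema$templates), schema_slot_names(schema))))
  start_ids <- token_ids(vocab, vapply(names_all, start_tag, ""))
  end_ids <- token_ids(vocab, vapply(names_all, end_tag, ""))
  names(start_ids) <- names_all
  names(end_ids) <- names_all
  tag_ids <- c(start_ids, end_ids)
  free_ids <- setdiff(seq_len(vocab_size(vocab)) - 1L,
                      c(token_ids(vocab, vocab$special_tags), vocab$eos_id))
  if (length(free_ids) == 0L) {
    stopf("vocabulary has no free-text tokens: textual slots would be underivable")
  }
  # 0-based id -> terminal class ("start:N", "end:N", "FREE", "EOS")
  id_class <- rep("FREE", vocab_size(vocab))
  id_class[vocab$eos_id + 1L] <- "EOS"
  for (nm in names_all) {
    id_class[start_ids[[nm]] + 1L] <- paste0("start:", nm)
    id_class[end_ids[[nm]] + 1L] <- paste0("end:", nm)
  }
  # tags in the vocabulary that name nothing in the schema are inert: they are
  # special tokens, hence excluded from FREE, and no production mentions them
  structure(list(schema = schema, vocab = vocab,
                 start_ids = start_ids, end_ids = end_ids,
                 free_ids = free_ids, id_class = id_class),
            class = "decoding_grammar")
}

#' @export
print.decoding_grammar <- function(x, ...) {
  cat(sprintf("<decoding_grammar> root=%s, %d templates, |V|=%d (%d free-text tokens)\n",
              x$schema$root, length(x$schema$templates), vocab_size(x$vocab),
              length(x$free_ids)))
  invisible(x)
}

#' Export the compiled grammar as EBNF-style text
#'
#' Human-readable rendering of the productions, for inspection only.
#'
#' @param grammar A `decoding_grammar`.
#' @return Character vector, one production per element.
#' @export
grammar_to_ebnf <- function(grammar) {
  sch <- grammar$schema
  rules <- c(sprintf("document ::= %s EOS", sch$root),
             "POINT ::= FREE_TEXT_TOKEN+")
  for (tn in names(sch$templates)) {
    parts <- vapply(sch$templates[[tn]], function(s) {
      body <- if (s$kind == "textual") "POINT" else paste(s$templates, collapse = " | ")
      unit <- sprintf("(\"%s\" (%s) \"%s\")", start_tag(s$name), body, end_tag(s$name))
      mult <- if (is.infinite(s$max)) sprintf("{%d,}", s$min) else sprintf("{%d,%d}", s$min, as.integer(s$max))
      paste0(unit, mult)
    }, "")
    rules <- c(rules, sprintf("%s ::= \"%s\" %s \"%s\"", tn, start_tag(tn),
                              paste(parts, collapse = " "), end_tag(tn)))
  }
  rules
}

# ---- incremental parser state ----
#
# The state is a persistent stack of frames:
#   tpl  frame: template being derived; slot index currently filled; filler
#               count for that slot
#   text frame: inside a textual slot; number of free tokens consumed
#   tslot frame: inside a template-valued slot; whether its instance is done
# advancing returns a new state; old states stay valid (needed for lookahead
# probing and for the mask/accepted coherence guarantee).

new_parser_state <- function(grammar, stack, complete) {
  st <- list(grammar = grammar, stack = stack, complete = complete)
  st$accepted <- accepted_terminals(st)
  class(st) <- "parser_state"
  st
}

#' Initialize an incremental parser
#'
#' @param grammar A `decoding_grammar`.
#' @return A `parser_state` positioned at document start; the only accepted
#'   terminal is the start tag of the root template.
#' @export
init_parser <- function(grammar) {
  new_parser_state(grammar, list(), complete = FALSE)
}

#' @export
print.parser_state <- function(x, ...) {
  cat(sprintf("<parser_state> depth=%d complete=%s accepted={%s}\n",
              length(x$stack), x$complete,
              paste(utils::head(x$accepted, 8), collapse = ", ")))
  invisible(x)
}

# Accepted terminal classes of a state (character vector of
# "start:N"/"end:N"/"FREE"/"EOS").
accepted_terminals <- function(state) {
  g <- state$grammar
  sch <- g$schema
  if (state$complete) return("EOS")
  if (length(state$stack) == 0L) return(paste0("start:", sch$root))
  top <- state$stack[[length(state$stack)]]
  if (top$kind == "text") {
    acc <- "FREE"
    if (top$n >= 1L) acc <- c(acc, paste0("end:", top$slot))
    return(acc)
  }
  if (top$kind == "tslot") {
    if (top$done) return(paste0("end:", top$slot))
    return(paste0("start:", top$allowed))
  }
  # tpl frame
  slots <- sch$templates[[top$template]]
  acc <- character()
  i <- top$slot_idx
  cnt <- top$count
  if (i >= 1L && i <= length(slots) && cnt < slots[[i]]$max) {
    acc <- c(acc, paste0("start:", slots[[i]]$name))
  }
  # may move on past the current slot if its minimum is met
  can_leave <- i == 0L || cnt >= slots[[i]]$min
  if (can_leave) {
    j <- i + 1L
    while (j <= length(slots)) {
      if (slots[[j]]$max >= 1L) acc <- c(acc, paste0("start:", slots[[j]]$name))
      if (slots[[j]]$min > 0L) break
      j <- j + 1L
    }
    if (j > length(slots)) acc <- c(acc, paste0("end:", top$template))
  }
  unique(acc)
}

#' Advance the incremental parser by one token
#'
#' Feeds one vocabulary token. The token's terminal class must be in the
#' state's accepted set; feeding a non-accepted token is a hard error (a
#' decoder driving the parser must mask first). Returns the successor state;
#' `complete` becomes TRUE exactly when the root template has been closed.
#'
#' @param state A `parser_state`.
#' @param token_id 0-based token id.
#' @return The new `parser_state`.
#' @export
advance_parser <- function(state, token_id) {
  g <- state$grammar
  if (!is_count(token_id) || token_id >= vocab_size(g$vocab)) {
    stopf("token id out of range: %s", format(token_id))
  }
  cls <- g$id_class[token_id + 1L]
  if (!terminal_accepted(state, cls)) {
    stopf("token %d ('%s', class %s) is not accepted here; accepted: {%s}",
          token_id, token_surfaces(g$vocab, token_id), cls,
          paste(state$accepted, collapse = ", "),
          class = "gcdecode_advance_error")
  }
  stack <- state$stack
  sch <- g$schema
  if (cls == "EOS") {
    return(new_parser_state(g, stack, complete = TRUE))
  }
  if (cls == "FREE") {
    top <- stack[[length(stack)]]
    top$n <- top$n + 1L
    stack[[length(stack)]] <- top
    return(new_parser_state(g, stack, complete = FALSE))
  }
  name <- sub("^(start|end):", "", cls)
  is_start <- startsWith(cls, "start:")
  if (is_start) {
    if (length(stack) == 0L ||
        (stack[[length(stack)]]$kind == "tslot" && !stack[[length(stack)]]$done)) {
      # opening a template instance (root or inside a template-valued slot)
      stack[[length(stack) + 1L]] <- list(kind = "tpl", template = name,
                                          slot_idx = 0L, count = 0L)
      return(new_parser_state(g, stack, complete = FALSE))
    }
    # opening a filler of a slot of the template on top
    top <- stack[[length(stack)]]
    slots <- sch$templates[[top$template]]
    j <- match(name, vapply(slots, `[[`, "", "name"))
    if (j == top$slot_idx) top$count <- top$count + 1L
    else { top$slot_idx <- j; top$count <- 1L }
    stack[[length(stack)]] <- top
    sd <- slots[[j]]
    frame <- if (sd$kind == "textual") {
      list(kind = "text", slot = name, n = 0L)
    } else {
      list(kind = "tslot", slot = name, allowed = sd$templates, done = FALSE)
    }
    stack[[length(stack) + 1L]] <- frame
    return(new_parser_state(g, stack, complete = FALSE))
  }
  # end tag: closes either the slot on top or the template on top
  top <- stack[[length(stack)]]
  if (top$kind %in% c("text", "tslot")) {
    stack[[length(stack)]] <- NULL
    return(new_parser_state(g, stack, complete = FALSE))
  }
  # closing a template
  stack[[length(stack)]] <- NULL
  if (length(stack) == 0L) {
    return(new_parser_state(g, stack, complete = TRUE))
  }
  below <- stack[[length(stack)]]
  below$done <- TRUE
  stack[[length(stack)]] <- below
  new_parser_state(g, stack, complete = FALSE)
}

terminal_accepted <- function(state, cls) cls %in% state$accepted

#' Token ids currently accepted by a parser state
#'
#' The image of the accepted terminal classes in the vocabulary: tag terminals
#' map to their atomic tokens, the free-text terminal to every non-tag,
#' non-EOS token.
#'
#' @param state A `parser_state`.
#' @return Integer vector of 0-based token ids.
#' @export
accepted_token_ids <- function(state) {
  g <- state$grammar
  ids <- integer()
  for (cls in state$accepted) {
    if (cls == "FREE") ids <- c(ids, g$free_ids)
    else if (cls == "EOS") ids <- c(ids, g$vocab$eos_id)
    else if (startsWith(cls, "start:")) ids <- c(ids, g$start_ids[[sub("^start:", "", cls)]])
    else ids <- c(ids, g$end_ids[[sub("^end:", "", cls)]])
  }
  sort(unique(ids))
}

#' Vocabulary mask of the current parser state
#'
#' The additive mask applied to a token distribution before the argmax: 0 for
#' every token whose terminal class is currently accepted, -Inf otherwise.
#'
#' @param state A `parser_state`; must not be complete-and-exhausted (the set
#'   of accepted tokens must be non-empty).
#' @param vocab Optional `vocabulary`; defaults to the grammar's. Must agree
#'   in size with the grammar's vocabulary.
#' @return Numeric vector of length |V| over \{0, -Inf\}.
#' @export
vocabulary_mask <- function(state, vocab = NULL) {
  g <- state$grammar
  if (!is.null(vocab) && vocab_size(vocab) != vocab_size(g$vocab)) {
    stopf("mask vocabulary size %d does not match grammar vocabulary size %d",
          vocab_size(vocab), vocab_size(g$vocab))
  }
  ids <- accepted_token_ids(state)
  if (length(ids) == 0L) {
    stopf("no vocabulary token is accepted: grammar/vocabulary inconsistency")
  }
  mask <- rep(-Inf, vocab_size(g$vocab))
  mask[ids + 1L] <- 0
  mask
}
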