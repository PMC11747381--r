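#' Linearize a template instance to a flat tagged string
#'
#' Serializes the nested structure into a single string, wrapping every filler
#' in `[start:name]` / `[end:name]` tags. Slots are emitted in canonical (byte
#' lexicographic) order at every level; multiple fillers of one slot become
#' consecutive complete tag pairs; a template-valued filler nests the inner
#' instance's own tag pair inside the slot's pair. The result is a pure
#' function of the canonical instance.
#'
#' @param inst A `template_instance` conforming to `schema`.
#' @param schema A `template_schema`.
#' @return Character scalar.
#' @export
#' @examples
#' sch <- template_schema(list(Outcome = list(slot_def("hasObservedResult"))),
#'                        root = "Outcome")
#' x <- template_instance("Outcome",
#'        list(hasObservedResult = list("After 3 months of treatment...")))
#' linearize(x, sch)
linearize <- function(inst, schema) {
  validate_instance(inst, schema)
  linearize_unchecked(canonicalize(inst))
}

# Serialization core; assumes canonical order, performs no validation.
linearize_unchecked <- function(inst) {
  parts <- character()
  for (sn in names(inst$fillers)) {
    for (f in inst$fillers[[sn]]) {
      body <- if (is_text_filler(f)) f$text else linearize_unchecked(f$instance)
      parts <- c(parts, start_tag(sn), body, end_tag(sn))
    }
  }
  paste0(start_tag(inst$template), paste(parts, collapse = ""), end_tag(inst$template))
}

# ---- lexing ----

# Split a linearization into events: start/end tags and free-text chunks,
# each with its 1-based character offset.
lex_linearization <- function(text) {
  events <- list()
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    m <- regexpr("\\[(start|end):", rest)
    if (m == -1L) {
      events[[length(events) + 1L]] <- list(type = "text", value = rest, pos = pos)
      break
    }
    if (m > 1L) {
      events[[length(events) + 1L]] <-
        list(type = "text", value = substr(rest, 1L, m - 1L), pos = pos)
    }
    tag_start <- pos + as.integer(m) - 1L
    tail_s <- substr(text, tag_start, n)
    close_rel <- regexpr("]", tail_s, fixed = TRUE)
    if (close_rel == -1L) {
      parse_error("unterminated tag", tag_start)
    }
    tag <- substr(tail_s, 1L, as.integer(close_rel))
    mm <- regmatches(tag, regexec(tag_regex, tag, perl = TRUE))[[1]]
    if (length(mm) != 3L) parse_error(sprintf("malformed tag '%s'", tag), tag_start)
    events[[length(events) + 1L]] <-
      list(type = mm[2], value = mm[3], pos = tag_start)
    pos <- tag_start + nchar(tag)
  }
  events
}

parse_error <- function(msg, pos, expected = NULL) {
  stop(errorCondition(
    sprintf("syntax error at character %d: %s", pos, msg),
    pos = pos, expected = expected,
    class = c("gcdecode_parse_error", "gcdecode_error", "error", "condition")
  ))
}

# ---- strict (phase-2) parsing ----

#' Parse a linearization back into a template instance
#'
#' Strict structural parsing of a tag-delimited string: tags must be balanced,
#' properly nested, known to the schema, and in canonical grouped order;
#' filler multiplicities must respect the slot bounds; free text may occur
#' only inside textual slots, must be non-empty, and must segment under greedy
#' longest-match against the vocabulary (it is stored as the raw surface
#' string). Any violation raises a condition of class `gcdecode_parse_error`
#' carrying the character position.
#'
#' @param text Character scalar, the linearization.
#' @param schema A `template_schema`.
#' @param vocab A `vocabulary` covering the schema (see [check_vocab_covers()]).
#' @return The parsed, canonical `template_instance`.
#' @export
parse_linearization <- function(text, schema, vocab) {
  check_vocab_covers(vocab, schema)
  events <- lex_linearization(text)
  if (length(events) == 0L) parse_error("empty input", 1L)
  env <- new.env(parent = emptyenv())
  env$i <- 1L
  peek <- function() if (env$i <= length(events)) events[[env$i]] else NULL
  take <- function() { e <- peek(); env$i <- env$i + 1L; e }

  parse_template <- function() {
    e <- take()
    # caller guarantees e is start:<defined template>
    tn <- e$value
    slots <- schema$templates[[tn]]
    snames <- vapply(slots, `[[`, "", "name")
    cur <- 0L                     # index of slot currently being filled
    counts <- integer(length(slots))
    fillers <- stats::setNames(vector("list", length(slots)), snames)

    check_mins <- function(from, to, pos) {
      for (k in seq_len(length(slots))) {
        if (k >= from && k <= to && counts[k] < slots[[k]]$min) {
          parse_error(sprintf("template '%s': slot '%s' requires at least %d filler(s)",
                              tn, snames[k], slots[[k]]$min), pos)
        }
      }
    }

    repeat {
      e <- peek()
      if (is.null(e)) parse_error(sprintf("unexpected end of input inside template '%s'", tn),
                                  nchar_end(events))
      if (e$type == "text") {
        parse_error("free text outside a textual slot", e$pos)
      }
      if (e$type == "end") {
        if (e$value != tn) {
          parse_error(sprintf("end tag mismatch: expected %s but found %s",
                              end_tag(tn), end_tag(e$value)),
                      e$pos, expected = end_tag(tn))
        }
        check_mins(max(cur, 1L), length(slots), e$pos)
        take()
        return(template_instance(tn, Filter(Negate(is.null), fillers)))
      }
      # start tag: either a slot of this template or an error
      j <- match(e$value, snames)
      if (is.na(j)) {
        parse_error(sprintf("unexpected tag %s inside template '%s'",
                            start_tag(e$value), tn), e$pos)
      }
      if (j < cur) {
        parse_error(sprintf("slot '%s' out of canonical order in template '%s'",
                            e$value, tn), e$pos)
      }
      if (j > cur) check_mins(max(cur, 1L), j - 1L, e$pos)
      cur <- j
      if (counts[j] + 1L > slots[[j]]$max) {
        parse_error(sprintf("slot '%s' exceeds max_count %s", e$value,
                            format(slots[[j]]$max)), e$pos)
      }
      counts[j] <- counts[j] + 1L
      f <- parse_filler(slots[[j]])
      fillers[[j]] <- c(fillers[[j]], list(f))
    }
  }

  parse_filler <- function(sd) {
    open <- take()                 # start:<slot>
    if (sd$kind == "textual") {
      e <- peek()
      if (is.null(e) || e$type != "text") {
        parse_error(sprintf("textual slot '%s' requires at least one free-text token",
                            sd$name), if (is.null(e)) nchar_end(events) else e$pos)
      }
      take()
      tryCatch(tokenize_text(vocab, e$value),
               gcdecode_tokenize_error = function(err) {
                 parse_error(sprintf("slot '%s': %s", sd$name, conditionMessage(err)), e$pos)
               })
      close_slot(sd, open)
      text_filler(e$value)
    } else {
      e <- peek()
      if (is.null(e) || e$type != "start" || !e$value %in% sd$templates) {
        parse_error(sprintf("slot '%s' requires an instance of %s",
                            sd$name, paste(sd$templates, collapse = "|")),
                    if (is.null(e)) nchar_end(events) else e$pos)
      }
      inner <- parse_template()
      close_slot(sd, open)
      instance_filler(inner)
    }
  }

  close_slot <- function(sd, open) {
    e <- peek()
    if (is.null(e) || e$type != "end" || e$value != sd$name) {
      if (!is.null(e) && e$type == "end") {
        parse_error(sprintf("end tag mismatch: expected %s but found %s",
                            end_tag(sd$name), end_tag(e$value)),
                    e$pos, expected = end_tag(sd$name))
      }
      parse_error(sprintf("expected %s", end_tag(sd$name)),
                  if (is.null(e)) nchar_end(events) else e$pos,
                  expected = end_tag(sd$name))
    }
    take()
  }

  first <- peek()
  if (first$type != "start" || first$value != schema$root) {
    parse_error(sprintf("document must open with %s", start_tag(schema$root)),
                first$pos, expected = start_tag(schema$root))
  }
  if (is.null(schema$templates[[first$value]])) {
    parse_error(sprintf("unknown template '%s'", first$value), first$pos)
  }
  inst <- parse_template()
  trailing <- peek()
  if (!is.null(trailing)) parse_error("trailing content after root template", trailing$pos)
  canonicalize(inst)
}

nchar_end <- function(events) {
  last <- events[[length(events)]]
  last$pos + nchar(if (last$type == "text") last$value else start_tag(last$value))
}

#' Tokenize a full linearization into token ids
#'
#' Tags become their atomic special-token ids; free-text spans between tags
#' are segmented by greedy longest match ([tokenize_text()]). This is the
#' token sequence a decoder would have to emit to reproduce `text`.
#'
#' @param text Character scalar.
#' @param vocab A `vocabulary`.
#' @param append_eos Append the EOS token id.
#' @return Integer vector of 0-based token ids.
#' @export
tokenize_linearization <- function(text, vocab, append_eos = FALSE) {
  ids <- integer()
  for (e in lex_linearization(text)) {
    if (e$type == "text") {
      ids <- c(ids, tokenize_text(vocab, e$value))
    } else {
      tag <- if (e$type == "start") start_tag(e$value) else end_tag(e$value)
      ids <- c(ids, token_ids(vocab, tag))
    }
  }
  if (append_eos) ids <- c(ids, vocab$eos_id)
  ids
}
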