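#' Tag surface forms
#'
#' The linearization wraps every filler in `[start:name]` ... `[end:name]`.
#'
#' @param name Template or slot name.
#' @return Character scalar.
#' @export
start_tag <- function(name) paste0("[start:", name, "]")

#' @rdname start_tag
#' @export
end_tag <- function(name) paste0("[end:", name, "]")

tag_regex <- "^\\[(start|end):([^]\\[:\\s]+)\\]$"

is_tag_token <- function(tok) grepl(tag_regex, tok, perl = TRUE)

#' Construct a token vocabulary
#'
#' Token ids are 0-based positions in `tokens` (the convention of model
#' vocabularies). Special tag tokens of the form `[start:name]` / `[end:name]`
#' are treated as atomic single tokens; all remaining tokens except `eos` form
#' the free-text alphabet.
#'
#' @param tokens Character vector of unique token surfaces.
#' @param eos The end-of-sequence token; appended if not already present.
#' @return An object of class `vocabulary`.
#' @export
vocabulary <- function(tokens, eos = "</s>") {
  tokens <- as.character(tokens)
  if (!eos %in% tokens) tokens <- c(tokens, eos)
  if (anyDuplicated(tokens)) {
    stopf("duplicate token surfaces: %s",
          paste(unique(tokens[duplicated(tokens)]), collapse = ", "))
  }
  if (any(nchar(tokens) == 0L)) stopf("empty-string token not allowed")
  tags <- tokens[is_tag_token(tokens)]
  structure(list(tokens = tokens,
                 eos = eos,
                 eos_id = match(eos, tokens) - 1L,
                 special_tags = tags),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> %d tokens (%d special tags), eos=%s\n",
              length(x$tokens), length(x$special_tags), x$eos))
  invisible(x)
}

#' Vocabulary size
#' @param vocab A `vocabulary`.
#' @return Integer |V|.
#' @export
vocab_size <- function(vocab) length(vocab$tokens)

#' Map between token ids and surfaces
#'
#' Ids are 0-based. `token_ids` errors on unknown surfaces; `token_surfaces`
#' errors on out-of-range ids.
#'
#' @param vocab A `vocabulary`.
#' @param surfaces Character vector.
#' @return Integer / character vector.
#' @export
token_ids <- function(vocab, surfaces) {
  ids <- match(surfaces, vocab$tokens)
  if (anyNA(ids)) stopf("unknown token surface(s): %s",
                        paste(surfaces[is.na(ids)], collapse = ", "))
  ids - 1L
}

#' @rdname token_ids
#' @param ids Integer vector of 0-based token ids.
#' @export
token_surfaces <- function(vocab, ids) {
  if (length(ids) == 0L) return(character())
  if (any(ids < 0 | ids >= length(vocab$tokens))) stopf("token id out of range")
  vocab$tokens[ids + 1L]
}

#' Build a vocabulary covering a schema
#'
#' Adds the start/end tag of every template and slot name of `schema` as
#' special tokens (mirroring how such tags are added to a tokenizer
#' vocabulary), plus the supplied free-text tokens. With
#' `include_chars = TRUE` every single character occurring in `text_tokens` is
#' also a token, which guarantees that greedy longest-match segmentation of any
#' string over those characters succeeds.
#'
#' @param schema A `template_schema`.
#' @param text_tokens Character vector of free-text tokens (words); a space
#'   token is always included.
#' @param eos End-of-sequence token.
#' @param include_chars Add all single characters of `text_tokens`.
#' @return A `vocabulary` containing both tags of every schema name.
#' @export
make_vocabulary <- function(schema, text_tokens = character(), eos = "</s>",
                            include_chars = TRUE) {
  names_all <- sort_c(unique(c(names(schema$templates), schema_slot_names(schema))))
  tags <- c(vapply(names_all, start_tag, ""), vapply(names_all, end_tag, ""))
  text_tokens <- unique(c(text_tokens, " "))
  if (include_chars) {
    chars <- unique(unlist(strsplit(text_tokens, "", fixed = TRUE)))
    text_tokens <- unique(c(text_tokens, chars))
  }
  if (any(is_tag_token(text_tokens))) stopf("free-text tokens may not look like special tags")
  vocabulary(c(unname(tags), text_tokens), eos = eos)
}

#' Check that a vocabulary covers a schema's tags
#' @param vocab A `vocabulary`.
#' @param schema A `template_schema`.
#' @return TRUE invisibly; errors listing missing tags otherwise.
#' @export
check_vocab_covers <- function(vocab, schema) {
  names_all <- unique(c(names(schema$templates), schema_slot_names(schema)))
  need <- c(vapply(names_all, start_tag, ""), vapply(names_all, end_tag, ""))
  missing <- setdiff(need, vocab$tokens)
  if (length(missing)) {
    stopf("vocabulary is missing tag token(s): %s", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Greedy longest-match segmentation
#'
#' Segments `text` against the vocabulary by repeatedly taking the longest
#' token that prefixes the remaining input (ties impossible: surfaces are
#' unique). Special tag tokens and the EOS token never match inside free text.
#' Greedy matching is a committed choice: if at some position no token
#' prefixes the remainder, segmentation fails even if a different earlier
#' split would have succeeded.
#'
#' @param vocab A `vocabulary`.
#' @param text Character scalar.
#' @return Integer vector of 0-based token ids.
#' @export
#' @examples
#' v <- vocabulary(c("ab", "aba", "b"))
#' token_surfaces(v, tokenize_text(v, "abab"))  # "aba" "b"
tokenize_text <- function(vocab, text) {
  free <- setdiff(vocab$tokens, c(vocab$special_tags, vocab$eos))
  # order candidates by decreasing length so the first prefix hit is longest
  free <- free[order(-nchar(free))]
  ids <- integer()
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    hit <- NA_character_
    for (tok in free) {
      if (startsWith(rest, tok)) { hit <- tok; break }
    }
    if (is.na(hit)) {
      stopf("no vocabulary token matches text at character %d: %s", pos,
            substr(rest, 1, 20), class = "gcdecode_tokenize_error")
    }
    ids <- c(ids, match(hit, vocab$tokens) - 1L)
    pos <- pos + nchar(hit)
  }
  ids
}

#' Concatenate token surfaces back into a string
#' @param vocab A `vocabulary`.
#' @param ids 0-based token ids; the EOS token is dropped.
#' @return Character scalar.
#' @export
detokenize <- function(vocab, ids) {
  ids <- ids[ids != vocab$eos_id]
  paste(token_surfaces(vocab, ids), collapse = "")
}

#' Read and write vocabulary files
#'
#' JSON dialect: `{"eos": token, "tokens": [surface, ...]}`.
#'
#' @param path File path.
#' @return `read_vocabulary`: a `vocabulary`.
#' @export
read_vocabulary <- function(path) {
  if (!file.exists(path)) stopf("vocabulary file not found: %s", path)
  doc <- jsonlite::read_json(path)
  vocabulary(unlist(doc$tokens), eos = if (is.null(doc$eos)) "</s>" else doc$eos)
}

#' @rdname read_vocabulary
#' @param vocab A `vocabulary`.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(list(eos = vocab$eos, tokens = vocab$tokens), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
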