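#' Generative token distribution
#'
#' Numerically stable softmax of the model logits, the classical generative
#' distribution over the vocabulary.
#'
#' @param l Numeric vector of finite logits.
#' @return Probability vector of the same length (non-negative, sums to 1).
#' @export
gen_distribution <- function(l) {
  if (!is.numeric(l) || length(l) == 0L) stopf("logits must be a non-empty numeric vector")
  if (any(!is.finite(l))) stopf("logits contain NaN or infinite values")
  e <- exp(l - max(l))
  e / sum(e)
}

#' Mean cross-attention over heads
#'
#' Averages a heads-by-input-positions cross-attention matrix over heads.
#' Each head row must already be normalized (sum to 1), so the mean is itself
#' a distribution over input positions.
#'
#' @param C Numeric matrix, `heads x inputTokens`, non-negative, each row
#'   summing to 1 within 1e-6.
#' @return Numeric vector over input positions summing to 1.
#' @export
mean_head_attention <- function(C) {
  if (!is.matrix(C) || !is.numeric(C)) stopf("C must be a numeric matrix (heads x inputTokens)")
  if (any(C < 0)) stopf("attention values must be non-negative")
  rs <- rowSums(C)
  if (any(abs(rs - 1) > 1e-6)) {
    stopf("every attention head row must sum to 1 (max deviation %.3g)", max(abs(rs - 1)))
  }
  colMeans(C)
}

#' Copy (pointer) distribution over the vocabulary
#'
#' Projects an attention distribution over input positions onto the
#' vocabulary: for each token id occurring in the input, the attention values
#' at its positions are aggregated with `max` or `sum`; ids absent from the
#' input get 0. With `agg = "sum"` the result conserves the attention mass;
#' with `agg = "max"` mass may be lost when tokens repeat (the vector is used
#' for an argmax, so it is deliberately not renormalized).
#'
#' @param c_vec Numeric vector of non-negative attention values, one per
#'   input position.
#' @param input_ids Integer vector of 0-based input token ids, same length.
#' @param vocab_size Size of the vocabulary |V|.
#' @param agg `"max"` or `"sum"`.
#' @return Numeric vector of length `vocab_size`.
#' @export
#' @examples
#' pointer_distribution(c(0.2, 0.5, 0.3), c(5, 7, 5), 10, "sum")
pointer_distribution <- function(c_vec, input_ids, vocab_size, agg = c("max", "sum")) {
  agg <- match.arg(agg)
  if (length(c_vec) != length(input_ids)) {
    stopf("attention vector length %d does not match input length %d",
          length(c_vec), length(input_ids))
  }
  if (any(c_vec < 0)) stopf("attention values must be non-negative")
  if (length(input_ids) && (any(input_ids < 0) || any(input_ids >= vocab_size))) {
    stopf("input token id out of range")
  }
  out <- numeric(vocab_size)
  if (length(input_ids) == 0L) return(out)
  f <- if (agg == "max") max else sum
  agg_vals <- tapply(c_vec, factor(input_ids), f)
  out[as.integer(names(agg_vals)) + 1L] <- as.numeric(agg_vals)
  out
}

#' Mix generative and pointer distributions
#'
#' The pointer-generator convex combination
#' `p_gen * dist_gen + (1 - p_gen) * dist_ptr`, with the gate `p_gen` giving
#' the fraction assigned to the classical generative distribution.
#'
#' @param dist_gen,dist_ptr Numeric vectors of equal length |V|.
#' @param p_gen Scalar in \[0, 1\].
#' @return Numeric vector of length |V|.
#' @export
mix_distributions <- function(dist_gen, dist_ptr, p_gen) {
  if (length(dist_gen) != length(dist_ptr)) stopf("distribution lengths differ")
  if (!is.numeric(p_gen) || length(p_gen) != 1L || is.na(p_gen) || p_gen < 0 || p_gen > 1) {
    stopf("p_gen must be a scalar in [0, 1]")
  }
  p_gen * dist_gen + (1 - p_gen) * dist_ptr
}

# validate one scorer step output against the vocabulary
check_scorer_output <- function(out, nv) {
  if (!is.list(out) || is.null(out$logits)) stopf("scorer must return list(logits, ...)")
  if (length(out$logits) != nv) {
    stopf("scorer returned %d logits for vocabulary of size %d", length(out$logits), nv)
  }
  out
}

# the per-step distribution given the pointer mode
step_distribution <- function(out, input_ids, nv, pointer) {
  dist_gen <- gen_distribution(out$logits)
  if (pointer == "none") return(dist_gen)
  if (is.null(out$cross_attention) || is.null(out$p_gen)) {
    stopf("pointer mode '%s' requires the scorer to emit cross_attention and p_gen", pointer)
  }
  c_vec <- mean_head_attention(out$cross_attention)
  dist_ptr <- pointer_distribution(c_vec, input_ids, nv, agg = pointer)
  mix_distributions(dist_gen, dist_ptr, out$p_gen)
}

decode_result <- function(output_ids, vocab, valid, instance, steps) {
  structure(list(output_ids = output_ids,
                 surface = detokenize(vocab, output_ids),
                 valid = valid,
                 instance = instance,
                 steps = steps),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("<decode_result> %d steps, valid=%s\n", x$steps, x$valid))
  cat(substr(x$surface, 1, 200), if (nchar(x$surface) > 200) "..." else "", "\n")
  invisible(x)
}

#' Unconstrained greedy decoding
#'
#' The baseline decoding loop: at every step the token with the highest value
#' in the generative distribution is chosen, with no grammar involved.
#' Generation stops at the first EOS token or after `max_len` steps. The
#' output is then checked by attempting a strict parse of its surface; the
#' `valid` flag (and, when valid, the parsed instance) records the outcome —
#' an unparseable output is a result, not an error.
#'
#' @param scorer A scorer function `f(input_ids, prefix_ids)` returning
#'   `list(logits, cross_attention = NULL, p_gen = NULL)` (see
#'   [oracle_scorer()]).
#' @param input_ids Integer vector of 0-based source-token ids.
#' @param schema,vocab The schema and vocabulary used for the validity check.
#' @param max_len Maximum number of generation steps (>= 1).
#' @return A `decode_result`.
#' @export
greedy_decode <- function(scorer, input_ids, schema, vocab, max_len = 4096L) {
  if (!is_count(max_len) || max_len < 1) stopf("max_len must be >= 1")
  nv <- vocab_size(vocab)
  out_ids <- integer()
  repeat {
    step <- check_scorer_output(scorer(input_ids, out_ids), nv)
    dist <- gen_distribution(step$logits)
    nxt <- which.max(dist) - 1L          # ties: lowest id wins
    out_ids <- c(out_ids, nxt)
    if (nxt == vocab$eos_id || length(out_ids) >= max_len) break
  }
  surface <- detokenize(vocab, out_ids)
  inst <- tryCatch(parse_linearization(surface, schema, vocab),
                   gcdecode_parse_error = function(e) NULL)
  decode_result(out_ids, vocab, valid = !is.null(inst), instance = inst,
                steps = length(out_ids))
}

#' Grammar-constrained decoding
#'
#' The constrained decoding loop: at every step the vocabulary mask of the
#' incremental parser state is added to the token distribution before the
#' argmax, so only grammatically accepted tokens can be emitted, and each
#' emitted token advances the parser. When the unconstrained argmax token is
#' accepted anyway, the choice coincides with greedy decoding. With
#' `pointer = "max"` or `"sum"` the distribution is the pointer-generator
#' mixture instead of the plain generative distribution.
#'
#' Normal termination (EOS once the root template is closed) guarantees a
#' valid output and returns the parsed instance. If `max_len` is reached
#' before the grammar completes, the truncated result is flagged
#' `valid = FALSE` rather than force-closing open tags.
#'
#' @inheritParams greedy_decode
#' @param grammar A `decoding_grammar` built from the same schema/vocabulary.
#' @param pointer `"none"`, `"max"` or `"sum"`.
#' @param trace_file Optional path; when set, one JSON line per step is
#'   appended with the step index, accepted-set size, chosen token and p_gen.
#' @return A `decode_result`.
#' @export
gcd_decode <- function(scorer, input_ids, grammar, max_len = 4096L,
                       pointer = c("none", "max", "sum"), trace_file = NULL) {
  pointer <- match.arg(pointer)
  if (!is_count(max_len) || max_len < 1) stopf("max_len must be >= 1")
  vocab <- grammar$vocab
  nv <- vocab_size(vocab)
  state <- init_parser(grammar)
  out_ids <- integer()
  finished <- FALSE
  trace <- if (is.null(trace_file)) NULL else character()
  while (length(out_ids) < max_len) {
    step <- check_scorer_output(scorer(input_ids, out_ids), nv)
    dist <- step_distribution(step, input_ids, nv, pointer)
    mask <- vocabulary_mask(state)
    masked <- dist + mask
    nxt <- which.max(masked) - 1L        # ties: lowest id wins
    if (masked[nxt + 1L] == -Inf) {
      stopf("empty accepted set during constrained decoding")   # unreachable: mask errors first
    }
    if (!is.null(trace)) {
      trace <- c(trace, jsonlite::toJSON(
        list(step = length(out_ids) + 1L, accepted = sum(mask == 0),
             token = nxt, p_gen = step$p_gen),
        auto_unbox = TRUE, null = "null"))
    }
    out_ids <- c(out_ids, nxt)
    if (nxt == vocab$eos_id && state$complete) { finished <- TRUE; break }
    state <- advance_parser(state, nxt)
  }
  if (!is.null(trace_file)) writeLines(trace, trace_file)
  if (finished || state$complete) {
    inst <- parse_linearization(detokenize(vocab, out_ids), grammar$schema, vocab)
    decode_result(out_ids, vocab, valid = TRUE, instance = inst,
                  steps = length(out_ids))
  } else {
    decode_result(out_ids, vocab, valid = FALSE, instance = NULL,
                  steps = length(out_ids))
  }
}
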