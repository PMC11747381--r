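# Mock scorers. A scorer is a function f(input_ids, prefix_ids) returning
# list(logits, cross_attention, p_gen); it stands in for the decoder stack of
# a fine-tuned encoder-decoder model. All mocks are pure functions of their
# seed and the (input, prefix) pair: the step index is mixed into a sub-seed,
# so replaying any step reproduces it bit-identically.

random_attention <- function(n_input, heads) {
  if (n_input == 0L) return(NULL)
  C <- matrix(stats::runif(heads * n_input), nrow = heads)
  C / rowSums(C)
}

#' Oracle scorer with controllable noise
#'
#' Emits logits peaked at the reference token of the current step with
#' probability `1 - eps`, and at a uniformly random vocabulary token with
#' probability `eps`. Past the end of the reference the peak sits on EOS. Each
#' step also carries a random row-normalized cross-attention matrix over the
#' input and a random copy gate `p_gen`, so pointer-mode decoding is
#' exercisable. With `eps = 0`, greedy decoding reproduces the reference
#' exactly.
#'
#' @param reference Integer vector of 0-based token ids (typically a tokenized
#'   linearization, without EOS).
#' @param vocab A `vocabulary`.
#' @param eps Noise rate in \[0, 1\].
#' @param seed Integer seed making the scorer deterministic.
#' @param heads Number of attention heads to fake.
#' @return A scorer function.
#' @export
oracle_scorer <- function(reference, vocab, eps = 0, seed = 1L, heads = 4L) {
  if (eps < 0 || eps > 1) stopf("eps must be in [0, 1]")
  nv <- vocab_size(vocab)
  reference <- as.integer(reference)
  function(input_ids, prefix_ids) {
    t <- length(prefix_ids) + 1L
    with_rng(step_seed(seed, t), {
      target <- if (t <= length(reference)) reference[t] else vocab$eos_id
      if (eps > 0 && stats::runif(1) < eps) target <- sample.int(nv, 1L) - 1L
      logits <- stats::rnorm(nv)
      logits[target + 1L] <- logits[target + 1L] + 12
      list(logits = logits,
           cross_attention = random_attention(length(input_ids), heads),
           p_gen = stats::runif(1))
    })
  }
}

#' Uniform-random scorer
#'
#' Standard-normal logits at every step, independent of any reference: the
#' argmax is a uniformly random token. Used to probe decoder behavior under a
#' completely uninformed model.
#'
#' @inheritParams oracle_scorer
#' @return A scorer function.
#' @export
random_scorer <- function(vocab, seed = 1L, heads = 4L) {
  nv <- vocab_size(vocab)
  function(input_ids, prefix_ids) {
    t <- length(prefix_ids) + 1L
    with_rng(step_seed(seed, t), {
      list(logits = stats::rnorm(nv),
           cross_attention = random_attention(length(input_ids), heads),
           p_gen = stats::runif(1))
    })
  }
}

#' Adversarial scorer
#'
#' Piles the probability mass on structurally hostile tokens: at every step
#' the logits peak jointly on EOS and on a randomly chosen special tag token,
#' choices that are almost never grammatically acceptable at that position.
#' Unconstrained greedy decoding degenerates immediately; grammar-constrained
#' decoding must fall back to the best accepted token and still emit a valid
#' linearization.
#'
#' @inheritParams oracle_scorer
#' @return A scorer function.
#' @export
adversarial_scorer <- function(vocab, seed = 1L, heads = 4L) {
  nv <- vocab_size(vocab)
  tag_ids <- which(is_tag_token(vocab$tokens)) - 1L
  function(input_ids, prefix_ids) {
    t <- length(prefix_ids) + 1L
    with_rng(step_seed(seed, t), {
      logits <- stats::rnorm(nv)
      logits[vocab$eos_id + 1L] <- logits[vocab$eos_id + 1L] + 12
      if (length(tag_ids)) {
        tgt <- tag_ids[sample.int(length(tag_ids), 1L)]
        logits[tgt + 1L] <- logits[tgt + 1L] + 14
      }
      list(logits = logits,
           cross_attention = random_attention(length(input_ids), heads),
           p_gen = stats::runif(1))
    })
  }
}
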