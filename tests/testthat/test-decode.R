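test_that("gen_distribution is a softmax: normalized, order-preserving, oracle-exact", {
  expect_equal(gen_distribution(c(0, 0)), c(0.5, 0.5))
  set.seed(1)
  for (k in 1:20) {
    l <- stats::rnorm(30, sd = 5)
    d <- gen_distribution(l)
    expect_true(all(d >= 0))
    expect_lt(abs(sum(d) - 1), 1e-9)
    expect_identical(which.max(l), which.max(d))
    expect_identical(order(l), order(d))
  }
  # direct-formula oracle (no max-shift), safe at these magnitudes
  l <- c(1, 2, 3)
  expect_equal(gen_distribution(l), exp(l) / sum(exp(l)), tolerance = 1e-12)
  expect_error(gen_distribution(c(1, NaN)), "NaN")
  expect_error(gen_distribution(c(1, Inf)), "NaN|infinite")
})

test_that("mean_head_attention averages rows of a normalized attention matrix", {
  expect_equal(mean_head_attention(matrix(c(1, 0, 0, 1), 2, byrow = TRUE)),
               c(0.5, 0.5))
  one_row <- matrix(c(0.2, 0.3, 0.5), 1)
  expect_equal(mean_head_attention(one_row), as.numeric(one_row))
  set.seed(2)
  C <- matrix(stats::runif(35), 5, 7)
  C <- C / rowSums(C)
  expect_lt(abs(sum(mean_head_attention(C)) - 1), 1e-6)
  expect_error(mean_head_attention(C * 2), "sum to 1")
  expect_error(mean_head_attention(matrix(c(-0.5, 1.5), 1)), "non-negative")
})

test_that("pointer distributions aggregate repeated input tokens by max or sum", {
  # repeated token id 5 at positions 1 and 3
  ptr_sum <- pointer_distribution(c(0.2, 0.5, 0.3), c(5, 7, 5), 10, "sum")
  expect_equal(ptr_sum[5 + 1], 0.5)
  expect_equal(ptr_sum[7 + 1], 0.5)
  expect_equal(sum(ptr_sum), 1)
  expect_true(all(ptr_sum[-c(6, 8)] == 0))

  ptr_max <- pointer_distribution(c(0.2, 0.5, 0.3), c(5, 7, 5), 10, "max")
  expect_equal(ptr_max[5 + 1], 0.3)
  expect_equal(ptr_max[7 + 1], 0.5)

  # all-distinct input: max and sum coincide
  expect_identical(pointer_distribution(c(0.1, 0.9), c(2, 4), 6, "max"),
                   pointer_distribution(c(0.1, 0.9), c(2, 4), 6, "sum"))

  expect_error(pointer_distribution(c(0.5), c(1, 2), 4, "sum"), "length")
  expect_error(pointer_distribution(c(-0.1, 1.1), c(1, 2), 4, "sum"), "non-negative")
})

test_that("pointer mass conservation and max<=sum dominance hold on random draws", {
  set.seed(3)
  for (k in 1:200) {
    n_in <- sample(2:12, 1)
    nv <- sample(15:40, 1)
    heads <- sample(1:6, 1)
    input_ids <- sample(0:(nv - 1), n_in, replace = TRUE)
    C <- matrix(stats::runif(heads * n_in), heads)
    C <- C / rowSums(C)
    cv <- mean_head_attention(C)
    d_sum <- pointer_distribution(cv, input_ids, nv, "sum")
    d_max <- pointer_distribution(cv, input_ids, nv, "max")
    expect_lt(abs(sum(d_sum) - 1), 1e-9)
    expect_true(all(d_max <= d_sum + 1e-12))
    if (!anyDuplicated(input_ids)) expect_equal(d_max, d_sum)
    # mixing conserves mass for the sum variant at any gate value
    p <- stats::runif(1)
    expect_lt(abs(sum(mix_distributions(gen_distribution(stats::rnorm(nv)), d_sum, p)) - 1),
              1e-9)
  }
})

test_that("mixing limit cases reproduce the pure distributions", {
  dg <- c(0.8, 0.2)
  dp <- c(0.0, 1.0)
  expect_identical(mix_distributions(dg, dp, 1), dg)
  expect_identical(mix_distributions(dg, dp, 0), dp)
  expect_equal(mix_distributions(dg, dp, 0.5), c(0.4, 0.6))
  expect_error(mix_distributions(dg, dp, 1.2), "p_gen")
  expect_error(mix_distributions(dg, c(dp, 0), 0.5), "length")
})

test_that("a noise-free oracle makes greedy decoding reproduce the reference", {
  cfg <- small_cfg(21)
  sch <- gen_schema(cfg, seed = 21)
  vocab <- make_vocabulary(sch, cfg$text_vocab)
  x <- gen_instance(sch, cfg, seed = 22)
  lin <- linearize(x, sch)
  ref <- tokenize_linearization(lin, vocab)
  sc <- oracle_scorer(ref, vocab, eps = 0, seed = 5)
  res <- greedy_decode(sc, integer(), sch, vocab)
  expect_true(res$valid)
  expect_identical(res$surface, lin)
  expect_identical(res$output_ids, c(ref, vocab$eos_id))
  expect_identical(res$steps, length(res$output_ids))
  expect_true(instance_equal(res$instance, x))

  # truncation leaves unbalanced tags, hence invalid
  short <- greedy_decode(sc, integer(), sch, vocab, max_len = 3)
  expect_false(short$valid)
  expect_identical(short$steps, 3L)
})

test_that("grammar-constrained decoding equals greedy decoding when the argmax is accepted", {
  cfg <- small_cfg(23)
  sch <- gen_schema(cfg, seed = 23)
  vocab <- make_vocabulary(sch, cfg$text_vocab)
  g <- build_decoding_grammar(sch, vocab)
  for (k in 1:10) {
    x <- gen_instance(sch, cfg, seed = 3000 + k)
    ref <- tokenize_linearization(linearize(x, sch), vocab)
    sc <- oracle_scorer(ref, vocab, eps = 0, seed = k)
    res_g <- greedy_decode(sc, integer(), sch, vocab)
    res_c <- gcd_decode(sc, integer(), g)
    expect_identical(res_c$output_ids, res_g$output_ids)
    expect_true(res_c$valid)
  }
})

test_that("constrained decoding survives an adversarial scorer and stays valid", {
  cfg <- small_cfg(29)
  sch <- gen_schema(cfg, seed = 29)
  vocab <- make_vocabulary(sch, cfg$text_vocab)
  g <- build_decoding_grammar(sch, vocab)
  for (k in 1:10) {
    res <- gcd_decode(adversarial_scorer(vocab, seed = k), integer(), g)
    expect_true(res$valid)
    expect_invisible(validate_instance(res$instance, sch))
    # every emitted token was accepted: replay through a fresh parser
    st <- init_parser(g)
    for (id in res$output_ids) st <- advance_parser(st, id)
    expect_true(st$complete)
  }
})

test_that("masked argmax on a two-slot schema picks the best accepted token", {
  # adversarial mass sits on tags that are never acceptable mid-text
  sch <- template_schema(list(T = list(slot_def("a", min = 1, max = 1),
                                       slot_def("b", min = 1, max = 1))),
                         root = "T")
  vocab <- make_vocabulary(sch, c("w"))
  g <- build_decoding_grammar(sch, vocab)
  res <- gcd_decode(adversarial_scorer(vocab, seed = 4), integer(), g)
  expect_true(res$valid)
  inst <- res$instance
  expect_setequal(names(inst$fillers), c("a", "b"))
})

test_that("truncated constrained decodes are flagged invalid, not force-closed", {
  cfg <- small_cfg(31)
  sch <- gen_schema(cfg, seed = 31)
  vocab <- make_vocabulary(sch, cfg$text_vocab)
  g <- build_decoding_grammar(sch, vocab)
  res <- gcd_decode(random_scorer(vocab, seed = 9), integer(), g, max_len = 4)
  expect_false(res$valid)
  expect_null(res$instance)
  expect_identical(res$steps, 4L)
})

test_that("decoding is bit-identical across repeated runs with equal seeds", {
  cfg <- small_cfg(37)
  sch <- gen_schema(cfg, seed = 37)
  vocab <- make_vocabulary(sch, cfg$text_vocab)
  g <- build_decoding_grammar(sch, vocab)
  r1 <- gcd_decode(random_scorer(vocab, seed = 77), integer(), g)
  r2 <- gcd_decode(random_scorer(vocab, seed = 77), integer(), g)
  expect_identical(r1$output_ids, r2$output_ids)
  x <- gen_instance(sch, cfg, seed = 5)
  ref <- tokenize_linearization(linearize(x, sch), vocab)
  o1 <- greedy_decode(oracle_scorer(ref, vocab, eps = 0.4, seed = 7), integer(), sch, vocab)
  o2 <- greedy_decode(oracle_scorer(ref, vocab, eps = 0.4, seed = 7), integer(), sch, vocab)
  expect_identical(o1$output_ids, o2$output_ids)
})

test_that("pointer modes require attention and gate outputs from the scorer", {
  cfg <- small_cfg(41)
  sch <- gen_schema(cfg, seed = 41)
  vocab <- make_vocabulary(sch, cfg$text_vocab)
  g <- build_decoding_grammar(sch, vocab)
  bare_scorer <- function(input_ids, prefix_ids) {
    list(logits = with_rng_logits(length(prefix_ids)))
  }
  with_rng_logits <- function(t) { set.seed(1000 + t); stats::rnorm(vocab_size(vocab)) }
  expect_error(gcd_decode(bare_scorer, c(0L, 1L), g, pointer = "max"),
               "cross_attention")
  # with input tokens present, pointer decoding runs; every grammatically
  # completed run parses, and a run that exhausts max_len is flagged truncated
  # (the copy distribution can keep source words beating the closing tag)
  x <- gen_instance(sch, cfg, seed = 6)
  ref <- tokenize_linearization(linearize(x, sch), vocab)
  input_ids <- tokenize_text(vocab, paste(cfg$text_vocab[1:5], collapse = " "))
  for (ptr in c("max", "sum")) {
    res <- gcd_decode(oracle_scorer(ref, vocab, eps = 0.2, seed = 8), input_ids, g,
                      pointer = ptr, max_len = 400)
    expect_s3_class(res, "decode_result")
    if (res$valid) {
      expect_invisible(validate_instance(res$instance, sch))
    } else {
      expect_identical(res$steps, 400L)
    }
  }
})

test_that("decode traces record one step per emitted token", {
  sch <- tiny_schema()
  vocab <- make_vocabulary(sch, c("w"))
  g <- build_decoding_grammar(sch, vocab)
  ref <- tokenize_linearization("[start:T][start:s]w[end:s][end:T]", vocab)
  tf <- withr::local_tempfile(fileext = ".jsonl")
  res <- gcd_decode(oracle_scorer(ref, vocab, eps = 0, seed = 2), integer(), g,
                    trace_file = tf)
  lines <- readLines(tf)
  expect_length(lines, res$steps)
  rec <- jsonlite::fromJSON(lines[1])
  expect_setequal(names(rec), c("step", "accepted", "token", "p_gen"))
  expect_identical(rec$accepted, 1L)   # only the root start tag is accepted first
})
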