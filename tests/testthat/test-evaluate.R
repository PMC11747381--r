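test_that("normalized Levenshtein similarity matches the DP oracle", {
  expect_identical(norm_levenshtein_sim("abc", "abc"), 1)
  expect_identical(norm_levenshtein_sim("abc", ""), 0)
  expect_equal(norm_levenshtein_sim("kitten", "sitting"), 1 - 3 / 7)
  expect_warning(v <- norm_levenshtein_sim("", ""), "empty")
  expect_identical(v, 1)
  set.seed(4)
  alphabet <- c(letters[1:6], " ")
  for (k in 1:100) {
    s1 <- paste(sample(alphabet, sample(0:12, 1), replace = TRUE), collapse = "")
    s2 <- paste(sample(alphabet, sample(1:12, 1), replace = TRUE), collapse = "")
    got <- norm_levenshtein_sim(s1, s2)
    want <- 1 - dp_levenshtein(s1, s2) / max(nchar(s1), nchar(s2))
    expect_equal(got, want)
    expect_equal(got, norm_levenshtein_sim(s2, s1))   # symmetry
    expect_true(got >= 0 && got <= 1)
  }
})

test_that("filler equivalence: fuzzy for text, exact for nested instances", {
  expect_true(filler_equal(text_filler("timolol"), text_filler("timolol")))
  # 20 characters, one substitution: similarity 0.95
  a <- strrep("ab", 10)
  b <- paste0(substr(a, 1, 19), "x")
  expect_true(filler_equal(text_filler(a), text_filler(b)))
  # 10 characters, one substitution: similarity exactly 0.9 (boundary holds)
  c10 <- strrep("ab", 5)
  d10 <- paste0(substr(c10, 1, 9), "x")
  expect_true(filler_equal(text_filler(c10), text_filler(d10)))
  # 9 characters, one substitution: 1 - 1/9 < 0.9
  c9 <- strrep("a", 9)
  d9 <- paste0(substr(c9, 1, 8), "x")
  expect_false(filler_equal(text_filler(c9), text_filler(d9)))
  # mixed kinds never match
  inner <- template_instance("Inner", list(b = list("yyyyyyyyyy")))
  expect_false(filler_equal(text_filler("x"), instance_filler(inner)))
  # nested instances: identity only — one character off anywhere breaks it,
  # even though the same strings as textual fillers would pass the 0.9 rule
  inner2 <- template_instance("Inner", list(b = list(paste0("yyyyyyyyy", "x"))))
  expect_true(filler_equal(instance_filler(inner), instance_filler(inner)))
  expect_false(filler_equal(instance_filler(inner), instance_filler(inner2)))
  expect_true(filler_equal(text_filler("yyyyyyyyyy"), text_filler(paste0("yyyyyyyyy", "x"))))
})

test_that("pair counts perform maximum per-slot matching with tp+fp/tp+fn totals", {
  sch <- tiny_schema()
  two <- template_instance("T", list(s = list("aaaa", "bbbb")))
  expect_identical(unclass(pair_counts(two, two))[c("tp", "fp", "fn")],
                   list(tp = 2L, fp = 0L, fn = 0L))
  expect_identical(f1_score(pair_counts(two, two)), 1)

  extra <- template_instance("T", list(s = list("aaaa", "bbbb", "cccc")))
  cnt <- pair_counts(extra, two)
  expect_identical(cnt$fp, 1L)
  expect_identical(cnt$tp + cnt$fp, 3L)   # = number of predicted fillers
  expect_identical(cnt$tp + cnt$fn, 2L)   # = number of gold fillers

  disjoint <- pair_counts(template_instance("T", list(s = list("aaaa"))),
                          template_instance("T", list(s = list("zzzz"))))
  expect_identical(unclass(disjoint)[c("tp", "fp", "fn")],
                   list(tp = 0L, fp = 1L, fn = 1L))
  expect_identical(f1_score(disjoint), 0)

  expect_error(pair_counts(two, template_instance("U")), "mismatch")

  # fuzzy equality is not transitive; the matching must still be maximal
  base <- strrep("a", 10)
  near1 <- paste0(substr(base, 1, 9), "x")   # sim 0.9 to base
  p <- template_instance("T", list(s = list(base, near1)))
  g <- template_instance("T", list(s = list(near1, base)))
  expect_identical(pair_counts(p, g)$tp, 2L)
})

test_that("a crossed pairing is preferred when it yields more true positives", {
  sch <- tiny_schema()
  # gold1 has fillers {A}, gold2 {A,B,C}; pred1 {A,B,C}, pred2 {A}.
  # first-come pairing (pred1-gold1) yields tp=1+1=2; crossed yields tp=4.
  A <- "aaaaaa"; B <- "bbbbbb"; C <- "cccccc"
  pred1 <- template_instance("T", list(s = list(A, B, C)))
  pred2 <- template_instance("T", list(s = list(A)))
  gold1 <- template_instance("T", list(s = list(A)))
  gold2 <- template_instance("T", list(s = list(A, B, C)))
  res <- align_and_score(list(pred1, pred2), list(gold1, gold2))
  expect_identical(res$counts$tp, 4L)
  expect_identical(res$f1, 1)
  expect_identical(res$matching$gold[res$matching$pred == 1], 2L)
  expect_identical(res$matching$gold[res$matching$pred == 2], 1L)
})

test_that("degenerate alignments behave correctly", {
  one <- template_instance("T", list(s = list("aaaa")))
  res <- align_and_score(list(one), list(one))
  expect_identical(nrow(res$matching), 1L)
  expect_identical(res$f1, 1)

  # empty predictions: everything gold is a false negative
  gold <- template_instance("T", list(s = list("aaaa", "bbbb")))
  res2 <- align_and_score(list(), list(gold))
  expect_identical(unclass(res2$counts)[c("tp", "fp", "fn")],
                   list(tp = 0L, fp = 0L, fn = 2L))
  expect_identical(res2$f1, 0)

  # cross-type pairing is never considered
  u <- template_instance("U", list(s = list("aaaa")))
  sch <- template_schema(list(T = list(slot_def("s")), U = list(slot_def("s"))),
                         root = "T")
  res3 <- align_and_score(list(u), list(one))
  expect_identical(nrow(res3$matching), 0L)
  expect_identical(unclass(res3$counts)[c("tp", "fp", "fn")],
                   list(tp = 0L, fp = 1L, fn = 1L))
})

test_that("alignment optimum matches brute force on random cases", {
  for (s in 1:25) {
    case <- random_alignment_case(s)
    got <- align_and_score(case$preds, case$golds)
    want <- brute_force_align(case$preds, case$golds)
    expect_true(want$denom_constant)
    expect_equal(got$f1, want$f1, tolerance = 1e-12)
  }
})

test_that("swapping predictions and gold swaps fp and fn and preserves F1", {
  for (s in c(2, 5, 8, 11)) {
    case <- random_alignment_case(s)
    fwd <- align_and_score(case$preds, case$golds)
    rev <- align_and_score(case$golds, case$preds)
    expect_identical(fwd$counts$tp, rev$counts$tp)
    expect_identical(fwd$counts$fp, rev$counts$fn)
    expect_identical(fwd$counts$fn, rev$counts$fp)
    expect_equal(fwd$f1, rev$f1)
  }
})

test_that("adding a spurious predicted instance never increases F1", {
  set.seed(6)
  for (s in 1:10) {
    case <- random_alignment_case(s)
    base <- align_and_score(case$preds, case$golds)$f1
    cfg <- small_cfg(s)
    spurious <- gen_instance(case$schema, cfg, seed = 5000 + s)
    worse <- align_and_score(c(case$preds, list(spurious)), case$golds)$f1
    expect_lte(worse, base + 1e-12)
  }
})

test_that("F1 is bounded and 1 exactly when counts are clean", {
  expect_identical(f1_score(eval_counts(0, 0, 0)), 0)
  expect_identical(f1_score(eval_counts(5, 0, 0)), 1)
  expect_lt(f1_score(eval_counts(5, 1, 0)), 1)
  set.seed(7)
  for (k in 1:50) {
    cnt <- eval_counts(sample(0:9, 1), sample(0:9, 1), sample(0:9, 1))
    f <- f1_score(cnt)
    expect_true(f >= 0 && f <= 1)
    if (f == 1) expect_true(cnt$fp == 0 && cnt$fn == 0)
  }
})

test_that("corpus evaluation aggregates per slot, per template and overall", {
  sch <- ctro_mini_schema()
  cfg <- fixture_config(seed = 8)
  golds <- lapply(1:4, function(k) gen_instance(sch, cfg, seed = 600 + k))
  docs <- stats::setNames(golds, paste0("doc", 1:4))

  perfect <- evaluate_corpus(docs, docs, sch)
  expect_identical(perfect$total_micro_f1, 1)
  expect_gt(perfect$overall$tp, 0L)
  # overall counts equal the sums of per-slot counts
  expect_identical(perfect$overall$tp,
                   sum(vapply(perfect$per_slot, `[[`, 0L, "tp")))
  expect_identical(perfect$overall$fp,
                   sum(vapply(perfect$per_slot, `[[`, 0L, "fp")))
  expect_identical(perfect$overall$fn,
                   sum(vapply(perfect$per_slot, `[[`, 0L, "fn")))
  # ... and of per-template counts
  expect_identical(perfect$overall$tp,
                   sum(vapply(perfect$per_template, `[[`, 0L, "tp")))

  # empty predictions: F1 0 everywhere with counts
  empty <- evaluate_corpus(
    stats::setNames(lapply(1:4, function(k) list()), paste0("doc", 1:4)),
    docs, sch)
  expect_identical(empty$total_micro_f1, 0)
  expect_identical(empty$overall$tp, 0L)
  expect_identical(empty$overall$fn, perfect$overall$tp)

  # corruption strictly between the extremes
  preds <- stats::setNames(lapply(1:4, function(k) {
    corrupt_instance(golds[[k]], sch, n_ops = 3, seed = 700 + k)
  }), paste0("doc", 1:4))
  mid <- evaluate_corpus(preds, docs, sch)
  expect_true(mid$total_micro_f1 <= 1)

  expect_error(evaluate_corpus(docs[1:3], docs, sch), "unpaired")
})

test_that("report tables carry the schema's row inventory", {
  sch <- ctro_mini_schema()
  cfg <- fixture_config(seed = 9)
  docs <- stats::setNames(lapply(1:2, function(k) gen_instance(sch, cfg, seed = 800 + k)),
                          c("a", "b"))
  rep <- evaluate_corpus(docs, docs, sch)
  tt <- report_template_table(rep)
  expect_setequal(tt$name, names(sch$templates))
  st <- report_slot_table(rep)
  expect_identical(st$name[nrow(st)], "Total Micro F1 Score")
  expect_setequal(st$name[-nrow(st)], schema_slot_names(sch, "textual"))
  expect_true(all(c("AggregationMethod", "Author", "Title", "PMID") %in% st$name))
  full <- report_slot_table(rep, textual_only = FALSE)
  expect_setequal(full$name[-nrow(full)], schema_slot_names(sch))

  paths <- write_report(rep, file.path(withr::local_tempdir(), "report"))
  expect_true(all(file.exists(paths)))
  back <- jsonlite::read_json(paths[1])
  expect_equal(as.numeric(back$total_micro_f1), 1)
  tsv <- utils::read.delim(paths[3])
  expect_identical(nrow(tsv), nrow(st))
})
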