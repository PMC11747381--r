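# Shared builders and independent oracles for the test suite.
# Oracles are deliberately written as naive reference implementations,
# independent of the code paths they check.

# -- tiny hand-built schemas ---------------------------------------------

# one template, one textual slot
tiny_schema <- function(min = 0, max = Inf) {
  template_schema(list(T = list(slot_def("s", min = min, max = max))), root = "T")
}

# two templates, nesting, two textual slots
nested_schema <- function() {
  template_schema(list(
    Outer = list(slot_def("a", max = 2),
                 slot_def("hasInner", "template", templates = "Inner", max = 2)),
    Inner = list(slot_def("b", min = 1, max = 2))
  ), root = "Outer")
}

# schema carrying the tag names of the prototypical unconstrained syntax
# error (an Outcome whose textual slots use the has- prefixed names)
listing_schema <- function() {
  template_schema(list(
    Outcome = list(slot_def("hasObservedResult"),
                   slot_def("hasPValueChangeValue"))
  ), root = "Outcome")
}

listing_vocab <- function() {
  make_vocabulary(listing_schema(),
                  text_tokens = c("After 3 months of treatment...", "P=0.01"))
}

small_cfg <- function(seed = 1L) {
  fixture_config(seed = seed, n_templates = 3L, n_slots_per_template = 3L,
                 max_depth = 2L, max_fillers = 2L)
}

# -- independent oracles --------------------------------------------------

# dynamic-programming Levenshtein distance (textbook recurrence)
dp_levenshtein <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1] <- 0:n
  D[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    D[i + 1L, j + 1L] <- min(D[i, j + 1L] + 1L,
                             D[i + 1L, j] + 1L,
                             D[i, j] + (a[i] != b[j]))
  }
  D[n + 1L, m + 1L]
}

# recursive slot sort, an independent model of canonicalization
recursive_sort_oracle <- function(inst) {
  fl <- inst$fillers
  fl <- fl[lengths(fl) > 0]
  fl <- fl[sort(names(fl), method = "radix")]
  fl <- lapply(fl, function(slot) lapply(slot, function(f) {
    if (!is.null(f$text)) f else {
      structure(list(instance = recursive_sort_oracle(f$instance)),
                class = "slot_filler")
    }
  }))
  structure(list(template = inst$template, fillers = fl),
            class = "template_instance")
}

# stack machine over tags only: accepts iff start/end tags are balanced and
# properly nested (structure-free push-down check)
tags_balanced <- function(text) {
  stack <- character()
  pos <- 1L
  while (pos <= nchar(text)) {
    rest <- substr(text, pos, nchar(text))
    m <- regexpr("\\[(start|end):([^]\\[:\\s]+)\\]", rest, perl = TRUE)
    if (m == -1L) break
    tag <- regmatches(rest, m)
    name <- sub("^\\[(start|end):", "", sub("\\]$", "", tag))
    if (startsWith(tag, "[start:")) {
      stack <- c(stack, name)
    } else {
      if (length(stack) == 0L || stack[length(stack)] != name) return(FALSE)
      stack <- stack[-length(stack)]
    }
    pos <- pos + as.integer(m) + attr(m, "match.length") - 1L
  }
  length(stack) == 0L
}

# all one-to-one partial matchings of pred indices 1..np to gold indices
# 1..ng (including leaving any instance unmatched); returns a list of integer
# vectors over preds with NA for unmatched
all_partial_matchings <- function(np, ng) {
  out <- list()
  rec <- function(i, used, acc) {
    if (i > np) { out[[length(out) + 1L]] <<- acc; return(invisible()) }
    rec(i + 1L, used, c(acc, NA_integer_))
    for (j in seq_len(ng)) {
      if (!(j %in% used)) rec(i + 1L, c(used, j), c(acc, j))
    }
  }
  rec(1L, integer(), integer())
  out
}

# brute-force optimal alignment. For every template type, every same-type
# matching (including leaving instances unmatched) is enumerated and its
# counts scored from scratch. Along the way the reduction fact is checked:
# 2*tp + fp + fn must be identical for every matching of a type. Given that
# verified constancy, maximizing global F1 decomposes into maximizing tp per
# type, so the per-type enumeration maxima are summed for the global optimum.
brute_force_align <- function(preds, golds, threshold = 0.9) {
  ptypes <- vapply(preds, `[[`, "", "template")
  gtypes <- vapply(golds, `[[`, "", "template")
  types <- union(ptypes, gtypes)
  tot_tp <- 0L; tot_fp <- 0L; tot_fn <- 0L
  denom_constant <- TRUE
  nfill <- function(x) sum(lengths(x$fillers))
  for (tt in types) {
    pi <- which(ptypes == tt); gi <- which(gtypes == tt)
    tpM <- matrix(0L, length(pi), length(gi))
    fpM <- matrix(0L, length(pi), length(gi))
    fnM <- matrix(0L, length(pi), length(gi))
    for (a in seq_along(pi)) for (b in seq_along(gi)) {
      cnt <- pair_counts(preds[[pi[a]]], golds[[gi[b]]], threshold)
      tpM[a, b] <- cnt$tp; fpM[a, b] <- cnt$fp; fnM[a, b] <- cnt$fn
    }
    pred_tot <- vapply(preds[pi], nfill, 0L)
    gold_tot <- vapply(golds[gi], nfill, 0L)
    best <- NULL
    denoms <- integer()
    for (m in all_partial_matchings(length(pi), length(gi))) {
      dtp <- 0L; dfp <- 0L; dfn <- 0L
      for (a in seq_along(m)) {
        if (is.na(m[a])) dfp <- dfp + pred_tot[a]
        else { dtp <- dtp + tpM[a, m[a]]; dfp <- dfp + fpM[a, m[a]]; dfn <- dfn + fnM[a, m[a]] }
      }
      for (b in seq_along(gi)) if (!(b %in% m)) dfn <- dfn + gold_tot[b]
      denoms <- c(denoms, 2L * dtp + dfp + dfn)
      if (is.null(best) || dtp > best$tp ) best <- list(tp = dtp, fp = dfp, fn = dfn)
    }
    if (length(unique(denoms)) > 1L) denom_constant <- FALSE
    if (!is.null(best)) {
      tot_tp <- tot_tp + best$tp; tot_fp <- tot_fp + best$fp; tot_fn <- tot_fn + best$fn
    }
  }
  denom <- 2 * tot_tp + tot_fp + tot_fn
  list(f1 = if (denom == 0) 0 else 2 * tot_tp / denom,
       denom_constant = denom_constant)
}

# random instance pools for alignment tests: gold instances plus predictions
# derived by corruption or drawn fresh; pools are trimmed to at most
# `cap` instances per type so exhaustive enumeration stays feasible
random_alignment_case <- function(seed, cap = 5L) {
  cfg <- small_cfg(seed)
  sch <- gen_schema(cfg, seed = seed)
  n_gold <- (seed %% 2L) + 1L
  golds <- lapply(seq_len(n_gold), function(k) {
    gen_instance(sch, cfg, seed = seed * 101 + k)
  })
  preds <- lapply(seq_along(golds), function(k) {
    if (k %% 3 == 0) gen_instance(sch, cfg, seed = seed * 211 + k)
    else corrupt_instance(golds[[k]], sch, n_ops = k %% 4, seed = seed * 307 + k)
  })
  if (seed %% 4 == 0 && length(preds) > 1) preds <- preds[-1]
  trim <- function(pool) {
    types <- vapply(pool, `[[`, "", "template")
    keep <- unlist(lapply(unique(types), function(tt) {
      utils::head(which(types == tt), cap)
    }))
    pool[sort(keep)]
  }
  list(schema = sch,
       preds = trim(unlist(lapply(preds, collect_instances), recursive = FALSE)),
       golds = trim(unlist(lapply(golds, collect_instances), recursive = FALSE)))
}
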