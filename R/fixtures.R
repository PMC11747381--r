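#' Configuration for the synthetic-data generators
#'
#' Bundles the knobs of the fixture generators. The defaults describe a small
#' but structurally complete extraction problem: a handful of templates
#' nesting two levels deep, a few slots each, repeated fillers allowed (so max
#' and sum attention aggregation are distinguishable), and a clinical-flavored
#' free-text vocabulary.
#'
#' @param seed Base seed; every generator is a pure function of (config, seed).
#' @param n_templates Number of templates in generated schemas.
#' @param n_slots_per_template Slots per template (including nesting slots).
#' @param max_depth Maximum template nesting depth; 0 forces a single
#'   all-textual template.
#' @param max_fillers Cap on fillers sampled per slot.
#' @param text_vocab Words textual fillers are built from.
#' @param eps Noise rate for the oracle scorer, in \[0, 1\].
#' @return A `fixture_config`.
#' @export
fixture_config <- function(seed = 1L,
                           n_templates = 4L,
                           n_slots_per_template = 3L,
                           max_depth = 2L,
                           max_fillers = 2L,
                           text_vocab = c("patients", "treatment", "placebo",
                                          "glucose", "baseline", "reduction",
                                          "significant", "randomized", "weeks",
                                          "dose", "mg", "daily", "group",
                                          "mean", "pressure", "intraocular",
                                          "therapy", "efficacy", "outcome",
                                          "months"),
                           eps = 0.1) {
  if (eps < 0 || eps > 1) stopf("eps must be in [0, 1]")
  if (!is_count(max_depth)) stopf("max_depth must be a non-negative integer")
  if (!is_count(max_fillers) || max_fillers < 1) stopf("max_fillers must be >= 1")
  structure(list(seed = as.integer(seed), n_templates = as.integer(n_templates),
                 n_slots_per_template = as.integer(n_slots_per_template),
                 max_depth = as.integer(max_depth),
                 max_fillers = as.integer(max_fillers),
                 text_vocab = text_vocab, eps = eps),
            class = "fixture_config")
}

#' Generate a random template schema
#'
#' Draws a connected, acyclic template hierarchy: template 1 is the root and
#' every further template is attached as a template-valued slot of an earlier
#' one, respecting `max_depth`. Remaining slots are textual with random
#' multiplicity bounds (min 0 or 1, max 1-3). Deterministic per seed.
#'
#' @param cfg A `fixture_config`.
#' @param seed Seed; defaults to `cfg$seed`.
#' @return A `template_schema`.
#' @export
gen_schema <- function(cfg, seed = cfg$seed) {
  with_rng(seed, {
    n <- cfg$n_templates
    if (cfg$max_depth == 0L) n <- 1L
    tnames <- paste0("Tpl", LETTERS[seq_len(n)])
    level <- integer(n); level[1] <- 0L
    parent <- rep(NA_integer_, n)
    for (i in seq_len(n)[-1]) {
      pool <- which(level[seq_len(i - 1L)] < cfg$max_depth)
      if (length(pool) == 0L) { n <- i - 1L; tnames <- tnames[seq_len(n)]; break }
      parent[i] <- pool[sample.int(length(pool), 1L)]
      level[i] <- level[parent[i]] + 1L
    }
    slots <- rep(list(list()), n)
    for (i in seq_len(n)[-1]) {
      p <- parent[i]
      slots[[p]] <- c(slots[[p]],
                      list(slot_def(paste0("has", tnames[i]), "template",
                                    templates = tnames[i], min = 0L,
                                    max = sample(2:3, 1L))))
    }
    for (i in seq_len(n)) {
      need <- max(cfg$n_slots_per_template - length(slots[[i]]), 1L)
      for (j in seq_len(need)) {
        mn <- sample(0:1, 1L, prob = c(0.7, 0.3))
        mx <- max(mn, sample(1:3, 1L))
        slots[[i]] <- c(slots[[i]],
                        list(slot_def(sprintf("s%d%s", i, letters[j]),
                                      "textual", min = mn, max = mx)))
      }
    }
    template_schema(stats::setNames(slots, tnames), root = tnames[1])
  })
}

#' Generate a random conforming instance
#'
#' Samples filler counts within each slot's bounds (capped at
#' `cfg$max_fillers` above the minimum), draws textual fillers as one to
#' three words from `cfg$text_vocab`, and recurses into template-valued
#' slots. Deterministic per seed.
#'
#' @param schema A `template_schema`.
#' @param cfg A `fixture_config`.
#' @param seed Seed; defaults to `cfg$seed`.
#' @param template Template to instantiate; defaults to the schema root.
#' @return A conforming, canonical `template_instance`.
#' @export
gen_instance <- function(schema, cfg, seed = cfg$seed, template = schema$root) {
  with_rng(seed, gen_instance_impl(schema, cfg, template, depth = 0L))
}

gen_instance_impl <- function(schema, cfg, template, depth) {
  if (depth > 50L) stopf("nesting depth exceeds 50; is the schema cyclic with min_count > 0?")
  fillers <- list()
  for (sd in schema$templates[[template]]) {
    hi <- min(sd$max, max(sd$min, cfg$max_fillers))
    n <- if (hi <= sd$min) sd$min else sd$min + sample.int(hi - sd$min + 1L, 1L) - 1L
    if (n == 0L) next
    fillers[[sd$name]] <- lapply(seq_len(n), function(k) {
      if (sd$kind == "textual") {
        nw <- sample.int(3L, 1L)
        text_filler(paste(sample(cfg$text_vocab, nw, replace = TRUE), collapse = " "))
      } else {
        tt <- sd$templates[sample.int(length(sd$templates), 1L)]
        instance_filler(gen_instance_impl(schema, cfg, tt, depth + 1L))
      }
    })
  }
  canonicalize(template_instance(template, fillers))
}

#' Generate an abstract-like document with its gold annotation
#'
#' Produces a gold instance plus a source text emulating an abstract: every
#' textual filler of the gold structure occurs verbatim as a substring,
#' shuffled among distractor word runs. Deterministic per seed.
#'
#' @inheritParams gen_instance
#' @param n_distractors Number of distractor word runs.
#' @return A list with elements `text` (string) and `gold`
#'   (`template_instance`).
#' @export
gen_document <- function(schema, cfg, seed = cfg$seed, n_distractors = 4L) {
  with_rng(seed, {
    gold <- gen_instance_impl(schema, cfg, schema$root, depth = 0L)
    filler_texts <- collect_filler_texts(gold)
    distract <- vapply(seq_len(n_distractors), function(k) {
      paste(sample(cfg$text_vocab, sample(3:6, 1L), replace = TRUE), collapse = " ")
    }, "")
    pieces <- sample(c(filler_texts, distract))
    list(text = paste(pieces, collapse = " "), gold = gold)
  })
}

collect_filler_texts <- function(inst) {
  out <- character()
  for (fl in inst$fillers) for (f in fl) {
    out <- c(out, if (is_text_filler(f)) f$text else collect_filler_texts(f$instance))
  }
  out
}

# ---- instance corruption ----

# Enumerate edit sites. addr is a list of c(slot, index) pairs leading from
# the root to the instance owning the slot.
enumerate_sites <- function(inst, schema, addr = list()) {
  sites <- list()
  tn <- inst$template
  for (sn in names(inst$fillers)) {
    sd <- find_slot(schema, tn, sn)
    n <- length(inst$fillers[[sn]])
    for (k in seq_len(n)) {
      f <- inst$fillers[[sn]][[k]]
      ops <- character()
      if (n - 1L >= sd$min) ops <- c(ops, if (is_text_filler(f)) "delete" else "drop_nested")
      if (n + 1L <= sd$max) ops <- c(ops, "duplicate")
      if (is_text_filler(f)) ops <- c(ops, "perturb")
      for (op in ops) {
        sites[[length(sites) + 1L]] <- list(addr = addr, slot = sn, idx = k, op = op)
      }
      if (!is_text_filler(f)) {
        sites <- c(sites, enumerate_sites(f$instance, schema,
                                          c(addr, list(c(sn, k)))))
      }
    }
  }
  sites
}

apply_site_op <- function(inst, site) {
  if (length(site$addr) == 0L) {
    fl <- inst$fillers[[site$slot]]
    f <- fl[[site$idx]]
    fl <- switch(site$op,
      delete = ,
      drop_nested = fl[-site$idx],
      duplicate = append(fl, list(f), after = site$idx),
      perturb = { fl[[site$idx]] <- perturb_text(f); fl })
    inst$fillers[[site$slot]] <- fl
    if (length(fl) == 0L) inst$fillers[[site$slot]] <- NULL
    return(inst)
  }
  hop <- site$addr[[1]]
  child <- inst$fillers[[hop[1]]][[as.integer(hop[2])]]$instance
  site$addr <- site$addr[-1]
  inst$fillers[[hop[1]]][[as.integer(hop[2])]] <-
    instance_filler(apply_site_op(child, site))
  inst
}

perturb_text <- function(f) {
  s <- f$text
  i <- sample.int(nchar(s), 1L)
  ch <- substr(s, i, i)
  repl <- if (ch == "x") "y" else "x"
  text_filler(paste0(substr(s, 1, i - 1L), repl, substr(s, i + 1L, nchar(s))))
}

#' Randomly corrupt an instance
#'
#' Applies `n_ops` random edits, each one of: delete a filler, duplicate a
#' filler, perturb one character of a textual filler, or drop a nested
#' instance. Deletions and duplications respect the slot multiplicity bounds,
#' so the result still conforms to the schema. Deterministic per seed.
#'
#' @param inst A conforming `template_instance`.
#' @param schema A `template_schema`.
#' @param n_ops Number of edits (>= 0).
#' @param seed Seed.
#' @return A corrupted, conforming `template_instance`.
#' @export
corrupt_instance <- function(inst, schema, n_ops, seed = 1L) {
  if (!is_count(n_ops)) stopf("n_ops must be a non-negative integer")
  with_rng(seed, {
    out <- canonicalize(inst)
    for (k in seq_len(n_ops)) {
      sites <- enumerate_sites(out, schema)
      if (length(sites) == 0L) break
      site <- sites[[sample.int(length(sites), 1L)]]
      out <- apply_site_op(out, site)
    }
    canonicalize(out)
  })
}

#' Generate a fixture corpus on disk
#'
#' Writes a deterministic corpus to `dir`: the schema (`schema.json`), a
#' vocabulary covering it (`vocab.json`), gold instances
#' (`gold/<id>.json`), source documents (`documents/<id>.txt`) and the gold
#' linearizations (`linearizations/<id>.txt`).
#'
#' @param dir Output directory (created if missing).
#' @param cfg A `fixture_config`.
#' @param n_docs Number of documents.
#' @param schema Optional schema; defaults to a generated one.
#' @return The directory path, invisibly.
#' @export
write_fixtures <- function(dir, cfg = fixture_config(), n_docs = 5L, schema = NULL) {
  if (is.null(schema)) schema <- gen_schema(cfg)
  vocab <- make_vocabulary(schema, cfg$text_vocab)
  for (sub in c("", "gold", "documents", "linearizations")) {
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  write_schema(schema, file.path(dir, "schema.json"))
  write_vocabulary(vocab, file.path(dir, "vocab.json"))
  for (k in seq_len(n_docs)) {
    id <- sprintf("doc%03d", k)
    doc <- gen_document(schema, cfg, seed = cfg$seed + k)
    write_instances(doc$gold, file.path(dir, "gold", paste0(id, ".json")))
    writeLines(doc$text, file.path(dir, "documents", paste0(id, ".txt")))
    writeLines(linearize(doc$gold, schema),
               file.path(dir, "linearizations", paste0(id, ".txt")))
  }
  invisible(dir)
}
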