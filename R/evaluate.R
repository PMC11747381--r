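#' Normalized Levenshtein similarity
#'
#' `1 - levenshteinDistance(s1, s2) / max(|s1|, |s2|)`, on characters.
#' Symmetric, in \[0, 1\], and 1 exactly for equal strings. Two empty strings
#' are defined as similarity 1 (with a warning), since the formula's
#' denominator vanishes.
#'
#' @param s1,s2 Character scalars.
#' @return Numeric scalar in \[0, 1\].
#' @export
#' @examples
#' norm_levenshtein_sim("kitten", "sitting")  # 1 - 3/7
norm_levenshtein_sim <- function(s1, s2) {
  if (!is_string(s1) || !is_string(s2)) stopf("s1 and s2 must be character scalars")
  n <- max(nchar(s1), nchar(s2))
  if (n == 0L) {
    warning("both strings empty; defining similarity as 1")
    return(1)
  }
  d <- as.integer(utils::adist(s1, s2))
  1 - d / n
}

#' Slot-filler equivalence
#'
#' Textual fillers are equal when their normalized Levenshtein similarity is
#' at least `threshold` (default 0.9). Template-valued fillers are compared
#' non-recursively: only completely identical nested instances (equal
#' canonical serializations) count as equal. A textual and a template filler
#' are never equal.
#'
#' @param a,b `slot_filler`s.
#' @param threshold Similarity threshold for textual fillers.
#' @return Logical scalar.
#' @export
filler_equal <- function(a, b, threshold = 0.9) {
  a <- as_slot_filler(a); b <- as_slot_filler(b)
  ta <- is_text_filler(a); tb <- is_text_filler(b)
  if (ta != tb) return(FALSE)
  if (ta) return(norm_levenshtein_sim(a$text, b$text) >= threshold)
  identical(linearize_unchecked(canonicalize(a$instance)),
            linearize_unchecked(canonicalize(b$instance)))
}

#' True/false positive and false negative counts
#'
#' @param tp,fp,fn Non-negative integers.
#' @return An `eval_counts` object.
#' @export
eval_counts <- function(tp = 0L, fp = 0L, fn = 0L) {
  structure(list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn)),
            class = "eval_counts")
}

#' @export
print.eval_counts <- function(x, ...) {
  cat(sprintf("<eval_counts> tp=%d fp=%d fn=%d F1=%.4f\n", x$tp, x$fp, x$fn, f1_score(x)))
  invisible(x)
}

add_counts <- function(a, b) eval_counts(a$tp + b$tp, a$fp + b$fp, a$fn + b$fn)

#' Micro F1 from counts
#'
#' `2*tp / (2*tp + fp + fn)`, defined as 0 when the denominator is 0.
#'
#' @param counts An `eval_counts` (or list with tp/fp/fn).
#' @return Numeric scalar in \[0, 1\].
#' @export
f1_score <- function(counts) {
  denom <- 2 * counts$tp + counts$fp + counts$fn
  if (denom == 0) 0 else 2 * counts$tp / denom
}

# Maximum-cardinality matching of a boolean compatibility matrix
# (rows = predicted, cols = gold). Returns integer vector over rows: matched
# column index or NA.
max_boolean_matching <- function(compat) {
  np <- nrow(compat); ng <- ncol(compat)
  res <- rep(NA_integer_, np)
  if (np == 0L || ng == 0L || !any(compat)) return(res)
  idx <- which(compat, arr.ind = TRUE)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, np), rep(TRUE, ng)),
    edges = as.vector(t(cbind(idx[, 1], np + idx[, 2])))
  )
  m <- igraph::max_bipartite_match(g)$matching
  for (i in seq_len(np)) if (!is.na(m[i])) res[i] <- m[i] - np
  res
}

# Maximum-weight assignment for a non-negative integer weight matrix; zero
# weights are treated as no edge (matching on them adds nothing). Returns the
# matched column per row (NA if unmatched).
max_weight_assignment <- function(W) {
  np <- nrow(W); ng <- ncol(W)
  res <- rep(NA_integer_, np)
  if (np == 0L || ng == 0L || all(W <= 0)) return(res)
  idx <- which(W > 0, arr.ind = TRUE)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, np), rep(TRUE, ng)),
    edges = as.vector(t(cbind(idx[, 1], np + idx[, 2])))
  )
  m <- igraph::max_bipartite_match(g, weights = W[idx])$matching
  for (i in seq_len(np)) if (!is.na(m[i])) res[i] <- m[i] - np
  res
}

# Per-slot counts of one predicted/gold instance pair (same template type):
# per slot name a maximum one-to-one matching of fillers under filler_equal.
pair_counts_by_slot <- function(pred, gold, threshold = 0.9) {
  slots <- sort_c(union(names(pred$fillers), names(gold$fillers)))
  out <- list()
  for (sn in slots) {
    pf <- pred$fillers[[sn]]; if (is.null(pf)) pf <- list()
    gf <- gold$fillers[[sn]]; if (is.null(gf)) gf <- list()
    compat <- matrix(FALSE, nrow = length(pf), ncol = length(gf))
    for (i in seq_along(pf)) for (j in seq_along(gf)) {
      compat[i, j] <- filler_equal(pf[[i]], gf[[j]], threshold)
    }
    tp <- sum(!is.na(max_boolean_matching(compat)))
    out[[sn]] <- eval_counts(tp, length(pf) - tp, length(gf) - tp)
  }
  out
}

#' Score one predicted instance against one gold instance
#'
#' For each slot name, predicted fillers are matched one-to-one to gold
#' fillers under [filler_equal()] so that the number of matches is maximal.
#' Matched fillers are true positives, unmatched predicted fillers false
#' positives, unmatched gold fillers false negatives; hence
#' `tp + fp` = number of predicted fillers and `tp + fn` = number of gold
#' fillers. Only immediate fillers are counted; nested instances contribute as
#' single (identity-compared) fillers.
#'
#' @param pred,gold `template_instance`s of the same template type.
#' @param threshold Textual similarity threshold.
#' @return An `eval_counts`.
#' @export
pair_counts <- function(pred, gold, threshold = 0.9) {
  if (pred$template != gold$template) {
    stopf("template type mismatch: '%s' vs '%s'", pred$template, gold$template)
  }
  Reduce(add_counts, pair_counts_by_slot(pred, gold, threshold), eval_counts())
}

# counts contributed by an instance with no counterpart
unmatched_counts_by_slot <- function(inst, side = c("pred", "gold")) {
  side <- match.arg(side)
  out <- list()
  for (sn in names(inst$fillers)) {
    n <- length(inst$fillers[[sn]])
    out[[sn]] <- if (side == "pred") eval_counts(0L, n, 0L) else eval_counts(0L, 0L, n)
  }
  out
}

#' Optimal alignment of predicted and gold instances
#'
#' Finds, separately for every template type, the one-to-one matching of
#' predicted to gold instances that maximizes the global micro F1. Because
#' `tp + fp` and `tp + fn` always sum to the fixed totals of predicted and
#' gold fillers, `2*tp + fp + fn` is constant over matchings, and maximizing
#' F1 is equivalent to maximizing the total number of true positives — solved
#' here as a maximum-weight bipartite assignment with pairwise true-positive
#' counts as weights. Unmatched predicted instances contribute all their
#' immediate fillers as false positives, unmatched gold instances as false
#' negatives.
#'
#' @param preds,golds Lists of `template_instance`s (any mix of types; pairs
#'   are only ever formed within a type).
#' @param threshold Textual similarity threshold.
#' @return A list with elements `matching` (data frame: template, pred, gold —
#'   1-based indices into `preds`/`golds`), `counts` (overall `eval_counts`),
#'   `per_slot` and `per_template` (named lists of `eval_counts`), and `f1`.
#' @export
align_and_score <- function(preds, golds, threshold = 0.9) {
  ptypes <- vapply(preds, `[[`, "", "template")
  gtypes <- vapply(golds, `[[`, "", "template")
  per_slot <- list()
  per_template <- list()
  matching <- list()
  bump <- function(store, key, counts) {
    prev <- store[[key]]
    store[[key]] <- if (is.null(prev)) counts else add_counts(prev, counts)
    store
  }
  for (tt in sort_c(union(ptypes, gtypes))) {
    pi <- which(ptypes == tt)
    gi <- which(gtypes == tt)
    W <- matrix(0L, nrow = length(pi), ncol = length(gi))
    for (a in seq_along(pi)) for (b in seq_along(gi)) {
      W[a, b] <- pair_counts(preds[[pi[a]]], golds[[gi[b]]], threshold)$tp
    }
    assign_col <- max_weight_assignment(W)
    used_g <- stats::na.omit(assign_col)
    for (a in seq_along(pi)) {
      if (!is.na(assign_col[a])) {
        b <- assign_col[a]
        matching[[length(matching) + 1L]] <-
          data.frame(template = tt, pred = pi[a], gold = gi[b])
        by_slot <- pair_counts_by_slot(preds[[pi[a]]], golds[[gi[b]]], threshold)
      } else {
        by_slot <- unmatched_counts_by_slot(preds[[pi[a]]], "pred")
      }
      for (sn in names(by_slot)) {
        per_slot <- bump(per_slot, sn, by_slot[[sn]])
        per_template <- bump(per_template, tt, by_slot[[sn]])
      }
    }
    for (b in seq_along(gi)) {
      if (b %in% used_g) next
      by_slot <- unmatched_counts_by_slot(golds[[gi[b]]], "gold")
      for (sn in names(by_slot)) {
        per_slot <- bump(per_slot, sn, by_slot[[sn]])
        per_template <- bump(per_template, tt, by_slot[[sn]])
      }
    }
  }
  overall <- Reduce(add_counts, per_slot, eval_counts())
  matching <- if (length(matching)) do.call(rbind, matching) else
    data.frame(template = character(), pred = integer(), gold = integer())
  list(matching = matching, counts = overall,
       per_slot = per_slot, per_template = per_template,
       f1 = f1_score(overall))
}

#' Evaluate a corpus of predicted against gold documents
#'
#' Documents are paired by identifier (list names). Within each document,
#' predicted and gold instances of every template type are pooled across the
#' whole nesting (each nested instance participates in the alignment of its
#' own type) and aligned optimally per type; counts are summed corpus-wide.
#'
#' @param pred_docs,gold_docs Named lists: document id -> list of root
#'   `template_instance`s (a single instance is also accepted).
#' @param schema A `template_schema`; the report enumerates every template and
#'   slot of the schema, including those without any counts.
#' @param threshold Textual similarity threshold.
#' @return An `evaluation_report`: `overall` counts, `per_template` and
#'   `per_slot` maps of `eval_counts` with F1, and `total_micro_f1`.
#' @export
evaluate_corpus <- function(pred_docs, gold_docs, schema, threshold = 0.9) {
  if (is.null(names(pred_docs)) || is.null(names(gold_docs))) {
    stopf("documents must be named lists keyed by document id")
  }
  unpaired <- c(setdiff(names(pred_docs), names(gold_docs)),
                setdiff(names(gold_docs), names(pred_docs)))
  if (length(unpaired)) {
    stopf("unpaired document id(s): %s", paste(unique(unpaired), collapse = ", "))
  }
  as_root_list <- function(x) {
    if (inherits(x, "template_instance")) list(x) else x
  }
  per_slot <- stats::setNames(
    rep(list(eval_counts()), length(schema_slot_names(schema))),
    schema_slot_names(schema))
  per_template <- stats::setNames(
    rep(list(eval_counts()), length(schema$templates)),
    sort_c(names(schema$templates)))
  for (id in names(gold_docs)) {
    preds <- unlist(lapply(as_root_list(pred_docs[[id]]), collect_instances),
                    recursive = FALSE)
    golds <- unlist(lapply(as_root_list(gold_docs[[id]]), collect_instances),
                    recursive = FALSE)
    res <- align_and_score(preds, golds, threshold)
    for (sn in names(res$per_slot)) {
      if (is.null(per_slot[[sn]])) per_slot[[sn]] <- eval_counts()
      per_slot[[sn]] <- add_counts(per_slot[[sn]], res$per_slot[[sn]])
    }
    for (tn in names(res$per_template)) {
      if (is.null(per_template[[tn]])) per_template[[tn]] <- eval_counts()
      per_template[[tn]] <- add_counts(per_template[[tn]], res$per_template[[tn]])
    }
  }
  overall <- Reduce(add_counts, per_slot, eval_counts())
  slot_kinds <- vapply(names(per_slot), function(sn) {
    for (tn in names(schema$templates)) {
      sd <- find_slot(schema, tn, sn)
      if (!is.null(sd)) return(sd$kind)
    }
    "textual"
  }, "")
  structure(list(overall = overall,
                 per_template = per_template,
                 per_slot = per_slot,
                 slot_kinds = slot_kinds,
                 total_micro_f1 = f1_score(overall)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> total micro F1 = %.4f (tp=%d fp=%d fn=%d)\n",
              x$total_micro_f1, x$overall$tp, x$overall$fp, x$overall$fn))
  invisible(x)
}

counts_df <- function(counts_list) {
  data.frame(
    name = names(counts_list),
    tp = vapply(counts_list, `[[`, 0L, "tp"),
    fp = vapply(counts_list, `[[`, 0L, "fp"),
    fn = vapply(counts_list, `[[`, 0L, "fn"),
    f1 = vapply(counts_list, f1_score, 0),
    row.names = NULL
  )
}

#' Tabulate an evaluation report
#'
#' `report_template_table` has one row per template type.
#' `report_slot_table` has one row per slot plus a closing
#' `"Total Micro F1 Score"` row; by default it lists textual slots only,
#' mirroring how per-slot extraction quality is conventionally reported
#' (template-valued slots measure structure, which the per-template table
#' covers).
#'
#' @param report An `evaluation_report`.
#' @return A data frame with columns name, tp, fp, fn, f1.
#' @export
report_template_table <- function(report) {
  counts_df(report$per_template)
}

#' @rdname report_template_table
#' @param textual_only Restrict rows to textual slots.
#' @export
report_slot_table <- function(report, textual_only = TRUE) {
  cl <- report$per_slot
  if (textual_only) cl <- cl[names(cl)[report$slot_kinds[names(cl)] == "textual"]]
  df <- counts_df(cl)
  rbind(df, data.frame(name = "Total Micro F1 Score",
                       tp = report$overall$tp, fp = report$overall$fp,
                       fn = report$overall$fn, f1 = report$total_micro_f1))
}

#' Write an evaluation report to JSON and TSV
#'
#' The JSON file carries the complete report (all slots, all templates,
#' overall counts). The TSV files mirror the tabular layout: one file per
#' template table, one per slot table.
#'
#' @param report An `evaluation_report`.
#' @param prefix Output path prefix; writes `<prefix>.json`,
#'   `<prefix>_templates.tsv` and `<prefix>_slots.tsv`.
#' @return Character vector of the written paths, invisibly.
#' @export
write_report <- function(report, prefix) {
  json_path <- paste0(prefix, ".json")
  doc <- list(
    total_micro_f1 = report$total_micro_f1,
    overall = report$overall[c("tp", "fp", "fn")],
    per_template = lapply(report$per_template, function(cnt)
      c(cnt[c("tp", "fp", "fn")], list(f1 = f1_score(cnt)))),
    per_slot = lapply(report$per_slot, function(cnt)
      c(cnt[c("tp", "fp", "fn")], list(f1 = f1_score(cnt))))
  )
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  tpl_path <- paste0(prefix, "_templates.tsv")
  slot_path <- paste0(prefix, "_slots.tsv")
  utils::write.table(report_template_table(report), tpl_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report_slot_table(report), slot_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(json_path, tpl_path, slot_path))
}
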