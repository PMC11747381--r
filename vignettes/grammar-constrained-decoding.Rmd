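---
title: "Grammar-constrained decoding for nested template extraction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grammar-constrained decoding for nested template extraction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the model the package implements, the assumptions it
makes, the parameters that matter, and the design decisions taken where the
design was genuinely open. It states no empirical result that the test suite
and `scripts/acceptance.R` do not themselves compute.

## The extraction model

The package treats structured information extraction from clinical-trial
abstracts as slot filling over *nested templates*. A `template_schema`
declares record types (templates) and their named fields (slots); a slot is
either **textual** — filled with spans of source text — or **template-valued**
— filled with nested instances of other templates, as when a trial holds
arms and an arm holds outcomes. A `template_instance` is a filled structure
conforming to the schema: slot names exist, filler kinds match, filler
counts lie within each slot's `[min, max]` bounds, and textual fillers are
non-empty.

Sequence models cannot emit trees directly, so instances are **linearized**:
every filler is wrapped in `[start:name]` / `[end:name]` tags and the pieces
are concatenated. Two conventions make the mapping a bijection up to
canonical form:

* **Canonical slot order.** Slots serialize in case-sensitive lexicographic
  (byte) order on slot names, at every nesting level. Any arbitrary-but-fixed
  order would do; byte order is locale-independent and reproducible, and
  `canonicalize()` is the corresponding idempotent normal form.
* **Grouped repetition.** Multiple fillers of one slot appear as consecutive
  complete tag pairs, with no separator. Interleaving repeated slots of
  different names is not part of the language; grouping keeps the grammar
  deterministic and matches how repeated sibling fields appear in practice.

Textual fillers are stored as raw strings. Tokenization enters only at the
grammar/decoding boundary, which keeps evaluation independent of any
particular tokenizer.

## The grammar and the incremental parser

`build_decoding_grammar()` compiles a schema into the context-free grammar
of its linearization language. Terminal classes are the start and end tag of
every name (atomic special tokens, mirroring how such tags are added to a
model vocabulary), a free-text terminal, and EOS. During decoding the
free-text terminal is deliberately permissive: it covers every vocabulary
token that is not a special tag and not EOS. All the decoding phase must
prevent is the emission of structural tags inside text; constraining the
text itself is not its job.

The incremental parser is a deterministic pushdown automaton over these
terminals. Its state is a stack of frames (template being derived, current
slot index and filler count; textual slot with token count; template-valued
slot awaiting or having received its instance). From any state the
accepted-next-terminal set is computed directly:

* inside a textual slot: all free-text tokens, plus the slot's end tag once
  at least one token has been consumed (an empty textual filler is invalid —
  allowing it would make the empty string a legal filler and the grammar
  ambiguous under one-token lookahead);
* inside a template frame: another filler of the current slot while below
  its `max`; the start tag of any later slot reachable by skipping only
  slots whose `min` is satisfied; the template's end tag when all remaining
  minima are zero;
* EOS exactly when the root template has been closed.

Because tags carry their names, every accepted terminal leads to a unique
transition, so the grammar derived from *any* valid schema is deterministic
with one token of lookahead and no backtracking is ever needed. A
construction requiring backtracking would have to be rejected at build time;
under this encoding the situation cannot arise, so `build_decoding_grammar()`
only has schema/vocabulary consistency left to check. `vocabulary_mask()`
maps the accepted set to an additive mask over token ids — `0` for accepted,
`-Inf` otherwise — and `advance_parser()` treats a non-accepted token as a
hard error rather than a recoverable one: a decoder that masks first can
never trigger it, so triggering it indicates a decoder bug.

Parsing stored linearizations (phase two) is stricter than decoding: tags
must be balanced, known, and in canonical grouped order; multiplicities are
enforced; free text must segment under **greedy longest-match** against the
vocabulary, committed choice with no backtracking — if no token prefixes the
remaining text, segmentation fails even where a shorter earlier match would
have succeeded. The text is nevertheless stored as its raw surface string.
All violations raise a condition carrying the character position.

## Decoding loops and pointer-generator arithmetic

`greedy_decode()` is the unconstrained baseline: argmax of the softmax of
the scorer's logits at every step, stopping at EOS or `max_len`. Validity is
determined afterwards by attempting a strict parse; an unparseable output is
a flagged result, not an error. `gcd_decode()` adds the mask before the
argmax and advances the parser with every emitted token, so each completed
run parses by construction. Shared numerical choices:

* **Tie-breaking**: the lowest token id wins the argmax (R's `which.max`),
  for bit-reproducibility.
* **Masking** is additive in probability space exactly as stated above;
  `-Inf + finite` is robustly `-Inf` in IEEE arithmetic, and the chosen
  entry is checked to be finite.
* **Softmax** is computed with max-shifting; NaN or infinite logits are
  rejected.
* `max_len` defaults to 4096 steps. Truncation yields `valid = FALSE`
  rather than force-closing open tags: force-closing would fabricate
  structure the scorer never emitted.

Pointer-generator behavior mixes a copy distribution into the generative
one. `mean_head_attention()` averages a row-normalized heads-by-positions
cross-attention matrix (the package requires normalized input and asserts,
rather than silently renormalizing after the head average);
`pointer_distribution()` projects the result onto the vocabulary,
aggregating repeated input tokens with `max` or `sum`. The `sum` variant
conserves probability mass; the `max` variant may lose mass when tokens
repeat and is deliberately **not** renormalized — only an argmax consumes
it, so normalization is immaterial, and renormalizing would silently change
the mixture weights. `mix_distributions()` forms
`p_gen * dist_gen + (1 - p_gen) * dist_ptr`. The copy gate `p_gen` is part
of the scorer contract (in a real model it is a linear layer with sigmoid
activation inside the network); scorers lacking attention or gate outputs
cause pointer modes to raise, while `pointer = "none"` ignores them.

One behavior worth knowing: with pointer mixing and a small gate value, the
copy mass on source words can beat a closing tag's generative probability
for many consecutive steps, so a constrained pointer decode may keep
emitting legal free text until `max_len` and come back flagged as truncated.
That is the honest outcome — the guarantee is *every completed output
parses*, not *every run completes* — and it is consistent with pointer
variants degrading extraction quality in practice.

## Evaluation: alignment-optimal micro F1

Two textual fillers are equal when the normalized Levenshtein similarity of
their raw strings, `1 - d(s1, s2) / max(|s1|, |s2|)`, is at least 0.9. The
denominator counts characters, not tokens — the formula is defined on
strings, and character counting keeps it tokenizer-independent. Two empty
strings get similarity 1 with a warning (the formula is 0/0 there). Nested
template fillers are compared **non-recursively**: only completely identical
instances (equal canonical serializations) count as equal.

`pair_counts()` scores one predicted against one gold instance of the same
type: per slot, a maximum one-to-one matching of fillers under the
equivalence above (maximum matching matters because the 0.9 rule is not
transitive); matched fillers are true positives, unmatched predicted fillers
false positives, unmatched gold fillers false negatives. Consequently
`tp + fp` and `tp + fn` equal the fixed totals of predicted and gold
fillers, so over any instance matching the F1 denominator `2tp + fp + fn`
is constant — maximizing F1 is exactly maximizing total true positives.
`align_and_score()` exploits that reduction and solves a maximum-weight
bipartite assignment per template type with pairwise `tp` as weights
(via igraph); the test suite keeps the literal formulation — exhaustive
enumeration over all same-type matchings — as the independent oracle and
verifies the denominator constancy it relies on.

Open points resolved as follows:

* **Pooling.** Within a document, instances of every type are pooled across
  the whole nesting and aligned per type ("flat" pooling). A hierarchical
  variant — aligning nested instances only within matched parents — is a
  conceivable alternative; flat pooling is implemented because it never
  punishes a correct nested instance for an incorrectly attached parent.
* **Unmatched instances** contribute all their immediate fillers as false
  positives (predicted) or false negatives (gold); this is the only choice
  that preserves the `tp + fp` / `tp + fn` totals the reduction needs.
* **Report presentation.** The report object carries counts for every slot,
  and the overall counts equal the per-slot sums. The rendered per-slot
  table lists textual slots (plus the `Total Micro F1 Score` row): per-slot
  rows measure text extraction quality, while template-valued slots measure
  structure, which the per-template table covers.

## The synthetic-data generators

The fixtures module makes every mechanism testable without a trained model.
`gen_schema()` draws connected, acyclic template hierarchies;
`gen_instance()` draws conforming instances; `gen_document()` embeds every
textual filler verbatim among distractor word runs, emulating an abstract
that contains its slot strings; `corrupt_instance()` applies
conformance-preserving edits (delete, duplicate, perturb one character,
drop a nested instance) to drive evaluation tests. All generators are pure
functions of `(config, seed)`.

The mock scorers implement the decoder contract: `oracle_scorer()` peaks at
the reference token with probability `1 - eps` and at a uniformly random
token otherwise (past the reference it peaks at EOS), and also emits a
random row-normalized attention matrix and a random gate so pointer modes
are exercisable; `random_scorer()` is standard-normal logits;
`adversarial_scorer()` piles mass on EOS and a random tag token — choices
that are almost never legal. The symbol-level noise mixture is deliberately
simple: it suffices to demonstrate the central contrast (constrained
decoding's validity guarantee versus unconstrained decoding's fragility),
which is a structural property of the decoding loop, not of the error
pattern. What the generators do **not** emulate: real abstract language,
realistic attention statistics, learned error correlations, or the
morphological variety of real slot strings. Passing tests therefore
establish the correctness of the machinery — masking, parsing, alignment,
arithmetic — not extraction quality on real text, which depends entirely on
the scorer plugged in.

Default fixture conditions (`fixture_config()`): 4 templates, 3 slots per
template, nesting depth 2, at most 2 fillers sampled per slot, a 20-word
clinical-flavored free-text vocabulary, oracle noise 0.1. These describe a
small but structurally complete problem: every slot kind, repeated fillers
(so `max` and `sum` aggregation differ), and multi-level nesting.

A bundled miniature clinical-trial schema (`ctro_mini_schema()`, also
shipped as `inst/extdata/ctro_mini.json`) carries the domain's standard
template and slot vocabulary — nine templates and 42 textual slots with the
conventional reporting names — wired into an approximate topology (trial →
arms → interventions/outcomes → medications/endpoints). It exists for
realistic demonstrations and report-structure tests; it does not reproduce
the full ontology's semantics, only its template/slot shape. Multiplicities
are left open (min 0, unbounded max) since the source material does not pin
them down; the schema dialect makes them configurable.

## Parameters that matter

| Parameter | Where | Default | Notes |
|---|---|---|---|
| `threshold` | `filler_equal`, evaluation | 0.9 | similarity cut for textual equality |
| `max_len` | decoding loops | 4096 steps | truncation flags, never force-closes |
| `eps` | oracle scorer | — | 0 reproduces the reference; 0.3 is used as the noisy condition in the validity contrast |
| `pointer` | `gcd_decode` | `"none"` | `max`/`sum` require scorer attention and gate |
| `min`/`max` | slot definitions | 0 / unbounded | multiplicity bounds enforced by grammar and validator |
| `seed` | all generators/scorers | — | every stochastic component is a pure function of it |

## Problem sizes used by the checks

The test suite and the acceptance script size their simulations as follows:
the validity contrast runs 1,000 constrained decodes (random and adversarial
scorers, 20 random schemas) against 100 noisy greedy decodes; greedy
equivalence uses 100 noise-free references; alignment optimality compares
100–200 random cases (at most 5 instances per type, so exhaustive
enumeration of matchings stays exact) against the assignment solver; the
similarity measure is checked on 1,000 random string pairs against a
dynamic-programming oracle; pointer arithmetic on 1,000 random draws;
round-tripping on 1,000 instances over 20 schemas; and the report-structure
check evaluates a six-document corpus on the miniature schema against
itself. These sizes give the properties thousands of chances to fail while
keeping a full run in the low minutes on one CPU.

## Known limitations

* Beam search, sampling-based decoding, batching, and training (including
  the copy gate) are out of scope; the decoders are greedy.
* The grammar engine is specialized to the template linearization language;
  it is not a general CFG toolkit.
* Greedy longest-match segmentation is committed-choice and can fail on
  text a smarter segmentation could handle; vocabularies built with
  `make_vocabulary(..., include_chars = TRUE)` sidestep this by
  guaranteeing single-character fallback tokens.
* Pointer-mode decodes can run to `max_len` when the copy mass dominates
  closing tags (see above); callers should treat `valid = FALSE` with
  `steps == max_len` as truncation, not as a parser failure.
* The evaluator implements flat pooling; hierarchical alignment is noted as
  a possible variant but not implemented.
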